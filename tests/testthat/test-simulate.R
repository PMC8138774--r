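test_that("identical configurations reproduce identical studies", {
  cfg <- simulation_config(n_genes = 200, n_datasets = 3, n_case = 4,
                           n_control = 4, seed = 9)
  s1 <- simulate_consensome_studies(cfg, keep_matrices = TRUE)
  s2 <- simulate_consensome_studies(cfg, keep_matrices = TRUE)
  expect_identical(s1, s2)

  c1 <- simulate_chimeric_experiment(cfg, n_orthologues = 150)
  c2 <- simulate_chimeric_experiment(cfg, n_orthologues = 150)
  expect_identical(c1, c2)

  h1 <- simulate_hct_library(10, 20, query_set = c("g1", "g2"),
                             planted_overlap = 2,
                             universe = paste0("g", 1:200), seed = 4)
  h2 <- simulate_hct_library(10, 20, query_set = c("g1", "g2"),
                             planted_overlap = 2,
                             universe = paste0("g", 1:200), seed = 4)
  expect_identical(h1, h2)
})

test_that("degenerate planting fractions behave as stated", {
  cfg0 <- simulation_config(n_genes = 150, n_datasets = 2, n_case = 3,
                            n_control = 3, frac_true = 0, seed = 2)
  s0 <- simulate_consensome_studies(cfg0, min_datasets = 2)
  expect_length(s0$truth$true_genes, 0)
  expect_true(all(lengths(s0$truth$per_dataset_perturbed) == 0))

  cfg1 <- simulation_config(n_genes = 150, n_datasets = 3, n_case = 3,
                            n_control = 3, frac_true = 0.05,
                            replication_prob = 1, seed = 2)
  s1 <- simulate_consensome_studies(cfg1)
  for (hit in s1$truth$per_dataset_perturbed) {
    expect_setequal(hit, s1$truth$true_genes)
  }
})

test_that("invalid configurations are rejected with messages", {
  expect_error(simulation_config(frac_true = 1.2), "frac_true")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(effect_log2fc = NaN), "effect_log2fc")
  cfg <- simulation_config(n_genes = 100)
  expect_error(simulate_chimeric_experiment(cfg, n_orthologues = 200),
               "n_orthologues")
  expect_error(simulate_chimeric_experiment(cfg, hm_ratio = -1), "hm_ratio")
  expect_error(
    simulate_hct_library(5, 50, "g1", 1, universe = paste0("g", 1:10)),
    "universe"
  )
  expect_error(
    simulate_hct_library(5, 5, c("g1", "g2"), 3,
                         universe = paste0("g", 1:100)),
    "planted_overlap"
  )
})

test_that("per-dataset null discovery rates are calibrated", {
  cfg <- simulation_config(frac_true = 0, n_datasets = 3, seed = 12)
  sim <- simulate_consensome_studies(cfg)
  rates <- null_rates(sim$collection, alpha = 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / cfg$n_genes)
  expect_true(all(abs(rates - 0.05) < se3))
})

test_that("planted ground-truth sets are subsets of the emitted genes", {
  cfg <- simulation_config(n_genes = 300, n_datasets = 3, n_case = 3,
                           n_control = 3, seed = 14)
  sim <- simulate_consensome_studies(cfg)
  genes <- sim$collection$datasets[[1]]$id
  expect_true(all(sim$truth$true_genes %in% genes))
  expect_true(all(unlist(sim$truth$per_dataset_perturbed) %in% genes))

  chim <- simulate_chimeric_experiment(cfg, n_orthologues = 250)
  expect_true(all(chim$truth$planted_shared_up %in% rownames(chim$human)))
  expect_true(all(chim$truth$planted_hm_high %in% rownames(chim$human)))
  expect_true(all(chim$truth$planted_mouse_only %in% rownames(chim$mouse)))
  expect_true(all(chim$truth$planted_hm_high %in% chim$map$human_gene))
})

test_that("null chimeric simulation yields only type-I shared overlap", {
  cfg <- simulation_config(n_case = 8, n_control = 8, nb_mean_log_mu = 5,
                           nb_dispersion = 0.01, seed = 22)
  chim <- simulate_chimeric_experiment(cfg, n_shared_up = 0,
                                       n_shared_down = 0, n_human_only = 0,
                                       n_mouse_only = 0, n_hm_high = 0)
  expect_length(chim$truth$planted_shared_up, 0)
  hde <- de_table(chim$human, chim$human_groups, case = "WD", control = "NC")
  mde <- de_table(chim$mouse, chim$mouse_groups, case = "WD", control = "NC")
  pairs <- map_orthologues(hde, mde, chim$map, chim$human, chim$mouse,
                           chim$human_groups, chim$mouse_groups)
  ov <- overlap_counts(pairs, alpha = 0.05)
  n_shared <- ov$counts[["shared_up"]] + ov$counts[["shared_down"]]
  # expected shared-by-chance = n * alpha^2 = 5; allow wide Poisson slack
  expect_lt(n_shared, 25)
})

test_that("a fully planted HCT node attains the smallest library p", {
  universe <- sprintf("u%05d", 1:3000)
  query <- universe[1:6]
  sim <- simulate_hct_library(20, 100, query_set = query,
                              planted_overlap = 6, universe = universe,
                              seed = 8)
  res <- hct_intersection(query, sim$library)
  expect_identical(res$set_id[1], sim$truth$planted_node)
  expect_true(res$p[1] < min(res$p[-1]))
  expect_equal(res$k[1], 6)
})
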