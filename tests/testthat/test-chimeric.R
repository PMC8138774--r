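test_that("orthology map enforces strict 1:1 pairing", {
  expect_message(
    m <- orthology_map(c("m1", "m1", "m2", "m3"),
                       c("h1", "h2", "h3", "h3")),
    "non-1:1"
  )
  expect_equal(nrow(m), 0L) # every candidate pair touches a duplicate
  m2 <- orthology_map(c("m1", "m2"), c("h1", "h2"))
  expect_equal(nrow(m2), 2L)
})

test_that("map_orthologues joins tables and computes case-state ratios", {
  # counts chosen so CPM is easy: equal library sizes per species
  hx <- rbind(HG1 = c(30, 30, 10, 10), HG2 = c(10, 10, 20, 20),
              HG3 = c(60, 60, 70, 70))
  colnames(hx) <- c("wd1", "wd2", "nc1", "nc2")
  mx <- rbind(MG1 = c(10, 10, 10, 10), MG2 = c(10, 10, 20, 20),
              MG3 = c(80, 80, 70, 70))
  colnames(mx) <- colnames(hx)
  grp <- setNames(c("WD", "WD", "NC", "NC"), colnames(hx))
  hde <- de_table(hx, grp, case = "WD", control = "NC")
  mde <- de_table(mx, grp, case = "WD", control = "NC")

  map0 <- orthology_map(character(0), character(0))
  empty <- map_orthologues(hde, mde, map0, hx, mx, grp, grp)
  expect_equal(nrow(empty), 0L)

  map <- orthology_map(c("MG1", "MG2", "MG3"), c("HG1", "HG2", "HG3"))
  pairs <- map_orthologues(hde, mde, map, hx, mx, grp, grp)
  expect_equal(nrow(pairs), 3L)
  # same library size both species -> ratio is (case-mean ratio) with pc 0.5
  h_cpm <- 30 / 100 * 1e6
  m_cpm <- 10 / 100 * 1e6
  expect_equal(pairs$hm_ratio[pairs$human_gene == "HG1"],
               (h_cpm + 0.5) / (m_cpm + 0.5))

  # a pair absent from one table is dropped and counted
  map_extra <- orthology_map(c("MG1", "MGX"), c("HG1", "HGX"))
  expect_message(
    dropped <- map_orthologues(hde, mde, map_extra, hx, mx, grp, grp),
    "missing"
  )
  expect_equal(nrow(dropped), 1L)
})

test_that("swapping the species inverts the ratio exactly", {
  cfg <- simulation_config(n_genes = 120, n_case = 4, n_control = 4,
                           seed = 33)
  chim <- simulate_chimeric_experiment(cfg)
  hde <- de_table(chim$human, chim$human_groups, case = "WD", control = "NC")
  mde <- de_table(chim$mouse, chim$mouse_groups, case = "WD", control = "NC")
  fwd <- map_orthologues(hde, mde, chim$map, chim$human, chim$mouse,
                         chim$human_groups, chim$mouse_groups)
  swapped_map <- orthology_map(chim$map$human_gene, chim$map$mouse_gene)
  rev <- map_orthologues(mde, hde, swapped_map, chim$mouse, chim$human,
                         chim$mouse_groups, chim$human_groups)
  i <- match(fwd$human_gene, rev$mouse_gene)
  expect_equal(fwd$hm_ratio * rev$hm_ratio[i], rep(1, nrow(fwd)))
})

test_that("overlap cells are disjoint and cover single-species significance", {
  pairs <- make_pair_table(
    hg = c("h1", "h2", "h3"), mg = c("m1", "m2", "m3"),
    lfc_h = c(1, 1, -1), p_h = c(0.01, 0.01, 0.01),
    lfc_m = c(1, -1, -1), p_m = c(0.01, 0.01, 0.01),
    ratio = 1
  )
  ov <- overlap_counts(pairs, alpha = 0.05)
  expect_equal(ov$counts[["shared_up"]], 1L)
  expect_equal(ov$counts[["shared_down"]], 1L)
  # discordant both-significant pair lands in the human cell of its direction
  expect_equal(ov$counts[["human_only_up"]], 1L)
  expect_equal(sum(ov$counts), 3L)
  expect_identical(ov$genes$shared_up, "h1")
  expect_identical(ov$genes$shared_down, "h3")

  # property: cells partition the pairs significant in >= 1 species
  set.seed(44)
  rp <- make_pair_table(
    hg = sprintf("h%03d", 1:300), mg = sprintf("m%03d", 1:300),
    lfc_h = rnorm(300), p_h = runif(300),
    lfc_m = rnorm(300), p_m = runif(300),
    ratio = exp(rnorm(300, 0, 0.3))
  )
  ov2 <- overlap_counts(rp, alpha = 0.2)
  expect_equal(sum(ov2$counts), sum(rp$human_p < 0.2 | rp$mouse_p < 0.2))
  all_genes <- unlist(ov2$genes[c("shared_up", "shared_down",
                                  "human_only_up", "human_only_down")])
  expect_false(anyDuplicated(all_genes) > 0)

  expect_error(overlap_counts(rp, alpha = 1.5), "alpha")
})

test_that("hm_filter applies strict thresholds on p and ratio", {
  pairs <- make_pair_table(
    hg = c("h1", "h2", "h3", "h4"), mg = paste0("m", 1:4),
    lfc_h = c(-1, -1, -1, 1), p_h = c(0.01, 0.01, 0.06, 0.01),
    lfc_m = c(-2, -2, -2, -2), p_m = c(0.01, 0.01, 0.01, 0.01),
    ratio = c(1.19, 1.5, 1.5, 1.5)
  )
  expect_identical(hm_filter(pairs, 0.05, 1.2), c("h2", "h4"))
  # discordant pair h4 is removed when concordance is required
  expect_identical(hm_filter(pairs, 0.05, 1.2, require_concordant = TRUE),
                   "h2")
  # output is always a subset of pairs significant in both species
  both_sig <- pairs$human_gene[pairs$human_p < 0.05 & pairs$mouse_p < 0.05]
  expect_true(all(hm_filter(pairs, 0.05, 1.0) %in% both_sig))
  expect_error(hm_filter(pairs, 0.05, ratio_min = 0), "ratio_min")
})
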