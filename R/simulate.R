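# Synthetic-data generation. Counts are negative binomial with gene-level
# log-normal means; planted differential genes act multiplicatively on the
# case-group mean. Defaults emulate heterogeneous clinical case-control
# cohorts (biological CV 0.4, i.e. dispersion 0.16, n = 10 per group); for
# the chimeric-liver design pass dispersion 0.01 (BCV 0.1, genetically
# identical mice) and n = 8 per group.

#' Simulation configuration
#'
#' Validated parameter bundle shared by the simulators.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_datasets Number of independent case-control datasets (default
#'   10).
#' @param frac_true Fraction of genes planted as true positives (default
#'   0.05).
#' @param replication_prob Probability that a true gene is perturbed in any
#'   given dataset (default 0.7).
#' @param effect_log2fc Mean planted |log2 fold change| (default 1).
#' @param n_case,n_control Samples per group per dataset (default 10/10).
#' @param nb_mean_log_mu,nb_mean_log_sd Log-normal `meanlog`/`sdlog` of the
#'   baseline gene means (defaults 4 and 1, i.e. typical means of ~7-400
#'   counts).
#' @param nb_dispersion Negative-binomial dispersion `phi` in
#'   `var = mu + phi * mu^2` (default 0.16, a biological CV of 0.4).
#' @param seed Integer RNG seed (default 1). One global seed drives a
#'   per-dataset derived seed (`seed + dataset index`).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L, n_datasets = 10L,
                              frac_true = 0.05, replication_prob = 0.7,
                              effect_log2fc = 1.0, n_case = 10L,
                              n_control = 10L, nb_mean_log_mu = 4,
                              nb_mean_log_sd = 1, nb_dispersion = 0.16,
                              seed = 1L) {
  cfg <- list(
    n_genes = .check_count(n_genes, "n_genes"),
    n_datasets = .check_count(n_datasets, "n_datasets"),
    frac_true = .check_prob(frac_true, "frac_true"),
    replication_prob = .check_prob(replication_prob, "replication_prob"),
    effect_log2fc = {
      if (!is.numeric(effect_log2fc) || length(effect_log2fc) != 1L ||
          !is.finite(effect_log2fc) || effect_log2fc < 0) {
        stop("'effect_log2fc' must be a single non-negative finite number")
      }
      effect_log2fc
    },
    n_case = .check_count(n_case, "n_case"),
    n_control = .check_count(n_control, "n_control"),
    nb_mean_log_mu = {
      if (!is.numeric(nb_mean_log_mu) || !is.finite(nb_mean_log_mu)) {
        stop("'nb_mean_log_mu' must be finite")
      }
      nb_mean_log_mu
    },
    nb_mean_log_sd = {
      if (!is.numeric(nb_mean_log_sd) || !is.finite(nb_mean_log_sd) ||
          nb_mean_log_sd < 0) {
        stop("'nb_mean_log_sd' must be a non-negative finite number")
      }
      nb_mean_log_sd
    },
    nb_dispersion = .check_pos(nb_dispersion, "nb_dispersion"),
    seed = .check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "simulation_config")
}

# Internal: one genes-by-samples NB count matrix. `mu_case` / `mu_control`
# are per-gene means; columns are case samples then control samples.
.nb_matrix <- function(mu_case, mu_control, n_case, n_control, dispersion,
                       genes, sample_prefix) {
  size <- 1 / dispersion
  G <- length(genes)
  case <- matrix(stats::rnbinom(G * n_case, mu = rep(mu_case, n_case),
                                size = size), nrow = G)
  ctrl <- matrix(stats::rnbinom(G * n_control, mu = rep(mu_control, n_control),
                                size = size), nrow = G)
  m <- cbind(case, ctrl)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("%s_case_%02d", sample_prefix, seq_len(n_case)),
                   sprintf("%s_control_%02d", sample_prefix,
                           seq_len(n_control)))
  m
}

#' Simulate a multi-dataset case-control study collection
#'
#' Draws `n_datasets` independent case-control count datasets over a shared
#' gene universe. A fraction `frac_true` of genes is planted as true
#' positives; each true gene receives a direction (up/down, 50/50) drawn
#' once and held fixed across datasets, and is perturbed (case mean
#' multiplied by `2^effect_log2fc` in that direction) independently per
#' dataset with probability `replication_prob`. Each dataset is reduced to
#' a differential table via [de_table()] (Welch test, CPM, pseudocount
#' 0.5). Identical configurations give identical output.
#'
#' @param config A [simulation_config()].
#' @param min_datasets Passed to [study_collection()] (default 3).
#' @param keep_matrices Also return the raw count matrices and group labels
#'   (default `FALSE`; used by the pipeline to write them out).
#' @return List with `collection` (a [study_collection()]), `truth` (list
#'   with `true_genes`, `direction`, `per_dataset_perturbed`), and — when
#'   requested — `matrices` and `groups`.
#' @export
simulate_consensome_studies <- function(config, min_datasets = 3L,
                                        keep_matrices = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  mu <- stats::rlnorm(config$n_genes, config$nb_mean_log_mu,
                      config$nb_mean_log_sd)
  n_true <- round(config$frac_true * config$n_genes)
  true_genes <- sort(sample(genes, n_true))
  direction <- stats::setNames(sample(c(1, -1), n_true, replace = TRUE),
                               true_genes)

  tables <- vector("list", config$n_datasets)
  perturbed <- vector("list", config$n_datasets)
  matrices <- if (keep_matrices) vector("list", config$n_datasets) else NULL
  groups_list <- if (keep_matrices) vector("list", config$n_datasets) else NULL
  ds_ids <- sprintf("DS%02d", seq_len(config$n_datasets))
  for (j in seq_len(config$n_datasets)) {
    set.seed(config$seed + j)
    hit <- true_genes[stats::runif(n_true) < config$replication_prob]
    mu_case <- mu
    i <- match(hit, genes)
    mu_case[i] <- mu[i] * 2^(config$effect_log2fc * direction[hit])
    m <- .nb_matrix(mu_case, mu, config$n_case, config$n_control,
                    config$nb_dispersion, genes, ds_ids[j])
    grp <- stats::setNames(
      rep(c("case", "control"), c(config$n_case, config$n_control)),
      colnames(m)
    )
    tables[[j]] <- de_table(m, grp)
    perturbed[[j]] <- hit
    if (keep_matrices) {
      matrices[[j]] <- m
      groups_list[[j]] <- grp
    }
  }
  names(tables) <- ds_ids
  names(perturbed) <- ds_ids
  out <- list(
    collection = study_collection(tables, min_datasets = min_datasets),
    truth = list(true_genes = true_genes, direction = direction,
                 per_dataset_perturbed = perturbed)
  )
  if (keep_matrices) {
    names(matrices) <- ds_ids
    names(groups_list) <- ds_ids
    out$matrices <- matrices
    out$groups <- groups_list
  }
  out
}

#' Simulate a paired human/mouse chimeric count experiment
#'
#' Generates case/control (WD/NC) count matrices for two species over 1:1
#' identity-paired orthologues (`HGxxxxxx`/`MGxxxxxx`) sharing baseline
#' means, with planted gene sets:
#' * `shared_up` / `shared_down`: perturbed by `2^±effect_log2fc` in the
#'   case condition of both species;
#' * `human_only` / `mouse_only`: perturbed in one species (alternating
#'   directions);
#' * `hm_high`: repressed in both species, but more strongly in mouse
#'   (`-effect_log2fc - log2(hm_ratio)` vs `-effect_log2fc` in human), so
#'   the case-condition human:mouse expression ratio equals `hm_ratio`
#'   while both species remain differentially expressed — the structure of
#'   cholesterol-biosynthesis genes whose diet repression is weaker in
#'   human hepatocytes.
#'
#' @param config A [simulation_config()]; `n_case`/`n_control` are the
#'   per-species group sizes and `seed` fixes all draws.
#' @param n_orthologues Number of orthologue pairs (default
#'   `config$n_genes`); must not exceed `config$n_genes`.
#' @param hm_ratio Planted case-condition human:mouse expression ratio for
#'   the `hm_high` set (default 2.4); must be positive.
#' @param n_shared_up,n_shared_down,n_human_only,n_mouse_only,n_hm_high
#'   Planted set sizes (defaults 2, 2, 2, 2, 6).
#' @return List with `human`/`mouse` count matrices, `human_groups` /
#'   `mouse_groups` (WD/NC labels), `map` (an [orthology_map()]), and
#'   `truth` (planted sets; human identifiers except `planted_mouse_only`).
#' @export
simulate_chimeric_experiment <- function(config,
                                         n_orthologues = config$n_genes,
                                         hm_ratio = 2.4,
                                         n_shared_up = 2L, n_shared_down = 2L,
                                         n_human_only = 2L, n_mouse_only = 2L,
                                         n_hm_high = 6L) {
  stopifnot(inherits(config, "simulation_config"))
  .check_pos(hm_ratio, "hm_ratio")
  n_orthologues <- .check_count(n_orthologues, "n_orthologues")
  if (n_orthologues > config$n_genes) {
    stop("'n_orthologues' must not exceed config$n_genes")
  }
  sizes <- c(n_shared_up = .check_count(n_shared_up, "n_shared_up", 0L),
             n_shared_down = .check_count(n_shared_down, "n_shared_down", 0L),
             n_human_only = .check_count(n_human_only, "n_human_only", 0L),
             n_mouse_only = .check_count(n_mouse_only, "n_mouse_only", 0L),
             n_hm_high = .check_count(n_hm_high, "n_hm_high", 0L))
  if (sum(sizes) > n_orthologues) {
    stop("planted sets exceed the number of orthologues")
  }

  set.seed(config$seed)
  idx <- sprintf("%06d", seq_len(n_orthologues))
  hg <- paste0("HG", idx)
  mg <- paste0("MG", idx)
  mu <- stats::rlnorm(n_orthologues, config$nb_mean_log_mu,
                      config$nb_mean_log_sd)

  pick <- sample(seq_len(n_orthologues), sum(sizes))
  ends <- cumsum(sizes)
  starts <- stats::setNames(c(1L, utils::head(ends, -1L) + 1L), names(sizes))
  slot <- function(nm) {
    if (sizes[[nm]] == 0L) integer(0) else
      pick[starts[[nm]]:ends[[nm]]]
  }
  i_su <- slot("n_shared_up"); i_sd <- slot("n_shared_down")
  i_h <- slot("n_human_only"); i_m <- slot("n_mouse_only")
  i_hm <- slot("n_hm_high")

  e <- config$effect_log2fc
  lfc_h <- numeric(n_orthologues)
  lfc_m <- numeric(n_orthologues)
  lfc_h[i_su] <- e;  lfc_m[i_su] <- e
  lfc_h[i_sd] <- -e; lfc_m[i_sd] <- -e
  lfc_h[i_h] <- rep_len(c(e, -e), length(i_h))
  lfc_m[i_m] <- rep_len(c(e, -e), length(i_m))
  lfc_h[i_hm] <- -e
  lfc_m[i_hm] <- -e - log2(hm_ratio)

  human <- .nb_matrix(mu * 2^lfc_h, mu, config$n_case, config$n_control,
                      config$nb_dispersion, hg, "CHH")
  mouse <- .nb_matrix(mu * 2^lfc_m, mu, config$n_case, config$n_control,
                      config$nb_dispersion, mg, "CMH")
  relab <- function(m) {
    stats::setNames(rep(c("WD", "NC"), c(config$n_case, config$n_control)),
                    colnames(m))
  }
  list(
    human = human, mouse = mouse,
    human_groups = relab(human), mouse_groups = relab(mouse),
    map = orthology_map(mg, hg),
    truth = list(
      planted_shared_up = hg[i_su],
      planted_shared_down = hg[i_sd],
      planted_human_only = hg[i_h],
      planted_mouse_only = mg[i_m],
      planted_hm_high = hg[i_hm]
    )
  )
}

#' Simulate a node-HCT library with one planted enriched node
#'
#' Builds `n_nodes` gene sets of size `genes_per_node`. One node (chosen
#' under the seed) receives `planted_overlap` members of `query_set` plus
#' filler drawn from the universe outside the query set; every other node
#' samples uniformly from the whole universe (and may therefore overlap the
#' query by chance).
#'
#' @param n_nodes Number of nodes (default 50).
#' @param genes_per_node HCT set size per node (default 200).
#' @param query_set Character vector; must be contained in `universe`.
#' @param planted_overlap Number of query genes planted into the designated
#'   node; at most `min(genes_per_node, length(query_set))`.
#' @param universe Character vector of universe genes; at least
#'   `genes_per_node` long.
#' @param seed Integer RNG seed.
#' @return List with `library` (an [hct_library()]) and `truth`
#'   (`planted_node` identifier).
#' @export
simulate_hct_library <- function(n_nodes = 50L, genes_per_node = 200L,
                                 query_set, planted_overlap, universe,
                                 seed = 1L) {
  n_nodes <- .check_count(n_nodes, "n_nodes")
  genes_per_node <- .check_count(genes_per_node, "genes_per_node")
  planted_overlap <- .check_count(planted_overlap, "planted_overlap", 0L)
  seed <- .check_count(seed, "seed", min = 0L)
  universe <- unique(as.character(universe))
  query_set <- unique(as.character(query_set))
  if (length(universe) < genes_per_node) {
    stop("universe smaller than 'genes_per_node'")
  }
  if (!all(query_set %in% universe)) {
    stop("'query_set' must be contained in 'universe'")
  }
  if (planted_overlap > min(genes_per_node, length(query_set))) {
    stop("'planted_overlap' exceeds min(genes_per_node, |query_set|)")
  }
  background <- setdiff(universe, query_set)
  if (length(background) < genes_per_node - planted_overlap) {
    stop("universe too small outside the query set")
  }
  set.seed(seed)
  ids <- sprintf("NODE%03d", seq_len(n_nodes))
  planted <- sample(ids, 1L)
  nodes <- lapply(ids, function(id) {
    if (id == planted) {
      c(sample(query_set, planted_overlap),
        sample(background, genes_per_node - planted_overlap))
    } else {
      sample(universe, genes_per_node)
    }
  })
  names(nodes) <- ids
  list(library = hct_library(nodes, universe),
       truth = list(planted_node = planted))
}
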