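# End-to-end orchestration of the synthetic pipeline:
# simulate -> de -> consensome -> compare -> enrich. Stages communicate
# through tab-delimited files under the output directory so each stage can
# be re-run or skipped independently; a manifest of content hashes makes
# determinism checkable.

#' Pipeline configuration
#'
#' Validates every stage parameter up front so an invalid configuration is
#' rejected before any stage runs.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [simulation_config()] for the multi-dataset consensome
#'   simulation.
#' @param chimeric_sim A [simulation_config()] for the chimeric experiment
#'   (defaults to the low-dispersion, n = 8/8 regime of genetically
#'   identical mice).
#' @param alpha Per-dataset discovery / DEG threshold (default 0.05).
#' @param q_max Consensome and enrichment q cutoff (default 0.05).
#' @param fc_min Confidence-transcript fold-change threshold (default
#'   1.25).
#' @param ratio_min H:M relative-expression threshold (default 1.2).
#' @param min_datasets Consensome universe threshold (default 3).
#' @param pseudocount Log-transform / fold-change offset (default 0.5).
#' @param normalize `"cpm"` or `"none"` (default `"cpm"`).
#' @param test `"welch"` or `"student"` (default `"welch"`).
#' @param hm_ratio Planted chimeric H:M ratio (default 2.4).
#' @param hct_n_nodes,hct_genes_per_node,hct_universe_size,hct_planted_overlap
#'   Node-HCT simulation sizes (defaults 50, 200, 18000, 5).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(seed = seed),
                            chimeric_sim = simulation_config(
                              n_case = 8L, n_control = 8L,
                              nb_mean_log_mu = 5, nb_dispersion = 0.01,
                              seed = seed + 1000L
                            ),
                            alpha = 0.05, q_max = 0.05, fc_min = 1.25,
                            ratio_min = 1.2, min_datasets = 3L,
                            pseudocount = 0.5,
                            normalize = c("cpm", "none"),
                            test = c("welch", "student"),
                            hm_ratio = 2.4,
                            hct_n_nodes = 50L, hct_genes_per_node = 200L,
                            hct_universe_size = 18000L,
                            hct_planted_overlap = 5L,
                            seed = 1L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  seed <- .check_count(seed, "seed", min = 0L)
  normalize <- match.arg(normalize)
  test <- match.arg(test)
  stopifnot(inherits(sim, "simulation_config"),
            inherits(chimeric_sim, "simulation_config"))
  .check_prob(alpha, "alpha", strict = TRUE)
  .check_prob(q_max, "q_max", strict = TRUE)
  .check_pos(fc_min, "fc_min")
  .check_pos(ratio_min, "ratio_min")
  .check_pos(hm_ratio, "hm_ratio")
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("'pseudocount' must be non-negative")
  }
  cfg <- list(
    out_dir = out_dir, sim = sim, chimeric_sim = chimeric_sim,
    alpha = alpha, q_max = q_max, fc_min = fc_min, ratio_min = ratio_min,
    min_datasets = .check_count(min_datasets, "min_datasets"),
    pseudocount = pseudocount, normalize = normalize, test = test,
    hm_ratio = hm_ratio,
    hct_n_nodes = .check_count(hct_n_nodes, "hct_n_nodes"),
    hct_genes_per_node = .check_count(hct_genes_per_node,
                                      "hct_genes_per_node"),
    hct_universe_size = .check_count(hct_universe_size, "hct_universe_size"),
    hct_planted_overlap = .check_count(hct_planted_overlap,
                                       "hct_planted_overlap", 0L),
    seed = seed
  )
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order, writing every intermediate and
#' final artifact as tab-delimited text (or GMT) under `config$out_dir`,
#' then writes `manifest.tsv` listing each file with its MD5 content hash.
#' All randomness flows from the configured seeds, so re-running with the
#' same configuration reproduces identical hashes. Stage progress is
#' logged to the message stream; a failing stage aborts with an error
#' naming it.
#'
#' Stages: `simulate` writes per-dataset count matrices, group files,
#' chimeric matrices, the orthology map, ground truth and the node-HCT
#' library; `de` reads the matrices and writes per-dataset differential
#' tables plus the two species tables; `consensome` builds the consensome
#' table and the confidence-transcript GMT; `compare` writes the
#' orthologue pair table, overlap counts and the H:M gene-set GMT;
#' `enrich` intersects the H:M set with the node-HCT library.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "de", "consensome", "compare", "enrich")`, in pipeline
#'   order. Later stages read earlier stages' files from `out_dir`.
#' @return The manifest data frame (`path`, `md5`), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "de", "consensome",
                                    "compare", "enrich")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  ds_ids <- sprintf("DS%02d", seq_len(config$sim$n_datasets))

  run_stage <- function(stage, body) {
    .log_stage(stage, "started")
    tryCatch(body(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    .log_stage(stage, "done")
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sim <- simulate_consensome_studies(config$sim,
                                       min_datasets = config$min_datasets,
                                       keep_matrices = TRUE)
    for (id in ds_ids) {
      write_matrix(sim$matrices[[id]], od(paste0(id, "_counts.tsv")))
      write_groups(sim$groups[[id]], od(paste0(id, "_groups.tsv")))
    }
    write_table(data.frame(gene = sim$truth$true_genes,
                           direction = unname(sim$truth$direction),
                           stringsAsFactors = FALSE),
                od("truth_consensome.tsv"))

    chim <- simulate_chimeric_experiment(config$chimeric_sim,
                                         hm_ratio = config$hm_ratio)
    write_matrix(chim$human, od("chimeric_human_counts.tsv"))
    write_matrix(chim$mouse, od("chimeric_mouse_counts.tsv"))
    write_groups(chim$human_groups, od("chimeric_human_groups.tsv"))
    write_groups(chim$mouse_groups, od("chimeric_mouse_groups.tsv"))
    write_table(as.data.frame(chim$map), od("orthology_map.tsv"))
    planted <- chim$truth[lengths(chim$truth) > 0]
    if (length(planted) == 0L) planted <- list(NONE = "none")
    write_gmt(planted, od("truth_chimeric.gmt"))

    filler <- config$hct_universe_size - nrow(chim$human)
    if (filler < 0) stop("hct_universe_size smaller than the orthologue set")
    universe <- c(rownames(chim$human), sprintf("U%06d", seq_len(filler)))
    hct <- simulate_hct_library(
      n_nodes = config$hct_n_nodes,
      genes_per_node = config$hct_genes_per_node,
      query_set = chim$truth$planted_hm_high,
      planted_overlap = config$hct_planted_overlap,
      universe = universe,
      seed = config$seed + 2000L
    )
    write_gmt(hct$library$nodes, od("hct_library.gmt"))
    writeLines(universe, od("hct_universe.txt"))
    write_table(data.frame(planted_node = hct$truth$planted_node,
                           stringsAsFactors = FALSE),
                od("truth_hct.tsv"))
  })

  if ("de" %in% stages) run_stage("de", function() {
    for (id in ds_ids) {
      m <- read_matrix(od(paste0(id, "_counts.tsv")))
      g <- read_groups(od(paste0(id, "_groups.tsv")))
      write_table(de_table(m, g, test = config$test,
                           normalize = config$normalize,
                           pseudocount = config$pseudocount),
                  od(paste0(id, "_de.tsv")))
    }
    for (sp in c("human", "mouse")) {
      m <- read_matrix(od(paste0("chimeric_", sp, "_counts.tsv")))
      g <- read_groups(od(paste0("chimeric_", sp, "_groups.tsv")))
      write_table(de_table(m, g, test = config$test,
                           normalize = config$normalize,
                           pseudocount = config$pseudocount,
                           case = "WD", control = "NC"),
                  od(paste0("chimeric_", sp, "_de.tsv")))
    }
  })

  if ("consensome" %in% stages) run_stage("consensome", function() {
    tabs <- lapply(ds_ids, function(id) read_table(od(paste0(id, "_de.tsv"))))
    names(tabs) <- ds_ids
    coll <- study_collection(tabs, min_datasets = config$min_datasets)
    cons <- build_consensome(coll, alpha = config$alpha)
    write_table(cons, od("consensome.tsv"))
    cts <- list(
      CT_UP = confidence_transcripts(cons, config$q_max, config$fc_min, "up"),
      CT_DOWN = confidence_transcripts(cons, config$q_max, config$fc_min,
                                       "down")
    )
    cts <- cts[lengths(cts) > 0]
    if (length(cts) == 0L) {
      cts <- list(CT_NONE = "none")
    }
    write_gmt(cts, od("confidence_transcripts.gmt"))
  })

  if ("compare" %in% stages) run_stage("compare", function() {
    hde <- .as_differential_table(read_table(od("chimeric_human_de.tsv")))
    mde <- .as_differential_table(read_table(od("chimeric_mouse_de.tsv")))
    map <- read_orthology(od("orthology_map.tsv"))
    hx <- read_matrix(od("chimeric_human_counts.tsv"))
    mx <- read_matrix(od("chimeric_mouse_counts.tsv"))
    hg <- read_groups(od("chimeric_human_groups.tsv"))
    mg <- read_groups(od("chimeric_mouse_groups.tsv"))
    pairs <- map_orthologues(hde, mde, map, hx, mx, hg, mg,
                             pseudocount = config$pseudocount)
    write_table(pairs, od("ortholog_pairs.tsv"))
    ov <- overlap_counts(pairs, alpha = config$alpha)
    write_table(data.frame(cell = names(ov$counts),
                           count = unname(ov$counts),
                           stringsAsFactors = FALSE),
                od("overlap_counts.tsv"))
    hm <- hm_filter(pairs, alpha = config$alpha,
                    ratio_min = config$ratio_min)
    write_gmt(list(HM_HIGH = if (length(hm) > 0) hm else "none"),
              od("hm_genes.gmt"))
  })

  if ("enrich" %in% stages) run_stage("enrich", function() {
    hm <- read_gmt(od("hm_genes.gmt"))[["HM_HIGH"]]
    nodes <- read_gmt(od("hct_library.gmt"))
    universe <- readLines(od("hct_universe.txt"))
    lib <- hct_library(nodes, universe)
    res <- hct_intersection(hm, lib)
    write_table(res, od("hct_intersections.tsv"))
  })

  files <- sort(setdiff(list.files(config$out_dir), "manifest.tsv"))
  manifest <- data.frame(
    path = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE
  )
  write_table(manifest, od("manifest.tsv"))
  invisible(manifest)
}
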