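# Consensome meta-analysis: rank genes by how often they are "discovered"
# (two-sided p < alpha) across independent case-control datasets. The
# significance model is the exact Poisson-binomial upper tail under
# per-dataset null discovery rates, followed by Benjamini-Hochberg FDR.

#' Bundle per-dataset differential tables into a study collection
#'
#' @param tables Named list of [de_table()] results (or data frames with
#'   the same columns), one per dataset.
#' @param min_datasets Minimum number of datasets a gene must be measured
#'   in to enter the consensome universe (default 3).
#' @return A `study_collection`: list with `datasets` (the tables),
#'   `universe` (character vector of eligible genes) and `min_datasets`.
#' @export
study_collection <- function(tables, min_datasets = 3L) {
  min_datasets <- .check_count(min_datasets, "min_datasets")
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || anyDuplicated(names(tables)) ||
      !all(nzchar(names(tables)))) {
    stop("'tables' must be a uniquely named list of differential tables")
  }
  tables <- lapply(tables, .as_differential_table)
  ids <- lapply(tables, function(t) t$id)
  counts <- table(unlist(ids, use.names = FALSE))
  universe <- sort(names(counts)[counts >= min_datasets])
  if (length(universe) == 0L) {
    stop("empty universe: no gene is measured in >= ", min_datasets,
         " datasets")
  }
  structure(list(datasets = tables, universe = universe,
                 min_datasets = min_datasets),
            class = "study_collection")
}

# Internal: genes-by-datasets matrices of p and fold change (NA = gene not
# measured in that dataset), over the union of all measured genes.
.collection_grids <- function(collection) {
  stopifnot(inherits(collection, "study_collection"))
  tabs <- collection$datasets
  genes <- sort(unique(unlist(lapply(tabs, function(t) t$id),
                              use.names = FALSE)))
  J <- length(tabs)
  P <- matrix(NA_real_, length(genes), J,
              dimnames = list(genes, names(tabs)))
  FC <- P
  for (j in seq_len(J)) {
    i <- match(tabs[[j]]$id, genes)
    P[i, j] <- tabs[[j]]$p
    FC[i, j] <- tabs[[j]]$fold_change
  }
  list(genes = genes, p = P, fc = FC)
}

#' Binary discovery calls across datasets
#'
#' A gene is "discovered" in a dataset when it is measured there and its
#' two-sided p-value is strictly below `alpha`. Genes not measured in a
#' dataset are `NA` and do not count towards the number of opportunities.
#'
#' @param collection A [study_collection()].
#' @param alpha Per-dataset discovery threshold in (0, 1); default 0.05.
#' @return Integer matrix (genes x datasets) of 0/1 calls with `NA` for
#'   missing genes.
#' @export
discovery_calls <- function(collection, alpha = 0.05) {
  .check_prob(alpha, "alpha", strict = TRUE)
  g <- .collection_grids(collection)
  calls <- (g$p < alpha) + 0L
  calls
}

#' Per-dataset empirical null discovery rates
#'
#' The fraction of measured genes with p below `alpha` in each dataset.
#' These empirical rates parameterise the Poisson-binomial null so that a
#' dataset whose p-values are miscalibrated does not distort consensome
#' significance.
#'
#' @inheritParams discovery_calls
#' @return Named numeric vector, one rate per dataset.
#' @export
null_rates <- function(collection, alpha = 0.05) {
  .check_prob(alpha, "alpha", strict = TRUE)
  g <- .collection_grids(collection)
  apply(g$p, 2L, function(p) mean(p < alpha, na.rm = TRUE))
}

# Internal: exact Poisson-binomial probability mass function of the number
# of successes among independent Bernoulli(rates) trials, by dynamic
# programming (convolution one trial at a time). Stable for <= 100 trials.
.pb_dist <- function(rates) {
  f <- 1
  for (r in rates) {
    f <- c(f * (1 - r), 0) + c(0, f * r)
  }
  f
}

#' Poisson-binomial upper-tail probability
#'
#' `P(X >= d)` where `X` is the sum of independent Bernoulli variables
#' with the given success probabilities, computed from the exact dynamic-
#' programming distribution. With equal rates this reduces to the binomial
#' survival function.
#'
#' @param d Integer number of successes, `0 <= d <= length(rates)`.
#' @param rates Vector of success probabilities in `[0, 1]`.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' poisson_binomial_tail(3, c(0.05, 0.05, 0.05)) # 1.25e-4
#' poisson_binomial_tail(3, rep(0.5, 4))         # 5/16
#' @export
poisson_binomial_tail <- function(d, rates) {
  if (!is.numeric(rates) || length(rates) < 1L || anyNA(rates) ||
      any(rates < 0 | rates > 1)) {
    stop("'rates' must be probabilities in [0, 1]")
  }
  d <- .check_count(d, "d", min = 0L)
  if (d > length(rates)) stop("'d' must not exceed length(rates)")
  if (d == 0L) return(1)
  f <- .pb_dist(rates)
  min(1, sum(f[(d + 1L):length(f)]))
}

#' Build the consensome table
#'
#' For every gene in the universe: the discovery count `d`, the number of
#' datasets it was measured in `D`, the discovery rate `d/D`, the exact
#' Poisson-binomial upper-tail probability of observing at least `d`
#' discoveries under the datasets' null rates, the Benjamini-Hochberg
#' q-value across the universe, and the geometric mean of the per-dataset
#' linear fold changes. Genes are ranked by (q ascending, discovery rate
#' descending, |log2 mean fold change| descending, identifier).
#'
#' @inheritParams discovery_calls
#' @param min_datasets Universe membership threshold; defaults to the
#'   collection's own setting.
#' @param null_mode `"empirical"` (default) uses the observed per-dataset
#'   discovery fractions as null rates; `"nominal"` uses `alpha` for every
#'   dataset.
#' @return A `consensome_table`: data frame with columns `id`, `d`, `D`,
#'   `discovery_rate`, `p_consensome`, `q`, `mean_fc`, `rank`,
#'   `percentile` (100 * rank / universe size; small is strong).
#' @export
build_consensome <- function(collection, alpha = 0.05,
                             min_datasets = collection$min_datasets,
                             null_mode = c("empirical", "nominal")) {
  .check_prob(alpha, "alpha", strict = TRUE)
  null_mode <- match.arg(null_mode)
  min_datasets <- .check_count(min_datasets, "min_datasets")
  g <- .collection_grids(collection)
  measured <- !is.na(g$p)
  universe <- rownames(g$p)[rowSums(measured) >= min_datasets]
  if (length(universe) == 0L) stop("empty universe")
  keep <- match(universe, rownames(g$p))
  P <- g$p[keep, , drop = FALSE]
  FC <- g$fc[keep, , drop = FALSE]
  meas <- measured[keep, , drop = FALSE]

  rates <- switch(null_mode,
    empirical = null_rates(collection, alpha),
    nominal = rep(alpha, ncol(P))
  )
  calls <- (P < alpha) & meas
  d <- rowSums(calls, na.rm = TRUE)
  D <- rowSums(meas)

  # Genes sharing a measurement pattern share a Poisson-binomial null;
  # compute each pattern's full tail once.
  pattern <- apply(meas, 1L, function(m) paste(which(m), collapse = ","))
  p_cons <- numeric(length(universe))
  for (pat in unique(pattern)) {
    js <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1L]])
    f <- .pb_dist(rates[js])
    tail <- rev(cumsum(rev(f)))          # tail[k+1] = P(X >= k)
    tail <- pmin(1, pmax(0, tail))
    rows <- which(pattern == pat)
    p_cons[rows] <- tail[d[rows] + 1L]
  }

  q <- bh_fdr(p_cons)
  log_fc <- log(FC)
  mean_fc <- exp(rowSums(log_fc * meas, na.rm = TRUE) / D)

  ord <- order(q, -d / D, -abs(log2(mean_fc)), universe)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)

  out <- data.frame(
    id = universe, d = d, D = D, discovery_rate = d / D,
    p_consensome = p_cons, q = q, mean_fc = mean_fc, rank = rank,
    percentile = 100 * rank / length(universe),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensome_table", "data.frame")
  out
}

#' Extract confidence transcripts
#'
#' Confidence transcripts (CTs) are consensome genes passing a q-value
#' cutoff, optionally restricted by mean case:control fold change: `up`
#' keeps `mean_fc > fc_min`, `down` keeps `mean_fc < 1/fc_min`, `any`
#' keeps either.
#'
#' @param table A [build_consensome()] result.
#' @param q_max Strict q-value cutoff (default 0.05).
#' @param fc_min Fold-change threshold on the linear scale (default 1.25).
#' @param direction `"any"` (default), `"up"`, or `"down"`.
#' @return Character vector of gene identifiers.
#' @export
confidence_transcripts <- function(table, q_max = 0.05, fc_min = 1.25,
                                   direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  .check_prob(q_max, "q_max", strict = TRUE)
  .check_pos(fc_min, "fc_min")
  stopifnot(is.data.frame(table),
            all(c("id", "q", "mean_fc") %in% colnames(table)))
  keep_q <- table$q < q_max
  keep_fc <- switch(direction,
    up = table$mean_fc > fc_min,
    down = table$mean_fc < 1 / fc_min,
    any = table$mean_fc > fc_min | table$mean_fc < 1 / fc_min
  )
  table$id[keep_q & keep_fc]
}
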