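# Hypergeometric over-representation of gene sets, odds ratios, node-HCT
# intersection analysis, and Benjamini-Hochberg FDR.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to 1, returned in input order. A thin
#' validated wrapper around `stats::p.adjust(method = "BH")` so the same
#' correction is used across the consensome and all enrichment analyses.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in `[0, 1]`, in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("'p' must be probabilities in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of one gene set
#'
#' Tests whether `query` overlaps `reference` more than expected when both
#' are drawn from `universe`. With `k = |query ∩ reference|`,
#' `K = |reference|`, `n = |query|`, `N = |universe|`, the p-value is the
#' upper tail `P(X >= k)` of the hypergeometric distribution, and the odds
#' ratio is the 2x2 cross-product `k(N-K-n+k) / ((K-k)(n-k))` (0 when
#' `k = 0`; infinite when a denominator term vanishes with `k > 0`).
#' Query/reference members absent from the universe are dropped, with the
#' count reported via a message.
#'
#' @param query,reference,universe Character vectors of gene identifiers
#'   (duplicates removed).
#' @param set_id Identifier stored in the result row (default `NA`).
#' @param haldane If `TRUE`, add 0.5 to every 2x2 cell before forming the
#'   odds ratio (Haldane-Anscombe correction); off by default so plain
#'   cross-product ratios are reported.
#' @return One-row data frame: `set_id`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p`, `q` (`q` is `NA` here; it is filled in across a library by
#'   [hct_intersection()]).
#' @examples
#' hypergeom_overlap(letters[1:4], letters[1:5], letters[1:10])
#' @export
hypergeom_overlap <- function(query, reference, universe, set_id = NA_character_,
                              haldane = FALSE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  dropped <- sum(!(query %in% universe)) + sum(!(reference %in% universe))
  if (dropped > 0L) {
    message(dropped, " gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    reference <- intersect(reference, universe)
  }
  k <- length(intersect(query, reference))
  K <- length(reference)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  if (haldane) {
    or <- ((k + 0.5) * (N - K - n + k + 0.5)) /
      ((K - k + 0.5) * (n - k + 0.5))
  } else if (k == 0L) {
    or <- 0
  } else {
    den <- (K - k) * (n - k)
    or <- if (den == 0) Inf else k * (N - K - n + k) / den
  }
  data.frame(set_id = set_id, k = k, K = K, n = n, N = N,
             odds_ratio = or, p = p, q = NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct a node-HCT gene-set library
#'
#' A library of high-confidence transcriptional target (HCT) sets, one per
#' signalling-pathway node, together with the gene universe against which
#' intersections are tested. Node sets are restricted to the universe.
#'
#' @param nodes Named list of character vectors (node id -> HCT gene set).
#' @param universe Character vector of universe gene identifiers.
#' @return An `hct_library` (list with `nodes` and `universe`).
#' @export
hct_library <- function(nodes, universe) {
  stopifnot(is.list(nodes), length(nodes) >= 1L, !is.null(names(nodes)))
  if (anyDuplicated(names(nodes))) stop("node ids must be unique")
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  nodes <- lapply(nodes, function(s) intersect(unique(as.character(s)),
                                               universe))
  structure(list(nodes = nodes, universe = universe), class = "hct_library")
}

#' Node-HCT intersection analysis
#'
#' Tests a query gene set against every node's HCT set in a library via
#' [hypergeom_overlap()], applies Benjamini-Hochberg correction across
#' nodes, and sorts by (q, p, node id). Nodes with `q < 0.05` are the
#' conventional "significant intersections".
#'
#' @param query Character vector of gene identifiers.
#' @param library An [hct_library()].
#' @return Data frame with one row per node, columns `set_id`, `k`, `K`,
#'   `n`, `N`, `odds_ratio`, `p`, `q`.
#' @export
hct_intersection <- function(query, library) {
  stopifnot(inherits(library, "hct_library"))
  rows <- lapply(names(library$nodes), function(id) {
    suppressMessages(
      hypergeom_overlap(query, library$nodes[[id]], library$universe,
                        set_id = id)
    )
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
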