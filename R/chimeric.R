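# Cross-species comparison of the diet response within one chimeric liver:
# orthology-mapped pairing of human (CHH) and mouse (CMH) differential
# tables, DEG overlap partitioning, and the H:M relative-expression filter.

#' Construct a strict 1:1 orthology map
#'
#' Any gene appearing in more than one candidate pair disqualifies every
#' pair it touches; the number of pairs dropped this way is reported via a
#' message (the human:mouse expression ratio is undefined for ambiguous
#' mappings).
#'
#' @param mouse_gene,human_gene Character vectors of equal length giving
#'   candidate orthologue pairs.
#' @return An `orthology_map`: data frame with columns `mouse_gene`,
#'   `human_gene`.
#' @export
orthology_map <- function(mouse_gene, human_gene) {
  mouse_gene <- as.character(mouse_gene)
  human_gene <- as.character(human_gene)
  stopifnot(length(mouse_gene) == length(human_gene))
  ok <- !(duplicated(mouse_gene) | duplicated(mouse_gene, fromLast = TRUE) |
            duplicated(human_gene) | duplicated(human_gene, fromLast = TRUE))
  if (any(!ok)) {
    message(sum(!ok), " non-1:1 orthology pair(s) dropped")
  }
  out <- data.frame(mouse_gene = mouse_gene[ok], human_gene = human_gene[ok],
                    stringsAsFactors = FALSE)
  class(out) <- c("orthology_map", "data.frame")
  out
}

#' Pair human and mouse differential statistics over orthologues
#'
#' Joins the two species' differential tables on a 1:1 orthology map and
#' attaches the H:M relative expression ratio: the ratio of human to mouse
#' case-condition (e.g. Western diet) group means, computed after
#' within-species CPM normalization with a pseudocount. Pairs whose gene is
#' missing from either table or expression matrix are dropped and counted
#' in a message.
#'
#' @param human_de,mouse_de [de_table()] results for the two species.
#' @param map An [orthology_map()].
#' @param human_expr,mouse_expr Raw genes-by-samples count matrices for the
#'   two species (same genes as the respective tables).
#' @param human_groups,mouse_groups Group labels per sample (vector aligned
#'   to columns or named by column), using the `case`/`control` labels.
#' @param case,control Group labels naming the case (default `"WD"`) and
#'   control (default `"NC"`) condition.
#' @param pseudocount Offset added to both CPM means before the ratio
#'   (default 0.5).
#' @return An `ortholog_pair_table`: data frame with columns `human_gene`,
#'   `mouse_gene`, `human_log2fc`, `human_p`, `mouse_log2fc`, `mouse_p`,
#'   `human_case_mean`, `mouse_case_mean`, `hm_ratio`.
#' @export
map_orthologues <- function(human_de, mouse_de, map, human_expr, mouse_expr,
                            human_groups, mouse_groups,
                            case = "WD", control = "NC", pseudocount = 0.5) {
  stopifnot(inherits(map, "orthology_map"))
  human_de <- .as_differential_table(human_de)
  mouse_de <- .as_differential_table(mouse_de)
  hm <- .case_cpm_means(human_expr, human_groups, case, control, pseudocount)
  mm <- .case_cpm_means(mouse_expr, mouse_groups, case, control, pseudocount)

  ih <- match(map$human_gene, human_de$id)
  im <- match(map$mouse_gene, mouse_de$id)
  eh <- match(map$human_gene, names(hm))
  em <- match(map$mouse_gene, names(mm))
  ok <- !is.na(ih) & !is.na(im) & !is.na(eh) & !is.na(em)
  if (any(!ok)) {
    message(sum(!ok), " orthology pair(s) missing from a table; dropped")
  }
  ih <- ih[ok]; im <- im[ok]; eh <- eh[ok]; em <- em[ok]
  out <- data.frame(
    human_gene = map$human_gene[ok],
    mouse_gene = map$mouse_gene[ok],
    human_log2fc = human_de$log2fc[ih],
    human_p = human_de$p[ih],
    mouse_log2fc = mouse_de$log2fc[im],
    mouse_p = mouse_de$p[im],
    human_case_mean = hm[eh],
    mouse_case_mean = mm[em],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$hm_ratio <- (out$human_case_mean + pseudocount) /
    (out$mouse_case_mean + pseudocount)
  class(out) <- c("ortholog_pair_table", "data.frame")
  out
}

# Internal: CPM-normalized case-condition group means per gene.
.case_cpm_means <- function(mat, groups, case, control, pseudocount) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (!is.null(names(groups))) {
    if (is.null(colnames(mat)) || !all(colnames(mat) %in% names(groups))) {
      stop("missing group label for one or more samples")
    }
    groups <- groups[colnames(mat)]
  }
  if (length(groups) != ncol(mat)) stop("'groups' must label every sample")
  groups <- as.character(groups)
  if (!all(groups %in% c(case, control))) {
    stop(sprintf("group labels must all be '%s' or '%s'", case, control))
  }
  libsize <- colSums(mat)
  if (any(libsize <= 0)) stop("cannot CPM-normalize a column with sum <= 0")
  cpm <- sweep(mat, 2L, libsize, "/") * 1e6
  rowMeans(cpm[, groups == case, drop = FALSE])
}

.check_pair_table <- function(pairs) {
  need <- c("human_gene", "mouse_gene", "human_log2fc", "human_p",
            "mouse_log2fc", "mouse_p", "hm_ratio")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss) > 0L) {
    stop("not an ortholog pair table; missing columns: ",
         paste(miss, collapse = ", "))
  }
  invisible(pairs)
}

#' Partition orthologue pairs by cross-species DEG status
#'
#' Classifies every pair significant (p < `alpha`) in at least one species
#' into six mutually exclusive cells. `shared_up`/`shared_down` require
#' significance in both species with the same direction. Pairs significant
#' in both species but with discordant directions are assigned to the
#' human-only cell of the human direction (the human response is the
#' reference compartment in chimeric designs); pairs significant in one
#' species only go to that species' cell by its direction. Direction `up`
#' means `log2fc > 0`.
#'
#' @param pairs An [map_orthologues()] result (or data frame with the same
#'   columns).
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @return List of class `overlap_counts` with `counts` (named integer
#'   vector over the six cells) and `genes` (named list of human gene
#'   identifiers per cell; mouse identifiers for the mouse-only cells).
#' @export
overlap_counts <- function(pairs, alpha = 0.05) {
  .check_prob(alpha, "alpha", strict = TRUE)
  .check_pair_table(pairs)
  sig_h <- pairs$human_p < alpha
  sig_m <- pairs$mouse_p < alpha
  up_h <- pairs$human_log2fc > 0
  up_m <- pairs$mouse_log2fc > 0

  cell <- list(
    shared_up      = sig_h & sig_m & up_h & up_m,
    shared_down    = sig_h & sig_m & !up_h & !up_m,
    human_only_up  = sig_h & up_h & !(sig_m & up_m),
    human_only_down = sig_h & !up_h & !(sig_m & !up_m),
    mouse_only_up  = sig_m & up_m & !sig_h,
    mouse_only_down = sig_m & !up_m & !sig_h
  )
  genes <- list(
    shared_up = pairs$human_gene[cell$shared_up],
    shared_down = pairs$human_gene[cell$shared_down],
    human_only_up = pairs$human_gene[cell$human_only_up],
    human_only_down = pairs$human_gene[cell$human_only_down],
    mouse_only_up = pairs$mouse_gene[cell$mouse_only_up],
    mouse_only_down = pairs$mouse_gene[cell$mouse_only_down]
  )
  structure(list(
    counts = vapply(cell, sum, integer(1L)),
    genes = genes
  ), class = "overlap_counts")
}

#' Extract the H:M high relative-expression gene set
#'
#' Genes differentially expressed (p < `alpha`) in response to the case
#' condition in both species whose human:mouse relative expression ratio
#' strictly exceeds `ratio_min` (the "H:M > 1.2" construction at the
#' default threshold). Direction concordance is not required by default;
#' set `require_concordant = TRUE` to additionally demand the same
#' response sign in both species.
#'
#' @inheritParams overlap_counts
#' @param ratio_min Strict lower bound on `hm_ratio` (default 1.2).
#' @param require_concordant Require matching log2fc signs (default
#'   `FALSE`).
#' @return Character vector of human gene identifiers.
#' @export
hm_filter <- function(pairs, alpha = 0.05, ratio_min = 1.2,
                      require_concordant = FALSE) {
  .check_prob(alpha, "alpha", strict = TRUE)
  .check_pos(ratio_min, "ratio_min")
  .check_pair_table(pairs)
  keep <- pairs$human_p < alpha & pairs$mouse_p < alpha &
    pairs$hm_ratio > ratio_min
  if (require_concordant) {
    keep <- keep & (sign(pairs$human_log2fc) == sign(pairs$mouse_log2fc))
  }
  pairs$human_gene[keep]
}
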