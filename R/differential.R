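# Two-group differential statistics: Student/Welch t-tests on
# log2-transformed normalized abundances, fold changes, and assembly of
# per-dataset differential tables.

# Internal vectorised two-sample t machinery. `a`, `b` are matrices with
# one row per analyte. Returns t, df, p and a degeneracy indicator for
# rows where both groups have zero variance.
.t_rows <- function(a, b, pooled) {
  n1 <- ncol(a)
  n2 <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (n1 - 1)
  vb <- rowSums((b - mb)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, nrow(a))
  } else {
    se2 <- va / n1 + vb / n2
    df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
  }
  t <- (ma - mb) / sqrt(se2)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    sep <- degenerate & (ma != mb)
    t[degenerate] <- 0
    t[sep] <- sign(ma - mb)[sep] * Inf
    df[degenerate] <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
       degenerate = degenerate)
}

.check_group_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric vector of length >= 2", name))
  }
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom. When both
#' groups have zero variance the statistic degenerates: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` and the result is flagged.
#'
#' @param a,b Numeric sample vectors, each of length at least 2.
#' @return List with `t_stat`, `df`, `p`, and `flag` (`"ok"` or
#'   `"degenerate"`).
#' @examples
#' welch_t(c(1.1, 2.0, 2.9, 1.8), c(4.2, 5.1, 3.9, 4.8))
#' @export
welch_t <- function(a, b) {
  .check_group_vec(a, "a")
  .check_group_vec(b, "b")
  r <- .t_rows(matrix(a, nrow = 1L), matrix(b, nrow = 1L), pooled = FALSE)
  list(t_stat = r$t, df = r$df, p = r$p,
       flag = if (r$degenerate && r$p == 0) "degenerate" else "ok")
}

#' Student's pooled-variance t-test
#'
#' Two-sided t-test with pooled variance and `length(a) + length(b) - 2`
#' degrees of freedom; degenerate zero-variance cases are handled as in
#' [welch_t()].
#'
#' @inheritParams welch_t
#' @return List with `t_stat`, `df`, `p`, and `flag`.
#' @export
student_t <- function(a, b) {
  .check_group_vec(a, "a")
  .check_group_vec(b, "b")
  r <- .t_rows(matrix(a, nrow = 1L), matrix(b, nrow = 1L), pooled = TRUE)
  list(t_stat = r$t, df = r$df, p = r$p,
       flag = if (r$degenerate && r$p == 0) "degenerate" else "ok")
}

#' Case/control fold change
#'
#' Linear-scale fold change `(mean_case + pseudocount) /
#' (mean_control + pseudocount)` and its log2. A positive pseudocount is
#' required whenever a mean can be zero.
#'
#' @param mean_case,mean_control Non-negative group means on the
#'   normalized scale (vectorised).
#' @param pseudocount Non-negative offset added to both means.
#' @return List with `fold_change` and `log2fc`.
#' @examples
#' fold_change(20, 10, 0) # 2-fold, log2fc = 1
#' @export
fold_change <- function(mean_case, mean_control, pseudocount = 0) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount < 0) {
    stop("'pseudocount' must be a single non-negative number")
  }
  stopifnot(is.numeric(mean_case), is.numeric(mean_control),
            length(mean_case) == length(mean_control))
  if (any(mean_case < 0) || any(mean_control < 0)) {
    stop("group means must be non-negative")
  }
  if (any(mean_control + pseudocount == 0)) {
    stop("zero denominator: control mean and pseudocount are both zero")
  }
  fc <- (mean_case + pseudocount) / (mean_control + pseudocount)
  list(fold_change = fc, log2fc = log2(fc))
}

#' Percentage share, rounded half-up to one decimal
#'
#' Computes `100 * k / n` and rounds half-up to one decimal place, the
#' convention used when reporting e.g. "52 genes; 7.6% of total DEGs".
#'
#' @param k Non-negative integer count (vectorised).
#' @param n Positive integer total.
#' @return Numeric percentage(s) with one decimal.
#' @examples
#' share_percent(52, 681)    # 7.6
#' share_percent(1109, 1196) # 92.7
#' @export
share_percent <- function(k, n) {
  .check_count(n, "n", min = 1L)
  if (!is.numeric(k) || anyNA(k) || any(k != as.integer(k)) || any(k < 0)) {
    stop("'k' must be non-negative integer(s)")
  }
  if (any(k > n)) stop("'k' must not exceed 'n'")
  floor(1000 * k / n + 0.5) / 10
}

#' Per-dataset differential expression table
#'
#' Computes, for every row of a genes-by-samples matrix, group means on
#' the normalized scale, the fold change, and a two-group t-test on
#' `log2(normalized value + pseudocount)`. Counts-per-million
#' normalization divides each column by its sum times 1e6.
#'
#' All-zero rows are retained with `p = 1` and flag `"allzero"`; rows with
#' zero variance in both groups but separated means get `p = 0` and flag
#' `"degenerate"`. The table is sorted by p ascending with ties broken by
#' identifier.
#'
#' @param mat Numeric genes-by-samples matrix with row and column names.
#' @param groups Group labels: either a vector aligned with the columns of
#'   `mat` or a named vector keyed by column name. Every column must be
#'   labelled with one of `case`/`control`.
#' @param test `"welch"` (default) or `"student"`.
#' @param normalize `"cpm"` (default) or `"none"`.
#' @param pseudocount Offset used both inside the log transform and in the
#'   fold change (default 0.5).
#' @param case,control The two labels used in `groups` (defaults `"case"`,
#'   `"control"`), so that e.g. WD/NC labelled designs can be analysed
#'   directly.
#' @return A `differential_table`: a data frame with columns `id`,
#'   `mean_case`, `mean_control`, `fold_change`, `log2fc`, `t`, `df`, `p`,
#'   `flag`.
#' @export
de_table <- function(mat, groups, test = c("welch", "student"),
                     normalize = c("cpm", "none"), pseudocount = 0.5,
                     case = "case", control = "control") {
  test <- match.arg(test)
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (anyNA(mat) || any(!is.finite(mat))) stop("matrix must be finite")
  if (!is.null(names(groups))) {
    if (is.null(colnames(mat)) || !all(colnames(mat) %in% names(groups))) {
      stop("missing group label for one or more samples")
    }
    groups <- groups[colnames(mat)]
  }
  if (length(groups) != ncol(mat)) {
    stop("'groups' must label every sample column")
  }
  groups <- as.character(groups)
  if (!all(groups %in% c(case, control))) {
    stop(sprintf("group labels must all be '%s' or '%s'", case, control))
  }
  i_case <- which(groups == case)
  i_ctrl <- which(groups == control)
  if (length(i_case) < 2L || length(i_ctrl) < 2L) {
    stop("each group needs at least two samples")
  }

  norm <- mat
  if (normalize == "cpm") {
    libsize <- colSums(mat)
    if (any(libsize <= 0)) stop("cannot CPM-normalize a column with sum <= 0")
    norm <- sweep(mat, 2L, libsize, "/") * 1e6
  }
  x <- log2(norm + pseudocount)
  r <- .t_rows(x[, i_case, drop = FALSE], x[, i_ctrl, drop = FALSE],
               pooled = (test == "student"))

  mean_case <- rowMeans(norm[, i_case, drop = FALSE])
  mean_control <- rowMeans(norm[, i_ctrl, drop = FALSE])
  allzero <- rowSums(mat != 0) == 0L

  flag <- rep("ok", nrow(mat))
  flag[r$degenerate & r$p == 0] <- "degenerate"

  fc <- rep(1, nrow(mat))
  l2 <- rep(0, nrow(mat))
  nz <- !allzero
  if (any(nz)) {
    f <- fold_change(mean_case[nz], mean_control[nz], pseudocount)
    fc[nz] <- f$fold_change
    l2[nz] <- f$log2fc
  }
  p <- r$p
  t <- r$t
  if (any(allzero)) {
    p[allzero] <- 1
    t[allzero] <- 0
    flag[allzero] <- "allzero"
  }

  out <- data.frame(
    id = rownames(mat), mean_case = mean_case, mean_control = mean_control,
    fold_change = fc, log2fc = l2, t = t, df = r$df, p = p, flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

# Internal: validate that a data frame carries the differential_table
# contract (used when tables are read back from disk).
.as_differential_table <- function(df) {
  need <- c("id", "mean_case", "mean_control", "fold_change", "log2fc",
            "t", "df", "p", "flag")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop("not a differential table; missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicated identifiers in table")
  if (any(df$p < 0 | df$p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  class(df) <- unique(c("differential_table", class(df)))
  df
}
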