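#' Area under the ROC curve for a ranking
#'
#' Computes the AUROC of a score against binary labels via the rank-sum
#' (Mann-Whitney) identity. Used to quantify how well a gene ranking
#' recovers a planted positive set in simulations.
#'
#' @param score Numeric vector; larger values should indicate stronger
#'   evidence for the positive class.
#' @param label Logical vector (or coercible) of the same length; `TRUE`
#'   marks positives.
#' @return AUROC in `[0, 1]`; ties contribute 1/2.
#' @export
ranking_auc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ranking_auc() needs at least one positive and one negative label")
  }
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Internal: assert a scalar probability lies strictly/weakly in [0,1].
.check_prob <- function(x, name, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  lo <- if (strict) x > 0 else x >= 0
  hi <- if (strict) x < 1 else x <= 1
  if (!lo || !hi) {
    stop(sprintf(
      "'%s' must lie in %s0, 1%s (got %g)",
      name, if (strict) "(" else "[", if (strict) ")" else "]", x
    ))
  }
  invisible(x)
}

# Internal: positive scalar check.
.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name))
  }
  invisible(x)
}

# Internal: positive integer-valued scalar.
.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
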