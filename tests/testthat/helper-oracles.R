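# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Poisson-binomial upper tail by brute-force enumeration of all 2^D
# success/failure outcomes (vectorised over the outcome index).
pb_enum_tail <- function(d, rates) {
  D <- length(rates)
  m <- 0:(2^D - 1)
  prob <- rep(1, length(m))
  cnt <- integer(length(m))
  for (j in seq_len(D)) {
    bit <- (m %/% 2^(j - 1)) %% 2
    prob <- prob * ifelse(bit == 1, rates[j], 1 - rates[j])
    cnt <- cnt + bit
  }
  sum(prob[cnt >= d])
}

# Benjamini-Hochberg by the literal step-up formula:
# q_i = min_{j >= i} p_(j) * m / j, clipped to 1, in input order.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- cummin(rev(p[o] * m / seq_len(m)))
  q_sorted <- rev(pmin(1, q_sorted))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# draws of the query from a universe 1..N whose first K elements are the
# reference set.
hyper_enum_tail <- function(N, K, n, k) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Build a minimal differential table by hand for consensome unit tests.
make_de_table <- function(ids, p, fc = rep(1, length(ids))) {
  data.frame(
    id = ids, mean_case = 1, mean_control = 1,
    fold_change = fc, log2fc = log2(fc), t = 0, df = 1, p = p,
    flag = "ok", stringsAsFactors = FALSE
  )
}

# Construct an ortholog pair table directly for rule-level tests.
make_pair_table <- function(hg, mg, lfc_h, p_h, lfc_m, p_m, ratio) {
  data.frame(
    human_gene = hg, mouse_gene = mg,
    human_log2fc = lfc_h, human_p = p_h,
    mouse_log2fc = lfc_m, mouse_p = p_m,
    human_case_mean = ratio, mouse_case_mean = 1,
    hm_ratio = ratio, stringsAsFactors = FALSE
  )
}
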