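test_that("welch and student t match stats::t.test on regular data", {
  a <- c(1.1, 2.0, 2.9, 1.8)
  b <- c(4.2, 5.1, 3.9, 4.8)
  w <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)

  s <- student_t(a, b)
  refs <- t.test(a, b, var.equal = TRUE)
  expect_equal(s$t_stat, unname(refs$statistic), tolerance = 1e-12)
  expect_equal(s$df, unname(refs$parameter))
  expect_equal(s$p, refs$p.value, tolerance = 1e-10)

  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(2:9, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:9, 1), mean = runif(1, -2, 2))
    expect_equal(welch_t(x, y)$p, t.test(x, y)$p.value, tolerance = 1e-10)
    expect_equal(student_t(x, y)$p,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1 and swapping negates t", {
  a <- c(1, 2, 3)
  r <- welch_t(a, a)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p, 1)
  s <- student_t(c(1, 2), c(1, 2))
  expect_equal(s$t_stat, 0)
  expect_equal(s$p, 1)

  x <- c(0.3, 1.9, 2.2, 0.8)
  y <- c(1.4, 2.6, 3.3)
  expect_equal(student_t(x, y)$t_stat, -student_t(y, x)$t_stat)
  expect_equal(student_t(x, y)$p, student_t(y, x)$p)
})

test_that("zero-variance groups degenerate as specified", {
  r <- welch_t(c(0, 0, 0), c(5, 5, 5))
  expect_equal(r$p, 0)
  expect_identical(r$flag, "degenerate")
  eq <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t(1, c(1, 2)), "length")
  expect_error(student_t(c(1, 2, NA), c(1, 2)), "finite")
})

test_that("welch equals student when variances and sizes are equal", {
  a <- c(1.2, 3.4, 2.2, 5.0, 0.7)
  b <- a + 3 # identical variance, equal n
  w <- welch_t(a, b)
  s <- student_t(a, b)
  expect_equal(w$t_stat, s$t_stat)
  expect_equal(w$df, s$df)
  expect_equal(w$p, s$p)
})

test_that("fold change arithmetic and guards", {
  expect_equal(fold_change(10, 10, 0), list(fold_change = 1, log2fc = 0))
  expect_equal(fold_change(20, 10, 0), list(fold_change = 2, log2fc = 1))
  f <- fold_change(0, 10, 0.5)
  expect_equal(f$fold_change, 0.5 / 10.5)
  expect_equal(f$log2fc, log2(0.5 / 10.5))
  expect_error(fold_change(0, 0, 0), "zero")
  expect_error(fold_change(-1, 2, 0), "non-negative")
})

test_that("share_percent rounds half-up to one decimal", {
  expect_equal(share_percent(0, 10), 0)
  expect_equal(share_percent(1, 8), 12.5)
  expect_equal(share_percent(1, 16), 6.3) # 6.25 rounds up
  expect_equal(share_percent(c(1, 2), 3), c(33.3, 66.7))
  expect_error(share_percent(5, 4), "exceed")
  expect_error(share_percent(1, 0), "integer")
})

test_that("de_table flags, sorts and is invariant to column order/scale", {
  m <- rbind(
    G1 = c(40, 40, 40, 10, 10, 10),
    G2 = c(0, 0, 0, 0, 0, 0),
    G3 = c(12, 15, 9, 11, 16, 10)
  )
  colnames(m) <- paste0("s", 1:6)
  grp <- setNames(rep(c("case", "control"), each = 3), colnames(m))
  tab <- de_table(m, grp, normalize = "none", pseudocount = 0)
  g1 <- tab[tab$id == "G1", ]
  expect_identical(g1$flag, "degenerate")
  expect_equal(g1$log2fc, 2)
  expect_equal(g1$p, 0)
  g2 <- tab[tab$id == "G2", ]
  expect_identical(g2$flag, "allzero")
  expect_equal(g2$p, 1)
  expect_false(is.unsorted(tab$p))

  set.seed(7)
  m2 <- matrix(rnbinom(200 * 8, mu = 50, size = 5), nrow = 200,
               dimnames = list(sprintf("G%03d", 1:200), paste0("s", 1:8)))
  grp2 <- setNames(rep(c("case", "control"), each = 4), colnames(m2))
  t1 <- de_table(m2, grp2)
  perm <- sample(ncol(m2))
  t2 <- de_table(m2[, perm], grp2)
  expect_equal(t1, t2)
  t3 <- de_table(m2 * 7, grp2) # global scaling, cpm normalization
  expect_equal(t1$p, t3$p, tolerance = 1e-9)

  expect_error(de_table(m2, grp2[-1]), "label")
  expect_error(de_table(m2, setNames(rep("case", 8), colnames(m2))), "two")
})

test_that("type-I error is controlled on null simulations", {
  cfg <- simulation_config(frac_true = 0, n_datasets = 20, seed = 101)
  sim <- simulate_consensome_studies(cfg)
  p <- unlist(lapply(sim$collection$datasets, function(t) t$p))
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})

test_that("planted log2 fold changes are recovered by de_table", {
  cfg <- simulation_config(seed = 103)
  sim <- simulate_consensome_studies(cfg)
  dir <- sim$truth$direction
  errs <- unlist(lapply(names(sim$collection$datasets), function(id) {
    tab <- sim$collection$datasets[[id]]
    hit <- sim$truth$per_dataset_perturbed[[id]]
    est <- tab$log2fc[match(hit, tab$id)]
    est * dir[hit] # orient so the planted value is +1
  }))
  expect_lt(abs(median(errs) - 1), 0.25)
})
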