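test_that("wilcoxon rank-sum matches exact enumeration without ties", {
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  ## every group-size combination up to 6 vs 6
  set.seed(14)
  for (n1 in 1:6) for (n2 in 1:6) {
    v <- sample(seq_len(n1 + n2) + runif(n1 + n2, 0, 0.1))
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(wilcoxon_ranksum(x, y), ranksum_enum_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("wilcoxon handles ties, symmetry and empty groups", {
  expect_equal(wilcoxon_ranksum(c(1, 2), c(1, 2)), 1)
  x <- c(3.2, 1.5, 4.4, 2.2); y <- c(5.1, 0.7, 3.9)
  expect_equal(wilcoxon_ranksum(x, y), wilcoxon_ranksum(y, x))
  expect_true(is.na(wilcoxon_ranksum(numeric(0), y)))
  expect_true(is.na(wilcoxon_ranksum(c(NA_real_), y)))
})

test_that("vectorised rank-sum equals wilcox.test's normal approximation", {
  set.seed(25)
  m <- matrix(rnorm(50 * 20), 50, 20)
  m[7, ] <- round(m[7, ])  # introduce ties in one row
  is_case <- rep(c(TRUE, FALSE), each = 10)
  p_vec <- cfdiff:::.ranksum_p_rows(m, is_case)
  p_ref <- apply(m, 1L, function(r)
    suppressWarnings(stats::wilcox.test(r[is_case], r[!is_case],
                                        exact = FALSE,
                                        correct = TRUE)$p.value))
  expect_equal(unname(p_vec), unname(p_ref), tolerance = 1e-12)
})

test_that("log-gamma gaussian approximation uses both branches", {
  expect_equal(gamma_log_gaussian(2, 1), list(mean = 0, var = 1))
  expect_equal(gamma_log_gaussian(1, 2), list(mean = log(0.5), var = 1))
  expect_error(gamma_log_gaussian(0, 1), "positive")
  ## Monte-Carlo oracle at high shape
  set.seed(40)
  draws <- log(rgamma(1e6, shape = 100, rate = 1))
  ap <- gamma_log_gaussian(100, 1)
  expect_lt(abs(ap$mean - mean(draws)) / abs(mean(draws)), 0.02)
  expect_lt(abs(ap$var - var(draws)) / var(draws), 0.02)
})

test_that("meta average is the precision-weighted closed form", {
  expect_equal(meta_average(c(1, 3), c(1, 1)),
               list(eta_bar = 2, var_bar = 0.5))
  expect_equal(meta_average(5, 0.3), list(eta_bar = 5, var_bar = 0.3))
  dom <- meta_average(c(0, 10), c(1, 1e6))
  expect_lt(dom$eta_bar, 1e-4)
  ## order invariance and variance dominance
  set.seed(5)
  e <- rnorm(8); v <- rgamma(8, 2)
  o <- sample(8)
  expect_equal(meta_average(e, v), meta_average(e[o], v[o]))
  expect_lte(meta_average(e, v)$var_bar, min(v))
  ## against independently written sums
  expect_equal(meta_average(e, v)$eta_bar, sum(e / v) / sum(1 / v))
  expect_error(meta_average(numeric(0), numeric(0)), "empty")
})

test_that("ade_se meta-analyses individuals and standardises Z", {
  a <- ade_se(0.5, 0.25)
  expect_equal(a$ade, 0.5)
  expect_equal(a$se, 0.5)
  expect_equal(a$z, 1)
  expect_equal(a$z_individual, 1)
  expect_equal(ade_se(c(0, 0, 0), c(1, 2, 3))$ade, 0)
  ## random inputs against direct formulas, with missing individuals
  set.seed(6)
  m <- rnorm(10); v <- rgamma(10, 2)
  m[c(2, 9)] <- NA; v[c(2, 9)] <- NA
  ok <- !is.na(m)
  a <- ade_se(m, v)
  expect_equal(a$ade, sum(m[ok] / v[ok]) / sum(1 / v[ok]))
  expect_equal(a$se, sqrt(1 / sum(1 / v[ok])))
  expect_equal(a$z_individual[ok], m[ok] / sqrt(v[ok]))
  av <- ade_se(m, v, z_scale = "var")
  expect_equal(av$z_individual[ok], m[ok] / v[ok])
  all_na <- ade_se(c(NA_real_, NA_real_), c(NA_real_, NA_real_))
  expect_true(is.na(all_na$ade) && is.na(all_na$se))
})

test_that("multiplicity adjustments follow their definitions", {
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.03), "bh"),
               rep(0.03, 3))
  for (m in c("bh", "storey_q", "bonferroni", "holm"))
    expect_equal(adjust_multiplicity(rep(1, 5), m), rep(1, 5))
  expect_error(adjust_multiplicity(c(0.5, 0), "bh"), "\\(0, 1\\]")
  ## Storey q never exceeds BH when pi0 <= 1
  set.seed(8)
  p <- c(runif(80), runif(20, 0, 0.01))
  q_st <- adjust_multiplicity(p, "storey_q")
  q_bh <- adjust_multiplicity(p, "bh")
  expect_true(all(q_st <= q_bh + 1e-12))
  ## direct independent computation with the fixed lambda = 0.5 estimator
  pi0 <- min(1, sum(p > 0.5) / (0.5 * length(p)))
  m <- length(p)
  o <- order(p)
  q_direct <- numeric(m)
  for (i in seq_len(m))
    q_direct[o[i]] <- min(1, pi0 * min(m * p[o][i:m] / (i:m)))
  expect_equal(q_st, q_direct, tolerance = 1e-12)
  ## q-values are monotone in the p-value ordering
  expect_true(all(diff(q_st[order(p)]) >= -1e-12))
})

test_that("auprc integrates the precision-recall curve", {
  flags <- c(rep(TRUE, 5), rep(FALSE, 20))
  perfect <- 25:1
  expect_equal(auprc(perfect, flags), 1.0)
  reversed <- 1:25
  expect_equal(auprc(reversed, flags), auprc_enum(reversed, flags))
  ## random scores on random flag sets: equals the enumeration oracle
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    fl <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(fl) || all(fl)) next
    sc <- sample(n, replace = TRUE)  # with ties
    expect_equal(auprc(sc, fl), auprc_enum(sc, fl), tolerance = 1e-12)
  }
  expect_error(auprc(1:3, c(TRUE, TRUE, TRUE)), "non-causal")
})

test_that("random rankings score near prevalence", {
  set.seed(11)
  vals <- replicate(100, {
    fl <- c(rep(TRUE, 50), rep(FALSE, 9950))
    auprc(rnorm(10000), fl)
  })
  expect_lt(abs(mean(vals) - 0.005), 0.002)
})

test_that("empirical fdr counts non-causal discoveries", {
  q <- c(rep(0.001, 10), rep(0.5, 10))
  flags <- c(rep(TRUE, 8), rep(FALSE, 12))
  expect_equal(empirical_fdr(q, flags), 0.2)
  expect_equal(empirical_fdr(rep(0.9, 5), flags[1:5]), 0)
  expect_equal(empirical_fdr(c(0.001, 0.002), c(FALSE, FALSE)), 1.0)
})
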