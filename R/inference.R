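#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. Missing values are dropped; an empty group gives
#' `NA`.
#'
#' @param values_case,values_ctrl numeric vectors.
#' @return two-sided p-value in (0, 1], or `NA` if a group is empty.
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
wilcoxon_ranksum <- function(values_case, values_ctrl) {
  x <- values_case[!is.na(values_case)]
  y <- values_ctrl[!is.na(values_ctrl)]
  if (!length(x) || !length(y)) return(NA_real_)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  min(p, 1)
}

## vectorised normal-approximation rank-sum p-values for every row of a
## genes x individuals matrix; identical to wilcox.test's non-exact path
## (tie correction + continuity correction). Used by the pipeline, where
## sample sizes make the normal path the one wilcox.test would take.
.ranksum_p_rows <- function(mat, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  n <- n1 + n2
  apply_fun <- function(row) {
    if (anyNA(row)) {
      ok <- !is.na(row)
      return(wilcoxon_ranksum(row[is_case & ok], row[!is_case & ok]))
    }
    r <- rank(row)
    w <- sum(r[is_case]) - n1 * (n1 + 1) / 2
    nt <- table(r)
    tie_term <- sum(nt^3 - nt)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - n1 * n2 / 2
    z <- z - sign(z) * 0.5
    min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  }
  apply(mat, 1L, apply_fun)
}

#' Gaussian approximation of a log-Gamma random variable
#'
#' Local quadratic (Laplace) approximation of the density of
#' \eqn{\phi = \ln\lambda} when \eqn{\lambda \sim \mathrm{Gamma}(\alpha, \beta)}:
#' for \eqn{\alpha > 1} the expansion at the mode gives
#' \eqn{\phi \approx N(\ln((\alpha-1)/\beta),\ (\alpha-1)^{-1})}; for
#' \eqn{0 < \alpha \le 1} the expansion is taken at \eqn{\lambda = \alpha/\beta},
#' giving \eqn{N(\ln(\alpha/\beta),\ \alpha^{-1})}.
#'
#' @param alpha,beta Gamma shape and rate (vectors recycled; must be > 0).
#' @return list with numeric `mean` and `var`.
#' @export
gamma_log_gaussian <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive")
  hi <- alpha > 1
  m <- ifelse(hi, log(alpha - 1) - log(beta), log(alpha) - log(beta))
  v <- ifelse(hi, 1 / (alpha - 1), 1 / alpha)
  list(mean = m, var = v)
}

#' Inverse-variance (precision-weighted) meta-analytic average
#'
#' Combines per-individual Gaussian posteriors \eqn{N(\eta_i, \sigma_i^2)}
#' into a single summary Gaussian by precision weighting:
#' \deqn{\bar\eta = \frac{\sum_i \eta_i/\sigma_i^2}{\sum_i 1/\sigma_i^2},
#'       \qquad \bar\sigma^2 = \frac{1}{\sum_i 1/\sigma_i^2}.}
#'
#' @param etas numeric vector of means.
#' @param vars numeric vector of variances (> 0), same length.
#' @return list with `eta_bar` and `var_bar`.
#' @export
meta_average <- function(etas, vars) {
  if (!length(etas)) stop("empty input")
  if (length(etas) != length(vars)) stop("etas and vars lengths differ")
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop("variances must be positive and finite")
  w <- 1 / vars
  list(eta_bar = sum(etas * w) / sum(w), var_bar = 1 / sum(w))
}

#' Average disease effect and standard error across individuals
#'
#' Meta-analyses the per-individual posterior summaries of the log residual
#' disease effect: ADE is the inverse-variance-weighted mean of
#' \eqn{E[\ln\delta_{gi}]} with weights \eqn{1/V[\ln\delta_{gi}]}, SE the
#' square root of the combined variance, and the gene-level Wald statistic
#' is ADE/SE. Per-individual statistics are also returned, by default in
#' the standardised form \eqn{E[\ln\delta]/\sqrt{V[\ln\delta]}}
#' (`z_scale = "sd"`); `z_scale = "var"` divides by the variance instead.
#'
#' @param ln_delta_mean,ln_delta_var numeric vectors over individuals;
#'   `NA` pairs (individuals without reads) are dropped.
#' @param z_scale `"sd"` (Wald convention, default) or `"var"`.
#' @return list with `ade`, `se`, `z` (= ade/se) and `z_individual`;
#'   all `NA` when no individual contributes.
#' @export
ade_se <- function(ln_delta_mean, ln_delta_var, z_scale = c("sd", "var")) {
  z_scale <- match.arg(z_scale)
  ok <- !is.na(ln_delta_mean) & !is.na(ln_delta_var)
  if (!any(ok))
    return(list(ade = NA_real_, se = NA_real_, z = NA_real_,
                z_individual = rep(NA_real_, length(ln_delta_mean))))
  ma <- meta_average(ln_delta_mean[ok], ln_delta_var[ok])
  zi <- if (z_scale == "sd") ln_delta_mean / sqrt(ln_delta_var)
        else ln_delta_mean / ln_delta_var
  list(ade = ma$eta_bar, se = sqrt(ma$var_bar),
       z = ma$eta_bar / sqrt(ma$var_bar), z_individual = zi)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (`"bh"`), Storey q-values with the fixed
#' \eqn{\lambda = 0.5} estimator \eqn{\hat\pi_0 = \min(1,\ \#\{p > 0.5\} /
#' (0.5\,m))} (`"storey_q"`), or the family-wise error controls
#' `"bonferroni"` and `"holm"`.
#'
#' @param p_values numeric vector in (0, 1].
#' @param method adjustment method.
#' @return adjusted values, same length and order as the input.
#' @export
adjust_multiplicity <- function(p_values,
                                method = c("bh", "storey_q", "bonferroni",
                                           "holm")) {
  method <- match.arg(method)
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  if (method == "bh") return(p.adjust(p, "BH"))
  if (method == "bonferroni") return(p.adjust(p, "bonferroni"))
  if (method == "holm") return(p.adjust(p, "holm"))
  ## Storey q-values, pi0 at fixed lambda = 0.5
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  pi0 <- min(1, sum(pp > 0.5) / (0.5 * m))
  o <- order(pp, decreasing = TRUE)
  qq <- pi0 * m * pp[o] / rank(pp, ties.method = "max")[o]
  qq <- pmin(1, cummin(qq))
  q[ok][o] <- qq
  q
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall along the ranking
#' induced by `scores` (higher = more likely causal). Tied scores are
#' collapsed into a single threshold step, i.e. averaged.
#'
#' @param scores numeric ranking scores.
#' @param causal_flags logical (or 0/1) truth labels, same length.
#' @return area in \[0, 1\].
#' @export
auprc <- function(scores, causal_flags) {
  flags <- as.logical(causal_flags)
  if (length(scores) != length(flags)) stop("length mismatch")
  ok <- !is.na(scores) & !is.na(flags)
  scores <- scores[ok]; flags <- flags[ok]
  np <- sum(flags); nn <- sum(!flags)
  if (np == 0L || nn == 0L)
    stop("need at least one causal and one non-causal gene")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; f <- flags[o]
  tp <- cumsum(f); fp <- cumsum(!f)
  last <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * (prec + c(prec[1L], prec[-length(prec)])) / 2)
}

#' Empirical false discovery rate at a q-value cutoff
#'
#' Fraction of truly non-causal genes among those declared significant
#' (`q < cutoff`); defined as 0 when nothing is discovered.
#'
#' @param q_values estimated q-values.
#' @param causal_flags logical truth labels, same length.
#' @param cutoff significance cutoff (default 0.01).
#' @return value in \[0, 1\].
#' @export
empirical_fdr <- function(q_values, causal_flags, cutoff = 0.01) {
  flags <- as.logical(causal_flags)
  disc <- !is.na(q_values) & q_values < cutoff
  if (!any(disc)) return(0)
  sum(disc & !flags) / sum(disc)
}
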