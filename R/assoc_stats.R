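## Contingency statistics and quasi-likelihood trend models.

#' Pearson's chi-squared test of independence
#'
#' No continuity correction; expected counts from row/column margins.
#'
#' @param table Matrix of nonnegative integer counts (r x c).
#' @return Object of class `contingency_result`: observed, statistic_name,
#'   statistic, df, p.
#' @export
pearson_chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(observed = table, statistic_name = "pearson_chi2",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                 p = unname(ht$p.value)),
            class = "contingency_result")
}

## Fisher's exact test, implemented directly on the (noncentral)
## hypergeometric distribution so that whole margin families can be
## evaluated in one vectorized pass.

# support and central pmf of table cell a given margins (r1, c1, N)
hyper_support <- function(r1, c1, N) {
  max(0L, r1 + c1 - N):min(r1, c1)
}

# noncentral hypergeometric pmf over the support, odds ratio psi
nchyper_pmf <- function(supp, r1, c1, N, psi) {
  logw <- lchoose(r1, supp) + lchoose(N - r1, c1 - supp) + supp * log(psi)
  w <- exp(logw - max(logw))
  w / sum(w)
}

# conditional MLE of the odds ratio: solve E_psi[A] = a (monotone in psi)
cond_mle_or <- function(a, supp, r1, c1, N) {
  if (length(supp) == 1L) return(NA_real_)  # degenerate margins
  if (a == min(supp)) return(0)
  if (a == max(supp)) return(Inf)
  f <- function(logpsi) {
    sum(supp * nchyper_pmf(supp, r1, c1, N, exp(logpsi))) - a
  }
  exp(stats::uniroot(f, c(-40, 40), tol = 1e-10)$root)
}

# exact conditional CI: psi_lo solves P(A >= a | psi) = alpha/2,
# psi_hi solves P(A <= a | psi) = alpha/2 (one-sided at the boundary)
cond_ci <- function(a, supp, r1, c1, N, conf = 0.95) {
  alpha <- (1 - conf) / 2
  if (length(supp) == 1L) return(c(0, Inf))
  p_ge <- function(logpsi) sum(nchyper_pmf(supp, r1, c1, N,
                                           exp(logpsi))[supp >= a])
  p_le <- function(logpsi) sum(nchyper_pmf(supp, r1, c1, N,
                                           exp(logpsi))[supp <= a])
  lo <- if (a == min(supp)) 0 else
    exp(stats::uniroot(function(lp) p_ge(lp) - alpha, c(-45, 45),
                       tol = 1e-10)$root)
  hi <- if (a == max(supp)) Inf else
    exp(stats::uniroot(function(lp) p_le(lp) - alpha, c(-45, 45),
                       tol = 1e-10)$root)
  c(lo, hi)
}

# two-sided p for every value of a in the support at once (vectorized over
# the margin family); ties handled with the conventional (1 + eps) guard
fisher_p_family <- function(supp, r1, c1, N) {
  pmf <- stats::dhyper(supp, c1, N - c1, r1)
  vapply(seq_along(supp),
         function(i) sum(pmf[pmf <= pmf[i] * (1 + 1e-7)]),
         numeric(1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table; odds ratio by conditional maximum likelihood
#' on the noncentral hypergeometric distribution, with the exact conditional
#' 95% CI. With a zero cell the OR is reported on the extended scale (0 or
#' Inf) with a one-sided CI bound. The sample odds ratio (ad/bc) is also
#' reported.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Object of class `contingency_result` with `odds_ratio`
#'   (conditional MLE), `sample_odds_ratio`, `ci95`, `p`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop("`table` must be a 2x2 matrix of nonnegative integers",
         call. = FALSE)
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); N <- sum(table)
  supp <- hyper_support(r1, c1, N)
  p <- if (length(supp) == 1L) 1 else
    min(fisher_p_family(supp, r1, c1, N)[match(a, supp)], 1)
  or <- cond_mle_or(a, supp, r1, c1, N)
  ci <- cond_ci(a, supp, r1, c1, N)
  s_or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(observed = table, statistic_name = "fisher_exact",
                 statistic = NA_real_, df = NA_integer_,
                 odds_ratio = or, sample_odds_ratio = s_or,
                 ci95 = ci, p = p),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(x$statistic_name, ": ", sep = "")
  if (!is.na(x$statistic)) cat("statistic =", signif(x$statistic, 4),
                               "df =", x$df, "")
  if (!is.na(x$odds_ratio)) cat("OR =", signif(x$odds_ratio, 3),
                                "95% CI [", signif(x$ci95[1], 3), ",",
                                signif(x$ci95[2], 3), "] ")
  cat("p =", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}

#' Quasi-likelihood trend model
#'
#' Fits a quasi-binomial (logit link) or quasi-Poisson (log link) GLM of a
#' response on a single predictor. Dispersion is the Pearson chi-squared
#' statistic over residual df; standard errors are scaled by its square
#' root. Unbounded coefficients (separation) are flagged rather than
#' silently returned.
#'
#' @param response For quasi-binomial: successes (with `trials`), a
#'   proportion in `[0,1]` (with `trials` as weights), or a binary vector.
#'   For quasi-Poisson: nonnegative counts.
#' @param predictor Numeric or factor predictor.
#' @param family "quasibinomial" or "quasipoisson".
#' @param trials Binomial trial counts (quasi-binomial only).
#' @return Object of class `trend_fit`: family, coefficient (for the
#'   predictor), se, dispersion, p, separation flag, and the underlying glm.
#' @export
fit_quasi_glm <- function(response, predictor,
                          family = c("quasibinomial", "quasipoisson"),
                          trials = NULL) {
  family <- match.arg(family)
  if (length(unique(predictor)) < 2L) {
    stop("predictor must take at least two distinct values", call. = FALSE)
  }
  dat <- data.frame(y = response, x = predictor)
  fit <- if (family == "quasibinomial" && !is.null(trials)) {
    dat$trials <- trials
    stats::glm(cbind(y, trials - y) ~ x, data = dat,
               family = stats::quasibinomial())
  } else {
    stats::glm(y ~ x, data = dat,
               family = if (family == "quasibinomial")
                 stats::quasibinomial() else stats::quasipoisson())
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  j <- 2L  # single-predictor model: first non-intercept term
  separation <- !fit$converged || any(abs(coefs[-1, "Estimate"]) > 15)
  structure(list(family = family,
                 coefficient = coefs[j, "Estimate"],
                 se = coefs[j, "Std. Error"],
                 dispersion = sm$dispersion,
                 p = coefs[j, 4],
                 coefficients = coefs,
                 separation = separation,
                 glm = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(x$family, "trend: beta =", signif(x$coefficient, 4),
      "SE =", signif(x$se, 3), "dispersion =", signif(x$dispersion, 3),
      "p =", format.pval(x$p, digits = 3), "\n")
  if (x$separation) cat("warning: possible separation (unbounded coefficient)\n")
  invisible(x)
}
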