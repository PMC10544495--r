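## Binomial GLMM with a single (patient) random intercept, fitted by
## adaptive Gauss-Hermite quadrature; probability-scale average marginal
## effects integrate over the estimated random-intercept distribution.
## The linear mixed model for biopsy day wraps lme4::lmer.

# Gauss-Hermite nodes/weights (weight function exp(-z^2)) via Golub-Welsch
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# adaptive GH marginal log-likelihood of a random-intercept binomial GLMM.
# y: successes; size: trials (1 for Bernoulli); group: contiguous integers
# 1..G. One quadrature node is the Laplace approximation. Vectorized over
# groups (Newton mode-finding and node evaluation via rowsum).
agq_loglik <- function(beta, sigma, y, size, X, group, nodes = 15L) {
  gh <- gauss_hermite(nodes)
  eta0 <- drop(X %*% beta)
  sig2 <- max(sigma^2, 1e-12)
  G <- max(group)
  gf <- factor(group, levels = seq_len(G))
  u <- numeric(G)
  for (it in 1:50) {
    p <- stats::plogis(eta0 + u[group])
    g1 <- rowsum(y - size * p, gf)[, 1] - u / sig2
    g2 <- -rowsum(size * p * (1 - p), gf)[, 1] - 1 / sig2
    step <- g1 / g2
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- stats::plogis(eta0 + u[group])
  tau <- 1 / sqrt(rowsum(size * p * (1 - p), gf)[, 1] + 1 / sig2)
  H <- matrix(0, G, nodes)
  for (k in seq_len(nodes)) {
    uk <- u + sqrt(2) * tau * gh$nodes[k]
    pk <- stats::plogis(eta0 + uk[group])
    H[, k] <- rowsum(y * log(pk) + (size - y) * log1p(-pk), gf)[, 1] +
      stats::dnorm(uk, 0, sqrt(sig2), log = TRUE) +
      log(gh$weights[k]) + gh$nodes[k]^2
  }
  m <- apply(H, 1, max)
  ll_g <- log(sqrt(2) * tau) + m + log(rowSums(exp(H - m)))
  sum(ll_g) + sum(lchoose(size, y))
}

#' Fit a binomial GLMM with a patient random intercept
#'
#' Maximizes the marginal likelihood by adaptive Gauss-Hermite quadrature
#' (default 15 nodes) over a normal random intercept; one node is the
#' Laplace approximation. When more than 50 groups have more than 200
#' observations each, the fit falls back to Laplace with a warning.
#'
#' @param y Binary response (0/1), or a matrix `cbind(successes, failures)`.
#' @param x Predictor: factor (categorical, first level = reference) or
#'   numeric.
#' @param group Grouping identifier (patient).
#' @param nodes Number of quadrature nodes.
#' @return Object of class `glmm_fit`: `coefficients` (logit scale), `se`,
#'   `vcov` (of coefficients and log-sigma), `sigma` (random-intercept SD),
#'   `logLik`, `nodes`, `converged`, and for factor predictors
#'   `marginal_probs` (per-level probability, averaged over the random
#'   effect, with 95% CI).
#' @export
fit_binomial_glmm <- function(y, x, group, nodes = 15L) {
  if (is.matrix(y)) {
    size <- rowSums(y)
    y <- y[, 1]
  } else {
    size <- rep(1L, length(y))
  }
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("random effect unidentifiable: need at least 2 groups",
         call. = FALSE)
  }
  if (is.character(x)) x <- factor(x)
  if (is.factor(x) && any(table(x) == 0)) x <- droplevels(x)
  dat <- data.frame(x = x)
  X <- stats::model.matrix(~x, dat)
  big <- table(group)
  if (sum(big > 200) > 50 && nodes > 1L) {
    warning("many large groups: falling back to Laplace (1 node)")
    nodes <- 1L
  }
  start_glm <- stats::glm.fit(X, cbind(y, size - y),
                              family = stats::binomial())
  theta0 <- c(start_glm$coefficients, log_sigma = log(0.5))
  gi <- as.integer(group)
  negll <- function(theta) {
    k <- length(theta)
    -agq_loglik(theta[-k], exp(theta[k]), y, size, X, gi, nodes)
  }
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 200), hessian = TRUE)
  k <- length(opt$par)
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, k, k)
  })
  beta <- opt$par[-k]
  names(beta) <- colnames(X)
  sigma <- exp(opt$par[k])
  se <- sqrt(pmax(diag(vc), 0))
  fit <- structure(list(
    coefficients = beta,
    se = se[-k],
    sigma = unname(sigma),
    logLik = -opt$value,
    vcov = vc,
    nodes = nodes,
    converged = opt$convergence == 0L,
    x = x, y = y, size = size, X = X, group = gi
  ), class = "glmm_fit")
  if (!fit$converged) {
    warning("GLMM did not converge within 200 iterations")
    return(fit)
  }
  if (is.factor(x)) {
    lv <- levels(x)
    probs <- t(vapply(lv, function(l) {
      marginal_level_prob(fit, l, ci = TRUE)
    }, numeric(3)))
    colnames(probs) <- c("prob", "ci_low", "ci_high")
    fit$marginal_probs <- data.frame(level = lv, probs,
                                     row.names = NULL)
  }
  fit
}

#' Re-evaluate the marginal log-likelihood of a fitted GLMM
#'
#' Evaluates the adaptive-quadrature marginal log-likelihood at the fitted
#' (or supplied) parameters with any node count; `nodes = 1` gives the
#' Laplace approximation. Used to check quadrature refinement.
#'
#' @param fit A `glmm_fit`.
#' @param nodes Node count.
#' @param beta,sigma Optional parameter overrides.
#' @return Log-likelihood (scalar).
#' @export
glmm_loglik <- function(fit, nodes = fit$nodes, beta = fit$coefficients,
                        sigma = fit$sigma) {
  agq_loglik(beta, sigma, fit$y, fit$size, fit$X, fit$group, nodes)
}

# P(y=1 | eta) averaged over the random-intercept distribution
marginal_response <- function(eta, sigma, nodes = 15L) {
  gh <- gauss_hermite(nodes)
  vapply(eta, function(e) {
    sum(gh$weights * stats::plogis(e + sqrt(2) * sigma * gh$nodes)) / sqrt(pi)
  }, numeric(1))
}

level_eta <- function(fit, level) {
  dat <- data.frame(x = factor(level, levels = levels(fit$x)))
  drop(stats::model.matrix(~x, dat)[1, , drop = FALSE] %*% fit$coefficients)
}

# marginal probability for one predictor level, delta-method CI over
# (beta, log sigma)
marginal_level_prob <- function(fit, level, ci = FALSE, nodes = fit$nodes) {
  f <- function(theta) {
    k <- length(theta)
    b <- theta[-k]; s <- exp(theta[k])
    dat <- data.frame(x = factor(level, levels = levels(fit$x)))
    eta <- drop(stats::model.matrix(~x, dat)[1, , drop = FALSE] %*% b)
    marginal_response(eta, s, nodes)
  }
  theta <- c(fit$coefficients, log(max(fit$sigma, 1e-8)))
  p <- f(theta)
  if (!ci) return(p)
  gr <- num_grad(f, theta)
  se <- sqrt(max(drop(t(gr) %*% fit$vcov %*% gr), 0))
  c(p, max(p - 1.96 * se, 0), min(p + 1.96 * se, 1))
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Probability-scale average marginal effect
#'
#' For a categorical predictor, the AME of a level is the difference in the
#' response probability, integrated over the estimated random-intercept
#' distribution (same quadrature nodes as the fit), between that level and
#' the reference level. For a numeric predictor, the AME is the derivative
#' of the integrated response, averaged over the observed predictor values.
#' The CI uses the delta method, or a parametric bootstrap that redraws the
#' parameter vector from its estimated sampling distribution.
#'
#' @param fit A converged `glmm_fit`.
#' @param level For factor predictors: the level to contrast with the
#'   reference (default: all non-reference levels).
#' @param method "delta" or "bootstrap".
#' @param draws Bootstrap draw count (default 1000).
#' @param seed Seed for the bootstrap draws.
#' @return data.frame: level (or "slope"), ame, se, ci_low, ci_high.
#' @export
average_marginal_effect <- function(fit, level = NULL,
                                    method = c("delta", "bootstrap"),
                                    draws = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (method == "bootstrap" && draws <= 0) {
    stop("bootstrap draw count must be positive", call. = FALSE)
  }
  theta_hat <- c(fit$coefficients, log(max(fit$sigma, 1e-8)))
  ame_fun <- if (is.factor(fit$x)) {
    ref <- levels(fit$x)[1]
    if (is.null(level)) level <- setdiff(levels(fit$x), ref)
    function(theta, lv) {
      k <- length(theta); b <- theta[-k]; s <- exp(theta[k])
      eta_of <- function(l) {
        dat <- data.frame(x = factor(l, levels = levels(fit$x)))
        drop(stats::model.matrix(~x, dat)[1, , drop = FALSE] %*% b)
      }
      marginal_response(eta_of(lv), s, fit$nodes) -
        marginal_response(eta_of(ref), s, fit$nodes)
    }
  } else {
    level <- "slope"
    function(theta, lv) {
      k <- length(theta); b <- theta[-k]; s <- exp(theta[k])
      eta <- drop(fit$X %*% b)
      h <- 1e-4
      mean((marginal_response(eta + h * b[2], s, fit$nodes) -
            marginal_response(eta - h * b[2], s, fit$nodes)) / (2 * h))
    }
  }
  rows <- lapply(level, function(lv) {
    est <- ame_fun(theta_hat, lv)
    if (method == "delta") {
      gr <- num_grad(function(th) ame_fun(th, lv), theta_hat)
      se <- sqrt(max(drop(t(gr) %*% fit$vcov %*% gr), 0))
      data.frame(level = lv, ame = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 stringsAsFactors = FALSE)
    } else {
      set.seed(seed)
      L <- tryCatch(chol(fit$vcov), error = function(e) NULL)
      if (is.null(L)) stop("covariance not positive definite", call. = FALSE)
      sims <- vapply(seq_len(draws), function(i) {
        ame_fun(theta_hat + drop(t(L) %*% stats::rnorm(length(theta_hat))), lv)
      }, numeric(1))
      data.frame(level = lv, ame = est, se = stats::sd(sims),
                 ci_low = stats::quantile(sims, 0.025, names = FALSE),
                 ci_high = stats::quantile(sims, 0.975, names = FALSE),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("binomial GLMM (adaptive Gauss-Hermite,", x$nodes, "nodes)\n")
  cat("random-intercept SD:", signif(x$sigma, 4),
      " logLik:", signif(x$logLik, 8), "\n")
  print(data.frame(estimate = x$coefficients, se = x$se))
  if (!is.null(x$marginal_probs)) {
    cat("marginal probabilities (averaged over the random effect):\n")
    print(x$marginal_probs)
  }
  invisible(x)
}

#' Linear mixed model for biopsy day
#'
#' REML fit of `day ~ predictor + (1 | group)` via lme4. For a binary
#' predictor the probability-scale AME equals the fixed coefficient.
#'
#' @param day Numeric response (biopsy day, 5-7).
#' @param x Predictor (binary indicator or numeric).
#' @param group Grouping identifier (patient).
#' @return Object of class `lmm_fit`: coefficients, random-intercept SD,
#'   residual SD, `ame` (= the predictor coefficient) with SE, and the
#'   underlying lme4 fit.
#' @export
fit_lmm <- function(day, x, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("random effect unidentifiable: need at least 2 groups",
         call. = FALSE)
  }
  dat <- data.frame(day = day, x = x, g = group)
  fit <- suppressMessages(lme4::lmer(day ~ x + (1 | g), data = dat,
                                     REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = lme4::fixef(fit),
    group_sd = vc$sdcor[vc$grp == "g"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    ame = unname(sm[2, "Estimate"]),
    ame_se = unname(sm[2, "Std. Error"]),
    lmer = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("LMM: AME =", signif(x$ame, 4), "SE =", signif(x$ame_se, 3),
      "| group SD =", signif(x$group_sd, 3),
      "residual SD =", signif(x$residual_sd, 3), "\n")
  invisible(x)
}
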