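#' Laplace-approximate log-likelihood of a Poisson random-intercept GLMM
#'
#' Counts are modelled as Poisson with a log link, fixed effects from
#' `formula`, and one Gaussian random intercept per site with standard
#' deviation `sigma_u`. The per-site integral over the random intercept
#' is approximated by Laplace's method at the conditional mode (found by
#' Newton iterations on the one-dimensional conditional log-posterior).
#' With `sigma_u = 0` the value equals the ordinary Poisson GLM
#' log-likelihood exactly.
#'
#' @param beta fixed-effect coefficients on the log scale.
#' @param sigma_u random-intercept standard deviation, `>= 0`.
#' @param dataset a [count_dataset()]; the response is the per-visit
#'   count.
#' @param formula one-sided fixed-effects formula over site and visit
#'   covariates (e.g. `~ year * snag_ba`).
#' @param tol Newton convergence tolerance on the mode (default 1e-10).
#' @return Laplace-approximate log-likelihood.
#' @export
glmm_laplace_loglik <- function(beta, sigma_u, dataset, formula,
                                tol = 1e-10) {
  stopifnot(inherits(dataset, "count_dataset"), sigma_u >= 0)
  X <- build_design_matrix(dataset, formula, level = "observation")
  y <- dataset$counts$count
  eta <- drop(X %*% beta)
  site <- match(dataset$counts$site, dataset$sites$site)
  if (sigma_u == 0) {
    return(sum(stats::dpois(y, exp(eta), log = TRUE)))
  }
  n_sites <- dataset$n_sites
  # Newton iterations on all site modes simultaneously
  u <- rep(0, n_sites)
  for (it in 1:100) {
    mu <- exp(eta + u[site])
    grad <- drop(rowsum(y - mu, site)) - u / sigma_u^2
    hess <- -drop(rowsum(mu, site)) - 1 / sigma_u^2
    step <- grad / hess
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  if (any(!is.finite(u))) stop("random-intercept mode search diverged")
  mu <- exp(eta + u[site])
  g <- drop(rowsum(stats::dpois(y, mu, log = TRUE), site)) +
    stats::dnorm(u, 0, sigma_u, log = TRUE)
  curvature <- drop(rowsum(mu, site)) + 1 / sigma_u^2
  sum(g + 0.5 * log(2 * pi) - 0.5 * log(curvature))
}

#' Fit a Poisson random-intercept GLMM by Laplace approximation
#'
#' Maximizes [glmm_laplace_loglik()] over the fixed effects and
#' `log(sigma_u)` jointly with BFGS, starting from the Poisson GLM
#' estimates.
#'
#' @inheritParams glmm_laplace_loglik
#' @return An object of class `glmm_fit` with `beta` (fixed effects),
#'   `sigma_u`, `loglik`, `vcov` (fixed effects + log sigma), `aicc`
#'   (effective sample size = number of sites), and `n_params`.
#' @export
fit_glmm <- function(dataset, formula) {
  X <- build_design_matrix(dataset, formula, level = "observation")
  y <- dataset$counts$count
  glm0 <- stats::glm.fit(X, y, family = stats::poisson())
  start <- c(glm0$coefficients, log_sigma = log(0.5))
  k <- length(start)
  negll <- function(par) {
    v <- tryCatch(
      -glmm_laplace_loglik(
        par[-k], exp(par[k]), dataset, formula
      ),
      error = function(e) Inf
    )
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(start, negll,
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-12)
  )
  hess <- stats::optimHess(opt$par, negll)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, k, k))
  nm <- c(colnames(X), "log_sigma_u")
  names(opt$par) <- nm
  dimnames(vc) <- list(nm, nm)
  ll <- -opt$value
  structure(
    list(
      formula = stats::as.formula(formula),
      beta = opt$par[-k], sigma_u = unname(exp(opt$par[k])),
      loglik = ll, vcov = vc, n_params = k,
      aicc = aicc(ll, k, dataset$n_sites),
      convergence = opt$convergence == 0L
    ),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson random-intercept GLMM (Laplace):",
      deparse(x$formula), "\n")
  se <- sqrt(diag(x$vcov))[seq_along(x$beta)]
  print(data.frame(estimate = round(x$beta, 4), se = round(se, 4)))
  cat(
    "  sigma_u =", format(x$sigma_u, digits = 4),
    " logLik =", format(x$loglik, digits = 6),
    " AICc =", format(x$aicc, digits = 6), "\n"
  )
  invisible(x)
}
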