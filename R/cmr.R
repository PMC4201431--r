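#' Huggins conditional log-likelihood
#'
#' Closed-population likelihood conditional on being captured at least
#' once, which drops abundance from the likelihood and allows covariates
#' on capture probability:
#' `prod_i prod_j p_ij^y_ij (1-p_ij)^(1-y_ij) / p*_i` with
#' `p*_i = 1 - prod_j (1 - p_ij)`.
#'
#' @param beta coefficients on the logit scale. For `"M0"` a single
#'   intercept; for `"Mt"` one coefficient per occasion; for a formula,
#'   the coefficients of the individual-covariate design matrix
#'   (capture probability constant across occasions).
#' @param histories a [capture_history_set()] (any number of occasions,
#'   typically the two visits of one closed season).
#' @param p_model `"M0"`, `"Mt"`, or a one-sided formula over the
#'   columns of `histories$site_covariates`.
#' @return Conditional log-likelihood.
#' @export
huggins_conditional_loglik <- function(beta, histories, p_model = "M0") {
  y <- histories$histories
  P <- huggins_p_matrix(beta, histories, p_model)
  pstar <- 1 - apply(1 - P, 1L, prod)
  if (any(pstar <= 0)) return(-Inf)
  sum(y * log(P) + (1 - y) * log(1 - P)) - sum(log(pstar))
}

# capture-probability matrix (individuals x occasions) for a p model
huggins_p_matrix <- function(beta, histories, p_model) {
  y <- histories$histories
  n <- nrow(y)
  J <- ncol(y)
  if (identical(p_model, "M0")) {
    stopifnot(length(beta) == 1L)
    matrix(stats::plogis(beta), n, J)
  } else if (identical(p_model, "Mt")) {
    stopifnot(length(beta) == J)
    matrix(stats::plogis(beta), n, J, byrow = TRUE)
  } else {
    f <- stats::as.formula(p_model)
    if (is.null(histories$site_covariates)) {
      stop("covariate p model needs site_covariates on the histories")
    }
    X <- stats::model.matrix(f, data = histories$site_covariates)
    stopifnot(length(beta) == ncol(X))
    matrix(stats::plogis(drop(X %*% beta)), n, J)
  }
}

huggins_n_par <- function(histories, p_model) {
  if (identical(p_model, "M0")) {
    1L
  } else if (identical(p_model, "Mt")) {
    ncol(histories$histories)
  } else {
    ncol(stats::model.matrix(
      stats::as.formula(p_model),
      data = histories$site_covariates
    ))
  }
}

#' Fit a Huggins closed-population model
#'
#' Maximizes the conditional-on-capture likelihood and derives abundance
#' by the Horvitz-Thompson estimator `N_hat = sum_i 1 / p*_i`, with
#' variance combining the Horvitz-Thompson term
#' `sum_i (1 - p*_i) / p*_i^2` and a delta-method term for the estimated
#' coefficients.
#'
#' @inheritParams huggins_conditional_loglik
#' @param n_sites optional number of sites, to also report per-site mean
#'   abundance.
#' @return An object of class `huggins_fit` with `beta`, `vcov`,
#'   `loglik`, `N_hat`, `se_N`, `n_params`, and (if `n_sites` is given)
#'   `N_per_site`, `se_per_site`.
#' @export
fit_huggins <- function(histories, p_model = "M0", n_sites = NULL) {
  stopifnot(inherits(histories, "capture_history_set"))
  k <- huggins_n_par(histories, p_model)
  negll <- function(b) {
    v <- -huggins_conditional_loglik(b, histories, p_model)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(rep(0, k), negll,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12)
  )
  # restart once from the optimum to polish the solution
  opt <- stats::optim(opt$par, negll,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12)
  )
  hess <- stats::optimHess(opt$par, negll)
  vc <- tryCatch(solve(hess), error = function(e) {
    matrix(NA_real_, k, k)
  })

  nhat_fun <- function(b) {
    P <- huggins_p_matrix(b, histories, p_model)
    pstar <- 1 - apply(1 - P, 1L, prod)
    sum(1 / pstar)
  }
  P <- huggins_p_matrix(opt$par, histories, p_model)
  pstar <- 1 - apply(1 - P, 1L, prod)
  unstable <- any(pstar < 1e-6)
  if (unstable) warning("capture probability near zero: unstable N_hat")
  N_hat <- sum(1 / pstar)
  var_ht <- sum((1 - pstar) / pstar^2)
  g <- drop(num_jacobian(function(b) nhat_fun(b), opt$par))
  var_beta <- if (all(is.finite(vc))) drop(g %*% vc %*% g) else NA_real_
  se_N <- sqrt(var_ht + max(var_beta, 0))

  out <- list(
    p_model = p_model, beta = opt$par, vcov = vc,
    loglik = -opt$value, n_params = k,
    N_hat = N_hat, se_N = se_N, pstar = pstar,
    n_observed = nrow(histories$histories),
    convergence = opt$convergence == 0L, unstable = unstable
  )
  if (!is.null(n_sites)) {
    out$n_sites <- n_sites
    out$N_per_site <- N_hat / n_sites
    out$se_per_site <- se_N / n_sites
  }
  structure(out, class = "huggins_fit")
}

#' @export
print.huggins_fit <- function(x, ...) {
  cat("Huggins closed-population model (", format(x$p_model), ")\n")
  cat(
    "  N_hat =", format(x$N_hat, digits = 4),
    "(SE", format(x$se_N, digits = 3), ") from",
    x$n_observed, "observed individuals\n"
  )
  if (!is.null(x$N_per_site)) {
    cat(
      "  per site:", format(x$N_per_site, digits = 3),
      "(SE", format(x$se_per_site, digits = 3), ")\n"
    )
  }
  invisible(x)
}

#' Horvitz-Thompson abundance from a Huggins fit
#'
#' @param fit a [fit_huggins()] result.
#' @return data.frame with `N_hat`, `se`, and per-site values when the
#'   fit knows the number of sites.
#' @export
huggins_abundance <- function(fit) {
  stopifnot(inherits(fit, "huggins_fit"))
  out <- data.frame(N_hat = fit$N_hat, se = fit$se_N)
  if (!is.null(fit$N_per_site)) {
    out$N_per_site <- fit$N_per_site
    out$se_per_site <- fit$se_per_site
  }
  out
}

# class labels for interval lengths, tolerant of floating-point jitter
interval_classes <- function(intervals) {
  r <- round(intervals, 6)
  match(r, unique(r))
}

# expand CJS parameters to per-interval survival and per-occasion
# recapture probability
cjs_expand <- function(beta, n_occ, intervals, phi_structure, p_structure,
                       p_groups = NULL) {
  n_int <- n_occ - 1L
  stopifnot(length(intervals) == n_int)
  if (phi_structure == "constant") {
    phi_unit <- stats::plogis(beta[1L])
    phi_int <- phi_unit^intervals # per-unit-time survival to the interval power
    i <- 1L
  } else if (phi_structure == "interval") {
    lens <- interval_classes(intervals)
    k <- max(lens)
    phi_int <- stats::plogis(beta[seq_len(k)])[lens]
    i <- k
  } else {
    stop("unknown phi_structure")
  }
  if (p_structure == "constant") {
    p_occ <- rep(stats::plogis(beta[i + 1L]), n_occ)
  } else if (p_structure == "time") {
    p_occ <- c(NA, stats::plogis(beta[i + seq_len(n_occ - 1L)]))
  } else if (p_structure == "group") {
    if (is.null(p_groups)) stop("p_groups required for grouped p")
    stopifnot(length(p_groups) == n_occ - 1L)
    k <- length(unique(p_groups))
    p_occ <- c(NA, stats::plogis(beta[i + seq_len(k)])[
      match(p_groups, unique(p_groups))
    ])
  } else {
    stop("unknown p_structure")
  }
  list(phi_int = phi_int, p_occ = p_occ)
}

cjs_n_par <- function(n_occ, intervals, phi_structure, p_structure,
                      p_groups = NULL) {
  k_phi <- switch(phi_structure,
    constant = 1L,
    interval = max(interval_classes(intervals))
  )
  k_p <- switch(p_structure,
    constant = 1L,
    time = n_occ - 1L,
    group = length(unique(p_groups))
  )
  k_phi + k_p
}

#' Cormack-Jolly-Seber log-likelihood with unequal intervals
#'
#' Conditional on first capture. Under the `"constant"` survival
#' structure a single per-unit-time (annual) apparent survival `phi` is
#' raised to the interval length, so unequal gaps between occasions are
#' handled as `phi^Delta`; the `"interval"` structure instead estimates
#' one interval-survival probability per distinct interval length
#' (intervals of the same length share a parameter). Recapture
#' probability may be constant, occasion-specific (`"time"`), or shared
#' within groups of occasions (`"group"`, e.g. one value per study
#' year).
#'
#' @param beta logit-scale parameters: survival block then recapture
#'   block.
#' @param histories a [capture_history_set()].
#' @param phi_structure `"constant"` or `"interval"`.
#' @param p_structure `"constant"`, `"time"`, or `"group"`.
#' @param p_groups for `"group"`: integer group label per recapture
#'   occasion (occasions 2..n).
#' @param intervals interval lengths (years); default
#'   `diff(occasion_times)`.
#' @return Log-likelihood.
#' @export
cjs_loglik <- function(beta, histories,
                       phi_structure = c("constant", "interval"),
                       p_structure = c("constant", "time", "group"),
                       p_groups = NULL, intervals = NULL) {
  stopifnot(inherits(histories, "capture_history_set"))
  phi_structure <- match.arg(phi_structure)
  p_structure <- match.arg(p_structure)
  y <- histories$histories
  n_occ <- ncol(y)
  if (is.null(intervals)) intervals <- diff(histories$occasion_times)
  pars <- cjs_expand(
    beta, n_occ, intervals, phi_structure, p_structure, p_groups
  )
  phi <- pars$phi_int # survival over interval j -> j+1
  p <- pars$p_occ # recapture probability at occasion j (j >= 2)

  # chi_j: probability an animal alive at occasion j is never seen again
  chi <- numeric(n_occ)
  chi[n_occ] <- 1
  if (n_occ >= 2L) {
    for (j in seq(n_occ - 1L, 1L)) {
      chi[j] <- (1 - phi[j]) + phi[j] * (1 - p[j + 1L]) * chi[j + 1L]
    }
  }
  ll <- 0
  for (i in seq_len(nrow(y))) {
    h <- y[i, ]
    f <- which(h == 1L)[1L]
    l <- max(which(h == 1L))
    if (f < l) {
      for (j in seq(f, l - 1L)) {
        ll <- ll + log(phi[j]) +
          h[j + 1L] * log(p[j + 1L]) +
          (1L - h[j + 1L]) * log(1 - p[j + 1L])
      }
    }
    ll <- ll + log(chi[l])
  }
  ll
}

#' Fit a Cormack-Jolly-Seber model
#'
#' @inheritParams cjs_loglik
#' @param histories a [capture_history_set()] with at least three
#'   occasions (two occasions leave survival and recapture confounded).
#' @return An object of class `cjs_fit` with logit-scale `beta`,
#'   `vcov`, back-transformed `phi` (per unit time for `"constant"`,
#'   per interval otherwise), `p`, `loglik`, `aicc` (effective sample
#'   size = number of individuals), and `n_params`.
#' @export
fit_cjs <- function(histories,
                    phi_structure = c("constant", "interval"),
                    p_structure = c("constant", "time", "group"),
                    p_groups = NULL, intervals = NULL) {
  stopifnot(inherits(histories, "capture_history_set"))
  phi_structure <- match.arg(phi_structure)
  p_structure <- match.arg(p_structure)
  n_occ <- ncol(histories$histories)
  if (n_occ < 3L) {
    stop("need at least three occasions: with two, survival and recapture are confounded")
  }
  if (is.null(intervals)) intervals <- diff(histories$occasion_times)
  k <- cjs_n_par(n_occ, intervals, phi_structure, p_structure, p_groups)
  negll <- function(b) {
    v <- -cjs_loglik(b, histories, phi_structure, p_structure,
      p_groups = p_groups, intervals = intervals
    )
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(rep(0, k), negll,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12)
  )
  hess <- stats::optimHess(opt$par, negll)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, k, k))
  pars <- cjs_expand(
    opt$par, n_occ, intervals, phi_structure, p_structure, p_groups
  )
  n_ind <- nrow(histories$histories)
  ll <- -opt$value
  structure(
    list(
      beta = opt$par, vcov = vc, loglik = ll, n_params = k,
      phi_structure = phi_structure, p_structure = p_structure,
      intervals = intervals, p_groups = p_groups,
      phi = if (phi_structure == "constant") {
        stats::plogis(opt$par[1L])
      } else {
        stats::plogis(opt$par[seq_len(max(interval_classes(intervals)))])
      },
      phi_interval = pars$phi_int,
      p = pars$p_occ[-1L],
      aicc = aicc(ll, k, n_ind),
      convergence = opt$convergence == 0L
    ),
    class = "cjs_fit"
  )
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(
    "CJS model: phi", x$phi_structure, "/ p", x$p_structure, "\n",
    " phi =", format(x$phi, digits = 3),
    if (x$phi_structure == "constant") "(per year)" else "(per interval)",
    "\n  interval survival:", format(x$phi_interval, digits = 3),
    "\n  p =", format(x$p, digits = 3),
    "\n  logLik =", format(x$loglik, digits = 6),
    " AICc =", format(x$aicc, digits = 6), "\n"
  )
  invisible(x)
}

#' Fit a capture-mark-recapture comparison model
#'
#' Thin dispatcher over [fit_huggins()] and [fit_cjs()].
#'
#' @param histories a [capture_history_set()].
#' @param model `"huggins-m0"`, `"huggins-mt"`, `"cjs-const"`, or
#'   `"cjs-interval"`.
#' @param ... passed on to the underlying fitter.
#' @return A `huggins_fit` or `cjs_fit`.
#' @export
fit_cmr <- function(histories,
                    model = c(
                      "huggins-m0", "huggins-mt",
                      "cjs-const", "cjs-interval"
                    ),
                    ...) {
  model <- match.arg(model)
  switch(model,
    "huggins-m0" = fit_huggins(histories, p_model = "M0", ...),
    "huggins-mt" = fit_huggins(histories, p_model = "Mt", ...),
    "cjs-const" = fit_cjs(histories, phi_structure = "constant", ...),
    "cjs-interval" = fit_cjs(histories, phi_structure = "interval", ...)
  )
}
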