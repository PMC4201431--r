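#' Zero-inflated Poisson probability mass function
#'
#' Mixture placing probability `psi` on a structural zero and
#' `1 - psi` on a Poisson count: `psi * 1{k=0} + (1-psi) * dpois(k, lambda)`.
#' Used as the distribution of initial latent abundance when some sites
#' hold no animals at all.
#'
#' @param k non-negative integer count(s).
#' @param lambda Poisson mean, positive.
#' @param psi zero-inflation probability in `[0, 1)`.
#' @return Probability mass at `k`.
#' @export
zip_pmf <- function(k, lambda, psi = 0) {
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  if (lambda <= 0) stop("lambda must be positive")
  if (psi < 0 || psi >= 1) stop("psi must be in [0, 1)")
  psi * (k == 0) + (1 - psi) * stats::dpois(k, lambda)
}

#' Latent abundance transition probability
#'
#' Probability that a site holding `n_prev` individuals holds `n_next`
#' one season later, when each individual survives (and stays) with
#' probability `omega` and recruits arrive as a Poisson count with mean
#' `gamma`:
#' `P(n_next | n_prev) = sum_s Binom(s; n_prev, omega) Pois(n_next - s; gamma)`.
#'
#' @param n_next,n_prev non-negative integers.
#' @param omega apparent survival probability in `[0, 1]`.
#' @param gamma recruitment rate, non-negative.
#' @return Transition probability.
#' @export
transition_pmf <- function(n_next, n_prev, omega, gamma) {
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  if (n_next < 0 || n_prev < 0) stop("abundances must be non-negative")
  s <- 0:min(n_prev, n_next)
  sum(stats::dbinom(s, n_prev, omega) * stats::dpois(n_next - s, gamma))
}

#' Tabulated transition matrix on 0..K
#'
#' `(K+1) x (K+1)` matrix with entry `[n_prev+1, n_next+1]` equal to
#' [transition_pmf()]. Rows sum to one minus the truncated tail mass;
#' an adequate `K` leaves a deficit below 1e-8.
#'
#' @inheritParams transition_pmf
#' @param K truncation bound for latent abundance.
#' @return Stochastic (up to truncation) matrix.
#' @export
build_transition_matrix <- function(omega, gamma, K) {
  if (K < 0) stop("K must be non-negative")
  m <- cpp_transition_matrix(omega, gamma, as.integer(K))
  dimnames(m) <- list(0:K, 0:K)
  m
}

#' Specify an N-mixture model
#'
#' Declares the covariate structure of each parameter of a single-season
#' or dynamic N-mixture model. Initial abundance `lambda` and recruitment
#' `gamma` use a log link over site covariates; detection `p` uses a
#' logit link over site x season x visit covariates; apparent survival
#' `omega` is a single logit-scale constant (covariates on survival are
#' not supported: with two seasons they are weakly identified and
#' routinely break convergence). The `ZIP` mixture adds one intercept-only
#' zero-inflation probability `psi`.
#'
#' @param lambda one-sided formula for initial abundance (log link).
#' @param gamma one-sided formula for recruitment (log link); ignored for
#'   single-season data.
#' @param omega must be `~ 1` (constant apparent survival, logit link).
#' @param p one-sided formula for detection (logit link).
#' @param mixture `"P"` (Poisson) or `"ZIP"` (zero-inflated Poisson).
#' @param K latent-abundance truncation bound; default
#'   `max(count) + 100` at fit time.
#' @param name optional label used in model-selection tables.
#' @return An object of class `nmix_spec`.
#' @export
nmix_spec <- function(lambda = ~1, gamma = ~1, omega = ~1, p = ~1,
                      mixture = c("ZIP", "P"), K = NULL, name = NULL) {
  mixture <- match.arg(mixture)
  omega <- stats::as.formula(omega)
  if (length(all.vars(omega)) > 0L) {
    stop("apparent survival is modelled as constant; use omega = ~ 1")
  }
  if (is.null(name)) {
    fmt <- function(f) {
      txt <- paste(deparse(stats::as.formula(f)[[2]]), collapse = "")
      if (txt == "1") "(.)" else paste0("(", txt, ")")
    }
    name <- paste0(
      "lam", fmt(lambda), " gam", fmt(gamma), " om(.) p", fmt(p),
      " [", mixture, "]"
    )
  }
  structure(
    list(
      lambda = stats::as.formula(lambda), gamma = stats::as.formula(gamma),
      omega = omega, p = stats::as.formula(p),
      mixture = mixture, K = K, name = name
    ),
    class = "nmix_spec"
  )
}

# Internal: assemble counts matrix and design matrices for a spec.
# Counts and detection rows are ordered site-major, season, visit.
nmix_frame <- function(dataset, spec, seasons = NULL) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(spec, "nmix_spec"))
  counts_df <- dataset$counts
  if (!is.null(seasons)) {
    keep <- counts_df$season %in% seasons
    counts_df <- counts_df[keep, , drop = FALSE]
    sub <- dataset
    sub$counts <- counts_df
    sub$n_seasons <- length(seasons)
  } else {
    sub <- dataset
  }
  T <- sub$n_seasons
  J <- sub$n_visits
  n <- sub$n_sites
  y <- matrix(counts_df$count, nrow = n, ncol = T * J, byrow = TRUE)
  X_lam <- build_design_matrix(sub, spec$lambda, level = "site")
  X_p <- build_design_matrix(sub, spec$p, level = "observation")
  X_gam <- if (T > 1L) {
    build_design_matrix(sub, spec$gamma, level = "site")
  } else {
    NULL
  }
  K <- spec$K
  if (is.null(K)) K <- max(y) + 100L
  if (K < max(y)) stop("K must be at least the maximum observed count")
  list(
    y = y, X_lam = X_lam, X_gam = X_gam, X_p = X_p,
    T = T, J = J, n_sites = n, K = as.integer(K),
    mixture = spec$mixture
  )
}

# Internal: split a packed coefficient vector into link-scale blocks.
nmix_unpack <- function(beta, fr) {
  k_lam <- ncol(fr$X_lam)
  k_psi <- if (fr$mixture == "ZIP") 1L else 0L
  k_gam <- if (fr$T > 1L) ncol(fr$X_gam) else 0L
  k_om <- if (fr$T > 1L) 1L else 0L
  k_p <- ncol(fr$X_p)
  stopifnot(length(beta) == k_lam + k_psi + k_gam + k_om + k_p)
  i <- 0L
  take <- function(k) {
    out <- beta[seq_len(k) + i]
    i <<- i + k
    out
  }
  list(
    b_lam = take(k_lam),
    psi_logit = if (k_psi) take(1L) else NULL,
    b_gam = if (k_gam) take(k_gam) else NULL,
    om_logit = if (k_om) take(1L) else NULL,
    b_p = take(k_p)
  )
}

nmix_param_names <- function(fr) {
  c(
    paste0("lambda:", colnames(fr$X_lam)),
    if (fr$mixture == "ZIP") "psi:(Intercept)",
    if (fr$T > 1L) paste0("gamma:", colnames(fr$X_gam)),
    if (fr$T > 1L) "omega:(Intercept)",
    paste0("p:", colnames(fr$X_p))
  )
}

# Internal: natural-scale parameters for each site/observation.
nmix_natural <- function(beta, fr) {
  bl <- nmix_unpack(beta, fr)
  lambda <- exp(drop(fr$X_lam %*% bl$b_lam))
  psi <- if (fr$mixture == "ZIP") stats::plogis(bl$psi_logit) else 0
  p <- matrix(
    stats::plogis(drop(fr$X_p %*% bl$b_p)),
    nrow = fr$n_sites, ncol = fr$T * fr$J, byrow = TRUE
  )
  gamma <- omega <- NULL
  if (fr$T > 1L) {
    gamma <- exp(drop(fr$X_gam %*% bl$b_gam))
    omega <- stats::plogis(bl$om_logit)
  }
  list(lambda = lambda, psi = psi, gamma = gamma, omega = omega, p = p)
}

nmix_loglik_frame <- function(beta, fr) {
  nat <- nmix_natural(beta, fr)
  mix_code <- if (fr$mixture == "ZIP") 1L else 0L
  if (fr$T == 1L) {
    cpp_single_loglik(fr$y, nat$lambda, nat$psi, nat$p, fr$K, mix_code)
  } else {
    gam <- matrix(nat$gamma, nrow = fr$n_sites, ncol = fr$T - 1L)
    om <- rep(nat$omega, fr$T - 1L)
    cpp_dyn_loglik(
      fr$y, nat$lambda, nat$psi, gam, om, nat$p,
      fr$K, fr$T, fr$J, mix_code
    )
  }
}

#' Single-season N-mixture log-likelihood
#'
#' For one closed season with `J` repeated visits:
#' `sum_i log sum_N mix(N; lambda_i, psi) prod_j Binom(n_ij; N, p_ij)`,
#' latent abundance truncated at `K`.
#'
#' @param beta packed coefficient vector on link scales, ordered as
#'   lambda block, psi (ZIP only), p block.
#' @param dataset a [count_dataset()] (restricted to one season via
#'   `season`).
#' @param spec an [nmix_spec()].
#' @param season which primary season to use (default the first).
#' @return Log-likelihood value.
#' @export
single_season_loglik <- function(beta, dataset, spec,
                                 season = NULL) {
  if (is.null(season)) season <- sort(unique(dataset$counts$season))[1L]
  fr <- nmix_frame(dataset, spec, seasons = season)
  nmix_loglik_frame(beta, fr)
}

#' Dynamic N-mixture log-likelihood
#'
#' Open-population likelihood over `T >= 2` primary seasons: the latent
#' abundance chain starts from a Poisson or zero-inflated Poisson state,
#' evolves by binomial survival plus Poisson recruitment between
#' seasons, and generates binomial counts at each secondary visit.
#' Evaluated by a forward pass over the truncated latent support 0..K;
#' sites are independent.
#'
#' @param beta packed coefficient vector on link scales, ordered as
#'   lambda block, psi (ZIP only), gamma block, omega, p block.
#' @param dataset a [count_dataset()] with at least two seasons.
#' @param spec an [nmix_spec()].
#' @return Log-likelihood value (`-Inf` if the data are impossible under
#'   the truncation or parameters).
#' @export
dynamic_loglik <- function(beta, dataset, spec) {
  fr <- nmix_frame(dataset, spec)
  if (fr$T < 2L) stop("dynamic likelihood needs at least two seasons")
  nmix_loglik_frame(beta, fr)
}

nmix_start_values <- function(fr) {
  mean1 <- mean(apply(fr$y[, seq_len(fr$J), drop = FALSE], 1L, max))
  st <- log(max(mean1, 0.25) / 0.4) # crude guess assuming p ~ 0.4
  out <- c(st, rep(0, ncol(fr$X_lam) - 1L))
  if (fr$mixture == "ZIP") out <- c(out, stats::qlogis(0.15))
  if (fr$T > 1L) {
    meanT <- mean(apply(
      fr$y[, (fr$T - 1L) * fr$J + seq_len(fr$J), drop = FALSE], 1L, max
    ))
    out <- c(
      out, log(max(meanT, 0.25)), rep(0, ncol(fr$X_gam) - 1L),
      stats::qlogis(0.5)
    )
  }
  c(out, stats::qlogis(0.35), rep(0, ncol(fr$X_p) - 1L))
}

#' Fit an N-mixture model by maximum likelihood
#'
#' Maximizes the single-season or dynamic N-mixture likelihood over the
#' packed link-scale coefficient vector with BFGS from several jittered
#' starting points, keeping the best converged solution. Standard errors
#' come from the inverse numerical Hessian at the optimum; AICc uses the
#' number of sites as the effective sample size.
#'
#' @param dataset a [count_dataset()].
#' @param spec an [nmix_spec()]. With `seasons` of length 1 a
#'   single-season model is fitted and `gamma`/`omega` are dropped.
#' @param starts number of random starts (default 5).
#' @param seasons optional subset of seasons to fit on.
#' @param start_values optional coefficient vector used as the first
#'   start (e.g. a previous fit, for bootstrap refits).
#' @param jitter_sd standard deviation of the Gaussian jitter applied to
#'   the extra starts.
#' @param check_K if `TRUE`, verify that raising `K` by 50 changes the
#'   maximized log-likelihood by less than 1e-6 and warn otherwise.
#' @return An object of class `nmix_fit` with elements `beta`, `loglik`,
#'   `vcov`, `aicc`, `n_params`, `convergence`, `spec`, and the model
#'   frame.
#' @export
fit_nmix <- function(dataset, spec, starts = 5L, seasons = NULL,
                     start_values = NULL, jitter_sd = 0.5,
                     check_K = FALSE) {
  fr <- nmix_frame(dataset, spec, seasons = seasons)
  negll <- function(b) {
    v <- -nmix_loglik_frame(b, fr)
    if (!is.finite(v)) 1e10 else v
  }
  base_start <- if (is.null(start_values)) nmix_start_values(fr) else start_values
  best <- NULL
  for (s in seq_len(max(1L, starts))) {
    st <- if (s == 1L) {
      base_start
    } else {
      base_start + stats::rnorm(length(base_start), 0, jitter_sd)
    }
    opt <- tryCatch(
      stats::optim(st, negll,
        method = "BFGS",
        control = list(maxit = 500, reltol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  converged <- best$convergence == 0L && best$value < 1e9

  hess <- tryCatch(
    stats::optimHess(best$par, negll),
    error = function(e) NULL
  )
  vc <- NULL
  se_ok <- FALSE
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) >= 0)) {
      se_ok <- TRUE
    }
  }
  if (!se_ok) {
    vc <- matrix(NA_real_, length(best$par), length(best$par))
  }
  nm <- nmix_param_names(fr)
  names(best$par) <- nm
  dimnames(vc) <- list(nm, nm)

  ll <- -best$value
  k <- length(best$par)
  fit <- structure(
    list(
      spec = spec, frame = fr, beta = best$par, loglik = ll,
      vcov = vc, n_params = k, n_eff = fr$n_sites,
      aicc = aicc(ll, k, fr$n_sites),
      convergence = converged, se_available = se_ok,
      optim = best
    ),
    class = "nmix_fit"
  )
  if (check_K) {
    fr2 <- fr
    fr2$K <- fr$K + 50L
    ll2 <- nmix_loglik_frame(best$par, fr2)
    if (abs(ll2 - ll) > 1e-6) {
      warning(
        "log-likelihood changed by ", signif(abs(ll2 - ll), 3),
        " when K was raised by 50; increase K"
      )
    }
  }
  fit
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat("N-mixture model:", x$spec$name, "\n")
  cat(
    "  logLik =", format(x$loglik, digits = 6),
    " K_par =", x$n_params,
    " AICc =", format(x$aicc, digits = 6),
    if (!x$convergence) " [NOT CONVERGED]" else "", "\n"
  )
  se <- sqrt(diag(x$vcov))
  print(data.frame(
    estimate = round(x$beta, 4),
    se = round(se, 4)
  ))
  invisible(x)
}

#' @export
coef.nmix_fit <- function(object, ...) object$beta

#' @export
vcov.nmix_fit <- function(object, ...) object$vcov

#' @export
logLik.nmix_fit <- function(object, ...) {
  structure(object$loglik,
    df = object$n_params, nobs = object$n_eff,
    class = "logLik"
  )
}

#' Project expected abundance forward in time
#'
#' Deterministic expectation of the latent dynamics started from
#' `n_start`: one step is `E[N_t] = omega * E[N_{t-1}] + gamma`, so after
#' `t - 1` steps
#' `E[N_t] = n_start * omega^(t-1) + gamma * (1 - omega^(t-1)) / (1 - omega)`,
#' approaching the equilibrium `gamma / (1 - omega)`. For `omega = 1` the
#' limit `n_start + (t-1) * gamma` is used.
#'
#' @param n_start initial expected abundance.
#' @param omega apparent survival per transition, in `[0, 1]`.
#' @param gamma recruitment per transition, non-negative.
#' @param t season index (1 = initial state).
#' @return Expected abundance at season `t`.
#' @export
project_abundance <- function(n_start, omega, gamma, t) {
  if (t < 1 || t != round(t)) stop("t must be an integer >= 1")
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  s <- t - 1
  if (omega == 1) {
    n_start + s * gamma
  } else {
    n_start * omega^s + gamma * (1 - omega^s) / (1 - omega)
  }
}

# expected abundance per site at a given season as a function of beta
nmix_expected_abundance_beta <- function(beta, fr, season) {
  nat <- nmix_natural(beta, fr)
  e <- (1 - nat$psi) * nat$lambda
  if (season > 1L) {
    for (t in seq_len(season - 1L)) e <- nat$omega * e + nat$gamma
  }
  e
}

#' Expected site-level abundance with delta-method standard errors
#'
#' Season 1 expectation is `(1 - psi) * lambda_i`; later seasons apply
#' the survival-plus-recruitment expectation recursion. Standard errors
#' propagate the coefficient covariance through a numerical gradient.
#'
#' @param fit a converged [fit_nmix()] result.
#' @param season season index (1-based).
#' @return data.frame with columns `site`, `expected_N`, `se`.
#' @export
expected_site_abundance <- function(fit, season = 1L) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (!fit$convergence) stop("refusing to predict from a non-converged fit")
  fr <- fit$frame
  if (season > fr$T) stop("season exceeds the fitted number of seasons")
  e <- nmix_expected_abundance_beta(fit$beta, fr, season)
  g <- num_jacobian(
    function(b) nmix_expected_abundance_beta(b, fr, season), fit$beta
  )
  v <- g %*% fit$vcov %*% t(g)
  data.frame(
    site = seq_len(fr$n_sites),
    expected_N = e,
    se = sqrt(pmax(diag(v), 0))
  )
}

# central-difference Jacobian of a vector-valued function
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- eps * max(1, abs(x[k]))
    xp <- x
    xm <- x
    xp[k] <- x[k] + h
    xm[k] <- x[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Simulate replicate count data from a fitted N-mixture model
#'
#' Draws latent abundances from the fitted initial-state mixture,
#' propagates them by binomial survival and Poisson recruitment, and
#' thins them binomially with the fitted detection probabilities. Used
#' by the parametric bootstrap.
#'
#' @param object a fitted `nmix_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of count matrices (sites x season*visit columns).
#' @export
simulate.nmix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  nat <- nmix_natural(object$beta, fr)
  n <- fr$n_sites
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    N <- matrix(0L, n, fr$T)
    zero <- if (fr$mixture == "ZIP") {
      stats::rbinom(n, 1L, nat$psi)
    } else {
      rep(0L, n)
    }
    N[, 1L] <- ifelse(zero == 1L, 0L, stats::rpois(n, nat$lambda))
    if (fr$T > 1L) {
      for (t in 2:fr$T) {
        N[, t] <- stats::rbinom(n, N[, t - 1L], nat$omega) +
          stats::rpois(n, nat$gamma)
      }
    }
    y <- matrix(0L, n, fr$T * fr$J)
    for (t in seq_len(fr$T)) {
      for (j in seq_len(fr$J)) {
        col <- (t - 1L) * fr$J + j
        y[, col] <- stats::rbinom(n, N[, t], nat$p[, col])
      }
    }
    reps[[r]] <- y
  }
  reps
}

# swap the counts of a dataset for a simulated matrix (bootstrap refits)
replace_counts <- function(dataset, y) {
  stopifnot(inherits(dataset, "count_dataset"))
  dataset$counts$count <- as.integer(t(y))[
    seq_len(nrow(dataset$counts))
  ]
  dataset
}
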