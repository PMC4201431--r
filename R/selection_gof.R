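#' Second-order Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, the small-sample
#' correction appropriate when the number of parameters is not small
#' relative to the number of replicates (here, sites).
#'
#' @param loglik maximized log-likelihood.
#' @param K_par number of estimated parameters.
#' @param n_eff effective sample size (number of sites for N-mixture
#'   models).
#' @return AICc value.
#' @export
aicc <- function(loglik, K_par, n_eff) {
  if (n_eff <= K_par + 1) {
    stop("AICc undefined: effective sample size must exceed K + 1")
  }
  -2 * loglik + 2 * K_par + 2 * K_par * (K_par + 1) / (n_eff - K_par - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` where `Delta_i`
#' is each model's AICc distance from the best model. Invariant to
#' adding a constant to all AICc values.
#'
#' @param aicc_values numeric vector of AICc (or Delta-AICc) values.
#' @return Weights summing to one.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 1L) stop("need at least one model")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank a candidate set of fitted models by AICc
#'
#' @param fits named list of fitted models, each carrying `loglik`,
#'   `n_params`, and optionally `aicc` and a spec `name`.
#' @param n_eff effective sample size; defaults to the `n_eff` stored on
#'   the first fit.
#' @return An object of class `model_set`: the fits (AICc order) plus a
#'   ranking table with columns `model`, `K`, `loglik`, `AICc`,
#'   `delta_AICc`, `weight`.
#' @export
model_sel_table <- function(fits, n_eff = NULL) {
  stopifnot(length(fits) >= 1L)
  nms <- names(fits)
  if (is.null(nms)) nms <- rep("", length(fits))
  for (i in seq_along(fits)) {
    if (nms[i] == "") {
      nms[i] <- if (!is.null(fits[[i]]$spec$name)) {
        fits[[i]]$spec$name
      } else {
        paste0("model_", i)
      }
    }
  }
  if (is.null(n_eff)) n_eff <- fits[[1L]]$n_eff
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  K <- vapply(fits, function(f) f$n_params, numeric(1))
  a <- if (is.null(n_eff)) {
    vapply(fits, function(f) f$aicc, numeric(1))
  } else {
    mapply(aicc, ll, K, MoreArgs = list(n_eff = n_eff))
  }
  ord <- order(a)
  tab <- data.frame(
    model = nms[ord], K = K[ord], loglik = ll[ord], AICc = a[ord],
    delta_AICc = a[ord] - min(a), weight = akaike_weights(a)[ord],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(fits = fits[ord], table = tab, n_eff = n_eff),
    class = "model_set"
  )
}

#' @export
print.model_set <- function(x, ...) {
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$AICc <- round(tab$AICc, 2)
  tab$delta_AICc <- round(tab$delta_AICc, 2)
  tab$weight <- round(tab$weight, 2)
  print(tab)
  invisible(x)
}

#' Model-average a single parameter across a candidate set
#'
#' Weighted average `theta_bar = sum w_i theta_i` with the unconditional
#' standard error
#' `SE_unc = sum_i w_i sqrt(se_i^2 + (theta_i - theta_bar)^2)`,
#' which folds between-model spread into the reported uncertainty, and a
#' Wald 95% interval.
#'
#' @param estimates per-model estimates; `NA` where a model omits the
#'   parameter.
#' @param ses per-model standard errors (same pattern of `NA`).
#' @param weights Akaike weights (summing to one over all models).
#' @param shrinkage if `TRUE`, models omitting the parameter contribute
#'   an estimate of 0 with SE 0 (shrinking the average toward zero); if
#'   `FALSE`, weights are renormalized over the models containing it.
#' @return data.frame with `estimate`, `se_unconditional`, `lower`,
#'   `upper`.
#' @export
model_average_parameter <- function(estimates, ses, weights,
                                    shrinkage = FALSE) {
  if (length(estimates) != length(weights) ||
        length(ses) != length(weights)) {
    stop("estimates, ses and weights must have equal length")
  }
  has <- !is.na(estimates)
  if (!any(has)) stop("parameter absent from every model")
  if (shrinkage) {
    est <- ifelse(has, estimates, 0)
    se <- ifelse(has, ses, 0)
    w <- weights
  } else {
    est <- estimates[has]
    se <- ses[has]
    w <- weights[has] / sum(weights[has])
  }
  theta <- sum(w * est)
  se_unc <- sum(w * sqrt(se^2 + (est - theta)^2))
  data.frame(
    estimate = theta, se_unconditional = se_unc,
    lower = theta - 1.96 * se_unc, upper = theta + 1.96 * se_unc
  )
}

#' Model-averaged link-scale coefficients of an N-mixture candidate set
#'
#' Collects each named coefficient across the set and applies
#' [model_average_parameter()], giving the usual table of averaged
#' slopes with unconditional SEs and 95% limits (an interval excluding
#' zero indicates an effect).
#'
#' @param model_set a [model_sel_table()] result over `nmix_fit`s.
#' @param parameters coefficient names to average; default every
#'   non-intercept coefficient appearing in any model.
#' @param shrinkage passed to [model_average_parameter()].
#' @return data.frame with one row per coefficient.
#' @export
model_average_coefficients <- function(model_set, parameters = NULL,
                                       shrinkage = FALSE) {
  stopifnot(inherits(model_set, "model_set"))
  fits <- model_set$fits
  w <- model_set$table$weight
  all_names <- unique(unlist(lapply(fits, function(f) names(f$beta))))
  if (is.null(parameters)) {
    parameters <- all_names[!grepl("(Intercept)", all_names, fixed = TRUE)]
  }
  out <- do.call(rbind, lapply(parameters, function(pn) {
    est <- vapply(fits, function(f) {
      if (pn %in% names(f$beta)) unname(f$beta[pn]) else NA_real_
    }, numeric(1))
    se <- vapply(fits, function(f) {
      if (pn %in% names(f$beta)) {
        sqrt(f$vcov[pn, pn])
      } else {
        NA_real_
      }
    }, numeric(1))
    cbind(parameter = pn, model_average_parameter(est, se, w, shrinkage))
  }))
  rownames(out) <- NULL
  out
}

#' Predict one N-mixture parameter on the response scale
#'
#' @param object a fitted `nmix_fit`.
#' @param parameter `"lambda"` (initial abundance), `"gamma"`
#'   (recruitment), `"p"` (detection), or `"abundance"` (expected
#'   abundance at `season`, including zero inflation and dynamics).
#' @param newdata data.frame of covariate values (raw formula scale); if
#'   omitted, the fitted design rows are used.
#' @param season season for `parameter = "abundance"`.
#' @param ... unused.
#' @return data.frame with `estimate` and delta-method `se` per row.
#' @export
predict.nmix_fit <- function(object, parameter = c(
                               "lambda", "gamma", "p", "abundance"
                             ),
                             newdata = NULL, season = 1L, ...) {
  parameter <- match.arg(parameter)
  fr <- object$frame
  fun <- function(beta) {
    bl <- nmix_unpack(beta, fr)
    if (parameter == "abundance") {
      if (is.null(newdata)) {
        return(nmix_expected_abundance_beta(beta, fr, season))
      }
      X <- stats::model.matrix(object$spec$lambda, data = newdata)
      lam <- exp(drop(X %*% bl$b_lam))
      psi <- if (fr$mixture == "ZIP") stats::plogis(bl$psi_logit) else 0
      e <- (1 - psi) * lam
      if (season > 1L) {
        Xg <- stats::model.matrix(object$spec$gamma, data = newdata)
        gam <- exp(drop(Xg %*% bl$b_gam))
        om <- stats::plogis(bl$om_logit)
        for (t in seq_len(season - 1L)) e <- om * e + gam
      }
      return(e)
    }
    link_formula <- switch(parameter,
      lambda = object$spec$lambda,
      gamma = object$spec$gamma,
      p = object$spec$p
    )
    coefs <- switch(parameter,
      lambda = bl$b_lam, gamma = bl$b_gam, p = bl$b_p
    )
    if (parameter == "gamma" && is.null(coefs)) {
      stop("single-season fit has no recruitment parameter")
    }
    X <- if (is.null(newdata)) {
      switch(parameter, lambda = fr$X_lam, gamma = fr$X_gam, p = fr$X_p)
    } else {
      stats::model.matrix(link_formula, data = newdata)
    }
    eta <- drop(X %*% coefs)
    if (parameter == "p") stats::plogis(eta) else exp(eta)
  }
  est <- fun(object$beta)
  g <- num_jacobian(fun, object$beta)
  v <- g %*% object$vcov %*% t(g)
  data.frame(estimate = est, se = sqrt(pmax(diag(v), 0)))
}

#' Model-averaged predictions across a candidate set
#'
#' Averages response-scale predictions over every model in the set with
#' Akaike weights, attaching unconditional SEs. Supports abundance-vs-
#' covariate and detection-vs-covariate curves.
#'
#' @param model_set a [model_sel_table()] over `nmix_fit`s.
#' @param parameter,newdata,season as in [predict.nmix_fit()].
#' @return data.frame with `estimate`, `se_unconditional`, `lower`,
#'   `upper` per row of `newdata`.
#' @export
model_average_predictions <- function(model_set, parameter, newdata = NULL,
                                      season = 1L) {
  stopifnot(inherits(model_set, "model_set"))
  w <- model_set$table$weight
  preds <- lapply(
    model_set$fits, stats::predict,
    parameter = parameter, newdata = newdata, season = season
  )
  est <- vapply(preds, function(p) p$estimate, preds[[1]]$estimate)
  se <- vapply(preds, function(p) p$se, preds[[1]]$se)
  est <- matrix(est, ncol = length(w))
  se <- matrix(se, ncol = length(w))
  avg <- drop(est %*% w)
  se_unc <- vapply(seq_len(nrow(est)), function(r) {
    sum(w * sqrt(se[r, ]^2 + (est[r, ] - avg[r])^2))
  }, numeric(1))
  data.frame(
    estimate = avg, se_unconditional = se_unc,
    lower = avg - 1.96 * se_unc, upper = avg + 1.96 * se_unc
  )
}

#' Chi-square discrepancy of a fitted N-mixture model
#'
#' `T = sum_itj (n_itj - E[n_itj])^2 / max(E[n_itj], eps)` with expected
#' counts `E[n_itj] = E[N_it] * p_itj` under the fitted parameters.
#'
#' @param fit a fitted `nmix_fit`.
#' @param y optional count matrix (sites x season*visit) to score;
#'   defaults to the data the model was fitted to.
#' @param eps floor for expected counts in the denominator.
#' @return The discrepancy statistic (non-negative).
#' @export
chisq_stat <- function(fit, y = NULL, eps = 1e-8) {
  stopifnot(inherits(fit, "nmix_fit"))
  fr <- fit$frame
  if (is.null(y)) y <- fr$y
  nat <- nmix_natural(fit$beta, fr)
  expN <- vapply(
    seq_len(fr$T),
    function(t) nmix_expected_abundance_beta(fit$beta, fr, t),
    numeric(fr$n_sites)
  )
  expN <- matrix(expN, nrow = fr$n_sites)
  expected <- matrix(0, fr$n_sites, fr$T * fr$J)
  for (t in seq_len(fr$T)) {
    for (j in seq_len(fr$J)) {
      col <- (t - 1L) * fr$J + j
      expected[, col] <- expN[, t] * nat$p[, col]
    }
  }
  sum((y - expected)^2 / pmax(expected, eps))
}

#' Parametric-bootstrap goodness of fit
#'
#' Simulates `B` replicate datasets from the fitted model at its MLE,
#' recomputes the chi-square discrepancy on each (after refitting by
#' default), and reports `p = Pr(T_b >= T_obs)`. A small bootstrap p
#' indicates lack of fit.
#'
#' @param fit a converged `nmix_fit`.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed (results are reproducible given the seed).
#' @param mode `"refit"` refits the model to each replicate (full
#'   parametric bootstrap); `"plugin"` scores replicates at the original
#'   MLE (faster, approximate).
#' @param plus_one if `TRUE`, report `(1 + #{T_b >= T_obs}) / (1 + B)`
#'   instead of the raw proportion.
#' @return List of class `nmix_gof`: `p_value`, `t_obs`, `t_boot`,
#'   `mode`, `B`.
#' @export
parametric_bootstrap_gof <- function(fit, B = 200L, seed = NULL,
                                     mode = c("refit", "plugin"),
                                     plus_one = FALSE) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (B < 1L) stop("B must be at least 1")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- chisq_stat(fit)
  reps <- simulate(fit, nsim = B)
  fr <- fit$frame
  t_boot <- numeric(B)
  for (b in seq_len(B)) {
    if (mode == "plugin") {
      fit_b <- fit
      fit_b$frame$y <- reps[[b]]
    } else {
      fr_b <- fr
      fr_b$y <- reps[[b]]
      negll <- function(bb) {
        v <- -nmix_loglik_frame(bb, fr_b)
        if (!is.finite(v)) 1e10 else v
      }
      opt <- stats::optim(fit$beta, negll,
        method = "BFGS",
        control = list(maxit = 300, reltol = 1e-8)
      )
      fit_b <- fit
      fit_b$beta <- opt$par
      fit_b$frame <- fr_b
    }
    t_boot[b] <- chisq_stat(fit_b)
  }
  hits <- sum(t_boot >= t_obs)
  p <- if (plus_one) (1 + hits) / (1 + B) else hits / B
  structure(
    list(p_value = p, t_obs = t_obs, t_boot = t_boot, mode = mode, B = B),
    class = "nmix_gof"
  )
}

#' @export
print.nmix_gof <- function(x, ...) {
  cat(
    "Parametric-bootstrap GOF (", x$mode, ", B = ", x$B, "): ",
    "T_obs = ", format(x$t_obs, digits = 4),
    ", p = ", format(x$p_value, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}
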