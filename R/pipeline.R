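#' Candidate model set varying one parameter at a time
#'
#' Builds the vary-one-at-a-time design used when sites are too few for
#' an all-combinations strategy: hypothesis structures on initial
#' abundance (snag and/or conifer basal area), on recruitment (nest-box
#' treatment, alone or interacting with snag or conifer basal area),
#' and on detection (year, precipitation, Julian day, trap height),
#' each varied while the other parameters are held at the structure
#' given by `base`.
#'
#' @param mixture `"ZIP"` or `"P"`, applied to every model.
#' @param base named list with elements `lambda`, `gamma`, `p` giving
#'   the formulas held constant while another parameter is varied.
#' @param K truncation bound passed to every spec.
#' @return Named list of [nmix_spec()]s (the null model first).
#' @export
candidate_set_study <- function(mixture = "ZIP",
                                base = list(
                                  lambda = ~1, gamma = ~1,
                                  p = ~ year * precip + year * julian_day + height
                                ),
                                K = NULL) {
  lambda_structures <- list(
    ~snag_ba, ~conifer_ba, ~ snag_ba + conifer_ba
  )
  gamma_structures <- list(
    ~boxes, ~ boxes * snag_ba, ~ boxes * conifer_ba
  )
  p_structures <- list(
    ~ year + height + precip + julian_day,
    ~ precip + julian_day + year * height,
    ~ year * precip + year * julian_day + height,
    ~ year * precip + year * julian_day + year * height,
    ~ snag_ba + conifer_ba
  )
  specs <- list(nmix_spec(
    lambda = base$lambda, gamma = base$gamma, p = base$p,
    mixture = mixture, K = K
  ))
  for (f in lambda_structures) {
    specs <- c(specs, list(nmix_spec(
      lambda = f, gamma = base$gamma, p = base$p, mixture = mixture, K = K
    )))
  }
  for (f in gamma_structures) {
    specs <- c(specs, list(nmix_spec(
      lambda = base$lambda, gamma = f, p = base$p, mixture = mixture, K = K
    )))
  }
  for (f in p_structures) {
    specs <- c(specs, list(nmix_spec(
      lambda = base$lambda, gamma = base$gamma, p = f,
      mixture = mixture, K = K
    )))
  }
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs[!duplicated(names(specs))]
}

#' Run the full BACI count-model workflow
#'
#' Centres covariates, screens collinear pairs (vetoing candidate
#' models that contain both members of a flagged pair), fits every
#' candidate dynamic N-mixture model, ranks them by AICc, model-averages
#' coefficients and seasonal abundance for an average site, optionally
#' runs the parametric-bootstrap goodness of fit on the top model, and
#' optionally fits the comparison estimators (Huggins, CJS, Poisson
#' GLMM) when capture histories are supplied.
#'
#' @param dataset a [count_dataset()] (raw covariates; centring is done
#'   here).
#' @param candidates named list of [nmix_spec()]s; default a compact
#'   vary-one-at-a-time set via [candidate_set_study()].
#' @param histories optional [capture_history_set()] for the
#'   capture-mark-recapture comparison.
#' @param gof_B bootstrap replicates for goodness of fit (0 to skip).
#' @param gof_mode `"refit"` or `"plugin"`.
#' @param glmm_formula fixed-effects formula for the comparison GLMM.
#' @param starts,seed optimizer starts per model and RNG seed.
#' @param allow_nonconverged keep non-converged fits (with a warning)
#'   instead of failing.
#' @return An object of class `baci_analysis`: `model_table` (ranked
#'   models), `averaged_coefficients`, `abundance` (model-averaged
#'   expected abundance per season with unconditional SE), `gof`,
#'   `comparison`, `collinear`, and the fitted `model_set`.
#' @export
run_baci_analysis <- function(dataset, candidates = NULL,
                              histories = NULL, gof_B = 0L,
                              gof_mode = "plugin",
                              glmm_formula = ~ year * snag_ba,
                              starts = 3L, seed = NULL,
                              allow_nonconverged = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  dataset <- center_covariates(dataset)
  if (is.null(candidates)) candidates <- candidate_set_study()

  flagged <- screen_collinearity(dataset)
  if (nrow(flagged) > 0L) {
    banned <- lapply(seq_len(nrow(flagged)), function(i) {
      c(flagged$var1[i], flagged$var2[i])
    })
    keep <- vapply(candidates, function(sp) {
      vars <- unique(c(
        all.vars(sp$lambda), all.vars(sp$gamma), all.vars(sp$p)
      ))
      !any(vapply(banned, function(b) all(b %in% vars), logical(1)))
    }, logical(1))
    if (any(!keep)) {
      warning(
        sum(!keep), " candidate model(s) vetoed for collinear covariates"
      )
      candidates <- candidates[keep]
    }
  }

  fits <- lapply(candidates, function(sp) {
    fit_nmix(dataset, sp, starts = starts)
  })
  conv <- vapply(fits, function(f) f$convergence, logical(1))
  if (any(!conv)) {
    msg <- paste(
      "non-converged model(s):",
      paste(names(fits)[!conv], collapse = "; ")
    )
    if (!allow_nonconverged) stop(msg)
    warning(msg)
  }
  ms <- model_sel_table(fits)
  avg_coefs <- model_average_coefficients(ms)

  # model-averaged abundance for an average site (centred covariates
  # at their means)
  site_covs <- setdiff(names(dataset$sites), "site")
  avg_site <- as.data.frame(lapply(dataset$sites[site_covs], mean))
  abundance <- do.call(rbind, lapply(seq_len(dataset$n_seasons), function(t) {
    pr <- model_average_predictions(
      ms, "abundance", newdata = avg_site, season = t
    )
    cbind(season = t, pr)
  }))

  gof <- NULL
  if (gof_B > 0L) {
    gof <- parametric_bootstrap_gof(
      ms$fits[[1L]], B = gof_B, mode = gof_mode
    )
  }

  comparison <- NULL
  if (!is.null(histories)) {
    comparison <- compare_estimators(
      dataset, histories, ms,
      glmm_formula = glmm_formula
    )
  }

  structure(
    list(
      model_table = ms$table, model_set = ms,
      averaged_coefficients = avg_coefs, abundance = abundance,
      gof = gof, comparison = comparison, collinear = flagged,
      dataset = dataset
    ),
    class = "baci_analysis"
  )
}

#' @export
print.baci_analysis <- function(x, ...) {
  cat("== Model ranking (AICc) ==\n")
  tab <- x$model_table
  tab$loglik <- NULL
  tab$AICc <- round(tab$AICc, 2)
  tab$delta_AICc <- round(tab$delta_AICc, 2)
  tab$weight <- round(tab$weight, 2)
  print(utils::head(tab, 6))
  cat("\n== Model-averaged coefficients ==\n")
  ac <- x$averaged_coefficients
  ac[, -1] <- round(ac[, -1], 2)
  print(ac)
  cat("\n== Model-averaged abundance, average site ==\n")
  ab <- x$abundance
  ab[, -1] <- round(ab[, -1], 2)
  print(ab)
  if (!is.null(x$gof)) {
    cat("\n")
    print(x$gof)
  }
  if (!is.null(x$comparison)) {
    cat("\n== Comparison estimators ==\n")
    print(x$comparison)
  }
  invisible(x)
}

# season-restricted capture histories (closed-population pieces)
season_histories <- function(histories, occasions) {
  h <- histories$histories[, occasions, drop = FALSE]
  keep <- rowSums(h) > 0L
  capture_history_set(
    h[keep, , drop = FALSE],
    histories$occasion_times[occasions],
    site = histories$site[keep],
    individual = histories$individual[keep],
    site_covariates = if (is.null(histories$site_covariates)) {
      NULL
    } else {
      histories$site_covariates[keep, , drop = FALSE]
    }
  )
}

#' Fit the comparison estimators alongside the dynamic model
#'
#' Per-season Huggins closed-population abundance (time-dependent
#' capture probability, pooled across sites), constant-survival CJS with
#' unequal intervals and year-grouped recapture, and the Poisson
#' random-intercept GLMM on raw counts.
#'
#' @param dataset a (centred) [count_dataset()].
#' @param histories a [capture_history_set()] over
#'   `n_seasons * n_visits` occasions.
#' @param model_set optional fitted [model_sel_table()] to include the
#'   dynamic model-averaged abundance in the table.
#' @param glmm_formula fixed-effects formula for the GLMM.
#' @return data.frame with one row per estimator x season abundance
#'   (and survival rows), plus fitted objects as attributes.
#' @export
compare_estimators <- function(dataset, histories, model_set = NULL,
                               glmm_formula = ~ year * snag_ba) {
  J <- dataset$n_visits
  TT <- dataset$n_seasons
  n_sites <- dataset$n_sites
  rows <- list()

  hug <- list()
  for (t in seq_len(TT)) {
    ht <- season_histories(histories, (t - 1L) * J + seq_len(J))
    f <- fit_huggins(ht, p_model = "Mt", n_sites = n_sites)
    hug[[t]] <- f
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "huggins", quantity = "abundance_per_site", season = t,
      estimate = f$N_per_site, se = f$se_per_site
    )
  }

  cjs <- NULL
  if (ncol(histories$histories) >= 3L) {
    yr_groups <- rep(seq_len(TT), each = J)[-1L]
    cjs <- fit_cjs(histories,
      phi_structure = "constant", p_structure = "group",
      p_groups = yr_groups
    )
    # survival over the between-season gap
    gap <- histories$occasion_times[J + 1L] - histories$occasion_times[J]
    se_phi <- sqrt(cjs$vcov[1L, 1L]) *
      abs(cjs$phi * (1 - cjs$phi)) # delta method back from logit
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "cjs", quantity = "annual_survival", season = NA,
      estimate = cjs$phi, se = se_phi
    )
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "cjs", quantity = "gap_survival", season = NA,
      estimate = cjs$phi^gap, se = NA
    )
  }

  glmm <- fit_glmm(dataset, glmm_formula)
  X0 <- stats::model.matrix(
    stats::as.formula(glmm_formula),
    data = data.frame(
      year = c(0, 1),
      lapply(
        dataset$sites[setdiff(names(dataset$sites), "site")], mean
      )
    )
  )
  eta <- drop(X0 %*% glmm$beta)
  for (t in seq_len(min(TT, 2L))) {
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "glmm", quantity = "mean_count", season = t,
      estimate = exp(eta[t]), se = NA
    )
  }

  if (!is.null(model_set)) {
    site_covs <- setdiff(names(dataset$sites), "site")
    avg_site <- as.data.frame(lapply(dataset$sites[site_covs], mean))
    for (t in seq_len(TT)) {
      pr <- model_average_predictions(
        model_set, "abundance", newdata = avg_site, season = t
      )
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = "dynamic_nmix", quantity = "abundance_per_site",
        season = t, estimate = pr$estimate, se = pr$se_unconditional
      )
    }
    om <- stats::plogis(
      model_set$fits[[1L]]$beta[["omega:(Intercept)"]]
    )
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = "dynamic_nmix", quantity = "gap_survival", season = NA,
      estimate = om, se = NA
    )
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- list(huggins = hug, cjs = cjs, glmm = glmm)
  out
}
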