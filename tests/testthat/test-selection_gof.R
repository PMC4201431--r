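test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(-500, 12, 56), 1000 + 24 + 312 / 43)
  expect_equal(aicc(-500, 12, 56) - (1000 + 24), 7.2558, tolerance = 1e-4)
  expect_equal(aicc(-500, 12, 1e9), 1024, tolerance = 1e-5) # AIC limit
  expect_error(aicc(-500, 12, 13), "exceed")
})

test_that("Akaike weights reproduce the field-study ranking arithmetic", {
  deltas <- c(0, 2.11, 2.99, 5.25, 8.45, 11.21)
  w <- akaike_weights(deltas)
  expect_equal(round(w, 2), c(0.60, 0.21, 0.13, 0.04, 0.01, 0.00))
  expect_equal(round(w[1] + w[2], 2), 0.81) # top two models combined
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(deltas + 1038.58), w, tolerance = 1e-12)
  expect_equal(akaike_weights(5), 1)
})

test_that("parameter averaging uses the unconditional SE formula", {
  one <- model_average_parameter(2.5, 0.4, 1)
  expect_equal(one$estimate, 2.5)
  expect_equal(one$se_unconditional, 0.4)

  two <- model_average_parameter(c(1, 3), c(0, 0), c(0.5, 0.5))
  expect_equal(two$estimate, 2)
  expect_equal(two$se_unconditional, 1) # purely between-model spread

  # CI excludes zero iff |estimate| > 1.96 * SE
  m <- model_average_parameter(c(0.5, 0.7), c(0.1, 0.1), c(0.6, 0.4))
  excl <- m$lower > 0 | m$upper < 0
  expect_equal(excl, abs(m$estimate) > 1.96 * m$se_unconditional)

  # averaging inflates SE beyond the weighted within-model SEs
  m2 <- model_average_parameter(c(1, 3), c(0.2, 0.3), c(0.5, 0.5))
  expect_gte(m2$se_unconditional, 0.5 * 0.2 + 0.5 * 0.3)

  expect_error(model_average_parameter(1:3, 1:2, c(0.5, 0.5)), "length")

  # shrinkage treats absent coefficients as zero with zero variance
  shr <- model_average_parameter(c(2, NA), c(0.1, NA), c(0.6, 0.4),
                                 shrinkage = TRUE)
  expect_equal(shr$estimate, 1.2)
  nos <- model_average_parameter(c(2, NA), c(0.1, NA), c(0.6, 0.4))
  expect_equal(nos$estimate, 2)
})

test_that("model ranking table orders by AICc with weights summing to one", {
  fake_fit <- function(ll, k, name) {
    structure(list(loglik = ll, n_params = k, n_eff = 56,
                   spec = list(name = name)), class = "nmix_fit")
  }
  fits <- list(fake_fit(-507.29, 12, "a"), fake_fit(-505.29, 13, "b"),
               fake_fit(-512, 11, "c"))
  ms <- model_sel_table(fits, n_eff = 56)
  expect_equal(ms$table$delta_AICc[1], 0)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(ms$table$AICc) >= 0))
  expect_equal(
    ms$table$weight,
    unname(akaike_weights(ms$table$AICc)),
    tolerance = 1e-12
  )
})

test_that("model-averaged predictions combine response-scale curves", {
  ds <- make_tiny_dataset(matrix(1L, 4, 4), site_covs = data.frame(
    snag_ba = c(-1, 0, 1, 2)
  ))
  spec <- nmix_spec(lambda = ~snag_ba, gamma = ~1, p = ~1,
                    mixture = "P", K = 30)
  fr <- dynmix:::nmix_frame(ds, spec)
  mk <- function(beta) {
    structure(
      list(spec = spec, frame = fr, beta = beta, vcov = diag(1e-4, 5),
           loglik = -10, n_params = 5, n_eff = 56, convergence = TRUE),
      class = "nmix_fit"
    )
  }
  b <- c(log(2), -0.3, log(1), 0, qlogis(0.4))
  f1 <- mk(b); f2 <- mk(b)
  ms <- model_sel_table(list(m1 = f1, m2 = f2), n_eff = 56)
  nd <- data.frame(snag_ba = c(0, 1))
  pr <- model_average_predictions(ms, "lambda", newdata = nd)
  single <- predict(f1, "lambda", newdata = nd)
  # identical models: average equals the common value, SE the weighted SE
  expect_equal(pr$estimate, single$estimate)
  expect_equal(pr$se_unconditional, single$se, tolerance = 1e-10)

  # two different models against the hand formula
  b2 <- c(log(3), -0.1, log(1), 0, qlogis(0.4))
  f3 <- mk(b2)
  f3$loglik <- -10.5
  ms2 <- model_sel_table(list(m1 = f1, m3 = f3), n_eff = 56)
  w <- ms2$table$weight
  pr2 <- model_average_predictions(ms2, "lambda", newdata = nd)
  p1 <- predict(ms2$fits[[1]], "lambda", newdata = nd)$estimate
  p2 <- predict(ms2$fits[[2]], "lambda", newdata = nd)$estimate
  expect_equal(pr2$estimate, w[1] * p1 + w[2] * p2)
  # negative averaged slope gives a monotone decreasing abundance curve
  curve <- model_average_predictions(
    ms2, "lambda", newdata = data.frame(snag_ba = seq(-2, 2, 0.5))
  )
  expect_true(all(diff(curve$estimate) < 0))
})

test_that("chi-square discrepancy matches hand arithmetic", {
  ds <- make_tiny_dataset(matrix(c(3L, 1L), 1, 2), T = 1, J = 2)
  spec <- nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 40)
  fr <- dynmix:::nmix_frame(ds, spec)
  fit <- structure(
    list(spec = spec, frame = fr, beta = c(log(4), qlogis(0.5)),
         vcov = diag(1e-4, 2), convergence = TRUE),
    class = "nmix_fit"
  )
  # expected count 4 * 0.5 = 2 in both cells; obs (3, 1)
  expect_equal(chisq_stat(fit), 0.5 + 0.5)
  expect_equal(chisq_stat(fit, y = matrix(c(2L, 2L), 1, 2)), 0)
  expect_gte(chisq_stat(fit, y = matrix(c(9L, 0L), 1, 2)), 0)
})

test_that("bootstrap GOF is seed-reproducible and p = 1 at perfect fit", {
  ds <- make_tiny_dataset(matrix(c(2L, 2L), 1, 2), T = 1, J = 2)
  spec <- nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 40)
  fr <- dynmix:::nmix_frame(ds, spec)
  fit <- structure(
    list(spec = spec, frame = fr, beta = c(log(4), qlogis(0.5)),
         vcov = diag(1e-4, 2), convergence = TRUE),
    class = "nmix_fit"
  )
  g <- parametric_bootstrap_gof(fit, B = 30, seed = 9, mode = "plugin")
  expect_equal(g$p_value, 1) # T_obs = 0 cannot be beaten
  g2 <- parametric_bootstrap_gof(fit, B = 30, seed = 9, mode = "plugin")
  expect_identical(g$t_boot, g2$t_boot)
  expect_identical(g$p_value, g2$p_value)
  expect_error(parametric_bootstrap_gof(fit, B = 0), "at least 1")
})

test_that("ZIP fits zero-heavy data better than Poisson by bootstrap p", {
  set.seed(47)
  sc <- sim_scenario(
    n_sites = 60L, n_treated = 30L,
    lambda_coefs = c("(Intercept)" = log(4)), psi = 0.45,
    gamma_coefs = c("(Intercept)" = log(3)), omega = 0.5,
    p_coefs = c("(Intercept)" = qlogis(0.5)), seed = 470L
  )
  st <- simulate_baci_study(sc)
  fz <- fit_nmix(st$dataset,
    nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "ZIP", K = 50),
    starts = 1)
  fp <- fit_nmix(st$dataset,
    nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 50),
    starts = 1)
  gz <- parametric_bootstrap_gof(fz, B = 100, seed = 48, mode = "plugin")
  gp <- parametric_bootstrap_gof(fp, B = 100, seed = 48, mode = "plugin")
  expect_gt(gz$p_value, gp$p_value)
})
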