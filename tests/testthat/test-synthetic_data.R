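test_that("covariate generator is deterministic and hits field calibration", {
  sc <- make_study_scenario(seed = 101)
  set.seed(101)
  c1 <- simulate_covariates(sc)
  set.seed(101)
  c2 <- simulate_covariates(sc)
  expect_identical(c1, c2)
  expect_equal(sum(c1$sites$boxes), 29)
  expect_equal(nrow(c1$sites), 56)
  expect_equal(nrow(c1$visits), 56 * 4)

  big <- sc
  big$n_sites <- 100000L
  big$n_treated <- 50000L
  set.seed(102)
  cb <- simulate_covariates(big)
  expect_lt(abs(mean(cb$sites$snag_ba) - 3.4), 0.1)
  expect_lt(abs(mean(cb$sites$conifer_ba) - 1.4), 0.05)
  expect_true(all(cb$sites$snag_ba >= 0))
  # per season x visit precipitation means
  pm <- with(cb$visits, tapply(precip, list(season, visit), mean))
  expect_equal(unname(pm), matrix(c(6.2, 5.4, 7.3, 12.2), 2, 2),
               tolerance = 0.05)
})

test_that("latent dynamics follow the ZIP initial state and transitions", {
  sc <- sim_scenario(
    n_sites = 100000L, n_treated = 0L,
    lambda_coefs = c("(Intercept)" = log(3)), psi = 0.25,
    gamma_coefs = c("(Intercept)" = log(2)), omega = 0.6,
    p_coefs = c("(Intercept)" = 0)
  )
  set.seed(103)
  cv <- simulate_covariates(sc)
  N <- simulate_latent_dynamics(sc, cv)
  expect_lt(abs(mean(N[, 1]) - 0.75 * 3) / (0.75 * 3), 0.01)
  expect_gte(mean(N[, 1] == 0), 0.25)

  sc1 <- sc
  sc1$psi <- 1
  set.seed(104)
  cv1 <- simulate_covariates(sc1)
  expect_true(all(simulate_latent_dynamics(sc1, cv1)[, 1] == 0))

  scc <- sc
  scc$omega <- 1
  scc$gamma_coefs <- c("(Intercept)" = -Inf) # gamma = 0: pure survival
  scc$n_sites <- 5000L
  set.seed(105)
  cvc <- simulate_covariates(scc)
  Nc <- simulate_latent_dynamics(scc, cvc)
  expect_identical(Nc[, 1], Nc[, 2])
})

test_that("counts are binomial thinnings bounded by the latent state", {
  sc <- sim_scenario(
    n_sites = 20000L, n_treated = 0L,
    lambda_coefs = c("(Intercept)" = log(2)), psi = 0,
    gamma_coefs = c("(Intercept)" = log(1)), omega = 0.5,
    p_coefs = c("(Intercept)" = qlogis(0.35))
  )
  set.seed(106)
  cv <- simulate_covariates(sc)
  latent <- matrix(1L, sc$n_sites, 2) # unit abundance: counts Bernoulli(p)
  ds <- simulate_counts(sc, cv, latent)
  expect_lt(abs(mean(ds$counts$count) - 0.35), 0.005)

  set.seed(107)
  N <- simulate_latent_dynamics(sc, cv)
  ds2 <- simulate_counts(sc, cv, N)
  bound <- N[cbind(ds2$counts$site, ds2$counts$season)]
  expect_true(all(ds2$counts$count <= bound))

  scp <- sc
  scp$p_coefs <- c("(Intercept)" = Inf) # perfect detection
  ds3 <- simulate_counts(scp, cv, N)
  expect_identical(ds3$counts$count, as.integer(bound))
})

test_that("capture histories are the individual twin of the counts", {
  sc <- sim_scenario(
    n_sites = 5000L, n_treated = 0L,
    lambda_coefs = c("(Intercept)" = log(2.5)), psi = 0,
    gamma_coefs = c("(Intercept)" = log(1.5)), omega = 0.55,
    p_coefs = c("(Intercept)" = qlogis(0.4))
  )
  set.seed(108)
  cv <- simulate_covariates(sc)
  N <- simulate_latent_dynamics(sc, cv)
  set.seed(109)
  hs <- simulate_capture_histories(sc, cv, N)
  # visit-1 detections per site should match the count distribution
  det1 <- tabulate(hs$site[hs$histories[, 1] == 1], nbins = sc$n_sites)
  set.seed(110)
  ds <- simulate_counts(sc, cv, N)
  cnt1 <- ds$counts$count[ds$counts$season == 1 & ds$counts$visit == 1]
  tab <- function(x) tabulate(factor(pmin(x, 6), levels = 0:6), 7)
  suppressWarnings(
    gof <- chisq.test(rbind(tab(det1), tab(cnt1)))
  )
  expect_gt(gof$p.value, 0.01)

  # recapture fraction across years ~ omega * p*
  seen1 <- rowSums(hs$histories[, 1:2]) > 0
  seen2 <- rowSums(hs$histories[, 3:4]) > 0
  pstar <- 1 - (1 - 0.4)^2
  expect_lt(abs(mean(seen2[seen1]) - 0.55 * pstar), 0.02)

  sc0 <- sc
  sc0$omega <- 0
  set.seed(111)
  cv0 <- simulate_covariates(sc0)
  N0 <- simulate_latent_dynamics(sc0, cv0)
  hs0 <- simulate_capture_histories(sc0, cv0, N0)
  both <- rowSums(hs0$histories[, 1:2]) > 0 &
    rowSums(hs0$histories[, 3:4]) > 0
  expect_false(any(both))
})

test_that("the field-calibrated scenario reproduces the printed quantities", {
  sc <- make_study_scenario(seed = 1)
  expect_equal(sc$lambda_coefs[["snag_ba"]], -0.19)
  expect_equal(sc$lambda_coefs[["conifer_ba"]], 0.09)
  expect_equal(plogis(sc$p_coefs[["(Intercept)"]]), 0.17)
  expect_equal(sc$p_coefs[["precip"]], -0.07)
  expect_equal(sc$p_coefs[["julian_day"]], -0.02)
  expect_equal(exp(sc$gamma_coefs[["(Intercept)"]]), 6)
  expect_equal(sc$omega, 0.18)

  big <- sc
  big$n_sites <- 10000L
  big$n_treated <- 5000L
  set.seed(112)
  cv <- simulate_covariates(big)
  par <- dynmix:::scenario_parameters(big, cv)
  expect_equal(mean((1 - par$psi) * par$lambda), 2.7, tolerance = 0.02)
  # implied season-2 expectation near the reported 7.1
  expect_equal(mean(0.18 * (1 - par$psi) * par$lambda + par$gamma),
               6.5, tolerance = 0.05)
})

test_that("whole-study simulation is reproducible from the scenario seed", {
  sc <- make_study_scenario(seed = 314)
  s1 <- simulate_baci_study(sc, histories = TRUE)
  s2 <- simulate_baci_study(sc, histories = TRUE)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$histories$histories, s2$histories$histories)
})
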