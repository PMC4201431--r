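test_that("zero-inflated Poisson pmf has the mixture form and normalizes", {
  expect_equal(zip_pmf(0, 2, 0), exp(-2))
  expect_equal(zip_pmf(0, 2, 0.3), 0.3 + 0.7 * exp(-2))
  expect_equal(zip_pmf(3, 1.5, 0.2), 0.8 * dpois(3, 1.5))
  expect_equal(sum(zip_pmf(0:80, 2, 0.3)), 1, tolerance = 1e-12)
  expect_error(zip_pmf(-1, 2, 0.3), "non-negative")
  expect_error(zip_pmf(0, 2, 1), "psi")
})

test_that("transition pmf enumerates survivors convolved with recruits", {
  expect_equal(transition_pmf(0, 0, 0.5, 1), exp(-1))
  expect_equal(transition_pmf(1, 1, 0.5, 0), 0.5)
  expect_equal(transition_pmf(0, 1, 0.5, 0), 0.5)
  # two residents, omega .5, gamma 1: P(1|2) = (2*.5*.5*e^-1) + (.25*e^-1)
  expect_equal(transition_pmf(1, 2, 0.5, 1), 0.75 * exp(-1))
  rows <- vapply(0:200, transition_pmf, numeric(1),
                 n_prev = 4, omega = 0.3, gamma = 2.5)
  expect_equal(sum(rows), 1, tolerance = 1e-12)
})

test_that("transition matrix tabulates the pmf with bounded tail loss", {
  m <- build_transition_matrix(0, 0, 5)
  expect_equal(unname(m[, 1]), rep(1, 6))
  expect_true(all(m[, -1] == 0))

  omega <- 0.4; gamma <- 3
  margin <- ceiling(gamma + 10 * sqrt(gamma))
  K <- margin + 8
  m2 <- build_transition_matrix(omega, gamma, K)
  # rows with n_prev <= K - margin keep all but < 1e-8 of their mass
  expect_true(all(rowSums(m2)[seq_len(K - margin + 1)] >= 1 - 1e-8))
  for (np in c(0, 3, 8)) {
    for (nn in c(0, 2, 7)) {
      expect_equal(m2[np + 1, nn + 1],
                   transition_pmf(nn, np, omega, gamma),
                   tolerance = 1e-14, ignore_attr = TRUE)
    }
  }
})

test_that("single-season likelihood matches the closed-form series", {
  # counts (0,0): sum_N Pois(N;lam) q^(2N) = exp(lam (q^2 - 1))
  ds <- make_tiny_dataset(matrix(c(0L, 0L), 1, 2), T = 1, J = 2)
  spec <- nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 200)
  ll <- single_season_loglik(c(log(1), qlogis(0.5)), ds, spec)
  expect_equal(ll, -0.75, tolerance = 1e-10)

  # brute-force enumeration oracle on nonzero counts
  y <- matrix(c(2L, 1L), 1, 2)
  ds2 <- make_tiny_dataset(y, T = 1, J = 2)
  lam <- 3.2; p <- 0.37
  brute <- log(sum(dpois(0:200, lam) *
                   dbinom(2, 0:200, p) * dbinom(1, 0:200, p)))
  ll2 <- single_season_loglik(
    c(log(lam), qlogis(p)), ds2,
    nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 200)
  )
  expect_equal(ll2, brute, tolerance = 1e-10)

  # perfect detection makes unequal repeated counts impossible
  ds3 <- make_tiny_dataset(matrix(c(2L, 3L), 1, 2), T = 1, J = 2)
  ll3 <- single_season_loglik(
    c(log(2), 40), ds3,
    nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 50)
  )
  expect_equal(ll3, -Inf)
})

test_that("dynamic likelihood equals exhaustive enumeration", {
  set.seed(21)
  for (case in 1:5) {
    n <- 3
    y <- matrix(sample(0:3, n * 4, replace = TRUE), n, 4)
    lam <- runif(1, 0.5, 3)
    psi <- runif(1, 0, 0.4)
    om <- runif(1, 0.1, 0.9)
    gam <- runif(1, 0.2, 3)
    p <- runif(1, 0.2, 0.8)
    ds <- make_tiny_dataset(y)
    spec <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1,
                      mixture = "ZIP", K = 60)
    beta <- c(log(lam), qlogis(psi), log(gam), qlogis(om), qlogis(p))
    expect_equal(
      dynamic_loglik(beta, ds, spec),
      brute_dyn_loglik(y, lam, psi, om, gam, p, K = 60),
      tolerance = 1e-10
    )
  }
})

test_that("closure limit: omega = 1, gamma = 0 reduces to one closed season", {
  set.seed(22)
  y <- matrix(rpois(5 * 4, 2), 5, 4)
  ds <- make_tiny_dataset(y)
  lam <- 2.5; p <- 0.45
  spec_dyn <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1,
                        mixture = "P", K = 80)
  ll_dyn <- dynamic_loglik(
    c(log(lam), -300, 300, qlogis(p)), ds, spec_dyn
  )
  ds_pooled <- make_tiny_dataset(y, T = 1, J = 4)
  ll_single <- single_season_loglik(
    c(log(lam), qlogis(p)), ds_pooled,
    nmix_spec(lambda = ~1, p = ~1, mixture = "P", K = 80)
  )
  expect_equal(ll_dyn, ll_single, tolerance = 1e-8)
})

test_that("ZIP with psi = 0 reproduces the Poisson likelihood exactly", {
  set.seed(23)
  y <- matrix(rpois(6 * 4, 2), 6, 4)
  ds <- make_tiny_dataset(y)
  bP <- c(log(2), log(1.5), qlogis(0.5), qlogis(0.4))
  bZ <- c(log(2), -Inf, log(1.5), qlogis(0.5), qlogis(0.4))
  bZ[2] <- qlogis(1e-300) # psi -> 0 on the logit scale
  llP <- dynamic_loglik(bP, ds,
    nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 60))
  llZ <- dynamic_loglik(bZ, ds,
    nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "ZIP", K = 60))
  expect_equal(llZ, llP, tolerance = 1e-12)
})

test_that("likelihood is invariant to site and within-season visit order", {
  set.seed(24)
  y <- matrix(rpois(8 * 4, 2), 8, 4)
  ds <- make_tiny_dataset(y)
  spec <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "ZIP", K = 60)
  beta <- c(log(2), qlogis(0.2), log(1), qlogis(0.5), qlogis(0.4))
  ll <- dynamic_loglik(beta, ds, spec)
  # permute sites
  perm <- sample(8)
  ds_p <- make_tiny_dataset(y[perm, ])
  expect_equal(dynamic_loglik(beta, ds_p, spec), ll, tolerance = 1e-12)
  # swap the two visits within each season (detection is constant here)
  ds_v <- make_tiny_dataset(y[, c(2, 1, 4, 3)])
  expect_equal(dynamic_loglik(beta, ds_v, spec), ll, tolerance = 1e-12)
})

test_that("truncation bound K is stable once adequate", {
  set.seed(25)
  sc <- sim_scenario(
    n_sites = 40L, n_treated = 20L,
    lambda_coefs = c("(Intercept)" = log(2)), psi = 0,
    gamma_coefs = c("(Intercept)" = log(2)), omega = 0.5,
    p_coefs = c("(Intercept)" = qlogis(0.5)), seed = 77L
  )
  st <- simulate_baci_study(sc)
  f <- fit_nmix(
    st$dataset,
    nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 60),
    starts = 1
  )
  spec2 <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 120)
  expect_equal(
    dynamic_loglik(f$beta, st$dataset, spec2), f$loglik,
    tolerance = 1e-6
  )
  expect_true(f$convergence)
})

test_that("all-zero counts drive lambda to the zero boundary", {
  ds <- make_tiny_dataset(matrix(0L, 10, 4))
  f <- fit_nmix(
    ds, nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 30),
    starts = 1
  )
  expect_lt(exp(f$beta[["lambda:(Intercept)"]]), 0.05)
  expect_gt(f$loglik, -0.5) # probability of all-zero data near 1
})

test_that("abundance projection follows the expectation recursion", {
  expect_equal(project_abundance(10, 0.5, 3, 1), 10)
  expect_equal(project_abundance(10, 0.5, 3, 2), 8)
  expect_equal(project_abundance(10, 0.5, 3, 3), 7) # 10*.25 + 3*1.5
  expect_equal(project_abundance(10, 0.5, 3, 400), 6, tolerance = 1e-9)
  expect_equal(project_abundance(10, 1, 3, 4), 19) # omega = 1 limit
  expect_error(project_abundance(10, 0.5, 3, 0), "integer")
})

test_that("expected site abundance applies the mixture mean and dynamics", {
  set.seed(26)
  y <- matrix(rpois(4 * 4, 2), 4, 4)
  ds <- make_tiny_dataset(y)
  spec <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "ZIP", K = 40)
  fr <- dynmix:::nmix_frame(ds, spec)
  beta <- c(log(4), qlogis(0.5), log(2), qlogis(0.6), qlogis(0.4))
  fit <- structure(
    list(spec = spec, frame = fr, beta = beta,
         vcov = diag(1e-4, 5), convergence = TRUE),
    class = "nmix_fit"
  )
  e1 <- expected_site_abundance(fit, season = 1)
  expect_equal(e1$expected_N, rep(0.5 * 4, 4)) # (1 - psi) * lambda
  e2 <- expected_site_abundance(fit, season = 2)
  expect_equal(e2$expected_N, rep(0.6 * 2 + 2, 4)) # omega*E[N1] + gamma
  fit$convergence <- FALSE
  expect_error(expected_site_abundance(fit, 1), "non-converged")
})

test_that("delta-method SE of expected abundance tracks the bootstrap SD", {
  set.seed(27)
  sc <- sim_scenario(
    n_sites = 80L, n_treated = 40L,
    lambda_coefs = c("(Intercept)" = log(2.5)), psi = 0,
    gamma_coefs = c("(Intercept)" = log(2)), omega = 0.5,
    p_coefs = c("(Intercept)" = qlogis(0.5)), seed = 88L
  )
  st <- simulate_baci_study(sc)
  spec <- nmix_spec(lambda = ~1, gamma = ~1, p = ~1, mixture = "P", K = 50)
  fit <- fit_nmix(st$dataset, spec, starts = 1)
  se_delta <- expected_site_abundance(fit, 1)$se[1]
  reps <- simulate(fit, nsim = 60, seed = 1)
  boot <- vapply(reps, function(y) {
    fr <- fit$frame
    fr$y <- y
    opt <- stats::optim(fit$beta, function(b) {
      v <- -dynmix:::nmix_loglik_frame(b, fr)
      if (!is.finite(v)) 1e10 else v
    }, method = "BFGS", control = list(maxit = 200, reltol = 1e-8))
    dynmix:::nmix_expected_abundance_beta(opt$par, fr, 1)[1]
  }, numeric(1))
  expect_gt(se_delta / sd(boot), 0.5)
  expect_lt(se_delta / sd(boot), 2)
})
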