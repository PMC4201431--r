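# shared fixture builders and independent oracles

# tiny count dataset: explicit counts matrix (sites x T*J), site covariates
make_tiny_dataset <- function(y, T = 2, J = 2, site_covs = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  counts <- expand.grid(visit = seq_len(J), season = seq_len(T),
                        site = seq_len(n))[, c("site", "season", "visit")]
  counts <- counts[order(counts$site, counts$season, counts$visit), ]
  counts$count <- as.integer(t(y))
  counts$year <- counts$season - 1
  sites <- data.frame(site = seq_len(n))
  if (!is.null(site_covs)) sites <- cbind(sites, site_covs)
  count_dataset(counts, sites)
}

# exhaustive-enumeration oracle for the two-season dynamic likelihood
brute_dyn_loglik <- function(y, lambda, psi, omega, gamma, p, K = 60) {
  # y: matrix sites x 4 (s1v1 s1v2 s2v1 s2v2); lambda, gamma scalars or
  # per-site; p scalar or sites x 4
  n <- nrow(y)
  lambda <- rep(lambda, length.out = n)
  gamma <- rep(gamma, length.out = n)
  if (length(p) == 1) p <- matrix(p, n, 4)
  ll <- 0
  for (i in seq_len(n)) {
    tot <- 0
    for (N1 in 0:K) {
      m <- psi * (N1 == 0) + (1 - psi) * dpois(N1, lambda[i])
      g1 <- dbinom(y[i, 1], N1, p[i, 1]) * dbinom(y[i, 2], N1, p[i, 2])
      if (m * g1 == 0) next
      for (N2 in 0:K) {
        s <- 0:min(N1, N2)
        tr <- sum(dbinom(s, N1, omega) * dpois(N2 - s, gamma[i]))
        g2 <- dbinom(y[i, 3], N2, p[i, 3]) * dbinom(y[i, 4], N2, p[i, 4])
        tot <- tot + m * g1 * tr * g2
      }
    }
    ll <- ll + log(tot)
  }
  ll
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal
# Jacobi matrix); oracle for the GLMM Laplace approximation
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  Jm[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(Jm, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# exact (to quadrature accuracy) Poisson random-intercept loglik
gh_glmm_loglik <- function(beta, sigma_u, dataset, formula, n_nodes = 61) {
  X <- build_design_matrix(dataset, formula, level = "observation")
  y <- dataset$counts$count
  eta <- drop(X %*% beta)
  site <- match(dataset$counts$site, dataset$sites$site)
  gh <- gauss_hermite(n_nodes)
  u <- sqrt(2) * sigma_u * gh$nodes
  ll <- 0
  for (i in unique(site)) {
    rows <- which(site == i)
    contrib <- vapply(seq_along(u), function(q) {
      sum(dpois(y[rows], exp(eta[rows] + u[q]), log = TRUE))
    }, numeric(1))
    ll <- ll + log(sum(gh$weights / sqrt(pi) * exp(contrib)))
  }
  ll
}

# capture histories from capture counts on two occasions
make_two_occasion_histories <- function(x10, x01, x11) {
  h <- rbind(
    matrix(rep(c(1L, 0L), x10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), x01), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), x11), ncol = 2, byrow = TRUE)
  )
  capture_history_set(h, c(0, 0.1))
}
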