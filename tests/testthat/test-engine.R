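test_that("zero dynamics make follow-up a copy of baseline in the implied moments", {
  theta <- lcs_parameters(mu_ede0 = 3.4, mu_bdi0 = 2.3,
                          phi_ee = 2.5, phi_bb = 1.3, phi_eb = 0.9,
                          psi_dede = 0, psi_dbdi = 0)
  mom <- implied_moments(theta)
  expect_equal(unname(mom$mu), c(3.4, 2.3, 3.4, 2.3))
  expect_equal(mom$sigma["ede_t1", "ede_t1"], 2.5)
  expect_equal(mom$sigma["ede_t0", "ede_t1"], 2.5)
  expect_equal(mom$sigma["bdi_t0", "bdi_t1"], 1.3)
  expect_equal(mom$sigma["ede_t1", "bdi_t1"], 0.9)
})

test_that("nonrecursive coupling is solved exactly by the (I - A)^-1 algebra", {
  # dE = zE + 0.5 dB, dB = zB + 0.5 dE with unit exogenous variances:
  # reduced form divides by (1 - 0.25), so Var(d) = 1.25/0.5625 = 20/9 and
  # Cov(dE, dB) = 1/0.5625 = 16/9
  theta <- lcs_parameters(eps_ede = 0.5, eps_bdi = 0.5)
  mom <- implied_moments(theta)
  expect_equal(unname(mom$mu), rep(0, 4))
  expect_equal(mom$sigma["ede_t1", "ede_t1"], 1 + 20 / 9)
  expect_equal(mom$sigma["bdi_t1", "bdi_t1"], 1 + 20 / 9)
  expect_equal(mom$sigma["ede_t1", "bdi_t1"], 16 / 9)
  expect_equal(mom$sigma["ede_t0", "ede_t1"], 1)
  expect_equal(mom$sigma["ede_t0", "bdi_t1"], 0)
  expect_error(implied_moments(lcs_parameters(eps_ede = 2, eps_bdi = 0.5)),
               "singular")
})

test_that("implied moments match the per-case simulation oracle", {
  points <- list(
    default_truth(),
    lcs_parameters(mu_ede0 = 1, mu_bdi0 = -1, phi_ee = 2, phi_bb = 1,
                   phi_eb = -0.5, alpha_ede = 0.3, alpha_bdi = -0.2,
                   beta_ede = -0.2, beta_bdi = -0.4, gamma_ede = 0.1,
                   gamma_bdi = 0.3, eps_ede = 0.4, eps_bdi = 0.4,
                   psi_dede = 0.8, psi_dbdi = 1.2))
  for (k in seq_along(points)) {
    theta <- points[[k]]
    set.seed(100 + k)
    X <- simulate_lcs_cases(theta, 200000)
    mom <- implied_moments(theta)
    n <- nrow(X)
    for (j in 1:4) {
      mc_se <- sd(X[, j]) / sqrt(n)
      expect_lt(abs(mean(X[, j]) - mom$mu[j]), 4 * mc_se)
    }
    Xc <- sweep(X, 2, colMeans(X))
    for (a in 1:4) for (b in a:4) {
      prod_ab <- Xc[, a] * Xc[, b]
      mc_se <- sd(prod_ab) / sqrt(n)
      expect_lt(abs(mean(prod_ab) - mom$sigma[a, b]), 4 * mc_se)
    }
  }
})

test_that("FIML log-density has its closed form for a single complete case", {
  theta <- lcs_parameters(phi_ee = 1, phi_bb = 1, psi_dede = 0, psi_dbdi = 0)
  mom <- implied_moments(theta)
  # baseline-only case: its implied submatrix is the 2x2 identity here
  x <- matrix(mom$mu + c(0.3, -0.2, 0.3, -0.2), 1, 4,
              dimnames = list(NULL, c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")))
  x[, 3:4] <- NA  # baseline-only case keeps the submatrix nonsingular
  expect_equal(fiml_loglik(theta, x),
               mvn_logdens(x[1, 1:2], mom$mu[1:2], mom$sigma[1:2, 1:2]))
  # the textbook closed form: observed subvector at the mean under an
  # identity implied covariance contributes -(p/2) log(2*pi)
  x0 <- matrix(c(0, 0, NA, NA), 1, 4,
               dimnames = list(NULL, c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")))
  expect_equal(fiml_loglik(theta, x0), -log(2 * pi))
})

test_that("pattern-grouped FIML equals the per-case brute force", {
  panel <- make_panel(300, seed = 17)
  X <- as.matrix(panel[, c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")])
  theta <- default_truth()
  expect_equal(fiml_loglik(theta, X), bruteforce_fiml(theta, X),
               tolerance = 1e-10)
  # casewise evaluation sums to the total
  expect_equal(sum(fiml_loglik(theta, X, casewise = TRUE)),
               fiml_loglik(theta, X), tolerance = 1e-10)
  # a case missing all four scores is rejected
  Xbad <- rbind(X, NA)
  expect_error(fiml_loglik(theta, Xbad), "zero observed")
})

test_that("saturated FIML on complete data equals the closed-form solution", {
  panel <- make_panel(400, seed = 23, dropout_rate = 0)
  X <- as.matrix(panel[, c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")])
  sat <- fit_saturated(X)
  expect_equal(unname(sat$mu), unname(colMeans(X)), tolerance = 1e-10)
  S_ml <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(unname(sat$sigma), unname(S_ml), tolerance = 1e-10)
  # log-likelihood equals the closed-form multivariate-normal maximum
  ll_closed <- -0.5 * nrow(X) *
    (4 * log(2 * pi) + determinant(S_ml, logarithm = TRUE)$modulus[1] + 4)
  expect_equal(sat$loglik, ll_closed, tolerance = 1e-8)
})

test_that("baseline (independence) model has closed-form FIML with missingness", {
  panel <- make_panel(500, seed = 29)
  base <- fit_baseline(panel)
  expect_identical(base$df, 6L)
  X <- as.matrix(panel[, c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")])
  # per-variable ML moments over observed cases
  for (j in 1:4) {
    x <- X[, j][!is.na(X[, j])]
    expect_equal(unname(base$mu[j]), mean(x))
    expect_equal(base$sigma[j, j], mean((x - mean(x))^2))
  }
  # the reported log-likelihood equals a per-case brute-force evaluation
  ll_brute <- sum(vapply(seq_len(nrow(X)), function(i) {
    v <- which(!is.na(X[i, ]))
    mvn_logdens(X[i, v], base$mu[v], base$sigma[v, v, drop = FALSE])
  }, numeric(1)))
  expect_equal(base$loglik, ll_brute, tolerance = 1e-10)
})

test_that("degrees of freedom reproduce the variant battery layout", {
  v <- lcs_variants()
  expect_length(v, 10)
  expect_identical(model_df(v$final), 2L)
  for (nm in c("free_alpha_ede", "free_alpha_bdi", "free_eps_ede")) {
    expect_identical(model_df(v[[nm]]), 1L)
  }
  for (nm in grep("^fix_", names(v), value = TRUE)) {
    expect_identical(model_df(v[[nm]]), 3L)
  }
  expect_error(lcs_variant("bad", c(nonsense = 0)), "unknown")
})

test_that("estimates recover the generating truth at large n", {
  panel <- make_panel(5000, seed = 31, dropout_rate = 0)
  fit <- fit_model(lcs_variants()$final, panel, se = "naive")
  expect_true(fit$converged)
  truth <- default_truth()
  for (p in fit$free) {
    expect_lt(abs(fit$estimates[[p]] - truth[[p]]), 3 * fit$se_naive[[p]],
              label = paste("recovery of", p))
  }
})

test_that("nesting orders the maximized log-likelihoods", {
  panel <- make_panel(800, seed = 37)
  prep <- bilcs:::fiml_prepare(panel)
  v <- lcs_variants()
  final <- fit_model(v$final, prep, se = "none")
  sat <- fit_saturated(prep)
  expect_gte(sat$loglik, final$loglik)
  for (nm in c("fix_beta_ede", "fix_eps_bdi", "fix_phi_eb")) {
    nested <- fit_model(v[[nm]], prep, se = "none")
    expect_gte(final$loglik + 1e-6, nested$loglik,
               label = paste("nesting vs", nm))
  }
  # a variant constraining a truly nonzero coupling fits strictly worse
  nested <- fit_model(v$fix_eps_bdi, prep, se = "none")
  expect_gt(final$loglik, nested$loglik)
  # richer model on the same data cannot fit worse
  richer <- fit_model(v$free_alpha_ede, prep, se = "none")
  expect_gte(richer$loglik + 1e-6, final$loglik)
})

test_that("sandwich covariance scales as 1/n when the panel is duplicated", {
  panel <- make_panel(400, seed = 41)
  cols <- c("ede_t0", "bdi_t0", "ede_t1", "bdi_t1")
  fit1 <- fit_model(lcs_variants()$final, panel[, cols])
  panel2 <- rbind(panel[, cols], panel[, cols])
  fit2 <- fit_model(lcs_variants()$final, panel2)
  expect_true(fit1$converged && fit2$converged)
  ratio <- fit1$se_sandwich / fit2$se_sandwich
  expect_equal(unname(ratio), rep(sqrt(2), length(ratio)), tolerance = 0.02)
})

test_that("heteroskedastic disturbances inflate the sandwich errors", {
  # disturbance SD of the depression change increases with baseline ED score:
  # the information equality breaks and the robust SEs must exceed the naive
  # ones for the affected regression paths
  set.seed(43)
  n <- 20000
  theta <- default_truth()
  base <- MASS::mvrnorm(n, c(theta[["mu_ede0"]], theta[["mu_bdi0"]]),
                        matrix(c(theta[["phi_ee"]], theta[["phi_eb"]],
                                 theta[["phi_eb"]], theta[["phi_bb"]]), 2))
  e0 <- base[, 1]; b0 <- base[, 2]
  d_e <- theta[["beta_ede"]] * e0 + theta[["gamma_ede"]] * b0 +
    rnorm(n, 0, sqrt(theta[["psi_dede"]]))
  het_sd <- sqrt(theta[["psi_dbdi"]]) * (0.25 + abs(e0 - mean(e0)))
  d_b <- theta[["beta_bdi"]] * b0 + theta[["gamma_bdi"]] * e0 +
    theta[["eps_bdi"]] * d_e + rnorm(n, 0, het_sd)
  panel <- cbind(ede_t0 = e0, bdi_t0 = b0, ede_t1 = e0 + d_e,
                 bdi_t1 = b0 + d_b)
  fit <- fit_model(lcs_variants()$final, panel)
  expect_true(fit$converged)
  for (p in c("beta_bdi", "gamma_bdi", "psi_dbdi")) {
    expect_gt(fit$se_sandwich[[p]], fit$se_naive[[p]],
              label = paste("sandwich >", p))
  }
})

test_that("fitting refuses panels smaller than the free parameter count", {
  panel <- make_panel(8, seed = 47, dropout_rate = 0)
  expect_error(fit_model(lcs_variants()$final, panel), "fewer cases")
})
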