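#' Dropout specification for synthetic cohorts
#'
#' @param mechanism "MCAR" (follow-up blanked independently of everything) or
#'   "MAR_on_baseline" (dropout probability a logistic function of baseline
#'   scores).
#' @param target_rate expected follow-up missingness proportion in [0, 1).
#'   Default 0.229, the attrition of the reference cohort (36 of 157).
#' @param logit_slopes length-2 numeric: log-odds slopes on baseline
#'   (ede_t0, bdi_t0). Must be zero under MCAR.
#' @return object of class `lcs_dropout`.
#' @export
dropout_spec <- function(mechanism = c("MCAR", "MAR_on_baseline"),
                         target_rate = 0.229,
                         logit_slopes = c(0, 0)) {
  mechanism <- match.arg(mechanism)
  if (target_rate < 0 || target_rate >= 1) stop("target_rate must be in [0, 1)")
  logit_slopes <- rep_len(as.numeric(logit_slopes), 2)
  if (mechanism == "MCAR" && any(logit_slopes != 0)) {
    stop("MCAR requires zero logit slopes")
  }
  structure(list(mechanism = mechanism, target_rate = target_rate,
                 logit_slopes = logit_slopes), class = "lcs_dropout")
}

#' Generative configuration for synthetic cohorts
#'
#' Defaults reproduce the statistical frame of the reference cohort: n = 157;
#' baseline means 3.43 (EDE-Q total) and 2.278 (depression total already on
#' the divided-by-10 analysis scale) with SDs 1.58 and 1.141; a configurable
#' baseline correlation (0.5 — a synthetic-only choice, the source analysis
#' does not print one); ~22.9% follow-up attrition. The default true paths
#' are illustrative, not published estimates: negative proportional effects,
#' positive cross-lagged effects, a positive ED-change-to-depression-change
#' coupling, and disturbance variances chosen so the implied follow-up SDs
#' match the reference cohort's printed follow-up SDs.
#'
#' @param n_participants cohort size.
#' @param baseline_means,baseline_sds length-2 (EDE-Q, depression/10).
#' @param baseline_correlation in (-1, 1).
#' @param true_paths full parameter vector ([lcs_parameters()]); its baseline
#'   moment entries are overwritten from the four arguments above.
#' @param dropout a [dropout_spec()].
#' @param clamp_to_range clamp generated scores to instrument ranges
#'   (off by default: the model is a normal model).
#' @param seed integer seed.
#' @return object of class `lcs_synth_config`.
#' @export
synthetic_config <- function(n_participants = 157,
                             baseline_means = c(3.43, 2.278),
                             baseline_sds = c(1.58, 1.141),
                             baseline_correlation = 0.5,
                             true_paths = NULL,
                             dropout = dropout_spec(),
                             clamp_to_range = FALSE,
                             seed = 1L) {
  if (n_participants < 1) stop("need a positive cohort size")
  if (any(baseline_sds <= 0)) stop("baseline SDs must be positive")
  if (abs(baseline_correlation) >= 1) {
    stop("baseline correlation must lie strictly inside (-1, 1)")
  }
  if (is.null(true_paths)) {
    true_paths <- lcs_parameters(
      beta_ede = -0.45, beta_bdi = -0.65,
      gamma_ede = 0.25, gamma_bdi = 0.25,
      eps_ede = 0, eps_bdi = 0.30,
      psi_dede = 1.74, psi_dbdi = 0.98)
  }
  true_paths[["mu_ede0"]] <- baseline_means[1]
  true_paths[["mu_bdi0"]] <- baseline_means[2]
  true_paths[["phi_ee"]] <- baseline_sds[1]^2
  true_paths[["phi_bb"]] <- baseline_sds[2]^2
  true_paths[["phi_eb"]] <- baseline_correlation * prod(baseline_sds)
  structure(list(n_participants = as.integer(n_participants),
                 baseline_means = baseline_means,
                 baseline_sds = baseline_sds,
                 baseline_correlation = baseline_correlation,
                 true_paths = true_paths,
                 dropout = dropout,
                 clamp_to_range = clamp_to_range,
                 seed = as.integer(seed)),
            class = "lcs_synth_config")
}

#' Simulate cases from the structural model at an arbitrary parameter point
#'
#' Draws the exogenous baseline pair and the change disturbances, then solves
#' the two simultaneous change equations exactly per case, so nonrecursive
#' points (both change couplings nonzero) are simulated correctly. Used as
#' the Monte-Carlo oracle for [implied_moments()] and inside
#' [generate_cohort()].
#'
#' @param theta full parameter vector.
#' @param n number of cases.
#' @return n x 4 matrix with columns ede_t0, bdi_t0, ede_t1, bdi_t1.
#' @export
simulate_lcs_cases <- function(theta, n) {
  det <- 1 - theta[["eps_ede"]] * theta[["eps_bdi"]]
  if (abs(det) < 1e-12) stop("eps_ede * eps_bdi = 1: system is singular")
  Phi <- matrix(c(theta[["phi_ee"]], theta[["phi_eb"]],
                  theta[["phi_eb"]], theta[["phi_bb"]]), 2, 2)
  base <- MASS::mvrnorm(n, mu = c(theta[["mu_ede0"]], theta[["mu_bdi0"]]),
                        Sigma = Phi)
  if (n == 1) base <- matrix(base, 1, 2)
  e0 <- base[, 1]; b0 <- base[, 2]
  z_e <- stats::rnorm(n, 0, sqrt(theta[["psi_dede"]]))
  z_b <- stats::rnorm(n, 0, sqrt(theta[["psi_dbdi"]]))
  # reduced form of: dE = aE + eps_ede * dB; dB = aB + eps_bdi * dE
  a_e <- theta[["alpha_ede"]] + theta[["beta_ede"]] * e0 +
    theta[["gamma_ede"]] * b0 + z_e
  a_b <- theta[["alpha_bdi"]] + theta[["gamma_bdi"]] * e0 +
    theta[["beta_bdi"]] * b0 + z_b
  d_e <- (a_e + theta[["eps_ede"]] * a_b) / det
  d_b <- (a_b + theta[["eps_bdi"]] * a_e) / det
  cbind(ede_t0 = e0, bdi_t0 = b0, ede_t1 = e0 + d_e, bdi_t1 = b0 + d_b)
}

#' Generate a synthetic two-wave cohort
#'
#' Draws the baseline pair from a bivariate normal, computes the latent
#' changes from the structural equations in causal order (forward simulation
#' requires a recursive truth: at most one change coupling nonzero), sets
#' T1 = T0 + change, and applies the configured dropout to the follow-up
#' scores. Deterministic under a fixed seed.
#'
#' @param config an [synthetic_config()].
#' @return wide data frame (participant_id, ede_t0, bdi_t0, ede_t1, bdi_t1)
#'   with the generative truth attached as attribute `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "lcs_synth_config"))
  theta <- config$true_paths
  if (theta[["eps_ede"]] != 0 && theta[["eps_bdi"]] != 0) {
    stop("forward simulation requires a recursive truth: ",
         "at most one of eps_ede, eps_bdi may be nonzero")
  }
  set.seed(config$seed)
  X <- simulate_lcs_cases(theta, config$n_participants)
  if (config$clamp_to_range) {
    X[, c("ede_t0", "ede_t1")] <- pmin(pmax(X[, c("ede_t0", "ede_t1")], 0), 6)
    X[, c("bdi_t0", "bdi_t1")] <- pmin(pmax(X[, c("bdi_t0", "bdi_t1")], 0), 6.3)
  }
  panel <- data.frame(participant_id = sprintf("P%04d",
                                               seq_len(config$n_participants)),
                      X)
  panel <- apply_dropout(panel, config$dropout,
                         seed = config$seed + 1000003L)
  attr(panel, "truth") <- theta
  panel
}

# Solve the logistic intercept so that mean dropout probability hits the
# target rate given the linear predictor offsets.
solve_dropout_intercept <- function(offsets, target_rate) {
  if (target_rate == 0) return(-Inf)
  f <- function(a) mean(stats::plogis(a + offsets)) - target_rate
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("target dropout rate unreachable")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Blank follow-up scores according to a dropout specification
#'
#' Each case's follow-up is blanked independently with probability
#' plogis(intercept + slopes . baseline); the intercept is solved numerically
#' so the expected missingness rate equals the target rate.
#'
#' @param panel wide panel with complete follow-up columns ede_t1, bdi_t1.
#' @param spec a [dropout_spec()].
#' @param seed integer seed.
#' @return the panel with follow-up blanked (NA) for dropouts.
#' @export
apply_dropout <- function(panel, spec, seed = 1L) {
  stopifnot(inherits(spec, "lcs_dropout"))
  if (anyNA(panel$ede_t1) || anyNA(panel$bdi_t1)) {
    stop("apply_dropout expects complete follow-up scores")
  }
  if (spec$target_rate == 0) return(panel)
  offsets <- spec$logit_slopes[1] * panel$ede_t0 +
    spec$logit_slopes[2] * panel$bdi_t0
  a <- solve_dropout_intercept(offsets, spec$target_rate)
  set.seed(seed)
  drop <- stats::runif(nrow(panel)) < stats::plogis(a + offsets)
  panel$ede_t1[drop] <- NA_real_
  panel$bdi_t1[drop] <- NA_real_
  panel
}

#' Generate item-level responses with a target reliability
#'
#' Parallel-items model: item_j = F + e_j with a common standard-normal
#' factor and iid noise whose variance is chosen so the population Cronbach's
#' alpha equals `target_alpha` (via the common inter-item correlation
#' r = alpha / (k - alpha (k - 1))).
#'
#' @param n_cases number of cases.
#' @param k_items number of items (>= 2).
#' @param target_alpha population reliability in (0, 1).
#' @param seed integer seed.
#' @return n_cases x k_items numeric matrix.
#' @export
generate_item_responses <- function(n_cases, k_items, target_alpha, seed = 1L) {
  if (k_items < 2) stop("need at least 2 items")
  if (target_alpha <= 0 || target_alpha >= 1) {
    stop("target_alpha must lie strictly inside (0, 1)")
  }
  r <- target_alpha / (k_items - target_alpha * (k_items - 1))
  if (r <= 0 || r >= 1) stop("infeasible target reliability for k = ", k_items)
  noise_var <- (1 - r) / r
  set.seed(seed)
  f <- stats::rnorm(n_cases)
  f + matrix(stats::rnorm(n_cases * k_items, 0, sqrt(noise_var)),
             n_cases, k_items)
}
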