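# Canonical parameter order for the bivariate two-wave LCS model.
# Means/covariance of the baseline pair, LCS intercepts (alpha),
# proportional/autoregressive effects (beta), cross-lagged effects (gamma),
# change-on-change couplings (eps), and change disturbance variances (psi).
lcs_param_names <- c(
  "mu_ede0", "mu_bdi0",
  "phi_ee", "phi_bb", "phi_eb",
  "alpha_ede", "alpha_bdi",
  "beta_ede", "beta_bdi",
  "gamma_ede", "gamma_bdi",
  "eps_ede", "eps_bdi",
  "psi_dede", "psi_dbdi"
)

# Parameters that are variances and are optimised on the log scale.
lcs_variance_params <- c("phi_ee", "phi_bb", "psi_dede", "psi_dbdi")

#' Construct a full LCS parameter vector
#'
#' Builds the named 15-element parameter vector of the bivariate latent
#' change score model: baseline means (`mu_ede0`, `mu_bdi0`), baseline
#' variances/covariance (`phi_ee`, `phi_bb`, `phi_eb`), change intercepts
#' (`alpha_ede`, `alpha_bdi`), proportional effects of a construct's own
#' baseline on its change (`beta_ede`, `beta_bdi`), cross-lagged effects of
#' the other construct's baseline (`gamma_ede`, `gamma_bdi`),
#' change-on-change couplings (`eps_ede`: change in depression driving
#' change in eating-disorder psychopathology; `eps_bdi`: the reverse), and
#' change disturbance variances (`psi_dede`, `psi_dbdi`).
#'
#' Unspecified structural paths default to zero; unspecified moments default
#' to a unit-variance uncorrelated baseline centred at zero with unit
#' disturbance variances.
#'
#' @param ... named parameter values overriding the defaults.
#' @return a named numeric vector of length 15.
#' @examples
#' theta <- lcs_parameters(mu_ede0 = 3.43, mu_bdi0 = 2.278,
#'                         phi_ee = 1.58^2, phi_bb = 1.141^2,
#'                         beta_ede = -0.45)
#' @export
lcs_parameters <- function(...) {
  theta <- c(
    mu_ede0 = 0, mu_bdi0 = 0,
    phi_ee = 1, phi_bb = 1, phi_eb = 0,
    alpha_ede = 0, alpha_bdi = 0,
    beta_ede = 0, beta_bdi = 0,
    gamma_ede = 0, gamma_bdi = 0,
    eps_ede = 0, eps_bdi = 0,
    psi_dede = 1, psi_dbdi = 1
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), lcs_param_names)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown or unnamed parameter(s): ", paste(bad, collapse = ", "))
    }
    theta[names(dots)] <- dots
  }
  if (theta["phi_ee"] < 0 || theta["phi_bb"] < 0 ||
      theta["psi_dede"] < 0 || theta["psi_dbdi"] < 0) {
    stop("variance parameters must be nonnegative")
  }
  if (theta["phi_ee"] * theta["phi_bb"] - theta["phi_eb"]^2 < 0) {
    stop("baseline covariance matrix is not positive semi-definite")
  }
  theta
}

#' Define a model variant by its constraint set
#'
#' A variant is a named set of parameters held fixed (usually at zero) while
#' the remaining parameters are estimated freely.
#'
#' @param name label for the variant.
#' @param fixed named numeric vector of parameters fixed at given values.
#' @param constraint human-readable description of how the variant differs
#'   from the primary (final) model.
#' @return an object of class `lcs_variant`.
#' @export
lcs_variant <- function(name, fixed = numeric(0), constraint = "") {
  if (length(fixed)) {
    bad <- setdiff(names(fixed), lcs_param_names)
    if (length(bad)) stop("unknown parameter(s) in constraint set: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(name = name, fixed = fixed, constraint = constraint),
            class = "lcs_variant")
}

#' The ten-variant battery of nested model comparisons
#'
#' Returns the primary ("final") model — both change intercepts and the
#' depression-to-ED change coupling fixed to zero — plus three unconstrained
#' variants (each of those three parameters freed singly) and six constrained
#' variants (each freely estimated effect, or the baseline covariance, fixed
#' to zero singly on top of the final model).
#'
#' @return named list of 10 `lcs_variant` objects; the first is the final model.
#' @export
lcs_variants <- function() {
  final_fixed <- c(alpha_ede = 0, alpha_bdi = 0, eps_ede = 0)
  v <- list(
    final = lcs_variant("final", final_fixed, "primary model"),
    free_alpha_ede = lcs_variant(
      "free_alpha_ede", final_fixed[c("alpha_bdi", "eps_ede")],
      "alpha_ede freed"),
    free_alpha_bdi = lcs_variant(
      "free_alpha_bdi", final_fixed[c("alpha_ede", "eps_ede")],
      "alpha_bdi freed"),
    free_eps_ede = lcs_variant(
      "free_eps_ede", final_fixed[c("alpha_ede", "alpha_bdi")],
      "eps_ede freed")
  )
  for (p in c("beta_ede", "beta_bdi", "gamma_ede", "gamma_bdi",
              "eps_bdi", "phi_eb")) {
    fx <- c(final_fixed, stats::setNames(0, p))
    v[[paste0("fix_", p)]] <- lcs_variant(paste0("fix_", p), fx,
                                          paste(p, "= 0"))
  }
  v
}

free_param_names <- function(variant) {
  setdiff(lcs_param_names, names(variant$fixed))
}

#' Model degrees of freedom
#'
#' Degrees of freedom of an LCS model variant against the saturated model of
#' the four observed variables: 14 identified moments (4 means + 10 unique
#' covariance elements) minus the number of freely estimated parameters.
#'
#' @param variant an `lcs_variant`.
#' @return integer degrees of freedom.
#' @export
model_df <- function(variant) {
  stopifnot(inherits(variant, "lcs_variant"))
  df <- 14L - length(free_param_names(variant))
  if (df < 0L) stop("variant is over-parameterized (df < 0)")
  df
}

#' @export
print.lcs_variant <- function(x, ...) {
  cat("LCS model variant:", x$name, "\n")
  if (nzchar(x$constraint)) cat("  ", x$constraint, "\n")
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  } else {
    cat("  fixed: none (saturated structural parameterization)\n")
  }
  cat("  free parameters:", length(free_param_names(x)),
      " df:", model_df(x), "\n")
  invisible(x)
}
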