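# Duplication matrix D_p: vec(S) = D %*% vech(S) for symmetric S.
duplication_matrix <- function(p) {
  D <- matrix(0, p * p, p * (p + 1) / 2)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

vech <- function(S) S[lower.tri(S, diag = TRUE)]

#' Likelihood-ratio chi-square against the saturated model
#'
#' @param model_fit an `lcs_fit`.
#' @param saturated_fit the [fit_saturated()] result on the same panel.
#' @return list with `chisq` (clamped at zero for round-off) and `df`.
#' @export
model_chisq <- function(model_fit, saturated_fit) {
  if (model_fit$n != saturated_fit$n) {
    stop("model and saturated fits come from different panels (n differs)")
  }
  chisq <- max(2 * (saturated_fit$loglik - model_fit$loglik), 0)
  list(chisq = chisq, df = model_fit$df)
}

#' Comparative Fit Index
#'
#' CFI = 1 - max(chisq_M - df_M, 0) / max(chisq_B - df_B, chisq_M - df_M, 0).
#' A degenerate baseline (chisq_B <= df_B) yields 1 with a flag.
#'
#' @param chisq_m,df_m model statistic and degrees of freedom.
#' @param chisq_b,df_b baseline (independence) statistic and df.
#' @return numeric in [0, 1], with attribute `degenerate_baseline` when the
#'   baseline carries no misfit.
#' @export
cfi <- function(chisq_m, df_m, chisq_b, df_b) {
  if (df_b <= 0) stop("baseline df must be positive")
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, chisq_m - df_m, 0)
  if (den == 0) {
    return(structure(1, degenerate_baseline = chisq_b <= df_b))
  }
  out <- 1 - num / den
  if (chisq_b <= df_b) attr(out, "degenerate_baseline") <- TRUE
  out
}

#' Tucker-Lewis Index
#'
#' TLI = ((chisq_B/df_B) - (chisq_M/df_M)) / ((chisq_B/df_B) - 1),
#' deliberately not clipped, so values slightly above 1 are reported as such.
#'
#' @inheritParams cfi
#' @return numeric (can exceed 1).
#' @export
tli <- function(chisq_m, df_m, chisq_b, df_b) {
  if (df_b <= 0) stop("baseline df must be positive")
  if (df_m <= 0) stop("model df must be positive")
  rb <- chisq_b / df_b
  if (abs(rb - 1) < 1e-12) {
    return(structure(1, degenerate_baseline = TRUE))
  }
  out <- (rb - chisq_m / df_m) / (rb - 1)
  if (rb <= 1) attr(out, "degenerate_baseline") <- TRUE
  out
}

#' Root Mean Square Error of Approximation
#'
#' sqrt(max(chisq - df, 0) / (df * (n - 1))). The divisor n - 1 is the common
#' software convention; `divisor_n` switches to n.
#'
#' @param chisq model chi-square.
#' @param df model degrees of freedom (> 0).
#' @param n number of cases.
#' @param divisor_n use n instead of n - 1.
#' @return nonnegative numeric.
#' @export
rmsea <- function(chisq, df, n, divisor_n = FALSE) {
  if (df <= 0) stop("RMSEA undefined for df = 0")
  if (n <= 1) stop("need n > 1")
  den <- if (divisor_n) n else n - 1
  sqrt(max(chisq - df, 0) / (df * den))
}

#' Standardized Root Mean Square Residual
#'
#' Root mean square of the standardized covariance residuals over the 10
#' unique elements of the 4x4 covariance (residual divided by the product of
#' the saturated standard deviations); mean residuals are excluded.
#'
#' @param saturated_moments,implied_moments lists with `mu` and `sigma` on the
#'   same four variables (e.g. a `lcs_satfit` and [implied_moments()] output).
#' @return nonnegative numeric.
#' @export
srmr <- function(saturated_moments, implied_moments) {
  S <- saturated_moments$sigma
  M <- implied_moments$sigma
  if (!all(dim(S) == dim(M))) stop("moment structures differ in dimension")
  sds <- sqrt(diag(S))
  if (any(sds <= 0)) stop("zero variance in saturated moments")
  std_resid <- (S - M) / tcrossprod(sds)
  sqrt(mean(vech(std_resid)^2))
}

#' Bayesian Information Criterion
#'
#' -2 loglik + k log(n), with n all cases entering the FIML likelihood.
#'
#' @param loglik maximized log-likelihood.
#' @param n_free_params number of freely estimated parameters k.
#' @param n_cases n.
#' @return numeric.
#' @export
bic <- function(loglik, n_free_params, n_cases) {
  if (n_cases <= 0) stop("need a positive case count")
  -2 * loglik + n_free_params * log(n_cases)
}

#' Mean-scaled (robust) chi-square
#'
#' Scales the likelihood-ratio statistic by c = tr(U Gamma) / df, where Gamma
#' is the asymptotic covariance of the sample mean-and-covariance moment
#' vector estimated from fourth-order moments of the listwise-complete cases,
#' and U is the normal-theory residual weight projection at the fitted point.
#' Under multivariate normality c tends to 1; excess kurtosis inflates c and
#' deflates the scaled statistic.
#'
#' @param model_fit a converged `lcs_fit` with df > 0.
#' @param panel the fitted panel (defaults to the cached one).
#' @param min_complete minimum number of listwise-complete cases required.
#' @return list with `chisq_scaled`, `scaling`, `chisq`, `df`.
#' @export
robust_scaled_chisq <- function(model_fit, panel = NULL, min_complete = 50) {
  stopifnot(inherits(model_fit, "lcs_fit"))
  if (model_fit$df <= 0) stop("robust scaling undefined for a saturated model (df = 0)")
  prep <- if (is.null(panel)) model_fit$prep
          else if (inherits(panel, "lcs_fiml_data")) panel
          else fiml_prepare(panel)
  X <- prep$X[stats::complete.cases(prep$X), , drop = FALSE]
  nc <- nrow(X)
  if (nc < min_complete) {
    stop("need at least ", min_complete, " listwise-complete cases, have ", nc)
  }
  sat <- fit_saturated(prep)
  chisq <- model_chisq(model_fit, sat)$chisq

  # Gamma: asymptotic covariance of (xbar, vech(S)) from complete-case
  # fourth-order moments.
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  Z <- cbind(Xc, t(apply(Xc, 1, function(r) vech(tcrossprod(r)))))
  Zc <- sweep(Z, 2, colMeans(Z))
  Gamma <- crossprod(Zc) / nc

  # Normal-theory ML weight at the fitted implied moments.
  mom <- implied_moments(model_fit$estimates)
  siginv <- solve(mom$sigma)
  D <- duplication_matrix(4)
  V <- matrix(0, 14, 14)
  V[1:4, 1:4] <- siginv
  V[5:14, 5:14] <- 0.5 * t(D) %*% (siginv %x% siginv) %*% D

  # Jacobian of the implied moment vector wrt free parameters (natural scale).
  free <- model_fit$free
  theta_hat <- model_fit$estimates
  moment_vec <- function(theta) {
    m <- implied_moments(theta)
    c(m$mu, vech(m$sigma))
  }
  Delta <- matrix(0, 14, length(free))
  for (j in seq_along(free)) {
    h <- 1e-6 * (1 + abs(theta_hat[free[j]]))
    tp <- theta_hat; tp[free[j]] <- tp[free[j]] + h
    tm <- theta_hat; tm[free[j]] <- tm[free[j]] - h
    Delta[, j] <- (moment_vec(tp) - moment_vec(tm)) / (2 * h)
  }

  VD <- V %*% Delta
  U <- V - VD %*% solve(t(Delta) %*% VD) %*% t(VD)
  scaling <- sum(diag(U %*% Gamma)) / model_fit$df
  if (!is.finite(scaling) || scaling <= 0) stop("degenerate scaling factor")
  list(chisq_scaled = chisq / scaling, scaling = scaling,
       chisq = chisq, df = model_fit$df)
}

#' Chi-square difference test between nested variants
#'
#' @param full_fit the less constrained fit.
#' @param nested_fit the more constrained fit (its fixed set must contain the
#'   full model's).
#' @param scaled apply a Satorra-Bentler-style mean correction to the
#'   difference statistic, dividing by
#'   (df_nested * c_nested - df_full * c_full) / (df_nested - df_full) with
#'   the per-model scaling factors from [robust_scaled_chisq()]. Default
#'   FALSE: the plain maximum-likelihood difference.
#' @return list with `delta_chisq` (clamped at 0), `delta_df`, `p_value`, and
#'   `identical` flag when the variants coincide (p reported as 1). When
#'   `scaled`, also `scaling_diff`.
#' @export
chi_diff_test <- function(full_fit, nested_fit, scaled = FALSE) {
  stopifnot(inherits(full_fit, "lcs_fit"), inherits(nested_fit, "lcs_fit"))
  if (full_fit$n != nested_fit$n) stop("fits come from different panels")
  fixed_full <- names(full_fit$variant$fixed)
  fixed_nested <- names(nested_fit$variant$fixed)
  if (!all(fixed_full %in% fixed_nested)) {
    stop("variants are not nested: '", nested_fit$variant$name,
         "' does not constrain a superset of '", full_fit$variant$name, "'")
  }
  delta_df <- nested_fit$df - full_fit$df
  delta_chisq <- max(2 * (full_fit$loglik - nested_fit$loglik), 0)
  if (delta_df == 0) {
    return(list(delta_chisq = delta_chisq, delta_df = 0L, p_value = 1,
                identical = TRUE))
  }
  out <- list(delta_chisq = delta_chisq, delta_df = delta_df,
              p_value = stats::pchisq(delta_chisq, delta_df,
                                      lower.tail = FALSE),
              identical = FALSE)
  if (scaled) {
    if (full_fit$df == 0) stop("scaled difference needs a non-saturated full model")
    c_full <- robust_scaled_chisq(full_fit)$scaling
    c_nested <- robust_scaled_chisq(nested_fit)$scaling
    c_diff <- (nested_fit$df * c_nested - full_fit$df * c_full) / delta_df
    if (!is.finite(c_diff) || c_diff <= 0) {
      stop("degenerate difference scaling factor")
    }
    out$scaling_diff <- c_diff
    out$delta_chisq <- delta_chisq / c_diff
    out$p_value <- stats::pchisq(out$delta_chisq, delta_df, lower.tail = FALSE)
  }
  out
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", "")))
}

#' Full fit-index battery for one fit
#'
#' @param model_fit an `lcs_fit`.
#' @param saturated_fit,baseline_fit reference fits on the same panel.
#' @param robust also compute the mean-scaled chi-square (needs complete
#'   cases; see [robust_scaled_chisq()]).
#' @return list of class `lcs_fit_indices`.
#' @export
fit_indices <- function(model_fit, saturated_fit, baseline_fit,
                        robust = FALSE) {
  mc <- model_chisq(model_fit, saturated_fit)
  bc <- model_chisq_sat(baseline_fit, saturated_fit)
  mom <- implied_moments(model_fit$estimates)
  out <- list(
    chisq = mc$chisq, df = mc$df,
    p_chisq = if (mc$df > 0)
      stats::pchisq(mc$chisq, mc$df, lower.tail = FALSE) else NA_real_,
    cfi = as.numeric(cfi(mc$chisq, mc$df, bc$chisq, bc$df)),
    tli = if (mc$df > 0) as.numeric(tli(mc$chisq, mc$df, bc$chisq, bc$df))
          else NA_real_,
    rmsea = if (mc$df > 0) rmsea(mc$chisq, mc$df, model_fit$n) else NA_real_,
    srmr = srmr(saturated_fit, mom),
    bic = bic(model_fit$loglik, model_fit$n_free, model_fit$n),
    robust_chisq = NA_real_, scaling = NA_real_
  )
  if (robust && mc$df > 0) {
    rs <- robust_scaled_chisq(model_fit)
    out$robust_chisq <- rs$chisq_scaled
    out$scaling <- rs$scaling
  }
  class(out) <- "lcs_fit_indices"
  out
}

# chi-square of a reference (lcs_satfit-style) fit vs the saturated fit
model_chisq_sat <- function(ref_fit, saturated_fit) {
  list(chisq = max(2 * (saturated_fit$loglik - ref_fit$loglik), 0),
       df = ref_fit$df)
}

#' Nested model comparison table
#'
#' Fits the final model, the three unconstrained variants and the six
#' constrained variants, computes the fit-index battery for each, and tests
#' every alternative against the final model with a chi-square difference
#' test. The decision column applies the retention logic of nested model
#' comparison: a significant test on an unconstrained variant argues for
#' freeing the parameter, a significant test on a constrained variant argues
#' for keeping the effect freely estimated.
#'
#' @param panel data frame/matrix with ede_t0, bdi_t0, ede_t1, bdi_t1 on the
#'   analysis scale.
#' @param variants list of `lcs_variant`s; the first is the comparator.
#'   Defaults to [lcs_variants()].
#' @param alpha significance level for the decision column.
#' @param robust compute mean-scaled chi-squares per row.
#' @param se standard-error mode forwarded to [fit_model()].
#' @return data.frame of class `lcs_comparison` with one row per variant, and
#'   attributes `fits`, `saturated`, `baseline`.
#' @export
comparison_table <- function(panel, variants = lcs_variants(), alpha = 0.05,
                             robust = FALSE, se = "none") {
  prep <- if (inherits(panel, "lcs_fiml_data")) panel else fiml_prepare(panel)
  sat <- fit_saturated(prep)
  base <- fit_baseline(prep)
  fits <- lapply(variants, function(v) {
    tryCatch(fit_model(v, prep, se = se),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "lcs_fit_error"))
  })
  comparator <- fits[[1]]
  if (inherits(comparator, "lcs_fit_error")) {
    stop("comparator model failed: ", comparator$error)
  }
  if (!comparator$converged) {
    stop("comparator model did not converge; cannot build the table")
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    v <- variants[[i]]
    if (inherits(f, "lcs_fit_error") || !f$converged) {
      return(data.frame(model = v$name, constraint = v$constraint,
                        converged = FALSE, chisq = NA, df = model_df(v),
                        bic = NA, cfi = NA, tli = NA, rmsea = NA, srmr = NA,
                        delta_chisq = NA, delta_df = NA, p_value = NA,
                        stars = "", decision = "did not converge"))
    }
    ix <- fit_indices(f, sat, base, robust = robust)
    if (i == 1) {
      dchi <- ddf <- p <- NA_real_
      decision <- "comparator"
    } else {
      freed <- f$df < comparator$df
      ct <- if (freed) chi_diff_test(f, comparator)
            else chi_diff_test(comparator, f)
      dchi <- ct$delta_chisq; ddf <- ct$delta_df; p <- ct$p_value
      sig <- !is.na(p) && p < alpha
      decision <- if (freed) {
        if (sig) "free the parameter" else "keep fixed to zero"
      } else {
        if (sig) "retain the free effect" else "effect can be fixed"
      }
    }
    data.frame(model = v$name, constraint = v$constraint, converged = TRUE,
               chisq = ix$chisq, df = ix$df, bic = ix$bic, cfi = ix$cfi,
               tli = ix$tli, rmsea = ix$rmsea, srmr = ix$srmr,
               delta_chisq = dchi, delta_df = ddf, p_value = p,
               stars = p_stars(p), decision = decision)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "saturated") <- sat
  attr(tab, "baseline") <- base
  attr(tab, "alpha") <- alpha
  class(tab) <- c("lcs_comparison", "data.frame")
  tab
}

#' @export
print.lcs_comparison <- function(x, digits = 3, ...) {
  cat("Nested model comparisons (comparator:", x$model[1], ")\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) round(col, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
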