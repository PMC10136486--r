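#' Enrollment accounting
#'
#' Computes enrolled = referred - declined - excluded and, when a completer
#' count is given, the completion percentage (one decimal).
#'
#' @param referred,declined,excluded nonnegative integers.
#' @param completed optional nonnegative integer, must not exceed enrolled.
#' @return list with `enrolled` and (when `completed` given) `completed`,
#'   `completion_pct`.
#' @export
sample_flow_summary <- function(referred, declined, excluded,
                                completed = NULL) {
  counts <- c(referred, declined, excluded, completed)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (declined + excluded > referred) {
    stop("declined + excluded exceeds referred")
  }
  enrolled <- referred - declined - excluded
  out <- list(referred = referred, declined = declined, excluded = excluded,
              enrolled = enrolled)
  if (!is.null(completed)) {
    if (completed > enrolled) stop("completed exceeds enrolled")
    out$completed <- completed
    out$completion_pct <- round(100 * completed / enrolled, 1)
  }
  out
}

#' Proportion of a count over a base, as a one-decimal percentage
#'
#' @param numerator,denominator nonnegative counts.
#' @return percentage rounded to one decimal.
#' @export
pct_of <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round(100 * numerator / denominator, 1)
}

#' Run the full two-wave coupling analysis
#'
#' Orchestrates descriptives, the depression-score rescaling (division by 10,
#' used to keep both constructs on comparable scales during estimation), the
#' ten-variant nested comparison battery, and a narrative summary of which
#' effects the chi-square difference tests retain.
#'
#' @param panel wide data frame; EDE-Q total columns `edeq_total_t0/_t1` (or
#'   `ede_t0/_t1`), depression totals `bdi_t0/_t1`.
#' @param rescale_bdi divide depression scores by 10 before fitting (default
#'   TRUE; set FALSE if the input is already on the analysis scale).
#' @param alpha significance level for retention decisions.
#' @param robust compute mean-scaled chi-squares in the comparison table.
#' @param se standard-error mode for the comparator refit ("both" gives naive
#'   and sandwich SEs).
#' @param outdir optional directory; when given, writes descriptives.csv,
#'   comparison.csv, results.json.
#' @param seed recorded in the output bundle (the analysis itself is
#'   deterministic).
#' @return list of class `lcs_analysis`: `descriptives`, `comparison`,
#'   `final_fit`, `retained`, `seed`.
#' @export
run_analysis <- function(panel, rescale_bdi = TRUE, alpha = 0.05,
                         robust = FALSE, se = "both", outdir = NULL,
                         seed = NA_integer_) {
  nms <- names(panel)
  ede0 <- intersect(c("ede_t0", "edeq_total_t0"), nms)[1]
  ede1 <- intersect(c("ede_t1", "edeq_total_t1"), nms)[1]
  if (is.na(ede0) || is.na(ede1) || !all(c("bdi_t0", "bdi_t1") %in% nms)) {
    stop("panel must contain EDE-Q total and BDI columns at both timepoints")
  }
  desc <- descriptives_table(panel,
                             bdi_scale = if (rescale_bdi) "raw" else "div10")
  fit_panel <- data.frame(
    ede_t0 = panel[[ede0]],
    bdi_t0 = panel$bdi_t0 / if (rescale_bdi) 10 else 1,
    ede_t1 = panel[[ede1]],
    bdi_t1 = panel$bdi_t1 / if (rescale_bdi) 10 else 1)
  comp <- comparison_table(fit_panel, alpha = alpha, robust = robust)
  final_fit <- fit_model(lcs_variants()$final, fit_panel, se = se)

  retained <- character(0)
  for (i in seq_len(nrow(comp))[-1]) {
    d <- comp$decision[i]
    if (d == "retain the free effect") {
      retained <- c(retained, sub("^fix_", "", comp$model[i]))
    }
  }
  freed <- sub("^free_", "", comp$model[comp$decision == "free the parameter"])

  out <- structure(list(descriptives = desc, comparison = comp,
                        final_fit = final_fit, retained = retained,
                        freed = freed, alpha = alpha, seed = seed,
                        rescale_bdi = rescale_bdi,
                        package_version = as.character(
                          utils::packageVersion("bilcs"))),
                   class = "lcs_analysis")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(desc$table, file.path(outdir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(comp), file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, alpha = alpha,
           package_version = out$package_version,
           retained = retained, freed = freed,
           final = list(
             loglik = final_fit$loglik, n = final_fit$n, df = final_fit$df,
             estimates = as.list(final_fit$estimates[final_fit$free]),
             se_naive = as.list(final_fit$se_naive),
             se_sandwich = as.list(final_fit$se_sandwich)),
           comparison = as.data.frame(comp)),
      file.path(outdir, "results.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  out
}

#' @export
print.lcs_analysis <- function(x, ...) {
  cat("Two-wave bivariate LCS analysis (n =", x$final_fit$n, ")\n\n")
  print(x$descriptives)
  cat("\n")
  print(x$comparison)
  cat("\nRetained free effects (constrained-variant tests significant at alpha =",
      x$alpha, "):\n  ", paste(x$retained, collapse = ", "), "\n")
  cat("Parameters to free (unconstrained-variant tests significant):\n  ",
      if (length(x$freed)) paste(x$freed, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Simulation-based parameter recovery study
#'
#' Repeatedly generates cohorts at a known truth, fits a model variant to
#' each, and summarises per-parameter bias, empirical and mean model-based
#' standard errors, and 95% Wald confidence-interval coverage. Optionally
#' also runs a chi-square difference test per replicate (e.g. to calibrate
#' its type-I error when the tested parameter is truly zero).
#'
#' @param config an [synthetic_config()]; its seed anchors the replicate
#'   stream.
#' @param n_replicates number of simulated cohorts.
#' @param variant variant fitted to each replicate (default: final model).
#' @param test optional list(full =, nested =) of variants for a per-replicate
#'   difference test.
#' @param se "naive" to collect model-based SEs and coverage (slower),
#'   "none" for estimates only.
#' @param test_alpha nominal level for the difference-test rejection rate.
#' @return list of class `lcs_recovery`: `summary` data frame (one row per
#'   free parameter), `rejection_rate` (when `test` given), `n_converged`,
#'   `n_replicates`.
#' @export
run_recovery_study <- function(config, n_replicates = 200,
                               variant = lcs_variants()$final,
                               test = NULL, se = c("naive", "none"),
                               test_alpha = 0.05) {
  se <- match.arg(se)
  stopifnot(inherits(config, "lcs_synth_config"))
  if (n_replicates == 0) {
    return(structure(list(summary = data.frame(), rejection_rate = NA_real_,
                          n_converged = 0L, n_replicates = 0L),
                     class = "lcs_recovery"))
  }
  truth <- config$true_paths
  free <- free_param_names(variant)
  est <- ses <- matrix(NA_real_, n_replicates, length(free),
                       dimnames = list(NULL, free))
  pvals <- rep(NA_real_, n_replicates)
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    panel <- generate_cohort(cfg_r)
    prep <- fiml_prepare(panel)
    fit <- tryCatch(fit_model(variant, prep, se = se),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    conv[r] <- TRUE
    est[r, ] <- fit$estimates[free]
    if (se == "naive") ses[r, ] <- fit$se_naive[free]
    if (!is.null(test)) {
      full <- if (identical(test$full$name, variant$name)) fit
              else tryCatch(fit_model(test$full, prep, se = "none"),
                            error = function(e) NULL)
      nested <- if (identical(test$nested$name, variant$name)) fit
                else tryCatch(fit_model(test$nested, prep, se = "none"),
                              error = function(e) NULL)
      if (!is.null(full) && !is.null(nested) &&
          full$converged && nested$converged) {
        pvals[r] <- chi_diff_test(full, nested)$p_value
      }
    }
  }
  ok <- conv
  summary_rows <- lapply(free, function(p) {
    e <- est[ok, p]
    tr <- truth[[p]]
    emp_se <- stats::sd(e)
    row <- data.frame(parameter = p, truth = tr, mean_estimate = mean(e),
                      bias = mean(e) - tr, empirical_se = emp_se,
                      mean_se = NA_real_, coverage = NA_real_)
    if (se == "naive") {
      s <- ses[ok, p]
      covered <- abs(e - tr) <= stats::qnorm(0.975) * s
      row$mean_se <- mean(s, na.rm = TRUE)
      row$coverage <- mean(covered, na.rm = TRUE)
    }
    row
  })
  rejection <- if (is.null(test)) NA_real_
               else mean(pvals[!is.na(pvals)] < test_alpha)
  structure(list(summary = do.call(rbind, summary_rows),
                 rejection_rate = rejection,
                 n_converged = sum(ok), n_replicates = n_replicates,
                 truth = truth, seed = config$seed),
            class = "lcs_recovery")
}

#' @export
print.lcs_recovery <- function(x, digits = 3, ...) {
  cat("Parameter recovery over", x$n_converged, "of", x$n_replicates,
      "converged replicates\n")
  if (nrow(x$summary)) {
    y <- x$summary
    num <- vapply(y, is.numeric, logical(1))
    y[num] <- lapply(y[num], round, digits)
    print(y, row.names = FALSE)
  }
  if (!is.na(x$rejection_rate)) {
    cat("difference-test rejection rate:", round(x$rejection_rate, 3), "\n")
  }
  invisible(x)
}
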