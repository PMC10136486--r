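#' Score the Beck Depression Inventory-II
#'
#' Total = sum of the 21 items (each 0-3). No proration: any missing item is
#' an error.
#'
#' @param item_scores numeric vector of exactly 21 item scores.
#' @return integer total in 0-63.
#' @export
score_bdi <- function(item_scores) {
  if (length(item_scores) != 21) {
    stop("BDI-II requires exactly 21 items, got ", length(item_scores))
  }
  if (anyNA(item_scores)) stop("missing BDI item; totals are not prorated")
  if (any(item_scores < 0 | item_scores > 3)) {
    stop("BDI items must lie in [0, 3]")
  }
  as.integer(sum(item_scores))
}

#' Score the Eating Disorder Examination Questionnaire 6.0
#'
#' Each subscale (restraint, eating concern, weight concern, shape concern)
#' is the mean of its items; the total score is, by default, the mean of the
#' four subscale means (the standard EDE-Q 6.0 convention). With balanced
#' item counts the alternative item-mean total coincides; `total` switches
#' between the two conventions.
#'
#' @param items_by_subscale named list of four numeric vectors of item scores
#'   (0-6): restraint, eating, weight, shape.
#' @param total "subscale_mean" (default) or "item_mean".
#' @return list with `subscales` (named length-4 vector) and `total`.
#' @export
score_edeq <- function(items_by_subscale,
                       total = c("subscale_mean", "item_mean")) {
  total <- match.arg(total)
  if (length(items_by_subscale) != 4) {
    stop("expected four subscales, got ", length(items_by_subscale))
  }
  lens <- lengths(items_by_subscale)
  if (any(lens == 0)) stop("empty subscale")
  all_items <- unlist(items_by_subscale, use.names = FALSE)
  if (anyNA(all_items)) stop("missing EDE-Q item")
  if (any(all_items < 0 | all_items > 6)) stop("EDE-Q items must lie in [0, 6]")
  sub <- vapply(items_by_subscale, mean, numeric(1))
  tot <- switch(total,
                subscale_mean = mean(sub),
                item_mean = mean(all_items))
  list(subscales = sub, total = tot)
}

#' Score the SCL-90-R Global Severity Index
#'
#' Mean of all 90 item scores (each 0-4).
#'
#' @param item_scores numeric vector of 90 item scores.
#' @return numeric GSI.
#' @export
score_gsi <- function(item_scores) {
  if (length(item_scores) != 90) {
    stop("SCL-90-R requires 90 items, got ", length(item_scores))
  }
  if (anyNA(item_scores)) stop("missing SCL-90-R item")
  if (any(item_scores < 0 | item_scores > 4)) {
    stop("SCL-90-R items must lie in [0, 4]")
  }
  mean(item_scores)
}

#' Cronbach's alpha
#'
#' alpha = (k / (k - 1)) * (1 - sum of item variances / variance of the item
#' sum), on listwise-complete cases with the n - 1 variance divisor. May be
#' negative for incoherent scales.
#'
#' @param item_table matrix/data frame, cases in rows, items in columns.
#' @return numeric reliability coefficient.
#' @export
cronbach_alpha <- function(item_table) {
  X <- as.matrix(item_table)
  k <- ncol(X)
  if (k < 2) stop("need at least 2 items")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete cases")
  total_var <- stats::var(rowSums(X))
  if (total_var <= 0) stop("zero variance of the item sum")
  (k / (k - 1)) * (1 - sum(apply(X, 2, stats::var)) / total_var)
}

#' Depression severity band from a BDI-II total
#'
#' 29 or higher: severe; 20-28: at risk for moderate depression; below 20:
#' below the moderate threshold.
#'
#' @param bdi_total numeric total(s) in 0-63.
#' @return character vector in {"below_moderate", "moderate", "severe"}.
#' @export
classify_depression <- function(bdi_total) {
  if (any(!is.na(bdi_total) & (bdi_total < 0 | bdi_total > 63))) {
    stop("BDI total must lie in [0, 63]")
  }
  ifelse(is.na(bdi_total), NA_character_,
         ifelse(bdi_total >= 29, "severe",
                ifelse(bdi_total >= 20, "moderate", "below_moderate")))
}

#' Clinical-range flag from the EDE-Q total score
#'
#' TRUE when the total score is at or above the validated patient/control
#' cut-off of 2.5.
#'
#' @param edeq_total numeric total(s) in 0-6.
#' @return logical vector.
#' @export
classify_ed_clinical <- function(edeq_total) {
  if (any(!is.na(edeq_total) & (edeq_total < 0 | edeq_total > 6))) {
    stop("EDE-Q total must lie in [0, 6]")
  }
  ifelse(is.na(edeq_total), NA, edeq_total >= 2.5)
}

ctq_cutoffs <- c(emotional_abuse = 16, physical_abuse = 13, sexual_abuse = 13,
                 emotional_neglect = 18, physical_neglect = 13)

#' Severe childhood trauma screen (CTQ)
#'
#' TRUE (exclude) when ANY subscale meets or exceeds its severity cut-off:
#' emotional abuse >= 16, physical abuse >= 13, sexual abuse >= 13, emotional
#' neglect >= 18, physical neglect >= 13.
#'
#' @param ctq_subscales named numeric vector or list with elements
#'   emotional_abuse, physical_abuse, sexual_abuse, emotional_neglect,
#'   physical_neglect.
#' @return logical scalar.
#' @export
screen_trauma <- function(ctq_subscales) {
  x <- unlist(ctq_subscales)
  missing_sub <- setdiff(names(ctq_cutoffs), names(x))
  if (length(missing_sub)) {
    stop("missing CTQ subscale(s): ", paste(missing_sub, collapse = ", "))
  }
  x <- x[names(ctq_cutoffs)]
  if (anyNA(x)) stop("missing CTQ subscale score")
  any(x >= ctq_cutoffs)
}

#' Body mass index
#'
#' @param weight_kg positive weight in kilograms.
#' @param height_m positive height in meters.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(is.na(weight_kg)) || any(is.na(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive")
  }
  weight_kg / height_m^2
}

#' Descriptive table with cut-off proportions
#'
#' Means and standard deviations of each variable at baseline and follow-up
#' over the available cases per cell, with counts, plus the proportions of
#' completers below the EDE-Q clinical cut-off (2.5) and below the moderate
#' depression threshold (BDI < 20) at follow-up.
#'
#' @param panel wide data frame; baseline columns suffixed `_t0`, follow-up
#'   `_t1`. Recognised stems: any shared by both timepoints (e.g. edeq_total,
#'   bdi, gsi, bmi). A `bdi_t1` column is interpreted on the raw 0-63 scale
#'   unless `bdi_scale` says otherwise.
#' @param bdi_scale "raw" (0-63) or "div10"; cut-offs are rescaled to match.
#' @return list of class `lcs_descriptives` with `table` (one row per
#'   variable) and `cutoffs` (proportions among completers).
#' @export
descriptives_table <- function(panel, bdi_scale = c("raw", "div10")) {
  bdi_scale <- match.arg(bdi_scale)
  if (!nrow(panel)) stop("empty panel")
  nms <- names(panel)
  stems_t0 <- sub("_t0$", "", grep("_t0$", nms, value = TRUE))
  stems_t1 <- sub("_t1$", "", grep("_t1$", nms, value = TRUE))
  stems <- union(stems_t0, stems_t1)
  if (!length(stems)) stop("no *_t0 / *_t1 columns found")
  cell <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(n = 0, mean = NA_real_, sd = NA_real_))
    c(n = length(x), mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  rows <- lapply(stems, function(s) {
    t0 <- if (paste0(s, "_t0") %in% nms) cell(panel[[paste0(s, "_t0")]])
          else c(n = 0, mean = NA_real_, sd = NA_real_)
    t1 <- if (paste0(s, "_t1") %in% nms) cell(panel[[paste0(s, "_t1")]])
          else c(n = 0, mean = NA_real_, sd = NA_real_)
    data.frame(variable = s, n_t0 = t0["n"], mean_t0 = t0["mean"],
               sd_t0 = t0["sd"], n_t1 = t1["n"], mean_t1 = t1["mean"],
               sd_t1 = t1["sd"])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  cutoffs <- list()
  bdi_cut <- if (bdi_scale == "raw") 20 else 2.0
  ede_col <- intersect(c("edeq_total_t1", "ede_t1", "edeq_t1"), nms)[1]
  if (!is.na(ede_col)) {
    x <- panel[[ede_col]]
    x <- x[!is.na(x)]
    cutoffs$edeq_below_clinical <- list(
      n = sum(x < 2.5), completers = length(x),
      pct = round(100 * sum(x < 2.5) / length(x), 1))
  }
  bdi_col <- intersect(c("bdi_t1", "bdi_total_t1"), nms)[1]
  if (!is.na(bdi_col)) {
    x <- panel[[bdi_col]]
    x <- x[!is.na(x)]
    cutoffs$bdi_below_moderate <- list(
      n = sum(x < bdi_cut), completers = length(x),
      pct = round(100 * sum(x < bdi_cut) / length(x), 1))
  }
  structure(list(table = tab, cutoffs = cutoffs), class = "lcs_descriptives")
}

#' @export
print.lcs_descriptives <- function(x, digits = 2, ...) {
  tab <- x$table
  fmt <- function(m, s, n) ifelse(
    n == 0, "-", paste0(round(m, digits), " ± ", round(s, digits),
                        " (n=", n, ")"))
  out <- data.frame(variable = tab$variable,
                    baseline = fmt(tab$mean_t0, tab$sd_t0, tab$n_t0),
                    follow_up = fmt(tab$mean_t1, tab$sd_t1, tab$n_t1))
  print(out, row.names = FALSE)
  for (nm in names(x$cutoffs)) {
    co <- x$cutoffs[[nm]]
    cat(nm, ": ", co$n, "/", co$completers, " (", co$pct, "%)\n", sep = "")
  }
  invisible(x)
}

#' Read a two-wave panel from CSV
#'
#' Accepts wide input (one row per participant, columns suffixed `_t0`/`_t1`)
#' or long input (one row per participant-timepoint with a timepoint column
#' coded T0/T1). Column names can be remapped via `mapping`
#' (standard_name = file_name). Missing values must use `na_string`.
#'
#' @param path CSV path (UTF-8, header required).
#' @param format "wide" or "long".
#' @param mapping named character vector renaming file columns to standard
#'   names.
#' @param id_col,time_col identifier and timepoint columns for long input.
#' @param na_string missing-value sentinel.
#' @return wide data frame, one row per participant.
#' @export
read_panel <- function(path, format = c("wide", "long"), mapping = NULL,
                       id_col = "participant_id", time_col = "timepoint",
                       na_string = c("NA", "")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_string,
                        fileEncoding = "UTF-8")
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(df)) {
        stop("mapped column '", mapping[[std]], "' not found in ", path)
      }
      names(df)[names(df) == mapping[[std]]] <- std
    }
  }
  if (format == "wide") return(df)
  if (!all(c(id_col, time_col) %in% names(df))) {
    stop("long input needs '", id_col, "' and '", time_col, "' columns")
  }
  tp <- toupper(trimws(df[[time_col]]))
  if (!all(tp %in% c("T0", "T1"))) stop("timepoint must be T0 or T1")
  if (anyDuplicated(paste(df[[id_col]], tp))) {
    stop("duplicate (participant, timepoint) rows")
  }
  vars <- setdiff(names(df), c(id_col, time_col))
  ids <- unique(df[[id_col]])
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (v in vars) {
    for (t in c("T0", "T1")) {
      col <- rep(NA, length(ids))
      sel <- tp == t
      col[match(df[[id_col]][sel], ids)] <- df[[v]][sel]
      out[[paste0(v, "_", tolower(t))]] <- col
    }
  }
  out
}
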