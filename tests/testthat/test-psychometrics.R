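test_that("BDI scoring sums 21 items, rejects bad input, ignores item order", {
  expect_identical(score_bdi(rep(0, 21)), 0L)
  expect_identical(score_bdi(rep(3, 21)), 63L)
  expect_identical(score_bdi(rep(1, 21)), 21L)
  items <- c(rep(0:3, 5), 2)
  set.seed(11)
  for (i in 1:5) expect_identical(score_bdi(sample(items)), score_bdi(items))
  expect_error(score_bdi(rep(1, 20)), "21 items")
  expect_error(score_bdi(c(rep(1, 20), 4)), "\\[0, 3\\]")
  expect_error(score_bdi(c(rep(1, 20), NA)), "missing")
})

test_that("EDE-Q scoring averages within subscales and across them", {
  zeros <- list(restraint = rep(0, 5), eating = rep(0, 5),
                weight = rep(0, 5), shape = rep(0, 5))
  s <- score_edeq(zeros)
  expect_equal(unname(s$subscales), rep(0, 4))
  expect_equal(s$total, 0)
  expect_equal(score_edeq(lapply(zeros, function(x) x + 6))$total, 6)
  uneven <- list(restraint = c(4, 4), eating = 2, weight = c(2, 2, 2), shape = 4)
  expect_equal(score_edeq(uneven)$total, 3.0)
  # item-mean convention differs from the subscale-mean one when item counts
  # are unbalanced
  expect_equal(score_edeq(uneven, total = "item_mean")$total, mean(c(4, 4, 2, 2, 2, 2, 4)))
  expect_error(score_edeq(uneven[1:3]), "four subscales")
  expect_error(score_edeq(list(a = numeric(0), b = 1, c = 1, d = 1)), "empty")
  expect_error(score_edeq(list(a = 7, b = 1, c = 1, d = 1)), "\\[0, 6\\]")
})

test_that("GSI is the mean of the 90 items", {
  expect_equal(score_gsi(rep(0, 90)), 0)
  expect_equal(score_gsi(rep(4, 90)), 4)
  expect_equal(score_gsi(rep(c(0, 2), each = 45)), 1.0)
  expect_error(score_gsi(rep(1, 89)), "90 items")
  expect_error(score_gsi(c(rep(1, 89), 5)), "\\[0, 4\\]")
})

test_that("Cronbach's alpha matches closed forms on exact fixtures", {
  # two perfectly correlated equal-variance items
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cronbach_alpha(cbind(x, x)), 1.0)
  # two exactly uncorrelated items
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3, 4), c(2, 0, 0, 2))), 0.0)
  # compound-symmetric covariance, k = 10, r = 0.5: Spearman-Brown gives
  # k r / (1 + (k - 1) r) = 10/11
  k <- 10; r <- 0.5
  sigma <- matrix(r, k, k); diag(sigma) <- 1
  X <- MASS::mvrnorm(50, mu = rep(0, k), Sigma = sigma, empirical = TRUE)
  expect_equal(cronbach_alpha(X), k * r / (1 + (k - 1) * r), tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(x)), "2 items")
  expect_error(cronbach_alpha(cbind(x[1:2], x[1:2])), "3 complete cases")
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "zero variance")
})

test_that("depression bands use the 20/29 inclusive cut-offs", {
  expect_identical(classify_depression(29), "severe")
  expect_identical(classify_depression(20), "moderate")
  expect_identical(classify_depression(19), "below_moderate")
  expect_identical(classify_depression(c(0, 28, 63)),
                   c("below_moderate", "moderate", "severe"))
  expect_error(classify_depression(64), "\\[0, 63\\]")
  # monotonicity of band through the sum score: raising any item never
  # lowers the band
  bands <- c(below_moderate = 1, moderate = 2, severe = 3)
  set.seed(21)
  for (i in 1:20) {
    items <- sample(0:3, 21, replace = TRUE)
    j <- sample(which(items < 3), 1)
    bumped <- items; bumped[j] <- bumped[j] + 1
    expect_gte(bands[classify_depression(score_bdi(bumped))],
               bands[classify_depression(score_bdi(items))])
  }
})

test_that("EDE-Q clinical range is inclusive at 2.5", {
  expect_false(classify_ed_clinical(2.49))
  expect_true(classify_ed_clinical(2.5))
  expect_false(classify_ed_clinical(0))
  expect_error(classify_ed_clinical(6.5), "\\[0, 6\\]")
})

test_that("trauma screen fires when any CTQ subscale reaches its cut-off", {
  minimal <- c(emotional_abuse = 5, physical_abuse = 5, sexual_abuse = 5,
               emotional_neglect = 5, physical_neglect = 5)
  expect_false(screen_trauma(minimal))
  ea <- minimal; ea["emotional_abuse"] <- 16
  expect_true(screen_trauma(ea))
  pn <- minimal; pn["physical_neglect"] <- 13
  expect_true(screen_trauma(pn))
  one_below <- c(emotional_abuse = 15, physical_abuse = 12, sexual_abuse = 12,
                 emotional_neglect = 17, physical_neglect = 12)
  expect_false(screen_trauma(one_below))
  # monotone in every subscale
  for (nm in names(one_below)) {
    bumped <- one_below; bumped[nm] <- bumped[nm] + 1
    expect_gte(screen_trauma(bumped), screen_trauma(one_below))
  }
  expect_error(screen_trauma(minimal[-1]), "missing CTQ")
})

test_that("BMI is weight over squared height", {
  expect_equal(compute_bmi(50, 1.60), 19.53, tolerance = 1e-3)
  expect_equal(compute_bmi(64, 2.00), 16.0)
  expect_error(compute_bmi(0, 1.6), "positive")
  expect_error(compute_bmi(50, -1), "positive")
})

test_that("descriptives handle constants, counts, and cut-off proportions", {
  panel <- data.frame(edeq_total_t0 = rep(2, 10), edeq_total_t1 = rep(2, 10),
                      bdi_t0 = rep(15, 10), bdi_t1 = rep(15, 10))
  d <- descriptives_table(panel)
  expect_equal(d$table$mean_t0, c(2, 15))
  expect_equal(d$table$sd_t0, c(0, 0))
  expect_equal(d$table$n_t1, c(10, 10))

  # 121 completers: 65 below the EDE-Q cut-off, 90 below moderate depression
  panel2 <- data.frame(
    edeq_total_t0 = rep(3, 157),
    edeq_total_t1 = c(rep(2.0, 65), rep(3.0, 56), rep(NA, 36)),
    bdi_t0 = rep(25, 157),
    bdi_t1 = c(rep(10, 90), rep(30, 31), rep(NA, 36)))
  d2 <- descriptives_table(panel2)
  expect_equal(d2$cutoffs$edeq_below_clinical$pct, 53.7)
  expect_equal(d2$cutoffs$bdi_below_moderate$pct, 74.4)
  # proportions times completer count round back to the integer numerators
  expect_equal(round(d2$cutoffs$edeq_below_clinical$pct / 100 * 121), 65)
  expect_equal(round(d2$cutoffs$bdi_below_moderate$pct / 100 * 121), 90)
  expect_error(descriptives_table(panel[0, ]), "empty")
})

test_that("CSV panels round-trip in wide and long layouts", {
  wide <- data.frame(participant_id = c("a", "b", "c"),
                     edeq_total_t0 = c(3.1, 2.2, 4.0),
                     edeq_total_t1 = c(2.0, NA, 3.5),
                     bdi_t0 = c(20, 25, 30), bdi_t1 = c(10, NA, 28))
  f <- tempfile(fileext = ".csv")
  write.csv(wide, f, row.names = FALSE, na = "NA")
  got <- read_panel(f, "wide")
  expect_equal(got$edeq_total_t1, wide$edeq_total_t1)

  long <- data.frame(
    participant_id = c("a", "a", "b", "c", "c"),
    timepoint = c("T0", "T1", "T0", "T0", "T1"),
    edeq_total = c(3.1, 2.0, 2.2, 4.0, 3.5),
    bdi = c(20, 10, 25, 30, 28))
  fl <- tempfile(fileext = ".csv")
  write.csv(long, fl, row.names = FALSE)
  gotl <- read_panel(fl, "long")
  expect_equal(gotl$edeq_total_t0, c(3.1, 2.2, 4.0))
  expect_equal(gotl$edeq_total_t1, c(2.0, NA, 3.5))
  expect_equal(gotl$bdi_t1, c(10, NA, 28))

  # column remapping
  names(wide)[2] <- "EDEQ.baseline"
  write.csv(wide, f, row.names = FALSE)
  got2 <- read_panel(f, "wide", mapping = c(edeq_total_t0 = "EDEQ.baseline"))
  expect_true("edeq_total_t0" %in% names(got2))
  # duplicate (participant, timepoint) rows are rejected
  bad <- rbind(long, long[1, ])
  write.csv(bad, fl, row.names = FALSE)
  expect_error(read_panel(fl, "long"), "duplicate")
})
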