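test_that("death ratios are simple area fractions with guarded edge cases", {
  expect_equal(death_ratio(50, 200), 0.25)
  expect_equal(death_ratio(0, 200), 0)
  expect_equal(death_ratio(200, 200), 1)
  expect_true(is.na(death_ratio(0, 0)))
  expect_error(death_ratio(-1, 10), "nonnegative")
  expect_error(death_ratio(20, 10), "exceed")
})

test_that("dead-cell-loss correction floors late values and is idempotent", {
  expect_equal(correct_dead_cell_loss(100, 60), 100)
  expect_equal(correct_dead_cell_loss(100, 150), 150)
  expect_equal(correct_dead_cell_loss(100, 100), 100)
  set.seed(1)
  a <- runif(500, 0, 1000); b <- runif(500, 0, 1000)
  once <- correct_dead_cell_loss(a, b)
  expect_identical(correct_dead_cell_loss(a, once), once)
})

test_that("growth is area ratio with undefined zero baseline", {
  expect_equal(compute_growth(400, 200), 2)
  expect_equal(compute_growth(200, 200), 1)
  expect_equal(compute_growth(100, 200), 0.5)
  expect_true(is.na(compute_growth(100, 0)))
})

test_that("growth clamps follow the stated order and are idempotent", {
  expect_equal(clamp_growth(0.7, NA)$growth_72, 1)
  expect_equal(clamp_growth(10, NA, mgc = 4)$growth_72, 8)
  g <- clamp_growth(4, 3, mgc = 4)
  expect_equal(c(g$growth_72, g$growth_144), c(4, 4))
  expect_equal(clamp_growth(5, NA, mgc = 2)$growth_72, 4)
  # controls are not capped at 2*mgc
  expect_equal(clamp_growth(5, NA, mgc = 2, treated = FALSE)$growth_72, 5)
  set.seed(2)
  for (i in 1:50) {
    raw72 <- runif(1, 0, 12); raw144 <- runif(1, 0, 12); mgc <- runif(1, 1, 6)
    g1 <- clamp_growth(raw72, raw144, mgc)
    g2 <- clamp_growth(g1$growth_72, g1$growth_144, mgc)
    expect_equal(g1, g2)
    expect_gte(g1$growth_72, 1)
    expect_lte(g1$growth_72, min(8, 2 * mgc))
  }
})

test_that("the ANOVA gate opens only on significant dose effects", {
  flat <- anova_gate(rep(0.1, 12), c("control", "control", rep(1:5, each = 2)))
  expect_false(flat$gate_open)
  expect_equal(flat$p_value, 1)

  set.seed(4)
  vals <- c(rnorm(2, 0.05, 0.01), rnorm(2, 0.05, 0.01), rnorm(2, 0.9, 0.01),
            rnorm(2, 0.9, 0.01), rnorm(2, 0.9, 0.01))
  grp <- c("control", "control", rep(c("d1", "d2", "d3", "d4"), each = 2))
  res <- anova_gate(vals, grp)
  expect_true(res$gate_open)
  # independent oracle: F statistic from group sums of squares
  gm <- tapply(vals, grp, mean); n_g <- tapply(vals, grp, length)
  ssb <- sum(n_g * (gm[unique(grp)] - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  f <- (ssb / (length(unique(grp)) - 1)) / (ssw / (length(vals) - length(unique(grp))))
  p_oracle <- pf(f, length(unique(grp)) - 1, length(vals) - length(unique(grp)),
                 lower.tail = FALSE)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)

  expect_error(anova_gate(c(0.1, 0.2), c("control", "d1")), "control")
})

test_that("noiseless log-logistic data are recovered to high precision", {
  doses <- 0.1 * 3^(0:7)
  truth <- list(c = 0, d = 1, b = 2, e = doses[4])
  y <- ll4(rep(doses, 2), truth$c, truth$d, truth$b, truth$e)
  fit <- fit_log_logistic(rep(doses, 2), y)
  expect_true(fit$converged)
  expect_lt(abs(fit$ld50 / truth$e - 1), 1e-6)
  expect_lt(abs(fit$b - truth$b), 1e-4)

  closed <- fit_log_logistic(doses, rep(0.1, 8), gate_open = FALSE)
  expect_true(is.na(closed$ld50))
  expect_true(closed$gated)

  few <- fit_log_logistic(c(1, 3, 9), c(0.1, 0.5, 0.9))
  expect_true(is.na(few$ld50))
})

test_that("AUCd normalisation hits its closed-form anchors", {
  expect_equal(auc_death(rep(1, 8), m = 0.2), 1)
  expect_equal(auc_death(rep(0.2, 8), m = 0.2), 0)
  expect_equal(auc_death(rep(0, 8), m = 0.4), -1)
  # independent fine-grid integrator on the piecewise-linear interpolant
  set.seed(5)
  for (i in 1:20) {
    y <- runif(8); m <- runif(1, 0.05, 0.95)
    fine_x <- seq(1, 8, length.out = 14001)
    fine_y <- approx(1:8, y - m, xout = fine_x)$y
    raw <- sum((fine_y[-1] + fine_y[-length(fine_y)]) / 2 * diff(fine_x)) / 7
    expected <- if (raw > 0) raw / (1 - m) else if (raw < 0) raw / m else 0
    expect_equal(auc_death(y, m), expected, tolerance = 1e-9)
  }
})

test_that("raising any death ratio never lowers AUCd", {
  set.seed(6)
  for (i in 1:30) {
    y <- runif(8); m <- runif(1, 0.05, 0.95)
    delta <- runif(8, 0, 0.3) * rbinom(8, 1, 0.5)
    expect_gte(auc_death(pmin(y + delta, 1), m) - auc_death(y, m), -1e-12)
  }
})

test_that("AUCpi anchors and clipping behave as specified", {
  expect_equal(auc_prolif_inhibition(rep(1, 8), mgc = 3), 1)
  expect_equal(auc_prolif_inhibition(rep(3, 8), mgc = 3), 0)
  expect_equal(auc_prolif_inhibition(rep(6, 8), mgc = 3), -1)  # clipped at -1
  expect_true(is.na(auc_prolif_inhibition(rep(1, 8), mgc = 1)))
})

test_that("LD50 display rescaling maps the dose range onto [0, 1]", {
  expect_equal(normalize_ld50_display(0.1, 0.1, 218.7), 1)
  expect_equal(normalize_ld50_display(218.7, 0.1, 218.7), 0)
  expect_equal(normalize_ld50_display(sqrt(0.1 * 218.7), 0.1, 218.7), 0.5)
  expect_true(is.na(normalize_ld50_display(NA, 0.1, 218.7)))
  expect_error(normalize_ld50_display(-1, 0.1, 218.7), "> 0")
  expect_error(normalize_ld50_display(1, 10, 1), "dmin")
})

test_that("assemble_metrics recovers planted series metrics from area tables", {
  doses <- 0.1 * 3^(0:7)
  series <- simulate_dose_response(doses, ld50 = doses[5], hill = 2,
                                   sigma = 0.02, seed = 21)
  areas <- series_to_area_table(series)
  mets <- assemble_metrics(areas)
  expect_equal(nrow(mets), 1L)
  expect_false(is.na(mets$ld50))
  expect_lt(abs(log(mets$ld50 / doses[5]) / log(3)), 0.5)
  expect_gt(mets$aucd, 0.2)
  expect_gt(mets$aucpi, 0.2)
  expect_true(mets$gate_p < 0.0005)

  # duplicate position rows collide
  dup <- rbind(areas, areas[1, ])
  expect_error(assemble_metrics(dup), "duplicate")

  # without the 0-h baseline, growth metrics are undetermined
  no_t0 <- areas[areas$timepoint_h != 0, ]
  m2 <- assemble_metrics(no_t0)
  expect_true(is.na(m2$aucpi))
  expect_false(is.na(m2$aucd))
  expect_match(m2$qc_flags, "no_growth_baseline")
})

test_that("metrics tables round-trip through the nd-aware CSV format", {
  mets <- data.frame(cell_line = "L1", culture = "3D", drug = c("a", "b"),
                     timepoint_h = 72, ld50 = c(2.5, NA),
                     ld50_display = c(0.61, NA), aucd = c(0.4, 0.01),
                     aucpi = c(0.8, NA), gate_p = c(1e-8, 0.2),
                     qc_flags = c("", "gate_closed"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(mets, path)
  txt <- readLines(path)
  expect_true(any(grepl("nd", txt)))
  back <- read_metrics_table(path)
  expect_equal(back, mets, tolerance = 1e-12)
})
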