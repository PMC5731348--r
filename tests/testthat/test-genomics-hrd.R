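seg_row <- function(chrom, start, end, tcn, cn_a, cn_b) {
  data.frame(chrom = chrom, start = start, end = end, tcn = tcn,
             cn_a = cn_a, cn_b = cn_b, stringsAsFactors = FALSE)
}

test_that("segment states follow the ploidy-dependent thresholds", {
  m2 <- ploidy_model("2n")
  cls <- classify_segments(rbind(
    seg_row("1", 0, 2e7, 3.0, 1.5, 1.5),        # gain
    seg_row("2", 0, 2e7, 1.2, 1.1, 0.1),        # loss with LOH
    seg_row("3", 0, 2e7, 2.0, 1.0, 1.0)), m2)   # neutral, no LOH
  expect_equal(as.character(cls$state), c("gain", "loss", "neutral"))
  expect_equal(cls$loh, c(FALSE, TRUE, FALSE))

  m34 <- ploidy_model("3n-4n")
  cls2 <- classify_segments(seg_row("5", 0, 2e7, 4.0, 4.0, 0.0), m34)
  expect_equal(as.character(cls2$state), "neutral")  # copy-neutral LOH
  expect_true(cls2$loh)
})

test_that("segment table invariants are enforced", {
  expect_error(validate_segments(seg_row("1", 10, 10, 2, 1, 1)), "end > start")
  expect_error(validate_segments(seg_row("1", 0, 10, 2, 0.4, 1)), "cn_a >= cn_b")
  expect_error(validate_segments(seg_row("1", 0, 10, 3, 1, 1)), "within 0.3")
  expect_error(validate_segments(rbind(seg_row("1", 0, 100, 2, 1, 1),
                                       seg_row("1", 50, 150, 2, 1, 1))),
               "overlapping")
})

hrd_fixture <- function() {
  rbind(
    # chr1: 12 Mb loss-LOH flanked by background (counts)
    seg_row("1", 0, 3e7, 2, 1, 1),
    seg_row("1", 3e7, 4.2e7, 1, 1, 0),
    seg_row("1", 4.2e7, 1e8, 2, 1, 1),
    # chr2: 9 Mb loss-LOH (too short)
    seg_row("2", 0, 3e7, 2, 1, 1),
    seg_row("2", 3e7, 3.9e7, 1, 1, 0),
    seg_row("2", 3.9e7, 1e8, 2, 1, 1),
    # chr3: 20 Mb copy-neutral LOH (excluded)
    seg_row("3", 0, 3e7, 2, 1, 1),
    seg_row("3", 3e7, 5e7, 2, 2, 0),
    seg_row("3", 5e7, 1e8, 2, 1, 1))
}

test_that("the modified score keeps only long non-neutral partial-chromosome LOH", {
  m <- ploidy_model("2n")
  res <- hrd_score(hrd_fixture(), m)
  expect_equal(res$score, 1L)
  expect_equal(res$contributing_regions$chrom, "1")
  expect_equal(res$stratum, "low")
  expect_equal(res$score, oracle_hrd_score(hrd_fixture(), m))

  # LOH spanning a chromosome's full extent is excluded
  whole <- rbind(seg_row("4", 0, 9e7, 1, 1, 0))
  expect_equal(hrd_score(whole, m)$score, 0L)

  # book-ended LOH pieces merge before length thresholding
  merged <- rbind(seg_row("5", 0, 3e7, 2, 1, 1),
                  seg_row("5", 3e7, 3.6e7, 1, 1, 0),
                  seg_row("5", 3.6e7, 4.2e7, 1, 1, 0),
                  seg_row("5", 4.2e7, 1e8, 2, 1, 1))
  expect_equal(hrd_score(merged, m)$score, 1L)

  # sex chromosomes do not count by default
  x_loh <- rbind(seg_row("X", 0, 3e7, 2, 1, 1),
                 seg_row("X", 3e7, 5e7, 1, 1, 0),
                 seg_row("X", 5e7, 1e8, 2, 1, 1))
  expect_equal(hrd_score(x_loh, m)$score, 0L)

  expect_warning(empty <- hrd_score(hrd_fixture()[0, ], m), "empty")
  expect_equal(empty$score, 0L)
})

test_that("raising the length cutoff never raises the score", {
  m <- ploidy_model("2n")
  for (seed in 1:40) {
    tab <- random_segment_table(seed)
    s10 <- hrd_score(tab, m, min_length = 1e7)$score
    s15 <- hrd_score(tab, m, min_length = 1.5e7)$score
    expect_lte(s15, s10)
  }
  # adding a copy-neutral LOH region never changes the modified score
  base <- hrd_fixture()
  extra <- rbind(base, seg_row("6", 0, 2e7, 2, 1, 1),
                 seg_row("6", 2e7, 6e7, 2, 2, 0),
                 seg_row("6", 6e7, 9e7, 2, 1, 1))
  expect_equal(hrd_score(extra, m)$score, hrd_score(base, m)$score)
})

test_that("the scorer agrees with the naive oracle on random tables", {
  m2 <- ploidy_model("2n"); m34 <- ploidy_model("3n-4n")
  for (seed in 1:100) {
    tab <- random_segment_table(seed)
    expect_equal(hrd_score(tab, m2)$score, oracle_hrd_score(tab, m2))
    tab4 <- random_segment_table(seed + 1000, "3n-4n")
    expect_equal(hrd_score(tab4, m34)$score, oracle_hrd_score(tab4, m34))
  }
})

test_that("segment tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- hrd_fixture()
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_segment_table(path)
  expect_equal(back, validate_segments(tab))
})

cohort_fixture <- function(seed = 77, slopes = NULL) {
  scores <- setNames(c(3, 5, 7, 9, 11, 13, 15, 19, 22), sprintf("L%d", 1:9))
  if (is.null(slopes)) slopes <- setNames(rep(0, 6), sprintf("d%d", 1:6))
  simulate_cohort(scores, slopes, sigma = 0.05, seed = seed)
}

test_that("associations report OLS R-squared and slope", {
  co <- cohort_fixture(slopes = setNames(c(0.02, 0, 0, 0, 0, 0),
                                         sprintf("d%d", 1:6)))
  # exact linearity when sigma = 0
  co0 <- simulate_cohort(co$hrd_scores,
                         setNames(c(0.02, 0), c("a", "b")), sigma = 0, seed = 1)
  asc0 <- associate_hrd(co0$hrd_scores, co0$metrics)
  expect_equal(asc0$r_squared[asc0$drug == "a" & asc0$metric == "aucd"], 1,
               tolerance = 1e-12)
  expect_equal(asc0$slope[asc0$drug == "a" & asc0$metric == "aucd"], 0.02,
               tolerance = 1e-9)
  # zero-slope drug with sigma = 0: constant metric, R^2 undefined -> 0
  expect_equal(asc0$r_squared[asc0$drug == "b" & asc0$metric == "aucd"], 0)

  # noisy null matches the cor^2 oracle
  asc <- associate_hrd(co$hrd_scores, co$metrics)
  for (i in seq_len(nrow(asc))) {
    sub <- co$metrics[co$metrics$drug == asc$drug[i], ]
    y <- sub[[asc$metric[i]]]
    expect_equal(asc$r_squared[i],
                 oracle_pearson(co$hrd_scores[sub$cell_line], y)^2,
                 tolerance = 1e-9)
  }
})

test_that("sampling FDR is deterministic and separates planted signal", {
  slopes <- setNames(c(0.04, 0.04, 0, 0, 0, 0), sprintf("d%d", 1:6))
  co <- cohort_fixture(seed = 5, slopes = slopes)
  asc <- associate_hrd(co$hrd_scores, co$metrics)
  f1 <- estimate_fdr(asc, co$hrd_scores, co$metrics, n_samplings = 200,
                     seed = 9)
  f2 <- estimate_fdr(asc, co$hrd_scores, co$metrics, n_samplings = 200,
                     seed = 9)
  expect_equal(f1$fdr, f2$fdr)
  planted <- f1$drug %in% c("d1", "d2") & f1$metric == "aucd"
  expect_true(all(f1$fdr[planted] < 0.1))
  expect_true(all(f1$significant[planted]))
  expect_error(estimate_fdr(asc, co$hrd_scores, co$metrics, n_samplings = 10,
                            seed = 1), ">= 100")
})

test_that("stratified Welch tests separate high and low HRD groups", {
  scores <- setNames(c(3, 5, 7, 9, 11, 13, 15, 19, 22), sprintf("L%d", 1:9))
  hi <- scores >= 10
  set.seed(16)
  metrics <- data.frame(
    cell_line = names(scores), culture = "3D", drug = "carboplatin",
    timepoint_h = 72,
    aucd = ifelse(hi, rnorm(9, 0.8, 0.05), rnorm(9, 0.2, 0.05)),
    aucpi = rnorm(9, 0.5, 0.05), stringsAsFactors = FALSE)
  res <- stratified_group_test(scores, metrics)
  row <- res[res$metric == "aucd", ]
  expect_lt(row$p_value, 0.05)
  expect_true(row$significant)
  expect_equal(row$p_value,
               oracle_welch_p(metrics$aucd[hi], metrics$aucd[!hi]),
               tolerance = 1e-9)
  same <- res[res$metric == "aucpi", ]
  expect_gt(same$p_value, 0.05)
})
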