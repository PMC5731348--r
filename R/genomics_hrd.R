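#' Ploidy-dependent copy-number thresholds
#'
#' Gain/loss calls depend on the cell line's estimated ploidy: near-diploid
#' (`"2n"`) lines use gain > 2.7 / loss < 1.3, near-tri/tetraploid
#' (`"3n-4n"`) lines use gain > 4.7 / loss < 2.3. Loss of heterozygosity is
#' called when the copy number of one allele falls below
#' `loh_allele_threshold` (default 0.5; configurable, e.g. for samples with
#' contaminating non-tumour DNA).
#'
#' @param ploidy_class `"2n"` or `"3n-4n"`.
#' @param loh_allele_threshold minor-allele copy-number cutoff for LOH.
#' @return list of class `ploidy_model` with `gain_threshold`,
#'   `loss_threshold`, `loh_allele_threshold`, `ploidy_class`.
#' @export
ploidy_model <- function(ploidy_class = c("2n", "3n-4n"),
                         loh_allele_threshold = 0.5) {
  ploidy_class <- match.arg(ploidy_class)
  th <- if (ploidy_class == "2n") c(gain = 2.7, loss = 1.3)
        else c(gain = 4.7, loss = 2.3)
  structure(list(ploidy_class = ploidy_class,
                 gain_threshold = th[["gain"]], loss_threshold = th[["loss"]],
                 loh_allele_threshold = loh_allele_threshold),
            class = "ploidy_model")
}

#' Validate an allele-specific copy-number segment table
#'
#' Columns `chrom, start, end, tcn, cn_a, cn_b` with 0-based half-open
#' coordinates. Invariants: `end > start`, `cn_a >= cn_b >= 0`,
#' `tcn ~ cn_a + cn_b` (within 0.3), segments per chromosome sorted and
#' non-overlapping.
#'
#' @param segments data.frame of segments.
#' @return the table sorted by (chrom, start), invisibly validated.
#' @export
validate_segments <- function(segments) {
  req <- c("chrom", "start", "end", "tcn", "cn_a", "cn_b")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols) > 0L)
    stop("segment table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(segments$end <= segments$start))
    stop("segments must satisfy end > start")
  if (any(segments$cn_b < 0 | segments$cn_a < segments$cn_b))
    stop("allele copy numbers must satisfy cn_a >= cn_b >= 0")
  if (any(abs(segments$tcn - (segments$cn_a + segments$cn_b)) > 0.3))
    stop("tcn must equal cn_a + cn_b within 0.3")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch)
  }
  rownames(segments) <- NULL
  segments
}

#' Read a segment table TSV
#'
#' Tab-separated with header `chrom start end tcn cn_a cn_b`
#' (0-based, half-open coordinates).
#'
#' @param path TSV file path.
#' @return validated, sorted segment data.frame.
#' @export
read_segment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  validate_segments(df)
}

#' Classify segments into gain/loss/neutral and LOH
#'
#' A segment is a gain when `tcn > gain_threshold`, a loss when
#' `tcn < loss_threshold`, otherwise neutral; LOH is flagged when the minor
#' allele's copy number is below the LOH threshold (independently of the
#' gain/loss state, so copy-neutral LOH is representable).
#'
#' @param segments validated segment table.
#' @param model [ploidy_model()].
#' @return the table with added columns `state` (factor gain/loss/neutral)
#'   and `loh` (logical).
#' @export
classify_segments <- function(segments, model) {
  stopifnot(inherits(model, "ploidy_model"))
  segments <- validate_segments(segments)
  state <- ifelse(segments$tcn > model$gain_threshold, "gain",
                  ifelse(segments$tcn < model$loss_threshold, "loss",
                         "neutral"))
  segments$state <- factor(state, levels = c("gain", "loss", "neutral"))
  segments$loh <- pmin(segments$cn_a, segments$cn_b) < model$loh_allele_threshold
  segments
}

.SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "x", "y")

#' Modified HRD-LOH score from allele-specific copy-number segments
#'
#' Counts loss-of-heterozygosity regions as a proxy for homologous
#' recombination repair deficiency, in the modified form: book-ended LOH
#' segments per chromosome are merged into maximal regions; a region counts
#' when (1) it is longer than `min_length` (strict, default 10 Mb),
#' (2) it is a copy-number *loss* by its length-weighted mean total copy
#' number (copy-neutral and gained LOH are excluded), and (3) it does not
#' span the chromosome's full extent in the table. Autosomes only
#' (chromosome 17 included); set `classic = TRUE` for the original 15 Mb /
#' chromosome-17-excluded variant without the copy-neutral exclusion.
#'
#' @param segments segment table.
#' @param model [ploidy_model()].
#' @param min_length minimum region length in bp (default `1e7`).
#' @param classic use the classic scoring variant (15 Mb, chr17 excluded,
#'   copy-neutral LOH counted).
#' @param exclude_sex drop X/Y chromosomes (default `TRUE`).
#' @return list of class `hrd_result`: `score` (integer),
#'   `contributing_regions` (data.frame `chrom, start, end, length`),
#'   `stratum` (`"high"` when score >= 10, else `"low"`).
#' @export
hrd_score <- function(segments, model, min_length = 1e7, classic = FALSE,
                      exclude_sex = TRUE) {
  if (classic) min_length <- 1.5e7
  if (nrow(segments) == 0L) {
    warning("empty segment table; HRD score 0")
    return(structure(list(score = 0L,
                          contributing_regions = data.frame(
                            chrom = character(0L), start = numeric(0L),
                            end = numeric(0L), length = numeric(0L)),
                          stratum = "low"),
                     class = "hrd_result"))
  }
  cls <- classify_segments(segments, model)
  if (exclude_sex) cls <- cls[!(cls$chrom %in% .SEX_CHROMS), , drop = FALSE]
  if (classic) cls <- cls[!(cls$chrom %in% c("17", "chr17")), , drop = FALSE]
  regions <- list()
  for (ch in unique(cls$chrom)) {
    s <- cls[cls$chrom == ch, , drop = FALSE]
    chrom_min <- min(s$start); chrom_max <- max(s$end)
    l <- s[s$loh, , drop = FALSE]
    if (nrow(l) == 0L) next
    # merge book-ended LOH segments into maximal regions
    grp <- cumsum(c(1L, as.integer(l$start[-1L] != l$end[-nrow(l)])))
    for (g in split(l, grp)) {
      rstart <- min(g$start); rend <- max(g$end); rlen <- rend - rstart
      w_tcn <- sum(g$tcn * (g$end - g$start)) / sum(g$end - g$start)
      is_loss <- w_tcn < model$loss_threshold
      spans_chrom <- rstart == chrom_min && rend == chrom_max
      keep <- rlen > min_length && !spans_chrom &&
        (if (classic) TRUE else is_loss)
      if (keep)
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = rstart, end = rend, length = rlen,
          stringsAsFactors = FALSE)
    }
  }
  contributing <- if (length(regions) > 0L) do.call(rbind, regions)
    else data.frame(chrom = character(0L), start = numeric(0L),
                    end = numeric(0L), length = numeric(0L))
  score <- nrow(contributing)
  structure(list(score = score, contributing_regions = contributing,
                 stratum = if (score >= 10L) "high" else "low"),
            class = "hrd_result")
}

# Simple-regression R^2 and slope via QR least squares; a constant response
# has no explainable variance (R^2 = 0).
.ols_r2 <- function(x, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(list(r2 = 0, slope = 0))
  fit <- stats::.lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  list(r2 = max(0, min(1, 1 - rss / tss)),
       slope = unname(fit$coefficients[2L]))
}

#' Associate drug-response metrics with HRD scores
#'
#' For every drug x metric (x culture x timepoint) combination, ordinary
#' least-squares of the metric on the per-line HRD score; reports the
#' coefficient of determination R^2 and the slope.
#'
#' @param hrd_scores named numeric vector of HRD scores (names are cell
#'   lines).
#' @param metrics metrics data.frame ([assemble_metrics()] schema).
#' @param metric_cols metric columns to associate (default AUCd and AUCpi).
#' @return data.frame `drug, metric, culture, timepoint_h, n, r_squared,
#'   slope`; combinations with fewer than 4 complete lines or zero score
#'   variance get `NA` (flagged in `qc`).
#' @export
associate_hrd <- function(hrd_scores, metrics,
                          metric_cols = c("aucd", "aucpi")) {
  stopifnot(!is.null(names(hrd_scores)))
  combos <- unique(metrics[, c("drug", "culture", "timepoint_h")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- metrics$drug == combos$drug[i] &
      metrics$culture == combos$culture[i] &
      metrics$timepoint_h == combos$timepoint_h[i]
    sub <- metrics[sel, , drop = FALSE]
    score <- hrd_scores[sub$cell_line]
    for (mc in metric_cols) {
      y <- sub[[mc]]
      keep <- is.finite(y) & is.finite(score)
      qc <- ""
      if (sum(keep) < 4L) {
        r2 <- NA_real_; slope <- NA_real_; qc <- "too_few_lines"
      } else if (stats::var(score[keep]) == 0) {
        r2 <- NA_real_; slope <- NA_real_; qc <- "no_score_variance"
      } else {
        fit <- .ols_r2(score[keep], y[keep])
        r2 <- fit$r2; slope <- fit$slope
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug = combos$drug[i], metric = mc, culture = combos$culture[i],
        timepoint_h = combos$timepoint_h[i], n = sum(keep),
        r_squared = r2, slope = slope, qc = qc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sampling-based false discovery rate for R-squared associations
#'
#' Estimates, by random re-assignment of HRD scores to cell lines, how many
#' of the observed R^2 values would be expected by chance: for each
#' observed R^2 used as threshold `t`,
#' `FDR(t) = mean_null count(R2_null >= t) / max(1, count(R2_obs >= t))`,
#' clipped to `[0, 1]`. Deterministic under a fixed seed.
#'
#' @param associations output of [associate_hrd()] (observed R^2 values).
#' @param hrd_scores named score vector as passed to [associate_hrd()].
#' @param metrics the same metrics table.
#' @param n_samplings number of random score re-assignments (>= 100).
#' @param seed RNG seed (required; the permutations are the only source of
#'   randomness).
#' @param metric_cols metric columns, matching the associate call.
#' @param r2_threshold,fdr_threshold significance rule applied to the
#'   result (defaults R^2 > 0.61, FDR < 0.1).
#' @return `associations` with added columns `fdr` and `significant`.
#' @export
estimate_fdr <- function(associations, hrd_scores, metrics,
                         n_samplings = 1000L, seed,
                         metric_cols = c("aucd", "aucpi"),
                         r2_threshold = 0.61, fdr_threshold = 0.1) {
  if (n_samplings < 100L) stop("n_samplings must be >= 100")
  if (missing(seed)) stop("an explicit seed is required")
  obs <- associations$r_squared
  null_counts <- numeric(length(obs))  # per-threshold summed null exceedances
  null_store <- vector("list", n_samplings)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  finite_obs <- obs[is.finite(obs)]
  # precompute per-association (cell lines, metric values), so each sampling
  # only re-runs the regressions with re-assigned scores
  pairs <- lapply(seq_len(nrow(associations)), function(i) {
    sel <- metrics$drug == associations$drug[i] &
      metrics$culture == associations$culture[i] &
      metrics$timepoint_h == associations$timepoint_h[i]
    sub <- metrics[sel, , drop = FALSE]
    list(lines = sub$cell_line, y = sub[[associations$metric[i]]])
  })
  for (s in seq_len(n_samplings)) {
    perm <- hrd_scores
    names(perm) <- sample(names(hrd_scores))
    null_r2 <- vapply(pairs, function(p) {
      x <- perm[p$lines]
      keep <- is.finite(p$y) & is.finite(x)
      if (sum(keep) < 4L || stats::var(x[keep]) == 0) return(NA_real_)
      .ols_r2(x[keep], p$y[keep])$r2
    }, numeric(1L))
    null_r2 <- null_r2[is.finite(null_r2)]
    null_store[[s]] <- null_r2
    for (j in seq_along(obs)) {
      if (is.finite(obs[j]))
        null_counts[j] <- null_counts[j] + sum(null_r2 >= obs[j])
    }
  }
  fdr <- rep(NA_real_, length(obs))
  for (j in seq_along(obs)) {
    if (!is.finite(obs[j])) next
    observed_ge <- sum(finite_obs >= obs[j])
    fdr[j] <- min(max((null_counts[j] / n_samplings) / max(1, observed_ge), 0), 1)
  }
  associations$fdr <- fdr
  associations$significant <- is.finite(obs) & is.finite(fdr) &
    obs > r2_threshold & fdr < fdr_threshold
  # the pooled permutation-null R^2 draws, for calibration diagnostics
  attr(associations, "null_r2") <- unlist(null_store)
  attr(associations, "n_samplings") <- n_samplings
  associations
}

#' Stratified Welch test of drug responses by HRD class
#'
#' Cell lines are split into high (score >= 10) and low (< 10) HRD strata;
#' per drug (x metric x culture x timepoint), a two-sided Welch t-test
#' compares the metric between the strata.
#'
#' @param hrd_scores named numeric vector of HRD scores.
#' @param metrics metrics data.frame.
#' @param metric_cols metric columns to test.
#' @return data.frame `drug, metric, culture, timepoint_h, n_high, n_low,
#'   p_value, significant`; strata with fewer than 2 lines give `NA`.
#' @export
stratified_group_test <- function(hrd_scores, metrics,
                                  metric_cols = c("aucd", "aucpi")) {
  stratum <- ifelse(hrd_scores >= 10, "high", "low")
  combos <- unique(metrics[, c("drug", "culture", "timepoint_h")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- metrics$drug == combos$drug[i] &
      metrics$culture == combos$culture[i] &
      metrics$timepoint_h == combos$timepoint_h[i]
    sub <- metrics[sel, , drop = FALSE]
    st <- stratum[sub$cell_line]
    for (mc in metric_cols) {
      y <- sub[[mc]]
      keep <- is.finite(y) & !is.na(st)
      hi <- y[keep & st == "high"]; lo <- y[keep & st == "low"]
      p <- if (length(hi) >= 2L && length(lo) >= 2L)
        tryCatch(stats::t.test(hi, lo)$p.value, error = function(e) NA_real_)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        drug = combos$drug[i], metric = mc, culture = combos$culture[i],
        timepoint_h = combos$timepoint_h[i],
        n_high = length(hi), n_low = length(lo), p_value = p,
        significant = is.finite(p) && p < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
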