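#' Build drug-response profile matrix from a metrics table
#'
#' One row per (cell_line, culture), columns the chosen metrics per drug in
#' a fixed (alphabetical) drug order. Undetermined `ld50_display` values are
#' imputed as 0 (beyond the maximum dose) inside clustering feature matrices
#' only, and every imputed cell is recorded in the `imputed` attribute.
#'
#' @param metrics metrics data.frame ([assemble_metrics()]).
#' @param timepoint timepoint (hours) to select.
#' @param use metric columns to include (subset of
#'   `c("aucd", "aucpi", "ld50_display")`).
#' @return numeric matrix with rownames `cell_line|culture` and attribute
#'   `imputed` (logical matrix of the same shape).
#' @export
profile_matrix <- function(metrics, timepoint = 72,
                           use = c("aucd", "aucpi")) {
  stopifnot(all(use %in% c("aucd", "aucpi", "ld50_display")))
  sub <- metrics[metrics$timepoint_h == timepoint, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no metrics at timepoint ", timepoint)
  keys <- sort(unique(paste(sub$cell_line, sub$culture, sep = "|")))
  drugs <- sort(unique(sub$drug))
  cols <- as.vector(t(outer(drugs, use, paste, sep = ":")))
  mat <- matrix(NA_real_, length(keys), length(cols),
                dimnames = list(keys, cols))
  skey <- paste(sub$cell_line, sub$culture, sep = "|")
  for (i in seq_len(nrow(sub))) {
    for (m in use)
      mat[match(skey[i], keys), paste(sub$drug[i], m, sep = ":")] <- sub[[m]][i]
  }
  imputed <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if ("ld50_display" %in% use) {
    ld_cols <- grepl(":ld50_display$", colnames(mat))
    nd <- is.na(mat[, ld_cols, drop = FALSE])
    mat[, ld_cols][nd] <- 0
    imputed[, ld_cols][nd] <- TRUE
  }
  attr(mat, "imputed") <- imputed
  mat
}

# Deterministic hclust: rows ordered by name first so ties break by key.
.hclust_det <- function(mat, method) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
}

#' Hierarchical clustering of patient response profiles
#'
#' Agglomerative clustering of (cell_line, culture) drug-response profiles
#' with Euclidean distance and complete linkage. Profiles with more than
#' 50% missing entries are excluded with a warning; remaining missing
#' entries are imputed per column with the column mean (flagged in the
#' `imputed_cells` attribute). Leaf order is deterministic (profiles sorted
#' by key before clustering).
#'
#' @param mat profile matrix ([profile_matrix()]).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, optional `clusters` (named cut), `excluded`.
#' @export
cluster_profiles <- function(mat, k = NULL) {
  frac_missing <- rowMeans(is.na(mat))
  excluded <- rownames(mat)[frac_missing > 0.5]
  if (length(excluded) > 0L) {
    warning("profiles excluded (> 50% missing): ",
            paste(excluded, collapse = ", "))
    mat <- mat[frac_missing <= 0.5, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("need >= 2 complete profiles")
  imputed <- is.na(mat)
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) mat[nas, j] <- mean(mat[, j], na.rm = TRUE)
  }
  hc <- .hclust_det(mat, "complete")
  res <- list(hclust = hc, excluded = excluded, imputed_cells = imputed)
  if (!is.null(k)) res$clusters <- stats::cutree(hc, k = k)
  res
}

#' Hierarchical clustering of drugs by averaged response parameters
#'
#' Drugs are summarised by their response triplet (AUCd, AUCpi, rescaled
#' LD50) averaged over all cell lines, then clustered with Euclidean
#' distance and average linkage (UPGMA).
#'
#' @param metrics metrics data.frame.
#' @param timepoint timepoint (hours) to select.
#' @param k optional number of flat clusters.
#' @return list with `hclust`, `features` (drug x metric matrix), optional
#'   `clusters`.
#' @export
cluster_drugs <- function(metrics, timepoint = 72, k = NULL) {
  sub <- metrics[metrics$timepoint_h == timepoint, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no metrics at timepoint ", timepoint)
  drugs <- sort(unique(sub$drug))
  feats <- t(vapply(drugs, function(d) {
    rows <- sub[sub$drug == d, ]
    ld <- rows$ld50_display
    ld[is.na(ld)] <- 0  # nd = no kill within the dose range
    c(aucd = mean(rows$aucd, na.rm = TRUE),
      aucpi = mean(rows$aucpi, na.rm = TRUE),
      ld50_display = mean(ld))
  }, numeric(3L)))
  rownames(feats) <- drugs
  hc <- .hclust_det(feats, "average")
  res <- list(hclust = hc, features = feats)
  if (!is.null(k)) res$clusters <- stats::cutree(hc, k = k)
  res
}

#' Therapeutic index from paired LD50 values
#'
#' `TI = log10(ld50_normal / ld50_cancer)`: positive when cancer cells die
#' at a lower dose than normal epithelial cells (favourable). `NA`
#' (undetermined LD50) propagates.
#'
#' @param ld50_pdcl LD50 in the patient-derived cancer cell line.
#' @param ld50_normal LD50 in the normal reference cells, same dose units.
#' @return therapeutic index (vectorised), `NA` where either input is `NA`.
#' @export
therapeutic_index <- function(ld50_pdcl, ld50_normal) {
  if (any(ld50_pdcl <= 0 | ld50_normal <= 0, na.rm = TRUE))
    stop("LD50 values must be > 0")
  log10(ld50_normal / ld50_pdcl)
}

#' Per-drug 2D-vs-3D culture differences
#'
#' Computes per (drug, cell line) deltas `metric_3D - metric_2D` and, per
#' drug, a two-sided Welch t-test of the 2D against the 3D values across
#' cell lines; drugs with `p < 0.05` are flagged. Drugs with fewer than 3
#' cell lines measured in both cultures are not tested (`NA` p-value).
#'
#' @param metrics_2d,metrics_3d metrics data.frames for the two cultures at
#'   one timepoint.
#' @param metric column to compare (`"aucd"` or `"aucpi"`).
#' @return list with `deltas` (drug x cell_line matrix) and `tests`
#'   (data.frame `drug, p_value, significant, n`).
#' @export
culture_difference <- function(metrics_2d, metrics_3d, metric = "aucd") {
  stopifnot(metric %in% c("aucd", "aucpi", "ld50_display"))
  k2 <- paste(metrics_2d$drug, metrics_2d$cell_line, sep = "|")
  k3 <- paste(metrics_3d$drug, metrics_3d$cell_line, sep = "|")
  common <- intersect(k2, k3)
  if (length(common) == 0L) stop("no matched drug x cell_line keys")
  v2 <- metrics_2d[[metric]][match(common, k2)]
  v3 <- metrics_3d[[metric]][match(common, k3)]
  drug <- sub("\\|.*$", "", common)
  line <- sub("^[^|]*\\|", "", common)
  drugs <- sort(unique(drug)); lines <- sort(unique(line))
  deltas <- matrix(NA_real_, length(drugs), length(lines),
                   dimnames = list(drugs, lines))
  deltas[cbind(match(drug, drugs), match(line, lines))] <- v3 - v2
  tests <- do.call(rbind, lapply(drugs, function(d) {
    sel <- drug == d & is.finite(v2) & is.finite(v3)
    n <- sum(sel)
    p <- NA_real_
    if (n >= 3L) {
      p <- tryCatch(stats::t.test(v2[sel], v3[sel])$p.value,
                    error = function(e) NA_real_)
    }
    data.frame(drug = d, p_value = p,
               significant = is.finite(p) && p < 0.05, n = n,
               stringsAsFactors = FALSE)
  }))
  list(deltas = deltas, tests = tests)
}

#' Paired test of a drug combination against a single agent
#'
#' Two-sided paired Student t-test of combination vs single-drug metric
#' values paired by cell line. Identical vectors (zero pair variance) give
#' p = 1.
#'
#' @param combo_values,single_values metric values paired by cell line.
#' @return list with `p_value` and `n`; `p_value` is `NA` (flagged) when
#'   fewer than 3 complete pairs exist.
#' @export
combination_test <- function(combo_values, single_values) {
  stopifnot(length(combo_values) == length(single_values))
  keep <- is.finite(combo_values) & is.finite(single_values)
  x <- combo_values[keep]; y <- single_values[keep]
  if (length(x) < 3L) return(list(p_value = NA_real_, n = length(x)))
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(p_value = if (all(d == 0)) 1 else 0, n = length(x)))
  list(p_value = stats::t.test(x, y, paired = TRUE)$p.value, n = length(x))
}

#' Pearson concordance between biological replicates
#'
#' @param rep1,rep2 metric vectors from two independent replicate screens;
#'   incomplete pairs are dropped.
#' @return list with `r` (Pearson correlation, `NA` when undefined) and `n`
#'   (pairs used). Requires at least 3 complete pairs; zero variance in
#'   either vector yields `NA`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  stopifnot(length(rep1) == length(rep2))
  keep <- is.finite(rep1) & is.finite(rep2)
  x <- rep1[keep]; y <- rep2[keep]
  if (length(x) < 3L) stop("need >= 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x)))
  list(r = stats::cor(x, y), n = length(x))
}
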