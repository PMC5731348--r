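#' Death ratio from mask areas
#'
#' Fraction of the all-cell area occupied by dead cells:
#' `area_pi / area_total`. An empty total area yields `NA` (the observation
#' is flagged empty upstream).
#'
#' @param area_pi dead-cell (PI) mask area in pixels.
#' @param area_total all-cell (Hoechst + PI) mask area in pixels.
#' @return numeric in `[0, 1]`, or `NA` when `area_total == 0`. Vectorised.
#' @export
death_ratio <- function(area_pi, area_total) {
  if (any(area_pi < 0 | area_total < 0, na.rm = TRUE))
    stop("areas must be nonnegative")
  if (any(area_pi > area_total, na.rm = TRUE))
    stop("area_pi must not exceed area_total")
  ifelse(area_total == 0, NA_real_, area_pi / area_total)
}

#' Dead-cell-loss correction for late timepoints
#'
#' Dead cells cannot move away, so the dead-cell area cannot truly decrease
#' between 72 h and 144 h; an apparent decrease reflects disintegrated cells
#' that no longer stain with PI. The 144-h PI area is therefore floored at
#' the 72-h value measured at the same position. Idempotent.
#'
#' @param pi_area_72,pi_area_144 PI areas at the same position.
#' @return corrected 144-h PI area (vectorised).
#' @export
correct_dead_cell_loss <- function(pi_area_72, pi_area_144) {
  pmax(pi_area_144, pi_area_72)
}

#' Raw growth from total areas
#'
#' Ratio of the all-cell area at a later timepoint to the area at drug test
#' start (0 h), at the same position.
#'
#' @param area_total_t total area at 72 or 144 h.
#' @param area_total_0 total area at 0 h.
#' @return raw growth factor; `NA` (undetermined) when the baseline is 0.
#' @export
compute_growth <- function(area_total_t, area_total_0) {
  if (any(area_total_t < 0 | area_total_0 < 0, na.rm = TRUE))
    stop("areas must be nonnegative")
  ifelse(is.na(area_total_0) | area_total_0 == 0, NA_real_,
         area_total_t / area_total_0)
}

#' Growth clamping rules
#'
#' Applies, in order: (1) growth below 1 is set to 1 (cells migrating out of
#' the imaged position are a measurement artefact, not shrinkage);
#' (2) growth is capped at 8 (three doublings in three days) to filter
#' artefacts; (3) for drug-treated wells only, growth is capped at twice the
#' median control growth `mgc`; (4) 144-h growth is floored at the 72-h
#' value (dead-cell-loss rationale applied to growth). Idempotent.
#'
#' @param raw_72,raw_144 raw growth values at one position (either may be
#'   `NA` when that timepoint is missing).
#' @param mgc median growth of controls at the matching timepoint (used only
#'   for the treated cap).
#' @param treated logical; apply the `2 * mgc` cap (rule 3)?
#' @return list with `growth_72` and `growth_144`.
#' @export
clamp_growth <- function(raw_72, raw_144, mgc = Inf, treated = TRUE) {
  clamp1 <- function(g) {
    g <- pmax(g, 1)
    g <- pmin(g, 8)
    if (treated) g <- pmin(g, 2 * mgc)
    g
  }
  g72 <- clamp1(raw_72)
  g144 <- clamp1(raw_144)
  if (!is.na(g72) && !is.na(g144)) g144 <- max(g144, g72)
  list(growth_72 = g72, growth_144 = g144)
}

#' ANOVA gate for dose-response fitting
#'
#' LD50 fitting is only attempted when drug treatment significantly changed
#' cell death: a classic one-way ANOVA of per-position death ratios with
#' groups `{control} + {each dose}` must give `p < 0.0005` (strict).
#'
#' @param values per-observation death ratios.
#' @param groups group labels (character/factor); the control group plus one
#'   group per dose.
#' @param control_label label identifying the control group.
#' @return list with `p_value` and `gate_open`.
#' @export
anova_gate <- function(values, groups, control_label = "control") {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  keep <- is.finite(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (sum(groups == control_label) < 2L)
    stop("need >= 2 control observations for the ANOVA gate")
  if (length(unique(groups[groups != control_label])) < 1L)
    stop("need >= 1 treated group")
  if (stats::var(values) == 0)
    return(list(p_value = 1, gate_open = FALSE))
  fit <- stats::lm(values ~ factor(groups))
  p <- stats::anova(fit)[["Pr(>F)"]][1L]
  if (!is.finite(p)) p <- 1
  list(p_value = p, gate_open = p < 0.0005)
}

#' Increasing four-parameter log-logistic curve
#'
#' `f(x) = c + (d - c) / (1 + (e / x)^b)` with `e` the LD50 and `b > 0` the
#' Hill slope of the increasing (kill) curve.
#'
#' @param x dose (> 0).
#' @param c_lower,d_upper lower/upper asymptotes.
#' @param b Hill slope (> 0).
#' @param ld50 half-effect dose.
#' @return response values.
#' @export
ll4 <- function(x, c_lower, d_upper, b, ld50) {
  c_lower + (d_upper - c_lower) / (1 + (ld50 / x)^b)
}

#' Constrained log-logistic fit of a death dose-response series
#'
#' Least-squares fit of the increasing four-parameter log-logistic with
#' constraints `0 <= c <= d <= 1`, Hill slope `b > 0`, the LD50 optimised on
#' the log scale. Three data-driven initialisations are tried and the best
#' residual kept. The fit is only meaningful downstream when the ANOVA gate
#' opened; a closed gate, fewer than 4 distinct doses or non-convergence all
#' yield an undetermined (`NA`) LD50.
#'
#' @param dose per-observation doses (> 0); replicate observations per dose
#'   are used as-is.
#' @param response per-observation death ratios in `[0, 1]`.
#' @param gate_open result of [anova_gate()]; `FALSE` short-circuits to nd.
#' @return list (class `ll4_fit`) with `b`, `c_lower`, `d_upper`, `ld50`,
#'   `converged`, `gated` (TRUE when the gate was closed), `rss`.
#' @export
fit_log_logistic <- function(dose, response, gate_open = TRUE) {
  nd <- function(gated) list(b = NA_real_, c_lower = NA_real_,
                             d_upper = NA_real_, ld50 = NA_real_,
                             converged = FALSE, gated = gated, rss = NA_real_)
  if (!gate_open) return(structure(nd(TRUE), class = "ll4_fit"))
  keep <- is.finite(dose) & is.finite(response) & dose > 0
  dose <- dose[keep]; response <- response[keep]
  if (length(unique(dose)) < 4L) return(structure(nd(FALSE), class = "ll4_fit"))

  obj <- function(par) {
    cc <- par[1L]; dd <- par[2L]
    pred <- ll4(dose, cc, dd, exp(par[3L]), exp(par[4L]))
    sum((response - pred)^2) + 1e6 * max(0, cc - dd)^2
  }
  ld <- sort(unique(dose))
  lo <- min(response); hi <- max(response)
  mid <- (lo + hi) / 2
  # dose where the response first crosses the midpoint (log interpolation)
  agg <- vapply(ld, function(x) mean(response[dose == x]), numeric(1L))
  cross <- ld[which(agg >= mid)[1L]]
  if (is.na(cross)) cross <- exp(mean(log(range(dose))))
  starts <- list(c(lo, hi, log(1), log(cross)),
                 c(lo, hi, log(2), log(exp(mean(log(range(dose)))))),
                 c(lo, hi, log(4), log(cross)))
  lower <- c(0, 0, log(1e-3), log(min(dose)) - 5)
  upper <- c(1, 1, log(1e3), log(max(dose)) + 5)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e1)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(structure(nd(FALSE), class = "ll4_fit"))
  par <- best$par
  structure(list(b = exp(par[3L]), c_lower = par[1L], d_upper = par[2L],
                 ld50 = exp(par[4L]), converged = best$convergence == 0L,
                 gated = FALSE, rss = best$value),
            class = "ll4_fit")
}

# Trapezoidal mean of y over x, normalised by the span of x.
.trapz_mean <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  o <- order(x); x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2) / (x[length(x)] - x[1L])
}

#' Normalised area under the death curve (AUCd)
#'
#' Trapezoidal mean of `death_ratio - m` over the equally spaced log3-dose
#' index grid (`m` is the median control death ratio), normalised so the
#' result is in `[-1, 1]`: positive raw areas are divided by `1 - m`
#' (head-room to full kill), negative ones by `m`.
#'
#' @param ratios per-dose death ratios, ordered by increasing dose on the
#'   1:3 dilution grid.
#' @param m median control death ratio at the same timepoint.
#' @param dose_index optional grid coordinates (defaults to `1:length`,
#'   i.e. the log3-dose index); `NA` ratios are dropped with their
#'   coordinate.
#' @return AUCd in `[-1, 1]`, `NA` if fewer than 2 finite doses.
#' @export
auc_death <- function(ratios, m, dose_index = seq_along(ratios)) {
  if (!is.finite(m) || m < 0 || m > 1)
    stop("control median m must be in [0, 1]")
  raw <- .trapz_mean(dose_index, ratios - m)
  if (!is.finite(raw)) return(NA_real_)
  if (raw > 0) {
    if (m >= 1) return(NA_real_)  # degenerate: no head-room, cannot occur with valid ratios
    val <- raw / (1 - m)
  } else if (raw < 0) {
    if (m <= 0) return(NA_real_)
    val <- raw / m
  } else val <- 0
  min(max(val, -1), 1)
}

#' Normalised area under the proliferation-inhibition curve (AUCpi)
#'
#' Per dose, inhibition is `(mgc - growth) / (mgc - 1)` (1 = complete
#' arrest, 0 = control-like growth), clipped to `[-1, 1]`; AUCpi is its
#' trapezoidal mean over the log3-dose index grid. When controls did not
#' grow (`mgc <= 1 + 1e-6`) the metric is undetermined.
#'
#' @param growth per-dose clamped growth values, ordered by increasing dose.
#' @param mgc median growth of controls at the same timepoint.
#' @param dose_index optional grid coordinates (defaults to dose index).
#' @return AUCpi in `[-1, 1]`, or `NA` when undetermined.
#' @export
auc_prolif_inhibition <- function(growth, mgc, dose_index = seq_along(growth)) {
  if (!is.finite(mgc) || mgc <= 1 + 1e-6) return(NA_real_)
  pi_vals <- pmin(pmax((mgc - growth) / (mgc - 1), -1), 1)
  .trapz_mean(dose_index, pi_vals)
}

#' Rescale an LD50 onto the dose range for display
#'
#' Maps the log LD50 linearly onto `[0, 1]` so that 1 corresponds to the
#' minimum and 0 to the maximum dose of the series (clipped); `NA`
#' (undetermined) propagates.
#'
#' @param ld50 fitted LD50 (dose units), or `NA`.
#' @param dmin,dmax minimum / maximum dose of the series (`0 < dmin < dmax`).
#' @return value in `[0, 1]` or `NA`.
#' @export
normalize_ld50_display <- function(ld50, dmin, dmax) {
  if (!(dmin > 0 && dmax > dmin)) stop("need 0 < dmin < dmax")
  if (is.na(ld50)) return(NA_real_)
  if (ld50 <= 0) stop("ld50 must be > 0")
  val <- (log(dmax) - log(ld50)) / (log(dmax) - log(dmin))
  min(max(val, 0), 1)
}

#' Assemble response metrics from an area table
#'
#' Full per-drug quantification: applies the dead-cell-loss correction per
#' position, computes per-position death ratios and clamped growth, derives
#' control statistics (`m`: median control death ratio, `mgc`: median
#' control growth; untreated and solvent controls pooled), aggregates the
#' positions of one dose by summing areas before ratios, gates the LD50 fit
#' with a one-way ANOVA (`p < 0.0005`), and computes LD50 (with display
#' rescaling), AUCd and AUCpi per drug x cell line x culture x timepoint.
#'
#' @param areas area table ([read_area_table()] schema), covering all
#'   timepoints of the plate(s). Growth metrics require the 0-h timepoint;
#'   without it death metrics are still computed.
#' @return metrics data.frame with columns `cell_line, culture, drug,
#'   timepoint_h, ld50, ld50_display, aucd, aucpi, gate_p, qc_flags`.
#' @export
assemble_metrics <- function(areas) {
  validate_area_table(areas)
  key <- paste(areas$plate, areas$well, areas$position, areas$timepoint_h,
               sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (plate, well, position, timepoint) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  out <- list()
  for (grp in split(areas, paste(areas$cell_line, areas$culture, sep = "|"))) {
    out[[length(out) + 1L]] <- .metrics_one_group(grp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Death ratio tolerant of the dead-cell-loss correction: the corrected PI
# area may exceed a shrunken later total area, so the ratio is capped at 1.
.ratio_capped <- function(area_pi, area_total) {
  ifelse(is.na(area_total) | area_total == 0, NA_real_,
         pmin(area_pi / area_total, 1))
}

# Metrics for one cell line x culture (controls shared within the group).
.metrics_one_group <- function(grp) {
  tps <- sort(setdiff(unique(grp$timepoint_h), 0))
  has_t0 <- 0 %in% grp$timepoint_h
  pos_key <- paste(grp$plate, grp$well, grp$position, sep = "|")

  # per-position wide tables of areas by timepoint
  pos <- unique(data.frame(pkey = pos_key, plate = grp$plate, well = grp$well,
                           position = grp$position, drug = grp$drug,
                           concentration = grp$concentration, unit = grp$unit,
                           role = grp$role, stringsAsFactors = FALSE))
  get_area <- function(col, tp) {
    v <- rep(NA_real_, nrow(pos))
    sel <- grp$timepoint_h == tp
    idx <- match(pos_key[sel], pos$pkey)
    v[idx] <- grp[[col]][sel]
    v
  }
  a_tot <- lapply(c(0, tps), function(tp) get_area("area_total", tp))
  names(a_tot) <- as.character(c(0, tps))
  a_pi <- lapply(tps, function(tp) get_area("area_pi", tp))
  names(a_pi) <- as.character(tps)

  # dead-cell-loss correction per position (144 h floored at 72 h)
  if (all(c("72", "144") %in% names(a_pi)))
    a_pi[["144"]] <- correct_dead_cell_loss(a_pi[["72"]], a_pi[["144"]])

  is_ctrl <- pos$role != "treated"
  ctrl_label <- "control"
  rows <- list()
  for (tp in tps) {
    tpc <- as.character(tp)
    dr_pos <- .ratio_capped(a_pi[[tpc]], a_tot[[tpc]])
    m <- stats::median(dr_pos[is_ctrl], na.rm = TRUE)

    # per-position clamped growth (controls first, to obtain mgc)
    raw <- if (has_t0) compute_growth(a_tot[[tpc]], a_tot[["0"]])
           else rep(NA_real_, nrow(pos))
    raw72 <- if (has_t0 && "72" %in% names(a_tot) && tp > 72)
      compute_growth(a_tot[["72"]], a_tot[["0"]]) else rep(NA_real_, nrow(pos))
    ctrl_growth <- vapply(which(is_ctrl), function(i) {
      g <- clamp_growth(if (tp > 72) raw72[i] else raw[i],
                        if (tp > 72) raw[i] else NA_real_, treated = FALSE)
      if (tp > 72) g$growth_144 else g$growth_72
    }, numeric(1L))
    mgc <- stats::median(ctrl_growth, na.rm = TRUE)
    growth_pos <- rep(NA_real_, nrow(pos))
    for (i in seq_len(nrow(pos))) {
      g <- clamp_growth(if (tp > 72) raw72[i] else raw[i],
                        if (tp > 72) raw[i] else NA_real_,
                        mgc = mgc, treated = !is_ctrl[i])
      growth_pos[i] <- if (tp > 72) g$growth_144 else g$growth_72
    }

    for (d in unique(pos$drug[pos$role == "treated"])) {
      sel <- pos$role == "treated" & pos$drug == d
      doses <- sort(unique(pos$concentration[sel]))
      if (length(doses) < 2L) next
      # aggregate the positions of one dose by summing areas before ratios
      dr_dose <- vapply(doses, function(x) {
        ii <- sel & pos$concentration == x
        .ratio_capped(sum(a_pi[[tpc]][ii], na.rm = TRUE),
                      sum(a_tot[[tpc]][ii], na.rm = TRUE))
      }, numeric(1L))
      growth_dose <- vapply(doses, function(x) {
        ii <- sel & pos$concentration == x
        mean(growth_pos[ii], na.rm = TRUE)
      }, numeric(1L))

      # ANOVA gate on per-position ratios, control group pooled
      obs <- c(dr_pos[is_ctrl], dr_pos[sel])
      gl <- c(rep(ctrl_label, sum(is_ctrl)),
              as.character(pos$concentration[sel]))
      gate <- tryCatch(anova_gate(obs, gl, ctrl_label),
                       error = function(e) list(p_value = NA_real_,
                                                gate_open = FALSE))
      fit <- fit_log_logistic(pos$concentration[sel], dr_pos[sel],
                              gate_open = isTRUE(gate$gate_open))
      ld50 <- if (isTRUE(fit$converged)) fit$ld50 else NA_real_
      flags <- character(0L)
      if (!isTRUE(gate$gate_open)) flags <- c(flags, "gate_closed")
      if (!has_t0) flags <- c(flags, "no_growth_baseline")
      aucd <- auc_death(dr_dose, m)
      aucpi <- if (has_t0) auc_prolif_inhibition(growth_dose, mgc)
               else NA_real_
      if (has_t0 && is.na(aucpi)) flags <- c(flags, "controls_not_growing")
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = grp$cell_line[1L], culture = grp$culture[1L], drug = d,
        timepoint_h = tp, ld50 = ld50,
        ld50_display = if (is.na(ld50)) NA_real_ else
          normalize_ld50_display(ld50, min(doses), max(doses)),
        aucd = aucd, aucpi = aucpi, gate_p = gate$p_value,
        qc_flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

.METRICS_COLS <- c("cell_line", "culture", "drug", "timepoint_h", "ld50",
                   "ld50_display", "aucd", "aucpi", "gate_p", "qc_flags")

#' Write / read a metrics table
#'
#' CSV with header
#' `cell_line,culture,drug,timepoint_h,ld50,ld50_display,aucd,aucpi,gate_p,qc_flags`;
#' undetermined values are written as the literal `nd`.
#'
#' @param metrics metrics data.frame ([assemble_metrics()]).
#' @param path CSV file path.
#' @return `write_metrics_table`: `path`, invisibly; `read_metrics_table`:
#'   the data.frame with `nd` parsed back to `NA`.
#' @export
write_metrics_table <- function(metrics, path) {
  stopifnot(all(.METRICS_COLS %in% names(metrics)))
  out <- metrics[, .METRICS_COLS]
  for (col in c("ld50", "ld50_display", "aucd", "aucpi", "gate_p")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "nd", format(v, digits = 15))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.METRICS_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("metrics table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (col in c("timepoint_h", "ld50", "ld50_display", "aucd", "aucpi",
                "gate_p")) {
    v <- df[[col]]
    v[v == "nd"] <- NA
    df[[col]] <- as.numeric(v)
  }
  df$qc_flags[is.na(df$qc_flags)] <- ""
  df
}
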