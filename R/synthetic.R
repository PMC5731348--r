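# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Rendering parameters for synthetic well images
#'
#' Defaults emulate the assay's imaging geometry (512 x 512 pixels at
#' 2.767 um/pixel) and dye behaviour on an 8-bit intensity scale: live
#' nuclei are Hoechst-dim (signal-to-background 4, comfortably above the
#' assay's SNR > 2 requirement), dead nuclei are Hoechst-bright and
#' PI-positive, live-cell PI equals background. Nuclei are hard
#' (non-anti-aliased) disks so ground-truth areas are exact pixel counts.
#'
#' @param size image side length in pixels.
#' @param pixel_size micrometres per pixel.
#' @param radius_range min/max nucleus radius in pixels (uniform draw).
#' @param background background intensity.
#' @param live_hoechst,dead_hoechst Hoechst disk intensities.
#' @param live_pi,dead_pi PI disk intensities.
#' @param noise_sd Gaussian noise standard deviation.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(size = 512L, pixel_size = 2.767,
                        radius_range = c(4, 7), background = 10,
                        live_hoechst = 40, dead_hoechst = 80,
                        live_pi = 10, dead_pi = 60, noise_sd = 3) {
  stopifnot(size >= 32L, all(radius_range >= 1),
            live_hoechst / background >= 2, dead_hoechst > live_hoechst,
            dead_pi > background, noise_sd >= 0)
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 radius_range = radius_range, background = background,
                 live_hoechst = live_hoechst, dead_hoechst = dead_hoechst,
                 live_pi = live_pi, dead_pi = dead_pi, noise_sd = noise_sd),
            class = "render_spec")
}

#' Render one synthetic two-channel well image with ground truth
#'
#' Places `n_live + n_dead` non-overlapping hard disks (rejection sampling;
#' centres rejected when closer than 90% of the radius sum, errors when the
#' requested count is infeasible), paints them with the render-spec channel
#' intensities, adds Gaussian noise, and returns the image together with
#' exact truth masks and areas.
#'
#' @param n_live,n_dead nucleus counts.
#' @param spec [render_spec()].
#' @param seed RNG seed; the render is a pure function of
#'   (arguments, seed).
#' @return list with `mip` ([mip_image()] with `hoechst` and `pi`
#'   channels) and `truth` (list: `mask_total`, `mask_dead`, `area_total`,
#'   `area_pi`, `dead_fraction`).
#' @export
render_well <- function(n_live, n_dead, spec = render_spec(), seed = 1L) {
  n <- n_live + n_dead
  with_seed(seed, {
    sz <- spec$size
    centers <- matrix(numeric(0L), 0L, 2L); radii <- numeric(0L)
    attempts <- 0L
    while (nrow(centers) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(n, 1L))
        stop("requested nuclei count infeasible for this image size")
      r <- stats::runif(1L, spec$radius_range[1L], spec$radius_range[2L])
      cx <- stats::runif(1L, r + 1, sz - r)
      cy <- stats::runif(1L, r + 1, sz - r)
      if (nrow(centers) > 0L) {
        d <- sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)
        if (any(d < 0.9 * (radii + r))) next
      }
      centers <- rbind(centers, c(cx, cy)); radii <- c(radii, r)
    }
    is_dead <- c(rep(FALSE, n_live), rep(TRUE, n_dead))
    hoechst <- matrix(spec$background, sz, sz)
    pi_img <- matrix(spec$background, sz, sz)
    mask_total <- matrix(FALSE, sz, sz)
    mask_dead <- matrix(FALSE, sz, sz)
    for (i in seq_len(n)) {
      # rasterise within the disk's bounding box only
      r <- radii[i]; cx <- centers[i, 1L]; cy <- centers[i, 2L]
      rows <- max(1L, floor(cx - r)):min(sz, ceiling(cx + r))
      cols <- max(1L, floor(cy - r)):min(sz, ceiling(cy + r))
      inside <- outer((rows - cx)^2, (cols - cy)^2, `+`) <= r^2
      idx <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))[inside, , drop = FALSE]
      mask_total[idx] <- TRUE
      if (is_dead[i]) {
        mask_dead[idx] <- TRUE
        hoechst[idx] <- spec$dead_hoechst
        pi_img[idx] <- spec$dead_pi
      } else {
        hoechst[idx] <- spec$live_hoechst
        pi_img[idx] <- spec$live_pi
      }
    }
    if (spec$noise_sd > 0) {
      hoechst <- pmax(hoechst + stats::rnorm(sz * sz, 0, spec$noise_sd), 0)
      pi_img <- pmax(pi_img + stats::rnorm(sz * sz, 0, spec$noise_sd), 0)
    }
    area_total <- sum(mask_total); area_pi <- sum(mask_dead)
    list(mip = mip_image(list(hoechst = hoechst, pi = pi_img),
                         pixel_size = spec$pixel_size,
                         provenance = sprintf("synthetic_seed%d", seed)),
         truth = list(mask_total = mask_total, mask_dead = mask_dead,
                      area_total = area_total, area_pi = area_pi,
                      dead_fraction = if (area_total > 0)
                        area_pi / area_total else NA_real_))
  })
}

#' Simulate a measured dose-response series
#'
#' Death ratios are drawn as `clip(f(x) + N(0, sigma), 0, 1)` with `f` the
#' increasing four-parameter log-logistic kill curve; growth follows a
#' decreasing arrest model `g(x) = 1 + (mgc - 1) / (1 + (x/gi50)^k)` plus
#' noise. Control observations (dose `NA`) are drawn at `f = floor` and
#' `g = mgc`. Deterministic under the seed.
#'
#' @param doses dose grid (default 8-point 1:3 dilution series).
#' @param ld50,hill,floor,ceiling kill-curve parameters.
#' @param mgc true control growth; `gi50`, `k` arrest-model parameters.
#' @param n_positions replicate positions per dose (and per control).
#' @param sigma Gaussian noise sd on death ratios and growth.
#' @param seed RNG seed.
#' @return data.frame `dose` (NA for controls), `position`, `role`,
#'   `death_ratio`, `growth`, with the generating parameters in attribute
#'   `truth`.
#' @export
simulate_dose_response <- function(doses = 0.1 * 3^(0:7), ld50, hill = 2,
                                   floor = 0.05, ceiling = 0.95, mgc = 2.5,
                                   gi50 = ld50, k = 2, n_positions = 2L,
                                   sigma = 0.05, seed = 1L) {
  stopifnot(sigma >= 0, all(doses > 0))
  with_seed(seed, {
    grid <- expand.grid(position = seq_len(n_positions), dose = doses)
    f <- ll4(grid$dose, floor, ceiling, hill, ld50)
    g <- 1 + (mgc - 1) / (1 + (grid$dose / gi50)^k)
    treated <- data.frame(
      dose = grid$dose, position = grid$position, role = "treated",
      death_ratio = pmin(pmax(f + stats::rnorm(nrow(grid), 0, sigma), 0), 1),
      growth = pmax(g + stats::rnorm(nrow(grid), 0, sigma), 0),
      stringsAsFactors = FALSE)
    ctrl <- data.frame(
      dose = NA_real_, position = seq_len(n_positions),
      role = "untreated_control",
      death_ratio = pmin(pmax(floor + stats::rnorm(n_positions, 0, sigma), 0), 1),
      growth = pmax(mgc + stats::rnorm(n_positions, 0, sigma), 0),
      stringsAsFactors = FALSE)
    out <- rbind(ctrl, treated)
    attr(out, "truth") <- list(ld50 = ld50, hill = hill, floor = floor,
                               ceiling = ceiling, mgc = mgc, gi50 = gi50,
                               k = k, sigma = sigma, doses = doses)
    out
  })
}

#' Simulate a complete renderable drug plate with ground truth
#'
#' Generates the plate layout, per-condition nucleus counts from an
#' exponential-growth-plus-arrest model and log-logistic kill curve, and a
#' rendered two-channel image per well position and timepoint. Controls
#' grow by `mgc_true` per 72 h; treated growth is reduced by the arrest
#' model; dead fractions follow the kill curve (constant in time by
#' default).
#'
#' @param drug drug name.
#' @param doses 8-point 1:3 dose grid.
#' @param ld50,hill,floor,ceiling kill-curve truth.
#' @param mgc_true control growth factor per 72 h.
#' @param gi50,k arrest-model truth.
#' @param n0 live-nucleus count per position at 0 h.
#' @param timepoints imaging hours (default `c(0, 72, 144)`).
#' @param n_positions positions per well.
#' @param spec [render_spec()].
#' @param seed RNG seed.
#' @param out_dir optional directory; when given, images are written as
#'   TIFFs under the package naming convention plus a `layout.csv` and a
#'   `truth.json`.
#' @return list with `images` (named list of `mip_image` with parse
#'   attributes), `layout` (validated data.frame) and `truth` (per-dose
#'   planted dead fractions and growth per timepoint, plus parameters).
#' @export
simulate_plate <- function(drug = "drugA", doses = 0.1 * 3^(0:7),
                           ld50 = 0.1 * 3^3, hill = 2, floor = 0.05,
                           ceiling = 0.95, mgc_true = 2, gi50 = ld50, k = 2,
                           n0 = 60L, timepoints = c(0, 72, 144),
                           n_positions = 2L, spec = render_spec(),
                           seed = 1L) {
  conditions <- data.frame(
    well = sprintf("B%02d", seq_len(length(doses) + 1L)),
    drug = c(rep(drug, length(doses)), ""),
    concentration = c(doses, NA_real_),
    role = c(rep("treated", length(doses)), "untreated_control"),
    stringsAsFactors = FALSE)
  layout <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    data.frame(plate = "simplate", well = conditions$well[i],
               position = paste0("p", seq_len(n_positions)),
               cell_line = "SIM1", culture = "3D",
               drug = conditions$drug[i],
               concentration = conditions$concentration[i], unit = "uM",
               role = conditions$role[i],
               timepoints = I(rep(list(timepoints), n_positions)),
               stringsAsFactors = FALSE)
  }))
  validate_plate_layout(layout)

  growth_at <- function(dose, tp) {
    if (tp == 0) return(1)
    gc <- mgc_true^(tp / 72)
    if (is.na(dose)) gc else 1 + (gc - 1) / (1 + (dose / gi50)^k)
  }
  dead_frac_at <- function(dose, tp) {
    if (tp == 0 || is.na(dose)) return(floor)
    ll4(dose, floor, ceiling, hill, ld50)
  }

  images <- list(); truth_rows <- list()
  img_idx <- 0L
  for (i in seq_len(nrow(layout))) {
    for (tp in timepoints) {
      img_idx <- img_idx + 1L
      dose <- layout$concentration[i]
      g <- growth_at(dose, tp)
      f <- dead_frac_at(dose, tp)
      n_tot <- max(1L, round(n0 * g))
      n_dead <- round(n_tot * f)
      rw <- render_well(n_tot - n_dead, n_dead, spec, seed = seed + img_idx)
      id <- sprintf("simplate_%s_%s_%gh", layout$well[i], layout$position[i], tp)
      img <- rw$mip
      attr(img, "plate") <- "simplate"; attr(img, "well") <- layout$well[i]
      attr(img, "position") <- layout$position[i]; attr(img, "timepoint") <- tp
      images[[id]] <- img
      truth_rows[[img_idx]] <- data.frame(
        well = layout$well[i], position = layout$position[i],
        timepoint_h = tp, dose = dose, growth = g, dead_fraction_model = f,
        dead_fraction_truth = rw$truth$dead_fraction,
        area_total = rw$truth$area_total, area_pi = rw$truth$area_pi,
        stringsAsFactors = FALSE)
    }
  }
  truth <- list(per_image = do.call(rbind, truth_rows),
                params = list(drug = drug, doses = doses, ld50 = ld50,
                              hill = hill, floor = floor, ceiling = ceiling,
                              mgc_true = mgc_true, gi50 = gi50, k = k,
                              n0 = n0, seed = seed))
  list(images = images, layout = layout, truth = truth)
}

#' Write a simulated plate to disk
#'
#' TIFF images under the package naming convention, the layout as
#' `layout.csv` and the truth as `truth.json`.
#'
#' @param plate result of [simulate_plate()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulated_plate <- function(plate, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(plate$images)) {
    img <- plate$images[[id]]
    for (ch in names(img$channels)) {
      write_intensity_tiff(img$channels[[ch]],
                           file.path(out_dir, sprintf("%s_%s.tif", id, ch)))
    }
  }
  lay <- plate$layout
  lay$timepoints <- vapply(lay$timepoints, paste, character(1L), collapse = ";")
  utils::write.csv(lay, file.path(out_dir, "layout.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(plate$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate an allele-specific copy-number segment table with planted LOH
#'
#' Builds a heterozygous background at the requested ploidy and plants
#' tagged LOH regions: `loss_loh` (counts toward the HRD score when longer
#' than 10 Mb), `copy_neutral_loh` (LOH at background total copy number,
#' excluded by the modified score), `whole_chromosome_loh` (spans the
#' chromosome, excluded) and `short_loh` (a loss-LOH below the length
#' cutoff). Small uniform jitter (+-0.05) is added to copy numbers.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param ploidy_class `"2n"` or `"3n-4n"`.
#' @param planted data.frame `chrom, start, end, tag`; regions must not
#'   overlap. For `whole_chromosome_loh` the start/end are ignored and the
#'   full chromosome is used.
#' @param seed RNG seed for the jitter.
#' @return list with `segments` (validated table) and `true_score` (count
#'   of planted regions the modified HRD rule should score).
#' @export
simulate_segments <- function(chrom_sizes, ploidy_class = "2n",
                              planted = NULL, seed = 1L) {
  tags <- c("loss_loh", "copy_neutral_loh", "whole_chromosome_loh",
            "short_loh")
  base <- if (ploidy_class == "2n") list(tcn = 2, a = 1, b = 1)
          else list(tcn = 4, a = 2, b = 2)
  loss_tcn <- if (ploidy_class == "2n") 1 else 2
  if (is.null(planted))
    planted <- data.frame(chrom = character(0L), start = numeric(0L),
                          end = numeric(0L), tag = character(0L))
  stopifnot(all(planted$tag %in% tags), all(planted$chrom %in% names(chrom_sizes)))
  with_seed(seed, {
    rows <- list()
    emit <- function(chrom, start, end, tcn, a, b) {
      j <- stats::runif(1L, -0.05, 0.05)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end, tcn = tcn + j,
        cn_a = a + j / 2, cn_b = max(b + j / 2, 0), stringsAsFactors = FALSE)
    }
    for (ch in names(chrom_sizes)) {
      size <- chrom_sizes[[ch]]
      pl <- planted[planted$chrom == ch, , drop = FALSE]
      whole <- pl$tag == "whole_chromosome_loh"
      if (any(whole)) {
        if (nrow(pl) > 1L) stop("whole_chromosome_loh cannot share a chromosome")
        emit(ch, 0, size, loss_tcn, loss_tcn, 0)
        next
      }
      pl <- pl[order(pl$start), , drop = FALSE]
      if (nrow(pl) > 1L && any(pl$start[-1L] < pl$end[-nrow(pl)]))
        stop("planted regions overlap on chromosome ", ch)
      if (any(pl$end > size)) stop("planted region exceeds chromosome ", ch)
      cursor <- 0
      for (i in seq_len(nrow(pl))) {
        if (pl$start[i] > cursor)
          emit(ch, cursor, pl$start[i], base$tcn, base$a, base$b)
        tcn <- switch(pl$tag[i],
                      loss_loh = loss_tcn, short_loh = loss_tcn,
                      copy_neutral_loh = base$tcn)
        emit(ch, pl$start[i], pl$end[i], tcn, tcn, 0)
        cursor <- pl$end[i]
      }
      if (cursor < size) emit(ch, cursor, size, base$tcn, base$a, base$b)
    }
    segments <- validate_segments(do.call(rbind, rows))
    scoreable <- planted$tag %in% c("loss_loh", "short_loh") &
      (planted$end - planted$start) > 1e7 &
      !(planted$chrom %in% c("X", "Y", "chrX", "chrY"))
    list(segments = segments, true_score = sum(scoreable))
  })
}

#' Simulate a drug-screen cohort with planted HRD associations
#'
#' Per cell line an HRD score; per drug a planted linear effect of the
#' score on the metric: `metric = intercept + slope * score + N(0, sigma)`.
#' Slopes of 0 give a planted-null cohort for FDR calibration.
#'
#' @param scores named numeric vector of HRD scores (names = cell lines).
#' @param slopes_aucd,slopes_aucpi named numeric vectors (names = drugs) of
#'   planted slopes per metric.
#' @param sigma noise sd.
#' @param intercept baseline metric value.
#' @param culture,timepoint constants stamped on the metrics rows.
#' @param seed RNG seed.
#' @return list with `hrd_scores`, `metrics` (data.frame in the metrics
#'   schema subset used by [associate_hrd()]) and `truth` (the planted
#'   slopes).
#' @export
simulate_cohort <- function(scores, slopes_aucd, slopes_aucpi = NULL,
                            sigma = 0.05, intercept = 0.2, culture = "3D",
                            timepoint = 72, seed = 1L) {
  stopifnot(!is.null(names(scores)), length(scores) >= 4L,
            !is.null(names(slopes_aucd)))
  if (is.null(slopes_aucpi))
    slopes_aucpi <- stats::setNames(rep(0, length(slopes_aucd)),
                                    names(slopes_aucd))
  with_seed(seed, {
    grid <- expand.grid(cell_line = names(scores), drug = names(slopes_aucd),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    metrics <- data.frame(
      cell_line = grid$cell_line, culture = culture, drug = grid$drug,
      timepoint_h = timepoint,
      aucd = intercept + slopes_aucd[grid$drug] * scores[grid$cell_line] +
        stats::rnorm(n, 0, sigma),
      aucpi = intercept + slopes_aucpi[grid$drug] * scores[grid$cell_line] +
        stats::rnorm(n, 0, sigma),
      stringsAsFactors = FALSE)
    rownames(metrics) <- NULL
    list(hrd_scores = scores, metrics = metrics,
         truth = list(slopes_aucd = slopes_aucd,
                      slopes_aucpi = slopes_aucpi, sigma = sigma,
                      intercept = intercept))
  })
}
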