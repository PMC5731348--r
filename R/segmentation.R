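#' Segmentation parameters
#'
#' Tunable parameters of the control-calibrated sequential local-mean
#' thresholding pipeline. Intensities are on the package's 0-255 working
#' scale; radii are in pixels.
#'
#' @param initial_radius starting window radius used to segment control
#'   images when calibrating the large-structure radius.
#' @param small_radius radius of the second, fine Hoechst pass that recovers
#'   small low-contrast live nuclei (about one nucleus diameter at
#'   2.767 um/pixel).
#' @param offset_hoechst,offset_pi,offset_tracker additive offsets `c` of the
#'   local-mean rule `pixel > local_mean + c`. The Hoechst/PI defaults sit
#'   just above the background noise floor so flat background is not marked
#'   foreground; the tracker offset is negative (generous) because the
#'   fibroblast mask is used for exclusion.
#' @param min_object_area connected components smaller than this many pixels
#'   are removed as sub-nuclear debris (~150 um^2 at default resolution).
#' @param median_radius radius of the median pre-smoothing (see
#'   [median_smooth()]).
#' @param outlier_mad_factor images whose global Hoechst median deviates from
#'   the control median by more than this many MADs are re-thresholded.
#' @param adapted_offset_scale multiplier applied to the offsets when
#'   re-thresholding flagged images (< 1 means more sensitive).
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(initial_radius = 10, small_radius = 5,
                       offset_hoechst = 5, offset_pi = 5, offset_tracker = -2,
                       min_object_area = 20, median_radius = 0.5,
                       outlier_mad_factor = 3, adapted_offset_scale = 0.5) {
  if (initial_radius < 1 || small_radius < 1) stop("radii must be >= 1")
  if (min_object_area < 0) stop("min_object_area must be >= 0")
  structure(list(initial_radius = initial_radius, small_radius = small_radius,
                 offset_hoechst = offset_hoechst, offset_pi = offset_pi,
                 offset_tracker = offset_tracker,
                 min_object_area = min_object_area,
                 median_radius = median_radius,
                 outlier_mad_factor = outlier_mad_factor,
                 adapted_offset_scale = adapted_offset_scale),
            class = "seg_params")
}

# Reflect-pad a matrix by r on every side (symmetric padding, edge pixel
# duplicated: [b a | a b c ... y z | z y]). Requires r <= dim.
pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  if (r > n || r > p) stop("reflection radius exceeds image size")
  ri <- c(rev(seq_len(r)), seq_len(n), n:(n - r + 1L))
  ci <- c(rev(seq_len(r)), seq_len(p), p:(p - r + 1L))
  m[ri, ci, drop = FALSE]
}

# Pixel offsets of the discrete disk kernel of the given radius. Follows the
# source-platform convention (offsets with dx^2 + dy^2 <= r^2 + 1), under
# which the default radius 0.5 is the 5-pixel cross; radius < 0.5 is the
# identity kernel.
.disk_offsets <- function(radius) {
  if (radius < 0.5) return(cbind(dx = 0L, dy = 0L))
  rmax <- as.integer(ceiling(radius + 1))
  g <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  g <- g[g$dx^2 + g$dy^2 <= radius^2 + 1, , drop = FALSE]
  as.matrix(g)
}

#' Median smoothing with a disk-shaped kernel
#'
#' Replaces each pixel by the median of its disk neighbourhood, with
#' reflected borders. The disk of the default radius 0.5 is the 5-pixel
#' cross; radius 0 (any radius below 0.5) is the identity.
#'
#' @param img numeric matrix (one channel).
#' @param radius kernel radius in pixels (>= 0).
#' @return smoothed matrix of the same dimensions.
#' @export
median_smooth <- function(img, radius = 0.5) {
  if (radius < 0) stop("radius must be >= 0")
  off <- .disk_offsets(radius)
  k <- nrow(off)
  if (k == 1L) return(img)
  r <- max(abs(off))
  pad <- pad_reflect(img, r)
  n <- nrow(img); p <- ncol(img)
  # one shifted copy of the image per kernel offset
  layers <- vector("list", k)
  for (i in seq_len(k)) {
    layers[[i]] <- pad[(r + 1L + off[i, "dx"]):(r + n + off[i, "dx"]),
                       (r + 1L + off[i, "dy"]):(r + p + off[i, "dy"]),
                       drop = FALSE]
  }
  # odd-even transposition sort across the k layers, then take the middle
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    idx <- seq.int(start, k - 1L, by = 2L)
    for (i in idx) {
      lo <- pmin(layers[[i]], layers[[i + 1L]])
      hi <- pmax(layers[[i]], layers[[i + 1L]])
      layers[[i]] <- lo; layers[[i + 1L]] <- hi
    }
  }
  if (k %% 2L == 1L) layers[[(k + 1L) %/% 2L]]
  else (layers[[k %/% 2L]] + layers[[k %/% 2L + 1L]]) / 2
}

# Local mean over the square window of side 2*radius+1 with reflected
# borders, computed with a summed-area table.
local_mean <- function(img, radius) {
  r <- as.integer(radius)
  if (r < 1L) stop("radius must be >= 1")
  pad <- pad_reflect(img, r)
  S <- rbind(0, apply(pad, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  n <- nrow(img); p <- ncol(img); w <- 2L * r + 1L
  sums <- S[(w + 1L):(w + n), (w + 1L):(w + p), drop = FALSE] -
    S[1L:n, (w + 1L):(w + p), drop = FALSE] -
    S[(w + 1L):(w + n), 1L:p, drop = FALSE] +
    S[1L:n, 1L:p, drop = FALSE]
  sums / (w * w)
}

#' Local-mean thresholding
#'
#' Marks a pixel foreground when its intensity strictly exceeds the mean of
#' the surrounding square window (side `2*radius + 1`, reflected borders)
#' plus an additive offset `c`:
#' `mask(p) = image(p) > local_mean(p, radius) + offset`.
#'
#' @param img numeric matrix (one channel).
#' @param radius window radius in pixels (>= 1).
#' @param offset additive intensity offset `c`.
#' @return logical matrix of the same dimensions.
#' @export
local_mean_threshold <- function(img, radius, offset = 0) {
  img > local_mean(img, radius) + offset
}

# Connected-component labelling (4-connected) via EBImage.
.label <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

#' Calibrate the large-structure radius from control images
#'
#' Segments the Hoechst channel of untreated-control images with the
#' current radius, finds the largest connected component across all
#' controls, and takes the radius of its equivalent circle (rounded up),
#' bounded to `[initial_radius, image_size / 2]`. Because a window smaller
#' than a structure only captures the parts of its interior that see
#' background, the estimate is refined iteratively (re-thresholding with
#' the updated radius) until it is stable, so the largest organoids are
#' eventually captured whole. The result drives the coarse Hoechst pass.
#'
#' @param control_images list of numeric matrices (Hoechst channel of
#'   control images).
#' @param params [seg_params()].
#' @param max_iter refinement iterations (the estimate usually stabilises
#'   in 2-3).
#' @return list with `radius` (pixels) and `fallback` (`TRUE` when no
#'   foreground was found in any control and the initial radius was kept).
#' @export
estimate_control_radius <- function(control_images, params = seg_params(),
                                    max_iter = 5L) {
  if (length(control_images) < 1L) stop("need at least one control image")
  dims <- dim(control_images[[1L]])
  r_cap <- floor(min(dims) / 2)
  smoothed <- lapply(control_images, median_smooth, radius = params$median_radius)
  pass_area <- function(radius) {
    max_area <- 0
    for (sm in smoothed) {
      mask <- local_mean_threshold(sm, radius, params$offset_hoechst)
      if (!any(mask)) next
      lab <- .label(mask)
      max_area <- max(max_area, max(tabulate(lab[lab > 0L])))
    }
    max_area
  }
  r <- params$initial_radius
  for (it in seq_len(max_iter)) {
    max_area <- pass_area(r)
    if (max_area == 0) {
      if (it > 1L) break  # earlier pass found foreground; keep current r
      warning("no foreground in any control image; falling back to initial_radius")
      return(list(radius = params$initial_radius, fallback = TRUE))
    }
    r_new <- min(max(ceiling(sqrt(max_area / pi)), params$initial_radius), r_cap)
    if (r_new == r) break
    r <- r_new
  }
  list(radius = r, fallback = FALSE)
}

#' Two-pass Hoechst segmentation
#'
#' Union of a coarse local-mean threshold (control-derived large radius,
#' detects big structures such as organoids) and a fine pass (small radius,
#' recovers small low-contrast live nuclei the coarse pass misses).
#'
#' @param img Hoechst channel matrix (already smoothed).
#' @param large_radius control-derived radius (see
#'   [estimate_control_radius()]).
#' @param small_radius fine-pass radius.
#' @param offset additive threshold offset for both passes.
#' @return logical mask.
#' @export
segment_hoechst <- function(img, large_radius, small_radius, offset = 5) {
  local_mean_threshold(img, large_radius, offset) |
    local_mean_threshold(img, small_radius, offset)
}

#' Single-pass PI segmentation
#'
#' The PI channel stains only dead cells, so one local-mean threshold pass
#' suffices.
#'
#' @param img PI channel matrix (already smoothed).
#' @param radius window radius.
#' @param offset additive threshold offset.
#' @return logical mask.
#' @export
segment_pi <- function(img, radius, offset = 5) {
  local_mean_threshold(img, radius, offset)
}

#' Combine channel masks and remove artefacts
#'
#' `mask_total = (hoechst | pi)` minus fibroblast pixels, with 4-connected
#' components smaller than `min_object_area` removed; `mask_dead` is the PI
#' mask restricted to `mask_total`, so `mask_dead` is always a subset of
#' `mask_total`.
#'
#' @param h_mask,pi_mask logical masks of the same dimensions.
#' @param min_object_area components with fewer pixels are dropped.
#' @param fibroblast_mask optional logical mask of fibroblast (tracker)
#'   signal to exclude in co-culture screens.
#' @return list with `mask_total` and `mask_dead`.
#' @export
combine_and_clean <- function(h_mask, pi_mask, min_object_area = 20,
                              fibroblast_mask = NULL) {
  stopifnot(identical(dim(h_mask), dim(pi_mask)))
  total <- h_mask | pi_mask
  if (!is.null(fibroblast_mask)) {
    stopifnot(identical(dim(fibroblast_mask), dim(total)))
    total <- total & !fibroblast_mask
  }
  if (min_object_area > 0 && any(total)) {
    lab <- .label(total)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_area)
    total <- matrix(lab %in% keep & lab > 0L, nrow(total), ncol(total))
  }
  list(mask_total = total, mask_dead = pi_mask & total)
}

#' Flag images with global intensity shifts
#'
#' High drug concentrations can shift whole-image Hoechst intensities; such
#' images are flagged as outliers against the plate's control baseline and
#' later re-thresholded with adapted sensitivity. An image is flagged when
#' its global median deviates from the median of the control-image medians
#' by more than `factor` times their MAD.
#'
#' @param medians numeric vector of per-image global Hoechst medians.
#' @param is_control logical vector marking the control images.
#' @param factor MAD multiplier (default 3).
#' @return logical vector of flags; when fewer than 3 controls are available
#'   outlier detection is disabled with a warning and no image is flagged
#'   (attribute `disabled` set to `TRUE`).
#' @export
detect_intensity_outliers <- function(medians, is_control, factor = 3) {
  stopifnot(length(medians) == length(is_control))
  if (sum(is_control) < 3L) {
    warning("fewer than 3 control images; intensity-outlier detection disabled")
    flags <- rep(FALSE, length(medians))
    attr(flags, "disabled") <- TRUE
    return(flags)
  }
  ctrl <- medians[is_control]
  base <- stats::median(ctrl)
  spread <- stats::mad(ctrl)
  flags <- abs(medians - base) > factor * spread
  attr(flags, "disabled") <- FALSE
  flags
}

#' Segment one annotated MIP into total/dead masks
#'
#' Applies median smoothing, the two-pass Hoechst threshold, the single-pass
#' PI threshold (at the control-derived large radius), optional fibroblast
#' exclusion from a tracker channel (radius 35, c = -2 defaults), and
#' small-object removal.
#'
#' @param mip a [mip_image()] with `hoechst` and `pi` channels (optionally
#'   `tracker`).
#' @param large_radius control-derived radius.
#' @param params [seg_params()].
#' @param offset_scale multiplier on the Hoechst/PI offsets (used for the
#'   adapted re-thresholding of intensity outliers).
#' @return list with `mask_total` and `mask_dead`.
#' @export
segment_well <- function(mip, large_radius, params = seg_params(),
                         offset_scale = 1) {
  h <- median_smooth(mip$channels$hoechst, params$median_radius)
  p <- median_smooth(mip$channels$pi, params$median_radius)
  h_mask <- segment_hoechst(h, large_radius, params$small_radius,
                            params$offset_hoechst * offset_scale)
  pi_mask <- segment_pi(p, large_radius, params$offset_pi * offset_scale)
  fib <- NULL
  if (!is.null(mip$channels$tracker)) {
    tr <- median_smooth(mip$channels$tracker, params$median_radius)
    fib <- local_mean_threshold(tr, 35, params$offset_tracker)
  }
  combine_and_clean(h_mask, pi_mask, params$min_object_area, fib)
}

#' Measure mask areas into an area record
#'
#' @param masks list with `mask_total`, `mask_dead` (from
#'   [combine_and_clean()] / [segment_well()]).
#' @param annotation one annotated image row (see [annotate_mips()]).
#' @param extra_flags additional qc flags to attach (character vector).
#' @return one-row area-table data.frame; an all-empty total mask is flagged
#'   `empty`.
#' @export
measure_areas <- function(masks, annotation, extra_flags = character(0L)) {
  area_total <- sum(masks$mask_total)
  area_pi <- sum(masks$mask_dead)
  flags <- extra_flags
  if (area_total == 0L) flags <- c(flags, "empty")
  data.frame(
    plate = annotation$plate, well = annotation$well,
    position = annotation$position, cell_line = annotation$cell_line,
    culture = annotation$culture, drug = annotation$drug,
    concentration = annotation$concentration, unit = annotation$unit,
    role = annotation$role, timepoint_h = annotation$timepoint,
    area_pi = area_pi, area_total = area_total,
    qc_flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Segment a whole annotated plate into an area table
#'
#' Driver over all images of one (or more) plates: calibrates the large
#' radius from untreated-control images, flags intensity outliers against
#' the control baseline, segments every image (outliers with offsets scaled
#' by `adapted_offset_scale` and flagged `outlier_intensity;rethresholded`),
#' and measures areas.
#'
#' @param images named list of `mip_image` objects ([load_mip_dir()]).
#' @param layout validated plate layout.
#' @param params [seg_params()].
#' @return area-table data.frame (one row per matched image).
#' @export
segment_plate <- function(images, layout, params = seg_params()) {
  ann <- annotate_mips(images, layout)$annotated
  if (nrow(ann) == 0L) stop("no images matched the layout")
  rows <- list()
  for (pl in unique(ann$plate)) {
    sub <- ann[ann$plate == pl, , drop = FALSE]
    is_ctrl <- sub$role != "treated"
    ctrl_imgs <- lapply(sub$image_id[sub$role == "untreated_control"],
                        function(id) images[[id]]$channels$hoechst)
    if (length(ctrl_imgs) == 0L)
      ctrl_imgs <- lapply(sub$image_id[is_ctrl],
                          function(id) images[[id]]$channels$hoechst)
    cal <- estimate_control_radius(ctrl_imgs, params)
    meds <- vapply(sub$image_id,
                   function(id) stats::median(images[[id]]$channels$hoechst),
                   numeric(1L))
    flags <- detect_intensity_outliers(meds, is_ctrl, params$outlier_mad_factor)
    for (i in seq_len(nrow(sub))) {
      scale <- if (flags[i]) params$adapted_offset_scale else 1
      masks <- segment_well(images[[sub$image_id[i]]], cal$radius, params,
                            offset_scale = scale)
      extra <- if (flags[i]) c("outlier_intensity", "rethresholded")
               else character(0L)
      rows[[length(rows) + 1L]] <- measure_areas(masks, sub[i, ], extra)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_area_table(out)
  out
}
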