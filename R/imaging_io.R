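#' Multi-channel confocal image stack
#'
#' Container for one imaging position: a 3D intensity grid
#' (slices x rows x cols) per named channel. At least the `hoechst` (all
#' nuclei) and `pi` (dead nuclei) channels must be present; an optional
#' `tracker` channel carries a cytoplasmic fibroblast stain in co-culture
#' screens.
#'
#' @param channels named list of 3D numeric arrays (slices x rows x cols),
#'   all with identical dimensions and nonnegative intensities.
#' @param pixel_size lateral resolution in micrometres per pixel (> 0).
#' @param slice_spacing axial slice distance in micrometres.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size = 2.767, slice_spacing = 50) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (!all(c("hoechst", "pi") %in% names(channels)))
    stop("image_stack requires at least 'hoechst' and 'pi' channels")
  dims <- lapply(channels, dim)
  for (d in dims) {
    if (length(d) != 3L) stop("each channel must be a 3D array (slices x rows x cols)")
    if (!identical(d, dims[[1L]])) stop("all channels must share dimensions")
  }
  if (dims[[1L]][1L] < 1L) stop("no slices")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1L))))
    stop("intensities must be nonnegative")
  structure(list(channels = channels, pixel_size = pixel_size,
                 slice_spacing = slice_spacing),
            class = "image_stack")
}

#' Two-dimensional maximum-intensity projection
#'
#' @param channels named list of 2D numeric matrices sharing dimensions.
#' @param pixel_size micrometres per pixel.
#' @param provenance identifier of the source stack (free text).
#' @return an object of class `mip_image`.
#' @export
mip_image <- function(channels, pixel_size = 2.767, provenance = NA_character_) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  dims <- lapply(channels, dim)
  for (d in dims) {
    if (length(d) != 2L) stop("each channel must be a 2D matrix")
    if (!identical(d, dims[[1L]])) stop("all channels must share dimensions")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "mip_image")
}

#' Maximum-intensity projection of an image stack
#'
#' Collapses each channel of a confocal stack to a single 2D image by taking
#' the per-pixel maximum over slices.
#'
#' @param stack an [image_stack()].
#' @return a [mip_image()] with identical row/col dimensions.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "image_stack")) stop("expected an image_stack")
  if (dim(stack$channels[[1L]])[1L] < 1L) stop("no slices")
  proj <- lapply(stack$channels, function(ch) {
    apply(ch, c(2L, 3L), max)
  })
  mip_image(proj, pixel_size = stack$pixel_size,
            provenance = attr(stack, "id") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- file naming convention ------------------------------------------------

#' Parse an image file name into its plate/well/position/timepoint/channel key
#'
#' The package's naming convention is
#' `{plate}_{well}_{position}_{timepoint}h_{channel}.tif`, e.g.
#' `plate1_B03_p1_72h_hoechst.tif`. Position tokens are `p` followed by an
#' integer; timepoints are integer hours.
#'
#' @param filename file name (directories and case-insensitive `.tif`/`.tiff`
#'   extension are tolerated).
#' @return a list with elements `plate`, `well`, `position`, `timepoint`
#'   (numeric hours) and `channel`, or `NULL` when the name does not match.
#' @export
parse_image_filename <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base, regexec(
    "^(.+)_([A-Pa-p][0-9]{1,2})_(p[0-9]+)_([0-9]+)h_([A-Za-z]+)\\.[Tt][Ii][Ff]{1,2}$",
    base))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(plate = m[2L], well = m[3L], position = m[4L],
       timepoint = as.numeric(m[5L]), channel = tolower(m[6L]))
}

# --- TIFF IO ---------------------------------------------------------------

# Intensities are stored on an 8-bit-like scale (0..255). TIFFs are written
# as 32-bit float samples scaled to [0,1] so fractional intensities survive
# the round trip.
.TIFF_SCALE <- 255

#' Read a TIFF file as an intensity matrix or stack
#'
#' A multi-page TIFF is treated as the slices of one channel (3D array,
#' slices x rows x cols); a single page yields a 2D matrix. Intensities are
#' rescaled to the package's 0-255 working scale.
#'
#' @param path TIFF file path.
#' @return numeric matrix (single page) or 3D array (multi page).
#' @export
read_intensity_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    p * .TIFF_SCALE
  })
  if (length(pages) == 1L) return(pages[[1L]])
  arr <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Write an intensity matrix or stack to a TIFF file
#'
#' @param img 2D matrix or 3D array (slices x rows x cols) on the 0-255
#'   working scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(img, path) {
  clip01 <- function(m) pmin(pmax(m / .TIFF_SCALE, 0), 1)
  if (length(dim(img)) == 3L) {
    pages <- lapply(seq_len(dim(img)[1L]), function(i) clip01(img[i, , ]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(clip01(img), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Load a directory of MIP TIFFs into annotated-ready images
#'
#' File names must follow the package convention (see
#' [parse_image_filename()]); the channel pages of one
#' plate/well/position/timepoint are assembled into a single [mip_image()].
#'
#' @param dir directory containing `.tif` files.
#' @param pixel_size micrometres per pixel recorded on each image.
#' @return named list of `mip_image` objects; names are
#'   `plate_well_position_timepointh` keys. Each image carries its parsed key
#'   as attributes `plate`, `well`, `position`, `timepoint`.
#' @export
load_mip_dir <- function(dir, pixel_size = 2.767) {
  files <- list.files(dir, pattern = "\\.[Tt][Ii][Ff]{1,2}$", full.names = TRUE)
  keys <- lapply(files, parse_image_filename)
  ok <- !vapply(keys, is.null, logical(1L))
  if (any(!ok))
    warning(sprintf("%d file(s) did not match the naming convention and were skipped",
                    sum(!ok)))
  files <- files[ok]; keys <- keys[ok]
  if (length(files) == 0L) return(list())
  id <- vapply(keys, function(k)
    sprintf("%s_%s_%s_%gh", k$plate, k$well, k$position, k$timepoint), character(1L))
  out <- list()
  for (g in unique(id)) {
    sel <- which(id == g)
    chans <- list()
    for (i in sel) chans[[keys[[i]]$channel]] <- read_intensity_tiff(files[i])
    img <- mip_image(chans, pixel_size = pixel_size, provenance = g)
    k <- keys[[sel[1L]]]
    attr(img, "plate") <- k$plate; attr(img, "well") <- k$well
    attr(img, "position") <- k$position; attr(img, "timepoint") <- k$timepoint
    out[[g]] <- img
  }
  out
}

# --- plate layout ----------------------------------------------------------

.LAYOUT_COLS <- c("plate", "well", "position", "cell_line", "culture",
                  "drug", "concentration", "unit", "role", "timepoints")
.ROLES <- c("treated", "untreated_control", "solvent_control")

#' Validate a plate-layout table
#'
#' Checks the layout invariants: unique (plate, well, position) keys, known
#' roles and culture types, at least one control per plate, and (warning
#' only) that each drug's treated concentrations form a 1:3 geometric
#' dilution series.
#'
#' @param layout data.frame with the layout columns (see
#'   [read_plate_layout()]).
#' @return the layout, invisibly; errors on violated invariants.
#' @export
validate_plate_layout <- function(layout) {
  missing_cols <- setdiff(.LAYOUT_COLS, names(layout))
  if (length(missing_cols) > 0L)
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(layout$plate, layout$well, layout$position, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (plate, well, position) keys in layout: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(layout$role %in% .ROLES))
    stop("unknown role(s): ", paste(setdiff(layout$role, .ROLES), collapse = ", "))
  if (!all(layout$culture %in% c("2D", "3D")))
    stop("culture must be '2D' or '3D'")
  for (p in unique(layout$plate)) {
    sub <- layout[layout$plate == p, ]
    if (!any(sub$role != "treated"))
      stop(sprintf("plate '%s' has no control wells", p))
  }
  tr <- layout[layout$role == "treated" & !is.na(layout$concentration), ]
  for (d in unique(tr$drug)) {
    conc <- sort(unique(tr$concentration[tr$drug == d]))
    if (length(conc) >= 2L) {
      ratios <- conc[-1L] / conc[-length(conc)]
      if (any(abs(ratios - 3) > 0.15 * 3))
        warning(sprintf("drug '%s': concentrations deviate from a 1:3 dilution series", d))
    }
  }
  invisible(layout)
}

#' Read a plate-layout CSV
#'
#' Expected header:
#' `plate,well,position,cell_line,culture,drug,concentration,unit,role,timepoints`
#' where `timepoints` lists the imaging hours separated by `;` (e.g.
#' `0;72;144`). Control rows may leave `drug`/`concentration` empty.
#'
#' @param path CSV file path.
#' @return validated layout data.frame; `concentration` numeric, `timepoints`
#'   a list-column of numeric hour vectors.
#' @export
read_plate_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.LAYOUT_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  df$concentration <- suppressWarnings(as.numeric(df$concentration))
  df$timepoints <- lapply(strsplit(df$timepoints, ";", fixed = TRUE),
                          function(x) as.numeric(x))
  validate_plate_layout(df)
  df
}

#' Join MIP images to their plate-layout rows
#'
#' Each image (keyed by plate/well/position parsed from its file name) is
#' matched to exactly one layout row; unmatched images are reported in the
#' result rather than silently dropped.
#'
#' @param images named list of `mip_image` objects as produced by
#'   [load_mip_dir()] (each carrying `plate`, `well`, `position`, `timepoint`
#'   attributes).
#' @param layout validated plate layout.
#' @return list with `annotated` (data.frame of image key + layout columns +
#'   `image_id` into `images`) and `unmatched` (character vector of image
#'   ids with no layout row).
#' @export
annotate_mips <- function(images, layout) {
  validate_plate_layout(layout)
  lkey <- paste(layout$plate, layout$well, layout$position, sep = "|")
  rows <- list(); unmatched <- character(0L)
  for (id in names(images)) {
    img <- images[[id]]
    ikey <- paste(attr(img, "plate"), attr(img, "well"), attr(img, "position"),
                  sep = "|")
    hit <- which(lkey == ikey)
    if (length(hit) == 0L) {
      unmatched <- c(unmatched, id)
      next
    }
    lr <- layout[hit, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, plate = lr$plate, well = lr$well, position = lr$position,
      cell_line = lr$cell_line, culture = lr$culture, drug = lr$drug,
      concentration = lr$concentration, unit = lr$unit, role = lr$role,
      timepoint = attr(img, "timepoint"), stringsAsFactors = FALSE)
  }
  if (length(unmatched) > 0L)
    warning(sprintf("%d image(s) without a layout row: %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  annotated <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(image_id = character(0L))
  list(annotated = annotated, unmatched = unmatched)
}

# --- area tables -----------------------------------------------------------

.AREA_COLS <- c("plate", "well", "position", "cell_line", "culture", "drug",
                "concentration", "unit", "role", "timepoint_h", "area_pi",
                "area_total", "qc_flags")
.QC_FLAGS <- c("outlier_intensity", "rethresholded", "empty")

#' Validate an area table
#'
#' @param records data.frame in the area-table schema.
#' @return the records, invisibly; errors on violated invariants
#'   (`0 <= area_pi <= area_total`, unknown qc flags, bad columns).
#' @export
validate_area_table <- function(records) {
  missing_cols <- setdiff(.AREA_COLS, names(records))
  if (length(missing_cols) > 0L)
    stop("area table is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(records$area_pi < 0 | records$area_total < records$area_pi)
  if (length(bad) > 0L)
    stop("area invariant 0 <= area_pi <= area_total violated at row(s) ",
         paste(bad, collapse = ", "))
  flags <- unlist(strsplit(records$qc_flags[nzchar(records$qc_flags)], ";",
                           fixed = TRUE))
  if (length(flags) > 0L && !all(flags %in% .QC_FLAGS))
    stop("unknown qc flag(s): ", paste(setdiff(flags, .QC_FLAGS), collapse = ", "))
  invisible(records)
}

#' Write / read the per-image area table
#'
#' The area table is the assay's atomic observation record: one row per
#' plate/well/position/timepoint with the dead-cell (PI) and all-cell
#' (Hoechst + PI) mask areas in pixels and semicolon-separated qc flags.
#' `read_area_table(write_area_table(x)) == x`.
#'
#' @param records area-table data.frame.
#' @param path CSV file path.
#' @return `write_area_table`: `path` invisibly. `read_area_table`: the
#'   validated data.frame (errors name the offending line on malformed rows).
#' @export
write_area_table <- function(records, path) {
  validate_area_table(records)
  utils::write.csv(records[, .AREA_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_area_table
#' @export
read_area_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(qc_flags = "character")),
    error = function(e) stop("malformed area table: ", conditionMessage(e)))
  missing_cols <- setdiff(.AREA_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("area table header is missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (col in c("concentration", "timepoint_h", "area_pi", "area_total")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(as.character(df[[col]])))
    if (length(bad) > 0L)
      stop(sprintf("malformed value in column '%s' at line %d", col, bad[1L] + 1L))
    df[[col]] <- v
  }
  df$qc_flags[is.na(df$qc_flags)] <- ""
  bad <- which(df$area_pi < 0 | df$area_total < df$area_pi)
  if (length(bad) > 0L)
    stop(sprintf("area invariant violated at line %d (area_pi > area_total)",
                 bad[1L] + 1L))
  validate_area_table(df)
  df
}
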