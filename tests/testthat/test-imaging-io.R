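make_stack <- function(slices, n = 4, seed = 1) {
  set.seed(seed)
  mk <- function() {
    a <- array(runif(slices * n * n, 0, 100), dim = c(slices, n, n))
    a
  }
  image_stack(list(hoechst = mk(), pi = mk()))
}

test_that("maximum projection reduces stacks to per-pixel maxima", {
  s1 <- make_stack(1)
  m1 <- max_project(s1)
  expect_equal(m1$channels$hoechst, s1$channels$hoechst[1, , ])

  two <- image_stack(list(
    hoechst = array(c(3, 7), dim = c(2, 1, 1)),
    pi = array(c(1, 2), dim = c(2, 1, 1))))
  expect_equal(max_project(two)$channels$hoechst[1, 1], 7)

  s5 <- make_stack(5, n = 6, seed = 42)
  m5 <- max_project(s5)
  # loop-based per-pixel oracle
  for (ch in c("hoechst", "pi")) {
    expected <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      mx <- -Inf
      for (k in 1:5) mx <- max(mx, s5$channels[[ch]][k, i, j])
      expected[i, j] <- mx
    }
    expect_equal(m5$channels[[ch]], expected)
  }
})

test_that("degenerate stacks are rejected", {
  expect_error(image_stack(list(hoechst = array(0, c(0, 4, 4)),
                                pi = array(0, c(0, 4, 4)))), "no slices")
  expect_error(image_stack(list(hoechst = array(0, c(2, 4, 4)))), "channels")
  expect_error(image_stack(list(hoechst = array(0, c(2, 4, 4)),
                                pi = array(0, c(2, 4, 5)))), "dimensions")
})

test_that("file names parse under the naming convention", {
  k <- parse_image_filename("plate1_B03_p2_72h_hoechst.tif")
  expect_equal(k$plate, "plate1")
  expect_equal(k$well, "B03")
  expect_equal(k$position, "p2")
  expect_equal(k$timepoint, 72)
  expect_equal(k$channel, "hoechst")
  expect_null(parse_image_filename("not_a_match.tif"))
  expect_null(parse_image_filename("plate1_B03_p2_hoechst.tif"))
})

make_layout <- function() {
  data.frame(plate = "p1", well = c("B01", "B02", "C01"),
             position = "p1", cell_line = "L1", culture = "3D",
             drug = c("d", "d", ""), concentration = c(1, 3, NA),
             unit = "uM", role = c("treated", "treated", "untreated_control"),
             timepoints = I(list(c(0, 72), c(0, 72), c(0, 72))),
             stringsAsFactors = FALSE)
}

test_that("layout invariants are enforced", {
  expect_silent(validate_plate_layout(make_layout()))
  dup <- make_layout(); dup$well[2] <- "B01"
  expect_error(validate_plate_layout(dup), "duplicate")
  noctrl <- make_layout()[1:2, ]
  expect_error(validate_plate_layout(noctrl), "control")
  badrole <- make_layout(); badrole$role[1] <- "mystery"
  expect_error(validate_plate_layout(badrole), "role")
  baddil <- make_layout(); baddil$concentration[2] <- 10
  expect_warning(validate_plate_layout(baddil), "dilution")
})

test_that("annotation matches every image or reports it", {
  layout <- make_layout()
  img <- function(well) {
    m <- mip_image(list(hoechst = matrix(1, 4, 4), pi = matrix(0, 4, 4)))
    attr(m, "plate") <- "p1"; attr(m, "well") <- well
    attr(m, "position") <- "p1"; attr(m, "timepoint") <- 72
    m
  }
  res <- annotate_mips(list(a = img("B01"), b = img("B02")), layout)
  expect_equal(nrow(res$annotated), 2L)
  expect_length(res$unmatched, 0L)

  expect_warning(
    res2 <- annotate_mips(list(a = img("B01"), b = img("Z99")), layout),
    "without a layout row")
  expect_equal(nrow(res2$annotated), 1L)
  expect_equal(res2$unmatched, "b")
  # total function on matched keys
  expect_equal(nrow(res2$annotated) + length(res2$unmatched), 2L)

  dup <- layout; dup$well[2] <- "B01"
  expect_error(annotate_mips(list(a = img("B01")), dup), "duplicate")
})

test_that("area tables round-trip bit-exactly including qc flags", {
  rec <- data.frame(plate = "p1", well = c("B01", "B02", "C01"),
                    position = "p1", cell_line = "L1", culture = "2D",
                    drug = c("d", "d", ""), concentration = c(1, 3, NA),
                    unit = "uM", role = c("treated", "treated",
                                          "untreated_control"),
                    timepoint_h = 72, area_pi = c(10L, 0L, 5L),
                    area_total = c(100L, 50L, 5L),
                    qc_flags = c("", "rethresholded;outlier_intensity", "empty"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_table(rec, path)
  back <- read_area_table(path)
  expect_equal(back, rec)

  empty <- rec[0, ]
  write_area_table(empty, path)
  expect_equal(nrow(read_area_table(path)), 0L)
})

test_that("corrupt area tables are rejected with a line reference", {
  rec <- data.frame(plate = "p1", well = "B01", position = "p1",
                    cell_line = "L1", culture = "2D", drug = "d",
                    concentration = 1, unit = "uM", role = "treated",
                    timepoint_h = 72, area_pi = 10, area_total = 100,
                    qc_flags = "", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_table(rec, path)
  txt <- readLines(path)
  txt[2] <- sub("10,100", "200,100", txt[2])
  writeLines(txt, path)
  expect_error(read_area_table(path), "line 2")

  bad <- rec; bad$area_pi <- 200
  expect_error(write_area_table(bad, path), "invariant")
})

test_that("intensity TIFFs round-trip for pages and stacks", {
  path <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(runif(64, 0, 255), 8, 8)
  write_intensity_tiff(m, path)
  expect_equal(read_intensity_tiff(path), m, tolerance = 1e-4)

  arr <- array(runif(3 * 8 * 8, 0, 255), dim = c(3, 8, 8))
  write_intensity_tiff(arr, path)
  expect_equal(read_intensity_tiff(path), arr, tolerance = 1e-4)
})

test_that("a simulated plate written to disk reloads and annotates", {
  dir <- withr::local_tempdir()
  pl <- simulate_plate(doses = c(1, 3, 9, 27), timepoints = c(0, 72),
                       spec = render_spec(size = 64L, radius_range = c(2, 3)),
                       n0 = 8L, seed = 5)
  write_simulated_plate(pl, dir)
  imgs <- load_mip_dir(dir)
  expect_equal(length(imgs), length(pl$images))
  layout <- read_plate_layout(file.path(dir, "layout.csv"))
  res <- annotate_mips(imgs, layout)
  expect_length(res$unmatched, 0L)
  expect_equal(nrow(res$annotated), length(imgs))
})
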