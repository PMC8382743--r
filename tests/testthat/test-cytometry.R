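test_that("well-separated nuclei are each detected once", {
  p <- scene_params(field_width = 800, field_height = 800, n_cells = 50,
                    noise_sd = 500, rng_seed = 10)
  sc <- generate_scene(p)
  lab <- detect_nuclei(sc$images$nuclear, segmentation_params())
  expect_identical(max(lab), 50L)
})

test_that("a blank image yields zero labels with a warning, not an error", {
  img <- channel_image(matrix(100, 64, 64), 1, "nuclear")
  expect_warning(lab <- detect_nuclei(
    img, segmentation_params(threshold_method = "fixed",
                             fixed_threshold = 500)),
    "empty")
  expect_identical(max(lab), 0L)
})

test_that("touching nuclei split by watershed only when requested", {
  img <- touching_pair_image(radius_px = 8, overlap_frac = 0.3)
  sp_on <- segmentation_params(split_touching = TRUE, max_nucleus_area = 600)
  sp_off <- segmentation_params(split_touching = FALSE,
                                max_nucleus_area = 600)
  expect_identical(max(detect_nuclei(img, sp_on)), 2L)
  expect_identical(max(detect_nuclei(img, sp_off)), 1L)
})

test_that("area filtering removes regions outside the allowed range", {
  img <- disk_image(list(c(20, 20), c(80, 80)), radius_px = 4)
  img$pixels[50, 50] <- 10000 # single hot pixel, area 1 um^2
  lab <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                                min_nucleus_area = 10))
  expect_identical(max(lab), 2L)
  lab2 <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0,
                                                 min_nucleus_area = 100,
                                                 max_nucleus_area = 200))
  expect_identical(max(lab2), 0L)
})

test_that("zero expansion returns the nucleus labels unchanged", {
  lab <- matrix(0L, 32, 32)
  lab[10:12, 10:12] <- 1L
  attr(lab, "pixel_size") <- 1
  out <- segment_cells(lab, segmentation_params(cell_expansion_radius = 0))
  expect_identical(out, lab)
})

test_that("expansion stays within the requested radius and keeps nuclei", {
  img <- disk_image(list(c(60, 60)), radius_px = 5, dim = c(120, 120))
  nuc <- detect_nuclei(img, segmentation_params(smoothing_sigma = 0))
  cell <- segment_cells(nuc, segmentation_params(cell_expansion_radius = 3))
  expect_true(all(cell[nuc > 0] == nuc[nuc > 0])) # nucleus retained
  # every added pixel lies within 3 um of some nucleus pixel
  added <- which(cell > 0 & nuc == 0)
  nucpx <- which(nuc > 0)
  nr <- nrow(nuc)
  rr <- function(i) (i - 1) %% nr
  cc <- function(i) (i - 1) %/% nr
  for (i in added) {
    dmin <- sqrt(min((rr(nucpx) - rr(i))^2 + (cc(nucpx) - cc(i))^2))
    expect_lte(dmin, 3)
  }
})

test_that("contested territory splits along the perpendicular bisector", {
  lab <- matrix(0L, 40, 60)
  lab[20, 21] <- 1L # single-pixel nuclei 10 px apart along x
  lab[20, 31] <- 2L
  attr(lab, "pixel_size") <- 1
  out <- segment_cells(lab, segmentation_params(cell_expansion_radius = 10))
  claimed <- which(out > 0)
  x0 <- (claimed - 1) %/% 40 # 0-based column
  # bisector at x = 25: strictly left -> 1, strictly right -> 2
  expect_true(all(out[claimed][x0 < 25] == 1L))
  expect_true(all(out[claimed][x0 > 25] == 2L))
})

test_that("expansion agrees with an exhaustive nearest-nucleus oracle", {
  withr::local_seed(5)
  for (case in 1:3) {
    nr <- 48; nc <- 64
    lab <- matrix(0L, nr, nc)
    for (k in 1:4) {
      r <- sample(5:(nr - 5), 1); c <- sample(5:(nc - 5), 1)
      lab[r + (-1:1), c + (-1:1)] <- k
    }
    attr(lab, "pixel_size") <- 1
    radius <- sample(4:9, 1)
    out <- segment_cells(lab,
                         segmentation_params(cell_expansion_radius = radius))
    fg <- which(lab > 0)
    fr <- (fg - 1) %% nr; fc <- (fg - 1) %/% nr; fl <- lab[fg]
    for (i in seq_len(nr * nc)) {
      r <- (i - 1) %% nr; c <- (i - 1) %/% nr
      d2 <- (fr - r)^2 + (fc - c)^2
      best <- min(d2)
      if (lab[i] > 0) {
        expect_identical(out[i], lab[i])
      } else if (best > radius^2) {
        expect_identical(out[i], 0L)
      } else if (sum(d2 == best & fl != fl[which.min(d2)]) == 0) {
        # nearest nucleus unique: labels must agree; ties may go either way
        expect_identical(out[i], fl[which.min(d2)])
      }
    }
  }
})

test_that("measurements convert pixels to physical units correctly", {
  lab <- matrix(0L, 40, 40)
  lab[21, 11] <- 1L # 0-based (x = 10, y = 20)
  attr(lab, "pixel_size") <- 2
  img <- channel_image(matrix(7, 40, 40), 2, "marker")
  tab <- measure_cells(lab, list(img))
  expect_equal(tab$x_um, 20)
  expect_equal(tab$y_um, 40)
  expect_equal(tab$area_um2, 4)
  expect_equal(tab$marker_mean, 7)
})

test_that("noiseless synthetic intensities are measured exactly", {
  p <- scene_params(field_width = 300, field_height = 300, n_cells = 8,
                    reporter_functions = list(gfp = function(x) 100 + 7 * x),
                    noise_sd = 0, rng_seed = 12)
  sc <- generate_scene(p)
  # hard-edged disks, no smoothing: the detected mask is the true disk
  lab <- detect_nuclei(sc$images$nuclear,
                       segmentation_params(smoothing_sigma = 0))
  tab <- measure_cells(lab, sc$images)
  idx <- match_cells(tab, sc$cells)
  expect_true(all(!is.na(idx)))
  expect_equal(tab$nuclear_mean[idx], sc$cells$nuclear_true,
               tolerance = 1e-12)
  # reporter true values are non-integer; rendering quantises to integers
  expect_equal(tab$gfp_mean[idx], sc$cells$gfp_true, tolerance = 1e-3)
})

test_that("zero labels give an empty table with intact metadata", {
  lab <- matrix(0L, 16, 16)
  attr(lab, "pixel_size") <- 1
  tab <- measure_cells(lab, list(channel_image(matrix(1, 16, 16), 1, "a")),
                       chamber_id = "ch1", condition = "ctrl")
  expect_identical(nrow(tab), 0L)
  expect_identical(attr(tab, "chamber_id"), "ch1")
  expect_identical(attr(tab, "condition"), "ctrl")
  expect_true("a_mean" %in% names(tab))
})

test_that("mismatched channel dimensions are rejected", {
  lab <- matrix(0L, 16, 16); lab[5, 5] <- 1L
  attr(lab, "pixel_size") <- 1
  expect_error(measure_cells(lab, list(channel_image(matrix(1, 8, 8), 1,
                                                     "a"))),
               "dimensions")
})

test_that("row count equals label count and expansion drops no label", {
  sc <- small_scene(n_cells = 25, noise_sd = 300, seed = 21)
  nuc <- detect_nuclei(sc$images$nuclear, segmentation_params())
  cell <- segment_cells(nuc, segmentation_params(cell_expansion_radius = 4))
  expect_setequal(unique(as.vector(cell[cell > 0])),
                  unique(as.vector(nuc[nuc > 0])))
  tab <- measure_cells(cell, sc$images)
  expect_identical(nrow(tab), as.integer(max(nuc)))
})

test_that("matched cells recover ground truth at realistic noise", {
  # recovery and intensity fidelity across seeds at SNR 5, spacing 2.5 r
  for (seed in c(31, 32)) {
    p <- scene_params(field_width = 700, field_height = 700, n_cells = 80,
                      nucleus_radius_mean = 5, nucleus_radius_sd = 0.5,
                      min_center_spacing = 12.5,
                      reporter_functions = list(gfp = function(x) 3000),
                      nuclear_intensity = 10000, background_level = 200,
                      noise_sd = 2000, rng_seed = seed)
    sc <- generate_scene(p)
    lab <- detect_nuclei(sc$images$nuclear, segmentation_params())
    tab <- measure_cells(lab, sc$images)
    idx <- match_cells(tab, sc$cells, tol_um = 2)
    tpr <- mean(!is.na(idx))
    spurious <- (nrow(tab) - sum(!is.na(idx))) / nrow(sc$cells)
    expect_gte(tpr, 0.95)
    expect_lte(spurious, 0.02)
    m <- !is.na(idx)
    tol <- 3 * 2000 / sqrt(tab$area_um2[idx[m]])
    expect_true(all(abs(tab$gfp_mean[idx[m]] - 3000) < tol + 1))
  }
})
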