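test_that("distance runs perpendicular from the opening edge", {
  tab <- tibble::tibble(x_um = c(350, 350, -20), y_um = c(10, 10, 5))
  left <- assign_distance(tab, opening_spec("left", 0))
  expect_equal(left$distance_um, c(350, 350, 0))
  expect_equal(left$outside_chamber, c(FALSE, FALSE, TRUE))

  right <- assign_distance(tab, opening_spec("right", 500))
  expect_equal(right$distance_um[1], 150)

  top <- assign_distance(tab, opening_spec("top", 0))
  expect_equal(top$distance_um, c(10, 10, 5))
})

test_that("channel normalisation is an exact per-cell ratio", {
  tab <- tibble::tibble(gfp_mean = c(10, 20, 30), nuclear_mean = c(10, 20, 30))
  expect_equal(normalize_channel(tab, "gfp", "nuclear")$gfp_over_nuclear,
               c(1, 1, 1))
  tab2 <- tab
  tab2$gfp_mean <- tab2$gfp_mean * 2
  expect_equal(normalize_channel(tab2, "gfp", "nuclear")$gfp_over_nuclear,
               c(2, 2, 2))

  tab3 <- tibble::tibble(gfp_mean = c(5, 5, 5), nuclear_mean = c(10, 0, 2))
  out <- normalize_channel(tab3, "gfp", "nuclear")
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_excluded"), 1L)

  tab4 <- tibble::tibble(gfp_mean = c(1, 2), nuclear_mean = c(0, 0))
  expect_error(normalize_channel(tab4, "gfp", "nuclear"), "zero")
})

test_that("normalised profiles recover the reporter shape up to a factor", {
  f <- function(x) 2000 + 4 * x
  p <- scene_params(field_width = 1200, field_height = 600, n_cells = 400,
                    reporter_functions = list(gfp = f), noise_sd = 100,
                    rng_seed = 14)
  sc <- generate_scene(p)
  lab <- detect_nuclei(sc$images$nuclear, segmentation_params())
  tab <- assign_distance(measure_cells(lab, sc$images),
                         opening_spec("left", 0))
  tab <- normalize_channel(tab, "gfp", "nuclear")
  prof <- moving_profile(tab, "gfp_over_nuclear", window_width = 200,
                         step = 50, min_cells = 10)
  ok <- !is.na(prof$median)
  ratio <- prof$median[ok] / (f(prof$center_um[ok]) / 10000)
  expect_lt(max(ratio) / min(ratio), 1.15) # constant factor across windows
})

test_that("moving windows summarise exactly what falls inside them", {
  # constant input: median equals the constant, IQR collapses
  tab <- tibble::tibble(distance_um = runif(200, 0, 500), v = 7)
  prof <- moving_profile(tab, "v", window_width = 100, step = 50,
                         min_cells = 5)
  ok <- !is.na(prof$median)
  expect_true(all(prof$median[ok] == 7))
  expect_true(all(prof$q75[ok] - prof$q25[ok] == 0))

  # oracle equivalence: brute-force per-window recomputation
  withr::local_seed(15)
  tab2 <- tibble::tibble(distance_um = runif(3000, 0, 2000),
                         v = rnorm(3000))
  prof2 <- moving_profile(tab2, "v", window_width = 150, step = 40,
                          min_cells = 10)
  for (i in sample(nrow(prof2), 20)) {
    ctr <- prof2$center_um[i]
    vals <- tab2$v[tab2$distance_um >= ctr - 75 & tab2$distance_um < ctr + 75]
    if (length(vals) < 10) {
      expect_true(is.na(prof2$median[i]))
    } else {
      expect_equal(prof2$median[i], median(vals))
      expect_equal(prof2$q25[i], unname(quantile(vals, 0.25)))
      expect_equal(prof2$q75[i], unname(quantile(vals, 0.75)))
    }
  }

  # values = distance on a dense uniform table: median tracks the centre
  tab3 <- tibble::tibble(distance_um = seq(0, 1000, by = 0.5))
  tab3$v <- tab3$distance_um
  prof3 <- moving_profile(tab3, "v", window_width = 100, step = 25,
                          min_cells = 20)
  mid <- !is.na(prof3$median) & prof3$center_um >= 50 &
    prof3$center_um <= 950
  expect_true(all(abs(prof3$median[mid] - prof3$center_um[mid]) < 25))

  # under-populated windows are flagged absent
  tab4 <- tibble::tibble(distance_um = c(rep(10, 30), 400), v = 1)
  prof4 <- moving_profile(tab4, "v", window_width = 50, step = 100,
                          min_cells = 10)
  expect_true(is.na(prof4$median[prof4$center_um == 400]))
  expect_identical(prof4$n[prof4$center_um == 400], 1L)

  # empty input gives an empty profile
  empty <- moving_profile(tibble::tibble(distance_um = double(),
                                         v = double()), "v")
  expect_identical(nrow(empty), 0L)
})

test_that("profiles are monotone for monotone noiseless input", {
  tab <- tibble::tibble(distance_um = runif(2000, 0, 1500))
  tab$v <- sqrt(tab$distance_um) + 2
  prof <- moving_profile(tab, "v", min_cells = 10)
  med <- prof$median[!is.na(prof$median)]
  expect_true(all(diff(med) >= 0))
})

test_that("half-max positions interpolate the 50% crossing", {
  prof <- tibble::tibble(center_um = c(100, 200, 300, 400, 500),
                         median = c(0, 0, 50, 100, 100))
  expect_equal(half_max_position(prof), 300)

  # min + 0.5 * (max - min) = 40, first reached exactly at the 200 um node
  prof2 <- tibble::tibble(center_um = c(100, 200, 300),
                          median = c(0, 40, 80))
  expect_equal(half_max_position(prof2), 200)

  # interpolation between nodes
  prof3 <- tibble::tibble(center_um = c(0, 100, 200),
                          median = c(0, 10, 100))
  expect_equal(half_max_position(prof3), 100 + 40 / 90 * 100)

  expect_error(half_max_position(tibble::tibble(center_um = 1:5 * 100,
                                                median = rep(3, 5))),
               class = "memic_flat_profile")
  expect_error(half_max_position(tibble::tibble(center_um = c(1, 2),
                                                median = c(1, 2))),
               "3 populated")
})

test_that("a sampled logistic profile returns its own midpoint", {
  x0 <- 837
  xs <- seq(0, 2000, by = 10)
  prof <- tibble::tibble(center_um = xs,
                         median = 1 / (1 + exp(-(xs - x0) / 60)))
  expect_lt(abs(half_max_position(prof) - x0), 10)
})

test_that("half-max is shift-equivariant and scale-invariant", {
  withr::local_seed(16)
  tab <- tibble::tibble(distance_um = runif(4000, 0, 2000))
  tab$v <- 100 + 900 / (1 + exp(-(tab$distance_um - 700) / 100)) +
    rnorm(4000, 0, 20)
  prof <- moving_profile(tab, "v")
  h <- half_max_position(prof)

  delta <- 250
  tab_shift <- dplyr::mutate(tab, distance_um = distance_um + delta)
  h_shift <- half_max_position(moving_profile(tab_shift, "v"))
  expect_equal(h_shift, h + delta, tolerance = 1e-8)

  tab_scaled <- dplyr::mutate(tab, v = v * 13.7)
  expect_equal(half_max_position(moving_profile(tab_scaled, "v")), h,
               tolerance = 1e-8)
})

test_that("binned fractions count strict threshold exceedances per bin", {
  tab <- tibble::tibble(distance_um = c(rep(100, 20), rep(700, 10)),
                        marker = c(rep(5, 7), rep(1, 13), rep(5, 10)))
  bf <- binned_fraction(tab, "marker", threshold = 2, bin_width = 500)
  expect_equal(bf$fraction, c(7 / 20, 1))
  expect_equal(bf$bin_lo, c(0, 500))
  expect_equal(bf$bin_hi, c(500, 1000))

  # saturation: everything positive
  tab2 <- tibble::tibble(distance_um = runif(50, 0, 1000), marker = 10)
  bf2 <- binned_fraction(tab2, "marker", threshold = 2, bin_width = 250)
  expect_true(all(bf2$fraction == 1))

  # half-open bins: a cell exactly on an edge belongs to the upper bin
  tab3 <- tibble::tibble(distance_um = c(499.999, 500), marker = 10)
  bf3 <- binned_fraction(tab3, "marker", threshold = 1, bin_width = 500)
  expect_equal(bf3$bin_lo, c(0, 500))
  expect_equal(bf3$n, c(1L, 1L))
})

test_that("binned fractions track a known positivity probability", {
  withr::local_seed(17)
  n <- 4000
  tab <- tibble::tibble(distance_um = runif(n, 0, 2000))
  p_pos <- ifelse(tab$distance_um >= 1000, 0.8, 0.2)
  tab$marker <- ifelse(runif(n) < p_pos, 10, 0)
  bf <- binned_fraction(tab, "marker", threshold = 5, bin_width = 250)
  expected <- ifelse(bf$bin_lo >= 1000, 0.8, 0.2)
  # ~500 cells per bin: 4 binomial sd
  expect_true(all(abs(bf$fraction - expected) <
                    4 * sqrt(0.2 * 0.8 / 450)))
})
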