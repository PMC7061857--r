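test_that("difference map is zero for identical frames and recovers encoded uniform dA", {
  sp <- tiny_section(A = 0, seed = 2, wall_texture_cv = 0, noise_sd = 0)
  p <- render_pair(sp)
  m <- difference_map(p$unstained, p$unstained, identity_alignment())
  expect_true(all(m$dA == 0))

  sp2 <- tiny_section(A = 0.5, seed = 2, wall_texture_cv = 0, noise_sd = 0)
  p2 <- render_pair(sp2)
  m2 <- difference_map(p2$unstained, p2$stained, identity_alignment(),
                       background = p2$truth$label == 0L)
  expect_true(all(abs(m2$dA[p2$truth$wall] - 0.5) < 0.01))
  expect_lt(abs(mean(m2$dA[p2$truth$label == 0L])), 0.005)
})

test_that("scalar background adjustment removes a constant illumination drift", {
  sp <- tiny_section(A = 0.5, seed = 2, noise_sd = 0)
  p <- render_pair(sp)
  ## lamp dimming between the frames: the stained frame's background reads
  ## 10 grey levels lower; a transmission factor adds a flat absorbance
  ## offset which the background reference removes
  st_d <- array(as.integer(round(p$stained * 245 / 255)), dim(p$stained))
  m <- difference_map(p$unstained, st_d, identity_alignment(),
                      background = p$truth$label == 0L)
  expect_gt(m$offset, 0.01) # the drift was detected...
  expect_lt(abs(mean(m$dA[p$truth$wall]) - 0.5), 0.02) # ...and removed
})

test_that("background region overlapping lignified labels is rejected", {
  sp <- tiny_section(A = 0.5, seed = 2)
  p <- render_pair(sp)
  expect_error(
    difference_map(p$unstained, p$stained, identity_alignment(),
                   background = p$truth$wall, labels = p$truth$wall),
    "overlaps")
})

test_that("point sampling reads uniform and piecewise maps exactly", {
  sp <- tiny_section(A = 0.5, seed = 2, wall_texture_cv = 0, noise_sd = 0)
  p <- render_pair(sp)
  m <- uniform_map(p$truth, 0.42)
  tab <- sample_points(m, p$truth, n = 10, area_px = 12, seed = 1)
  expect_true(all(abs(tab$absorbance - 0.42) < 1e-12))
  expect_equal(nrow(tab), 10)

  ## two wall regions with different values: per-type point means are exact
  lay2 <- lattice_cells(c("IF", "MX"), n_cells = 8, seed = 5)
  sp2 <- section_spec(lay2$cells, lay2$width, lay2$height,
                      type_absorbance = c(IF = 0.2, MX = 0.8), seed = 5)
  p2 <- render_pair(sp2)
  m2 <- uniform_map(p2$truth, 0)
  m2$dA[p2$truth$wall & p2$truth$type == "IF"] <- 0.2
  m2$dA[p2$truth$wall & p2$truth$type == "MX"] <- 0.8
  tab2 <- sample_points(m2, p2$truth, n = 15, area_px = 12, seed = 2)
  expect_equal(mean(tab2$absorbance[tab2$cell_type == "IF"]), 0.2, tolerance = 1e-12)
  expect_equal(mean(tab2$absorbance[tab2$cell_type == "MX"]), 0.8, tolerance = 1e-12)

  expect_error(sample_points(m, p$truth, n = 1e5, seed = 1), "insufficient")
})

test_that("12-pixel points at the default pitch have ~0.7 um diameter", {
  off <- lignoquant:::circle_offsets(12)
  diam_px <- max(sqrt(off$dx^2 + off$dy^2)) * 2 + 1
  expect_lt(abs(diam_px * 0.179 - 0.7), 0.2)
})

test_that("area-weighted totals follow the stated arithmetic", {
  expect_equal(weighted_total(c(1, 2, 3), rep(1 / 3, 3)), 2)
  expect_equal(weighted_total(c(2, 4, 4), c(0.5, 0.25, 0.25)), 3)
  expect_equal(weighted_total(5, 1), 5)
  expect_error(weighted_total(c(1, 2), c(-0.5, 1.5)), "non-negative")
  expect_error(weighted_total(c(1, 2), c(0.6, 0.3)), "sum to 1")
})

test_that("false colour is anchored at the colormap ends and monotone in dA", {
  m <- matrix(c(0, 0.25, 0.5, 1, 1.5, NA), 2)
  fc <- false_color(m)
  expect_equal(fc$index[1, 1], 0)
  expect_equal(fc$index[2, 2], 255)
  expect_equal(fc$index[1, 3], 255) # clipped above 1
  idx <- fc$index[!is.na(fc$index)]
  expect_true(all(diff(sort(idx)) >= 0))
})

test_that("plateau detection finds the 95% point of a saturating series", {
  h <- 10; w <- 10
  truth <- list(wall = matrix(TRUE, h, w),
                type = matrix("IF", h, w))
  mk <- function(v) structure(list(dA = matrix(v, h, w),
                                   valid = matrix(TRUE, h, w)),
                              class = "absorbance_map")
  times <- seq(0, 240, by = 10)
  tau <- 30
  tc <- time_course(lapply(1 - exp(-times / tau), mk), times, truth)
  expect_gte(tc$plateau$plateau_time_s, 2 * tau)
  expect_lte(tc$plateau$plateau_time_s, 4 * tau)

  tc2 <- time_course(lapply(c(0.5, 0.5, 0.5), mk), c(0, 60, 120), truth)
  expect_equal(tc2$plateau$plateau_time_s, 0)

  ## fading after the maximum does not move the plateau
  vals <- c(0.1, 0.5, 1.0, 0.98, 0.6, 0.3)
  tc3 <- time_course(lapply(vals, mk), seq(0, 50, by = 10), truth)
  expect_equal(tc3$plateau$plateau_time_s, 20)
})

test_that("cambium-distance bins are half-open with phloem-side exclusion", {
  cambium <- cbind(x = c(0, 0), y = c(0, 100))
  tab <- data.frame(x = c(49.9, 50, 250, -5), y = c(10, 20, 30, 40),
                    absorbance = 1)
  expect_warning(
    out <- bin_by_cambium_distance(tab, cambium, pitch_um = 1,
                                   xylem_side = c(100, 50)),
    "phloem")
  expect_equal(attr(out, "excluded"), 1L)
  expect_equal(as.character(out$stage), c("I", "II", "III"))
})
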