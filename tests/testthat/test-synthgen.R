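test_that("zero-absorbance walls render stained identical to unstained", {
  sp <- tiny_section(A = 0, seed = 2, wall_texture_cv = 0, noise_sd = 0)
  p <- render_pair(sp)
  expect_identical(p$stained, p$unstained)
})

test_that("grey-intensity absorbance of the stained frame recovers the encoded truth", {
  sp <- tiny_section(A = 0.5, seed = 2, wall_texture_cv = 0, noise_sd = 0,
                     unstained_od = 0)
  p <- render_pair(sp)
  A <- pixel_to_absorbance(to_grey(p$stained))
  expect_true(all(abs(A[p$truth$wall] - 0.5) < 0.01))
})

test_that("rendering is deterministic under a fixed seed", {
  sp <- tiny_section(A = 0.7, seed = 9, noise_sd = 3)
  expect_identical(render_pair(sp), render_pair(sp))
  sp2 <- tiny_section(A = 0.7, seed = 10, noise_sd = 3)
  expect_false(identical(render_pair(sp)$stained, render_pair(sp2)$stained))
})

test_that("declared types without wall pixels fail loudly", {
  lay <- lattice_cells("IF", n_cells = 2, seed = 1)
  cells <- rbind(lay$cells,
                 data.frame(id = 3, type = "MX", cx = 1e4, cy = 1e4,
                            r_px = 10, wall_px = 3))
  sp <- section_spec(cells, lay$width, lay$height,
                     type_absorbance = c(IF = 0.5, MX = 1))
  expect_error(render_pair(sp), "MX")
})

test_that("round trip holds within 0.01 across the absorbance range and is monotone", {
  lay <- lattice_cells("IF", n_cells = 4, seed = 1)
  rec <- vapply(seq(0, 2, by = 0.25), function(a) {
    sp <- section_spec(lay$cells, lay$width, lay$height,
                       type_absorbance = c(IF = a), noise_sd = 0, seed = 1)
    p <- render_pair(sp)
    m <- difference_map(p$unstained, p$stained, identity_alignment())
    mean(m$dA[p$truth$wall]) - mean(p$truth$a_true[p$truth$wall])
  }, 0)
  expect_true(all(abs(rec) < 0.01))
  means <- vapply(seq(0, 2, by = 0.25), function(a) {
    sp <- section_spec(lay$cells, lay$width, lay$height,
                       type_absorbance = c(IF = a), noise_sd = 0, seed = 1)
    p <- render_pair(sp)
    m <- difference_map(p$unstained, p$stained, identity_alignment())
    mean(m$dA[p$truth$wall])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("ground-truth type means equal the area-weighted raster means", {
  sp <- arabidopsis_spec(seed = 4, cells_per_type = 2)
  p <- render_pair(sp)
  for (tt in names(p$truth$type_means)) {
    sel <- p$truth$wall & !is.na(p$truth$type) & p$truth$type == tt
    expect_equal(p$truth$type_means[[tt]], mean(p$truth$a_true[sel]),
                 tolerance = 1e-9)
  }
  expect_true(nrow(p$truth$adjacency) > 0)
})

test_that("measurement tables reproduce encoded effects and cooperativity mixtures", {
  types <- c("A", "B", "C")
  eff <- list(WT = c(A = 1, B = 1, C = 1), mut = c(A = 0.5, B = 1.2, C = 0.8))

  ## zero-noise, full cooperativity: points adjacent to B equal B's mean
  tab <- make_measurement_sets(types, eff, n_reps = 2, rep_cv = 0,
                               point_cv = 0,
                               cooperativity = data.frame(source = "B",
                                                          target = "A",
                                                          weight = 1),
                               seed = 1)
  aB <- tab$absorbance[tab$cell_type == "A" & tab$adjacent_to == "B"]
  bSelf <- tab$absorbance[tab$cell_type == "B" & tab$adjacent_to == "self"]
  expect_equal(unique(round(aB, 12)), unique(round(bSelf, 12)))

  ## zero weight: context does not move the mean
  tab0 <- make_measurement_sets(types, eff, n_reps = 2, rep_cv = 0,
                                point_cv = 0, seed = 1)
  aB0 <- tab0$absorbance[tab0$cell_type == "A" & tab0$adjacent_to == "B"]
  aS0 <- tab0$absorbance[tab0$cell_type == "A" & tab0$adjacent_to == "self"]
  expect_equal(mean(aB0), mean(aS0), tolerance = 1e-12)

  ## stated effects recovered within 3 SE at 5% CV
  eff5 <- list(WT = c(MX = 1, XF = 1, IF = 0.5, LP = 0.5, PX = 0.25))
  tab5 <- make_measurement_sets(names(eff5$WT), eff5, n_reps = 5,
                                base_absorbance = 1, rep_cv = 0.05,
                                point_cv = 0.05, n_points = 50, seed = 42)
  for (tt in names(eff5$WT)) {
    v <- tab5$absorbance[tab5$cell_type == tt]
    se <- sd(v) / sqrt(5) # replicate means are the independent unit
    expect_lt(abs(mean(v) - eff5$WT[[tt]]), 3 * max(se, 0.05 * eff5$WT[[tt]] / sqrt(5)))
  }

  ## cooperativity on a pair with no shared wall fails
  expect_error(
    make_measurement_sets(types, eff,
                          adjacency = data.frame(a = "A", b = "B"),
                          cooperativity = data.frame(source = "C", target = "A",
                                                     weight = 0.5)),
    "no shared wall")
})

test_that("gaussian-band spectra are additive with the right argmax", {
  s0 <- make_spectrum(list())
  expect_true(all(s0$absorbance == 0))
  s1 <- make_spectrum(list(c(550, 30, 1.0)))
  expect_lte(abs(attr(s1, "lambda_max") - 550), 1)
  s2 <- make_spectrum(list(c(550, 30, 1.0), c(550, 30, 1.0)))
  expect_equal(max(s2$absorbance), 2, tolerance = 1e-9)
  expect_error(make_spectrum(grid = seq(400, 700, 1)), "visible range")
})
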