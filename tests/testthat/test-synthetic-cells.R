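test_that("shape specs validate their invariants", {
  expect_error(shape_spec(4, 4), "length_um > width_um")
  expect_error(shape_spec(12, 4, width_wobble = 0.3), "width_wobble")
  expect_error(shape_spec(12, 4, cap_aspect = 1.5), "cap_aspect")
  expect_error(shape_spec(12, 4, bend_curvature = 0.5), "too strong")
})

test_that("analytic ground truth matches closed forms", {
  # hemispherical caps: spherocylinder closed form
  tr <- make_contour(shape_spec(12, 4))$truth
  or <- spherocyl_oracle(12, 2)
  expect_equal(tr$volume, or$volume, tolerance = 1e-6)
  expect_equal(tr$surface, or$surface, tolerance = 1e-6)
  expect_equal(tr$width, or$width, tolerance = 1e-6)
  # flat caps: rectangle profile, V = (pi/4) w^2 L, S = pi w L
  tr0 <- make_contour(shape_spec(10, 4, cap_aspect = 0))$truth
  expect_equal(tr0$volume, pi / 4 * 16 * 10, tolerance = 1e-6)
  expect_equal(tr0$surface, pi * 4 * 10, tolerance = 1e-6)
})

test_that("generator is a pure function of spec and seed", {
  a <- make_contour(shape_spec(12, 4, width_wobble = 0.1, seed = 42))
  b <- make_contour(shape_spec(12, 4, width_wobble = 0.1, seed = 42))
  c <- make_contour(shape_spec(12, 4, width_wobble = 0.1, seed = 43))
  expect_identical(a$contour$points, b$contour$points)
  expect_identical(a$truth, b$truth)
  expect_false(isTRUE(all.equal(a$contour$points, c$contour$points)))
})

test_that("slice quantification converges to the generator's truth", {
  set.seed(5)
  for (i in 1:5) {
    spec <- shape_spec(runif(1, 9, 15), runif(1, 3, 4.5),
                       cap_aspect = runif(1, 0.5, 1),
                       width_wobble = runif(1, 0, 0.15), seed = i)
    cell <- make_contour(spec, n_points = 6000)
    g50 <- quantify_cell(cell$contour, n_segments = 50)
    expect_equal(g50$volume, cell$truth$volume, tolerance = 0.01)
    expect_equal(g50$surface, cell$truth$surface, tolerance = 0.01)
    g1000 <- quantify_cell(cell$contour, n_segments = 1000,
                           resample_to = 6000)
    expect_equal(g1000$volume, cell$truth$volume, tolerance = 0.001)
    expect_equal(g1000$surface, cell$truth$surface, tolerance = 0.001)
  }
})

test_that("rasterised mask area converges to polygon area", {
  cell <- make_contour(shape_spec(12, 4))
  poly_area <- abs(rodsize:::polygon_area(cell$contour$points))
  err <- vapply(c(0.1, 0.05), function(px) {
    r <- render_cell(cell$contour, render_spec(pixel_size_um = px))
    abs(sum(r$mask) * px^2 - poly_area) / poly_area
  }, numeric(1))
  expect_lt(err[1], 0.02)
  expect_lt(err[2], err[1])
})

test_that("rendering is deterministic and honours the septum flag", {
  cell <- make_contour(shape_spec(12, 4))
  r1 <- render_cell(cell$contour,
                    render_spec(noise_sd = 0.02, septum = TRUE, seed = 9))
  r2 <- render_cell(cell$contour,
                    render_spec(noise_sd = 0.02, septum = TRUE, seed = 9))
  expect_identical(r1$brightfield, r2$brightfield)
  expect_identical(r1$marker, r2$marker)

  off <- render_cell(cell$contour, render_spec(septum = FALSE))
  on <- render_cell(cell$contour, render_spec(septum = TRUE))
  expect_lt(max(off$marker), 0.2)          # no band anywhere
  expect_gt(max(on$marker), 0.5)           # bright mid-cell band
  # the band sits at mid-length: bright pixels near the image centre column
  bright <- which(on$marker > 0.5, arr.ind = TRUE)
  expect_lt(max(abs(bright[, 2] - ncol(on$marker) / 2)) *
              on$pixel_size_um, 1)
})

test_that("bent cells keep their arc-length geometry approximately", {
  straight <- make_contour(shape_spec(12, 4))
  bent <- make_contour(shape_spec(12, 4, bend_curvature = 0.05))
  g <- quantify_cell(bent$contour)
  # bending is a robustness probe: geometry within a few percent
  expect_equal(g$volume, straight$truth$volume, tolerance = 0.05)
  expect_equal(g$surface, straight$truth$surface, tolerance = 0.05)
})
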