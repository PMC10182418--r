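test_that("principal axis matches symmetry and closed forms", {
  ax <- estimate_axis(rect_contour(10, 4))
  expect_equal(abs(ax$direction), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(sort(c(ax$extremity_a[1], ax$extremity_b[1]))),
               c(-5, 5), tolerance = 1e-9)

  th <- 30 * pi / 180
  ax30 <- estimate_axis(transform_contour(rect_contour(10, 4), th))
  expect_equal(abs(sum(ax30$direction * c(cos(th), sin(th)))), 1,
               tolerance = 1e-9)

  set.seed(11)
  for (theta in runif(5, 0, pi)) {
    ax_e <- estimate_axis(ellipse_contour(6, 2, theta))
    ang <- acos(min(1, abs(sum(ax_e$direction * c(cos(theta),
                                                  sin(theta))))))
    expect_lt(ang, 1 * pi / 180)
  }
})

test_that("degenerate contours raise explicit axis errors", {
  t <- seq(0, 2 * pi, length.out = 9)[-9]
  circle <- contour(cbind(cos(t), sin(t)))
  # a circle has no unique axis but is not degenerate; should not error
  expect_s3_class(estimate_axis(circle), "axis_frame")
  line_pts <- cbind(seq(0, 1, length.out = 9), seq(0, 1, length.out = 9))
  expect_error(estimate_axis(contour(line_pts, check = FALSE)))
})

test_that("cell length is the projection span", {
  expect_equal(as.numeric(cell_length(estimate_axis(rect_contour(10, 4)))),
               10, tolerance = 1e-9)
  sc <- make_contour(shape_spec(12, 4))
  expect_equal(as.numeric(cell_length(estimate_axis(sc$contour))), 12,
               tolerance = 1e-6)
  # homogeneity
  sc3 <- contour(sc$contour$points * 3, check = FALSE)
  expect_equal(as.numeric(cell_length(estimate_axis(sc3))), 36,
               tolerance = 1e-6)
  # tip-to-tip distance equals the span for a straight cell
  len <- cell_length(estimate_axis(sc$contour))
  expect_equal(attr(len, "tip_to_tip"), as.numeric(len), tolerance = 1e-3)
})

test_that("slice widths: constant profile, cap closed form, invariances", {
  prof <- slice_widths(rect_contour(10, 4), n_segments = 50)
  expect_equal(prof$widths, rep(4, 50), tolerance = 1e-9)
  expect_equal(prof$slice_height, 0.2, tolerance = 1e-12)
  expect_equal(prof$slice_height, prof$length / prof$n_segments)

  # spherocylinder cap: w_i = 2 sqrt(r^2 - s^2) at slab-centre offset s
  sc <- make_contour(shape_spec(12, 4), n_points = 4000)
  pr <- slice_widths(sc$contour, n_segments = 200, resample_to = 4000)
  d <- pr$slice_height
  centres <- (seq_len(200) - 0.5) * d
  oracle <- function(x) {
    r <- 2
    ifelse(x < r, 2 * sqrt(pmax(0, r^2 - (r - x)^2)),
           ifelse(x > 12 - r, 2 * sqrt(pmax(0, r^2 - (x - (12 - r))^2)), 4))
  }
  expect_lt(max(abs(pr$widths - oracle(centres))), 0.01)

  # rotation invariance of the whole profile
  pr_rot <- slice_widths(transform_contour(sc$contour, 1.1, c(5, -7)),
                         n_segments = 200, resample_to = 4000)
  expect_lt(max(abs(pr_rot$widths - pr$widths)), 1e-9)

  expect_error(slice_widths(rect_contour(), n_segments = 1), "at least 2")
  expect_error(slice_widths(rect_contour(), n_segments = 50,
                            resample_to = 10), "fewer points")
})

test_that("mean width, volume and surface follow the slice formulas", {
  prof <- structure(list(n_segments = 3L, widths = c(1, 2, 3),
                         slice_height = 0.5, length = 1.5),
                    class = "width_profile")
  expect_equal(mean_width(prof), 2)
  expect_equal(cell_volume(prof), pi / 4 * 0.5 * (1 + 4 + 9))
  expect_equal(cell_surface(prof), pi * 0.5 * 6)

  # spherocylinder continuum limits (closed-form oracle)
  or <- spherocyl_oracle(12, 2)
  sc <- make_contour(shape_spec(12, 4), n_points = 4000)
  pr <- slice_widths(sc$contour, n_segments = 1000, resample_to = 8000)
  expect_equal(mean_width(pr), or$width, tolerance = 1e-3)
  expect_equal(cell_volume(pr), or$volume, tolerance = 1e-3)
  expect_equal(cell_surface(pr), or$surface, tolerance = 1e-3)
})

test_that("quantify_cell composes the pipeline and is rigid-motion safe", {
  g <- quantify_cell(rect_contour(10, 4))
  expect_equal(g$length, 10, tolerance = 1e-9)
  expect_equal(g$width, 4, tolerance = 1e-9)
  expect_equal(g$surface, 40 * pi, tolerance = 1e-9)
  expect_equal(g$volume, 40 * pi, tolerance = 1e-9)
  expect_equal(g$sv_ratio, 1, tolerance = 1e-9)

  sc <- make_contour(shape_spec(12, 4))
  g1 <- quantify_cell(sc$contour)
  or <- spherocyl_oracle(12, 2)
  expect_equal(g1$length, 12, tolerance = 0.01)
  expect_equal(g1$width, or$width, tolerance = 0.01)
  expect_equal(g1$surface, or$surface, tolerance = 0.01)
  expect_equal(g1$volume, or$volume, tolerance = 0.01)

  g2 <- quantify_cell(transform_contour(sc$contour, 2.2, c(-4, 9)))
  for (f in c("length", "width", "surface", "volume", "sv_ratio"))
    expect_equal(g2[[f]], g1[[f]], tolerance = 1e-9)

  # the segment count is honoured
  g3 <- quantify_cell(sc$contour, n_segments = 10)
  expect_equal(g3$profile$n_segments, 10L)
  expect_equal(g3$profile$slice_height, g3$length / 10, tolerance = 1e-12)
})

test_that("surface-to-volume tracks 4/width across a width sweep", {
  ws <- seq(2.5, 5.5, by = 0.5)
  sv <- vapply(ws, function(w) {
    quantify_cell(make_contour(shape_spec(14, w))$contour)$sv_ratio
  }, numeric(1))
  expect_true(all(diff(sv) < 0))            # monotone decreasing in width
  expect_lt(max(abs(sv - 4 / ws) / (4 / ws)), 0.15)  # cylinder-dominated
})

test_that("per-cell table output is well-formed", {
  tab <- quantify_cells(list(a = rect_contour(10, 4),
                             b = rect_contour(8, 3)))
  expect_equal(tab$cell_id, c("a", "b"))
  expect_equal(tab$volume_um3[1], 40 * pi, tolerance = 1e-9)
  expect_equal(tab$n_segments, c(50L, 50L))
})
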