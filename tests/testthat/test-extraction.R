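test_that("a noiseless mask yields one accurate contour", {
  cell <- make_contour(shape_spec(12, 4))
  r <- render_cell(cell$contour, render_spec(pixel_size_um = 0.1))
  cts <- extract_contours(r$mask, 0.1)
  expect_length(cts, 1L)
  g <- quantify_cell(cts[[1]])
  expect_equal(g$length, cell$truth$length, tolerance = 0.02)
  expect_equal(g$width, cell$truth$width, tolerance = 0.02)
  expect_equal(g$volume, cell$truth$volume, tolerance = 0.02)
})

test_that("blank images give an empty list, bad pixels an error", {
  expect_length(extract_contours(matrix(0, 50, 50), 0.1), 0L)
  bad <- matrix(0, 50, 50); bad[10, 10] <- NA
  expect_error(extract_contours(bad, 0.1), "non-finite")
  expect_error(extract_contours(matrix(0, 5, 5), -1), "positive")
})

test_that("two well-separated cells are both recovered", {
  cells <- list(make_contour(shape_spec(11, 4, seed = 1)),
                make_contour(shape_spec(9, 3.4, seed = 2)))
  fld <- render_field(cells, septum = c(FALSE, FALSE), pixel_size_um = 0.1)
  cts <- extract_contours(fld$mask, 0.1)
  expect_length(cts, 2L)
  areas <- unname(sort(vapply(cts, function(ct)
    abs(rodsize:::polygon_area(ct$points)), numeric(1))))
  truth <- sort(vapply(cells, function(cl)
    abs(rodsize:::polygon_area(cl$contour$points)), numeric(1)))
  expect_equal(areas, truth, tolerance = 0.02)
})

test_that("components touching the border or below min area are dropped", {
  img <- matrix(0, 60, 60)
  img[1:10, 1:10] <- 1                     # touches the border
  img[30:31, 30:31] <- 1                   # tiny speck
  img[40:55, 20:50] <- 1                   # valid object
  cts <- extract_contours(img, 0.1, segmentation_params(min_area_um2 = 1))
  expect_length(cts, 1L)
  expect_gt(abs(rodsize:::polygon_area(cts[[1]]$points)), 3)
})

test_that("dark-polarity extraction segments brightfield-like images", {
  cell <- make_contour(shape_spec(12, 4))
  r <- render_cell(cell$contour,
                   render_spec(pixel_size_um = 0.05, noise_sd = 0.01,
                               seed = 4))
  cts <- extract_contours(r$brightfield, 0.05,
                          segmentation_params(threshold_method = "otsu",
                                              polarity = "dark",
                                              smoothing_um = 0.1))
  expect_length(cts, 1L)
  g <- quantify_cell(cts[[1]])
  # the dark halo straddles the true edge; expect rough agreement only
  expect_equal(g$length, cell$truth$length, tolerance = 0.1)
  expect_equal(g$width, cell$truth$width, tolerance = 0.15)
})

test_that("septum selection keeps marked cells and rejects unmarked", {
  cell <- make_contour(shape_spec(12, 4))
  on <- render_cell(cell$contour, render_spec(pixel_size_um = 0.1,
                                              septum = TRUE))
  off <- render_cell(cell$contour, render_spec(pixel_size_um = 0.1,
                                               septum = FALSE))
  cts_on <- extract_contours(on$mask, 0.1)
  cts_off <- extract_contours(off$mask, 0.1)
  sel_on <- select_septated(cts_on, on$marker, 0.1)
  sel_off <- select_septated(cts_off, off$marker, 0.1)
  expect_length(sel_on$kept, 1L)
  expect_length(sel_off$kept, 0L)
  expect_gt(sel_on$scores$septum_snr, 2)
  expect_lt(sel_off$scores$septum_snr, 1.5)
})

test_that("a mixed field recovers exactly the septated subset", {
  set.seed(21)
  cells <- lapply(1:20, function(i)
    make_contour(shape_spec(runif(1, 9, 14), runif(1, 3.2, 4.4),
                            seed = i)))
  septum <- rep(c(TRUE, FALSE), c(8, 12))[sample(20)]
  fld <- render_field(cells, septum, pixel_size_um = 0.1,
                      septum_contrast = 10, seed = 2)
  cts <- extract_contours(fld$mask, 0.1)
  expect_length(cts, 20L)
  sel <- select_septated(cts, fld$marker, 0.1,
                         segmentation_params(septum_snr_min = 2))
  expect_length(sel$kept, 8L)
})
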