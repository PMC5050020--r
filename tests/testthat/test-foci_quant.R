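test_that("thresholding is boundary-inclusive and validates its input", {
  zero <- matrix(0, 5, 5)
  expect_false(any(threshold_channel(zero, 0.1)))
  ones <- matrix(1, 5, 5)
  expect_true(all(threshold_channel(ones, 0.1)))
  m <- matrix(c(0.09999, 0.1, 0.10001, 0), 2, 2)
  expect_identical(as.vector(threshold_channel(m, 0.1)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(threshold_channel(m, 1.5), "\\[0, 1\\]")
})

test_that("connectivity defines object merging for diagonal pixels", {
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  o8 <- label_objects(m, connectivity = 8L)
  expect_equal(nrow(o8), 1L)
  expect_equal(o8$area_px, 2L)
  o4 <- label_objects(m, connectivity = 4L)
  expect_equal(nrow(o4), 2L)
  expect_equal(o4$area_px, c(1L, 1L))
  expect_equal(nrow(label_objects(matrix(FALSE, 3, 3))), 0L)
})

test_that("labeling matches an independent flood-fill oracle on random masks", {
  for (seed in 1:6) {
    sc <- random_scene(40, 40, p_red = 0.3, p_blue = 0, seed = seed)
    for (conn in c(4L, 8L)) {
      ours <- quadfoci:::.label_components(sc$red, conn)
      oracle <- flood_label(sc$red, conn)
      # same partition: label images must be a relabeling of each other
      expect_equal(max(ours), max(oracle))
      key <- paste(ours[sc$red], oracle[sc$red])
      expect_equal(length(unique(key)), max(oracle))
    }
  }
})

test_that("object measurements carry exact areas and physical units", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:6] <- TRUE  # 3x5 rectangle
  obj <- label_objects(m, pixel_size_um = 0.5)
  expect_equal(obj$area_px, 15L)
  expect_equal(obj$area_um2, 15 * 0.25)  # area_px * pixel_size^2, exactly
  expect_equal(obj$max_dim_um, 5 * 0.5)
  expect_equal(obj$centroid_row, 2)      # 0-based mean of rows 1..3
  # Feret diameter of the same rectangle: corner-to-corner pixel centers
  objf <- label_objects(m, pixel_size_um = 0.5, feret = TRUE)
  expect_equal(objf$max_dim_um, sqrt(2^2 + 4^2) * 0.5)
})

test_that("blue gating keeps whole objects on any overlap and drops the rest", {
  red <- matrix(FALSE, 8, 8); blue <- matrix(FALSE, 8, 8)
  red[2:3, 2:3] <- TRUE           # object fully outside blue
  red[6:7, 5:7] <- TRUE           # object with exactly one pixel on blue
  blue[6, 5] <- TRUE
  gated <- gate_by_blue(red, blue)
  expect_false(any(gated[2:3, 2:3]))
  expect_true(all(gated[6:7, 5:7]))
  expect_error(gate_by_blue(red, matrix(FALSE, 4, 4)), "dimensions")
})

test_that("gating matches the brute-force per-object oracle on random scenes", {
  for (seed in 1:8) {
    sc <- random_scene(35, 35, p_red = 0.25, p_blue = 0.08, seed = 100 + seed)
    for (conn in c(4L, 8L)) {
      expect_identical(gate_by_blue(sc$red, sc$blue, conn),
                       gate_oracle(sc$red, sc$blue, conn))
    }
  }
})

test_that("enlarging the blue mask never removes gated red objects", {
  sc <- random_scene(40, 40, p_red = 0.3, p_blue = 0.05, seed = 42)
  g1 <- gate_by_blue(sc$red, sc$blue)
  grown <- sc$blue | random_scene(40, 40, 0.1, 0, seed = 43)$red
  g2 <- gate_by_blue(sc$red, grown)
  expect_true(all(g2[g1]))
})

test_that("trimmed mean removes floor(trim*n) per tail and matches the oracle", {
  expect_equal(trimmed_mean_area(1:10, 0.10), 5.5)  # drops {1, 10}
  expect_equal(trimmed_mean_area(rep(7, 50), 0.2), 7)
  expect_equal(trimmed_mean_area(c(3, 9), 0.10), 6)  # n < 3: plain mean
  expect_true(is.na(trimmed_mean_area(numeric(0))))
  expect_error(trimmed_mean_area(1:5, 0.6), "trim_fraction")
  set.seed(7)
  areas <- rlnorm(1000, log(20), 0.5)
  expect_equal(trimmed_mean_area(areas, 0.10),
               trimmed_mean_oracle(areas, 0.10), tolerance = 1e-9)
  for (n in c(3, 9, 10, 11, 250)) {
    x <- rlnorm(n, 2, 0.8)
    expect_equal(trimmed_mean_area(x, 0.10), trimmed_mean_oracle(x, 0.10),
                 tolerance = 1e-9)
  }
})

test_that("foci count equals the exact object count for equal-area objects", {
  img <- matrix(0, 30, 30); blue <- matrix(1, 30, 30)
  # 6 disjoint 2x2 squares, all area 4
  for (k in 0:5) img[(k %% 3) * 9 + 2:3, (k %/% 3) * 9 + 2:3] <- 0.5
  m <- multichannel_image(img, matrix(0, 30, 30), blue, 0.2)
  q <- quantify_image(m, n_cells = 1)
  expect_equal(q$n_objects, 6L)
  expect_equal(q$foci_count, 6)
  expect_equal(q$area_total_px, 24L)
  expect_equal(q$area_total_um2, 24 * 0.04)
})

test_that("empty images quantify to zero and per-cell fields behave", {
  blank <- generate_image(sim_image_spec(n_cells = 4, foci_per_cell_mean = 0,
                                         stray_red_foci = 0, seed = 5))
  q <- quantify_image(blank$image)
  expect_equal(q$foci_count, 0)
  expect_equal(q$area_total_px, 0L)
  expect_equal(q$n_cells, 4L)

  # foci but no cells: per-cell values undefined, warned
  img <- matrix(0, 20, 20); img[5:6, 5:6] <- 0.5
  blue <- matrix(0, 20, 20); blue[5:6, 5:6] <- 0.5  # too small for a nucleus
  m <- multichannel_image(img, matrix(0, 20, 20), blue, 0.2)
  expect_warning(q2 <- quantify_image(m), "per-cell")
  expect_true(is.na(q2$foci_per_cell))
})

test_that("quantification is invariant to intensifying already-stained pixels", {
  g <- generate_image(sim_image_spec(n_cells = 6, foci_per_cell_mean = 5,
                                     noise_sd = 0, background = 0, seed = 9))
  img <- g$image
  boosted <- multichannel_image(pmin(img$red * 2, 1), img$green, img$blue,
                                img$pixel_size_um, img$source_id)
  # doubling clips at 1 but every pixel >= 0.1 stays >= 0.1 and none crosses up
  stopifnot(!any(img$red < 0.1 & pmin(img$red * 2, 1) >= 0.1))
  q1 <- quantify_image(img); q2 <- quantify_image(boosted)
  expect_equal(q1$foci_count, q2$foci_count)
  expect_equal(q1$area_total_px, q2$area_total_px)
})

test_that("raising the red threshold never increases total stained area", {
  g <- generate_image(sim_image_spec(n_cells = 6, foci_per_cell_mean = 6,
                                     focus_intensity = c(0.05, 0.9),
                                     seed = 12))
  areas <- vapply(c(0.05, 0.1, 0.3, 0.6), function(thr) {
    quantify_image(g$image, threshold_config(red_threshold = thr))$area_total_px
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("nucleus counting honours the minimum area and cells.csv override", {
  g <- generate_image(sim_image_spec(n_cells = 5, foci_per_cell_mean = 0,
                                     seed = 21))
  expect_equal(count_cells(g$image$blue, g$image$pixel_size_um), 5L)
  expect_equal(count_cells(matrix(0, 50, 50), 0.25), 0L)
  # a blue blob below the minimum area is not a cell
  tiny <- matrix(0, 40, 40); tiny[20:21, 20:21] <- 0.8  # 4 px = 0.25 um2
  expect_equal(count_cells(tiny, 0.25), 0L)
  q <- quantify_image(g$image, n_cells = 17L)
  expect_equal(q$n_cells, 17L)
})
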