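make_image <- function(red, green, blue, ps = 0.25) {
  multichannel_image(red, green, blue, ps, "coloc-test")
}

test_that("disjoint red and green staining yields no events", {
  red <- matrix(0, 20, 20); green <- matrix(0, 20, 20)
  red[3:5, 3:5] <- 0.5; green[10:12, 10:12] <- 0.5
  ev <- detect_coloc_events(make_image(red, green, matrix(1, 20, 20)))
  expect_equal(nrow(ev), 0L)
})

test_that("an identical red/green disk is one event with the disk's area", {
  red <- matrix(0, 20, 20); red[8:12, 8:12] <- 0.6
  blue <- matrix(1, 20, 20)
  ev <- detect_coloc_events(make_image(red, red, blue))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$area_px, 25L)
  expect_equal(ev$area_um2, 25 * 0.0625)
  expect_equal(ev$compartment, "nuclear")
})

test_that("the event set is symmetric in red and green", {
  sc <- random_scene(30, 30, 0.2, 0, seed = 5)
  g2 <- random_scene(30, 30, 0.2, 0, seed = 6)
  blue <- matrix(1, 30, 30)
  a <- detect_coloc_events(make_image(sc$red * 0.5, g2$red * 0.5, blue))
  b <- detect_coloc_events(make_image(g2$red * 0.5, sc$red * 0.5, blue))
  expect_equal(a$area_px, b$area_px)
  expect_equal(a$centroid_row, b$centroid_row)
})

test_that("raising the minimum event area never increases the event count", {
  g <- generate_image(sim_image_spec(n_cells = 9, foci_per_cell_mean = 5,
                                     coloc_fraction = 0.6,
                                     focus_radius_um = 0.6, seed = 31))
  counts <- vapply(c(0, 0.25, 0.5, 1), function(a) {
    nrow(detect_coloc_events(g$image,
                             threshold_config(min_coloc_area_um2 = a)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted colocalization fraction is recovered", {
  # expected events = planted coloc pairs (binomial around 0.3 per red focus)
  tot_events <- 0; tot_planted <- 0
  for (seed in 1:4) {
    g <- generate_image(sim_image_spec(n_cells = 16, foci_per_cell_mean = 6,
                                       coloc_fraction = 0.3,
                                       coloc_cyto_fraction = 0.3,
                                       focus_radius_um = 0.5, seed = seed))
    ev <- detect_coloc_events(g$image, threshold_config(min_coloc_area_um2 = 0.2))
    tot_events <- tot_events + nrow(ev)
    tot_planted <- tot_planted + g$truth$summary$n_coloc_nuclear +
      g$truth$summary$n_coloc_cyto
  }
  expect_gt(tot_planted, 60)
  expect_equal(tot_events, tot_planted, tolerance = 0.08)
})

test_that("compartment classification matches planted truth >= 95%", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    g <- generate_image(sim_image_spec(n_cells = 12, foci_per_cell_mean = 5,
                                       coloc_fraction = 1,
                                       coloc_cyto_fraction = 0.5,
                                       focus_radius_um = 0.5, seed = 50 + seed))
    ev <- detect_coloc_events(g$image, threshold_config(min_coloc_area_um2 = 0.2))
    truth <- g$truth$foci[g$truth$foci$channel == "coloc", ]
    # match each event to the nearest planted coloc focus
    for (i in seq_len(nrow(ev))) {
      d <- (truth$row - ev$centroid_row[i])^2 +
        (truth$col - ev$centroid_col[i])^2
      j <- which.min(d)
      if (d[j] < 4^2) {
        total <- total + 1
        hits <- hits + (truth$compartment[j] == ev$compartment[i])
      }
    }
  }
  expect_gt(total, 100)
  expect_gte(hits / total, 0.95)
})

test_that("large-focus filtering applies the 0.5 um any-dimension cutoff", {
  obj <- data.frame(label = 1:3, max_dim_um = c(0.4, 0.6, 0.5))
  kept <- filter_large_foci(obj)
  expect_equal(kept$label, c(2L, 3L))
  # motor-neuron preset: planted large green foci are all retained
  g <- generate_image(sim_image_spec(n_cells = 9, foci_per_cell_mean = 0,
                                     stray_red_foci = 0,
                                     green_foci_per_cell_mean = 1.3,
                                     green_focus_radius_um = 0.45, seed = 77))
  mask <- threshold_channel(g$image$green, 0.1)
  obj <- label_objects(mask, g$image$pixel_size_um)
  expect_equal(nrow(filter_large_foci(obj, 0.5)),
               sum(g$truth$cells$n_green_only))
})

test_that("incidence summaries divide events by total cells", {
  events <- data.frame(
    image_id = rep("i1", 41),
    compartment = rep(c("nuclear", "cytoplasmic"), c(17, 24)),
    cell_id = seq_len(41))
  cells <- data.frame(image_id = "i1", cell_count = 1860L)
  design <- data.frame(image_id = "i1", experiment_id = "e1",
                       line_id = "C9", group = "case",
                       condition = "untreated")
  s <- summarize_coloc(events, cells, design)
  expect_equal(round(s$incidence_events_nuclear, 1), 0.9)
  expect_equal(round(s$incidence_events_cytoplasmic, 1), 1.3)
  expect_equal(s$n_events_nuclear, 17L)
  # zero events give zero incidences
  s0 <- summarize_coloc(events[0, ], cells, design)
  expect_equal(s0$incidence_events_nuclear, 0)
  expect_equal(s0$incidence_cells_cytoplasmic, 0)
  # cells-with-event incidence can never exceed events-per-cell incidence
  expect_lte(s$incidence_cells_nuclear, s$incidence_events_nuclear)
})
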