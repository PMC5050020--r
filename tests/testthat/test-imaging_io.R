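test_that("integer normalization maps full scale to 1 and zero to 0", {
  p8 <- matrix(255L, 4, 4)
  expect_equal(normalize_plane(p8, 8L), matrix(1, 4, 4))
  p16 <- matrix(0L, 4, 4)
  expect_equal(normalize_plane(p16, 16L), matrix(0, 4, 4))
  # idempotence on already-normalized floats
  f <- matrix(runif(16), 4, 4)
  expect_identical(normalize_plane(f), f)
})

test_that("TIFF write/read round-trips integer planes bit-exactly", {
  set.seed(11)
  for (bits in c(8L, 16L)) {
    full <- 2^bits - 1L
    planes <- lapply(1:3, function(i) {
      matrix(sample.int(full + 1L, 6 * 9, replace = TRUE) - 1L, 6, 9)
    })
    path <- withr::local_tempfile(fileext = ".tif")
    quadfoci:::write_tiff_raw(planes, path, bits, pixel_size_um = 0.2)
    rt <- quadfoci:::read_tiff_raw(path)
    expect_identical(rt$planes, planes)
    expect_equal(rt$bits, bits)
    expect_equal(rt$pixel_size_um, 0.2, tolerance = 1e-6)
  }
})

test_that("interleaved RGB pages and both byte orders are readable", {
  # hand-build a one-page interleaved RGB little-endian file
  w <- 3L; h <- 2L
  r <- matrix(as.integer(c(10, 20, 30, 40, 50, 60)), h, w, byrow = TRUE)
  g <- r + 1L; b <- r + 2L
  inter <- integer(w * h * 3L)
  inter[seq(1, by = 3, length.out = w * h)] <- as.integer(t(r))
  inter[seq(2, by = 3, length.out = w * h)] <- as.integer(t(g))
  inter[seq(3, by = 3, length.out = w * h)] <- as.integer(t(b))
  strip <- as.raw(inter)
  u16 <- quadfoci:::.u16; u32 <- quadfoci:::.u32
  e <- quadfoci:::.ifd_entry
  ifd <- c(u16(8L),
           e(256L, 3L, 1L, w), e(257L, 3L, 1L, h), e(258L, 3L, 1L, 8L),
           e(259L, 3L, 1L, 1L), e(262L, 3L, 1L, 2L),
           e(273L, 4L, 1L, 8L), e(277L, 3L, 1L, 3L),
           e(279L, 4L, 1L, length(strip)),
           u32(0L))
  path <- withr::local_tempfile(fileext = ".tif")
  con <- file(path, "wb")
  writeBin(charToRaw("II"), con); writeBin(c(u16(42L), u32(8L + length(strip))), con)
  writeBin(strip, con); writeBin(ifd, con)
  close(con)
  rt <- quadfoci:::read_tiff_raw(path)
  expect_length(rt$planes, 3L)
  expect_identical(rt$planes, list(r, g, b))

  img <- load_image(path, pixel_size_um = 0.5)
  expect_equal(img$red, r / 255)
  expect_equal(img$pixel_size_um, 0.5)
})

test_that("load_image reports missing channels and missing pixel size", {
  planes <- list(matrix(1L, 3, 3), matrix(2L, 3, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  quadfoci:::write_tiff_raw(planes, path, 8L, pixel_size_um = 0.2)
  expect_error(load_image(path), "missing channel 'blue'")

  path2 <- withr::local_tempfile(fileext = ".tif")
  quadfoci:::write_tiff_raw(list(matrix(0L, 2, 2), matrix(0L, 2, 2),
                                 matrix(0L, 2, 2)), path2, 8L)
  expect_error(load_image(path2), "pixel_size_um")
  expect_s3_class(load_image(path2, pixel_size_um = 0.3),
                  "multichannel_image")

  txt <- withr::local_tempfile(fileext = ".tif")
  writeLines("not an image", txt)
  expect_error(load_image(txt), "not a TIFF")
})

test_that("synthetic image survives a write/load round trip bit-exactly", {
  g <- generate_image(sim_image_spec(n_cells = 4, foci_per_cell_mean = 4,
                                     seed = 3, source_id = "rt"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(g$image, path)
  back <- load_image(path, source_id = "rt")
  expect_identical(back$red, g$image$red)
  expect_identical(back$green, g$image$green)
  expect_identical(back$blue, g$image$blue)
  expect_equal(back$pixel_size_um, g$image$pixel_size_um, tolerance = 1e-6)
})

test_that("read_table validates schemas, types and duplicate keys", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("a", "a"), group = "case", gene = "G1",
                       replicate = 1:2, incl_intensity = c(10, 20),
                       excl_intensity = c(30, 40)),
            path, row.names = FALSE)
  tab <- read_table(path, "bands")
  expect_equal(nrow(tab), 2L)
  expect_type(tab$incl_intensity, "double")

  expect_error(read_table(path, "nope"), "unknown schema")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,replicate,incl_intensity,excl_intensity",
               "a,case,G1,1,ten,30"), bad)
  expect_error(read_table(bad, "bands"), "line 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample = "a", group = "case", gene = "G1",
                       replicate = c(1, 1), incl_intensity = 1,
                       excl_intensity = 2), dup, row.names = FALSE)
  expect_error(read_table(dup, "bands"), "duplicate key")
})

test_that("bands written by the generator re-read identically", {
  tab <- generate_psi_table(n_case = 2, n_control = 2, seed = 8)$bands
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read_table(path, "bands")
  expect_equal(back$incl_intensity, tab$incl_intensity, tolerance = 1e-7)
  expect_equal(back$excl_intensity, tab$excl_intensity, tolerance = 1e-7)
  expect_identical(back$sample, tab$sample)
})

test_that("config files parse with comments and numeric coercion", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# thresholds", "red_threshold = 0.2",
               "channel_red = 1", "label = hello  # trailing"), path)
  cfg <- read_config(path)
  expect_equal(cfg$red_threshold, 0.2)
  expect_equal(cfg$channel_red, 1)
  expect_equal(cfg$label, "hello")
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("just words", bad)
  expect_error(read_config(bad), "malformed")
})
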