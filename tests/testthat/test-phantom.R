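test_that("phantom generation is a pure function of (config, index)", {
  cfg <- phantom_config(image_size = 64, seed = 7)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  d <- generate_phantom(cfg, 4)
  expect_false(identical(a$image, d$image))
})

test_that("noise-free, vessel-free phantoms are exactly two-valued regions", {
  cfg <- phantom_config(image_size = 64, vessel_count = 0, noise_sd = 0,
                        seed = 1)
  ph <- generate_phantom(cfg, 1)
  bg <- cfg$background_hu
  gland <- ph$image[ph$mask == 1]
  expect_true(all(ph$image[ph$mask == 0] == bg))
  expect_true(all(gland >= cfg$gland_hu_range[1] &
                  gland <= cfg$gland_hu_range[2]))
  # thresholding at background reconstructs the mask (self-consistency)
  expect_identical((ph$image != bg) * 1, ph$mask)
})

test_that("masks are binary, small and shape-matched across many phantoms", {
  cfg <- phantom_config(image_size = 64, seed = 5)
  for (i in seq_len(30)) {
    ph <- generate_phantom(cfg, i)
    expect_identical(dim(ph$image), dim(ph$mask))
    expect_true(all(ph$mask %in% c(0, 1)))
    frac <- sum(ph$mask == 1) / length(ph$mask)   # brute-force scan
    expect_gt(frac, 0)
    expect_lt(frac, 0.25)
  }
})

test_that("vessels never overlap the gland mask", {
  cfg <- phantom_config(image_size = 64, vessel_count = 10, noise_sd = 0,
                        seed = 3)
  ph <- generate_phantom(cfg, 2)
  # on gland pixels only gland HU values appear; vessels live off-mask
  gl <- ph$image[ph$mask == 1]
  expect_true(all(gl >= cfg$gland_hu_range[1] & gl <= cfg$gland_hu_range[2]))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(image_size = 16), "image_size")
  expect_error(phantom_config(gland_hu_range = c(100, 60)), "low <= high")
  expect_error(phantom_config(vessel_count = -1), "vessel_count")
  expect_error(phantom_config(noise_sd = -2), "noise_sd")
})

test_that("generate_dataset writes a reproducible manifest of pairs", {
  cfg <- phantom_config(image_size = 64, seed = 9)
  d1 <- file.path(tempdir(), "ph_a")
  d2 <- file.path(tempdir(), "ph_b")
  man <- generate_dataset(cfg, 8, d1)
  expect_equal(nrow(man), 8)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  generate_dataset(cfg, 8, d2)
  for (i in seq_len(8)) {   # byte-identical reruns
    expect_identical(readBin(man$image_path[i], "raw", 1e6),
                     readBin(file.path(d2, basename(man$image_path[i])),
                             "raw", 1e6))
    expect_identical(readBin(man$mask_path[i], "raw", 1e6),
                     readBin(file.path(d2, basename(man$mask_path[i])),
                             "raw", 1e6))
  }
  # written pairs round-trip to the in-memory phantoms
  ph <- generate_phantom(cfg, 5)
  hu <- read_hu_slice(man$image_path[5])
  expect_lt(max(abs(hu - ph$image)), 0.5 + 1e-9)   # 16-bit rounding only
  expect_identical(read_mask_png(man$mask_path[5]), ph$mask * 1)
  unlink(c(d1, d2), recursive = TRUE)
})
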