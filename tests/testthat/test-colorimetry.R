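test_that("optical density transform matches the Beer-Lambert formula", {
  expect_equal(rgb_to_od(c(255, 255, 255)), c(0, 0, 0))
  # -log10(26/255) evaluated by hand
  expect_equal(unname(rgb_to_od(c(26, 255, 255))[1]), 0.9915668, tolerance = 1e-6)
  # zero intensity clamps to 1 before the log -> finite OD
  od <- rgb_to_od(c(0, 128, 255))
  expect_true(all(is.finite(od)))
  expect_equal(unname(od[1]), -log10(1 / 255))
  # monotone decreasing in intensity, componentwise
  darker <- rgb_to_od(c(50, 60, 70)); lighter <- rgb_to_od(c(120, 130, 140))
  expect_true(all(darker >= lighter))
  expect_error(rgb_to_od(c(1, 2, 3), i0 = 0), "positive")
})

test_that("stain vectors sampled from control pixels average the OD", {
  expect_equal(sample_stain_vector(rbind(c(255, 255, 255)))$od, c(0, 0, 0))
  two <- od_to_rgb(rbind(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4)))
  expect_equal(sample_stain_vector(two)$od, c(0.3, 0.3, 0.3), tolerance = 1e-9)
  # round-trip of the Fast Red control signature
  fr <- c(0.283, 0.949, 0.757)
  px <- od_to_rgb(matrix(fr, 5, 3, byrow = TRUE))
  expect_equal(sample_stain_vector(px)$od, fr, tolerance = 1e-3)
  expect_error(sample_stain_vector(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("stain matrix is normalized, invertible, and rejects collinearity", {
  sm <- stain_matrix()
  expect_equal(colSums(sm$basis^2), c(red = 1, brown = 1, blue = 1))
  expect_lt(max(abs(sm$inverse %*% sm$basis - diag(3))), 1e-10)
  v <- stain_vector("a", c(0.2, 0.4, 0.6))
  expect_error(stain_matrix(list(red = v, brown = v, blue = v)), "collinear|singular")
  expect_error(stain_vector("zero", c(0, 0, 0)), "not all zero")
})

test_that("deconvolution inverts the forward model and clips negatives", {
  sm <- stain_matrix()
  od <- sm$basis[, "blue"] * 0.7
  expect_equal(unname(deconvolve(od, sm)), c(0, 0, 0.7), tolerance = 1e-9)
  expect_equal(unname(deconvolve(c(0, 0, 0), sm)), c(0, 0, 0))
  od2 <- 0.5 * sm$basis[, "red"] + 0.2 * sm$basis[, "brown"]
  expect_equal(unname(deconvolve(od2, sm)), c(0.5, 0.2, 0), tolerance = 1e-9)
  # off-basis OD can imply negative stain amounts; those are clipped to zero
  expect_true(all(deconvolve(c(2, 0, 0), sm) >= 0))
})

test_that("deconvolution round-trips random concentration triples", {
  sm <- stain_matrix()
  # concentrations bounded so that per-channel OD stays below log10(i0):
  # darker pixels are clamped to intensity 1 by the OD transform and cannot
  # round-trip
  withr::with_seed(42, {
    conc <- matrix(runif(600, 0, 1.1), ncol = 3)
    rgb <- stains_to_rgb(conc, sm)
    back <- deconvolve(rgb_to_od(rgb), sm)
    expect_lt(max(abs(back - conc)), 1e-6)
  })
})

test_that("HSB conversion follows the standard HSV convention", {
  expect_equal(unname(rgb_to_hsb(c(255, 0, 0))), c(0, 1, 1))
  gray <- rgb_to_hsb(c(128, 128, 128))
  expect_equal(unname(gray), c(0, 0, 128 / 255))
  expect_equal(unname(rgb_to_hsb(c(0, 0, 255))), c(240, 1, 1))
  # cross-check against grDevices::rgb2hsv on random pixels
  withr::with_seed(9, {
    px <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
    ours <- rgb_to_hsb(px)
    ref <- t(grDevices::rgb2hsv(t(px), maxColorValue = 255))
    expect_equal(ours[, 1], ref[, 1] * 360, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(ours[, 2], ref[, 2], tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(ours[, 3], ref[, 3], tolerance = 1e-9, ignore_attr = TRUE)
  })
})

test_that("positive pixel counting matches constructed ground truth", {
  rng <- hsb_range(250, 300, 0.45, 0.85, 0.35, 0.85)   # nuclei box
  nuc <- c(115, 60, 160)
  tile <- array(255, dim = c(10, 10, 3))
  for (k in 1:3) tile[1:4, , k] <- nuc[k]              # exactly 40% painted
  expect_equal(positive_pixel_percent(tile, rng), 40)
  all_in <- array(0, dim = c(4, 4, 3))
  for (k in 1:3) all_in[, , k] <- nuc[k]
  expect_equal(positive_pixel_percent(all_in, rng), 100)
  # modular hue interval: 350-10 degrees must capture a 355-degree tile
  wrap <- hsb_range(350, 10, 0.5, 1, 0.5, 1)
  col355 <- grDevices::col2rgb(grDevices::hsv(355 / 360, 1, 1))[, 1]
  t355 <- array(rep(col355, each = 16), dim = c(4, 4, 3))
  expect_equal(positive_pixel_percent(t355, wrap), 100)
})

test_that("positive pixel counting equals the brute-force per-pixel oracle", {
  rng <- hsb_range(320, 355, 0.25, 0.55, 0.75, 1)
  withr::with_seed(12, {
    for (rep in 1:5) {
      px <- matrix(sample(0:255, 120, replace = TRUE), ncol = 3)
      expect_equal(positive_pixel_percent(px, rng), ppc_brute_force(px, rng))
      # invariance under pixel permutation
      expect_equal(positive_pixel_percent(px[sample(nrow(px)), ], rng),
                   positive_pixel_percent(px, rng))
    }
  })
})

test_that("overlapping PPC compartment ranges are rejected at load", {
  expect_error(
    ppc_config(nuclei = hsb_range(250, 300, 0.4, 0.8, 0.3, 0.9),
               cytoplasm = hsb_range(290, 340, 0.5, 0.7, 0.5, 0.95),
               stroma = hsb_range(0, 40, 0.1, 0.3, 0.8, 1)),
    "overlap")
  expect_s3_class(default_ppc_config(), "ppc_config")
  # wraparound hue arcs participate in the disjointness check
  expect_error(
    ppc_config(nuclei = hsb_range(350, 10, 0.4, 0.8, 0.3, 0.9),
               cytoplasm = hsb_range(5, 40, 0.5, 0.7, 0.5, 0.95),
               stroma = hsb_range(100, 140, 0.1, 0.3, 0.8, 1)),
    "overlap")
})

test_that("color deconvolution quantification matches forward-model oracles", {
  cfg <- cd_config()
  t08 <- uniform_stain_tile(c(0.8, 0, 0))
  q <- cd_quantify(t08, cfg, "red")
  expect_equal(q$pct_pos, 100)
  expect_equal(q$mean_od, 0.8, tolerance = 1e-6)
  expect_equal(q$od_x_pctpos, 80, tolerance = 1e-4)
  blank <- array(255, dim = c(4, 4, 3))
  expect_equal(cd_quantify(blank, cfg, "red"),
               list(pct_pos = 0, mean_od = 0, od_x_pctpos = 0))
  half <- rbind(stains_to_rgb(matrix(c(1, 0, 0), 8, 3, byrow = TRUE), cfg$stain_matrix),
                matrix(255, 8, 3))
  qh <- cd_quantify(half, cfg, "red")
  expect_equal(qh$pct_pos, 50)
  expect_equal(qh$mean_od, 1, tolerance = 1e-6)
  expect_equal(qh$od_x_pctpos, 50, tolerance = 1e-4)
})

test_that("co-expression excludes double-stained pixels", {
  cfg <- cd_config()
  sm <- cfg$stain_matrix
  only_red <- matrix(c(0.8, 0, 0), 8, 3, byrow = TRUE)
  both <- matrix(c(0.8, 0.8, 0), 4, 3, byrow = TRUE)
  neither <- matrix(0, 4, 3)
  tile <- stains_to_rgb(rbind(only_red, both, neither), sm)
  ce <- ce_quantify(tile, cfg)
  expect_equal(ce$pctpos_ce_red, 50)
  expect_equal(ce$pctpos_ce_brown, 0)
  all_both <- stains_to_rgb(matrix(c(0.8, 0.8, 0), 8, 3, byrow = TRUE), sm)
  expect_equal(ce_quantify(all_both, cfg),
               list(pctpos_ce_red = 0, pctpos_ce_brown = 0))
  expect_equal(ce_quantify(array(255, dim = c(3, 3, 3)), cfg),
               list(pctpos_ce_red = 0, pctpos_ce_brown = 0))
})

test_that("co-expression percentage never exceeds the single-stain percentage", {
  cfg <- cd_config()
  withr::with_seed(5, {
    for (rep in 1:10) {
      conc <- matrix(runif(90, 0, 1.2), ncol = 3)
      tile <- stains_to_rgb(conc, cfg$stain_matrix)
      ce <- ce_quantify(tile, cfg)
      expect_lte(ce$pctpos_ce_red, cd_quantify(tile, cfg, "red")$pct_pos)
      expect_lte(ce$pctpos_ce_brown, cd_quantify(tile, cfg, "brown")$pct_pos)
    }
  })
})

test_that("colorimetry configuration survives a JSON round trip", {
  cfg <- cd_config()
  batches <- list(batch1 = default_ppc_config("batch1"),
                  batch2 = default_ppc_config("batch2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_colorimetry_config(cfg, batches, path)
  back <- read_colorimetry_config(path)
  expect_equal(back$cd$stain_matrix$basis, cfg$stain_matrix$basis)
  expect_equal(back$cd$positivity_threshold, cfg$positivity_threshold)
  expect_equal(back$ppc[[2]]$batch_id, "batch2")
  expect_equal(back$ppc[[1]]$ranges$nuclei, batches$batch1$ranges$nuclei)
})
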