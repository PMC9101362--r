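# Literal per-pixel/per-point oracle for the off-axis renderer: transcribes
# the interference formula with explicit loops, independent of the
# vectorized implementation.
oracle_render <- function(points, amps, cfg) {
  H <- cfg$resolution[1]; W <- cfg$resolution[2]
  k <- 2 * pi / cfg$wavelength
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    ux <- (c - (W + 1) / 2) * cfg$pixel_pitch
    uy <- ((H + 1) / 2 - r) * cfg$pixel_pitch
    O <- 0 + 0i
    for (j in seq_len(nrow(points))) {
      d <- sqrt((ux - points[j, 1])^2 + (uy - points[j, 2])^2 +
                  (cfg$scene_distance + points[j, 3])^2)
      O <- O + (amps[j] / d) * exp(1i * k * d)
    }
    R <- exp(1i * k * sin(cfg$reference_angle) * ux)
    out[r, c] <- Mod(O + R)^2
  }
  out
}

make_pc <- function(points, amps) {
  structure(list(points = points, amplitudes = amps,
                 labels = paste0("P", seq_len(nrow(points)))),
            class = "point_cloud")
}

test_that("feature values map to normalized point amplitudes", {
  lay <- fix_layout
  pc <- values_to_pointcloud(lay, rep(2.5, 14))
  expect_true(all(pc$amplitudes == 1))
  vals <- seq(0, 13)
  pc2 <- values_to_pointcloud(lay, vals, eps = 0.05)
  expect_equal(min(pc2$amplitudes), 0.05)
  expect_equal(max(pc2$amplitudes), 1)
  sub <- subset_layout(lay, lay$labels[1:10])
  expect_length(values_to_pointcloud(sub, 1:10)$amplitudes, 10)
  expect_error(values_to_pointcloud(lay, c(rep(1, 13), NA)), "non-finite")
})

test_that("zero object wave leaves the unit reference intensity", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  pc <- make_pc(fix_layout$coords[1:3, ], rep(0, 3))
  intensity <- render_hologram(pc, cfg)
  expect_lt(max(abs(intensity - 1)), 1e-12)
})

test_that("the renderer matches the literal-loop oracle", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  set.seed(21)
  for (npts in c(1, 3, 5)) {
    pts <- fix_layout$coords[sample(14, npts), , drop = FALSE]
    amps <- runif(npts, 0.05, 1)
    got <- render_hologram(make_pc(pts, amps), cfg)
    want <- oracle_render(pts, amps, cfg)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # single on-axis point
  got1 <- render_hologram(make_pc(matrix(c(0, 0, 1), 1), 1), cfg)
  want1 <- oracle_render(matrix(c(0, 0, 1), 1), 1, cfg)
  expect_lt(max(abs(got1 - want1)), 1e-10)
})

test_that("the object wave is additive over point clouds", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  pts1 <- fix_layout$coords[1:2, ]
  pts2 <- fix_layout$coords[3:5, ]
  a1 <- c(0.3, 0.8); a2 <- c(0.5, 0.2, 1)
  k <- 2 * pi / cfg$wavelength
  # predicted union intensity from the two oracle object waves
  O_of <- function(pts, amps) {
    H <- cfg$resolution[1]; W <- cfg$resolution[2]
    O <- matrix(0 + 0i, H, W)
    for (r in 1:H) for (c in 1:W) {
      ux <- (c - (W + 1) / 2) * cfg$pixel_pitch
      uy <- ((H + 1) / 2 - r) * cfg$pixel_pitch
      for (j in seq_len(nrow(pts))) {
        d <- sqrt((ux - pts[j, 1])^2 + (uy - pts[j, 2])^2 +
                    (cfg$scene_distance + pts[j, 3])^2)
        O[r, c] <- O[r, c] + (amps[j] / d) * exp(1i * k * d)
      }
    }
    O
  }
  Ref <- outer(rep(1, 32), (seq_len(32) - 16.5) * cfg$pixel_pitch)
  Ref <- exp(1i * k * sin(cfg$reference_angle) * Ref)
  want <- Mod(O_of(pts1, a1) + O_of(pts2, a2) + Ref)^2
  got <- render_hologram(make_pc(rbind(pts1, pts2), c(a1, a2)), cfg)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("intensity respects the coherent upper bound", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  pts <- fix_layout$coords[1:5, ]
  amps <- runif(5, 0.1, 1)
  intensity <- render_hologram(make_pc(pts, amps), cfg)
  # r_min over the pixel grid for each point
  H <- 32; W <- 32
  ux <- (seq_len(W) - (W + 1) / 2) * cfg$pixel_pitch
  uy <- ((H + 1) / 2 - seq_len(H)) * cfg$pixel_pitch
  r_min <- min(vapply(1:5, function(j) {
    min(sqrt(outer(uy - pts[j, 2], ux - pts[j, 1],
                   function(a, b) a^2 + b^2) +
               (cfg$scene_distance + pts[j, 3])^2))
  }, numeric(1)))
  expect_lte(max(intensity), (1 + sum(amps) / r_min)^2)
})

test_that("perturbing one electrode's amplitude changes the field", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  pts <- fix_layout$coords[1:6, ]
  a <- rep(0.5, 6)
  b <- a; b[4] <- 0.9
  i1 <- render_hologram(make_pc(pts, a), cfg)
  i2 <- render_hologram(make_pc(pts, b), cfg)
  expect_gt(sqrt(sum((i1 - i2)^2)), 0)
})

test_that("colorize is deterministic, monotone and 8-bit RGB", {
  cfg <- cgh_config()
  const <- colorize(matrix(5, 10, 10), cfg)
  expect_equal(dim(const), c(10, 10, 3))
  expect_true(all(const[, , 1] == const[1, 1, 1]))
  grad <- matrix(seq(0, 1, length.out = 100), 10, 10)
  rgb1 <- colorize(grad, cfg)
  expect_identical(rgb1, colorize(grad, cfg))
  expect_true(all(rgb1 >= 0 & rgb1 <= 255))
  # larger intensity never maps to a cooler (lower) palette index
  lut <- holofm:::jet_lut()
  key <- paste(lut[, 1], lut[, 2], lut[, 3])
  px_key <- paste(as.numeric(rgb1[, , 1]), as.numeric(rgb1[, , 2]),
                  as.numeric(rgb1[, , 3]))
  idx <- match(px_key, key)[order(as.numeric(grad))]
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
  # extremes hit the palette ends
  expect_equal(idx[1], 1)
  expect_equal(idx[length(idx)], 256)
})

test_that("a full trial yields 45 maps at the 200x200x3 contract", {
  slice <- fix_ft$values[1, , , ]
  maps <- maps_for_trial(slice, fix_layout, cgh_config(), trial_id = 1)
  expect_length(maps, 45)
  expect_equal(dim(maps[[1]]$rgb), c(200, 200, 3))
  tags <- vapply(maps, function(m) paste(m$tags$characteristic, m$tags$band),
                 character(1))
  expect_false(any(duplicated(tags)))
  # one band restriction -> 9 maps
  one_band <- slice[, "gamma", , drop = FALSE]
  expect_length(maps_for_trial(one_band, fix_layout, cgh_config()), 9)
  # determinism
  maps2 <- maps_for_trial(slice, fix_layout, cgh_config(), trial_id = 1)
  expect_identical(maps, maps2)
})

test_that("the batched image renderer equals the per-map path", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  small <- feature_tensor(fix_ds$trials[1:2])
  chans <- c("F3", "F4", "T7", "O1")
  imgs <- render_feature_images(small, chans, fix_layout, cfg, "band_power")
  expect_equal(dim(imgs), c(32, 32, 3, 10))
  sub <- subset_layout(fix_layout, chans)
  ci <- match(chans, fix_layout$labels)
  maps <- maps_for_trial(small$values[2, ci, , , drop = TRUE], sub, cfg, 2)
  ref <- maps_as_images(maps[1:5])      # band_power block of trial 2
  expect_equal(imgs[, , , 6:10], ref, tolerance = 1e-12)
})

test_that("PNG export writes the tagged filename", {
  cfg <- cgh_config(resolution = c(32, 32), span = 4 * 32 / 200)
  maps <- maps_for_trial(fix_ft$values[1, , , ], fix_layout, cfg, trial_id = 7)
  dir <- tempfile("png"); dir.create(dir)
  f <- write_hologram_png(maps[[1]], dir)
  expect_true(file.exists(file.path(dir, "trial7_band_power_delta.png")))
  back <- png::readPNG(file.path(dir, "trial7_band_power_delta.png"))
  expect_equal(dim(back), c(32, 32, 3))
})
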