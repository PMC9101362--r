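#' Configuration of the computer-generated holography renderer
#'
#' The hologram plane is a square pixel grid at `z = -scene_distance`
#' (illumination travels along the Z axis); electrode positions live on the
#' unit sphere, so all lengths are in head radii. The optics are
#' dimensionless: the defaults (wavelength 0.5, plane spanning 4 head radii
#' = twice the head diameter, scene distance 3 head radii, reference tilt
#' 30 degrees so the carrier fringe period covers many pixels) are frozen
#' for reproducibility; no physical constants are implied.
#'
#' @param resolution `c(H, W)` pixel grid, default `c(200, 200)`.
#' @param wavelength dimensionless wavelength of the simulated light.
#' @param span side length of the hologram plane in head radii (pixel pitch
#'   = `span / W`).
#' @param scene_distance distance from the electrode-sphere centre to the
#'   hologram plane (must exceed the sphere radius 1).
#' @param reference_angle off-axis tilt (radians, in `(0, pi/2)`) of the
#'   plane reference wave.
#' @param eps lower bound of the normalized point-source amplitudes.
#' @param colormap name of the colorize palette (only `"jet"` is shipped).
#' @return A `cgh_config` list (with derived `pixel_pitch`).
#' @export
cgh_config <- function(resolution = c(200, 200), wavelength = 0.5,
                       span = 4, scene_distance = 3,
                       reference_angle = pi / 6, eps = 0.05,
                       colormap = "jet") {
  stopifnot(length(resolution) == 2, all(resolution >= 2))
  if (scene_distance <= 1) stop("scene_distance must exceed the sphere radius 1")
  if (reference_angle <= 0 || reference_angle >= pi / 2)
    stop("reference_angle must be in (0, pi/2)")
  if (eps <= 0) stop("eps must be > 0")
  cfg <- list(resolution = as.integer(resolution), wavelength = wavelength,
              span = span, pixel_pitch = span / resolution[2],
              scene_distance = scene_distance,
              reference_angle = reference_angle, eps = eps,
              colormap = colormap)
  class(cfg) <- "cgh_config"
  cfg
}

#' Encode per-electrode feature values as a point cloud
#'
#' One point source per electrode, at the electrode's 3D position; the
#' feature value becomes the source amplitude after per-map min-max
#' normalization to `[eps, 1]`. When all values are equal every amplitude is
#' set to 1 (a uniformly "active" map).
#'
#' @param layout an `electrode_layout`.
#' @param values one finite feature value per layout label.
#' @param eps lower amplitude bound.
#' @return A `point_cloud`: list with `points` (n x 3), `amplitudes`,
#'   `labels`.
#' @export
values_to_pointcloud <- function(layout, values, eps = 0.05) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (length(values) != length(layout$labels))
    stop("need one value per electrode")
  if (!all(is.finite(values))) stop("non-finite feature value")
  rng <- range(values)
  amp <- if (rng[2] > rng[1]) {
    eps + (1 - eps) * (values - rng[1]) / (rng[2] - rng[1])
  } else rep(1, length(values))
  pc <- list(points = layout$coords, amplitudes = amp, labels = layout$labels)
  class(pc) <- "point_cloud"
  pc
}

# Complex per-electrode pixel fields exp(i k r) / r for a layout, plus the
# off-axis reference wave. Geometry-only, so it can be computed once per
# layout and reused for every map (rendering then reduces to one
# matrix-vector product per map).
hologram_gain <- function(layout, cfg) {
  H <- cfg$resolution[1]; W <- cfg$resolution[2]
  ux <- (seq_len(W) - (W + 1) / 2) * cfg$pixel_pitch
  uy <- ((H + 1) / 2 - seq_len(H)) * cfg$pixel_pitch
  px <- rep(ux, each = H)
  py <- rep(uy, times = W)
  k <- 2 * pi / cfg$wavelength
  n_ch <- nrow(layout$coords)
  G <- matrix(0 + 0i, H * W, n_ch)
  for (j in seq_len(n_ch)) {
    p <- layout$coords[j, ]
    r <- sqrt((px - p[1])^2 + (py - p[2])^2 + (cfg$scene_distance + p[3])^2)
    if (any(r < 1e-9)) stop("degenerate geometry: point on the hologram plane")
    G[, j] <- exp(1i * k * r) / r
  }
  ref <- exp(1i * k * sin(cfg$reference_angle) * px)
  list(G = G, ref = ref, H = H, W = W)
}

#' Render an off-axis point-source hologram
#'
#' The object wave at pixel `u` is the coherent sum over point sources
#' `O(u) = sum_j (a_j / r_j) exp(i 2 pi r_j / lambda)` with `r_j` the
#' Euclidean distance from source `j` to the pixel; the reference wave is
#' the tilted plane wave `R(u) = exp(i 2 pi sin(theta) u_x / lambda)`; the
#' recorded intensity is `|O + R|^2`.
#'
#' @param pc a `point_cloud`.
#' @param cfg a `cgh_config`.
#' @param gain optional precomputed [hologram_gain()] for `pc`'s layout
#'   (internal speed-up; geometry must match).
#' @return H x W nonnegative intensity matrix.
#' @export
render_hologram <- function(pc, cfg, gain = NULL) {
  stopifnot(inherits(pc, "point_cloud"))
  if (is.null(gain)) {
    lay <- structure(list(labels = pc$labels, coords = pc$points),
                     class = "electrode_layout")
    gain <- hologram_gain(lay, cfg)
  }
  field <- gain$G %*% pc$amplitudes + gain$ref
  matrix(Mod(field)^2, gain$H, gain$W)
}

#' Colorize an intensity field with a blue-to-red palette
#'
#' Min-max scales the field (a constant field maps to the lowest color) and
#' applies a fixed jet-style look-up table: low intensity is dark blue
#' ("inactive" electrodes), high intensity red ("active"). Deterministic.
#'
#' @param intensity numeric matrix.
#' @param cfg a `cgh_config`.
#' @return H x W x 3 integer array in `[0, 255]`.
#' @export
colorize <- function(intensity, cfg = cgh_config()) {
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  rng <- range(intensity)
  sc <- if (rng[2] > rng[1]) (intensity - rng[1]) / (rng[2] - rng[1])
        else array(0, dim(intensity))
  lut <- jet_lut()
  idx <- pmin(255L, pmax(0L, as.integer(floor(sc * 255)))) + 1L
  out <- array(0L, c(nrow(intensity), ncol(intensity), 3))
  for (c3 in 1:3) out[, , c3] <- matrix(lut[idx, c3], nrow(intensity))
  out
}

# 256-entry jet-style LUT (dark blue -> blue -> cyan -> green -> yellow ->
# red -> dark red), 8-bit per channel.
jet_lut <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    anchors <- c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
                 "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")
    ramp <- grDevices::colorRamp(anchors, space = "rgb")
    cache <<- round(ramp(seq(0, 1, length.out = 256)))
    cache
  }
})

#' Holographic feature maps for one trial
#'
#' Renders one hologram per (characteristic, band) pair from a single
#' trial's slice of the feature tensor: 9 characteristics x 5 subbands = 45
#' maps per trial (9 per subband).
#'
#' @param ft_slice channels x bands x characteristics numeric array (one
#'   trial of a [feature_tensor()], e.g. `ft$values[i, , , ]`).
#' @param layout the `electrode_layout` matching the slice's channel order.
#' @param cfg a `cgh_config`.
#' @param trial_id identifier stored in each map's tags.
#' @return List of `hologram_map` objects, each with `intensity`, `rgb` and
#'   `tags` (trial, characteristic, band).
#' @export
maps_for_trial <- function(ft_slice, layout, cfg = cgh_config(),
                           trial_id = 1L) {
  stopifnot(inherits(layout, "electrode_layout"))
  d <- dim(ft_slice)
  if (length(d) != 3 || d[1] != length(layout$labels))
    stop("slice must be channels x bands x characteristics")
  bands <- dimnames(ft_slice)[[2]] %||% names(eeg_bands())
  chars <- dimnames(ft_slice)[[3]] %||% characteristic_names()
  gain <- hologram_gain(layout, cfg)
  # batch all amplitude vectors into one matrix product
  amps <- matrix(0, d[1], d[2] * d[3])
  tags <- vector("list", d[2] * d[3])
  j <- 0L
  for (char in chars) for (band in bands) {
    j <- j + 1L
    amps[, j] <- values_to_pointcloud(layout, ft_slice[, band, char],
                                      eps = cfg$eps)$amplitudes
    tags[[j]] <- list(trial = trial_id, characteristic = char, band = band)
  }
  fields <- gain$G %*% amps + matrix(gain$ref, length(gain$ref), ncol(amps))
  maps <- vector("list", ncol(amps))
  for (j in seq_along(maps)) {
    intensity <- matrix(Mod(fields[, j])^2, gain$H, gain$W)
    maps[[j]] <- structure(
      list(intensity = intensity, rgb = colorize(intensity, cfg),
           tags = tags[[j]]),
      class = "hologram_map")
  }
  maps
}

#' Render one characteristic's maps straight into a CNN input array
#'
#' Memory-lean batched renderer used by the evaluation pipeline: for a fixed
#' characteristic it renders the 5 per-band holograms of every trial on the
#' given channel subset and writes the colorized images directly into a
#' single `(H, W, 3, n_trials * 5)` array (band-fastest within trial, values
#' in `[0, 1]`), without materializing intermediate `hologram_map` objects.
#' Numerically identical to [maps_for_trial()] + [maps_as_images()].
#'
#' @param ft a `feature_tensor`.
#' @param channels channel labels to render (e.g. a ranking's selection).
#' @param layout the full `electrode_layout` of the tensor.
#' @param cfg a `cgh_config`.
#' @param characteristic one of [characteristic_names()].
#' @return Image array of dim `(H, W, 3, n_trials * 5)`.
#' @export
render_feature_images <- function(ft, channels, layout, cfg, characteristic) {
  stopifnot(inherits(ft, "feature_tensor"))
  sub <- subset_layout(layout, channels)
  gain <- hologram_gain(sub, cfg)
  n <- dim(ft$values)[1]
  bands <- ft$bands
  nb <- length(bands)
  # amplitude matrix: one column per (trial, band), band fastest
  amps <- matrix(0, length(channels), n * nb)
  for (i in seq_len(n)) for (b in seq_len(nb)) {
    amps[, (i - 1) * nb + b] <-
      values_to_pointcloud(sub, ft$values[i, channels, b, characteristic],
                           eps = cfg$eps)$amplitudes
  }
  fields <- gain$G %*% amps + gain$ref
  intensity <- Mod(fields)^2
  # vectorized per-column min-max + jet LUT
  lo <- apply(intensity, 2, min)
  rng <- apply(intensity, 2, max) - lo
  rng[rng == 0] <- Inf
  sc <- sweep(sweep(intensity, 2, lo, "-"), 2, rng, "/")
  idx <- pmin(255L, pmax(0L, as.integer(floor(sc * 255)))) + 1L
  lut <- jet_lut() / 255
  out <- array(0, c(gain$H, gain$W, 3, n * nb))
  for (c3 in 1:3) out[, , c3, ] <- array(lut[idx, c3],
                                         c(gain$H, gain$W, n * nb))
  out
}

#' @export
print.hologram_map <- function(x, ...) {
  cat(sprintf("<hologram_map> %dx%d trial=%s char=%s band=%s\n",
              nrow(x$intensity), ncol(x$intensity),
              x$tags$trial, x$tags$characteristic, x$tags$band))
  invisible(x)
}

#' Write a hologram map's RGB image as PNG
#'
#' @param map a `hologram_map`.
#' @param dir output directory; the filename pattern is
#'   `trial<k>_<characteristic>_<band>.png`.
#' @return The written path, invisibly.
#' @export
write_hologram_png <- function(map, dir = ".") {
  stopifnot(inherits(map, "hologram_map"))
  file <- file.path(dir, sprintf("trial%s_%s_%s.png", map$tags$trial,
                                 map$tags$characteristic, map$tags$band))
  png::writePNG(map$rgb / 255, file)
  invisible(file)
}
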