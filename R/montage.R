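#' Electrode layouts for the supported EEG montages
#'
#' The package ships three montages named after the acquisition hardware of
#' the common affective-EEG corpora: `emotiv14` (14-channel Emotiv EPOC),
#' `biosemi32` (32-channel BioSemi ActiveTwo) and `scan62` (62-channel
#' NeuroScan cap). Labels follow the international 10-20 system and its
#' 10-10 extension; coordinates are idealized positions on a unit sphere in
#' a head-centred frame (+X right, +Y anterior, +Z apex), generated by the
#' classical proportional construction: the outer ring (Fpz, T7, Oz, T8,
#' ...) sits at 72 degrees of inclination from the vertex and intermediate
#' electrodes are spaced at equal fractions along the transverse arcs
#' joining the midline to the outer ring.
#'
#' The two cerebellar leads of the 62-channel cap (CB1/CB2) are not part of
#' the 10-10 grid; they are placed on the sphere's equator at the azimuth of
#' O1/O2, i.e. directly below the occipital electrodes. This is a package
#' convention, documented here because no standard angular table covers
#' those labels.
#'
#' @param montage_name one of `"emotiv14"`, `"biosemi32"`, `"scan62"`.
#' @return An object of class `electrode_layout`: a list with `labels`
#'   (character vector, montage order) and `coords` (numeric matrix,
#'   one row per label, columns `x`, `y`, `z`, unit norm).
#' @examples
#' lay <- standard_layout("emotiv14")
#' nrow(lay$coords)  # 14
#' @export
standard_layout <- function(montage_name) {
  labels <- switch(montage_name,
    emotiv14 = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                 "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    biosemi32 = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
                  "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
                  "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
                  "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2"),
    scan62 = c("Fp1", "Fpz", "Fp2", "AF3", "AF4", "F7", "F5", "F3", "F1",
               "Fz", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1",
               "FCz", "FC2", "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1",
               "Cz", "C2", "C4", "C6", "T8", "TP7", "CP5", "CP3", "CP1",
               "CPz", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1",
               "Pz", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POz",
               "PO4", "PO6", "PO8", "CB1", "O1", "Oz", "O2", "CB2"),
    stop("unknown montage name: ", montage_name)
  )
  tab <- ten_twenty_coordinates()
  miss <- setdiff(labels, rownames(tab))
  if (length(miss)) stop("no coordinates for label(s): ", paste(miss, collapse = ", "))
  layout <- list(labels = labels,
                 coords = tab[labels, , drop = FALSE],
                 montage = montage_name)
  class(layout) <- "electrode_layout"
  layout
}

#' Subset an electrode layout
#'
#' @param layout an `electrode_layout`.
#' @param labels labels to keep; order is preserved as given.
#' @return An `electrode_layout` restricted to `labels`.
#' @export
subset_layout <- function(layout, labels) {
  stopifnot(inherits(layout, "electrode_layout"))
  unknown <- setdiff(labels, layout$labels)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  out <- list(labels = as.character(labels),
              coords = layout$coords[labels, , drop = FALSE],
              montage = layout$montage)
  class(out) <- "electrode_layout"
  out
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes (%s)\n",
              length(x$labels), x$montage %||% "custom"))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.electrode_layout <- function(x, ...) {
  data.frame(label = x$labels,
             x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
             row.names = NULL)
}

#' Write an electrode layout to CSV (label,x,y,z)
#'
#' @param layout an `electrode_layout`.
#' @param file output path.
#' @export
write_layout_csv <- function(layout, file) {
  utils::write.csv(as.data.frame(layout), file, row.names = FALSE)
  invisible(file)
}

# --- idealized 10-20 / 10-10 coordinate construction ----------------------

# Point on the unit sphere from inclination `incl` (degrees from the vertex)
# and azimuth `az` (degrees from the anterior midline, rotating towards the
# given side; side = -1 left, +1 right, 0 midline).
sph_point <- function(incl, az, side) {
  a <- incl * pi / 180
  b <- az * pi / 180
  c(side * sin(a) * sin(b), sin(a) * cos(b), cos(a))
}

# Interpolate at arc fraction `t` (0 = midline point M, 1 = outer-ring point
# E) along the circle cut by the plane through M, E and E's mirror image.
arc_interp <- function(M, E, t) {
  Em <- c(-E[1], E[2], E[3])
  n <- pracma_cross(E - M, Em - M)
  n <- n / sqrt(sum(n^2))
  d <- sum(n * M)
  o <- d * n                      # circle centre: foot of the perpendicular
  rho <- sqrt(max(0, 1 - d^2))    # circle radius on the unit sphere
  e1 <- (M - o) / sqrt(sum((M - o)^2))
  e2 <- pracma_cross(n, e1)
  v <- E - o
  phi <- atan2(sum(v * e2), sum(v * e1))
  o + rho * (cos(t * phi) * e1 + sin(t * phi) * e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Full coordinate table for every label used by the three montages.
# Memoised: geometry is deterministic, so compute once per session.
ten_twenty_coordinates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pts <- list()
    add <- function(label, p) pts[[label]] <<- p

    # outer ring: inclination 72 deg, azimuth steps of 18 deg from Fpz
    ring <- list(
      Fpz = c(0, 0), Fp1 = c(18, -1), Fp2 = c(18, 1),
      AF7 = c(36, -1), AF8 = c(36, 1),
      F7 = c(54, -1), F8 = c(54, 1),
      FT7 = c(72, -1), FT8 = c(72, 1),
      T7 = c(90, -1), T8 = c(90, 1),
      TP7 = c(108, -1), TP8 = c(108, 1),
      P7 = c(126, -1), P8 = c(126, 1),
      PO7 = c(144, -1), PO8 = c(144, 1),
      O1 = c(162, -1), O2 = c(162, 1),
      Oz = c(180, 0))
    for (lab in names(ring)) add(lab, sph_point(72, ring[[lab]][1], ring[[lab]][2]))

    # midline: inclination steps of 18 deg along the nasion-inion arc
    add("Cz", c(0, 0, 1))
    add("FCz", sph_point(18, 0, 0)); add("CPz", sph_point(18, 180, 0))
    add("Fz", sph_point(36, 0, 0));  add("Pz", sph_point(36, 180, 0))
    add("AFz", sph_point(54, 0, 0)); add("POz", sph_point(54, 180, 0))

    # transverse rows: equal arc fractions midline -> outer ring;
    # numbered labels 1/3/5 sit at fractions 1/4, 1/2, 3/4
    rows <- list(
      AF = list(mid = "AFz", outer = "AF7", nums = c(3, 1)),
      F  = list(mid = "Fz",  outer = "F7",  nums = c(1, 3, 5)),
      FC = list(mid = "FCz", outer = "FT7", nums = c(1, 3, 5)),
      C  = list(mid = "Cz",  outer = "T7",  nums = c(1, 3, 5)),
      CP = list(mid = "CPz", outer = "TP7", nums = c(1, 3, 5)),
      P  = list(mid = "Pz",  outer = "P7",  nums = c(1, 3, 5)),
      PO = list(mid = "POz", outer = "PO7", nums = c(3, 5)))
    for (rw in names(rows)) {
      M <- pts[[rows[[rw]]$mid]]; E <- pts[[rows[[rw]]$outer]]
      for (num in rows[[rw]]$nums) {
        p <- arc_interp(M, E, (num + 1) / 8)
        add(paste0(rw, num), p)                       # left (odd)
        add(paste0(rw, num + 1), c(-p[1], p[2], p[3]))  # right mirror (even)
      }
    }

    # cerebellar leads of the 62-channel cap: equator, below O1/O2
    add("CB1", sph_point(90, 162, -1))
    add("CB2", sph_point(90, 162, 1))

    tab <- do.call(rbind, pts)
    rownames(tab) <- names(pts)
    colnames(tab) <- c("x", "y", "z")
    # snap numeric dust so midline x is exactly 0 and norms exactly 1
    tab[abs(tab) < 1e-12] <- 0
    tab <- tab / sqrt(rowSums(tab^2))
    cache <<- tab
    tab
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
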