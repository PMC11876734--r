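# LV polar-map sampling and perfusion metrics: SNR, CNR, blood-pool CoV,
# normal databases, total perfusion deficit.

# bilinear interpolation of a 2-D slice at mm coordinates (grid centered)
.bilinear <- function(sl, x_mm, y_mm, voxel_mm) {
  nx <- nrow(sl); ny <- ncol(sl)
  fx <- x_mm / voxel_mm + (nx + 1) / 2
  fy <- y_mm / voxel_mm + (ny + 1) / 2
  i0 <- pmin(pmax(floor(fx), 1L), nx - 1L)
  j0 <- pmin(pmax(floor(fy), 1L), ny - 1L)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  v00 <- sl[cbind(i0, j0)];     v10 <- sl[cbind(i0 + 1L, j0)]
  v01 <- sl[cbind(i0, j0 + 1L)]; v11 <- sl[cbind(i0 + 1L, j0 + 1L)]
  (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
}

#' Sample an LV polar map
#'
#' For every (angle, slice) sample, takes the maximal interpolated value
#' along a radial profile through the expected wall position (0.55 to
#' 1.35 times the analytic mid-wall radius at that angle and slice) --
#' the maximal-count sampling used by clinical polar-map software.  The
#' analytic LV geometry stands in for automatic segmentation, which is
#' out of scope for phantom data.
#'
#' @param image Reconstructed activity array `(nx, ny, nz)`.
#' @param lvg The `lv_geometry` of the phantom.
#' @param n_angular Angular samples per slice (default 36).
#' @param percent If TRUE, normalize to the LV maximum x 100 (percent
#'   uptake relative to the segmented LV); if FALSE keep image units.
#' @param n_radial Radial search samples.
#' @return Object of class `polar_map`: matrix `values`
#'   (n_angular x n_slices), `angles_deg`, `territory` (vessel label per
#'   angle), `percent`.
#' @export
sample_polar_map <- function(image, lvg, n_angular = 36L, percent = TRUE,
                             n_radial = 25L) {
  stopifnot(inherits(lvg, "lv_geometry"))
  img <- as.array(image)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  nz <- length(lvg$z_positions)
  if (dim(img)[3] != nz)
    stop("image slices do not match LV geometry", call. = FALSE)
  ang <- seq(0, 360, length.out = n_angular + 1L)[seq_len(n_angular)]
  th <- ang * pi / 180
  vals <- matrix(NA_real_, n_angular, nz)
  for (iz in seq_len(nz)) {
    z <- lvg$z_positions[iz]
    # mid-wall semi-axes of this slice's elliptical cross-section
    fo <- 1 - (z / lvg$outer[3])^2
    fi <- 1 - (z / lvg$inner[3])^2
    if (fo <= 0) next   # outside the shell
    ao <- lvg$outer[1] * sqrt(fo); bo <- lvg$outer[2] * sqrt(fo)
    ai <- if (fi > 0) lvg$inner[1] * sqrt(fi) else 0
    bi <- if (fi > 0) lvg$inner[2] * sqrt(fi) else 0
    # directional outer/inner radii of an ellipse
    ro <- 1 / sqrt((cos(th) / ao)^2 + (sin(th) / bo)^2)
    ri <- if (ai > 0) 1 / sqrt((cos(th) / ai)^2 + (sin(th) / bi)^2) else 0
    rmid <- (ro + ri) / 2
    tt <- seq(0.55, 1.35, length.out = n_radial)
    for (ia in seq_len(n_angular)) {
      rr <- rmid[ia] * tt
      xv <- lvg$center[1] + rr * cos(th[ia])
      yv <- lvg$center[2] + rr * sin(th[ia])
      vals[ia, iz] <- max(.bilinear(img[, , iz], xv, yv, lvg$voxel_mm))
    }
  }
  if (anyNA(vals)) stop("LV geometry extends outside the image", call. = FALSE)
  if (percent) vals <- 100 * vals / max(vals)
  structure(list(values = vals, angles_deg = ang,
                 territory = vessel_territory(ang), percent = percent),
            class = "polar_map")
}

#' Blood-pool volume of interest
#'
#' Samples image voxels inside a 15 x 15 x 15 mm volume of interest at
#' the LV lumen centroid -- an axis-aligned cube by default, or a
#' cylinder (diameter = height = `size_mm`) that follows the elongated
#' shape of the ventricle.
#'
#' @param image Activity array `(nx, ny, nz)`.
#' @param lvg The `lv_geometry`.
#' @param shape `"cube"` or `"cylinder"`.
#' @param size_mm Edge length / diameter in mm (default 15).
#' @return Object of class `blood_voi` with `values` (voxel samples).
#' @export
blood_voi <- function(image, lvg, shape = c("cube", "cylinder"),
                      size_mm = 15) {
  shape <- match.arg(shape)
  img <- as.array(image)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  v <- lvg$voxel_mm
  nx <- dim(img)[1]; ny <- dim(img)[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) * v - lvg$center[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * v - lvg$center[2]
  h <- size_mm / 2
  inx <- abs(xs) <= h; iny <- abs(ys) <= h
  inz <- abs(lvg$z_positions) <= h
  if (!any(inz)) inz[which.min(abs(lvg$z_positions))] <- TRUE
  vals <- c()
  for (iz in which(inz)) {
    sl <- img[, , iz]
    if (shape == "cube") vals <- c(vals, sl[inx, iny])
    else {
      R2 <- outer(xs^2, ys^2, "+")
      vals <- c(vals, sl[R2 <= h^2])
    }
  }
  structure(list(values = vals, shape = shape, size_mm = size_mm),
            class = "blood_voi")
}

.pm_values <- function(pm) if (inherits(pm, "polar_map")) pm$values else pm
.voi_values <- function(v) if (inherits(v, "blood_voi")) v$values else v

#' Signal-to-noise ratio
#'
#' Mean polar-map uptake divided by the standard deviation of the
#' blood-pool VOI voxels.
#'
#' @param pm A [sample_polar_map] result (use `percent = FALSE` so that
#'   polar and blood values share units).
#' @param voi A [blood_voi].
#' @return Scalar SNR.
#' @export
snr <- function(pm, voi) {
  s <- stats::sd(.voi_values(voi))
  if (s == 0) stop("blood-pool SD is zero; SNR undefined", call. = FALSE)
  mean(.pm_values(pm)) / s
}

#' Contrast-to-noise ratio
#'
#' (Mean polar-map uptake minus mean blood-pool value) divided by the
#' blood-pool standard deviation.
#'
#' @inheritParams snr
#' @return Scalar CNR.
#' @export
cnr <- function(pm, voi) {
  bv <- .voi_values(voi)
  s <- stats::sd(bv)
  if (s == 0) stop("blood-pool SD is zero; CNR undefined", call. = FALSE)
  (mean(.pm_values(pm)) - mean(bv)) / s
}

#' Blood-pool coefficient of variation
#'
#' SD / mean of the blood-pool VOI voxels -- the noise measure reported
#' alongside SNR and CNR.
#'
#' @param voi A [blood_voi].
#' @return Scalar CoV.
#' @export
cov_blood <- function(voi) {
  bv <- .voi_values(voi)
  m <- mean(bv)
  if (m <= 0) stop("blood-pool mean must be positive", call. = FALSE)
  stats::sd(bv) / m
}

#' Build a normal database from polar maps
#'
#' Per-sample mean and SD over a cohort of disease-free polar maps, the
#' reference against which perfusion deficits are scored.  Separate
#' databases are required per reconstruction protocol (the PRC protocol
#' redistributes uptake, so a database built for one protocol does not
#' transfer to the other).
#'
#' @param maps List of `polar_map`s (same shape, same condition and
#'   reconstruction mode).
#' @return Object of class `normal_db` with `mean`, `sd`, `n`.
#' @export
build_normal_database <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps", call. = FALSE)
  vs <- lapply(maps, .pm_values)
  d <- dim(vs[[1]])
  if (!all(vapply(vs, function(v) identical(dim(v), d), logical(1))))
    stop("polar maps differ in shape", call. = FALSE)
  arr <- simplify2array(vs)
  structure(list(mean = apply(arr, c(1, 2), mean),
                 sd = apply(arr, c(1, 2), stats::sd),
                 n = length(maps)),
            class = "normal_db")
}

#' Total perfusion deficit
#'
#' Extent-times-severity score against a normal database: a sample is
#' hypoperfused when it falls below `L = mean - k * max(SD, floor)`;
#' its severity is `min(1, (L - v) / L)`; TPD is 100 times the mean
#' severity over all samples.  Zero for maps at or above the normal
#' mean; 100 for an empty map; monotone in defect severity and extent.
#'
#' @param pm A `polar_map` (percent mode recommended, matching the
#'   database).
#' @param db A [build_normal_database] result.
#' @param k SD multiplier for the deficit threshold (default 2.5).
#' @param sd_floor_frac SD floor as a fraction of the sample's normal
#'   mean (default 0.05), guarding against degenerate SD estimates.
#' @return TPD in percent, in `[0, 100]`.
#' @export
tpd <- function(pm, db, k = 2.5, sd_floor_frac = 0.05) {
  v <- .pm_values(pm)
  if (!identical(dim(v), dim(db$mean)))
    stop("polar map and database shapes differ", call. = FALSE)
  L <- db$mean - k * pmax(db$sd, sd_floor_frac * db$mean)
  L <- pmax(L, 0)
  sev <- ifelse(v < L & L > 0, pmin(1, (L - v) / L), 0)
  100 * mean(sev)
}

#' Ischemic total perfusion deficit
#'
#' Stress TPD minus rest TPD.  The difference can be negative; set
#' `clamp = TRUE` to clip at zero.
#'
#' @param stress_tpd,rest_tpd TPD values in percent.
#' @param clamp Clip negative differences to zero (default FALSE).
#' @return iTPD in percent.
#' @export
itpd <- function(stress_tpd, rest_tpd, clamp = FALSE) {
  d <- stress_tpd - rest_tpd
  if (clamp) pmax(d, 0) else d
}
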