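# Parallel-beam projection geometry and a sparse matrix projector pair.
# The projector is pixel-driven with linear interpolation onto radial
# bins; the back-projector is its exact transpose.

#' Parallel-beam acquisition geometry
#'
#' Desk-scale geometry: a stack of independent 2-D short-axis slices,
#' projected by a parallel-beam system with `n_angles` views over 180
#' degrees and radial bins of the voxel pitch.
#'
#' @param nx,ny In-plane grid size (voxels).
#' @param voxel_mm In-plane voxel size (mm).
#' @param n_angles Number of projection angles over 180 degrees.
#' @param nz Number of slices.
#' @param n_radial Number of radial bins; default `nx + 1`.
#' @return Object of class `pet_geometry`.
#' @export
pet_geometry <- function(nx, ny = nx, voxel_mm = 2.0, n_angles = 96L,
                         nz = 1L, n_radial = nx + 1L) {
  stopifnot(nx >= 2, ny >= 2, voxel_mm > 0, n_angles >= 1, nz >= 1)
  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 voxel_mm = voxel_mm, n_angles = as.integer(n_angles),
                 angles = angles, nz = as.integer(nz),
                 n_radial = as.integer(n_radial)),
            class = "pet_geometry")
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf("<pet_geometry> %dx%d @ %.2f mm, %d angles x %d radial bins, %d slice(s)\n",
              x$nx, x$ny, x$voxel_mm, x$n_angles, x$n_radial, x$nz))
  invisible(x)
}

# world coordinates (mm) of voxel centers, grid centered on the origin
.grid_coords <- function(geom) {
  x <- (seq_len(geom$nx) - (geom$nx + 1) / 2) * geom$voxel_mm
  y <- (seq_len(geom$ny) - (geom$ny + 1) / 2) * geom$voxel_mm
  list(x = x, y = y)
}

#' Assemble the sparse system matrix of a geometry
#'
#' Rows are sinogram bins (radial index fastest, then angle), columns are
#' pixels (column-major).  Entries approximate the X-ray transform in mm:
#' each pixel deposits `voxel_mm` times its value, linearly interpolated
#' between the two radial bins straddling its projected coordinate.
#'
#' @param geom A [pet_geometry].
#' @return A `dgCMatrix` of dimension
#'   `(n_radial * n_angles) x (nx * ny)`.
#' @export
build_projector <- function(geom) {
  stopifnot(inherits(geom, "pet_geometry"))
  gc_ <- .grid_coords(geom)
  xc <- rep(gc_$x, times = geom$ny)
  yc <- rep(gc_$y, each = geom$nx)
  npix <- geom$nx * geom$ny
  ns <- geom$n_radial
  ds <- geom$voxel_mm
  s0 <- -(ns + 1) / 2   # bin center s_k = (k + s0) * ds for k = 1..ns
  ii <- jj <- integer(0); vv <- numeric(0)
  pix <- seq_len(npix)
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    s <- xc * cos(th) + yc * sin(th)
    t <- s / ds - s0
    k0 <- floor(t)
    w <- t - k0
    row_base <- (a - 1L) * ns
    ok0 <- k0 >= 1 & k0 <= ns
    ok1 <- (k0 + 1) >= 1 & (k0 + 1) <= ns
    ii <- c(ii, row_base + k0[ok0], row_base + k0[ok1] + 1L)
    jj <- c(jj, pix[ok0], pix[ok1])
    vv <- c(vv, (1 - w[ok0]) * ds, w[ok1] * ds)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(ns * geom$n_angles, npix))
}

# cache projectors per geometry signature (assembly is the expensive part)
.proj_cache <- new.env(parent = emptyenv())

.projector_for <- function(geom) {
  key <- paste(geom$nx, geom$ny, signif(geom$voxel_mm, 10), geom$n_angles,
               geom$n_radial, sep = "_")
  if (is.null(.proj_cache[[key]])) .proj_cache[[key]] <- build_projector(geom)
  .proj_cache[[key]]
}

# image array (nx x ny [x nz]) <-> pixel matrix (npix x nz)
.as_pixmat <- function(image, geom) {
  x <- as.array(image)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (!identical(dim(x), c(geom$nx, geom$ny, geom$nz)))
    stop("image grid ", paste(dim(x), collapse = "x"),
         " does not match geometry ",
         paste(c(geom$nx, geom$ny, geom$nz), collapse = "x"), call. = FALSE)
  matrix(x, nrow = geom$nx * geom$ny)
}

.as_image <- function(pixmat, geom) {
  array(as.numeric(pixmat), dim = c(geom$nx, geom$ny, geom$nz))
}

.as_sinomat <- function(sino, geom) {
  v <- if (inherits(sino, "sinogram")) sino$values else as.array(sino)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  matrix(v, nrow = geom$n_radial * geom$n_angles)
}

#' Sinogram container
#'
#' @param values Array `(n_radial, n_angles, nz)` of counts or expected
#'   counts.
#' @param geom The [pet_geometry] that produced it.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, geom) {
  v <- as.array(values)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  stopifnot(identical(dim(v)[1:2], c(geom$n_radial, geom$n_angles)))
  structure(list(values = v, geom = geom), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d radial x %d angles x %d slice(s), total %.4g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}

#' Attenuation factors for a density map
#'
#' Per-bin survival factors `exp(-integral of mu)` with
#' `mu = 0.0096/mm * density` (511 keV water value scaled by density).
#'
#' @param density Density array on the image grid (g/cm^3).
#' @param geom A [pet_geometry].
#' @return Array shaped like a sinogram, values in `(0, 1]`.
#' @export
attenuation_factors <- function(density, geom) {
  A <- .projector_for(geom)
  mu <- 0.0096 * .as_pixmat(density, geom)
  af <- exp(-as.matrix(A %*% mu))
  array(af, dim = c(geom$n_radial, geom$n_angles, geom$nz))
}

#' Forward project an activity image
#'
#' Line integrals (mm units) along parallel rays; if `att` is given the
#' result is multiplied bin-wise by the attenuation factors.  Linear in
#' the image; exact adjoint of [back_project].
#'
#' @param image Activity array `(nx, ny[, nz])`.
#' @param geom A [pet_geometry].
#' @param att Optional attenuation factors from [attenuation_factors].
#' @return A [sinogram].
#' @export
forward_project <- function(image, geom, att = NULL) {
  x <- .as_pixmat(image, geom)
  A <- .projector_for(geom)
  y <- as.matrix(A %*% x)
  if (!is.null(att)) y <- y * .as_sinomat(att, geom)
  sinogram(array(y, dim = c(geom$n_radial, geom$n_angles, geom$nz)), geom)
}

#' Back project a sinogram
#'
#' Exact adjoint of [forward_project] (attenuation applied first when
#' given, matching the forward order).
#'
#' @param sino A [sinogram] or bare array.
#' @param geom A [pet_geometry].
#' @param att Optional attenuation factors.
#' @return Activity array `(nx, ny, nz)`.
#' @export
back_project <- function(sino, geom, att = NULL) {
  y <- .as_sinomat(sino, geom)
  if (nrow(y) != geom$n_radial * geom$n_angles)
    stop("sinogram does not match geometry", call. = FALSE)
  if (!is.null(att)) y <- y * .as_sinomat(att, geom)
  A <- .projector_for(geom)
  .as_image(as.matrix(Matrix::crossprod(A, y)), geom)
}
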