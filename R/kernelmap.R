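# Tissue classification from density maps and the spatially variant,
# tissue-dependent positron-range blur operator.

# next 5-smooth integer >= n, for fast FFTs
.next_fast_len <- function(n) {
  n <- as.integer(n)
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# centered 'same' linear convolution of an array with an odd-sized kernel,
# zero padding (truncate at boundary).  x and k must have the same number
# of dimensions (2 or 3).
.convn_same <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  stopifnot(length(dx) == length(dk), all(dk %% 2 == 1))
  dp <- vapply(dx + dk - 1L, .next_fast_len, integer(1))
  xp <- array(0, dp); kp <- array(0, dp)
  if (length(dx) == 2L) {
    xp[seq_len(dx[1]), seq_len(dx[2])] <- x
    kp[seq_len(dk[1]), seq_len(dk[2])] <- k
  } else {
    xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
    kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  }
  yf <- stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE) / prod(dp)
  y <- Re(yf)
  off <- (dk - 1L) / 2L
  if (length(dx) == 2L)
    y[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2])]
  else
    y[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]), off[3] + seq_len(dx[3])]
}

# reflect an array in every dimension (kernel transpose for convolution)
.reflect_kernel <- function(k) {
  d <- dim(k)
  if (length(d) == 2L) k[d[1]:1, d[2]:1, drop = FALSE]
  else k[d[1]:1, d[2]:1, d[3]:1, drop = FALSE]
}

#' Classify tissue composition from a density map
#'
#' Maps voxel density (g/cm^3) to continuous (lung, soft, bone) fractions
#' by piecewise-linear interpolation between the class anchor densities
#' 0.26 (lung), 1.00 (soft tissue/water) and 1.92 (bone): densities at or
#' below the lung anchor (including air) are pure lung class, densities
#' at or above the bone anchor are pure bone, and intermediate densities
#' mix the two neighboring classes.  Continuous mixing avoids
#' classification seams at tissue boundaries.
#'
#' @param density Array (2-D or 3-D) of densities in g/cm^3.
#' @return Object of class `tissue_fractions`: list of arrays `lung`,
#'   `soft`, `bone`, each in `[0, 1]`, summing to one per voxel.
#' @export
classify_tissue <- function(density) {
  if (any(!is.finite(density)) || any(density < 0))
    stop("density map must be finite and nonnegative", call. = FALSE)
  d <- as.array(density)
  lung <- ifelse(d <= 0.26, 1, ifelse(d < 1.00, (1.00 - d) / (1.00 - 0.26), 0))
  bone <- ifelse(d >= 1.92, 1, ifelse(d > 1.00, (d - 1.00) / (1.92 - 1.00), 0))
  soft <- 1 - lung - bone
  structure(list(lung = lung, soft = soft, bone = bone, dim = dim(d)),
            class = "tissue_fractions")
}

# normalized spherical (or circular) averaging kernel of given radius (mm)
.ball_kernel <- function(radius_mm, voxel_size, ndim) {
  vs <- rep(voxel_size, length.out = ndim)
  hw <- pmax(floor(radius_mm / vs), 0)
  if (all(hw == 0)) return(NULL)
  ax <- lapply(seq_len(ndim), function(i) (-hw[i]:hw[i]) * vs[i])
  g <- do.call(expand.grid, ax)
  r2 <- rowSums(as.matrix(g)^2)
  k <- array(as.numeric(r2 <= radius_mm^2), dim = 2L * hw + 1L)
  k / sum(k)
}

#' Build a spatially variant kernel map
#'
#' Couples the three uniform per-tissue positron-range kernels with
#' per-voxel mixing weights derived from the density map.  The mixing
#' weights are the tissue fractions of [classify_tissue], optionally
#' averaged over a spherical neighborhood (default radius: the mean
#' positron range in water of the isotope, since the annihilation medium
#' is the neighborhood of the source voxel, not the voxel itself); set
#' `smooth_radius_mm = 0` for voxel-local weights.
#'
#' @param kernels Named list with elements `lung`, `soft` (or `water`),
#'   `bone`, each a [histogram_kernel] result on a common grid (2-D or
#'   3-D values).
#' @param density Density array matching the image grid.
#' @param voxel_size Image voxel size in mm (scalar or per-axis).
#' @param smooth_radius_mm Neighborhood radius for weight averaging (mm).
#' @return Object of class `kernel_map`.
#' @export
kernel_map <- function(kernels, density, voxel_size, smooth_radius_mm = 0) {
  nm <- names(kernels)
  if ("water" %in% nm && !"soft" %in% nm) nm[nm == "water"] <- "soft"
  names(kernels) <- nm
  stopifnot(all(c("lung", "soft", "bone") %in% names(kernels)))
  kv <- lapply(kernels[c("lung", "soft", "bone")], function(k) {
    if (inherits(k, "pr_kernel")) {
      if (max(abs(k$voxel_size[1:2] - rep(voxel_size, length.out = 2))) > 1e-9)
        stop("kernel voxel size (", k$voxel_size[1],
             " mm) does not match the image voxel size (", voxel_size[1],
             " mm)", call. = FALSE)
      k$values
    } else as.array(k)
  })
  kd <- lapply(kv, dim)
  if (!all(vapply(kd, identical, logical(1), kd[[1]])))
    stop("uniform kernels must share one grid shape", call. = FALSE)
  fr <- classify_tissue(density)
  ndim <- length(dim(as.array(density)))
  ndim_k <- length(kd[[1]])
  # 2-D kernels over a 3-D slice stack = per-slice (in-plane) application
  if (!(ndim_k == ndim || (ndim_k == 2L && ndim == 3L)))
    stop("kernel dimensionality (", ndim_k,
         ") is incompatible with the density map (", ndim, ")", call. = FALSE)
  if (smooth_radius_mm > 0) {
    bk <- .ball_kernel(smooth_radius_mm, voxel_size, ndim_k)
    if (!is.null(bk)) {
      smooth1 <- function(w) {
        if (ndim == ndim_k) return(.convn_same(w, bk))
        for (z in seq_len(dim(w)[3])) w[, , z] <- .convn_same(w[, , z], bk)
        w
      }
      w <- lapply(fr[c("lung", "soft", "bone")], smooth1)
      tot <- w$lung + w$soft + w$bone
      fr$lung <- w$lung / tot; fr$soft <- w$soft / tot; fr$bone <- w$bone / tot
    }
  }
  structure(list(kernels = kv, fractions = fr,
                 voxel_size = rep(voxel_size, length.out = ndim),
                 smooth_radius_mm = smooth_radius_mm),
            class = "kernel_map")
}

#' Composed positron-range kernel at one voxel
#'
#' Weighted sum of the three uniform kernels with the voxel's mixing
#' weights, renormalized to sum one.
#'
#' @param km A [kernel_map].
#' @param voxel_index Integer vector (one index per image dimension).
#' @return A `pr_kernel` holding the composed kernel.
#' @export
compose_kernel <- function(km, voxel_index) {
  stopifnot(inherits(km, "kernel_map"))
  idx <- matrix(as.integer(voxel_index), 1)
  w <- c(km$fractions$lung[idx], km$fractions$soft[idx], km$fractions$bone[idx])
  k <- w[1] * km$kernels$lung + w[2] * km$kernels$soft + w[3] * km$kernels$bone
  .pr_kernel_from_values(k, km$voxel_size[1])
}

# shared engine: source-driven spatially variant convolution
#   forward: y = sum_c K_c * (w_c . x)
#   adjoint: y = sum_c w_c . (K_c~ * x)
.svblur <- function(x, km, adjoint = FALSE) {
  stopifnot(inherits(km, "kernel_map"))
  x <- as.array(x)
  fdim <- dim(km$fractions$lung)
  if (!identical(dim(x), fdim))
    stop("image grid ", paste(dim(x), collapse = "x"),
         " does not match kernel map grid ", paste(fdim, collapse = "x"),
         call. = FALSE)
  perslice <- length(dim(km$kernels$soft)) == 2L && length(fdim) == 3L
  conv1 <- function(a, k) {
    if (!perslice) return(.convn_same(a, k))
    for (z in seq_len(dim(a)[3])) a[, , z] <- .convn_same(a[, , z], k)
    a
  }
  acc <- array(0, dim(x))
  for (cl in c("lung", "soft", "bone")) {
    w <- km$fractions[[cl]]
    k <- km$kernels[[cl]]
    if (adjoint) acc <- acc + w * conv1(x, .reflect_kernel(k))
    else acc <- acc + conv1(w * x, k)
  }
  acc
}

#' Apply the spatially variant positron-range blur
#'
#' Source-driven (scatter) formulation: each source voxel's activity is
#' spread according to its own composed kernel, so emitted activity is
#' conserved up to truncation at the image boundary (recorded in the
#' `boundary_loss` attribute as a fraction of the input total).
#'
#' @param image Activity array (2-D or 3-D) on the kernel-map grid.
#' @param km A [kernel_map].
#' @return Blurred array with attribute `boundary_loss`.
#' @export
apply_prc_blur <- function(image, km) {
  y <- .svblur(image, km, adjoint = FALSE)
  y[y < 0 & y > -1e-12] <- 0   # FFT round-off
  s <- sum(image)
  attr(y, "boundary_loss") <- if (s > 0) (s - sum(y)) / s else 0
  y
}

#' Adjoint of the spatially variant positron-range blur
#'
#' Exact adjoint of [apply_prc_blur] as a linear operator, needed for the
#' matched back-projection side of the PRC system model.
#'
#' @inheritParams apply_prc_blur
#' @return Array of the same shape as `image`.
#' @export
adjoint_prc_blur <- function(image, km) {
  y <- .svblur(image, km, adjoint = TRUE)
  y[y < 0 & y > -1e-12] <- 0
  y
}
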