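# File I/O: volumetric images as raw float64 + JSON header sidecar
# (coordinate convention documented in every sidecar), kernel archives,
# tabular exports.

#' Write a volumetric image (raw array + JSON sidecar)
#'
#' Stores the array as little-endian float64 in `<path>.raw` with a JSON
#' sidecar `<path>.json` holding dimensions, voxel size in mm and the
#' coordinate convention (0-based indices, world mm at voxel centers,
#' grid centered on the origin).  Round-trips float64 losslessly.
#'
#' @param image Numeric array (2-D or 3-D).
#' @param path Path without extension.
#' @param voxel_size Voxel size in mm (scalar or per-axis).
#' @return Invisibly, the two file paths.
#' @export
io_write_image <- function(image, path, voxel_size) {
  x <- as.array(image)
  raw_path <- paste0(path, ".raw")
  json_path <- paste0(path, ".json")
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  hdr <- list(dim = dim(x),
              voxel_size_mm = rep(voxel_size, length.out = length(dim(x))),
              dtype = "float64", byte_order = "little",
              order = "column-major",
              convention = "0-based voxel indices; world mm at voxel centers; grid centered on origin")
  jsonlite::write_json(hdr, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(raw_path, json_path))
}

#' Read a volumetric image written by [io_write_image]
#'
#' @param path Path without extension.
#' @return Numeric array with attribute `voxel_size_mm`.
#' @export
io_read_image <- function(path) {
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path))
    stop("missing header sidecar: ", json_path, call. = FALSE)
  hdr <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupt header sidecar ", json_path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(hdr$dim) || is.null(hdr$voxel_size_mm))
    stop("header sidecar ", json_path, " lacks dim/voxel_size_mm",
         call. = FALSE)
  n <- prod(hdr$dim)
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(v) != n)
    stop("raw payload shorter than header dimensions", call. = FALSE)
  x <- array(v, dim = hdr$dim)
  attr(x, "voxel_size_mm") <- hdr$voxel_size_mm
  x
}

#' Save / load a kernel archive
#'
#' Bundles the three uniform per-tissue kernels (plus provenance: n,
#' seeds, isotope, voxel size) into one RDS archive.
#'
#' @param kernels Named list of `pr_kernel`s (`lung`, `soft`, `bone`).
#' @param path Destination file.
#' @return `io_save_kernels`: invisibly, `path`;
#'   `io_load_kernels`: the kernel list.
#' @export
io_save_kernels <- function(kernels, path) {
  stopifnot(all(c("lung", "soft", "bone") %in% names(kernels)))
  saveRDS(kernels, path)
  invisible(path)
}

#' @rdname io_save_kernels
#' @export
io_load_kernels <- function(path) readRDS(path)

#' Export range summaries as CSV
#'
#' @param summaries List of [summarize_range] results.
#' @param path CSV destination.
#' @return Invisibly, the data frame written.
#' @export
io_write_range_csv <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(isotope = s$isotope, material = s$material, n = s$n,
               mean_range_mm = s$mean_range, max_range_mm = s$max_range,
               mean_path_mm = s$mean_path,
               p999_mm = unname(s$percentiles["99.9%"]))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export polar maps in long format
#'
#' One row per (subject, condition, mode, angle, slice) sample.
#'
#' @param maps Named nested list `maps[[subject]][[label]]` of
#'   `polar_map`s, or a flat list with a `meta` data frame.
#' @param df Data frame with columns `subject`, `condition`, `mode` and a
#'   list-column `map`; used when `maps` is NULL.
#' @param path CSV destination.
#' @return Invisibly, the long data frame.
#' @export
io_write_polar_csv <- function(maps = NULL, df = NULL, path) {
  rows <- list()
  if (is.null(df)) stop("provide df with subject/condition/mode/map",
                        call. = FALSE)
  for (i in seq_len(nrow(df))) {
    v <- .pm_values(df$map[[i]])
    idx <- which(!is.na(v), arr.ind = TRUE)
    rows[[i]] <- data.frame(subject = df$subject[i],
                            condition = df$condition[i],
                            mode = df$mode[i],
                            angle = idx[, 1], slice = idx[, 2],
                            value = v[idx])
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
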