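# Volume, surface, plan and report IO.
#
# Volumes travel as NRRD (detached headers are not used; raw little-endian
# encoding, spacing and axis origins in the header). The NRRD reader/writer
# here is deliberately minimal: it supports exactly the fields this package
# writes, and rejects malformed headers naming the offending field.

#' Write an OCT volume as NRRD
#'
#' @param vol an `OctVolume`.
#' @param path output file path (.nrrd).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "OctVolume"))
  d <- dim(vol$I)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# OCT intensity volume",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g", vol$spacing[1], vol$spacing[2],
                   vol$spacing[3]),
           sprintf("axis mins: %.9g %.9g %.9g", vol$x[1], vol$y[1], vol$w[1]),
           "endian: little",
           "encoding: raw",
           sprintf("acquisition_index:=%d", vol$acq_index),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(vol$I), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an OCT volume from NRRD
#'
#' @param path an NRRD file written by [write_volume()] (type double,
#'   raw little-endian encoding).
#' @return an `OctVolume`.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD"))
    stop("malformed NRRD: missing magic", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("malformed NRRD: header not terminated", call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1L]]
      fields[[trimws(kv[1L])]] <- trimws(kv[2L])
    } else {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop(sprintf("malformed NRRD: cannot parse header line '%s'", line),
             call. = FALSE)
      fields[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
  }
  need <- function(name) {
    v <- fields[[name]]
    if (is.null(v))
      stop(sprintf("malformed NRRD: missing field '%s'", name), call. = FALSE)
    v
  }
  if (need("type") != "double")
    stop("malformed NRRD: field 'type' must be double", call. = FALSE)
  if (need("encoding") != "raw")
    stop("malformed NRRD: field 'encoding' must be raw", call. = FALSE)
  if (as.integer(need("dimension")) != 3L)
    stop("malformed NRRD: field 'dimension' must be 3", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1L]])
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes <= 0L))
    stop("malformed NRRD: field 'sizes' invalid", call. = FALSE)
  spacings <- as.numeric(strsplit(need("spacings"), "\\s+")[[1L]])
  if (length(spacings) != 3L || any(!is.finite(spacings)) || any(spacings <= 0))
    stop("malformed NRRD: field 'spacings' invalid", call. = FALSE)
  mins <- as.numeric(strsplit(need("axis mins"), "\\s+")[[1L]])
  if (length(mins) != 3L || any(!is.finite(mins)))
    stop("malformed NRRD: field 'axis mins' invalid", call. = FALSE)
  n <- prod(sizes)
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    stop("malformed NRRD: truncated data block", call. = FALSE)
  acq <- as.integer(fields[["acquisition_index"]] %||% "0")
  oct_volume(array(vals, sizes),
             x = mins[1] + (seq_len(sizes[1]) - 1L) * spacings[1],
             y = mins[2] + (seq_len(sizes[2]) - 1L) * spacings[2],
             w = mins[3] + (seq_len(sizes[3]) - 1L) * spacings[3],
             spacing = spacings, acq_index = acq)
}

#' Write a surface model as a CSV height map
#'
#' Grid surfaces are written sample by sample; spline surfaces are sampled
#' on the grid given by `x` and `y`.
#'
#' @param surface a `SurfaceModel`.
#' @param path output CSV path.
#' @param x,y sampling grids, required for spline surfaces.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path, x = NULL, y = NULL) {
  stopifnot(inherits(surface, "SurfaceModel"))
  if (surface$kind == "grid") {
    x <- surface$x; y <- surface$y
    z <- surface$z; valid <- surface$valid
  } else {
    if (is.null(x) || is.null(y))
      stop("sampling grids x and y are required for spline surfaces",
           call. = FALSE)
    nx <- length(x); ny <- length(y)
    z <- matrix(eval_surface(surface, rep(x, times = ny), rep(y, each = nx)),
                nx, ny)
    valid <- is.finite(z)
  }
  df <- data.frame(x_um = rep(x, times = length(y)),
                   y_um = rep(y, each = length(x)),
                   z_um = as.vector(z),
                   valid = as.integer(as.vector(valid)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a surface height map from CSV
#'
#' @param path a CSV written by [write_surface_csv()].
#' @return a grid `SurfaceModel`.
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_um", "y_um", "z_um", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("malformed surface CSV: missing column '%s'", miss[1L]),
         call. = FALSE)
  x <- sort(unique(df$x_um)); y <- sort(unique(df$y_um))
  z <- matrix(NA_real_, length(x), length(y))
  v <- matrix(FALSE, length(x), length(y))
  ix <- match(df$x_um, x); iy <- match(df$y_um, y)
  z[cbind(ix, iy)] <- df$z_um
  v[cbind(ix, iy)] <- df$valid > 0
  surface_grid(x, y, z, v)
}

#' Write a pulse plan as CSV
#'
#' @param plan a `PulsePlan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "PulsePlan"))
  df <- data.frame(x_um = plan$x, y_um = plan$y, duration_us = plan$duration,
                   class = plan$class, energy_mJ = plan$energy,
                   order = plan$order)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pulse plan from CSV
#'
#' @param path a CSV written by [write_plan_csv()].
#' @return a `PulsePlan` data.frame.
#' @export
read_plan_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_um", "y_um", "duration_us", "class", "energy_mJ", "order")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("malformed plan CSV: missing column '%s'", miss[1L]),
         call. = FALSE)
  df <- df[order(df$order), , drop = FALSE]
  out <- data.frame(x = df$x_um, y = df$y_um, duration = df$duration_us,
                    class = df$class, energy = df$energy_mJ,
                    order = df$order)
  structure(out, class = c("PulsePlan", "data.frame"))
}

#' Write a rigid transform as JSON
#' @param transform a [rigid_transform()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "RigidTransform"))
  jsonlite::write_json(list(translation_um = transform$t,
                            angles_rad = transform$ang),
                       path, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path a JSON written by [write_transform_json()].
#' @return a `RigidTransform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$translation_um) || is.null(j$angles_rad))
    stop("malformed transform JSON: need translation_um and angles_rad",
         call. = FALSE)
  rigid_transform(j$translation_um, j$angles_rad)
}

#' Export phantom ground truth
#'
#' Writes the two CSV height maps (bone surface and endosteum boundary)
#' plus a JSON parameter record.
#'
#' @param phantom a `Phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "Phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surface_csv(surface_grid(phantom$x, phantom$y, phantom$zb),
                    file.path(dir, "bone_surface.csv"))
  write_surface_csv(surface_grid(phantom$x, phantom$y, phantom$ze),
                    file.path(dir, "endosteum_boundary.csv"))
  pars <- phantom$params
  pars$optics <- lapply(unclass(pars$optics), function(p)
    list(mu = p$mu, backscatter = p$backscatter, speckle = p$speckle))
  jsonlite::write_json(list(params = pars, t_e = phantom$t_e,
                            critical_hit = phantom$critical_hit,
                            seed = phantom$seed),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
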