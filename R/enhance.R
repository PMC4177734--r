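#' Volume history for speckle compounding
#'
#' Bundles co-registered volumes from previous loop rounds with per-round
#' lateral change masks. A mask entry is `TRUE` where the tissue has been
#' ablated since that volume was acquired: those columns carry outdated
#' structure and are excluded from compounding. Masks must be monotone -
#' once a column has changed relative to some round it has also changed
#' relative to every earlier round.
#'
#' @param volumes list of `OctVolume`, ordered oldest first.
#' @param masks list of logical lateral matrices (same lateral grid as the
#'   volumes), parallel to `volumes`.
#' @return an object of class `VolumeHistory`.
#' @export
volume_history <- function(volumes = list(), masks = list()) {
  stopifnot(length(volumes) == length(masks))
  if (length(volumes) > 0) {
    d0 <- dim(volumes[[1]]$I); sp0 <- volumes[[1]]$spacing
    for (i in seq_along(volumes)) {
      v <- volumes[[i]]
      stopifnot(inherits(v, "OctVolume"))
      if (!identical(dim(v$I), d0) || any(abs(v$spacing - sp0) > 1e-9))
        stop("history volumes must share grid dimensions and spacing",
             call. = FALSE)
      m <- masks[[i]]
      stopifnot(is.logical(m), all(dim(m) == d0[1:2]))
    }
    # monotone change masks: older rounds have seen at least as much change
    for (i in seq_len(length(volumes) - 1L)) {
      if (any(masks[[i + 1L]] & !masks[[i]]))
        stop("change masks must be monotone (once changed, stays changed)",
             call. = FALSE)
    }
  }
  structure(list(volumes = volumes, masks = masks), class = "VolumeHistory")
}

#' History compounding
#'
#' Speckle averaging across loop rounds: at each voxel the output is the
#' mean of the current volume and all history volumes whose change mask is
#' `FALSE` at that lateral position. Columns with no usable history pass
#' through unchanged. Because decorrelated speckle realizations average
#' incoherently, the speckle contrast in a static region drops as
#' `1/sqrt(N)` with the number of compounded volumes.
#'
#' @param current the current round's `OctVolume`.
#' @param history a [volume_history()] of co-registered prior rounds.
#' @return an `OctVolume` with the same grid and spacing.
#' @export
history_compound <- function(current, history) {
  stopifnot(inherits(current, "OctVolume"), inherits(history, "VolumeHistory"))
  if (length(history$volumes) == 0L) return(current)
  d <- dim(current$I)
  h0 <- history$volumes[[1]]
  if (!identical(dim(h0$I), d) || any(abs(h0$spacing - current$spacing) > 1e-9))
    stop("history volumes must match the current volume's grid and spacing",
         call. = FALSE)
  nz <- d[3]
  acc <- current$I
  cnt <- array(1, d)
  for (i in seq_along(history$volumes)) {
    use <- !history$masks[[i]]                  # lateral usability
    if (!any(use)) next
    use3 <- array(rep(use, times = nz), d)
    acc <- acc + history$volumes[[i]]$I * use3
    cnt <- cnt + use3
  }
  out <- current
  out$I <- acc / cnt
  out
}

#' Depth attenuation compensation
#'
#' Contrast enhancement for structures deep below the bone surface, using an
#' energy-remaining normalization: per A-scan,
#' `out(w) = I(w)^n / (2 * sum_{w' > w} I(w')^n + floor)`. The denominator is
#' (twice) the signal energy remaining below the sample, so the compensated
#' profile approximates the local scattering coefficient with the cumulative
#' Beer-Lambert decay divided out. The result is rescaled to the input
#' dynamic range.
#'
#' Below the penetration depth the remaining true signal energy vanishes
#' while noise does not, so a naive energy-remaining denominator amplifies
#' the noise floor without bound. The denominator therefore also carries the
#' expected noise energy still to come, estimated per volume from the
#' deepest tenth of the axial samples (which lie beyond the penetration
#' depth in any scan this loop acquires).
#'
#' @param vol an `OctVolume`.
#' @param exponent contrast exponent n > 0 (default 2).
#' @param floor small positive stabilizer added to the denominator, as a
#'   fraction of the input maximum (default 1e-6); guards all-dark A-scans.
#' @param noise_energy expected per-voxel noise contribution to `I^n`;
#'   `NULL` (default) estimates it from the deepest 10% of samples.
#' @return an `OctVolume` with compensated intensities.
#' @export
compensate_attenuation <- function(vol, exponent = 2, floor = 1e-6,
                                   noise_energy = NULL) {
  stopifnot(inherits(vol, "OctVolume"))
  if (!is.numeric(exponent) || exponent <= 0)
    stop("exponent must be positive", call. = FALSE)
  d <- dim(vol$I)
  top <- max(vol$I)
  if (top <= 0) {
    warning("all-zero volume: attenuation compensation returns zeros")
    return(vol)
  }
  nlat <- d[1] * d[2]; nz <- d[3]
  P <- matrix(vol$I^exponent, nlat, nz)
  eps <- floor * top^exponent
  if (is.null(noise_energy)) {
    deep <- seq.int(max(1L, nz - ceiling(nz / 10) + 1L), nz)
    noise_energy <- stats::median(P[, deep])
  }
  # tail sums: T[, k] = sum_{k' > k} P[, k'], plus expected noise energy
  # remaining below sample k
  out <- matrix(0, nlat, nz)
  tail <- numeric(nlat)
  for (k in seq(nz, 1L)) {
    out[, k] <- P[, k] / (2 * (tail + (nz - k) * noise_energy) + eps)
    tail <- tail + P[, k]
  }
  m <- max(out)
  if (m > 0) out <- out * (top / m)
  res <- vol
  res$I <- array(out, d)
  res
}
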