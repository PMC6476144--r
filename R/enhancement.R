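# Normalized differential enhancement:
#   NDE(t) = (SI(t) - SI_PRE) / (DE_MAX)_MUSCLE
# SI_PRE is the per-pixel mean of the pre-contrast frames; the normalizer is
# the maximal post-injection differential enhancement of the muscle-ROI mean
# curve. Dividing by the muscle enhancement makes the curves invariant to
# global intensity scaling and compensates (partially) for differences in the
# effectively administered contrast dose.

#' Per-pixel pre-contrast signal
#'
#' Mean of the first \code{n_baseline} frames, per pixel (or for one pixel).
#'
#' @param series A [dynamic_series()].
#' @param pixel Optional \code{c(y, x)}; when NULL the full SI_PRE map is
#'   returned.
#' @return Scalar or matrix (a.u.).
#' @export
compute_si_pre <- function(series, pixel = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  nb <- series$n_baseline
  base <- series$data[, , seq_len(nb), drop = FALSE]
  map <- if (nb == 1L) base[, , 1] else apply(base, c(1, 2), mean)
  if (is.null(pixel)) return(map)
  map[pixel[1], pixel[2]]
}

#' Maximal differential enhancement of the muscle reference
#'
#' Computes the muscle-ROI mean signal curve m(t), its baseline mean m_pre,
#' and returns \code{max over post-injection frames of (m(t) - m_pre)}. The
#' ROI-mean curve (rather than a per-pixel maximum) is used because a
#' per-pixel max on noisy data is biased upward.
#'
#' @param series A [dynamic_series()].
#' @param muscle An [roi_mask()] with label \code{"muscle"} (or any mask).
#' @return Positive scalar (a.u.).
#' @export
compute_muscle_demax <- function(series, muscle) {
  stopifnot(inherits(series, "dynamic_series"), inherits(muscle, "roi_mask"))
  check_mask_grid(muscle, series)
  nf <- n_frames(series); nb <- series$n_baseline
  m <- vapply(seq_len(nf),
              function(f) mean(series$data[, , f][muscle$mask]), numeric(1))
  demax <- max(m[(nb + 1L):nf] - mean(m[seq_len(nb)]))
  if (demax <= 0)
    stop("muscle region shows no positive enhancement; cannot normalize",
         call. = FALSE)
  demax
}

#' Pixel-wise normalized differential enhancement curves
#'
#' @param series A registered [dynamic_series()].
#' @param node Node [roi_mask()].
#' @param muscle Muscle [roi_mask()].
#' @return Object of class \code{nde_curves}: \code{curves} (n_pixels x
#'   n_frames matrix), \code{coords} (n_pixels x 2 pixel coordinates),
#'   \code{si_pre} (per-pixel baseline signal), \code{de_max_muscle},
#'   \code{frame_interval}, \code{n_baseline}, \code{grid}.
#' @export
compute_nde <- function(series, node, muscle) {
  stopifnot(inherits(series, "dynamic_series"), inherits(node, "roi_mask"))
  check_mask_grid(node, series)
  demax <- compute_muscle_demax(series, muscle)
  nf <- n_frames(series)
  idx <- which(node$mask)
  coords <- which(node$mask, arr.ind = TRUE)
  colnames(coords) <- c("y", "x")
  si_pre <- compute_si_pre(series)[idx]
  npix <- length(idx)
  curves <- matrix(NA_real_, npix, nf)
  for (f in seq_len(nf))
    curves[, f] <- (series$data[, , f][idx] - si_pre) / demax
  structure(
    list(curves = curves, coords = coords, si_pre = si_pre,
         de_max_muscle = demax, frame_interval = series$frame_interval,
         n_baseline = series$n_baseline, grid = dim(series$data)[1:2]),
    class = "nde_curves"
  )
}

#' @export
print.nde_curves <- function(x, ...) {
  cat(sprintf("<nde_curves> %d pixels x %d frames (%d baseline), DEmax_muscle=%.3f\n",
              nrow(x$curves), ncol(x$curves), x$n_baseline, x$de_max_muscle))
  invisible(x)
}

#' Export NDE curves as long-format CSV
#'
#' One row per (pixel, frame) with pixel coordinates and the NDE value.
#'
#' @param nde An [compute_nde()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nde_csv <- function(nde, path) {
  npix <- nrow(nde$curves); nf <- ncol(nde$curves)
  df <- data.frame(pixel = rep(seq_len(npix), times = nf),
                   y = rep(nde$coords[, "y"], times = nf),
                   x = rep(nde$coords[, "x"], times = nf),
                   frame = rep(seq_len(nf), each = npix),
                   nde = as.vector(nde$curves))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the NDE stack as NIfTI
#'
#' Pixels outside the node mask are zero.
#'
#' @param nde An [compute_nde()] result.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_nde_nifti <- function(nde, path) {
  nf <- ncol(nde$curves)
  a <- array(0, dim = c(nde$grid, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(0, nde$grid[1], nde$grid[2])
    fr[nde$coords] <- nde$curves[, f]
    a[, , f] <- fr
  }
  write_series(a, path)
}
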