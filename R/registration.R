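# Translation-only rigid registration of a dynamic series against a
# reference frame: normalized cross-correlation maximized on an integer
# offset grid, refined to subpixel precision by local quadratic
# interpolation of the NCC surface. NCC is insensitive to the global
# intensity changes a contrast bolus produces, which is why it is used
# instead of plain SSD.

#' Translate a 2D image by a (possibly fractional) shift
#'
#' Content at (y, x) moves to (y + dy, x + dx); exposed pixels are filled
#' with \code{fill}. Fractional shifts use bilinear interpolation.
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in pixels (rows, columns).
#' @param fill Fill value for pixels shifted in from outside the grid
#'   (default: the image median).
#' @return Shifted matrix of the same size.
#' @export
shift_image <- function(img, dy, dx, fill = stats::median(img)) {
  h <- nrow(img); w <- ncol(img)
  if (dy == 0 && dx == 0) return(img)
  # source coordinates for each output pixel
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  out <- matrix(fill, h, w)
  at <- function(yi, xi) {
    # clamped lookup with fill outside
    ok_y <- yi >= 1L & yi <= h
    ok_x <- xi >= 1L & xi <= w
    v <- matrix(fill, h, w)
    yi_c <- pmin(pmax(yi, 1L), h)
    xi_c <- pmin(pmax(xi, 1L), w)
    v[] <- img[cbind(rep(yi_c, times = w), rep(xi_c, each = h))]
    v[!ok_y, ] <- fill
    v[, !ok_x] <- fill
    v
  }
  if (all(fy == 0) && all(fx == 0)) return(at(as.integer(y0), as.integer(x0)))
  v00 <- at(as.integer(y0),      as.integer(x0))
  v10 <- at(as.integer(y0) + 1L, as.integer(x0))
  v01 <- at(as.integer(y0),      as.integer(x0) + 1L)
  v11 <- at(as.integer(y0) + 1L, as.integer(x0) + 1L)
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
    (1 - wy) * wx * v01 + wy * wx * v11
}

# Separable Gaussian blur with edge replication. Shift estimation runs on
# blurred copies of frame and reference: a symmetric blur moves no NCC peak,
# but it suppresses the high frequencies where bilinear resampling has a
# frequency-dependent phase error, which would otherwise bias fractional
# shift estimates on sharp-edged structures.
gsmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(m) {
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

# NCC between `frame` and `ref` under candidate shift (dy, dx) of the frame
# content relative to the reference, computed on the overlap region.
ncc_at_shift <- function(frame, ref, dy, dx) {
  h <- nrow(ref); w <- ncol(ref)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  if (length(ys) < 4L || length(xs) < 4L) return(-Inf)
  a <- frame[ys, xs, drop = FALSE]
  b <- ref[ys - dy, xs - dx, drop = FALSE]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(-Inf)
  sum(a * b) / den
}

# quadratic (3-point parabola) sub-grid refinement along one axis
parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)  # not a local max
  off <- 0.5 * (cm - cp) / den
  max(min(off, 0.5), -0.5)
}

# Exact spectral translation (circular): content moves by (+dy, +dx).
# Unlike bilinear resampling it applies no shift-dependent smoothing, so an
# NCC objective built on it is free of the interpolation artifact that
# biases fractional-shift estimates toward half-pixel offsets. Wraparound is
# handled by cropping a border before the metric is computed.
fft_translate <- function(F, dy, dx) {
  h <- nrow(F); w <- ncol(F)
  ky <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[seq_len(h)]
  kx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[seq_len(w)]
  py <- exp(-2i * pi * ky * dy / h)
  px <- exp(-2i * pi * kx * dx / w)
  # zero the Nyquist phase's imaginary part to keep the result real-valued
  if (h %% 2 == 0) py[h / 2 + 1] <- cos(2 * pi * ky[h / 2 + 1] * dy / h)
  if (w %% 2 == 0) px[w / 2 + 1] <- cos(2 * pi * kx[w / 2 + 1] * dx / w)
  Re(stats::fft(F * outer(py, px), inverse = TRUE)) / (h * w)
}

# NCC for a fractional candidate shift: the reference spectrum is translated
# by the candidate and compared with the frame on an interior crop (the
# border is dropped so circular wraparound never enters the metric).
ncc_frac <- function(frame, F_ref, dy, dx, border) {
  rs <- fft_translate(F_ref, dy, dx)
  h <- nrow(rs); w <- ncol(rs)
  ys <- (border + 1L):(h - border); xs <- (border + 1L):(w - border)
  a <- frame[ys, xs]; b <- rs[ys, xs]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(-Inf)
  sum(a * b) / den
}

# estimate the shift of `frame` relative to `ref` (pixels): integer NCC grid
# search, quadratic interpolation for a subpixel start, then Nelder-Mead
# polish of the continuous NCC objective
estimate_shift <- function(frame, ref, max_shift = 5L, refine = TRUE) {
  if (stats::sd(frame) == 0) return(list(shift = c(0, 0), score = NA_real_,
                                         degenerate = TRUE))
  offs <- seq.int(-max_shift, max_shift)
  ncc <- matrix(-Inf, length(offs), length(offs))
  for (i in seq_along(offs)) for (j in seq_along(offs))
    ncc[i, j] <- ncc_at_shift(frame, ref, offs[i], offs[j])
  best <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  dy <- offs[best[1]]; dx <- offs[best[2]]
  sub_dy <- sub_dx <- 0
  if (best[1] > 1L && best[1] < length(offs))
    sub_dy <- parabolic_offset(ncc[best[1] - 1L, best[2]], ncc[best[1], best[2]],
                               ncc[best[1] + 1L, best[2]])
  if (best[2] > 1L && best[2] < length(offs))
    sub_dx <- parabolic_offset(ncc[best[1], best[2] - 1L], ncc[best[1], best[2]],
                               ncc[best[1], best[2] + 1L])
  shift <- c(dy + sub_dy, dx + sub_dx)
  score <- max(ncc)
  if (refine) {
    border <- max_shift + 1L
    if (nrow(ref) > 2L * border + 4L && ncol(ref) > 2L * border + 4L) {
      F_ref <- stats::fft(ref)
      opt <- stats::optim(shift,
                          function(s) -ncc_frac(frame, F_ref, s[1], s[2], border),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 200L))
      cand <- opt$par
      # stay inside the searched range; reject runaway refinements
      if (all(abs(cand - c(dy, dx)) <= 1)) {
        shift <- cand
        score <- -opt$value
      }
    }
  }
  list(shift = shift, score = score, degenerate = FALSE)
}

#' Motion-correct a dynamic series by translation-only registration
#'
#' Each frame is aligned to the reference frame (by default the 2nd
#' post-injection frame, \code{n_baseline + 2}) by maximizing normalized
#' cross-correlation over integer shifts up to \code{max_shift}, refined to
#' subpixel precision, then resampled onto the reference grid. After
#' correction the shift of every corrected frame is re-estimated; these
#' residual shifts quantify unrecovered motion.
#'
#' @param series A [dynamic_series()].
#' @param reference_frame 1-based reference frame index; default
#'   \code{n_baseline + 2}.
#' @param max_shift Integer search radius in pixels.
#' @param motion_threshold Residual-shift magnitude (pixels) above which the
#'   series is flagged as not fully recovered.
#' @param smooth_sigma Optional Gaussian blur (pixels) applied to both images
#'   before the similarity metric is evaluated (the corrected output itself
#'   is always resampled from the unblurred frames); 0 (the default)
#'   disables it. A mild blur can stabilize estimation on very noisy data at
#'   the cost of some sensitivity to enhancement differences.
#' @return List with \code{series} (corrected [dynamic_series()]) and
#'   \code{report} (class \code{registration_report}: per-frame estimated and
#'   residual shifts, NCC scores, and the \code{flagged} boolean).
#' @export
register_series <- function(series, reference_frame = NULL, max_shift = 5L,
                            motion_threshold = 1.0, smooth_sigma = 0) {
  stopifnot(inherits(series, "dynamic_series"))
  nf <- n_frames(series)
  if (is.null(reference_frame)) reference_frame <- series$n_baseline + 2L
  reference_frame <- as.integer(reference_frame)
  if (reference_frame < 1L || reference_frame > nf)
    stop("`reference_frame` out of range", call. = FALSE)
  ref <- series$data[, , reference_frame]
  if (stats::sd(ref) == 0)
    stop("reference frame has zero variance; cannot register", call. = FALSE)
  ref_s <- gsmooth(ref, smooth_sigma)

  shifts <- residuals <- matrix(0, nf, 2,
                                dimnames = list(NULL, c("dy", "dx")))
  scores <- res_scores <- rep(NA_real_, nf)
  corrected <- series$data
  degenerate <- logical(nf)
  for (f in seq_len(nf)) {
    if (f == reference_frame) { scores[f] <- 1; res_scores[f] <- 1; next }
    est <- estimate_shift(gsmooth(series$data[, , f], smooth_sigma), ref_s,
                          max_shift)
    if (est$degenerate) {
      warning(sprintf("frame %d has zero variance; identity shift applied", f),
              call. = FALSE)
      degenerate[f] <- TRUE
      next
    }
    shifts[f, ] <- est$shift
    scores[f] <- est$score
    # spectral resampling: exact translation, no interpolation low-pass, so
    # re-registration of a corrected series is unbiased (wraparound touches
    # only a border strip as wide as the shift)
    if (any(est$shift != 0))
      corrected[, , f] <- fft_translate(stats::fft(series$data[, , f]),
                                        -est$shift[1], -est$shift[2])
    res <- estimate_shift(gsmooth(corrected[, , f], smooth_sigma), ref_s,
                          max_shift)
    residuals[f, ] <- res$shift
    res_scores[f] <- res$score
  }

  report <- structure(
    list(reference_frame = reference_frame, shift = shifts,
         residual_shift = residuals, score = scores,
         residual_score = res_scores, degenerate = degenerate,
         motion_threshold = motion_threshold,
         flagged = any(sqrt(rowSums(residuals^2)) > motion_threshold)),
    class = "registration_report"
  )
  out <- dynamic_series(corrected, frame_interval = series$frame_interval,
                        n_baseline = series$n_baseline)
  list(series = out, report = report)
}

#' Flag unrecoverable residual motion
#'
#' @param report A \code{registration_report} from [register_series()].
#' @param threshold Residual-shift magnitude in pixels; any frame whose
#'   post-correction residual exceeds it flags the series (such nodes are
#'   excluded from analysis downstream).
#' @return Logical scalar.
#' @export
flag_residual_motion <- function(report, threshold = report$motion_threshold) {
  stopifnot(inherits(report, "registration_report"))
  any(sqrt(rowSums(report$residual_shift^2)) > threshold)
}

#' @export
print.registration_report <- function(x, ...) {
  mag <- sqrt(rowSums(x$shift^2))
  res <- sqrt(rowSums(x$residual_shift^2))
  cat(sprintf("<registration_report> %d frames, reference %d\n",
              nrow(x$shift), x$reference_frame))
  cat(sprintf("  estimated shift: max %.2f px; residual: max %.3f px; flagged: %s\n",
              max(mag), max(res), x$flagged))
  invisible(x)
}

#' Write a registration report as CSV
#' @param report A \code{registration_report}.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registration_report <- function(report, path) {
  df <- data.frame(frame = seq_len(nrow(report$shift)),
                   shift_dy = report$shift[, 1], shift_dx = report$shift[, 2],
                   residual_dy = report$residual_shift[, 1],
                   residual_dx = report$residual_shift[, 2],
                   ncc = report$score, residual_ncc = report$residual_score)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
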