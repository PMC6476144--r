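#' Kinetic parameters for a phantom compartment
#'
#' Parameterizes the uptake-then-washout enhancement shape of one tissue
#' compartment as the product of a mono-exponential uptake and a
#' mono-exponential washout:
#' \deqn{E(t) = A \, (1 - e^{-k_{in}\Delta t}) \, e^{-k_{out}\Delta t},}
#' with \eqn{\Delta t = (f - f_{onset}) \cdot} frame interval in minutes and
#' \eqn{E = 0} before the onset frame.
#'
#' @param amplitude Peak-scale enhancement in baseline-relative arbitrary
#'   units (the noiseless signal is \code{baseline_signal * (1 + E(t))}).
#' @param k_in Uptake rate (1/min), strictly positive.
#' @param k_out Washout rate (1/min), non-negative.
#' @param onset_index First post-injection frame (1-based integer).
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(amplitude, k_in, k_out, onset_index = 4L) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(k_in) || length(k_in) != 1L || k_in <= 0)
    stop("`k_in` must be a single positive number", call. = FALSE)
  if (!is.numeric(k_out) || length(k_out) != 1L || k_out < 0)
    stop("`k_out` must be a single non-negative number", call. = FALSE)
  onset_index <- as.integer(onset_index)
  if (is.na(onset_index) || onset_index < 1L)
    stop("`onset_index` must be an integer >= 1", call. = FALSE)
  structure(
    list(amplitude = amplitude, k_in = k_in, k_out = k_out,
         onset_index = onset_index),
    class = "kinetic_params"
  )
}

#' Evaluate a compartment enhancement curve on the frame grid
#'
#' @param k A [kinetic_params()] object.
#' @param n_frames Number of frames.
#' @param frame_interval Minutes per frame.
#' @return Numeric vector of length \code{n_frames}; exactly zero before the
#'   onset frame.
#' @export
enhancement_curve <- function(k, n_frames, frame_interval) {
  if (!inherits(k, "kinetic_params")) k <- do.call(kinetic_params, as.list(k))
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L, frame_interval > 0)
  frames <- seq_len(n_frames)
  dt <- (frames - k$onset_index) * frame_interval
  y <- ifelse(dt < 0, 0,
              k$amplitude * (1 - exp(-k$k_in * dt)) * exp(-k$k_out * dt))
  if (any(!is.finite(y))) stop("enhancement curve is not finite", call. = FALSE)
  y
}

#' Specification of a two-compartment dynamic phantom
#'
#' Describes a single-slice dynamic series containing an elliptical lymph-node
#' stand-in with two concentric compartments (inner: higher, faster uptake and
#' steeper washout) plus a rectangular muscle reference strip, with additive
#' noise and optional per-frame rigid translation.
#'
#' @param grid Image size \code{c(height, width)} in pixels.
#' @param node_center Ellipse center \code{c(y, x)} in pixels.
#' @param node_axes Ellipse semi-axes \code{c(ay, ax)} in pixels.
#' @param inner_fraction Fraction of node area assigned to the concentric
#'   inner compartment, in (0, 1).
#' @param muscle_region Rectangle \code{c(y0, y1, x0, x1)} (inclusive pixel
#'   bounds) for the muscle strip; must not overlap the node.
#' @param kinetics_inner,kinetics_outer,kinetics_muscle [kinetic_params()]
#'   for each compartment.
#' @param baseline_signal Pre-contrast signal level (a.u.).
#' @param texture_amp Amplitude (a.u.) of a static, smooth anatomical
#'   background pattern added to every frame. Being constant in time it
#'   cancels out of every differential-enhancement quantity, but it gives
#'   pre-contrast frames the spatial structure real anatomy has, which the
#'   intensity-based registration needs. Set 0 to disable.
#' @param anatomy_contrast Static additive offset (a.u.) of the node tissue
#'   over the background (the muscle strip gets minus half of it), making
#'   both structures visible before contrast arrives, as on a T1-weighted
#'   image. Constant in time, so it also cancels from every differential
#'   quantity. Set 0 to disable.
#' @param noise_sigma Noise scale (a.u.); 0 for a noiseless phantom.
#' @param noise_model \code{"gaussian"} (additive) or \code{"rician"}
#'   (magnitude of complex Gaussian noise, as in magnitude MRI).
#' @param n_frames Number of scans (default 70).
#' @param n_baseline Pre-contrast scans (default 3; the bolus arrives between
#'   scans 3 and 4).
#' @param frame_interval Minutes per scan (default 46/70: a 70-scan series
#'   acquired over about 46 minutes).
#' @param motion_schedule Optional \code{n_frames x 2} matrix of per-frame
#'   rigid shifts \code{(dy, dx)} in pixels (may be fractional), or NULL.
#' @param seed RNG seed used for the noise draw.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid = c(64L, 64L),
                         node_center = c(28, 32),
                         node_axes = c(12, 10),
                         inner_fraction = 0.3,
                         muscle_region = c(52, 60, 16, 48),
                         kinetics_inner = kinetic_params(2.0, 1.5, 0.05),
                         kinetics_outer = kinetic_params(1.0, 0.5, 0.02),
                         kinetics_muscle = kinetic_params(0.4, 0.8, 0.03),
                         baseline_signal = 100,
                         texture_amp = 10,
                         anatomy_contrast = 60,
                         noise_sigma = 5,
                         noise_model = c("gaussian", "rician"),
                         n_frames = 70L,
                         n_baseline = 3L,
                         frame_interval = 46 / 70,
                         motion_schedule = NULL,
                         seed = 0L) {
  noise_model <- match.arg(noise_model)
  n_frames <- as.integer(n_frames); n_baseline <- as.integer(n_baseline)
  if (n_baseline >= n_frames)
    stop("`n_baseline` must be smaller than `n_frames`", call. = FALSE)
  if (n_frames < n_baseline + 2L)
    stop("series must have at least `n_baseline` + 2 frames", call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  if (inner_fraction <= 0 || inner_fraction >= 1)
    stop("`inner_fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (texture_amp < 0) stop("`texture_amp` must be >= 0", call. = FALSE)
  if (anatomy_contrast < 0)
    stop("`anatomy_contrast` must be >= 0", call. = FALSE)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 8L),
            length(node_center) == 2L, length(node_axes) == 2L,
            all(node_axes > 0), length(muscle_region) == 4L)
  if (muscle_region[1] < 1 || muscle_region[2] > grid[1] ||
      muscle_region[3] < 1 || muscle_region[4] > grid[2] ||
      muscle_region[1] > muscle_region[2] || muscle_region[3] > muscle_region[4])
    stop("`muscle_region` must be a valid rectangle inside the grid",
         call. = FALSE)
  if (!is.null(motion_schedule)) {
    motion_schedule <- as.matrix(motion_schedule)
    if (nrow(motion_schedule) != n_frames || ncol(motion_schedule) != 2L)
      stop("`motion_schedule` must be an n_frames x 2 matrix", call. = FALSE)
  }
  for (k in list(kinetics_inner, kinetics_outer, kinetics_muscle))
    if (!inherits(k, "kinetic_params"))
      stop("kinetics must be `kinetic_params` objects", call. = FALSE)

  spec <- structure(
    list(grid = grid, node_center = node_center, node_axes = node_axes,
         inner_fraction = inner_fraction, muscle_region = muscle_region,
         kinetics_inner = kinetics_inner, kinetics_outer = kinetics_outer,
         kinetics_muscle = kinetics_muscle,
         baseline_signal = baseline_signal, texture_amp = texture_amp,
         anatomy_contrast = anatomy_contrast, noise_sigma = noise_sigma,
         noise_model = noise_model, n_frames = n_frames,
         n_baseline = n_baseline, frame_interval = frame_interval,
         motion_schedule = motion_schedule, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  msk <- phantom_masks(spec)
  if (any(msk$node_mask & msk$muscle_mask))
    stop("node and muscle regions overlap", call. = FALSE)
  if (!any(msk$node_mask) || !any(msk$inner_mask) || !any(msk$outer_mask))
    stop("node geometry yields an empty compartment", call. = FALSE)
  spec
}

# static smooth background pattern (deterministic, seed-free); constant in
# time, so it cancels from SI(t) - SI_PRE and from the muscle DEmax
phantom_texture <- function(spec, masks = phantom_masks(spec)) {
  h <- spec$grid[1]; w <- spec$grid[2]
  tex <- matrix(0, h, w)
  if (spec$texture_amp > 0) {
    yy <- matrix(seq_len(h) / h, h, w)
    xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
    tex <- spec$texture_amp * (sin(2 * pi * 3 * yy) * cos(2 * pi * 2 * xx) +
                                 0.5 * sin(2 * pi * (yy + 2 * xx)))
  }
  if (spec$anatomy_contrast > 0) {
    tex <- tex + spec$anatomy_contrast * masks$node_mask -
      0.5 * spec$anatomy_contrast * masks$muscle_mask
  }
  tex
}

# compartment masks implied by the geometry (deterministic, seed-free)
phantom_masks <- function(spec) {
  h <- spec$grid[1]; w <- spec$grid[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  r2 <- ((yy - spec$node_center[1]) / spec$node_axes[1])^2 +
        ((xx - spec$node_center[2]) / spec$node_axes[2])^2
  node <- r2 <= 1
  # concentric ellipse scaled by sqrt(inner_fraction) has the target area share
  inner <- r2 <= spec$inner_fraction
  outer <- node & !inner
  muscle <- matrix(FALSE, h, w)
  mr <- spec$muscle_region
  muscle[mr[1]:mr[2], mr[3]:mr[4]] <- TRUE
  list(node_mask = node, inner_mask = inner, outer_mask = outer,
       muscle_mask = muscle)
}

#' Generate a synthetic dynamic series with ground truth
#'
#' Synthesizes the noiseless signal \code{baseline_signal * (1 + E_c(t))} per
#' compartment, applies the per-frame motion schedule (if any) by bilinear
#' resampling, then adds noise drawn with the spec's seed. Identical spec and
#' seed give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with \code{series} (a [dynamic_series()]) and \code{truth}
#'   (class \code{phantom_truth}: compartment masks, noiseless compartment
#'   curves on both the raw-enhancement and the NDE scale, applied shifts).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  msk <- phantom_masks(spec)
  h <- spec$grid[1]; w <- spec$grid[2]; nf <- spec$n_frames

  curves <- rbind(
    inner  = enhancement_curve(spec$kinetics_inner,  nf, spec$frame_interval),
    outer  = enhancement_curve(spec$kinetics_outer,  nf, spec$frame_interval),
    muscle = enhancement_curve(spec$kinetics_muscle, nf, spec$frame_interval)
  )

  base <- spec$baseline_signal
  texture <- phantom_texture(spec, msk)
  data <- array(base, dim = c(h, w, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(base, h, w)
    fr[msk$inner_mask]  <- base * (1 + curves["inner", f])
    fr[msk$outer_mask]  <- base * (1 + curves["outer", f])
    fr[msk$muscle_mask] <- base * (1 + curves["muscle", f])
    data[, , f] <- fr + texture
  }

  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  if (!is.null(spec$motion_schedule)) {
    shifts[] <- spec$motion_schedule
    for (f in seq_len(nf)) {
      if (any(shifts[f, ] != 0))
        data[, , f] <- shift_image(data[, , f], shifts[f, 1], shifts[f, 2],
                                   fill = base)
    }
  }

  if (spec$noise_sigma > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    if (spec$noise_model == "gaussian") {
      data <- data + array(stats::rnorm(length(data), 0, spec$noise_sigma),
                           dim = dim(data))
    } else {
      re <- data + array(stats::rnorm(length(data), 0, spec$noise_sigma),
                         dim = dim(data))
      im <- array(stats::rnorm(length(data), 0, spec$noise_sigma),
                  dim = dim(data))
      data <- sqrt(re^2 + im^2)
    }
  }

  series <- dynamic_series(data, frame_interval = spec$frame_interval,
                           n_baseline = spec$n_baseline)

  # NDE-scale truth: (SI - SI_pre)/DEmax_muscle = base*E(t) / (base*max Em)
  demax_scale <- max(curves["muscle", (spec$n_baseline + 1L):nf])
  if (demax_scale <= 0)
    stop("muscle kinetics produce no enhancement; cannot define NDE truth",
         call. = FALSE)
  truth <- structure(
    list(inner_mask = msk$inner_mask, outer_mask = msk$outer_mask,
         node_mask = msk$node_mask, muscle_mask = msk$muscle_mask,
         true_curves = curves / demax_scale,
         true_enhancement = curves,
         applied_shifts = shifts),
    class = "phantom_truth"
  )
  list(series = series, truth = truth)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d grid, %d frames (%d baseline), dt=%.3f min\n",
              x$grid[1], x$grid[2], x$n_frames, x$n_baseline, x$frame_interval))
  cat(sprintf("  node: center (%g,%g), axes (%g,%g), inner fraction %.2f\n",
              x$node_center[1], x$node_center[2], x$node_axes[1],
              x$node_axes[2], x$inner_fraction))
  cat(sprintf("  noise: %s sigma=%g, seed=%d, motion=%s\n", x$noise_model,
              x$noise_sigma, x$seed,
              if (is.null(x$motion_schedule)) "none" else "scheduled"))
  invisible(x)
}

#' Serialize / restore a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns the restored [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  for (nm in c("kinetics_inner", "kinetics_outer", "kinetics_muscle"))
    x[[nm]] <- unclass(x[[nm]])
  if (!is.null(x$motion_schedule))
    x$motion_schedule <- as.vector(t(x$motion_schedule))
  # emit numerics at full double precision so the spec round-trips exactly
  yaml::write_yaml(x, path, handlers = list(
    numeric = function(v) sprintf("%.17g", v)))
  invisible(path)
}

# undo the full-precision string encoding of numeric fields
restore_numeric <- function(x) {
  if (is.list(x)) return(lapply(x, restore_numeric))
  if (is.character(x)) {
    v <- suppressWarnings(as.numeric(x))
    if (!anyNA(v)) return(v)
  }
  x
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- restore_numeric(yaml::read_yaml(path))
  for (nm in c("kinetics_inner", "kinetics_outer", "kinetics_muscle"))
    x[[nm]] <- do.call(kinetic_params, x[[nm]])
  if (!is.null(x$motion_schedule))
    x$motion_schedule <- matrix(unlist(x$motion_schedule),
                                ncol = 2, byrow = TRUE)
  x$motion_rows <- NULL
  do.call(phantom_spec, x)
}
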