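# Semiquantitative parameters of cluster-averaged NDE curves: AUC, wash-in
# rate and wash-out rate. Wash-in and wash-out are normalized by the node's
# maximal enhancement (the maximum of the node-ROI mean NDE curve), shared
# by both clusters of a node; AUC is left unnormalized.

frame_times <- function(n, frame_interval) (seq_len(n) - 1) * frame_interval

#' Area under the NDE curve
#'
#' Trapezoidal integral over the post-injection window, from the last
#' baseline frame through the final frame, with time in minutes.
#'
#' @param curve Numeric NDE vector.
#' @param frame_interval Minutes per frame.
#' @param n_baseline Number of pre-contrast frames (integration starts at
#'   frame \code{n_baseline}).
#' @return AUC in a.u. (a.u. x min).
#' @export
auc <- function(curve, frame_interval, n_baseline = 1L) {
  stopifnot(all(is.finite(curve)), frame_interval > 0)
  n <- length(curve)
  i0 <- max(1L, as.integer(n_baseline))
  if (i0 >= n) stop("no post-injection frames to integrate", call. = FALSE)
  y <- curve[i0:n]
  sum((y[-1] + y[-length(y)]) / 2) * frame_interval
}

#' Wash-in rate
#'
#' Maximum slope of the NDE curve between two consecutive time points within
#' the window from the last baseline frame to the frame of maximal
#' enhancement, divided by the node's maximal enhancement.
#'
#' @param curve Numeric NDE vector.
#' @param n_baseline Number of pre-contrast frames.
#' @param frame_interval Minutes per frame.
#' @param normalizer Node-level maximal enhancement (a.u.); defaults to the
#'   curve's own maximum. Must be positive.
#' @return Wash-in rate in a.u./min (normalized).
#' @export
wash_in <- function(curve, n_baseline, frame_interval,
                    normalizer = max(curve)) {
  stopifnot(all(is.finite(curve)), frame_interval > 0)
  if (normalizer <= 0) stop("`normalizer` must be positive", call. = FALSE)
  i0 <- max(1L, as.integer(n_baseline))
  imax <- which.max(curve)
  if (imax < i0)
    stop("maximal enhancement precedes the last baseline frame", call. = FALSE)
  if (imax == i0) {
    warning("curve does not rise after baseline; wash-in set to 0",
            call. = FALSE)
    return(0)
  }
  slopes <- diff(curve[i0:imax]) / frame_interval
  max(slopes) / normalizer
}

#' Wash-out rate
#'
#' Ordinary least-squares slope of the curve tail (the last
#' \code{washout_frames} frames; 40 by default, i.e. scans 31-70 of a
#' 70-scan series), with time in minutes, divided by the node's maximal
#' enhancement. Negative when contrast clears.
#'
#' @param curve Numeric NDE vector.
#' @param frame_interval Minutes per frame.
#' @param normalizer Node-level maximal enhancement (a.u.); defaults to the
#'   curve's own maximum. Must be positive.
#' @param washout_frames Length of the fitted tail window.
#' @return Wash-out rate in a.u./min (normalized).
#' @export
wash_out <- function(curve, frame_interval, normalizer = max(curve),
                     washout_frames = 40L) {
  stopifnot(all(is.finite(curve)), frame_interval > 0)
  if (normalizer <= 0) stop("`normalizer` must be positive", call. = FALSE)
  n <- length(curve)
  w <- as.integer(washout_frames)
  if (w < 2L) stop("wash-out window needs at least 2 frames", call. = FALSE)
  if (n < w)
    stop(sprintf("curve has %d frames but the wash-out window needs %d; %s",
                 n, w, "shorten `washout_frames` explicitly"), call. = FALSE)
  idx <- (n - w + 1L):n
  t <- frame_times(n, frame_interval)[idx]
  y <- curve[idx]
  slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  slope / normalizer
}

#' Extract all semiquantitative parameters for a segmented node
#'
#' One row per cluster with AUC, wash-in, wash-out and volume percentage.
#' Both clusters share the node-level normalizer: the maximum of the
#' node-mean NDE curve.
#'
#' @param result A role-assigned [kmeans_segment()] result.
#' @param node_mean_curve Node-ROI mean NDE curve (defaults to the
#'   volume-weighted mean of the cluster curves, which equals the mean over
#'   all node pixels).
#' @param frame_interval,n_baseline Timing metadata; default to the values
#'   carried by the cluster result.
#' @param washout_frames Tail-window length for [wash_out()].
#' @param node_id,agent Optional identifiers copied into the rows.
#' @return A \code{param_table} data.frame (one row per cluster) with the
#'   normalizer in attribute \code{"max_enhancement_node"}.
#' @export
extract_all <- function(result, node_mean_curve = NULL,
                        frame_interval = result$frame_interval,
                        n_baseline = result$n_baseline,
                        washout_frames = 40L,
                        node_id = 1L, agent = "Gd-DTPA") {
  stopifnot(inherits(result, "cluster_result"))
  cl <- rownames(result$cluster_curves)
  if (!all(c("inner", "outer") %in% cl))
    stop("cluster roles must be assigned before parameter extraction",
         call. = FALSE)
  if (is.null(frame_interval) || is.null(n_baseline))
    stop("frame_interval and n_baseline are required", call. = FALSE)
  if (is.null(node_mean_curve))
    node_mean_curve <- as.vector(result$volume_pct[cl] %*%
                                   result$cluster_curves) / 100
  normalizer <- max(node_mean_curve)
  if (normalizer <= 0)
    stop("node-mean curve never enhances; normalizer undefined", call. = FALSE)

  rows <- do.call(rbind, lapply(cl, function(c1) {
    crv <- result$cluster_curves[c1, ]
    data.frame(node = node_id, agent = agent, cluster = c1,
               auc = auc(crv, frame_interval, n_baseline),
               wash_in = wash_in(crv, n_baseline, frame_interval, normalizer),
               wash_out = wash_out(crv, frame_interval, normalizer,
                                   washout_frames),
               volume_pct = unname(result$volume_pct[c1]),
               stringsAsFactors = FALSE)
  }))
  attr(rows, "max_enhancement_node") <- normalizer
  class(rows) <- c("param_table", "data.frame")
  rows
}
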