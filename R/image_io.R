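#' Dynamic (2D + time) signal-intensity series
#'
#' @param data Numeric array, height x width x n_frames.
#' @param frame_interval Minutes per frame.
#' @param n_baseline Number of pre-contrast frames; the bolus arrives between
#'   frames \code{n_baseline} and \code{n_baseline + 1} (1-based convention).
#' @return Object of class \code{dynamic_series}.
#' @export
dynamic_series <- function(data, frame_interval, n_baseline) {
  data <- drop_singletons(data)
  if (length(dim(data)) != 3L)
    stop("series data must be a height x width x time array", call. = FALSE)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("`n_baseline` must be >= 1", call. = FALSE)
  if (dim(data)[3] < n_baseline + 2L)
    stop("series too short: need at least `n_baseline` + 2 frames",
         call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  structure(
    list(data = data, frame_interval = frame_interval,
         n_baseline = n_baseline,
         injection_between = c(n_baseline, n_baseline + 1L)),
    class = "dynamic_series"
  )
}

n_frames <- function(series) dim(series$data)[3]

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %dx%d pixels, %d frames (%d baseline), dt=%.3f min\n",
              d[1], d[2], d[3], x$n_baseline, x$frame_interval))
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param mask Logical (or 0/1) matrix on the series grid.
#' @param label \code{"node"} or \code{"muscle"}.
#' @return Object of class \code{roi_mask}.
#' @export
roi_mask <- function(mask, label = c("node", "muscle")) {
  label <- match.arg(label)
  mask <- drop_singletons(mask)
  if (length(dim(mask)) != 2L)
    stop("mask must be a 2D image", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

check_mask_grid <- function(mask, series) {
  if (!all(dim(mask$mask) == dim(series$data)[1:2]))
    stop(sprintf("%s mask grid (%s) does not match series grid (%s)",
                 mask$label, paste(dim(mask$mask), collapse = "x"),
                 paste(dim(series$data)[1:2], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

drop_singletons <- function(a) {
  d <- dim(a)
  if (is.null(d)) return(a)
  keep <- d != 1L
  if (all(keep)) return(a)
  array(a, dim = if (any(keep)) d[keep] else 1L)
}

#' Read a dynamic series from a NIfTI file
#'
#' The on-disk volume may carry singleton axes (e.g. a 4D file with a
#' singleton slice axis); these are squeezed so the result is height x width
#' x time.
#'
#' @param path NIfTI file path.
#' @param frame_interval Minutes per frame.
#' @param n_baseline Number of pre-contrast frames.
#' @return A [dynamic_series()].
#' @export
load_series <- function(path, frame_interval, n_baseline) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- drop_singletons(as.array(RNifti::readNifti(path)))
  if (length(dim(a)) != 3L)
    stop("expected a 2D+time volume, got ", length(dim(a)), " non-singleton axes",
         call. = FALSE)
  dynamic_series(a, frame_interval = frame_interval, n_baseline = n_baseline)
}

#' Write a dynamic series (or plain array) as NIfTI
#'
#' @param series A [dynamic_series()] or numeric array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  a <- if (inherits(series, "dynamic_series")) series$data else series
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' Read / write a binary ROI mask as NIfTI
#'
#' @param path NIfTI file path.
#' @param label Mask label, \code{"node"} or \code{"muscle"}.
#' @return `load_mask` returns an [roi_mask()]; `write_mask` returns `path`.
#' @export
load_mask <- function(path, label = c("node", "muscle")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- drop_singletons(as.array(RNifti::readNifti(path)))
  roi_mask(a, label = match.arg(label))
}

#' @rdname load_mask
#' @param mask An [roi_mask()] or logical matrix.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(m), dim = dim(m))), path)
  invisible(path)
}

#' Load a node-parameter table (Table-1 shaped CSV)
#'
#' Expects the long format: one row per (node, cluster) with columns
#' \code{node, agent, cluster, auc, wash_in, wash_out, volume_pct}; optional
#' \code{*_sd} columns carry the per-node standard-deviation annotations and
#' are ignored by the statistics. Every node must have exactly one
#' \code{inner} and one \code{outer} row, one agent, and cluster volume
#' percentages summing to 100 (+/- 0.5).
#'
#' @param path CSV path; the default loads the packaged transcription of the
#'   15-node reference table (9 Gd-DTPA, 6 Gd-BOPTA nodes).
#' @return A \code{data.frame} of class \code{param_table}.
#' @export
load_param_table <- function(path = node_param_table_path()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("node", "agent", "cluster", "auc", "wash_in", "wash_out",
           "volume_pct")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("parameter table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_param_table(tab)
}

#' @rdname load_param_table
#' @export
node_param_table_path <- function() {
  system.file("extdata", "table1_node_params.csv", package = "nodedce",
              mustWork = TRUE)
}

validate_param_table <- function(tab) {
  agents <- c("Gd-DTPA", "Gd-BOPTA")
  if (!all(tab$agent %in% agents))
    stop("unknown agent label(s): ",
         paste(setdiff(unique(tab$agent), agents), collapse = ", "),
         call. = FALSE)
  if (!all(tab$cluster %in% c("inner", "outer")))
    stop("cluster labels must be 'inner' or 'outer'", call. = FALSE)
  for (nd in unique(tab$node)) {
    rows <- tab[tab$node == nd, ]
    if (nrow(rows) != 2L || !setequal(rows$cluster, c("inner", "outer")))
      stop(sprintf("node %s must have exactly one inner and one outer row", nd),
           call. = FALSE)
    if (length(unique(rows$agent)) != 1L)
      stop(sprintf("node %s has inconsistent agent labels", nd), call. = FALSE)
    vsum <- sum(rows$volume_pct)
    if (abs(vsum - 100) > 0.5)
      stop(sprintf("node %s cluster volumes sum to %.2f, not 100", nd, vsum),
           call. = FALSE)
  }
  class(tab) <- c("param_table", "data.frame")
  tab
}

#' Per-node directional summary of a parameter table
#'
#' Counts, over nodes, how the inner cluster compares with the outer one:
#' higher AUC, higher wash-in, wash-out at most the outer's (steeper or equal
#' decay), and smaller volume share.
#'
#' @param tab A [load_param_table()] result.
#' @return Named list of counts plus \code{n_nodes}.
#' @export
param_table_directions <- function(tab) {
  nodes <- unique(tab$node)
  pick <- function(nd, cl, col) tab[tab$node == nd & tab$cluster == cl, col]
  counts <- list(n_nodes = length(nodes),
                 auc_inner_gt_outer = 0L, wash_in_inner_gt_outer = 0L,
                 wash_out_inner_le_outer = 0L, volume_outer_gt_inner = 0L)
  for (nd in nodes) {
    if (pick(nd, "inner", "auc") > pick(nd, "outer", "auc"))
      counts$auc_inner_gt_outer <- counts$auc_inner_gt_outer + 1L
    if (pick(nd, "inner", "wash_in") > pick(nd, "outer", "wash_in"))
      counts$wash_in_inner_gt_outer <- counts$wash_in_inner_gt_outer + 1L
    if (pick(nd, "inner", "wash_out") <= pick(nd, "outer", "wash_out"))
      counts$wash_out_inner_le_outer <- counts$wash_out_inner_le_outer + 1L
    if (pick(nd, "outer", "volume_pct") > pick(nd, "inner", "volume_pct"))
      counts$volume_outer_gt_inner <- counts$volume_outer_gt_inner + 1L
  }
  counts
}
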