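# PCA variance screening and k-means segmentation of per-pixel NDE curves.
# Curves are clustered as raw NDE vectors (no further standardization): the
# muscle normalization already puts all pixels on one scale, and the
# enhancement magnitude is exactly the signal the segmentation should use.
# No spatial term enters the objective (neighborhood connectivity is not
# considered).

curves_matrix <- function(curves) {
  if (inherits(curves, "nde_curves")) curves$curves
  else as.matrix(curves)
}

#' PCA variance screen of an NDE curve set
#'
#' Principal component analysis of the centered curve matrix (pixels x
#' frames), reporting the percentage of variance each component explains.
#' Used to check that a small number of enhancement patterns (two, in normal
#' nodes) accounts for nearly all the variance, supporting k = 2 clusters.
#'
#' @param curves An [compute_nde()] result or a numeric matrix (one curve per
#'   row).
#' @return Object of class \code{pca_screen} with \code{explained_pct}
#'   (descending), \code{cumulative_pct} and \code{sdev}.
#' @export
pca_screen <- function(curves) {
  m <- curves_matrix(curves)
  if (nrow(m) < 2L)
    stop("PCA screen needs at least 2 curves", call. = FALSE)
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  tot <- sum(v)
  if (tot <= .Machine$double.eps * max(1, max(abs(m))))
    stop("curve set has zero variance; PCA screen undefined", call. = FALSE)
  pct <- 100 * v / tot
  structure(list(explained_pct = pct, cumulative_pct = cumsum(pct),
                 sdev = p$sdev),
            class = "pca_screen")
}

#' Number of components needed to reach a cumulative-variance threshold
#'
#' @param screen A [pca_screen()] result.
#' @param threshold_pct Cumulative explained-variance threshold in percent.
#' @return Integer count of leading components.
#' @export
n_components_for <- function(screen, threshold_pct = 90) {
  stopifnot(inherits(screen, "pca_screen"))
  which(screen$cumulative_pct >= threshold_pct - 1e-9)[1]
}

#' @export
print.pca_screen <- function(x, ...) {
  k <- min(5L, length(x$explained_pct))
  cat("<pca_screen> explained variance (%):",
      paste(sprintf("%.2f", x$explained_pct[seq_len(k)]), collapse = ", "),
      if (length(x$explained_pct) > k) "..." else "", "\n")
  cat(sprintf("  first two components: %.2f%% cumulative\n",
              x$cumulative_pct[min(2L, length(x$cumulative_pct))]))
  invisible(x)
}

#' Write a PCA screen as CSV
#' @param screen A [pca_screen()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pca_screen <- function(screen, path) {
  utils::write.csv(data.frame(component = seq_along(screen$explained_pct),
                              explained_pct = screen$explained_pct,
                              cumulative_pct = screen$cumulative_pct),
                   path, row.names = FALSE)
  invisible(path)
}

# k-means++ seeding (Arthur & Vassilvitskii): spreads initial centers by
# sampling points with probability proportional to squared distance from the
# nearest center chosen so far.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- m[sample.int(n, 1L), , drop = FALSE]
  d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
  while (nrow(centers) < k) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers <- rbind(centers, m[idx, , drop = FALSE])
    nd2 <- rowSums((m - matrix(m[idx, ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  centers
}

#' Segment node pixels by k-means on their NDE curves
#'
#' Full curves are the feature vectors; the objective is within-cluster
#' squared Euclidean distance, minimized by Lloyd iterations from k-means++
#' starts, keeping the best of \code{n_init} restarts. Deterministic for a
#' fixed \code{seed}. For \code{k = 2} (the default) clusters are labeled
#' \code{"inner"}/\code{"outer"} by [assign_cluster_roles()] unless
#' \code{assign_roles = FALSE}.
#'
#' @param curves An [compute_nde()] result (or matrix of curves, one per row).
#' @param k Number of clusters (default 2, the minimum able to expose
#'   heterogeneity).
#' @param seed RNG seed for the restarts.
#' @param n_init Number of k-means++ restarts.
#' @param assign_roles Assign inner/outer roles when \code{k == 2}.
#' @return Object of class \code{cluster_result}: \code{labels} (per-pixel
#'   cluster names), \code{label_map} (image, NA outside the node),
#'   \code{cluster_curves} (k x n_frames, row names = cluster names),
#'   \code{volume_pct}, \code{inertia}, plus curve metadata when available.
#' @export
kmeans_segment <- function(curves, k = 2L, seed = 0L, n_init = 20L,
                           assign_roles = TRUE) {
  m <- curves_matrix(curves)
  k <- as.integer(k)
  if (k < 1L || k > nrow(m))
    stop("`k` must be between 1 and the number of curves", call. = FALSE)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  best <- NULL
  for (i in seq_len(n_init)) {
    cen <- kmeanspp_centers(m, k)
    if (anyDuplicated(cen)) next  # degenerate draw (duplicated points)
    fit <- suppressWarnings(
      stats::kmeans(m, centers = cen, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    # fewer than k distinct curves: any assignment attains zero inertia
    best <- list(cluster = rep(seq_len(k), length.out = nrow(m)),
                 tot.withinss = 0)
  }

  labels <- as.character(best$cluster)
  curve_means <- t(vapply(sort(unique(labels)), function(cl)
    colMeans(m[labels == cl, , drop = FALSE]), numeric(ncol(m))))
  vol <- 100 * table(factor(labels, levels = rownames(curve_means))) / nrow(m)

  res <- structure(
    list(labels = labels,
         cluster_curves = curve_means,
         volume_pct = stats::setNames(as.numeric(vol), names(vol)),
         inertia = best$tot.withinss,
         k = k, seed = as.integer(seed), n_init = as.integer(n_init),
         tie_break = NA_character_,
         coords = if (inherits(curves, "nde_curves")) curves$coords else NULL,
         grid = if (inherits(curves, "nde_curves")) curves$grid else NULL,
         frame_interval = if (inherits(curves, "nde_curves"))
           curves$frame_interval else NULL,
         n_baseline = if (inherits(curves, "nde_curves"))
           curves$n_baseline else NULL),
    class = "cluster_result"
  )
  res$label_map <- build_label_map(res)
  if (assign_roles && k == 2L) res <- assign_cluster_roles(res)
  res
}

build_label_map <- function(res) {
  if (is.null(res$coords) || is.null(res$grid)) return(NULL)
  map <- matrix(NA_character_, res$grid[1], res$grid[2])
  map[res$coords] <- res$labels
  map
}

#' Name the two clusters by enhancement magnitude
#'
#' The cluster whose cluster-averaged curve has the larger AUC is labeled
#' \code{"inner"} (the medulla-adjacent center of a normal node takes up more
#' contrast), the other \code{"outer"}. On an exact AUC tie the cluster with
#' the larger peak value wins; the tie-break used is recorded in
#' \code{tie_break}. Spatial position plays no role.
#'
#' @param result A k = 2 [kmeans_segment()] result.
#' @return The relabeled \code{cluster_result}.
#' @export
assign_cluster_roles <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$k != 2L)
    stop("role assignment is defined only for k = 2", call. = FALSE)
  dt <- if (!is.null(result$frame_interval)) result$frame_interval else 1
  nb <- if (!is.null(result$n_baseline)) result$n_baseline else 1L
  aucs <- apply(result$cluster_curves, 1, auc, frame_interval = dt,
                n_baseline = nb)
  tie <- FALSE
  if (diff(range(aucs)) == 0) {
    tie <- TRUE
    aucs <- apply(result$cluster_curves, 1, max)
  }
  inner_old <- rownames(result$cluster_curves)[which.max(aucs)]
  roles <- stats::setNames(rep("outer", 2), rownames(result$cluster_curves))
  roles[inner_old] <- "inner"

  result$labels <- unname(roles[result$labels])
  rownames(result$cluster_curves) <- unname(roles[rownames(result$cluster_curves)])
  result$cluster_curves <- result$cluster_curves[c("inner", "outer"), ,
                                                 drop = FALSE]
  names(result$volume_pct) <- unname(roles[names(result$volume_pct)])
  result$volume_pct <- result$volume_pct[c("inner", "outer")]
  result$tie_break <- if (tie) "peak" else "auc"
  result$label_map <- build_label_map(result)
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k=%d, %d pixels, inertia=%.4g\n",
              x$k, length(x$labels), x$inertia))
  v <- paste(sprintf("%s %.1f%%", names(x$volume_pct), x$volume_pct),
             collapse = ", ")
  cat("  volume:", v, "\n")
  invisible(x)
}

#' Write cluster-averaged curves as CSV
#' @param result A [kmeans_segment()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_curves <- function(result, path) {
  cc <- result$cluster_curves
  df <- data.frame(cluster = rep(rownames(cc), each = ncol(cc)),
                   frame = rep(seq_len(ncol(cc)), times = nrow(cc)),
                   nde = as.vector(t(cc)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the segmentation label map as NIfTI
#'
#' Inner pixels are coded 1, outer 2 (other cluster names are coded by their
#' sorted order); background is 0.
#'
#' @param result A [kmeans_segment()] result carrying coordinates.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(result, path) {
  if (is.null(result$label_map))
    stop("cluster result carries no pixel coordinates", call. = FALSE)
  lv <- rownames(result$cluster_curves)
  code <- matrix(0, nrow(result$label_map), ncol(result$label_map))
  for (i in seq_along(lv)) code[result$label_map == lv[i] &
                                  !is.na(result$label_map)] <- i
  write_series(array(code, dim = c(dim(code), 1L)), path)
}

#' Plot the segmentation overlay to PNG
#'
#' @param result A [kmeans_segment()] result with coordinates.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_segmentation_png <- function(result, path) {
  if (is.null(result$label_map))
    stop("cluster result carries no pixel coordinates", call. = FALSE)
  lv <- rownames(result$cluster_curves)
  code <- matrix(NA_real_, nrow(result$label_map), ncol(result$label_map))
  for (i in seq_along(lv)) code[result$label_map == lv[i] &
                                  !is.na(result$label_map)] <- i
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(t(code[nrow(code):1, ]), col = c("red", "green3", "blue"),
                  axes = FALSE, main = "k-means segmentation")
  graphics::legend("topright", legend = lv,
                   fill = c("red", "green3", "blue")[seq_along(lv)])
  invisible(path)
}
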