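# gromos conformational clustering on a precomputed mutual-RMSD matrix:
# repeatedly take the unassigned item with the most unassigned neighbours
# within the cutoff as a cluster centroid, assign it and its neighbours,
# remove them, and iterate. Ties in neighbour count break to the lowest item
# index; final cluster ids are 1-based and ordered by decreasing population
# (ties by extraction order), matching the usual "clusters 1..k" narration.

#' gromos clustering of a distance matrix
#'
#' @param d symmetric distance matrix (e.g. [mutual_rmsd_matrix()]).
#' @param cutoff neighbour cutoff in the matrix units (Angstrom for RMSD);
#'   an item is a neighbour when its distance is `<= cutoff`.
#' @return list of class `gromos_clusters`: `labels` (per-item cluster id),
#'   `centroids` (per-cluster item index), `populations` (per-cluster size),
#'   `cutoff`, `item_labels`.
#' @export
gromos_cluster <- function(d, cutoff) {
  d <- check_distance_matrix(d)
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(d)
  adj <- d <= cutoff
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, n)
  labels <- integer(n)
  centroids <- integer(0)
  pops <- integer(0)
  k <- 0
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- vapply(idx, function(i) sum(adj[i, idx]), integer(1))
    center <- idx[which.max(counts)] # which.max -> lowest index on ties
    members <- c(center, idx[adj[center, idx]])
    members <- unique(members)
    k <- k + 1
    labels[members] <- k
    centroids[k] <- center
    pops[k] <- length(members)
    unassigned[members] <- FALSE
  }
  # renumber by decreasing population, ties by extraction order
  ord <- order(-pops, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(
    labels = relabel[labels],
    centroids = centroids[ord],
    populations = pops[ord],
    cutoff = cutoff,
    item_labels = rownames(d)
  ), class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat(sprintf("<gromos_clusters: %d items in %d clusters (cutoff %.2f), populations %s>\n",
              length(x$labels), length(x$populations), x$cutoff,
              paste(head(x$populations, 8), collapse = ",")))
  invisible(x)
}

#' Cluster membership by source trajectory/model
#'
#' Contingency counts of cluster id against a per-item source label (which
#' model each concatenated frame came from), plus per-cluster source purity —
#' the view used to ask whether different predictors' trajectories visit the
#' same conformational basin.
#'
#' @param result a [gromos_cluster()] result.
#' @param source_labels character vector, one per clustered item.
#' @return list: `counts` (source x cluster matrix), `purity` (per cluster,
#'   largest source fraction).
#' @export
cluster_membership_by_source <- function(result, source_labels) {
  n <- length(result$labels)
  if (length(source_labels) != n) {
    stop("source_labels length ", length(source_labels), " != items ", n)
  }
  k <- length(result$populations)
  counts <- table(
    source = factor(source_labels),
    cluster = factor(result$labels, levels = seq_len(k))
  )
  counts <- unclass(counts)
  purity <- apply(counts, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) NA_real_ else max(col) / tot
  })
  list(counts = counts, purity = purity)
}

#' Extract centroid structures from a concatenated trajectory
#'
#' @param traj the [or_trajectory()] whose frames were clustered (same frame
#'   order as the matrix rows).
#' @param result a [gromos_cluster()] result.
#' @param frame_indices optional mapping from matrix items to trajectory
#'   frames (for strided clustering); default identity.
#' @return list of [or_structure()]s, one per cluster, model ids
#'   `"cluster1"`, `"cluster2"`, ...
#' @export
extract_centroid_structures <- function(traj, result, frame_indices = NULL) {
  if (is.null(frame_indices)) frame_indices <- seq_len(n_frames(traj))
  lapply(seq_along(result$centroids), function(k) {
    item <- result$centroids[k]
    fr <- frame_indices[item]
    if (is.na(fr) || fr < 1 || fr > n_frames(traj)) {
      stop("centroid index ", item, " maps outside the trajectory")
    }
    s <- traj$topology
    s$xyz <- traj$frames[[fr]]
    s$model_id <- paste0("cluster", k)
    s
  })
}
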