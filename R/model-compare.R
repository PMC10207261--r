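# Model-to-model comparison: mutual RMSD matrix over candidate structures and
# a deterministic classical (Torgerson) MDS projection to 2D.

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-centre the squared distances, eigendecompose, take
#' the top `dims` eigenvectors scaled by the square roots of their
#' (non-negative-clamped) eigenvalues. Deterministic — no random
#' initialisation. The sign/rotation ambiguity is canonicalised so the first
#' item lies in the non-negative quadrant of every axis (if its coordinate on
#' an axis is zero, the first item with a non-zero coordinate decides the
#' sign). Negative eigenvalues (RMSD matrices need not be Euclidean) are
#' clamped to zero with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @return list of class `mds_embedding`: `coords` (n x dims, centred),
#'   `eigenvalues` (all n, sorted descending), `stress`
#'   (`sqrt(sum((d_emb - d)^2) / sum(d^2))`, 0 for an all-zero matrix).
#' @export
classical_mds <- function(d, dims = 2) {
  d <- check_distance_matrix(d)
  stopifnot(dims >= 1)
  n <- nrow(d)
  labels <- rownames(d)
  if (all(d == 0)) {
    coords <- matrix(0, n, dims, dimnames = list(labels, NULL))
    return(structure(list(coords = coords, eigenvalues = rep(0, n), stress = 0),
                     class = "mds_embedding"))
  }
  k <- min(dims, n - 1)
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("negative eigenvalues clamped to zero (non-Euclidean distances)")
  }
  coords <- matrix(0, n, dims, dimnames = list(labels, NULL))
  got <- fit$points
  if (!is.null(got) && ncol(got) > 0) {
    coords[, seq_len(ncol(got))] <- got
  }
  # canonical orientation: first (non-zero-deciding) item non-negative per axis
  scale0 <- max(abs(coords), 1e-300)
  for (j in seq_len(dims)) {
    nz <- which(abs(coords[, j]) > 1e-9 * scale0)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  emb_d <- as.matrix(stats::dist(coords))
  up <- upper.tri(d)
  stress <- sqrt(sum((emb_d[up] - d[up])^2) / sum(d[up]^2))
  structure(list(coords = coords, eigenvalues = eig, stress = stress),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding: %d items in %d dims, stress %.3g>\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' Compare candidate models by mutual RMSD and project to 2D
#'
#' Computes the pairwise optimal-superposition RMSD between all models on a
#' common selection (default: whole-chain backbone), then embeds the matrix in
#' the plane by classical MDS — the standard similarity view of a set of
#' structure-prediction candidates.
#'
#' @param models list of [or_structure()] objects with identical atom
#'   correspondence on the selection.
#' @param sel a [selection_spec()]; default backbone, all residues.
#' @param helices optional [helix_set()] if the selection restricts to helices.
#' @param dims MDS dimension (default 2).
#' @return list with `dist` (the [mutual_rmsd_matrix()]) and `mds`
#'   (the [classical_mds()] embedding).
#' @export
compare_models <- function(models, sel = selection_spec("backbone"),
                           helices = NULL, dims = 2) {
  if (length(models) < 2) stop("need at least 2 models to compare")
  idx <- resolve_selection(models[[1]], sel, helices)
  key0 <- with(models[[1]]$atoms[idx, ], paste(chain, resno, atom_name))
  for (m in seq_along(models)[-1]) {
    idx_m <- resolve_selection(models[[m]], sel, helices)
    key_m <- with(models[[m]]$atoms[idx_m, ], paste(chain, resno, atom_name))
    if (!identical(key0, key_m)) {
      bad <- which(key0 != key_m | is.na(key_m))[1]
      stop("atom correspondence mismatch at model ", m, ", first differing atom: ",
           if (is.na(bad)) "selection lengths differ" else key0[bad])
    }
  }
  labels <- vapply(models, `[[`, character(1), "model_id")
  d <- mutual_rmsd_matrix(lapply(models, `[[`, "xyz"), idx, labels)
  list(dist = d, mds = classical_mds(d, dims = dims))
}
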