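# Rigid superposition and RMSD: the numeric core shared by model comparison,
# stability descriptors and clustering. Kabsch is implemented once, SVD-based
# with proper-rotation sign correction; no quaternion path.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' corresponding point sets. Reflections are excluded by flipping the sign of
#' the smallest singular value when the cross-covariance determinant is
#' negative. The transform maps `mobile` onto `target` as
#' `mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,target n x 3 coordinate matrices, identical correspondence.
#' @return list with class `rigid_transform`: `rotation` (3x3, det +1),
#'   `translation` (3-vector), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  if (n < 3 || nrow(target) != n) stop("need >= 3 corresponding points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm); b <- sweep(target, 2, ct)
  # degeneracy: collinear (or coincident) point sets leave the rotation
  # underdetermined about the common axis
  if (svd(a, nu = 0, nv = 0)$d[2] < 1e-8 * (svd(a, nu = 0, nv = 0)$d[1] + 1e-30) ||
      svd(b, nu = 0, nv = 0)$d[2] < 1e-8 * (svd(b, nu = 0, nv = 0)$d[1] + 1e-30)) {
    stop("ill-conditioned superposition: points are (nearly) collinear")
  }
  cov <- crossprod(a, b)
  sv <- svd(cov)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  s <- sv$d; s[3] <- d * s[3]
  msd <- (sum(a^2) + sum(b^2) - 2 * sum(s)) / n
  trans <- ct - as.vector(cm %*% rot)
  structure(list(rotation = rot, translation = trans,
                 rmsd = sqrt(max(msd, 0))),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% transform$rotation, 2, transform$translation, "+")
}

# RMSD from precentered coordinate sums and the 3x3 cross-covariance;
# the workhorse for pairwise matrices (avoids re-forming n x 3 products).
rmsd_from_cov <- function(sa, sb, cov, n) {
  sv <- svd(cov)
  s <- sv$d
  if (det(sv$u %*% t(sv$v)) < 0) s[3] <- -s[3]
  sqrt(max((sa + sb - 2 * sum(s)) / n, 0))
}

#' RMSD after fitting on one atom set, measured on another
#'
#' Superposes `frame_a` onto `frame_b` using the `fit_indices` atoms, then
#' reports the RMSD over `measure_indices`. This is the standard construction
#' for e.g. fitting on the stable transmembrane core while measuring
#' heavy-atom drift of the whole receptor.
#'
#' @param frame_a,frame_b full-coordinate n x 3 matrices.
#' @param fit_indices atom indices used for the superposition.
#' @param measure_indices atom indices the RMSD is reported over (default:
#'   the fit set).
#' @return RMSD in Angstrom.
#' @export
rmsd_fitted <- function(frame_a, frame_b, fit_indices,
                        measure_indices = fit_indices) {
  if (length(measure_indices) == 0) stop("empty measure set")
  tr <- kabsch_superpose(frame_a[fit_indices, , drop = FALSE],
                         frame_b[fit_indices, , drop = FALSE])
  moved <- apply_transform(tr, frame_a[measure_indices, , drop = FALSE])
  diff <- moved - frame_b[measure_indices, , drop = FALSE]
  sqrt(sum(diff^2) / length(measure_indices))
}

#' Mutual RMSD matrix over frames
#'
#' Pairwise optimal-superposition RMSD between every pair of frames on a
#' common atom selection; each pair is fitted independently (no global
#' reference), matching the mutual-RMSD construction used for conformational
#' clustering.
#'
#' @param frames list of full-coordinate n x 3 matrices, or an
#'   [or_trajectory()].
#' @param indices atom indices of the selection (default: all atoms).
#' @param labels item labels for the matrix (default frame numbers).
#' @return symmetric `n_frames x n_frames` matrix (class `dist_matrix`) with
#'   zero diagonal, labelled rows/columns.
#' @export
mutual_rmsd_matrix <- function(frames, indices = NULL, labels = NULL) {
  if (inherits(frames, "or_trajectory")) frames <- frames$frames
  nf <- length(frames)
  if (nf < 1) stop("need at least one frame")
  if (is.null(indices)) indices <- seq_len(nrow(frames[[1]]))
  if (is.null(labels)) labels <- as.character(seq_len(nf))
  centered <- vector("list", nf)
  ssq <- numeric(nf)
  for (i in seq_len(nf)) {
    x <- frames[[i]][indices, , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    centered[[i]] <- x
    ssq[i] <- sum(x^2)
  }
  n <- length(indices)
  m <- matrix(0, nf, nf, dimnames = list(labels, labels))
  if (nf > 1) {
    for (i in 1:(nf - 1)) {
      for (j in (i + 1):nf) {
        val <- tryCatch(
          rmsd_from_cov(ssq[i], ssq[j], crossprod(centered[[i]], centered[[j]]), n),
          error = function(e) stop("RMSD failed for frame pair (", i, ",", j, "): ",
                                   conditionMessage(e))
        )
        m[i, j] <- m[j, i] <- val
      }
    }
  }
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Serialize / read a distance matrix as CSV with header labels
#' @param m a symmetric labelled matrix.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(m, path) {
  write.table(cbind(item = rownames(m), as.data.frame(unclass(m))), path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$item
  colnames(m) <- tab$item
  storage.mode(m) <- "double"
  class(m) <- c("dist_matrix", class(m))
  m
}

check_distance_matrix <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal is not zero")
  if (any(d < -tol)) stop("negative distances")
  d
}
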