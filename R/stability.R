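# Per-trajectory stability descriptors: RMSD time series against a fixed
# reference, TM6-TM7 spacing from fitted helix axes, a configurable linear
# activation index over interhelical C-alpha distances, and sodium-site
# occupancy at the conserved D2.50/E3.39 pocket.

#' Time series container
#' @param times ns. @param values metric values. @param metric name string.
#' @return class `or_series`.
#' @export
or_series <- function(times, values, metric = "metric") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("times must be increasing")
  structure(list(times = times, values = values, metric = metric),
            class = "or_series")
}

#' @export
print.or_series <- function(x, ...) {
  cat(sprintf("<or_series '%s': %d points, range [%.3g, %.3g]>\n",
              x$metric, length(x$values),
              suppressWarnings(min(x$values)), suppressWarnings(max(x$values))))
  invisible(x)
}

#' @export
as.data.frame.or_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' RMSD time series against a fixed reference structure
#'
#' Each frame is independently superposed onto the reference on the fit
#' selection; the RMSD is measured over the measure selection. The reference
#' is typically the initial predictor model, so the series reads as drift
#' away from the prediction.
#'
#' @param traj an [or_trajectory()].
#' @param reference an [or_structure()] with the same topology, or NULL to
#'   use frame 1.
#' @param fit_sel,measure_sel [selection_spec()]s; defaults: fit on backbone,
#'   measure all protein heavy atoms.
#' @param helices optional [helix_set()] for helix-restricted selections.
#' @return an [or_series()] (ns vs Angstrom).
#' @export
rmsd_timeseries <- function(traj, reference = NULL,
                            fit_sel = selection_spec("backbone"),
                            measure_sel = selection_spec("heavy"),
                            helices = NULL) {
  topo <- traj$topology
  if (is.null(reference)) {
    reference <- topo
    reference$xyz <- traj$frames[[1]]
  }
  fit_idx <- resolve_selection(topo, fit_sel, helices)
  meas_idx <- resolve_selection(topo, measure_sel, helices)
  ref_fit <- resolve_selection(reference, fit_sel, helices)
  ref_meas <- resolve_selection(reference, measure_sel, helices)
  if (length(ref_fit) != length(fit_idx) || length(ref_meas) != length(meas_idx)) {
    stop("selection resolves differently on trajectory topology and reference")
  }
  vals <- vapply(traj$frames, function(f) {
    tr <- kabsch_superpose(f[fit_idx, , drop = FALSE],
                           reference$xyz[ref_fit, , drop = FALSE])
    moved <- apply_transform(tr, f[meas_idx, , drop = FALSE])
    sqrt(sum((moved - reference$xyz[ref_meas, , drop = FALSE])^2) / length(meas_idx))
  }, numeric(1))
  or_series(traj$times, vals, "rmsd")
}

#' Best-fit helix axis through C-alpha coordinates
#'
#' Principal-component line through the centroid. The direction is oriented
#' intracellular-to-extracellular: positive z component; if the axis is
#' perpendicular to z, the largest-magnitude component is made positive.
#'
#' @param ca_coords m x 3 C-alpha coordinates, m >= 6.
#' @return list of class `helix_axis`: `point` (centroid), `direction`
#'   (unit vector), `residual` (RMS distance of points from the line).
#' @export
helix_axis <- function(ca_coords) {
  ca_coords <- as.matrix(ca_coords)
  m <- nrow(ca_coords)
  if (m < 6) stop("need at least 6 C-alpha positions to fit a helix axis")
  centroid <- colMeans(ca_coords)
  x <- sweep(ca_coords, 2, centroid)
  sv <- svd(x, nu = 0)
  dir <- sv$v[, 1]
  if (abs(dir[3]) > 1e-9) {
    if (dir[3] < 0) dir <- -dir
  } else if (dir[which.max(abs(dir))] < 0) {
    dir <- -dir
  }
  perp <- x - outer(as.vector(x %*% dir), dir)
  structure(list(point = centroid, direction = dir,
                 residual = sqrt(mean(rowSums(perp^2)))),
            class = "helix_axis")
}

# xy point where a helix axis crosses the plane z = z_mid; if the axis is
# (nearly) horizontal the axis point itself is used.
axis_point_at_z <- function(axis, z_mid) {
  if (abs(axis$direction[3]) < 1e-3) return(axis$point)
  axis$point + ((z_mid - axis$point[3]) / axis$direction[3]) * axis$direction
}

ca_indices_for_helix <- function(topo, helices, name) {
  r <- helices[[name]]
  if (is.null(r)) stop("helix not defined: ", name)
  idx <- which(topo$atoms$atom_name == "CA" & is_protein_atom(topo) &
                 topo$atoms$resno >= r[1] & topo$atoms$resno <= r[2])
  if (length(idx) == 0) stop("helix ", name, " has no C-alpha atoms in structure")
  idx[order(topo$atoms$resno[idx])]
}

#' Interhelix spacing time series (e.g. TM6-TM7)
#'
#' Default mode `axis_midplane`: fit each helix's axis per frame and measure
#' the distance between the two axes where they cross the membrane midplane
#' (the box z-centre) — the natural readout of a splaying motion. Mode
#' `ca_com` instead measures the distance between the C-alpha centroids of
#' the two helices' cytoplasmic halves.
#'
#' @param traj an [or_trajectory()].
#' @param helices a [helix_set()].
#' @param pair two helix names, default `c("TM6", "TM7")`.
#' @param mode `"axis_midplane"` or `"ca_com"`.
#' @param z_mid membrane midplane z (Angstrom). Default NULL: 0 for
#'   origin-centred coordinates (any protein z < 0), else box_z / 2.
#' @return an [or_series()] in Angstrom.
#' @export
tm_pair_distance <- function(traj, helices, pair = c("TM6", "TM7"),
                             mode = c("axis_midplane", "ca_com"), z_mid = NULL) {
  mode <- match.arg(mode)
  topo <- traj$topology
  ia <- ca_indices_for_helix(topo, helices, pair[1])
  ib <- ca_indices_for_helix(topo, helices, pair[2])
  if (pair[1] == pair[2]) {
    return(or_series(traj$times, rep(0, n_frames(traj)),
                     paste0("dist_", pair[1], "_", pair[2])))
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj$frames[[f]]
    if (mode == "axis_midplane") {
      zm <- if (!is.null(z_mid)) z_mid
            else if (min(fr[c(ia, ib), 3]) < 0) 0 else traj$box[f, 3] / 2
      pa <- axis_point_at_z(helix_axis(fr[ia, , drop = FALSE]), zm)
      pb <- axis_point_at_z(helix_axis(fr[ib, , drop = FALSE]), zm)
      sqrt(sum((pa - pb)^2))
    } else {
      half <- function(idx) {
        m <- length(idx)
        lo <- idx[seq_len(floor(m / 2))]
        hi <- idx[(floor(m / 2) + 1):m]
        # cytoplasmic = lower-z half
        if (mean(fr[lo, 3]) <= mean(fr[hi, 3])) lo else hi
      }
      ca <- colMeans(fr[half(ia), , drop = FALSE])
      cb <- colMeans(fr[half(ib), , drop = FALSE])
      sqrt(sum((ca - cb)^2))
    }
  }, numeric(1))
  or_series(traj$times, vals, paste0("dist_", pair[1], "_", pair[2]))
}

#' Activation index specification
#'
#' The activation index is a linear functional of interhelical C-alpha
#' distances: `intercept + sum(coef_k * d(CA_i_k, CA_j_k))`, with residue
#' pairs given as Ballesteros-Weinstein labels. The coefficient set is
#' supplied by the user (e.g. via a config file) — it is a published
#' calibration, not something this package hardcodes. By convention, values
#' below a user-chosen threshold indicate inactive-like conformations.
#'
#' @param terms data.frame with columns `bw_a`, `bw_b` (BW labels) and
#'   `coef` (1/Angstrom).
#' @param intercept scalar offset.
#' @return class `activation_spec`.
#' @export
activation_spec <- function(terms = data.frame(bw_a = character(),
                                               bw_b = character(),
                                               coef = numeric()),
                            intercept = 0) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("bw_a", "bw_b", "coef") %in% names(terms)))
  if (!all(is.finite(terms$coef))) stop("non-finite coefficient")
  pair_key <- paste(pmin(terms$bw_a, terms$bw_b), pmax(terms$bw_a, terms$bw_b))
  if (anyDuplicated(pair_key)) stop("duplicate BW pair in activation spec")
  structure(list(terms = terms, intercept = intercept),
            class = "activation_spec")
}

#' Activation-index time series
#'
#' @param traj an [or_trajectory()].
#' @param bw a [bw_map()] resolving the spec's BW labels.
#' @param spec an [activation_spec()].
#' @return an [or_series()] (dimensionless).
#' @export
activation_index <- function(traj, bw, spec) {
  stopifnot(inherits(spec, "activation_spec"))
  topo <- traj$topology
  ca_of <- function(label) {
    resno <- tryCatch(bw_lookup(bw, label),
                      error = function(e) stop("activation pair unresolvable: ", label))
    idx <- which(topo$atoms$atom_name == "CA" & topo$atoms$resno == resno &
                   is_protein_atom(topo))
    if (length(idx) != 1) stop("no unique C-alpha for BW ", label, " (residue ", resno, ")")
    idx
  }
  ia <- vapply(spec$terms$bw_a, ca_of, integer(1))
  ib <- vapply(spec$terms$bw_b, ca_of, integer(1))
  vals <- vapply(traj$frames, function(f) {
    if (length(ia) == 0) return(spec$intercept)
    d <- sqrt(rowSums((f[ia, , drop = FALSE] - f[ib, , drop = FALSE])^2))
    spec$intercept + sum(spec$terms$coef * d)
  }, numeric(1))
  or_series(traj$times, vals, "activation_index")
}

#' Sodium-site specification
#'
#' The class A GPCR ion pocket: acidic side chains at BW 2.50 and 3.39
#' coordinate the sodium ion through their carboxylate oxygens. A frame is
#' "occupied" when any selected ion lies within `contact_cutoff` of any
#' coordinating oxygen (minimum-image convention). The 3.0 Angstrom default
#' is a typical Na+-carboxylate coordination distance.
#'
#' @param positions BW labels of coordinating residues.
#' @param atoms coordinating atom names (carboxylate oxygens).
#' @param contact_cutoff Angstrom, > 0.
#' @return class `ion_site_spec`.
#' @export
ion_site_spec <- function(positions = c("2.50", "3.39"),
                          atoms = c("OD1", "OD2", "OE1", "OE2"),
                          contact_cutoff = 3.0) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  structure(list(positions = positions, atoms = atoms,
                 contact_cutoff = contact_cutoff),
            class = "ion_site_spec")
}

min_image_dist <- function(a, b, box) {
  d <- sweep(b, 2, a)
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(d^2))
}

#' Sodium-site occupancy along a trajectory
#'
#' @param traj an [or_trajectory()].
#' @param bw a [bw_map()].
#' @param site an [ion_site_spec()].
#' @param ion_indices atom indices of the ions to track; default: all atoms
#'   whose residue name marks a sodium (`NA`/`SOD`).
#' @return list of class `ion_occupancy`: `occupancy` (fraction in `[0,1]`),
#'   `first_binding_time` (ns, `NA` if never bound), `first_binding_frame`
#'   (1-based, `NA` if never), `series` (min ion-site distance per frame),
#'   `occupied` (logical per frame).
#' @export
ion_site_occupancy <- function(traj, bw, site = ion_site_spec(),
                               ion_indices = NULL) {
  topo <- traj$topology
  if (is.null(ion_indices)) {
    ion_indices <- which(topo$atoms$resname %in% c("NA", "SOD"))
  }
  site_resnos <- vapply(site$positions, function(p) bw_lookup(bw, p), integer(1))
  coord_idx <- which(topo$atoms$resno %in% site_resnos &
                       topo$atoms$atom_name %in% site$atoms)
  if (length(coord_idx) == 0) {
    stop("no coordinating atoms (", paste(site$atoms, collapse = "/"),
         ") found at site residues ", paste(site_resnos, collapse = ","))
  }
  nf <- n_frames(traj)
  mind <- rep(Inf, nf)
  if (length(ion_indices) > 0) {
    for (f in seq_len(nf)) {
      fr <- traj$frames[[f]]
      box <- traj$box[f, ]
      dists <- vapply(ion_indices, function(i) {
        min(min_image_dist(fr[i, ], fr[coord_idx, , drop = FALSE], box))
      }, numeric(1))
      mind[f] <- min(dists)
    }
  }
  occupied <- mind <= site$contact_cutoff
  first <- which(occupied)[1]
  structure(list(
    occupancy = mean(occupied),
    first_binding_time = if (is.na(first)) NA_real_ else traj$times[first],
    first_binding_frame = if (is.na(first)) NA_integer_ else first,
    series = or_series(traj$times, ifelse(is.finite(mind), mind, NA_real_),
                       "ion_site_min_dist"),
    occupied = occupied,
    cutoff = site$contact_cutoff
  ), class = "ion_occupancy")
}
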