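# Water permeation: detect complete intracellular <-> extracellular passages
# of individual water molecules through the receptor interior, with correct
# periodic-boundary unwrapping along z. A passage counts only if it traverses
# the transmembrane cylinder (a path through bulk solvent "around" the
# protein is discarded).

#' Compartment geometry for permeation analysis
#'
#' Space is split by two z planes (membrane slab extent) and a cylinder of
#' radius `cylinder_radius` around the helical bundle: below `z_lower` is the
#' intracellular (IC) compartment, above `z_upper` extracellular (EC);
#' inside the slab, points within the cylinder are transmembrane (TM) and
#' points outside it are BULK (membrane/solvent around the protein).
#'
#' @param z_lower,z_upper slab boundaries, Angstrom, `z_lower < z_upper`.
#'   Defaults +-20 about the box z-centre for an origin-centred box.
#' @param cylinder_center_xy fixed xy centre (2-vector) or
#'   `"bundle-centroid"` to use the per-frame centroid of the transmembrane
#'   C-alpha atoms.
#' @param cylinder_radius Angstrom, > 0; default 12 captures "through the
#'   receptor" for a 7-helix bundle.
#' @return class `compartment_spec`.
#' @export
compartment_spec <- function(z_lower = -20, z_upper = 20,
                             cylinder_center_xy = "bundle-centroid",
                             cylinder_radius = 12) {
  if (z_lower >= z_upper) stop("z_lower must be below z_upper")
  if (cylinder_radius <= 0) stop("cylinder_radius must be positive")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 cylinder_center_xy = cylinder_center_xy,
                 cylinder_radius = cylinder_radius),
            class = "compartment_spec")
}

#' Unwrap a periodic z coordinate series
#'
#' Removes apparent box-edge jumps: successive differences larger than half
#' the box are shifted by a whole box length (minimum-image increments,
#' accumulated), so a particle drifting across the boundary keeps a
#' continuous coordinate.
#'
#' @param z per-frame wrapped z values of one particle.
#' @param box_z per-frame box z lengths (scalar recycled).
#' @return continuous z series, same length.
#' @export
unwrap_z <- function(z, box_z) {
  n <- length(z)
  if (n <= 1) return(z)
  box_z <- rep_len(box_z, n)
  dz <- diff(z)
  b <- box_z[-1]
  dz <- dz - b * round(dz / b)
  cumsum(c(z[1], dz))
}

#' Assign a point to a permeation compartment
#'
#' @param xy 2-vector (or m x 2 matrix) of xy offsets from the cylinder
#'   centre, Angstrom.
#' @param z z coordinate(s), already unwrapped.
#' @param spec a [compartment_spec()].
#' @return character vector: `"IC"`, `"TM"`, `"EC"` or `"BULK"`.
#' @export
assign_region <- function(xy, z, spec) {
  xy <- matrix(xy, ncol = 2)
  r <- sqrt(rowSums(xy^2))
  out <- ifelse(z < spec$z_lower, "IC",
         ifelse(z > spec$z_upper, "EC",
         ifelse(r <= spec$cylinder_radius, "TM", "BULK")))
  out
}

# state machine over one water's per-frame region labels
events_from_regions <- function(regions, water_id) {
  events <- list()
  last_comp <- NA_character_
  saw_tm <- FALSE
  saw_bulk <- FALSE
  first_tm <- NA_integer_
  for (f in seq_along(regions)) {
    reg <- regions[f]
    if (reg == "IC" || reg == "EC") {
      if (!is.na(last_comp) && reg != last_comp && saw_tm && !saw_bulk) {
        events[[length(events) + 1]] <- data.frame(
          water_id = water_id, entry_frame = first_tm, exit_frame = f,
          direction = if (last_comp == "IC") "IC->EC" else "EC->IC",
          stringsAsFactors = FALSE
        )
      }
      last_comp <- reg
      saw_tm <- FALSE; saw_bulk <- FALSE; first_tm <- NA_integer_
    } else if (reg == "TM") {
      if (!saw_tm) first_tm <- f
      saw_tm <- TRUE
    } else { # BULK
      saw_bulk <- TRUE
    }
  }
  events
}

#' Detect complete water permeation events
#'
#' Tracks every selected water oxygen through box-folded z (minimum image
#' about the slab centre, so periodic-boundary jumps between the IC and EC
#' reservoirs are not mistaken for slab crossings) and per-frame radial
#' distance from the bundle axis, and emits one event per maximal
#' passage that starts in one compartment (IC or EC), traverses the TM
#' cylinder at least once without touching BULK, and ends in the opposite
#' compartment. Bounce-backs (return to the starting compartment) and
#' around-the-protein routes produce no events; a water may permeate more
#' than once.
#'
#' @param traj an [or_trajectory()].
#' @param spec a [compartment_spec()].
#' @param water_indices atom indices of water oxygens; default: oxygen atoms
#'   of water residues.
#' @param helices optional [helix_set()]; with `"bundle-centroid"` centring,
#'   restricts the centroid to TM-helix C-alpha atoms.
#' @return data.frame of class `permeation_events` with columns `water_id`,
#'   `entry_frame` (first TM frame of the passage), `exit_frame` (frame the
#'   far compartment is reached), `direction` (`"IC->EC"`/`"EC->IC"`).
#' @export
detect_permeations <- function(traj, spec = compartment_spec(),
                               water_indices = NULL, helices = NULL) {
  topo <- traj$topology
  if (is.null(water_indices)) {
    water_indices <- which(is_water_atom(topo) & topo$atoms$element == "O")
  }
  if (length(water_indices) == 0) stop("no water oxygens selected")
  nf <- n_frames(traj)

  # per-frame cylinder centre
  if (identical(spec$cylinder_center_xy, "bundle-centroid")) {
    ca_idx <- which(topo$atoms$atom_name == "CA" & is_protein_atom(topo))
    if (!is.null(helices)) {
      ca_idx <- ca_idx[topo$atoms$resno[ca_idx] %in% helix_resnos(helices)]
    }
    if (length(ca_idx) == 0) stop("no C-alpha atoms to centre the cylinder on")
    centers <- t(vapply(traj$frames,
                        function(f) colMeans(f[ca_idx, 1:2, drop = FALSE]),
                        numeric(2)))
  } else {
    centers <- matrix(as.numeric(spec$cylinder_center_xy), nf, 2, byrow = TRUE)
  }

  # fold z into one box period centred on the slab: compartments are defined
  # by position within the periodic box, so a particle that crosses the
  # periodic z boundary moves between the IC and EC reservoirs without ever
  # visiting TM -- which the state machine correctly ignores
  z_mid <- (spec$z_lower + spec$z_upper) / 2
  all_events <- list()
  for (w in water_indices) {
    zw <- vapply(seq_len(nf), function(f) traj$frames[[f]][w, 3], numeric(1))
    zrel <- zw - z_mid
    z <- z_mid + (zrel - traj$box[, 3] * round(zrel / traj$box[, 3]))
    dxy <- t(vapply(seq_len(nf), function(f) {
      d <- traj$frames[[f]][w, 1:2] - centers[f, ]
      b <- traj$box[f, 1:2]
      d - b * round(d / b)
    }, numeric(2)))
    regions <- assign_region(dxy, z, spec)
    wid <- paste0(topo$atoms$chain[w], topo$atoms$resno[w])
    all_events <- c(all_events, events_from_regions(regions, wid))
  }
  out <- if (length(all_events) == 0) {
    data.frame(water_id = character(), entry_frame = integer(),
               exit_frame = integer(), direction = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, all_events)
  }
  class(out) <- c("permeation_events", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Summarise permeation events
#'
#' @param events output of [detect_permeations()].
#' @param traj the trajectory the events came from (for the time span).
#' @return list: `n_total`, `n_ic_to_ec`, `n_ec_to_ic`, `duration_ns`,
#'   `rate_per_100ns` (total / (duration / 100 ns)).
#' @export
permeation_summary <- function(events, traj) {
  duration <- if (n_frames(traj) > 1) max(traj$times) - min(traj$times) else 0
  n_up <- sum(events$direction == "IC->EC")
  n_down <- sum(events$direction == "EC->IC")
  list(
    n_total = n_up + n_down,
    n_ic_to_ec = n_up,
    n_ec_to_ic = n_down,
    duration_ns = duration,
    rate_per_100ns = if (duration > 0) (n_up + n_down) / (duration / 100) else 0
  )
}

#' Reverse a trajectory in time (frame order flipped, times kept increasing)
#'
#' Useful for symmetry checks: time reversal must swap the two permeation
#' directions exactly.
#'
#' @param traj an [or_trajectory()].
#' @return an [or_trajectory()] with reversed frame order.
#' @export
reverse_trajectory <- function(traj) {
  nf <- n_frames(traj)
  or_trajectory(traj$topology, rev(traj$frames),
                traj$box[rev(seq_len(nf)), , drop = FALSE], traj$times)
}
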