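# Synthetic ground truth: idealized 7-helix transmembrane bundles in a
# periodic box, with scripted rigid drift, helix-pair splaying schedules,
# planted water permeation events and ion-binding schedules. These are the
# statistical stand-ins for real MD trajectories: every analysis in the
# package can be checked against the planted quantities exactly.

#' Bundle geometry specification
#'
#' Idealized transmembrane bundle: `n_helices` poly-alanine helices (backbone
#' N, CA, C, O plus CB) with standard alpha-helix geometry (1.5 Angstrom rise
#' and 100 degree twist per residue), axes vertical, placed on a circle of
#' `bundle_radius`, running in alternating directions, joined by short
#' unstructured loops. Box defaults to 100 x 100 x 120 Angstrom with
#' coordinates centred on the origin (membrane midplane at z = 0).
#'
#' @param n_helices number of helices (default 7).
#' @param residues_per_helix residues per helix (default 25).
#' @param bundle_radius circle radius for the helix axes, Angstrom.
#' @param helix_rise,helix_twist ideal helix parameters (Angstrom/residue,
#'   degrees/residue).
#' @param box box lengths, Angstrom.
#' @param loop_residues loop residues between consecutive helices.
#' @return class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 7, residues_per_helix = 25,
                        bundle_radius = 10, helix_rise = 1.5,
                        helix_twist = 100, box = c(100, 100, 120),
                        loop_residues = 4) {
  if (n_helices < 2) stop("need at least 2 helices")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (residues_per_helix < 6) stop("helices must have at least 6 residues")
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 bundle_radius = bundle_radius, helix_rise = helix_rise,
                 helix_twist = helix_twist, box = box,
                 loop_residues = loop_residues),
            class = "bundle_spec")
}

# local helix frame: radial/tangential unit vectors at bundle angle theta
.bundle_axis_xy <- function(spec, h) {
  theta <- 2 * pi * (h - 1) / spec$n_helices
  list(center = spec$bundle_radius * c(cos(theta), sin(theta)),
       inward = -c(cos(theta), sin(theta)),
       theta = theta)
}

#' Build an idealized helical bundle
#'
#' Returns the structure together with its helix ranges and a synthetic
#' Ballesteros-Weinstein map: the midpoint residue of helix `h` is labelled
#' `h.50` and the rest of the helix is numbered by offset (`h.49`, `h.51`,
#' ...). The residues at BW 2.50 and 3.39 are built as ASP and GLU carrying
#' explicit carboxylate-oxygen pseudo-atoms (OD1/OD2, OE1/OE2) so that
#' ion-site analyses have real coordination targets; all other residues are
#' alanine. Loop residues are present between helices and carry no BW label.
#'
#' @param spec a [bundle_spec()].
#' @return list: `structure` ([or_structure()]), `helices` ([helix_set()]),
#'   `bw` ([bw_map()]), `spec`.
#' @export
make_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  min_sep <- 2 * spec$bundle_radius * sin(pi / spec$n_helices)
  if (min_sep < 6) {
    stop("bundle_radius too small: adjacent helix axes ", round(min_sep, 1),
         " Angstrom apart would clash")
  }
  m <- spec$residues_per_helix
  mid <- ceiling(m / 2)
  rise <- spec$helix_rise
  twist_rad <- spec$helix_twist * pi / 180
  z_half <- rise * (m - 1) / 2

  rows <- list()
  coords <- list()
  resno <- 0
  bw_res <- integer(0); bw_lab <- character(0)
  helix_ranges <- list()

  add_atom <- function(name, element, resname, pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom_name = name, element = element, resno = resno, resname = resname,
      chain = "A", type = "ATOM", stringsAsFactors = FALSE
    )
    coords[[length(coords) + 1]] <<- pos
  }

  prev_end <- NULL
  for (h in seq_len(spec$n_helices)) {
    ax <- .bundle_axis_xy(spec, h)
    up <- (h %% 2 == 1) # odd helices run IC -> EC
    start_resno <- resno + 1
    for (i in seq_len(m)) {
      resno <- resno + 1
      zi <- if (up) -z_half + rise * (i - 1) else z_half - rise * (i - 1)
      phi <- twist_rad * (i - 1) + ax$theta + pi # CB side starts inward
      ring <- function(radius, dphi, dz) {
        c(ax$center + radius * c(cos(phi + dphi), sin(phi + dphi)), zi + dz)
      }
      bw_here <- sprintf("%d.%02d", h, 50 + (i - mid))
      resname <- "ALA"
      if (bw_here == "2.50") resname <- "ASP"
      if (bw_here == "3.39") resname <- "GLU"
      add_atom("N", "N", resname, ring(1.6, -0.5, -0.6))
      add_atom("CA", "C", resname, ring(2.3, 0, 0))
      add_atom("C", "C", resname, ring(1.7, 0.5, 0.6))
      add_atom("O", "O", resname, ring(2.0, 0.6, 1.2))
      add_atom("CB", "C", resname, ring(3.4, 0, 0))
      if (resname == "ASP") {
        add_atom("OD1", "O", resname, ring(4.5, -0.12, 0.4))
        add_atom("OD2", "O", resname, ring(4.5, 0.12, -0.4))
      }
      if (resname == "GLU") {
        add_atom("OE1", "O", resname, ring(4.5, -0.12, 0.4))
        add_atom("OE2", "O", resname, ring(4.5, 0.12, -0.4))
      }
      if (i >= 1 && i <= m) {
        bw_res <- c(bw_res, resno); bw_lab <- c(bw_lab, bw_here)
      }
    }
    helix_ranges[[paste0("TM", h)]] <- c(start_resno, resno)
    # loop to next helix: straight CA-only connector above/below the bundle
    if (h < spec$n_helices && spec$loop_residues > 0) {
      ax_next <- .bundle_axis_xy(spec, h + 1)
      z_loop <- if (up) z_half + 4 else -z_half - 4
      for (l in seq_len(spec$loop_residues)) {
        resno <- resno + 1
        tfrac <- l / (spec$loop_residues + 1)
        xy <- (1 - tfrac) * ax$center + tfrac * ax_next$center
        add_atom("N", "N", "GLY", c(xy + c(-0.7, 0), z_loop + 0.4))
        add_atom("CA", "C", "GLY", c(xy, z_loop))
        add_atom("C", "C", "GLY", c(xy + c(0.7, 0), z_loop - 0.4))
        add_atom("O", "O", "GLY", c(xy + c(0.9, 0.9), z_loop - 0.4))
      }
    }
  }

  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  struct <- or_structure(atoms, xyz, model_id = "bundle")
  list(structure = struct, helices = helix_set(helix_ranges),
       bw = bw_map(bw_res, bw_lab), spec = spec)
}

#' Scripted events for a synthetic trajectory
#'
#' @param splay list of splay entries, each
#'   `list(pair = c("TM6","TM7"), frames = c(f0, f1), dist = c(d0, d1))`:
#'   the xy axis distance of the pair is held at `d0` before `f0`, linearly
#'   interpolated to `d1` by `f1`, then held.
#' @param permeations list of [permeation_script()] entries.
#' @param ion_binding list of `list(frame = f, bound = TRUE/FALSE)` steps;
#'   the ion is unbound before the first step.
#' @param rigid_drift Angstrom/frame whole-protein translation along x.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param n_bulk_waters stationary far-field waters (never permeate).
#' @param seed RNG seed for the noise stream.
#' @return class `event_schedule`.
#' @export
event_schedule <- function(splay = list(), permeations = list(),
                           ion_binding = list(), rigid_drift = 0,
                           noise_sigma = 0, n_bulk_waters = 0, seed = 1) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(splay = splay, permeations = permeations,
                 ion_binding = ion_binding, rigid_drift = rigid_drift,
                 noise_sigma = noise_sigma, n_bulk_waters = n_bulk_waters,
                 seed = seed),
            class = "event_schedule")
}

#' Script one water's passage
#'
#' Kinds: `"cross"` — a complete IC->EC (or EC->IC) passage through the
#' bundle cylinder over `duration` frames; `"bounce"` — enters the TM region
#' and returns to its starting compartment (no event); `"around"` — crosses
#' the slab outside the cylinder, through bulk (no event). With
#' `wrap = TRUE` the water keeps drifting after a crossing until it wraps
#' through the periodic z boundary, exercising the unwrapping logic.
#'
#' @param water_id small integer distinguishing scripted waters.
#' @param start_frame frame the passage starts.
#' @param duration frames the passage takes (>= 1).
#' @param direction `"IC->EC"` or `"EC->IC"`.
#' @param kind `"cross"`, `"bounce"` or `"around"`.
#' @param wrap continue drifting through the periodic boundary afterwards.
#' @return list describing the script.
#' @export
permeation_script <- function(water_id, start_frame, duration,
                              direction = c("IC->EC", "EC->IC"),
                              kind = c("cross", "bounce", "around"),
                              wrap = FALSE) {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  if (duration < 1) stop("duration must be >= 1")
  list(water_id = water_id, start_frame = start_frame, duration = duration,
       direction = direction, kind = kind, wrap = wrap)
}

# continuous z path of a scripted water, evaluated at fractional frame u
# (1-based, may be non-integer when the sampling rate is changed)
.water_z <- function(script, u, z_src, z_dst, box_z) {
  t0 <- script$start_frame
  t1 <- script$start_frame + script$duration
  if (script$kind == "bounce") {
    if (u <= t0) return(z_src)
    if (u >= t1) return(z_src)
    half <- (t0 + t1) / 2
    z_mid <- (z_src + z_dst) / 2 # mid-slab turnaround
    if (u <= half) return(z_src + (z_mid - z_src) * (u - t0) / (half - t0))
    return(z_mid + (z_src - z_mid) * (u - half) / (t1 - half))
  }
  if (u <= t0) return(z_src)
  if (u < t1) return(z_src + (z_dst - z_src) * (u - t0) / (t1 - t0))
  z <- z_dst
  if (script$wrap) {
    # keep drifting past the periodic z boundary, but cap the excursion so
    # the wrapped-around water parks in the far reservoir without ever
    # re-entering the membrane slab from the other side
    drift <- sign(z_dst - z_src) * min(1.2 * (u - t1), 0.21 * box_z)
    z <- z + drift
  }
  z
}

#' Generate a synthetic trajectory from a bundle and an event schedule
#'
#' Deterministic given the schedule seed. Splaying is realized by rigid
#' radial displacement of the two named helices (half the distance change
#' each, along the line joining their axes); scripted waters are single-O
#' `HOH` residues following continuous z paths through (or around) the
#' bundle, wrapped into the periodic box; the sodium ion toggles between a
#' bulk parking position and the midpoint of the 2.50 carboxylate oxygens
#' according to the binding schedule; Gaussian noise is added to every atom.
#'
#' @param bundle output of [make_bundle()].
#' @param schedule an [event_schedule()].
#' @param n_frames number of frames.
#' @param dt_ns time step between frames (ns).
#' @return an [or_trajectory()] whose topology is the bundle plus scripted
#'   waters (chain `"W"`) and one sodium (chain `"I"`, present only when the
#'   schedule has ion steps). Ground truth is attached as attribute
#'   `"ground_truth"`.
#' @export
make_trajectory <- function(bundle, schedule = event_schedule(),
                            n_frames = 100, dt_ns = 1) {
  stopifnot(inherits(schedule, "event_schedule"))
  spec <- bundle$spec
  box <- spec$box
  prot <- bundle$structure
  np <- n_atoms(prot)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(schedule$seed)

  # atom index bookkeeping per helix for splay displacement
  helix_atoms <- lapply(bundle$helices, function(r) {
    which(prot$atoms$resno >= r[1] & prot$atoms$resno <= r[2])
  })

  # extra atoms: scripted waters, bulk waters, ion
  waters <- schedule$permeations
  nw <- length(waters)
  nb <- schedule$n_bulk_waters
  has_ion <- length(schedule$ion_binding) > 0
  extra <- list()
  if (nw > 0) {
    for (i in seq_len(nw)) {
      extra[[length(extra) + 1]] <- data.frame(
        atom_name = "O", element = "O", resno = 1000L + waters[[i]]$water_id,
        resname = "HOH", chain = "W", type = "HETATM", stringsAsFactors = FALSE
      )
    }
  }
  bulk_xy <- NULL
  if (nb > 0) {
    bulk_xy <- cbind(runif(nb, -0.4, 0.4) * box[1], runif(nb, -0.4, 0.4) * box[2])
    bulk_z <- sample(c(-1, 1), nb, replace = TRUE) * runif(nb, 0.33, 0.46) * box[3]
    for (i in seq_len(nb)) {
      extra[[length(extra) + 1]] <- data.frame(
        atom_name = "O", element = "O", resno = 2000L + i, resname = "HOH",
        chain = "W", type = "HETATM", stringsAsFactors = FALSE
      )
    }
  }
  if (has_ion) {
    extra[[length(extra) + 1]] <- data.frame(
      atom_name = "NA", element = "NA", resno = 3000L, resname = "NA",
      chain = "I", type = "HETATM", stringsAsFactors = FALSE
    )
  }
  atoms <- rbind(prot$atoms, do.call(rbind, extra))
  ntot <- nrow(atoms)

  # scripted water source/destination and radial offsets
  z_ic <- -0.30 * box[3]; z_ec <- 0.30 * box[3]
  wsrc <- numeric(nw); wdst <- numeric(nw); wxy <- matrix(0, max(nw, 1), 2)
  if (nw > 0) {
    for (i in seq_len(nw)) {
      s <- waters[[i]]
      up <- s$direction == "IC->EC"
      wsrc[i] <- if (up) z_ic else z_ec
      wdst[i] <- if (up) z_ec else z_ic
      wxy[i, ] <- if (s$kind == "around") c(22, 22 + i) else c(
        2.5 * cos(i), 2.5 * sin(i)
      )
    }
  }

  # ion bookkeeping: bound position follows the (possibly splayed/drifted)
  # 2.50 carboxylate midpoint
  od_idx <- which(prot$atoms$atom_name %in% c("OD1", "OD2"))
  ion_bound_at <- function(f) {
    bound <- FALSE
    for (st in schedule$ion_binding) if (f >= st$frame) bound <- st$bound
    bound
  }
  ion_bulk <- c(0.35 * box[1], 0.35 * box[2], 0.42 * box[3])

  # splay precomputation: base axis centres
  base_center <- function(hname) {
    idx <- which(prot$atoms$resno >= bundle$helices[[hname]][1] &
                   prot$atoms$resno <= bundle$helices[[hname]][2] &
                   prot$atoms$atom_name == "CA")
    colMeans(prot$xyz[idx, 1:2, drop = FALSE])
  }

  wrap_into_box <- function(v, b) v - b * round(v / b)

  frames <- vector("list", n_frames)
  splay_truth <- list()
  for (f in seq_len(n_frames)) {
    fr <- matrix(0, ntot, 3)
    pxyz <- prot$xyz
    # splay
    for (sp in schedule$splay) {
      c1 <- base_center(sp$pair[1]); c2 <- base_center(sp$pair[2])
      d0 <- sqrt(sum((c2 - c1)^2))
      target <- if (f <= sp$frames[1]) sp$dist[1]
        else if (f >= sp$frames[2]) sp$dist[2]
        else sp$dist[1] + (sp$dist[2] - sp$dist[1]) *
          (f - sp$frames[1]) / (sp$frames[2] - sp$frames[1])
      u <- (c2 - c1) / d0
      shift <- (target - d0) / 2
      i1 <- helix_atoms[[sp$pair[1]]]; i2 <- helix_atoms[[sp$pair[2]]]
      pxyz[i1, 1:2] <- sweep(pxyz[i1, 1:2, drop = FALSE], 2, shift * u, "-")
      pxyz[i2, 1:2] <- sweep(pxyz[i2, 1:2, drop = FALSE], 2, shift * u, "+")
    }
    if (schedule$rigid_drift != 0) {
      pxyz[, 1] <- pxyz[, 1] + schedule$rigid_drift * (f - 1)
    }
    fr[seq_len(np), ] <- pxyz
    at <- np
    if (nw > 0) {
      for (i in seq_len(nw)) {
        at <- at + 1
        z <- .water_z(waters[[i]], f, wsrc[i], wdst[i], box[3])
        fr[at, ] <- c(wxy[i, ], wrap_into_box(z, box[3]))
      }
    }
    if (nb > 0) {
      for (i in seq_len(nb)) {
        at <- at + 1
        fr[at, ] <- c(bulk_xy[i, ], bulk_z[i])
      }
    }
    if (has_ion) {
      at <- at + 1
      fr[at, ] <- if (ion_bound_at(f)) {
        colMeans(fr[od_idx, , drop = FALSE])
      } else {
        ion_bulk
      }
    }
    if (schedule$noise_sigma > 0) {
      fr <- fr + matrix(rnorm(3 * ntot, sd = schedule$noise_sigma), ntot, 3)
    }
    frames[[f]] <- fr
  }

  topo <- or_structure(atoms, frames[[1]], model_id = prot$model_id)
  traj <- or_trajectory(topo, frames, box, times = (seq_len(n_frames) - 1) * dt_ns)
  attr(traj, "ground_truth") <- list(
    schedule = schedule,
    n_crossings = if (nw == 0) 0L else sum(vapply(waters, function(s) s$kind == "cross", logical(1))),
    crossing_directions = if (nw == 0) character(0) else
      vapply(waters[vapply(waters, function(s) s$kind == "cross", logical(1))],
             `[[`, character(1), "direction"),
    ion_bound_frames = if (has_ion) which(vapply(seq_len(n_frames), ion_bound_at, logical(1))) else integer(0)
  )
  traj
}

# ---- model set with planted pairwise RMSDs ----------------------------------

# displacement basis orthogonal to rigid motions of the selection: random
# fields with translations and infinitesimal rotations projected out, then
# Gram-Schmidt, normalised so a unit coefficient gives 1 Angstrom RMSD over
# the selection
.displacement_basis <- function(xyz, sel, k) {
  n <- nrow(xyz)
  ns <- length(sel)
  xc <- sweep(xyz[sel, , drop = FALSE], 2, colMeans(xyz[sel, , drop = FALSE]))
  # rigid modes on the selection (3 translations + 3 rotations), as ns x 3 fields
  modes <- list(
    cbind(1, 0, 0)[rep(1, ns), ], cbind(0, 1, 0)[rep(1, ns), ],
    cbind(0, 0, 1)[rep(1, ns), ],
    cbind(0, -xc[, 3], xc[, 2]), cbind(xc[, 3], 0, -xc[, 1]),
    cbind(-xc[, 2], xc[, 1], 0)
  )
  dot <- function(a, b) sum(a * b)
  ortho <- list()
  for (m in modes) {
    v <- m
    for (o in ortho) v <- v - dot(v, o) * o
    nv <- sqrt(dot(v, v))
    if (nv > 1e-9) ortho[[length(ortho) + 1]] <- v / nv
  }
  basis <- list()
  for (j in seq_len(k)) {
    v <- matrix(rnorm(3 * ns), ns, 3)
    for (o in ortho) v <- v - dot(v, o) * o
    for (b in basis) v <- v - dot(v, b) * b
    v <- v / sqrt(dot(v, v))
    basis[[j]] <- v
  }
  # scale: coefficient c displaces selection atoms with RMS c over the selection
  lapply(basis, function(b) {
    full <- matrix(0, n, 3)
    full[sel, ] <- b * sqrt(ns)
    full
  })
}

#' Generate candidate-model variants with planted pairwise RMSDs
#'
#' Emulates a set of structure-prediction candidates whose mutual backbone
#' RMSDs are known by construction: each variant displaces the base structure
#' along smooth random fields orthogonal to rigid motions, with coefficients
#' taken from planted 2D coordinates, so the pairwise optimal-superposition
#' RMSD over the selection equals the planted planar distances (exactly 2D
#' embeddable by construction, up to second-order rotation effects).
#'
#' @param bundle output of [make_bundle()] (or any `or_structure` via
#'   `bundle$structure`).
#' @param k number of variants (>= 2).
#' @param planted_coords k x 2 matrix of planted plane coordinates whose
#'   pairwise distances are the target RMSDs (Angstrom). Default: random
#'   points in a disc of radius `spread`.
#' @param spread disc radius for random planted coordinates.
#' @param seed RNG seed.
#' @param sel [selection_spec()] the planted RMSDs refer to (default
#'   backbone).
#' @return list of [or_structure()]s (`model_ids` `"M1"`..`"Mk"`), with the
#'   planted coordinates attached as attribute `"planted_coords"`.
#' @export
make_model_set <- function(bundle, k, planted_coords = NULL, spread = 2,
                           seed = 1, sel = selection_spec("backbone")) {
  if (k < 2) stop("need k >= 2 model variants")
  base <- bundle$structure
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  if (is.null(planted_coords)) {
    ang <- runif(k, 0, 2 * pi)
    rad <- spread * sqrt(runif(k))
    planted_coords <- cbind(rad * cos(ang), rad * sin(ang))
  }
  planted_coords <- as.matrix(planted_coords)
  if (nrow(planted_coords) != k || ncol(planted_coords) != 2) {
    stop("planted_coords must be k x 2")
  }
  idx <- resolve_selection(base, sel, NULL)
  basis <- .displacement_basis(base$xyz, idx, 2)
  models <- lapply(seq_len(k), function(i) {
    s <- base
    s$xyz <- base$xyz + planted_coords[i, 1] * basis[[1]] +
      planted_coords[i, 2] * basis[[2]]
    s$model_id <- paste0("M", i)
    s
  })
  attr(models, "planted_coords") <- planted_coords
  models
}

#' Embed a planted distance matrix as 2D coordinates (for model sets)
#'
#' Utility for scripting model sets from a target distance matrix rather
#' than coordinates; errors if the matrix is not exactly 2D-embeddable.
#'
#' @param d symmetric distance matrix.
#' @param tol embeddability tolerance on stress.
#' @return k x 2 coordinate matrix.
#' @export
coords_from_distances <- function(d, tol = 1e-6) {
  emb <- classical_mds(d, dims = 2)
  if (emb$stress > tol) {
    stop("distance set is not 2D-embeddable (stress ", signif(emb$stress, 3), ")")
  }
  unname(emb$coords)
}

#' Plant a synthetic aligned MSA with controlled conservation
#'
#' Builds `n` aligned sequences in which exactly `n_conserved` carry
#' aspartate/glutamate at both anchor columns; the remainder carry a
#' non-acidic residue at one (or both) of them. Mirrors the computation of
#' family-wide conservation statistics at BW 2.50/3.39.
#'
#' @param n sequences.
#' @param n_conserved sequences with D/E at both anchors.
#' @param width alignment width.
#' @param anchor_cols 2-vector of anchor column indices.
#' @param seed RNG seed.
#' @return list: `msa` (character vector), `anchor_cols` (named by BW label).
#' @export
make_msa <- function(n = 100, n_conserved = 93, width = 40,
                     anchor_cols = c(10, 25), seed = 1) {
  if (n_conserved > n) stop("n_conserved cannot exceed n")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  alphabet <- strsplit("ACFGHIKLMNPQRSTVWY", "")[[1]] # no D/E in background
  msa <- vapply(seq_len(n), function(i) {
    s <- sample(alphabet, width, replace = TRUE)
    if (i <= n_conserved) {
      s[anchor_cols] <- sample(c("D", "E"), 2, replace = TRUE)
    } else {
      # spoil at least one anchor; the other may be acidic or not
      spoil <- sample(1:2, 1)
      s[anchor_cols[spoil]] <- sample(c(alphabet, "-"), 1)
      s[anchor_cols[-spoil]] <- sample(c("D", "E", "S", "A"), 1)
    }
    paste(s, collapse = "")
  }, character(1))
  names(msa) <- sprintf("OR%03d", seq_len(n))
  list(msa = msa, anchor_cols = c("2.50" = anchor_cols[1], "3.39" = anchor_cols[2]))
}
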