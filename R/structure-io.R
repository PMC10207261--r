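# Structures, trajectories, Ballesteros-Weinstein maps, helix definitions and
# atom selections. PDB parsing/writing is delegated to bio3d; the plain-text
# frame dialect is this package's own portable trajectory format.

STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP"
)
WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "SPC")
ION_RESNAMES <- c("NA", "SOD", "CL", "CLA", "K", "POT", "MG", "CA2", "ZN")

#' Construct a molecular structure
#'
#' A structure is an ordered atom table plus Cartesian coordinates in
#' Angstrom. Residue numbering is kept 1-based exactly as in the source file;
#' no renumbering is ever performed.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resno`
#'   (integer), `resname` (3-letter code), `chain`, and optionally `type`
#'   (`"ATOM"`/`"HETATM"`).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param model_id identifier string for the model this structure represents.
#' @return An object of class `or_structure`.
#' @export
or_structure <- function(atoms, xyz, model_id = "model") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("atom_name", "element", "resno", "resname", "chain")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    stop("xyz must be an n_atoms x 3 matrix")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, atom_name) triple: ", key[anyDuplicated(key)])
  }
  structure(
    list(atoms = atoms, xyz = xyz, model_id = as.character(model_id)),
    class = "or_structure"
  )
}

#' @export
print.or_structure <- function(x, ...) {
  cat(sprintf(
    "<or_structure '%s': %d atoms, %d residues, chains %s>\n",
    x$model_id, nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
    paste(unique(x$atoms$chain), collapse = ",")
  ))
  invisible(x)
}

n_atoms <- function(struct) nrow(struct$atoms)

#' Atom class predicates
#'
#' Waters and ions are recognised by residue name; hydrogens by
#' `element == "H"`. Everything with a standard amino-acid residue name is
#' protein.
#'
#' @param struct an `or_structure`.
#' @return logical vector over atoms.
#' @export
is_water_atom <- function(struct) struct$atoms$resname %in% WATER_RESNAMES

#' @rdname is_water_atom
#' @export
is_ion_atom <- function(struct) struct$atoms$resname %in% ION_RESNAMES

#' @rdname is_water_atom
#' @export
is_protein_atom <- function(struct) struct$atoms$resname %in% STANDARD_AA3

infer_element <- function(atom_name) {
  # leading alpha characters of the atom name, digits stripped; two-letter
  # ion names are taken whole, otherwise the first letter is the element
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  el <- substr(nm, 1, 1)
  el[nm %in% c("NA", "CL", "MG", "ZN", "FE", "BR")] <- nm[nm %in% c("NA", "CL", "MG", "ZN", "FE", "BR")]
  el
}

parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  box <- suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33)
  )))
  ang <- suppressWarnings(as.numeric(c(
    substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54)
  )))
  if (any(is.na(box))) return(NULL)
  if (!all(is.na(ang)) && any(abs(ang - 90) > 1e-3)) {
    stop("non-orthorhombic box in CRYST1 record; only orthorhombic boxes are supported")
  }
  box
}

pdb_to_structures <- function(pdb, model_prefix) {
  atom <- pdb$atom
  element <- atom$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- infer_element(atom$elety[blank])
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    atom_name = atom$elety,
    element = trimws(element),
    resno = as.integer(atom$resno),
    resname = atom$resid,
    chain = chain,
    type = atom$type,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    or_structure(atoms, coords,
                 model_id = if (nrow(xyz) == 1) model_prefix else sprintf("%s_%d", model_prefix, m))
  })
}

#' Read structures from a (multi-model) PDB file
#'
#' Returns one structure per `MODEL` record (a single structure if the file
#' has none). `HETATM` records (waters, ions) are retained and classified by
#' residue name. Coordinates are in Angstrom.
#'
#' @param path PDB file path.
#' @param dialect only `"pdb_multimodel"` is supported.
#' @return list of [or_structure()] objects; the box lengths parsed from a
#'   `CRYST1` record, if present, are attached as attribute `"box"`.
#' @export
read_structures <- function(path, dialect = "pdb_multimodel") {
  dialect <- match.arg(dialect, "pdb_multimodel")
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("malformed PDB '", path, "': ", conditionMessage(e))
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) stop("no atoms found in ", path)
  structs <- pdb_to_structures(pdb, model_prefix = sub("\\.pdb$", "", basename(path)))
  attr(structs, "box") <- parse_cryst1(readLines(path, n = 200))
  structs
}

#' Write structures to a multi-model PDB file
#'
#' All structures must share one atom table; each becomes a `MODEL` block.
#' The atom table round-trips exactly through [read_structures()].
#'
#' @param structs an `or_structure` or a list of them.
#' @param path output path.
#' @param box optional box lengths (3-vector, Angstrom) written as `CRYST1`.
#' @export
write_structures <- function(structs, path, box = NULL) {
  if (inherits(structs, "or_structure")) structs <- list(structs)
  a0 <- structs[[1]]$atoms
  for (s in structs[-1]) {
    if (!identical(s$atoms[c("atom_name", "resno", "resname", "chain")],
                   a0[c("atom_name", "resno", "resname", "chain")])) {
      stop("all structures in one multi-model file must share the atom table")
    }
  }
  xyz <- do.call(rbind, lapply(structs, function(s) as.vector(t(s$xyz))))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = a0$type, resno = a0$resno, resid = a0$resname,
    chain = ifelse(a0$chain == " ", "", a0$chain), elety = a0$atom_name,
    elesy = a0$element, eleno = seq_len(nrow(a0))
  )
  if (!is.null(box)) {
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90)
    writeLines(c(cryst, readLines(path)), path)
  }
  invisible(path)
}

#' Construct a trajectory
#'
#' Ordered frames of coordinates over a fixed topology, with per-frame
#' orthorhombic box lengths and time stamps in nanoseconds.
#'
#' @param topology an [or_structure()]; its coordinates are frame 1's unless
#'   frames are supplied explicitly.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param box per-frame box lengths: a 3-vector (constant box) or an
#'   n_frames x 3 matrix.
#' @param times per-frame time stamps (ns), strictly increasing.
#' @return An object of class `or_trajectory`.
#' @export
or_trajectory <- function(topology, frames, box, times) {
  stopifnot(inherits(topology, "or_structure"))
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    f
  })
  nf <- length(frames)
  if (nf == 0) stop("trajectory needs at least one frame")
  na <- n_atoms(topology)
  bad <- which(vapply(frames, function(f) nrow(f) != na || ncol(f) != 3, logical(1)))
  if (length(bad) > 0) stop("frame ", bad[1], " does not match topology atom count")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3) stop("box must be a 3-vector or n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be positive")
  times <- as.numeric(times)
  if (length(times) != nf) stop("times length must equal number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(topology = topology, frames = frames, box = box, times = times),
    class = "or_trajectory"
  )
}

#' @export
print.or_trajectory <- function(x, ...) {
  cat(sprintf(
    "<or_trajectory: %d frames, %d atoms, %.3g-%.3g ns, box %s A>\n",
    length(x$frames), n_atoms(x$topology), min(x$times), max(x$times),
    paste(sprintf("%.0f", x$box[1, ]), collapse = "x")
  ))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Read a trajectory
#'
#' Two dialects: `"pdb_multimodel"` (each `MODEL` block is a frame; box from
#' the `CRYST1` record unless given) and `"frames"`, this package's plain-text
#' dialect: a first line `natoms <n>`, then per frame a header line
#' `frame <time_ns> <box_x> <box_y> <box_z>` followed by n `x y z` lines.
#'
#' @param path input file.
#' @param dialect `"pdb_multimodel"` or `"frames"`.
#' @param dt_ns frame spacing used to synthesise time stamps for PDB input.
#' @param box box lengths override (3-vector, Angstrom).
#' @return An [or_trajectory()].
#' @export
read_trajectory <- function(path, dialect = c("pdb_multimodel", "frames"),
                            dt_ns = 1, box = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "pdb_multimodel") {
    structs <- read_structures(path)
    if (is.null(box)) box <- attr(structs, "box")
    if (is.null(box)) stop("no CRYST1 record in ", path, "; supply box= explicitly")
    frames <- lapply(structs, `[[`, "xyz")
    return(or_trajectory(structs[[1]], frames, box,
                         times = (seq_along(frames) - 1) * dt_ns))
  }
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) != 2 || hd[1] != "natoms") stop("bad frame-dialect header: ", lines[1])
  na <- as.integer(hd[2])
  body <- lines[-1]
  per <- na + 1
  nf <- length(body) %/% per
  if (nf * per != length(body)) stop("truncated frame file: ", path)
  frames <- vector("list", nf)
  boxes <- matrix(0, nf, 3)
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    block <- body[((f - 1) * per + 1):(f * per)]
    fh <- strsplit(trimws(block[1]), "\\s+")[[1]]
    if (fh[1] != "frame") stop("expected frame header at frame ", f)
    times[f] <- as.numeric(fh[2])
    boxes[f, ] <- as.numeric(fh[3:5])
    coords <- matrix(scan(text = block[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    frames[[f]] <- coords
  }
  topo_atoms <- data.frame(
    atom_name = rep("CA", na), element = rep("C", na), resno = seq_len(na),
    resname = rep("ALA", na), chain = rep("A", na), stringsAsFactors = FALSE
  )
  or_trajectory(or_structure(topo_atoms, frames[[1]]), frames, boxes, times)
}

#' Write a trajectory
#'
#' @param traj an [or_trajectory()].
#' @param path output file.
#' @param dialect `"pdb_multimodel"` or `"frames"` (see [read_trajectory()]).
#' @export
write_trajectory <- function(traj, path, dialect = c("pdb_multimodel", "frames")) {
  dialect <- match.arg(dialect)
  if (dialect == "pdb_multimodel") {
    structs <- lapply(seq_len(n_frames(traj)), function(f) {
      s <- traj$topology
      s$xyz <- traj$frames[[f]]
      s
    })
    return(write_structures(structs, path, box = traj$box[1, ]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("natoms %d", n_atoms(traj$topology)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %.10g %.6f %.6f %.6f", traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    writeLines(sprintf("%.6f %.6f %.6f", traj$frames[[f]][, 1],
                       traj$frames[[f]][, 2], traj$frames[[f]][, 3]), con)
  }
  invisible(path)
}

# ---- Ballesteros-Weinstein maps ---------------------------------------------

#' Ballesteros-Weinstein residue map
#'
#' Maps source-file residue numbers to Ballesteros-Weinstein labels of the
#' form `"T.NN"` (helix T, offset NN from the helix's x.50 anchor) or the loop
#' form (e.g. `"45.50"`). Maps are supplied as data, never inferred from
#' sequence motifs: motif conservation in olfactory receptors is too weak for
#' inference to be safe.
#'
#' @param resno integer residue numbers.
#' @param label character BW labels, same length.
#' @return An object of class `bw_map`.
#' @export
bw_map <- function(resno, label) {
  resno <- as.integer(resno)
  label <- as.character(label)
  if (length(resno) != length(label)) stop("resno and label lengths differ")
  ok <- grepl("^[0-9]{1,2}\\.[0-9]{2}$", label)
  if (any(!ok)) stop("BW label does not parse as segment.index: ", label[!ok][1])
  if (anyDuplicated(label)) stop("BW map not injective: duplicate label ", label[anyDuplicated(label)])
  if (anyDuplicated(resno)) stop("duplicate residue number in BW map")
  structure(data.frame(resno = resno, bw = label, stringsAsFactors = FALSE),
            class = c("bw_map", "data.frame"))
}

#' Read a BW map from a two-column TSV (residue_number, label)
#' @param path TSV file, optional header line.
#' @return a [bw_map()].
#' @export
read_bw_map <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("resno", "bw"), colClasses = "character")
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.integer(tab$resno[1])))) {
    tab <- tab[-1, , drop = FALSE] # header line
  }
  bw_map(as.integer(tab$resno), tab$bw)
}

#' Write a BW map as TSV
#' @param map a [bw_map()].
#' @param path output path.
#' @export
write_bw_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Look up the residue number carrying a BW label
#'
#' @param map a [bw_map()].
#' @param label BW label, e.g. `"2.50"`.
#' @return integer residue number.
#' @export
bw_lookup <- function(map, label) {
  hit <- match(label, map$bw)
  if (is.na(hit)) stop("BW label not in map: ", label)
  map$resno[hit]
}

#' Forward lookup: BW label of a residue number (NA if unmapped)
#' @rdname bw_lookup
#' @param resno residue number.
#' @export
bw_label <- function(map, resno) {
  map$bw[match(resno, map$resno)]
}

# ---- Helix definitions ------------------------------------------------------

#' Transmembrane helix residue ranges
#'
#' @param ranges named list, each element an inclusive `c(first, last)`
#'   residue-number interval; names are helix names (`TM1`..`TM7`, optionally
#'   `H8`). Intervals must not overlap and must span at least 6 residues.
#' @return An object of class `helix_set`.
#' @export
helix_set <- function(ranges) {
  if (is.null(names(ranges)) || any(!nzchar(names(ranges)))) {
    stop("helix ranges must be named")
  }
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || r[2] < r[1]) stop("each range must be c(first, last)")
    r
  })
  len <- vapply(ranges, function(r) r[2] - r[1] + 1L, integer(1))
  if (any(len < 6)) stop("helix ", names(ranges)[len < 6][1], " shorter than 6 residues")
  ord <- order(vapply(ranges, `[`, integer(1), 1))
  sorted <- ranges[ord]
  for (i in seq_along(sorted)[-1]) {
    if (sorted[[i]][1] <= sorted[[i - 1]][2]) {
      stop("helix ranges overlap: ", names(sorted)[i - 1], " and ", names(sorted)[i])
    }
  }
  structure(ranges, class = "helix_set")
}

#' Read helix ranges from a YAML file (`TM1: [start, end]`, ...)
#' @param path YAML file.
#' @return a [helix_set()].
#' @export
read_helix_set <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' is required")
  helix_set(yaml::read_yaml(path))
}

#' Write helix ranges as YAML
#' @param helices a [helix_set()].
#' @param path output path.
#' @export
write_helix_set <- function(helices, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' is required")
  yaml::write_yaml(lapply(unclass(helices), as.integer), path)
  invisible(path)
}

helix_resnos <- function(helices, which = names(helices)) {
  unlist(lapply(helices[which], function(r) seq(r[1], r[2])), use.names = FALSE)
}

# ---- Atom selections --------------------------------------------------------

#' Atom selection specification
#'
#' Selections are resolved deterministically to sorted atom indices; the same
#' spec on topologically identical structures yields identical index lists.
#' The `backbone` class is exactly N, CA, C, O per selected residue; `heavy`
#' is every non-hydrogen atom; `calpha` is CA only. Waters and ions are
#' excluded unless `protein_only = FALSE` or an explicit residue whitelist
#' names them.
#'
#' @param atoms atom class: `"backbone"`, `"heavy"` or `"calpha"`.
#' @param helices optional character vector of helix names to restrict to.
#' @param residues optional integer residue-number whitelist.
#' @param protein_only drop waters/ions (default TRUE).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(atoms = c("backbone", "heavy", "calpha"),
                           helices = NULL, residues = NULL, protein_only = TRUE) {
  atoms <- match.arg(atoms)
  structure(list(atoms = atoms, helices = helices,
                 residues = if (is.null(residues)) NULL else as.integer(residues),
                 protein_only = isTRUE(protein_only)),
            class = "selection_spec")
}

#' Resolve a selection to atom indices
#'
#' @param struct an [or_structure()].
#' @param sel a [selection_spec()].
#' @param helices a [helix_set()]; required when the spec names helices.
#' @return sorted integer atom indices (in atom-table order).
#' @export
resolve_selection <- function(struct, sel, helices = NULL) {
  stopifnot(inherits(struct, "or_structure"), inherits(sel, "selection_spec"))
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (sel$protein_only) keep <- keep & is_protein_atom(struct)
  keep <- keep & switch(sel$atoms,
    backbone = a$atom_name %in% c("N", "CA", "C", "O"),
    heavy = a$element != "H",
    calpha = a$atom_name == "CA"
  )
  if (!is.null(sel$helices)) {
    if (is.null(helices)) stop("selection names helices but no helix_set supplied")
    missing_h <- setdiff(sel$helices, names(helices))
    if (length(missing_h) > 0) stop("unknown helix: ", missing_h[1])
    keep <- keep & a$resno %in% helix_resnos(helices, sel$helices)
  }
  if (!is.null(sel$residues)) keep <- keep & a$resno %in% sel$residues
  idx <- which(keep)
  if (length(idx) == 0) stop("selection resolves to zero atoms")
  idx
}
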