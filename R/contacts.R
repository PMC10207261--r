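# Interhelix residue contact maps, interface comparison between models, and
# residue conservation counting at Ballesteros-Weinstein positions.

#' Construct a contact map
#'
#' @param pairs data.frame with columns `res_a`, `res_b` (residue numbers on
#'   the two helices) and `min_dist` (minimum heavy-atom distance, Angstrom).
#' @param pair the two helix names.
#' @param cutoff contact cutoff (Angstrom); every recorded distance must be
#'   `<= cutoff`.
#' @return data.frame of class `contact_map`.
#' @export
contact_map <- function(pairs, pair, cutoff) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("res_a", "res_b", "min_dist") %in% names(pairs)))
  if (any(pairs$min_dist > cutoff + 1e-9)) {
    stop("contact map contains a pair beyond the cutoff")
  }
  structure(pairs, class = c("contact_map", "data.frame"),
            helix_pair = as.character(pair), cutoff = cutoff)
}

#' Residue contacts between two helices
#'
#' A residue pair is in contact when the minimum distance between their
#' heavy atoms is at or below the cutoff. The default 4.5 Angstrom is a
#' conventional heavy-atom contact criterion; it is recorded on the output.
#'
#' @param struct an [or_structure()] (typically a cluster centroid).
#' @param helices a [helix_set()].
#' @param pair two helix names, default `c("TM6", "TM7")`.
#' @param cutoff Angstrom, > 0.
#' @return a [contact_map()]: one row per contacting residue pair with its
#'   minimum heavy-atom distance.
#' @export
interhelix_contacts <- function(struct, helices, pair = c("TM6", "TM7"),
                                cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- struct$atoms
  heavy <- a$element != "H" & is_protein_atom(struct)
  res_atoms <- function(hname) {
    r <- helices[[hname]]
    if (is.null(r)) stop("helix not defined: ", hname)
    idx <- which(heavy & a$resno >= r[1] & a$resno <= r[2])
    if (length(idx) == 0) stop("helix ", hname, " resolves to zero heavy atoms")
    split(idx, a$resno[idx])
  }
  atoms_a <- res_atoms(pair[1])
  atoms_b <- res_atoms(pair[2])
  rows <- list()
  for (ra in names(atoms_a)) {
    xa <- struct$xyz[atoms_a[[ra]], , drop = FALSE]
    for (rb in names(atoms_b)) {
      xb <- struct$xyz[atoms_b[[rb]], , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      mind <- sqrt(max(min(d2), 0))
      if (mind <= cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          res_a = as.integer(ra), res_b = as.integer(rb), min_dist = mind
        )
      }
    }
  }
  pairs <- if (length(rows) == 0) {
    data.frame(res_a = integer(), res_b = integer(), min_dist = numeric())
  } else {
    do.call(rbind, rows)
  }
  contact_map(pairs, pair, cutoff)
}

#' Compare two helix-interface contact maps
#'
#' Partitions, for each helix side, the interface residues into those shared
#' by both maps and those unique to one — the comparison used to spot a
#' helix-register shift between two models of the same receptor.
#'
#' @param map_a,map_b [contact_map()]s over the same helix pair.
#' @return list of class `interface_diff`, one element per helix side, each
#'   with `shared`, `only_a`, `only_b` residue-number sets.
#' @export
compare_interfaces <- function(map_a, map_b) {
  pa <- attr(map_a, "helix_pair"); pb <- attr(map_b, "helix_pair")
  if (!identical(pa, pb)) {
    stop("helix-pair mismatch: ", paste(pa, collapse = "-"), " vs ",
         paste(pb, collapse = "-"))
  }
  side <- function(col) {
    ra <- sort(unique(map_a[[col]])); rb <- sort(unique(map_b[[col]]))
    list(shared = intersect(ra, rb), only_a = setdiff(ra, rb),
         only_b = setdiff(rb, ra))
  }
  structure(setNames(list(side("res_a"), side("res_b")), pa),
            class = "interface_diff")
}

#' Residue conservation at aligned BW-anchored columns
#'
#' Given an alignment and the column carrying each Ballesteros-Weinstein
#' position of interest, counts the fraction of sequences whose residue at
#' that column is in the allowed set, and the joint fraction satisfying all
#' positions at once. Gaps count as not allowed.
#'
#' @param msa aligned sequences: a character vector of equal-length strings,
#'   a character matrix (rows = sequences), or a `Biostrings::AAStringSet`.
#' @param anchor_cols named integer vector: BW label -> alignment column.
#' @param allowed named list of allowed one-letter residue sets per BW label;
#'   default aspartate/glutamate (`D`/`E`) at every position.
#' @return list: `per_position` (named fractions), `joint` (fraction with all
#'   positions allowed), `n` (number of sequences).
#' @export
conservation_at_positions <- function(msa, anchor_cols, allowed = NULL) {
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  if (is.character(msa) && is.null(dim(msa))) {
    if (length(unique(nchar(msa))) != 1) stop("sequences are not aligned (unequal lengths)")
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  msa <- as.matrix(msa)
  if (nrow(msa) == 0) stop("empty alignment")
  if (is.null(names(anchor_cols)) || any(!nzchar(names(anchor_cols)))) {
    stop("anchor_cols must be named by BW label")
  }
  bad <- anchor_cols < 1 | anchor_cols > ncol(msa) | is.na(anchor_cols)
  if (any(bad)) stop("anchor column missing for position ", names(anchor_cols)[bad][1])
  if (is.null(allowed)) {
    allowed <- setNames(rep(list(c("D", "E")), length(anchor_cols)), names(anchor_cols))
  }
  ok <- vapply(names(anchor_cols), function(p) {
    msa[, anchor_cols[[p]]] %in% allowed[[p]]
  }, logical(nrow(msa)))
  ok <- matrix(ok, nrow = nrow(msa))
  per <- colMeans(ok)
  names(per) <- names(anchor_cols)
  list(per_position = per, joint = mean(rowSums(ok) == ncol(ok)), n = nrow(msa))
}

#' Read an aligned FASTA file as a character vector of sequences
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_msa_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package 'Biostrings' is required to read FASTA alignments")
  }
  as.character(Biostrings::readAAStringSet(path))
}
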