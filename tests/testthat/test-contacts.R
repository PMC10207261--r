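# Contact maps, interface comparison and conservation counting.

# two short parallel "helices" whose residue ladders are a known distance apart
two_helix_structure <- function(gap = 4.0, n = 6) {
  rows <- list(); coords <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      atom_name = c("CA", "CB"), element = "C", resno = i, resname = "ALA",
      chain = "A", stringsAsFactors = FALSE
    )
    coords[[length(coords) + 1]] <- rbind(c(0, 0, 3 * i), c(1, 0, 3 * i))
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      atom_name = c("CA", "CB"), element = "C", resno = 100 + i, resname = "ALA",
      chain = "A", stringsAsFactors = FALSE
    )
    coords[[length(coords) + 1]] <- rbind(c(1 + gap + 1, 0, 3 * i),
                                          c(1 + gap, 0, 3 * i))
  }
  s <- or_structure(do.call(rbind, rows), do.call(rbind, coords))
  hs <- helix_set(list(TM6 = c(1, n), TM7 = c(101, 100 + n)))
  list(struct = s, helices = hs)
}

test_that("contacts appear at and below the cutoff with recorded distances", {
  fx <- two_helix_structure(gap = 4.0)
  cm <- interhelix_contacts(fx$struct, fx$helices, cutoff = 4.5)
  expect_true(nrow(cm) >= 6) # each opposing pair at 4.0
  same_rung <- cm[cm$res_b - cm$res_a == 100, ]
  expect_equal(same_rung$min_dist, rep(4.0, nrow(same_rung)), tolerance = 1e-9)

  none <- interhelix_contacts(two_helix_structure(gap = 5.0)$struct,
                              fx$helices, cutoff = 4.5)
  expect_equal(nrow(none), 0)
  expect_error(interhelix_contacts(fx$struct, fx$helices, cutoff = -1),
               "positive")
})

test_that("contact maps are monotone in the cutoff (subset property)", {
  b <- small_bundle()
  tight <- interhelix_contacts(b$structure, b$helices, c("TM6", "TM7"), 5)
  loose <- interhelix_contacts(b$structure, b$helices, c("TM6", "TM7"), 7)
  key <- function(cm) paste(cm$res_a, cm$res_b)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gt(nrow(loose), nrow(tight))
})

test_that("a planted one-turn register shift moves the contact ladder", {
  b <- small_bundle(n_helices = 7, residues_per_helix = 15)
  s <- b$structure
  # shift TM6 along its axis by one helical turn (~3.6 residues * 1.5 A rise)
  r6 <- b$helices[["TM6"]]
  i6 <- which(s$atoms$resno >= r6[1] & s$atoms$resno <= r6[2])
  s2 <- s
  s2$xyz[i6, 3] <- s2$xyz[i6, 3] + 3.6 * 1.5
  cm_a <- interhelix_contacts(s, b$helices, c("TM6", "TM7"), 7)
  cm_b <- interhelix_contacts(s2, b$helices, c("TM6", "TM7"), 7)
  # per TM7 residue, the closest TM6 partner shifts by 3-4 positions
  closest <- function(cm) {
    sapply(split(cm, cm$res_b), function(g) g$res_a[which.min(g$min_dist)])
  }
  ca <- closest(cm_a); cb <- closest(cm_b)
  common <- intersect(names(ca), names(cb))
  expect_gt(length(common), 3)
  shifts <- cb[common] - ca[common]
  expect_equal(median(shifts), 4, tolerance = 1)
})

test_that("interface comparison partitions shared and unique residues", {
  mk <- function(res_a, res_b) {
    grid <- expand.grid(res_a = res_a, res_b = res_b)
    contact_map(cbind(grid, min_dist = 4.0), c("TM6", "TM7"), 4.5)
  }
  a <- mk(c(242L, 246L, 250L), c(279L, 286L, 290L))
  # identical maps: only shared
  same <- compare_interfaces(a, a)
  expect_equal(same$TM6$shared, c(242L, 246L, 250L))
  expect_length(same$TM6$only_a, 0)
  # disjoint maps: nothing shared
  disj <- compare_interfaces(mk(1:3, 10:12), mk(4:6, 13:15))
  expect_length(disj$TM6$shared, 0)
  # the hOR51E2 TM6-TM7 interface comparison: both models keep Y279/I286/I290
  # on TM7, while V246 is the only TM6 residue identified in both
  b <- mk(c(239L, 243L, 246L), c(279L, 286L, 290L))
  diff_ab <- compare_interfaces(a, b)
  expect_equal(diff_ab$TM6$shared, 246L)
  expect_equal(diff_ab$TM7$shared, c(279L, 286L, 290L))
  expect_equal(diff_ab$TM6$only_a, c(242L, 250L))
  expect_equal(diff_ab$TM6$only_b, c(239L, 243L))
  # symmetry: swapping arguments swaps only_a/only_b
  diff_ba <- compare_interfaces(b, a)
  expect_equal(diff_ba$TM6$only_a, diff_ab$TM6$only_b)
  expect_equal(diff_ba$TM6$only_b, diff_ab$TM6$only_a)
  # helix-pair mismatch
  c_map <- contact_map(data.frame(res_a = 1L, res_b = 2L, min_dist = 3),
                       c("TM1", "TM2"), 4.5)
  expect_error(compare_interfaces(a, c_map), "mismatch")
})

test_that("conservation fractions count allowed residues, gaps disallowed", {
  all_d <- c("AADAA", "CCDCC", "WWDWW")
  res <- conservation_at_positions(all_d, c("2.50" = 3))
  expect_equal(unname(res$per_position), 1.0)
  half <- c("AADAA", "AASAA")
  expect_equal(unname(conservation_at_positions(half, c("2.50" = 3))$per_position), 0.5)
  gap <- c("AA-AA", "AADAA")
  expect_equal(unname(conservation_at_positions(gap, c("2.50" = 3))$per_position), 0.5)
  expect_error(conservation_at_positions(all_d, c("2.50" = 99)), "2\\.50")
  expect_error(conservation_at_positions(c("AAA", "AAAA"), c("2.50" = 1)),
               "aligned")
})

test_that("joint conservation is exact on planted MSAs and bounded by per-position", {
  planted <- make_msa(n = 100, n_conserved = 93, seed = 17)
  res <- conservation_at_positions(planted$msa, planted$anchor_cols)
  expect_equal(res$joint, 0.93)
  expect_true(all(res$joint <= res$per_position + 1e-12))
  expect_equal(res$n, 100)
  # FASTA round trip preserves the computation
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(planted$msa), "\n", planted$msa), path)
  back <- read_msa_fasta(path)
  expect_equal(conservation_at_positions(back, planted$anchor_cols)$joint, 0.93)
})
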