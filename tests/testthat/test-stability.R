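# Stability descriptors: RMSD series, helix axes and TM spacing, activation
# index, sodium-site occupancy.

# 20 CA-only residues; residues 1-10 are the (static) fit set
drift_trajectory <- function(n_frames = 6, step = 0.1) {
  set.seed(42)
  base <- matrix(rnorm(60, sd = 5), 20, 3)
  topo <- ca_structure(base)
  frames <- lapply(seq_len(n_frames), function(f) {
    x <- base
    x[11:20, 1] <- x[11:20, 1] + step * (f - 1)
    x
  })
  or_trajectory(topo, frames, c(100, 100, 120), times = seq_len(n_frames) - 1)
}

test_that("rmsd series is zero for identical frames and linear under scripted drift", {
  traj <- drift_trajectory(step = 0)
  fit <- selection_spec("calpha", residues = 1:10)
  meas <- selection_spec("calpha", residues = 11:20)
  flat <- rmsd_timeseries(traj, fit_sel = fit, measure_sel = meas)
  expect_equal(flat$values, rep(0, 6), tolerance = 1e-10)

  traj <- drift_trajectory(step = 0.1)
  got <- rmsd_timeseries(traj, fit_sel = fit, measure_sel = meas)
  expect_equal(got$values, 0.1 * (0:5), tolerance = 1e-6)
})

test_that("rmsd series is frame-wise independent (reversal reverses values)", {
  traj <- drift_trajectory(step = 0.1)
  fit <- selection_spec("calpha", residues = 1:10)
  meas <- selection_spec("calpha", residues = 11:20)
  fwd <- rmsd_timeseries(traj, fit_sel = fit, measure_sel = meas)
  ref <- traj$topology # frame-1 coords as explicit reference
  rev_traj <- reverse_trajectory(traj)
  bwd <- rmsd_timeseries(rev_traj, reference = ref, fit_sel = fit,
                         measure_sel = meas)
  expect_equal(bwd$values, rev(fwd$values), tolerance = 1e-9)
})

ideal_helix_ca <- function(m = 120, rise = 1.5, twist = 100, center = c(0, 0)) {
  i <- seq_len(m) - 1
  phi <- twist * pi / 180 * i
  cbind(center[1] + 2.3 * cos(phi), center[2] + 2.3 * sin(phi), rise * i)
}

test_that("helix axis recovers orientation for ideal and rotated helices", {
  ca <- ideal_helix_ca()
  ax <- helix_axis(ca)
  expect_equal(abs(ax$direction), c(0, 0, 1), tolerance = 1e-3)
  expect_gte(ax$direction[3], 0)
  # rotate 90 degrees about x: z axis -> y axis
  rx <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  ax2 <- helix_axis(ca %*% rx)
  expect_equal(abs(ax2$direction), c(0, 1, 0), tolerance = 1e-3)
  expect_gte(ax2$direction[2], 0)
  # exact line: zero residual
  line <- cbind(0.1 * (1:8), 0.2 * (1:8), 1:8)
  expect_equal(helix_axis(line)$residual, 0, tolerance = 1e-9)
  expect_error(helix_axis(ca[1:5, ]), "6")
})

test_that("tm_pair_distance reads parallel helix spacing and self-distance", {
  ca_a <- ideal_helix_ca(12, center = c(0, 0))
  ca_b <- ideal_helix_ca(12, center = c(10, 0))
  ca_all <- rbind(ca_a, ca_b)
  ca_all[, 3] <- ca_all[, 3] - mean(ca_all[, 3]) # origin-centred
  topo <- ca_structure(ca_all)
  hs <- helix_set(list(TM1 = c(1, 12), TM2 = c(13, 24)))
  traj <- or_trajectory(topo, list(ca_all, ca_all), c(100, 100, 120), c(0, 1))
  got <- tm_pair_distance(traj, hs, pair = c("TM1", "TM2"))
  expect_equal(got$values, c(10, 10), tolerance = 0.3)
  self <- tm_pair_distance(traj, hs, pair = c("TM1", "TM1"))
  expect_equal(self$values, c(0, 0))
  expect_error(tm_pair_distance(traj, hs, pair = c("TM1", "TM9")), "TM9")
  # ca_com mode agrees for parallel vertical helices
  com <- tm_pair_distance(traj, hs, pair = c("TM1", "TM2"), mode = "ca_com")
  expect_equal(com$values, c(10, 10), tolerance = 0.3)
})

test_that("generator splay schedule is recovered at the endpoints, monotonically", {
  b <- small_bundle()
  sched <- event_schedule(
    splay = list(list(pair = c("TM6", "TM7"), frames = c(5, 45), dist = c(8, 14))),
    noise_sigma = 0, seed = 1
  )
  traj <- make_trajectory(b, sched, n_frames = 50)
  got <- tm_pair_distance(traj, b$helices)
  expect_lt(abs(got$values[1] - 8), 0.5)
  expect_lt(abs(got$values[50] - 14), 0.5)
  expect_true(all(diff(got$values) >= -1e-9))
})

activation_fixture <- function() {
  # four CA atoms with planted pair distances: (1,3)=8, (2,4)=6
  xyz <- rbind(c(0, 0, 0), c(0, 10, 0), c(8, 0, 0), c(0, 16, 0))
  topo <- ca_structure(xyz, resno = c(10L, 20L, 30L, 40L))
  bw <- bw_map(c(10L, 20L, 30L, 40L), c("1.50", "2.50", "3.50", "6.50"))
  traj <- or_trajectory(topo, list(xyz, xyz), c(50, 50, 50), c(0, 1))
  list(traj = traj, bw = bw)
}

test_that("activation index evaluates its linear functional exactly", {
  fx <- activation_fixture()
  const <- activation_index(fx$traj, fx$bw, activation_spec(intercept = -1))
  expect_equal(const$values, c(-1, -1))
  one <- activation_spec(data.frame(bw_a = "1.50", bw_b = "3.50", coef = 1))
  expect_equal(activation_index(fx$traj, fx$bw, one)$values, c(8, 8),
               tolerance = 1e-10)
  two <- activation_spec(data.frame(bw_a = c("1.50", "2.50"),
                                    bw_b = c("3.50", "6.50"),
                                    coef = c(1, -0.5)))
  expect_equal(activation_index(fx$traj, fx$bw, two)$values, c(5, 5),
               tolerance = 1e-10)
  bad <- activation_spec(data.frame(bw_a = "1.50", bw_b = "9.99", coef = 1))
  expect_error(activation_index(fx$traj, fx$bw, bad), "9\\.99")
})

test_that("activation index is linear in its coefficients", {
  fx <- activation_fixture()
  pairs <- data.frame(bw_a = c("1.50", "2.50"), bw_b = c("3.50", "6.50"))
  v <- function(coef, icpt = 0) {
    activation_index(fx$traj, fx$bw,
                     activation_spec(cbind(pairs, coef = coef), icpt))$values[1]
  }
  a <- c(1, -0.5); bb <- c(0.3, 2)
  expect_equal(v(a) + v(bb), v(a + bb), tolerance = 1e-10)
  expect_equal(2 * v(a, 1), v(2 * a, 2), tolerance = 1e-10)
})

test_that("ion occupancy follows the carboxylate geometry exactly", {
  b <- small_bundle()
  # bound from the first frame
  tr_bound <- make_trajectory(
    b, event_schedule(ion_binding = list(list(frame = 1, bound = TRUE)),
                      noise_sigma = 0, seed = 2), n_frames = 10
  )
  occ <- ion_site_occupancy(tr_bound, b$bw)
  expect_equal(occ$occupancy, 1.0)
  expect_equal(occ$first_binding_time, tr_bound$times[1])
  # never bound
  tr_free <- make_trajectory(
    b, event_schedule(ion_binding = list(list(frame = 1, bound = FALSE)),
                      noise_sigma = 0, seed = 2), n_frames = 10
  )
  occ0 <- ion_site_occupancy(tr_free, b$bw)
  expect_equal(occ0$occupancy, 0.0)
  expect_true(is.na(occ0$first_binding_time))
  # mutated site: no coordinating atoms
  expect_error(
    ion_site_occupancy(tr_bound, b$bw,
                       ion_site_spec(atoms = c("XX1", "XX2"))),
    "coordinating"
  )
})

test_that("occupancy is in [0,1] and monotone non-decreasing in the cutoff", {
  b <- small_bundle()
  tr <- make_trajectory(
    b, event_schedule(ion_binding = list(list(frame = 1, bound = FALSE),
                                         list(frame = 6, bound = TRUE)),
                      noise_sigma = 0.05, seed = 5), n_frames = 12
  )
  cutoffs <- c(0.5, 1, 2, 3, 5, 10, 60)
  occs <- vapply(cutoffs, function(cc) {
    ion_site_occupancy(tr, b$bw, ion_site_spec(contact_cutoff = cc))$occupancy
  }, numeric(1))
  expect_true(all(occs >= 0 & occs <= 1))
  expect_true(all(diff(occs) >= 0))
})
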