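# Water permeation: unwrapping, region assignment, event detection on
# hand-built paths and on generator-planted schedules.

test_that("unwrap_z handles constant, wrapping and drifting series", {
  expect_equal(unwrap_z(rep(3, 5), 120), rep(3, 5))
  # hand-traced minimum image: 59 -> -59 in a 120 box continues to 61
  expect_equal(unwrap_z(c(59, -59), 120), c(59, 61))
  drift <- seq(-30, 30, by = 5)
  expect_equal(unwrap_z(drift, 120), drift)
  # a full multi-wrap walk is restored to a straight line
  true_z <- seq(0, 400, by = 7)
  wrapped <- true_z - 120 * round(true_z / 120)
  expect_equal(unwrap_z(wrapped, 120), true_z)
})

test_that("assign_region discretizes the slab/cylinder geometry", {
  spec <- compartment_spec(z_lower = -20, z_upper = 20, cylinder_radius = 12)
  expect_equal(assign_region(c(0, 0), -21, spec), "IC")
  expect_equal(assign_region(c(0, 0), 21, spec), "EC")
  expect_equal(assign_region(c(12.1, 0), 0, spec), "BULK")
  expect_equal(assign_region(c(11.9, 0), 0, spec), "TM")
  expect_equal(assign_region(c(0, 0), -20, spec), "TM") # boundary inside slab
})

# topology: 8 protein CA atoms ringed around the origin (bundle centroid)
# plus one water oxygen whose path we script frame by frame
path_trajectory <- function(water_xyz, box = c(100, 100, 120)) {
  ang <- 2 * pi * (0:7) / 8
  prot <- cbind(6 * cos(ang), 6 * sin(ang), seq(-14, 14, length.out = 8))
  atoms <- data.frame(
    atom_name = c(rep("CA", 8), "O"),
    element = c(rep("C", 8), "O"),
    resno = c(1:8, 101L),
    resname = c(rep("ALA", 8), "HOH"),
    chain = c(rep("A", 8), "W"),
    stringsAsFactors = FALSE
  )
  frames <- lapply(seq_len(nrow(water_xyz)), function(f) {
    rbind(prot, water_xyz[f, , drop = FALSE])
  })
  topo <- or_structure(atoms, frames[[1]])
  or_trajectory(topo, frames, box, times = seq_len(length(frames)) - 1)
}

test_that("a monotone through-cylinder path yields exactly one IC->EC event", {
  z <- seq(-35, 35, length.out = 15)
  traj <- path_trajectory(cbind(0, 0, z))
  ev <- detect_permeations(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "IC->EC")
  expect_equal(ev$water_id, "W101")
  expect_lte(ev$entry_frame, ev$exit_frame)
  # entry is the first TM frame, exit the first EC frame
  expect_equal(ev$entry_frame, which(z >= -20)[1])
  expect_equal(ev$exit_frame, which(z > 20)[1])
})

test_that("bounce-backs and around-the-protein routes produce no events", {
  z_bounce <- c(-30, -25, -15, -5, -15, -25, -30)
  expect_equal(nrow(detect_permeations(path_trajectory(cbind(0, 0, z_bounce)))), 0)
  # crosses the slab but radially outside the cylinder: through BULK
  z_around <- seq(-35, 35, length.out = 15)
  expect_equal(nrow(detect_permeations(path_trajectory(cbind(30, 0, z_around)))), 0)
})

test_that("a PBC wrap while drifting in the extracellular bulk is not a crossing", {
  # apparent jump +59 -> -59 (box 120) during upward EC drift
  z <- c(25, 30, 40, 50, 59, -59, -55, -50)
  traj <- path_trajectory(cbind(0, 0, z))
  expect_equal(nrow(detect_permeations(traj)), 0)
})

test_that("a water can permeate more than once and directions are tracked", {
  up <- seq(-30, 30, length.out = 9)
  z <- c(up, rev(up)[-1]) # IC -> EC -> IC
  traj <- path_trajectory(cbind(0, 0, z))
  ev <- detect_permeations(traj)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$direction, c("IC->EC", "EC->IC"))
})

test_that("time reversal swaps the direction counts exactly", {
  b <- small_bundle()
  sched <- event_schedule(
    permeations = list(
      permeation_script(1, 5, 20, "IC->EC"),
      permeation_script(2, 30, 15, "IC->EC", wrap = TRUE),
      permeation_script(3, 10, 25, "EC->IC"),
      permeation_script(4, 40, 10, "IC->EC", kind = "bounce")
    ),
    n_bulk_waters = 3, noise_sigma = 0, seed = 9
  )
  traj <- make_trajectory(b, sched, n_frames = 60)
  fwd <- permeation_summary(detect_permeations(traj, helices = b$helices), traj)
  bwd <- permeation_summary(
    detect_permeations(reverse_trajectory(traj), helices = b$helices), traj
  )
  expect_equal(fwd$n_ic_to_ec, 2)
  expect_equal(fwd$n_ec_to_ic, 1)
  expect_equal(bwd$n_ic_to_ec, fwd$n_ec_to_ic)
  expect_equal(bwd$n_ec_to_ic, fwd$n_ic_to_ec)
})

test_that("permeation summary computes per-direction counts and rates", {
  b <- small_bundle(n_helices = 2, residues_per_helix = 8)
  tr <- make_trajectory(b, event_schedule(noise_sigma = 0, seed = 1), n_frames = 5)
  empty <- detect_permeations(
    path_trajectory(cbind(0, 0, rep(-40, 4)))
  )
  s0 <- permeation_summary(empty, path_trajectory(cbind(0, 0, rep(-40, 4))))
  expect_equal(s0$n_total, 0)
  expect_equal(s0$rate_per_100ns, 0)

  # 3 crossings over 500 ns -> 0.6 per 100 ns
  ev3 <- data.frame(water_id = c("a", "b", "c"), entry_frame = 1,
                    exit_frame = 2, direction = "IC->EC")
  traj500 <- path_trajectory(cbind(0, 0, rep(-40, 6)))
  traj500$times <- seq(0, 500, length.out = 6)
  s3 <- permeation_summary(ev3, traj500)
  expect_equal(s3$n_ic_to_ec, 3)
  expect_equal(s3$rate_per_100ns, 0.6)
})

test_that("waters are required and errors name the problem", {
  ang <- 2 * pi * (0:7) / 8
  prot <- ca_structure(cbind(6 * cos(ang), 6 * sin(ang), seq(-14, 14, length.out = 8)))
  traj <- or_trajectory(prot, list(prot$xyz), c(100, 100, 120), 0)
  expect_error(detect_permeations(traj), "water")
})
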