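# Shared fixtures and independent oracles. Everything is built in code; no
# binary fixtures.

# small bundle for fast tests (full 7x25 geometry is exercised where needed)
small_bundle <- function(n_helices = 7, residues_per_helix = 23) {
  make_bundle(bundle_spec(n_helices = n_helices,
                          residues_per_helix = residues_per_helix))
}

# bare structure of CA atoms at given coordinates, one residue per atom
ca_structure <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A",
                         model_id = "test") {
  atoms <- data.frame(
    atom_name = "CA", element = "C", resno = resno, resname = "ALA",
    chain = chain, stringsAsFactors = FALSE
  )
  or_structure(atoms, xyz, model_id)
}

# random proper rotation via QR with sign fix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- independent Kabsch oracle: dense Euler-angle rotation grid -------------
# Uses only the trace identity rmsd^2 = (|A|^2+|B|^2 - 2 tr(R C^T...)) / n,
# evaluated for every grid rotation; no SVD anywhere.
euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  rz1 %*% ry %*% rz2
}

grid_rmsd_oracle <- function(mobile, target, step_deg = 3) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(target, 2, colMeans(target))
  cv <- crossprod(a, b) # maximize tr(t(R) %*% cv) over rotations R (a %*% R ~ b)
  n <- nrow(a)
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- alphas
  best <- -Inf
  for (be in betas) {
    for (al in alphas) {
      for (ga in gammas) {
        r <- euler_rotation(al, be, ga)
        tr <- sum(r * cv)
        if (tr > best) best <- tr
      }
    }
  }
  sqrt(max((sum(a^2) + sum(b^2) - 2 * best) / n, 0))
}

# vectorised version (rotations precomputed as m x 9), for the acceptance run
grid_rmsd_oracle_fast <- function(mobile, target, grid9) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(target, 2, colMeans(target))
  cv <- crossprod(a, b)
  n <- nrow(a)
  tr <- as.vector(grid9 %*% as.vector(cv))
  sqrt(max((sum(a^2) + sum(b^2) - 2 * max(tr)) / n, 0))
}

euler_grid9 <- function(step_deg = 3) {
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  g <- expand.grid(a = alphas, b = betas, c = alphas)
  t(mapply(function(a, b, c) as.vector(euler_rotation(a, b, c)),
           g$a, g$b, g$c))
}

# --- independent gromos oracle: literal re-implementation with loops --------
gromos_oracle <- function(d, cutoff) {
  n <- nrow(d)
  assigned <- rep(FALSE, n)
  raw_labels <- integer(n)
  centers <- integer(0)
  sizes <- integer(0)
  k <- 0
  while (!all(assigned)) {
    best_i <- NA
    best_count <- -1
    for (i in seq_len(n)) {
      if (assigned[i]) next
      count <- 0
      for (j in seq_len(n)) {
        if (j != i && !assigned[j] && d[i, j] <= cutoff) count <- count + 1
      }
      if (count > best_count) { # strict >: ties keep the lowest index
        best_count <- count
        best_i <- i
      }
    }
    members <- best_i
    for (j in seq_len(n)) {
      if (j != best_i && !assigned[j] && d[best_i, j] <= cutoff) {
        members <- c(members, j)
      }
    }
    k <- k + 1
    raw_labels[members] <- k
    centers <- c(centers, best_i)
    sizes <- c(sizes, length(members))
    assigned[members] <- TRUE
  }
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  list(labels = remap[raw_labels], centroids = centers[ord],
       populations = sizes[ord])
}

random_distance_matrix <- function(n, scale = 5) {
  pts <- matrix(runif(n * 3, 0, scale), n, 3)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  m
}
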