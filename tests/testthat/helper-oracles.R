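# Independent oracles and small fixtures shared across tests.

# Brute-force pairwise energy: plain scalar loops over atom pairs, written
# independently of pair_energy(). Only for uncharged toy atoms (resid TOY).
bf_pair_energy <- function(a, b, model = energy_model()) {
  stopifnot(all(a$resid == "TOY"), all(b$resid == "TOY"))
  total <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      dx <- a$x[i] - b$x[j]
      dy <- a$y[i] - b$y[j]
      dz <- a$z[i] - b$z[j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r > model$cutoff) next
      sig <- (model$sigma[[a$element[i]]] + model$sigma[[b$element[j]]]) / 2
      eps <- sqrt(model$epsilon[[a$element[i]]] * model$epsilon[[b$element[j]]])
      rp <- max(r, model$softcore_floor * sig)
      sr6 <- (sig / rp)^6
      total <- total + 4 * eps * (sr6 * sr6 - sr6)
    }
  }
  total
}

# Brute-force global energy of one subunit: sum of bf_pair_energy over all
# other subunits.
bf_global_energy <- function(frame, ring, position, model = energy_model()) {
  mine <- frame[frame$ring == ring & frame$position == position, ]
  subs <- unique(frame[, c("ring", "position")])
  total <- 0
  for (k in seq_len(nrow(subs))) {
    if (subs$ring[k] == ring && subs$position[k] == position) next
    other <- frame[frame$ring == subs$ring[k] & frame$position == subs$position[k], ]
    total <- total + bf_pair_energy(mine, other, model)
  }
  total
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(atoms, R, shift) {
  co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- co[, 1] + shift[1]
  atoms$y <- co[, 2] + shift[2]
  atoms$z <- co[, 3] + shift[3]
  atoms
}

# standard small toy: 2 x 4 ring assembly, 8 atoms per subunit
small_toy <- function(...) {
  make_toy_assembly(n_per_ring = 4, atoms_per_subunit = 8, seed = 11, ...)
}

# minimum interatomic distance between two subunits of a frame
min_gap <- function(frame, r1, p1, r2, p2) {
  a <- as.matrix(frame[frame$ring == r1 & frame$position == p1, c("x", "y", "z")])
  b <- as.matrix(frame[frame$ring == r2 & frame$position == p2, c("x", "y", "z")])
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)))
}
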