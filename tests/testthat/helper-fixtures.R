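# shared fixtures and independent oracles

# rigidly transform a mol_structure (rotation matrix R, translation t)
rigid_transform <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(R)
  new <- sweep(new, 2, t, "+")
  structure$atoms$x <- new[, 1]
  structure$atoms$y <- new[, 2]
  structure$atoms$z <- new[, 3]
  structure
}

random_rotation_matrix <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent brute-force double-loop EDA oracle (no shared code with
# pairwise_eda, which is vectorised)
brute_force_eda <- function(frag_a, frag_b, kc = 332.0522, two_six = TRUE) {
  xa <- as.matrix(frag_a$structure$atoms[, c("x", "y", "z")])
  xb <- as.matrix(frag_b$structure$atoms[, c("x", "y", "z")])
  elec <- rep_ <- disp <- 0
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      elec <- elec + kc * frag_a$charges[i] * frag_b$charges[j] / r
      eij <- sqrt(frag_a$epsilon[i] * frag_b$epsilon[j])
      rij <- frag_a$rmin_half[i] + frag_b$rmin_half[j]
      rep_ <- rep_ + eij * (rij / r)^12
      disp <- disp - (if (two_six) 2 else 1) * eij * (rij / r)^6
    }
  }
  list(elec = elec, rep = rep_, disp = disp)
}

# hand-written minimal PDB text (fixed columns), for parser fixtures
pdb_atom_line <- function(serial, name, resname, resid, x, y, z, element) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resid, x, y, z, element)
}

# tiny water-dimer-like fixture for hydrogen-bond tests: one O-H donor on
# the "host", one O acceptor on the "guest", collinear along x
hbond_fixture <- function(da_dist = 2.8, hda_angle = 0) {
  # donor O at origin, H along x; acceptor at distance da_dist, rotated by
  # hda_angle (degrees) about the donor
  th <- hda_angle * pi / 180
  acc <- c(cos(th), sin(th), 0) * da_dist
  atoms <- data.frame(
    serial = 1:3,
    name = c("OD", "HD", "OA"),
    resname = c("HST", "HST", "GST"),
    resid = c(1L, 1L, 2L),
    element = c("O", "H", "O"),
    x = c(0, 0.96, acc[1]),
    y = c(0, 0, acc[2]),
    z = c(0, 0, acc[3]))
  list(structure = mol_structure(atoms),
       selection = list(host = 1:2, guest = 3L))
}
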