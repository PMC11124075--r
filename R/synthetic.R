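#' Build a synthetic cyclodextrin-like host with known ground truth
#'
#' Constructs an idealised truncated-cone host: glycosidic oxygens on an
#' ellipse in the base (z = 0) plane, one planar six-atom pyran ring per
#' glucose unit whose plane makes exactly `tilt_deg` with the base plane
#' under the package's tilt convention, primary-rim (O6) oxygens above the
#' plane and secondary-rim (O2/O3) oxygens below.  The construction is
#' deterministic, and every injected parameter (tilt, ellipticity,
#' circularity = `ellipticity`) is recovered exactly by the corresponding
#' descriptor.  This is fixture geometry, not chemistry: bond lengths are
#' convenient constants and no hydrogens are generated.
#'
#' @param n_units 6, 7 or 8 glucose units (alpha/beta/gamma-CD).
#' @param base_radius semi-major axis of the glycosidic-oxygen ellipse (A).
#' @param ellipticity in-plane axis ratio of that ellipse, in (0, 1];
#'   equals the resulting cavity circularity.
#' @param tilt_deg target tilt angle of every pyran ring (degrees, in
#'   (0, 180)).
#' @param rim_offset height of the rim oxygens above/below the base plane (A).
#' @param ring_radius circumradius of the planar pyran hexagons (A).
#' @return list with `structure` (a [mol_structure()]) and `topology`
#'   (the ground-truth [cd_topology()]).
#' @export
build_cd <- function(n_units = 7, base_radius = 5.0, ellipticity = 1.0,
                     tilt_deg = 80, rim_offset = 2.5, ring_radius = 1.43) {
  stopifnot(n_units %in% 6:8, base_radius > 0,
            ellipticity > 0, ellipticity <= 1,
            tilt_deg > 0, tilt_deg < 180, rim_offset > 0, ring_radius > 0)
  n <- n_units
  a <- base_radius
  b <- ellipticity * base_radius
  phi <- 2 * pi * (seq_len(n) - 1) / n
  glyc <- cbind(a * cos(phi), b * sin(phi), 0)
  spacing <- sqrt(rowSums((glyc - glyc[c(n, seq_len(n - 1)), ])^2))
  if (min(spacing) / 2 - ring_radius < 0.05)
    stop("infeasible geometry: pyran rings overlap the glycosidic oxygens ",
         "(increase base_radius or decrease ring_radius)")
  tau <- .rad(tilt_deg)
  zhat <- c(0, 0, 1)
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  ring_alpha <- .rad((seq_along(ring_names) - 2) * 60) # C1 at 0, C4 at 180
  atoms <- list()
  serial <- 0L
  topo_rings <- vector("list", n)
  topo_glyc <- integer(n)
  topo_prim <- integer(n)
  topo_sec <- vector("list", n)
  push <- function(name, element, xyz, resid) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(serial = serial, name = name,
                                   resname = "GLC", resid = resid,
                                   element = element,
                                   x = xyz[1], y = xyz[2], z = xyz[3])
    serial
  }
  for (k in seq_len(n)) {
    g_prev <- glyc[if (k == 1) n else k - 1, ] # O4 of this unit
    g_next <- glyc[k, ]                        # bridged by C1 of this unit
    ctr <- (g_prev + g_next) / 2
    rhat <- .unit(c(ctr[1], ctr[2], 0), "ring radial direction")
    normal <- sin(tau) * rhat + cos(tau) * zhat
    e_up <- .unit(zhat - sum(zhat * normal) * normal)
    e_t <- pracma_cross(normal, e_up)
    if (sum(e_t * (g_next - ctr)) < 0) e_t <- -e_t # C1 side faces g_next
    ring_serials <- integer(6)
    for (j in seq_along(ring_names)) {
      pos <- ctr + ring_radius * (cos(ring_alpha[j]) * e_t +
                                  sin(ring_alpha[j]) * e_up)
      el <- if (ring_names[j] == "O5") "O" else "C"
      ring_serials[j] <- push(ring_names[j], el, pos, k)
    }
    topo_rings[[k]] <- ring_serials
    topo_glyc[k] <- push("O4", "O", g_prev, k)
    topo_prim[k] <- push("O6", "O", ctr + c(0, 0, rim_offset), k)
    o2 <- push("O2", "O", ctr - c(0, 0, rim_offset) + 0.7 * e_t, k)
    o3 <- push("O3", "O", ctr - c(0, 0, rim_offset) - 0.7 * e_t, k)
    topo_sec[[k]] <- c(o2, o3)
  }
  structure_ <- mol_structure(do.call(rbind, atoms),
                              label = sprintf("synthetic %d-unit CD", n))
  list(structure = structure_,
       topology = cd_topology(topo_glyc, topo_rings, topo_prim, topo_sec))
}

#' Build a rigid three-ring guest template
#'
#' A planar, rigid scaffold mimicking a three-ring organophosphorus guest
#' (aromatic rings A and B bridged by a P/O-containing ring C), with its
#' tail-to-head (ring B to ring A) vector along +z and its mass-weighted
#' centre of mass at the origin.  Bond lengths are fixture constants.
#'
#' @param ring_radius hexagon circumradius (A).
#' @return list with `structure` (a [mol_structure()], resname `DPO`) and
#'   `guest_vector` (serials `c(tail, head)`).
#' @export
build_guest <- function(ring_radius = 1.4) {
  # rings live in the x-z plane
  mk <- function(center, prefix, elements) {
    ang <- .rad(90 + 60 * (0:5))
    data.frame(name = paste0(prefix, 1:6), resname = "DPO", resid = 1L,
               element = elements,
               x = center[1] + ring_radius * cos(ang),
               y = center[2],
               z = center[3] + ring_radius * sin(ang))
  }
  ringA <- mk(c(0, 0, 2.1), "CA", rep("C", 6))       # head ring
  ringB <- mk(c(0, 0, -2.1), "CB", rep("C", 6))      # tail ring
  ringC <- mk(c(2.4, 0, 0), "CC", c("P", "C", "C", "C", "C", "O"))
  ringC$name[1] <- "P1"; ringC$name[6] <- "OC1"
  # exocyclic P=O oxygen
  po <- data.frame(name = "OP1", resname = "DPO", resid = 1L, element = "O",
                   x = 2.4 + ring_radius * 1.05, y = 0, z = 0.9)
  atoms <- rbind(ringA, ringB, ringC, po)
  atoms$serial <- seq_len(nrow(atoms))
  st <- mol_structure(atoms[, c("serial", "name", "resname", "resid",
                                "element", "x", "y", "z")],
                      label = "synthetic three-ring guest")
  # vector atoms: bottom vertex of ring B (tail) -> top vertex of ring A (head)
  tail <- st$atoms$serial[st$atoms$name == "CB4"]
  head_ <- st$atoms$serial[st$atoms$name == "CA1"]
  # recentre the mass-weighted COM at the origin
  shift <- com(st)
  st$atoms[, c("x", "y", "z")] <- sweep(as.matrix(st$atoms[, c("x", "y", "z")]),
                                        2, shift)
  list(structure = st, guest_vector = c(tail, head_))
}

#' Place a rigid guest into a host cavity at a prescribed pose
#'
#' Rigidly rotates and translates the guest so that its mass-weighted COM
#' sits at signed depth `d_signed` on the host cavity axis and its
#' tail-to-head vector makes angle `theta` with the +z axis of the host
#' frame (azimuth measured from the host x axis).
#'
#' @param host list with `structure` and `topology` (e.g. from
#'   [build_cd()]), or a [mol_structure()] plus `topology=`.
#' @param guest list with `structure` and `guest_vector` (e.g. from
#'   [build_guest()]).
#' @param d_signed target signed COM depth (A).
#' @param theta target orientation angle (degrees, \[0, 180\]).
#' @param azimuth in-plane direction of the tilt (degrees).
#' @param topology host topology when `host` is a bare structure.
#' @return list with `structure` (host + guest complex) and `selection`
#'   (`host`, `guest`, `guest_vector` serials in the combined numbering).
#' @export
place_guest <- function(host, guest, d_signed, theta, azimuth = 0,
                        topology = NULL) {
  host_st <- if (inherits(host, "mol_structure")) host else host$structure
  topology <- topology %||% host$topology
  if (is.null(topology)) stop("supply a host topology")
  stopifnot(theta >= 0, theta <= 180)
  basis <- build_frame_basis(host_st, topology)
  gst <- guest$structure
  gxyz <- coords(gst)
  p <- coords(gst, guest$guest_vector)
  v0 <- .unit(p[2, ] - p[1, ], "guest vector")
  th <- .rad(theta); az <- .rad(azimuth)
  v1 <- sin(th) * (cos(az) * basis$x_axis + sin(az) * basis$y_axis) +
    cos(th) * basis$z_axis
  R <- .rotation_between(v0, v1)
  gcom <- com(gst)
  target <- basis$origin + d_signed * basis$z_axis
  new_xyz <- sweep(gxyz, 2, gcom) %*% t(R)
  new_xyz <- sweep(new_xyz, 2, target, "+")
  ga <- gst$atoms
  offset <- max(host_st$atoms$serial)
  new_serial <- ga$serial + offset
  ga$serial <- new_serial
  ga$resid <- ga$resid + max(host_st$atoms$resid)
  ga$x <- new_xyz[, 1]; ga$y <- new_xyz[, 2]; ga$z <- new_xyz[, 3]
  combined <- mol_structure(rbind(host_st$atoms, ga),
                            label = paste0(host_st$label, " + guest"))
  list(structure = combined,
       selection = list(host = host_st$atoms$serial,
                        guest = new_serial,
                        guest_vector = guest$guest_vector + offset))
}

#' Simulate a binding-mode switching descriptor trajectory
#'
#' A hidden three-state Markov chain over `{BS, BP, UNBOUND}` emulates a
#' guest that jumps between the two inclusion modes and occasionally
#' leaves the cavity.  Per frame, the signed COM depth and orientation are
#' drawn from the active state's Gaussians and (optionally) a complex
#' structure is emitted via [place_guest()].  The hidden-state log is
#' returned as ground truth for recovery tests.  Fully reproducible for a
#' fixed seed.
#'
#' @param host,guest as for [place_guest()].
#' @param n_frames number of frames.
#' @param dt_ps frame spacing (ps).
#' @param transition_matrix 3x3 row-stochastic matrix over (BS, BP,
#'   UNBOUND).  The default jumps between the bound modes with occasional
#'   unbound excursions.
#' @param state_means 3x2 matrix of per-state (d_signed, theta) means; the
#'   defaults are typical inclusion-complex poses (BS: -1.0 A / 20 deg,
#'   BP: 1.2 A / 152 deg) and an unbound excursion at 9 A.
#' @param state_sds 3x2 matrix of per-state Gaussian SDs.
#' @param seed integer RNG seed.
#' @param emit_structures emit structures (TRUE) or only the descriptor
#'   log (faster).
#' @return list with `trajectory` (`mol_trajectory` or NULL), `log` (data
#'   frame `frame`, `time_ps`, `state`, `d_signed`, `theta`, `azimuth`)
#'   and `params`.
#' @export
simulate_descriptor_trajectory <- function(host, guest, n_frames = 1000,
                                           dt_ps = 10,
                                           transition_matrix = NULL,
                                           state_means = NULL,
                                           state_sds = NULL,
                                           seed = 1,
                                           emit_structures = TRUE) {
  states <- c("BS", "BP", "UNBOUND")
  transition_matrix <- transition_matrix %||%
    matrix(c(0.90, 0.08, 0.02,
             0.08, 0.90, 0.02,
             0.05, 0.05, 0.90), 3, 3, byrow = TRUE,
           dimnames = list(states, states))
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    stop("transition_matrix rows must sum to 1")
  state_means <- state_means %||% rbind(BS = c(-1.0, 20),
                                        BP = c(1.2, 152),
                                        UNBOUND = c(9.0, 90))
  state_sds <- state_sds %||% rbind(BS = c(0.5, 8),
                                    BP = c(0.5, 8),
                                    UNBOUND = c(0.5, 30))
  if (any(state_sds < 0)) stop("state_sds must be >= 0")
  set.seed(seed)
  # stationary distribution as the initial-state law
  ev <- eigen(t(transition_matrix))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  s <- integer(n_frames)
  s[1] <- sample.int(3, 1, prob = stat)
  for (i in seq_len(n_frames - 1))
    s[i + 1] <- sample.int(3, 1, prob = transition_matrix[s[i], ])
  d <- rnorm(n_frames, state_means[s, 1], state_sds[s, 1])
  th <- pmin(179.9, pmax(0.1, rnorm(n_frames, state_means[s, 2], state_sds[s, 2])))
  az <- runif(n_frames, 0, 360)
  log <- data.frame(frame = seq_len(n_frames),
                    time_ps = (seq_len(n_frames) - 1) * dt_ps,
                    state = states[s], d_signed = d, theta = th, azimuth = az)
  traj <- NULL
  if (emit_structures) {
    frames <- lapply(seq_len(n_frames), function(i)
      place_guest(host, guest, d[i], th[i], az[i])$structure)
    traj <- trajectory(frames, log$time_ps)
  }
  list(trajectory = traj, log = log,
       params = list(transition_matrix = transition_matrix,
                     state_means = state_means, state_sds = state_sds,
                     n_frames = n_frames, dt_ps = dt_ps, seed = seed))
}

#' Random two-fragment toy charge/LJ system
#'
#' Non-overlapping random coordinates (minimum separation 2 A), charges in
#' \[-1, 1\] e, LJ well depths in \[0, 0.3\] kcal/mol and Rmin/2 in
#' \[1.2, 2.2\] A.  Deterministic per seed; used as oracle fixtures for the
#' pairwise energy decomposition.
#'
#' @param n_a,n_b atom counts of the two fragments.
#' @param seed integer RNG seed.
#' @return list with `frag_a`, `frag_b` ([ff_fragment()] objects).
#' @export
toy_charge_system <- function(n_a = 5, n_b = 4, seed = 1) {
  stopifnot(n_a >= 1, n_b >= 1)
  set.seed(seed)
  n <- n_a + n_b
  box <- max(8, 2.5 * n^(1 / 3) * 2)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- runif(3, 0, box)
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - cand)^2))) >= 2.0)
      pts <- rbind(pts, cand)
  }
  mk <- function(idx, label) {
    st <- mol_structure(data.frame(serial = seq_along(idx),
                                   name = paste0("X", seq_along(idx)),
                                   resname = "TOY", resid = 1L,
                                   element = "C",
                                   x = pts[idx, 1], y = pts[idx, 2],
                                   z = pts[idx, 3]),
                        label = label)
    ff_fragment(st, charges = runif(length(idx), -1, 1),
                epsilon = runif(length(idx), 0, 0.3),
                rmin_half = runif(length(idx), 1.2, 2.2))
  }
  list(frag_a = mk(seq_len(n_a), "toy fragment A"),
       frag_b = mk(n_a + seq_len(n_b), "toy fragment B"))
}
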