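#' Host-fixed reference frame of a cyclodextrin
#'
#' Builds the analysis frame of the host: the origin is the (unweighted)
#' centroid of the glycosidic oxygens, the z axis is the least-squares plane
#' normal of those oxygens with its sign chosen to point from the secondary
#' rim towards the primary rim, and the x axis points towards the first
#' unit's glycosidic oxygen projected into the plane.
#'
#' @param structure a [mol_structure()].
#' @param topology a [cd_topology()] valid for `structure`.
#' @return list of class `host_frame` with `origin`, `x_axis`, `y_axis`,
#'   `z_axis` (orthonormal, right-handed).
#' @export
build_frame_basis <- function(structure, topology) {
  g <- coords(structure, topology$glycosidic)
  origin <- unname(colMeans(g))
  gc <- sweep(g, 2, origin)
  e <- eigen(crossprod(gc) / nrow(gc), symmetric = TRUE)
  # plane normal = eigenvector of the smallest eigenvalue; the oxygen set is
  # degenerate (collinear) when the two largest eigenvalues do not separate
  # from zero
  if (e$values[2] < 1e-8 * max(e$values[1], 1))
    stop("glycosidic oxygens are collinear/degenerate; cannot fit a plane")
  z <- e$vectors[, 3]
  prim <- colMeans(coords(structure, topology$prim_rim))
  sec <- colMeans(coords(structure, unlist(topology$sec_rim)))
  if (sum(z * (prim - sec)) < 0) z <- -z
  v <- g[1, ] - origin
  x <- v - sum(v * z) * z
  if (.vnorm(x) < 1e-10)
    stop("unit-1 glycosidic oxygen projects onto the origin; degenerate frame")
  x <- .unit(x)
  y <- pracma_cross(z, x)
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z),
            class = "host_frame")
}

#' @export
print.host_frame <- function(x, ...) {
  cat("<host_frame> origin (", paste(sprintf("%.2f", x$origin), collapse = ", "),
      ") z (", paste(sprintf("%.3f", x$z_axis), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Signed host-guest centre-of-mass distance
#'
#' Magnitude: Euclidean distance between the guest's mass-weighted centre of
#' mass and the frame origin.  Sign: negative when the guest COM is farther
#' from the primary-rim oxygen centroid than from the secondary-rim oxygen
#' centroid (i.e. the guest sits on the secondary-rim side), positive
#' otherwise.
#'
#' @param structure a [mol_structure()] of the complex.
#' @param topology host [cd_topology()].
#' @param selection list with at least `guest` (atom serials).
#' @param basis optional precomputed [build_frame_basis()] result.
#' @param use_host_com use the whole-host mass-weighted COM as the reference
#'   point instead of the glycosidic-oxygen centroid (requires
#'   `selection$host`).
#' @return signed distance in Angstrom.
#' @export
signed_com_distance <- function(structure, topology, selection, basis = NULL,
                                use_host_com = FALSE) {
  if (!length(selection$guest)) stop("empty guest selection")
  basis <- basis %||% build_frame_basis(structure, topology)
  ref <- if (use_host_com) {
    if (!length(selection$host)) stop("use_host_com requires selection$host")
    com(structure, selection$host)
  } else basis$origin
  g <- com(structure, selection$guest)
  prim <- colMeans(coords(structure, topology$prim_rim))
  sec <- colMeans(coords(structure, unlist(topology$sec_rim)))
  s <- if (.vnorm(g - prim) > .vnorm(g - sec)) -1 else 1
  s * .vnorm(g - ref)
}

#' Guest orientation angle
#'
#' Angle (degrees, 0-180) between the guest's tail-to-head vector (tail in
#' ring B, head in ring A) and the +z axis of the host frame.
#'
#' @inheritParams signed_com_distance
#' @param selection list with `guest_vector`, an ordered pair of guest atom
#'   serials `c(tail, head)`.
#' @return angle in degrees.
#' @export
guest_orientation <- function(structure, selection, basis) {
  gv <- selection$guest_vector
  if (length(gv) != 2) stop("selection$guest_vector must be two atom serials")
  p <- coords(structure, gv)
  v <- p[2, ] - p[1, ]
  if (.vnorm(v) < 1e-9) stop("zero-length guest vector")
  .angle_deg(v, basis$z_axis)
}

#' Glucose tilt angles
#'
#' For each glucose unit, fits a least-squares plane to the six pyran-ring
#' atoms and reports the angle between the ring-plane normal and the host z
#' axis.  The normal is oriented to have a positive component along the
#' unit's outward radial direction, which maps the tilt onto (0, 180)
#' degrees: 90 degrees is a ring parallel to the cavity axis, values below
#' 90 lean the secondary-rim edge outwards (a more open secondary rim).
#'
#' @inheritParams signed_com_distance
#' @return list with `per_unit` (degrees) and `mean`.
#' @export
tilt_angles <- function(structure, topology, basis = NULL) {
  basis <- basis %||% build_frame_basis(structure, topology)
  z <- basis$z_axis
  per_unit <- vapply(topology$pyran_rings, function(ring) {
    p <- coords(structure, ring)
    ctr <- colMeans(p)
    pc <- sweep(p, 2, ctr)
    e <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
    if (e$values[2] < 1e-10 * max(e$values[1], 1))
      stop("degenerate pyran-ring geometry")
    n <- e$vectors[, 3]
    r <- ctr - basis$origin
    r <- r - sum(r * z) * z
    if (.vnorm(r) < 1e-9) stop("pyran-ring centroid sits on the cavity axis")
    if (sum(n * r) < 0) n <- -n
    .angle_deg(n, z)
  }, numeric(1))
  list(per_unit = per_unit, mean = mean(per_unit))
}

#' Cavity circularity
#'
#' Distortion parameter of the glycosidic-oxygen ring: the oxygens are
#' projected onto the host frame's base plane and the square root of the
#' ratio of the smaller to the larger eigenvalue of their 2x2 covariance is
#' returned (the axis ratio of the best-fit ellipse).  1 for a perfect
#' circle.
#'
#' @inheritParams signed_com_distance
#' @return circularity in (0, 1].
#' @export
circularity <- function(structure, topology, basis = NULL) {
  if (length(topology$glycosidic) < 5)
    stop("circularity needs at least 5 glycosidic oxygens")
  basis <- basis %||% build_frame_basis(structure, topology)
  g <- sweep(coords(structure, topology$glycosidic), 2, basis$origin)
  uv <- g %*% cbind(basis$x_axis, basis$y_axis)
  C <- crossprod(sweep(uv, 2, colMeans(uv))) / nrow(uv)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] < 1e-12) stop("degenerate projected-oxygen covariance")
  sqrt(max(0, ev[2]) / ev[1])
}

#' Hydrogen-bond criteria
#'
#' Geometric hydrogen-bond definition: donor-acceptor distance cutoff and
#' hydrogen-donor-acceptor angle cutoff (the defaults applied by the common
#' MD analysis tools).
#'
#' @param max_da_distance donor-acceptor distance cutoff (A), default 3.5.
#' @param max_angle H-D-A angle cutoff (degrees), default 30.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_angle = 30) {
  stopifnot(max_da_distance > 0, max_angle > 0)
  structure(list(max_da_distance = max_da_distance, max_angle = max_angle),
            class = "hbond_criteria")
}

#' Count host-guest hydrogen bonds
#'
#' Donors are O/N atoms with a covalently bound hydrogen (H within 1.2 A);
#' acceptors are O/N atoms.  A donor-acceptor pair across the host/guest
#' boundary is counted (once, in either direction) when the D-A distance
#' and the H-D-A angle satisfy `criteria`.
#'
#' @inheritParams signed_com_distance
#' @param selection list with `host` and `guest` atom-serial sets.
#' @param criteria a [hbond_criteria()].
#' @return integer hydrogen-bond count.
#' @export
count_hbonds <- function(structure, selection, criteria = hbond_criteria()) {
  a <- structure$atoms
  if (!any(a$element == "H"))
    stop("no hydrogen atoms in the structure; hydrogen-bond counting ",
         "requires explicit hydrogens")
  on_idx <- which(a$element %in% c("O", "N"))
  h_idx <- which(a$element == "H")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # attach each H to its nearest O/N within covalent range
  donors <- list()
  for (h in h_idx) {
    d <- sqrt(colSums((t(xyz[on_idx, , drop = FALSE]) - xyz[h, ])^2))
    j <- which.min(d)
    if (length(j) && d[j] <= 1.2)
      donors[[length(donors) + 1]] <- c(D = on_idx[j], H = h)
  }
  in_host <- a$serial %in% selection$host
  in_guest <- a$serial %in% selection$guest
  pairs <- character(0)
  for (dh in donors) {
    D <- dh[["D"]]; H <- dh[["H"]]
    acc <- on_idx[(in_host[D] & in_guest[on_idx]) |
                  (in_guest[D] & in_host[on_idx])]
    acc <- setdiff(acc, D)
    for (A in acc) {
      da <- .vnorm(xyz[A, ] - xyz[D, ])
      if (da > criteria$max_da_distance) next
      ang <- .angle_deg(xyz[H, ] - xyz[D, ], xyz[A, ] - xyz[D, ])
      if (ang <= criteria$max_angle)
        pairs <- c(pairs, paste(D, A))
    }
  }
  length(unique(pairs))
}

#' Classify the binding mode of a frame
#'
#' UNBOUND when the absolute signed COM distance exceeds the cutoff;
#' otherwise BS when the guest orientation is below 90 degrees and BP when
#' it is 90 degrees or above (the exact-90 tie breaks to BP).
#'
#' @param d_signed signed COM distance(s), Angstrom.
#' @param theta guest orientation(s), degrees.
#' @param cutoff bound/unbound distance cutoff (A), default 6.5.
#' @return character vector over `{"BS", "BP", "UNBOUND"}`.
#' @export
classify_mode <- function(d_signed, theta, cutoff = 6.5) {
  ifelse(abs(d_signed) > cutoff, "UNBOUND",
         ifelse(theta < 90, "BS", "BP"))
}

#' All geometric descriptors of one frame
#'
#' Computes the signed COM distance, guest orientation, per-unit tilt
#' angles, circularity, hydrogen-bond count and binding-mode label from a
#' single internally consistent host frame.
#'
#' @inheritParams signed_com_distance
#' @param criteria a [hbond_criteria()].
#' @param cutoff bound/unbound distance cutoff (A).
#' @param hbonds count hydrogen bonds?  With `"auto"` (default) the count is
#'   `NA` when the structure carries no hydrogens, as is common for
#'   heavy-atom models.
#' @return list of class `cd_descriptors` with fields `d_signed`, `theta`,
#'   `tau` (per unit), `tau_mean`, `circularity`, `n_hbonds`, `mode`.
#' @export
describe_frame <- function(structure, topology, selection,
                           criteria = hbond_criteria(), cutoff = 6.5,
                           hbonds = "auto") {
  basis <- build_frame_basis(structure, topology)
  d <- signed_com_distance(structure, topology, selection, basis)
  th <- guest_orientation(structure, selection, basis)
  tau <- tilt_angles(structure, topology, basis)
  circ <- circularity(structure, topology, basis)
  nhb <- if (identical(hbonds, "auto")) {
    if (any(structure$atoms$element == "H"))
      count_hbonds(structure, selection, criteria) else NA_integer_
  } else if (isTRUE(hbonds)) {
    count_hbonds(structure, selection, criteria)
  } else NA_integer_
  structure(list(d_signed = d, theta = th, tau = tau$per_unit,
                 tau_mean = tau$mean, circularity = circ,
                 n_hbonds = nhb, mode = classify_mode(d, th, cutoff)),
            class = "cd_descriptors")
}

#' @export
print.cd_descriptors <- function(x, ...) {
  cat(sprintf("<cd_descriptors> d = %+.2f A, theta = %.1f deg, tau = %.1f deg, circ = %.3f, mode = %s\n",
              x$d_signed, x$theta, x$tau_mean, x$circularity, x$mode))
  invisible(x)
}

#' Descriptor table of a trajectory
#'
#' Applies [describe_frame()] to every frame.
#'
#' @param traj a `mol_trajectory` (see [trajectory()]).
#' @inheritParams describe_frame
#' @return data frame with columns `frame`, `time_ps`, `d_signed`, `theta`,
#'   `tau_mean`, `circularity`, `n_hbonds`, `mode`.
#' @export
describe_trajectory <- function(traj, topology, selection,
                                criteria = hbond_criteria(), cutoff = 6.5,
                                hbonds = "auto") {
  rows <- lapply(seq_along(traj$frames), function(i) {
    d <- describe_frame(traj$frames[[i]], topology, selection, criteria,
                        cutoff, hbonds)
    data.frame(frame = i, time_ps = traj$times[i], d_signed = d$d_signed,
               theta = d$theta, tau_mean = d$tau_mean,
               circularity = d$circularity, n_hbonds = d$n_hbonds,
               mode = d$mode)
  })
  do.call(rbind, rows)
}
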