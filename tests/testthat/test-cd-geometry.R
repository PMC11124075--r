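test_that("canonical-pose host frame sits at the origin with z up", {
  cd <- build_cd(7, tilt_deg = 80)
  b <- build_frame_basis(cd$structure, cd$topology)
  expect_equal(b$origin, c(0, 0, 0), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(b$z_axis, c(0, 0, 1), tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal right-handed triad
  M <- cbind(b$x_axis, b$y_axis, b$z_axis)
  expect_equal(t(M) %*% M, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(det(M), 1, tolerance = 1e-10)
})

test_that("the frame rotates with the structure", {
  cd <- build_cd(7)
  set.seed(11)
  for (k in 1:3) {
    R <- random_rotation_matrix()
    t <- runif(3, -20, 20)
    rot <- rigid_transform(cd$structure, R, t)
    b <- build_frame_basis(rot, cd$topology)
    # oracle: apply R to the canonical axes directly
    expect_equal(b$z_axis, as.vector(R %*% c(0, 0, 1)), tolerance = 1e-8)
    expect_equal(b$origin, as.vector(R %*% c(0, 0, 0)) + t, tolerance = 1e-8)
  }
})

test_that("the z axis honours the rim orientation rule", {
  # flip the host upside down: primary rim now points to -z
  cd <- build_cd(7)
  flipped <- rigid_transform(cd$structure, diag(c(1, -1, -1)))
  b <- build_frame_basis(flipped, cd$topology)
  expect_equal(b$z_axis, c(0, 0, -1), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("signed COM distance reports depth and rim side by construction", {
  cd <- build_cd(7)
  g <- build_guest()
  for (d in c(3, -3, 0)) {
    cx <- place_guest(cd, g, d_signed = d, theta = 0)
    got <- signed_com_distance(cx$structure, cd$topology, cx$selection)
    expect_equal(got, d, tolerance = 1e-8)
  }
})

test_that("sign rule agrees with a direct rim-distance comparison", {
  cd <- build_cd(7)
  g <- build_guest()
  set.seed(7)
  for (k in 1:20) {
    d <- runif(1, -8, 8)
    cx <- place_guest(cd, g, d, theta = runif(1, 0, 180),
                      azimuth = runif(1, 0, 360))
    got <- signed_com_distance(cx$structure, cd$topology, cx$selection)
    # oracle: explicit distances from the guest COM to the rim centroids
    am <- cx$structure$atoms
    gm <- am[am$serial %in% cx$selection$guest, ]
    mass <- atom_masses(cx$structure, gm$serial)
    gc <- colSums(as.matrix(gm[, c("x", "y", "z")]) * mass) / sum(mass)
    rim <- function(serials) colMeans(as.matrix(
      am[am$serial %in% serials, c("x", "y", "z")]))
    dp <- sqrt(sum((gc - rim(cd$topology$prim_rim))^2))
    ds <- sqrt(sum((gc - rim(unlist(cd$topology$sec_rim)))^2))
    expect_equal(got > 0, dp <= ds)
    expect_equal(abs(got), abs(d), tolerance = 1e-8)
  }
})

test_that("guest orientation matches the axis geometry", {
  cd <- build_cd(7)
  g <- build_guest()
  b <- build_frame_basis(cd$structure, cd$topology)
  for (th in c(0, 90, 180, 20, 151.8)) {
    cx <- place_guest(cd, g, d_signed = 1, theta = th, azimuth = 123)
    expect_equal(guest_orientation(cx$structure, cx$selection, b), th,
                 tolerance = 1e-8)
  }
  # zero-length vector errors
  sel <- place_guest(cd, g, 0, 0)$selection
  sel$guest_vector <- rep(sel$guest_vector[1], 2)
  expect_error(guest_orientation(place_guest(cd, g, 0, 0)$structure, sel, b),
               "zero-length")
})

test_that("tilt angles recover the generator's ground truth", {
  for (tau in c(77, 80, 88, 95)) {
    cd <- build_cd(7, tilt_deg = tau)
    t <- tilt_angles(cd$structure, cd$topology)
    expect_equal(t$mean, tau, tolerance = 1e-6)
    expect_equal(unname(t$per_unit), rep(tau, 7), tolerance = 1e-6)
  }
})

test_that("circularity equals the built-in ellipticity and is 1 for a circle", {
  expect_equal(circularity(build_cd(7, ellipticity = 1)$structure,
                           build_cd(7, ellipticity = 1)$topology),
               1, tolerance = 1e-10)
  for (e in c(0.8, 0.95)) {
    cd <- build_cd(7, ellipticity = e)
    expect_equal(circularity(cd$structure, cd$topology), e, tolerance = 1e-6)
  }
})

test_that("all descriptors are invariant under rigid motion", {
  cd <- build_cd(8, ellipticity = 0.9, tilt_deg = 84)
  g <- build_guest()
  cx <- place_guest(cd, g, d_signed = -2.2, theta = 37, azimuth = 200)
  ref <- describe_frame(cx$structure, cd$topology, cx$selection)
  set.seed(5)
  for (k in 1:5) {
    R <- random_rotation_matrix()
    t <- runif(3, -30, 30)
    moved <- rigid_transform(cx$structure, R, t)
    got <- describe_frame(moved, cd$topology, cx$selection)
    expect_equal(got$d_signed, ref$d_signed, tolerance = 1e-8)
    expect_equal(got$theta, ref$theta, tolerance = 1e-8)
    expect_equal(got$tau_mean, ref$tau_mean, tolerance = 1e-8)
    expect_equal(got$circularity, ref$circularity, tolerance = 1e-8)
    expect_identical(got$mode, ref$mode)
  }
})

test_that("hydrogen bonds obey the distance and angle cutoffs", {
  good <- hbond_fixture(da_dist = 2.8, hda_angle = 0)
  expect_equal(count_hbonds(good$structure, good$selection), 1)
  far <- hbond_fixture(da_dist = 4.0, hda_angle = 0)
  expect_equal(count_hbonds(far$structure, far$selection), 0)
  bent <- hbond_fixture(da_dist = 2.8, hda_angle = 45)
  expect_equal(count_hbonds(bent$structure, bent$selection), 0)
  # boundary: exactly at the default cutoffs counts
  edge <- hbond_fixture(da_dist = 3.5, hda_angle = 29.9)
  expect_equal(count_hbonds(edge$structure, edge$selection), 1)
  # hydrogens required
  noh <- good$structure
  noh$atoms <- noh$atoms[noh$atoms$element != "H", ]
  expect_error(count_hbonds(noh, good$selection), "hydrogen")
})

test_that("mode classification covers the plane with the stated boundaries", {
  # values typical of the three host:guest poses
  expect_identical(classify_mode(-1.0, 20), "BS")
  expect_identical(classify_mode(8.5, 45), "UNBOUND")
  expect_identical(classify_mode(1.2, 151.8), "BP")
  # exhaustive grid: total function, only the three labels, exact boundaries
  d <- seq(-12, 12, by = 0.5)
  th <- seq(0, 180, by = 2.5)
  grid <- expand.grid(d = d, th = th)
  lab <- classify_mode(grid$d, grid$th)
  expect_true(all(lab %in% c("BS", "BP", "UNBOUND")))
  expect_true(all((abs(grid$d) > 6.5) == (lab == "UNBOUND")))
  bound <- lab[abs(grid$d) <= 6.5]
  expect_true(all((grid$th[abs(grid$d) <= 6.5] < 90) == (bound == "BS")))
  # ties: the cutoff itself is bound; theta = 90 is BP
  expect_identical(classify_mode(6.5, 10), "BS")
  expect_identical(classify_mode(0, 90), "BP")
})

test_that("describe_frame composes the descriptors consistently", {
  cd <- build_cd(7, ellipticity = 0.95, tilt_deg = 82)
  g <- build_guest()
  cases <- list(c(-1.5, 25, 0), c(1.2, 152, 120), c(8.5, 45, 300))
  modes <- c("BS", "BP", "UNBOUND")
  for (i in seq_along(cases)) {
    p <- cases[[i]]
    cx <- place_guest(cd, g, p[1], p[2], p[3])
    got <- describe_frame(cx$structure, cd$topology, cx$selection)
    expect_equal(got$d_signed, p[1], tolerance = 1e-6)
    expect_equal(got$theta, p[2], tolerance = 1e-6)
    expect_equal(got$tau_mean, 82, tolerance = 1e-6)
    expect_equal(got$circularity, 0.95, tolerance = 1e-6)
    expect_identical(got$mode, modes[i])
    expect_true(is.na(got$n_hbonds)) # heavy-atom fixture carries no H
  }
})
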