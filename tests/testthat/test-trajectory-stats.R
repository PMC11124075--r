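test_that("histogram densities integrate to one", {
  # constant series: a single occupied bin carrying all the mass
  h <- descriptor_histogram(rep(3.2, 50), bin_width = 0.25)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(sum(h$density * 0.25), 1, tolerance = 1e-12)
  # random input, odd width
  set.seed(2)
  h2 <- descriptor_histogram(rnorm(1000, sd = 4), bin_width = 0.37)
  expect_equal(sum(h2$density * 0.37), 1, tolerance = 1e-12)
  expect_equal(sum(h2$count), 1000)
  expect_error(descriptor_histogram(numeric(0), 0.1), "empty")
  expect_error(descriptor_histogram(1:3, -1), "bin_width")
})

test_that("uniform samples fill bins evenly within the binomial bound", {
  set.seed(123)
  x <- runif(1e5)
  h <- descriptor_histogram(x, bin_width = 0.1, range = c(0, 1))
  p <- 0.1
  sigma <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(h$count / 1e5 - p) < 4 * sigma))
})

test_that("bound fraction counts frames inside the cutoff", {
  expect_equal(bound_fraction(rep(0, 10)), 1)
  expect_equal(bound_fraction(rep(10, 10)), 0)
  expect_equal(bound_fraction(c(-7, -6, 0, 6, 7)), 3 / 5)
  # permutation invariance
  set.seed(1)
  d <- rnorm(500, 5, 3)
  expect_equal(bound_fraction(d), bound_fraction(sample(d)))
})

test_that("mode occupancies sum to one and transitions count label changes", {
  occ <- mode_occupancy(rep("BS", 10))
  expect_equal(unname(occ$fractions["BS"]), 1)
  expect_equal(occ$n_transitions, 0)
  alt <- mode_occupancy(rep(c("BS", "BP"), 5))
  expect_equal(alt$n_transitions, 9)
  expect_equal(sum(alt$fractions), 1)
  # occupancy is permutation-invariant, the transition count is not
  set.seed(3)
  m <- sample(c("BS", "BP", "UNBOUND"), 200, replace = TRUE)
  shuffled <- c(sort(m)) # grouped ordering: minimal transitions
  expect_equal(mode_occupancy(shuffled)$fractions, mode_occupancy(m)$fractions)
  expect_lt(mode_occupancy(shuffled)$n_transitions, mode_occupancy(m)$n_transitions)
})

test_that("block averages match the hand-computed oracle", {
  expect_equal(block_average(rep(5.5, 40))$sd_of_block_means, 0)
  # indicator of the first of 4 blocks, length 20: block means (1,0,0,0)
  s <- rep(c(1, 0, 0, 0), each = 5)
  b <- block_average(s, n_blocks = 4)
  expect_equal(b$block_means, c(1, 0, 0, 0))
  expect_equal(b$mean, 0.25)
  expect_equal(b$sd_of_block_means, 0.5) # sd({1,0,0,0})
  # global mean recovered when the length divides evenly
  set.seed(4)
  x <- rnorm(100)
  expect_equal(block_average(x, 5)$mean, mean(x), tolerance = 1e-12)
  # remainder frames at the end are dropped
  expect_equal(block_average(c(rep(1, 9), 100), n_blocks = 3)$mean, 1)
  expect_error(block_average(1:10, 1), "at least 2")
  expect_error(block_average(1:3, 5), "shorter")
})

test_that("block-average spread shrinks with vanishing noise", {
  set.seed(9)
  base <- sin(seq(0, 2 * pi, length.out = 500))
  sds <- c(1, 0.1, 0)
  spread <- vapply(sds, function(s)
    block_average(base * 0 + rnorm(500, sd = s))$sd_of_block_means, 0)
  expect_lt(spread[2], spread[1])
  expect_equal(spread[3], 0)
})

test_that("contiguous-mode grouping partitions the profile", {
  g <- group_contiguous_modes(1:5, c("BS", "BS", "BS", "BP", "BP"))
  expect_equal(g$start, c(1, 4))
  expect_equal(g$end, c(3, 5))
  expect_equal(g$mode, c("BS", "BP"))
  one <- group_contiguous_modes(-7, "BS")
  expect_equal(nrow(one), 1)
  expect_equal(one$start, one$end)
  alt <- group_contiguous_modes(1:6, rep(c("BS", "BP"), 3))
  expect_equal(nrow(alt), 6)
  # the intervals exactly partition the coordinates
  set.seed(6)
  z <- sort(runif(50)); m <- sample(c("BS", "BP", "UNBOUND"), 50, TRUE)
  iv <- group_contiguous_modes(z, m)
  expect_equal(sum(iv$n_points), 50)
  expect_true(all(iv$start <= iv$end))
  expect_true(all(head(iv$end, -1) < tail(iv$start, -1)))
  expect_error(group_contiguous_modes(c(1, 1, 2), c("a", "b", "c")),
               "strictly increasing")
})

test_that("Markov-chain occupancy and bound fraction are recovered from descriptors", {
  cd <- build_cd(7)
  g <- build_guest()
  # symmetric BS<->BP chain with ~10% stationary unbound weight
  P <- matrix(c(0.85, 0.10, 0.05,
                0.10, 0.85, 0.05,
                0.225, 0.225, 0.55), 3, 3, byrow = TRUE)
  sim <- simulate_descriptor_trajectory(cd, g, n_frames = 10000, seed = 21,
                                        transition_matrix = P,
                                        emit_structures = FALSE)
  lab <- classify_mode(sim$log$d_signed, sim$log$theta)
  truth <- mode_occupancy(sim$log$state)$fractions
  got <- mode_occupancy(lab)$fractions
  # classification from the noisy emissions agrees with the hidden-state
  # dwell fractions to within the 3-sigma multinomial sampling band
  for (s in names(truth)) {
    sigma <- sqrt(truth[s] * (1 - truth[s]) / 10000)
    expect_lt(abs(got[s] - truth[s]), 3 * sigma + 0.01)
  }
  bf <- bound_fraction(sim$log$d_signed)
  bf_truth <- mean(sim$log$state != "UNBOUND")
  expect_lt(abs(bf - bf_truth), 3 * sqrt(bf_truth * (1 - bf_truth) / 10000) + 0.01)
})

test_that("trajectory subsampling keeps the requested cadence", {
  cd <- build_cd(6)
  g <- build_guest()
  sim <- simulate_descriptor_trajectory(cd, g, n_frames = 21, dt_ps = 5,
                                        seed = 2)
  sub <- subsample_frames(sim$trajectory, every_ps = 10)
  expect_equal(sub$times, seq(0, 100, by = 10))
})
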