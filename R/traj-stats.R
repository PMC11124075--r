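#' Normalised histogram of a descriptor series
#'
#' Fixed-width binning with densities that integrate to one over the
#' histogram support (`sum(density * bin_width) == 1`).
#'
#' @param values numeric series (e.g. per-frame COM distances or angles).
#' @param bin_width bin width in the units of `values`; the package-wide
#'   conventions are 0.25 A for distances and 5 degrees for angles.
#' @param range optional `c(lo, hi)` limits; defaults to the data range
#'   expanded to whole bins.
#' @return data frame with `lower`, `upper`, `mid`, `count`, `density`.
#' @export
descriptor_histogram <- function(values, bin_width, range = NULL) {
  if (!length(values)) stop("empty series")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(range)) {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- ceiling(max(values) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- range[1]; hi <- range[2]
    if (any(values < lo | values > hi))
      stop("values fall outside the requested range")
    hi <- lo + ceiling((hi - lo) / bin_width) * bin_width
  }
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- hist(values, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
             mid = h$mids, count = h$counts,
             density = h$counts / (length(values) * bin_width))
}

#' Fraction of bound frames
#'
#' A frame is bound when its absolute signed COM distance is within the
#' cutoff (default 6.5 A, the distance separating the inclusion complex
#' from the dissociated guest).
#'
#' @param d_signed per-frame signed COM distances (A).
#' @param cutoff bound/unbound cutoff (A).
#' @return fraction in \[0, 1\].
#' @export
bound_fraction <- function(d_signed, cutoff = 6.5) {
  if (!length(d_signed)) stop("empty series")
  mean(abs(d_signed) <= cutoff)
}

#' Binding-mode occupancies and transition counts
#'
#' @param modes per-frame mode labels (character, e.g. from
#'   [classify_mode()]).
#' @return list with `fractions` (named, summing to 1), `n_transitions`
#'   (label changes between consecutive frames) and `transitions` (count
#'   table from-mode x to-mode).
#' @export
mode_occupancy <- function(modes) {
  if (!length(modes)) stop("empty series")
  modes <- as.character(modes)
  tab <- table(modes)
  frac <- as.numeric(tab) / length(modes)
  names(frac) <- names(tab)
  n <- length(modes)
  if (n > 1) {
    from <- modes[-n]; to <- modes[-1]
    chg <- from != to
    trans <- table(factor(from[chg], levels = names(tab)),
                   factor(to[chg], levels = names(tab)))
  } else {
    chg <- logical(0)
    trans <- table(factor(character(0), levels = names(tab)),
                   factor(character(0), levels = names(tab)))
  }
  list(fractions = frac, n_transitions = sum(chg), transitions = trans)
}

#' Block average of a time series
#'
#' Splits the series into `n_blocks` equal contiguous blocks (remainder
#' frames at the end are dropped) and returns the mean of the block means
#' together with their standard deviation -- the usual uncertainty estimate
#' for correlated MD time series.
#'
#' @param values numeric series.
#' @param n_blocks number of blocks (default 5).
#' @return list of class `block_average` with `mean`, `sd_of_block_means`,
#'   `n_blocks`, `block_means`.
#' @export
block_average <- function(values, n_blocks = 5) {
  if (n_blocks < 2) stop("n_blocks must be at least 2")
  if (length(values) < n_blocks)
    stop("series shorter than the number of blocks")
  per <- floor(length(values) / n_blocks)
  used <- values[seq_len(per * n_blocks)]
  bm <- colMeans(matrix(used, nrow = per, ncol = n_blocks))
  structure(list(mean = mean(bm), sd_of_block_means = sd(bm),
                 n_blocks = n_blocks, block_means = bm),
            class = "block_average")
}

#' @export
print.block_average <- function(x, ...) {
  cat(sprintf("<block_average> %.4g +/- %.4g (%d blocks)\n",
              x$mean, x$sd_of_block_means, x$n_blocks))
  invisible(x)
}

#' Group a mode profile into contiguous intervals
#'
#' Merges maximal runs of identical mode labels along an ordered coordinate
#' (e.g. the centre-z of a docking search space) into intervals; singleton
#' runs are kept as one-point intervals.
#'
#' @param coordinate strictly increasing numeric coordinate.
#' @param mode mode label per coordinate.
#' @return data frame with `start`, `end`, `mode`, `n_points`; the
#'   intervals are sorted, non-overlapping, and exactly partition the
#'   input coordinates.
#' @export
group_contiguous_modes <- function(coordinate, mode) {
  if (length(coordinate) != length(mode)) stop("lengths differ")
  if (!length(coordinate)) stop("empty profile")
  if (any(diff(coordinate) <= 0)) stop("coordinate must be strictly increasing")
  r <- rle(as.character(mode))
  end_i <- cumsum(r$lengths)
  start_i <- end_i - r$lengths + 1
  data.frame(start = coordinate[start_i], end = coordinate[end_i],
             mode = r$values, n_points = r$lengths)
}

#' Subsample a trajectory at a fixed cadence
#'
#' Keeps every frame whose timestamp is a multiple of `every_ps` (within
#' tolerance).  The conventional end-state analysis cadence -- 1001 frames
#' at a 10 ps step over a 10 ns window -- corresponds to the default.
#'
#' @param traj a `mol_trajectory`.
#' @param every_ps cadence in picoseconds (default 10).
#' @return a subsampled `mol_trajectory`.
#' @export
subsample_frames <- function(traj, every_ps = 10) {
  stopifnot(every_ps > 0)
  keep <- which(abs(traj$times / every_ps - round(traj$times / every_ps)) < 1e-9)
  if (!length(keep)) stop("no frames at the requested cadence")
  trajectory(traj$frames[keep], traj$times[keep])
}
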