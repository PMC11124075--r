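#' MM-PBSA decomposition ledger
#'
#' Book-keeps the end-state binding-energy decomposition
#' `e_bind = e_mm + g_sol` with
#' `e_mm = bonded + nonbonded = (bonded_h + bonded_g) + (vdw + elec)` and
#' `g_sol = polar + nonpolar`.  Each aggregate is taken verbatim from
#' `components` when supplied there and otherwise computed from its
#' immediate parts, so the ledger can run at whatever level of detail the
#' input provides.  Inputs may be scalars (summary means) or aligned
#' per-frame series; with series, each aggregate is reported as its mean
#' with a block-averaged standard deviation.
#'
#' The entropy term is deliberately optional: without `minus_tds` the
#' result is a binding *energy* (`e_bind`); when `minus_tds` (-T dS,
#' kcal/mol) is supplied a `g_bind = e_bind + minus_tds` row is added.
#'
#' @param components named list (or one-row data frame) of numeric scalars
#'   or equal-length series: parts `bonded_h`, `bonded_g`, `vdw`, `elec`,
#'   `polar`, `nonpolar`; optional aggregates `bonded`, `nonbonded`,
#'   `e_mm`, `g_sol`, `e_bind`; optional `minus_tds`.
#' @param n_blocks blocks for the block-averaged uncertainties (series
#'   input only).
#' @return data frame of class `mmpbsa_summary` with columns `term`,
#'   `mean`, `sd` (NA for scalar input).
#' @export
mmpbsa_ledger <- function(components, n_blocks = 5) {
  cl <- lapply(as.list(components), as.numeric)
  lens <- unique(lengths(cl))
  if (length(setdiff(lens, 1)) > 1)
    stop("per-frame series must all have the same length")
  series <- max(lens) > 1
  if (series) {
    n <- max(lens)
    cl <- lapply(cl, function(v) if (length(v) == 1) rep(v, n) else v)
  }
  get <- function(nm, parts) {
    if (!is.null(cl[[nm]])) return(cl[[nm]])
    vals <- cl[parts]
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    Reduce(`+`, vals)
  }
  out <- list()
  out$bonded <- get("bonded", c("bonded_h", "bonded_g"))
  out$nonbonded <- get("nonbonded", c("vdw", "elec"))
  cl$bonded <- out$bonded; cl$nonbonded <- out$nonbonded
  out$e_mm <- get("e_mm", c("bonded", "nonbonded"))
  out$g_sol <- get("g_sol", c("polar", "nonpolar"))
  cl$e_mm <- out$e_mm; cl$g_sol <- out$g_sol
  out$e_bind <- get("e_bind", c("e_mm", "g_sol"))
  if (is.null(out$e_bind))
    stop("components are insufficient to form e_bind = e_mm + g_sol")
  if (!is.null(cl$minus_tds)) out$g_bind <- out$e_bind + cl$minus_tds
  out <- out[!vapply(out, is.null, logical(1))]
  summ <- lapply(names(out), function(nm) {
    v <- out[[nm]]
    if (series) {
      b <- block_average(v, n_blocks)
      data.frame(term = nm, mean = b$mean, sd = b$sd_of_block_means)
    } else data.frame(term = nm, mean = v, sd = NA_real_)
  })
  res <- do.call(rbind, summ)
  class(res) <- c("mmpbsa_summary", class(res))
  res
}

#' Bundled MM-PBSA component table for the CD:DOPO complexes
#'
#' Reference MM-PBSA decomposition means (and block-averaged standard
#' deviations) in kcal/mol for the alpha-, beta- and gamma-cyclodextrin
#' complexes with DOPO in the BS and BP binding modes.
#'
#' @return wide data frame with one row per (host, mode).
#' @export
mmpbsa_dataset <- function() {
  read_component_table(system.file("extdata", "mmpbsa_components_cd_dopo.csv",
                                   package = "cdbind", mustWork = TRUE))
}

#' Additivity check of an MM-PBSA component table
#'
#' For every (host, mode) column, recomputes each tabulated aggregate from
#' its immediate parts (`bonded` from host+guest bonded terms, `nonbonded`
#' from vdW+electrostatics, `e_mm` from `bonded`+`nonbonded`, `g_sol` from
#' polar+nonpolar, `e_bind` from `e_mm`+`g_sol`) and compares.  Deviations
#' up to 0.05 kcal/mol are exact at one-decimal printing; up to `tolerance`
#' they are flagged as rounding of unrounded sums; beyond that they fail.
#'
#' @param table wide component table (see [mmpbsa_dataset()]).
#' @param tolerance flag/fail boundary (kcal/mol), default 0.15.
#' @return data frame with `host`, `mode`, `quantity`, `printed`,
#'   `recomputed`, `deviation`, `status`.
#' @export
mmpbsa_check_table <- function(table, tolerance = 0.15) {
  need <- c("bonded_h", "bonded_g", "bonded", "vdw", "elec", "nonbonded",
            "e_mm", "polar", "nonpolar", "g_sol", "e_bind")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  add <- function(i, quantity, printed, recomputed) {
    dev <- abs(recomputed - printed)
    status <- if (dev <= 0.05 + 1e-9) "ok"
              else if (dev <= tolerance + 1e-9) "rounding" else "fail"
    rows[[length(rows) + 1]] <<- data.frame(
      host = table$host[i], mode = table$mode[i], quantity = quantity,
      printed = printed, recomputed = recomputed, deviation = dev,
      status = status)
  }
  for (i in seq_len(nrow(table))) {
    add(i, "bonded", table$bonded[i], table$bonded_h[i] + table$bonded_g[i])
    add(i, "nonbonded", table$nonbonded[i], table$vdw[i] + table$elec[i])
    add(i, "e_mm", table$e_mm[i], table$bonded[i] + table$nonbonded[i])
    add(i, "g_sol", table$g_sol[i], table$polar[i] + table$nonpolar[i])
    add(i, "e_bind", table$e_bind[i], table$e_mm[i] + table$g_sol[i])
  }
  do.call(rbind, rows)
}
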