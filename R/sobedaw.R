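#' sobEDAw weighting parameters
#'
#' The dimensionless parameters (r, a, c) of the exponential weighting that
#' splits the DFT correlation energy between the SAPT-like dispersion and
#' exchange-repulsion terms.  They are calibrated per level of theory; the
#' built-in preset is the B3LYP-D3(BJ)/6-31+G(d,p) calibration
#' (r = 2.571, a = 0.071, c = 0.575).  Other levels must be supplied
#' explicitly.
#'
#' @param r,a,c weighting parameters; `r > 0`, `c` in \[0, 1\].
#' @param level optional level-of-theory label; must name a built-in preset
#'   when given without explicit parameters.
#' @return list of class `sobedaw_params`.
#' @export
sobedaw_params <- function(r = NULL, a = NULL, c = NULL, level = NULL) {
  presets <- list("B3LYP-D3(BJ)/6-31+G(d,p)" = c(r = 2.571, a = 0.071, c = 0.575))
  if (is.null(r) && is.null(a) && is.null(c)) {
    level <- level %||% "B3LYP-D3(BJ)/6-31+G(d,p)"
    if (is.null(presets[[level]]))
      stop("no built-in parameter preset for level '", level,
           "'; supply r, a, c explicitly")
    p <- presets[[level]]
    r <- p[["r"]]; a <- p[["a"]]; c <- p[["c"]]
  }
  if (is.null(r) || is.null(a) || is.null(c))
    stop("supply all of r, a, c (or none, to use the preset)")
  if (r <= 0) stop("r must be > 0")
  if (c < 0 || c > 1) stop("c must be in [0, 1]")
  structure(list(r = r, a = a, c = c, level = level), class = "sobedaw_params")
}

#' Correlation-energy weighting factor omega
#'
#' `omega = exp(-r * (dc/els - a)) * (1 - c) + c`: the fraction of the DFT
#' correlation energy folded into the SAPT-like dispersion term; the
#' remainder goes to exchange-repulsion.  Undefined when the electrostatic
#' component is zero.
#'
#' @param dc dispersion-correction component (kcal/mol).
#' @param els electrostatic component (kcal/mol), nonzero.
#' @param params a [sobedaw_params()].
#' @return dimensionless weight (vectorised).
#' @export
omega_weight <- function(dc, els, params = sobedaw_params()) {
  if (any(els == 0)) stop("els must be nonzero (omega is undefined)")
  exp(-params$r * (dc / els - params$a)) * (1 - params$c) + params$c
}

#' Recombine DFT component energies into SAPT-like terms (sobEDAw)
#'
#' From the raw components -- electrostatics `els`, exchange `x`, Pauli
#' repulsion `rep`, orbital interaction `orb`, DFT correlation `dftc` and
#' dispersion correction `dc` -- computes
#' `xrep = (x + rep) + (1 - omega) * dftc`,
#' `disp = dc + omega * dftc`,
#' `c_total = dftc + dc`, and the omega-free interaction energy
#' `eint = els + x + rep + orb + dftc + dc`.  By construction
#' `xrep + disp = (x + rep) + c_total` and
#' `eint = els + xrep + orb + disp` for any omega.
#'
#' @param components list or one-row data frame with numeric fields `els`,
#'   `x`, `rep`, `orb`, `dftc`, `dc` (kcal/mol).  A multi-row data frame is
#'   processed row-wise.
#' @param params a [sobedaw_params()].
#' @return for a single component set, a list of class `sobedaw_result`
#'   with `omega`, `xrep`, `disp`, `c_total`, `eint`; for a multi-row data
#'   frame, the input with those columns appended.
#' @export
sobedaw_recombine <- function(components, params = sobedaw_params()) {
  need <- c("els", "x", "rep", "orb", "dftc", "dc")
  if (is.data.frame(components) && nrow(components) > 1) {
    miss <- setdiff(need, names(components))
    if (length(miss)) stop("components missing: ", paste(miss, collapse = ", "))
    omega <- omega_weight(components$dc, components$els, params)
    out <- components
    out$omega <- omega
    out$xrep <- (components$x + components$rep) + (1 - omega) * components$dftc
    out$disp <- components$dc + omega * components$dftc
    out$c_total <- components$dftc + components$dc
    out$eint <- with(components, els + x + rep + orb + dftc + dc)
    return(out)
  }
  cl <- as.list(components)
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("components missing: ", paste(miss, collapse = ", "))
  cl[need] <- lapply(cl[need], as.numeric)
  omega <- omega_weight(cl$dc, cl$els, params)
  structure(list(
    omega = omega,
    xrep = (cl$x + cl$rep) + (1 - omega) * cl$dftc,
    disp = cl$dc + omega * cl$dftc,
    c_total = cl$dftc + cl$dc,
    eint = cl$els + cl$x + cl$rep + cl$orb + cl$dftc + cl$dc),
    class = "sobedaw_result")
}

#' @export
print.sobedaw_result <- function(x, ...) {
  cat(sprintf(paste0("<sobedaw_result> omega %.4f  xrep %7.2f  disp %7.2f  ",
                     "c %7.2f  eint %7.2f kcal/mol\n"),
              x$omega, x$xrep, x$disp, x$c_total, x$eint))
  invisible(x)
}

#' Binding free energy ledger
#'
#' `gbind = eint + def_total + sol_total + gcorr`, where the deformation
#' total is `def_h + def_g` (host and guest geometry relaxation), the
#' solvation total is `polar + nonpolar`, and `gcorr` is the thermal
#' free-energy correction.  Aggregate values (`def_total`, `sol_total`) may
#' be supplied directly instead of their parts.
#'
#' @param eint interaction energy (kcal/mol) or a `sobedaw_result` (its
#'   `eint` is used).
#' @param def_h,def_g host/guest deformation energies (kcal/mol).
#' @param def_total deformation total, overriding `def_h + def_g`.
#' @param polar,nonpolar solvation components (kcal/mol).
#' @param sol_total solvation total, overriding `polar + nonpolar`.
#' @param gcorr thermal correction to the free energy (kcal/mol).
#' @return list with `eint`, `def_total`, `sol_total`, `gcorr`, `gbind`.
#' @export
binding_free_energy <- function(eint, def_h = NULL, def_g = NULL,
                                def_total = NULL, polar = NULL,
                                nonpolar = NULL, sol_total = NULL,
                                gcorr = 0) {
  if (inherits(eint, "sobedaw_result")) eint <- eint$eint
  def_total <- def_total %||%
    (if (!is.null(def_h) && !is.null(def_g)) def_h + def_g
     else stop("supply def_total or both def_h and def_g"))
  sol_total <- sol_total %||%
    (if (!is.null(polar) && !is.null(nonpolar)) polar + nonpolar
     else stop("supply sol_total or both polar and nonpolar"))
  list(eint = eint, def_total = def_total, sol_total = sol_total,
       gcorr = gcorr, gbind = eint + def_total + sol_total + gcorr)
}

# ---------------------------------------------------------------------------
# component tables

#' Read a component-energy table
#'
#' Accepts either a long CSV with columns `host`, `mode`, `phase`, `term`,
#' `value` (one component per row) or a wide CSV with one row per
#' (host, mode, phase) and one column per term.  Long input is pivoted to
#' wide.
#'
#' @param path CSV file path.
#' @return wide data frame: `host`, `mode`, `phase`, then one numeric
#'   column per term.
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("term", "value") %in% names(tab))) {
    keys <- intersect(c("host", "mode", "phase"), names(tab))
    wide <- stats::reshape(tab, idvar = keys, timevar = "term",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    return(wide)
  }
  tab
}

#' Bundled DFT component-energy table for the CD:DOPO complexes
#'
#' Reference sobEDAw component energies (kcal/mol) for the alpha-, beta-
#' and gamma-cyclodextrin complexes with the flame retardant DOPO, in the
#' BS and BP binding modes and in gas and water phases, together with the
#' printed aggregate rows (`xrep`, `disp`, `c`, `eint`, `def`, `sol`,
#' `gbind`) used by the consistency suite.
#'
#' @return wide data frame (see [read_component_table()]).
#' @export
sobedaw_dataset <- function() {
  read_component_table(system.file("extdata", "sobedaw_components_cd_dopo.csv",
                                   package = "cdbind", mustWork = TRUE))
}

#' Consistency check of a sobEDAw component table
#'
#' Recomputes the recombined quantities from the raw components of each
#' (host, mode, phase) column and compares them with the tabulated
#' aggregates: `xrep` and `disp` via the omega weighting, `c` as
#' `dftc + dc`, `eint` as the omega-free component sum, and `gbind` as the
#' ledger over the tabulated `eint`, `def`, `sol`, `gcorr`.  Deviations up
#' to 0.05 kcal/mol count as exact at one-decimal printing; deviations
#' within `tolerance` are flagged as rounding of unrounded sums; larger
#' ones fail.
#'
#' @param table wide component table (see [sobedaw_dataset()]).
#' @param params a [sobedaw_params()].
#' @param tolerance flag/fail boundary (kcal/mol), default 0.15.
#' @return data frame with one row per checked aggregate: `host`, `mode`,
#'   `phase`, `quantity`, `printed`, `recomputed`, `deviation`, `status`
#'   (`"ok"`, `"rounding"`, `"fail"`).
#' @export
sobedaw_consistency <- function(table, params = sobedaw_params(),
                                tolerance = 0.15) {
  res <- sobedaw_recombine(table, params)
  rows <- list()
  add <- function(i, quantity, printed, recomputed) {
    dev <- abs(recomputed - printed)
    status <- if (dev <= 0.05 + 1e-9) "ok"
              else if (dev <= tolerance + 1e-9) "rounding" else "fail"
    rows[[length(rows) + 1]] <<- data.frame(
      host = table$host[i], mode = table$mode[i], phase = table$phase[i],
      quantity = quantity, printed = printed, recomputed = recomputed,
      deviation = dev, status = status)
  }
  for (i in seq_len(nrow(table))) {
    add(i, "xrep", table$xrep[i], res$xrep[i])
    add(i, "disp", table$disp[i], res$disp[i])
    add(i, "c", table$c[i], res$c_total[i])
    add(i, "eint", table$eint[i], res$eint[i])
    add(i, "def", table$def[i], table$def_h[i] + table$def_g[i])
    add(i, "sol", table$sol[i], table$polar[i] + table$nonpolar[i])
    g <- binding_free_energy(table$eint[i], def_total = table$def[i],
                             sol_total = table$sol[i], gcorr = table$gcorr[i])
    add(i, "gbind", table$gbind[i], g$gbind)
  }
  do.call(rbind, rows)
}
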