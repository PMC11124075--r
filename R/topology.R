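#' Cyclodextrin topology
#'
#' Book-keeping for one cyclodextrin ring: which atoms are the glycosidic
#' (bridging) oxygens, the six pyran-ring atoms of each glucose unit, and
#' the primary-rim (O6) and secondary-rim (O2/O3) hydroxyl oxygens.
#'
#' @param glycosidic integer vector of glycosidic-oxygen serials, one per
#'   glucose unit, in ring order.
#' @param pyran_rings list of length-6 integer vectors (O5, C1..C5 serials),
#'   one per unit, same order.
#' @param prim_rim integer vector of primary-rim (O6) oxygen serials per unit.
#' @param sec_rim list of integer vectors of secondary-rim (O2/O3) oxygen
#'   serials per unit.
#' @return an object of class `cd_topology`.
#' @export
cd_topology <- function(glycosidic, pyran_rings, prim_rim, sec_rim) {
  n <- length(glycosidic)
  if (!n %in% 6:8)
    warning("unusual unit count for a cyclodextrin: ", n)
  if (length(pyran_rings) != n || length(prim_rim) != n || length(sec_rim) != n)
    stop("per-unit lists must all have length ", n)
  if (any(vapply(pyran_rings, function(r)
    length(r) != 6 || anyDuplicated(r) > 0, logical(1))))
    stop("each pyran ring needs 6 distinct atom serials")
  rimset <- c(unlist(sec_rim), prim_rim)
  if (anyDuplicated(rimset)) stop("primary and secondary rim sets must be disjoint")
  structure(list(n_units = n,
                 glycosidic = as.integer(glycosidic),
                 pyran_rings = lapply(pyran_rings, as.integer),
                 prim_rim = as.integer(prim_rim),
                 sec_rim = lapply(sec_rim, as.integer)),
            class = "cd_topology")
}

#' @export
print.cd_topology <- function(x, ...) {
  cat("<cd_topology> ", x$n_units, " glucose units\n", sep = "")
  invisible(x)
}

#' Detect cyclodextrin topology from atom names and connectivity
#'
#' Identifies the glycosidic oxygens of a cyclodextrin as the ring-bridging
#' O4 atoms: an O4 is glycosidic when the C1 of a *different* glucose
#' residue lies within the covalent cutoff (1.8 A).  Units are ordered by
#' traversing the glycosidic linkage cycle starting from the lowest residue
#' index, in the direction of increasing residue index.  Explicit `hints`
#' always win and are returned verbatim.
#'
#' @param structure a [mol_structure()] containing one cyclodextrin
#'   (6-8 glucopyranose residues with standard atom names O2, O3, O4, O5,
#'   O6, C1..C5).
#' @param hints optional list with elements `glycosidic`, `pyran_rings`,
#'   `prim_rim`, `sec_rim` (see [cd_topology()]); used verbatim when given.
#' @param covalent_cutoff bridging-bond distance criterion in Angstrom.
#' @return a [cd_topology()].
#' @export
detect_cd_topology <- function(structure, hints = NULL, covalent_cutoff = 1.8) {
  if (!is.null(hints))
    return(cd_topology(hints$glycosidic, hints$pyran_rings,
                       hints$prim_rim, hints$sec_rim))
  a <- structure$atoms
  o4 <- a[a$name == "O4", , drop = FALSE]
  c1 <- a[a$name == "C1", , drop = FALSE]
  if (!nrow(o4) || !nrow(c1))
    stop("no O4/C1 atoms found; supply explicit topology hints")
  # glycosidic O4: a C1 of another residue within the covalent cutoff
  bridge <- vector("list", nrow(o4))
  for (i in seq_len(nrow(o4))) {
    d <- sqrt((c1$x - o4$x[i])^2 + (c1$y - o4$y[i])^2 + (c1$z - o4$z[i])^2)
    hit <- which(d <= covalent_cutoff & c1$resid != o4$resid[i])
    if (length(hit) > 1)
      stop("ambiguous glycosidic bridging for O4 serial ", o4$serial[i],
           "; supply explicit topology hints")
    if (length(hit) == 1)
      bridge[[i]] <- c(own = o4$resid[i], partner = c1$resid[hit])
  }
  keep <- !vapply(bridge, is.null, logical(1))
  o4 <- o4[keep, , drop = FALSE]
  bridge <- bridge[keep]
  units <- sort(unique(o4$resid))
  n <- length(units)
  if (!n %in% 6:8)
    stop("detected ", n, " glucose units; expected 6, 7 or 8 ",
         "(supply explicit topology hints to override)")
  if (nrow(o4) != n)
    stop("found ", nrow(o4), " glycosidic oxygens for ", n, " units; ",
         "supply explicit topology hints")
  # linkage map: residue -> residue whose C1 its O4 bridges
  nxt <- setNames(vapply(bridge, `[[`, 0, "partner"),
                  vapply(bridge, `[[`, 0, "own"))
  # traverse the cycle from the lowest residue index, then orient the walk
  # so that the second unit carries the smaller residue index (i.e. indices
  # increase around the ring for the canonical 1..n labelling)
  start <- min(units)
  order_res <- integer(n)
  order_res[1] <- start
  for (k in 2:n) {
    order_res[k] <- unname(nxt[as.character(order_res[k - 1])])
    if (is.na(order_res[k]))
      stop("glycosidic linkage does not form a closed cycle; ",
           "supply explicit topology hints")
  }
  if (anyDuplicated(order_res) || !setequal(order_res, units))
    stop("glycosidic linkage does not form a single cycle over all units")
  if (order_res[2] > order_res[n])
    order_res <- c(order_res[1], rev(order_res[-1]))
  pick <- function(res, nm) {
    s <- a$serial[a$resid == res & a$name == nm]
    if (length(s) != 1)
      stop("residue ", res, ": expected exactly one atom named ", nm)
    s
  }
  cd_topology(
    glycosidic = vapply(order_res, function(r) pick(r, "O4"), 0L),
    pyran_rings = lapply(order_res, function(r)
      vapply(c("O5", "C1", "C2", "C3", "C4", "C5"), pick, 0L, res = r)),
    prim_rim = vapply(order_res, function(r) pick(r, "O6"), 0L),
    sec_rim = lapply(order_res, function(r) c(pick(r, "O2"), pick(r, "O3"))))
}
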