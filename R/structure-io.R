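#' Molecular structure container
#'
#' A minimal ordered-atom container used throughout the package.  Atoms are
#' stored as a data frame with one row per atom; coordinates are in Angstrom.
#'
#' @param atoms data frame with columns `serial` (unique integer), `name`
#'   (atom name), `resname` (residue name), `resid` (integer residue index),
#'   `element` (element symbol) and Cartesian coordinates `x`, `y`, `z` (A).
#' @param bonds optional two-column integer matrix of bonded atom serials.
#' @param label free-text label carried through I/O.
#'
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = NULL, label = "") {
  need <- c("serial", "name", "resname", "resid", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (!all(bonds %in% atoms$serial))
      stop("bond endpoints must reference existing atom serials")
  }
  structure(list(atoms = atoms, bonds = bonds, label = label),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("<mol_structure> ", nrow(x$atoms), " atoms",
      if (nzchar(x$label)) paste0("  [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.mol_structure <- function(x) nrow(x$atoms)

# coordinate matrix (n x 3) of a structure, optionally for a serial subset
coords <- function(structure, serials = NULL) {
  a <- structure$atoms
  if (!is.null(serials)) {
    idx <- match(serials, a$serial)
    if (anyNA(idx)) stop("unknown atom serial(s): ",
                         paste(serials[is.na(idx)], collapse = ", "))
    a <- a[idx, , drop = FALSE]
  }
  as.matrix(a[, c("x", "y", "z")])
}

#' Atomic masses of a structure's atoms
#'
#' Standard atomic masses looked up from the element symbol.  Unknown
#' elements raise an error; there is no silent unit-mass fallback.
#'
#' @param structure a [mol_structure()].
#' @param serials optional atom serials to restrict to.
#' @return numeric vector of masses (u).
#' @export
atom_masses <- function(structure, serials = NULL) {
  a <- structure$atoms
  if (!is.null(serials)) a <- a[match(serials, a$serial), , drop = FALSE]
  el <- trimws(a$element)
  if (any(!nzchar(el))) stop("atoms without an element symbol; cannot assign masses")
  m <- .element_table()$mass[match(el, .element_table()$symb)]
  if (anyNA(m) || any(m == 0))
    stop("unknown element(s): ",
         paste(unique(el[is.na(m) | m == 0]), collapse = ", "))
  m
}

# bio3d's periodic-table data, loaded once per session
.element_cache <- new.env(parent = emptyenv())
.element_table <- function() {
  if (is.null(.element_cache$tab)) {
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    tab <- e$elements
    tab$symb <- as.character(tab$symb)
    .element_cache$tab <- tab
  }
  .element_cache$tab
}

# mass-weighted centre of mass of a serial selection
com <- function(structure, serials = NULL, weighted = TRUE) {
  xyz <- coords(structure, serials)
  if (weighted) {
    m <- atom_masses(structure, serials %||% structure$atoms$serial)
    colSums(xyz * m) / sum(m)
  } else {
    colMeans(xyz)
  }
}

# ---------------------------------------------------------------------------
# PDB / XYZ reading

# light validation pass over PDB lines: coordinate fields must parse and
# MODEL blocks must agree in atom count and atom identity/order
.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record at line ", i,
           ": coordinate fields do not parse")
  }
  # split atom records by MODEL
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) >= 2) {
    model_of <- findInterval(which(is_atom), model_starts)
    keys <- split(paste(substr(lines[is_atom], 13, 16),
                        substr(lines[is_atom], 7, 11)), model_of)
    n <- lengths(keys)
    if (length(unique(n)) > 1)
      stop("MODEL blocks have differing atom counts: ",
           paste(unique(n), collapse = ", "))
    ref <- keys[[1]]
    for (k in seq_along(keys)) {
      if (!identical(keys[[k]], ref))
        stop("atom ordering/identity differs between MODEL 1 and MODEL ", k)
    }
  }
  invisible(length(model_starts))
}

.structure_from_bio3d <- function(atom, xyz_row, label) {
  el <- trimws(atom$elesy)
  # fall back to the leading letter(s) of the atom name when the element
  # column is absent (common in hand-made files)
  fix <- is.na(el) | !nzchar(el)
  if (any(fix)) el[fix] <- gsub("[^A-Za-z].*$", "", trimws(atom$elety[fix]))
  xyz <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  mol_structure(data.frame(serial = atom$eleno,
                           name = trimws(atom$elety),
                           resname = trimws(atom$resid),
                           resid = atom$resno,
                           element = el,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                label = label)
}

.read_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header at line 1: expected an atom count")
  if (length(lines) < n + 2) stop("XYZ file truncated: expected ", n, " atom lines")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "[[:space:]]+")[[1]]
    if (length(tok) < 4) stop("malformed XYZ record at line ", i + 2)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) stop("malformed XYZ record at line ", i + 2,
                         ": coordinates do not parse")
    out[[i]] <- data.frame(serial = i, name = tok[1], resname = "MOL",
                           resid = 1L, element = tok[1],
                           x = xyz[1], y = xyz[2], z = xyz[3])
  }
  mol_structure(do.call(rbind, out), label = basename(path))
}

#' Read a molecular structure
#'
#' Reads a single structure from a PDB (ATOM/HETATM records; only the first
#' MODEL of a multi-model file) or XYZ file.  Coordinates are in Angstrom.
#'
#' @param path path to the file.
#' @param dialect `"pdb"` (default) or `"xyz"`; guessed from the file
#'   extension when missing.
#' @return a [mol_structure()].
#' @export
read_structure <- function(path, dialect = c("pdb", "xyz")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(dialect) && grepl("\\.xyz$", path, ignore.case = TRUE))
    dialect <- "xyz"
  dialect <- match.arg(dialect)
  if (dialect == "xyz") return(.read_xyz(path))
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  .structure_from_bio3d(pdb$atom, pdb$xyz[1, ], basename(path))
}

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per MODEL record; all MODELs must contain the same atoms in the
#' same order.  Frame timestamps are `0, dt, 2 dt, ...` picoseconds.
#'
#' @param path path to a multi-model PDB file.
#' @param dt_ps frame spacing in picoseconds (default 1).
#' @return a `mol_trajectory`: list with `frames` (list of
#'   [mol_structure()]) and `times` (ps).
#' @export
read_trajectory <- function(path, dt_ps = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i)
    .structure_from_bio3d(pdb$atom, pdb$xyz[i, ], basename(path)))
  trajectory(frames, times = (seq_along(frames) - 1) * dt_ps)
}

#' Assemble a trajectory from structures
#'
#' @param frames list of [mol_structure()] with identical atom counts and
#'   matching serials.
#' @param times strictly increasing per-frame timestamps (ps).
#' @return a `mol_trajectory`.
#' @export
trajectory <- function(frames, times = seq_along(frames) - 1) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  ref <- frames[[1]]$atoms$serial
  for (k in seq_along(frames)) {
    s <- frames[[k]]$atoms$serial
    if (length(s) != length(ref) || !all(s == ref))
      stop("frame ", k, " does not match frame 1 in atom count/serials")
  }
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop("times must match the number of frames")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(frames = frames, times = times), class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat("<mol_trajectory> ", length(x$frames), " frames x ",
      nrow(x$frames[[1]]$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.mol_trajectory <- function(x) length(x$frames)

# ---------------------------------------------------------------------------
# writing

#' Write a structure (or trajectory) to a PDB file
#'
#' Fixed-column ATOM records, coordinates to three decimals.  A
#' `mol_trajectory` is written as a multi-model file.
#'
#' @param structure a [mol_structure()] or `mol_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (inherits(structure, "mol_trajectory")) {
    a <- structure$frames[[1]]$atoms
    xyz <- do.call(rbind, lapply(structure$frames, function(f)
      as.vector(t(coords(f)))))
  } else {
    a <- structure$atoms
    if (!nrow(a)) stop("cannot write an empty structure")
    xyz <- matrix(as.vector(t(coords(structure))), nrow = 1)
  }
  if (any(nchar(trimws(a$name)) > 4))
    stop("atom name(s) longer than the 4-character PDB field")
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, elesy = a$element)
  invisible(path)
}
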