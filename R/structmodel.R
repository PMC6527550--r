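# Core structural data model: atoms, structures, rigid-body poses and the
# geometry primitives every downstream stage relies on. Coordinates are in
# Angstrom throughout; axes are right-handed; no unit conversion happens at
# module boundaries.

#' Default van der Waals radii (Angstrom), keyed by element symbol
#'
#' Heavy-atom radii used for clash detection. Unknown elements (including the
#' pseudo-beads of the synthetic pocket systems) fall back to the carbon-like
#' 1.70 Angstrom bead radius.
#'
#' @format Named numeric vector.
#' @export
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, X = 1.70)

vdw_radius_for <- function(element, radii = default_vdw_radii) {
  r <- unname(radii[element])
  r[is.na(r)] <- unname(radii["X"])
  r
}

#' Construct a Structure from an atom table
#'
#' A `Structure` is the package's pseudo-atomic protein model: an ordered
#' atom table plus two annotations used by the egress machinery -- the set of
#' residues whose side-chain torsion is sampled (`flexible_residues`) and the
#' atom subset treated as backbone when normal-mode displacements are scaled
#' (`backbone_mask`).
#'
#' @param atoms data.frame with columns `element`, `name`, `res_index`,
#'   `res_name`, `chain`, `x`, `y`, `z`, `occupancy`, and optionally `radius`
#'   (filled from [default_vdw_radii] when absent) and `polar` (logical
#'   donor/acceptor flag, default `FALSE`).
#' @param flexible_residues integer vector of residue indices flagged mobile.
#' @param backbone_mask logical vector, one per atom; defaults to all `TRUE`.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, flexible_residues = integer(0),
                          backbone_mask = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  req <- c("element", "name", "res_index", "res_name", "chain",
           "x", "y", "z", "occupancy")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (!all(atoms$occupancy > 0 & atoms$occupancy <= 1))
    stop("occupancies must lie in (0, 1]")
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius_for(atoms$element)
  if (!all(atoms$radius > 0)) stop("van der Waals radii must be positive")
  if (is.null(atoms$polar)) atoms$polar <- FALSE
  if (is.null(backbone_mask)) backbone_mask <- rep(TRUE, nrow(atoms))
  stopifnot(length(backbone_mask) == nrow(atoms))
  # residue indices must not decrease within a chain
  for (ch in unique(atoms$chain)) {
    ri <- atoms$res_index[atoms$chain == ch]
    if (is.unsorted(ri)) stop("residue indices decrease within chain ", ch)
  }
  flexible_residues <- as.integer(flexible_residues)
  if (!all(flexible_residues %in% atoms$res_index))
    stop("flexible_residues must be residues present in the structure")
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, flexible_residues = flexible_residues,
         backbone_mask = backbone_mask),
    class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$res_index))), "residues,",
      length(unique(x$atoms$chain)), "chain(s);",
      length(x$flexible_residues), "flexible residue(s)\n")
  invisible(x)
}

#' Atom coordinates as an N x 3 matrix
#' @param structure a `Structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Read a PDB file into a Structure
#'
#' Fixed-column ATOM/HETATM records are parsed (via bio3d). Hydrogens are
#' dropped by default because all downstream clash logic is heavy-atom.
#' Alternate locations are resolved per atom site by keeping the conformer
#' with the highest occupancy, ties going to the first in file -- downstream
#' stages need a single coordinate set even when the deposited model carries
#' 0.8/0.2 conformers.
#'
#' @param path file path.
#' @param keep_hydrogens keep H atoms (default `FALSE`).
#' @param altloc one of `"highest_occupancy"` (default) or `"first"`.
#' @param radii named radius table, see [default_vdw_radii].
#' @return a `Structure`; atoms in file order.
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE,
                     altloc = c("highest_occupancy", "first"),
                     radii = default_vdw_radii) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("not a parseable PDB file: ", path,
                             " (", conditionMessage(e), ")"))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("format error: no ATOM/HETATM records in ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    # locate the offending line for the error message
    lines <- readLines(path, warn = FALSE)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    bad <- which(rec)[which(!is.finite(at$x) | !is.finite(at$y) |
                              !is.finite(at$z))[1]]
    stop("format error: malformed coordinate field at line ", bad)
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- toupper(substr(trimws(at$elety), 1, 1))
  }
  elem[is.na(elem) | elem == ""] <-
    toupper(substr(trimws(at$elety), 1, 1))[is.na(elem) | elem == ""]
  occ <- at$o
  occ[is.na(occ)] <- 1
  # clamp zero/negative occupancies (some files use 0.00 placeholders)
  occ[occ <= 0] <- 1e-3
  occ[occ > 1] <- 1
  atoms <- data.frame(
    element = trimws(elem), name = trimws(at$elety),
    res_index = at$resno, res_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    stringsAsFactors = FALSE)
  if (!keep_hydrogens) {
    is_h <- atoms$element %in% c("H", "D")
    atoms <- atoms[!is_h, , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("format error: no heavy atoms in ", path)
  # altloc policy: one conformer per (chain, residue, atom name) site
  key <- paste(atoms$chain, atoms$res_index, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      win <- if (altloc == "highest_occupancy") {
        idx[which.max(atoms$occupancy[idx])]  # ties: first in file
      } else idx[1]
      keep[setdiff(idx, win)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$alt <- NULL
  atoms$radius <- vdw_radius_for(atoms$element, radii)
  new_structure(atoms)
}

#' Write a Structure as a fixed-column PDB file
#'
#' Standard ATOM records (HETATM for non-standard residue names is not
#' distinguished; readers treat both alike here), with a TER record after
#' each chain and a terminal END. Coordinates are written to three decimals
#' in columns 31-54, so a read/write round trip preserves them to 1e-3
#' Angstrom.
#'
#' @param structure a `Structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "Structure"))
  at <- structure$atoms
  if (nrow(at) == 0) stop("cannot write an empty structure")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  serial <- seq_len(nrow(at))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    "ATOM", serial,
    ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
    " ", substr(at$res_name, 1, 3), substr(at$chain, 1, 1),
    at$res_index %% 10000L, " ",
    at$x, at$y, at$z, at$occupancy, 0,
    substr(at$element, 1, 2))
  # TER after the last atom of each chain, preserving file order
  chain_last <- !duplicated(at$chain, fromLast = TRUE)
  out <- character(0)
  for (i in seq_along(lines)) {
    out <- c(out, lines[i])
    if (chain_last[i]) out <- c(out, "TER")
  }
  writeLines(c(out, "END"), con)
  invisible(path)
}

#' Unweighted geometric centre of an atom subset
#'
#' @param x an N x 3 coordinate matrix, or a `Structure` (optionally
#'   subset with `which`).
#' @param which optional atom indices when `x` is a `Structure`.
#' @return length-3 numeric vector (Angstrom).
#' @export
geometric_center <- function(x, which = NULL) {
  if (inherits(x, "Structure")) {
    x <- coords(x)
    if (!is.null(which)) x <- x[which, , drop = FALSE]
  }
  x <- rbind(x)  # accept a bare length-3 vector as one atom
  if (nrow(x) == 0) stop("geometric_center of an empty atom subset")
  colMeans(x)
}

#' Euclidean separation between two points
#'
#' @param a,b length-3 numeric vectors (Angstrom).
#' @return distance in Angstrom (non-negative, symmetric).
#' @export
separation <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

# ---- rigid-body poses -------------------------------------------------------

#' Construct a rigid-body Pose
#'
#' A pose is a unit quaternion rotation, a translation in Angstrom, and an
#' optional vector of dihedral angles (degrees, in `[-180, 180)`) for
#' rotatable bonds -- in this package those are the single torsions of the
#' gate side chains or of a ligand.
#'
#' @param rotation length-4 quaternion `(w, x, y, z)`; normalised on input.
#' @param translation length-3 vector (Angstrom).
#' @param torsions numeric vector of dihedrals in degrees.
#' @return an object of class `Pose`.
#' @export
new_pose <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0),
                     torsions = numeric(0)) {
  n <- sqrt(sum(rotation^2))
  if (!is.finite(n) || n < 1e-12) stop("degenerate quaternion")
  rotation <- rotation / n
  torsions <- wrap_angle(torsions)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 torsions = torsions), class = "Pose")
}

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("Pose: t = (%.2f, %.2f, %.2f) A, |q| = %.6f, %d torsion(s)\n",
              x$translation[1], x$translation[2], x$translation[3],
              sqrt(sum(x$rotation^2)), length(x$torsions)))
  invisible(x)
}

# wrap degrees into [-180, 180)
wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Quaternion to 3 x 3 rotation matrix
#' @param q length-4 unit quaternion `(w, x, y, z)`.
#' @return 3 x 3 orthonormal matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Axis-angle rotation as a quaternion
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return length-4 unit quaternion.
#' @export
axis_angle_quat <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

#' Quaternion product `a * b`
#' @param a,b length-4 quaternions.
#' @return length-4 quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

#' Apply a pose to reference coordinates
#'
#' Rotates about the reference centroid, then translates: the translation
#' component is the displacement of the body centroid from its reference
#' position.
#'
#' @param ref N x 3 reference coordinates.
#' @param pose a `Pose`.
#' @return N x 3 transformed coordinates.
#' @export
apply_pose <- function(ref, pose) {
  ctr <- colMeans(ref)
  R <- quat_to_matrix(pose$rotation)
  sweep(sweep(ref, 2, ctr) %*% t(R), 2, ctr + pose$translation, `+`)
}
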