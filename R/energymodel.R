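# Simplified receptor--ligand interaction energy: 12-6 Lennard-Jones plus a
# switched polar well for flagged donor/acceptor pairs, and a hard-sphere
# clash count. This bead-level model stands in for a full force field; the
# egress analyses only need relative energies and steric feasibility.

#' Interaction-energy parameters
#'
#' @param epsilon Lennard-Jones well depth, kcal/mol (per pair). The
#'   default (0.02) keeps the unspecific dispersion attraction weak --
#'   binding specificity in this model comes from the polar wells, and the
#'   repulsive branch still seals bead walls against thermal penetration.
#' @param sigma Lennard-Jones sigma in Angstrom. `NULL` (default) derives a
#'   per-pair sigma from the atoms' van der Waals radii,
#'   `sigma_ij = (r_i + r_j) * 2^(-1/6)`, which puts the pair minimum at
#'   radius contact.
#' @param polar_strength well depth (kcal/mol) for flagged donor-acceptor
#'   pairs; individual receptor atoms may override it via a
#'   `polar_strength` atom column.
#' @param overlap_factor clash threshold: a pair clashes when closer than
#'   `overlap_factor * (r_i + r_j)`. Default 0.7.
#' @param cutoff non-bonded cutoff in Angstrom (default 12).
#' @param r_hb,r_hb_off polar switching: the well is full for `r < r_hb`
#'   (default 3.0 A) and switches smoothly (cosine) to zero at `r_hb_off`
#'   (default 3.5 A).
#' @return an object of class `EnergyParams`.
#' @export
energy_params <- function(epsilon = 0.02, sigma = NULL, polar_strength = 1.5,
                          overlap_factor = 0.7, cutoff = 12,
                          r_hb = 3.0, r_hb_off = 3.5) {
  stopifnot(epsilon > 0, is.null(sigma) || sigma > 0,
            overlap_factor > 0, overlap_factor <= 1,
            cutoff > 0, r_hb_off > r_hb, r_hb > 0)
  if (!is.null(sigma) && cutoff <= sigma)
    stop("cutoff must exceed sigma")
  structure(list(epsilon = epsilon, sigma = sigma,
                 polar_strength = polar_strength,
                 overlap_factor = overlap_factor, cutoff = cutoff,
                 r_hb = r_hb, r_hb_off = r_hb_off),
            class = "EnergyParams")
}

# ---- neighbour search -------------------------------------------------------

#' All cross pairs within a cutoff (cell list or brute force)
#'
#' Returns index pairs `(i, j)` with `|A[i,] - B[j,]| < cutoff`. The cell-list
#' path bins `B` into cubic cells of edge `cutoff` and inspects the 27
#' neighbouring cells of each `A` atom; it is exact and is cross-checked
#' against the brute-force path in the test suite.
#'
#' @param A,B coordinate matrices (n x 3, m x 3).
#' @param cutoff distance cutoff, Angstrom.
#' @param method `"auto"` (cell list for large problems), `"cell"`, `"brute"`.
#' @return list with integer vectors `i`, `j` and numeric `d` (distances).
#' @export
neighbor_pairs <- function(A, B, cutoff, method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  A <- rbind(A); B <- rbind(B)
  if (method == "auto")
    method <- if (nrow(A) * nrow(B) > 250000) "cell" else "brute"
  if (method == "brute") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    return(list(i = unname(hit[, 1]), j = unname(hit[, 2]),
                d = unname(sqrt(pmax(d2[hit], 0)))))
  }
  # cell list over B
  cell <- function(X) floor(sweep(X, 2, c(0, 0, 0)) / cutoff)
  cb <- cell(B)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  bins <- split(seq_len(nrow(B)), keyb)
  ca <- cell(A)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- jj <- integer(0); dd <- numeric(0)
  for (ia in seq_len(nrow(A))) {
    keys <- paste(ca[ia, 1] + off[, 1], ca[ia, 2] + off[, 2],
                  ca[ia, 3] + off[, 3])
    cand <- unlist(bins[keys], use.names = FALSE)
    if (length(cand) == 0) next
    d2 <- (B[cand, 1] - A[ia, 1])^2 + (B[cand, 2] - A[ia, 2])^2 +
      (B[cand, 3] - A[ia, 3])^2
    sel <- d2 < cutoff^2
    if (any(sel)) {
      ii <- c(ii, rep.int(ia, sum(sel)))
      jj <- c(jj, cand[sel])
      dd <- c(dd, sqrt(d2[sel]))
    }
  }
  list(i = ii, j = jj, d = dd)
}

# resolve ligand coordinates / radii / polar flags from a RingLigand + Pose
ligand_scene <- function(ligand, pose = NULL) {
  xyz <- as.matrix(ligand$beads[, c("x", "y", "z")])
  if (!is.null(pose)) xyz <- apply_pose(xyz, pose)
  list(xyz = xyz, radius = ligand$beads$radius, polar = ligand$beads$polar)
}

receptor_scene <- function(structure) {
  ps <- structure$atoms$polar_strength
  list(xyz = coords(structure), radius = structure$atoms$radius,
       polar = structure$atoms$polar,
       polar_strength = if (is.null(ps)) rep(NA_real_, nrow(structure$atoms)) else ps)
}

#' Count receptor--ligand steric clashes
#'
#' A pair clashes when its centre distance is below
#' `overlap_factor * (r_i + r_j)`. Only heavy-atom receptor--ligand pairs are
#' considered; the count is symmetric in pair order by construction.
#'
#' @param structure receptor `Structure`.
#' @param ligand a `RingLigand` (see [make_ring_ligand]).
#' @param pose ligand `Pose` (default: reference placement).
#' @param params `EnergyParams`.
#' @param method neighbour-search method, see [neighbor_pairs].
#' @return integer clash count.
#' @export
clash_count <- function(structure, ligand, pose = NULL,
                        params = energy_params(), method = "auto") {
  rec <- receptor_scene(structure)
  lig <- ligand_scene(ligand, pose)
  rmax <- params$overlap_factor * (max(rec$radius) + max(lig$radius))
  np <- neighbor_pairs(lig$xyz, rec$xyz, rmax, method)
  if (length(np$i) == 0) return(0L)
  thr <- params$overlap_factor * (lig$radius[np$i] + rec$radius[np$j])
  sum(np$d < thr)
}

# core pairwise energy given resolved scenes; r = 0 is a singularity
pair_energy <- function(lig, rec, params, method = "auto") {
  np <- neighbor_pairs(lig$xyz, rec$xyz, params$cutoff, method)
  if (length(np$i) == 0) return(0)
  r <- np$d
  if (any(r == 0)) stop("singularity: coincident atoms (r = 0)")
  sig <- if (is.null(params$sigma)) {
    (lig$radius[np$i] + rec$radius[np$j]) * 2^(-1 / 6)
  } else rep(params$sigma, length(r))
  sr6 <- (sig / r)^6
  e <- sum(4 * params$epsilon * (sr6^2 - sr6))
  pol <- lig$polar[np$i] & rec$polar[np$j]
  if (any(pol)) {
    rp <- r[pol]
    g <- ifelse(rp < params$r_hb, 1,
                ifelse(rp >= params$r_hb_off, 0,
                       0.5 * (1 + cos(pi * (rp - params$r_hb) /
                                        (params$r_hb_off - params$r_hb)))))
    strength <- rec$polar_strength[np$j[pol]]
    strength[is.na(strength)] <- params$polar_strength
    e <- e - sum(strength * g)
  }
  e
}

#' Receptor--ligand interaction energy
#'
#' Sum over receptor--ligand pairs within the cutoff of a 12-6 Lennard-Jones
#' term, `4 eps ((sigma/r)^12 - (sigma/r)^6)`, minus a switched polar well
#' for flagged donor-acceptor pairs (full below `r_hb`, cosine-switched to
#' zero at `r_hb_off`). Returns 0 when no pair is in range.
#'
#' @inheritParams clash_count
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(structure, ligand, pose = NULL,
                               params = energy_params(), method = "auto") {
  pair_energy(ligand_scene(ligand, pose), receptor_scene(structure),
              params, method)
}

# ---- gate torsions ----------------------------------------------------------

#' Set the hinge torsions of the gate side chains
#'
#' Gate residues (built by [make_toy_pocket]) are short arms with a single
#' hinge: beads after the anchor rotate about the hinge axis through the
#' anchor bead. Angles are absolute (degrees, relative to the reference
#' geometry stored at build time).
#'
#' @param structure a `Structure` carrying gate definitions (`$gates`).
#' @param angles_deg numeric vector, one angle per gate residue.
#' @return the structure with updated gate-bead coordinates and
#'   `$gate_angles` recorded.
#' @export
set_gate_torsions <- function(structure, angles_deg) {
  g <- structure$gates
  if (is.null(g)) stop("structure carries no gate definitions")
  stopifnot(length(angles_deg) == length(g))
  xyz <- coords(structure)
  for (k in seq_along(g)) {
    gk <- g[[k]]
    R <- quat_to_matrix(axis_angle_quat(gk$axis, angles_deg[k]))
    ref <- gk$ref_moving  # reference coords of the moving beads
    anchor <- gk$anchor_xyz
    xyz[gk$moving_idx, ] <- sweep(sweep(ref, 2, anchor) %*% t(R), 2, anchor, `+`)
  }
  structure <- set_coords(structure, xyz)
  structure$gate_angles <- wrap_angle(angles_deg)
  structure
}

# ---- local minimisation -----------------------------------------------------

#' Steepest-descent minimisation of a ligand pose
#'
#' Minimises the receptor--ligand interaction energy over the stated degrees
#' of freedom: rigid-body translation and rotation of the ligand, and
#' optionally the gate hinge torsions of the receptor. Gradients are numeric
#' central differences (1e-4 A for translations, 1e-3 degrees for angles);
#' the tiny DOF count makes analytic torsion gradients unnecessary. Steps
#' use backtracking line search, so the returned energy never exceeds the
#' starting energy.
#'
#' @param structure receptor `Structure`.
#' @param ligand `RingLigand`.
#' @param pose starting `Pose`.
#' @param params `EnergyParams`.
#' @param include_gates also relax gate torsions (requires gate definitions).
#' @param max_steps,step_size,grad_tol descent controls: iteration cap,
#'   initial step (A / deg), and the gradient-norm stopping threshold.
#' @return list with `pose`, `gate_angles`, `energy`, `iterations`,
#'   `converged`.
#' @export
minimize_pose <- function(structure, ligand, pose, params = energy_params(),
                          include_gates = FALSE, max_steps = 200,
                          step_size = 0.1, grad_tol = 1e-3) {
  n_gate <- if (include_gates) length(structure$gates) else 0
  gate0 <- if (n_gate > 0) {
    if (is.null(structure$gate_angles)) rep(0, n_gate) else structure$gate_angles
  } else numeric(0)
  # DOF vector: 3 translation (A), 3 rotation (deg, axis-angle increments),
  # then gate angles (deg)
  ref <- ligand_scene(ligand)$xyz
  energy_at <- function(x) {
    q <- pose$rotation
    rot <- x[4:6]
    ang <- sqrt(sum(rot^2))
    if (ang > 1e-12) q <- quat_multiply(axis_angle_quat(rot, ang), q)
    p <- new_pose(q, x[1:3], pose$torsions)
    s <- structure
    if (n_gate > 0) s <- set_gate_torsions(s, x[7:(6 + n_gate)])
    interaction_energy(s, ligand, p, params)
  }
  x <- c(pose$translation, 0, 0, 0, gate0)
  h <- c(rep(1e-4, 3), rep(1e-3, 3), rep(1e-3, n_gate))
  e <- energy_at(x)
  if (!is.finite(e)) stop("non-finite energy at start of minimisation")
  step <- step_size
  converged <- FALSE
  it <- 0
  while (it < max_steps) {
    it <- it + 1
    g <- vapply(seq_along(x), function(k) {
      xp <- x; xm <- x
      xp[k] <- x[k] + h[k]; xm[k] <- x[k] - h[k]
      (energy_at(xp) - energy_at(xm)) / (2 * h[k])
    }, numeric(1))
    if (any(!is.finite(g)))
      stop("non-finite gradient at iteration ", it,
           " (energy ", signif(e, 6), ")")
    gn <- sqrt(sum(g^2))
    if (gn < grad_tol) { converged <- TRUE; break }
    dir <- -g / gn
    # backtracking
    ok <- FALSE
    s <- step
    for (bt in 1:20) {
      xn <- x + s * dir
      en <- energy_at(xn)
      if (is.finite(en) && en < e) { ok <- TRUE; break }
      s <- s / 2
    }
    if (!ok) { converged <- gn < 10 * grad_tol; break }
    x <- xn; e <- en
    step <- min(step_size, s * 2)  # expand again after successful steps
  }
  q <- pose$rotation
  rot <- x[4:6]; ang <- sqrt(sum(rot^2))
  if (ang > 1e-12) q <- quat_multiply(axis_angle_quat(rot, ang), q)
  list(pose = new_pose(q, x[1:3], pose$torsions),
       gate_angles = if (n_gate > 0) wrap_angle(x[7:(6 + n_gate)]) else numeric(0),
       energy = e, iterations = it, converged = converged)
}
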