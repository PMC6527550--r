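# Synthetic study systems: a toy deep-pocket receptor with a -1 binding
# well, a three-residue toll-like barrier, a lateral cavity station and a
# solvent gate; ideal ring-bead ligands in named puckering conformers; and
# the kinetic / SPR datasets used by the affinity fitting stages. All
# generators are pure functions of (parameters, seed).

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of their seed without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# fold a global seed and a stage counter into a fresh 31-bit seed
fold_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

# ---- ring ligands -----------------------------------------------------------

#' Construct a RingLigand from a bead table
#'
#' @param beads data.frame with columns `element`, `name`, `x`, `y`, `z`
#'   and optionally `radius`, `polar`.
#' @param conformer_label label recorded on the ligand.
#' @param ring_idx indices of the six ring beads (ordered O5, C1..C5).
#' @param marker_idx index of the C4-hydroxyl marker bead used by the
#'   migration termination criterion (NA if absent).
#' @return object of class `RingLigand`.
#' @export
new_ring_ligand <- function(beads, conformer_label = NA_character_,
                            ring_idx = seq_len(min(6, nrow(beads))),
                            marker_idx = NA_integer_) {
  stopifnot(is.data.frame(beads), nrow(beads) >= 1)
  if (is.null(beads$radius)) beads$radius <- vdw_radius_for(beads$element)
  if (is.null(beads$polar)) beads$polar <- FALSE
  if (length(ring_idx) == 6) {
    xyz <- as.matrix(beads[ring_idx, c("x", "y", "z")])
    d <- sqrt(rowSums((xyz - xyz[c(2:6, 1), ])^2))
    if (any(d < 1.3 | d > 1.7))
      stop("consecutive ring-bead distances must lie in [1.3, 1.7] A")
  }
  rownames(beads) <- NULL
  structure(list(beads = beads, conformer_label = conformer_label,
                 ring_idx = ring_idx, marker_idx = marker_idx),
            class = "RingLigand")
}

#' @export
print.RingLigand <- function(x, ...) {
  cat("RingLigand:", nrow(x$beads), "beads, conformer",
      x$conformer_label, "\n")
  invisible(x)
}

#' Ring-bead coordinates of a ligand under a pose
#' @param ligand a `RingLigand`.
#' @param pose optional `Pose`.
#' @return 6 x 3 matrix of ring-bead positions.
#' @export
ring_coords <- function(ligand, pose = NULL) {
  xyz <- ligand_scene(ligand, pose)$xyz
  xyz[ligand$ring_idx, , drop = FALSE]
}

#' Build an ideal six-bead ring ligand in a named conformer
#'
#' Ring beads ordered O5, C1..C5 on a hexagon of radius 1.45 A with the
#' out-of-plane pattern of the requested canonical conformer, amplitude
#' Q = 0.55 A (Q = 0 for `"planar"`). Two exocyclic beads are attached: a
#' C6 analogue on C5 and the designated C4-hydroxyl marker bead on C4
#' (both pointing out of the ring plane so the ligand stays compact
#' laterally). O5 and the marker are flagged polar.
#'
#' @param conformer_label one of `"4C1"`, `"1C4"`, `"1S3"`, `"B3O"`,
#'   `"planar"` (any of the 38 canonical labels is also accepted).
#' @param q_amp puckering amplitude, A.
#' @return a `RingLigand`.
#' @export
make_ring_ligand <- function(conformer_label = "4C1", q_amp = 0.55) {
  pats <- conformer_patterns()
  if (conformer_label == "planar") {
    zpat <- rep(0, 6)
  } else if (conformer_label %in% names(pats)) {
    zpat <- pats[[conformer_label]]
  } else {
    stop("unknown conformer label: ", conformer_label,
         " (supported: planar, ", paste(utils::head(names(pats), 4),
                                        collapse = ", "), ", ...)")
  }
  ring <- ideal_ring(zpat, q_amp = q_amp)
  nm <- c("O5", "C1", "C2", "C3", "C4", "C5")
  el <- c("O", rep("C", 5))
  # exocyclic beads: 35% outward in the ring plane, the rest axial
  exo_at <- function(k, len) {
    out <- ring[k, ] - c(0, 0, ring[k, 3])
    out <- out / sqrt(sum(out^2))
    ring[k, ] + len * (0.35 * out + c(0, 0, 0.937))
  }
  c6 <- exo_at(6, 1.5)    # on C5
  o4m <- exo_at(5, 1.4)   # marker on C4
  beads <- data.frame(
    element = c(el, "C", "O"),
    name = c(nm, "C6", "O4M"),
    x = c(ring[, 1], c6[1], o4m[1]),
    y = c(ring[, 2], c6[2], o4m[2]),
    z = c(ring[, 3], c6[3], o4m[3]),
    polar = c(TRUE, rep(FALSE, 5), FALSE, TRUE),
    stringsAsFactors = FALSE)
  new_ring_ligand(beads, conformer_label, ring_idx = 1:6, marker_idx = 8L)
}

# ---- toy pocket -------------------------------------------------------------

#' Specification of a synthetic deep-pocket system
#'
#' Geometry of the toy receptor: a cylindrical pocket of radius
#' `pocket_radius`, closed at the bottom, `pocket_depth` deep from the -1
#' binding position to the solvent mouth. An exit channel of length
#' `channel_length` leads to the mouth; at its base, `n_gate_residues`
#' three-bead side-chain arms reach inward to tip radius `channel_radius`,
#' forming the toll-like barrier (the effective aperture is smaller than
#' the ligand, so the closed barrier is impassable). Each gate has one
#' hinge torsion; `gate_opening` is the radial tip retraction available to
#' a mobile gate. A polar lateral-cavity station of well depth
#' `cavity_well_depth` sits between barrier and mouth, and a two-bead
#' solvent-gate pair marks the mouth rim.
#'
#' @param pocket_depth A, -1 centre to mouth (default 13).
#' @param pocket_radius wall radius, A (default 5).
#' @param channel_length barrier-to-mouth distance, A (default 7).
#' @param channel_radius closed-barrier tip radius, A (default 1.2); must be
#'   smaller than the ligand's circumscribed radius.
#' @param n_gate_residues number of barrier arms (default 3).
#' @param gate_opening radial retraction available to mobile gates, A
#'   (default 3.5).
#' @param wall_bead_spacing wall lattice spacing, A (default 1.2).
#' @param cavity_well_depth lateral-cavity polar well depth, kcal/mol
#'   (default 2.5).
#' @param minus1_well_depth -1 site polar well depth, kcal/mol (default 3).
#' @param seed integer seed for the wall jitter.
#' @return object of class `ToyPocketSpec`.
#' @export
toy_pocket_spec <- function(pocket_depth = 13, pocket_radius = 5,
                            channel_length = 7, channel_radius = 1.2,
                            n_gate_residues = 3, gate_opening = 3.5,
                            wall_bead_spacing = 1.2,
                            cavity_well_depth = 2.5,
                            minus1_well_depth = 3,
                            seed = 1L) {
  stopifnot(pocket_depth > 0, pocket_radius > 0, channel_length > 0,
            channel_length < pocket_depth, channel_radius > 0,
            n_gate_residues >= 1, gate_opening > 0, wall_bead_spacing > 0,
            cavity_well_depth >= 0, minus1_well_depth >= 0)
  structure(as.list(environment()), class = "ToyPocketSpec")
}

# gate tip radial position as a function of hinge angle chi (deg);
# anchor at radius ra, arm length L pointing inward
gate_tip_radius <- function(chi_deg, ra, L) {
  sqrt(ra^2 + L^2 - 2 * ra * L * cos(chi_deg * pi / 180))
}

# hinge angle achieving a given radial tip retraction
gate_open_angle <- function(retraction, ra, L) {
  target <- (ra - L) + retraction
  f <- function(chi) gate_tip_radius(chi, ra, L) - target
  if (f(180) < 0) return(180)
  stats::uniroot(f, c(0, 180))$root
}

# orientation that stands the ring plane vertically (normal along +x),
# with ring beads confined near the y-z plane
corridor_quat <- function() axis_angle_quat(c(0, 1, 0), 90)

#' Build a certified toy pocket system
#'
#' Constructs the receptor, places the ligand clash-free at the -1 site,
#' and certifies the three defining properties by exhaustive pose-grid
#' scans: (i) the -1 placement is clash-free; (ii) with gates at their
#' reference positions, every pose crossing the barrier slab clashes (no
#' rigid exit); (iii) with gates displaced by `gate_opening` (and with
#' gates deleted) a clash-free corridor of 0.5 A waypoints runs from the
#' -1 site past the mouth. Construction fails if any certificate fails.
#'
#' Polar well depths are calibrated by construction: the site-bead
#' strengths are scaled so that the polar energy of the ligand posed at the
#' -1 centre (resp. the cavity station) equals minus the requested depth.
#'
#' @param spec a `ToyPocketSpec`.
#' @param params `EnergyParams` used for the certificates.
#' @param certify `"full"`, `"fast"` (coarser grid), or `"none"`.
#' @return object of class `ToyPocket`: list with `structure`, `ligand`,
#'   `annotations` (named sites and ids), `spec`, `params`.
#' @export
make_toy_pocket <- function(spec = toy_pocket_spec(),
                            params = energy_params(), certify = "full") {
  sp <- spec
  lig <- make_ring_ligand("4C1")
  lig_circ <- max(sqrt(rowSums(ring_coords(lig)[, 1:2]^2)))
  if (sp$channel_radius >= lig_circ)
    stop("channel_radius must be below the ligand circumscribed radius (",
         signif(lig_circ, 3), " A) for a closed barrier")
  z_bottom <- -0.8 * sp$pocket_radius
  z_mouth <- sp$pocket_depth
  z_gate <- sp$pocket_depth - sp$channel_length
  jit <- function(n) stats::rnorm(n, 0, 0.08)

  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  bead_row <- function(x, y, z, res_name, element = "C", radius = 1.70,
                       polar = FALSE, strength = NA_real_) {
    data.frame(element = element, name = "B", res_name = res_name,
               x = x, y = y, z = z, radius = radius, polar = polar,
               polar_strength = strength, stringsAsFactors = FALSE)
  }
  with_seed(sp$seed, {
    # bottom cap: disc of beads
    for (r in seq(0, sp$pocket_radius, by = sp$wall_bead_spacing)) {
      nb <- max(1, round(2 * pi * r / sp$wall_bead_spacing))
      az <- 2 * pi * seq_len(nb) / nb
      add(bead_row(r * cos(az) + jit(nb), r * sin(az) + jit(nb),
                   z_bottom + jit(nb), "BOT"))
    }
    # cylinder wall: staggered rings aligned so one ring sits exactly in
    # the gate plane (its springs to the barrier cluster node are then
    # horizontal, keeping the collective gate flap the softest mode)
    ks <- seq(ceiling((z_bottom + 0.6 * sp$wall_bead_spacing - z_gate) /
                        sp$wall_bead_spacing),
              floor((z_mouth - z_gate) / sp$wall_bead_spacing))
    zs <- z_gate + sp$wall_bead_spacing * ks
    for (k in seq_along(zs)) {
      nb <- max(8, round(2 * pi * sp$pocket_radius / sp$wall_bead_spacing))
      az <- 2 * pi * (seq_len(nb) + 0.5 * (k %% 2)) / nb
      near_gate <- abs(zs[k] - z_gate) < 1.1 * sp$wall_bead_spacing
      jx <- if (near_gate) rep(0, nb) else jit(nb)
      jy <- if (near_gate) rep(0, nb) else jit(nb)
      jz <- if (abs(zs[k] - z_gate) < 1e-9) {
        # smooth second-harmonic ripple: gives the collective barrier flap
        # a small but strictly positive stiffness (a first-harmonic ripple
        # would be cancelled exactly by a rigid translation) while keeping
        # the ring's elastic response smooth
        0.05 * sin(2 * az)
      } else if (near_gate) rep(0, nb) else jit(nb)
      add(bead_row(sp$pocket_radius * cos(az) + jx,
                   sp$pocket_radius * sin(az) + jy,
                   zs[k] + jz, "WAL"))
    }
    # plinth: an outer collar around the lower pocket plus a ground
    # apron. The pocket walls of a real enzyme are the interior of a
    # globular protein, not a free-standing tube; the plinth stiffens the
    # tube's cantilever sway so that the softest non-rigid motion is the
    # collective flap of the barrier side chains.
    r_col <- sp$pocket_radius + 1.4
    for (z in seq(z_bottom + sp$wall_bead_spacing, z_gate + 2,
                  by = sp$wall_bead_spacing)) {
      nb <- round(2 * pi * r_col / sp$wall_bead_spacing)
      az <- 2 * pi * seq_len(nb) / nb
      add(bead_row(r_col * cos(az) + jit(nb), r_col * sin(az) + jit(nb),
                   z + jit(nb), "PLN"))
    }
    for (r in c(r_col, r_col + sp$wall_bead_spacing)) {
      nb <- round(2 * pi * r / sp$wall_bead_spacing)
      az <- 2 * pi * seq_len(nb) / nb
      add(bead_row(r * cos(az) + jit(nb), r * sin(az) + jit(nb),
                   z_bottom + jit(nb), "PLN"))
    }
  })
  # -1 site beads (polar, inward-protruding; strengths calibrated below)
  site_az <- c(90, 210, 330) * pi / 180
  add(bead_row(4.0 * cos(site_az), 4.0 * sin(site_az), rep(0, 3),
               "SIT", element = "O", radius = 1.52, polar = TRUE,
               strength = 1))
  # lateral cavity station: polar beads on the far side of the channel,
  # midway between barrier and mouth -- outside the elastic-network
  # cutoff of the barrier cluster node (so the station does not stiffen
  # the gate flap) and out of polar range of the solvent-gate pair
  z_cav <- z_gate + 0.5 * sp$channel_length
  cav_az <- c(160, 180, 200, 170, 190) * pi / 180
  cav_z <- z_cav + c(-0.35, -0.35, -0.35, 0.35, 0.35)
  add(bead_row(4.1 * cos(cav_az), 4.1 * sin(cav_az), cav_z,
               "CAV", element = "O", radius = 1.52, polar = TRUE,
               strength = 1))
  # solvent-gate pair at the mouth rim
  add(bead_row(4.2 * cos(c(90, 270) * pi / 180),
               4.2 * sin(c(90, 270) * pi / 180), rep(z_mouth, 2),
               "SOL", element = "O", radius = 1.52, polar = TRUE,
               strength = 0.5))
  fixed <- do.call(rbind, rows)
  fixed$res_index <- seq_len(nrow(fixed))
  fixed$chain <- "R"
  fixed$occupancy <- 1
  # toll-barrier gate arms: anchor -> mid -> tip, reaching inward at z_gate
  arm_ra <- sp$pocket_radius - 0.8
  arm_L <- arm_ra - sp$channel_radius
  gate_az <- 2 * pi * (seq_len(sp$n_gate_residues) - 1) / sp$n_gate_residues
  gate_rows <- list()
  gate_defs <- list()
  next_res <- nrow(fixed)
  n_fixed <- nrow(fixed)
  for (g in seq_along(gate_az)) {
    u <- c(cos(gate_az[g]), sin(gate_az[g]), 0)
    anchor <- arm_ra * u
    mid <- (arm_ra - arm_L / 2) * u
    tip <- sp$channel_radius * u
    next_res <- next_res + 1L
    df <- data.frame(
      element = "C", name = c("GA", "GB", "GC"), res_name = "GAT",
      x = c(anchor[1], mid[1], tip[1]), y = c(anchor[2], mid[2], tip[2]),
      z = z_gate + c(0, 0, 0), radius = 1.9, polar = FALSE,
      polar_strength = NA_real_, res_index = next_res, chain = "R",
      occupancy = 1, stringsAsFactors = FALSE)
    gate_rows[[g]] <- df
  }
  atoms <- rbind(fixed, do.call(rbind, gate_rows))
  atoms <- atoms[, c("element", "name", "res_index", "res_name", "chain",
                     "x", "y", "z", "occupancy", "radius", "polar",
                     "polar_strength")]
  gate_res_ids <- unique(atoms$res_index[atoms$res_name == "GAT"])
  backbone <- atoms$res_name != "GAT"
  stru <- new_structure(atoms, flexible_residues = gate_res_ids,
                        backbone_mask = backbone)
  # gate hinge definitions: vertical axis through the anchor bead
  gates <- list()
  for (g in seq_along(gate_res_ids)) {
    idx <- which(stru$atoms$res_index == gate_res_ids[g])
    gates[[g]] <- list(
      res_index = gate_res_ids[g],
      anchor_idx = idx[1], moving_idx = idx[2:3],
      anchor_xyz = as.numeric(coords(stru)[idx[1], ]),
      axis = c(0, 0, 1),
      ref_moving = coords(stru)[idx[2:3], , drop = FALSE])
  }
  stru$gates <- gates
  stru$gate_angles <- rep(0, length(gates))
  chi_open <- gate_open_angle(sp$gate_opening, arm_ra, arm_L)

  ann <- list(
    minus1_center = c(0, 0, 0),
    cavity_center = c(-1.3, 0, z_cav),
    exit_point = c(0, 0, z_mouth),
    barrier_z = z_gate,
    gate_residue_ids = gate_res_ids,
    solvent_gate_ids = which(stru$atoms$res_name == "SOL"),
    chi_open = chi_open,
    corridor_rotation = corridor_quat(),
    start_pose = new_pose())

  # calibrate polar strengths so the stated well depths hold by
  # construction; each site group is calibrated in isolation (other polar
  # groups zeroed) so cross-talk cannot skew the scale
  polar_energy_with <- function(stru2, pose, only = NULL) {
    p2 <- params; p2$epsilon <- 1e-12  # isolate the polar term
    if (!is.null(only)) {
      zero <- stru2$atoms$res_name != only
      stru2$atoms$polar_strength[zero] <- 0
    }
    interaction_energy(stru2, lig, pose, p2)
  }
  # scale a group so the TOTAL polar energy at its reference pose equals
  # minus the requested depth (cross-terms from the other polar groups
  # are measured and compensated exactly)
  calibrate <- function(stru, group, pose, depth) {
    sel <- stru$atoms$res_name == group
    if (depth <= 0) {
      stru$atoms$polar_strength[sel] <- 0
      return(stru)
    }
    e_own <- polar_energy_with(stru, pose, only = group)
    if (e_own > -1e-9)
      stop("construction error: ", group, " beads out of polar range")
    others <- stru
    others$atoms$polar_strength[sel] <- 0
    e_cross <- polar_energy_with(others, pose)
    s <- (-depth - e_cross) / e_own
    if (s <= 0)
      stop("construction error: cross-terms exceed the requested ",
           group, " depth")
    stru$atoms$polar_strength[sel] <- s * stru$atoms$polar_strength[sel]
    stru
  }
  stru <- calibrate(stru, "SIT", ann$start_pose, sp$minus1_well_depth)
  cav_pose <- new_pose(ann$corridor_rotation, ann$cavity_center)
  stru <- calibrate(stru, "CAV", cav_pose, sp$cavity_well_depth)

  pocket <- structure(list(structure = stru, ligand = lig,
                           annotations = ann, spec = sp, params = params),
                      class = "ToyPocket")
  if (certify != "none") certify_pocket(pocket, level = certify)
  pocket
}

#' @export
print.ToyPocket <- function(x, ...) {
  cat("ToyPocket:", nrow(x$structure$atoms), "receptor beads,",
      length(x$annotations$gate_residue_ids), "gate arm(s), depth",
      x$spec$pocket_depth, "A\n")
  invisible(x)
}

# pose grids used by the certificates and by the exhaustive scans of the
# path-search tests
scan_orientations <- function(step_deg = 30) {
  qs <- list(c(1, 0, 0, 0))
  for (az in seq(0, 180 - step_deg, by = step_deg)) {
    ax <- c(cos(az * pi / 180), sin(az * pi / 180), 0)
    for (tilt in seq(step_deg, 90, by = step_deg)) {
      for (spin in c(0, 60)) {
        q <- quat_multiply(axis_angle_quat(ax, tilt),
                           axis_angle_quat(c(0, 0, 1), spin))
        qs[[length(qs) + 1L]] <- q
      }
    }
  }
  qs
}

# minimum clash count over a pose grid (orientations x lateral offsets x z)
min_clash_over_grid <- function(pocket, z_levels, offsets, orientations,
                                structure = pocket$structure) {
  lig <- pocket$ligand
  params <- pocket$params
  ref <- ligand_scene(lig)$xyz
  ctr <- colMeans(ref)
  rxyz <- coords(structure)
  rrad <- structure$atoms$radius
  # restrict receptor to the scanned z-range for speed
  zr <- range(z_levels) + c(-6, 6)
  keep <- rxyz[, 3] >= zr[1] & rxyz[, 3] <= zr[2]
  rxyz <- rxyz[keep, , drop = FALSE]; rrad <- rrad[keep]
  lrad <- lig$beads$radius
  thr2 <- (params$overlap_factor * outer(lrad, rrad, `+`))^2
  trans <- as.matrix(expand.grid(x = offsets$x, y = offsets$y, z = z_levels))
  blocks <- do.call(rbind, lapply(orientations, function(q)
    sweep(ref, 2, ctr) %*% t(quat_to_matrix(q))))
  cpp_min_clash_grid(blocks, nrow(ref), trans, rxyz, thr2)
}

# clash-free corridor certificate: at every 0.5 A z-waypoint from the -1
# site to past the mouth there is a clash-free pose (fixed vertical-ring
# orientation, centred on the axis)
corridor_clash_counts <- function(pocket, structure = pocket$structure,
                                  dz = 0.5) {
  ann <- pocket$annotations
  zs <- seq(0, pocket$spec$pocket_depth + 2.5, by = dz)
  vapply(zs, function(z) {
    pose <- new_pose(ann$corridor_rotation, c(0, 0, z))
    clash_count(structure, pocket$ligand, pose, pocket$params)
  }, numeric(1))
}

#' Certify the defining properties of a toy pocket
#'
#' Runs the three build-time certificates (clash-free -1 placement, blocked
#' rigid barrier, open corridor under gate displacement / gate removal) and
#' fails with a construction error if any does not hold.
#'
#' @param pocket a `ToyPocket`.
#' @param level `"full"` or `"fast"` (coarser scan grid).
#' @return `TRUE` invisibly.
#' @export
certify_pocket <- function(pocket, level = "full") {
  ann <- pocket$annotations
  sp <- pocket$spec
  if (clash_count(pocket$structure, pocket$ligand, ann$start_pose,
                  pocket$params) != 0)
    stop("construction error: no clash-free -1 placement")
  # blocked barrier: every pose in the barrier slab clashes
  step_xy <- if (level == "full") 0.5 else 0.6
  step_deg <- if (level == "full") 30 else 45
  zstep <- if (level == "full") 0.25 else 0.5
  rmax <- sp$pocket_radius - 1.7
  g <- seq(-rmax, rmax, by = step_xy)
  offsets <- list(x = g, y = g)
  z_levels <- ann$barrier_z + seq(-1.25, 1.25, by = zstep)
  mc <- min_clash_over_grid(pocket, z_levels, offsets,
                            scan_orientations(step_deg))
  if (mc < 1)
    stop("construction error: rigid barrier is not closed ",
         "(clash-free pose found in the barrier slab)")
  # open corridor with gates displaced by gate_opening
  open_stru <- set_gate_torsions(pocket$structure,
                                 rep(ann$chi_open,
                                     length(ann$gate_residue_ids)))
  cc_open <- corridor_clash_counts(pocket, open_stru)
  if (any(cc_open > 0))
    stop("construction error: corridor blocked with gates displaced by ",
         sp$gate_opening, " A")
  # open corridor with gates removed entirely
  no_gate <- pocket$structure
  keep <- no_gate$atoms$res_name != "GAT"
  no_gate <- new_structure(no_gate$atoms[keep, , drop = FALSE],
                           backbone_mask = no_gate$backbone_mask[keep])
  cc_rm <- corridor_clash_counts(pocket, no_gate)
  if (any(cc_rm > 0))
    stop("construction error: corridor blocked even without gates")
  invisible(TRUE)
}

#' Remove the gate arms from a pocket's receptor
#'
#' @param pocket a `ToyPocket`.
#' @return the receptor `Structure` without the gate residues.
#' @export
pocket_without_gates <- function(pocket) {
  s <- pocket$structure
  keep <- s$atoms$res_name != "GAT"
  new_structure(s$atoms[keep, , drop = FALSE],
                backbone_mask = s$backbone_mask[keep])
}

#' Write a toy pocket (receptor + ligand) as a two-chain PDB file
#'
#' @param pocket a `ToyPocket`.
#' @param path output path.
#' @param pose optional ligand `Pose` (default: reference -1 placement).
#' @return `path`, invisibly.
#' @export
write_toy_pocket <- function(pocket, path, pose = NULL) {
  s <- pocket$structure
  lx <- ligand_scene(pocket$ligand, pose)$xyz
  lb <- pocket$ligand$beads
  lig_atoms <- data.frame(
    element = lb$element, name = lb$name,
    res_index = max(s$atoms$res_index) + 1L, res_name = "LIG", chain = "L",
    x = lx[, 1], y = lx[, 2], z = lx[, 3], occupancy = 1,
    radius = lb$radius, polar = lb$polar, polar_strength = NA_real_,
    stringsAsFactors = FALSE)
  all_atoms <- rbind(s$atoms, lig_atoms)
  write_pdb(new_structure(all_atoms), path)
}

# ---- kinetic and SPR datasets ----------------------------------------------

#' Simulate a competitive-inhibition rate dataset
#'
#' Rates follow the competitive model with multiplicative Gaussian noise,
#' `v = model * (1 + N(0, noise_cv))` -- rate errors scale with signal. The
#' default design mirrors the inhibition assays: six substrate
#' concentrations spanning 0.8-6.6 mM crossed with six inhibitor
#' concentrations spanning 0.4-3 x Ki, each combination in duplicate.
#'
#' @param Vmax,KM,Ki true parameters (`KM`, `Ki` in mM).
#' @param S_grid substrate grid, mM (default 6 points, 0.8-6.6).
#' @param I_grid inhibitor grid, mM (default 6 points, 0.4-3 x Ki).
#' @param replicates replicates per combination (default 2).
#' @param noise_cv coefficient of variation of the noise (default 0.05).
#' @param seed integer seed.
#' @return data.frame with columns `S`, `I`, `v`, `replicate`.
#' @export
make_kinetic_dataset <- function(Vmax = 1, KM = 2, Ki = 2.55,
                                 S_grid = NULL, I_grid = NULL,
                                 replicates = 2, noise_cv = 0.05,
                                 seed = 1L) {
  stopifnot(Vmax > 0, KM > 0, Ki > 0, noise_cv >= 0, replicates >= 1)
  if (is.null(S_grid)) S_grid <- seq(0.8, 6.6, length.out = 6)
  if (is.null(I_grid)) I_grid <- seq(0.4, 3, length.out = 6) * Ki
  if (any(S_grid <= 0) || any(I_grid < 0))
    stop("concentration grids must be positive (I may include 0)")
  des <- expand.grid(S = S_grid, I = I_grid,
                     replicate = seq_len(replicates))
  mu <- competitive_rate(des$S, des$I, Vmax, KM, Ki)
  des$v <- with_seed(seed, mu * (1 + stats::rnorm(nrow(des), 0, noise_cv)))
  des$v <- pmax(des$v, 1e-12)
  des
}

#' Simulate a steady-state SPR dilution series
#'
#' Equilibrium responses `Req = Rmax C / (KD + C)` over a geometric
#' concentration series from 0.1 x KD to 10 x KD, with multiplicative
#' Gaussian noise and one concentration (the middle of the series) injected
#' in duplicate.
#'
#' @param KD true dissociation constant, M.
#' @param Rmax saturating response, response units (default 100).
#' @param n_conc number of distinct concentrations (>= 4; default 8).
#' @param noise_cv coefficient of variation (default 0.02).
#' @param seed integer seed.
#' @return data.frame with columns `C` (M) and `Req`.
#' @export
make_spr_dataset <- function(KD, Rmax = 100, n_conc = 8, noise_cv = 0.02,
                             seed = 1L) {
  stopifnot(KD > 0, Rmax > 0, noise_cv >= 0)
  if (n_conc < 4) stop("n_conc < 4: the 1:1 fit would be under-determined")
  C <- KD * 10^seq(-1, 1, length.out = n_conc)
  C <- c(C, C[ceiling(n_conc / 2)])  # duplicate one concentration
  mu <- Rmax * C / (KD + C)
  Req <- with_seed(seed, mu * (1 + stats::rnorm(length(C), 0, noise_cv)))
  data.frame(C = C, Req = pmax(Req, 0))
}
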