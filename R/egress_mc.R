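# Metropolis Monte Carlo ligand migration: random rigid-body perturbations
# of the ligand, bounded backbone breathing along low normal modes, a
# best-of-k rotamer trial for the gate hinges, and Metropolis acceptance on
# the receptor-ligand interaction energy. Trajectories terminate once both
# the centre-of-mass and the C4-hydroxyl-marker separations from the start
# exceed the termination distance.

#' Monte Carlo migration configuration
#'
#' @param t_max maximum translation per step, A (default 1.0).
#' @param rot_max maximum rotation per step, deg (default 20).
#' @param kT Metropolis temperature parameter, kcal/mol (default 1.7,
#'   chosen so that barrier crossings are sampled while the sealed-gate
#'   control stays sealed).
#' @param mode_amp_max bound on the backbone breathing amplitude, A
#'   (max-node convention; default 0.5). Zero disables mode moves.
#' @param n_low_modes modes the breathing move draws from (default 6).
#' @param minimize run a short rigid-body minimisation on each proposal
#'   (default FALSE; the gate rotamer trial already relaxes the receptor
#'   side).
#' @param gate_k rotamer candidates per gate and step (default 5).
#' @param gate_limit hinge angle bound, deg (default 90).
#' @param max_steps step cap (default 40000). The emulated protocol runs
#'   until the termination distance is reached, so the cap is a
#'   first-passage compute budget rather than a physical parameter.
#' @param d_term termination distance, A (default 15).
#' @param seed integer seed.
#' @param snapshot_every keep every n-th accepted snapshot (default 5; the
#'   states table always records every step).
#' @return object of class `MCConfig`.
#' @export
mc_config <- function(t_max = 1.0, rot_max = 20, kT = 1.7,
                      mode_amp_max = 0.5, n_low_modes = 6,
                      minimize = FALSE, gate_k = 5, gate_limit = 90,
                      max_steps = 40000, d_term = 15, seed = 1L,
                      snapshot_every = 5) {
  stopifnot(t_max > 0, rot_max > 0, kT > 0, mode_amp_max >= 0,
            n_low_modes >= 1, gate_k >= 1, max_steps >= 1, d_term > 0)
  structure(as.list(environment()), class = "MCConfig")
}

#' Metropolis acceptance decision
#'
#' Accept when the energy does not increase, otherwise with probability
#' `exp(-dE/kT)`. Exposed separately so the chain's equilibrium behaviour
#' can be verified on analytic toy systems.
#'
#' @param dE energy change, kcal/mol.
#' @param kT temperature parameter, kcal/mol.
#' @return logical.
#' @export
metropolis_accept <- function(dE, kT) {
  if (!is.finite(dE)) return(FALSE)
  dE <= 0 || stats::runif(1) < exp(-dE / kT)
}

# precomputed evaluation context: receptor reference coordinates split
# into static atoms and the mobile gate beads, per-mode unit displacement
# fields (max-node amplitude 1), squared Lennard-Jones sigmas, and the
# (small) polar pair bookkeeping
mc_context <- function(structure, ligand, modes, config,
                       params = energy_params()) {
  rxyz <- coords(structure)
  n_modes <- if (config$mode_amp_max > 0 && !is.null(modes))
    min(config$n_low_modes, length(modes$eigenvalues)) else 0
  fields <- NULL
  if (n_modes > 0) {
    if (is.null(modes$nodes)) stop("ModeSet lacks node bookkeeping")
    fields <- lapply(seq_len(n_modes), function(m) {
      v <- matrix(modes$vectors[, m], ncol = 3, byrow = TRUE)
      v <- v / max(sqrt(rowSums(v^2)))       # max-node amplitude 1
      v[modes$nodes$atom2node, , drop = FALSE]
    })
  }
  lb <- ligand$beads
  lrad <- lb$radius
  gate_idx <- unlist(lapply(structure$gates, `[[`, "moving_idx"))
  sidx <- setdiff(seq_len(nrow(rxyz)), gate_idx)
  strength <- structure$atoms$polar_strength
  if (is.null(strength)) strength <- rep(NA_real_, nrow(rxyz))
  strength[is.na(strength)] <- params$polar_strength
  # squared pair sigmas (minimum at radius contact)
  sig2 <- function(idx) (outer(lrad, structure$atoms$radius[idx], `+`) *
                           2^(-1 / 6))^2
  gates <- lapply(seq_along(structure$gates), function(k) {
    gk <- structure$gates[[k]]
    v <- sweep(gk$ref_moving, 2, gk$anchor_xyz)
    u <- gk$axis / sqrt(sum(gk$axis^2))
    uxv <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                 u[3] * v[, 1] - u[1] * v[, 3],
                 u[1] * v[, 2] - u[2] * v[, 1])
    uuv <- outer(as.numeric(v %*% u), u)
    c(gk, list(sig2 = sig2(gk$moving_idx), ref_centered = v,
               rod_uxv = uxv, rod_uuv = uuv))
  })
  list(structure = structure, ligand = ligand, params = params,
       config = config,
       rs_ref = rxyz[sidx, , drop = FALSE], sidx = sidx,
       sig2_s = sig2(sidx),
       pol_l = which(lb$polar),
       pol_s = which(structure$atoms$polar[sidx]),
       strength_s = strength[sidx],
       fields_s = if (n_modes > 0)
         lapply(fields, function(f) f[sidx, , drop = FALSE]) else NULL,
       fields_g = if (n_modes > 0)
         lapply(fields, function(f) f[gate_idx, , drop = FALSE]) else NULL,
       lref = as.matrix(lb[, c("x", "y", "z")]),
       lrad = lrad, lpolar = lb$polar,
       n_modes = n_modes,
       n_gate = length(structure$gates), gate_idx = gate_idx,
       gates = gates)
}

# gate moving-bead coordinates for a hinge angle, via the precomputed
# Rodrigues terms (breathing displacement of the gate beads follows the
# cluster field)
mc_gate_xyz <- function(ctx, k, angle, mode_idx, mode_amp) {
  gk <- ctx$gates[[k]]
  th <- angle * pi / 180
  xyz <- (gk$ref_centered - gk$rod_uuv) * cos(th) +
    gk$rod_uxv * sin(th) + gk$rod_uuv
  xyz[, 1] <- xyz[, 1] + gk$anchor_xyz[1]
  xyz[, 2] <- xyz[, 2] + gk$anchor_xyz[2]
  xyz[, 3] <- xyz[, 3] + gk$anchor_xyz[3]
  if (ctx$n_modes > 0 && mode_idx > 0 && mode_amp != 0) {
    rows <- match(gk$moving_idx, ctx$gate_idx)
    xyz <- xyz + mode_amp * ctx$fields_g[[mode_idx]][rows, , drop = FALSE]
  }
  xyz
}

# Lennard-Jones (+ polar for the static wall) energy pieces, working in
# squared distances; the polar pairs are a small precomputed subset
mc_energy_static <- function(ctx, lxyz, mode_idx, mode_amp) {
  p <- ctx$params
  rx <- ctx$rs_ref
  if (ctx$n_modes > 0 && mode_idx > 0 && mode_amp != 0)
    rx <- rx + mode_amp * ctx$fields_s[[mode_idx]]
  e <- cpp_lj_energy(lxyz, rx, ctx$sig2_s, p$cutoff^2, 4 * p$epsilon)
  if (!is.finite(e)) return(Inf)
  if (length(ctx$pol_l) > 0 && length(ctx$pol_s) > 0) {
    lp <- lxyz[ctx$pol_l, , drop = FALSE]
    rp0 <- rx[ctx$pol_s, , drop = FALSE]
    d2 <- outer(rowSums(lp^2), rowSums(rp0^2), `+`) - 2 * tcrossprod(lp, rp0)
    rp <- sqrt(pmax(d2, 0))
    g <- ifelse(rp < p$r_hb, 1,
                ifelse(rp >= p$r_hb_off, 0,
                       0.5 * (1 + cos(pi * (rp - p$r_hb) /
                                        (p$r_hb_off - p$r_hb)))))
    e <- e - sum(sweep(g, 2, ctx$strength_s[ctx$pol_s], `*`))
  }
  e
}

mc_energy_gate <- function(ctx, k, lxyz, gxyz) {
  p <- ctx$params
  cpp_lj_energy(lxyz, gxyz, ctx$gates[[k]]$sig2, p$cutoff^2,
                4 * p$epsilon)
}

mc_state_energy <- function(ctx, state) {
  lxyz <- apply_pose(ctx$lref, state$pose)
  e <- mc_energy_static(ctx, lxyz, state$mode_idx, state$mode_amp)
  if (ctx$n_gate > 0) {
    for (k in seq_len(ctx$n_gate)) {
      gx <- mc_gate_xyz(ctx, k, state$gate_angles[k], state$mode_idx,
                        state$mode_amp)
      e <- e + mc_energy_gate(ctx, k, lxyz, gx)
    }
  }
  e
}

#' One Metropolis Monte Carlo migration step
#'
#' Proposal: ligand random translation (uniform in a ball of radius
#' `t_max`) and rotation (uniform axis, angle uniform up to `rot_max`);
#' backbone breathing redrawn along one of the `n_low_modes` lowest modes
#' with amplitude uniform in `[-mode_amp_max, mode_amp_max]` (absolute
#' displacement from the reference structure, so the breathing stays
#' bounded and the proposal symmetric); a best-of-`gate_k` rotamer trial
#' per mobile gate; optional short minimisation. Accepted iff the energy
#' change passes the Metropolis criterion; a rejected step returns the
#' prior state unchanged. Non-finite proposal energies auto-reject.
#'
#' @param ctx context from `mc_context` (internal; built by
#'   [run_migration]).
#' @param state list with `pose`, `gate_angles`, `mode_idx`, `mode_amp`,
#'   `energy`.
#' @return list `(state, accepted)`.
#' @export
mc_step <- function(ctx, state) {
  cfg <- ctx$config
  # ligand rigid-body proposal
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  tr <- state$pose$translation + u * cfg$t_max * stats::runif(1)^(1 / 3)
  ax <- stats::rnorm(3)
  q <- quat_multiply(axis_angle_quat(ax, stats::runif(1, 0, cfg$rot_max)),
                     state$pose$rotation)
  pose2 <- new_pose(q, tr, state$pose$torsions)
  # backbone breathing proposal
  mode_idx <- state$mode_idx; mode_amp <- state$mode_amp
  if (ctx$n_modes > 0) {
    mode_idx <- sample.int(ctx$n_modes, 1)
    mode_amp <- stats::runif(1, -cfg$mode_amp_max, cfg$mode_amp_max)
  }
  gate_angles <- state$gate_angles
  lxyz <- apply_pose(ctx$lref, pose2)
  gate_e <- numeric(ctx$n_gate)
  if (ctx$n_gate > 0) {
    mobile <- length(ctx$structure$flexible_residues) > 0
    cut2 <- ctx$params$cutoff^2
    eps4 <- 4 * ctx$params$epsilon
    for (k in seq_len(ctx$n_gate)) {
      # best-of-k rotamer trial per mobile gate, scored on the
      # ligand-gate energy alone; candidates evaluated in one batch
      cand <- if (mobile)
        c(gate_angles[k], stats::runif(cfg$gate_k - 1, -cfg$gate_limit,
                                       cfg$gate_limit))
      else gate_angles[k]
      gk <- ctx$gates[[k]]
      th <- cand * pi / 180
      escore <- numeric(length(cand))
      drows <- if (ctx$n_modes > 0 && mode_idx > 0 && mode_amp != 0)
        mode_amp * ctx$fields_g[[mode_idx]][match(gk$moving_idx,
                                                  ctx$gate_idx), ,
                                            drop = FALSE]
      else NULL
      for (ci in seq_along(cand)) {
        g <- (gk$ref_centered - gk$rod_uuv) * cos(th[ci]) +
          gk$rod_uxv * sin(th[ci]) + gk$rod_uuv
        g[, 1] <- g[, 1] + gk$anchor_xyz[1]
        g[, 2] <- g[, 2] + gk$anchor_xyz[2]
        g[, 3] <- g[, 3] + gk$anchor_xyz[3]
        if (!is.null(drows)) g <- g + drows
        escore[ci] <- cpp_lj_energy(lxyz, g, gk$sig2, cut2, eps4)
      }
      best <- which.min(escore)
      gate_angles[k] <- cand[best]
      gate_e[k] <- escore[best]
    }
  }
  state2 <- list(pose = pose2, gate_angles = gate_angles,
                 mode_idx = mode_idx, mode_amp = mode_amp)
  if (isTRUE(cfg$minimize)) {
    mn <- minimize_pose(ctx$structure, ctx$ligand, pose2, ctx$params,
                        max_steps = 15, grad_tol = 1e-2)
    state2$pose <- mn$pose
    lxyz <- apply_pose(ctx$lref, mn$pose)
    if (ctx$n_gate > 0)
      gate_e <- vapply(seq_len(ctx$n_gate), function(k)
        mc_energy_gate(ctx, k, lxyz,
                       mc_gate_xyz(ctx, k, gate_angles[k], mode_idx,
                                   mode_amp)), numeric(1))
  }
  e2 <- mc_energy_static(ctx, lxyz, mode_idx, mode_amp) + sum(gate_e)
  state2$energy <- e2
  if (metropolis_accept(e2 - state$energy, cfg$kT)) {
    list(state = state2, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

#' Run a Monte Carlo migration trajectory
#'
#' Iterates [mc_step] from the start pose until both the centre-of-mass
#' and the marker-bead separations from their initial positions exceed
#' `d_term`, or `max_steps` is reached. Deterministic for a fixed seed.
#'
#' @param structure receptor `Structure` (gates mobile iff listed in
#'   `flexible_residues`).
#' @param ligand `RingLigand` with a marker bead.
#' @param start_pose clash-free starting `Pose`.
#' @param modes `ModeSet` for the breathing moves (may be `NULL` when
#'   `mode_amp_max = 0`).
#' @param config an `MCConfig`.
#' @param params `EnergyParams`.
#' @return object of class `Trajectory`: `states` data.frame (step,
#'   energy, sep_com, sep_c4, accepted), `snapshots` (pose, gate angles and
#'   breathing state per accepted step), `acceptance_rate`,
#'   `terminated_reason` (`"distance"` or `"max_steps"`).
#' @export
run_migration <- function(structure, ligand, start_pose, modes = NULL,
                          config = mc_config(), params = energy_params()) {
  ctx <- mc_context(structure, ligand, modes, config, params)
  if (clash_count(structure, ligand, start_pose, params) > 0)
    stop("start pose is not clash-free")
  com0 <- colMeans(apply_pose(ctx$lref, start_pose))
  c40 <- apply_pose(ctx$lref, start_pose)[ligand$marker_idx, ]
  state <- list(pose = start_pose,
                gate_angles = rep(0, ctx$n_gate),
                mode_idx = 0L, mode_amp = 0)
  state$energy <- mc_state_energy(ctx, state)
  rows <- matrix(NA_real_, config$max_steps, 5)
  snaps <- list()
  n_acc <- 0L
  n_run <- 0L
  reason <- "max_steps"
  with_seed(config$seed, {
    for (step in seq_len(config$max_steps)) {
      out <- mc_step(ctx, state)
      state <- out$state
      lx <- apply_pose(ctx$lref, state$pose)
      sep_com <- separation(colMeans(lx), com0)
      sep_c4 <- separation(lx[ligand$marker_idx, ], c40)
      rows[step, ] <- c(step, state$energy, sep_com, sep_c4, out$accepted)
      n_run <- step
      if (out$accepted) {
        n_acc <- n_acc + 1L
        if (n_acc %% config$snapshot_every == 1L || config$snapshot_every == 1L)
          snaps[[length(snaps) + 1L]] <- list(step = step, pose = state$pose,
                                              gate_angles = state$gate_angles,
                                              mode_idx = state$mode_idx,
                                              mode_amp = state$mode_amp,
                                              energy = state$energy)
      }
      if (sep_com > config$d_term && sep_c4 > config$d_term) {
        reason <- "distance"
        break
      }
    }
  })
  tab <- as.data.frame(rows[seq_len(n_run), , drop = FALSE])
  names(tab) <- c("step", "energy", "sep_com", "sep_c4", "accepted")
  structure(list(states = tab, snapshots = snaps,
                 acceptance_rate = n_acc / nrow(tab),
                 terminated_reason = reason,
                 start = list(com = com0, c4 = c40)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d steps, acceptance %.2f, terminated by %s (max sep %.1f A)\n",
    nrow(x$states), x$acceptance_rate, x$terminated_reason,
    max(x$states$sep_com)))
  invisible(x)
}

#' Re-evaluate the stored energy of an accepted snapshot
#'
#' Bookkeeping check: reconstructs the scene of a stored snapshot and
#' recomputes its interaction energy.
#'
#' @param structure,ligand,modes,config,params as passed to
#'   [run_migration].
#' @param snapshot one element of a trajectory's `snapshots`.
#' @return energy in kcal/mol.
#' @export
reevaluate_snapshot <- function(structure, ligand, modes, config, params,
                                snapshot) {
  ctx <- mc_context(structure, ligand, modes, config, params)
  mc_state_energy(ctx, list(pose = snapshot$pose,
                            gate_angles = snapshot$gate_angles,
                            mode_idx = snapshot$mode_idx,
                            mode_amp = snapshot$mode_amp))
}

#' Binding-energy versus separation profile of migration trajectories
#'
#' Bins the accepted states of one or more trajectories into separation
#' bins and reports the mean energy and visit count per bin. Bins that are
#' local minima of the mean energy and whose visit count exceeds the
#' median count of their neighbourhood (window of two bins each side) are
#' flagged as dwell bins -- the signature of a metastable station such as a
#' lateral cavity between barrier and exit.
#'
#' @param trajectories a `Trajectory` or list of them.
#' @param bin_width bin width, A (default 0.5).
#' @param min_depth minimum depth (kcal/mol) below the neighbourhood for a
#'   bin to count as a dwell station (default 0.25; guards against flagging
#'   thermal noise on a flat profile).
#' @return data.frame: `sep_lo`, `sep_mid`, `mean_energy`, `count`,
#'   `dwell`.
#' @export
energy_distance_profile <- function(trajectories, bin_width = 0.5,
                                    min_depth = 0.25) {
  if (inherits(trajectories, "Trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0) stop("no trajectories given")
  st <- do.call(rbind, lapply(trajectories, function(t)
    t$states[t$states$accepted == 1, c("sep_com", "energy")]))
  if (nrow(st) == 0) stop("no accepted states to profile")
  b <- floor(st$sep_com / bin_width)
  lev <- seq(min(b), max(b))
  me <- tapply(st$energy, factor(b, levels = lev), mean)
  ct <- tapply(st$energy, factor(b, levels = lev), length)
  ct[is.na(ct)] <- 0
  n <- length(lev)
  dwell <- rep(FALSE, n)
  for (k in seq_len(n)) {
    if (is.na(me[k])) next
    lo <- max(1, k - 2); hi <- min(n, k - 2 + 4)
    nb <- setdiff(lo:hi, k)
    nbme <- me[nb]; nbme <- nbme[!is.na(nbme)]
    if (length(nbme) == 0) next
    neighbours_up <- all(me[intersect(nb, c(k - 1, k + 1))] >= me[k],
                         na.rm = TRUE)
    dwell[k] <- neighbours_up && me[k] < max(nbme) - min_depth &&
      me[k] <= min(nbme) + 1e-12 &&
      ct[k] > stats::median(ct[nb])
  }
  data.frame(sep_lo = lev * bin_width, sep_mid = (lev + 0.5) * bin_width,
             mean_energy = as.numeric(me), count = as.integer(ct),
             dwell = dwell, row.names = NULL)
}

#' Write a trajectory as TSV (and optionally a multi-MODEL PDB)
#'
#' @param trajectory a `Trajectory`.
#' @param tsv_path states table output.
#' @param pdb_path optional multi-MODEL PDB of the accepted ligand poses.
#' @param ligand required when `pdb_path` is given.
#' @return invisibly, `tsv_path`.
#' @export
write_trajectory <- function(trajectory, tsv_path, pdb_path = NULL,
                             ligand = NULL) {
  utils::write.table(trajectory$states, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(pdb_path)) {
    stopifnot(!is.null(ligand))
    con <- file(pdb_path, "w"); on.exit(close(con))
    for (k in seq_along(trajectory$snapshots)) {
      xyz <- apply_pose(as.matrix(ligand$beads[, c("x", "y", "z")]),
                       trajectory$snapshots[[k]]$pose)
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s LIG L%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(xyz)), ligand$beads$name, 1L,
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
        substr(ligand$beads$element, 1, 2)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(tsv_path)
}
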