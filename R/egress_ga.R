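# Multi-objective genetic search for ligand exit paths: NSGA-II over
# fixed-length waypoint chains, minimising total steric clash while
# maximising the reach (largest separation from the start site). The
# non-dominated front traces out the clash-versus-separation profile that
# distinguishes a sealed pocket from one with an open egress corridor.

#' Genetic-search configuration
#'
#' @param population individuals per generation (>= 10; default 40).
#' @param generations number of generations (default 120).
#' @param waypoint_count waypoints per path including the fixed start
#'   (>= 3; default 9).
#' @param step_max maximum translation between consecutive waypoints, A
#'   (default 2).
#' @param mut_t,mut_rot,mut_tor mutation scales: translation (A), rotation
#'   (deg), gate torsion (deg).
#' @param p_mut per-gene mutation probability (default 0.3).
#' @param p_cross crossover probability (default 0.9).
#' @param seed integer seed.
#' @param target_reach optional early stop: end the search once a
#'   clash-free candidate reaches this separation (A).
#' @return object of class `GAConfig`.
#' @export
ga_config <- function(population = 60, generations = 250,
                      waypoint_count = 9, step_max = 2.0,
                      mut_t = 0.5, mut_rot = 20, mut_tor = 30,
                      p_mut = 0.3, p_cross = 0.9, seed = 1L,
                      target_reach = NULL) {
  stopifnot(population >= 10, waypoint_count >= 3, step_max > 0,
            generations >= 1)
  structure(as.list(environment()), class = "GAConfig")
}

# clip step vectors to the per-segment bound
clip_steps <- function(steps, step_max) {
  n <- sqrt(rowSums(steps^2))
  f <- pmin(1, step_max / pmax(n, 1e-12))
  steps * f
}

random_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# genome: steps ((W-1) x 3), quats (list of W-1), tors ((W-1) x n_gate or NULL)
# half the initial population are coherent rays (a random direction with a
# shared random orientation), the rest are random walks -- rays give the
# search long straight probes in every direction to refine
random_genome <- function(ga, n_gate, gate_limit, ray = FALSE) {
  W <- ga$waypoint_count
  if (ray) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    steps <- matrix(rep(d * stats::runif(1, 0.7, 1) * ga$step_max,
                        each = W - 1), ncol = 3)
    q <- random_quat()
    quats <- replicate(W - 1, q, simplify = FALSE)
  } else {
    dir <- matrix(stats::rnorm(3 * (W - 1)), ncol = 3)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    len <- stats::runif(W - 1, 0.3 * ga$step_max, ga$step_max)
    steps <- dir * len
    quats <- replicate(W - 1, random_quat(), simplify = FALSE)
  }
  tors <- if (n_gate > 0)
    matrix(stats::runif((W - 1) * n_gate, -gate_limit, gate_limit),
           ncol = n_gate) else NULL
  list(steps = steps, quats = quats, tors = tors)
}

# precomputed clash context: receptor coordinates and per-pair thresholds,
# split into static atoms and gate atoms (which move with torsion genes)
ga_context <- function(structure, ligand, params) {
  rxyz <- coords(structure)
  lref <- as.matrix(ligand$beads[, c("x", "y", "z")])
  thr <- params$overlap_factor *
    outer(ligand$beads$radius, structure$atoms$radius, `+`)
  gate_idx <- unlist(lapply(structure$gates, `[[`, "moving_idx"))
  static_idx <- setdiff(seq_len(nrow(rxyz)), gate_idx)
  list(structure = structure, ligand = ligand, params = params,
       lref = lref, lctr = colMeans(lref),
       rs = rxyz[static_idx, , drop = FALSE],
       thr_s = thr[, static_idx, drop = FALSE]^2,
       gate_idx = gate_idx,
       gate_ref = rxyz[gate_idx, , drop = FALSE],
       thr_g = if (length(gate_idx) > 0)
         thr[, gate_idx, drop = FALSE]^2 else NULL)
}

ga_clash <- function(ctx, lxyz, gate_xyz = NULL) {
  n <- cpp_pair_count(lxyz, ctx$rs, ctx$thr_s)
  if (!is.null(ctx$thr_g)) {
    if (is.null(gate_xyz)) gate_xyz <- ctx$gate_ref
    n <- n + cpp_pair_count(lxyz, gate_xyz, ctx$thr_g)
  }
  as.integer(n)
}

# decode a genome into a PathCandidate (clash counts, separations);
# waypoints are evaluated as one batched distance computation against the
# static receptor
evaluate_genome <- function(genome, ctx, start_pose, ga, use_tors) {
  W <- ga$waypoint_count
  cum <- apply(clip_steps(genome$steps, ga$step_max), 2, cumsum)
  if (W == 2) cum <- matrix(cum, nrow = 1)
  seps <- c(0, sqrt(rowSums(cum^2)))
  nb <- nrow(ctx$lref)
  clashes <- integer(W)
  for (k in seq_len(W)) {
    pose <- if (k == 1) start_pose else
      new_pose(genome$quats[[k - 1]],
               start_pose$translation + cum[k - 1, ], start_pose$torsions)
    lxyz <- apply_pose(ctx$lref, pose)
    gxyz <- NULL
    if (use_tors && !is.null(genome$tors) && k >= 2) {
      s2 <- set_gate_torsions(ctx$structure, genome$tors[k - 1, ])
      gxyz <- coords(s2)[ctx$gate_idx, , drop = FALSE]
    }
    clashes[k] <- ga_clash(ctx, lxyz, gxyz)
  }
  structure(list(genome = genome, clash_counts = clashes,
                 separations = seps, total_clash = sum(clashes),
                 reach = max(seps)), class = "PathCandidate")
}

#' @export
print.PathCandidate <- function(x, ...) {
  cat(sprintf("PathCandidate: %d waypoints, total clash %d, reach %.2f A\n",
              length(x$separations), x$total_clash, x$reach))
  invisible(x)
}

# non-dominated filter for (minimise clash, maximise reach)
nondominated <- function(clash, reach) {
  n <- length(clash)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dom <- clash <= clash[i] & reach >= reach[i] &
      (clash < clash[i] | reach > reach[i])
    if (any(dom)) keep[i] <- FALSE
  }
  keep
}

# fast non-dominated sorting; returns front index per individual
nd_sort <- function(clash, reach) {
  n <- length(clash)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  fr <- 0L
  while (length(remaining) > 0) {
    fr <- fr + 1L
    nd <- nondominated(clash[remaining], reach[remaining])
    rank[remaining[nd]] <- fr
    remaining <- remaining[!nd]
  }
  rank
}

crowding_distance <- function(clash, reach) {
  n <- length(clash)
  if (n <= 2) return(rep(Inf, n))
  cd <- rep(0, n)
  for (obj in list(clash, reach)) {
    o <- order(obj)
    rng <- max(obj) - min(obj)
    cd[o[1]] <- Inf; cd[o[n]] <- Inf
    if (rng > 0)
      for (k in 2:(n - 1))
        cd[o[k]] <- cd[o[k]] + (obj[o[k + 1]] - obj[o[k - 1]]) / rng
  }
  cd
}

mutate_genome <- function(genome, ga, n_gate, gate_limit) {
  W <- nrow(genome$steps) + 1
  for (k in seq_len(W - 1)) {
    if (stats::runif(1) < ga$p_mut)
      genome$steps[k, ] <- genome$steps[k, ] + stats::rnorm(3, 0, ga$mut_t)
    if (stats::runif(1) < ga$p_mut) {
      ax <- stats::rnorm(3)
      dq <- axis_angle_quat(ax, stats::rnorm(1, 0, ga$mut_rot))
      genome$quats[[k]] <- quat_multiply(dq, genome$quats[[k]])
    }
    # smoothing moves: migration paths are continuous, so inheriting the
    # predecessor's gene is an effective local operator
    if (k >= 2 && stats::runif(1) < 0.2)
      genome$quats[[k]] <- genome$quats[[k - 1]]
    if (k >= 2 && stats::runif(1) < 0.2)
      genome$steps[k, ] <- genome$steps[k - 1, ]
    if (n_gate > 0 && stats::runif(1) < ga$p_mut) {
      genome$tors[k, ] <- pmin(pmax(
        genome$tors[k, ] + stats::rnorm(n_gate, 0, ga$mut_tor),
        -gate_limit), gate_limit)
    }
  }
  genome$steps <- clip_steps(genome$steps, ga$step_max)
  genome
}

crossover_genomes <- function(a, b, ga) {
  W <- nrow(a$steps) + 1
  cut <- sample(seq_len(W - 2), 1)  # one-point over waypoint index
  child <- a
  idx <- (cut + 1):(W - 1)
  child$steps[idx, ] <- b$steps[idx, , drop = FALSE]
  child$quats[idx] <- b$quats[idx]
  if (!is.null(a$tors)) child$tors[idx, ] <- b$tors[idx, , drop = FALSE]
  child
}

#' Evolve ligand exit paths with NSGA-II
#'
#' Searches fixed-length waypoint chains (poses of the ligand, first
#' waypoint fixed at the start pose, consecutive translations bounded by
#' `step_max`) for paths that simultaneously minimise the summed clash
#' count and maximise the reach. With `receptor_mode = "gate-torsions"` the
#' per-waypoint gate hinge angles are part of the genome; with
#' `"mode-displaced"` the receptor is first displaced along a normal mode
#' (backbone-amplitude convention) and then held rigid.
#'
#' @param structure receptor `Structure`.
#' @param ligand `RingLigand`.
#' @param start_pose clash-free starting `Pose` (error otherwise).
#' @param receptor_mode `"rigid"`, `"gate-torsions"`, or `"mode-displaced"`.
#' @param ga a `GAConfig`.
#' @param params `EnergyParams`.
#' @param modes `ModeSet`, required for `"mode-displaced"`.
#' @param mode_index,mode_amplitude mode choice and backbone amplitude (A)
#'   for `"mode-displaced"` (defaults: lowest non-rigid mode, 2.2 A).
#' @param gate_limit hinge angle bound (deg) for `"gate-torsions"`.
#' @return the final non-dominated set: a list of `PathCandidate`s with
#'   class `ParetoFront` (attributes `receptor_mode`, `config`).
#' @export
evolve_exit_paths <- function(structure, ligand, start_pose,
                              receptor_mode = c("rigid", "gate-torsions",
                                                "mode-displaced"),
                              ga = ga_config(), params = energy_params(),
                              modes = NULL, mode_index = 1,
                              mode_amplitude = 2.2, gate_limit = 90) {
  receptor_mode <- match.arg(receptor_mode)
  if (receptor_mode == "mode-displaced") {
    if (is.null(modes)) stop("mode-displaced search needs a ModeSet")
    structure <- displace_structure(structure, modes, mode_index,
                                    mode_amplitude, scale_by = "backbone")
  }
  if (clash_count(structure, ligand, start_pose, params) > 0)
    stop("start pose is not clash-free")
  n_gate <- if (receptor_mode == "gate-torsions")
    length(structure$gates) else 0
  use_tors <- receptor_mode == "gate-torsions"
  ctx <- ga_context(structure, ligand, params)
  with_seed(ga$seed, {
    pop <- lapply(seq_len(ga$population), function(k)
      evaluate_genome(random_genome(ga, n_gate, gate_limit,
                                    ray = k <= ga$population / 2),
                      ctx, start_pose, ga, use_tors))
    for (gen in seq_len(ga$generations)) {
      clash <- vapply(pop, `[[`, numeric(1), "total_clash")
      reach <- vapply(pop, `[[`, numeric(1), "reach")
      rank <- nd_sort(clash, reach)
      cd <- rep(0, length(pop))
      for (fr in unique(rank)) {
        sel <- rank == fr
        cd[sel] <- crowding_distance(clash[sel], reach[sel])
      }
      tournament <- function() {
        ij <- sample.int(length(pop), 2)
        i <- ij[1]; j <- ij[2]
        if (rank[i] < rank[j] ||
            (rank[i] == rank[j] && cd[i] > cd[j])) i else j
      }
      offspring <- vector("list", ga$population)
      for (k in seq_len(ga$population)) {
        pa <- pop[[tournament()]]$genome
        g <- if (stats::runif(1) < ga$p_cross)
          crossover_genomes(pa, pop[[tournament()]]$genome, ga) else pa
        g <- mutate_genome(g, ga, n_gate, gate_limit)
        offspring[[k]] <- evaluate_genome(g, ctx, start_pose, ga, use_tors)
      }
      # elitist environmental selection over parents + offspring
      all_pop <- c(pop, offspring)
      clash <- vapply(all_pop, `[[`, numeric(1), "total_clash")
      reach <- vapply(all_pop, `[[`, numeric(1), "reach")
      rank <- nd_sort(clash, reach)
      keep <- integer(0)
      for (fr in sort(unique(rank))) {
        sel <- which(rank == fr)
        if (length(keep) + length(sel) <= ga$population) {
          keep <- c(keep, sel)
        } else {
          cdf <- crowding_distance(clash[sel], reach[sel])
          keep <- c(keep, sel[order(-cdf)][seq_len(ga$population -
                                                     length(keep))])
          break
        }
      }
      pop <- all_pop[keep]
      if (!is.null(ga$target_reach)) {
        cl <- vapply(pop, `[[`, numeric(1), "total_clash")
        rc <- vapply(pop, `[[`, numeric(1), "reach")
        if (any(cl == 0 & rc >= ga$target_reach)) break
      }
    }
    clash <- vapply(pop, `[[`, numeric(1), "total_clash")
    reach <- vapply(pop, `[[`, numeric(1), "reach")
    front <- pop[nondominated(clash, reach)]
    # deduplicate identical objective pairs
    key <- paste(vapply(front, `[[`, numeric(1), "total_clash"),
                 round(vapply(front, `[[`, numeric(1), "reach"), 6))
    front <- front[!duplicated(key)]
    attr(front, "receptor_mode") <- receptor_mode
    attr(front, "config") <- ga
    class(front) <- "ParetoFront"
    front
  })
}

#' @export
print.ParetoFront <- function(x, ...) {
  clash <- vapply(x, `[[`, numeric(1), "total_clash")
  reach <- vapply(x, `[[`, numeric(1), "reach")
  cat("ParetoFront:", length(x), "candidates; best clash-free reach:",
      if (any(clash == 0)) sprintf("%.2f A", max(reach[clash == 0]))
      else "none", "\n")
  invisible(x)
}

#' Does the front contain a clash-free exit?
#'
#' @param front a `ParetoFront`.
#' @param exit_distance reach (A) that counts as having left the pocket.
#' @return logical.
#' @export
exit_found <- function(front, exit_distance) {
  clash <- vapply(front, `[[`, numeric(1), "total_clash")
  reach <- vapply(front, `[[`, numeric(1), "reach")
  any(clash == 0 & reach >= exit_distance)
}

#' Clash-versus-separation profile of a Pareto front
#'
#' Pools every waypoint of every candidate and reports, per 0.5 A
#' separation bin, the minimum clash count observed -- the profile whose
#' rigid-versus-displaced contrast distinguishes a sealed barrier from an
#' open one.
#'
#' @param front a `ParetoFront` (or list of `PathCandidate`s).
#' @param bin_width bin width in A (default 0.5).
#' @return data.frame: `sep_lo`, `sep_mid`, `min_clash`.
#' @export
clash_vs_separation <- function(front, bin_width = 0.5) {
  if (length(front) == 0) stop("empty front")
  sep <- unlist(lapply(front, `[[`, "separations"))
  cl <- unlist(lapply(front, `[[`, "clash_counts"))
  b <- floor(sep / bin_width)
  agg <- tapply(cl, b, min)
  data.frame(sep_lo = as.numeric(names(agg)) * bin_width,
             sep_mid = (as.numeric(names(agg)) + 0.5) * bin_width,
             min_clash = as.integer(agg), row.names = NULL)
}

#' Write a path candidate as a multi-MODEL PDB for visualisation
#'
#' @param candidate a `PathCandidate`.
#' @param ligand the `RingLigand` searched with.
#' @param start_pose the start `Pose` used in the search.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_path_pdb <- function(candidate, ligand, start_pose, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cum <- apply(clip_steps(candidate$genome$steps, Inf), 2, cumsum)
  W <- length(candidate$separations)
  for (k in seq_len(W)) {
    pose <- if (k == 1) start_pose else
      new_pose(candidate$genome$quats[[k - 1]],
               start_pose$translation + cum[k - 1, ], start_pose$torsions)
    xyz <- ligand_scene(ligand, pose)$xyz
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s LIG L%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(xyz)), ligand$beads$name, 1L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(ligand$beads$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
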