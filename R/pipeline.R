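# Orchestration of the full egress analysis: build the study system,
# compute elastic modes, search exit paths on the rigid receptor, repeat
# after lowest-mode backbone displacement if the rigid search finds no
# exit, run the Monte Carlo migration ensemble, and assemble a
# machine-readable report. Every stage draws its seed from the global seed
# through a fixed counter scheme, so toggling stages does not reshuffle
# the randomness of the others.

#' Pipeline configuration
#'
#' @param pocket a `ToyPocketSpec` describing the synthetic system (the
#'   default study system), or `NULL` with `pdb_path` + `annotations` to
#'   analyse an external structure.
#' @param pdb_path,annotations optional external receptor: a PDB file and a
#'   list with at least `minus1_center`, `exit_point` and a start pose.
#' @param anm an `ANMConfig`.
#' @param ga a `GAConfig`.
#' @param mc an `MCConfig`.
#' @param energy an `EnergyParams`.
#' @param stages character subset of
#'   `c("generate", "anm", "ga", "migrate", "profile")`.
#' @param displacement_amplitude backbone amplitude (A) for the
#'   mode-displaced re-run (default 2.2).
#' @param n_migrations Monte Carlo seeds in the ensemble (default 20).
#' @param out_dir artefact directory (`NULL`: nothing written).
#' @param seed global integer seed.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(pocket = toy_pocket_spec(),
                            pdb_path = NULL, annotations = NULL,
                            anm = anm_config(cutoff = 5.05, n_modes = 6),
                            ga = ga_config(),
                            mc = mc_config(),
                            energy = energy_params(),
                            stages = c("generate", "anm", "ga", "migrate",
                                       "profile"),
                            displacement_amplitude = 2.2,
                            n_migrations = 20,
                            out_dir = NULL, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "PipelineConfig")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks stage names, sub-configuration classes and the input choice;
#' errors list the offending fields.
#'
#' @param config a `PipelineConfig` (or bare list).
#' @return `TRUE` invisibly.
#' @export
validate_pipeline_config <- function(config) {
  problems <- character(0)
  known <- c("generate", "anm", "ga", "migrate", "profile")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0)
    problems <- c(problems, paste0("unknown stage name(s): ",
                                   paste(bad, collapse = ", ")))
  chk <- function(field, cls) {
    if (!is.null(config[[field]]) && !inherits(config[[field]], cls))
      problems <<- c(problems, paste0(field, " must be a ", cls))
  }
  chk("pocket", "ToyPocketSpec"); chk("anm", "ANMConfig")
  chk("ga", "GAConfig"); chk("mc", "MCConfig")
  chk("energy", "EnergyParams")
  if (is.null(config$pocket) && is.null(config$pdb_path))
    problems <- c(problems, "either pocket or pdb_path must be given")
  if (!is.null(config$pdb_path) && is.null(config$annotations))
    problems <- c(problems, "pdb_path input needs site annotations")
  if (is.null(config$seed))
    problems <- c(problems, "seed must be set")
  if (length(problems) > 0)
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full egress analysis
#'
#' Stage order: generate (or load) the receptor system; ANM modes; exit
#' path search on the rigid receptor; if no clash-free exit is found,
#' displace the backbone along the lowest non-rigid mode (trying both
#' signs of the displacement amplitude) and search again; Monte Carlo
#' migration ensemble with mobile gates; energy-separation profile with
#' dwell-bin detection. Fully deterministic for a fixed global seed.
#'
#' @param config a `PipelineConfig`.
#' @return object of class `EgressReport`: rigid/mode-displaced exit
#'   booleans, the displacement amplitude used, the Monte Carlo exit
#'   fraction, dwell bins, profile tables, artefact paths and provenance.
#' @export
run_egress_analysis <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  seed_of <- function(k) fold_seed(config$seed, k)
  out <- list(stages_run = character(0), failed_stage = NULL,
              profile_files = list())
  art <- function(name) {
    if (is.null(config$out_dir)) return(NULL)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(config$out_dir, name)
  }
  # -- generate ---------------------------------------------------------------
  if (!is.null(config$pocket)) {
    sp <- config$pocket
    sp$seed <- seed_of(1)
    pocket <- make_toy_pocket(sp, params = config$energy, certify = "fast")
  } else {
    stru <- read_pdb(config$pdb_path)
    pocket <- list(structure = stru, ligand = make_ring_ligand("4C1"),
                   annotations = config$annotations,
                   spec = NULL, params = config$energy)
    class(pocket) <- "ToyPocket"
  }
  out$stages_run <- c(out$stages_run, "generate")
  ann <- pocket$annotations
  exit_distance <- separation(ann$minus1_center, ann$exit_point)
  if (!is.null(config$out_dir))
    write_toy_pocket(pocket, art("system.pdb"))
  # -- anm --------------------------------------------------------------------
  modes <- NULL
  if ("anm" %in% config$stages) {
    modes <- anm_modes(pocket$structure, config$anm)
    out$stages_run <- c(out$stages_run, "anm")
    if (!is.null(config$out_dir))
      write_modeset(modes, art("modes.tsv"), art("modes.json"))
  }
  # -- ga ---------------------------------------------------------------------
  rigid_exit <- NA; mode_exit <- NA; amp_used <- NA_real_
  if ("ga" %in% config$stages) {
    ga <- config$ga; ga$seed <- seed_of(2)
    front_rigid <- evolve_exit_paths(pocket$structure, pocket$ligand,
                                     ann$start_pose, "rigid", ga,
                                     config$energy)
    rigid_exit <- exit_found(front_rigid, exit_distance)
    prof_rigid <- clash_vs_separation(front_rigid)
    out$profile_rigid <- prof_rigid
    if (!is.null(config$out_dir)) {
      utils::write.table(prof_rigid, art("clash_profile_rigid.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      out$profile_files$rigid <- art("clash_profile_rigid.tsv")
    }
    if (!rigid_exit && !is.null(modes)) {
      ga2 <- config$ga; ga2$seed <- seed_of(3)
      front_disp <- NULL
      for (amp in c(config$displacement_amplitude,
                    -config$displacement_amplitude)) {
        # a displacement sign that squeezes the start site counts as no exit
        fd <- tryCatch(
          evolve_exit_paths(pocket$structure, pocket$ligand,
                            ann$start_pose, "mode-displaced",
                            ga2, config$energy, modes = modes,
                            mode_index = 1, mode_amplitude = amp),
          error = function(e) NULL)
        if (!is.null(fd)) front_disp <- fd
        if (!is.null(fd) && exit_found(fd, exit_distance)) {
          amp_used <- amp
          break
        }
      }
      mode_exit <- !is.null(front_disp) &&
        exit_found(front_disp, exit_distance)
      if (is.na(amp_used)) amp_used <- -config$displacement_amplitude
      if (!is.null(front_disp)) {
        prof_disp <- clash_vs_separation(front_disp)
        out$profile_displaced <- prof_disp
        if (!is.null(config$out_dir)) {
          utils::write.table(prof_disp, art("clash_profile_displaced.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
          out$profile_files$displaced <- art("clash_profile_displaced.tsv")
        }
      }
    } else if (rigid_exit) {
      mode_exit <- TRUE
      amp_used <- 0
    }
    out$stages_run <- c(out$stages_run, "ga")
  }
  # -- migrate ----------------------------------------------------------------
  exit_fraction <- NA_real_; trajs <- NULL
  if ("migrate" %in% config$stages) {
    trajs <- lapply(seq_len(config$n_migrations), function(k) {
      mcfg <- config$mc
      mcfg$seed <- seed_of(100 + k)
      mcfg$gate_limit <- if (!is.null(ann$chi_open)) ann$chi_open else 90
      run_migration(pocket$structure, pocket$ligand, ann$start_pose,
                    modes, mcfg, config$energy)
    })
    exit_fraction <- mean(vapply(trajs, function(t)
      t$terminated_reason == "distance", logical(1)))
    out$stages_run <- c(out$stages_run, "migrate")
  }
  # -- profile ----------------------------------------------------------------
  dwell <- NULL
  if ("profile" %in% config$stages && !is.null(trajs)) {
    prof <- energy_distance_profile(trajs)
    out$energy_profile <- prof
    dwell <- prof[prof$dwell, c("sep_lo", "sep_mid", "mean_energy",
                                "count")]
    if (!is.null(config$out_dir)) {
      utils::write.table(prof, art("energy_profile.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      out$profile_files$energy <- art("energy_profile.tsv")
    }
    out$stages_run <- c(out$stages_run, "profile")
  }
  report <- structure(c(list(
    rigid_exit_found = rigid_exit,
    mode_displaced_exit_found = mode_exit,
    displacement_amplitude = amp_used,
    mc_exit_fraction = exit_fraction,
    dwell_bins = dwell,
    exit_distance = exit_distance,
    provenance = list(seed = config$seed,
                      config_md5 = config_digest(config),
                      package_version =
                        as.character(utils::packageVersion("exoegress")),
                      r_version = R.version.string)),
    out), class = "EgressReport")
  if (!is.null(config$out_dir)) {
    skim <- report
    skim$energy_profile <- NULL; skim$profile_rigid <- NULL
    skim$profile_displaced <- NULL
    jsonlite::write_json(skim, file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  report
}

#' @export
print.EgressReport <- function(x, ...) {
  cat("EgressReport\n")
  cat("  rigid exit found:         ", x$rigid_exit_found, "\n")
  cat("  mode-displaced exit found:", x$mode_displaced_exit_found,
      sprintf(" (amplitude %.1f A)", x$displacement_amplitude), "\n")
  cat("  MC exit fraction:         ", x$mc_exit_fraction, "\n")
  if (!is.null(x$dwell_bins) && nrow(x$dwell_bins) > 0)
    cat("  dwell bins at:            ",
        paste(sprintf("%.2f A", x$dwell_bins$sep_mid), collapse = ", "),
        "\n")
  invisible(x)
}
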