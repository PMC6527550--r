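# shared fixtures: a cached default toy pocket (building + certifying one
# is a few seconds, so the suite reuses a single instance), tiny ad-hoc
# structures, and single-bead "ligands" for closed-form energy checks

pocket_cache <- new.env(parent = emptyenv())

default_pocket <- function() {
  if (is.null(pocket_cache$pk))
    pocket_cache$pk <- make_toy_pocket(certify = "fast")
  pocket_cache$pk
}

mc_pocket <- function() default_pocket()

pocket_modes <- function(pk = default_pocket()) {
  key <- paste0("modes_", substr(digest_coords(pk), 1, 8))
  if (is.null(pocket_cache[[key]]))
    pocket_cache[[key]] <- anm_modes(pk$structure,
                                     anm_config(cutoff = 5.05, n_modes = 6))
  pocket_cache[[key]]
}

digest_coords <- function(pk) {
  paste0(nrow(pk$structure$atoms), "_",
         round(sum(abs(coords(pk$structure))), 3))
}

# a bare structure from a coordinate matrix (all carbon beads, one residue
# per atom)
atoms_structure <- function(xyz, element = "C", polar = FALSE,
                            radius = NULL) {
  xyz <- rbind(xyz)
  at <- data.frame(element = element, name = "X",
                   res_index = seq_len(nrow(xyz)), res_name = "RES",
                   chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, stringsAsFactors = FALSE)
  if (!is.null(radius)) at$radius <- radius
  at$polar <- polar
  new_structure(at)
}

# single-bead ligand for pairwise closed-form checks
bead_ligand <- function(radius = 1.7, polar = FALSE) {
  new_ring_ligand(data.frame(element = "C", name = "B", x = 0, y = 0,
                             z = 0, radius = radius, polar = polar,
                             stringsAsFactors = FALSE),
                  ring_idx = integer(0))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}
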