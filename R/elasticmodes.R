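# Anisotropic network model (ANM) normal modes and mode-directed
# displacement. Nodes are one bead per residue by default (a C-alpha
# analogue); springs of stiffness gamma connect nodes within the cutoff.

#' ANM configuration
#'
#' @param cutoff spring cutoff in Angstrom (default 15.0).
#' @param gamma uniform spring constant, arbitrary units (default 1.0).
#' @param n_modes number of non-rigid modes to report (default 10).
#' @param cluster_size group this many consecutive residues into one node
#'   (default 1, i.e. one node per residue). Clustering coarsens large
#'   systems; with singleton clusters it reduces to the plain residue ANM.
#' @return object of class `ANMConfig`.
#' @export
anm_config <- function(cutoff = 15.0, gamma = 1.0, n_modes = 10,
                       cluster_size = 1) {
  stopifnot(cutoff > 0, gamma > 0, n_modes >= 1, cluster_size >= 1)
  structure(list(cutoff = cutoff, gamma = gamma, n_modes = n_modes,
                 cluster_size = cluster_size), class = "ANMConfig")
}

#' Node positions for the ANM
#'
#' One node per residue (the residue's bead centroid), or per cluster of
#' `cluster_size` consecutive residues. With `cluster_side_chains = TRUE`
#' (the default) all non-backbone atoms are pooled into a single cluster
#' node: mobile side-chain assemblies such as the toll-barrier arms move as
#' one collective unit, in the spirit of clustered normal-mode analyses,
#' and sparse side-chain beads cannot produce spurious near-zero modes.
#' Returns the node coordinates, the atom-to-node map, and which nodes
#' contain backbone atoms.
#'
#' @param structure a `Structure`.
#' @param cluster_size residues per node.
#' @param cluster_side_chains pool non-backbone atoms into one node.
#' @return list with `xyz` (N x 3), `atom2node` (integer per atom),
#'   `node_ids` (character), `is_backbone` (logical per node).
#' @export
anm_nodes <- function(structure, cluster_size = 1,
                      cluster_side_chains = TRUE) {
  at <- structure$atoms
  reskey <- paste(at$chain, at$res_index, sep = ":")
  sc <- !structure$backbone_mask
  if (cluster_side_chains && any(sc)) reskey[sc] <- ".sidechain."
  resfac <- factor(reskey, levels = unique(reskey))
  res_idx <- as.integer(resfac)
  if (cluster_size > 1) {
    node_of_res <- (seq_len(nlevels(resfac)) - 1L) %/% cluster_size + 1L
    node <- node_of_res[res_idx]
  } else node <- res_idx
  xyz <- coords(structure)
  dimnames(xyz) <- NULL
  n <- max(node)
  nx <- vapply(1:n, function(k) colMeans(xyz[node == k, , drop = FALSE]),
               numeric(3))
  is_bb <- vapply(1:n, function(k) any(structure$backbone_mask[node == k]),
                  logical(1))
  list(xyz = t(nx), atom2node = node,
       node_ids = as.character(1:n), is_backbone = is_bb)
}

#' Build the ANM stiffness operator (Hessian)
#'
#' Standard ANM: for each node pair within the cutoff the 3x3 super-element
#' is `-gamma * (rhat rhat^T)`; diagonal blocks are minus the sum of the
#' off-diagonal blocks in their row, making every row-block sum zero. The
#' result is exactly symmetric.
#'
#' @param nodes N x 3 node coordinate matrix.
#' @param config an `ANMConfig`.
#' @return 3N x 3N symmetric matrix.
#' @export
build_anm_hessian <- function(nodes, config = anm_config()) {
  nodes <- rbind(nodes)
  n <- nrow(nodes)
  if (n < 2) stop("ANM needs at least 2 nodes")
  H <- matrix(0, 3 * n, 3 * n)
  np <- neighbor_pairs(nodes, nodes, config$cutoff)
  sel <- np$i < np$j
  pi_ <- np$i[sel]; pj <- np$j[sel]; d <- np$d[sel]
  if (any(d < 1e-9)) stop("coincident ANM nodes")
  for (k in seq_along(pi_)) {
    i <- pi_[k]; j <- pj[k]
    r <- nodes[j, ] - nodes[i, ]
    blk <- -config$gamma * tcrossprod(r) / sum(r^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Diagonalise an ANM Hessian into a ModeSet
#'
#' Eigenpairs sorted by ascending eigenvalue. Rigid-body modes are those
#' with `|lambda| < rigid_tol * max(lambda)`; they are identified, counted,
#' and excluded from the reported modes. Reported vectors are orthonormal;
#' each is sign-fixed so its first component larger than 1e-6 in magnitude
#' is positive.
#'
#' @param hessian 3N x 3N symmetric matrix from [build_anm_hessian].
#' @param n_modes number of non-rigid modes to report.
#' @param rigid_tol relative tolerance for the rigid-mode eigenvalues.
#' @return object of class `ModeSet`: `eigenvalues` (ascending, length
#'   `n_modes`), `vectors` (3N x n_modes, orthonormal), `n_rigid`,
#'   `rigid_vectors`.
#' @export
compute_modes <- function(hessian, n_modes = 10, rigid_tol = 1e-8) {
  eg <- eigen(hessian, symmetric = TRUE)
  ord <- order(eg$values)           # ascending
  val <- eg$values[ord]
  vec <- eg$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(val))
  rigid <- abs(val) < rigid_tol * max(lam_max, 1)
  n_rigid <- sum(rigid)
  nz <- which(!rigid)
  if (length(nz) < n_modes)
    stop("only ", length(nz), " non-rigid modes available, need ", n_modes)
  keep <- nz[seq_len(n_modes)]
  V <- vec[, keep, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    lead <- which(abs(V[, k]) > 1e-6)[1]
    if (!is.na(lead) && V[lead, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(eigenvalues = val[keep], vectors = V,
                 n_rigid = n_rigid,
                 rigid_vectors = vec[, which(rigid), drop = FALSE]),
            class = "ModeSet")
}

#' Compute ANM modes for a structure
#'
#' Convenience wrapper: nodes, Hessian, eigensolve. The returned `ModeSet`
#' carries the node bookkeeping needed by [displace_structure].
#'
#' @param structure a `Structure`.
#' @param config an `ANMConfig`.
#' @return `ModeSet` with `nodes` attached.
#' @export
anm_modes <- function(structure, config = anm_config()) {
  nodes <- anm_nodes(structure, config$cluster_size)
  H <- build_anm_hessian(nodes$xyz, config)
  ms <- compute_modes(H, config$n_modes)
  ms$nodes <- nodes
  ms
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", length(x$eigenvalues), "non-rigid modes (",
      x$n_rigid, "rigid );  lambda:",
      paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Displace a structure along a normal mode
#'
#' Every atom moves with its node's mode displacement. The mode vector is
#' rescaled so that the largest per-node displacement -- over backbone nodes
#' when `scale_by = "backbone"` (the convention used for the 2.2 A
#' backbone-displacement analyses), or over all nodes when
#' `scale_by = "all"` -- equals `amplitude` in Angstrom. Amplitude 0 returns
#' the structure unchanged; displacements are linear in amplitude.
#'
#' @param structure the `Structure` the modes were computed from.
#' @param modes a `ModeSet` from [anm_modes] (must carry node bookkeeping).
#' @param mode index of the mode to use (1 = lowest non-rigid).
#' @param amplitude target maximum node displacement, Angstrom (may be
#'   negative to reverse the mode direction).
#' @param scale_by `"backbone"` or `"all"`, see above.
#' @return a displaced `Structure`.
#' @export
displace_structure <- function(structure, modes, mode = 1, amplitude,
                               scale_by = c("backbone", "all")) {
  scale_by <- match.arg(scale_by)
  if (is.null(modes$nodes))
    stop("ModeSet lacks node bookkeeping; use anm_modes() on this structure")
  nd <- modes$nodes
  if (length(nd$atom2node) != nrow(structure$atoms))
    stop("mode/structure node mismatch")
  if (amplitude == 0) return(structure)
  v <- matrix(modes$vectors[, mode], ncol = 3, byrow = TRUE)  # N x 3
  nrm <- sqrt(rowSums(v^2))
  ref <- if (scale_by == "backbone" && any(nd$is_backbone))
    max(nrm[nd$is_backbone]) else max(nrm)
  if (ref < 1e-12) stop("mode has no displacement on the scaling node set")
  disp <- v * (amplitude / ref)
  xyz <- coords(structure) + disp[nd$atom2node, , drop = FALSE]
  set_coords(structure, xyz)
}

#' Serialise a ModeSet to TSV + JSON
#'
#' Writes the displacement vectors as a TSV (node, mode, dx, dy, dz) and the
#' eigenvalues as a JSON list.
#'
#' @param modes a `ModeSet`.
#' @param tsv_path,json_path output paths.
#' @return invisibly, the TSV path.
#' @export
write_modeset <- function(modes, tsv_path, json_path) {
  n <- nrow(modes$vectors) / 3
  tab <- do.call(rbind, lapply(seq_along(modes$eigenvalues), function(k) {
    v <- matrix(modes$vectors[, k], ncol = 3, byrow = TRUE)
    data.frame(node = 1:n, mode = k, dx = v[, 1], dy = v[, 2], dz = v[, 3])
  }))
  utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(eigenvalues = modes$eigenvalues,
                            n_rigid = modes$n_rigid),
                       json_path, digits = NA, auto_unbox = TRUE)
  invisible(tsv_path)
}
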