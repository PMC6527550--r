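# Cremer-Pople puckering coordinates for six-membered rings, canonical
# conformer classification on the puckering sphere, a classical
# well-tempered metadynamics engine for analytic 2-D potentials, and
# free-energy-surface extrema reporting.
#
# Ring convention: atoms ordered O5, C1, C2, C3, C4, C5 (j = 0..5 in the
# Fourier sums); theta = 0 corresponds to the 4C1 chair under this ordering.

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Standard construction: translate to the centroid, define the mean plane
#' from the two Fourier sums, project out-of-plane displacements `z_j`, and
#' form the puckering amplitudes `q2` (with phase `phi2`) and `q3`. Then
#' `Q = sqrt(q2^2 + q3^2)`, `cos(theta) = q3/Q`. Invariant under rigid
#' motion of the ring.
#'
#' @param ring 6 x 3 coordinate matrix, rows ordered O5, C1, C2, C3, C4, C5.
#' @return object of class `PuckerCoords`: `Q` (A), `theta` (deg, 0..180),
#'   `phi` (deg, 0..360), and Cartesian components `qx`, `qy`, `qz` with
#'   `qx^2 + qy^2 + qz^2 = Q^2`.
#' @export
cremer_pople <- function(ring) {
  ring <- rbind(ring)
  if (nrow(ring) != 6 || ncol(ring) != 3)
    stop("cremer_pople needs exactly 6 ordered ring positions")
  N <- 6
  j <- 0:5
  r <- sweep(ring, 2, colMeans(ring))
  Rp <- colSums(r * sin(2 * pi * j / N))
  Rpp <- colSums(r * cos(2 * pi * j / N))
  nvec <- c(Rp[2] * Rpp[3] - Rp[3] * Rpp[2],
            Rp[3] * Rpp[1] - Rp[1] * Rpp[3],
            Rp[1] * Rpp[2] - Rp[2] * Rpp[1])
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-12) stop("degenerate ring: cannot define mean plane")
  # orient the normal so theta = 0 is the 4C1 chair for the O5,C1..C5
  # ordering (the convention adopted throughout this package)
  nvec <- -nvec / nn
  z <- as.numeric(r %*% nvec)
  q2c <- sqrt(2 / N) * sum(z * cos(4 * pi * j / N))
  q2s <- -sqrt(2 / N) * sum(z * sin(4 * pi * j / N))
  q3 <- sqrt(1 / N) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  phi <- if (q2 < 1e-12) 0 else atan2(q2s, q2c) %% (2 * pi)
  theta <- if (Q < 1e-12) 0 else acos(pmin(1, pmax(-1, q3 / Q)))
  structure(list(
    Q = Q, theta = theta * 180 / pi, phi = phi * 180 / pi,
    qx = Q * sin(theta) * cos(phi), qy = Q * sin(theta) * sin(phi),
    qz = Q * cos(theta)), class = "PuckerCoords")
}

#' @export
print.PuckerCoords <- function(x, ...) {
  cat(sprintf("PuckerCoords: Q = %.3f A, theta = %.1f deg, phi = %.1f deg\n",
              x$Q, x$theta, x$phi))
  invisible(x)
}

# ---- canonical conformer vertices ------------------------------------------
# The 38 canonical conformers are defined geometrically (which atoms lie
# above/below the four- or five-atom plane) and their (theta, phi) vertices
# derived by running cremer_pople on the ideal construction. Superscript
# atoms (before the letter) lie above the plane, subscripts below; labels
# are written without commas, e.g. "B3O" for the boat with C3 and O5 below.

ring_atom_labels <- c("O", "1", "2", "3", "4", "5")

# build ideal ring with out-of-plane pattern z (length 6, sum 0), amplitude-
# normalised to Q = q_amp
ideal_ring <- function(zpat, q_amp = 0.55, radius = 1.45) {
  ang <- 2 * pi * (0:5) / 6
  base <- cbind(radius * cos(ang), radius * sin(ang), zpat)
  for (it in 1:3) {  # rescale z; iterate since the mean plane shifts
    cp <- cremer_pople(base)
    if (cp$Q < 1e-12) break
    base[, 3] <- base[, 3] * (q_amp / cp$Q)
  }
  base
}

conformer_patterns <- function() {
  lab <- ring_atom_labels
  pats <- list()
  add <- function(name, z) pats[[name]] <<- z
  chair <- rep(c(1, -1), 3)          # O5,C2,C4 up; C1,C3,C5 down => 4C1
  add("4C1", chair)
  add("1C4", -chair)
  # boats: para pairs same side, other four coplanar
  para <- list(c(1, 4), c(2, 5), c(3, 6))  # (O5,C3), (C1,C4), (C2,C5)
  for (p in para) {
    z <- rep(-0.5, 6); z[p] <- 1
    up <- paste0(sort(lab[p]), collapse = "")
    add(paste0(up, "B"), z)          # pair above the plane
    add(paste0("B", up), -z)         # pair below
  }
  # skew-boats: meta pair on opposite sides, other four coplanar
  skews <- list(c("1", "3"), c("3", "1"), c("1", "5"), c("5", "1"),
                c("O", "2"), c("2", "O"))
  for (s in skews) {
    z <- rep(0, 6)
    z[match(s[1], lab)] <- 1
    z[match(s[2], lab)] <- -1
    add(paste0(s[1], "S", s[2]), z)
  }
  # envelopes: one atom out of plane
  for (a in seq_along(lab)) {
    z <- rep(-0.2, 6); z[a] <- 1
    add(paste0(lab[a], "E"), z)
    add(paste0("E", lab[a]), -z)
  }
  # half-chairs: adjacent pair on opposite sides (both orientations)
  for (a in seq_along(lab)) {
    b <- a %% 6 + 1
    z <- rep(0, 6); z[a] <- 1; z[b] <- -1
    add(paste0(lab[a], "H", lab[b]), z)
    add(paste0(lab[b], "H", lab[a]), -z)
  }
  pats
}

conformer_vertices <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pats <- conformer_patterns()
    tab <- do.call(rbind, lapply(names(pats), function(nm) {
      cp <- cremer_pople(ideal_ring(pats[[nm]]))
      data.frame(label = nm, theta = cp$theta, phi = cp$phi,
                 stringsAsFactors = FALSE)
    }))
    cache <<- tab
    tab
  }
})

#' Classify puckering coordinates as a canonical conformer
#'
#' If `Q < planar_tol` the ring is `"planar"`. Otherwise the nearest of the
#' 38 canonical conformer vertices (2 chairs, 6 boats, 6 skew-boats, 12
#' half-chairs, 12 envelopes) on the `(theta, phi)` sphere by great-circle
#' distance; ties broken by the fixed canonical ordering of the vertex
#' table.
#'
#' @param coords a `PuckerCoords` (or anything with `Q`, `theta`, `phi`).
#' @param planar_tol amplitude below which the ring counts as planar (A).
#' @return conformer label, e.g. `"4C1"`, `"1S3"`, `"B3O"`, `"planar"`.
#' @export
classify_conformer <- function(coords, planar_tol = 0.05) {
  if (coords$Q < planar_tol) return("planar")
  vt <- conformer_vertices()
  t1 <- coords$theta * pi / 180; p1 <- coords$phi * pi / 180
  t2 <- vt$theta * pi / 180; p2 <- vt$phi * pi / 180
  # great-circle distance on the puckering sphere
  d <- acos(pmin(1, pmax(-1, cos(t1) * cos(t2) +
                           sin(t1) * sin(t2) * cos(p1 - p2))))
  vt$label[which.min(d)]
}

# ---- well-tempered metadynamics on analytic 2-D potentials -----------------

#' Well-tempered metadynamics configuration
#'
#' @param gauss_height initial Gaussian height, kcal/mol (default 1).
#' @param gauss_width Gaussian width in collective-variable units
#'   (default 0.1).
#' @param bias_factor well-tempered bias factor gamma > 1 (default 10).
#' @param stride dynamics steps between depositions (default 200).
#' @param kT thermal energy in kcal/mol (default 0.596, i.e. 300 K).
#' @param n_steps total dynamics steps.
#' @param seed RNG seed.
#' @param dt integration step (arbitrary time units).
#' @param diffusion walker diffusion coefficient (CV units^2 / time).
#' @return object of class `MetadConfig`.
#' @export
metad_config <- function(gauss_height = 1, gauss_width = 0.1,
                         bias_factor = 10, stride = 200, kT = 0.596,
                         n_steps = 300000, seed = 1, dt = 5e-4,
                         diffusion = 1) {
  stopifnot(bias_factor > 1, stride >= 1, kT > 0, gauss_height > 0,
            gauss_width > 0, n_steps >= stride)
  structure(list(gauss_height = gauss_height, gauss_width = gauss_width,
                 bias_factor = bias_factor, stride = stride, kT = kT,
                 n_steps = n_steps, seed = seed, dt = dt,
                 diffusion = diffusion), class = "MetadConfig")
}

# separable Gaussian filter with edge renormalisation
gauss_filter2 <- function(M, dx, dy, sigma) {
  conv1 <- function(A, step) {
    k <- stats::dnorm(seq(-3 * sigma, 3 * sigma, by = step), 0, sigma)
    half <- (length(k) - 1) / 2
    out <- A
    for (i in seq_len(nrow(A))) {
      idx <- (i - half):(i + half)
      ok <- idx >= 1 & idx <= nrow(A)
      out[i, ] <- colSums(A[idx[ok], , drop = FALSE] * k[ok]) / sum(k[ok])
    }
    out
  }
  t(conv1(t(conv1(M, dx)), dy))
}

#' Run well-tempered metadynamics on an analytic 2-D potential
#'
#' An overdamped Langevin walker explores `potential(x, y)` plus the
#' history-dependent bias. Gaussians of width `gauss_width` are deposited
#' every `stride` steps with the well-tempered height decay
#' `h = gauss_height * exp(-V_bias / ((gamma - 1) kT))`. The free-energy
#' estimator on the grid is `F = -(gamma / (gamma - 1)) * V_bias`,
#' min-shifted to zero. The bias and its gradient are accumulated on the
#' output grid (bilinear interpolation between nodes), which keeps the cost
#' per step independent of the number of hills.
#'
#' @param potential function of two numeric vectors `(x, y)` returning the
#'   energy in kcal/mol; must be finite on the grid.
#' @param config a `MetadConfig`.
#' @param xlim,ylim CV ranges (walker boundaries are reflective).
#' @param nx,ny grid resolution.
#' @param x0,y0 walker start (defaults to the grid minimum of the
#'   potential).
#' @return object of class `FELGrid`: `x`, `y` axes, `values` (kcal/mol,
#'   min 0), `bias` grid, `hills` (step, x, y, height), `config`, and the
#'   convergence diagnostic `basin_drift` (drift of the free-energy range
#'   explored over the final 20% of depositions).
#' @export
run_wt_metadynamics <- function(potential, config = metad_config(),
                                xlim = c(-2, 2), ylim = c(-2, 2),
                                nx = 81, ny = 81, x0 = NULL, y0 = NULL) {
  gx <- seq(xlim[1], xlim[2], length.out = nx)
  gy <- seq(ylim[1], ylim[2], length.out = ny)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  V <- outer(gx, gy, potential)
  if (any(!is.finite(V))) stop("potential not finite on the grid")
  if (is.null(x0) || is.null(y0)) {
    mi <- which(V == min(V), arr.ind = TRUE)[1, ]
    x0 <- gx[mi[1]]; y0 <- gy[mi[2]]
  }
  set.seed(config$seed)
  kT <- config$kT; gam <- config$bias_factor
  D <- config$diffusion; dt <- config$dt
  drift_c <- D * dt / kT
  noise_c <- sqrt(2 * D * dt)
  w <- config$gauss_width
  bias <- matrix(0, nx, ny)
  n_dep <- config$n_steps %/% config$stride
  hills <- matrix(0, n_dep, 4)
  colnames(hills) <- c("step", "x", "y", "height")
  # time-averaged bias over the final half of the depositions: the
  # instantaneous well-tempered bias fluctuates pointwise, its running
  # average converges much faster to the free-energy shape
  avg_from <- ceiling(n_dep / 2)
  bias_sum <- matrix(0, nx, ny)
  n_avg <- 0L
  # finite-difference gradient of the physical potential, precomputed
  h <- 1e-5
  gradVx <- function(x, y) (potential(x + h, y) - potential(x - h, y)) / (2 * h)
  gradVy <- function(x, y) (potential(x, y + h) - potential(x, y - h)) / (2 * h)
  # per-deposition snapshot of the left/right basin free-energy difference
  # (split at the x-axis midpoint) for the convergence diagnostic
  est_snap <- numeric(n_dep)
  mid <- ceiling(nx / 2)
  x <- x0; y <- y0
  idep <- 0L
  bilin <- function(M, x, y) {
    fx <- (x - gx[1]) / dx; fy <- (y - gy[1]) / dy
    i <- pmin(pmax(floor(fx), 0), nx - 2); j <- pmin(pmax(floor(fy), 0), ny - 2)
    tx <- fx - i; ty <- fy - j
    i <- i + 1; j <- j + 1
    M[i, j] * (1 - tx) * (1 - ty) + M[i + 1, j] * tx * (1 - ty) +
      M[i, j + 1] * (1 - tx) * ty + M[i + 1, j + 1] * tx * ty
  }
  for (step in seq_len(config$n_steps)) {
    # bias gradient by central difference of the bilinear bias field
    bgx <- (bilin(bias, min(x + dx, gx[nx]), y) -
              bilin(bias, max(x - dx, gx[1]), y)) / (2 * dx)
    bgy <- (bilin(bias, x, min(y + dy, gy[ny])) -
              bilin(bias, x, max(y - dy, gy[1]))) / (2 * dy)
    fx <- gradVx(x, y) + bgx
    fy <- gradVy(x, y) + bgy
    x <- x - drift_c * fx + noise_c * stats::rnorm(1)
    y <- y - drift_c * fy + noise_c * stats::rnorm(1)
    # reflective boundaries
    if (x < xlim[1]) x <- 2 * xlim[1] - x
    if (x > xlim[2]) x <- 2 * xlim[2] - x
    if (y < ylim[1]) y <- 2 * ylim[1] - y
    if (y > ylim[2]) y <- 2 * ylim[2] - y
    if (step %% config$stride == 0L) {
      idep <- idep + 1L
      vb_here <- bilin(bias, x, y)
      hgt <- config$gauss_height * exp(-vb_here / ((gam - 1) * kT))
      gxx <- exp(-(gx - x)^2 / (2 * w^2))
      gyy <- exp(-(gy - y)^2 / (2 * w^2))
      bias <- bias + hgt * tcrossprod(gxx, gyy)
      hills[idep, ] <- c(step, x, y, hgt)
      if (idep >= avg_from) {
        bias_sum <- bias_sum + bias
        n_avg <- n_avg + 1L
      }
      est_snap[idep] <- (gam / (gam - 1)) *
        (max(bias[1:mid, ]) - max(bias[(mid + 1):nx, ]))
    }
  }
  bias_est <- if (n_avg > 0) bias_sum / n_avg else bias
  fel <- -(gam / (gam - 1)) * bias_est
  # the estimator is only defined down to the resolution of the deposited
  # Gaussians: filter at that width to remove hill granularity
  fel <- gauss_filter2(fel, dx, dy, w)
  fel <- fel - min(fel)
  tail_n <- max(2L, ceiling(0.2 * idep))
  tail_idx <- seq(idep - tail_n + 1L, idep)
  basin_drift <- diff(range(est_snap[tail_idx]))
  structure(list(x = gx, y = gy, values = fel, bias = bias,
                 hills = as.data.frame(hills[seq_len(idep), , drop = FALSE]),
                 config = config, basin_drift = basin_drift),
            class = "FELGrid")
}

#' @export
print.FELGrid <- function(x, ...) {
  cat(sprintf("FELGrid: %d x %d, range %.2f kcal/mol, drift %.3f\n",
              length(x$x), length(x$y), max(x$values), x$basin_drift))
  invisible(x)
}

#' Free energy difference between two basins of a FEL grid
#'
#' Basin free energies are Boltzmann integrals of the surface over disks
#' around the stated centres: `F_b = -kT ln sum exp(-F/kT)`. Returns
#' `F(basin_b) - F(basin_a)`.
#'
#' @param fel a `FELGrid` (or list with `x`, `y`, `values`).
#' @param a,b length-2 basin centres in CV units.
#' @param radius basin radius in CV units.
#' @param kT thermal energy, kcal/mol.
#' @return free-energy difference in kcal/mol.
#' @export
fel_basin_delta <- function(fel, a, b, radius = 0.5, kT = 0.596) {
  gx <- fel$x; gy <- fel$y
  XX <- matrix(gx, length(gx), length(gy))
  YY <- matrix(gy, length(gx), length(gy), byrow = TRUE)
  fb <- function(ctr) {
    m <- (XX - ctr[1])^2 + (YY - ctr[2])^2 <= radius^2
    if (!any(m)) stop("basin at (", ctr[1], ", ", ctr[2], ") not on grid")
    -kT * log(sum(exp(-fel$values[m] / kT)))
  }
  fb(b) - fb(a)
}

#' Minima and inter-basin barrier of a free-energy grid
#'
#' Local minima are grid points below all 8 neighbours and within
#' `depth_max` of the global minimum. The barrier between two named basins
#' is the minimax saddle: the smallest energy threshold at which the two
#' basin cells become connected through cells at or below the threshold
#' (the maximum along the lowest-cost grid path).
#'
#' @param fel a `FELGrid` (or list with `x`, `y`, `values`).
#' @param basin_a,basin_b length-2 CV coordinates of the two basins; each is
#'   snapped to the nearest grid local minimum.
#' @param depth_max report minima within this much of the global minimum
#'   (kcal/mol).
#' @return list: `minima` (data.frame x, y, value), `barrier` (kcal/mol above
#'   the shallower basin's minimum... reported as the saddle energy), and
#'   `saddle_energy` (absolute saddle height on the grid scale).
#' @export
fel_extrema <- function(fel, basin_a = NULL, basin_b = NULL, depth_max = Inf) {
  Fv <- fel$values
  nx <- nrow(Fv); ny <- ncol(Fv)
  is_min <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- pmin(pmax(1:nx + di, 1), nx)
    jj <- pmin(pmax(1:ny + dj, 1), ny)
    is_min <- is_min & (Fv <= Fv[ii, jj])
  }
  # strictness at plateaus: require strictly below at least one neighbour
  idx <- which(is_min & Fv <= min(Fv) + depth_max, arr.ind = TRUE)
  minima <- data.frame(x = fel$x[idx[, 1]], y = fel$y[idx[, 2]],
                       value = Fv[idx])
  minima <- minima[order(minima$value), , drop = FALSE]
  out <- list(minima = minima)
  if (!is.null(basin_a) && !is.null(basin_b)) {
    snap <- function(ctr) {
      if (nrow(minima) == 0) stop("no minima on grid")
      k <- which.min((minima$x - ctr[1])^2 + (minima$y - ctr[2])^2)
      c(which.min(abs(fel$x - minima$x[k])), which.min(abs(fel$y - minima$y[k])))
    }
    a <- snap(basin_a); b <- snap(basin_b)
    # minimax saddle by threshold flood fill over sorted cell energies
    ord <- order(Fv)
    lab <- matrix(0L, nx, ny)   # 0 = unfilled
    parent <- integer(0)        # union-find over component ids
    find <- function(k) { while (parent[k] != k) k <- parent[k]; k }
    comp_of <- matrix(0L, nx, ny)
    ncomp <- 0L
    saddle <- NA_real_
    for (cell in ord) {
      i <- (cell - 1) %% nx + 1; jq <- (cell - 1) %/% nx + 1
      ncomp <- ncomp + 1L
      parent[ncomp] <- ncomp
      comp_of[i, jq] <- ncomp
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di; nj <- jq + dj
        if (ni < 1 || ni > nx || nj < 1 || nj > ny) next
        cn <- comp_of[ni, nj]
        if (cn > 0L) {
          ra <- find(cn); rb <- find(comp_of[i, jq])
          if (ra != rb) parent[ra] <- rb
        }
      }
      ca <- comp_of[a[1], a[2]]; cb <- comp_of[b[1], b[2]]
      if (ca > 0L && cb > 0L && find(ca) == find(cb)) {
        saddle <- Fv[i, jq]
        break
      }
    }
    if (is.na(saddle)) stop("basins could not be connected on the grid")
    out$saddle_energy <- saddle
    out$barrier <- saddle - Fv[a[1], a[2]]
    out$barrier_from_b <- saddle - Fv[b[1], b[2]]
  }
  out
}

#' Write a FEL grid as TSV plus JSON metadata, and its hills log
#'
#' @param fel a `FELGrid`.
#' @param tsv_path grid output (x, y, free_energy).
#' @param json_path metadata output.
#' @param hills_path optional hills log (step, x, y, height).
#' @return invisibly, `tsv_path`.
#' @export
write_fel <- function(fel, tsv_path, json_path, hills_path = NULL) {
  grid <- expand.grid(x = fel$x, y = fel$y)
  grid$free_energy <- as.vector(fel$values)
  utils::write.table(grid, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(config = unclass(fel$config),
                            basin_drift = fel$basin_drift,
                            n_hills = nrow(fel$hills)),
                       json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(hills_path))
    utils::write.table(fel$hills, hills_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(tsv_path)
}
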