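# analytic surfaces and oracles shared by the metadynamics tests; the
# double wells live on the ring-puckering CV scale (wells a few tenths of
# a unit wide), the scale the default 0.1-unit Gaussians are sized for

kT_md <- 0.596  # 300 K in kcal/mol

dwell_pot <- function(a = 3, x0 = 0.45, b = 6, tilt = 0) {
  function(x, y) a * ((x / x0)^2 - 1)^2 + b * y^2 + tilt * (x / x0)
}

# basin free-energy difference by direct numerical integration of the
# Boltzmann weight over the two half-planes either side of x = split
quad_delta_f <- function(potential, xlim, ylim, split = 0, kT = kT_md,
                         n = 201) {
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  V <- outer(gx, gy, potential)
  w <- exp(-V / kT)
  left <- sum(w[gx < split, ]); right <- sum(w[gx >= split, ])
  -kT * (log(right) - log(left))
}
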