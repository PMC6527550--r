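#!/usr/bin/env Rscript
# Ring-puckering free-energy surfaces with the classical well-tempered
# metadynamics engine: a double-well surface in the (qx, qy) plane standing
# for the chair/skew-boat competition, validated against quadrature, plus
# conformer classification of the generated ligands.

library(exoegress)

out <- "results/05_puckering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
kT <- 0.596  # 300 K

# asymmetric double well on the puckering CV scale: the deeper basin plays
# the role of the chair, the shallower one the skew boat
pot <- function(x, y) 3 * ((x / 0.45)^2 - 1)^2 + 6 * y^2 + 0.7 * (x / 0.45)
fel <- run_wt_metadynamics(pot, metad_config(kT = kT, n_steps = 300000,
                                             seed = 5),
                           xlim = c(-0.95, 0.95), ylim = c(-0.6, 0.6),
                           nx = 77, ny = 49)
write_fel(fel, file.path(out, "fel.tsv"), file.path(out, "fel_meta.json"),
          file.path(out, "hills.tsv"))

dF <- fel_basin_delta(fel, c(-0.45, 0), c(0.45, 0), radius = 0.25, kT = kT)
quad <- local({
  gx <- seq(-0.95, 0.95, length.out = 201)
  gy <- seq(-0.6, 0.6, length.out = 201)
  w <- exp(-outer(gx, gy, pot) / kT)
  -kT * (log(sum(w[gx >= 0, ])) - log(sum(w[gx < 0, ])))
})
ex <- fel_extrema(fel, basin_a = c(-0.45, 0), basin_b = c(0.45, 0))
cat(sprintf("basin dF: estimated %.2f vs quadrature %.2f kcal/mol\n",
            dF, quad))
cat(sprintf("barrier from the deeper basin: %.2f kcal/mol (drift %.2f)\n",
            ex$barrier, fel$basin_drift))

# conformer classification of the generated crystallographic states
for (lab in c("4C1", "1S3")) {
  cp <- cremer_pople(ring_coords(make_ring_ligand(lab)))
  cat(sprintf("%s: Q = %.2f A, theta = %.0f, phi = %.0f -> %s\n", lab,
              cp$Q, cp$theta, cp$phi, classify_conformer(cp)))
}
cat("FEL written to", out, "\n")
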