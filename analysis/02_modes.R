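#!/usr/bin/env Rscript
# Anisotropic-network normal modes of the pocket receptor: the lowest
# non-rigid mode is the collective flap of the barrier side chains -- the
# motion that, scaled to a 2.2 A backbone displacement, opens the product
# exit corridor.

library(exoegress)

out <- "results/02_modes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pocket <- make_toy_pocket(certify = "none")
modes <- anm_modes(pocket$structure, anm_config(cutoff = 5.05, n_modes = 6))
print(modes)
cat("rigid modes:", modes$n_rigid,
    " lowest non-rigid eigenvalue:", signif(modes$eigenvalues[1], 3), "\n")
write_modeset(modes, file.path(out, "modes.tsv"),
              file.path(out, "eigenvalues.json"))

# the displaced structure used by the second-stage path search
disp <- displace_structure(pocket$structure, modes, 1, 2.2,
                           scale_by = "backbone")
bb <- pocket$structure$backbone_mask
moved <- sqrt(rowSums((coords(disp) - coords(pocket$structure))^2))
cat("max backbone displacement:", round(max(moved[bb]), 2), "A;",
    "max gate displacement:", round(max(moved[!bb]), 1), "A\n")
cat("Modes written to", out, "\n")
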