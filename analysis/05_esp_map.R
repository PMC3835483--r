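#!/usr/bin/env Rscript
# Membrane-internal ESP on the model-built cholesterol geometry: hydroxyl
# plus ring positions 2-4 face the polar head-group domain (methanol-like
# dielectric), the rest the hydrophobic core (cyclohexane-like). Two charge
# patterns are mapped: the hydroxyl-polarised "fixture-like" set (a very
# restricted assignment, hydroxyl + anchor carbon only) and a long-axis
# dipole for contrast.

suppressMessages(library(icpca))
dir.create("results", showWarnings = FALSE)

g <- cholesterol_graph()
s <- cholesterol_structure()
o <- which(g$labels == "O3")
regions <- assign_regions(g, polar_atoms = c(o, 2L, 3L, 4L),
                          eps_polar = 32.6, eps_core = 2.02)
print(regions)

pts <- sample_surface(s, scale = 1.1, density = 3)
cat("dot surface:", nrow(pts), "points\n")

for (pattern in c("fixture-like", "dipole")) {
  q <- generate_charges(g, pattern)
  esp <- esp_at_points(pts, s, q, regions, temperature = 300, clamp = 5)
  tag <- sub("-", "_", pattern)
  write_surface_esp(esp, sprintf("results/esp_%s.tsv", tag))
  write_esp_pdb(s, esp, sprintf("results/esp_%s.pdb", tag))
  i <- which.min(esp$phi); j <- which.max(esp$phi)
  cat(sprintf(
    "%s: phi in [%.2f, %.2f] kT/e; min at %s surface (%s region), max at %s\n",
    pattern, min(esp$phi, na.rm = TRUE), max(esp$phi, na.rm = TRUE),
    g$labels[esp$atom[i]], esp$region[i], g$labels[esp$atom[j]]))
}
cat("ESP maps written to results/\n")
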