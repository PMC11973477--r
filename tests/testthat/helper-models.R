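# Shared fixtures, built in code.

# Random but reproducible site-interaction model: intrinsic pKa in 2..11,
# pairwise penalties in 0..2 log units.
rand_model <- function(n, seed, ...) {
  set.seed(seed)
  p <- runif(n, 2, 11)
  eps <- matrix(0, n, n)
  eps[upper.tri(eps)] <- runif(n * (n - 1) / 2, 0, 2)
  eps <- eps + t(eps)
  site_interaction_model(p, interaction = eps, ...)
}

write_water_xyz <- function(path, charge = NULL) {
  comment <- if (is.null(charge)) "water" else sprintf("charge=%d water", charge)
  writeLines(c("3", comment,
               "O   0.000000   0.000000   0.117300",
               "H   0.000000   0.757200  -0.469200",
               "H   0.000000  -0.757200  -0.469200"), path)
  path
}

# A toy fully protonated diamine-like template: 2 N sites, each with one
# exchangeable proton, plus a C backbone. 1-based indices.
toy_template <- function() {
  atoms <- data.frame(
    element = c("N", "H", "C", "C", "N", "H", "H", "H"),
    x = c(0, 0.5, 1.2, 2.4, 3.6, 4.1, -0.5, 3.4),
    y = c(0, 0.9, 0.3, 0.8, 0.2, 1.0, -0.8, -0.9),
    z = c(0, 0, 0.1, -0.1, 0, 0.1, 0.2, 0.3))
  molecular_structure(atoms, net_charge = 2L, title = "toy diamine")
}

toy_sites <- function(s = toy_template()) {
  proton_sites(s, labels = c("N1", "N2"), heavy_atom = c(1L, 5L),
               proton_atom = c(2L, 6L),
               site_class = c("aliphatic_amine", "aliphatic_amine"))
}

# Single-state-per-charge free-energy table reproducing a given stepwise
# ladder exactly (step 1 = most basic), used to rebuild published ladders.
table_from_ladder <- function(steps, molecule = "mol",
                              tc = thermo_constants()) {
  n <- length(steps)
  GH <- proton_free_energy(tc)
  ids <- vapply(0:n, function(k)
    paste0(strrep("1", k), strrep("0", n - k)), character(1))
  G <- numeric(n + 1)
  for (k in seq_len(n)) G[k + 1] <- G[k] + GH - steps[k] * tc$RT_ln10
  free_energy_table(
    data.frame(molecule = molecule, microstate = ids,
               conformer = 1L, G = G, method = "reconstructed"),
    site_count = n, reference_charge = n)
}
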