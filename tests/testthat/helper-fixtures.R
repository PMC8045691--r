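# Shared fixtures: posterior-mean variance components reported for the
# SAWYT grain-yield analysis, used as the worked-example input throughout.
sawyt_vc <- function() {
  variance_components(
    D = 0.616, T = 0.613, V = 0.182, DV = 0.161, TV = 0.327,
    GE = 0.105, e = 0.682
  )
}

# one-breed posterior means from the same analysis
sawyt_onebreed <- c(G = 0.122, GE = 0.127, e = 0.670)

# small pedigree with two F1s from the same synthetic, so that pairs whose
# shared ancestry passes through the doubled synthetic are represented
oracle_pedigree <- function() {
  as_pedigree(rbind(
    as.data.frame(example_pedigree(3)),
    data.frame(id = "F1b", sire = "S1", dam = "V3", group = "SD")
  ))
}

# random grammar-valid pedigree for property-style tests
random_pedigree <- function(n_extra = 10, seed = 1) {
  scheme <- sim_scheme(
    n_d = 2, n_t = 2, n_v = 6, n_s = 2,
    crosses = c(f1 = 2, bc1 = 3, bc2 = 3, bc3 = 2),
    n_locations = 2, n_cycles = 2, envs_per_genotype = 2, reps = 1
  )
  simulate_pedigree(scheme, seed = seed)
}
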