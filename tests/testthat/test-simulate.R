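test_that("the default scheme reproduces the trial-template pedigree counts", {
  ped <- simulate_pedigree(sim_scheme(), seed = 1)
  expect_equal(sum(is.na(ped$sire)), 10 + 21 + 105) # pure founders
  expect_equal(sum(ped$group == "S"), 16)
  expect_length(attr(ped, "terminal"), 88)
  # founder pool = pure founders + synthetics
  expect_equal(sum(is.na(ped$sire)) + sum(ped$group == "S"), 152)
  # depth-4 schemes contain 6.25%-synthetic genotypes
  fr <- breed_fractions(ped)
  term <- fr[fr$id %in% attr(ped, "terminal"), ]
  expect_setequal(unique(100 * term$f_D), c(50, 25, 12.5, 6.25))
  expect_equal(sum(100 * term$f_D == 6.25), 7)
  # deterministic given the seed
  expect_identical(
    as.data.frame(simulate_pedigree(sim_scheme(), seed = 5)),
    as.data.frame(simulate_pedigree(sim_scheme(), seed = 5))
  )
  expect_false(identical(
    as.data.frame(simulate_pedigree(sim_scheme(), seed = 5)),
    as.data.frame(simulate_pedigree(sim_scheme(), seed = 6))
  ))
})

test_that("a depth-1 single-cross scheme yields the five-individual pedigree", {
  ped <- simulate_pedigree(
    sim_scheme(
      n_d = 1, n_t = 1, n_v = 1, n_s = 1, crosses = c(f1 = 1),
      n_locations = 1, n_cycles = 1, envs_per_genotype = 1
    ),
    seed = 1
  )
  expect_equal(nrow(ped), 5)
  expect_equal(sort(unique(ped$group)), c("D", "S", "SD", "T", "V"))
})

test_that("phenotype simulation is seeded and respects degenerate variances", {
  scheme <- sim_scheme(
    n_d = 2, n_t = 2, n_v = 4, n_s = 2, crosses = c(f1 = 3, bc1 = 3),
    n_locations = 3, n_cycles = 2, envs_per_genotype = 4, reps = 2
  )
  ped <- simulate_pedigree(scheme, seed = 2)
  # all variances zero: records equal the fixed environment effect exactly
  sim0 <- simulate_phenotypes(ped, variance_components(), scheme, seed = 3)
  expect_equal(sim0$data$value, unname(sim0$truth$env_effects[sim0$data$env]))
  # seeded rerun is identical
  vc <- variance_components(D = 0.5, T = 0.5, V = 0.2, DV = 0.1, TV = 0.2,
    GE = 0.1, e = 0.5
  )
  s1 <- simulate_phenotypes(ped, vc, scheme, seed = 4)
  s2 <- simulate_phenotypes(ped, vc, scheme, seed = 4)
  expect_identical(s1$data, s2$data)
  expect_equal(nrow(s1$data), length(attr(ped, "terminal")) * 4 * 2)
  # truth is returned on the support of each component
  expect_named(s1$truth$a, c("D", "T", "V", "DV", "TV"))
})

test_that("replicated breeding-value draws match the analytic genotypic variance", {
  ped <- example_pedigree(1)
  pk <- partial_kinship(ped)
  vc <- sawyt_vc()
  scheme <- sim_scheme(
    n_d = 1, n_t = 1, n_v = 1, n_s = 1, crosses = c(f1 = 1),
    n_locations = 1, n_cycles = 1, envs_per_genotype = 1, reps = 1
  )
  set.seed(99)
  n_rep <- 4000
  totals <- vapply(seq_len(n_rep), function(i) {
    tr <- simulate_phenotypes(pk, vc, scheme, seed = i)$truth$a
    sum(vapply(tr, function(aq) {
      if ("F1" %in% names(aq)) aq[["F1"]] else 0
    }, numeric(1)))
  }, numeric(1))
  expected <- genotypic_variance(pk, vc)$total[ped$id == "F1"]
  se <- expected * sqrt(2 / (n_rep - 1)) # SE of a normal sample variance
  expect_lt(abs(var(totals) - expected), 3 * se)
})

test_that("simulation files round-trip through the package readers", {
  scheme <- sim_scheme(
    n_d = 1, n_t = 1, n_v = 2, n_s = 1, crosses = c(f1 = 2),
    n_locations = 2, n_cycles = 1, envs_per_genotype = 2, reps = 1
  )
  ped <- simulate_pedigree(scheme, seed = 1)
  sim <- simulate_phenotypes(ped, variance_components(e = 0.5), scheme, seed = 1)
  dir <- withr::local_tempdir()
  write_simulation(sim, ped, dir)
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"), quiet = TRUE)
  phe2 <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(as.data.frame(ped2), as.data.frame(ped), ignore_attr = TRUE)
  expect_equal(phe2$value, sim$data$value)
})

test_that("gene dropping recovers the defining single-individual variances", {
  cfg <- gene_drop_config(
    n_loci = 2, p_D = 0.4, p_T = 0.3, p_V = 0.6, replicates = 4e4
  )
  ped <- tibble::tibble(
    id = c("D1", "T1", "V1", "V2"), sire = NA_character_,
    dam = NA_character_, group = c("D", "T", "V", "V")
  )
  gd <- gene_drop(ped, cfg, seed = 2)
  # founder variances are the ploidy-scaled allele-effect variances
  for (id in c("D1", "T1", "V1")) {
    i <- which(rownames(gd$empirical) == id)
    expect_lt(abs(gd$empirical[i, i] - gd$predicted[i, i]), 3 * gd$se[i, i])
  }
  expect_equal(gd$predicted["D1", "D1"], cfg$sigma2[["D"]])
  # unrelated founders: covariances are null within Monte-Carlo error
  expect_lt(abs(gd$empirical["V1", "V2"]), 3 * gd$se["V1", "V2"])
})

test_that("segregation variance appears after the F1 iff frequencies diverge", {
  ped <- example_pedigree(2)
  # diverged frequencies: BC1 variance exceeds what pure-breed weights give
  cfg <- gene_drop_config(
    n_loci = 1, p_D = 0.2, p_T = 0.2, p_V = 0.8, replicates = 6e4
  )
  expect_gt(cfg$sigma2[["DV"]], 0)
  gd <- gene_drop(ped, cfg, seed = 3)
  i_f1 <- which(rownames(gd$empirical) == "F1")
  i_bc <- which(rownames(gd$empirical) == "BC1")
  # F1 carries no segregation variance; BC1 does
  pk <- partial_kinship(ped)
  expect_equal(pk$matrices$DV["F1", "F1"], 0)
  seg_bc1 <- pk$matrices$DV["BC1", "BC1"] * cfg$sigma2[["DV"]] +
    pk$matrices$TV["BC1", "BC1"] * cfg$sigma2[["TV"]]
  additive_only <- gd$predicted[i_bc, i_bc] - seg_bc1
  expect_lt(
    abs(gd$empirical[i_bc, i_bc] - gd$predicted[i_bc, i_bc]),
    3 * gd$se[i_bc, i_bc]
  )
  expect_gt(gd$empirical[i_bc, i_bc] - additive_only, 3 * gd$se[i_bc, i_bc])

  # identical frequencies: segregation variances vanish and the BC1
  # empirical variance matches the purely additive prediction
  cfg0 <- gene_drop_config(
    n_loci = 1, p_D = 0.5, p_T = 0.5, p_V = 0.5, replicates = 6e4
  )
  expect_equal(cfg0$sigma2[["DV"]], 0)
  expect_equal(cfg0$sigma2[["TV"]], 0)
  gd0 <- gene_drop(ped, cfg0, seed = 4)
  expect_lt(
    abs(gd0$empirical[i_bc, i_bc] - gd0$predicted[i_bc, i_bc]),
    3 * gd0$se[i_bc, i_bc]
  )
})

test_that("degenerate gene-drop configurations are rejected", {
  expect_error(gene_drop_config(effects = 0), class = "swt_error_genedrop")
  expect_error(gene_drop_config(replicates = 100))
  expect_error(gene_drop_config(p_D = 0))
})
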