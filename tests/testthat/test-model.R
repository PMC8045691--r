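sim_small <- function(seed = 3, vc = variance_components(
                        D = 0.6, T = 0.6, V = 0.2, DV = 0.15, TV = 0.3,
                        GE = 0.1, e = 0.7
                      )) {
  scheme <- sim_scheme(
    n_d = 3, n_t = 3, n_v = 12, n_s = 4,
    crosses = c(f1 = 8, bc1 = 12, bc2 = 8, bc3 = 4),
    n_locations = 4, n_cycles = 2, envs_per_genotype = 6, reps = 2
  )
  ped <- simulate_pedigree(scheme, seed = seed)
  list(ped = ped, sim = simulate_phenotypes(ped, vc, scheme, seed = seed + 1))
}

test_that("with no data the variance chain samples its prior", {
  empty <- tibble::tibble(
    genotype = character(), env = character(), value = numeric()
  )
  fit <- fit_multibreed(empty, example_pedigree(2),
    prior = prior_spec(nu = 5, S2 = 3.114),
    n_iter = 4000, n_burnin = 500, seed = 11
  )
  # scaled-inv-chi2 prior mean nu S2 / (nu - 2) = 5 * 3.114 / 3
  expect_equal(
    unname(colMeans(fit$draws)),
    rep(5 * 3.114 / 3, ncol(fit$draws)),
    tolerance = 0.05
  )
  expect_true(all(fit$draws > 0))
})

test_that("chains are deterministic given a seed and draws are positive", {
  d <- sim_small()
  f1 <- fit_multibreed(d$sim$data, d$ped, n_iter = 150, n_burnin = 50, seed = 9)
  f2 <- fit_multibreed(d$sim$data, d$ped, n_iter = 150, n_burnin = 50, seed = 9)
  f3 <- fit_multibreed(d$sim$data, d$ped, n_iter = 150, n_burnin = 50, seed = 10)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$b_draws, f2$b_draws)
  expect_false(identical(f1$draws, f3$draws))
  expect_true(all(f1$draws > 0))
  expect_equal(nrow(f1$draws), 100)
})

test_that("records referencing unknown genotypes are rejected by name", {
  dat <- tibble::tibble(genotype = "NOPE", env = "E1", value = 1)
  expect_error(
    fit_multibreed(dat, example_pedigree(2), n_iter = 10, n_burnin = 1),
    regexp = "NOPE", class = "swt_error_records"
  )
})

test_that("genotypes outside a component's support get no effect column", {
  ped <- example_pedigree(2)
  dat <- tibble::tibble(
    genotype = c("D1", "D1", "BC1", "BC1"),
    env = c("E1", "E2", "E1", "E2"), value = c(1, 2, 3, 4)
  )
  fit <- fit_multibreed(dat, ped, n_iter = 220, n_burnin = 10, seed = 1)
  # a pure D founder has f_V = 0: it is not in the sampled V support
  expect_false("D1" %in% fit$support$V)
  expect_true("D1" %in% fit$support$D)
  bv <- breeding_values(fit)
  expect_equal(bv$a_V[bv$genotype == "D1"], 0)
})

test_that("a single-breed multi-breed fit equals the one-breed fit draw for draw", {
  ped <- tibble::tibble(
    id = c("P1", "P2", "X1", "X2"),
    sire = c(NA, NA, "P1", "P1"), dam = c(NA, NA, "P2", "P2"),
    group = "V"
  )
  set.seed(5)
  dat <- tidyr::expand_grid(
    genotype = c("P1", "P2", "X1", "X2"), env = c("E1", "E2")
  )
  dat$value <- rnorm(nrow(dat), 4)
  fv <- fit_multibreed(dat, ped,
    components = "V", n_iter = 400, n_burnin = 100, seed = 21
  )
  f1 <- fit_multibreed(dat, ped,
    one_breed = TRUE, n_iter = 400, n_burnin = 100, seed = 21
  )
  # on an all-V pedigree A_V is the numerator relationship matrix itself
  expect_equal(unname(fv$draws), unname(f1$draws))
  expect_equal(fv$b_draws, f1$b_draws)
})

test_that("relabelling environments permutes fixed effects, not variances", {
  d <- sim_small(seed = 8)
  dat <- d$sim$data
  swapped <- dat
  e1 <- "L01:C01"
  e2 <- "L02:C02"
  swapped$env[dat$env == e1] <- e2
  swapped$env[dat$env == e2] <- e1
  f1 <- fit_multibreed(dat, d$ped, n_iter = 900, n_burnin = 300, seed = 2)
  f2 <- fit_multibreed(swapped, d$ped, n_iter = 900, n_burnin = 300, seed = 2)
  b1 <- colMeans(f1$b_draws)
  b2 <- colMeans(f2$b_draws)
  expect_equal(b1[[e1]], b2[[e2]], tolerance = 0.15)
  expect_equal(b1[[e2]], b2[[e1]], tolerance = 0.15)
  expect_equal(colMeans(f1$draws), colMeans(f2$draws), tolerance = 0.2)
})

test_that("residual variance matches closed-form marginal posterior on one-way data", {
  # Pure-V genotypes fitted with only the D component active: no genetic
  # term touches the data, so the model reduces to y = b + ge_g + e with
  # one environment.  Under balance the marginal likelihood of
  # (s2e, s2ge) has a three-eigenvalue closed form; 2-D quadrature over it
  # is an independent oracle for the posterior mean of sigma2_e.
  set.seed(31)
  G <- 8
  r <- 6
  nu <- 5
  S2 <- 0.5
  K <- 1e8
  ped <- tibble::tibble(
    id = paste0("V", 1:G), sire = NA_character_, dam = NA_character_,
    group = "V"
  )
  dat <- tibble::tibble(
    genotype = rep(ped$id, each = r), env = "E1",
    value = rep(rnorm(G, 0, sqrt(0.3)), each = r) + rnorm(G * r, 2, 0.8)
  )
  y <- dat$value
  n <- G * r
  ssw <- sum((y - ave(y, dat$genotype))^2)
  gm <- tapply(y, dat$genotype, mean)
  ssb <- r * sum((gm - mean(y))^2)
  loglik <- function(s2e, s2ge) {
    l1 <- s2e # within-genotype contrasts, n - G of them
    l2 <- s2e + r * s2ge # between-genotype contrasts, G - 1
    l3 <- s2e + r * s2ge + n * 2 * K # intercept + env column both hit the mean
    -0.5 * ((n - G) * log(l1) + (G - 1) * log(l2) + log(l3) +
      ssw / l1 + ssb / l2 + n * mean(y)^2 / l3)
  }
  lprior <- function(s2, nu, S2) {
    -(nu / 2 + 1) * log(s2) - nu * S2 / (2 * s2)
  }
  grid_e <- seq(0.2, 2.5, length.out = 180)
  grid_g <- seq(0.01, 3, length.out = 180)
  lp <- outer(grid_e, grid_g, function(a, b) {
    mapply(function(x, z) loglik(x, z) + lprior(x, nu, S2) + lprior(z, nu, S2),
      a, b
    )
  })
  w <- exp(lp - max(lp))
  oracle_mean_e <- sum(w * grid_e) / sum(w)

  fit <- fit_multibreed(dat, ped,
    components = "D", prior = prior_spec(nu = nu, S2 = S2, K = K),
    n_iter = 4000, n_burnin = 1000, seed = 13
  )
  draws_e <- fit$draws[, "e"]
  mc_se <- sd(draws_e) / sqrt(synwheat:::ess_draws(draws_e))
  expect_lt(abs(mean(draws_e) - oracle_mean_e), 3 * mc_se + 0.01)
})

test_that("posterior summaries report mean, SD and shortest HPD intervals", {
  expect_equal(
    hpd_interval(rep(3, 500)), c(lower = 3, upper = 3)
  )
  set.seed(1)
  z <- rnorm(1e5)
  h <- hpd_interval(z)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  # skewed draws: HPD is strictly narrower than the equal-tail interval
  x <- rexp(2e4)
  h <- hpd_interval(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(diff(unname(h)), unname(q[2] - q[1]))

  d <- sim_small()
  fit <- fit_multibreed(d$sim$data, d$ped, n_iter = 300, n_burnin = 50, seed = 3)
  ps <- posterior_summary(fit)
  expect_named(
    ps, c("component", "nu", "S2", "mean", "sd", "hpd_lower", "hpd_upper")
  )
  expect_equal(ps$component, c("e", "GE", "D", "T", "V", "DV", "TV"))
  expect_true(all(ps$hpd_lower <= ps$mean & ps$mean <= ps$hpd_upper))
  expect_identical(tidy(fit), ps)
  expect_error(
    posterior_summary(
      fit_multibreed(d$sim$data, d$ped, n_iter = 60, n_burnin = 10, seed = 3)
    ),
    class = "swt_error_settings"
  )
})

test_that("breeding values recompose as the sum of origin components", {
  d <- sim_small()
  fit <- fit_multibreed(d$sim$data, d$ped, n_iter = 400, n_burnin = 100, seed = 6)
  bv <- breeding_values(fit)
  expect_equal(
    bv$total,
    rowSums(as.matrix(bv[, paste0("a_", c("D", "T", "V", "DV", "TV"))]))
  )
  # more data per genotype sharpens the prediction of the true totals
  truth <- d$sim$truth$a
  tot_true <- sapply(bv$genotype, function(g) {
    sum(sapply(names(truth), function(q) {
      if (g %in% names(truth[[q]])) truth[[q]][[g]] else 0
    }))
  })
  obs <- bv$genotype %in% d$sim$terminal
  expect_gt(cor(bv$total[obs], tot_true[obs]), 0.3)
})

test_that("glance reports chain health", {
  d <- sim_small()
  fit <- fit_multibreed(d$sim$data, d$ped, n_iter = 300, n_burnin = 50, seed = 3)
  g <- glance(fit)
  expect_equal(g$n_records, nrow(d$sim$data))
  expect_equal(g$n_draws, 250)
  expect_gt(g$min_ess, 0)
})

test_that("invalid chain settings and priors are rejected", {
  d <- sim_small()
  expect_error(
    fit_multibreed(d$sim$data, d$ped, n_iter = 10, n_burnin = 20),
    class = "swt_error_settings"
  )
  expect_error(prior_spec(K = 10), class = "swt_error_prior")
  expect_error(
    fit_multibreed(d$sim$data, d$ped,
      prior = prior_spec(S2 = c(e = 1, GE = 1)), n_iter = 10, n_burnin = 1
    ),
    class = "swt_error_prior"
  )
})
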