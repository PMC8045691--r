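#' Simulation scheme for a synthetic-derivative breeding program
#'
#' Describes the crossing and trial structure the pedigree/phenotype
#' generator emulates: counts of pure founders, number of doubled
#' synthetics, number of terminal crosses at each backcross depth, and
#' the location-by-cycle trial grid.  The defaults reproduce the SAWYT
#' template: 10 diploid, 21 tetraploid and 105 hexaploid founders, 16
#' synthetics, and 88 terminal crosses (12 F1, 45 BC1, 24 BC2, 7 BC3);
#' trials run in an unbalanced grid where each terminal genotype is
#' observed in a random subset of environments with two replicates per
#' cell (incomplete-block yield trials with two replicates).
#'
#' @param n_d,n_t,n_v Numbers of D, T and V founders.
#' @param n_s Number of synthetic (S) lines.
#' @param crosses Named integer vector: terminal crosses per depth,
#'   names among `f1`, `bc1`, `bc2`, `bc3` (depth at most the 6.25%
#'   synthetic BC3).
#' @param n_locations,n_cycles Trial grid dimensions; environments are
#'   location-cycle combinations.
#' @param envs_per_genotype Environments in which each terminal genotype
#'   is observed (drawn at random without replacement), at most
#'   `n_locations * n_cycles`.
#' @param reps Records per observed genotype-environment cell.
#' @return A list of class `swt_scheme`.
#' @export
sim_scheme <- function(n_d = 10, n_t = 21, n_v = 105, n_s = 16,
                       crosses = c(f1 = 12, bc1 = 45, bc2 = 24, bc3 = 7),
                       n_locations = 20, n_cycles = 5,
                       envs_per_genotype = 25, reps = 2) {
  stopifnot(
    n_d >= 1, n_t >= 1, n_v >= 1, n_s >= 1,
    all(names(crosses) %in% c("f1", "bc1", "bc2", "bc3")),
    all(crosses >= 0), sum(crosses) >= 1,
    n_locations >= 1, n_cycles >= 1, reps >= 1,
    envs_per_genotype >= 1, envs_per_genotype <= n_locations * n_cycles
  )
  structure(
    list(
      n_d = n_d, n_t = n_t, n_v = n_v, n_s = n_s, crosses = crosses,
      n_locations = n_locations, n_cycles = n_cycles,
      envs_per_genotype = envs_per_genotype, reps = reps
    ),
    class = "swt_scheme"
  )
}

#' Simulate a grammar-valid synthetic-wheat pedigree
#'
#' Builds the crossing structure of the breeding scheme: D x T hybrids
#' doubled into synthetics, F1 = S x V, and successive backcrosses to
#' fresh pure V lines.  Founders are unrelated and non-inbred.  Each
#' terminal backcross gets its own chain of intermediate crosses;
#' parents for every cross are drawn at random from the founder pools.
#' Terminal (phenotyped) genotypes are recorded in the `terminal`
#' attribute.
#'
#' @param scheme A [sim_scheme()].
#' @param seed Integer seed.
#' @return A validated pedigree with attribute `terminal` (ids of the
#'   terminal crosses).
#' @export
simulate_pedigree <- function(scheme = sim_scheme(), seed = 1) {
  stopifnot(inherits(scheme, "swt_scheme"))
  set.seed(seed)
  d_ids <- sprintf("D%03d", seq_len(scheme$n_d))
  t_ids <- sprintf("T%03d", seq_len(scheme$n_t))
  v_ids <- sprintf("V%03d", seq_len(scheme$n_v))
  s_ids <- sprintf("S%03d", seq_len(scheme$n_s))

  rows <- list()
  add <- function(id, sire, dam, group) {
    rows[[length(rows) + 1L]] <<- c(id, sire, dam, group)
  }
  for (id in d_ids) add(id, NA, NA, "D")
  for (id in t_ids) add(id, NA, NA, "T")
  for (id in v_ids) add(id, NA, NA, "V")
  for (i in seq_len(scheme$n_s)) {
    add(s_ids[i], sample(d_ids, 1), sample(t_ids, 1), "S")
  }

  terminal <- character()
  counter <- 0L
  depths <- c(f1 = 0L, bc1 = 1L, bc2 = 2L, bc3 = 3L)
  for (type in names(scheme$crosses)) {
    for (k in seq_len(scheme$crosses[[type]])) {
      counter <- counter + 1L
      prev <- sample(s_ids, 1)
      depth <- depths[[type]]
      # F1 then `depth` backcrosses; only the last node is terminal
      for (g in 0:depth) {
        id <- if (g == depth) {
          sprintf("X%03d", counter)
        } else {
          sprintf("X%03d.%d", counter, g)
        }
        add(id, sample(v_ids, 1), prev, "SD")
        prev <- id
      }
      terminal <- c(terminal, prev)
    }
  }
  m <- do.call(rbind, rows)
  ped <- as_pedigree(tibble(
    id = m[, 1], sire = m[, 2], dam = m[, 3], group = m[, 4]
  ))
  attr(ped, "terminal") <- terminal
  ped
}

#' Simulate phenotypes from the multi-breed mixed model
#'
#' Generates trait records under the same generative model the sampler
#' fits: breeding values `a_Q ~ N(0, A_Q sigma2_Q)` on each component
#' support, iid genotype-by-environment effects, Gaussian residuals, and
#' fixed environment effects drawn once from
#' `N(env_mean, env_sd^2)` over the location-by-cycle grid.  Defaults for
#' the environment level emulate dryland wheat yield trials (mean 4 t/ha
#' across environments, between-environment spread 1 t/ha).
#'
#' @param ped Pedigree (or [partial_kinship()] object); terminal
#'   genotypes taken from its `terminal` attribute, or all `SD`
#'   individuals when absent.
#' @param vc True [variance_components()].
#' @param scheme A [sim_scheme()] providing the trial grid.
#' @param seed Integer seed.
#' @param env_mean,env_sd Mean and spread of the fixed environment
#'   effects (trait units).
#' @return A list of class `swt_sim`: `data` (tibble `genotype`,
#'   `location`, `cycle`, `env`, `value`), `truth` (list with `vc`, the
#'   drawn effect vectors `a` per component, `env_effects`, `ge`), and
#'   `terminal`.
#' @export
simulate_phenotypes <- function(ped, vc, scheme = sim_scheme(), seed = 1,
                                env_mean = 4, env_sd = 1) {
  pk <- if (inherits(ped, "swt_kinship")) ped else partial_kinship(ped)
  vc <- as_varcomp(vc)
  set.seed(seed)
  terminal <- attr(pk$pedigree, "terminal") %||%
    pk$pedigree$id[pk$pedigree$group == "SD"]
  stopifnot(length(terminal) >= 1)

  a <- lapply(KIN_COMPONENTS, function(q) {
    sup <- pk$support[[q]]
    out <- stats::setNames(numeric(length(sup)), sup)
    if (length(sup) > 0 && vc[[q]] > 0) {
      A <- pk$matrices[[q]][sup, sup, drop = FALSE]
      ch <- tryCatch(chol(A), error = function(e) {
        chol(A + diag(1e-8 * mean(diag(A)), nrow(A)))
      })
      out[] <- drop(crossprod(ch, stats::rnorm(length(sup)))) * sqrt(vc[[q]])
    }
    out
  })
  names(a) <- KIN_COMPONENTS

  envs <- expand.grid(
    location = sprintf("L%02d", seq_len(scheme$n_locations)),
    cycle = sprintf("C%02d", seq_len(scheme$n_cycles)),
    stringsAsFactors = FALSE
  )
  env_eff <- stats::rnorm(nrow(envs), env_mean, env_sd)
  names(env_eff) <- paste(envs$location, envs$cycle, sep = ":")

  recs <- purrr::map_dfr(terminal, function(g) {
    pick <- sample(nrow(envs), scheme$envs_per_genotype)
    tibble(
      genotype = g,
      location = rep(envs$location[pick], each = scheme$reps),
      cycle = rep(envs$cycle[pick], each = scheme$reps)
    )
  })
  recs$env <- paste(recs$location, recs$cycle, sep = ":")

  gval <- vapply(recs$genotype, function(g) {
    sum(vapply(KIN_COMPONENTS, function(q) {
      if (g %in% names(a[[q]])) a[[q]][[g]] else 0
    }, numeric(1)))
  }, numeric(1))

  cells <- unique(paste(recs$genotype, recs$env, sep = "\r"))
  ge <- stats::setNames(
    stats::rnorm(length(cells), 0, sqrt(vc[["GE"]])), cells
  )
  recs$value <- unname(
    env_eff[recs$env] + gval +
      ge[paste(recs$genotype, recs$env, sep = "\r")] +
      stats::rnorm(nrow(recs), 0, sqrt(vc[["e"]]))
  )

  structure(
    list(
      data = recs,
      truth = list(vc = vc, a = a, env_effects = env_eff, ge = ge),
      terminal = terminal
    ),
    class = "swt_sim"
  )
}

#' Configuration for the gene-dropping oracle
#'
#' The oracle simulates unlinked biallelic loci on each of the three
#' subgenome lineages (the D lineage shared by D, S, V and derivatives;
#' the two T lineages shared by T, S, V and derivatives).  Founder
#' alleles are Bernoulli draws with breed-specific frequencies; each
#' locus has an additive effect size.  Differences in allele frequency
#' between breeds generate segregation variance.
#'
#' Analytic component variances implied by the configuration (used to
#' scale the tabular predictions):
#' `sigma2_D = 2 sum_l a_l^2 p_D q_D`, `sigma2_T = 4 sum_l a_l^2 p_T q_T`,
#' `sigma2_V = 6 sum_l a_l^2 p_V q_V`,
#' `sigma2_DV = 1/2 sum_l a_l^2 (p_D - p_V)^2`,
#' `sigma2_TV = 1/2 sum_l a_l^2 (p_T - p_V)^2`
#' (per-subgenome locus sets share frequencies and effects).
#'
#' @param n_loci Unlinked biallelic loci per subgenome.
#' @param p_D,p_T,p_V Allele frequencies per breed (scalar or length
#'   `n_loci`), strictly inside (0, 1).
#' @param effects Additive effect size per locus (scalar or length
#'   `n_loci`).
#' @param replicates Monte-Carlo replicates (>= 1e4).
#' @return A list of class `swt_gdconfig` with the analytic variances in
#'   `$sigma2`.
#' @export
gene_drop_config <- function(n_loci = 2, p_D = 0.5, p_T = 0.3, p_V = 0.7,
                             effects = 1, replicates = 1e4) {
  rec <- function(x) rep_len(as.numeric(x), n_loci)
  p_D <- rec(p_D)
  p_T <- rec(p_T)
  p_V <- rec(p_V)
  effects <- rec(effects)
  stopifnot(
    n_loci >= 1, replicates >= 1e4,
    all(p_D > 0 & p_D < 1), all(p_T > 0 & p_T < 1), all(p_V > 0 & p_V < 1)
  )
  if (all(effects == 0)) {
    abort("all locus effects are zero: degenerate configuration",
      class = "swt_error_genedrop"
    )
  }
  a2 <- effects^2
  sigma2 <- c(
    D = 2 * sum(a2 * p_D * (1 - p_D)),
    T = 4 * sum(a2 * p_T * (1 - p_T)),
    V = 6 * sum(a2 * p_V * (1 - p_V)),
    DV = 0.5 * sum(a2 * (p_D - p_V)^2),
    TV = 0.5 * sum(a2 * (p_T - p_V)^2)
  )
  structure(
    list(
      n_loci = n_loci, p_D = p_D, p_T = p_T, p_V = p_V,
      effects = effects, replicates = as.integer(replicates),
      sigma2 = sigma2
    ),
    class = "swt_gdconfig"
  )
}

# subgenome lineages present per breed group: 1 = D lineage, 2:3 = T lineages
subgenomes_of <- function(group) {
  switch(group,
    D = 1L, T = 2:3, V = 1:3, S = 1:3, SD = 1:3
  )
}

#' Gene-dropping Monte-Carlo oracle for relationship coefficients
#'
#' Drops founder alleles down the pedigree, treating each allopolyploid
#' subgenome as an independent diploid; chromosome doubling at a
#' synthetic node is implemented literally (the transmitted gamete is
#' copied, so the two within-subgenome copies are identical).  Returns
#' the empirical covariance matrix of genotypic values across replicates
#' together with the covariances predicted from [partial_kinship()]
#' weighted by the configuration's analytic component variances, under
#' both scoring rules for the synthetic diagonal (`purebred` tabular rule
#' and literal `doubled` copies); entries whose ancestry passes through
#' the doubled copies of a synthetic are flagged, since there the two
#' rules genuinely differ and literal doubling follows the `doubled`
#' variant.
#'
#' @param ped A pedigree (small: the oracle is quadratic in individuals
#'   and linear in replicates).
#' @param config A [gene_drop_config()].
#' @param seed Integer seed.
#' @param chunk Replicates per vectorized chunk.
#' @return A list of class `swt_genedrop`: `empirical` and `se`
#'   (matrices), `predicted` and `predicted_doubled`, `report` (tidy
#'   per-pair tibble with z-scores under both rules and an `s_affected`
#'   flag), and `config`.
#' @export
gene_drop <- function(ped, config = gene_drop_config(), seed = 1,
                      chunk = 1e5) {
  ped <- as_pedigree(ped)
  stopifnot(inherits(config, "swt_gdconfig"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  L <- config$n_loci
  R <- config$replicates
  set.seed(seed)

  freq_of <- function(group, sg) {
    if (sg == 1L) {
      switch(group, D = config$p_D, V = config$p_V,
        abort("internal: lineage-1 founder must be D or V")
      )
    } else {
      switch(group, T = config$p_T, V = config$p_V,
        abort("internal: lineage-2/3 founder must be T or V")
      )
    }
  }

  G <- matrix(0, R, n, dimnames = list(NULL, ped$id))
  done <- 0L
  while (done < R) {
    m <- min(chunk, R - done)
    # alleles[[i]][[sg]] = list(h1, h2): m x L 0/1 matrices
    alleles <- vector("list", n)
    gv <- matrix(0, m, n)
    for (i in seq_len(n)) {
      g <- ped$group[i]
      sgs <- subgenomes_of(g)
      al <- list()
      for (sg in sgs) {
        if (si[i] == 0L) {
          p <- freq_of(g, sg)
          h1 <- matrix(stats::rbinom(m * L, 1L, rep(p, each = m)), m, L)
          h2 <- matrix(stats::rbinom(m * L, 1L, rep(p, each = m)), m, L)
        } else if (g == "S") {
          # one gamete from whichever parent carries this lineage, doubled
          par <- if (sg == 1L) {
            if (ped$group[si[i]] == "D") si[i] else di[i]
          } else {
            if (ped$group[si[i]] == "T") si[i] else di[i]
          }
          h1 <- gamete(alleles[[par]][[as.character(sg)]], m, L)
          h2 <- h1
        } else {
          h1 <- gamete(alleles[[si[i]]][[as.character(sg)]], m, L)
          h2 <- gamete(alleles[[di[i]]][[as.character(sg)]], m, L)
        }
        al[[as.character(sg)]] <- list(h1 = h1, h2 = h2)
        gv[, i] <- gv[, i] + (h1 + h2) %*% config$effects
      }
      alleles[[i]] <- al
    }
    G[done + seq_len(m), ] <- gv
    done <- done + m
  }

  emp <- stats::cov(G)
  ctr <- sweep(G, 2, colMeans(G))
  se <- matrix(0, n, n, dimnames = dimnames(emp))
  for (i in seq_len(n)) {
    prod <- ctr * ctr[, i]
    se[, i] <- apply(prod, 2, stats::sd) / sqrt(R)
  }

  pred_of <- function(rule) {
    pk <- partial_kinship(ped, s_diag = rule)
    Reduce(`+`, lapply(KIN_COMPONENTS, function(q) {
      pk$matrices[[q]] * config$sigma2[[q]]
    }))
  }
  pred <- pred_of("purebred")
  pred_dbl <- pred_of("doubled")

  pairs <- which(lower.tri(emp, diag = TRUE), arr.ind = TRUE)
  report <- tibble(
    id1 = ped$id[pairs[, 1]], id2 = ped$id[pairs[, 2]],
    empirical = emp[pairs], se = se[pairs],
    predicted = pred[pairs], predicted_doubled = pred_dbl[pairs],
    s_affected = pred[pairs] != pred_dbl[pairs]
  )
  report$z <- (report$empirical - report$predicted) / report$se
  report$z_doubled <- (report$empirical - report$predicted_doubled) / report$se

  structure(
    list(
      empirical = emp, se = se, predicted = pred,
      predicted_doubled = pred_dbl, report = report, config = config
    ),
    class = "swt_genedrop"
  )
}

# one gamete per replicate per locus from a diploid {h1, h2} pair
gamete <- function(hap, m, L) {
  pick <- matrix(stats::runif(m * L) < 0.5, m, L)
  out <- hap$h1
  out[pick] <- hap$h2[pick]
  out
}

#' @export
print.swt_genedrop <- function(x, ...) {
  rep <- x$report
  plain <- rep[!rep$s_affected, ]
  cat(
    "Gene-dropping oracle:", x$config$replicates, "replicates,",
    nrow(rep), "pairs\n",
    " max |z| (tabular-rule pairs):", round(max(abs(plain$z)), 2), "\n",
    " S-affected pairs:", sum(rep$s_affected),
    "(compare z vs z_doubled in $report)\n"
  )
  invisible(x)
}

#' @method tidy swt_genedrop
#' @export
tidy.swt_genedrop <- function(x, ...) x$report

#' Write simulated data in the package's file dialects
#'
#' @param sim A [simulate_phenotypes()] result.
#' @param ped The pedigree it was simulated from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, ped, dir) {
  stopifnot(inherits(sim, "swt_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(ped, file.path(dir, "pedigree.csv"))
  readr::write_csv(
    sim$data[, c("genotype", "location", "cycle", "value")],
    file.path(dir, "phenotypes.csv"),
    progress = FALSE
  )
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
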