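# Phenotype records: genotype, environment (= location:cycle), trait value.
normalize_records <- function(data, require_value = TRUE) {
  data <- as_tibble(data)
  if (!"genotype" %in% names(data)) {
    abort("phenotype data must have a 'genotype' column",
      class = "swt_error_records"
    )
  }
  if (!"env" %in% names(data)) {
    if (!all(c("location", "cycle") %in% names(data))) {
      abort("phenotype data must have 'env' or 'location' + 'cycle' columns",
        class = "swt_error_records"
      )
    }
    data$env <- paste(data$location, data$cycle, sep = ":")
  }
  data$genotype <- as.character(data$genotype)
  data$env <- as.character(data$env)
  if (require_value) {
    if (!"value" %in% names(data)) {
      abort("phenotype data must have a 'value' column",
        class = "swt_error_records"
      )
    }
    drop <- !is.finite(data$value)
    if (any(drop)) {
      inform(paste0("dropping ", sum(drop), " record(s) with missing value"))
      data <- data[!drop, ]
    }
  }
  data[, intersect(c("genotype", "env", "value"), names(data))]
}

#' Read a phenotype file
#'
#' Delimited text (comma or tab autodetected) with header
#' `genotype,location,cycle,value`; the environment id is formed as
#' `location:cycle`.  A pre-formed `env` column is also accepted in place
#' of `location` and `cycle`.
#'
#' @param path Path to the phenotype file.
#' @return Tibble with columns `genotype`, `env`, `value`.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, progress = FALSE,
    show_col_types = FALSE
  )
  normalize_records(dat)
}

#' Prior specification for the variance components
#'
#' Every variance component receives a scaled inverse chi-squared prior
#' with degrees of freedom `nu` and scale `S2`; the fixed environment
#' effects receive a proper Normal prior with large diagonal variance `K`
#' (rather than a flat prior, which would make the posterior improper
#' under the over-parameterized intercept-plus-all-environments design).
#'
#' When `S2` is `NULL` it is derived from the data at fit time: the
#' phenotypic variance is partitioned equally across the model's variance
#' components and `S2` is set so that the prior mode `nu S2 / (nu + 2)`
#' equals each component's share.
#'
#' @param nu Prior degrees of freedom (scalar or named vector), > 0.
#' @param S2 Prior scale (scalar, named vector, or `NULL` for the
#'   data-derived default), > 0.
#' @param K Fixed-effect prior variance, > 1e7.
#' @return A list of class `swt_prior`.
#' @export
prior_spec <- function(nu = 5, S2 = NULL, K = 1e8) {
  stopifnot(all(nu > 0), is.null(S2) || all(S2 > 0))
  if (K <= 1e7) {
    abort("fixed-effect prior variance K must exceed 1e7",
      class = "swt_error_prior"
    )
  }
  structure(list(nu = nu, S2 = S2, K = K), class = "swt_prior")
}

resolve_prior <- function(prior, comp_names, y) {
  k <- length(comp_names)
  expand <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1 && is.null(names(x))) {
      return(stats::setNames(rep(as.numeric(x), k), comp_names))
    }
    miss <- setdiff(comp_names, names(x))
    if (length(miss) > 0) {
      abort(paste0("prior value missing for: ", paste(miss, collapse = ", ")),
        class = "swt_error_prior"
      )
    }
    stats::setNames(as.numeric(x[comp_names]), comp_names)
  }
  nu <- expand(prior$nu, 5)
  if (is.null(prior$S2)) {
    if (length(y) < 2) {
      abort("cannot derive default prior scales without data; supply S2",
        class = "swt_error_prior"
      )
    }
    share <- stats::var(y) / k
    S2 <- stats::setNames(share * (nu + 2) / nu, comp_names)
  } else {
    S2 <- expand(prior$S2, NULL)
  }
  list(nu = nu, S2 = S2, K = prior$K)
}

# Eigen-form Gaussian block sampler.  For an effect u with likelihood
# contribution N(Zu, I sigma2_e) (Z an incidence with column counts d > 0)
# and prior N(0, G sigma2_u), the full conditional is
# N(C^-1 Z'r / sigma2_e, C^-1) with C = D/sigma2_e + G^-1/sigma2_u.
# Writing M = D^-1/2 G^-1 D^-1/2 = U L U' (computed once), draws cost two
# dense matrix-vector products per iteration instead of a Cholesky.
make_eigen_block <- function(d, Ginv) {
  dh <- sqrt(d)
  M <- t(Ginv / dh) / dh
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(
    d = d, dh = dh, U = eg$vectors, lambda = pmax(eg$values, 0),
    Ginv = Ginv
  )
}

draw_eigen_block <- function(blk, ztr, s2e, s2u) {
  w <- 1 / (1 / s2e + blk$lambda / s2u)
  t1 <- crossprod(blk$U, ztr / (blk$dh * s2e))
  mu <- blk$U %*% (w * t1)
  z <- stats::rnorm(length(blk$d))
  drop(mu + blk$U %*% (sqrt(w) * z)) / blk$dh
}

# Scaled inverse chi-squared full-conditional draw:
# sigma2 | . ~ ScInvChi2(nu + q, (quad + nu S2) / (nu + q)).
draw_scinvchi2 <- function(nu, S2, q, quad) {
  (quad + nu * S2) / stats::rchisq(1, df = nu + q)
}

build_design <- function(data, pk, comp_names) {
  data <- normalize_records(data)
  ped_ids <- pk$pedigree$id
  bad <- setdiff(unique(data$genotype), ped_ids)
  if (length(bad) > 0) {
    abort(
      paste0(
        "genotype(s) absent from pedigree: ",
        paste(bad, collapse = ", ")
      ),
      class = "swt_error_records"
    )
  }
  n <- nrow(data)
  env <- factor(data$env, levels = unique(data$env))
  obs_geno <- unique(data$genotype)

  comps <- lapply(comp_names, function(q) {
    sup <- if (q == "onebreed") ped_ids else pk$support[[q]]
    obs <- intersect(sup, obs_geno)
    unobs <- setdiff(sup, obs)
    map <- match(data$genotype, obs) # NA where record not in this component
    list(q = q, obs = obs, unobs = unobs, map = map)
  })
  names(comps) <- comp_names

  cell <- factor(
    paste(data$genotype, data$env, sep = "\r"),
    levels = unique(paste(data$genotype, data$env, sep = "\r"))
  )
  list(
    data = data, y = data$value, n = n, env = env,
    comps = comps, cell = cell
  )
}

# Submatrix inverse with a logged ridge fallback when the factorization
# fails on a numerically singular support block.
safe_inverse <- function(A, label) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * mean(diag(A))
    warn(paste0(
      "relationship block ", label,
      " is numerically singular; adding ridge ", format(ridge)
    ))
    ch <- chol(A + diag(ridge, nrow(A)))
  }
  chol2inv(ch)
}

#' Fit the multi-breed hierarchical Bayesian mixed model
#'
#' Gibbs sampler for the mixed model
#' `y = X b + sum_Q Z_Q a_Q + Z_GE ge + e`, where `b` holds fixed
#' environment (location-by-cycle) effects with a proper `N(0, K)` prior,
#' each `a_Q ~ N(0, A_Q sigma2_Q)` is the vector of breeding values of
#' origin `Q` on the support of the partial relationship matrix `A_Q`,
#' `ge ~ N(0, I sigma2_GE)` is the iid genotype-by-environment
#' interaction over observed genotype-environment cells, and
#' `e ~ N(0, I sigma2_e)`.  All variance components carry scaled inverse
#' chi-squared priors; every full conditional is conjugate (Normal for
#' location blocks, scaled inverse chi-squared for variances) and blocks
#' are updated jointly via the mixed-model-equations system.
#'
#' Breeding values of pedigree members in a component's support that have
#' no phenotype records do not enter the likelihood; the chain samples the
#' phenotyped subset (the marginal model is identical) and their posterior
#' means are recovered from the conditional expectation given the sampled
#' relatives.
#'
#' @param data Phenotype records: columns `genotype`, `value` and `env`
#'   (or `location` + `cycle`).
#' @param pedigree A pedigree, or a precomputed [partial_kinship()]
#'   object.
#' @param components Genetic components to include, a subset of
#'   `c("D", "T", "V", "DV", "TV")`, or `"onebreed"` for the
#'   homogeneous-variance model on the classical numerator relationship
#'   matrix.
#' @param one_breed Shorthand for `components = "onebreed"`.
#' @param prior A [prior_spec()].
#' @param n_iter Total chain length (default 20000).
#' @param n_burnin Discarded iterations (default 10000).
#' @param thin Thinning interval.
#' @param seed Integer seed; identical inputs and seed give identical
#'   chains.
#' @param store_effects Keep per-draw breeding-value samples (memory
#'   heavy); posterior means are always accumulated.
#' @return An object of class `swt_fit` with elements `draws` (matrix of
#'   retained variance-component draws), `b_draws`, `blup` (posterior-mean
#'   breeding values, see [breeding_values()]), `prior`, `settings`,
#'   `support` and, if requested, `effect_draws`.
#' @seealso [posterior_summary()], [breeding_values()], [autoplot.swt_fit()]
#' @export
fit_multibreed <- function(data, pedigree,
                           components = c("D", "T", "V", "DV", "TV"),
                           one_breed = FALSE,
                           prior = prior_spec(),
                           n_iter = 20000, n_burnin = 10000, thin = 1,
                           seed = 1, store_effects = FALSE) {
  if (one_breed) components <- "onebreed"
  stopifnot(all(components %in% c(KIN_COMPONENTS, "onebreed")))
  if (!(n_iter > n_burnin && n_burnin >= 0 && thin >= 1)) {
    abort("need n_iter > n_burnin >= 0 and thin >= 1",
      class = "swt_error_settings"
    )
  }
  pk <- if (inherits(pedigree, "swt_kinship")) {
    pedigree
  } else {
    partial_kinship(pedigree)
  }

  data <- normalize_records(data)
  has_data <- nrow(data) > 0
  vc_names <- c("e", "GE", components)

  if (has_data) {
    dsg <- build_design(data, pk, components)
    y <- dsg$y
    n <- dsg$n
    env <- dsg$env
    p_env <- nlevels(env)
    env_i <- as.integer(env)
    # X = [1 | env indicators]; X'X is constant, so draw b in eigen form too
    cnts <- tabulate(env_i, p_env)
    XtX <- rbind(
      c(n, cnts),
      cbind(cnts, diag(cnts, nrow = p_env))
    )
    eg_b <- eigen(XtX, symmetric = TRUE)
    Ub <- eg_b$vectors
    lb <- pmax(eg_b$values, 0)

    cell_i <- as.integer(dsg$cell)
    n_cell <- nlevels(dsg$cell)
    d_cell <- tabulate(cell_i, n_cell)

    blocks <- lapply(dsg$comps, function(cm) {
      if (length(cm$obs) == 0) {
        return(NULL)
      }
      Aq <- pk$matrices[[cm$q]]
      Aoo <- Aq[cm$obs, cm$obs, drop = FALSE]
      Ainv <- safe_inverse(Aoo, paste0("A_", cm$q))
      d <- tabulate(cm$map[!is.na(cm$map)], length(cm$obs))
      blk <- make_eigen_block(d, Ainv)
      blk$map <- cm$map
      blk$obs <- cm$obs
      blk$unobs <- cm$unobs
      if (length(cm$unobs) > 0) {
        blk$P <- Aq[cm$unobs, cm$obs, drop = FALSE] %*% Ainv
      }
      blk
    })
  } else {
    dsg <- NULL
    blocks <- list()
  }
  pr <- resolve_prior(prior, vc_names, if (has_data) data$value else numeric())

  n_keep <- floor((n_iter - n_burnin) / thin)
  if (n_keep < 1) abort("no retained draws", class = "swt_error_settings")
  draws <- matrix(NA_real_, n_keep, length(vc_names),
    dimnames = list(NULL, vc_names)
  )
  b_draws <- if (has_data) {
    matrix(NA_real_, n_keep, 1 + p_env,
      dimnames = list(NULL, c("(Intercept)", levels(env)))
    )
  } else {
    NULL
  }
  effect_draws <- if (store_effects) {
    lapply(blocks, function(blk) {
      if (is.null(blk)) NULL else matrix(NA_real_, n_keep, length(blk$obs))
    })
  } else {
    NULL
  }

  set.seed(seed)
  s2 <- stats::setNames(pr$S2, vc_names) # initialize at prior scale
  if (has_data) {
    b <- numeric(1 + p_env)
    a <- lapply(blocks, function(blk) {
      if (is.null(blk)) numeric() else numeric(length(blk$obs))
    })
    ge <- numeric(n_cell)
    fit_b <- numeric(n)
    fit_a <- lapply(blocks, function(blk) numeric(n))
    fit_ge <- numeric(n)
    blup_acc <- lapply(blocks, function(blk) {
      if (is.null(blk)) {
        NULL
      } else {
        numeric(length(blk$obs) + length(blk$unobs))
      }
    })
  }
  kept <- 0L

  for (it in seq_len(n_iter)) {
    if (has_data) {
      resid <- y - fit_b - Reduce(`+`, fit_a, numeric(n)) - fit_ge

      # fixed environment effects
      r <- resid + fit_b
      Xtr <- c(sum(r), rowsum_vec(r, env_i, p_env))
      w <- 1 / ((lb + s2[["e"]] / pr$K) / s2[["e"]])
      t1 <- crossprod(Ub, Xtr / s2[["e"]])
      b <- drop(Ub %*% (w * t1 + sqrt(w) * stats::rnorm(length(t1))))
      fit_b <- b[1] + b[1 + env_i]
      resid <- r - fit_b

      # breeding values by origin
      for (qn in names(blocks)) {
        blk <- blocks[[qn]]
        if (is.null(blk)) next
        in_q <- !is.na(blk$map)
        r <- resid + fit_a[[qn]]
        ztr <- rowsum_vec(r[in_q], blk$map[in_q], length(blk$obs))
        a[[qn]] <- draw_eigen_block(blk, ztr, s2[["e"]], s2[[qn]])
        fit_a[[qn]] <- ifelse(in_q, a[[qn]][blk$map], 0)
        fit_a[[qn]][!in_q] <- 0
        resid <- r - fit_a[[qn]]
      }

      # genotype x environment cells (diagonal system)
      r <- resid + fit_ge
      ztr <- rowsum_vec(r, cell_i, n_cell)
      cvar <- 1 / (d_cell / s2[["e"]] + 1 / s2[["GE"]])
      ge <- ztr / s2[["e"]] * cvar + sqrt(cvar) * stats::rnorm(n_cell)
      fit_ge <- ge[cell_i]
      resid <- r - fit_ge

      s2[["e"]] <- draw_scinvchi2(
        pr$nu[["e"]], pr$S2[["e"]], n, sum(resid^2)
      )
      s2[["GE"]] <- draw_scinvchi2(
        pr$nu[["GE"]], pr$S2[["GE"]], n_cell, sum(ge^2)
      )
      for (qn in names(blocks)) {
        blk <- blocks[[qn]]
        if (is.null(blk)) {
          s2[[qn]] <- draw_scinvchi2(pr$nu[[qn]], pr$S2[[qn]], 0, 0)
          next
        }
        wa <- blk$dh * a[[qn]]
        t1 <- crossprod(blk$U, wa)
        quad <- sum(blk$lambda * t1^2)
        s2[[qn]] <- draw_scinvchi2(
          pr$nu[[qn]], pr$S2[[qn]], length(blk$obs), quad
        )
      }
    } else {
      for (qn in vc_names) {
        s2[[qn]] <- draw_scinvchi2(pr$nu[[qn]], pr$S2[[qn]], 0, 0)
      }
    }

    if (any(!is.finite(s2)) || any(s2 > 1e12)) {
      abort(
        paste0(
          "divergent chain at iteration ", it, ": ",
          paste(vc_names, signif(s2, 3), sep = "=", collapse = ", ")
        ),
        class = "swt_error_divergent"
      )
    }

    if (it > n_burnin && (it - n_burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- s2
      if (has_data) {
        b_draws[kept, ] <- b
        for (qn in names(blocks)) {
          blk <- blocks[[qn]]
          if (is.null(blk)) next
          full <- if (length(blk$unobs) > 0) {
            c(a[[qn]], drop(blk$P %*% a[[qn]]))
          } else {
            a[[qn]]
          }
          blup_acc[[qn]] <- blup_acc[[qn]] + full
          if (store_effects) effect_draws[[qn]][kept, ] <- a[[qn]]
        }
      }
    }
  }

  blup <- NULL
  if (has_data) {
    ped_ids <- pk$pedigree$id
    bv <- matrix(0, length(ped_ids), length(components),
      dimnames = list(ped_ids, components)
    )
    for (qn in names(blocks)) {
      blk <- blocks[[qn]]
      if (is.null(blk)) next
      bv[c(blk$obs, blk$unobs), qn] <- blup_acc[[qn]] / n_keep
    }
    blup <- tibble(genotype = ped_ids)
    for (qn in components) blup[[paste0("a_", qn)]] <- unname(bv[, qn])
    blup$total <- unname(rowSums(bv))
  }

  structure(
    list(
      draws = draws, b_draws = b_draws, blup = blup,
      effect_draws = effect_draws,
      components = components, prior = pr,
      settings = list(
        n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
        n_records = if (has_data) dsg$n else 0L
      ),
      support = if (has_data) {
        lapply(blocks, function(blk) if (is.null(blk)) character() else blk$obs)
      } else {
        list()
      },
      data = data
    ),
    class = "swt_fit"
  )
}

rowsum_vec <- function(x, idx, nbin) {
  drop(rowsum(x, factor(idx, levels = seq_len(nbin)), reorder = FALSE))
}

#' @export
print.swt_fit <- function(x, ...) {
  cat(
    "Multi-breed Gibbs fit:", paste(x$components, collapse = ", "),
    "\n  records:", x$settings$n_records,
    "  retained draws:", nrow(x$draws), "\n"
  )
  print(posterior_summary(x), n = Inf)
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest empirical interval containing a given fraction of the draws.
#'
#' @param x Numeric vector of MCMC draws.
#' @param prob Coverage probability (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) {
    return(c(lower = x[1], upper = x[n]))
  }
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Posterior summary of the variance components
#'
#' @param fit An [fit_multibreed()] object.
#' @param prob HPD coverage (default 0.95).
#' @return Tibble with columns `component`, `nu`, `S2`, `mean`, `sd`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "swt_fit"))
  if (nrow(fit$draws) < 200) {
    abort("need at least 200 retained draws for a posterior summary",
      class = "swt_error_settings"
    )
  }
  purrr::map_dfr(colnames(fit$draws), function(cn) {
    x <- fit$draws[, cn]
    h <- hpd_interval(x, prob)
    tibble(
      component = cn,
      nu = fit$prior$nu[[cn]], S2 = fit$prior$S2[[cn]],
      mean = mean(x), sd = stats::sd(x),
      hpd_lower = h[["lower"]], hpd_upper = h[["upper"]]
    )
  })
}

#' @rdname posterior_summary
#' @param x An `swt_fit` object.
#' @param ... Unused.
#' @method tidy swt_fit
#' @export
tidy.swt_fit <- function(x, ...) posterior_summary(x, ...)

#' Fit-level diagnostics
#'
#' One-row summary: record and genotype counts, chain settings and the
#' minimum effective sample size across variance components (initial
#' positive sequence estimator on the retained draws).
#'
#' @param x An `swt_fit` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance swt_fit
#' @export
glance.swt_fit <- function(x, ...) {
  ess <- apply(x$draws, 2, ess_draws)
  tibble(
    n_records = x$settings$n_records,
    n_genotypes = if (is.null(x$data)) 0L else {
      dplyr::n_distinct(x$data$genotype)
    },
    n_draws = nrow(x$draws),
    n_iter = x$settings$n_iter,
    n_burnin = x$settings$n_burnin,
    min_ess = min(ess)
  )
}

ess_draws <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) {
    return(n)
  }
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' Posterior-mean breeding values by breed of origin
#'
#' Per genotype, the posterior mean of each origin-specific breeding-value
#' component in the fit, plus their sum (`total`), which recomposes the
#' genotype's overall breeding value.  Pedigree members outside a
#' component's support carry 0 in that column.
#'
#' @param fit An [fit_multibreed()] object fitted with data.
#' @return Tibble with columns `genotype`, one `a_<Q>` column per fitted
#'   component, and `total`.
#' @export
breeding_values <- function(fit) {
  stopifnot(inherits(fit, "swt_fit"))
  if (is.null(fit$blup)) {
    abort("fit has no data records, so no breeding values",
      class = "swt_error_records"
    )
  }
  fit$blup
}
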