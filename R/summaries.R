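CROSS_TYPES <- c("F1", "BC1", "BC2", "BC3")

#' Per-cross-type variance decomposition
#'
#' Evaluates the additive, segregation and total additive genetic variance
#' of the canonical synthetic-derivative cross types (F1 = SHW x V and the
#' first three backcrosses to V, i.e. 50, 25, 12.5 and 6.25 percent
#' synthetic genome), given a set of variance components.  The
#' representative individual of each cross type is non-inbred with
#' unrelated parents ([example_pedigree()]), so the additive part is
#' `f_D sigma2_D + f_T sigma2_T + f_V sigma2_V` and the segregation part
#' uses the Table-style coefficients of the crossbred parent.
#'
#' @param vc Variance components (the genetic five are required; `GE` and
#'   `e` are needed only when `heritability = TRUE`).
#' @param cross_types Subset of `c("F1", "BC1", "BC2", "BC3")`.
#' @param heritability Add the narrow-sense heritability column (requires
#'   `GE` and `e` in `vc`).
#' @param replication Optional [replication_summary()]; when supplied, a
#'   line-mean repeatability column is added.
#' @return Tibble with one row per cross type: `cross`, `pct_synthetic`,
#'   `additive`, `segregation`, `total` and optionally `h2_narrow`,
#'   `repeatability`.
#' @examples
#' vc <- variance_components(
#'   D = 0.616, T = 0.613, V = 0.182,
#'   DV = 0.161, TV = 0.327, GE = 0.105, e = 0.682
#' )
#' group_variances(vc)
#' @export
group_variances <- function(vc, cross_types = CROSS_TYPES,
                            heritability = TRUE, replication = NULL) {
  vc <- as_varcomp(vc)
  bad <- setdiff(cross_types, CROSS_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown cross type(s): ", paste(bad, collapse = ", ")),
      class = "swt_error_cross_type"
    )
  }
  gv <- genotypic_variance(example_pedigree(depth = 4), vc)
  reps <- stats::setNames(c("F1", "BC1", "BC2", "BC3"), CROSS_TYPES)
  out <- gv[match(reps[cross_types], gv$id), ]
  res <- tibble(
    cross = cross_types,
    pct_synthetic = 100 * breed_fractions(example_pedigree(4))$f_D[
      match(reps[cross_types], example_pedigree(4)$id)
    ],
    additive = out$additive,
    segregation = out$segregation,
    total = out$total
  )
  if (heritability) {
    res$h2_narrow <- narrow_sense_h2(res$total, vc[["GE"]], vc[["e"]])
  }
  if (!is.null(replication)) {
    res$repeatability <- line_mean_repeatability(
      res$total, vc[["GE"]], vc[["e"]], replication
    )
  }
  res
}

#' Narrow-sense heritability
#'
#' Ratio of total additive variance to phenotypic variance on a
#' single-plot basis: `sigma2_A / (sigma2_A + sigma2_GE + sigma2_e)`.
#' The plot basis (no division of the interaction and residual terms by
#' replication numbers) is used deliberately: replication-adjusted
#' divisors belong to the line-mean repeatability
#' ([line_mean_repeatability()]), not to the narrow-sense ratio.
#'
#' @param total_additive Total additive variance (additive + segregation).
#' @param sigma2_GE Genotype-by-environment variance.
#' @param sigma2_e Residual variance.
#' @return Heritability in `[0, 1]`, vectorized over `total_additive`.
#' @export
narrow_sense_h2 <- function(total_additive, sigma2_GE, sigma2_e) {
  check_nonneg(total_additive, sigma2_GE, sigma2_e)
  denom <- total_additive + sigma2_GE + sigma2_e
  if (any(denom == 0)) {
    abort("phenotypic variance is zero", class = "swt_error_zero_denominator")
  }
  total_additive / denom
}

#' Line-mean repeatability
#'
#' Repeatability (broad-sense heritability on a line-mean basis):
#' `sigma2_A / (sigma2_A + sigma2_GE / yl + sigma2_e / (yl b))`, where
#' `yl` is the average number of year-location cells per genotype and `b`
#' the average number of replicates per cell, both taken from a
#' [replication_summary()].
#'
#' @inheritParams narrow_sense_h2
#' @param replication A [replication_summary()] (or any list with `yl`
#'   and `b`).
#' @return Repeatability in `[0, 1]`, vectorized over `total_additive`.
#' @export
line_mean_repeatability <- function(total_additive, sigma2_GE, sigma2_e,
                                    replication) {
  check_nonneg(total_additive, sigma2_GE, sigma2_e)
  yl <- replication$yl
  b <- replication$b
  stopifnot(yl > 0, b > 0)
  denom <- total_additive + sigma2_GE / yl + sigma2_e / (yl * b)
  if (any(denom == 0)) {
    abort("zero denominator", class = "swt_error_zero_denominator")
  }
  total_additive / denom
}

check_nonneg <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("variance inputs must be finite and non-negative",
      class = "swt_error_varcomp"
    )
  }
  invisible(NULL)
}

#' Replication structure of a trial data set
#'
#' Summarizes how often genotypes were replicated: `n` total records,
#' `n_G` genotypes, `n_GYL` genotype-by-environment (year-location) cells,
#' and the derived averages `yl = n_GYL / n_G` (cells per genotype) and
#' `b = n / n_GYL` (replicates per cell) used by
#' [line_mean_repeatability()].
#'
#' @param data Phenotype data frame with columns `genotype` and either
#'   `env` or `location` + `cycle`.
#' @return A one-row tibble of class `swt_replication` with columns `n`,
#'   `n_G`, `n_GYL`, `yl`, `b`.
#' @export
replication_summary <- function(data) {
  data <- normalize_records(data, require_value = FALSE)
  n <- nrow(data)
  n_g <- dplyr::n_distinct(data$genotype)
  n_gyl <- dplyr::n_distinct(paste(data$genotype, data$env, sep = "\r"))
  structure(
    tibble(n = n, n_G = n_g, n_GYL = n_gyl, yl = n_gyl / n_g, b = n / n_gyl),
    class = c("swt_replication", class(tibble()))
  )
}

#' Pearson correlation between two breeding-value columns
#'
#' Joins two breeding-value tables on genotype and returns the Pearson
#' correlation of the chosen columns over the shared genotypes, e.g. to
#' compare the sum-by-origin multi-breed prediction with the one-breed
#' prediction.
#'
#' @param x,y Data frames with a `genotype` column, or numeric vectors of
#'   equal length.
#' @param column Column to compare when `x`, `y` are data frames
#'   (default `"total"`).
#' @return Pearson correlation coefficient (length-1 numeric).
#' @export
compare_blups <- function(x, y, column = "total") {
  if (is.data.frame(x)) {
    j <- dplyr::inner_join(
      x[, c("genotype", column)], y[, c("genotype", column)],
      by = "genotype", suffix = c("_x", "_y")
    )
    xv <- j[[paste0(column, "_x")]]
    yv <- j[[paste0(column, "_y")]]
  } else {
    xv <- x
    yv <- y
  }
  if (length(xv) < 3) {
    abort("need at least 3 shared genotypes", class = "swt_error_blup_compare")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort("constant breeding-value column", class = "swt_error_blup_compare")
  }
  stats::cor(xv, yv)
}
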