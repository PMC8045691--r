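KIN_COMPONENTS <- c("D", "T", "V", "DV", "TV")

#' Partial numerator relationship matrices
#'
#' Builds, by a single pass of the tabular method over the topologically
#' ordered pedigree, the five partial numerator relationship matrices
#' `A_Q`, `Q in {D, T, V, DV, TV}`, that decompose the additive genetic
#' covariance among individuals by breed of origin (`D`, `T`, `V`) and by
#' segregation term (`DV`, `TV`), plus the classical one-breed numerator
#' relationship matrix `A` used by the homogeneous-variance comparison
#' model.  The covariance between breeding values is then
#' `Cov(G_i, G_i') = sum_Q a_Q(i, i') * sigma2_Q`.
#'
#' Off-diagonals follow the purebred recursion applied component-wise:
#' `a_Q(i, i') = (a_Q(sire_i, i') + a_Q(dam_i, i')) / 2`, with unknown
#' parents contributing 0.  Diagonals:
#' * pure founder / pure line of breed `Q`: `a_Q(i,i) = 1 + F_i^Q`, zero in
#'   every other component;
#' * synthetic `S` node: `a_D(i,i) = 1 + F_i^D`, `a_T(i,i) = 1 + F_i^T`,
#'   zero in `V` and the segregation components (the doubled copies are
#'   scored at the purebred rate; see `s_diag` below);
#' * other non-founders: `a_Q(i,i) = f_i^Q + a_Q(sire, dam) / 2` for the
#'   pure-breed components, and for the segregation components
#'   `a_DV(i,i) = 2 (f_s^D f_s^V + f_d^D f_d^V) + a_DV(sire, dam) / 2`,
#'   `a_TV(i,i) = 4 (f_s^T f_s^V + f_d^T f_d^V) + a_TV(sire, dam) / 2`,
#'   where `s`, `d` index the sire and dam.  The segregation weights sum
#'   over both parents; for a parent that is itself purebred or synthetic
#'   the product `f^D f^V` (or `f^T f^V`) vanishes, so in a backcross to a
#'   pure V line only the crossbred parent contributes, recovering the
#'   single-parent textbook rule.  The `a_seg(sire, dam)/2` carry-over
#'   keeps the component-wise recursion exact when the parents are
#'   related; it is zero for crosses between unrelated parents.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @param s_diag How to score the doubled allele copies on the D and T
#'   diagonals of a synthetic `S` node.  `"purebred"` (default) treats the
#'   two copies within each subgenome like the two alleles of a
#'   non-inbred purebred, giving `a_D(S,S) = 1 + F^D`.  `"doubled"` treats
#'   the copies as identical by descent (which is what literal chromosome
#'   doubling produces), giving `a_D(S,S) = 2 (1 + F^D)` and doubling the
#'   synthetic's D and T covariances with every other individual (its
#'   gamete is deterministic); gene-dropping ([gene_drop()]) reproduces
#'   this variant,
#'   not the default.  The default follows the standard tabular rules;
#'   the discrepancy is surfaced, not resolved, by the oracle report.
#' @return An object of class `swt_kinship`: a list with elements
#'   `matrices` (named list `D`, `T`, `V`, `DV`, `TV`, `onebreed` of
#'   symmetric matrices with id dimnames), `support` (named list of id
#'   vectors with nonzero diagonal per component), `fractions` (the
#'   [breed_fractions()] tibble), `inbreeding` (tibble of `F_D`, `F_T`,
#'   `F_V` per individual) and `pedigree`.
#' @examples
#' ped <- example_pedigree(depth = 1)
#' pk <- partial_kinship(ped)
#' diag(pk$matrices$DV)
#' @export
partial_kinship <- function(ped, s_diag = c("purebred", "doubled")) {
  ped <- as_pedigree(ped)
  s_diag <- match.arg(s_diag)
  fr <- breed_fractions(ped)
  n <- nrow(ped)
  ids <- ped$id
  idx <- stats::setNames(seq_len(n), ids)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  f <- as.matrix(fr[, c("f_D", "f_T", "f_V")])

  A <- lapply(c(KIN_COMPONENTS, "onebreed"), function(q) {
    matrix(0, n, n, dimnames = list(ids, ids))
  })
  names(A) <- c(KIN_COMPONENTS, "onebreed")
  Fpb <- matrix(0, n, 3, dimnames = list(ids, c("F_D", "F_T", "F_V")))

  parent_a <- function(M, s, d) if (s == 0L) 0 else M[s, d]

  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    g <- ped$group[i]
    founder <- s == 0L
    if (!founder && i > 1L) {
      j <- seq_len(i - 1L)
      for (q in names(A)) {
        # literal doubling makes the S gamete deterministic, doubling the
        # synthetic's own D/T covariances with everyone else
        mult <- if (s_diag == "doubled" && g == "S" && q %in% c("D", "T")) {
          2
        } else {
          1
        }
        A[[q]][i, j] <- mult * (A[[q]][s, j] + A[[q]][d, j]) / 2
        A[[q]][j, i] <- A[[q]][i, j]
      }
    }
    # within-breed inbreeding from the parents' partial relationship
    if (!founder) {
      Fpb[i, ] <- c(A$D[s, d], A$T[s, d], A$V[s, d]) / 2
    }
    if (g %in% PURE_BREEDS) {
      A[[g]][i, i] <- 1 + Fpb[i, paste0("F_", g)]
    } else if (g == "S") {
      dbl <- if (s_diag == "doubled") 2 else 1
      A$D[i, i] <- dbl * (1 + Fpb[i, "F_D"])
      A$T[i, i] <- dbl * (1 + Fpb[i, "F_T"])
    } else {
      carry <- vapply(KIN_COMPONENTS, function(q) parent_a(A[[q]], s, d),
        numeric(1)
      )
      A$D[i, i] <- f[i, "f_D"] + carry[["D"]] / 2
      A$T[i, i] <- f[i, "f_T"] + carry[["T"]] / 2
      A$V[i, i] <- f[i, "f_V"] + carry[["V"]] / 2
      A$DV[i, i] <- 2 * (f[s, "f_D"] * f[s, "f_V"] +
        f[d, "f_D"] * f[d, "f_V"]) + carry[["DV"]] / 2
      A$TV[i, i] <- 4 * (f[s, "f_T"] * f[s, "f_V"] +
        f[d, "f_T"] * f[d, "f_V"]) + carry[["TV"]] / 2
    }
    A$onebreed[i, i] <- 1 + parent_a(A$onebreed, s, d) / 2
  }

  support <- lapply(A[KIN_COMPONENTS], function(M) ids[diag(M) > 0])
  structure(
    list(
      matrices = A, support = support, fractions = fr,
      inbreeding = tibble(
        id = ids, group = ped$group,
        F_D = unname(Fpb[, 1]), F_T = unname(Fpb[, 2]),
        F_V = unname(Fpb[, 3])
      ),
      pedigree = ped
    ),
    class = "swt_kinship"
  )
}

#' @export
print.swt_kinship <- function(x, ...) {
  cat("Partial numerator relationship matrices for", nrow(x$pedigree),
    "individuals\n"
  )
  for (q in KIN_COMPONENTS) {
    cat(sprintf("  A_%-3s support: %d individuals\n", q, length(x$support[[q]])))
  }
  invisible(x)
}

#' Tidy a kinship object into sparse triplets
#'
#' @param x A [partial_kinship()] object.
#' @param ... Unused.
#' @return Tibble with columns `component`, `row`, `col`, `value`
#'   (lower triangle, nonzero entries only).
#' @method tidy swt_kinship
#' @export
tidy.swt_kinship <- function(x, ...) {
  purrr::map_dfr(names(x$matrices), function(q) {
    M <- x$matrices[[q]]
    keep <- which(lower.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    tibble(
      component = q,
      row = rownames(M)[keep[, 1]],
      col = colnames(M)[keep[, 2]],
      value = M[keep]
    )
  })
}

#' Construct a set of variance components
#'
#' Container for the seven dispersion parameters of the multi-breed model:
#' pure-breed additive variances (`D`, `T`, `V`), segregation variances
#' (`DV`, `TV`), genotype-by-environment variance (`GE`) and residual
#' variance (`e`), all in squared trait units.
#'
#' @param D,T,V Pure-breed additive variances.
#' @param DV,TV Segregation variances.
#' @param GE Genotype-by-environment interaction variance.
#' @param e Residual variance.
#' @return Named numeric vector of class `swt_varcomp`.
#' @export
variance_components <- function(D = 0, T = 0, V = 0, DV = 0, TV = 0,
                                GE = 0, e = 0) {
  vc <- c(D = D, T = T, V = V, DV = DV, TV = TV, GE = GE, e = e)
  if (any(!is.finite(vc)) || any(vc < 0)) {
    abort("variance components must be finite and non-negative",
      class = "swt_error_varcomp"
    )
  }
  structure(vc, class = "swt_varcomp")
}

as_varcomp <- function(vc) {
  if (inherits(vc, "swt_varcomp")) {
    return(vc)
  }
  vc <- unlist(vc)
  miss <- setdiff(c("D", "T", "V", "DV", "TV"), names(vc))
  if (length(miss) > 0) {
    abort(paste0(
      "missing variance component(s): ",
      paste(miss, collapse = ", ")
    ), class = "swt_error_varcomp")
  }
  do.call(variance_components, as.list(vc[intersect(
    c("D", "T", "V", "DV", "TV", "GE", "e"), names(vc)
  )]))
}

#' Genotypic variance of each individual
#'
#' Evaluates, for every individual, the weights its genotypic variance
#' places on each dispersion parameter: the additive part
#' `a_D(i,i) sigma2_D + a_T(i,i) sigma2_T + a_V(i,i) sigma2_V` (which for
#' pure and synthetic lines reduces to the `(1 + F)` purebred forms), the
#' segregation part `a_DV(i,i) sigma2_DV + a_TV(i,i) sigma2_TV`, and their
#' total.
#'
#' @param ped A pedigree or a [partial_kinship()] object.
#' @param vc Variance components ([variance_components()] or named vector).
#' @return Tibble with columns `id`, `group`, `additive`, `segregation`,
#'   `total` plus the five diagonal weights `a_D` ... `a_TV`.
#' @export
genotypic_variance <- function(ped, vc) {
  pk <- if (inherits(ped, "swt_kinship")) ped else partial_kinship(ped)
  vc <- as_varcomp(vc)
  w <- vapply(KIN_COMPONENTS, function(q) diag(pk$matrices[[q]]),
    numeric(nrow(pk$pedigree))
  )
  additive <- unname(drop(
    w[, c("D", "T", "V"), drop = FALSE] %*% vc[c("D", "T", "V")]
  ))
  segregation <- unname(drop(
    w[, c("DV", "TV"), drop = FALSE] %*% vc[c("DV", "TV")]
  ))
  tibble(
    id = pk$pedigree$id, group = pk$pedigree$group,
    additive = additive, segregation = segregation,
    total = additive + segregation,
    a_D = unname(w[, "D"]), a_T = unname(w[, "T"]), a_V = unname(w[, "V"]),
    a_DV = unname(w[, "DV"]), a_TV = unname(w[, "TV"])
  )
}

#' Write and read relationship matrices as sparse triplet text
#'
#' One file per component (`A_D.txt`, `A_T.txt`, `A_V.txt`, `A_DV.txt`,
#' `A_TV.txt`, `A_onebreed.txt`) plus `ids.txt` holding the pedigree
#' order.  Each matrix file holds the nonzero lower triangle as
#' tab-separated `row-id  col-id  value` with full floating precision, so
#' a round trip is bitwise exact.
#'
#' @param pk A [partial_kinship()] object.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (writer); a named list of matrices (reader).
#' @export
write_kinship <- function(pk, dir) {
  stopifnot(inherits(pk, "swt_kinship"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(rownames(pk$matrices[[1]]), file.path(dir, "ids.txt"))
  for (q in names(pk$matrices)) {
    M <- pk$matrices[[q]]
    keep <- which(lower.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    lines <- sprintf(
      "%s\t%s\t%.17g",
      rownames(M)[keep[, 1]], colnames(M)[keep[, 2]], M[keep]
    )
    writeLines(lines, file.path(dir, paste0("A_", q, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(dir) {
  ids <- readLines(file.path(dir, "ids.txt"))
  n <- length(ids)
  files <- list.files(dir, pattern = "^A_.*\\.txt$")
  out <- lapply(files, function(fn) {
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    path <- file.path(dir, fn)
    if (file.size(path) > 0) {
      tr <- utils::read.table(path,
        sep = "\t", colClasses = c("character", "character", "numeric"),
        col.names = c("row", "col", "value")
      )
      bad <- setdiff(unique(c(tr$row, tr$col)), ids)
      if (length(bad) > 0) {
        abort(
          paste0(
            "triplet id(s) absent from ids.txt in ", fn, ": ",
            paste(bad, collapse = ", ")
          ),
          class = "swt_error_triplet"
        )
      }
      upper <- match(tr$row, ids) < match(tr$col, ids)
      if (any(upper)) {
        abort(paste0("triplet entries above the diagonal in ", fn),
          class = "swt_error_triplet"
        )
      }
      M[cbind(tr$row, tr$col)] <- tr$value
      M[cbind(tr$col, tr$row)] <- tr$value
    }
    M
  })
  names(out) <- sub("^A_(.*)\\.txt$", "\\1", files)
  out[intersect(c(KIN_COMPONENTS, "onebreed"), names(out))]
}

#' Canonical pedigree of the synthetic-derivative crossing scheme
#'
#' Builds the textbook pedigree used throughout: unrelated non-inbred
#' founders `D1`, `T1`, the doubled synthetic `S1 = D1 x T1`, the F1
#' `S1 x V1`, and `depth` successive backcrosses to fresh unrelated pure
#' V lines (depth 1 gives the 25% synthetic BC1, up to depth 4).
#'
#' @param depth Number of generations past the synthetic: 1 = F1 only,
#'   2 = up to BC1, ..., 4 = up to BC3 (6.25% synthetic).
#' @return A pedigree tibble; the terminal cross is the last row.
#' @export
example_pedigree <- function(depth = 4) {
  stopifnot(depth >= 1, depth <= 4)
  rows <- list(
    c("D1", NA, NA, "D"), c("T1", NA, NA, "T"),
    c("S1", "D1", "T1", "S"), c("V1", NA, NA, "V"),
    c("F1", "S1", "V1", "SD")
  )
  prev <- "F1"
  if (depth >= 2) {
    for (g in seq_len(depth - 1)) {
      vid <- paste0("V", g + 1)
      bid <- paste0("BC", g)
      rows <- c(rows, list(c(vid, NA, NA, "V"), c(bid, vid, prev, "SD")))
      prev <- bid
    }
  }
  m <- do.call(rbind, rows)
  as_pedigree(tibble(
    id = m[, 1], sire = m[, 2], dam = m[, 3], group = m[, 4]
  ))
}
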