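#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Breed-group labels and the number of independent subgenomes each carries.
# D = Ae. tauschii (diploid, genome DD), T = T. turgidum (tetraploid, AABB),
# V = T. aestivum (hexaploid, AABBDD), S = synthetic hexaploid wheat (doubled
# D x T hybrid), SD = synthetic derivative (S x V and backcrosses to V).
BREED_GROUPS <- c("D", "T", "V", "S", "SD")
PLOIDY_GENOMES <- c(D = 1L, T = 2L, V = 3L, S = 3L, SD = 3L)
PURE_BREEDS <- c("D", "T", "V")

#' Validate and topologically order a wheat pedigree
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` and `group`.
#' `group` must be one of `D`, `T`, `V` (pure breeds), `S` (synthetic
#' hexaploid wheat, a doubled D x T hybrid) or `SD` (synthetic derivative,
#' i.e. S x V and successive backcrosses to V).  Unknown parents are coded
#' `NA`, the empty string or `"0"` and are only allowed for founders (both
#' parents unknown); founders must be pure-breed.  Selfing (`sire == dam`)
#' is permitted, as wheat lines are routinely selfed.
#'
#' The crossing grammar is enforced, never inferred from parents:
#' * `D`, `T`, `V` offspring require both parents of the same pure breed;
#' * `S` requires one `D` parent and one `T` parent;
#' * `SD` requires one `V` parent and one `S` or `SD` parent.
#'
#' Rows are reordered so that parents always precede offspring (stable
#' Kahn's algorithm; ties broken by input order, so matrix layouts built
#' from the ordered pedigree are reproducible).
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`, `group`.
#' @return A tibble of class `swt_pedigree` with character columns `id`,
#'   `sire`, `dam` (`NA` for unknown) and `group`, in topological order.
#' @examples
#' ped <- tibble::tribble(
#'   ~id,  ~sire, ~dam, ~group,
#'   "S1", "D1",  "T1", "S",
#'   "D1", NA,    NA,   "D",
#'   "T1", NA,    NA,   "T",
#'   "V1", NA,    NA,   "V",
#'   "F1", "S1",  "V1", "SD"
#' )
#' as_pedigree(ped)
#' @export
as_pedigree <- function(ped) {
  if (inherits(ped, "swt_pedigree")) {
    return(ped)
  }
  ped <- as_tibble(ped)
  required <- c("id", "sire", "dam", "group")
  if (!all(required %in% names(ped))) {
    abort(
      paste0(
        "pedigree must have columns id, sire, dam, group; missing: ",
        paste(setdiff(required, names(ped)), collapse = ", ")
      ),
      class = "swt_error_columns"
    )
  }
  ped <- dplyr::mutate(
    ped[required],
    dplyr::across(dplyr::everything(), ~ trimws(as.character(.x)))
  )
  ped$sire[ped$sire %in% c("", "0")] <- NA_character_
  ped$dam[ped$dam %in% c("", "0")] <- NA_character_

  if (anyNA(ped$id) || any(ped$id %in% c("", "0"))) {
    abort("individual ids must be non-missing and not '0'",
      class = "swt_error_bad_id"
    )
  }
  dup <- unique(ped$id[duplicated(ped$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate individual id(s): ", paste(dup, collapse = ", ")),
      class = "swt_error_duplicate_id"
    )
  }
  bad_group <- setdiff(unique(ped$group), BREED_GROUPS)
  if (length(bad_group) > 0) {
    abort(
      paste0(
        "unknown breed group label(s): ", paste(bad_group, collapse = ", "),
        " (expected D, T, V, S or SD)"
      ),
      class = "swt_error_unknown_group"
    )
  }

  known_sire <- !is.na(ped$sire)
  known_dam <- !is.na(ped$dam)
  partial <- xor(known_sire, known_dam)
  if (any(partial)) {
    abort(
      paste0(
        "individual(s) with exactly one known parent: ",
        paste(ped$id[partial], collapse = ", "),
        "; parents must be both known or both unknown"
      ),
      class = "swt_error_partial_parentage"
    )
  }
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  missing_parent <- setdiff(parents, ped$id)
  if (length(missing_parent) > 0) {
    abort(
      paste0(
        "parent id(s) absent from pedigree: ",
        paste(missing_parent, collapse = ", ")
      ),
      class = "swt_error_missing_parent"
    )
  }

  is_founder <- !known_sire
  bad_founder <- is_founder & !(ped$group %in% PURE_BREEDS)
  if (any(bad_founder)) {
    abort(
      paste0(
        "founder(s) must be pure-breed (D, T or V): ",
        paste(ped$id[bad_founder], collapse = ", ")
      ),
      class = "swt_error_grammar"
    )
  }

  # crossing grammar for non-founders
  grp <- stats::setNames(ped$group, ped$id)
  for (i in which(!is_founder)) {
    pg <- sort(c(grp[[ped$sire[i]]], grp[[ped$dam[i]]]))
    g <- ped$group[i]
    ok <- switch(g,
      D = identical(pg, c("D", "D")),
      T = identical(pg, c("T", "T")),
      V = identical(pg, c("V", "V")),
      S = identical(pg, c("D", "T")),
      SD = identical(pg, c("S", "V")) || identical(pg, c("SD", "V"))
    )
    if (!ok) {
      abort(
        paste0(
          "breed-grammar violation at '", ped$id[i], "': group ", g,
          " cannot arise from parents of group ", pg[1], " x ", pg[2]
        ),
        class = "swt_error_grammar"
      )
    }
  }

  ped <- topo_order(ped)
  class(ped) <- c("swt_pedigree", class(ped))
  ped
}

# Stable Kahn topological sort; ties broken by input order.  Reports a cycle
# path when the pedigree is not acyclic.
topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  repeat {
    ready <- which(!placed &
      (si == 0L | placed[pmax(si, 1L)]) &
      (di == 0L | placed[pmax(di, 1L)]))
    if (length(ready) == 0) break
    order_out[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
  }
  if (k < n) {
    stuck <- ped$id[!placed]
    # walk parent links among the stuck set to exhibit one cycle
    path <- stuck[1]
    cur <- stuck[1]
    repeat {
      i <- idx[cur]
      nxt <- if (!is.na(ped$sire[i]) && ped$sire[i] %in% stuck) {
        ped$sire[i]
      } else {
        ped$dam[i]
      }
      if (nxt %in% path) {
        path <- c(path[which(path == nxt):length(path)], nxt)
        break
      }
      path <- c(path, nxt)
      cur <- nxt
    }
    abort(
      paste0(
        "pedigree contains a cycle: ",
        paste(rev(path), collapse = " -> ")
      ),
      class = "swt_error_cycle"
    )
  }
  ped[order_out, ]
}

#' Read a pedigree file
#'
#' Reads a delimited text file (comma or tab, autodetected) with header
#' `id,sire,dam,group`, validates it and returns it in topological order.
#' Unknown parents may be encoded as an empty field or `"0"`.
#'
#' @param path Path to the pedigree file.
#' @param quiet If `FALSE` (default), report counts per breed group.
#' @return A validated [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path, quiet = FALSE) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  ped <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  ped <- as_pedigree(ped)
  if (!quiet) {
    counts <- table(factor(ped$group, levels = BREED_GROUPS))
    inform(paste0(
      "pedigree: ", nrow(ped), " individuals (",
      paste(names(counts), counts, sep = "=", collapse = ", "), ")"
    ))
  }
  ped
}

#' Write a pedigree file
#'
#' Writes the comma-delimited dialect accepted by [read_pedigree()]; unknown
#' parents are written as empty fields.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- as_tibble(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Breed-composition coefficients
#'
#' Computes, for every individual, the coefficients `f_D`, `f_T`, `f_V`
#' that weight the pure-breed additive variances in the genotypic variance
#' of that individual.  Pure-breed founders and pure-breed lines carry an
#' indicator for their own breed.  A synthetic (`S`) node carries
#' `f_D = f_T = 1` and `f_V = 0`: chromosome doubling of the D x T hybrid
#' restores a full diploid complement of both parental subgenome sets.  All
#' other non-founders average their parents:
#' `f_i = (f_sire + f_dam) / 2`, so e.g. the F1 of S x V has
#' `f_D = f_T = f_V = 1/2` and the g-th backcross to V has
#' `f_D = f_T = 2^-(g+1)`.  `100 * f_D` is the "percent synthetic genome"
#' label used for derivative lines (50, 25, 12.5, 6.25).
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @return Tibble with columns `id`, `group`, `f_D`, `f_T`, `f_V`.
#' @export
breed_fractions <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  f <- matrix(0, n, 3, dimnames = list(ped$id, c("f_D", "f_T", "f_V")))
  for (i in seq_len(n)) {
    g <- ped$group[i]
    if (is.na(ped$sire[i])) {
      f[i, paste0("f_", g)] <- 1
    } else if (g %in% PURE_BREEDS) {
      f[i, paste0("f_", g)] <- 1
    } else if (g == "S") {
      f[i, c("f_D", "f_T")] <- 1
    } else {
      f[i, ] <- (f[idx[ped$sire[i]], ] + f[idx[ped$dam[i]], ]) / 2
    }
  }
  tibble(
    id = ped$id, group = ped$group,
    f_D = unname(f[, 1]), f_T = unname(f[, 2]), f_V = unname(f[, 3])
  )
}

#' Within-breed inbreeding coefficients
#'
#' The inbreeding coefficient of individual `i` within pure breed
#' `PB` (D, T or V) is the probability that, at a locus of that breed's
#' subgenome(s), the paternal and maternal alleles are identical by
#' descent.  Because the allopolyploid subgenomes pair independently at
#' meiosis, each subgenome behaves as a diploid and the classical relation
#' `F_i = a(sire, dam) / 2` applies per breed-of-origin component, with
#' `a` the corresponding partial relationship coefficient.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @return Tibble with columns `id`, `group`, `F_D`, `F_T`, `F_V`.
#' @export
inbreeding <- function(ped) {
  pk <- partial_kinship(ped)
  pk$inbreeding
}
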