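#' Validate and topologically order a pedigree
#'
#' Checks identifiers, materializes parents that are referenced but not
#' listed as founder rows, and reorders the pedigree so that every known
#' parent precedes its offspring. Identifiers are opaque strings; the
#' sentinel for an unknown parent is `"0"` by milk-recording convention.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (character or
#'   coercible); additional columns (e.g. `birth_date`) are carried along.
#' @param unknown sentinel value marking an unknown parent. `NA` is always
#'   treated as unknown as well.
#' @return A data.frame of class `ped_df`, topologically ordered, with
#'   columns `id`, `sire`, `dam` (unknown parents normalised to `unknown`)
#'   plus any extra input columns. Materialized founders receive `NA` in the
#'   extra columns.
#' @examples
#' ped <- data.frame(id = "x", sire = "s", dam = "d")
#' order_pedigree(ped)$id   # "s" "d" "x"
#' @export
order_pedigree <- function(ped, unknown = "0") {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[is.na(ped$sire) | ped$sire == unknown] <- unknown
  ped$dam[is.na(ped$dam) | ped$dam == unknown] <- unknown
  if (anyDuplicated(ped$id))
    stop("duplicate individual id: ", ped$id[duplicated(ped$id)][1])
  if (any(ped$id == unknown))
    stop("an individual carries the unknown-parent sentinel as id")

  parents <- unique(c(ped$sire, ped$dam))
  parents <- setdiff(parents, c(unknown, ped$id))
  if (length(parents)) {
    extra <- ped[rep(NA_integer_, length(parents)), , drop = FALSE]
    extra$id <- parents
    extra$sire <- unknown
    extra$dam <- unknown
    ped <- rbind(extra, ped)
    rownames(ped) <- NULL
  }

  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$id)  # NA = unknown
  di <- match(ped$dam, ped$id)
  if (any(si == idx, na.rm = TRUE) || any(di == idx, na.rm = TRUE)) {
    bad <- ped$id[which(si == idx | di == idx)[1]]
    stop("pedigree cycle detected involving individual ", bad)
  }
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    ready <- which(ready)
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < n) {
    # walk the parent graph from an unplaced node until a repeat: that is a cycle
    cur <- which(!placed)[1]
    seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[!is.na(nxt) & !placed[nxt]]
      cur <- nxt[1]
    }
    stop("pedigree cycle detected involving individual ", ped$id[cur])
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unknown") <- unknown
  class(out) <- c("ped_df", "data.frame")
  out
}

#' Zero-based parent indices of an ordered pedigree
#'
#' @param ped an ordered pedigree from [order_pedigree()].
#' @return list with integer vectors `sire` and `dam`, `-1L` for unknown.
#' @keywords internal
#' @export
ped_indices <- function(ped) {
  unknown <- attr(ped, "unknown")
  if (is.null(unknown)) unknown <- "0"
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  list(sire = ifelse(is.na(si), -1L, si - 1L),
       dam = ifelse(is.na(di), -1L, di - 1L))
}

#' Inbreeding coefficients
#'
#' Exact inbreeding coefficients by the Meuwissen-Luo recursion. Individuals
#' with at least one unknown parent are non-inbred by construction (unknown
#' parents are unrelated founders).
#'
#' @param ped an ordered pedigree from [order_pedigree()].
#' @return named numeric vector of F in `[0, 1)`, one per individual.
#' @export
inbreeding <- function(ped) {
  ix <- ped_indices(ped)
  f <- inbreeding_ml(ix$sire, ix$dam)
  names(f) <- ped$id
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly by Henderson's rules with inbreeding-corrected
#' Mendelian-sampling variances (at most 9 contributions per individual).
#' `Var(u) = A sigma2_u` for the additive genetic effect of the animal model.
#'
#' @param ped an ordered pedigree from [order_pedigree()].
#' @param f inbreeding coefficients, as returned by [inbreeding()].
#' @return a symmetric positive-definite `dgCMatrix` with dimnames `ped$id`.
#' @export
make_Ainv <- function(ped, f = inbreeding(ped)) {
  ix <- ped_indices(ped)
  tr <- ainverse_triplets(ix$sire, ix$dam, as.numeric(f))
  n <- nrow(ped)
  Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                       dims = c(n, n), dimnames = list(ped$id, ped$id))
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Quadratic in pedigree size; intended for small pedigrees and as an
#' independent cross-check of [make_Ainv()] (`diag(A) = 1 + F`,
#' `Ainv %*% A = I`).
#'
#' @inheritParams make_Ainv
#' @return dense numeric matrix with dimnames `ped$id`.
#' @export
make_A <- function(ped) {
  ix <- ped_indices(ped)
  n <- nrow(ped)
  s <- ix$sire + 1L  # 0 = unknown
  d <- ix$dam + 1L
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (s[i] > 0) A[j, s[i]] else 0) +
                   (if (d[i] > 0) A[j, d[i]] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  A
}

#' Pedigree completeness statistics
#'
#' Equivalent generations per individual (sum over known ancestors of
#' `(1/2)^g`), the fraction of known ancestors per ancestor generation up to
#' `max_gen`, and population summaries. `ids` restricts the population
#' summaries to a subset (e.g. cows with records).
#'
#' @param ped an ordered pedigree from [order_pedigree()].
#' @param max_gen deepest ancestor generation examined.
#' @param ids individuals over which the per-generation completeness and the
#'   mean are computed; defaults to all.
#' @return list with `eq_gen` (named vector), `completeness` (length
#'   `max_gen`, generation g = fraction of the `2^g` ancestor slots filled,
#'   averaged over `ids`), and `mean_eq_gen`.
#' @export
pedigree_completeness <- function(ped, max_gen = 14, ids = ped$id) {
  ix <- ped_indices(ped)
  n <- nrow(ped)
  s <- ix$sire + 1L
  d <- ix$dam + 1L
  eq <- numeric(n)
  for (i in seq_len(n)) {
    es <- if (s[i] > 0) 0.5 * (1 + eq[s[i]]) else 0
    ed <- if (d[i] > 0) 0.5 * (1 + eq[d[i]]) else 0
    eq[i] <- es + ed
  }
  names(eq) <- ped$id
  # known-ancestor counts by generation distance
  kn <- matrix(0, n, max_gen)
  for (i in seq_len(n)) {
    kn[i, 1] <- (s[i] > 0) + (d[i] > 0)
    if (max_gen > 1) {
      for (g in 2:max_gen) {
        kn[i, g] <- (if (s[i] > 0) kn[s[i], g - 1] else 0) +
                    (if (d[i] > 0) kn[d[i], g - 1] else 0)
      }
    }
  }
  sel <- match(ids, ped$id)
  if (anyNA(sel)) stop("unknown ids in completeness subset")
  comp <- colMeans(kn[sel, , drop = FALSE] /
                     matrix(2^(1:max_gen), length(sel), max_gen, byrow = TRUE))
  list(eq_gen = eq, completeness = comp, mean_eq_gen = mean(eq[sel]))
}

#' Read / write pedigree files
#'
#' Headered CSV with columns `id,sire,dam[,birth_date]`; `"0"` marks an
#' unknown parent. The writer emits the same dialect, so a pedigree
#' round-trips unchanged.
#'
#' @param path file path.
#' @param unknown unknown-parent sentinel.
#' @return `read_pedigree`: an ordered `ped_df`. `write_pedigree`: `path`,
#'   invisibly.
#' @export
read_pedigree <- function(path, unknown = "0") {
  df <- read.csv(path, colClasses = "character")
  order_pedigree(df, unknown = unknown)
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame to write.
#' @export
write_pedigree <- function(ped, path) {
  keep <- intersect(c("id", "sire", "dam", "birth_date"), names(ped))
  write.csv(as.data.frame(ped)[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
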