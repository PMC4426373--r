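#' Pedigree construction and validation
#'
#' A `qg_pedigree` is a data frame with columns `id`, `sire`, `dam`,
#' `generation`, `cross_type` and `family`, stored in topological order
#' (every parent precedes all of its offspring). Unknown parents are coded
#' `NA`; founders (both parents unknown) are assumed non-inbred and mutually
#' unrelated.
#'
#' @param id character or integer vector of individual identifiers.
#' @param sire,dam parent identifiers; `NA`, `""` or `"0"` mean unknown.
#' @param generation optional generation label per individual (e.g. P1/F1/F2).
#' @param cross_type optional cross-type label per individual.
#' @param family optional full-sib family label per individual.
#' @return a `qg_pedigree` data frame in topological order.
#' @examples
#' ped <- pedigree(id = c("s1", "d1", "o1"),
#'                 sire = c(NA, NA, "s1"), dam = c(NA, NA, "d1"))
#' relationship_matrix(ped)["o1", "s1"]  # 0.5
#' @export
pedigree <- function(id, sire, dam, generation = NULL, cross_type = NULL,
                     family = NULL) {
  id   <- as.character(id)
  sire <- normalize_parent(sire)
  dam  <- normalize_parent(dam)
  n <- length(id)
  stopifnot(length(sire) == n, length(dam) == n)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  missing_parents <- setdiff(c(sire, dam), c(id, NA))
  if (length(missing_parents))
    stop("parent(s) not present as records: ",
         paste(missing_parents, collapse = ", "))
  ped <- data.frame(
    id = id, sire = sire, dam = dam,
    generation = if (is.null(generation)) NA_character_ else as.character(generation),
    cross_type = if (is.null(cross_type)) NA_character_ else as.character(cross_type),
    family     = if (is.null(family)) NA_character_ else as.character(family),
    stringsAsFactors = FALSE)
  ped <- ped[topological_order(ped$id, ped$sire, ped$dam), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("qg_pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn topological sort, stable in input order; errors on cycles
# (an individual that is its own ancestor) naming the ids involved.
topological_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- idx[sire]  # NA where unknown
  di <- idx[dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) < n)
    stop("pedigree contains a cycle involving id(s): ",
         paste(id[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' Read a pedigree CSV
#'
#' Expects header `id,sire,dam,generation,cross_type,family`; unknown parents
#' are written `0` or left empty. Rows may appear in any order; the returned
#' pedigree is topologically sorted.
#'
#' @param path path to a pedigree CSV file.
#' @return a `qg_pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, sire, dam")
  pedigree(id = df$id, sire = df$sire, dam = df$dam,
           generation = df[["generation"]], cross_type = df[["cross_type"]],
           family = df[["family"]])
}

#' Write a pedigree CSV
#' @param ped a `qg_pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Additive (numerator) relationship matrix
#'
#' Recursive tabular construction in topological order:
#' \eqn{a_{ii} = 1 + F_i} with \eqn{F_i = 0.5\,a_{s_i d_i}}, and
#' \eqn{a_{ij} = 0.5 (a_{j s_i} + a_{j d_i})} for \eqn{j} older than \eqn{i};
#' unknown parents contribute 0.
#'
#' @param ped a `qg_pedigree`.
#' @return dense symmetric matrix with dimnames = ids; attribute
#'   `"inbreeding"` carries the per-individual coefficient \eqn{F_i = a_{ii}-1}.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    prev <- seq_len(i - 1L)
    if (length(prev)) {
      row_s <- if (is.na(s)) 0 else A[s, prev]
      row_d <- if (is.na(d)) 0 else A[d, prev]
      a_prev <- 0.5 * (row_s + row_d)
      A[i, prev] <- a_prev
      A[prev, i] <- a_prev
    }
    Fi <- if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
    A[i, i] <- 1 + Fi
  }
  attr(A, "inbreeding") <- stats::setNames(diag(A) - 1, ped$id)
  A
}

#' Inbreeding coefficients without forming the dense relationship matrix
#'
#' Meuwissen & Luo style ancestor traversal: \eqn{a_{ii}} is accumulated as
#' \eqn{\sum_j L_{ij}^2 d_j} over ancestors \eqn{j}, where \eqn{d_j} is the
#' Mendelian-sampling variance of \eqn{j}; \eqn{F_i = a_{ii} - 1}.
#'
#' @param ped a `qg_pedigree`.
#' @return named numeric vector of \eqn{F_i}.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fi <- numeric(n)
  dmen <- numeric(n)  # Mendelian sampling variance, filled in order
  founder <- is.na(si) & is.na(di)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dmen[i] <- mendelian_variance(s, d, Fi)
    if (is.na(s) || is.na(d)) { Fi[i] <- 0; next }
    # founders are unrelated: offspring of two founders are non-inbred
    if (founder[s] && founder[d]) { Fi[i] <- 0; next }
    # accumulate a_ii by tracing ancestors of i, youngest first
    L <- numeric(n)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * dmen[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * L[j]
    }
    Fi[i] <- aii - 1
  }
  stats::setNames(Fi, ped$id)
}

mendelian_variance <- function(s, d, Fi) {
  if (is.na(s) && is.na(d)) return(1)
  if (is.na(s)) return(0.75 - 0.25 * Fi[d])
  if (is.na(d)) return(0.75 - 0.25 * Fi[s])
  0.5 - 0.25 * (Fi[s] + Fi[d])
}

#' Sparse inverse of the relationship matrix
#'
#' Henderson's rules with inbreeding: each individual contributes
#' \eqn{1/d_i} to its own diagonal, \eqn{-1/(2 d_i)} to parent-offspring
#' cells and \eqn{1/(4 d_i)} to parent-parent cells, where \eqn{d_i} is the
#' Mendelian-sampling variance computed from parental inbreeding.
#'
#' @param ped a `qg_pedigree`.
#' @return sparse symmetric `Matrix::dsCMatrix` \eqn{A^{-1}} with dimnames.
#' @export
sparse_ainverse <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fi <- inbreeding(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    alpha <- 1 / mendelian_variance(s, d, Fi)
    add(i, i, alpha)
    for (p in c(s, d)) {
      if (is.na(p)) next
      add(i, p, -alpha / 2); add(p, i, -alpha / 2)
      add(p, p, alpha / 4)
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, alpha / 4); add(d, s, alpha / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' @export
print.qg_pedigree <- function(x, ...) {
  cat("qg_pedigree:", nrow(x), "individuals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  NextMethod()
}
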