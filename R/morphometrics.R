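#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the k landmarks from their
#' centroid; the standard geometric-morphometric size measure, in the input
#' units.
#'
#' @param coords k x 2 matrix of landmark coordinates.
#' @return positive scalar.
#' @examples
#' centroid_size(rbind(c(1,1), c(1,-1), c(-1,1), c(-1,-1)))  # sqrt(8)
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  centred <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

# rotation (det +1) taking a centred configuration to its canonical frame:
# major principal axis along x, sign fixed by the x third moment (falling
# back to the y third moment for symmetric shapes)
canonical_gauge <- function(m) {
  eg <- eigen(crossprod(m), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  th <- atan2(v1[2], v1[1])
  # for row-vector points, m %*% R(th) rotates the configuration by -th,
  # taking the major axis onto x
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- m %*% R
  s <- sum(rot[, 1]^3)
  if (abs(s) < 1e-12) s <- sum(rot[, 2]^3)
  if (s < 0) R <- -R  # rotate by pi (still det +1)
  R
}

# Optimal rotation (no reflection) of centred config X onto centred target Y.
procrustes_rotation <- function(X, Y) {
  sv <- svd(crossprod(X, Y))
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Centres every configuration, scales it to unit centroid size, and
#' iteratively rotates all configurations to their updating consensus
#' (generalized least-squares superimposition). Iteration stops when the
#' consensus moves by less than `tol` (root-mean-square coordinate change).
#'
#' @param shapes list of k x 2 landmark matrices (or a `qg_landmarks` object
#'   from [read_tps()] / [simulate_landmarks()]).
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @param max_iter maximum GPA iterations (default 100).
#' @return object of class `qg_gpa`: list with `consensus` (k x 2),
#'   `aligned` (k x 2 x n array), `centroid_size` (length-n vector of the
#'   original sizes), `ids`, and the iteration count.
#' @export
generalized_procrustes <- function(shapes, tol = 1e-10, max_iter = 100) {
  ids <- names(shapes)
  shapes <- lapply(shapes, as.matrix)
  n <- length(shapes)
  if (n < 2) stop("need at least 2 configurations")
  k <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 0L) == k))
    stop("all configurations must share the same landmark count")
  cs <- vapply(shapes, centroid_size, 0)
  pre <- lapply(shapes, function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  consensus <- pre[[1L]]
  aligned <- pre
  it <- 0L
  repeat {
    it <- it + 1L
    aligned <- lapply(pre, function(m) m %*% procrustes_rotation(m, consensus))
    new_cons <- Reduce(`+`, aligned) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    # fix the consensus' rotational gauge: align it to the first config's frame
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
    if (it >= max_iter)
      stop("GPA failed to converge in ", max_iter,
           " iterations (last consensus change ", format(delta), ")")
  }
  # fix the rotational gauge canonically (the consensus is otherwise only
  # defined up to rotation, and would depend on the input order): rotate so
  # the consensus' major principal axis lies along x, with the sign chosen
  # by the third moment of the x coordinates
  gauge <- canonical_gauge(consensus)
  consensus <- consensus %*% gauge
  aligned <- lapply(aligned, function(m) m %*% gauge)
  arr <- array(unlist(aligned), dim = c(k, 2, n),
               dimnames = list(NULL, c("x", "y"), ids))
  structure(list(consensus = consensus, aligned = arr,
                 centroid_size = stats::setNames(cs, ids), ids = ids,
                 iterations = it),
            class = "qg_gpa")
}

# Thin-plate-spline bending-energy matrix of a k x 2 reference configuration.
# Kernel U(r) = r^2 log r^2; returns the k x k bending-energy matrix whose
# null space is spanned by [1, x, y].
bending_energy <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  if (abs(det(L)) < 1e-300)
    stop("singular bending-energy system: collinear consensus landmarks")
  Linv <- solve(L)
  Be <- Linv[1:k, 1:k]
  (Be + t(Be)) / 2
}

# Orthonormal basis (2k x 4) of the similarity directions at a centred,
# unit-size reference: x/y translation, scaling, rotation.
similarity_basis <- function(ref) {
  k <- nrow(ref)
  t1 <- as.vector(rbind(rep(1, k), rep(0, k))) / sqrt(k)
  t2 <- as.vector(rbind(rep(0, k), rep(1, k))) / sqrt(k)
  sc <- as.vector(t(ref))                       # unit norm: CS = 1
  ro <- as.vector(t(cbind(-ref[, 2], ref[, 1])))
  cbind(t1, t2, sc, ro / sqrt(sum(ro^2)))
}

#' Partial-warp scores (including the uniform component)
#'
#' Eigen-decomposes the thin-plate-spline bending-energy matrix of the GPA
#' consensus; each aligned shape's deviation from the consensus is projected
#' onto the principal-warp basis (x and y components of the k-3 non-trivial
#' eigenvectors, 2k-6 scores) plus an orthonormal basis of the 2-dimensional
#' uniform (affine) subspace, for 2k-4 scores per individual. With `alpha = 0`
#' all directions are weighted equally.
#'
#' @param gpa a `qg_gpa` object.
#' @param alpha principal-warp weight exponent; scores are scaled by
#'   eigenvalue^(-alpha/2). Default 0 (unweighted).
#' @return n x (2k-4) matrix of scores with rownames = ids; attributes
#'   `"basis"` (2k x (2k-4) orthonormal matrix, uniform columns last) and
#'   `"consensus"`.
#' @export
partial_warps <- function(gpa, alpha = 0) {
  stopifnot(inherits(gpa, "qg_gpa"))
  ref <- gpa$consensus
  k <- nrow(ref)
  Be <- bending_energy(ref)
  eg <- eigen(Be, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  if (sum(keep) != k - 3)
    stop("expected ", k - 3, " principal warps, got ", sum(keep))
  E <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  # interleaved (x1,y1,...,xk,yk) basis vectors for x- and y-displacements
  nonuni <- matrix(0, 2 * k, 2 * (k - 3))
  for (j in seq_len(k - 3)) {
    nonuni[seq(1, 2 * k, 2), 2 * j - 1] <- E[, j]
    nonuni[seq(2, 2 * k, 2), 2 * j]     <- E[, j]
  }
  S <- similarity_basis(ref)
  qr_all <- qr(cbind(S, nonuni))
  full <- qr.Q(qr_all, complete = TRUE)
  uni <- full[, (ncol(S) + ncol(nonuni) + 1):(2 * k), drop = FALSE]  # 2 cols
  stopifnot(ncol(uni) == 2)
  # deterministic sign for the complement columns
  for (j in seq_len(ncol(uni))) {
    m <- which.max(abs(uni[, j]))
    if (uni[m, j] < 0) uni[, j] <- -uni[, j]
  }
  w <- if (alpha == 0) rep(1, k - 3) else lam^(-alpha / 2)
  basis <- cbind(sweep(nonuni, 2, rep(w, each = 2), `*`), uni)
  n <- dim(gpa$aligned)[3]
  dev <- t(vapply(seq_len(n), function(i)
    as.vector(t(gpa$aligned[, , i] - ref)), numeric(2 * k)))
  scores <- dev %*% basis
  colnames(scores) <- c(paste0("PW", rep(seq_len(k - 3), each = 2),
                               c("x", "y")), "Uni1", "Uni2")
  rownames(scores) <- gpa$ids
  attr(scores, "basis") <- basis
  attr(scores, "consensus") <- ref
  scores
}

#' Relative warps: principal components of partial-warp scores
#'
#' Unweighted PCA of the partial-warp score matrix; scores are multiplied by
#' 1000 for reporting, per-axis percent variance explained (PVE) sums to 100,
#' and each axis' sign is fixed so its largest-magnitude loading is positive.
#'
#' @param scores n x (2k-4) partial-warp score matrix.
#' @param scale_factor multiplier applied to scores (default 1000).
#' @return object of class `qg_relwarps`: list with `scores`
#'   (n x (2k-4), columns `RelW1`...), `pve`, `loadings`, `sdev`,
#'   `scale_factor`.
#' @export
relative_warps <- function(scores, scale_factor = 1000) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 individuals")
  pc <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sc <- pc$x
  for (j in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  v <- pc$sdev^2
  pve <- 100 * v / sum(v)
  labs <- paste0("RelW", seq_len(ncol(sc)))
  colnames(sc) <- labs
  colnames(rot) <- labs
  names(pve) <- labs
  structure(list(scores = sc * scale_factor, pve = pve, loadings = rot,
                 sdev = pc$sdev, scale_factor = scale_factor),
            class = "qg_relwarps")
}

#' Drop named relative warps from downstream analysis
#'
#' Removes the given axes (e.g. a warp judged to be a handling artifact) from
#' the score matrix; remaining columns keep their original labels.
#'
#' @param rw a `qg_relwarps` object or a score matrix with RelW columns.
#' @param indices integer indices of warps to drop (may be empty).
#' @return score matrix without the dropped columns, original labels kept.
#' @export
exclude_warps <- function(rw, indices) {
  scores <- if (inherits(rw, "qg_relwarps")) rw$scores else as.matrix(rw)
  indices <- as.integer(indices)
  if (length(indices) == 0) return(scores)
  if (any(indices < 1 | indices > ncol(scores)))
    stop("warp index out of range 1..", ncol(scores))
  if (length(unique(indices)) >= ncol(scores))
    stop("cannot exclude every warp: no shape variables would remain")
  scores[, -unique(indices), drop = FALSE]
}

#' Full morphometric decomposition of a set of landmark configurations
#'
#' Runs GPA, partial warps and relative warps in one call.
#'
#' @inheritParams generalized_procrustes
#' @inheritParams relative_warps
#' @param alpha relative-warp weight exponent (default 0, ordinary PCA).
#' @return list with `gpa`, `partial_warps`, `relwarps`, `centroid_size`.
#' @export
shape_decomposition <- function(shapes, alpha = 0, scale_factor = 1000,
                                tol = 1e-10, max_iter = 100) {
  gpa <- generalized_procrustes(shapes, tol = tol, max_iter = max_iter)
  pw <- partial_warps(gpa, alpha = alpha)
  rw <- relative_warps(pw, scale_factor = scale_factor)
  list(gpa = gpa, partial_warps = pw, relwarps = rw,
       centroid_size = gpa$centroid_size)
}

#' Read / write landmark files in the TPS dialect
#'
#' Records of the form `LM=k`, k lines of `x y`, then `ID=<identifier>` and
#' optionally `SCALE=<s>` (coordinates are multiplied by the scale when
#' present). Blank lines and CRLF endings are tolerated.
#'
#' @param path file path.
#' @return named list of k x 2 coordinate matrices (class `qg_landmarks`).
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(gsub("\r", "", lines))
  lines <- lines[lines != ""]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("malformed TPS file: expected LM= at line ", i)
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[i + j], "\\s+")[[1]]))
      if (length(xy) != 2 || anyNA(xy))
        stop("malformed coordinate line: '", lines[i + j], "'")
      coords[j, ] <- xy
    }
    i <- i + k + 1L
    id <- NULL; scale <- 1
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      else if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                                ignore.case = TRUE))
      else stop("unexpected TPS line: '", lines[i], "'")
      i <- i + 1L
    }
    if (is.null(id)) id <- as.character(length(out) + 1L)
    out[[id]] <- coords * scale
  }
  class(out) <- c("qg_landmarks", "list")
  out
}

#' @rdname read_tps
#' @param shapes named list of k x 2 matrices.
#' @export
write_tps <- function(shapes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(shapes)) {
    m <- shapes[[id]]
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(sprintf("%.10g %.10g", m[, 1], m[, 2]), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}
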