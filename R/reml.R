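#' Animal-model specification
#'
#' Declares the response, fixed effects, random effects and covariates of a
#' pedigree animal model. Fixed-effect and random-term names refer to columns
#' supplied by the pedigree (`generation`, `cross_type`, `family`, `dam`,
#' `sire`) or to phenotype-table columns (covariates). The random term
#' `"micro"` is the full-sib family rearing-tank effect, `"dam"`/`"sire"` are
#' maternal/paternal environment effects, and `"animal"` is the additive
#' genetic effect with covariance proportional to the relationship matrix.
#'
#' @param response trait (column) name.
#' @param fixed character vector of fixed factors, subset of
#'   `c("generation", "cross_type")`.
#' @param random character vector of random terms, subset of
#'   `c("micro", "dam", "sire", "animal")`.
#' @param covariates character vector of numeric covariate columns
#'   (e.g. `"CentroidSize"`).
#' @return a `qg_model` list.
#' @export
qg_model <- function(response, fixed = c("generation", "cross_type"),
                     random = c("micro", "animal"), covariates = character()) {
  if (length(fixed))
    fixed <- match.arg(fixed, c("generation", "cross_type"),
                       several.ok = TRUE)
  else fixed <- character(0)
  if (length(random))
    random <- match.arg(random, c("micro", "dam", "sire", "animal"),
                        several.ok = TRUE)
  structure(list(response = response, fixed = fixed, random = random,
                 covariates = covariates),
            class = "qg_model")
}

# merge pedigree structure columns into the phenotype table
merge_pedigree <- function(data, ped) {
  stopifnot("id" %in% names(data))
  pd <- as.data.frame(ped)[, c("id", "sire", "dam", "generation",
                               "cross_type", "family")]
  keep <- setdiff(names(data), c("sire", "dam", "family"))
  merged <- merge(data[, keep, drop = FALSE], pd, by = "id",
                  suffixes = c("", ".ped"), sort = FALSE)
  for (col in c("generation", "cross_type")) {
    pedcol <- paste0(col, ".ped")
    if (pedcol %in% names(merged)) {
      fill <- is.na(merged[[col]])
      merged[[col]][fill] <- merged[[pedcol]][fill]
      merged[[pedcol]] <- NULL
    }
  }
  merged
}

# fixed-effect design matrix with aliased columns dropped; keeps the
# model.matrix "assign" attribute for per-term Wald tests
build_design <- function(df, fixed, covariates) {
  nonest <- fixed[vapply(fixed,
    function(f) length(unique(stats::na.omit(df[[f]]))) < 2, TRUE)]
  fixed <- setdiff(fixed, nonest)
  terms <- c(fixed, covariates)
  form <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else stats::as.formula("~ 1")
  for (f in fixed) df[[f]] <- factor(df[[f]])
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    asg <- attr(X, "assign")[keep]
    X <- X[, keep, drop = FALSE]
    attr(X, "assign") <- asg
  }
  attr(X, "term_labels") <- c("(Intercept)", terms)
  attr(X, "dropped") <- dropped
  attr(X, "nonestimable") <- nonest
  X
}

# covariance structure (n x n) for one random term, rows aligned to df rows
term_structure <- function(term, df, A = NULL) {
  if (term == "animal") {
    return(A[df$id, df$id, drop = FALSE])
  }
  col <- switch(term, micro = "family", dam = "dam", sire = "sire",
                stop("unknown random term: ", term))
  f <- df[[col]]
  if (all(is.na(f))) stop("random term '", term, "' needs column '", col, "'")
  Z <- stats::model.matrix(~ 0 + factor(f))
  tcrossprod(Z)
}

# ---- generic AI-REML for variance structures linear in their parameters ----
#
# V(theta) = sum_c theta_c * K_c. Average-information updates with
# step-halving; parameters in `nonneg` are kept >= 0 by boundary projection.
# Returns estimates, asymptotic SEs from the inverse AI matrix, and the
# restricted log-likelihood.
reml_engine <- function(y, X, Ks, nonneg, start = NULL,
                        max_iter = 100, tol_ll = 1e-8, tol_par = 1e-6,
                        method = c("ai", "em"), em_q = NULL) {
  method <- match.arg(method)
  n <- length(y)
  p <- ncol(X)
  nc <- length(Ks)
  vtot <- max(stats::var(stats::lm.fit(X, y)$residuals) * (n - 1) / (n - p),
              .Machine$double.eps)
  floor_v <- 1e-8 * vtot
  if (is.null(start)) {
    start <- numeric(nc)
    start[nonneg] <- vtot / sum(nonneg)
  }
  theta <- start

  evaluate <- function(theta) {
    # tiny ridge keeps boundary-singular optima (e.g. perfectly correlated
    # traits) numerically reachable without affecting interior estimates
    V <- diag(1e-8 * vtot, n)
    for (c in seq_len(nc)) V <- V + theta[c] * Ks[[c]]
    cholV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cholV)) return(NULL)
    Vinv <- chol2inv(cholV)
    VinvX <- Vinv %*% X
    XtViX <- crossprod(X, VinvX)
    cholX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cholX)) return(NULL)
    beta <- backsolve(cholX, forwardsolve(t(cholX), crossprod(VinvX, y)))
    Py <- as.vector(Vinv %*% y - VinvX %*% beta)
    ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholX))) +
                  sum(y * Py))
    list(ll = ll, Vinv = Vinv, VinvX = VinvX, XtViX = XtViX, cholX = cholX,
         beta = as.vector(beta), Py = Py)
  }

  st <- evaluate(theta)
  if (is.null(st)) stop("REML: starting values give a singular V")
  boundary <- rep(FALSE, nc)
  converged <- FALSE
  AI <- diag(nc)
  trajectory <- numeric(0)
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    trajectory <- c(trajectory, st$ll)
    KPy <- vapply(Ks, function(K) as.vector(K %*% st$Py), numeric(n))
    yPKPy <- as.vector(crossprod(st$Py, KPy))
    M <- st$VinvX %*% chol2inv(st$cholX)          # Vinv X (X'VinvX)^-1
    trPK <- vapply(seq_len(nc), function(c) {
      sum(st$Vinv * Ks[[c]]) - sum(M * (Ks[[c]] %*% st$VinvX))
    }, 0)
    score <- -0.5 * (trPK - yPKPy)
    if (method == "em") {
      qs <- if (is.null(em_q)) rep(n, nc) else em_q
      theta_new <- pmax(theta + theta^2 / qs * (yPKPy - trPK), floor_v)
      st_new <- evaluate(theta_new)
      if (is.null(st_new)) stop("EM-REML: singular V during iteration")
      d_par <- max(abs(theta_new - theta)) / vtot
      d_ll <- abs(st_new$ll - st$ll) / (1 + abs(st$ll))
      theta <- theta_new
      st <- st_new
      if (d_ll < tol_ll && d_par < tol_par) { converged <- TRUE; break }
      next
    }
    PKPy <- vapply(seq_len(nc), function(c) {
      v <- KPy[, c]
      as.vector(st$Vinv %*% v -
                st$VinvX %*% backsolve(st$cholX,
                  forwardsolve(t(st$cholX), crossprod(st$VinvX, v))))
    }, numeric(n))
    AI <- 0.5 * crossprod(KPy, PKPy)
    AI <- (AI + t(AI)) / 2
    # hold parameters stuck at the zero boundary whose score pushes them lower
    held <- boundary & (score < 0)
    free <- which(!held)
    delta <- numeric(nc)
    AIf <- AI[free, free, drop = FALSE]
    ridge <- 1e-8 * mean(diag(AIf))
    delta[free] <- tryCatch(
      solve(AIf + diag(ridge, length(free)), score[free]),
      error = function(e) score[free] / (diag(AIf) + ridge))
    # cap the proposal so ill-conditioned AI matrices cannot fling the
    # parameters out of the feasible region beyond recovery by halving
    cap <- 2 * max(vtot, max(abs(theta)))
    if (max(abs(delta)) > cap) delta <- delta * cap / max(abs(delta))
    stepsize <- 1
    improved <- FALSE
    for (h in 1:20) {
      theta_new <- theta + stepsize * delta
      hit <- nonneg & theta_new < floor_v
      theta_new[hit] <- floor_v
      st_new <- evaluate(theta_new)
      if (!is.null(st_new) && st_new$ll > st$ll - 1e-10) {
        improved <- TRUE
        break
      }
      stepsize <- stepsize / 2
    }
    if (!improved) {
      # AI direction failed: fall back to a scaled-gradient (EM-flavoured) step
      qs <- if (is.null(em_q)) rep(n, nc) else em_q
      theta_new <- theta
      theta_new[free] <- pmax(theta[free] + theta[free]^2 / qs[free] *
                              (yPKPy[free] - trPK[free]),
                              ifelse(nonneg[free], floor_v, theta[free]))
      st_new <- evaluate(theta_new)
      if (is.null(st_new) || st_new$ll < st$ll - 1e-6) {
        converged <- TRUE  # no ascent available: accept current point
        st_new <- st
        theta_new <- theta
      }
    }
    boundary <- nonneg & theta_new <= floor_v * 1.000001
    d_par <- max(abs(theta_new - theta)) / vtot
    d_ll <- abs(st_new$ll - st$ll) / (1 + abs(st$ll))
    theta <- theta_new
    st <- st_new
    if (d_ll < tol_ll && d_par < tol_par) { converged <- TRUE; break }
    # boundary-singular optima: likelihood flat while parameters creep
    stall <- if (d_ll < tol_ll) stall + 1L else 0L
    if (stall >= 5L) { converged <- TRUE; break }
  }
  if (!converged)
    stop("REML failed to converge after ", max_iter,
         " iterations; log-likelihood trajectory: ",
         paste(sprintf("%.4f", utils::tail(trajectory, 5)), collapse = ", "))
  se <- rep(NA_real_, nc)
  covtheta <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covtheta)) se <- sqrt(pmax(diag(covtheta), 0))
  theta_out <- theta
  theta_out[boundary] <- 0
  list(theta = theta_out, se = se, cov = covtheta, logLik = st$ll,
       beta = st$beta, beta_cov = chol2inv(st$cholX), boundary = boundary,
       iterations = iter, Py = st$Py, n = n, rank_X = p)
}

#' Fit a univariate Gaussian animal model by REML
#'
#' Average-information REML with EM-flavoured fallback steps and nonnegative
#' variance constraints by boundary projection. Rows with a missing response,
#' covariate or fixed-effect level are dropped listwise.
#'
#' @param data phenotype data frame with an `id` column.
#' @param ped a `qg_pedigree` (required when the model has an animal term).
#' @param spec a [qg_model()] with identity link.
#' @param A optional precomputed relationship matrix (else computed from
#'   `ped`).
#' @param ... passed to the optimizer (`max_iter`, `tol_ll`, `tol_par`,
#'   `method = "ai"` or `"em"`).
#' @return object of class `qg_reml`: variance components with SEs,
#'   restricted log-likelihood, fixed-effect estimates, and bookkeeping for
#'   [heritability()], [lrt_random_effect()] and [wald_fixed_effects()].
#' @export
fit_univariate_reml <- function(data, ped, spec, A = NULL, ...) {
  stopifnot(inherits(spec, "qg_model"))
  df <- merge_pedigree(data, ped)
  used <- c(spec$response, spec$covariates,
            intersect(spec$fixed, names(df)))
  df <- df[stats::complete.cases(df[, used, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < 2) stop("fewer than 2 complete observations")
  if ("micro" %in% spec$random && length(unique(df$family)) < 2)
    stop("response present for fewer than 2 families")
  if ("animal" %in% spec$random && is.null(A))
    A <- relationship_matrix(ped)
  y <- df[[spec$response]]
  X <- build_design(df, spec$fixed, spec$covariates)
  Ks <- lapply(spec$random, term_structure, df = df, A = A)
  Ks <- c(Ks, list(diag(nrow(df))))
  vnames <- c(paste0("V_", c(micro = "f", dam = "m", sire = "s",
                             animal = "A")[spec$random]), "V_R")
  names(Ks) <- vnames
  em_q <- c(vapply(spec$random, function(tm) {
    if (tm == "animal") nrow(df) else
      length(unique(df[[switch(tm, micro = "family", dam = "dam",
                               sire = "sire")]]))
  }, 0), nrow(df))
  fit <- reml_engine(y, X, Ks, nonneg = rep(TRUE, length(Ks)),
                     em_q = em_q, ...)
  structure(list(
    components = stats::setNames(fit$theta, vnames),
    se = stats::setNames(fit$se, vnames),
    cov = fit$cov, logLik = fit$logLik,
    fixef = stats::setNames(fit$beta, colnames(X)),
    fixef_cov = fit$beta_cov, X_assign = attr(X, "assign"),
    term_labels = attr(X, "term_labels"), dropped = attr(X, "dropped"),
    nonestimable = attr(X, "nonestimable"),
    boundary = stats::setNames(fit$boundary, vnames),
    ids = df$id, n = fit$n, rank_X = fit$rank_X,
    iterations = fit$iterations, spec = spec), class = "qg_reml")
}

#' @export
print.qg_reml <- function(x, ...) {
  cat("Animal model (REML):", x$spec$response, "~",
      paste(x$spec$fixed, collapse = " + "),
      "| random:", paste(x$spec$random, collapse = " + "), "\n")
  cat("n =", x$n, ", restricted logLik =", format(x$logLik), "\n")
  tab <- data.frame(estimate = x$components, SE = x$se,
                    boundary = x$boundary)
  print(tab, ...)
  h2 <- heritability(x)
  if (!is.null(h2))
    cat(sprintf("h2 = %.3f (SE %.3f)\n", h2["h2"], h2["SE"]))
  invisible(x)
}

# variance-ratio with delta-method SE; numerator = one component,
# denominator = sum of all variance components
variance_ratio <- function(fit, numerator) {
  comps <- fit$components
  if (!numerator %in% names(comps)) return(NULL)
  vp <- sum(comps)
  if (vp <= 0) stop("total phenotypic variance is zero")
  ratio <- comps[[numerator]] / vp
  se <- NA_real_
  if (!is.null(fit$cov)) {
    g <- rep(-comps[[numerator]] / vp^2, length(comps))
    g[names(comps) == numerator] <- (vp - comps[[numerator]]) / vp^2
    se <- sqrt(max(0, as.numeric(t(g) %*% fit$cov %*% g)))
  }
  c(stats::setNames(ratio, NULL), SE = se)
}

#' Narrow-sense heritability from fitted components
#'
#' h2 = V_A / V_P with V_P the sum of all fitted variance components; SE by
#' the delta method from the AI covariance of the components. Also accepts a
#' named numeric vector of components (names containing `V_A`/`Va`), in which
#' case no SE is available.
#'
#' @param fit a `qg_reml` fit or named numeric vector of variance components.
#' @return named vector `c(h2, SE)` (SE `NA` when unavailable), or `NULL` if
#'   the model has no animal term.
#' @export
heritability <- function(fit) {
  if (is.numeric(fit)) {
    nm <- names(fit)
    va <- fit[match(TRUE, nm %in% c("V_A", "Va", "VA"))]
    if (is.na(va)) stop("no additive component found")
    return(c(h2 = as.numeric(va) / sum(fit), SE = NA_real_))
  }
  r <- variance_ratio(fit, "V_A")
  if (is.null(r)) return(NULL)
  stats::setNames(r, c("h2", "SE"))
}

#' Maternal-effect proportion m2 = V_m / V_P
#' @inheritParams heritability
#' @return named vector `c(m2, SE)` or `NULL` when the model has no dam term.
#' @export
maternal_proportion <- function(fit) {
  if (is.numeric(fit)) {
    nm <- names(fit)
    vm <- fit[match(TRUE, nm %in% c("V_m", "Vm", "VM"))]
    if (is.na(vm)) stop("no maternal component found")
    return(c(m2 = as.numeric(vm) / sum(fit), SE = NA_real_))
  }
  r <- variance_ratio(fit, "V_m")
  if (is.null(r)) return(NULL)
  stats::setNames(r, c("m2", "SE"))
}

#' Likelihood-ratio test for one random effect
#'
#' chi-square = 2 (logL_full - logL_reduced), clipped at zero, referred to a
#' chi-square with 1 df (the conventional, conservative treatment of the
#' boundary null).
#'
#' @param full,reduced `qg_reml` fits on identical data rows; `reduced` must
#'   drop exactly one random term of `full`.
#' @return data frame with `statistic`, `df`, `p.value`.
#' @export
lrt_random_effect <- function(full, reduced) {
  if (!identical(sort(full$ids), sort(reduced$ids)))
    stop("full and reduced fits use different data rows")
  if (identical(full$spec$random, reduced$spec$random))
    return(data.frame(term = NA_character_,
                      statistic = max(0, 2 * (full$logLik - reduced$logLik)),
                      df = 1,
                      p.value = stats::pchisq(
                        max(0, 2 * (full$logLik - reduced$logLik)), 1,
                        lower.tail = FALSE)))
  dropped <- setdiff(full$spec$random, reduced$spec$random)
  if (length(dropped) != 1)
    stop("reduced model must drop exactly one random term")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  data.frame(term = dropped, statistic = chi2, df = 1,
             p.value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Wald F-tests for fixed effects
#'
#' Per-term Wald F with numerator df = estimable coefficients of the term and
#' denominator df = n - rank(X) (residual approximation).
#'
#' @param fit a `qg_reml` fit.
#' @return data frame with one row per fixed term: `F`, `ndf`, `ddf`,
#'   `p.value`; terms with no estimable coefficient are flagged
#'   non-estimable (`NA` statistics).
#' @export
wald_fixed_effects <- function(fit) {
  asg <- fit$X_assign
  labels <- fit$term_labels
  ddf <- fit$n - fit$rank_X
  rows <- lapply(setdiff(unique(asg), 0), function(tm) {
    idx <- which(asg == tm)
    b <- fit$fixef[idx]
    Vb <- fit$fixef_cov[idx, idx, drop = FALSE]
    Fstat <- tryCatch(
      as.numeric(t(b) %*% solve(Vb, b)) / length(idx),
      error = function(e) NA_real_)
    data.frame(term = labels[tm + 1L], F = Fstat, ndf = length(idx),
               ddf = ddf,
               p.value = stats::pf(Fstat, length(idx), ddf,
                                   lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(0), F = numeric(0),
                      ndf = integer(0), ddf = integer(0),
                      p.value = numeric(0))
  # terms entirely aliased out of the design (incl. single-level factors)
  missing_terms <- union(setdiff(labels[-1L], out$term), fit$nonestimable)
  if (length(missing_terms))
    out <- rbind(out, data.frame(term = missing_terms, F = NA_real_,
                                 ndf = NA_integer_, ddf = ddf,
                                 p.value = NA_real_))
  rownames(out) <- NULL
  out
}
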