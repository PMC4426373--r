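#' Fit a bivariate Gaussian animal model by REML
#'
#' Two traits are stacked and the genetic (animal) term carries a full 2 x 2
#' covariance matrix (V_A1, V_A2, COV_A). Other random terms (`micro`,
#' `dam`, `sire`) are fitted with trait-specific variances and no
#' cross-trait covariance. Residuals have trait-specific variances plus a
#' residual covariance on individuals measured for both traits (omitted
#' automatically when the traits share no individuals).
#'
#' @param data phenotype data frame with an `id` column.
#' @param ped a `qg_pedigree`.
#' @param spec1,spec2 [qg_model()] specs for the two traits (both must
#'   include an `"animal"` random term).
#' @param constrain_cov if `TRUE` the genetic covariance is fixed at zero
#'   (the reduced model of the genetic-correlation LRT).
#' @param A optional precomputed relationship matrix.
#' @param ... passed to the optimizer.
#' @return object of class `qg_reml_biv` with the stacked component vector
#'   (`V_A:1`, `V_A:2`, `COV_A`, per-trait environmental terms, `V_R:1`,
#'   `V_R:2`, `COV_R`), SEs, log-likelihood, and the G-matrix PSD flag.
#' @export
fit_bivariate_reml <- function(data, ped, spec1, spec2,
                               constrain_cov = FALSE, A = NULL, ...) {
  stopifnot(inherits(spec1, "qg_model"), inherits(spec2, "qg_model"))
  if (!("animal" %in% spec1$random) || !("animal" %in% spec2$random))
    stop("both traits must include an animal term")
  if (is.null(A)) A <- relationship_matrix(ped)
  df <- merge_pedigree(data, ped)
  specs <- list(spec1, spec2)
  sub <- lapply(specs, function(sp) {
    used <- c(sp$response, sp$covariates, intersect(sp$fixed, names(df)))
    df[stats::complete.cases(df[, used, drop = FALSE]), , drop = FALSE]
  })
  n1 <- nrow(sub[[1]]); n2 <- nrow(sub[[2]])
  if (n1 < 2 || n2 < 2) stop("fewer than 2 complete observations for a trait")
  y <- c(sub[[1]][[spec1$response]], sub[[2]][[spec2$response]])
  # perfectly correlated responses make the bivariate model unidentified:
  # the genetic correlation is +/-1 by construction, so fit trait 1
  # univariately and report the implied degenerate G
  shared0 <- intersect(sub[[1]]$id, sub[[2]]$id)
  if (length(shared0) >= 3) {
    rp0 <- stats::cor(sub[[1]][[spec1$response]][match(shared0, sub[[1]]$id)],
                      sub[[2]][[spec2$response]][match(shared0, sub[[2]]$id)])
    if (is.finite(rp0) && abs(rp0) >= 1 - 1e-10 && !constrain_cov) {
      uni <- fit_univariate_reml(data, ped, spec1, A = A, ...)
      va <- uni$components[["V_A"]]; vr <- uni$components[["V_R"]]
      comps <- c("V_A:1" = va, "V_A:2" = va, COV_A = sign(rp0) * va,
                 "V_R:1" = vr, "V_R:2" = vr, COV_R = sign(rp0) * vr)
      return(structure(list(components = comps,
                            se = rep(NA_real_, length(comps)), cov = NULL,
                            logLik = uni$logLik, boundary = NULL,
                            psd_projected = FALSE, degenerate_pair = TRUE,
                            n = c(n1 = nrow(sub[[1]]), n2 = nrow(sub[[2]])),
                            ids = list(sub[[1]]$id, sub[[2]]$id),
                            specs = list(spec1, spec2),
                            constrain_cov = FALSE, iterations = uni$iterations),
                       class = "qg_reml_biv"))
    }
  }
  X1 <- build_design(sub[[1]], spec1$fixed, spec1$covariates)
  X2 <- build_design(sub[[2]], spec2$fixed, spec2$covariates)
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))
  ntot <- n1 + n2
  r1 <- seq_len(n1); r2 <- n1 + seq_len(n2)
  pad <- function(K, rows) {
    out <- matrix(0, ntot, ntot)
    out[rows, rows] <- K
    out
  }
  Ks <- list(); nonneg <- logical(0); em_q <- numeric(0)
  add_K <- function(K, name, nn, q) {
    Ks[[name]] <<- K; nonneg <<- c(nonneg, nn); em_q <<- c(em_q, q)
  }
  add_K(pad(A[sub[[1]]$id, sub[[1]]$id], r1), "V_A:1", TRUE, n1)
  add_K(pad(A[sub[[2]]$id, sub[[2]]$id], r2), "V_A:2", TRUE, n2)
  if (!constrain_cov) {
    Kc <- matrix(0, ntot, ntot)
    Kc[r1, r2] <- A[sub[[1]]$id, sub[[2]]$id]
    Kc[r2, r1] <- t(Kc[r1, r2])
    add_K(Kc, "COV_A", FALSE, ntot)
  }
  for (tr in 1:2) {
    for (tm in setdiff(specs[[tr]]$random, "animal")) {
      nm <- paste0("V_", c(micro = "f", dam = "m", sire = "s")[tm], ":", tr)
      add_K(pad(term_structure(tm, sub[[tr]]), if (tr == 1) r1 else r2),
            nm, TRUE,
            length(unique(sub[[tr]][[switch(tm, micro = "family",
                                            dam = "dam", sire = "sire")]])))
    }
  }
  add_K(pad(diag(n1), r1), "V_R:1", TRUE, n1)
  add_K(pad(diag(n2), r2), "V_R:2", TRUE, n2)
  shared <- intersect(sub[[1]]$id, sub[[2]]$id)
  if (length(shared) >= 3) {
    Kr <- matrix(0, ntot, ntot)
    i1 <- match(shared, sub[[1]]$id)
    i2 <- n1 + match(shared, sub[[2]]$id)
    Kr[cbind(i1, i2)] <- 1
    Kr[cbind(i2, i1)] <- 1
    add_K(Kr, "COV_R", FALSE, ntot)
  }
  # informed starts: split each trait's OLS residual variance equally over
  # its variance terms; start covariances from the phenotypic correlation
  start <- numeric(length(Ks))
  names(start) <- names(Ks)
  vtot <- vapply(1:2, function(tr) {
    rows <- if (tr == 1) r1 else r2
    Xt <- if (tr == 1) X1 else X2
    stats::var(stats::lm.fit(Xt, y[rows])$residuals)
  }, 0)
  for (nm in names(Ks)) {
    if (grepl(":1$", nm)) start[nm] <- vtot[1]
    if (grepl(":2$", nm)) start[nm] <- vtot[2]
  }
  for (tr in 1:2) {
    sel <- grepl(paste0(":", tr, "$"), names(Ks))
    start[sel] <- start[sel] / sum(sel)
  }
  if (length(shared) >= 3 || !constrain_cov) {
    m1 <- match(shared, sub[[1]]$id)
    m2 <- match(shared, sub[[2]]$id)
    r_p <- if (length(shared) >= 3)
      stats::cor(y[r1][m1], y[r2][m2]) else 0
    if (!is.finite(r_p)) r_p <- 0
    if ("COV_A" %in% names(Ks))
      start["COV_A"] <- 0.9 * r_p * sqrt(start[["V_A:1"]] * start[["V_A:2"]])
    if ("COV_R" %in% names(Ks))
      start["COV_R"] <- 0.9 * r_p * sqrt(start[["V_R:1"]] * start[["V_R:2"]])
  }
  fit <- reml_engine(y, X, Ks, nonneg = nonneg, em_q = em_q,
                     start = unname(start), ...)
  comps <- stats::setNames(fit$theta, names(Ks))
  # PSD projection of the 2x2 genetic covariance matrix
  psd_flag <- FALSE
  if ("COV_A" %in% names(comps)) {
    bound <- sqrt(comps[["V_A:1"]] * comps[["V_A:2"]])
    if (abs(comps[["COV_A"]]) > bound) {
      comps[["COV_A"]] <- sign(comps[["COV_A"]]) * bound
      psd_flag <- TRUE
    }
  }
  structure(list(components = comps,
                 se = stats::setNames(fit$se, names(Ks)), cov = fit$cov,
                 logLik = fit$logLik, boundary = fit$boundary,
                 psd_projected = psd_flag, n = c(n1 = n1, n2 = n2),
                 ids = list(sub[[1]]$id, sub[[2]]$id),
                 specs = list(spec1, spec2),
                 constrain_cov = constrain_cov,
                 iterations = fit$iterations), class = "qg_reml_biv")
}

#' Genetic correlation from a bivariate REML fit
#'
#' r_A = COV_A / sqrt(V_A1 V_A2), clamped to \[-1, 1\] after the PSD
#' projection. If the covariance-constrained fit is supplied, significance is
#' assessed by a 1-df likelihood-ratio test against it.
#'
#' @param fit unconstrained `qg_reml_biv` fit.
#' @param fit_constrained optional matching fit with `constrain_cov = TRUE`.
#' @return data frame with `r_A`, the component estimates, and (when the
#'   constrained fit is given) the LRT `statistic` and `p.value`. `r_A` is
#'   `NA` when either additive variance is zero.
#' @export
genetic_correlation <- function(fit, fit_constrained = NULL) {
  comps <- fit$components
  va1 <- comps[["V_A:1"]]; va2 <- comps[["V_A:2"]]
  cov_a <- comps[["COV_A"]]
  r <- if (va1 <= 0 || va2 <= 0) NA_real_ else
    max(-1, min(1, cov_a / sqrt(va1 * va2)))
  out <- data.frame(r_A = r, COV_A = cov_a, V_A1 = va1, V_A2 = va2,
                    statistic = NA_real_, df = NA_integer_,
                    p.value = NA_real_)
  if (!is.null(fit_constrained)) {
    stopifnot(inherits(fit_constrained, "qg_reml_biv"),
              fit_constrained$constrain_cov)
    chi2 <- max(0, 2 * (fit$logLik - fit_constrained$logLik))
    out$statistic <- chi2
    out$df <- 1L
    out$p.value <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  }
  out
}
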