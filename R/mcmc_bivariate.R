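#' Bivariate Gaussian + binary animal model by Gibbs sampling
#'
#' Joint animal model for one Gaussian trait and one binary (logit-link)
#' trait. The additive genetic effects of the two traits carry a full 2 x 2
#' covariance matrix G with an inverse-Wishart prior (conjugate update);
#' the binary liability is sampled by Polya-Gamma augmentation with its
#' residual variance fixed at 1; the Gaussian residual variance gets an
#' inverse-gamma prior; environmental random terms (`micro`, `dam`, `sire`)
#' are trait-specific and mutually independent, and the cross-trait residual
#' covariance is fixed at 0 (the genetic covariance is identified through
#' the pedigree).
#'
#' @param data phenotype data frame with an `id` column.
#' @param ped a `qg_pedigree`.
#' @param spec_gauss [qg_model()] for the Gaussian trait (must include
#'   `"animal"`).
#' @param spec_binary [threshold_model()] for the binary trait (must include
#'   `"animal"`).
#' @inheritParams fit_animal_mcmc
#' @return object of class `qg_mcmc_biv`: `draws` with columns `V_A1`,
#'   `V_A2`, `COV_A`, `r_A`, environmental variances, `V_R1`, `V_R2`;
#'   settings; posterior summaries via [posterior_mode()]/[hpd_interval()]
#'   on the columns.
#' @export
fit_bivariate_mcmc <- function(data, ped, spec_gauss, spec_binary,
                               nitt = 100000, burnin = 10000, thin = 90,
                               prior = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(spec_gauss, "qg_model"),
            inherits(spec_binary, "qg_threshold"),
            "animal" %in% spec_gauss$random,
            "animal" %in% spec_binary$random)
  if (!is.null(seed)) set.seed(seed)
  df <- merge_pedigree(data, ped)
  specs <- list(spec_gauss, spec_binary)
  sub <- lapply(specs, function(sp) {
    used <- c(sp$response, sp$covariates, intersect(sp$fixed, names(df)))
    df[stats::complete.cases(df[, used, drop = FALSE]), , drop = FALSE]
  })
  if (!length(intersect(sub[[1]]$id, sub[[2]]$id)))
    stop("the two traits share no individuals")
  y1 <- sub[[1]][[spec_gauss$response]]
  y2 <- as.integer(sub[[2]][[spec_binary$response]])
  if (!all(y2 %in% 0:1)) stop("binary response must be 0/1")
  n1 <- length(y1); n2 <- length(y2)
  N <- nrow(ped)
  Ainv <- sparse_ainverse(ped)
  X1 <- build_design(sub[[1]], spec_gauss$fixed, spec_gauss$covariates)
  X2 <- build_design(sub[[2]], spec_binary$fixed, spec_binary$covariates)
  p1 <- ncol(X1); p2 <- ncol(X2)

  env1 <- setdiff(spec_gauss$random, "animal")
  env2 <- setdiff(spec_binary$random, "animal")
  env_mats <- c(lapply(env1, random_term_matrices, df = sub[[1]], ped = ped,
                       Ainv = NULL),
                lapply(env2, random_term_matrices, df = sub[[2]], ped = ped,
                       Ainv = NULL))
  env_trait <- c(rep(1L, length(env1)), rep(2L, length(env2)))
  env_names <- c(if (length(env1))
    paste0("V_", c(micro = "f", dam = "m", sire = "s")[env1], "1"),
    if (length(env2))
      paste0("V_", c(micro = "f", dam = "m", sire = "s")[env2], "2"))
  Ke <- length(env_mats)
  qs <- vapply(env_mats, `[[`, 0, "q")

  Za1 <- Matrix::sparseMatrix(i = seq_len(n1), j = match(sub[[1]]$id, ped$id),
                              x = 1, dims = c(n1, N))
  Za2 <- Matrix::sparseMatrix(i = seq_len(n2), j = match(sub[[2]]$id, ped$id),
                              x = 1, dims = c(n2, N))
  zero <- function(nr, nc) Matrix::Matrix(0, nr, nc, sparse = TRUE)
  Wrow <- function(tr) {
    Xb <- if (tr == 1) cbind(Matrix::Matrix(X1, sparse = TRUE), zero(n1, p2))
          else cbind(zero(n2, p1), Matrix::Matrix(X2, sparse = TRUE))
    envb <- if (Ke) do.call(cbind, lapply(seq_len(Ke), function(k) {
      if (env_trait[k] == tr) env_mats[[k]]$Z
      else zero(if (tr == 1) n1 else n2, qs[k])
    })) else NULL
    ab <- if (tr == 1) cbind(Za1, zero(n1, N)) else cbind(zero(n2, N), Za2)
    if (is.null(envb)) cbind(Xb, ab) else cbind(Xb, envb, ab)
  }
  W <- rbind(Wrow(1), Wrow(2))
  ntheta <- p1 + p2 + sum(qs) + 2 * N
  offs_env <- p1 + p2 + cumsum(c(0, qs[-length(qs)]))
  idx_env <- lapply(seq_len(Ke), function(k) offs_env[k] + seq_len(qs[k]))
  idx_a <- p1 + p2 + sum(qs) + seq_len(2 * N)
  r1 <- seq_len(n1); r2 <- n1 + seq_len(n2)

  # priors
  vp1 <- stats::var(y1); vp2 <- 1 + pi^2 / 3
  k1 <- length(spec_gauss$random); k2 <- length(spec_binary$random)
  if (is.null(prior))
    prior <- list(nu = 0.002, nu_G = 2 + 0.002,
                  V_G = diag(c(vp1 / (k1 + 1), vp2 / (k2 + 1))),
                  V_env = vp1 / (k1 + 1), V_R = vp1 / (k1 + 1))
  G <- prior$V_G
  sigma2_env <- rep(vp1 / (k1 + 1), Ke)
  sigma2_e1 <- vp1 / (k1 + 1)
  theta <- numeric(ntheta)
  l2 <- (y2 - 0.5) * 2
  kappa2 <- y2 - 0.5

  keep <- seq.int(burnin + thin, nitt, by = thin)
  nkeep <- length(keep)
  cn <- c("V_A1", "V_A2", "COV_A", "r_A", env_names, "V_R1", "V_R2")
  draws <- matrix(NA_real_, nkeep, length(cn), dimnames = list(NULL, cn))

  for (it in seq_len(nitt)) {
    eta <- as.vector(W %*% theta)
    omega <- .rpg1(l2)
    prec_l <- 1 + omega
    l2 <- stats::rnorm(n2, (eta[r2] + kappa2) / prec_l, sqrt(1 / prec_l))
    yy <- c(y1, l2)
    wts <- c(rep(1 / sigma2_e1, n1), rep(1, n2))
    Ginv_kron <- Matrix::kronecker(solve(G), Ainv)
    blocks <- c(list(Matrix::Diagonal(p1 + p2, 0)),
                if (Ke) lapply(seq_len(Ke), function(k)
                  Matrix::Diagonal(qs[k]) / sigma2_env[k]),
                list(Ginv_kron))
    Wd <- W * wts  # row scaling
    C <- Matrix::forceSymmetric(Matrix::crossprod(W, Wd) +
                                Matrix::bdiag(blocks))
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE, super = FALSE)
    b <- Matrix::crossprod(Wd, yy)
    mu <- as.vector(Matrix::solve(ch, b, system = "A"))
    z <- stats::rnorm(ntheta)
    devn <- as.vector(Matrix::solve(ch,
              Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
    theta <- mu + devn
    # genetic covariance update (inverse-Wishart conjugate)
    U <- matrix(theta[idx_a], N, 2)
    S <- crossprod(U, as.matrix(Ainv %*% U))
    S <- (S + t(S)) / 2
    scale_post <- prior$nu_G * prior$V_G + S
    df_post <- prior$nu_G + N
    Winv <- stats::rWishart(1, df_post, solve(scale_post))[, , 1]
    G <- solve(Winv)
    G <- (G + t(G)) / 2
    for (k in seq_len(Ke)) {
      u <- theta[idx_env[[k]]]
      sigma2_env[k] <- 1 / stats::rgamma(1, shape = (qs[k] + prior$nu) / 2,
        rate = (sum(u^2) + prior$nu * prior$V_env) / 2)
    }
    resid1 <- y1 - as.vector(W[r1, ] %*% theta)
    sigma2_e1 <- 1 / stats::rgamma(1, shape = (n1 + prior$nu) / 2,
      rate = (sum(resid1^2) + prior$nu * prior$V_R) / 2)
    pos <- match(it, keep)
    if (!is.na(pos))
      draws[pos, ] <- c(G[1, 1], G[2, 2], G[1, 2],
                        G[1, 2] / sqrt(G[1, 1] * G[2, 2]),
                        sigma2_env, sigma2_e1, 1)
    if (verbose && it %% 10000 == 0) message("iteration ", it, " / ", nitt)
  }
  structure(list(draws = draws,
                 settings = list(nitt = nitt, burnin = burnin, thin = thin,
                                 seed = seed, prior = prior),
                 n = c(n1 = n1, n2 = n2), retained = nkeep,
                 specs = list(spec_gauss, spec_binary)),
            class = "qg_mcmc_biv")
}

#' Summarize the genetic correlation of a bivariate MCMC fit
#'
#' Posterior mode and 95% HPD interval of the per-draw genetic correlation;
#' the correlation is called significant when the HPD excludes 0.
#'
#' @param fit a `qg_mcmc_biv` fit.
#' @return list with `mode`, `hpd`, `significant`, `draws`.
#' @export
mcmc_genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "qg_mcmc_biv"))
  r <- fit$draws[, "r_A"]
  hpd <- hpd_interval(r)
  list(mode = posterior_mode(r), hpd = hpd,
       significant = hpd["lower"] > 0 || hpd["upper"] < 0, draws = r)
}
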