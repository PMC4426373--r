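#' Threshold (logit-link) animal-model specification
#'
#' A [qg_model()] for a binary response analysed on the liability scale with
#' a logit link: the residual variance of the latent liability is fixed at 1
#' and the logistic link contributes an extra pi^2/3 to the phenotypic
#' variance on the liability scale.
#'
#' @inheritParams qg_model
#' @return a `qg_model` with class `qg_threshold` and `link = "logit"`.
#' @export
threshold_model <- function(response, fixed = "generation",
                            random = c("micro", "animal"),
                            covariates = character()) {
  spec <- qg_model(response, fixed = fixed, random = random,
                   covariates = covariates)
  spec$link <- "logit"
  class(spec) <- c("qg_threshold", class(spec))
  spec
}

# Default inverse-gamma prior: the observed-scale phenotypic variance is
# divided equally among the random terms (incl. residual), with a small
# degree of belief nu.
default_prior <- function(n_random, vp, nu = 0.002) {
  list(nu = nu, V = vp / (n_random + 1))
}

# sparse random-effect design + prior-precision for one term
random_term_matrices <- function(term, df, ped, Ainv) {
  if (term == "animal") {
    Z <- Matrix::sparseMatrix(i = seq_len(nrow(df)),
                              j = match(df$id, ped$id), x = 1,
                              dims = c(nrow(df), nrow(ped)))
    return(list(Z = Z, Ginv = Ainv, q = nrow(ped)))
  }
  col <- switch(term, micro = "family", dam = "dam", sire = "sire")
  f <- factor(df[[col]])
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(df)), j = as.integer(f), x = 1,
                            dims = c(nrow(df), nlevels(f)))
  list(Z = Z, Ginv = Matrix::Diagonal(nlevels(f)), q = nlevels(f))
}

#' Fit a univariate animal model by Gibbs sampling
#'
#' Gaussian responses use standard conjugate updates; binary responses use
#' the logit link with Polya-Gamma data augmentation (all conditionals
#' conjugate) and the latent-liability residual variance fixed at 1.
#' Variance components get inverse-gamma priors that divide the phenotypic
#' variance equally among the random terms, with degree of belief `nu`
#' (vague by default).
#'
#' @param data phenotype data frame with an `id` column.
#' @param ped a `qg_pedigree`.
#' @param spec a [qg_model()] (Gaussian) or [threshold_model()] (binary).
#' @param nitt total iterations (default 100000).
#' @param burnin discarded initial iterations (default 10000).
#' @param thin thinning interval (default 90, giving 1000 retained draws at
#'   the defaults).
#' @param prior list with `nu` and scale `V` (default: [default_prior()]).
#' @param seed optional RNG seed, recorded in the result.
#' @param verbose print progress every 10000 iterations.
#' @return object of class `qg_mcmc`: matrix `draws` of variance components
#'   (binary models include the constant `V_R = 1` column), `fixef_draws`,
#'   `deviance` per draw, chain settings, and posterior-mean latents for
#'   [dic()].
#' @export
fit_animal_mcmc <- function(data, ped, spec, nitt = 100000, burnin = 10000,
                            thin = 90, prior = NULL, seed = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(spec, "qg_model"))
  binary <- inherits(spec, "qg_threshold")
  if (!is.null(seed)) set.seed(seed)
  df <- merge_pedigree(data, ped)
  used <- c(spec$response, spec$covariates, intersect(spec$fixed, names(df)))
  df <- df[stats::complete.cases(df[, used, drop = FALSE]), , drop = FALSE]
  y <- df[[spec$response]]
  n <- length(y)
  if (binary) {
    y <- as.integer(y)
    if (!all(y %in% 0:1)) stop("binary response must be 0/1")
    if (length(unique(y)) < 2) stop("binary response has a single class")
  }
  X <- build_design(df, spec$fixed, spec$covariates)
  if (binary) check_separation(df, spec$fixed, y)
  Ainv <- if ("animal" %in% spec$random) sparse_ainverse(ped) else NULL
  terms <- lapply(spec$random, random_term_matrices, df = df, ped = ped,
                  Ainv = Ainv)
  names(terms) <- spec$random
  K <- length(terms)
  vp_obs <- if (binary) 1 + pi^2 / 3 else stats::var(y)
  if (is.null(prior)) prior <- default_prior(K, vp_obs)
  nu <- prior$nu
  s2 <- prior$V

  p <- ncol(X)
  W <- Matrix::Matrix(X, sparse = TRUE)
  for (tm in terms) W <- cbind(W, tm$Z)
  qs <- vapply(terms, `[[`, 0, "q")
  offs <- p + cumsum(c(0, qs[-length(qs)]))  # start offset per term
  idx_term <- lapply(seq_len(K), function(k) offs[k] + seq_len(qs[k]))
  WtW <- Matrix::crossprod(W)
  ntheta <- p + sum(qs)

  sigma2 <- stats::setNames(rep(vp_obs / (K + 1), K), spec$random)
  sigma2_e <- if (binary) 1 else vp_obs / (K + 1)
  theta <- numeric(ntheta)
  l <- if (binary) (y - 0.5) * 2 else y  # latent liability init

  # --- precomputed sparse machinery -----------------------------------
  # The coefficient matrix C = W' R^-1 W + blockdiag(0, G_k^-1 / s2_k) is
  # assembled thousands of times with a fixed sparsity pattern, so we build
  # the pattern template once and refresh only the numeric values:
  #  - gvals[[k]] holds G_k^-1 aligned to the template entries;
  #  - Q maps per-observation residual weights to the W'R^-1W entries
  #    (row r of W contributes w_a * w_b * rinv_r to entry (a, b)).
  Gfull <- lapply(seq_len(K), function(k) {
    blocks <- c(list(Matrix::Diagonal(p, 0)),
                lapply(seq_len(K), function(j)
                  if (j == k) terms[[j]]$Ginv else
                    Matrix::Diagonal(qs[j], 0)))
    methods::as(Matrix::forceSymmetric(Matrix::bdiag(blocks)), "CsparseMatrix")
  })
  abs_x <- function(M) { M@x <- abs(M@x) + 1; M }
  tmplt <- Matrix::forceSymmetric(Reduce(`+`, c(list(abs_x(methods::as(
    Matrix::forceSymmetric(WtW), "CsparseMatrix"))), lapply(Gfull, abs_x))))
  tmplt <- methods::as(tmplt, "CsparseMatrix")
  t_j <- rep.int(seq_len(ntheta), diff(tmplt@p))
  t_code <- tmplt@i + as.numeric(ntheta) * (t_j - 1)
  align <- function(M) {
    j <- rep.int(seq_len(ntheta), diff(M@p))
    pos <- match(M@i + as.numeric(ntheta) * (j - 1), t_code)
    v <- numeric(length(t_code))
    v[pos] <- M@x
    v
  }
  gvals <- lapply(Gfull, align)
  Wtr <- methods::as(W, "TsparseMatrix")
  by_row <- split(data.frame(col = Wtr@j + 1L, val = Wtr@x), Wtr@i + 1L)
  q_i <- vector("list", length(by_row))
  q_j <- vector("list", length(by_row))
  q_x <- vector("list", length(by_row))
  for (r in seq_along(by_row)) {
    cc <- by_row[[r]]$col; vv <- by_row[[r]]$val
    pr_ <- expand.grid(a = seq_along(cc), b = seq_along(cc))
    pr_ <- pr_[cc[pr_$a] <= cc[pr_$b], ]  # upper triangle of C
    code <- (cc[pr_$a] - 1L) + as.numeric(ntheta) * (cc[pr_$b] - 1L)
    q_i[[r]] <- match(code, t_code)
    q_j[[r]] <- rep.int(as.integer(names(by_row)[r]), nrow(pr_))
    q_x[[r]] <- vv[pr_$a] * vv[pr_$b]
  }
  Qmap <- Matrix::sparseMatrix(i = unlist(q_i), j = unlist(q_j),
                               x = unlist(q_x),
                               dims = c(length(t_code), n))
  base_w <- as.vector(Qmap %*% rep(1, n))  # W'W entries on the template
  chol_fac <- {
    tmplt@x <- base_w / sigma2_e +
      Reduce(`+`, lapply(seq_len(K), function(k) gvals[[k]] / sigma2[k]))
    Matrix::Cholesky(tmplt, LDL = FALSE, perm = TRUE, super = FALSE)
  }

  # Marginal log-likelihood of the working data at the given variances, with
  # the location effects AND random effects integrated out via the
  # mixed-model equations: for Gaussian traits the data are y with residual
  # variance sigma2_e; for binary traits, conditional on the Polya-Gamma
  # weights omega, the likelihood in eta is Gaussian with working response
  # kappa/omega and residual variance 1 + 1/omega (the +1 is the fixed
  # liability residual), so the liabilities never enter. Terms constant in
  # the variances are dropped (only Metropolis differences matter).
  # Returns the Cholesky factor and conditional mean for the location draw.
  eval_state <- function(wvals, b, quad0, logdetR, sigma2, sigma2_e) {
    Cx <- wvals / sigma2_e
    for (k in seq_len(K)) Cx <- Cx + gvals[[k]] / sigma2[k]
    tmplt@x <- Cx
    ch <- update(chol_fac, tmplt)
    bb <- b / sigma2_e
    th <- Matrix::solve(ch, bb, system = "A")
    quad <- quad0 / sigma2_e - sum(th@x * bb@x)
    ldC <- 2 * c(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    ll <- -0.5 * (logdetR + n * log(sigma2_e) + sum(qs * log(sigma2)) +
                  ldC + quad)
    list(ll = ll, ch = ch, th = as.vector(th))
  }
  # IG(nu/2, nu*s2/2) prior density on each variance, plus the log-scale
  # Jacobian of the Metropolis parameterization
  log_prior <- function(v2) sum(-(nu / 2) * log(v2) - (nu * s2 / 2) / v2)

  keep <- seq.int(burnin + thin, nitt, by = thin)
  nkeep <- length(keep)
  if (nkeep < 1) stop("no retained draws: check nitt/burnin/thin")
  vnames <- c(paste0("V_", c(micro = "f", dam = "m", sire = "s",
                             animal = "A")[spec$random]), "V_R")
  draws <- matrix(NA_real_, nkeep, K + 1,
                  dimnames = list(NULL, vnames))
  fixef_draws <- matrix(NA_real_, nkeep, p, dimnames = list(NULL, colnames(X)))
  deviance <- numeric(nkeep)
  latent_sum <- numeric(n)
  s <- 0L
  kappa <- if (binary) y - 0.5 else NULL

  # Metropolis state: log variances (residual appended for Gaussian traits)
  n_mh <- 3L
  step <- 0.5
  logv <- log(c(sigma2, if (!binary) sigma2_e))
  nv <- length(logv)
  if (!binary) {
    wvals0 <- base_w
    b0 <- Matrix::crossprod(W, y)
    quad0 <- sum(y^2)
  }
  cur <- NULL

  for (it in seq_len(nitt)) {
    if (binary) {
      omega <- .rpg1(l)
      prec_l <- 1 + omega
      rinv <- omega / prec_l
      wvals0 <- as.vector(Qmap %*% rinv)
      b0 <- Matrix::crossprod(W, kappa / prec_l)
      quad0 <- 0  # constant in the variances given omega; dropped
      cur <- NULL
    }
    if (is.null(cur)) {
      cur <- eval_state(wvals0, b0, quad0, 0, sigma2, sigma2_e)
      cur_post <- cur$ll + log_prior(exp(logv))
    }
    # variance components: random-walk Metropolis on the log scale against
    # the collapsed posterior (locations, random effects and - for binary
    # traits - liabilities all integrated out)
    for (prop in seq_len(n_mh)) {
      logv_new <- logv + stats::rnorm(nv, 0, step)
      v_new <- exp(logv_new)
      s2_new <- v_new[seq_len(K)]
      s2e_new <- if (binary) 1 else v_new[nv]
      st_new <- eval_state(wvals0, b0, quad0, 0, s2_new, s2e_new)
      post_new <- st_new$ll + log_prior(v_new)
      acc <- log(stats::runif(1)) < post_new - cur_post
      if (acc) {
        logv <- logv_new
        sigma2 <- s2_new
        sigma2_e <- s2e_new
        cur <- st_new
        cur_post <- post_new
      }
      if (it <= burnin)  # adapt toward ~35% acceptance during burn-in
        step <- exp(log(step) + 0.05 * ((if (acc) 1 else 0) - 0.35))
    }
    # joint location draw at the accepted variances
    z <- stats::rnorm(ntheta)
    dev <- as.vector(Matrix::solve(cur$ch,
             Matrix::solve(cur$ch, z, system = "Lt"), system = "Pt"))
    theta <- cur$th + dev
    if (binary) {
      eta <- as.vector(W %*% theta)
      l <- stats::rnorm(n, (eta + kappa) / prec_l, sqrt(1 / prec_l))
      # ancillarity move: rescale one random term and its variance jointly
      # (u_k = s_k w_k with w_k fixed), Metropolis-corrected for the prior;
      # moves the scale direction that conditioning on omega pins down
      for (k in seq_len(K)) {
        s_old <- sqrt(sigma2[k])
        idx <- idx_term[[k]]
        u <- theta[idx]
        Zw <- as.vector(terms[[k]]$Z %*% u) / s_old
        ssq <- sum(Zw^2)
        if (ssq < 1e-12) next
        r <- l - eta + s_old * Zw
        m <- sum(r * Zw) / ssq
        s_new <- stats::rnorm(1, m, sqrt(1 / ssq))
        if (abs(s_new) < 1e-12) next
        log_acc <- -(nu + 1) * (log(abs(s_new)) - log(s_old)) -
          (nu * s2 / 2) * (1 / s_new^2 - 1 / s_old^2)
        if (log(stats::runif(1)) < log_acc) {
          theta[idx] <- (s_new / s_old) * u
          sigma2[k] <- s_new^2
          eta <- eta + (s_new - s_old) * Zw
        }
      }
      logv <- log(sigma2)
      cur <- NULL  # variances changed; collapsed state must be re-evaluated
    }
    pos <- match(it, keep)
    if (!is.na(pos)) {
      s <- s + 1L
      draws[pos, ] <- c(sigma2, sigma2_e)
      fixef_draws[pos, ] <- theta[seq_len(p)]
      if (binary) {
        pr <- stats::plogis(l)
        deviance[pos] <- -2 * sum(y * log(pr) + (1 - y) * log1p(-pr))
        latent_sum <- latent_sum + l
      } else {
        mu_y <- as.vector(W %*% theta)
        deviance[pos] <- -2 * sum(stats::dnorm(y, mu_y, sqrt(sigma2_e),
                                               log = TRUE))
        latent_sum <- latent_sum + mu_y
      }
    }
    if (verbose && it %% 10000 == 0)
      message("iteration ", it, " / ", nitt)
  }
  structure(list(draws = draws, fixef_draws = fixef_draws,
                 deviance = deviance, latent_mean = latent_sum / nkeep,
                 y = y, binary = binary, spec = spec,
                 settings = list(nitt = nitt, burnin = burnin, thin = thin,
                                 seed = seed, prior = prior),
                 n = n, retained = nkeep), class = "qg_mcmc")
}

#' @rdname fit_animal_mcmc
#' @export
fit_binary_animal_mcmc <- function(data, ped, spec, ...) {
  if (!inherits(spec, "qg_threshold"))
    stop("spec must be a threshold_model()")
  fit_animal_mcmc(data, ped, spec, ...)
}

# warn when a fixed-effect level is perfectly separated (all-0 or all-1)
check_separation <- function(df, fixed, y) {
  for (f in fixed) {
    tab <- table(df[[f]], y)
    if (any(tab == 0 & rowSums(tab) > 0))
      warning("fixed effect '", f, "' has a level with an all-0 or all-1 ",
              "response; its estimate is prior-dominated")
  }
  invisible(NULL)
}

#' Liability-scale heritability from binary-model draws
#'
#' Per draw, h2 = V_A / (V_f + V_m + V_s + V_A + V_R + pi^2/3) with the
#' residual fixed at 1; the pi^2/3 term is the variance of the logistic link.
#' Summarized by the posterior mode and 95% HPD interval.
#'
#' @param samples a `qg_mcmc` fit of a binary trait, or a matrix/vector of
#'   variance-component draws with a `V_A` column.
#' @return list with `draws`, `mode`, `hpd` (95%).
#' @export
binary_heritability <- function(samples) {
  draws <- if (inherits(samples, "qg_mcmc")) samples$draws else
    as.matrix(samples)
  if (!"V_A" %in% colnames(draws)) stop("draws must include a V_A column")
  h2 <- unname(draws[, "V_A"] / (rowSums(draws) + pi^2 / 3))
  list(draws = h2,
       mode = if (length(h2) >= 100) posterior_mode(h2) else mean(h2),
       hpd = if (length(h2) >= 100) hpd_interval(h2) else
         c(lower = min(h2), upper = max(h2)))
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' (sorted-window algorithm).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 100) stop("need at least 100 draws")
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Posterior mode by kernel density estimation
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth by default. A
#' `multimodal` attribute flags densities with more than one substantial
#' local maximum (secondary peaks above half the main peak).
#'
#' @param draws numeric vector of at least 100 draws (constant vectors are
#'   returned as-is).
#' @param bw bandwidth specification passed to [stats::density()].
#' @return the mode (scalar), with attribute `multimodal`.
#' @export
posterior_mode <- function(draws, bw = "nrd0") {
  x <- draws[is.finite(draws)]
  if (length(unique(x)) == 1L)
    return(structure(x[1], multimodal = FALSE))
  if (length(x) < 100) stop("need at least 100 draws")
  d <- stats::density(x, bw = bw)
  mode <- d$x[which.max(d$y)]
  yy <- d$y
  peaks <- which(diff(sign(diff(yy))) == -2) + 1L
  multi <- sum(yy[peaks] > 0.5 * max(yy)) > 1
  structure(mode, multimodal = multi)
}

#' Lag-autocorrelation diagnostics of retained draws
#'
#' Lag-1 autocorrelation per variance component; the chain passes when every
#' finite autocorrelation is below 0.1 in magnitude (constant components are
#' reported `NA` and ignored).
#'
#' @param samples a `qg_mcmc` fit or a draws matrix.
#' @param lag lag at which to report the autocorrelation (default 1).
#' @return list with `autocorr` (named vector), `pass` (logical), `lag`.
#' @export
chain_diagnostics <- function(samples, lag = 1) {
  draws <- if (inherits(samples, "qg_mcmc")) samples$draws else
    as.matrix(samples)
  ac <- apply(draws, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::acf(x, lag.max = lag, plot = FALSE)$acf[lag + 1]
  })
  list(autocorr = ac, pass = all(abs(ac) < 0.1, na.rm = TRUE), lag = lag)
}

#' Deviance information criterion
#'
#' DIC = mean posterior deviance + pD, with the effective parameter count
#' pD = mean deviance - deviance at the posterior mean of the latent
#' predictor (and residual variance, for Gaussian responses). For binary
#' models the deviance is conditional on the latent liabilities.
#'
#' @param fit a `qg_mcmc` fit.
#' @return scalar DIC, with attributes `Dbar` and `pD`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "qg_mcmc"))
  dbar <- mean(fit$deviance)
  if (fit$binary) {
    pr <- stats::plogis(fit$latent_mean)
    dhat <- -2 * sum(fit$y * log(pr) + (1 - fit$y) * log1p(-pr))
  } else {
    s2 <- mean(fit$draws[, "V_R"])
    dhat <- -2 * sum(stats::dnorm(fit$y, fit$latent_mean, sqrt(s2),
                                  log = TRUE))
  }
  pd <- dbar - dhat
  structure(dbar + pd, Dbar = dbar, pD = pd)
}

#' @export
print.qg_mcmc <- function(x, ...) {
  cat("Bayesian animal model (", if (x$binary) "logit threshold" else
    "Gaussian", "): ", x$spec$response, "\n", sep = "")
  cat("n =", x$n, ", retained draws =", x$retained, "\n")
  modes <- apply(x$draws, 2, function(v)
    if (stats::sd(v) == 0) v[1] else posterior_mode(v))
  hpds <- apply(x$draws, 2, function(v)
    if (stats::sd(v) == 0) c(v[1], v[1]) else hpd_interval(v))
  tab <- data.frame(mode = modes, hpd_low = hpds[1, ], hpd_high = hpds[2, ])
  print(tab, ...)
  invisible(x)
}
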