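#' Simulation configuration
#'
#' Defaults emulate the study design: 73 wild founders (anadromous and
#' resident dams and sires), 75 F1 full/half-sib families (mean 88
#' offspring) of the four pure cross types, and 69 F2 families (mean 137
#' offspring) including the AR x AR and RA x RA intercrosses, for roughly
#' 16,000 individuals across three generations. Family sizes are drawn from
#' a negative binomial matched to the reported means; half-sib structure
#' arises from parent pools smaller than the family count (42 dams / 31
#' sires in F1, 41 / 53 in F2).
#'
#' @param founders named integer vector `c(dam_A, dam_R, sire_A, sire_R)`.
#' @param f1_families,f2_families named integer vectors of family counts per
#'   cross type.
#' @param f1_mean_size,f2_mean_size mean offspring per family.
#' @param size_dispersion negative-binomial size parameter of family sizes.
#' @param min_family_size lower clamp on family sizes.
#' @param f1_parent_pool,f2_parent_pool `c(dams, sires)` pool sizes drawn on
#'   to create families (sharing rate = families / pool).
#' @param smolt_prevalence,mature_prevalence,indeterminate_rate target class
#'   fractions of the shared-liability life-history generator.
#' @param missing_rate fraction of phenotype records set missing at random.
#' @return a `sim_config` list.
#' @export
sim_config <- function(founders = c(dam_A = 21, dam_R = 21,
                                    sire_A = 16, sire_R = 15),
                       f1_families = c(AxA = 23, AxR = 15, RxA = 19,
                                       RxR = 18),
                       f2_families = c(AxA = 15, AxR = 10, RxA = 13,
                                       RxR = 11, ARxAR = 10, RAxRA = 10),
                       f1_mean_size = 88, f2_mean_size = 137,
                       size_dispersion = 8, min_family_size = 2,
                       f1_parent_pool = c(dams = 42, sires = 31),
                       f2_parent_pool = c(dams = 41, sires = 53),
                       smolt_prevalence = 0.716,
                       mature_prevalence = 0.127,
                       indeterminate_rate = 0.04,
                       missing_rate = 0.02) {
  cfg <- list(founders = founders, f1_families = f1_families,
              f2_families = f2_families, f1_mean_size = f1_mean_size,
              f2_mean_size = f2_mean_size,
              size_dispersion = size_dispersion,
              min_family_size = min_family_size,
              f1_parent_pool = f1_parent_pool,
              f2_parent_pool = f2_parent_pool,
              smolt_prevalence = smolt_prevalence,
              mature_prevalence = mature_prevalence,
              indeterminate_rate = indeterminate_rate,
              missing_rate = missing_rate)
  stopifnot(all(unlist(cfg[1:3]) >= 0), f1_mean_size >= 1, f2_mean_size >= 1,
            !is.null(names(f1_families)), !is.null(names(f2_families)))
  class(cfg) <- "sim_config"
  cfg
}

# dam/sire morph required by a cross-type token ("AR" = F1 of an AxR cross)
cross_parents <- function(xtype) {
  switch(xtype,
         AxA = c("A", "A"), AxR = c("A", "R"),
         RxA = c("R", "A"), RxR = c("R", "R"),
         ARxAR = c("AR", "AR"), RAxRA = c("RA", "RA"),
         stop("unknown cross type: ", xtype))
}

family_sizes <- function(nfam, mu, size, minsize) {
  pmax(stats::rnbinom(nfam, mu = mu, size = size), minsize)
}

#' Simulate a three-generation study-like pedigree
#'
#' P1 founders, F1 families of the four pure cross types, and F2 families
#' including the two intercross types, with half-sib structure from shared
#' parents. Deterministic under `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a `qg_pedigree`.
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  fo <- cfg$founders
  dams <- c(sprintf("P1DA%02d", seq_len(fo["dam_A"])),
            sprintf("P1DR%02d", seq_len(fo["dam_R"])))
  sires <- c(sprintf("P1SA%02d", seq_len(fo["sire_A"])),
             sprintf("P1SR%02d", seq_len(fo["sire_R"])))
  dam_morph <- rep(c("A", "R"), fo[c("dam_A", "dam_R")])
  sire_morph <- rep(c("A", "R"), fo[c("sire_A", "sire_R")])
  rows <- data.frame(id = c(dams, sires), sire = NA, dam = NA,
                     generation = "P1", cross_type = "founder", family = NA)

  pick_pool <- function(ids, npool) {
    npool <- min(npool, length(ids))
    sample(ids, npool)
  }
  make_families <- function(fam_counts, gen, mean_size, pool_sizes,
                            dam_sets, sire_sets) {
    # dam_sets/sire_sets: named lists morph -> candidate parent ids
    fam_rows <- list()
    counter <- 0L
    for (xt in names(fam_counts)) {
      nf <- fam_counts[[xt]]
      if (nf == 0) next
      pm <- cross_parents(xt)
      dcand <- dam_sets[[pm[1]]]
      scand <- sire_sets[[pm[2]]]
      if (!length(dcand) || !length(scand))
        stop("no available parents for cross type ", xt)
      dn <- max(1, round(nf * pool_sizes["dams"] / sum(fam_counts)))
      sn <- max(1, round(nf * pool_sizes["sires"] / sum(fam_counts)))
      # grow the pools when the requested sharing rate is infeasible for a
      # small cross-type count
      while (dn * sn < nf && (dn < length(dcand) || sn < length(scand))) {
        if (dn < length(dcand) &&
            (sn >= length(scand) || dn / length(dcand) <= sn / length(scand)))
          dn <- dn + 1
        else sn <- sn + 1
      }
      dpool <- pick_pool(dcand, dn)
      spool <- pick_pool(scand, sn)
      if (length(dpool) * length(spool) < nf)
        stop("infeasible config: ", nf, " ", xt,
             " families but only ", length(dpool) * length(spool),
             " distinct parent pairs")
      d_i <- rep_len(seq_along(dpool), nf)
      s_i <- (rep_len(seq_along(spool), nf) +
                rep(seq_len(nf) - 1L, 1) %/% length(spool)) %%
        length(spool) + 1L
      sizes <- family_sizes(nf, mean_size, cfg$size_dispersion,
                            cfg$min_family_size)
      for (f in seq_len(nf)) {
        counter <- counter + 1L
        fam_id <- sprintf("%s_%s_%02d", gen, xt, f)
        n_off <- sizes[f]
        fam_rows[[length(fam_rows) + 1L]] <- data.frame(
          id = sprintf("%s%s%02dI%03d", gen, xt, f, seq_len(n_off)),
          sire = spool[s_i[f]], dam = dpool[d_i[f]],
          generation = gen, cross_type = xt, family = fam_id)
      }
    }
    do.call(rbind, fam_rows)
  }

  f1 <- make_families(cfg$f1_families, "F1", cfg$f1_mean_size,
                      cfg$f1_parent_pool,
                      dam_sets = split(dams, dam_morph),
                      sire_sets = split(sires, sire_morph))
  # F2 parents come from F1 individuals of the matching cross background:
  # "AR" parents are F1 fish from AxR families, "RA" from RxA; pure-type F2
  # families use F1 parents of the same pure cross type.
  f1_by_type <- split(f1$id, f1$cross_type)
  background <- function(m) switch(m, A = f1_by_type[["AxA"]],
                                   R = f1_by_type[["RxR"]],
                                   AR = f1_by_type[["AxR"]],
                                   RA = f1_by_type[["RxA"]])
  morphs <- unique(unlist(lapply(names(cfg$f2_families), cross_parents)))
  dam_sets2 <- sire_sets2 <- list()
  for (m in morphs) {
    cand <- background(m)
    half <- sample(cand)
    dam_sets2[[m]] <- half[seq_len(ceiling(length(half) / 2))]
    sire_sets2[[m]] <- setdiff(half, dam_sets2[[m]])
  }
  f2 <- make_families(cfg$f2_families, "F2", cfg$f2_mean_size,
                      cfg$f2_parent_pool,
                      dam_sets = dam_sets2, sire_sets = sire_sets2)
  all_rows <- rbind(rows, f1, f2)
  pedigree(id = all_rows$id, sire = all_rows$sire, dam = all_rows$dam,
           generation = all_rows$generation,
           cross_type = all_rows$cross_type, family = all_rows$family)
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw from N(0, G); each non-founder is the parent average plus a
#' Mendelian-sampling deviation with covariance G/2 scaled by
#' (1 - (F_s + F_d)/2) (or the single-known-parent analogue).
#'
#' @param ped a `qg_pedigree`.
#' @param G additive genetic covariance: scalar variance or t x t PSD matrix.
#' @param seed RNG seed.
#' @return N x t matrix of breeding values, rownames = ids.
#' @export
simulate_breeding_values <- function(ped, G, seed = 1) {
  set.seed(seed)
  G <- as.matrix(G)
  t_n <- ncol(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("G must be positive semidefinite")
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  Fi <- inbreeding(ped)
  bv <- matrix(0, n, t_n, dimnames = list(ped$id, colnames(G)))
  rmvn <- function(m, S) {
    if (all(S == 0)) return(matrix(0, m, ncol(S)))
    MASS::mvrnorm(m, mu = rep(0, ncol(S)), Sigma = S)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      bv[i, ] <- rmvn(1, G)
    } else if (is.na(s) || is.na(d)) {
      p <- if (is.na(s)) d else s
      bv[i, ] <- 0.5 * bv[p, ] + rmvn(1, (0.75 - 0.25 * Fi[p]) * G)
    } else {
      ms_scale <- 0.5 * (1 - 0.5 * (Fi[s] + Fi[d]))
      bv[i, ] <- 0.5 * (bv[s, ] + bv[d, ]) + rmvn(1, ms_scale * G)
    }
  }
  bv
}

#' Trait generator configuration
#'
#' @param mu grand mean.
#' @param Vf,Vm,Vs,VA,VR variance components (family/micro, maternal
#'   environment, paternal environment, additive genetic, residual).
#' @param gen_effects,xtype_effects named fixed-effect shifts by generation /
#'   cross type (unnamed levels get 0).
#' @return a `trait_config` list.
#' @export
trait_config <- function(mu = 0, Vf = 0, Vm = 0, Vs = 0, VA = 0, VR = 1,
                         gen_effects = NULL, xtype_effects = NULL) {
  stopifnot(Vf >= 0, Vm >= 0, Vs >= 0, VA >= 0, VR >= 0)
  structure(list(mu = mu, Vf = Vf, Vm = Vm, Vs = Vs, VA = VA, VR = VR,
                 gen_effects = gen_effects, xtype_effects = xtype_effects),
            class = "trait_config")
}

effect_lookup <- function(levels_vec, effects) {
  if (is.null(effects)) return(numeric(length(levels_vec)))
  out <- effects[levels_vec]
  out[is.na(out)] <- 0
  unname(out)
}

# structural (non-residual) part of one trait on phenotyped individuals
structural_part <- function(ped, rows, tc, bv) {
  fam <- factor(ped$family[rows])
  dam <- factor(ped$dam[rows])
  sire <- factor(ped$sire[rows])
  eff <- function(f, v) {
    if (v == 0) return(numeric(length(rows)))
    stats::rnorm(nlevels(f), 0, sqrt(v))[as.integer(f)]
  }
  tc$mu +
    effect_lookup(ped$generation[rows], tc$gen_effects) +
    effect_lookup(ped$cross_type[rows], tc$xtype_effects) +
    eff(fam, tc$Vf) + eff(dam, tc$Vm) + eff(sire, tc$Vs) +
    if (tc$VA > 0) bv[rows] else 0
}

#' Simulate phenotypes over a pedigree
#'
#' Gaussian traits follow `mu + generation + cross_type + family(Vf) +
#' dam(Vm) + sire(Vs) + breeding value + N(0, VR)`. The life-history
#' category comes from a single shared liability with logistic residuals
#' (variance pi^2/3) and two opposite-tail thresholds solved to hit the
#' configured smolt and mature prevalences, which makes the logit-scale
#' heritability formula the exact estimand and couples the two binary traits
#' near r_A = -1. Founders (generation P1) are unphenotyped.
#'
#' @param ped a `qg_pedigree`.
#' @param traits named list of [trait_config()]s; breeding values for traits
#'   with `VA > 0` are simulated internally from a diagonal G unless `bvs`
#'   (a matrix with matching columns) is given.
#' @param cfg a [sim_config()] (controls life-history prevalences and
#'   missingness).
#' @param seed RNG seed.
#' @param bvs optional precomputed breeding-value matrix (rownames = ids).
#' @param liability optional [trait_config()] for the life-history liability
#'   (default: VA = 2, Vf = 0.3, no fixed effects).
#' @param life_history logical: generate the life-history category.
#' @return phenotype data frame (`id`, one column per trait, `life_history`,
#'   `LHSmolt`, `LHMature` when requested).
#' @export
simulate_phenotypes <- function(ped, traits = list(), cfg = sim_config(),
                                seed = 1, bvs = NULL, liability = NULL,
                                life_history = TRUE) {
  set.seed(seed)
  rows <- which(ped$generation != "P1" | is.na(ped$generation))
  n <- length(rows)
  out <- data.frame(id = ped$id[rows])
  need_bv <- names(traits)[vapply(traits, function(tc) tc$VA > 0, TRUE)]
  if (is.null(bvs) && length(need_bv)) {
    G <- diag(vapply(traits[need_bv], `[[`, 0, "VA"), length(need_bv))
    colnames(G) <- need_bv
    bvs <- simulate_breeding_values(ped, G, seed = seed + 1L)
  }
  for (nm in names(traits)) {
    tc <- traits[[nm]]
    bvcol <- if (tc$VA > 0) bvs[, nm] else NULL
    y <- structural_part(ped, rows, tc, bvcol) +
      stats::rnorm(n, 0, sqrt(tc$VR))
    if (cfg$missing_rate > 0)
      y[stats::runif(n) < cfg$missing_rate] <- NA
    out[[nm]] <- y
  }
  if (life_history) {
    if (is.null(liability)) liability <- trait_config(VA = 2, Vf = 0.3)
    bvl <- if (liability$VA > 0)
      simulate_breeding_values(ped, liability$VA, seed = seed + 2L)[, 1]
    else NULL
    part <- structural_part(ped, rows, liability, bvl)
    liab <- part + stats::rlogis(n)
    t_hi <- prevalence_threshold(part, cfg$smolt_prevalence, upper = TRUE)
    t_lo <- prevalence_threshold(part, cfg$mature_prevalence, upper = FALSE)
    cat_ <- ifelse(liab > t_hi, "smolt",
                   ifelse(liab < t_lo, "mature", "parr"))
    mid <- which(cat_ == "parr")
    frac_mid <- length(mid) / n
    if (frac_mid > 0 && cfg$indeterminate_rate > 0) {
      q <- min(1, cfg$indeterminate_rate / frac_mid)
      flip <- mid[stats::runif(length(mid)) < q]
      cat_[flip] <- "indeterminate"
    }
    out$life_history <- cat_
    lh <- binarize_life_history(cat_)
    out$LHSmolt <- lh$LHSmolt
    out$LHMature <- lh$LHMature
  }
  out
}

# threshold t with P(part + logistic > t) = prev (upper) or
# P(part + logistic < t) = prev (lower), marginalizing over the realized
# structural+genetic liability parts
prevalence_threshold <- function(part, prev, upper = TRUE) {
  f <- if (upper) function(t) mean(stats::plogis(part - t)) - prev
       else function(t) mean(stats::plogis(t - part)) - prev
  lim <- max(abs(part)) + 50
  stats::uniroot(f, c(-lim, lim))$root
}

#' Simulate landmark configurations with known shape structure
#'
#' Shapes are the consensus plus independent Gaussian deviations along
#' orthonormal shape axes confined to the tangent space (orthogonal to
#' translation, scale and rotation at the consensus), then disguised with
#' random rotation, translation and log-normal scale nuisance.
#'
#' @param n number of configurations.
#' @param axis_variances variances along the shape axes, in squared units of
#'   unit-centroid-size shape space (default `c(4, 2, 1) * 1e-4`).
#' @param consensus optional k x 2 reference (default: a 13-landmark fish
#'   outline).
#' @param size_mean,size_cv centroid-size nuisance: log-normal with this
#'   mean and coefficient of variation.
#' @param seed RNG seed.
#' @return `qg_landmarks` list of k x 2 matrices, with attributes
#'   `consensus` (unit size) and `axes`.
#' @export
simulate_landmarks <- function(n, axis_variances = c(4, 2, 1) * 1e-4,
                               consensus = NULL, size_mean = 1800,
                               size_cv = 0.35, seed = 1) {
  set.seed(seed)
  if (is.null(consensus)) consensus <- fish_consensus()
  k <- nrow(consensus)
  consensus <- sweep(consensus, 2, colMeans(consensus))
  consensus <- consensus / sqrt(sum(consensus^2))
  na <- length(axis_variances)
  if (na > 2 * k - 4)
    stop("at most ", 2 * k - 4, " shape axes for ", k, " landmarks")
  S <- similarity_basis(consensus)
  raw <- matrix(stats::rnorm(2 * k * na), 2 * k, na)
  raw <- raw - S %*% crossprod(S, raw)
  axes <- qr.Q(qr(raw))[, seq_len(na), drop = FALSE]
  shapes <- vector("list", n)
  sdlog <- sqrt(log(1 + size_cv^2))
  for (i in seq_len(n)) {
    scores <- stats::rnorm(na, 0, sqrt(axis_variances))
    dev <- axes %*% scores
    m <- consensus + matrix(dev, k, 2, byrow = TRUE)
    sz <- size_mean * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    m <- sz * (m %*% R)
    m <- sweep(m, 2, stats::runif(2, -500, 500), `+`)
    shapes[[i]] <- m
  }
  names(shapes) <- sprintf("sim%04d", seq_len(n))
  structure(shapes, class = c("qg_landmarks", "list"),
            consensus = consensus, axes = axes)
}

# 13-landmark left-side fish outline (snout, head, dorsal fin base,
# caudal peduncle, tail fork, ventral landmarks), digitizing order
# snout -> dorsal -> caudal -> ventral
fish_consensus <- function() {
  cbind(
    x = c(0.00, 0.12, 0.35, 0.55, 0.78, 0.92, 1.00, 0.92, 0.78, 0.55,
          0.30, 0.10, 0.02),
    y = c(0.00, 0.10, 0.14, 0.12, 0.08, 0.05, 0.00, -0.05, -0.08, -0.12,
          -0.13, -0.09, -0.04))
}
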