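# Shared fixtures and independent oracles for the test suite.

# small study-shaped simulation config (sizes chosen so a full REML or MCMC
# fit runs in seconds; the methods vignette records the scaling)
small_cfg <- function(scale = 1, ...) {
  sim_config(
    f1_families = pmax(round(c(AxA = 8, AxR = 6, RxA = 6, RxR = 6) * scale), 1),
    f2_families = pmax(round(c(AxA = 5, AxR = 4, RxA = 4, RxR = 4,
                               ARxAR = 3, RAxRA = 3) * scale), 1),
    f1_mean_size = 12, f2_mean_size = 14, missing_rate = 0, ...)
}

# random pedigree generator for relationship-matrix property tests:
# nf founders then random matings (possibly inbred loops) across rounds
random_pedigree <- function(n, nf = max(4L, round(n / 4)), seed = 1) {
  set.seed(seed)
  id <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    pool <- seq_len(i - 1L)
    pair <- sample(pool, 2)
    sire[i] <- id[pair[1]]
    dam[i] <- id[pair[2]]
  }
  pedigree(id, sire, dam)
}

# Gene-dropping Monte Carlo oracle for additive relationships: founders get
# unique allele labels, alleles segregate independently down the pedigree;
# a_ij is estimated as twice the realized kinship (mean IBD probability of
# randomly drawn alleles), a_ii as 1 + P(the two alleles of i are IBD).
gene_drop_alleles <- function(ped, reps) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A1 <- matrix(0L, reps, n)
  A2 <- matrix(0L, reps, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    for (slot in 1:2) {
      p <- if (slot == 1) si[i] else di[i]
      if (is.na(p)) {
        next_allele <- next_allele + 1L
        val <- rep.int(next_allele, reps)
      } else {
        pick <- stats::runif(reps) < 0.5
        val <- ifelse(pick, A1[, p], A2[, p])
      }
      if (slot == 1) A1[, i] <- val else A2[, i] <- val
    }
  }
  list(A1 = A1, A2 = A2, ids = ped$id)
}

gene_drop_a <- function(drop, i, j) {
  A1 <- drop$A1; A2 <- drop$A2
  if (i == j) {
    return(1 + mean(A1[, i] == A2[, i]))
  }
  2 * 0.25 * (mean(A1[, i] == A1[, j]) + mean(A1[, i] == A2[, j]) +
              mean(A2[, i] == A1[, j]) + mean(A2[, i] == A2[, j]))
}

# balanced paternal half-sib design: s sires, each mated to k unrelated dams,
# one offspring per dam; returns ped + phenotypes with given h2
halfsib_data <- function(s, k, h2, vp = 1, seed = 1) {
  set.seed(seed)
  va <- h2 * vp
  sire_id <- sprintf("S%03d", seq_len(s))
  dam_id <- sprintf("D%04d", seq_len(s * k))
  off_id <- sprintf("O%04d", seq_len(s * k))
  ped <- pedigree(
    id = c(sire_id, dam_id, off_id),
    sire = c(rep(NA, s + s * k), rep(sire_id, each = k)),
    dam = c(rep(NA, s + s * k), dam_id))
  bv_s <- stats::rnorm(s, 0, sqrt(va))
  bv_d <- stats::rnorm(s * k, 0, sqrt(va))
  bv_o <- 0.5 * rep(bv_s, each = k) + 0.5 * bv_d +
    stats::rnorm(s * k, 0, sqrt(va / 2))
  y <- bv_o + stats::rnorm(s * k, 0, sqrt(vp - va))
  data.frame(id = off_id, sire = rep(sire_id, each = k), y = y)
}

# ANOVA sire-model heritability oracle from mean squares (4 * intraclass)
halfsib_anova_h2 <- function(df, k) {
  fit <- stats::aov(y ~ sire, df)
  tab <- summary(fit)[[1]]
  msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
  v_sire <- (msb - msw) / k
  4 * v_sire / (v_sire + msw)
}
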