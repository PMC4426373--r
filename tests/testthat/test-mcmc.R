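# posterior-summary utilities ------------------------------------------------

test_that("HPD intervals are the narrowest mass-covering windows", {
  set.seed(1)
  u <- runif(50000)
  h <- hpd_interval(u)
  expect_equal(unname(h["upper"] - h["lower"]), 0.95, tolerance = 0.01)
  z <- rnorm(1e5)
  hz <- hpd_interval(z)
  expect_equal(unname(hz), c(-1.96, 1.96), tolerance = 0.05)
  hc <- hpd_interval(rep(3.3, 200))
  expect_equal(unname(hc["upper"] - hc["lower"]), 0)
  expect_error(hpd_interval(z, mass = 1.2), "in \\(0, 1\\)")
  expect_error(hpd_interval(rnorm(20)), "at least 100")
})

test_that("the posterior mode finds the density peak and flags bimodality", {
  set.seed(2)
  m <- posterior_mode(rnorm(20000, 0.6, 0.1))
  expect_equal(as.numeric(m), 0.6, tolerance = 0.02)
  expect_false(attr(m, "multimodal"))
  bim <- posterior_mode(c(rnorm(10000, -2, 0.3), rnorm(10000, 2, 0.3)))
  expect_true(attr(bim, "multimodal"))
  expect_lt(min(abs(as.numeric(bim) - c(-2, 2))), 0.15)
  expect_equal(as.numeric(posterior_mode(rep(1.5, 500))), 1.5)
})

test_that("lag autocorrelation diagnostics separate white noise from AR(1)", {
  set.seed(3)
  wn <- cbind(a = rnorm(2000), b = rnorm(2000))
  d <- chain_diagnostics(wn)
  expect_true(all(abs(d$autocorr) < 0.05))
  expect_true(d$pass)
  ar <- as.numeric(arima.sim(list(ar = 0.5), 4000))
  d2 <- chain_diagnostics(cbind(x = ar, const = rep(1, 4000)))
  expect_equal(unname(d2$autocorr["x"]), 0.5, tolerance = 0.06)
  expect_true(is.na(d2$autocorr["const"]))
  expect_false(d2$pass)
})

test_that("liability-scale heritability follows its closed form", {
  one <- matrix(c(1, 1), 1, dimnames = list(NULL, c("V_A", "V_R")))
  expect_equal(binary_heritability(one)$draws, 1 / (2 + pi^2 / 3))
  zero <- matrix(c(0, 1), 1, dimnames = list(NULL, c("V_A", "V_R")))
  expect_equal(binary_heritability(zero)$draws, 0)
  huge <- matrix(c(1e9, 1), 1, dimnames = list(NULL, c("V_A", "V_R")))
  expect_equal(binary_heritability(huge)$draws, 1, tolerance = 1e-6)
})

# samplers --------------------------------------------------------------------

mcmc_ped <- simulate_pedigree(small_cfg(), seed = 2)

test_that("binary chains keep the residual fixed at 1 and are reproducible", {
  cfg <- small_cfg()
  ph <- simulate_phenotypes(mcmc_ped, cfg = cfg, seed = 21,
                            liability = trait_config(VA = 2, Vf = 0.3))
  spec <- threshold_model("LHSmolt", fixed = "generation",
                          random = c("micro", "animal"))
  fit <- fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 800, burnin = 200,
                         thin = 2, seed = 5)
  expect_true(all(fit$draws[, "V_R"] == 1))
  expect_equal(nrow(fit$draws), (800 - 200) / 2)
  expect_true(all(fit$draws > 0))
  h2d <- binary_heritability(fit)$draws
  expect_true(all(h2d > 0 & h2d < 1))
  refit <- fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 800, burnin = 200,
                           thin = 2, seed = 5)
  expect_identical(fit$draws, refit$draws)
})

test_that("zero genetic variance yields a near-zero liability heritability", {
  cfg <- small_cfg(scale = 1.4)
  ped <- simulate_pedigree(cfg, seed = 6)
  ph <- simulate_phenotypes(ped, cfg = cfg, seed = 22,
                            liability = trait_config(VA = 0, Vf = 0.5))
  spec <- threshold_model("LHSmolt", fixed = "generation",
                          random = c("micro", "animal"))
  fit <- fit_animal_mcmc(ph, ped, spec, nitt = 4000, burnin = 1000,
                         thin = 3, prior = list(nu = 1, V = (1 + pi^2/3)/3),
                         seed = 7)
  h2 <- binary_heritability(fit)
  expect_lt(as.numeric(h2$mode), 0.1)
})

test_that("Gaussian Gibbs posterior agrees with the REML point estimates", {
  cfg <- small_cfg()
  ph <- simulate_phenotypes(mcmc_ped, traits = list(
    y = trait_config(mu = 5, Vf = 0.5, VA = 2, VR = 2,
                     gen_effects = c(F1 = 0, F2 = 1))),
    cfg = cfg, seed = 23, life_history = FALSE)
  spec <- qg_model("y", fixed = "generation", random = c("micro", "animal"))
  fit <- fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 3000, burnin = 800,
                         thin = 2, seed = 8)
  reml <- fit_univariate_reml(ph, mcmc_ped, spec)
  post_mean <- colMeans(fit$draws)
  expect_equal(post_mean[["V_A"]], reml$components[["V_A"]],
               tolerance = 0.35 * reml$components[["V_A"]] + 0.3)
  expect_equal(post_mean[["V_R"]], reml$components[["V_R"]],
               tolerance = 0.35 * reml$components[["V_R"]] + 0.3)
})

test_that("vague-prior results are insensitive to doubling the belief", {
  cfg <- small_cfg()
  ph <- simulate_phenotypes(mcmc_ped, traits = list(
    y = trait_config(mu = 0, Vf = 0.4, VA = 2, VR = 2)),
    cfg = cfg, seed = 24, life_history = FALSE)
  spec <- qg_model("y", fixed = "generation", random = c("micro", "animal"))
  vp <- var(ph$y, na.rm = TRUE)
  f1 <- fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 9000, burnin = 2000,
                        thin = 4, prior = list(nu = 1, V = vp / 3), seed = 9)
  f2 <- fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 9000, burnin = 2000,
                        thin = 4, prior = list(nu = 2, V = vp / 3), seed = 9)
  h2_of <- function(f) {
    d <- f$draws
    posterior_mode(d[, "V_A"] / rowSums(d))
  }
  expect_lt(abs(as.numeric(h2_of(f1)) - as.numeric(h2_of(f2))), 0.05)
})

test_that("separation in a fixed effect is warned about", {
  cfg <- small_cfg()
  ph <- simulate_phenotypes(mcmc_ped, cfg = cfg, seed = 25,
                            liability = trait_config(VA = 1, Vf = 0.3))
  ph$LHSmolt[ph$id %in% mcmc_ped$id[mcmc_ped$generation == "F2"]] <- 1L
  spec <- threshold_model("LHSmolt", fixed = "generation", random = "micro")
  expect_warning(
    fit_animal_mcmc(ph, mcmc_ped, spec, nitt = 300, burnin = 100, thin = 2,
                    seed = 10), "all-0 or all-1")
})

test_that("DIC is reproducible and penalizes superfluous structure", {
  cfg <- small_cfg()
  ph <- simulate_phenotypes(mcmc_ped, traits = list(
    y = trait_config(mu = 0, Vf = 0.6, VR = 1.5)),
    cfg = cfg, seed = 26, life_history = FALSE)
  spec_small <- qg_model("y", fixed = "generation", random = "micro")
  f_a <- fit_animal_mcmc(ph, mcmc_ped, spec_small, nitt = 1500, burnin = 400,
                         thin = 2, seed = 11)
  f_b <- fit_animal_mcmc(ph, mcmc_ped, spec_small, nitt = 1500, burnin = 400,
                         thin = 2, seed = 11)
  expect_equal(dic(f_a), dic(f_b))
  spec_big <- qg_model("y", fixed = "generation",
                       random = c("micro", "dam", "sire"))
  f_c <- fit_animal_mcmc(ph, mcmc_ped, spec_big, nitt = 1500, burnin = 400,
                         thin = 2, seed = 11)
  # data were generated without dam/sire variance: the bigger model should
  # not be rewarded (small slack for Monte Carlo noise in pD)
  expect_gt(dic(f_c), dic(f_a) - 8)
})
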