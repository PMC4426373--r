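#' Per-trait animal-model presets
#'
#' The fixed/random structure used for each trait's animal model: most size
#' and growth traits condition on generation, cross type and the family
#' micro environment; relative warps add a centroid-size covariate; RelW3
#' additionally carries a maternal (dam) effect; the binary life-history
#' traits use the logit threshold model with generation and micro.
#'
#' @param trait trait name (e.g. `"mo24Length"`, `"RelW3"`, `"LHSmolt"`);
#'   `NULL` returns the full preset table.
#' @return a [qg_model()] / [threshold_model()] for the trait, or a data
#'   frame of all presets when `trait` is `NULL`.
#' @export
trait_presets <- function(trait = NULL) {
  size_growth <- c("mo12Length", "mo12Weight", "mo12Kfact", "mo15Length",
                   "mo15Weight", "mo15Kfact", "IGRL1", "IGRW1",
                   "mo24Length", "mo24Weight", "mo24Kfact", "IGRL2",
                   "IGRW2")
  warps <- paste0("RelW", 2:6)
  tab <- rbind(
    data.frame(trait = size_growth, link = "identity",
               fixed = "generation,cross_type", random = "micro,animal",
               covariates = ""),
    data.frame(trait = c("AvgPix", "CentroidSize"), link = "identity",
               fixed = "cross_type", random = "micro,animal",
               covariates = ""),
    data.frame(trait = setdiff(warps, "RelW3"), link = "identity",
               fixed = "cross_type", random = "micro,animal",
               covariates = "CentroidSize"),
    data.frame(trait = "RelW3", link = "identity", fixed = "cross_type",
               random = "micro,dam,animal", covariates = "CentroidSize"),
    data.frame(trait = c("LHSmolt", "LHMature"), link = "logit",
               fixed = "generation", random = "micro,animal",
               covariates = ""))
  if (is.null(trait)) return(tab)
  row <- tab[tab$trait == trait, ]
  if (nrow(row) == 0) stop("no preset for trait: ", trait)
  split_csv <- function(s) if (s == "") character(0) else
    strsplit(s, ",")[[1]]
  if (row$link == "logit")
    threshold_model(trait, fixed = split_csv(row$fixed),
                    random = split_csv(row$random))
  else
    qg_model(trait, fixed = split_csv(row$fixed),
             random = split_csv(row$random),
             covariates = split_csv(row$covariates))
}

#' Per-family smolt and mature proportions
#'
#' Min/mean/max proportion of classified offspring per family that are
#' smolts (and that are mature), summarized per cross type, per generation,
#' and globally, with family and individual counts.
#'
#' @param ped a `qg_pedigree`.
#' @param data phenotype data frame with `LHSmolt` / `LHMature` (or a
#'   `life_history` column, which is decomposed on the fly).
#' @return data frame with rows per cross type, generation and `Global`.
#' @export
summarize_families <- function(ped, data) {
  if (!all(c("LHSmolt", "LHMature") %in% names(data))) {
    if (!"life_history" %in% names(data))
      stop("data needs LHSmolt/LHMature or life_history")
    data <- cbind(data, binarize_life_history(data$life_history))
  }
  df <- merge(data[, c("id", "LHSmolt", "LHMature")],
              as.data.frame(ped)[, c("id", "generation", "cross_type",
                                     "family")], by = "id")
  df <- df[!is.na(df$family), ]
  fam <- do.call(rbind, lapply(split(df, df$family), function(d) {
    smolt <- d$LHSmolt[!is.na(d$LHSmolt)]
    mature <- d$LHMature[!is.na(d$LHMature)]
    if (!length(smolt) && !length(mature)) return(NULL)
    data.frame(family = d$family[1], generation = d$generation[1],
               cross_type = d$cross_type[1],
               p_smolt = if (length(smolt)) mean(smolt) else NA_real_,
               p_mature = if (length(mature)) mean(mature) else NA_real_,
               n = nrow(d))
  }))
  dropped <- setdiff(unique(df$family), fam$family)
  if (length(dropped))
    warning("excluded ", length(dropped),
            " family(ies) with no classified offspring")
  summarize_group <- function(d, label) {
    data.frame(group = label,
               min_smolt = min(d$p_smolt, na.rm = TRUE),
               mean_smolt = mean(d$p_smolt, na.rm = TRUE),
               max_smolt = max(d$p_smolt, na.rm = TRUE),
               min_mature = min(d$p_mature, na.rm = TRUE),
               mean_mature = mean(d$p_mature, na.rm = TRUE),
               max_mature = max(d$p_mature, na.rm = TRUE),
               n_families = nrow(d), n_individuals = sum(d$n))
  }
  out <- rbind(
    do.call(rbind, lapply(split(fam, fam$cross_type), function(d)
      summarize_group(d, d$cross_type[1]))),
    do.call(rbind, lapply(split(fam, fam$generation), function(d)
      summarize_group(d, d$generation[1]))),
    summarize_group(fam, "Global"))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates: trait derivation, morphometric decomposition, life-history
#' class statistics, REML animal models for Gaussian traits, the Bayesian
#' threshold model for a binary trait, and the discriminant classification,
#' writing result CSVs when `out_dir` is given. Stages are skipped when
#' their inputs are absent. Simulated inputs are produced when `data` /
#' `ped` are omitted.
#'
#' @param ped a `qg_pedigree` (default: simulated from `cfg`).
#' @param data phenotype data frame (default: simulated).
#' @param shapes optional `qg_landmarks` for the morphometric stage.
#' @param reml_traits character vector of Gaussian traits to fit by REML
#'   (presets from [trait_presets()] used when available).
#' @param mcmc_trait optional binary trait for the threshold model.
#' @param dfa_predictors predictors for the discriminant stage (default:
#'   all numeric traits present).
#' @param cfg a [sim_config()] used when simulating.
#' @param seed RNG seed (recorded in the run log).
#' @param drop_warps relative warps dropped before downstream tables
#'   (default 1, the anesthesia-artifact axis).
#' @param mcmc_settings list of `nitt`, `burnin`, `thin` overrides.
#' @param out_dir optional output directory for result CSVs and a run log.
#' @param alpha significance level used in summary tables.
#' @return list of stage results (`data`, `morpho`, `class_stats`, `reml`,
#'   `mcmc`, `dfa`, `families`, `log`).
#' @export
run_pipeline <- function(ped = NULL, data = NULL, shapes = NULL,
                         reml_traits = character(),
                         mcmc_trait = NULL,
                         dfa_predictors = NULL, cfg = sim_config(),
                         seed = 1, drop_warps = 1,
                         mcmc_settings = list(), out_dir = NULL,
                         alpha = 0.05) {
  log <- list(seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (is.null(ped)) ped <- simulate_pedigree(cfg, seed = seed)
  if (is.null(data))
    data <- simulate_phenotypes(ped, traits = list(
      mo12Length = trait_config(mu = 86.5, Vf = 7.6, VA = 17.9, VR = 87.4),
      mo24Length = trait_config(mu = 212, Vf = 32.5, VA = 273.3,
                                VR = 439.9)),
      cfg = cfg, seed = seed)
  if (!is.null(mcmc_trait) && !mcmc_trait %in% names(data))
    stop("mcmc trait '", mcmc_trait, "' not present in the data")
  missing_tr <- setdiff(reml_traits, names(data))
  if (length(missing_tr))
    stop("REML trait(s) not present in the data: ",
         paste(missing_tr, collapse = ", "))
  data <- derive_traits(data)
  result <- list(ped = ped, data = data, log = log)

  if (!is.null(shapes)) {
    dec <- shape_decomposition(shapes)
    keep <- exclude_warps(dec$relwarps, drop_warps)
    morpho <- data.frame(id = rownames(keep),
                         CentroidSize = unname(dec$centroid_size), keep)
    data <- merge(data, morpho, by = "id", all.x = TRUE)
    result$morpho <- dec
    result$data <- data
  }

  if ("life_history" %in% names(data)) {
    numeric_traits <- names(data)[vapply(data, is.numeric, TRUE)]
    numeric_traits <- setdiff(numeric_traits, c("LHSmolt", "LHMature"))
    cls <- lapply(numeric_traits, function(tr)
      tryCatch(cbind(trait = tr, anova_by_class(data, tr)),
               error = function(e) NULL))
    result$class_stats <- do.call(rbind, cls)
    result$families <- summarize_families(ped, data)
  }

  if (length(reml_traits)) {
    A <- relationship_matrix(ped)
    result$reml <- lapply(stats::setNames(reml_traits, reml_traits),
      function(tr) {
        spec <- tryCatch(trait_presets(tr), error = function(e)
          qg_model(tr, fixed = "generation", random = c("micro", "animal")))
        fit <- fit_univariate_reml(data, ped, spec, A = A)
        fit
      })
    result$reml_table <- do.call(rbind, lapply(names(result$reml),
      function(tr) {
        fit <- result$reml[[tr]]
        h2 <- heritability(fit)
        m2 <- maternal_proportion(fit)
        comp <- function(nm) if (nm %in% names(fit$components))
          fit$components[[nm]] else NA_real_
        data.frame(trait = tr, n = fit$n, Vf = comp("V_f"), Vm = comp("V_m"),
                   Va = comp("V_A"), Vr = comp("V_R"),
                   m2 = if (is.null(m2)) NA_real_ else m2[["m2"]],
                   h2 = if (is.null(h2)) NA_real_ else h2[["h2"]],
                   h2_se = if (is.null(h2)) NA_real_ else h2[["SE"]])
      }))
  }

  if (!is.null(mcmc_trait)) {
    spec <- tryCatch(trait_presets(mcmc_trait), error = function(e)
      threshold_model(mcmc_trait))
    args <- c(list(data = data, ped = ped, spec = spec, seed = seed),
              mcmc_settings)
    fit <- do.call(fit_animal_mcmc, args)
    result$mcmc <- fit
    h2 <- binary_heritability(fit)
    result$mcmc_table <- data.frame(
      trait = mcmc_trait, n = fit$n, h2_mode = as.numeric(h2$mode),
      h2_hpd_low = h2$hpd[["lower"]], h2_hpd_high = h2$hpd[["upper"]],
      dic = as.numeric(dic(fit)))
  }

  if (!is.null(dfa_predictors) && "life_history" %in% names(data)) {
    dfa <- fit_dfa(data, dfa_predictors)
    result$dfa <- classify_and_score(dfa)
    result$dfa_model <- dfa
  }

  result$log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phenotypes(result$data, file.path(out_dir, "phenotypes.csv"))
    write_pedigree(ped, file.path(out_dir, "pedigree.csv"))
    if (!is.null(result$reml_table))
      utils::write.csv(result$reml_table,
                       file.path(out_dir, "reml_components.csv"),
                       row.names = FALSE)
    if (!is.null(result$mcmc_table))
      utils::write.csv(result$mcmc_table,
                       file.path(out_dir, "mcmc_summary.csv"),
                       row.names = FALSE)
    if (!is.null(result$class_stats))
      utils::write.csv(result$class_stats,
                       file.path(out_dir, "class_anova.csv"),
                       row.names = FALSE)
    if (!is.null(result$families))
      utils::write.csv(result$families,
                       file.path(out_dir, "family_proportions.csv"),
                       row.names = FALSE)
    writeLines(sprintf("%s %s=%s", result$log$started, names(result$log),
                       vapply(result$log, as.character, "")),
               file.path(out_dir, "run_log.txt"))
  }
  result
}
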