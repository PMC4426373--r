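#' One-way ANOVA of a trait across life-history classes
#'
#' @param data phenotype data frame.
#' @param trait trait column name.
#' @param class_col grouping column (default `"life_history"`).
#' @return data frame with `F`, `ndf`, `ddf`, `p.value`.
#' @export
anova_by_class <- function(data, trait, class_col = "life_history") {
  df <- data[stats::complete.cases(data[, c(trait, class_col)]), ]
  df[[class_col]] <- factor(df[[class_col]])
  if (nlevels(df[[class_col]]) < 2)
    stop("need at least 2 classes with observations")
  fit <- stats::aov(stats::reformulate(class_col, trait), data = df)
  tab <- summary(fit)[[1]]
  data.frame(F = tab$`F value`[1], ndf = tab$Df[1], ddf = tab$Df[2],
             p.value = tab$`Pr(>F)`[1])
}

#' Tukey-Kramer pairwise comparisons of class means
#'
#' Studentized-range adjustment with Kramer's unequal-n standard errors on
#' the pooled ANOVA variance.
#'
#' @inheritParams anova_by_class
#' @param conf.level confidence level of the adjusted intervals.
#' @return data frame with one row per class pair: `diff`, `lwr`, `upr`,
#'   `p.adj`.
#' @export
tukey_kramer <- function(data, trait, class_col = "life_history",
                         conf.level = 0.95) {
  df <- data[stats::complete.cases(data[, c(trait, class_col)]), ]
  df[[class_col]] <- factor(df[[class_col]])
  if (nlevels(df[[class_col]]) < 2)
    stop("need at least 2 classes with observations")
  fit <- stats::aov(stats::reformulate(class_col, trait), data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)[[1]]
  out <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  names(out) <- c("comparison", "diff", "lwr", "upr", "p.adj")
  out
}

#' Pairwise phenotypic correlation matrix
#'
#' Pearson correlations for quantitative pairs and Spearman when either
#' trait is binary, on pairwise-complete observations; reports estimate,
#' p-value and n per pair plus the count of significant off-diagonal pairs
#' at `alpha` (two-sided, no multiplicity correction).
#'
#' @param data phenotype data frame.
#' @param traits character vector of trait columns.
#' @param binary_traits columns to treat as binary (Spearman); default:
#'   columns with at most two distinct non-missing values.
#' @param alpha significance level for the significant-pair count.
#' @return object of class `qg_cormat`: list with `estimate` and `p.value`
#'   matrices, `n` matrix, `method` matrix, long-format `pairs` data frame,
#'   and `n_significant`.
#' @export
correlation_matrix <- function(data, traits, binary_traits = NULL,
                               alpha = 0.05) {
  X <- data[, traits, drop = FALSE]
  if (is.null(binary_traits))
    binary_traits <- traits[vapply(X, function(v)
      length(unique(stats::na.omit(v))) <= 2, TRUE)]
  t_n <- length(traits)
  est <- pmat <- nmat <- matrix(NA_real_, t_n, t_n,
                                dimnames = list(traits, traits))
  method <- matrix(NA_character_, t_n, t_n, dimnames = list(traits, traits))
  diag(est) <- 1
  pairs <- list()
  for (i in seq_len(t_n - 1)) for (j in (i + 1):t_n) {
    xi <- X[[i]]; xj <- X[[j]]
    ok <- stats::complete.cases(xi, xj)
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    meth <- if (traits[i] %in% binary_traits ||
                traits[j] %in% binary_traits) "spearman" else "pearson"
    method[i, j] <- method[j, i] <- meth
    if (n < 3 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
      warning("constant or insufficient data for pair ", traits[i], " / ",
              traits[j])
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], xj[ok], method = meth, exact = FALSE))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    est[i, j] <- est[j, i] <- r
    pmat[i, j] <- pmat[j, i] <- p
    pairs[[length(pairs) + 1L]] <-
      data.frame(trait1 = traits[i], trait2 = traits[j], method = meth,
                 r = r, p = p, n = n)
  }
  pairs <- do.call(rbind, pairs)
  structure(list(estimate = est, p.value = pmat, n = nmat, method = method,
                 pairs = pairs, alpha = alpha,
                 n_significant = sum(pairs$p < alpha, na.rm = TRUE),
                 n_pairs = nrow(pairs)),
            class = "qg_cormat")
}

#' @export
print.qg_cormat <- function(x, ...) {
  cat("Phenotypic correlations:", x$n_pairs, "pairs,", x$n_significant,
      "significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Linear discriminant analysis of life-history classification
#'
#' Fits an LDA of class on the predictor traits with proportional class
#' priors; individuals missing any predictor or the class label are removed
#' (complete-case analysis).
#'
#' @param data phenotype data frame.
#' @param predictors character vector of predictor columns.
#' @param class_col class-label column (default `"life_history"`).
#' @return object of class `qg_dfa` wrapping the `MASS::lda` fit with the
#'   complete-case `n` and the training data for resubstitution scoring.
#' @export
fit_dfa <- function(data, predictors, class_col = "life_history") {
  df <- data[stats::complete.cases(data[, c(predictors, class_col)]),
             c(predictors, class_col)]
  df[[class_col]] <- factor(df[[class_col]])
  counts <- table(df[[class_col]])
  if (any(counts == 0)) df[[class_col]] <- droplevels(df[[class_col]])
  if (any(table(df[[class_col]]) < length(predictors)))
    stop("a class has fewer complete cases than predictors")
  sds <- vapply(df[predictors], stats::sd, 0)
  if (any(sds == 0))
    stop("constant (aliased) predictor(s): ",
         paste(predictors[sds == 0], collapse = ", "))
  fit <- MASS::lda(stats::reformulate(predictors, class_col), data = df)
  structure(list(lda = fit, predictors = predictors, class_col = class_col,
                 n = nrow(df), training = df), class = "qg_dfa")
}

#' Classify individuals and score accuracy
#'
#' Hard class assignment from the LDA posterior; accuracy is the percent of
#' complete cases whose assignment matches the observed class
#' (resubstitution accuracy when `newdata` is the training set, the
#' default).
#'
#' @param model a `qg_dfa` fit.
#' @param newdata optional data frame with the same predictors (defaults to
#'   the training data).
#' @return list with `class` (predicted), `posterior`, `confusion` matrix,
#'   and `accuracy` (percent correctly assigned among labelled cases).
#' @export
classify_and_score <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "qg_dfa"))
  if (is.null(newdata)) newdata <- model$training
  if (!all(model$predictors %in% names(newdata)))
    stop("newdata lacks predictor column(s): ",
         paste(setdiff(model$predictors, names(newdata)), collapse = ", "))
  df <- newdata[stats::complete.cases(
    newdata[, model$predictors, drop = FALSE]), , drop = FALSE]
  pr <- stats::predict(model$lda, df)
  obs <- if (model$class_col %in% names(df))
    factor(df[[model$class_col]], levels = levels(pr$class)) else NULL
  confusion <- NULL
  accuracy <- NA_real_
  if (!is.null(obs)) {
    ok <- !is.na(obs)
    confusion <- table(observed = obs[ok], predicted = pr$class[ok])
    accuracy <- 100 * mean(pr$class[ok] == obs[ok])
  }
  list(class = pr$class, posterior = pr$posterior, confusion = confusion,
       accuracy = accuracy)
}
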