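# four-class fixture with configurable separation
class_fixture <- function(n_per = 30, sep = 0, seed = 1) {
  set.seed(seed)
  classes <- c("mature", "parr", "indeterminate", "smolt")
  data.frame(
    id = sprintf("i%03d", seq_len(4 * n_per)),
    life_history = rep(classes, each = n_per),
    y = rnorm(4 * n_per) + rep(sep * (0:3), each = n_per))
}

test_that("one-way ANOVA matches the textbook closed form", {
  # hand-computed 2-class n=4 fixture
  df <- data.frame(life_history = c("a", "a", "b", "b"),
                   y = c(1, 3, 6, 10))
  out <- anova_by_class(df, "y")
  # means 2 and 8; SSB = 2*(2-5)^2 + 2*(8-5)^2 = 36; SSW = 2 + 8 = 10
  expect_equal(out$F, (36 / 1) / (10 / 2))
  expect_equal(out$ndf, 1)
  expect_equal(out$ddf, 2)
  expect_equal(out$p.value, pf(7.2, 1, 2, lower.tail = FALSE))
  # strong separation is detected
  strong <- class_fixture(sep = 3, seed = 2)
  expect_lt(anova_by_class(strong, "y")$p.value, 1e-4)
  expect_error(anova_by_class(df[1:2, ], "y"), "2 classes")
})

test_that("ANOVA F is near 1 on average under the null", {
  fs <- vapply(1:40, function(s)
    anova_by_class(class_fixture(seed = s), "y")$F, 0)
  expect_equal(mean(fs), 1, tolerance = 0.25)
})

test_that("Tukey-Kramer reduces to the pooled t-test for two groups", {
  df <- data.frame(life_history = rep(c("a", "b"), c(8, 12)),
                   y = c(rnorm(8), rnorm(12, 1)))
  tk <- tukey_kramer(df, "y")
  tt <- t.test(y ~ life_history, df, var.equal = TRUE)
  expect_equal(tk$p.adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey-Kramer is calibrated under the null and finds outliers", {
  set.seed(5)
  any_sig <- vapply(1:80, function(s) {
    any(tukey_kramer(class_fixture(n_per = 15, seed = 100 + s), "y")$p.adj
        < 0.05)
  }, TRUE)
  expect_lte(mean(any_sig), 0.10)  # familywise ~5% plus sampling slack
  # one outlying class: exactly its three comparisons significant
  df <- class_fixture(n_per = 40, seed = 6)
  df$y[df$life_history == "smolt"] <- df$y[df$life_history == "smolt"] + 2
  tk <- tukey_kramer(df, "y")
  hit <- grepl("smolt", tk$comparison)
  expect_true(all(tk$p.adj[hit] < 0.05))
  expect_true(all(tk$p.adj[!hit] > 0.05))
})

test_that("correlation matrix chooses methods, counts pairs and flags", {
  set.seed(7)
  n <- 150
  df <- data.frame(matrix(rnorm(n * 22), n))
  names(df) <- paste0("t", 1:22)
  df$t22 <- as.integer(df$t1 + rnorm(n) > 0)  # binary trait
  cm <- correlation_matrix(df, names(df))
  expect_equal(cm$n_pairs, 22 * 21 / 2)  # 231 off-diagonal pairs
  expect_equal(diag(cm$estimate), rep(1, 22), ignore_attr = TRUE)
  expect_equal(cm$estimate, t(cm$estimate))
  expect_equal(cm$method["t1", "t22"], "spearman")
  expect_equal(cm$method["t1", "t2"], "pearson")
  # independent traits: about 5% of pairs significant
  null_df <- data.frame(matrix(rnorm(200 * 22), 200))
  cm0 <- correlation_matrix(null_df, names(null_df))
  expect_lt(cm0$n_significant / cm0$n_pairs, 0.12)
  expect_gt(cm0$n_significant / cm0$n_pairs, 0.005)
  # a trait with its own copy
  df$copy <- df$t2
  cm2 <- correlation_matrix(df, c("t2", "copy", "t3"))
  expect_equal(cm2$estimate["t2", "copy"], 1)
  # significant-pair count is monotone as alpha decreases
  n_at <- vapply(c(0.05, 0.01, 0.001), function(a)
    sum(cm$pairs$p < a, na.rm = TRUE), 0)
  expect_true(all(diff(n_at) <= 0))
  # constant column
  df$flat <- 1
  expect_warning(correlation_matrix(df, c("t1", "flat")), "constant")
})

test_that("LDA separates, respects priors at chance, and is affine invariant", {
  set.seed(8)
  n <- 60
  sep <- data.frame(
    id = seq_len(4 * n),
    life_history = rep(c("mature", "parr", "indeterminate", "smolt"),
                       each = n),
    x1 = rnorm(4 * n, rep(c(0, 10, 20, 30), each = n), 0.5),
    x2 = rnorm(4 * n, rep(c(0, -10, 5, -5), each = n), 0.5))
  m <- fit_dfa(sep, c("x1", "x2"))
  sc <- classify_and_score(m)
  expect_equal(sc$accuracy, 100)
  # affine rescaling of a predictor leaves accuracy unchanged
  sep2 <- sep
  sep2$x1 <- 1000 * sep2$x1 - 77
  expect_equal(classify_and_score(fit_dfa(sep2, c("x1", "x2")))$accuracy, 100)
  # identical class distributions with unequal sizes: accuracy near the
  # largest class prior
  set.seed(9)
  sizes <- c(mature = 260, parr = 60, indeterminate = 40, smolt = 80)
  flat <- data.frame(life_history = rep(names(sizes), sizes),
                     x1 = rnorm(sum(sizes)), x2 = rnorm(sum(sizes)))
  acc <- classify_and_score(fit_dfa(flat, c("x1", "x2")))$accuracy
  expect_equal(acc, 100 * max(sizes) / sum(sizes), tolerance = 0.12)
  # permuted labels: chance-level accuracy
  perm <- sep
  perm$life_history <- sample(perm$life_history)
  acc_perm <- classify_and_score(fit_dfa(perm, c("x1", "x2")))$accuracy
  expect_lt(acc_perm, 35)
  expect_error(classify_and_score(m, data.frame(z = 1)), "lacks predictor")
})

test_that("the 1-D two-class boundary sits midway between class means", {
  set.seed(10)
  df <- data.frame(life_history = rep(c("a", "b"), each = 400),
                   x = c(rnorm(400, 0), rnorm(400, 4)))
  m <- fit_dfa(df, "x")
  mid <- (mean(df$x[df$life_history == "a"]) +
          mean(df$x[df$life_history == "b"])) / 2
  # locate the decision boundary by root-finding the posterior difference
  post_diff <- function(x)
    diff(as.vector(classify_and_score(m, data.frame(x = x))$posterior))
  boundary <- uniroot(post_diff, c(mid - 1, mid + 1), tol = 1e-10)$root
  expect_equal(boundary, mid, tolerance = 1e-6)
  expect_equal(as.character(
    classify_and_score(m, data.frame(x = mid - 0.5))$class), "a")
  expect_equal(as.character(
    classify_and_score(m, data.frame(x = mid + 0.5))$class), "b")
})

test_that("degenerate DFA inputs error clearly", {
  df <- data.frame(life_history = rep(c("a", "b"), each = 5),
                   x1 = rnorm(10), x2 = 1)
  expect_error(fit_dfa(df, c("x1", "x2")), "aliased")
  df2 <- data.frame(life_history = rep(c("a", "b"), c(2, 30)),
                    x1 = rnorm(32), x2 = rnorm(32), x3 = rnorm(32))
  expect_error(fit_dfa(df2, c("x1", "x2", "x3")), "fewer complete cases")
})
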