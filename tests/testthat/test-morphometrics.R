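rotmat <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

test_that("centroid size has the right value, homogeneity and invariances", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(8))
  moved <- sq %*% rotmat(0.83) + matrix(c(5, -2), 4, 2, byrow = TRUE)
  expect_equal(centroid_size(moved), sqrt(8))
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("GPA removes similarity transforms and finds the mean shape", {
  base <- smoltqg:::fish_consensus()
  # identical shapes under rotation/translation/scale align exactly
  sh <- list(a = base,
             b = 2.3 * base %*% rotmat(1.2) +
               matrix(c(10, 4), nrow(base), 2, byrow = TRUE))
  g <- generalized_procrustes(sh)
  expect_lt(sqrt(sum((g$aligned[, , 1] - g$aligned[, , 2])^2)), 1e-10)
  # consensus of two shapes is equidistant from both
  set.seed(3)
  sh2 <- list(a = base + matrix(rnorm(26, 0, 0.01), ncol = 2), b = base)
  g2 <- generalized_procrustes(sh2)
  d <- apply(g2$aligned, 3, function(m) sqrt(sum((m - g2$consensus)^2)))
  expect_equal(d[[1]], d[[2]], tolerance = 1e-8)
  # simulated shapes: consensus close to the generating mean shape
  shapes <- simulate_landmarks(100, seed = 11)
  g3 <- generalized_procrustes(shapes)
  cons_true <- attr(shapes, "consensus")
  R <- smoltqg:::procrustes_rotation(g3$consensus, cons_true)
  expect_lt(sqrt(sum((g3$consensus %*% R - cons_true)^2)), 0.01)
})

test_that("partial warps: count, zero at consensus, affine shear is uniform", {
  shapes <- simulate_landmarks(60, seed = 5)
  g <- generalized_procrustes(shapes)
  pw <- partial_warps(g)
  expect_equal(ncol(pw), 2 * 13 - 4)  # 13 landmarks -> 22 scores
  # a shape equal to the consensus scores zero on every warp
  g_self <- g
  g_self$aligned[, , 1] <- g$consensus
  pw_self <- partial_warps(g_self)
  expect_lt(max(abs(pw_self[1, ])), 1e-12)
  # pure affine shear of the consensus: uniform component only
  cons <- g$consensus
  sheared <- cbind(cons[, 1] + 0.06 * cons[, 2], cons[, 2])
  g2 <- generalized_procrustes(list(a = cons, b = sheared))
  pw2 <- partial_warps(g2)
  nonuni <- pw2[, seq_len(2 * 13 - 6), drop = FALSE]
  uni <- pw2[, c("Uni1", "Uni2"), drop = FALSE]
  expect_lt(max(abs(nonuni)), 1e-8)
  expect_gt(max(abs(uni)), 1e-4)
})

test_that("relative warps: PVE normalization, rank-1 case, spectrum recovery", {
  # rank-1 shape variation concentrates all PVE on axis 1
  s1 <- simulate_landmarks(150, axis_variances = 4e-4, seed = 6)
  d1 <- shape_decomposition(s1)
  expect_equal(ncol(d1$relwarps$scores), 22)
  expect_gt(d1$relwarps$pve[1], 99)
  expect_equal(sum(d1$relwarps$pve), 100)
  # configured spectrum {4, 2, 1} recovered in the PVE ratios
  s2 <- simulate_landmarks(800, axis_variances = c(4, 2, 1) * 1e-4, seed = 7)
  d2 <- shape_decomposition(s2)
  v <- d2$relwarps$pve[1:3] / d2$relwarps$pve[3]
  expect_equal(unname(v), c(4, 2, 1), tolerance = 0.15)
  expect_error(relative_warps(d2$partial_warps[1, , drop = FALSE]),
               "at least 2")
})

test_that("relative-warp variance accounting and order invariance hold", {
  shapes <- simulate_landmarks(80, seed = 8)
  g <- generalized_procrustes(shapes)
  pw <- partial_warps(g)
  rw <- relative_warps(pw)
  # PCA preserves total variance of the projected scores (x1000 scale)
  expect_equal(sum(apply(rw$scores, 2, var)),
               sum(apply(pw * 1000, 2, var)), tolerance = 1e-8)
  # reordering individuals leaves the consensus unchanged
  g2 <- generalized_procrustes(rev(shapes))
  expect_equal(g2$consensus, g$consensus, tolerance = 1e-10)
})

test_that("exclude_warps drops axes but keeps original labels", {
  shapes <- simulate_landmarks(40, seed = 9)
  rw <- shape_decomposition(shapes)$relwarps
  kept <- exclude_warps(rw, 1)
  expect_equal(ncol(kept), 21)
  expect_equal(colnames(kept), paste0("RelW", 2:22))
  expect_equal(exclude_warps(rw, integer(0)), rw$scores)
  expect_error(exclude_warps(rw, 23), "out of range")
  expect_error(exclude_warps(rw, 1:22), "every warp")
})

test_that("TPS files round-trip, tolerating CRLF, blanks and SCALE", {
  shapes <- simulate_landmarks(3, seed = 10)
  path <- tempfile(fileext = ".tps")
  write_tps(shapes, path)
  back <- read_tps(path)
  expect_equal(names(back), names(shapes))
  expect_equal(back[[2]], shapes[[2]], tolerance = 1e-9, ignore_attr = TRUE)
  # hand-built dialect variants
  txt <- c("LM=3", "0 0", "1.5 0", "0 2.0", "ID=fishA", "SCALE=2", "",
           "LM=3\r", "1 1\r", "2 1\r", "1 3\r", "ID=fishB\r")
  writeLines(txt, path)
  lm <- read_tps(path)
  expect_equal(lm$fishA, rbind(c(0, 0), c(3, 0), c(0, 4)))
  expect_equal(lm$fishB, rbind(c(1, 1), c(2, 1), c(1, 3)))
  writeLines(c("LM=2", "1 1", "oops"), path)
  expect_error(read_tps(path), "coordinate")
})
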