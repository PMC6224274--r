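test_that("multivariate regression recovers exact linear structure", {
  set.seed(1)
  x <- rnorm(40)
  B <- rnorm(57)
  Y <- outer(x, B)
  fit <- mv_regress(Y, x)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[2, ]), B, tolerance = 1e-9)
  expect_lt(max(abs(fit$fitted + fit$residuals - Y)), 1e-12)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(fit$design, fit$residuals))), 1e-8)
  expect_error(mv_regress(Y, cbind(x, x)), "rank-deficient")
})

test_that("null R-squared concentrates near q / (n - 1)", {
  n <- 30
  r2s <- vapply(1:400, function(i) {
    set.seed(i)
    mv_regress(matrix(rnorm(n * 5), n), rnorm(n))$r_squared
  }, 0)
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.25)
})

test_that("the allometric effect direction is recovered from noisy data", {
  set.seed(7)
  n <- 100
  x <- rnorm(n)
  B <- rnorm(57); B <- B / sqrt(sum(B^2)) * 0.5
  Y <- outer(x, B) + matrix(rnorm(n * 57, 0, 0.05), n)
  fit <- mv_regress(Y, x)
  vc <- vector_correlation(fit$coefficients[2, ], B)
  expect_gt(vc$R, 0.95)
})

test_that("shape scores satisfy their algebraic identities", {
  set.seed(2)
  x <- rnorm(50)
  B <- rnorm(57)
  Y <- outer(x, B)
  s <- shape_score(Y, B)
  expect_equal(s, x * sqrt(sum(B^2)), tolerance = 1e-9)
  expect_equal(cor(s, x), 1, tolerance = 1e-12)
  # univariate reduction: s = y * sign(beta)
  y <- rnorm(20)
  expect_equal(shape_score(matrix(y), -2.5), -y)
  # invariance under joint orthogonal rotation
  Q <- qr.Q(qr(matrix(rnorm(57 * 57), 57)))
  expect_lt(max(abs(shape_score(Y %*% Q, as.vector(B %*% Q)) - s)), 1e-9)
  expect_error(shape_score(Y, rep(0, 57)), "zero")
})

test_that("sequential MANCOVA matches the classical univariate oracle", {
  set.seed(3)
  n <- 30
  df <- data.frame(size = rnorm(n),
                   trophic_mode = factor(rep(c("a", "b"), n / 2)))
  y <- rnorm(n) + 0.5 * df$size
  tab <- mancova(y, ~ size * trophic_mode, df, n_perm = 0)
  oracle <- stats::anova(stats::lm(y ~ size * trophic_mode, df))
  expect_equal(tab$SS[1:3], oracle$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(tab$F[1:3], oracle$`F value`[1:3], tolerance = 1e-9)
  expect_equal(tab$Df[1:4], oracle$Df, tolerance = 0)
  # SS decomposition and R2 sums
  expect_equal(sum(tab$SS[1:4]), tab$SS[5], tolerance = 1e-9)
  expect_equal(sum(tab$R2[1:4]), 1, tolerance = 1e-9)
})

test_that("RRPP p-values are reproducible, bounded away from zero, and signal real effects", {
  set.seed(4)
  n <- 40
  df <- data.frame(size = rnorm(n),
                   trophic_mode = factor(sample(rep(c("a", "b"), n / 2))))
  Y <- outer(df$size, rnorm(10)) + matrix(rnorm(n * 10, 0, 0.5), n)
  t1 <- mancova(Y, ~ size * trophic_mode, df, n_perm = 199, seed = 9)
  t2 <- mancova(Y, ~ size * trophic_mode, df, n_perm = 199, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$p[1:3] >= 1 / 200))
  expect_lte(t1$p[1], 0.01) # strong size effect detected
  df_empty <- df; levels(df_empty$trophic_mode) <- c("a", "b", "ghost")
  expect_error(mancova(Y, ~ size * trophic_mode, df_empty, n_perm = 0),
               "empty factor level")
})

test_that("vector correlation reproduces the analytic R to theta conversion", {
  vp <- vector_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(vp$R, 1, tolerance = 1e-12)
  expect_equal(vp$theta, 0, tolerance = 1e-12)
  vc <- vector_correlation(c(1, 0), c(0, 3))
  expect_equal(vc$R, 0)
  expect_equal(vc$theta, 90)
  # negative alignment counts as correlation (PC direction is arbitrary)
  expect_equal(vector_correlation(c(1, 1), c(-1, -1))$R, 1, tolerance = 1e-12)
  expect_error(vector_correlation(c(0, 0), c(1, 1)), "zero")
})

test_that("vector-correlation permutation test detects aligned effects and is calibrated", {
  set.seed(5)
  n <- 60
  ref <- rnorm(57); ref <- ref / sqrt(sum(ref^2))
  x <- rnorm(n)
  Y <- outer(x, ref) + matrix(rnorm(n * 57, 0, 0.1), n)
  r <- vector_correlation_test(Y, x, ref, n_perm = 999, seed = 1)
  expect_lte(r$p, 0.01)
  expect_gt(r$R, 0.9)
  # independent covariate: p roughly uniform (spot check it is not tiny)
  r0 <- vector_correlation_test(Y, rnorm(n), ref, n_perm = 199, seed = 2)
  expect_gte(r0$p, 1 / 200)
  # row permutation variant runs and agrees on the observed statistic
  r2 <- vector_correlation_test(Y, x, ref, n_perm = 99, seed = 3,
                                permute = "rows")
  expect_equal(r2$R, r$R)
})

test_that("allometry-free shapes are orthogonal to size and keep group structure", {
  set.seed(6)
  n <- 80
  size <- rnorm(n)
  group <- rep(c(0, 1), n / 2)
  e1 <- c(1, rep(0, 56)); e2 <- c(0, 1, rep(0, 55))
  Y <- outer(size, e1) + outer(group, 0.8 * e2) +
    matrix(rnorm(n * 57, 0, 0.05), n)
  m <- fit_pca(Y)
  af <- allometry_free(Y, size, m)
  expect_lt(max(abs(colMeans(af$residuals))), 1e-9)
  refit <- mv_regress(af$residuals, size)
  expect_lt(refit$r_squared, 1e-9)
  # group separation survives allometry removal: along the PC most aligned
  # with the group effect the group means stay apart
  align <- abs(as.vector(t(m$rotation) %*% e2))
  ax <- which.max(align)
  gap <- abs(diff(tapply(af$scores[, ax], group, mean)))
  expect_gt(gap, 0.5)
})

test_that("balanced bootstrap honours its contracts", {
  groups <- factor(rep(c("lecithotrophic", "planktotrophic"), c(10, 30)))
  const <- c(rep(1, 10), rep(2, 30))
  bt <- bootstrap_groups(const, groups, n_boot = 50, seed = 1)
  expect_equal(bt$m, 10)
  expect_true(all(vapply(bt$ci, function(ci) diff(ci) == 0, TRUE)))
  expect_equal(unname(bt$diff_ci), c(1, 1), ignore_attr = TRUE)
  # default replicate count and reproducibility
  expect_equal(formals(bootstrap_groups)$n_boot, 1000)
  b1 <- bootstrap_groups(rnorm(40), groups, n_boot = 20, seed = 5)
  expect_error(bootstrap_groups(c(1, rep(2, 5)),
                                factor(rep(c("a", "b"), c(1, 5)))),
               "fewer than 2")
})

test_that("predicted shapes along size behave like the fitted line", {
  sim <- simulate_species_set(population_params(n_species = 40, seed = 13))
  X <- shape_matrix(sim$outlines)
  size <- sim$table$larval_length
  fit <- mv_regress(X, size)
  pred <- predict_shapes_along_size(fit, sizes = c(mean(size), 250, 400, 600))
  # prediction at the sample mean is the mean shape
  expect_lt(max(abs(pred$vectors[1, ] - colMeans(X))), 1e-9)
  # predictions are collinear in shape space
  D <- sweep(pred$vectors[-1, ], 2, pred$vectors[1, ])
  expect_lt(qr(D)$rank, 2.5)
  # with a positive allometric slope, predicted aspect ratio rises with
  # size; normalized shapes carry the body (long) axis along x, so width /
  # length is the y-extent over the x-extent in that frame
  aspects <- vapply(pred$outlines[-1], function(o) {
    p <- o$points
    diff(range(p[, 2])) / diff(range(p[, 1]))
  }, 0)
  expect_true(all(diff(aspects) > 0))
})
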