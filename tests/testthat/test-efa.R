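test_that("decomposition of analytic shapes matches first-harmonic theory", {
  circ <- circle_outline(r = 3, center = c(10, -3), n = 2000, phase = 0.7)
  cc <- efa_decompose(circ, 8)
  expect_equal(cc$a0, 10, tolerance = 1e-6)
  expect_equal(cc$c0, -3, tolerance = 1e-6)
  # first-harmonic ellipse has radius 3 regardless of the phase split
  # (up to the O(1/n^2) polygon discretization of the circle)
  expect_equal(sqrt(cc$an[1]^2 + cc$bn[1]^2), 3, tolerance = 1e-6)
  pw <- harmonic_power(cc)
  expect_lt(sum(pw[-1]) / sum(pw), 1e-6)

  # under index parameterization the trigonometric coefficients are exact
  ell <- ellipse_outline(a = 5, b = 2, n = 200)
  cd <- efa_decompose(ell, 8, method = "dft")
  expect_equal(cd$an[1], 5, tolerance = 1e-9)
  expect_equal(cd$dn[1], 2, tolerance = 1e-9)
  expect_lt(max(abs(c(cd$bn[1], cd$cn[1]))), 1e-9)
  # chord-length parameterization smears an eccentric ellipse across
  # harmonics: first-harmonic terms are close but not equal to the semi-axes
  ci <- efa_decompose(ell, 8)
  expect_equal(ci$an[1], 5, tolerance = 0.15)
  expect_equal(ci$dn[1], 2, tolerance = 0.15)
  expect_lt(max(abs(c(ci$bn[1], ci$cn[1]))), 1e-9)
})

test_that("DFT decomposition at the Nyquist limit reproduces every vertex", {
  for (seed in 1:5) {
    K <- c(64, 63, 100, 57, 200)[seed]
    poly <- random_star_polygon(k = K, seed = seed)
    cp <- efa_decompose(poly, K %/% 2, method = "dft")
    rec <- efa_reconstruct(cp, K, as_outline = FALSE)
    err <- max(sqrt(rowSums((rec - poly$points)^2)))
    expect_lt(err, 1e-6 * outline_perimeter(poly))
  }
})

test_that("normalization removes similarity transforms and start shifts", {
  # transform an arc-uniform outline so the discrete sampling is identical up
  # to phase; the normalized coefficients must then agree to high precision
  o <- resample_outline(default_nauplius(), 200)
  v0 <- to_shape_vector(efa_normalize(efa_decompose(o, 15)))
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    t <- similarity_transform(o, s = runif(1, 0.2, 5), ang = runif(1, 0, 2 * pi),
                              tr = rnorm(2, 0, 50), shift = sample(200, 1))
    v <- to_shape_vector(efa_normalize(efa_decompose(t, 15)))
    worst <- max(worst, max(abs(v - v0)))
  }
  expect_lt(worst, 1e-8)
})

test_that("normalized coefficients satisfy the (1, 0, 0) convention and idempotence", {
  shapes <- list(default_nauplius(), default_nauplius(0.5, 0.6, 0.1),
                 ellipse_outline(3, 1))
  for (o in shapes) {
    cn <- efa_normalize(efa_decompose(resample_outline(o, 200), 15))
    expect_equal(cn$an[1], 1, tolerance = 1e-9)
    expect_lt(max(abs(c(cn$bn[1], cn$cn[1]))), 1e-9)
    expect_equal(cn$a0, 0)
    cn2 <- efa_normalize(cn)
    expect_equal(to_shape_vector(cn2), to_shape_vector(cn), tolerance = 1e-12)
  }
  degen <- structure(list(a0 = 0, c0 = 0, an = 0, bn = 0, cn = 0, dn = 0,
                          T = 1, n_harmonics = 1L, normalized = FALSE),
                     class = "efa")
  expect_error(efa_normalize(degen), "degenerate")
})

test_that("power is conserved under start-point shifts", {
  o <- resample_outline(default_nauplius(), 200)
  p0 <- sum(harmonic_power(efa_decompose(o, 30)))
  for (shift in c(37, 101, 150)) {
    os <- similarity_transform(o, shift = shift)
    ps <- sum(harmonic_power(efa_decompose(os, 30)))
    expect_equal(ps, p0, tolerance = 1e-9)
  }
})

test_that("harmonic selection matches an exhaustive scan and handles ellipses", {
  expect_equal(choose_n_harmonics(efa_decompose(ellipse_outline(5, 2), 20)), 1L)
  expect_equal(choose_n_harmonics(efa_decompose(circle_outline(n = 100), 20)), 1L)

  set.seed(8)
  coefs <- lapply(1:6, function(i) {
    o <- make_nauplius_outline(
      shape_params(runif(1, 0.5, 1.2), runif(1, 0.1, 0.6), runif(1, 0, 0.3),
                   size = 300), n_points = 200, seed = i, noise_sd = 0.02)
    efa_decompose(resample_outline(o, 200), 30)
  })
  got <- choose_n_harmonics(coefs, 0.99)
  # brute-force oracle: smallest N whose cumulative power fraction clears
  # the threshold for every outline
  scan <- vapply(1:30, function(N) {
    all(vapply(coefs, function(cc) {
      pw <- harmonic_power(cc)
      sum(pw[1:N]) / sum(pw) > 0.99
    }, TRUE))
  }, TRUE)
  expect_equal(got, which(scan)[1])
})

test_that("reconstruction error decreases with harmonic count and N=1 is an ellipse", {
  set.seed(5)
  for (rep in 1:5) {
    o <- resample_outline(make_nauplius_outline(
      shape_params(runif(1, 0.5, 1.2), runif(1, 0.1, 0.6), runif(1, 0, 0.3),
                   size = 300), seed = rep, noise_sd = 0.02), 200)
    cc <- efa_decompose(o, 30)
    # RMS error at the matched parameter values, per harmonic count
    pc <- rbind(o$points, o$points[1, ])
    tt <- c(0, cumsum(sqrt(rowSums(diff(pc)^2))))
    tpar <- tt[-length(tt)] / max(tt)
    errs <- vapply(1:30, function(N) {
      phi <- outer(2 * pi * tpar, 1:N)
      x <- cc$a0 + cos(phi) %*% cc$an[1:N] + sin(phi) %*% cc$bn[1:N]
      y <- cc$c0 + cos(phi) %*% cc$cn[1:N] + sin(phi) %*% cc$dn[1:N]
      sqrt(mean((x - o$points[, 1])^2 + (y - o$points[, 2])^2))
    }, 0)
    expect_true(all(diff(errs) <= 1e-9))
  }
  # one-harmonic reconstruction is an ellipse: convex, no curvature flips
  o <- default_nauplius()
  r1 <- efa_reconstruct(efa_decompose(resample_outline(o, 200), 1), 100)
  p <- r1$points
  v1 <- p[c(2:100, 1), ] - p
  v2 <- v1[c(2:100, 1), ]
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  expect_true(all(cross > 0) || all(cross < 0))
})

test_that("circle reconstruction is radially exact", {
  # dense polygon so the O(1/n^2) discretization sits below the tolerance
  circ <- circle_outline(r = 2, n = 4000)
  rec <- efa_reconstruct(efa_decompose(circ, 10), 200)
  r <- sqrt(rowSums(rec$points^2))
  expect_lt(max(abs(r - 2)), 1e-6 * 2)
})

test_that("shape vectors have the documented layout and round trip", {
  cn <- efa_normalize(efa_decompose(resample_outline(default_nauplius(), 200), 15))
  v <- to_shape_vector(cn, 15)
  expect_length(v, 57)
  expect_identical(names(v)[1:5], c("d1", "a2", "b2", "c2", "d2"))
  back <- from_shape_vector(v)
  expect_equal(to_shape_vector(back), v)
  expect_equal(back$an[1], 1)
  # non-normalized input is rejected
  expect_error(to_shape_vector(efa_decompose(default_nauplius(), 15)),
               "not normalized")
  # zero vector: pure normalized first harmonic with d1 = 0 collapses to a
  # segment (zero enclosed area)
  z <- from_shape_vector(rep(0, 57))
  pts <- efa_reconstruct(z, 100, as_outline = FALSE)
  expect_lt(diff(range(pts[, 2])), 1e-12)
  expect_equal(diff(range(pts[, 1])), 2, tolerance = 1e-6)
})
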