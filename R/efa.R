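#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes elliptic Fourier coefficients of a closed outline under the
#' standard piecewise-linear, chord-length (arc length of the polygon)
#' parameterization: for each harmonic n, `a_n`, `b_n` describe the x
#' increments and `c_n`, `d_n` the y increments against cumulative chord
#' length t with period T (the perimeter). The constant terms `a0`, `c0`
#' are the curve centroid of the piecewise-linear parameterization, so that
#'
#'   x(t) = a0 + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#'
#' and likewise y(t) with `c0`, `c_n`, `d_n`.
#'
#' Two variants are available. `method = "integral"` (the default, used
#' throughout the pipeline) evaluates the exact Fourier integrals of the
#' piecewise-linear closed curve — the classical formulation, robust to
#' unevenly spaced vertices. `method = "dft"` instead takes the discrete
#' Fourier transform of the vertex sequence under index parameterization:
#' for K vertices and N = floor(K / 2) harmonics the truncated series is the
#' trigonometric interpolant and reproduces every vertex to machine
#' precision, which makes it the right tool for verifying that the
#' coefficient pipeline is lossless. After uniform arc-length resampling the
#' two parameterizations coincide and the variants differ only in how they
#' treat the curve between vertices.
#'
#' @param o A closed [outline()] with at least `2 * n_harmonics + 2` points
#'   (`2 * n_harmonics` for `method = "dft"`).
#' @param n_harmonics Number of harmonics N (>= 1).
#' @param method `"integral"` (piecewise-linear Fourier integrals) or
#'   `"dft"` (trigonometric interpolation of the vertices).
#' @return An object of class `efa`: list with `a0`, `c0`, coefficient
#'   vectors `an`, `bn`, `cn`, `dn` of length N, perimeter `T`,
#'   `n_harmonics`, and a `normalized` flag.
#' @references Kuhl & Giardina (1982) Elliptic Fourier features of a closed
#'   contour. Computer Graphics and Image Processing 18:236-258.
#' @export
efa_decompose <- function(o, n_harmonics = 15,
                          method = c("integral", "dft")) {
  o <- as_outline(o)
  N <- check_count(n_harmonics, "n_harmonics", 1L)
  method <- match.arg(method)
  p <- o$points
  K <- nrow(p)
  if (method == "dft") {
    if (K < 2L * N) {
      stop(sprintf("need at least %d points for %d harmonics", 2L * N, N),
           call. = FALSE)
    }
    T <- outline_perimeter(o)
    zx <- stats::fft(p[, 1L]) / K
    zy <- stats::fft(p[, 2L]) / K
    idx <- seq_len(N) + 1L
    an <- 2 * Re(zx[idx]); bn <- -2 * Im(zx[idx])
    cn <- 2 * Re(zy[idx]); dn <- -2 * Im(zy[idx])
    if (2L * N == K) { # Nyquist harmonic: cosine only, single weight
      an[N] <- Re(zx[N + 1L]); bn[N] <- 0
      cn[N] <- Re(zy[N + 1L]); dn[N] <- 0
    }
    return(structure(list(a0 = Re(zx[1L]), c0 = Re(zy[1L]),
                          an = an, bn = bn, cn = cn, dn = dn,
                          T = T, n_harmonics = N, normalized = FALSE),
                     class = "efa"))
  }
  if (K < 2L * N + 2L) {
    stop(sprintf("need at least %d points for %d harmonics", 2L * N + 2L, N),
         call. = FALSE)
  }
  pc <- rbind(p, p[1L, ])
  dxy <- diff(pc)
  dt <- sqrt(rowSums(dxy^2))
  t <- c(0, cumsum(dt))
  T <- t[length(t)]
  n <- seq_len(N)
  phi <- outer(2 * pi * t / T, n) # (K+1) x N
  cosphi <- cos(phi); sinphi <- sin(phi)
  dcos <- cosphi[-1L, , drop = FALSE] - cosphi[-nrow(cosphi), , drop = FALSE]
  dsin <- sinphi[-1L, , drop = FALSE] - sinphi[-nrow(sinphi), , drop = FALSE]
  const <- T / (2 * pi^2 * n^2)
  vx <- dxy[, 1L] / dt
  vy <- dxy[, 2L] / dt
  an <- const * colSums(vx * dcos)
  bn <- const * colSums(vx * dsin)
  cn <- const * colSums(vy * dcos)
  dn <- const * colSums(vy * dsin)
  # centroid of the piecewise-linear curve: trapezoid rule is exact
  a0 <- sum((pc[-1L, 1L] + pc[-nrow(pc), 1L]) / 2 * dt) / T
  c0 <- sum((pc[-1L, 2L] + pc[-nrow(pc), 2L]) / 2 * dt) / T
  structure(list(a0 = a0, c0 = c0, an = an, bn = bn, cn = cn, dn = dn,
                 T = T, n_harmonics = N, normalized = FALSE),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa> %d harmonics, perimeter %.4g%s\n", x$n_harmonics, x$T,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

# rotate harmonic matrices: phase shift by theta (start point) and plane
# rotation by psi, returning the coefficient set
efa_rotate <- function(c, theta, psi) {
  n <- seq_len(c$n_harmonics)
  ct <- cos(n * theta); st <- sin(n * theta)
  # phase: [a b; c d] %*% [[cos, -sin], [sin, cos]] with angle n*theta
  an <- c$an * ct + c$bn * st
  bn <- -c$an * st + c$bn * ct
  cn <- c$cn * ct + c$dn * st
  dn <- -c$cn * st + c$dn * ct
  # plane rotation by psi: [[cos, sin], [-sin, cos]] %*% [a b; c d]
  cp <- cos(psi); sp <- sin(psi)
  an2 <- cp * an + sp * cn
  bn2 <- cp * bn + sp * dn
  cn2 <- -sp * an + cp * cn
  dn2 <- -sp * bn + cp * dn
  c$an <- an2; c$bn <- bn2; c$cn <- cn2; c$dn <- dn2
  c
}

#' Normalize elliptic Fourier coefficients
#'
#' Makes the coefficients invariant to translation, scale, in-plane rotation
#' and starting point using the first-harmonic ellipse: the centroid terms
#' are zeroed, the starting phase is rotated to the first ellipse's
#' semi-major axis, the plane is rotated so that axis lies along x, and all
#' coefficients are divided by the semi-major axis length. The result always
#' has `a1 = 1`, `b1 = c1 = 0` (the three constants dropped from shape
#' vectors).
#'
#' The semi-major axis direction is ambiguous by 180 degrees; the ambiguity
#' is resolved deterministically by requiring the mean of the first quarter
#' of the reconstructed points to have positive y (falling back to the sign
#' of `d1` for shapes symmetric enough to leave that mean at zero).
#' Reflection is deliberately not normalized away: all outlines are ingested
#' counterclockwise and mirroring is biologically meaningful.
#'
#' @param c An `efa` object from [efa_decompose()].
#' @return A normalized `efa` object (`T` set to 1).
#' @export
efa_normalize <- function(c) {
  if (!inherits(c, "efa")) stop("'c' must be an efa object", call. = FALSE)
  a1 <- c$an[1L]; b1 <- c$bn[1L]; c1 <- c$cn[1L]; d1 <- c$dn[1L]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-300) {
    stop("degenerate first harmonic: cannot normalize", call. = FALSE)
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  c$a0 <- 0; c$c0 <- 0
  cand <- lapply(c(theta, theta + pi), function(th) {
    r <- efa_rotate(c, th, 0)
    psi <- atan2(r$cn[1L], r$an[1L])
    r <- efa_rotate(c, th, psi)
    E <- sqrt(r$an[1L]^2 + r$cn[1L]^2)
    if (E < 1e-300) stop("degenerate first harmonic: cannot normalize", call. = FALSE)
    for (f in c("an", "bn", "cn", "dn")) r[[f]] <- r[[f]] / E
    r$T <- 1
    r$normalized <- TRUE
    r
  })
  score <- vapply(cand, function(r) {
    pts <- efa_reconstruct(r, 120L, as_outline = FALSE)
    mean(pts[1:30, 2L])
  }, 0)
  pick <- if (max(abs(score)) > 1e-9) which.max(score) else {
    if (cand[[1L]]$dn[1L] >= 0) 1L else 2L
  }
  cand[[pick]]
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` uniformly spaced
#' parameter values over one period (the inverse Fourier transform used to
#' draw hypothetical shapes).
#'
#' @param c An `efa` object.
#' @param n_points Number of points to evaluate; default 200.
#' @param as_outline Return an [outline()] (default) or a bare matrix.
#' @return An [outline()] (or matrix) of the reconstructed curve.
#' @export
efa_reconstruct <- function(c, n_points = 200, as_outline = TRUE) {
  if (!inherits(c, "efa")) stop("'c' must be an efa object", call. = FALSE)
  n_points <- check_count(n_points, "n_points", 3L)
  t <- (0:(n_points - 1L)) / n_points
  n <- seq_len(c$n_harmonics)
  phi <- outer(2 * pi * t, n)
  x <- c$a0 + cos(phi) %*% c$an + sin(phi) %*% c$bn
  y <- c$c0 + cos(phi) %*% c$cn + sin(phi) %*% c$dn
  pts <- cbind(as.vector(x), as.vector(y))
  if (!as_outline) return(pts)
  outline(pts)
}

#' Harmonic power and harmonic number selection
#'
#' The power of harmonic n is `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`.
#' `choose_n_harmonics` returns the smallest N whose cumulative power
#' fraction (harmonics 1..N over all available harmonics) exceeds
#' `threshold` for every outline in the set — the rule of keeping enough
#' harmonics to explain more than 99% of the shape information.
#'
#' @param cs An `efa` object or list of them (all with the same maximum
#'   harmonic count).
#' @param threshold Cumulative power fraction to exceed, in (0, 1);
#'   default 0.99.
#' @return `harmonic_power`: vector of per-harmonic powers.
#'   `choose_n_harmonics`: the selected N.
#' @export
choose_n_harmonics <- function(cs, threshold = 0.99) {
  check_number(threshold, "threshold", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (inherits(cs, "efa")) cs <- list(cs)
  needed <- vapply(cs, function(c) {
    pw <- harmonic_power(c)
    frac <- cumsum(pw) / sum(pw)
    as.integer(which(frac > threshold)[1L])
  }, 0L)
  max(needed)
}

#' @rdname choose_n_harmonics
#' @param c An `efa` object.
#' @export
harmonic_power <- function(c) {
  (c$an^2 + c$bn^2 + c$cn^2 + c$dn^2) / 2
}

#' Flatten normalized coefficients to a shape vector (and back)
#'
#' The shape vector used for all statistics: coefficients of harmonics
#' 1..`n_harmonics` excluding the three constants of the first harmonic
#' (`a1 = 1`, `b1 = c1 = 0` after normalization), giving `4 * N - 3`
#' variables (57 for the default N = 15), ordered `d1, a2, b2, c2, d2, ...`.
#'
#' @param c A normalized `efa` object with at least `n_harmonics` harmonics.
#' @param n_harmonics Number of harmonics to keep; default 15.
#' @return `to_shape_vector`: named numeric vector of length
#'   `4 * n_harmonics - 3`. `from_shape_vector`: a normalized `efa` object
#'   with the constants reinserted.
#' @export
to_shape_vector <- function(c, n_harmonics = 15) {
  if (!inherits(c, "efa")) stop("'c' must be an efa object", call. = FALSE)
  N <- check_count(n_harmonics, "n_harmonics", 1L)
  if (c$n_harmonics < N) {
    stop(sprintf("coefficients hold %d harmonics, need %d", c$n_harmonics, N),
         call. = FALSE)
  }
  if (abs(c$an[1L] - 1) > 1e-6 || abs(c$bn[1L]) > 1e-6 || abs(c$cn[1L]) > 1e-6) {
    stop("coefficients are not normalized (a1, b1, c1) != (1, 0, 0)", call. = FALSE)
  }
  v <- c(c$dn[1L])
  names(v) <- "d1"
  if (N >= 2L) {
    rest <- rbind(c$an[2:N], c$bn[2:N], c$cn[2:N], c$dn[2:N])
    nm <- as.vector(outer(c("a", "b", "c", "d"), 2:N, paste0))
    v <- c(v, stats::setNames(as.vector(rest), nm))
  }
  v
}

#' @rdname to_shape_vector
#' @param v Numeric vector of length `4 * N - 3`.
#' @export
from_shape_vector <- function(v) {
  len <- length(v)
  if ((len + 3L) %% 4L != 0L) {
    stop("shape vector length must be 4 * N - 3", call. = FALSE)
  }
  N <- (len + 3L) %/% 4L
  an <- c(1, rep(0, N - 1L)); bn <- rep(0, N); cn <- rep(0, N)
  dn <- c(v[1L], rep(0, N - 1L))
  if (N >= 2L) {
    rest <- matrix(v[-1L], nrow = 4L)
    an[2:N] <- rest[1L, ]; bn[2:N] <- rest[2L, ]
    cn[2:N] <- rest[3L, ]; dn[2:N] <- rest[4L, ]
  }
  structure(list(a0 = 0, c0 = 0, an = an, bn = bn, cn = cn, dn = dn,
                 T = 1, n_harmonics = N, normalized = TRUE),
            class = "efa")
}

#' Shape matrix from a set of outlines
#'
#' Convenience wrapper: resample, decompose, normalize and flatten a list of
#' outlines into the species-by-coefficients matrix used by the statistical
#' modules.
#'
#' @param outlines Named list of [outline()]s.
#' @param n_points Points for resampling; default 200.
#' @param n_harmonics Harmonics kept in the shape vector; default 15, or
#'   `"auto"` to select with [choose_n_harmonics()] at `threshold`.
#' @param threshold Power threshold for `"auto"`; default 0.99.
#' @param max_harmonics Harmonics computed before selection; default 30.
#' @return Matrix (species x coefficients) with an attribute `n_harmonics`.
#' @export
shape_matrix <- function(outlines, n_points = 200, n_harmonics = 15,
                         threshold = 0.99, max_harmonics = 30) {
  coefs <- lapply(outlines, function(o) {
    efa_normalize(efa_decompose(resample_outline(o, n_points), max_harmonics))
  })
  N <- if (identical(n_harmonics, "auto")) {
    choose_n_harmonics(coefs, threshold)
  } else check_count(n_harmonics, "n_harmonics", 1L)
  X <- do.call(rbind, lapply(coefs, to_shape_vector, n_harmonics = N))
  rownames(X) <- names(outlines)
  attr(X, "n_harmonics") <- N
  X
}
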