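#' Principal component morphospace of shape vectors
#'
#' Eigendecomposition of the sample variance-covariance matrix (divisor
#' n - 1) of the species-by-coefficients shape matrix. Species scores are the
#' centered data projected on the eigenvectors. Axis signs are fixed so that
#' each eigenvector's largest-magnitude entry is positive, making plots and
#' downstream vector correlations reproducible (the direction of a PC axis is
#' otherwise arbitrary).
#'
#' @param X Numeric matrix, species (rows) by shape variables (columns),
#'   at least 3 rows, no missing values.
#' @return An object of class `morphospace`: list with `mean` (column
#'   means), `rotation` (orthonormal eigenvectors, columns), `eigenvalues`
#'   (non-increasing, clamped at 0), `scores`, `var_explained` and
#'   `n_harmonics` (carried over from [shape_matrix()] if present).
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 species", call. = FALSE)
  if (anyNA(X)) stop("shape matrix contains missing values", call. = FALSE)
  if (all(abs(sweep(X, 2L, X[1L, ])) < .Machine$double.eps)) {
    stop("shape matrix is constant: no variation to decompose", call. = FALSE)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  flip <- apply(vecs, 2L, function(v) sign(v[which.max(abs(v))]))
  vecs <- sweep(vecs, 2L, flip, `*`)
  scores <- Xc %*% vecs
  colnames(vecs) <- colnames(scores) <- paste0("PC", seq_len(ncol(vecs)))
  rownames(vecs) <- colnames(X)
  rownames(scores) <- rownames(X)
  structure(list(mean = mu, rotation = vecs, eigenvalues = vals,
                 scores = scores, var_explained = vals / sum(vals),
                 n_harmonics = attr(X, "n_harmonics")),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  k <- min(5L, length(x$var_explained))
  cat(sprintf("<morphospace> %d species, %d variables\n",
              nrow(x$scores), length(x$mean)))
  cat("var explained:",
      paste(sprintf("%s %.1f%%", names(x$var_explained)[1:k] %||%
                      paste0("PC", 1:k), 100 * x$var_explained[1:k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a hypothetical outline along a principal component
#'
#' Builds the shape vector `mean + score * eigenvector(axis)`, converts it
#' back to elliptic Fourier coefficients and evaluates the inverse Fourier
#' transform. The default evaluation scores are plus/minus 2 SD of the
#' observed scores on that axis (the mean shape corresponds to `score = 0`).
#' The mean vector is added: the deviations along an eigenvector only make
#' anatomical sense relative to the mean shape.
#'
#' @param m A `morphospace` from [fit_pca()].
#' @param axis PC index.
#' @param score Score at which to reconstruct; default `2 * SD` of the
#'   observed scores on `axis`.
#' @param n_points Points in the reconstructed outline; default 200.
#' @return An [outline()].
#' @export
reconstruct_along_pc <- function(m, axis = 1L, score = NULL, n_points = 200) {
  axis <- check_count(axis, "axis", 1L)
  if (axis > ncol(m$rotation)) stop_field("axis", "exceeds fitted components")
  if (is.null(score)) score <- 2 * stats::sd(m$scores[, axis])
  v <- m$mean + score * m$rotation[, axis]
  efa_reconstruct(from_shape_vector(v), n_points)
}

#' Reconstruct the outline at an arbitrary position in morphospace
#'
#' @param m A `morphospace`.
#' @param scores Numeric vector of scores (recycled with zeros up to the
#'   number of components).
#' @param n_points Points in the outline.
#' @return An [outline()].
#' @export
reconstruct_from_scores <- function(m, scores, n_points = 200) {
  k <- ncol(m$rotation)
  s <- rep(0, k)
  s[seq_along(scores)] <- scores
  v <- m$mean + as.vector(m$rotation %*% s)
  efa_reconstruct(from_shape_vector(v), n_points)
}

# thin-plate spline solve: returns function mapping points, plus bending
# energy. U(r) = r^2 log r with U(0) = 0.
tps_solve <- function(reference, target) {
  P <- as_outline(reference)$points
  Q <- as_outline(target)$points
  if (nrow(P) != nrow(Q)) {
    stop("reference and target must have the same number of points", call. = FALSE)
  }
  n <- nrow(P)
  if (qr(cbind(1, P))$rank < 3L) {
    stop("collinear control points: thin-plate spline is singular", call. = FALSE)
  }
  D <- as.matrix(stats::dist(P))
  K <- D^2 * log(D)
  K[!is.finite(K)] <- 0
  Pm <- cbind(1, P)
  L <- rbind(cbind(K, Pm), cbind(t(Pm), matrix(0, 3L, 3L)))
  rhs <- rbind(Q, matrix(0, 3L, 2L))
  coef <- solve(L, rhs)
  W <- coef[seq_len(n), , drop = FALSE]
  A <- coef[(n + 1L):(n + 3L), , drop = FALSE]
  bending <- sum(diag(t(W) %*% K %*% W))
  map <- function(pts) {
    pts <- as.matrix(pts)
    d2 <- outer(rowSums(pts^2), rep(1, n)) +
      outer(rep(1, nrow(pts)), rowSums(P^2)) - 2 * pts %*% t(P)
    d2[d2 < 0] <- 0
    U <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0) # r^2 log r = d2 log(sqrt(d2))
    cbind(1, pts) %*% A + U %*% W
  }
  list(map = map, bending_energy = bending, W = W, A = A)
}

#' Thin-plate spline deformation grid
#'
#' Solves the standard thin-plate spline interpolation (kernel
#' `U(r) = r^2 log r`, affine plus bending terms, exact at the control
#' points) mapping the reference outline onto the target, with
#' point-by-index correspondence, and applies the map to a rectangular grid
#' covering the reference bounding box with a margin. This is the classical
#' visualization of shape change as a deformation from the mean outline.
#'
#' @param reference,target [outline()]s with equal point counts and
#'   index correspondence.
#' @param n_grid Grid nodes per side; default 24.
#' @param margin Bounding-box margin fraction; default 0.1.
#' @return An object of class `tps_grid`: list with `grid` (deformed node
#'   coordinates, (n_grid^2) x 2), `grid_ref` (undeformed nodes), `dim`
#'   (c(n_grid, n_grid)), `bending_energy`, `reference`, `target` and
#'   `mapped_reference` (deformed reference points, equal to the target up
#'   to numerical error).
#' @export
tps_grid <- function(reference, target, n_grid = 24, margin = 0.1) {
  n_grid <- check_count(n_grid, "n_grid", 2L)
  fit <- tps_solve(reference, target)
  P <- as_outline(reference)$points
  rx <- range(P[, 1L]); ry <- range(P[, 2L])
  rx <- rx + c(-1, 1) * margin * diff(rx)
  ry <- ry + c(-1, 1) * margin * diff(ry)
  gx <- seq(rx[1L], rx[2L], length.out = n_grid)
  gy <- seq(ry[1L], ry[2L], length.out = n_grid)
  nodes <- cbind(rep(gx, n_grid), rep(gy, each = n_grid))
  structure(list(grid = fit$map(nodes), grid_ref = nodes,
                 dim = c(n_grid, n_grid),
                 bending_energy = fit$bending_energy,
                 reference = as_outline(reference),
                 target = as_outline(target),
                 mapped_reference = fit$map(P)),
            class = "tps_grid")
}

#' @export
print.tps_grid <- function(x, ...) {
  cat(sprintf("<tps_grid> %d x %d nodes, bending energy %.4g\n",
              x$dim[1L], x$dim[2L], x$bending_energy))
  invisible(x)
}

#' Plot a thin-plate spline deformation grid
#'
#' @param x A `tps_grid`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.tps_grid <- function(x, ...) {
  g <- x$grid
  nr <- x$dim[1L]
  graphics::plot(g, type = "n", asp = 1, xlab = "", ylab = "", ...)
  for (i in seq_len(nr)) {
    graphics::lines(g[((i - 1L) * nr + 1L):(i * nr), ], col = "grey60")
    graphics::lines(g[seq(i, nr * nr, by = nr), ], col = "grey60")
  }
  graphics::lines(rbind(x$target$points, x$target$points[1L, ]), lwd = 2)
  invisible(x)
}

#' Morphospace scatter plot
#'
#' Scatter of species scores on two PCs, optionally colored by a categorical
#' variable and sized by a continuous one (with optional logarithmic
#' scaling, as used for aspect-ratio overlays).
#'
#' @param m A `morphospace`.
#' @param axes Two PC indices; default c(1, 2).
#' @param color_by Optional factor (one value per species).
#' @param size_by Optional positive numeric (one value per species).
#' @param log_size Log-scale the size gradient; default TRUE.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the score matrix of the plotted axes.
#' @export
plot_morphospace <- function(m, axes = c(1, 2), color_by = NULL,
                             size_by = NULL, log_size = TRUE, ...) {
  sc <- m$scores[, axes, drop = FALSE]
  col <- "black"
  if (!is.null(color_by)) {
    f <- as.factor(color_by)
    col <- grDevices::hcl.colors(nlevels(f), "Dark 2")[as.integer(f)]
  }
  cex <- 1
  if (!is.null(size_by)) {
    s <- if (log_size) log(size_by) else size_by
    cex <- 0.5 + 2 * (s - min(s)) / max(diff(range(s)), .Machine$double.eps)
  }
  graphics::plot(sc, col = col, cex = cex, pch = 19,
                 xlab = sprintf("%s (%.1f%%)", colnames(sc)[1L],
                                100 * m$var_explained[axes[1L]]),
                 ylab = sprintf("%s (%.1f%%)", colnames(sc)[2L],
                                100 * m$var_explained[axes[2L]]), ...)
  invisible(sc)
}
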