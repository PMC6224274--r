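#' Multivariate regression of shape on covariates
#'
#' Least-squares regression of each shape variable on the design (an
#' intercept is always included), the model `y = beta x + epsilon` behind
#' the allometry analysis. The fit's R-squared pools sums of squares over
#' all response columns: `R2 = 1 - SS_resid / SS_total`, with SS_total the
#' total squared deviation from the column means. An optional permutation
#' test permutes rows of `Y` against the design and uses R-squared as the
#' statistic.
#'
#' @param Y Response matrix, species by variables (a vector is treated as a
#'   one-column matrix).
#' @param x Covariate vector, factor, or matrix of covariates (no intercept
#'   column; one is added).
#' @param n_perm Number of permutations for the significance test; 0 (the
#'   default) skips it.
#' @param seed Seed for the permutation draw.
#' @return Object of class `shape_regression`: `coefficients` (rows
#'   `(Intercept)` then covariates), `fitted`, `residuals`, `r_squared`,
#'   `p_value` (or `NA`), `x`, `design`.
#' @export
mv_regress <- function(Y, x, n_perm = 0, seed = NULL) {
  Y <- as.matrix(Y)
  X <- design_matrix(x, nrow(Y))
  n <- nrow(Y)
  if (n <= ncol(X)) stop("need more species than design columns", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  coef <- qr.coef(qrX, Y)
  fitted <- qr.fitted(qrX, Y)
  resid <- Y - fitted
  ss_tot <- sum(sweep(Y, 2L, colMeans(Y))^2)
  r2 <- 1 - sum(resid^2) / ss_tot
  p <- NA_real_
  if (n_perm > 0) {
    r2s <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      rp <- Yp - qr.fitted(qrX, Yp)
      1 - sum(rp^2) / ss_tot
    }, 0))
    p <- (sum(r2s >= r2) + 1) / (n_perm + 1)
  }
  structure(list(coefficients = coef, fitted = fitted, residuals = resid,
                 r_squared = r2, p_value = p, x = x, design = X,
                 y_mean = colMeans(Y)),
            class = "shape_regression")
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("<shape_regression> %d obs, %d responses, R2 = %.4f",
              nrow(x$fitted), ncol(x$fitted), x$r_squared))
  if (!is.na(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

# build a design matrix (without intercept) from a vector/factor/matrix,
# then prepend the intercept
design_matrix <- function(x, n) {
  if (is.matrix(x)) {
    M <- x
  } else if (is.factor(x) || is.character(x)) {
    f <- as.factor(x)
    if (any(table(f) == 0L)) stop("empty factor level", call. = FALSE)
    M <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  } else {
    M <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "x"))
  }
  if (nrow(M) != n) stop("covariate length does not match Y", call. = FALSE)
  cbind(`(Intercept)` = 1, M)
}

#' Shape score: projection of shape data on a regression vector
#'
#' The one-dimensional summary of a multivariate regression:
#' `s = y b^T (b b^T)^(-1/2)`, i.e. the projection of each species' shape
#' onto the line parallel to the regression vector `b`, in units of the
#' response. For a univariate response this reduces to `y * sign(b)`.
#'
#' @param Y Shape matrix (species by variables) or vector.
#' @param beta Regression coefficient vector of the covariate of interest
#'   (length = number of shape variables).
#' @return Numeric vector of per-species scores.
#' @references Drake & Klingenberg (2008) The pace of morphological change.
#'   Proc. R. Soc. B 275:71-76.
#' @export
shape_score <- function(Y, beta) {
  Y <- as.matrix(Y)
  beta <- as.numeric(beta)
  if (length(beta) != ncol(Y)) {
    stop("'beta' length must match the number of shape variables", call. = FALSE)
  }
  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop("'beta' is the zero vector", call. = FALSE)
  as.vector(Y %*% beta) / nb
}

# internal engine for sequential (Type I) sums of squares with residual
# randomization (RRPP). designs: list of design matrices for the nested
# models M0 (first) .. M_full (last); labels: term names for rows 2..k.
sequential_ss_rrpp <- function(Y, designs, labels, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- length(designs) - 1L # number of terms
  Qs <- lapply(designs, function(D) qr.Q(qr(D)))
  ranks <- vapply(designs, function(D) qr(D)$rank, 0L)
  ss_model <- vapply(Qs, function(Q) sum(crossprod(Q, Y)^2), 0)
  ss_y <- sum(Y^2)
  ss_term <- diff(ss_model)
  df_term <- diff(ranks)
  ss_res <- ss_y - ss_model[length(ss_model)]
  df_res <- n - ranks[length(ranks)]
  ss_tot <- ss_y - ss_model[1L] # deviation from the null (intercept) model
  F_obs <- (ss_term / df_term) / (ss_res / df_res)
  p <- Z <- rep(NA_real_, k)
  if (n_perm > 0) {
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(i) sample.int(n)))
    for (j in seq_len(k)) {
      Qred <- Qs[[j]]
      fit_red <- Qred %*% crossprod(Qred, Y)
      res_red <- Y - fit_red
      Fs <- vapply(perms, function(pm) {
        Ys <- fit_red + res_red[pm, , drop = FALSE]
        mj1 <- sum(crossprod(Qs[[j + 1L]], Ys)^2)
        mj0 <- sum(crossprod(Qred, Ys)^2)
        resf <- sum(Ys^2) - sum(crossprod(Qs[[length(Qs)]], Ys)^2)
        ((mj1 - mj0) / df_term[j]) / (resf / df_res)
      }, 0)
      p[j] <- (sum(Fs >= F_obs[j]) + 1) / (n_perm + 1)
      Z[j] <- (F_obs[j] - mean(Fs)) / stats::sd(Fs)
    }
  }
  tab <- data.frame(
    term = c(labels, "Residuals", "Total"),
    Df = c(df_term, df_res, n - ranks[1L]),
    SS = c(ss_term, ss_res, ss_tot),
    R2 = c(ss_term, ss_res, ss_tot) / ss_tot,
    F = c(F_obs, NA, NA),
    Z = c(Z, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  class(tab) <- c("mancova_table", "data.frame")
  attr(tab, "n_perm") <- n_perm
  tab
}

#' @export
print.mancova_table <- function(x, digits = 4, ...) {
  cat(sprintf("Sequential (Type I) MANCOVA, %d permutations (RRPP)\n",
              attr(x, "n_perm") %||% 0L))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Sequential MANCOVA of shape on model terms with RRPP permutation tests
#'
#' Fits the terms of `formula` sequentially (Type I sums of squares): the SS
#' of term k is the drop in residual trace cross-product between the nested
#' models with terms 1..k-1 and 1..k. `F_k = (SS_k / df_k) / (SS_res /
#' df_res)`, `R2_k = SS_k / SS_total`. Significance is assessed by residual
#' randomization under the reduced model (RRPP): residuals of model k-1 are
#' row-permuted, added back to its fitted values, and the F statistic is
#' recomputed; `p = (#(F* >= F) + 1) / (n_perm + 1)`. The effect size Z is
#' `(F_obs - mean F*) / sd F*` on the raw F scale.
#'
#' @param Y Shape matrix (species by variables) or response vector.
#' @param formula One-sided formula of the model terms, e.g.
#'   `~ size * trophic_mode`; terms enter in `terms()` order.
#' @param data Data frame with the variables of `formula`.
#' @param n_perm Number of RRPP permutations; default 999.
#' @param seed Seed for the permutation draw.
#' @return A `mancova_table` data frame: one row per term plus `Residuals`
#'   and `Total`, with columns `Df`, `SS`, `R2`, `F`, `Z`, `p`.
#' @export
mancova <- function(Y, formula, data, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  tm <- stats::terms(formula, data = data)
  for (v in all.vars(formula)) {
    col <- data[[v]]
    if ((is.factor(col) || is.character(col)) && any(table(col) == 0L)) {
      stop(sprintf("empty factor level in '%s'", v), call. = FALSE)
    }
  }
  X <- stats::model.matrix(tm, data)
  asgn <- attr(X, "assign")
  labels <- attr(tm, "term.labels")
  if (nrow(X) != nrow(Y)) stop("'data' rows must match Y", call. = FALSE)
  designs <- lapply(0:length(labels), function(k) {
    X[, asgn <= k, drop = FALSE]
  })
  sequential_ss_rrpp(Y, designs, labels, n_perm = n_perm, seed = seed)
}

#' Vector correlation between two direction vectors
#'
#' `R` is the absolute value of the normalized dot product
#' `|v1 . v2| / (|v1| |v2|)` (absolute, because the direction of a PC axis is
#' arbitrary), and `theta = arccos(R)` expresses it as an angle in degrees:
#' 0 for parallel, 90 for orthogonal vectors.
#'
#' @param v1,v2 Nonzero numeric vectors of equal length.
#' @return Object of class `vector_correlation`: list with `R` and `theta`
#'   (degrees).
#' @export
vector_correlation <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop("vectors must have equal length", call. = FALSE)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector", call. = FALSE)
  R <- min(abs(sum(v1 * v2)) / (n1 * n2), 1)
  structure(list(R = R, theta = acos(R) * 180 / pi),
            class = "vector_correlation")
}

#' @export
print.vector_correlation <- function(x, ...) {
  cat(sprintf("<vector_correlation> R = %.4f, theta = %.2f deg", x$R, x$theta))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Permutation test of the correlation between a regression vector and a
#' reference direction
#'
#' Regresses the shape data on the covariate, takes the covariate's
#' coefficient vector and computes its vector correlation with
#' `reference_vector` (typically a PC eigenvector). The null distribution is
#' built by permuting the covariate values across species and recomputing R
#' (`permute = "covariate"`, the default) or by permuting the rows of the
#' shape data (`permute = "rows"`); `p = (#(R* >= R) + 1) / (n_perm + 1)`.
#'
#' @param Y Shape matrix, species by variables.
#' @param covariate Numeric vector or two-level factor.
#' @param reference_vector Direction to compare against (length = ncol(Y)).
#' @param n_perm Number of permutations; default 999.
#' @param seed Seed.
#' @param permute What to permute under the null.
#' @return A `vector_correlation` with elements `p` and `n_perm` added.
#' @export
vector_correlation_test <- function(Y, covariate, reference_vector,
                                    n_perm = 999, seed = NULL,
                                    permute = c("covariate", "rows")) {
  permute <- match.arg(permute)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  beta_of <- function(cov) {
    fit <- mv_regress(Y, cov)
    fit$coefficients[2L, ]
  }
  obs <- vector_correlation(beta_of(covariate), reference_vector)
  Rs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    b <- if (permute == "covariate") {
      beta_of(sample(covariate))
    } else {
      fit <- mv_regress(Y[sample.int(n), , drop = FALSE], covariate)
      fit$coefficients[2L, ]
    }
    vector_correlation(b, reference_vector)$R
  }, 0))
  obs$p <- (sum(Rs >= obs$R) + 1) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

#' Allometry-free shapes: residuals from the regression of shape on size
#'
#' Removes the shape variation explained by size: the allometry-free shape
#' of each species is the regression residual plus the mean shape (so it can
#' be reconstructed as an outline). If a fitted morphospace is supplied the
#' residual shapes are also projected onto its original eigenvectors, i.e.
#' scored in the unadjusted shape space.
#'
#' @param Y Shape matrix, species by variables.
#' @param size Size covariate (e.g. larval length).
#' @param morphospace Optional `morphospace` from [fit_pca()] fitted to the
#'   original shapes.
#' @return List with `model` (the [mv_regress()] fit), `residuals`,
#'   `shapes` (residuals + mean shape) and `scores` (projection onto the
#'   original eigenvectors, or `NULL`).
#' @export
allometry_free <- function(Y, size, morphospace = NULL) {
  Y <- as.matrix(Y)
  fit <- mv_regress(Y, size)
  shapes <- sweep(fit$residuals, 2L, colMeans(Y), `+`)
  scores <- NULL
  if (!is.null(morphospace)) {
    scores <- sweep(shapes, 2L, morphospace$mean) %*% morphospace$rotation
  }
  list(model = fit, residuals = fit$residuals, shapes = shapes,
       scores = scores)
}

#' Balanced bootstrap of group means
#'
#' Case-resampling bootstrap of per-group means for a two-level factor.
#' With `balanced = TRUE` (the default) each replicate samples the same
#' number of cases with replacement from each group — the size of the
#' smaller group — correcting for unequal group membership.
#'
#' @param values Numeric vector or matrix (rows = species).
#' @param groups Two-level factor (or coercible).
#' @param n_boot Number of replicates; default 1000.
#' @param balanced Equalize per-group sample size; default TRUE.
#' @param seed Seed.
#' @return Object of class `group_bootstrap`: list with `groups` (level
#'   names), `means` (observed group means), `boot` (list of replicate mean
#'   matrices per group), `ci` (2.5/97.5 percentile intervals per group),
#'   `diff` (replicate differences, level 2 minus level 1) and `diff_ci`.
#' @export
bootstrap_groups <- function(values, groups, n_boot = 1000, balanced = TRUE,
                             seed = NULL) {
  V <- as.matrix(values)
  f <- as.factor(groups)
  if (nlevels(f) != 2L) stop("'groups' must have exactly two levels", call. = FALSE)
  idx <- split(seq_len(nrow(V)), f)
  sizes <- lengths(idx)
  if (any(sizes < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 members",
                 names(idx)[which(sizes < 2L)[1L]]), call. = FALSE)
  }
  m <- min(sizes)
  boot <- with_seed(seed, {
    lapply(idx, function(ii) {
      k <- if (balanced) m else length(ii)
      B <- vapply(seq_len(n_boot), function(b) {
        colMeans(V[sample(ii, k, replace = TRUE), , drop = FALSE])
      }, numeric(ncol(V)))
      if (is.matrix(B)) t(B) else matrix(B, ncol = 1L)
    })
  })
  ci <- lapply(boot, function(B) {
    apply(B, 2L, stats::quantile, probs = c(0.025, 0.975))
  })
  d <- boot[[2L]] - boot[[1L]]
  structure(list(groups = levels(f),
                 means = t(vapply(idx, function(ii) colMeans(V[ii, , drop = FALSE]),
                                  numeric(ncol(V)))),
                 boot = boot, ci = ci, diff = d,
                 diff_ci = apply(d, 2L, stats::quantile, probs = c(0.025, 0.975)),
                 n_boot = n_boot, balanced = balanced, m = m),
            class = "group_bootstrap")
}

#' @export
print.group_bootstrap <- function(x, ...) {
  cat(sprintf("<group_bootstrap> %d replicates, %s resampling (%d per group)\n",
              x$n_boot, if (x$balanced) "balanced" else "full", x$m))
  print(x$means)
  invisible(x)
}

#' Predicted shapes along the size gradient
#'
#' Evaluates a fitted allometric regression at chosen sizes and reconstructs
#' the predicted shape vectors as outlines — the visualization of shape
#' change predicted by the regression model. Default sizes are the sample
#' mean and the 50% and 95% intervals of the observed sizes.
#'
#' @param model A `shape_regression` from [mv_regress()] with a single
#'   covariate and shape-vector responses (length `4 * N - 3`).
#' @param sizes Sizes at which to predict; default as described.
#' @param n_points Points per reconstructed outline.
#' @return List with `sizes`, `vectors` (predicted shape vectors) and
#'   `outlines`.
#' @export
predict_shapes_along_size <- function(model, sizes = NULL, n_points = 200) {
  if (!inherits(model, "shape_regression")) {
    stop("'model' must come from mv_regress()", call. = FALSE)
  }
  if (nrow(model$coefficients) != 2L) {
    stop("'model' must have a single covariate", call. = FALSE)
  }
  x <- as.numeric(model$x)
  if (is.null(sizes)) {
    sizes <- c(mean(x), stats::quantile(x, c(0.25, 0.75, 0.025, 0.975)))
    names(sizes) <- c("mean", "q25", "q75", "q2.5", "q97.5")
  }
  pred <- cbind(1, sizes) %*% model$coefficients
  outlines <- NULL
  if ((ncol(pred) + 3L) %% 4L == 0L) {
    outlines <- lapply(seq_along(sizes), function(i) {
      efa_reconstruct(from_shape_vector(pred[i, ]), n_points)
    })
    names(outlines) <- names(sizes)
  }
  list(sizes = sizes, vectors = pred, outlines = outlines)
}
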