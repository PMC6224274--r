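#' Read and write Newick trees with validation
#'
#' Thin wrappers around the ape parsers that enforce what downstream
#' comparative methods need: branch lengths present and non-negative, unique
#' tip labels. Polytomies are accepted (they are resolved with zero-length
#' branches where an algorithm needs a binary tree; the Brownian covariance
#' is identical either way).
#'
#' @param path Newick file path.
#' @param tree An `ape::phylo` tree to write.
#' @return `read_newick`: an `ape::phylo`. `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop(sprintf(
                     "failed to parse Newick file '%s': %s", path,
                     conditionMessage(e)), call. = FALSE))
  if (is.null(tree)) stop(sprintf("failed to parse Newick file '%s'", path),
                          call. = FALSE)
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicate tip labels: %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  invisible(tree)
}

# A phylo object is read as rooted at its basal node. The one shape that is
# conventionally an UNrooted tree in that encoding is a basal trichotomy on
# an otherwise binary tree (ape::unroot's output); reject that, but accept
# genuine polytomies (star trees and the like), which are resolved with
# zero-length branches where needed.
check_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(invisible(tree))
  ntip <- length(tree$tip.label)
  basal_children <- sum(tree$edge[, 1L] == ntip + 1L)
  others_binary <- tree$Nnode == 1L ||
    all(tabulate(tree$edge[, 1L])[-(ntip + 1L)] %in% c(0L, 2L))
  if (basal_children == 3L && others_binary && ntip > 3L) {
    stop("tree must be rooted (found an unrooted binary tree)", call. = FALSE)
  }
  invisible(tree)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Expected trait covariance under Brownian motion at unit rate:
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip path
#' lengths. Tree need not be ultrametric; path lengths are used as given.
#' Polytomies are fine (their covariance equals that of any zero-length
#' resolution); a basal trichotomy on an otherwise binary tree is rejected
#' as an unrooted tree.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return Tips-by-tips matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  check_rooted(tree)
  ape::vcv(tree)
}

# align a named vector/matrix of tip data to a tree; drop extra species with
# a warning; error on tips missing from the data
align_to_tree <- function(Y, tree) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) {
    if (nrow(Y) == length(tree$tip.label)) {
      rownames(Y) <- tree$tip.label
      warning("data rows are unnamed; assuming tree tip order")
    } else {
      stop("data rows must be named by tip label", call. = FALSE)
    }
  }
  missing <- setdiff(tree$tip.label, rownames(Y))
  if (length(missing)) {
    stop(sprintf("tips missing from the data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(rownames(Y), tree$tip.label)
  if (length(extra)) {
    warning(sprintf("%d species absent from the tree were dropped: %s",
                    length(extra), paste(utils::head(extra, 5L), collapse = ", ")))
  }
  Y[tree$tip.label, , drop = FALSE]
}

# GLS phylogenetic mean(s); returns list(a = mean vector, Cinv)
phylo_gls_mean <- function(Y, C) {
  Cinv <- solve(C)
  one <- rep(1, nrow(C))
  w <- as.vector(Cinv %*% one)
  a <- as.vector(crossprod(w, Y)) / sum(w)
  list(a = a, Cinv = Cinv, sum_w = sum(w))
}

# shared expected MSE ratio under BM: [tr(C) - n / (1' Cinv 1)] / (n - 1)
k_expected_ratio <- function(C, Cinv) {
  n <- nrow(C)
  (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
}

#' Blomberg's K: phylogenetic signal of a single trait
#'
#' K compares the observed ratio of the trait's mean squared error (about
#' the GLS phylogenetic mean) to its phylogenetically corrected mean squared
#' error, against the ratio expected under Brownian motion on the given
#' tree. K = 1 matches the Brownian expectation; K < 1 means relatives
#' resemble each other less than expected, K > 1 more. Significance comes
#' from permuting trait values across tips.
#'
#' @param y Named numeric vector of tip values (names = tip labels).
#' @param tree Rooted `ape::phylo` with branch lengths, >= 4 tips.
#' @param n_perm Number of permutations; default 999 (0 skips the test).
#' @param seed Seed.
#' @return Object of class `phylo_signal`: list with `statistic`, `p`,
#'   `n_perm`, `method = "K"`.
#' @references Blomberg, Garland & Ives (2003) Testing for phylogenetic
#'   signal in comparative data. Evolution 57:717-745.
#' @export
blomberg_k <- function(y, tree, n_perm = 999, seed = NULL) {
  validate_tree(tree)
  if (length(tree$tip.label) < 4L) stop("need at least 4 tips", call. = FALSE)
  y <- align_to_tree(y, tree)
  C <- bm_covariance(tree)
  g <- phylo_gls_mean(y, C)
  expected <- k_expected_ratio(C, g$Cinv)
  w <- as.vector(g$Cinv %*% rep(1, nrow(C)))
  k_of <- function(yv) {
    d <- yv - sum(w * yv) / g$sum_w
    (sum(d^2) / as.vector(crossprod(d, g$Cinv %*% d))) / expected
  }
  K <- k_of(as.vector(y))
  p <- NA_real_
  if (n_perm > 0) {
    Ks <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      k_of(sample(as.vector(y)))
    }, 0))
    p <- (sum(Ks >= K) + 1) / (n_perm + 1)
  }
  structure(list(statistic = K, p = p, n_perm = n_perm, method = "K"),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("<phylo_signal> %s = %.4f", x$method, x$statistic))
  if (!is.na(x$p)) cat(sprintf(", p = %.4g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  invisible(x)
}

# symmetric inverse square root with eigenvalue floor
inv_sqrt_sym <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Multivariate phylogenetic signal K_mult
#'
#' Generalization of Blomberg's K to multivariate data: the numerator is the
#' summed squared Euclidean distance of the rows of `Y` from the GLS
#' phylogenetic mean vector; the denominator is the same quantity after
#' transforming the centered rows by the inverse square root of the
#' Brownian covariance matrix; their ratio is scaled by the same expected
#' ratio as the univariate K. With one trait K_mult equals K exactly.
#' Significance by permuting rows of `Y` across tips.
#'
#' @param Y Matrix of tip values (rows named by tip label) or named vector.
#' @param tree Rooted `ape::phylo`, >= 4 tips.
#' @param n_perm Permutations; default 999.
#' @param seed Seed.
#' @return A `phylo_signal` with `method = "K_mult"`.
#' @references Adams (2014) A generalized K statistic for estimating
#'   phylogenetic signal from shape and other high-dimensional multivariate
#'   data. Systematic Biology 63:685-697.
#' @export
k_mult <- function(Y, tree, n_perm = 999, seed = NULL) {
  validate_tree(tree)
  if (length(tree$tip.label) < 4L) stop("need at least 4 tips", call. = FALSE)
  Y <- align_to_tree(Y, tree)
  C <- bm_covariance(tree)
  g <- phylo_gls_mean(Y, C)
  expected <- k_expected_ratio(C, g$Cinv)
  Einv <- inv_sqrt_sym(C)
  w <- as.vector(g$Cinv %*% rep(1, nrow(C)))
  k_of <- function(M) {
    a <- as.vector(crossprod(w, M)) / g$sum_w
    D <- sweep(M, 2L, a)
    (sum(D^2) / sum((Einv %*% D)^2)) / expected
  }
  K <- k_of(Y)
  p <- NA_real_
  if (n_perm > 0) {
    n <- nrow(Y)
    Ks <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      k_of(Y[sample.int(n), , drop = FALSE])
    }, 0))
    p <- (sum(Ks >= K) + 1) / (n_perm + 1)
  }
  structure(list(statistic = K, p = p, n_perm = n_perm, method = "K_mult"),
            class = "phylo_signal")
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates internal-node values per trait as the values minimizing the sum
#' over branches of (change)^2 / branch length — the maximum-likelihood /
#' GLS solution under Brownian motion, obtained by solving the weighted
#' tree-Laplacian linear system (sparse; tips enter as fixed boundary
#' values). Used to place a phylogeny's internal nodes in morphospace.
#' Zero-length branches are replaced by a small epsilon (1e-8 of the tree
#' height) with a warning.
#'
#' @param Y Matrix of tip values (rows named by tip label) or named vector.
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @return Matrix of internal-node states; row names are ape node numbers
#'   (`n_tips + 1` is the root).
#' @export
ancestral_states <- function(Y, tree) {
  validate_tree(tree)
  check_rooted(tree)
  Y <- align_to_tree(Y, tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  el <- tree$edge.length
  if (any(el == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    if (eps == 0) stop("tree has no positive branch lengths", call. = FALSE)
    el[el == 0] <- eps
    warning("zero-length branches replaced by a small epsilon")
  }
  w <- 1 / el
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  # Laplacian over internal nodes (indices ntip+1 .. ntip+nnode)
  ii <- jj <- integer(0)
  vv <- numeric(0)
  B <- matrix(0, nnode, ncol(Y))
  diag_w <- numeric(nnode)
  int_id <- function(node) node - ntip
  for (e in seq_along(w)) {
    pnode <- int_id(parent[e])
    diag_w[pnode] <- diag_w[pnode] + w[e]
    if (child[e] <= ntip) {
      B[pnode, ] <- B[pnode, ] + w[e] * Y[child[e], ]
    } else {
      cnode <- int_id(child[e])
      diag_w[cnode] <- diag_w[cnode] + w[e]
      ii <- c(ii, pnode, cnode); jj <- c(jj, cnode, pnode)
      vv <- c(vv, -w[e], -w[e])
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nnode)),
                            j = c(jj, seq_len(nnode)),
                            x = c(vv, diag_w), dims = c(nnode, nnode))
  anc <- as.matrix(Matrix::solve(A, B))
  rownames(anc) <- as.character(ntip + seq_len(nnode))
  colnames(anc) <- colnames(Y)
  anc
}

#' Phylomorphospace coordinates
#'
#' Tip and maximum-likelihood ancestral-node positions on chosen morphospace
#' axes, with the tree's edges, ready for plotting a phylogeny over the
#' morphospace.
#'
#' @param m A `morphospace` from [fit_pca()] with row-named scores.
#' @param tree Rooted `ape::phylo`; tips must be a subset of the score rows.
#' @param axes Axes to project; default c(1, 2).
#' @return List with `nodes` (data frame: node_id, coordinates, is_tip) and
#'   `edges` (the tree's edge matrix), plus the pruned `tree`.
#' @export
phylomorphospace_coords <- function(m, tree, axes = c(1, 2)) {
  sc <- m$scores[, axes, drop = FALSE]
  keep <- intersect(tree$tip.label, rownames(sc))
  if (length(keep) < 3L) stop("fewer than 3 tree tips have scores", call. = FALSE)
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, keep)
  }
  tips <- sc[tree$tip.label, , drop = FALSE]
  anc <- ancestral_states(tips, tree)
  ntip <- length(tree$tip.label)
  nodes <- data.frame(
    node_id = c(tree$tip.label, rownames(anc)),
    rbind(tips, anc),
    is_tip = rep(c(TRUE, FALSE), c(ntip, nrow(anc))),
    row.names = NULL)
  names(nodes)[2:3] <- colnames(sc)
  list(nodes = nodes, edges = tree$edge, tree = tree)
}

#' Phylogenetic MANCOVA via Brownian whitening
#'
#' Accounts for non-independence among species: both the response matrix and
#' the full design matrix (including its intercept column) are premultiplied
#' by the inverse square root of the Brownian covariance matrix of the tree,
#' then the ordinary sequential (Type I) MANCOVA with RRPP permutation is
#' run on the transformed data. On a star phylogeny with equal unit branches
#' this reduces exactly to [mancova()].
#'
#' @param Y Shape matrix, rows named by tip label.
#' @param formula One-sided model formula, e.g. `~ size * trophic_mode`.
#' @param data Data frame of covariates, rows named (or ordered) as `Y`.
#' @param tree Rooted `ape::phylo`.
#' @param n_perm RRPP permutations; default 999.
#' @param seed Seed.
#' @return A `mancova_table`.
#' @export
phylo_lm <- function(Y, formula, data, tree, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(data)) || all(rownames(data) == as.character(seq_len(nrow(data))))) {
    if (!is.null(rownames(Y))) rownames(data) <- rownames(Y)
  }
  Y <- align_to_tree(Y, tree)
  data <- data[rownames(Y), , drop = FALSE]
  C <- bm_covariance(tree)
  Tm <- inv_sqrt_sym(C)
  tm <- stats::terms(formula, data = data)
  X <- stats::model.matrix(tm, data)
  asgn <- attr(X, "assign")
  labels <- attr(tm, "term.labels")
  Yt <- Tm %*% Y
  Xt <- Tm %*% X
  designs <- lapply(0:length(labels), function(k) {
    Xt[, asgn <= k, drop = FALSE]
  })
  sequential_ss_rrpp(Yt, designs, labels, n_perm = n_perm, seed = seed)
}
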