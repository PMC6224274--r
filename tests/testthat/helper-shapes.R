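# Geometric fixtures built in code.

circle_outline <- function(r = 1, center = c(0, 0), n = 200, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  outline(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

ellipse_outline <- function(a = 2, b = 1, n = 200, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  outline(cbind(a * cos(th), b * sin(th)))
}

random_star_polygon <- function(k = 64, amp = 0.3, seed = 1) {
  set.seed(seed)
  r <- 1 + amp * runif(k)
  th <- 2 * pi * (0:(k - 1)) / k
  outline(cbind(r * cos(th), r * sin(th)))
}

# apply scale s, rotation ang, translation tr, and start shift to raw points
similarity_transform <- function(o, s = 1, ang = 0, tr = c(0, 0), shift = 0) {
  p <- o$points
  A <- s * rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  q <- sweep(p %*% t(A), 2, -tr)
  if (shift > 0) {
    n <- nrow(q)
    shift <- ((shift - 1) %% n) + 1
    q <- q[c(shift:n, seq_len(shift - 1)), , drop = FALSE]
  }
  outline(q)
}

hausdorff_dist <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  d2[d2 < 0] <- 0
  max(sqrt(min_by_row <- apply(d2, 1, min)), sqrt(apply(d2, 2, min)))
}

default_nauplius <- function(aspect = 0.7, horn = 0.3, tail = 0.2,
                             size = 400, n = 200) {
  make_nauplius_outline(
    shape_params(aspect_ratio = aspect, rel_horn_length = horn,
                 tail_length = tail, size = size), n_points = n)
}

# normalized shape vector straight from an outline
nauplius_shape_vector <- function(o, n_harmonics = 15, n = 200) {
  to_shape_vector(efa_normalize(efa_decompose(resample_outline(o, n),
                                              n_harmonics)),
                  n_harmonics = n_harmonics)
}
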