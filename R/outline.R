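#' Closed planar outline
#'
#' Container for a closed outline: an ordered sequence of (x, y) vertices of
#' a simple polygon. The closing edge from the last vertex back to the first
#' is implicit; the last point is dropped if it duplicates the first.
#' On construction consecutive duplicate vertices are removed and the
#' orientation is made counterclockwise (positive signed area), the
#' convention all downstream analyses assume. The coordinate frame is
#' x rightward, y upward, with the larval anterior at +y.
#'
#' @param points Two-column numeric matrix or data frame of vertices.
#' @param start_index Index of the designated sampling start point.
#' @return An object of class `outline`: a list with elements `points`
#'   (n x 2 matrix with columns `x`, `y`), `closed` (always `TRUE`) and
#'   `start_index`.
#' @examples
#' sq <- outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' outline_area(sq)
#' @export
outline <- function(points, start_index = 1L) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points)) {
    stop("'points' must be a two-column numeric matrix", call. = FALSE)
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("outline points must be finite", call. = FALSE)
  }
  # drop explicit closure and consecutive duplicates
  n <- nrow(points)
  if (n >= 2L && all(points[1L, ] == points[n, ])) points <- points[-n, , drop = FALSE]
  if (nrow(points) >= 2L) {
    d <- rowSums(abs(points - points[c(2:nrow(points), 1L), , drop = FALSE]))
    # d[i] compares vertex i to its successor; keep i when it differs
    keep <- d > 0
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 3L) stop("an outline needs at least 3 distinct points", call. = FALSE)
  colnames(points) <- c("x", "y")
  if (polygon_area(points) < 0) {
    # reverse orientation keeping the first vertex first
    n <- nrow(points)
    points <- points[c(1L, n:2L), , drop = FALSE]
    start_index <- if (start_index == 1L) 1L else n - start_index + 2L
  }
  structure(list(points = points, closed = TRUE,
                 start_index = as.integer(start_index)),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %d points, perimeter %.4g, area %.4g\n",
              nrow(x$points), outline_perimeter(x), outline_area(x)))
  invisible(x)
}

as_outline <- function(x) {
  if (inherits(x, "outline")) x else outline(x)
}

# signed area of a polygon given as an open vertex matrix (shoelace)
polygon_area <- function(p) {
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  sum(p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]) / 2
}

#' Signed area, perimeter and centroid of an outline
#'
#' @param o An [outline()].
#' @return `outline_area`: signed area (positive, since outlines are
#'   counterclockwise). `outline_perimeter`: total polygon perimeter
#'   including the closing edge. `outline_centroid`: area centroid (x, y).
#' @export
outline_area <- function(o) polygon_area(as_outline(o)$points)

#' @rdname outline_area
#' @export
outline_perimeter <- function(o) {
  p <- as_outline(o)$points
  sum(sqrt(rowSums((p[c(2:nrow(p), 1L), , drop = FALSE] - p)^2)))
}

#' @rdname outline_area
#' @export
outline_centroid <- function(o) {
  p <- as_outline(o)$points
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  cr <- p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]
  a <- sum(cr) / 2
  c(x = sum((p[, 1L] + q[, 1L]) * cr) / (6 * a),
    y = sum((p[, 2L] + q[, 2L]) * cr) / (6 * a))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Test whether an outline is a simple (non-self-intersecting) polygon
#'
#' Exhaustive pairwise edge-intersection check, quadratic in the number of
#' vertices; intended for validation and testing rather than bulk use.
#'
#' @param o An [outline()].
#' @return `TRUE` if no two non-adjacent edges cross.
#' @export
outline_is_simple <- function(o) {
  p <- as_outline(o)$points
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j == i || nxt[j] == i) next
      if (segments_intersect(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# apply a 2x2 linear map and translation to an outline (internal)
transform_outline <- function(o, A = diag(2), b = c(0, 0)) {
  o <- as_outline(o)
  outline(sweep(o$points %*% t(A), 2L, -b), start_index = o$start_index)
}
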