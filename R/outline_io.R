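#' Trace the sub-pixel boundary of a binary mask
#'
#' Extracts the outline of the single foreground component of a binary mask
#' as a sub-pixel contour at the 0.5 level. The mask is lightly smoothed
#' with a Gaussian kernel first so that the marching-squares contour follows
#' the true boundary rather than the pixel staircase (an unsmoothed binary
#' contour overestimates perimeters by several percent). Image rows are
#' inverted so that the result lives in the package's x-rightward,
#' y-upward frame, with coordinates in pixels.
#'
#' @param mask A binary matrix (rows = image rows, top first), an
#'   `EBImage::Image`, or a path to a PNG/TIFF file.
#' @param smooth_sigma SD (pixels) of the Gaussian pre-smoothing; default
#'   1.5. Set to 0 to contour the raw mask.
#' @param min_area Minimum foreground area in pixels; default 100.
#' @return An [outline()] in pixel units, counterclockwise.
#' @export
trace_mask <- function(mask, smooth_sigma = 1.5, min_area = 100) {
  if (is.character(mask)) mask <- EBImage::readImage(mask)
  if (inherits(mask, "Image")) {
    # EBImage stores images as x (col) by y (row, top first): transpose back
    mask <- t(as.matrix(mask))
  }
  if (!is.matrix(mask)) stop("'mask' must be a matrix, Image or file path", call. = FALSE)
  m <- (mask > 0.5) * 1
  if (sum(m) < min_area) {
    stop(sprintf("foreground area %d below minimum %d", sum(m), as.integer(min_area)),
         call. = FALSE)
  }
  lab <- EBImage::bwlabel(EBImage::as.Image(t(m)))
  ncomp <- max(lab)
  if (ncomp != 1L) {
    stop(sprintf("mask must contain exactly one component, found %d components",
                 ncomp), call. = FALSE)
  }
  if (any(m[1L, ] > 0) || any(m[nrow(m), ] > 0) ||
      any(m[, 1L] > 0) || any(m[, ncol(m)] > 0)) {
    stop("foreground component touches the image border", call. = FALSE)
  }
  z <- m
  if (smooth_sigma > 0) {
    z <- t(as.matrix(EBImage::gblur(EBImage::as.Image(t(m)), sigma = smooth_sigma)))
  }
  # flip rows so y increases upward; contourLines wants z[x_index, y_index]
  zz <- t(z[nrow(z):1L, , drop = FALSE])
  cl <- grDevices::contourLines(seq_len(ncol(m)), seq_len(nrow(m)), zz,
                                levels = 0.5)
  if (length(cl) == 0L) stop("no 0.5-level contour found", call. = FALSE)
  # outer boundary = loop with largest absolute area (holes are smaller)
  areas <- vapply(cl, function(ct) abs(polygon_area(cbind(ct$x, ct$y))), 0)
  ct <- cl[[which.max(areas)]]
  outline(cbind(ct$x, ct$y))
}

#' Render an outline to a binary mask
#'
#' Rasterizes an outline: pixel centers strictly inside the polygon become
#' foreground. The outline is shifted and scaled into the image so that the
#' package's y-upward frame maps onto image rows (top row = largest y).
#'
#' @param o An [outline()].
#' @param width,height Image size in pixels.
#' @param margin Fraction of the image left blank around the shape;
#'   default 0.05.
#' @return A list with `mask` (0/1 matrix, rows top-first), and `scale`,
#'   `offset` mapping outline coordinates to pixel coordinates
#'   (`px = (xy - offset) * scale`).
#' @export
render_mask <- function(o, width = 256, height = 256, margin = 0.05) {
  p <- as_outline(o)$points
  rng_x <- range(p[, 1L]); rng_y <- range(p[, 2L])
  sc <- min((1 - 2 * margin) * width / diff(rng_x),
            (1 - 2 * margin) * height / diff(rng_y))
  off <- c(mean(rng_x) - (width / 2) / sc, mean(rng_y) - (height / 2) / sc)
  q <- sweep(p, 2L, off) * sc
  centers <- cbind(rep(seq_len(width) - 0.5, height),
                   rep(seq_len(height) - 0.5, each = width))
  inside <- mgcv::in.out(rbind(q, q[1L, ]), centers)
  grid <- matrix(inside * 1, nrow = height, ncol = width, byrow = TRUE)
  mask <- grid[nrow(grid):1L, , drop = FALSE] # top row = largest y
  list(mask = mask, scale = sc, offset = off)
}

#' Resample an outline to equally spaced points
#'
#' Resamples the polygon to exactly `n` points equally spaced in arc length,
#' starting at a standardized point: by convention the most posterior point
#' (minimal y, ties broken by minimal x), emulating the rule of starting at
#' the tip of the dorsal thoracic spine. Orientation stays counterclockwise.
#'
#' @param o An [outline()].
#' @param n Number of output points (>= 8); default 200.
#' @param start_rule `"most_posterior"` (default) or `"given_index"`.
#' @param start_index Vertex index used when `start_rule = "given_index"`;
#'   defaults to the outline's stored `start_index`.
#' @return An [outline()] with `n` points and `start_index = 1`.
#' @export
resample_outline <- function(o, n = 200,
                             start_rule = c("most_posterior", "given_index"),
                             start_index = NULL) {
  o <- as_outline(o)
  n <- check_count(n, "n", 8L)
  start_rule <- match.arg(start_rule)
  p <- o$points
  np <- nrow(p)
  s0 <- if (start_rule == "most_posterior") {
    cand <- which(p[, 2L] == min(p[, 2L]))
    cand[which.min(p[cand, 1L])]
  } else {
    idx <- start_index %||% o$start_index
    check_count(idx, "start_index", 1L)
    if (idx > np) stop_field("start_index", "exceeds number of points")
    idx
  }
  p <- p[c(s0:np, seq_len(s0 - 1L)), , drop = FALSE]
  pc <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate outline with zero perimeter", call. = FALSE)
  s <- total * (0:(n - 1L)) / n
  x <- stats::approx(cum, pc[, 1L], xout = s, method = "linear")$y
  y <- stats::approx(cum, pc[, 2L], xout = s, method = "linear")$y
  outline(cbind(x, y), start_index = 1L)
}

#' Linear measurements of an outline
#'
#' Computes the linear measurements used alongside the shape analysis:
#' larval length (extent along y, the anteroposterior axis), larval width
#' (extent along x), and their ratio, the aspect ratio (width / length).
#' Frontal horn length cannot be located from the outline alone (the horns
#' merge smoothly into the shield), so tip and base coordinates must be
#' supplied — from manual landmarks or from the generator's ground truth —
#' to obtain the horn length (mean of the pair) and the relative horn
#' length (horn length / larval length). The distance between the two horn
#' tips (`fh_width`) needs only the tips.
#'
#' @param o An [outline()], anterior at +y.
#' @param horn_tips Optional 2 x 2 matrix of horn tip coordinates.
#' @param horn_bases Optional 2 x 2 matrix of horn base coordinates.
#' @return A list: `length`, `width`, `aspect_ratio`, and (when landmarks
#'   are supplied) `frontal_horn_length`, `rel_horn_length`, `fh_width`;
#'   otherwise those are `NA`.
#' @export
measure_linear <- function(o, horn_tips = NULL, horn_bases = NULL) {
  p <- as_outline(o)$points
  len <- diff(range(p[, 2L]))
  wid <- diff(range(p[, 1L]))
  horn <- rel <- fhw <- NA_real_
  if (!is.null(horn_tips)) {
    horn_tips <- as.matrix(horn_tips)
    fhw <- sqrt(sum((horn_tips[1L, ] - horn_tips[2L, ])^2))
    if (!is.null(horn_bases)) {
      horn_bases <- as.matrix(horn_bases)
      horn <- mean(sqrt(rowSums((horn_tips - horn_bases)^2)))
      rel <- horn / len
    }
  }
  list(length = len, width = wid, aspect_ratio = wid / len,
       frontal_horn_length = horn, rel_horn_length = rel, fh_width = fhw)
}

#' Read and write outline coordinate files
#'
#' Outlines travel as plain CSV files with columns `x,y` (one vertex per
#' row) or as TPS landmark files (`LM=` count, coordinate lines, `ID=`
#' label). `read_outline_file` dispatches on the extension (`.tps` vs
#' anything else as CSV) and returns a single outline; multi-specimen TPS
#' files can be read with [read_tps()].
#'
#' @param path File path.
#' @param o An [outline()] to write.
#' @return `read_outline_file`: an [outline()]. Writers return the path
#'   invisibly.
#' @export
read_outline_file <- function(path) {
  if (grepl("\\.tps$", path, ignore.case = TRUE)) {
    ol <- read_tps(path)
    if (length(ol) != 1L) {
      stop(sprintf("expected a single specimen in '%s', found %d", path,
                   length(ol)), call. = FALSE)
    }
    return(ol[[1L]])
  }
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop(sprintf("outline CSV '%s' must have columns x,y", path), call. = FALSE)
  }
  outline(as.matrix(df[, c("x", "y")]))
}

#' @rdname read_outline_file
#' @export
write_outline_csv <- function(o, path) {
  p <- as_outline(o)$points
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}

#' Read and write TPS landmark files
#'
#' Minimal TPS support for closed outlines stored as a landmark block:
#' records of the form `LM=n`, n lines of `x y`, then `ID=label`.
#'
#' @param path File path.
#' @param outlines Named list of [outline()]s (names become IDs).
#' @return `read_tps`: a named list of outlines.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE)) {
      stop(sprintf("malformed TPS file '%s': expected LM= at line %d", path, i),
           call. = FALSE)
    }
    nlm <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    coords <- do.call(rbind, lapply(lines[(i + 1L):(i + nlm)], function(s) {
      as.numeric(strsplit(s, "[ \t]+")[[1L]])
    }))
    i <- i + nlm + 1L
    id <- sprintf("specimen%d", length(out) + 1L)
    while (i <= length(lines) && !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      }
      i <- i + 1L
    }
    out[[id]] <- outline(coords)
  }
  out
}

#' @rdname read_tps
#' @export
write_tps <- function(outlines, path) {
  if (inherits(outlines, "outline")) outlines <- list(specimen1 = outlines)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(outlines)) {
    p <- as_outline(outlines[[id]])$points
    writeLines(sprintf("LM=%d", nrow(p)), con)
    writeLines(sprintf("%.12g %.12g", p[, 1L], p[, 2L]), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

.SPECIES_LEVELS <- list(
  trophic_mode = c("planktotrophic", "lecithotrophic"),
  adult_habitat = c("borer", "parasitic", "deep-sea", "inter/sub-tidal",
                    "epibiotic", "pelagic"),
  larval_habitat = c("coastal water", "coral reef", "deep sea", "open ocean"),
  pld_class = c("<5 d", "5-30 d", ">30 d"))

#' Read and validate a species metadata table
#'
#' Reads the per-species metadata CSV: `species_id`, the linear measurements
#' (`larval_length`, `larval_width`, `frontal_horn_length` in micrometres,
#' optionally `fh_width`) and categorical descriptors (`trophic_mode`
#' mandatory; `adult_habitat`, `larval_habitat`, `pld_class` optional).
#' Lengths must be positive; categorical values must be among the documented
#' levels, and a violation reports the offending row and column.
#'
#' @param path CSV file path.
#' @return A validated data frame, one row per species.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("species_id", "larval_length", "larval_width",
                 "frontal_horn_length", "trophic_mode")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop(sprintf("species table '%s' is missing mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id values in species table", call. = FALSE)
  }
  for (col in c("larval_length", "larval_width", "frontal_horn_length")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    bad <- bad[!(col == "frontal_horn_length" & df[[col]][bad] == 0)]
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': lengths must be positive",
                   bad[1L], col), call. = FALSE)
    }
  }
  for (col in intersect(names(.SPECIES_LEVELS), names(df))) {
    bad <- which(!df[[col]] %in% .SPECIES_LEVELS[[col]])
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': unknown level '%s' (allowed: %s)",
                   bad[1L], col, df[[col]][bad[1L]],
                   paste(.SPECIES_LEVELS[[col]], collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}
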