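#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis:
#' outlines in, elliptic Fourier shape vectors, morphospace, allometry and
#' trophic-mode statistics, bootstraps, and (when a tree is given)
#' phylogenetic signal and phylogenetic MANCOVA, with every table written to
#' `out_dir` and a JSON manifest recording the run.
#'
#' @param outlines_dir Directory of per-species outline CSVs named
#'   `<species_id>.csv` (columns x,y). Alternatively `masks_dir` with
#'   `<species_id>.png` binary masks.
#' @param metadata Path to the species metadata CSV
#'   (see [read_species_table()]).
#' @param out_dir Output directory (created if needed).
#' @param masks_dir Optional directory of mask images instead of
#'   `outlines_dir`.
#' @param tree Optional Newick file path.
#' @param n_points Resampling points; default 200.
#' @param n_harmonics Harmonics kept (or `"auto"` to select at
#'   `harmonic_threshold`); default 15.
#' @param harmonic_threshold Cumulative power threshold for `"auto"`;
#'   default 0.99.
#' @param n_perm Permutations for all tests; default 999.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed Mandatory integer seed for every stochastic stage.
#' @param exclude Character vector of species_id to drop (e.g. outliers).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outlines_dir = NULL, metadata, out_dir,
                            masks_dir = NULL, tree = NULL, n_points = 200,
                            n_harmonics = 15, harmonic_threshold = 0.99,
                            n_perm = 999, n_boot = 1000, seed,
                            exclude = character()) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is mandatory: every stochastic stage must be reproducible",
         call. = FALSE)
  }
  if (is.null(outlines_dir) && is.null(masks_dir)) {
    stop("one of 'outlines_dir' or 'masks_dir' is required", call. = FALSE)
  }
  for (p in c(outlines_dir, masks_dir, metadata, tree)) {
    if (!file.exists(p)) stop(sprintf("path does not exist: %s", p), call. = FALSE)
  }
  cfg <- list(outlines_dir = outlines_dir, masks_dir = masks_dir,
              metadata = metadata, tree = tree, out_dir = out_dir,
              n_points = check_count(n_points, "n_points", 8L),
              n_harmonics = n_harmonics,
              harmonic_threshold = harmonic_threshold,
              n_perm = check_count(n_perm, "n_perm", 0L),
              n_boot = check_count(n_boot, "n_boot", 1L),
              seed = as.integer(seed),
              exclude = as.character(exclude))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory. `...` overrides any key.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("outlines_dir", "masks_dir", "metadata", "tree", "out_dir")) {
    if (!is.null(raw[[key]]) && !grepl("^(/|[A-Za-z]:)", raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full outline-morphometrics pipeline
#'
#' Executes, in order: outline ingest and resampling, elliptic Fourier
#' decomposition and normalization, shape-vector assembly, PCA morphospace,
#' vector-correlation tests of the regression vectors (size, aspect ratio,
#' relative horn length, trophic mode) against the leading PC axes,
#' sequential MANCOVA of shape on size and trophic mode, allometry-free
#' shapes with projection onto the original morphospace, balanced bootstrap
#' of relative horn length between trophic modes, and — when a tree is
#' supplied — Blomberg's K for the linear traits, K_mult for shape,
#' phylomorphospace coordinates and phylogenetic MANCOVA. Each stage writes
#' a CSV to `out_dir`; the run closes with a JSON manifest (package version,
#' config, per-stage row counts, output checksums). Reruns with the same
#' config and seed are bit-identical.
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_pipeline_config(cfg)
  if (!inherits(cfg, "pipeline_config")) stop("invalid config", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  counts <- list()
  outputs <- character()

  meta <- stage("metadata", read_species_table(cfg$metadata))
  meta <- meta[!meta$species_id %in% cfg$exclude, , drop = FALSE]
  counts$species <- nrow(meta)

  outlines <- stage("ingest", {
    lapply(stats::setNames(meta$species_id, meta$species_id), function(id) {
      if (!is.null(cfg$outlines_dir)) {
        f <- file.path(cfg$outlines_dir, paste0(id, ".csv"))
        if (!file.exists(f)) stop(sprintf("missing outline for species %s", id))
        read_outline_file(f)
      } else {
        f <- file.path(cfg$masks_dir, paste0(id, ".png"))
        if (!file.exists(f)) stop(sprintf("missing mask for species %s", id))
        trace_mask(f)
      }
    })
  })

  X <- stage("efa", shape_matrix(outlines, n_points = cfg$n_points,
                                 n_harmonics = cfg$n_harmonics,
                                 threshold = cfg$harmonic_threshold))
  counts$shape_variables <- ncol(X)
  outputs <- c(outputs, write_table(
    data.frame(species_id = rownames(X), X, check.names = FALSE),
    cfg$out_dir, "shape_vectors.csv"))

  m <- stage("pca", fit_pca(X))
  outputs <- c(outputs, write_table(
    data.frame(species_id = rownames(m$scores), m$scores, check.names = FALSE),
    cfg$out_dir, "pca_scores.csv"))
  outputs <- c(outputs, write_table(
    data.frame(component = colnames(m$rotation),
               eigenvalue = m$eigenvalues,
               var_explained = m$var_explained),
    cfg$out_dir, "pca_eigenvalues.csv"))

  size <- meta$larval_length
  aspect <- meta$larval_width / meta$larval_length
  rel_horn <- meta$frontal_horn_length / meta$larval_length
  trophic <- factor(meta$trophic_mode, levels = .TROPHIC_MODES)
  trophic_num <- as.numeric(trophic == "planktotrophic")

  vc <- stage("vector_correlations", {
    pairs <- list(
      list(label = "PC1 & aspect ratio", cov = aspect, axis = 1L),
      list(label = "PC2 & relative frontal horn length", cov = rel_horn, axis = 2L),
      list(label = "PC1 & size", cov = size, axis = 1L),
      list(label = "PC2 & trophic mode", cov = trophic_num, axis = 2L))
    rows <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      r <- vector_correlation_test(X, pr$cov, m$rotation[, pr$axis],
                                   n_perm = cfg$n_perm,
                                   seed = cfg$seed + i)
      data.frame(pair = pr$label, R = r$R, theta = r$theta, p = r$p)
    })
    do.call(rbind, rows)
  })
  outputs <- c(outputs, write_table(vc, cfg$out_dir, "vector_correlations.csv"))

  mc <- stage("mancova", {
    df <- data.frame(size = size, trophic_mode = trophic)
    mancova(X, ~ size * trophic_mode, df, n_perm = cfg$n_perm,
            seed = cfg$seed + 11L)
  })
  outputs <- c(outputs, write_table(as.data.frame(mc), cfg$out_dir, "mancova.csv"))

  af <- stage("allometry_free", allometry_free(X, size, m))
  outputs <- c(outputs, write_table(
    data.frame(species_id = rownames(X), af$scores, check.names = FALSE),
    cfg$out_dir, "allometry_free_scores.csv"))

  bt <- stage("bootstrap", bootstrap_groups(rel_horn, trophic,
                                            n_boot = cfg$n_boot,
                                            seed = cfg$seed + 21L))
  outputs <- c(outputs, write_table(
    data.frame(group = bt$groups,
               mean = as.vector(bt$means),
               boot_mean = vapply(bt$boot, mean, 0),
               ci_lower = vapply(bt$ci, function(ci) ci[1L], 0),
               ci_upper = vapply(bt$ci, function(ci) ci[2L], 0)),
    cfg$out_dir, "bootstrap_rel_horn.csv"))

  if (!is.null(cfg$tree)) {
    tree <- stage("tree", read_newick(cfg$tree))
    in_tree <- intersect(tree$tip.label, meta$species_id)
    tree <- ape::keep.tip(tree, in_tree)
    counts$tree_tips <- length(in_tree)
    rows_named <- function(v) stats::setNames(v, meta$species_id)[in_tree]
    ps <- stage("phylo_signal", {
      kA <- blomberg_k(rows_named(aspect), tree, n_perm = cfg$n_perm,
                       seed = cfg$seed + 31L)
      kH <- blomberg_k(rows_named(rel_horn), tree, n_perm = cfg$n_perm,
                       seed = cfg$seed + 32L)
      kM <- k_mult(X[in_tree, , drop = FALSE], tree, n_perm = cfg$n_perm,
                   seed = cfg$seed + 33L)
      data.frame(trait = c("aspect_ratio", "rel_horn_length", "shape"),
                 statistic = c("K", "K", "K_mult"),
                 value = c(kA$statistic, kH$statistic, kM$statistic),
                 p = c(kA$p, kH$p, kM$p))
    })
    outputs <- c(outputs, write_table(ps, cfg$out_dir, "phylo_signal.csv"))

    pm <- stage("phylomorphospace", phylomorphospace_coords(m, tree))
    outputs <- c(outputs, write_table(pm$nodes, cfg$out_dir,
                                      "phylomorphospace.csv"))

    plm <- stage("phylo_mancova", {
      df <- data.frame(size = rows_named(size),
                       trophic_mode = stats::setNames(trophic, meta$species_id)[in_tree])
      phylo_lm(X[in_tree, , drop = FALSE], ~ size * trophic_mode, df, tree,
               n_perm = cfg$n_perm, seed = cfg$seed + 41L)
    })
    outputs <- c(outputs, write_table(as.data.frame(plm), cfg$out_dir,
                                      "phylo_mancova.csv"))
  }

  cfg_plain <- unclass(cfg)
  manifest <- list(
    package = "naupliomorph",
    version = as.character(utils::packageVersion("naupliomorph")),
    config = cfg_plain,
    seed = cfg$seed,
    counts = counts,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    }))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated species set to disk in pipeline input layout
#'
#' Convenience for demos and tests: runs [simulate_species_set()] and writes
#' per-species outline CSVs plus the metadata CSV the pipeline expects.
#'
#' @param dir Output directory.
#' @param pop A [population_params()].
#' @param n_points Points per outline.
#' @return Invisibly, a list with `outlines_dir` and `metadata` paths.
#' @export
write_simulated_dataset <- function(dir, pop = population_params(),
                                    n_points = 200) {
  sim <- simulate_species_set(pop, n_points = n_points)
  odir <- file.path(dir, "outlines")
  dir.create(odir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$outlines)) {
    write_outline_csv(sim$outlines[[id]], file.path(odir, paste0(id, ".csv")))
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(sim$table, meta_path, row.names = FALSE)
  invisible(list(outlines_dir = odir, metadata = meta_path, sim = sim))
}
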