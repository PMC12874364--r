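#' Write an ensemble to plain-text trajectory files
#'
#' One TSV per realization (`run_0001.tsv`: sweep, mc_step, energy and
#' optionally max_cluster_size) plus a flat key-value sidecar manifest
#' (`run_0001.manifest`) holding every configuration field, the seed and the
#' first-assembly time.
#'
#' @param ensemble An `assembly_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectories <- function(ensemble, dir) {
  runs <- ensemble_runs(ensemble)
  cfg <- ensemble_config(ensemble)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in runs$realization) {
    tr <- dplyr::filter(tibble::as_tibble(ensemble), .data$realization == k)
    tr$realization <- NULL
    stem <- file.path(dir, sprintf("run_%04d", k))
    readr::write_tsv(tr, paste0(stem, ".tsv"), progress = FALSE)
    info <- runs[runs$realization == k, ]
    vals <- unclass(cfg)
    vals$seed <- info$seed  # the realization's own seed
    kv <- c(
      unlist(lapply(vals, as.character)),
      t_fas = as.character(info$t_fas),
      assembled = as.character(info$assembled)
    )
    writeLines(paste(names(kv), kv, sep = "\t"), paste0(stem, ".manifest"))
  }
  invisible(dir)
}

#' Read an ensemble back from trajectory files
#'
#' @param dir Directory written by [write_trajectories()].
#' @return An `assembly_ensemble`.
#' @export
read_trajectories <- function(dir) {
  files <- sort(list.files(dir, pattern = "^run_\\d+\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no trajectory files found in ", dir)
  read_manifest <- function(path) {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    stats::setNames(
      vapply(lines, function(x) if (length(x) > 1) x[2] else "", ""),
      vapply(lines, `[[`, "", 1)
    )
  }
  traj <- purrr::map2_dfr(files, seq_along(files), function(f, k) {
    dplyr::mutate(
      readr::read_tsv(f, show_col_types = FALSE, progress = FALSE),
      realization = k, .before = 1L
    )
  })
  mans <- lapply(sub("\\.tsv$", ".manifest", files), read_manifest)
  m1 <- mans[[1]]
  cfg <- sim_config(
    n_particles = as.integer(m1[["n_particles"]]),
    lattice = as.integer(m1[["lattice"]]),
    n_targets = as.integer(m1[["n_targets"]]),
    js = as.numeric(m1[["js"]]), jw = as.numeric(m1[["jw"]]),
    dmu = as.numeric(m1[["dmu"]]), dynamics = m1[["dynamics"]],
    mode = m1[["mode"]], n_steps = as.numeric(m1[["n_steps"]]),
    bin = as.numeric(m1[["bin"]]), seed = as.integer(m1[["seed"]])
  )
  num_or_na <- function(x) if (identical(x, "NA")) NA_real_ else as.numeric(x)
  runs <- tibble::tibble(
    realization = seq_along(files),
    seed = vapply(mans, function(m) as.integer(m[["seed"]]), 1L),
    t_fas = vapply(mans, function(m) num_or_na(m[["t_fas"]]), 1.0),
    assembled = vapply(mans, function(m) identical(m[["assembled"]], "TRUE"),
                       TRUE)
  )
  new_assembly_ensemble(traj, runs, cfg)
}

#' Write / read a target set
#'
#' Tabular text serialisation: one row per (target, label, row, col), exact
#' integers, 0-based offsets.
#'
#' @param x A `target_set`.
#' @param path File path.
#' @return `write_target_set()` returns `path` invisibly; `read_target_set()`
#'   returns a `target_set`.
#' @export
write_target_set <- function(x, path) {
  readr::write_tsv(target_table(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_target_set
#' @export
read_target_set <- function(path) {
  target_set(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write / read a fitted stochastic landscape
#'
#' Portable JSON serialisation of the standardisation parameters, the cell
#' table and the bias-correction vector.
#'
#' @param x An `slm_landscape`.
#' @param path File path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns an `slm_landscape`.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "slm_landscape"))
  payload <- unclass(x)
  payload$cells <- as.data.frame(payload$cells)
  payload$bias <- as.data.frame(payload$bias)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$cells <- tibble::as_tibble(as.data.frame(payload$cells))
  payload$bias <- tibble::as_tibble(as.data.frame(payload$bias))
  payload$center <- as.numeric(payload$center)
  payload$scale <- as.numeric(payload$scale)
  payload$axis_min <- as.numeric(payload$axis_min)
  payload$axis_max <- as.numeric(payload$axis_max)
  structure(payload, class = "slm_landscape")
}
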