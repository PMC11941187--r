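config_keys <- list(
  channel = c("L", "R0", "RL"),
  particle = c("l", "r"),
  noise = c("sigma_x"),
  run = c("n_rep", "seed", "max_steps", "sample_times", "occ_per_traj",
          "stream_offset"),
  analysis = c("n_bins_z", "n_bins_theta", "surv_grid_n", "s_lo", "s_hi")
)

#' Load a run configuration from a YAML file
#'
#' Reads a structured key-value document with blocks `channel`, `particle`,
#' `noise`, `run` and (optionally) `analysis`, validates it, and fills
#' defaults (`L = 15`, `R0 = 0.5`, `RL = 0.25`, `sigma_x = 0.05`,
#' `n_rep = 1000`). The `particle` block is required; unknown keys are
#' rejected with the offending name.
#'
#' @param path path to a YAML configuration file.
#' @return A [sim_config()]; any `analysis` options are attached as the
#'   `"analysis"` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  bad <- setdiff(names(doc), names(config_keys))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  for (blk in names(doc)) {
    extra <- setdiff(names(doc[[blk]]), config_keys[[blk]])
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s' block: %s", blk,
                   paste(extra, collapse = ", ")))
  }
  if (is.null(doc$particle) || is.null(doc$particle$r))
    stop("the 'particle' block with at least a radius 'r' is required ",
         "(set 'l: 0' explicitly for a sphere)")
  if (is.null(doc$particle$l))
    stop("the 'particle' block must state the length 'l' ",
         "(use 'l: 0' for a sphere)")
  chd <- doc$channel
  ch <- channel(L = chd$L %||% 15, R0 = chd$R0 %||% 0.5, RL = chd$RL %||% 0.25)
  p <- spherocylinder(l = doc$particle$l, r = doc$particle$r)
  run <- doc$run
  cfg <- sim_config(channel = ch, particle = p,
                    sigma_x = doc$noise$sigma_x %||% 0.05,
                    n_rep = run$n_rep %||% 1000,
                    seed = run$seed %||% 1,
                    max_steps = run$max_steps %||% 5e7,
                    sample_times = run$sample_times,
                    occ_per_traj = run$occ_per_traj %||% 2000,
                    stream_offset = run$stream_offset %||% 0)
  attr(cfg, "analysis") <- doc$analysis
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  doc <- list(
    channel = list(L = config$channel$L, R0 = config$channel$R0,
                   RL = config$channel$RL),
    particle = list(l = config$particle$l, r = config$particle$r),
    noise = list(sigma_x = config$sigma_x),
    run = list(n_rep = config$n_rep, seed = config$seed,
               max_steps = config$max_steps,
               sample_times = config$sample_times,
               occ_per_traj = config$occ_per_traj,
               stream_offset = config$stream_offset)
  )
  if (!is.null(attr(config, "analysis")))
    doc$analysis <- attr(config, "analysis")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write ensemble results and analyses to a directory
#'
#' Emits tidy CSV tables -- `fpt.csv` (per-trajectory first passage time,
#' censoring flag, acceptance counts), `samples.csv` (recorded states),
#' `occupancy.csv`, and, when `analyses` is supplied, `msd.csv`, `fits.csv`,
#' `hist_theta.csv`, `hist_z.csv`, `force_z.csv` -- plus `config.yaml` and a
#' `manifest.json` with the configuration echo, package version, seed and an
#' md5 checksum inventory. Floats are written at R's default text precision
#' (about 15 significant digits).
#'
#' @param result an [run_ensemble()] result.
#' @param analyses optional [analyze_ensemble()] output.
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_results <- function(result, analyses = NULL, outdir) {
  stopifnot(inherits(result, "ensemble_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    f <- file.path(outdir, name)
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  put(data.frame(trajectory = seq_along(result$fpt),
                 stream_id = result$stream_id,
                 fpt = result$fpt, censored = result$censored,
                 steps_run = result$steps_run,
                 accepted_translations = result$accepted_translations,
                 accepted_rotations = result$accepted_rotations),
      "fpt.csv")
  nt <- length(result$times)
  nr <- ncol(result$x)
  put(data.frame(t = rep(result$times, nr),
                 trajectory = rep(seq_len(nr), each = nt),
                 x = as.vector(result$x), y = as.vector(result$y),
                 z = as.vector(result$z), ux = as.vector(result$ux),
                 uy = as.vector(result$uy), uz = as.vector(result$uz)),
      "samples.csv")
  put(as.data.frame(result$occ), "occupancy.csv")
  if (!is.null(analyses)) {
    stopifnot(inherits(analyses, "ensemble_analysis"))
    if (!is.null(analyses$msd)) put(as.data.frame(analyses$msd), "msd.csv")
    fits <- data.frame(
      quantity = c("msd_alpha", "msd_D", "msd_t_lo", "msd_t_hi", "tmin",
                   "median_fpt", "censored_frac",
                   "surv_A", "surv_lambda", "surv_r_squared"),
      value = c(analyses$msd_fit$alpha %||% NA, analyses$msd_fit$D %||% NA,
                analyses$msd_fit$window[1] %||% NA,
                analyses$msd_fit$window[2] %||% NA,
                analyses$tmin %||% NA, analyses$median_fpt %||% NA,
                analyses$censored_frac,
                analyses$surv_fit$A %||% NA, analyses$surv_fit$lam %||% NA,
                analyses$surv_fit$r_squared %||% NA))
    put(fits, "fits.csv")
    if (!is.null(analyses$survival)) put(analyses$survival, "survival.csv")
    if (!is.null(analyses$hist_theta))
      put(as.data.frame(analyses$hist_theta), "hist_theta.csv")
    if (!is.null(analyses$hist_z))
      put(as.data.frame(analyses$hist_z), "hist_z.csv")
    if (!is.null(analyses$force)) put(analyses$force, "force_z.csv")
  }
  cfg_path <- file.path(outdir, "config.yaml")
  save_config(result$config, cfg_path)
  files <- c(files, cfg_path)
  manifest <- list(
    package = "conediff",
    version = as.character(packageVersion("conediff")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$config$seed,
    n_rep = result$config$n_rep,
    occ_stride = result$occ_stride,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Re-read a results directory written by [write_results()]
#'
#' Reconstructs an `"ensemble_result"` from `config.yaml`, `fpt.csv`,
#' `samples.csv` and `occupancy.csv`, so analyses can be (re)run from disk.
#'
#' @param outdir directory written by [write_results()].
#' @return An `"ensemble_result"`.
#' @export
read_results <- function(outdir) {
  cfg <- load_config(file.path(outdir, "config.yaml"))
  fpt <- read.csv(file.path(outdir, "fpt.csv"))
  smp <- read.csv(file.path(outdir, "samples.csv"))
  occ <- as.matrix(read.csv(file.path(outdir, "occupancy.csv")))
  colnames(occ) <- c("z", "abs_uz")
  nt <- length(unique(smp$t))
  nr <- nrow(fpt)
  shape <- function(v) matrix(v, nrow = nt, ncol = nr)
  structure(list(config = cfg,
                 fpt = fpt$fpt,
                 censored = fpt$censored,
                 accepted_translations = fpt$accepted_translations,
                 accepted_rotations = fpt$accepted_rotations,
                 steps_run = fpt$steps_run,
                 stream_id = fpt$stream_id,
                 times = smp$t[seq_len(nt)],
                 x = shape(smp$x), y = shape(smp$y), z = shape(smp$z),
                 ux = shape(smp$ux), uy = shape(smp$uy), uz = shape(smp$uz),
                 occ = occ,
                 occ_stride = max(1, ceiling(cfg$max_steps / cfg$occ_per_traj))),
            class = "ensemble_result")
}

#' Scan particle length and radius on a grid
#'
#' Runs one ensemble per `(l, r)` cell of `expand.grid(l_values, r_values)`
#' and summarizes each with the fitted anomalous exponent, median first
#' passage time and survival decay rate. Every cell gets a disjoint block of
#' RNG substreams derived from the base seed, so the table is identical
#' whatever the cell execution order. Infeasible cells (e.g. `r >= RL`) are
#' flagged and the scan continues.
#'
#' @param base_config a [sim_config()] supplying channel, noise and run
#'   parameters (its particle is replaced cell by cell).
#' @param l_values,r_values particle dimensions to scan.
#' @return Data frame with one row per cell: `l`, `r`, `alpha`, `D`, `tmin`,
#'   `median_fpt`, `lambda`, `A`, `r_squared`, `censored_frac`, `feasible`,
#'   `note`.
#' @export
run_scan <- function(base_config, l_values, r_values) {
  stopifnot(inherits(base_config, "sim_config"))
  grid <- expand.grid(l = l_values, r = r_values)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- data.frame(l = grid$l[i], r = grid$r[i], alpha = NA_real_,
                      D = NA_real_, tmin = NA_real_, median_fpt = NA_real_,
                      lambda = NA_real_, A = NA_real_, r_squared = NA_real_,
                      censored_frac = NA_real_, feasible = TRUE, note = "")
    res <- tryCatch({
      cfg <- sim_config(channel = base_config$channel,
                        particle = spherocylinder(grid$l[i], grid$r[i]),
                        sigma_x = base_config$sigma_x,
                        n_rep = base_config$n_rep,
                        seed = base_config$seed,
                        max_steps = base_config$max_steps,
                        sample_times = base_config$sample_times,
                        occ_per_traj = base_config$occ_per_traj,
                        stream_offset = base_config$stream_offset +
                          (i - 1) * base_config$n_rep)
      run_ensemble(cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$feasible <- FALSE
      row$note <- conditionMessage(res)
    } else {
      an <- analyze_ensemble(res)
      row$alpha <- an$msd_fit$alpha %||% NA_real_
      row$D <- an$msd_fit$D %||% NA_real_
      row$tmin <- an$tmin %||% NA_real_
      row$median_fpt <- an$median_fpt %||% NA_real_
      row$lambda <- an$surv_fit$lam %||% NA_real_
      row$A <- an$surv_fit$A %||% NA_real_
      row$r_squared <- an$surv_fit$r_squared %||% NA_real_
      row$censored_frac <- an$censored_frac
      if (length(an$notes)) row$note <- paste(an$notes, collapse = "; ")
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
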