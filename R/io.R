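#' Flat key-value configuration files
#'
#' A run is configured by a flat text file of `key = value` lines (`#`
#' comments allowed). Keys cover the cell parameters, the network fields
#' (`n_cells`, `dt`, `t_max`) and the noise fields (`sd_gD`, `sd_gExc`,
#' `draw`, `g_noise`, `beta_n`, `n_presyn`, `rate_hz`). An empty file (or
#' `NULL` path) resolves to the package defaults; any unknown key is a hard
#' error, which guards against silently misspelled parameter names.
#'
#' @param path file to read, or `NULL` for pure defaults.
#' @return A named list (class `timecell_config`) of resolved scalar
#'   values.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$g_L
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("malformed config line (expected 'key = value'): ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      if (is.character(cfg[[key]])) {
        cfg[[key]] <- val
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for key ", key, ": ", val)
        cfg[[key]] <- num
      }
    }
  }
  structure(cfg, class = "timecell_config")
}

#' @rdname load_config
#' @export
default_config <- function() {
  p <- cell_params()
  n <- noise_config()
  c(unclass(p),
    list(n_cells = 60, dt = 0.05, t_max = 150000,
         stim_amplitude = 4, stim_onset = 0, stim_duration = Inf,
         sd_gD = n$sd_gD, sd_gExc = n$sd_gExc, draw = n$draw,
         g_noise = n$g_noise, beta_n = n$beta_n,
         n_presyn = n$n_presyn, rate_hz = n$rate_hz))
}

#' @rdname load_config
#' @param config a resolved configuration list.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config))
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 15)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split a resolved configuration into typed objects
#'
#' @param config a `timecell_config` from [load_config()].
#' @return [as_cell_params()]: a [cell_params()]; [as_noise_config()]: a
#'   [noise_config()]; [as_network_config()]: a [network_config()].
#' @export
as_cell_params <- function(config) {
  do.call(cell_params, config[names(formals(cell_params))])
}

#' @rdname as_cell_params
#' @export
as_noise_config <- function(config) {
  noise_config(sd_gD = config$sd_gD, sd_gExc = config$sd_gExc,
               draw = config$draw, g_noise = config$g_noise,
               beta_n = config$beta_n, n_presyn = config$n_presyn,
               rate_hz = config$rate_hz)
}

#' @rdname as_cell_params
#' @export
as_network_config <- function(config) {
  stim <- stimulus_protocol(amplitude = config$stim_amplitude,
                            onset = config$stim_onset,
                            duration = config$stim_duration)
  network_config(n_cells = config$n_cells, params = as_cell_params(config),
                 stimulus = stim, dt = config$dt, t_max = config$t_max)
}

#' Write run outputs as delimited text
#'
#' Writes the spike tables, statistics tables and a JSON run manifest for a
#' protocol result into `out_dir` with deterministic file names. Re-running
#' overwrites atomically (write to a temporary file, then rename).
#'
#' @param x a `trial_set`, `spike_record`, `fig2_result` or
#'   `sweep_result`.
#' @param out_dir output directory (created if missing).
#' @param manifest named list of extra metadata (seeds, parameter
#'   overrides) merged into the manifest.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(x, out_dir, manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    tmp <- tempfile(tmpdir = out_dir)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    files <<- c(files, path)
  }
  meta <- c(list(package = "timecellr",
                 version = as.character(utils::packageVersion("timecellr")),
                 class = class(x)[1],
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            manifest)
  if (inherits(x, "trial_set")) {
    put(x$records, "spike_times.tsv")
    st <- scalar_stats(x)
    put(as.data.frame(st), "scalar_stats.tsv")
    meta$n_trials <- x$n_trials
    meta$base_seed <- x$base_seed
    meta$up_to_cell <- x$up_to_cell
    meta$n_excluded <- x$n_excluded
    meta$fit <- list(slope = attr(st, "slope"),
                     intercept = attr(st, "intercept"),
                     r_squared = attr(st, "r_squared"),
                     cv_asymptotic = attr(st, "cv_asymptotic"))
  } else if (inherits(x, "spike_record")) {
    put(x$spikes, "raster.tsv")
    put(x$inhibition, "inhibition_trace.tsv")
    if (!is.null(x$trajectory)) put(x$trajectory, "trajectory.tsv")
    fs <- data.frame(cell = seq_len(x$n_cells), first_spike = x$first_spike)
    put(fs, "first_spikes.tsv")
    meta$completed <- x$completed
    meta$t_final <- x$t_final
  } else if (inherits(x, "fig2_result")) {
    put(x$delays, "delays.tsv")
    if (!is.null(x$trajectory)) put(x$trajectory, "trajectory.tsv")
  } else if (inherits(x, "sweep_result")) {
    for (j in seq_along(x$values)) {
      put(as.data.frame(x$stats[[j]]),
          sprintf("stats_%s_%s.tsv", x$parameter, format(x$values[j])))
    }
    meta$parameter <- x$parameter
    meta$values <- x$values
    meta$n_excluded <- x$n_excluded
  } else stop("no output writer for class ", class(x)[1])
  mpath <- file.path(out_dir, "manifest.json")
  tmp <- tempfile(tmpdir = out_dir)
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, mpath)
  invisible(c(files, mpath))
}

#' Read a spike-time table
#'
#' Reads the delimited spike-record exchange format (columns `trial`,
#' `cell`, `time`) written by [write_outputs()].
#'
#' @param path a TSV file.
#' @return A data frame usable by [scalar_stats()] and
#'   [normalized_histograms()].
#' @export
read_spike_records <- function(path) {
  df <- read.delim(path)
  need <- c("trial", "cell", "time")
  if (!all(need %in% names(df)))
    stop("spike-record file must have columns: ", paste(need, collapse = ", "))
  df
}
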