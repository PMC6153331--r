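# Configuration files and spike-train persistence.

# default protocol values (the standard parameter set of the detection
# problem this package studies)
.config_defaults <- function() {
  list(N = 1e4, f = 3.2, T = 3.2, P = 5, L = 100,
       period = 400, dt_sim = 0.1,
       tau = NA_real_,            # NA: use the theory-optimal value
       theta0 = 190, theta_jump_factor = 1.8, tau_theta = 80,
       dA_pre = 0.1, tau_pre = 20, w_out = -6.2e-3,
       duration_ms = 12000e3, seed = 1)
}

#' Build and validate a run configuration
#'
#' Collects every knob of a learning run — problem parameters, neuron and
#' plasticity constants, protocol fields — with defaults set to the
#' standard parameter set (1e4 afferents at 3.2 Hz, 3.2 ms jitter, 100 ms
#' patterns presented every 400 ms; 0.1 ms integration bin, 80 ms threshold
#' decay, threshold jump 1.8 x theta0, trace increment 0.1 with 20 ms
#' decay; 12,000 s of simulated time).
#'
#' @param ... Named overrides of the defaults; unknown names are rejected.
#' @return An object of class `"run_config"` (a named list).
#' @examples
#' cfg <- run_config(P = 2, duration_ms = 4000)
#' cfg$period
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration values must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  num_pos <- c("N", "f", "L", "period", "dt_sim", "theta0",
               "theta_jump_factor", "tau_theta", "dA_pre", "tau_pre")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("configuration field '", k, "' must be a positive number")
  }
  if (!is.numeric(cfg$T) || cfg$T < 0)
    stop("configuration field 'T' must be a non-negative number")
  if (!is.numeric(cfg$P) || cfg$P < 1 || cfg$P != round(cfg$P))
    stop("configuration field 'P' must be a positive integer")
  if (!is.na(cfg$tau) && (!is.numeric(cfg$tau) || cfg$tau <= 0))
    stop("configuration field 'tau' must be positive (or NA for optimal)")
  if (!is.numeric(cfg$w_out) || cfg$w_out >= 0)
    stop("configuration field 'w_out' must be negative")
  if (cfg$period < cfg$L)
    stop("configuration field 'period' must be >= the pattern duration 'L'")
  if (!is.numeric(cfg$duration_ms) || cfg$duration_ms < 0)
    stop("configuration field 'duration_ms' must be non-negative")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys and invalid values are rejected with a message naming the
#' offending field. Missing keys take their defaults.
#'
#' @param path Path to a YAML file of `field: value` pairs.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param cfg A [run_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# deterministic 31-bit rolling hash of a config, for output-file headers
.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) format(v, digits = 17), ""),
             sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

#' Persist spike data as delimited text
#'
#' Writes two columns `afferent_id,time_ms` under a small metadata header
#' (comment lines `# key: value` carrying the population size, duration,
#' and optionally a config hash and seed). Times keep full float
#' precision, so a write/read round trip is lossless.
#'
#' @param x A [spike_data()] object.
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(x, path, seed = NULL, config = NULL) {
  stopifnot(inherits(x, "spike_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_afferents: %d", attr(x, "n_afferents")), con)
  writeLines(sprintf("# duration_ms: %.17g", attr(x, "duration")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", .config_hash(config)), con)
  writeLines("afferent_id,time_ms", con)
  if (nrow(x))
    writeLines(sprintf("%d,%.17g", x$afferent, x$time), con)
  invisible(path)
}

#' Read spike data written by [write_spikes()]
#'
#' Validates the format: afferent ids must be integers within the
#' population recorded in the header; malformed rows are reported with
#' their line number.
#'
#' @param path Input path.
#' @return A [spike_data()] object.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(m)) stop("missing metadata header '# ", key, ":' in ", path)
    sub(paste0("^# ", key, ":\\s*"), "", m[1])
  }
  n_aff <- as.integer(get_meta("n_afferents"))
  dur <- as.numeric(get_meta("duration_ms"))
  body <- which(!is_meta)
  hdr <- body[1]
  if (is.na(hdr) || lines[hdr] != "afferent_id,time_ms")
    stop("expected header 'afferent_id,time_ms' in ", path)
  rows <- body[-1]
  if (!length(rows))
    return(spike_data(integer(0), numeric(0), n_aff, dur))
  parts <- strsplit(lines[rows], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed row at line ", rows[bad[1]], " of ", path)
  aff <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  tms <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- which(is.na(aff) | is.na(tms))
  if (length(bad))
    stop("malformed row at line ", rows[bad[1]], " of ", path)
  if (any(aff < 1L | aff > n_aff))
    stop("afferent id out of range 1..", n_aff, " at line ",
         rows[which(aff < 1L | aff > n_aff)[1]], " of ", path)
  spike_data(aff, tms, n_aff, dur)
}

#' Execute a configured learning run and persist its results
#'
#' Orchestrates a full run from a [run_config()]: resolves the membrane
#' time constant (theory-optimal when `tau` is `NA`), runs
#' [run_learning()], evaluates it, and writes `result.json` (metrics and
#' configuration), `output_spikes.csv`, `weights.csv` and
#' `convergence.csv` into `out_dir`.
#'
#' @param cfg A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return The [run_learning()] fit, invisibly.
#' @export
run_from_config <- function(cfg, out_dir, seed = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(seed)) seed <- cfg$seed
  params <- theory_params(cfg$N, cfg$f, cfg$T, cfg$P, cfg$L)
  opt <- optimize_snr(params, enforce_dt_max = FALSE)
  tau <- if (is.na(cfg$tau)) opt$geometry$tau else cfg$tau
  fit <- run_learning(
    params,
    neuron_config(tau = tau, theta0 = cfg$theta0,
                  theta_jump_factor = cfg$theta_jump_factor,
                  tau_theta = cfg$tau_theta, dt_sim = cfg$dt_sim),
    plasticity_config(dA_pre = cfg$dA_pre, tau_pre = cfg$tau_pre,
                      w_out = cfg$w_out),
    duration = cfg$duration_ms, seed = seed, period = cfg$period)
  ev <- evaluate(fit, geometry_opt = opt$geometry)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = c(unclass(cfg), list(tau_used = tau)),
         seed = seed, config_hash = .config_hash(cfg),
         tau_opt = opt$geometry$tau, dt_opt = opt$geometry$dt_window,
         M_opt = opt$geometry$M_expected, snr_opt = opt$snr,
         n_output_spikes = length(fit$out_spikes),
         n_potentiated = fit$n_potentiated,
         final_convergence_index = utils::tail(fit$convergence_index$value, 1),
         P_learned = ev$P_learned, hit_rate = ev$hit_rate,
         false_alarm_rate = ev$false_alarm_rate, optimal = ev$optimal),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  out_sp <- spike_data(rep(1L, length(fit$out_spikes)), fit$out_spikes,
                       1L, cfg$duration_ms)
  write_spikes(out_sp, file.path(out_dir, "output_spikes.csv"),
               seed = seed, config = cfg)
  utils::write.csv(data.frame(afferent = seq_along(fit$w), w = fit$w),
                   file.path(out_dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(fit$convergence_index,
                   file.path(out_dir, "convergence.csv"), row.names = FALSE)
  invisible(fit)
}
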