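# Frozen Poisson patterns, jittered presentations, and input streams.

#' Construct a spike-data object
#'
#' A set of spike events over a population of afferents: a data frame with
#' integer column `afferent` (1-based index in `1..n_afferents`) and numeric
#' column `time` (ms), sorted by time, carrying the population size and the
#' nominal duration as attributes. Times are stored at full float precision;
#' quantization to simulation bins happens only at simulation time.
#'
#' @param afferent Integer vector of afferent indices.
#' @param time Numeric vector of spike times in ms.
#' @param n_afferents Population size `N`.
#' @param duration Nominal duration in ms. Jittered presentations may carry
#'   spikes slightly outside `[0, duration)`; persistence and simulation
#'   accept them.
#' @return An object of class `"spike_data"` (a data frame).
#' @export
spike_data <- function(afferent, time, n_afferents, duration) {
  stopifnot(length(afferent) == length(time))
  if (length(afferent) && (any(afferent < 1L) || any(afferent > n_afferents)))
    stop("afferent indices must be in 1..n_afferents")
  ord <- order(time)
  out <- data.frame(afferent = as.integer(afferent[ord]), time = time[ord])
  attr(out, "n_afferents") <- as.integer(n_afferents)
  attr(out, "duration") <- duration
  class(out) <- c("spike_data", "data.frame")
  out
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("Spike data: %d events over %d afferents, duration %g ms\n",
              nrow(x), attr(x, "n_afferents"), attr(x, "duration")))
  if (nrow(x)) {
    utils::str(utils::head(as.data.frame(x), 5), give.attr = FALSE)
  }
  invisible(x)
}

# internal: one homogeneous Poisson block over all afferents
.poisson_block <- function(n_afferents, rate_hz, duration) {
  k <- stats::rpois(1L, n_afferents * rate_hz / 1000 * duration)
  spike_data(afferent = sample.int(n_afferents, k, replace = TRUE),
             time = stats::runif(k, 0, duration),
             n_afferents = n_afferents, duration = duration)
}

#' Generate a set of frozen Poisson patterns
#'
#' Draws `P` independent realizations of the homogeneous Poisson process at
#' rate `f` over `N` afferents, each of duration `L`. These "frozen noise"
#' patterns are generated once and replayed at every presentation; being
#' independent realizations, distinct patterns overlap only at chance level.
#'
#' @param params A [theory_params()] object.
#' @param seed Optional integer seed.
#' @return An object of class `"pattern_set"`: list with `patterns` (list of
#'   `P` [spike_data()] blocks of duration `L`), `params`, `seed`.
#' @examples
#' ps <- generate_pattern_set(theory_params(100, 10, P = 2, L = 50), seed = 1)
#' length(ps$patterns)
#' @export
generate_pattern_set <- function(params, seed = NULL) {
  stopifnot(inherits(params, "theory_params"))
  if (!is.null(seed)) set.seed(seed)
  pats <- replicate(params$P,
                    .poisson_block(params$N, params$f, params$L),
                    simplify = FALSE)
  structure(list(patterns = pats, params = params, seed = seed),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: %d frozen Poisson pattern(s), %d afferents, L = %g ms\n",
              length(x$patterns), x$params$N, x$params$L))
  cat(sprintf("  spikes per pattern: %s\n",
              paste(vapply(x$patterns, nrow, 0L), collapse = ", ")))
  invisible(x)
}

#' Jitter one presentation of a frozen pattern
#'
#' Shifts every spike time independently by a uniform draw on `[-T, T]`,
#' preserving afferent identities and spike count. Jittered spikes may cross
#' the pattern boundaries and may reorder; they are not clipped, since
#' clipping would distort edge statistics.
#'
#' @param pattern A [spike_data()] pattern block.
#' @param T Jitter half-width in ms (>= 0).
#' @return A [spike_data()] object with the same duration attribute.
#' @export
jitter_presentation <- function(pattern, T) {
  stopifnot(inherits(pattern, "spike_data"), T >= 0)
  if (T == 0 || nrow(pattern) == 0L) return(pattern)
  spike_data(pattern$afferent,
             pattern$time + stats::runif(nrow(pattern), -T, T),
             n_afferents = attr(pattern, "n_afferents"),
             duration = attr(pattern, "duration"))
}

#' Build the full input stream: jittered patterns embedded in Poisson noise
#'
#' Patterns are presented cyclically (1, 2, ..., P, 1, 2, ...) once per
#' `period`, each presentation centred within its period cycle; at each
#' presentation every spike of the frozen pattern is shifted by an
#' independent uniform jitter on `[-T, T]`. Between presentations all `N`
#' afferents fire as fresh homogeneous Poisson processes at rate `f`, so the
#' stream has the same mean rate everywhere and the patterns are not
#' distinguishable by their firing density.
#'
#' @param pattern_set A [generate_pattern_set()] result.
#' @param total_duration Stream duration in ms.
#' @param period Presentation period in ms (default 400; must be >= `L`).
#' @param seed Optional integer seed.
#' @return List with `stream` (a [spike_data()] over `total_duration`) and
#'   `annotation`: list with `period` and `onsets`, a data frame of
#'   presentation onset `time` (ms) and `pattern` id.
#' @examples
#' p <- theory_params(50, 20, T = 2, P = 2, L = 50)
#' ps <- generate_pattern_set(p, seed = 1)
#' st <- build_stream(ps, total_duration = 2000, seed = 2)
#' head(st$annotation$onsets)
#' @export
build_stream <- function(pattern_set, total_duration, period = 400,
                         seed = NULL) {
  stopifnot(inherits(pattern_set, "pattern_set"))
  if (!is.null(seed)) set.seed(seed)
  .stream_window(pattern_set, 0, total_duration, period)
}

# internal: stream over the window [t0, t1) with globally indexed
# presentation onsets offset + period*k, so that a long run can be built
# chunk by chunk (chunks aligned to multiples of `period` never split a
# presentation window: the pattern is centred within its cycle).
.stream_window <- function(pattern_set, t0, t1, period) {
  params <- pattern_set$params
  if (period < params$L)
    stop("'period' must be at least the pattern duration L")
  L <- params$L
  N <- params$N
  total_duration <- t1
  offset <- (period - L) / 2
  k_first <- ceiling((t0 - offset) / period)
  k_last <- floor((t1 - offset - L) / period)
  ks <- if (k_last >= k_first) seq(k_first, k_last) else integer(0)
  n_pres <- length(ks)
  onsets <- offset + period * ks
  pids <- (ks %% params$P) + 1L

  aff_l <- vector("list", n_pres); tms_l <- vector("list", n_pres)
  # jittered presentations
  for (i in seq_len(n_pres)) {
    pat <- pattern_set$patterns[[pids[i]]]
    jit <- jitter_presentation(pat, params$T)
    aff_l[[i]] <- jit$afferent
    tms_l[[i]] <- jit$time + onsets[i]
  }
  # fresh Poisson noise in the gaps between presentation windows
  gap_starts <- pmax(t0, c(t0, onsets + L))
  gap_ends <- pmin(t1, c(onsets, t1))
  ga <- vector("list", length(gap_starts)); gt <- ga
  for (g in seq_along(gap_starts)) {
    glen <- gap_ends[g] - gap_starts[g]
    if (glen <= 0) next
    blk <- .poisson_block(N, params$f, glen)
    ga[[g]] <- blk$afferent
    gt[[g]] <- blk$time + gap_starts[g]
  }
  aff <- c(unlist(aff_l), unlist(ga))
  tms <- c(unlist(tms_l), unlist(gt))
  keep <- tms >= t0 & tms < t1
  stream <- spike_data(aff[keep], tms[keep], N, total_duration)
  list(stream = stream,
       annotation = list(period = period,
                         onsets = data.frame(time = onsets,
                                             pattern = pids)))
}
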