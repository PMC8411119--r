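#' Binned firing rates from a spike record
#'
#' Exact bookkeeping: `rate * bin_width_s * n_neurons` recovers the spike
#' count in every bin, and summing counts over bins recovers the record's
#' total. A trailing partial bin keeps its actual width.
#'
#' @param spikes A [spike_record()].
#' @param bin_width Bin width (ms).
#' @param population Population id to select (`NULL`: all events, treated as
#'   one population).
#' @param n_neurons Number of neurons indexed by the record (required to
#'   shape the matrix; indices above it are an error).
#' @param t_start,t_end Time range (defaults: 0 to the record's duration).
#' @return An object of class `rate_trace`: list with `breaks`, `mid`,
#'   `width` (ms) and the `n_neurons x n_bins` matrix `rate` (Hz).
#' @export
bin_rates <- function(spikes, bin_width, population = NULL, n_neurons,
                      t_start = 0, t_end = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(t_end)) t_end <- attr(spikes, "duration")
  ev <- if (is.null(population)) spikes else
    spikes[spikes$population == population, , drop = FALSE]
  if (nrow(ev) && max(ev$neuron) > n_neurons) {
    stop("spike record indexes more neurons than n_neurons")
  }
  breaks <- seq(t_start, t_end, by = bin_width)
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)
  n_bins <- length(breaks) - 1L
  width <- diff(breaks)

  counts <- matrix(0, n_neurons, n_bins)
  keep <- ev$time_ms > t_start & ev$time_ms <= t_end
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev)) {
    bin <- findInterval(ev$time_ms, breaks, left.open = TRUE,
                        rightmost.closed = TRUE)
    tab <- table(factor(ev$neuron, levels = seq_len(n_neurons)),
                 factor(bin, levels = seq_len(n_bins)))
    counts <- matrix(as.numeric(tab), n_neurons, n_bins)
  }
  structure(list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 width = width,
                 rate = counts / rep(width / 1000, each = n_neurons),
                 population = population),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace> %d neurons x %d bins of %g ms, mean %.3g Hz\n",
              nrow(x$rate), ncol(x$rate), x$width[1], mean(x$rate)))
  invisible(x)
}

#' Spearman rank correlation with average-rank tie handling
#'
#' Undefined (zero-variance) inputs are reported as missing rather than an
#' error so that ensemble aggregation can count and exclude them.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return The coefficient in `[-1, 1]`, or `NA` if either input has zero
#'   variance.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Run an experiment over an ensemble of seeds
#'
#' Runs `experiment(seed)` independently for `n_seeds` consecutive seeds
#' starting at `base_seed`. Runs share no mutable state; a failing seed is
#' recorded and excluded with a warning, never dropped silently. The summary
#' is recomputable from the stored per-seed results.
#'
#' @param experiment A `function(seed)` returning a numeric scalar or vector
#'   (consistent shape across seeds).
#' @param n_seeds Number of seeds (the full protocols use 20).
#' @param base_seed First seed.
#' @return An object of class `seed_ensemble`: list with `results` (named by
#'   seed), `mean`, `sd`, `seeds`, `failed_seeds`.
#' @export
ensemble_run <- function(experiment, n_seeds = 20, base_seed = 1) {
  seeds <- base_seed + seq_len(n_seeds) - 1L
  results <- list(); failed <- integer()
  for (s in seeds) {
    r <- tryCatch(experiment(s), error = function(e) {
      warning(sprintf("seed %d failed and was excluded: %s", s,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(r)) failed <- c(failed, s) else results[[as.character(s)]] <- r
  }
  if (!length(results)) stop("every seed failed")
  vals <- do.call(rbind, lapply(results, rbind))
  structure(list(results = results,
                 mean = colMeans(vals, na.rm = TRUE),
                 sd = apply(vals, 2, sd, na.rm = TRUE),
                 seeds = seeds, failed_seeds = failed,
                 n_seeds = length(results)),
            class = "seed_ensemble")
}

#' @export
print.seed_ensemble <- function(x, ...) {
  cat(sprintf("<seed_ensemble> %d seeds (%d failed): mean %s, sd %s\n",
              x$n_seeds, length(x$failed_seeds),
              paste(signif(x$mean, 4), collapse = ", "),
              paste(signif(x$sd, 4), collapse = ", ")))
  invisible(x)
}
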