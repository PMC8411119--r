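#' Deterministic hash of a configuration
#'
#' Polynomial byte hash of the canonical JSON serialization, used to stamp
#' every output so results from different configurations refuse to
#' aggregate.
#'
#' @param config Any R list.
#' @return A short hex string.
#' @export
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(as.character(
    jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 67108859  # prime < 2^26: exact doubles
  sprintf("%07x", h)
}

#' Write / read a run manifest
#'
#' @param path File path (JSON).
#' @param config Configuration list (hashed into the manifest).
#' @param seed RNG seed of the run.
#' @param extra Optional named list of additional fields.
#' @return The manifest list, invisibly (write) or visibly (read).
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  m <- c(list(config_hash = config_hash(config), seed = seed,
              package = "idipnet",
              version = as.character(utils::packageVersion("idipnet")),
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write / read a spike log as delimited text
#'
#' Columns `population`, `neuron`, `time_ms`; the record's duration and any
#' metadata go to a JSON sidecar at `<path>.json`.
#'
#' @param spikes A [spike_record()].
#' @param path Output path (TSV).
#' @param config Optional configuration to hash into the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_log <- function(spikes, path, config = NULL, seed = NULL) {
  write.table(as.data.frame(spikes), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  side <- list(duration = attr(spikes, "duration"))
  if (!is.null(config)) side$config_hash <- config_hash(config)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spike_log
#' @export
read_spike_log <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "numeric"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- spike_record(df$population, df$neuron, df$time_ms, side$duration)
  attr(out, "config_hash") <- side$config_hash
  out
}

#' Write / read a dense weight snapshot
#'
#' The matrix goes to a TSV, the metadata (dimensions, seed, configuration
#' hash, snapshot time) to a JSON sidecar.
#'
#' @param w Numeric matrix.
#' @param path Output path (TSV).
#' @param config,seed,time_ms Optional metadata.
#' @return `path`, invisibly.
#' @export
write_weight_snapshot <- function(w, path, config = NULL, seed = NULL,
                                  time_ms = NULL) {
  write.table(w, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  side <- list(nrow = nrow(w), ncol = ncol(w))
  if (!is.null(config)) side$config_hash <- config_hash(config)
  if (!is.null(seed)) side$seed <- seed
  if (!is.null(time_ms)) side$time_ms <- time_ms
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weight_snapshot
#' @export
read_weight_snapshot <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
  dimnames(w) <- NULL
  stopifnot(nrow(w) == side$nrow, ncol(w) == side$ncol)
  attr(w, "config_hash") <- side$config_hash
  attr(w, "time_ms") <- side$time_ms
  w
}

#' Write / read a binned rate trace
#'
#' @param trace A [bin_rates()] result.
#' @param path Output path (TSV; one row per bin, one column per neuron).
#' @param config Optional configuration to hash into the sidecar.
#' @return `path`, invisibly.
#' @export
write_rate_trace <- function(trace, path, config = NULL) {
  df <- data.frame(bin_start = trace$breaks[-length(trace$breaks)],
                   bin_end = trace$breaks[-1], t(trace$rate))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(population = trace$population)
  if (!is.null(config)) side$config_hash <- config_hash(config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_rate_trace
#' @export
read_rate_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  breaks <- c(df$bin_start, df$bin_end[nrow(df)])
  rate <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  dimnames(rate) <- NULL
  structure(list(breaks = breaks,
                 mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 width = diff(breaks), rate = rate,
                 population = if (is.null(side$population)) NULL else side$population),
            class = "rate_trace")
}

#' Aggregate per-seed results, refusing mixed configurations
#'
#' @param runs A list of lists, each with fields `value` (numeric) and
#'   `config_hash`.
#' @return List with `mean`, `sd`, `n`.
#' @export
aggregate_runs <- function(runs) {
  hashes <- vapply(runs, `[[`, "", "config_hash")
  if (length(unique(hashes)) > 1) {
    stop("refusing to aggregate results with different config hashes: ",
         paste(unique(hashes), collapse = ", "))
  }
  vals <- vapply(runs, `[[`, 0, "value")
  list(mean = mean(vals), sd = sd(vals), n = length(vals))
}

#' Read a model configuration file
#'
#' Structured-text (YAML) configuration with one section per parameter table;
#' the shipped defaults mirror the two model parameter tables.
#'
#' @param path Path to a YAML file, or one of `"hippocampal"`,
#'   `"recurrent"` for the shipped defaults.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (path %in% c("hippocampal", "recurrent")) {
    path <- system.file("extdata", paste0(path, ".yaml"), package = "idipnet")
  }
  yaml::read_yaml(path)
}

#' Build a hippocampal network from a configuration list
#' @param config A list as returned by [read_config()].
#' @param seed Optional seed.
#' @return A [build_hippocampal_net()] object.
#' @export
hippocampal_net_from_config <- function(config, seed = NULL) {
  tr <- config$track
  build_hippocampal_net(
    seed = seed,
    n_ca3 = config$populations$n_ca3, n_e = config$populations$n_e,
    n_i = config$populations$n_i, n_groups = config$populations$n_groups,
    track = track_geometry(n_fields = tr$n_fields,
                           circumference = tr$circumference,
                           sigma_pc = tr$sigma_pc, a_c = tr$a_c,
                           secs_between_fields = tr$secs_between_fields),
    w_ie = config$weights$w_ie, w_ei = config$weights$w_ei,
    offset_sd = config$tuning$offset_sd,
    i_ex_e = config$currents$i_ex_e, i_ex_i = config$currents$i_ex_i,
    idip = config$idip, hebb = config$hebbian)
}

#' Build a recurrent network specification from a configuration list
#' @param config A list as returned by [read_config()].
#' @return A [recurrent_net_spec()].
#' @export
recurrent_spec_from_config <- function(config) {
  recurrent_net_spec(
    n_e = config$populations$n_e, n_i = config$populations$n_i,
    n_ex = config$populations$n_ex,
    p_ee = config$connectivity$p_ee, p_ie = config$connectivity$p_ie,
    p_ei = config$connectivity$p_ei, p_ii = config$connectivity$p_ii,
    p_ex = config$connectivity$p_ex,
    mu_w = config$weights$mu, sigma_wrec = config$weights$sigma_wrec,
    sigma_win = config$weights$sigma_win,
    input_gain = config$weights$input_gain,
    wi_we_ratio = config$weights$wi_we_ratio,
    rate = config$input$rate,
    idip = config$idip, istdp = config$istdp)
}
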