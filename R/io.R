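#' Save a membrane model as JSON
#'
#' @param model a [membrane_model()].
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  x <- unclass(model)
  x$channels <- lapply(x$channels, function(ch) {
    ch$gates <- lapply(ch$gates, unclass)
    unclass(ch)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a membrane model from JSON
#'
#' Schema violations are reported with the offending field path.
#' Loading is the exact inverse of [save_model()].
#'
#' @param path JSON file written by [save_model()] (or hand-edited).
#' @return a [membrane_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]])) stop("model schema: missing '", where, field, "'")
    obj[[field]]
  }
  chans <- lapply(seq_along(need(x, "channels", "")), function(i) {
    ch <- x$channels[[i]]
    here <- sprintf("channels[%d]/", i)
    gates <- lapply(seq_along(ch$gates), function(j) {
      g <- ch$gates[[j]]
      ghere <- sprintf("%sgates[%d]/", here, j)
      tau <- need(g, "tau", ghere)
      tau <- if (identical(tau$form, "constant")) tau$base
             else tau[c("base", "amp", "v1", "k1", "v2", "k2")]
      gating_spec(need(g, "name", ghere), need(g, "power", ghere),
                  need(g, "vh", ghere), need(g, "k", ghere), tau)
    })
    channel_spec(need(ch, "name", here), need(ch, "gbar", here),
                 need(ch, "erev", here), gates)
  })
  membrane_model(chans,
                 area_cm2 = need(x, "area_cm2", ""), cm = need(x, "cm", ""),
                 leak_gbar = need(x, "leak_gbar", ""),
                 leak_erev = need(x, "leak_erev", ""),
                 bias_pA = need(x, "bias_pA", ""), v_init = need(x, "v_init", ""),
                 name = need(x, "name", ""))
}

#' Write a simulated trace as CSV (+ JSON sidecar)
#'
#' Columns: `t_ms`, `V_mV`, one `I_<name>_pA` per recorded current, and
#' `I_stim_pA`.  A JSON sidecar (same path with extension `.json`) records
#' dt, seed, spike onsets and a hash of the model definition.
#'
#' @param trace a `sim_trace` from [simulate()].
#' @param path CSV output path.
#' @param threshold spike-detection threshold for the sidecar (mV).
#' @export
write_trace <- function(trace, path, threshold = -10) {
  df <- data.frame(t_ms = trace$t, V_mV = trace$V)
  if (!is.null(trace$currents))
    for (nm in colnames(trace$currents))
      df[[paste0("I_", nm, "_pA")]] <- trace$currents[, nm]
  df$I_stim_pA <- trace$stimulus
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(dt = trace$dt, seed = trace$seed,
                  model = trace$model_name,
                  model_hash = trace$model_hash,
                  spike_onsets_ms = detect_spikes(trace, threshold)$onset_times)
  jsonlite::write_json(sidecar, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace CSV written by [write_trace()]
#' @param path CSV path.
#' @return a `sim_trace` (stimulus and currents restored; gating is not stored).
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  icols <- grep("^I_.*_pA$", names(df), value = TRUE)
  icols <- setdiff(icols, "I_stim_pA")
  cur <- NULL
  if (length(icols)) {
    cur <- as.matrix(df[icols])
    colnames(cur) <- sub("^I_", "", sub("_pA$", "", icols))
  }
  new_trace(t = df$t_ms, V = df$V_mV, dt = df$t_ms[2] - df$t_ms[1],
            currents = cur, stimulus = df$I_stim_pA, gating = NULL,
            seed = NULL, model_name = NA_character_, model_hash = NA_character_)
}

model_hash <- function(model) {
  # cheap content hash: serialize to canonical JSON and sum a rolling hash
  s <- jsonlite::serializeJSON(model, digits = 15)
  v <- utf8ToInt(s)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 4096)))
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the
#' configuration, the master seed, package version and model hash.
#'
#' @param path output JSON path.
#' @param config named list describing the run.
#' @param seed master seed.
#' @param model optional [membrane_model()] whose hash is recorded.
#' @export
write_manifest <- function(path, config, seed, model = NULL) {
  jsonlite::write_json(
    list(package = "olmcell",
         version = as.character(utils::packageVersion("olmcell")),
         seed = seed,
         model_hash = if (!is.null(model)) model_hash(model) else NULL,
         config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Derive independent sub-seeds from a master seed
#'
#' Counter-based expansion so that each consumer (OU background, observation
#' noise, perturbation phase, ...) gets its own reproducible stream.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @param stream stream label (integer offset).
#' @return integer vector of length `n`, all below 2^31.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  as.integer((as.double(seed) * 48271 + stream * 16807 +
                99991 * seq_len(n)) %% 2147483629) + 1L
}
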