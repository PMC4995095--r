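# On-disk formats: signal container (directory of full-precision CSV
# channels plus a JSON metadata file), event/interval CSV tables, and
# the YAML pipeline configuration.

#' Write a recording to a signal container
#'
#' Writes each channel of a recording (continuous signals and event
#' series) to its own full-precision CSV file inside `path`, plus a
#' `meta.json` carrying the rate/units/t0 attributes, channel order, and
#' an optional configuration hash.  Round-trips bit-exactly through
#' [read_signals()].
#'
#' @param recording named list of [continuous_signal()] /
#'   [event_series()] objects.
#' @param path container directory (created if absent).
#' @param config_hash optional hash string embedded in the metadata.
#' @return `path`, invisibly.
#' @export
write_signals <- function(recording, path, config_hash = NULL) {
  stopifnot(is.list(recording), length(names(recording)) == length(recording))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(container = "twitchgate-signals", version = 1L,
               config_hash = config_hash, channels = list())
  for (nm in names(recording)) {
    ch <- recording[[nm]]
    file <- paste0(nm, ".csv")
    if (inherits(ch, "continuous_signal")) {
      writeLines(c("value", sprintf("%.17g", ch$samples)), file.path(path, file))
      meta$channels[[nm]] <- list(type = "continuous", file = file,
                                  rate_hz = ch$rate_hz, t0_s = ch$t0_s,
                                  label = ch$label, units = ch$units,
                                  n = length(ch$samples))
    } else if (inherits(ch, "event_series")) {
      writeLines(c("time_s", sprintf("%.17g", ch$times_s)), file.path(path, file))
      meta$channels[[nm]] <- list(type = "events", file = file,
                                  t0_s = ch$t0_s, duration_s = ch$duration_s,
                                  label = ch$label)
    } else stop("write_signals: channel '", nm, "' is not a supported type")
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from a signal container
#'
#' @param path container directory written by [write_signals()].
#' @return named list of channels in their original order.
#' @export
read_signals <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("read_signals: no meta.json in ", path)
  meta <- jsonlite::read_json(mf)
  if (!identical(meta$container, "twitchgate-signals"))
    stop("read_signals: ", path, " is not a twitchgate signal container")
  out <- list()
  for (nm in names(meta$channels)) {
    ch <- meta$channels[[nm]]
    vals <- scan(file.path(path, ch$file), what = double(), skip = 1L, quiet = TRUE)
    if (identical(ch$type, "continuous")) {
      if (is.null(ch$rate_hz))
        stop("read_signals: channel '", nm, "' is missing the rate_hz attribute")
      if (is.null(ch$t0_s))
        stop("read_signals: channel '", nm, "' is missing the t0_s attribute")
      out[[nm]] <- continuous_signal(vals, ch$rate_hz, ch$t0_s,
                                     ch$label %||% "", ch$units %||% "")
    } else if (identical(ch$type, "events")) {
      out[[nm]] <- event_series(vals, ch$label %||% "",
                                t0_s = ch$t0_s %||% NA_real_,
                                duration_s = ch$duration_s %||% NA_real_)
    } else stop("read_signals: channel '", nm, "' has unknown type")
  }
  attr(out, "config_hash") <- meta$config_hash
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an event or interval series to CSV
#'
#' Point events: columns `time_s`, `label`; intervals: `onset_s`,
#' `offset_s`, `label`.  Times are written with 9 decimal digits;
#' intervals are half-open.
#'
#' @param series an [event_series()] or [interval_series()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(series, path) {
  if (inherits(series, "event_series")) {
    df <- data.frame(time_s = sprintf("%.9f", series$times_s),
                     label = rep(series$label, length(series$times_s)))
    if (!nrow(df)) df <- df[0, ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(series, "interval_series")) {
    df <- data.frame(onset_s = sprintf("%.9f", series$onset_s),
                     offset_s = sprintf("%.9f", series$offset_s),
                     label = series$label)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else stop("write_events: unsupported object")
  invisible(path)
}

#' Read an event or interval series from CSV
#'
#' The header decides the type: `time_s` yields an [event_series()],
#' `onset_s`/`offset_s` an [interval_series()].  Unsorted times are a
#' validation error; an empty table with a header is an empty series.
#'
#' @param path CSV file path.
#' @return an [event_series()] or [interval_series()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_s" %in% names(df)) {
    if (nrow(df) && is.unsorted(df$time_s))
      stop("read_events: times in ", path, " are not sorted")
    event_series(df$time_s,
                 label = if (nrow(df) && "label" %in% names(df)) df$label[1L] else "")
  } else if (all(c("onset_s", "offset_s") %in% names(df))) {
    interval_series(df$onset_s, df$offset_s,
                    if ("label" %in% names(df)) df$label else character())
  } else stop("read_events: ", path, " has neither a time_s nor an onset_s/offset_s header")
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed configuration; embedded in every output the
#' pipeline writes so results can be traced to the exact configuration
#' that produced them.
#'
#' @param cfg any R object.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Assemble and validate a full pipeline configuration
#'
#' Nested sections mirror the stage configurations: `session`
#' ([session_config()]), `scoring` ([scoring_config()]), `spindle`
#' ([spindle_criteria()]), `jitter` ([jitter_spec()]), `infusion`
#' ([infusion_design()]), plus a global `seed` and overall `alpha`
#' (0.05; the bands use the jitter section's 0.01).  Unknown keys in any
#' section are rejected.
#'
#' @param x named list (e.g. parsed YAML) or nothing for all defaults.
#' @return list of class `pipeline_config` with fully built sections and
#'   a `hash` field.
#' @export
pipeline_config <- function(x = list()) {
  known <- c("session", "scoring", "spindle", "jitter", "infusion", "seed", "alpha")
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("pipeline_config: unknown key(s): ", paste(bad, collapse = ", "))
  build <- function(section, ctor) {
    args <- x[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("pipeline_config: unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  seed <- as.integer(x$seed %||% 1L)
  sess_args <- x$session %||% list()
  if (is.null(sess_args$seed)) sess_args$seed <- seed
  x$session <- sess_args
  cfg <- list(session = build("session", session_config),
              scoring = build("scoring", scoring_config),
              spindle = build("spindle", spindle_criteria),
              jitter = build("jitter", jitter_spec),
              infusion = build("infusion", infusion_design),
              seed = seed,
              alpha = x$alpha %||% 0.05)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the sections of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path) %||% list())
}
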