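# Plain-text trace and event-table round-trips.

fmt_num <- function(x) sprintf("%.17g", x)

num_or_na <- function(s, default = NA_real_) {
  if (is.null(s)) return(default)
  s <- trimws(s)
  if (s %in% c("NA", "NaN", "")) return(NA_real_)
  as.numeric(s)
}

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    val <- meta[[nm]]
    if (is.null(val)) next
    writeLines(paste0("# ", nm, "\t", val), con)
  }
}

parse_header <- function(lines) {
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  vals <- lapply(kv, function(p) paste(p[-1], collapse = "\t"))
  names(vals) <- vapply(kv, `[[`, "", 1)
  vals
}

#' Write and read traces as self-describing text files
#'
#' The file carries `# key<TAB>value` metadata lines (sampling rate,
#' voltage, seed, JSON-encoded filter history) followed by one current
#' sample (pA) per line at full precision, so the round-trip is lossless.
#'
#' @param trace An `sc_trace`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   `sc_trace`.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    format = "subkinetics_trace_v1",
    fs = fmt_num(trace_fs(trace)),
    voltage = fmt_num(trace_voltage(trace)),
    seed = attr(trace, "seed"),
    filter_history = jsonlite::toJSON(trace_history(trace), auto_unbox = TRUE,
                                      digits = NA)))
  writeLines(fmt_num(trace$current), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  for (req in c("fs", "voltage")) {
    if (is.null(meta[[req]]))
      stop_bad("malformed trace file: missing metadata field '", req, "'")
  }
  body <- lines[!grepl("^# ", lines)]
  hist <- if (!is.null(meta$filter_history))
    jsonlite::fromJSON(meta$filter_history, simplifyVector = FALSE) else list()
  new_trace(as.numeric(body), fs = num_or_na(meta$fs),
            voltage = num_or_na(meta$voltage), filter_history = hist,
            seed = if (!is.null(meta$seed)) as.integer(num_or_na(meta$seed)) else NULL)
}

#' Write and read event tables
#'
#' Tab-separated dwell table (`class`, `start_s`, `duration_s`, `mean_pA`)
#' preceded by `# key<TAB>value` metadata (dead time, voltage, sampling
#' rate, JSON class table). Events must be contiguous; reading validates
#' contiguity.
#'
#' @param events An `event_seq`.
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` an
#'   `event_seq`.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    format = "subkinetics_events_v1",
    dead_time = fmt_num(attr(events, "dead_time") %||% 0),
    voltage = fmt_num(attr(events, "voltage") %||% NA_real_),
    fs = fmt_num(attr(events, "fs") %||% NA_real_),
    classes = jsonlite::toJSON(attr(events, "event_classes"), digits = NA)))
  writeLines("class\tstart_s\tduration_s\tmean_pA", con)
  writeLines(paste(events$class, fmt_num(events$start),
                   fmt_num(events$duration), fmt_num(events$amplitude),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!grepl("^# ", lines)]
  tb <- utils::read.delim(text = body, sep = "\t", stringsAsFactors = FALSE)
  gaps <- abs(tb$start_s[-1] - (tb$start_s + tb$duration_s)[-nrow(tb)])
  if (nrow(tb) > 1 && any(gaps > 1e-9))
    stop_bad("non-contiguous events in ", path)
  classes <- if (!is.null(meta$classes))
    tibble::as_tibble(jsonlite::fromJSON(meta$classes)) else conductance_classes()
  new_event_seq(tb$class, tb$start_s, tb$duration_s, tb$mean_pA,
                dead_time = num_or_na(meta$dead_time, 0),
                voltage = num_or_na(meta$voltage),
                fs = num_or_na(meta$fs), classes = classes)
}

#' Import a dwell list (class label + duration pairs)
#'
#' Builds a contiguous event sequence from the de-facto dwell-table
#' convention used by single-channel software: ordered (class, duration ms)
#' pairs; starts are reconstructed cumulatively from zero.
#'
#' @param dwells Data frame with columns `class` and `duration_ms`.
#' @param voltage Optional holding potential (mV).
#' @param classes Conductance-class table for amplitudes.
#' @return An `event_seq` (amplitudes from the class conductances when
#'   `voltage` is given, `NA` otherwise).
#' @export
import_dwell_list <- function(dwells, voltage = NA_real_,
                              classes = conductance_classes()) {
  dwells <- tibble::as_tibble(dwells)
  stopifnot(all(c("class", "duration_ms") %in% names(dwells)))
  dur <- dwells$duration_ms * 1e-3
  start <- cumsum(c(0, head(dur, -1)))
  amp <- if (is.finite(voltage))
    classes$conductance[match(dwells$class, classes$label)] * voltage * 1e-3
  else rep(NA_real_, nrow(dwells))
  new_event_seq(dwells$class, start, dur, amp, voltage = voltage,
                classes = classes)
}
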