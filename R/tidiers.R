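# broom-style tidiers for fitted objects.

#' Tidy a dwell-time mixture fit
#'
#' @param x A `dwell_mixture_fit`.
#' @param ... Unused.
#' @return Tibble with one row per exponential component: `component`,
#'   `tau_ms`, `area`.
#' @export
tidy.dwell_mixture_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), tau_ms = x$taus, area = x$areas)
}

#' @rdname tidy.dwell_mixture_fit
#' @export
glance.dwell_mixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, logLik = x$loglik, n_events = x$n_events,
                 t_dead_ms = x$t_dead, degenerate = x$degenerate)
}

#' Tidy a MIL rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return Tibble with one row per directed edge: `from`, `to`, `rate`
#'   (s^-1), `se_log_rate` (if computed) and `identifiable`.
#' @export
tidy.rate_fit <- function(x, ...) {
  r <- x$model$rates
  edge <- paste(r$from, r$to, sep = "->")
  tibble::tibble(from = r$from, to = r$to, rate = r$rate,
                 se_log_rate = if (is.null(x$se)) NA_real_ else x$se,
                 identifiable = !(edge %in% x$unidentifiable))
}

#' @rdname tidy.rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, t_dead = x$t_dead, voltage = x$voltage,
                 records_used = x$records_used, converged = x$converged,
                 n_unidentifiable = length(x$unidentifiable))
}

#' Tidy a Boltzmann Po-voltage fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`; `dG` in kJ mol^-1.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("po_max", "dG", "z"),
                 estimate = c(x$po_max, x$dG, x$z),
                 std.error = unname(x$se))
}

#' @rdname tidy.boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  rss <- sum((x$fitted$po - x$fitted$fitted)^2)
  tibble::tibble(temperature = x$temperature, rss = rss,
                 n = nrow(x$fitted), flat = x$flat)
}

#' Structured-text report for a dwell-time fit
#'
#' Writes time constants (ms), percentage areas, log-likelihood and the
#' component count in the layout conventional for lifetime tables.
#'
#' @param x A `dwell_mixture_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dwell_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dwell mixture fit: k = ", x$k, ", n = ", x$n_events,
           ", t_dead_ms = ", x$t_dead, ", logLik = ", format(x$loglik)),
    "tau_ms\tarea_pct",
    paste(fmt_num(x$taus), fmt_num(100 * x$areas), sep = "\t")), con)
  invisible(path)
}

#' Structured-text report for a rate fit
#'
#' Edge list with rates (s^-1) and optional SEs, log-likelihood, dead time
#' and voltage.
#'
#' @param x A `rate_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  td <- tidy(x)
  writeLines(c(
    paste0("# rate fit: model = ", x$model$name, ", voltage_mV = ", x$voltage,
           ", t_dead_s = ", x$t_dead, ", logLik = ", format(x$loglik),
           ", records = ", x$records_used),
    "from\tto\trate_per_s\tse_log_rate\tidentifiable",
    paste(td$from, td$to, fmt_num(td$rate), td$se_log_rate, td$identifiable,
          sep = "\t")), con)
  invisible(path)
}
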