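# Voltage-level analyses: Boltzmann Po-voltage fits and full-vs-substate
# current partitioning.

FARADAY <- 96485       # C mol^-1
GAS_CONST <- 8.314     # J mol^-1 K^-1

#' Fit a Boltzmann relation to open probability versus voltage
#'
#' Fits Po(V) = Po_max / (1 + exp((dG + z F V) / (R T))) by nonlinear least
#' squares, with V in volts and dG in J mol^-1 internally. A negative
#' effective gating charge z means Po increases with depolarization.
#' Initialization: Po_max from the largest observed Po; dG and z from a
#' linear fit to the logit of Po/Po_max.
#'
#' @param po_table Data frame with columns `voltage` (mV by default) and
#'   `po`, at four or more distinct voltages.
#' @param temperature Absolute temperature (K); default 295.15 K (22 C).
#' @param voltage_unit `"mV"` (default) or `"V"`.
#' @return A `boltzmann_fit`: list with `po_max`, `dG` (kJ mol^-1), `z`,
#'   standard errors, `temperature`, `fitted` tibble and flags
#'   (`flat = TRUE` when z is indistinguishable from 0).
#' @export
boltzmann_fit <- function(po_table, temperature = 295.15,
                          voltage_unit = c("mV", "V")) {
  voltage_unit <- match.arg(voltage_unit)
  po_table <- tibble::as_tibble(po_table)
  stopifnot(all(c("voltage", "po") %in% names(po_table)))
  if (length(unique(po_table$voltage)) < 4)
    stop_bad("need Po at >= 4 distinct voltages")
  v <- po_table$voltage * if (voltage_unit == "mV") 1e-3 else 1
  po <- po_table$po
  RT <- GAS_CONST * temperature
  pomax0 <- max(po) * 1.05
  pomax0 <- min(max(pomax0, 1e-6), 1)
  y <- pmin(pmax(po / pomax0, 1e-6), 1 - 1e-6)
  lg <- log(1 / y - 1) # = (dG + zFV)/RT
  lf <- lm(lg ~ v)
  dG0 <- unname(coef(lf)[1]) * RT
  z0 <- unname(coef(lf)[2]) * RT / FARADAY
  if (!is.finite(z0)) z0 <- -1
  if (!is.finite(dG0)) dG0 <- 0
  # a voltage-insensitive relation is degenerate for the full model: report
  # z = 0, Po_max consistent with the observed mean, and flag it
  if (abs(z0) < 1e-10 || stats::sd(po) < 1e-12 * max(abs(po), 1)) {
    mp <- mean(po)
    if (2 * mp <= 1) {
      pomax <- 2 * mp
      dG <- 0
    } else {
      pomax <- 1
      dG <- RT * log(1 / mp - 1)
    }
    return(structure(
      list(po_max = pomax, dG = dG / 1000, z = 0,
           se = c(po_max = NA_real_, dG = NA_real_, z = NA_real_),
           temperature = temperature, flat = TRUE,
           fitted = tibble::tibble(voltage = po_table$voltage, po = po,
                                   fitted = rep(mp, length(po))),
           nls = NULL),
      class = "boltzmann_fit"))
  }
  df <- data.frame(v = v, po = po)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      po ~ pomax / (1 + exp((dG + z * FARADAY * v) / RT)),
      data = df,
      start = list(pomax = pomax0, dG = dG0, z = z0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop_bad(
      "Boltzmann fit failed to converge (starts: pomax=", signif(pomax0, 3),
      ", dG=", signif(dG0, 3), " J/mol, z=", signif(z0, 3), "): ",
      conditionMessage(e)))
  cf <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  flat <- is.finite(ses["z"]) && abs(cf["z"]) < 2 * ses["z"] ||
    abs(cf["z"]) < 1e-8
  structure(
    list(po_max = unname(cf["pomax"]), dG = unname(cf["dG"]) / 1000,
         z = unname(cf["z"]),
         se = c(po_max = unname(ses["pomax"]), dG = unname(ses["dG"]) / 1000,
                z = unname(ses["z"])),
         temperature = temperature, flat = unname(flat),
         fitted = tibble::tibble(voltage = po_table$voltage, po = po,
                                 fitted = predict(fit)),
         nls = fit),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> Po_max =", signif(x$po_max, 3),
      " dG =", signif(x$dG, 3), "kJ/mol  z =", signif(x$z, 3),
      " (T =", x$temperature, "K)\n")
  if (x$flat) cat("note: z indistinguishable from 0 (flat Po-V relation)\n")
  invisible(x)
}

#' Predict Po from a Boltzmann fit
#'
#' @param object A `boltzmann_fit`.
#' @param voltage Voltages (mV).
#' @param ... Unused.
#' @return Predicted Po.
#' @export
predict.boltzmann_fit <- function(object, voltage, ...) {
  RT <- GAS_CONST * object$temperature
  object$po_max / (1 + exp((object$dG * 1000 + object$z * FARADAY *
                              voltage * 1e-3) / RT))
}

#' Partition the mean current between full and subconductance openings
#'
#' For each single-channel record (idealized with the merged-substate
#' scheme): the mean current carried while in full-open classes and while in
#' substate classes, their percentage split, aggregated by voltage; plus a
#' weighted linear extrapolation of the substate percentage to 0 mV over the
#' window `voltage <= extrapolation_window` (default +20 mV), where direct
#' measurement is impossible because amplitudes vanish.
#'
#' @param records List of `list(trace =, events =)` pairs; each `events`
#'   must carry its voltage attribute.
#' @param extrapolation_window Upper voltage (mV) of the regression window.
#' @return A `current_partition`: list with `by_record`, `by_voltage`
#'   (mean +/- SE currents and percent substate) and `extrapolation`
#'   (percent substate at 0 mV with standard error and 95% CI).
#' @export
current_partition <- function(records, extrapolation_window = 20) {
  stopifnot(length(records) >= 1)
  by_record <- purrr::imap_dfr(records, function(r, i) {
    mc <- mean_class_currents(r$trace, r$events)
    v <- attr(r$events, "voltage")
    full <- sum(mc$mean_current[mc$class == "O"])
    sub <- sum(mc$mean_current[grepl("^S", mc$class)])
    tot <- full + sub
    tibble::tibble(
      record = i, voltage = v, full_current = full, sub_current = sub,
      pct_sub = ifelse(abs(tot) > 1e-12, 100 * sub / tot, NA_real_),
      no_openings = abs(tot) <= 1e-12)
  })
  by_voltage <- by_record |>
    dplyr::group_by(.data$voltage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_full = mean(.data$full_current),
      se_full = ifelse(dplyr::n() > 1, sd(.data$full_current) / sqrt(dplyr::n()), NA_real_),
      mean_sub = mean(.data$sub_current),
      se_sub = ifelse(dplyr::n() > 1, sd(.data$sub_current) / sqrt(dplyr::n()), NA_real_),
      pct_sub = mean(.data$pct_sub, na.rm = TRUE),
      se_pct = ifelse(sum(!is.na(.data$pct_sub)) > 1,
                      sd(.data$pct_sub, na.rm = TRUE) /
                        sqrt(sum(!is.na(.data$pct_sub))), NA_real_),
      .groups = "drop")
  win <- by_record[!is.na(by_record$pct_sub) &
                     by_record$voltage <= extrapolation_window, ]
  extrapolation <- NULL
  if (nrow(win) >= 2 && length(unique(win$voltage)) >= 2) {
    lf <- lm(pct_sub ~ voltage, data = win)
    pr <- predict(lf, newdata = data.frame(voltage = 0), se.fit = TRUE)
    extrapolation <- tibble::tibble(
      voltage = 0, pct_sub = pr$fit, se = pr$se.fit,
      ci_lo = pr$fit - 1.96 * pr$se.fit, ci_hi = pr$fit + 1.96 * pr$se.fit)
  }
  structure(list(by_record = by_record, by_voltage = by_voltage,
                 extrapolation = extrapolation,
                 extrapolation_window = extrapolation_window),
            class = "current_partition")
}

#' @export
print.current_partition <- function(x, ...) {
  cat("<current_partition>\n")
  print(x$by_voltage)
  if (!is.null(x$extrapolation)) {
    cat("substate share extrapolated to 0 mV: ",
        signif(x$extrapolation$pct_sub, 3), "% (95% CI ",
        signif(x$extrapolation$ci_lo, 3), "-",
        signif(x$extrapolation$ci_hi, 3), ")\n", sep = "")
  }
  invisible(x)
}
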