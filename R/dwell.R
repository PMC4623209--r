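# Dwell-time distributions and exponential-mixture maximum likelihood.

#' Log-binned dwell-time histogram
#'
#' Bins dwell durations on a logarithmic time axis (by default 10 bins per
#' decade) and returns counts together with their square roots, the
#' conventional ordinate for single-channel lifetime distributions.
#'
#' @param durations Dwell durations (ms), all > 0.
#' @param bins_per_decade Number of bins per decade of time.
#' @return A `dwell_hist` tibble with `bin_lo`, `bin_hi`, `mid` (geometric
#'   midpoint, ms), `count` and `sqrt_count`.
#' @export
log_binned_histogram <- function(durations, bins_per_decade = 10) {
  if (!length(durations)) stop_bad("no durations supplied")
  if (any(durations <= 0)) stop_bad("durations must be positive")
  lo <- floor(log10(min(durations)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(durations)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  cnt <- graphics::hist(durations, breaks = edges, plot = FALSE,
                        right = FALSE)$counts
  structure(
    tibble::tibble(bin_lo = head(edges, -1), bin_hi = edges[-1],
                   mid = sqrt(head(edges, -1) * edges[-1]),
                   count = cnt, sqrt_count = sqrt(cnt)),
    n = length(durations), bins_per_decade = bins_per_decade,
    class = c("dwell_hist", class(tibble::tibble()))
  )
}

# Mixture log-likelihood of left-truncated exponentials. Each component is
# renormalized by exp(t_dead/tau), i.e. the conditional density given
# t >= t_dead is sum_i a_i (1/tau_i) exp(-(t - t_dead)/tau_i).
trunc_exp_mix_loglik <- function(t, taus, areas, t_dead) {
  lk <- vapply(seq_along(taus), function(i)
    log(areas[i]) - log(taus[i]) - (t - t_dead) / taus[i], numeric(length(t)))
  if (is.null(dim(lk))) lk <- matrix(lk, nrow = length(t))
  m <- apply(lk, 1, max)
  sum(m + log(rowSums(exp(lk - m))))
}

theta_to_par <- function(theta, k) {
  taus <- exp(theta[seq_len(k)])
  if (k == 1) return(list(taus = taus, areas = 1))
  w <- c(theta[(k + 1):(2 * k - 1)], 0)
  w <- exp(w - max(w))
  list(taus = taus, areas = w / sum(w))
}

#' Fit an exponential mixture to dwell times by maximum likelihood
#'
#' Maximizes the log-likelihood of a k-component exponential mixture
#' left-truncated at the dead time (each component conditioned on exceeding
#' `t_dead`). Optimization runs in unconstrained coordinates (log time
#' constants, softmax areas) from a deterministic grid of quantile-based
#' initializations plus seeded random restarts.
#'
#' For `k = 1` the maximum-likelihood estimate has the closed form
#' `tau = mean(t) - t_dead`, which the numerical optimum matches.
#'
#' @param durations Dwell durations (ms), all >= `t_dead`.
#' @param k Number of exponential components.
#' @param t_dead Dead time (ms).
#' @param n_restarts Extra random restarts.
#' @param seed Seed for the random restarts.
#' @return A `dwell_mixture_fit` with fields `taus` (ms, increasing),
#'   `areas` (summing to 1), `loglik`, `k`, `n_events`, `t_dead` and a
#'   `degenerate` flag (components collapsing onto one another).
#' @export
fit_exp_mixture <- function(durations, k, t_dead = 0, n_restarts = 3,
                            seed = 1) {
  stopifnot(k >= 1, all(durations >= t_dead), length(durations) >= 2)
  t <- as.numeric(durations)
  nll <- function(theta) {
    p <- theta_to_par(theta, k)
    if (any(!is.finite(p$taus)) || any(p$taus <= 0)) return(1e300)
    -trunc_exp_mix_loglik(t, p$taus, p$areas, t_dead)
  }
  ngr <- function(theta) {
    p <- theta_to_par(theta, k)
    if (any(!is.finite(p$taus)) || any(p$taus <= 0)) return(rep(0, length(theta)))
    ts <- t - t_dead
    f <- vapply(seq_len(k), function(i)
      p$areas[i] / p$taus[i] * exp(-ts / p$taus[i]), numeric(length(t)))
    if (is.null(dim(f))) f <- matrix(f, nrow = length(t))
    S <- rowSums(f)
    g_tau <- vapply(seq_len(k), function(i)
      sum(f[, i] / S * (ts / p$taus[i] - 1)), numeric(1))
    if (k == 1) return(-g_tau)
    g_w <- vapply(seq_len(k), function(j)
      sum(f[, j] / S) - length(t) * p$areas[j], numeric(1))
    -c(g_tau, g_w[seq_len(k - 1)])
  }
  shifted <- pmax(t - t_dead, .Machine$double.eps)
  starts <- list()
  if (k == 1) {
    starts[[1]] <- log(mean(shifted))
  } else {
    # quantile-based spread of initial taus; equal areas
    qs <- quantile(shifted, probs = seq(0.15, 0.95, length.out = k))
    qs <- pmax(qs, 1e-6)
    starts[[1]] <- c(log(qs), rep(0, k - 1))
    starts[[2]] <- c(log(mean(shifted)) + seq(-1.5, 1.5, length.out = k),
                     rep(0, k - 1))
  }
  rs <- with_seed_if(seed, lapply(seq_len(n_restarts), function(i)
    c(log(mean(shifted)) + stats::rnorm(k, 0, 1.2), rep(0, max(k - 1, 0)))))
  starts <- c(starts, rs)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, gr = ngr, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_bad("exponential mixture fit failed from all starts")
  p <- theta_to_par(best$par, k)
  ord <- order(p$taus)
  taus <- unname(p$taus[ord])
  areas <- unname(p$areas[ord])
  degenerate <- k > 1 && (any(diff(log(taus)) < 0.05) || any(areas < 1e-4))
  structure(
    list(taus = taus, areas = areas, loglik = -best$value, k = k,
         n_events = length(t), t_dead = t_dead, degenerate = degenerate),
    class = "dwell_mixture_fit"
  )
}

#' @export
print.dwell_mixture_fit <- function(x, ...) {
  cat("<dwell_mixture_fit> k =", x$k, " n =", x$n_events,
      " logLik =", format(x$loglik), "\n")
  print(tibble::tibble(tau_ms = x$taus, area = x$areas))
  invisible(x)
}

#' Select the number of exponential components by likelihood-ratio testing
#'
#' Fits mixtures with increasing component counts and keeps adding a
#' component while twice the gain in log-likelihood exceeds the chi-squared
#' critical value with 2 degrees of freedom (one tau, one area) at the
#' requested confidence level. A candidate whose fit is degenerate
#' (components collapsing onto one another or carrying vanishing area, i.e.
#' structure below the resolvable limit) is never accepted regardless of
#' its likelihood. Returns the smallest adequate count.
#'
#' @param durations Dwell durations (ms).
#' @param k_max Largest component count to consider.
#' @param t_dead Dead time (ms).
#' @param alpha Significance level (default 0.05, i.e. P = 0.95 confidence).
#' @param seed Seed passed to the mixture fits.
#' @return Integer: the selected component count.
#' @export
select_component_count <- function(durations, k_max = 4, t_dead = 0,
                                   alpha = 0.05, seed = 1) {
  stopifnot(k_max >= 1)
  crit <- qchisq(1 - alpha, df = 2)
  fit <- fit_exp_mixture(durations, 1, t_dead, seed = seed)
  k <- 1L
  while (k < k_max) {
    nxt <- tryCatch(fit_exp_mixture(durations, k + 1L, t_dead, seed = seed),
                    error = function(e) NULL)
    if (is.null(nxt) || nxt$degenerate) break
    if (2 * (nxt$loglik - fit$loglik) <= crit) break
    fit <- nxt
    k <- k + 1L
  }
  k
}
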