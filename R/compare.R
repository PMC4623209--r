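# Amplitude histograms, 1-D Earth Mover's Distance, and classical MDS for
# model discrimination.

#' Default normalized-amplitude grid
#'
#' 100 uniform bins spanning -0.2 to 1.2 of the full-open current, the
#' shared grid on which amplitude distributions are compared.
#'
#' @param n_bins Number of bins.
#' @param lo,hi Grid limits (fractions of the full-open current).
#' @return Numeric vector of bin edges.
#' @export
default_amp_grid <- function(n_bins = 100, lo = -0.2, hi = 1.2) {
  seq(lo, hi, length.out = n_bins + 1)
}

#' All-points amplitude histogram of a trace
#'
#' Bins the sample currents, normalized by the full-open current so the
#' amplitude axis is dimensionless and distances are comparable across
#' voltages, into a shared grid and returns a unit-mass density. Samples
#' outside the grid are counted in the nearest edge bin. Supplying `events`
#' plus `classes` restricts the histogram to samples classified into those
#' conductance classes.
#'
#' @param trace An `sc_trace`.
#' @param grid Bin edges on the normalized axis; see [default_amp_grid()].
#' @param normalize_by Full-open current (pA); default 199 pS times the
#'   trace voltage.
#' @param events Optional aligned `event_seq` for class-conditional
#'   histograms.
#' @param classes Class labels to keep when `events` is given.
#' @param source Optional label for the histogram.
#' @return An `amp_hist` tibble with `bin_lo`, `bin_hi`, `mid`, `density`;
#'   densities integrate to one.
#' @export
amplitude_histogram <- function(trace, grid = default_amp_grid(),
                                normalize_by = NULL, events = NULL,
                                classes = NULL, source = NULL) {
  v <- trace_voltage(trace)
  normalize_by <- normalize_by %||% (199 * v * 1e-3)
  if (!is.finite(normalize_by) || normalize_by == 0)
    stop_bad("normalize_by must be a nonzero full-open current in pA")
  x <- trace$current
  if (!is.null(events) && !is.null(classes)) {
    idx <- findInterval(trace_time(trace), events$start)
    x <- x[events$class[idx] %in% classes]
  }
  if (!length(x)) stop_bad("no samples selected for the amplitude histogram")
  z <- x / normalize_by
  z <- pmin(pmax(z, grid[1] + 1e-12), grid[length(grid)] - 1e-12)
  cnt <- graphics::hist(z, breaks = grid, plot = FALSE, right = FALSE)$counts
  w <- diff(grid)
  structure(
    tibble::tibble(bin_lo = head(grid, -1), bin_hi = grid[-1],
                   mid = (head(grid, -1) + grid[-1]) / 2,
                   density = cnt / sum(cnt) / w),
    grid = grid, n_samples = length(x), source = source,
    normalize_by = normalize_by,
    class = c("amp_hist", class(tibble::tibble()))
  )
}

#' 1-D Earth Mover's Distance between two amplitude histograms
#'
#' The optimal-transport (Wasserstein-1) distance between two unit-mass
#' histograms on an identical grid, computed by the closed form
#' sum over bins of |CDF1 - CDF2| times the bin width.
#'
#' @param h1,h2 `amp_hist` objects on the same grid.
#' @return Nonnegative distance on the normalized amplitude axis.
#' @export
emd_1d <- function(h1, h2) {
  g1 <- attr(h1, "grid"); g2 <- attr(h2, "grid")
  if (length(g1) != length(g2) || max(abs(g1 - g2)) > 1e-12)
    stop_bad("histograms are on different grids")
  w <- diff(g1)
  p1 <- h1$density * w
  p2 <- h2$density * w
  sum(abs(cumsum(p1 - p2)) * w)
}

#' Pairwise EMD matrix
#'
#' @param hists List of `amp_hist` objects on a shared grid.
#' @param labels Labels; defaults to the histograms' `source` attributes or
#'   names.
#' @return An `emd_matrix`: symmetric matrix with zero diagonal.
#' @export
emd_matrix <- function(hists, labels = NULL) {
  n <- length(hists)
  labels <- labels %||% names(hists) %||%
    vapply(seq_len(n), function(i)
      attr(hists[[i]], "source") %||% paste0("h", i), character(1))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d <- emd_1d(hists[[i]], hists[[j]])
    m[i, j] <- d
    m[j, i] <- d
  }
  structure(m, class = c("emd_matrix", "matrix"))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: double-centres the squared distances and embeds on the
#' top eigenvectors scaled by the square roots of their eigenvalues;
#' deterministic up to rotation and reflection. A warning flag is set when
#' negative eigenvalues dominate (non-Euclidean distances).
#'
#' @param d Distance matrix (e.g. an `emd_matrix`).
#' @param dims Embedding dimension.
#' @return An `mds_embedding` tibble with `label` and coordinate columns
#'   `dim1`, `dim2`, ...; attributes `eig` (all eigenvalues), `gof`
#'   (goodness-of-fit) and `non_euclidean` flag. Coordinates are centred.
#' @export
mds_embed <- function(d, dims = 2) {
  d <- as.matrix(d)
  res <- cmdscale(d, k = dims, eig = TRUE)
  pts <- res$points
  pts <- sweep(pts, 2, colMeans(pts))
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  neg <- sum(pmax(-res$eig, 0))
  pos <- sum(pmax(res$eig, 0))
  out <- tibble::as_tibble(pts)
  out <- dplyr::bind_cols(tibble::tibble(label = rownames(d) %||%
                                           paste0("p", seq_len(nrow(d)))), out)
  structure(out, eig = res$eig, gof = res$GOF,
            non_euclidean = neg > 0.05 * pos,
            class = c("mds_embedding", class(tibble::tibble())))
}

#' Rank candidate gating models against experimental amplitude distributions
#'
#' For each candidate model: simulate to amplitude-distribution
#' stationarity, histogram the simulated trace on the shared grid, and
#' compute the EMD to every experimental histogram. Models are ranked by
#' their mean EMD to the experimental set; inter-experimental EMDs and a
#' classical MDS embedding of the pooled distance matrix are returned for
#' context.
#'
#' @param experimental List of `amp_hist` objects (or `sc_trace`s, which are
#'   histogrammed with `normalize_by`).
#' @param models Named list; each element is either a single `gating_model`
#'   (one simulation compared to every experimental histogram) or a list of
#'   per-record `gating_model`s (rates fitted/derived per channel, as in
#'   per-record model comparison: one simulation per experimental record,
#'   paired EMDs).
#' @param voltage Holding potential (mV) for the model simulations.
#' @param normalize_by Full-open current (pA) shared by all histograms.
#' @param modes Simulation chain mode per model; defaults to
#'   `"fast_gating"` for models named/preset `fast_gating`, else
#'   `"standard"`.
#' @param noise_sd Baseline noise SD (pA) for the simulations.
#' @param tol,chunk,max_chunks Stationarity settings; see
#'   [simulate_to_stationarity()]. With the default `weighting =
#'   "stationary"` a single `chunk`-long simulation is used per model.
#' @param region Optional amplitude window `c(lo, hi)` on the normalized
#'   axis: distances are then computed between the histograms renormalized
#'   to this window. `c(0.15, 0.95)` compares the sublevel-structure region
#'   only (excluding the closed and full-open peaks), the part of the
#'   amplitude distribution in which merged-substate, explicit-substate and
#'   fast-flicker schemes actually differ; `NULL` (default) compares the
#'   full all-points distributions.
#' @param weighting `"stationary"` (default): model histograms are built by
#'   mixing the simulated class-conditional amplitude distributions with
#'   the model's exact stationary class occupancies — a variance-reduced
#'   estimator of the stationary amplitude distribution whose occupancy
#'   weights carry no sampling noise, so model rankings reflect amplitude
#'   structure rather than which simulation happened to draw an active or
#'   quiet window. `"empirical"`: plain all-points histograms of
#'   stationarity-converged simulations.
#' @param seed Integer seed.
#' @param ... Passed on to [acquisition_chain()] (e.g. `fs_sim`).
#' @return A `discrimination_report`: list with `ranking` (tibble: model,
#'   mean/min/max EMD to experiments, rank), `emd` (pooled `emd_matrix`),
#'   `inter_experimental` (mean off-diagonal experimental EMD) and `mds`.
#' @export
model_discrimination_report <- function(experimental, models,
                                        voltage = 30, normalize_by = NULL,
                                        modes = NULL, noise_sd = NULL,
                                        tol = 0.02, chunk = 5, max_chunks = 20,
                                        region = NULL,
                                        weighting = c("stationary", "empirical"),
                                        seed = NULL, ...) {
  weighting <- match.arg(weighting)
  dist_fun <- function(h1, h2) {
    if (is.null(region)) return(emd_1d(h1, h2))
    g <- attr(h1, "grid")
    w <- diff(g)
    keep <- h1$mid > region[1] & h1$mid < region[2]
    p1 <- (h1$density * w)[keep]
    p2 <- (h2$density * w)[keep]
    if (sum(p1) <= 0 || sum(p2) <= 0)
      stop_bad("no histogram mass inside the comparison region")
    sum(abs(cumsum(p1 / sum(p1) - p2 / sum(p2))) * w[keep])
  }
  stopifnot(length(experimental) >= 1, length(models) >= 1)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, character(1))
  normalize_by <- normalize_by %||% (199 * voltage * 1e-3)
  grid <- default_amp_grid()
  exp_hists <- purrr::imap(experimental, function(e, i) {
    if (inherits(e, "amp_hist")) e
    else amplitude_histogram(e, grid = grid, normalize_by = normalize_by,
                             source = paste0("exp", i))
  })
  names(exp_hists) <- paste0("exp", seq_along(exp_hists))
  ne <- length(exp_hists)
  sim_hist <- function(m, nm, j) {
    md <- if (!is.null(modes)) modes[[nm]] else
      if (grepl("fast", m$name)) "fast_gating" else "standard"
    sseed <- child_seed(seed, 97L * match(nm, names(models)) + j)
    if (weighting == "empirical") {
      tr <- simulate_to_stationarity(m, voltage = voltage, chunk = chunk,
                                     tol = tol, max_chunks = max_chunks,
                                     mode = md, noise_sd = noise_sd,
                                     seed = sseed, ...)
      return(amplitude_histogram(tr, grid = grid,
                                 normalize_by = normalize_by, source = nm))
    }
    p <- sample_path(m, chunk, seed = sseed)
    tr <- acquisition_chain(p, m, voltage = voltage, mode = md,
                            noise_sd = noise_sd,
                            seed = child_seed(sseed, 3L), ...)
    # simulated class-conditional shapes mixed with exact stationary weights
    cls <- p$class[findInterval(trace_time(tr), p$start)]
    po <- class_po(m)
    w <- diff(grid)
    dens <- numeric(length(w))
    for (ci in seq_len(nrow(po))) {
      sel <- cls == po$class[ci]
      if (!any(sel)) next
      z <- tr$current[sel] / normalize_by
      z <- pmin(pmax(z, grid[1] + 1e-12), grid[length(grid)] - 1e-12)
      cnt <- graphics::hist(z, breaks = grid, plot = FALSE, right = FALSE)$counts
      dens <- dens + po$po[ci] * cnt / sum(cnt) / w
    }
    dens <- dens / sum(dens * w)
    structure(
      tibble::tibble(bin_lo = head(grid, -1), bin_hi = grid[-1],
                     mid = (head(grid, -1) + grid[-1]) / 2, density = dens),
      grid = grid, n_samples = nrow(tr), source = nm,
      normalize_by = normalize_by,
      class = c("amp_hist", class(tibble::tibble())))
  }
  mod_hists <- list()
  dists <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "gating_model")) {
      h <- sim_hist(m, nm, 0L)
      mod_hists[[nm]] <- h
      dists[[nm]] <- vapply(exp_hists, dist_fun, numeric(1), h1 = h)
    } else {
      stopifnot(length(m) == ne)
      ds <- numeric(ne)
      for (j in seq_len(ne)) {
        h <- sim_hist(m[[j]], nm, j)
        mod_hists[[paste0(nm, ".", j)]] <- h
        ds[j] <- dist_fun(exp_hists[[j]], h)
      }
      dists[[nm]] <- ds
    }
  }
  all_h <- c(exp_hists, mod_hists)
  dm <- emd_matrix(all_h, labels = names(all_h))
  ranking <- purrr::map_dfr(names(models), function(nm) {
    ds <- dists[[nm]]
    tibble::tibble(model = nm, mean_emd = mean(ds), min_emd = min(ds),
                   max_emd = max(ds))
  }) |>
    dplyr::arrange(.data$mean_emd) |>
    dplyr::mutate(rank = dplyr::row_number())
  inter <- if (ne > 1) mean(dm[seq_len(ne), seq_len(ne)][upper.tri(diag(ne))]) else NA_real_
  structure(
    list(ranking = ranking, emd = dm, inter_experimental = inter,
         mds = if (nrow(dm) >= 3) mds_embed(dm) else NULL),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("<discrimination_report>\n")
  print(x$ranking)
  if (is.finite(x$inter_experimental %||% NA))
    cat("mean inter-experimental EMD:", format(x$inter_experimental), "\n")
  invisible(x)
}

#' Write a distance matrix or embedding as a tab-separated table
#'
#' @param x An `emd_matrix` or `mds_embedding`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(x, path) {
  if (inherits(x, "emd_matrix")) {
    df <- as.data.frame(unclass(x))
    df <- cbind(label = rownames(x), df)
    readr::write_tsv(tibble::as_tibble(df), path)
  } else {
    readr::write_tsv(tibble::as_tibble(x), path)
  }
  invisible(path)
}
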