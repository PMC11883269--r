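#' Run an ensemble of independent model simulations
#'
#' Trajectory k uses seed `base_seed + k - 1`, so an ensemble is
#' reproducible bit-for-bit from `base_seed`. By default trajectories are
#' recorded on an (approximately) hourly grid rather than the full `dt`
#' grid, which keeps a 1000-run ensemble at the default horizon to a few
#' megabytes; pass `record_every = 1` for the full grid.
#'
#' @param params A [model_params()] object.
#' @param n_sims Number of simulations (the reference analysis uses 1000).
#' @param base_seed Integer seed of the first trajectory.
#' @param record_every Steps between records; default ~1 h of model time.
#' @return A `lineage_ensemble`: list of `lineage_trajectory` objects.
#' @export
run_ensemble <- function(params, n_sims = 1000, base_seed = 1,
                         record_every = NULL) {
  validate_model_params(params)
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (is.null(record_every))
    record_every <- max(1L, as.integer(round(1 / params$dt)))
  sims <- lapply(seq_len(n_sims), function(k) {
    tryCatch(
      simulate_trajectory(params, seed = base_seed + k - 1,
                          record_every = record_every),
      error = function(e) stop(sprintf("simulation with seed %d failed: %s",
                                       base_seed + k - 1, conditionMessage(e)),
                               call. = FALSE))
  })
  structure(sims, class = "lineage_ensemble")
}

#' Rank-sort and average an ensemble of trajectories
#'
#' Reproduces the reference post-processing: within each simulation the
#' per-lineage cell-number curves are sorted by their final total
#' (inner + outer) cell number, in decreasing order; curves of equal rank
#' are then averaged across simulations, with pointwise standard deviations.
#' Rank 1 is the emergent MPC-like lineage.
#'
#' @param ensemble A `lineage_ensemble` (or plain list of trajectories) on a
#'   common time grid.
#' @return An `ensemble_summary`: list with `times`, rank x time matrices
#'   `mean_total_by_rank`, `sd_total_by_rank`, `mean_inner_by_rank`,
#'   `mean_outer_by_rank`, `n_sims` and `seeds`.
#' @export
rank_sort_average <- function(ensemble) {
  if (length(ensemble) == 0) stop("ensemble is empty")
  times <- ensemble[[1]]$times
  for (tr in ensemble)
    if (!isTRUE(all.equal(tr$times, times)))
      stop("trajectories must share a common time grid")
  n <- ncol(ensemble[[1]]$outer)
  nt <- length(times)
  acc <- function() array(0, dim = c(length(ensemble), n, nt))
  tot <- acc(); inn <- acc(); out <- acc()
  for (s in seq_along(ensemble)) {
    tr <- ensemble[[s]]
    ord <- order(final_totals(tr), decreasing = TRUE)
    tot[s, , ] <- t(tr$outer[, ord] + tr$inner[, ord])
    inn[s, , ] <- t(tr$inner[, ord])
    out[s, , ] <- t(tr$outer[, ord])
  }
  mean_rank <- function(a) apply(a, c(2, 3), mean)
  sd_rank <- function(a) {
    if (dim(a)[1] < 2) return(matrix(0, n, nt))
    apply(a, c(2, 3), sd)
  }
  structure(list(
    times = times,
    mean_total_by_rank = mean_rank(tot),
    sd_total_by_rank = sd_rank(tot),
    mean_inner_by_rank = mean_rank(inn),
    mean_outer_by_rank = mean_rank(out),
    n_sims = length(ensemble),
    seeds = vapply(ensemble, function(tr) tr$seed, integer(1))
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  fin <- x$mean_total_by_rank[, length(x$times)]
  cat(sprintf("<ensemble_summary> %d sims, %d ranks, t in [0, %g] h\n",
              x$n_sims, nrow(x$mean_total_by_rank), max(x$times)))
  cat("mean final totals by rank:", paste(sprintf("%.1f", fin),
                                          collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ensemble_summary <- function(x, ...) {
  nrk <- nrow(x$mean_total_by_rank)
  nt <- length(x$times)
  data.frame(
    time_h = rep(x$times, times = nrk),
    rank = rep(seq_len(nrk), each = nt),
    mean_total = as.vector(t(x$mean_total_by_rank)),
    sd_total = as.vector(t(x$sd_total_by_rank)),
    mean_inner = as.vector(t(x$mean_inner_by_rank)),
    mean_outer = as.vector(t(x$mean_outer_by_rank))
  )
}

#' Per-simulation dominance ratio
#'
#' Ratio of the largest to the second-largest final lineage total within one
#' simulation, with the denominator floored at 1 cell to avoid division by
#' (near) zero when the runner-up lineage has collapsed.
#'
#' @param trajectory A `lineage_trajectory`.
#' @return A single number >= 0.
#' @export
dominance_ratio <- function(trajectory) {
  tot <- sort(final_totals(trajectory), decreasing = TRUE)
  tot[1] / max(tot[2], 1)
}

#' Fraction of simulations with exactly one dominant lineage
#'
#' @param ensemble A `lineage_ensemble`.
#' @param factor Dominance factor; a run counts when the largest final total
#'   is at least `factor` times the second largest.
#' @return Fraction in [0, 1].
#' @export
emergence_fraction <- function(ensemble, factor = 2) {
  mean(vapply(ensemble, function(tr) {
    tot <- sort(final_totals(tr), decreasing = TRUE)
    tot[1] >= factor * tot[2]
  }, logical(1)))
}

#' Growth-classification thresholds
#'
#' The source study separates "MPC-like" from "non-MPC-like" growth only
#' qualitatively. The package operationalises the dichotomy against the
#' uninhibited closed-form total at the horizon
#' ([uninhibited_closed_form()]): a lineage is MPC-like when its final total
#' reaches at least 50\% of that reference, non-MPC-like when it stays at or
#' below 20\%. Between the two lies a deliberate gray zone.
#'
#' @return Named list with `mpc_like` (0.5) and `non_mpc_like` (0.2).
#' @export
growth_class_thresholds <- function() {
  list(mpc_like = 0.5, non_mpc_like = 0.2)
}

#' Sweep one model parameter and measure an ensemble metric
#'
#' For each grid value the parameter is substituted into `params`, an
#' ensemble of `n_sims` trajectories is run (seeds deterministic in
#' `base_seed`), and the metric is evaluated per simulation:
#' `"dominance_ratio"` ([dominance_ratio()]), `"final_total_rank1"` (largest
#' final lineage total) or `"emergence_fraction"` (indicator that the
#' largest final total is at least twice the second).
#'
#' @param params Baseline [model_params()].
#' @param grid Named list of length 1: the parameter (`"sigma"` or
#'   `"gamma"`) mapped to a numeric vector of values.
#' @param n_sims Simulations per grid value.
#' @param metric Metric name.
#' @param base_seed Seed for the first simulation of each grid value.
#' @return A data.frame with columns `param`, `value`, `metric`,
#'   `metric_mean`, `metric_sd`, `n_sims`.
#' @export
sweep_parameters <- function(params, grid, n_sims = 100,
                             metric = c("dominance_ratio",
                                        "final_total_rank1",
                                        "emergence_fraction"),
                             base_seed = 1) {
  metric <- match.arg(metric)
  if (!is.list(grid) || length(grid) != 1 || is.null(names(grid)))
    stop("grid must be a named list of length 1")
  pname <- names(grid)
  if (!pname %in% c("sigma", "gamma"))
    stop("sweep supports parameters 'sigma' and 'gamma'")
  values <- grid[[1]]
  if (length(values) == 0) stop("empty parameter grid")
  per_sim <- function(tr) {
    switch(metric,
           dominance_ratio = dominance_ratio(tr),
           final_total_rank1 = max(final_totals(tr)),
           emergence_fraction = {
             tot <- sort(final_totals(tr), decreasing = TRUE)
             as.numeric(tot[1] >= 2 * tot[2])
           })
  }
  rows <- lapply(values, function(v) {
    p <- params
    p[[pname]] <- v
    ens <- run_ensemble(p, n_sims = n_sims, base_seed = base_seed)
    m <- vapply(ens, per_sim, numeric(1))
    data.frame(param = pname, value = v, metric = metric,
               metric_mean = mean(m), metric_sd = sd(m), n_sims = n_sims)
  })
  do.call(rbind, rows)
}

#' Plot rank-sorted mean curves with +/- 1 s.d. bands
#'
#' Rank-1 (the MPC-like lineage) is drawn with a shaded +/- 1 s.d. band;
#' the remaining ranks share a gray band spanning their s.d. envelopes.
#'
#' @param x An `ensemble_summary`.
#' @param which One of `"total"`, `"inner"`, `"outer"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ensemble_summary <- function(x, which = c("total", "inner", "outer"),
                                  ...) {
  which <- match.arg(which)
  mean_m <- switch(which, total = x$mean_total_by_rank,
                   inner = x$mean_inner_by_rank,
                   outer = x$mean_outer_by_rank)
  sd_m <- x$sd_total_by_rank
  t <- x$times
  nrk <- nrow(mean_m)
  ylim <- c(0, max(mean_m[1, ] + sd_m[1, ]) * 1.05)
  graphics::matplot(t, t(mean_m), type = "n", xlab = "time (h)",
                    ylab = sprintf("mean %s cells per lineage", which),
                    ylim = ylim, ...)
  if (nrk > 1) {
    lo <- apply(mean_m[-1, , drop = FALSE] - sd_m[-1, , drop = FALSE], 2, min)
    hi <- apply(mean_m[-1, , drop = FALSE] + sd_m[-1, , drop = FALSE], 2, max)
    graphics::polygon(c(t, rev(t)), c(pmax(lo, 0), rev(hi)), border = NA,
                      col = grDevices::adjustcolor("gray50", 0.3))
  }
  graphics::polygon(c(t, rev(t)),
                    c(pmax(mean_m[1, ] - sd_m[1, ], 0),
                      rev(mean_m[1, ] + sd_m[1, ])),
                    border = NA, col = grDevices::adjustcolor("gold", 0.4))
  cols <- c("goldenrod3", "magenta3", "red3", "blue3", "green4")
  for (k in seq_len(nrk))
    graphics::lines(t, mean_m[k, ], col = cols[(k - 1) %% length(cols) + 1],
                    lwd = if (k == 1) 2 else 1)
  invisible(x)
}
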