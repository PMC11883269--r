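#' Identify the leading lineage from marginal-cell counts
#'
#' A lineage leads when its marginal (outer) cell count exceeds the largest
#' count among all other lineages by at least `alpha`. The lead is
#' re-evaluated from the current state at every integration step, so it can
#' change over time. With `alpha = 0` an exact tie is broken in favour of
#' the lowest lineage index.
#'
#' @param outer_counts Numeric vector of per-lineage marginal-cell counts.
#' @param alpha Margin in cells, >= 0.
#' @return The 1-based index of the leading lineage, or `NA_integer_` when
#'   no lineage leads.
#' @examples
#' leading_lineage(c(10, 3, 2, 4, 1), alpha = 5)  # 1
#' leading_lineage(c(5, 5, 5, 5, 5), alpha = 1)   # NA
#' @export
leading_lineage <- function(outer_counts, alpha) {
  if (length(outer_counts) < 2)
    stop("at least two lineages are required")
  if (any(!is.finite(outer_counts)) || any(outer_counts < 0))
    stop("outer_counts must be finite and non-negative")
  if (alpha < 0) stop("alpha must be >= 0")
  mx <- which.max(outer_counts)
  if (outer_counts[mx] - max(outer_counts[-mx]) >= alpha) mx else NA_integer_
}

#' Hill-type division-rate multipliers
#'
#' The piecewise inhibition function of the model, evaluated at the current
#' marginal-cell counts. In the threshold variant nothing is inhibited until
#' one lineage leads by [leading_lineage()]'s margin; then every non-lead
#' lineage's division rate is multiplied by
#' \eqn{K^m / (K^m + O_{lead}^m)} while the lead keeps multiplier 1. In the
#' mutual variant every lineage is continuously inhibited by the marginal
#' cells of all others: \eqn{h_i = K^m / (K^m + (\sum_{j \ne i} O_j)^m)}.
#' All multipliers lie in (0, 1].
#'
#' @param outer_counts Numeric vector of per-lineage marginal-cell counts.
#' @param params A [model_params()] object.
#' @return Numeric vector of multipliers, one per lineage.
#' @examples
#' p <- model_params("mutual", K_hill = 20, m_hill = 2)
#' division_multipliers(rep(5, 5), p)  # all 0.5
#' @export
division_multipliers <- function(outer_counts, params) {
  validate_model_params(params)
  if (any(outer_counts < 0)) stop("outer_counts must be non-negative")
  n <- length(outer_counts)
  Km <- params$K_hill^params$m_hill
  if (params$version == "threshold") {
    h <- rep(1, n)
    lead <- leading_lineage(outer_counts, params$alpha)
    if (!is.na(lead)) {
      h[] <- Km / (Km + outer_counts[lead]^params$m_hill)
      h[lead] <- 1
    }
    h
  } else {
    s <- sum(outer_counts) - outer_counts
    Km / (Km + s^params$m_hill)
  }
}

#' Construct a lineage state
#'
#' @param outer,inner Non-negative per-lineage cell counts (may be
#'   non-integer; the model tracks population sizes, not individual cells).
#' @param t Time in hours.
#' @return A `lineage_state` list.
#' @export
lineage_state <- function(outer, inner, t = 0) {
  stopifnot(length(outer) == length(inner), all(outer >= 0), all(inner >= 0),
            t >= 0)
  structure(list(outer = as.numeric(outer), inner = as.numeric(inner),
                 t = as.numeric(t)), class = "lineage_state")
}

#' Deterministic drift of the lineage-competition model
#'
#' Encodes the model's division rules. Marginal (outer) cells divide at rate
#' `r` scaled by the inhibition multiplier `h`; anticlinal and periclinal
#' orientations are equally likely, so half of the outer divisions add an
#' outer cell and half push a daughter into the inner layer. Inner cells
#' divide at the reduced rate `gamma * r * h` and always add inner cells:
#' \deqn{dO_i/dt = \tfrac{1}{2} r h_i O_i, \qquad
#'       dI_i/dt = \tfrac{1}{2} r h_i O_i + \gamma r h_i I_i.}
#'
#' @param state A [lineage_state()].
#' @param multipliers Multipliers from [division_multipliers()] evaluated at
#'   the same state.
#' @param params A [model_params()] object.
#' @return A list with numeric vectors `dO` and `dI` (cells per hour).
#' @export
drift_rates <- function(state, multipliers, params) {
  h <- multipliers
  dO <- 0.5 * params$r * h * state$outer
  dI <- 0.5 * params$r * h * state$outer + params$gamma * params$r * h *
    state$inner
  list(dO = dO, dI = dI)
}

.noise_scale <- function(x, coupling) {
  switch(coupling,
         multiplicative = x,
         additive = rep(1, length(x)),
         demographic = sqrt(x))
}

#' One Euler-Maruyama step of the model
#'
#' Advances the state by `dt` hours:
#' \eqn{X \leftarrow \max(0,\; X + dt\,\mu(X) + \sigma g(X) \sqrt{dt}\, Z)}
#' where the drift comes from [drift_rates()] with multipliers re-evaluated
#' at the current state, `g` is set by `params$noise_coupling`, and `Z` are
#' the supplied standard-normal draws. Components are clamped at zero from
#' below; under multiplicative or demographic coupling an empty lineage
#' stays empty.
#'
#' @param state A [lineage_state()].
#' @param params A [model_params()] object.
#' @param noise_draws Standard-normal draws, one per state component:
#'   the `n_lineages` outer components first, then the inner components.
#' @return The updated `lineage_state` with `t` advanced by `dt`.
#' @export
em_step <- function(state, params, noise_draws) {
  n <- length(state$outer)
  if (length(noise_draws) != 2 * n)
    stop("noise_draws must have one value per state component (2 * n)")
  h <- division_multipliers(state$outer, params)
  dr <- drift_rates(state, h, params)
  sq <- sqrt(params$dt)
  zO <- noise_draws[seq_len(n)]
  zI <- noise_draws[n + seq_len(n)]
  gO <- .noise_scale(state$outer, params$noise_coupling)
  gI <- .noise_scale(state$inner, params$noise_coupling)
  O <- state$outer + params$dt * dr$dO + params$sigma * gO * sq * zO
  I <- state$inner + params$dt * dr$dI + params$sigma * gI * sq * zI
  if (any(!is.finite(O)) || any(!is.finite(I)))
    stop(sprintf("non-finite state after step at t = %g h", state$t))
  lineage_state(pmax(O, 0), pmax(I, 0), state$t + params$dt)
}

#' Simulate one stochastic trajectory of the lineage-competition model
#'
#' Starts every lineage from a single marginal cell (`O_i = 1`, `I_i = 0`)
#' at t = 0 and integrates to `params$t_end` by Euler-Maruyama, re-evaluating
#' the leading lineage and the inhibition multipliers at every step. The
#' integration loop runs in compiled code driven by R's RNG, so a trajectory
#' is fully determined by `seed`.
#'
#' @param params A [model_params()] object.
#' @param seed Integer RNG seed for this trajectory.
#' @param record_every Record every `record_every`-th step (1 = full grid).
#'   The initial and final states are always recorded.
#' @return A `lineage_trajectory`: list with `times` (hours), matrices
#'   `outer` and `inner` (time x lineage), `seed` and `params`.
#' @examples
#' tr <- simulate_trajectory(model_params("threshold"), seed = 1)
#' tail(tr$times, 1)
#' @export
simulate_trajectory <- function(params, seed, record_every = 1L) {
  validate_model_params(params)
  stopifnot(record_every >= 1)
  set.seed(as.integer(seed))
  version <- match(params$version, c("threshold", "mutual")) - 1L
  coupling <- match(params$noise_coupling,
                    c("multiplicative", "additive", "demographic")) - 1L
  res <- .sim_core(params$n_lineages, params$r, params$gamma, params$sigma,
                   params$K_hill, params$m_hill, params$alpha, version,
                   coupling, params$t_end, params$dt,
                   as.integer(record_every))
  structure(list(times = res$times, outer = res$outer, inner = res$inner,
                 seed = as.integer(seed), params = params),
            class = "lineage_trajectory")
}

#' Final per-lineage total cell numbers of a trajectory
#'
#' @param trajectory A `lineage_trajectory`.
#' @return Numeric vector of `inner + outer` counts at the final time.
#' @export
final_totals <- function(trajectory) {
  k <- nrow(trajectory$outer)
  trajectory$outer[k, ] + trajectory$inner[k, ]
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lineage_trajectory> %d lineages, t in [0, %g] h (%d records), seed %d\n",
    ncol(x$outer), max(x$times), length(x$times), x$seed))
  cat("final totals:", paste(sprintf("%.1f", final_totals(x)),
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lineage_trajectory <- function(x, ...) {
  n <- ncol(x$outer)
  data.frame(
    time_h = rep(x$times, times = n),
    lineage = rep(seq_len(n), each = length(x$times)),
    outer = as.vector(x$outer),
    inner = as.vector(x$inner)
  )
}
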