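#' Configuration for the synthetic lineage-table generator
#'
#' The generator emulates the statistical structure of the curated imaging
#' tables: five founder marginal cells imaged every 6 h for 120 h; Phase I
#' (up to `phase1_end`, default 54 h, inside the observed 48-60 h range)
#' with near-uniform stochastic division; Phase II in which one lineage (the
#' emergent MPC) keeps a high division rate while the others decay linearly
#' to mitotic inactivity over `phase2_decay_h`; inner cells dividing at
#' `gamma` times the outer-cell probability; anticlinal and periclinal outer
#' divisions equally likely; plus a few mitotically inert antheridium cells
#' that are flagged and drop out once mature.
#'
#' Division is Bernoulli per cell per frame interval (matching the imaging
#' cadence), so the `rate_*` fields are probabilities per frame, not
#' per-hour rates.
#'
#' @param n_founders Number of founder (non-antheridium) marginal cells.
#' @param phase1_end End of Phase I, hours.
#' @param rate_outer_phase1 Outer-cell division probability per frame in
#'   Phase I (all lineages).
#' @param rate_outer_phase2_mpc Outer-cell probability per frame for the MPC
#'   lineage in Phase II.
#' @param rate_outer_phase2_other Initial outer-cell probability per frame
#'   for non-MPC lineages in Phase II (decays to 0).
#' @param gamma Inner/outer probability ratio (default 0.5).
#' @param p_anticlinal Probability that an outer-cell division is anticlinal.
#' @param interval Frame interval, hours.
#' @param t_end Last frame, hours.
#' @param n_antheridia Number of antheridium cells.
#' @param antheridium_mature_h Time at which antheridia mature and drop out
#'   of the table.
#' @param phase2_decay_h Hours over which non-MPC Phase II probability
#'   decays linearly to zero; `Inf` keeps it constant.
#' @param jitter_px Daughter placement jitter, pixels.
#' @param founder_spacing_px Spacing of founder cells along the margin.
#' @param seed Integer RNG seed; the generator is fully determined by it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_founders = 5, phase1_end = 54,
                         rate_outer_phase1 = 0.15,
                         rate_outer_phase2_mpc = 0.45,
                         rate_outer_phase2_other = 0.10, gamma = 0.5,
                         p_anticlinal = 0.5, interval = 6, t_end = 120,
                         n_antheridia = 3, antheridium_mature_h = 48,
                         phase2_decay_h = 24, jitter_px = 3,
                         founder_spacing_px = 40, seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$rate_outer_phase1, cfg$rate_outer_phase2_mpc,
             cfg$rate_outer_phase2_other, cfg$gamma, cfg$p_anticlinal)
  if (any(probs < 0) || any(probs > 1))
    stop("rates, gamma and p_anticlinal must be probabilities in [0, 1]")
  if (cfg$phase1_end >= cfg$t_end) stop("phase1_end must be < t_end")
  if (cfg$interval <= 0 || cfg$t_end %% cfg$interval != 0)
    stop("t_end must be a positive multiple of interval")
  if (cfg$n_founders < 1) stop("n_founders must be >= 1")
  structure(cfg, class = "synth_config")
}

.outer_rate <- function(cfg, lineage, mpc, window_start) {
  if (window_start < cfg$phase1_end) return(cfg$rate_outer_phase1)
  if (identical(lineage, mpc)) return(cfg$rate_outer_phase2_mpc)
  if (is.infinite(cfg$phase2_decay_h)) return(cfg$rate_outer_phase2_other)
  decay <- max(0, 1 - (window_start - cfg$phase1_end) / cfg$phase2_decay_h)
  cfg$rate_outer_phase2_other * decay
}

#' Generate a synthetic lineage table with its ground-truth ledger
#'
#' Runs the discrete-time branching process described in [synth_config()].
#' The MPC lineage is designated at the end of Phase I as the lineage with
#' the most cells (ties to the lowest founder index), mirroring the
#' stochastic emergence of the real progenitor. All ground-truth quantities
#' are book-kept during generation, independently of the analysis
#' functions, so they can serve as an exact oracle: the division-event
#' ledger, per-lineage per-time cell counts, the MPC lineage id, and
#' per-root progeny division totals for the cells present at `phase1_end`
#' over the following 60 h (or until `t_end` if sooner).
#'
#' @param cfg A [synth_config()].
#' @return List with `table` (a [lineage_table()]) and `truth` (list:
#'   `events`, `counts`, `mpc_lineage`, `progeny` with `start_t`,
#'   `duration`, `totals`, `root_layer`).
#' @export
generate_lineage_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(cfg$seed))
  times <- seq(0, cfg$t_end, by = cfg$interval)
  lineages <- paste0("L", seq_len(cfg$n_founders))

  next_id <- 0L
  new_id <- function(k = 1L) {
    ids <- sprintf("c%05d", next_id + seq_len(k))
    next_id <<- next_id + k
    ids
  }
  live <- data.frame(
    id = new_id(cfg$n_founders),
    lineage = lineages,
    layer = "outer",
    x = 20 + (seq_len(cfg$n_founders) - 1) * cfg$founder_spacing_px,
    y = 25,
    antheridium = FALSE,
    parent = NA_character_,
    stringsAsFactors = FALSE)
  if (cfg$n_antheridia > 0) {
    anth <- data.frame(
      id = new_id(cfg$n_antheridia),
      lineage = paste0("A", seq_len(cfg$n_antheridia)),
      layer = "inner",
      x = 30 + (seq_len(cfg$n_antheridia) - 1) * cfg$founder_spacing_px,
      y = 70,
      antheridium = TRUE,
      parent = NA_character_,
      stringsAsFactors = FALSE)
    live <- rbind(live, anth)
  }

  counts <- matrix(0L, cfg$n_founders, length(times),
                   dimnames = list(lineages, times))
  events <- list()
  mpc <- NA_character_
  progeny_start <- cfg$phase1_end
  progeny_dur <- min(60, cfg$t_end - cfg$phase1_end)
  owner <- character(0)   # nucleus id -> progeny root id
  root_layer <- character(0)
  progeny_totals <- integer(0)

  records <- list()
  emit <- function(t) {
    keep <- !(live$antheridium & t >= cfg$antheridium_mature_h)
    lv <- live[keep, ]
    records[[length(records) + 1L]] <<- data.frame(
      nucleus_id = lv$id, time_h = t, x_px = lv$x, y_px = lv$y,
      lineage_id = lv$lineage, layer = lv$layer,
      is_antheridium = lv$antheridium, parent_id = lv$parent,
      stringsAsFactors = FALSE)
    non_a <- lv[!lv$antheridium, ]
    tc <- table(non_a$lineage)
    counts[names(tc), as.character(t)] <<- as.integer(tc)
  }
  emit(0)

  for (t in times[-1]) {
    ws <- t - cfg$interval
    if (is.na(mpc) && ws >= cfg$phase1_end) {
      prev <- counts[, as.character(ws)]
      mpc <- lineages[which.max(prev)]
    }
    if (ws == progeny_start) {
      roots <- live$id[!live$antheridium]
      owner <- stats::setNames(roots, roots)
      root_layer <- stats::setNames(live$layer[!live$antheridium], roots)
      progeny_totals <- stats::setNames(integer(length(roots)), roots)
    }
    live$parent <- NA_character_
    can_divide <- !live$antheridium
    p <- vapply(seq_len(nrow(live)), function(i) {
      if (!can_divide[i]) return(0)
      po <- .outer_rate(cfg, live$lineage[i], mpc, ws)
      if (live$layer[i] == "outer") po else cfg$gamma * po
    }, numeric(1))
    divides <- stats::runif(nrow(live)) < p
    while (any(divides)) {
      i <- which(divides)[1]
      parent <- live[i, ]
      ids <- new_id(2L)
      if (parent$layer == "outer") {
        anticlinal <- stats::runif(1) < cfg$p_anticlinal
        layers <- if (anticlinal) c("outer", "outer") else c("outer", "inner")
        orient <- if (anticlinal) "anticlinal" else "periclinal"
      } else {
        layers <- c("inner", "inner")
        orient <- "inner"
      }
      daughters <- data.frame(
        id = ids, lineage = parent$lineage, layer = layers,
        x = pmax(0, parent$x + stats::runif(2, -cfg$jitter_px,
                                            cfg$jitter_px)),
        y = pmax(0, parent$y + stats::runif(2, -cfg$jitter_px,
                                            cfg$jitter_px)),
        antheridium = FALSE, parent = parent$id,
        stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- data.frame(
        parent_id = parent$id, daughter1 = ids[1], daughter2 = ids[2],
        lineage_id = parent$lineage, t_start = ws, t_end = t,
        parent_layer = parent$layer, orientation = orient,
        stringsAsFactors = FALSE)
      if (length(owner) && !is.na(owner[parent$id]) &&
          t > progeny_start && t <= progeny_start + progeny_dur) {
        rt <- owner[[parent$id]]
        progeny_totals[rt] <- progeny_totals[rt] + 1L
        owner[ids] <- rt
      }
      # dividing parent is replaced by its two daughters (appended, with
      # division flags FALSE so daughters cannot re-divide this frame)
      live <- rbind(live[-i, ], daughters)
      divides <- c(divides[-i], FALSE, FALSE)
    }
    emit(t)
  }

  events <- if (length(events)) do.call(rbind, events) else NULL
  tab <- lineage_table(do.call(rbind, records), interval = cfg$interval)
  list(table = tab,
       truth = list(events = events, counts = counts, mpc_lineage = mpc,
                    progeny = list(start_t = progeny_start,
                                   duration = progeny_dur,
                                   totals = progeny_totals,
                                   root_layer = root_layer)))
}

#' Render a lineage table as a series of synthetic nuclei images
#'
#' One frame per time point; every nucleus becomes an isotropic Gaussian
#' spot of the given amplitude at its `(x_px, y_px)` position, on a
#' background of additive Gaussian noise. The returned ground-truth centre
#' list makes the series usable as a segmentation benchmark.
#'
#' @param tab A [lineage_table()].
#' @param spot_sigma Spot standard deviation, pixels.
#' @param noise_sd Background noise standard deviation (intensity units).
#' @param amplitude Peak spot intensity.
#' @param shape Frame dimensions `c(rows, cols)`; default grows to fit all
#'   positions plus a margin. Positions outside `shape` raise an error.
#' @param seed RNG seed for the noise.
#' @return List with `frames` (list of matrices, named by time) and
#'   `centers` (data.frame `time_h`, `nucleus_id`, `x`, `y`).
#' @export
generate_nuclei_series <- function(tab, spot_sigma = 2, noise_sd = 2,
                                   amplitude = 100, shape = NULL, seed = 1) {
  rec <- tab$records
  margin <- ceiling(4 * spot_sigma) + 2
  if (is.null(shape))
    shape <- c(ceiling(max(rec$y_px)) + margin + 1,
               ceiling(max(rec$x_px)) + margin + 1)
  if (any(rec$x_px < 0) || any(rec$y_px < 0) ||
      any(rec$x_px > shape[2] - 1) || any(rec$y_px > shape[1] - 1))
    stop("nucleus positions fall outside the frame shape")
  set.seed(as.integer(seed))
  rad <- ceiling(4 * spot_sigma)
  frames <- lapply(tab$time_points, function(t) {
    fr <- matrix(if (noise_sd > 0) stats::rnorm(prod(shape), 0, noise_sd)
                 else 0, shape[1], shape[2])
    at_t <- rec[rec$time_h == t, ]
    for (k in seq_len(nrow(at_t))) {
      cx <- at_t$x_px[k]
      cy <- at_t$y_px[k]
      ri <- max(1, floor(cy + 1 - rad)):min(shape[1], ceiling(cy + 1 + rad))
      ci <- max(1, floor(cx + 1 - rad)):min(shape[2], ceiling(cx + 1 + rad))
      spot <- amplitude *
        exp(-(outer((ri - 1 - cy)^2, (ci - 1 - cx)^2, "+")) /
              (2 * spot_sigma^2))
      fr[ri, ci] <- fr[ri, ci] + spot
    }
    fr
  })
  names(frames) <- tab$time_points
  list(frames = frames,
       centers = data.frame(time_h = rec$time_h, nucleus_id = rec$nucleus_id,
                            x = rec$x_px, y = rec$y_px))
}
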