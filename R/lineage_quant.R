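#' Cell numbers per lineage over time
#'
#' Counts non-antheridium records per lineage at every time point,
#' reproducing the per-lineage cell-number curves used to identify the MPC
#' lineage (the one lineage whose count keeps rising through Phase II).
#'
#' @param tab A [lineage_table()].
#' @param lineage_ids Lineages to include; default all, in first-appearance
#'   order. Unknown ids raise an error.
#' @return An integer matrix, lineages x time points (dimnames set).
#' @export
cells_per_lineage <- function(tab, lineage_ids = NULL) {
  rec <- tab$records[!tab$records$is_antheridium, ]
  all_ids <- unique(tab$records$lineage_id[!tab$records$is_antheridium])
  if (is.null(lineage_ids)) lineage_ids <- all_ids
  unknown <- setdiff(lineage_ids, all_ids)
  if (length(unknown))
    stop("unknown lineage id(s): ", paste(unknown, collapse = ", "))
  tp <- tab$time_points
  counts <- matrix(0L, nrow = length(lineage_ids), ncol = length(tp),
                   dimnames = list(lineage_ids, tp))
  t_idx <- match(rec$time_h, tp)
  l_idx <- match(rec$lineage_id, lineage_ids)
  keep <- !is.na(l_idx)
  for (k in which(keep))
    counts[l_idx[k], t_idx[k]] <- counts[l_idx[k], t_idx[k]] + 1L
  counts
}

#' Divided / undivided labels per time window
#'
#' Labels every non-antheridium nucleus alive during each window of
#' `window_h` hours as `divided` when a division event with it as parent
#' falls inside the window (window `(start, start + window_h]`), mirroring
#' the two-colour division maps built from 12 h frames.
#'
#' @param tab A [lineage_table()].
#' @param window_h Window length in hours; must be a positive multiple of
#'   the table's frame interval.
#' @return A data.frame with columns `nucleus_id`, `lineage_id`,
#'   `window_start`, `window_end`, `divided` (logical).
#' @export
divisions_per_window <- function(tab, window_h = 12) {
  if (window_h <= 0 || abs(window_h / tab$interval -
                           round(window_h / tab$interval)) > 1e-9)
    stop(sprintf("window_h (%g) must be a positive multiple of the %g h frame interval",
                 window_h, tab$interval))
  ev <- division_events(tab)
  rec <- tab$records[!tab$records$is_antheridium, ]
  t0 <- min(tab$time_points)
  t_max <- max(tab$time_points)
  starts <- seq(t0, t_max - window_h, by = window_h)
  if (t_max - t0 < window_h) stop("table spans less than one window")
  out <- lapply(starts, function(ws) {
    we <- ws + window_h
    # alive during [ws, we): present at a frame in that span
    alive <- rec[rec$time_h >= ws & rec$time_h < we, ]
    ids <- alive[!duplicated(alive$nucleus_id),
                 c("nucleus_id", "lineage_id")]
    div_parents <- ev$parent_id[ev$t_end > ws & ev$t_end <= we]
    data.frame(nucleus_id = ids$nucleus_id, lineage_id = ids$lineage_id,
               window_start = ws, window_end = we,
               divided = ids$nucleus_id %in% div_parents)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Total division events of cells and all their progeny
#'
#' For each root nucleus present at `start_t`, counts every division event
#' whose parent is the root or any of its descendants and whose window ends
#' within `(start_t, start_t + duration]`. Daughters born inside the window
#' join the root's subtree, so later divisions by them are counted too.
#' This is the per-cell statistic behind the layer comparison (marginal
#' cells averaging about twice the division events of inner cells over a
#' 60 h window).
#'
#' @param tab A [lineage_table()].
#' @param start_t Window start, hours; roots must be present then.
#' @param duration Window length, hours (default 60).
#' @param roots Character vector of root nucleus ids; default all
#'   non-antheridium nuclei present at `start_t`.
#' @return Named integer vector of total division events per root.
#' @export
progeny_division_totals <- function(tab, start_t, duration = 60,
                                    roots = NULL) {
  rec <- tab$records
  at_start <- rec$nucleus_id[rec$time_h == start_t & !rec$is_antheridium]
  if (is.null(roots)) roots <- at_start
  absent <- setdiff(roots, at_start)
  if (length(absent))
    stop("root(s) not present at start_t: ", paste(absent, collapse = ", "))
  ev <- division_events(tab)
  ev <- ev[ev$t_end > start_t & ev$t_end <= start_t + duration, ]
  ev <- ev[order(ev$t_end), ]
  owner <- stats::setNames(roots, roots)  # nucleus id -> root id
  totals <- stats::setNames(integer(length(roots)), roots)
  for (k in seq_len(nrow(ev))) {
    root <- owner[ev$parent_id[k]]
    if (!is.na(root)) {
      totals[root] <- totals[root] + 1L
      owner[ev$daughter1[k]] <- root
      owner[ev$daughter2[k]] <- root
    }
  }
  totals
}

#' Welch's unequal-variance t-test
#'
#' Implemented from the closed form: \eqn{t = (\bar x - \bar y) /
#' \sqrt{s_x^2/n_x + s_y^2/n_y}} with Welch-Satterthwaite degrees of
#' freedom and a two-tailed p-value from the t distribution. Errors when
#' both sample variances are zero (the statistic is degenerate).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `mean_x`, `mean_y`, `t`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))$t  # -3.674
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two observations")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0)
    stop("degenerate test: both group variances are zero")
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(mean_x = mean(x), mean_y = mean(y), t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Compare division activity between the outermost and inner layers
#'
#' Welch's two-tailed t-test on per-cell progeny division totals
#' (see [progeny_division_totals()]) of outer-layer versus inner-layer
#' roots. The source analysis reports means of 8.1 (outermost, n = 24)
#' versus 3.9 (inner, n = 14) over 60 h, P < 0.0001.
#'
#' @param outer_totals,inner_totals Numeric vectors of per-root division
#'   totals for outermost-layer and inner-layer cells.
#' @return List with `mean_outer`, `mean_inner`, `t`, `df`, `p_two_tailed`.
#' @export
compare_layer_divisions <- function(outer_totals, inner_totals) {
  w <- welch_t_test(outer_totals, inner_totals)
  list(mean_outer = w$mean_x, mean_inner = w$mean_y, t = w$t, df = w$df,
       p_two_tailed = w$p_value)
}

#' Anticlinal versus periclinal division frequencies
#'
#' Collects division events whose parent sat in the outermost (marginal)
#' layer, classifies them from the daughters' layers (both outer =
#' anticlinal, mixed = periclinal; inner-cell divisions are excluded), and
#' tests the anticlinal fraction against 0.5 with an exact two-sided
#' binomial test — the model's equal-likelihood rule.
#'
#' @param tab A [lineage_table()].
#' @param lineage_ids Restrict to these lineages; default all.
#' @return List with `n_anticlinal`, `n_periclinal`, `p_binomial`.
#' @export
orientation_summary <- function(tab, lineage_ids = NULL) {
  ev <- division_events(tab)
  if (!is.null(lineage_ids)) ev <- ev[ev$lineage_id %in% lineage_ids, ]
  ev <- ev[ev$parent_layer == "outer" &
             ev$orientation %in% c("anticlinal", "periclinal"), ]
  if (nrow(ev) == 0)
    stop("degenerate test: no classifiable marginal-layer division events")
  n_a <- sum(ev$orientation == "anticlinal")
  n_p <- sum(ev$orientation == "periclinal")
  list(n_anticlinal = n_a, n_periclinal = n_p,
       p_binomial = stats::binom.test(n_a, n_a + n_p, 0.5)$p.value)
}
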