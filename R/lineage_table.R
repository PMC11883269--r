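#' Construct a cell-lineage tracking table
#'
#' The container for per-nucleus, per-time tracking records as produced by
#' manual curation of time-lapse imaging (or by
#' [generate_lineage_table()]). `records` must hold the columns
#' `nucleus_id`, `time_h`, `x_px`, `y_px`, `lineage_id`, `layer`
#' (`"outer"` or `"inner"`), `is_antheridium` (logical) and `parent_id`
#' (`NA` except on the first record of a daughter after a division; both
#' daughters of a division carry the parent's id at the same time point).
#' Coordinates are 0-based pixels (x = column, y = row).
#'
#' @param records A data.frame with the columns above.
#' @param interval Hours between frames (typically 6 or 12). Inferred from
#'   the time points when `NULL`.
#' @return A validated `lineage_table`: list with `records`, sorted
#'   `time_points` and `interval`.
#' @export
lineage_table <- function(records, interval = NULL) {
  tab <- structure(list(records = records,
                        time_points = sort(unique(records$time_h)),
                        interval = interval),
                   class = "lineage_table")
  if (is.null(interval)) {
    d <- diff(tab$time_points)
    tab$interval <- if (length(d)) d[1] else NA_real_
  }
  validate_lineage_table(tab)
  tab
}

#' Validate a lineage table, reporting offending rows
#'
#' Checks the documented invariants: required columns, evenly spaced time
#' points at `interval`, unique `(nucleus_id, time_h)` pairs, layer labels,
#' parents present (as non-divided nuclei) at the preceding time point, and
#' divisions producing exactly two daughters. Violations raise an error
#' listing the offending row numbers of `records`.
#'
#' @param tab A `lineage_table`.
#' @return `tab`, invisibly, when valid.
#' @export
validate_lineage_table <- function(tab) {
  req <- c("nucleus_id", "time_h", "x_px", "y_px", "lineage_id", "layer",
           "is_antheridium", "parent_id")
  miss <- setdiff(req, names(tab$records))
  if (length(miss))
    stop("lineage table is missing column(s): ", paste(miss, collapse = ", "))
  rec <- tab$records
  if (nrow(rec) == 0) stop("lineage table has no records")
  tp <- tab$time_points
  if (length(tp) > 1) {
    d <- diff(tp)
    if (any(abs(d - tab$interval) > 1e-9))
      stop(sprintf("time points are not evenly spaced at interval %g h",
                   tab$interval))
  }
  dup <- duplicated(rec[c("nucleus_id", "time_h")])
  if (any(dup))
    stop("duplicate (nucleus_id, time_h) records at row(s): ",
         paste(which(dup), collapse = ", "))
  bad_layer <- !(rec$layer %in% c("outer", "inner"))
  if (any(bad_layer))
    stop("invalid layer (must be 'outer' or 'inner') at row(s): ",
         paste(which(bad_layer), collapse = ", "))
  # a parent must exist at the preceding frame
  has_parent <- which(!is.na(rec$parent_id) & rec$parent_id != "")
  if (length(has_parent)) {
    prev_t <- rec$time_h[has_parent] - tab$interval
    key <- paste(rec$nucleus_id, rec$time_h)
    orphan <- !(paste(rec$parent_id[has_parent], prev_t) %in% key)
    if (any(orphan))
      stop("parent_id absent at the preceding time point at row(s): ",
           paste(has_parent[orphan], collapse = ", "))
    n_daughters <- table(paste(rec$parent_id[has_parent],
                               rec$time_h[has_parent]))
    if (any(n_daughters != 2))
      stop("division(s) without exactly two daughters: ",
           paste(names(n_daughters)[n_daughters != 2], collapse = "; "))
  }
  invisible(tab)
}

#' @export
print.lineage_table <- function(x, ...) {
  cat(sprintf(
    "<lineage_table> %d records, %d nuclei, %d lineages, t in [%g, %g] h every %g h\n",
    nrow(x$records), length(unique(x$records$nucleus_id)),
    length(unique(x$records$lineage_id)), min(x$time_points),
    max(x$time_points), x$interval))
  invisible(x)
}

#' Extract division events from a lineage table
#'
#' A division is recognised from annotation (two records sharing a
#' `parent_id` at the same time point), never inferred from positions. Each
#' event is assigned the window `(t - interval, t]` in which it occurred and
#' classified from its daughters' layers: both outer = `"anticlinal"`, one
#' outer and one inner = `"periclinal"`, both inner = `"inner"` (an
#' inner-cell division, excluded from the marginal-orientation test).
#' Events any of whose daughters is antheridium-flagged are dropped.
#'
#' @param tab A `lineage_table`.
#' @return A data.frame with columns `parent_id`, `daughter1`, `daughter2`,
#'   `lineage_id`, `t_start`, `t_end`, `parent_layer`, `orientation`.
#' @export
division_events <- function(tab) {
  rec <- tab$records
  idx <- which(!is.na(rec$parent_id) & rec$parent_id != "" &
                 !rec$is_antheridium)
  cols <- c("parent_id", "daughter1", "daughter2", "lineage_id", "t_start",
            "t_end", "parent_layer", "orientation")
  if (!length(idx)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  d <- rec[idx, ]
  key <- paste(d$parent_id, d$time_h)
  sp <- split(seq_len(nrow(d)), key)
  parent_key <- paste(rec$nucleus_id, rec$time_h)
  rows <- lapply(sp, function(ii) {
    dd <- d[ii, ]
    layers <- sort(dd$layer)
    orientation <- if (identical(layers, c("outer", "outer"))) {
      "anticlinal"
    } else if (identical(layers, c("inner", "outer"))) {
      "periclinal"
    } else if (identical(layers, c("inner", "inner"))) {
      "inner"
    } else {
      "unknown"
    }
    pl <- rec$layer[match(paste(dd$parent_id[1], dd$time_h[1] - tab$interval),
                          parent_key)]
    data.frame(parent_id = dd$parent_id[1], daughter1 = dd$nucleus_id[1],
               daughter2 = dd$nucleus_id[2], lineage_id = dd$lineage_id[1],
               t_start = dd$time_h[1] - tab$interval, t_end = dd$time_h[1],
               parent_layer = if (is.na(pl)) "unknown" else pl,
               orientation = orientation)
  })
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev[order(ev$t_end, ev$parent_id), ]
}
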