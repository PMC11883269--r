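#' Read a lineage-tracking table from delimited text
#'
#' Expects a comma-separated UTF-8 file with header columns exactly
#' `nucleus_id,time_h,x_px,y_px,lineage_id,layer,is_antheridium,parent_id`
#' (a missing `parent_id` is encoded as an empty field). The table is
#' validated on read; invariant violations are reported with the offending
#' data-row numbers.
#'
#' @param path Path to the CSV file.
#' @param interval Frame interval in hours; inferred when `NULL`.
#' @return A [lineage_table()].
#' @export
read_lineage_table <- function(path, interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("nucleus_id", "time_h", "x_px", "y_px", "lineage_id", "layer",
           "is_antheridium", "parent_id")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (cl in c("time_h", "x_px", "y_px")) rec[[cl]] <- as.numeric(rec[[cl]])
  rec$is_antheridium <- as.logical(toupper(rec$is_antheridium))
  rec$parent_id[!is.na(rec$parent_id) & rec$parent_id == ""] <- NA_character_
  lineage_table(rec, interval = interval)
}

#' Write a lineage table as delimited text
#'
#' Inverse of [read_lineage_table()]: comma-separated, UTF-8, missing
#' `parent_id` as the empty field, rows ordered by time then nucleus id, so
#' re-writing an identical table is byte-identical.
#'
#' @param tab A [lineage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(tab, path) {
  rec <- tab$records[order(tab$records$time_h, tab$records$nucleus_id), ]
  rec$parent_id[is.na(rec$parent_id)] <- ""
  rec$is_antheridium <- tolower(as.character(rec$is_antheridium))
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis object as delimited text
#'
#' Methods exist for `ensemble_summary` (columns `time_h`, `rank`,
#' `mean_total`, `sd_total`, `mean_inner`, `mean_outer`, ordered by rank
#' then time) and plain data.frames (detections, quantification tables),
#' written with deterministic row order so identical objects produce
#' byte-identical files. An empty detection set yields a header-only file.
#'
#' @param x Object to write.
#' @param path Output path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @rdname write_results
#' @export
write_results.ensemble_summary <- function(x, path, ...) {
  df <- as.data.frame(x)
  df <- df[order(df$rank, df$time_h),
           c("time_h", "rank", "mean_total", "sd_total", "mean_inner",
             "mean_outer")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.data.frame <- function(x, path, ...) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a grayscale image as ASCII PGM (P2)
#'
#' Plain-text portable graymap is the package's on-disk image format (no
#' TIFF reader is available in the supported dependency set; see the
#' vignette). Intensities are rounded and clipped to `[0, maxval]` on
#' write.
#'
#' @param path File path.
#' @return `read_pgm`: a numeric matrix.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  nc <- as.integer(tok[2])
  nr <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img Numeric matrix.
#' @param maxval Maximum gray value.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  v <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}
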