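# Packaged calibration tables and calibration-table serialization.
#
# The packaged tables transcribe the printed FEM interval divisions for
# the 3x3, 4x4 and 6x6 reference arrays verbatim, one column set per
# sheet-pair distance.  Known print inconsistencies (the distance-1
# interval 5/6 overlap of the 3x3 table, a stray upper bound in the 4x4
# distance-2 column) are preserved as printed; the decoder resolves
# overlaps toward the higher-current interval and flags the ambiguity.

packaged_array_info <- function(array) {
  switch(array,
         "3x3" = list(n_sheets = 3L, tips = 3L),
         "4x4" = list(n_sheets = 4L, tips = 4L),
         "6x6" = list(n_sheets = 6L, tips = 6L),
         stop(sprintf("no packaged calibration for array '%s'", array),
              call. = FALSE))
}

#' Packaged calibration tables
#'
#' Loads the packaged current-interval division for a reference array
#' (`"3x3"`, `"4x4"` or `"6x6"`) and one sheet-pair distance.  Values are
#' transcribed verbatim from the printed FEM characterisation of the
#' reference device, including its known inconsistencies (see the
#' package vignette); currents are in uA.
#'
#' @param array array label: `"3x3"`, `"4x4"` or `"6x6"`.
#' @param distance sheet-pair separation in sheet pitches (1 = adjacent
#'   sheets, i.e. the "AB" column set).
#' @return a `calibration_table`.
#' @examples
#' packaged_table("3x3", distance = 1)
#' @export
packaged_table <- function(array = c("3x3", "4x4", "6x6"), distance = 1L) {
  array <- match.arg(array)
  info <- packaged_array_info(array)
  path <- system.file("extdata", paste0("calibration_", array, ".csv"),
                      package = "mnscreen", mustWork = TRUE)
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  raw <- raw[raw$distance == as.integer(distance), , drop = FALSE]
  if (nrow(raw) == 0L)
    stop(sprintf("no packaged column for distance %d in the %s table",
                 distance, array), call. = FALSE)
  rows <- data.frame(interval = raw$interval, states = raw$states,
                     lower_uA = raw$lower_uA, upper_uA = raw$upper_uA,
                     length_uA = raw$length_uA)
  new_calibration_table(rows, info$tips, distance, "packaged",
                        pair = raw$pair[1L])
}

#' All packaged tables of an array, keyed by distance
#'
#' @inheritParams packaged_table
#' @return named list of `calibration_table`s, names `"1"`, `"2"`, ...
#' @export
packaged_tables <- function(array = c("3x3", "4x4", "6x6")) {
  array <- match.arg(array)
  info <- packaged_array_info(array)
  ds <- seq_len(info$n_sheets - 1L)
  stats::setNames(lapply(ds, function(d) packaged_table(array, d)),
                  as.character(ds))
}

#' Check printed interval lengths against the interval bounds
#'
#' Compares each closed interval's printed `length_uA` with
#' `upper_uA - lower_uA` and reports the rows that disagree by more than
#' `tol` (bounds in the printed tables are rounded to 1 uA, so a 1 uA
#' slack is the natural tolerance).
#'
#' @param table a `calibration_table`.
#' @param tol allowed absolute discrepancy, uA.
#' @return data.frame of inconsistent rows with the implied and printed
#'   lengths (zero rows when the table is internally consistent).
#' @export
check_table_consistency <- function(table, tol = 1) {
  stopifnot(inherits(table, "calibration_table"))
  implied <- table$upper_uA - table$lower_uA
  bad <- !is.na(implied) & !is.na(table$length_uA) &
    abs(implied - table$length_uA) > tol
  out <- data.frame(interval = table$interval[bad],
                    states = table$states[bad],
                    implied_length = implied[bad],
                    printed_length = table$length_uA[bad])
  rownames(out) <- NULL
  out
}

#' Read and write calibration tables
#'
#' Calibration tables serialize to JSON (fields `interval`, `states`,
#' `lower_uA`, `upper_uA`, `length_uA` plus the `n`, `pair_distance`,
#' `source` and `pair` metadata) and to a CSV mirroring the printed
#' table layout with the metadata in `#`-prefixed header lines.  Both
#' round-trip losslessly.
#'
#' @param table a `calibration_table`.
#' @param path file path.
#' @return the table (invisibly for writers).
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @export
write_calibration_json <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  obj <- list(n = attr(table, "n"),
              pair_distance = attr(table, "pair_distance"),
              source = attr(table, "source"),
              pair = attr(table, "pair"),
              rows = as.data.frame(table))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(table)
}

#' @rdname calibration_io
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(obj$rows)
  for (col in c("lower_uA", "upper_uA", "length_uA"))
    rows[[col]] <- as.numeric(rows[[col]])
  new_calibration_table(rows, obj$n, obj$pair_distance, obj$source,
                        pair = obj$pair)
}

#' @rdname calibration_io
#' @export
write_calibration_csv <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# calibration table: %d-tip sheets, pair distance %d, source %s, pair %s",
                     attr(table, "n"), attr(table, "pair_distance"),
                     attr(table, "source"),
                     if (is.null(attr(table, "pair"))) "NA"
                     else attr(table, "pair")), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "")
  invisible(table)
}

#' @rdname calibration_io
#' @export
read_calibration_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec(
    "(\\d+)-tip sheets, pair distance (\\d+), source (\\S+), pair (\\S+)",
    hdr))[[1]]
  if (length(meta) != 5L)
    stop("not a calibration CSV written by write_calibration_csv",
         call. = FALSE)
  rows <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  pair <- if (meta[5] == "NA") NULL else meta[5]
  new_calibration_table(rows, as.integer(meta[2]), as.integer(meta[3]),
                        meta[4], pair = pair)
}
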