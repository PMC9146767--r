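#' Exhaustively sweep the penetration states of one sheet pair
#'
#' Enumerates every penetrated/unpenetrated assignment of the `2n` tips
#' of a tested sheet pair ([enumerate_pair_states()]) and solves the
#' forward problem for each, producing the full current distribution used
#' to calibrate current intervals.  Non-tested sheets keep a fixed flag
#' pattern (all unpenetrated by default, which minimises their electrical
#' footprint) and are floating unless `nontested = "absent"`.
#'
#' @param geometry an [array_geometry()].
#' @param skin a [skin_model()].
#' @param config a [solver_config()]; sweeps are usually run at the
#'   coarse 100 um resolution.
#' @param pair integer pair of sheet ids to drive (source, ground).
#' @param others flag value (0 or 1) given to the tips of non-tested
#'   sheets.
#' @param nontested `"floating"` or `"absent"`.
#' @param grid optional pre-built `grid_model` (rebuilt otherwise).
#' @return a `sweep_result` data.frame with columns `pair`,
#'   `combination_index`, `state_low`, `state_high`, `current_uA`;
#'   attribute `n` is the tips-per-sheet count.
#' @export
sweep_pair <- function(geometry, skin, config = solver_config(voxel_size = 100),
                       pair = c(1L, 2L), others = 1L,
                       nontested = c("floating", "absent"), grid = NULL) {
  nontested <- match.arg(nontested)
  if (is.null(grid)) grid <- discretize(geometry, skin, config)
  ns <- geometry$n_sheets; nt <- geometry$tips_per_sheet
  combos <- enumerate_pair_states(nt)
  base <- matrix(as.integer(others), nrow = ns, ncol = nt)
  out_cur <- numeric(nrow(combos))
  out_low <- integer(nrow(combos)); out_high <- integer(nrow(combos))
  ch <- NULL
  for (k in seq_len(nrow(combos))) {
    st <- base
    st[pair[1L], ] <- combos[k, seq_len(nt)]
    st[pair[2L], ] <- combos[k, nt + seq_len(nt)]
    sys <- build_system(grid, penetration_state(st), pair[1L], pair[2L],
                        config, nontested)
    sol <- solve_system(sys, config, chol = ch)
    ch <- sol$chol
    rec <- record_from_solution(grid, penetration_state(st), sys, sol$phi)
    out_cur[k] <- rec$current_uA
    out_low[k] <- rec$state$low; out_high[k] <- rec$state$high
  }
  res <- data.frame(pair = paste0(LETTERS[pair[1L]], LETTERS[pair[2L]]),
                    combination_index = seq_len(nrow(combos)) - 1L,
                    state_low = out_low, state_high = out_high,
                    current_uA = out_cur)
  attr(res, "n") <- nt
  attr(res, "pair_ids") <- pair
  class(res) <- c("sweep_result", "data.frame")
  res
}

check_sweep <- function(records) {
  n <- attr(records, "n", exact = TRUE)
  if (is.null(n))
    n <- max(records$state_high)
  need <- 2^(2 * n)
  if (nrow(records) != need ||
      anyDuplicated(records$combination_index) > 0L)
    stop(sprintf("incomplete sweep: expected %d unique combinations, got %d",
                 need, nrow(records)), call. = FALSE)
  n
}

#' Partition sweep records into nests
#'
#' Splits the currents of a complete sweep by `N_total` (summed
#' unpenetrated tips over the tested pair), by canonical transdermal
#' state, or by `N_max_s` (the larger per-sheet count).
#'
#' @param records a `sweep_result`.
#' @param key `"N_total"`, `"state"` or `"N_max_s"`.
#' @return a named list of current vectors (uA), in ascending key order.
#' @export
group_records <- function(records, key = c("N_total", "state", "N_max_s")) {
  key <- match.arg(key)
  check_sweep(records)
  g <- switch(key,
              N_total = records$state_low + records$state_high,
              state = paste0(records$state_low, "-", records$state_high),
              N_max_s = records$state_high)
  if (key == "state") {
    ord <- order(records$state_high, records$state_low)
    lv <- unique(g[ord])
    split(records$current_uA, factor(g, levels = lv))
  } else {
    split(records$current_uA, g)
  }
}

#' Per-state mean currents of a complete sweep
#'
#' Arithmetic mean of the test current for every canonical conductive
#' state, with all nonconductive states (one sheet fully unpenetrated)
#' pooled into the single "n+" class, in [state_rank()] order.
#'
#' @param records a `sweep_result`.
#' @return a `state_means` data.frame with columns `label`, `rank`,
#'   `n_records`, `mean_uA`; attribute `n`.
#' @export
state_means <- function(records) {
  n <- check_sweep(records)
  noncond <- records$state_high == n
  lab <- ifelse(noncond, paste0(n, "+"),
                paste0(records$state_low, "-", records$state_high))
  rnk <- ifelse(noncond, (n * (n + 1L)) %/% 2L,
                (records$state_high * (records$state_high + 1L)) %/% 2L +
                  records$state_low)
  agg <- aggregate(records$current_uA, list(label = lab, rank = rnk),
                   function(x) c(mean = mean(x), n = length(x)))
  df <- data.frame(label = agg$label, rank = agg$rank,
                   n_records = as.integer(agg$x[, "n"]),
                   mean_uA = agg$x[, "mean"])
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  attr(df, "n") <- n
  class(df) <- c("state_means", "data.frame")
  df
}

new_calibration_table <- function(rows, n, pair_distance, source,
                                  pair = NULL) {
  stopifnot(all(c("interval", "states", "lower_uA", "upper_uA",
                  "length_uA") %in% names(rows)))
  rows <- rows[order(rows$interval), ]
  rownames(rows) <- NULL
  attr(rows, "n") <- as.integer(n)
  attr(rows, "pair_distance") <- as.integer(pair_distance)
  attr(rows, "source") <- source
  attr(rows, "pair") <- pair
  class(rows) <- c("calibration_table", "data.frame")
  rows
}

#' Build a calibration table from per-state mean currents
#'
#' Divides the current axis into ordered intervals, one per state class:
#' the boundary between two adjacent ranked states is the midpoint of
#' their mean currents, the first interval is half-open above, and the
#' nonconductive class closes at 0 uA.
#'
#' @param means a `state_means` table (ranked, "n+" pooled last).
#' @param pair_distance sheet separation of the calibrated pair, in
#'   sheet pitches.
#' @param pair optional pair label (e.g. "AB").
#' @return a `calibration_table` data.frame with columns `interval`,
#'   `states`, `lower_uA`, `upper_uA`, `length_uA`.
#' @export
interval_boundaries <- function(means, pair_distance = 1L, pair = NULL) {
  stopifnot(inherits(means, "state_means"))
  n <- attr(means, "n")
  m <- means$mean_uA
  if (is.unsorted(rev(m), strictly = TRUE) && is.unsorted(m, strictly = TRUE))
    stop("state means must be strictly monotone along the state ranking",
         call. = FALSE)
  if (any(diff(m) == 0))
    stop("adjacent state means are tied; calibration is degenerate",
         call. = FALSE)
  k <- length(m)
  bnd <- (m[-k] + m[-1L]) / 2        # boundary below state i (i = 1..k-1)
  lower <- c(bnd, 0)
  upper <- c(NA_real_, bnd)
  rows <- data.frame(interval = seq_len(k), states = means$label,
                     lower_uA = lower, upper_uA = upper,
                     length_uA = upper - lower)
  new_calibration_table(rows, n, pair_distance, "computed", pair)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration table (%s; %d-tip sheets, pair distance %d)\n",
              attr(x, "source"), attr(x, "n"), attr(x, "pair_distance")))
  print.data.frame(x, ...)
  invisible(x)
}

# parse a calibration-table "states" field ("0-3; 2-2" or "6+") into a
# data.frame of (low, high) count pairs; the pooled "n+" class expands to
# every state with high == n
parse_state_group <- function(states, n) {
  labs <- trimws(strsplit(states, "[;,]")[[1]])
  labs <- labs[nzchar(labs)]
  out <- lapply(labs, function(lab) {
    if (grepl("\\+$", lab)) {
      data.frame(low = 0:n, high = n)
    } else {
      ab <- as.integer(strsplit(lab, "-")[[1]])
      data.frame(low = min(ab), high = max(ab))
    }
  })
  unique(do.call(rbind, out))
}

#' Event-count heat map of intervals against a state axis
#'
#' Counts, for every calibration interval, the transdermal events
#' (position-specific tip assignments) falling on each axis value.  In
#' `"combinatorial"` mode counts come from the table's state-to-interval
#' assignment and [substate_count()] and are exact; in `"by_current"`
#' mode the actual sweep records are binned by their computed current,
#' so bleed-over across interval boundaries becomes visible.
#'
#' @param table a `calibration_table`.
#' @param n tips per sheet (defaults to the table's).
#' @param axis `"state"`, `"N_total"` or `"N_max_s"`.
#' @param mode `"combinatorial"` or `"by_current"`.
#' @param records a `sweep_result`, required in `"by_current"` mode.
#' @return an integer matrix, intervals in rows, axis values in columns.
#' @export
heatmap_counts <- function(table, n = attr(table, "n"),
                           axis = c("state", "N_total", "N_max_s"),
                           mode = c("combinatorial", "by_current"),
                           records = NULL) {
  axis <- match.arg(axis); mode <- match.arg(mode)
  stopifnot(inherits(table, "calibration_table"))
  states_all <- conductive_states(n)
  cols <- switch(axis,
                 state = states_all$label,
                 N_total = as.character(0:(2 * n)),
                 N_max_s = as.character(0:n))
  m <- matrix(0L, nrow = nrow(table), ncol = length(cols),
              dimnames = list(interval = table$interval, axis = cols))
  if (mode == "combinatorial") {
    for (r in seq_len(nrow(table))) {
      grp <- parse_state_group(table$states[r], n)
      for (q in seq_len(nrow(grp))) {
        lo <- grp$low[q]; hi <- grp$high[q]
        cnt <- substate_count(c(lo, hi), n)
        col <- switch(axis,
                      state = if (hi == n) paste0(n, "+")
                              else paste0(lo, "-", hi),
                      N_total = as.character(lo + hi),
                      N_max_s = as.character(hi))
        m[r, col] <- m[r, col] + cnt
      }
    }
  } else {
    if (is.null(records))
      stop("'records' required in by_current mode", call. = FALSE)
    check_sweep(records)
    for (k in seq_len(nrow(records))) {
      lk <- lookup_state(records$current_uA[k], table)
      lo <- records$state_low[k]; hi <- records$state_high[k]
      col <- switch(axis,
                    state = if (hi == n) paste0(n, "+")
                            else paste0(lo, "-", hi),
                    N_total = as.character(lo + hi),
                    N_max_s = as.character(hi))
      r <- match(lk$interval, table$interval)
      m[r, col] <- m[r, col] + 1L
    }
  }
  m
}

#' Per-interval probability, mean and deviation
#'
#' Normalises each interval's event counts over a numeric axis
#' (`N_total` or `N_max_s`) into probabilities and summarises them by
#' their mean and population standard deviation.
#'
#' @param counts a count matrix from [heatmap_counts()] with numeric
#'   column names.
#' @return a data.frame with columns `interval`, `n_events`, `mean`,
#'   `deviation` and `empty` (flagging rows without events); the
#'   row-normalised probability matrix is attached as attribute
#'   `probabilities`.
#' @export
interval_summary <- function(counts) {
  vals <- suppressWarnings(as.numeric(colnames(counts)))
  if (any(is.na(vals)))
    stop("interval_summary needs a numeric axis (N_total or N_max_s)",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- rowSums(counts)
  probs <- counts / ifelse(tot > 0, tot, NA_real_)
  mu <- as.numeric(probs %*% vals)
  sdv <- sqrt(as.numeric(probs %*% vals^2) - mu^2)
  sdv[!is.na(sdv) & sdv < 0] <- 0
  out <- data.frame(interval = as.integer(rownames(counts)),
                    n_events = as.integer(tot),
                    mean = mu, deviation = sdv, empty = tot == 0)
  attr(out, "probabilities") <- probs
  out
}

#' Distinct N_total values mapped to each interval
#'
#' As the test current decreases, more transdermal conditions (distinct
#' total unpenetrated-tip counts) share one current interval.  For the
#' pooled "n+" class the totals range over `n .. 2n`.
#'
#' @param table a `calibration_table`.
#' @param n tips per sheet (defaults to the table's).
#' @return an integer vector, one entry per interval.
#' @export
distinct_totals_per_interval <- function(table, n = attr(table, "n")) {
  stopifnot(inherits(table, "calibration_table"))
  vapply(seq_len(nrow(table)), function(r) {
    grp <- parse_state_group(table$states[r], n)
    length(unique(grp$low + grp$high))
  }, integer(1))
}

#' Modal N_max_s of each interval
#'
#' For grouped tables (6x6) an interval can mix states with different
#' per-sheet maxima; the decoder uses the modal value, weighted by the
#' combinatorial event count of each member state.
#'
#' @param table a `calibration_table`.
#' @param n tips per sheet (defaults to the table's).
#' @return integer vector of modal `N_max_s`, one per interval.
#' @export
interval_nmax <- function(table, n = attr(table, "n")) {
  cm <- heatmap_counts(table, n, axis = "N_max_s", mode = "combinatorial")
  vals <- as.integer(colnames(cm))
  vapply(seq_len(nrow(cm)), function(r) vals[which.max(cm[r, ])], integer(1))
}
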