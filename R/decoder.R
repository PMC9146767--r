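# Numerical check screening: interval lookup, the exact logic decoder
# (per-sheet unpenetrated-tip counts) and the fuzzy logic decoder
# (max/median estimation and total-count formulas).

mn_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "mn_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Map a test current to its transdermal state (or state group)
#'
#' Finds the calibration interval containing a measured current.
#' Intervals are half-open `[lower, upper)` with the first interval
#' unbounded above.  If the current falls inside a printed overlap
#' region the higher-current (lower-numbered) interval wins and the
#' result is flagged ambiguous.
#'
#' @param current measured inter-sheet current, uA; must be >= 0.
#' @param table a `calibration_table`.
#' @return a list of class `state_lookup`: `interval`, `states`
#'   (data.frame of member low/high counts), `label`, `state` (a
#'   [canonical_state()] when the interval maps to a single state, else
#'   NULL), `nonconductive`, `n_max` (modal per-sheet maximum of the
#'   member states), `ambiguous`.
#' @examples
#' lookup_state(250, packaged_table("3x3", 1))$label  # "1-1"
#' @export
lookup_state <- function(current, table) {
  stopifnot(inherits(table, "calibration_table"))
  if (!is.finite(current) || current < 0)
    mn_error("mn_input", "current must be a nonnegative number, got %s",
             format(current))
  n <- attr(table, "n")
  upper <- ifelse(is.na(table$upper_uA), Inf, table$upper_uA)
  hit <- which(current >= table$lower_uA & current < upper)
  if (length(hit) == 0L)                      # gap in a printed table
    hit <- which.min(pmax(table$lower_uA - current, current - upper))
  row <- min(hit)
  grp <- parse_state_group(table$states[row], n)
  noncond <- all(grp$high == n)
  single <- nrow(grp) == 1L
  nmax_tab <- interval_nmax(table, n)
  structure(list(interval = table$interval[row],
                 states = grp,
                 label = table$states[row],
                 state = if (single) canonical_state(grp$low, grp$high, n)
                         else NULL,
                 nonconductive = noncond,
                 n_max = nmax_tab[match(row, seq_len(nrow(table)))],
                 ambiguous = length(hit) > 1L),
            class = "state_lookup")
}

as_state <- function(x, what = "state") {
  if (inherits(x, "state_lookup")) {
    if (is.null(x$state) && x$nonconductive) {
      # pooled "n+" class: any member state carries the nonconductive flag
      nmax <- max(x$states$high)
      return(canonical_state(x$states$low[1], nmax, nmax))
    }
    if (is.null(x$state))
      mn_error("mn_usage",
               "%s maps to a state group, not a single state; the exact method needs a one-to-one table",
               what)
    x <- x$state
  }
  if (!inherits(x, "transdermal_state"))
    stop(sprintf("'%s' must be a transdermal_state or state_lookup", what),
         call. = FALSE)
  x
}

state_pair <- function(s) c(s$low, s$high)

check_conductive <- function(s, name) {
  if (s$nonconductive)
    mn_error("mn_ambiguity",
             "pair %s is nonconductive (one sheet fully unpenetrated): the state-to-current correspondence is lost",
             name)
}

# does the unordered pair {a, b} equal the state's count multiset?
matches_pair <- function(s, a, b) {
  (s$low == min(a, b)) && (s$high == max(a, b))
}

#' Exact logic decoding of a three-sheet area
#'
#' Recovers the per-sheet unpenetrated-tip counts (A, B, C) from the
#' three pairwise transdermal states.  Each state supplies the two
#' counts of its pair without saying which sheet carries which; the
#' branch logic resolves the assignment: if the two A-C counts are equal
#' then A = C and the A-B state yields B; otherwise B is the count common
#' to the A-B and B-C states (matched multiset-wise, so a duplicated
#' value can only be used once), and A and C are the complementary
#' elements of their pairs.
#'
#' @param sAB,sBC,sAC [canonical_state()]s (or [lookup_state()] results)
#'   for the A-B, B-C and A-C pairs; all must be conductive.
#' @return integer vector `c(A, B, C)` of unpenetrated-tip counts.
#' @examples
#' s <- function(a, b) canonical_state(a, b, 3)
#' exact_decode_three(s(1, 2), s(1, 2), s(2, 2))  # 2 1 2
#' @export
exact_decode_three <- function(sAB, sBC, sAC) {
  sAB <- as_state(sAB, "sAB"); sBC <- as_state(sBC, "sBC")
  sAC <- as_state(sAC, "sAC")
  check_conductive(sAB, "AB"); check_conductive(sBC, "BC")
  check_conductive(sAC, "AC")
  ab <- state_pair(sAB); bc <- state_pair(sBC); ac <- state_pair(sAC)

  if (ac[1] == ac[2]) {
    A <- C <- ac[1]
    if (ab[1] == A) B <- ab[2]
    else if (ab[2] == A) B <- ab[1]
    else mn_error("mn_inconsistency",
                  "pair AB: neither count equals the shared A = C count %d", A)
  } else {
    if (bc[1] == ab[1] || bc[1] == ab[2]) B <- bc[1] else B <- bc[2]
    if (ab[1] == B) A <- ab[2]
    else if (ab[2] == B) A <- ab[1]
    else mn_error("mn_inconsistency",
                  "pair AB: no count matches the middle-sheet count %d", B)
    if (bc[1] == B) C <- bc[2]
    else if (bc[2] == B) C <- bc[1]
    else mn_error("mn_inconsistency",
                  "pair BC: no count matches the middle-sheet count %d", B)
  }
  if (!matches_pair(sAB, A, B))
    mn_error("mn_inconsistency", "pair AB is inconsistent with (A, B) = (%d, %d)",
             A, B)
  if (!matches_pair(sBC, B, C))
    mn_error("mn_inconsistency", "pair BC is inconsistent with (B, C) = (%d, %d)",
             B, C)
  if (!matches_pair(sAC, A, C))
    mn_error("mn_inconsistency", "pair AC is inconsistent with (A, C) = (%d, %d)",
             A, C)
  c(A = A, B = B, C = C)
}

#' Extend an exact decode to the next sheet
#'
#' Given the known count of sheet X and the transdermal state of the
#' X-Y pair, the count of sheet Y is the element of the pair
#' complementary to X's count (the matched element is used up; if both
#' elements equal the known count, Y's count equals it too).
#'
#' @param prev known unpenetrated-tip count of the previous sheet.
#' @param sXY conductive [canonical_state()] of the X-Y pair.
#' @return integer count for sheet Y.
#' @examples
#' exact_extend(2, canonical_state(2, 0, 3))  # 0
#' @export
exact_extend <- function(prev, sXY) {
  sXY <- as_state(sXY, "sXY")
  check_conductive(sXY, "XY")
  prev <- as.integer(prev)
  if (prev == sXY$low) sXY$high
  else if (prev == sXY$high) sXY$low
  else mn_error("mn_inconsistency",
                "pair state %s does not contain the previous sheet count %d",
                state_label(sXY), prev)
}

#' Exact logic decoding of a whole array
#'
#' Applies [exact_decode_three()] to sheets A, B, C and then chains
#' [exact_extend()] along each further adjacent pair (C-D, D-E, ...),
#' yielding the exact unpenetrated-tip count of every sheet.
#'
#' @param states a named list of conductive states: `AB`, `BC`, `AC`,
#'   then one adjacent-pair state (`CD`, `DE`, ...) per further sheet.
#' @return named integer vector of per-sheet counts (`A`, `B`, ...).
#' @examples
#' s <- function(a, b) canonical_state(a, b, 4)
#' exact_decode_chain(list(AB = s(0, 1), BC = s(0, 2),
#'                         AC = s(1, 2), CD = s(2, 2)))
#' @export
exact_decode_chain <- function(states) {
  need <- c("AB", "BC", "AC")
  if (!all(need %in% names(states)))
    stop("'states' must contain at least AB, BC and AC", call. = FALSE)
  counts <- as.integer(exact_decode_three(states$AB, states$BC, states$AC))
  names(counts) <- c("A", "B", "C")
  extra <- setdiff(names(states), need)
  n_sheets <- 3L + length(extra)
  if (n_sheets > 3L) {
    for (k in 4:n_sheets) {
      nm <- paste0(LETTERS[k - 1L], LETTERS[k])
      if (!nm %in% names(states))
        stop(sprintf("missing adjacent-pair state '%s'", nm), call. = FALSE)
      counts <- c(counts,
                  stats::setNames(exact_extend(counts[[k - 1L]], states[[nm]]),
                                  LETTERS[k]))
    }
  }
  counts
}

#' Fuzzy max/median recovery from three pairwise maxima
#'
#' Three pairwise tests over sheets A, B, C each reveal the larger of
#' the two sheets' unpenetrated-tip counts.  The three-comparison flow
#' recovers the maximum and the median of the underlying per-sheet
#' counts; the minimum stays unknown.  Valid inputs have their two
#' largest values equal (both pairs containing the maximal sheet report
#' the same maximum); otherwise the result is flagged invalid but still
#' returned.
#'
#' @param mAB,mBC,mAC per-pair maxima (`N_max_s`) of the A-B, B-C and
#'   A-C tests.
#' @return a list with `n_max`, `n_med` and `valid`.
#' @examples
#' fuzzy_max_med(2, 3, 3)  # n_max 3, n_med 2
#' @export
fuzzy_max_med <- function(mAB, mBC, mAC) {
  inputs <- c(mAB, mBC, mAC)
  if (any(inputs < 0)) mn_error("mn_input", "pairwise maxima must be >= 0")
  MAX <- max(mAB, mBC); MED <- min(mAB, mBC)
  M <- max(MED, mAC);   MED <- min(MED, mAC)
  MAX <- max(M, MAX)
  srt <- sort(inputs, decreasing = TRUE)
  valid <- srt[1] == srt[2]
  if (!valid)
    warning("pairwise maxima are not realisable by any count triple (top two differ)",
            call. = FALSE)
  list(n_max = MAX, n_med = MED, valid = valid)
}

#' Fuzzy estimate of the total unpenetrated-tip count
#'
#' Two estimation schemes, both replacing each unknown minimum by half
#' its known companion: the disjoint-pairs scheme
#' `N = 1.5 * sum(pairwise maxima)` and the three-sheet scheme
#' `N = N_MAX + 1.5 * N_MED`.
#'
#' @param inputs for `scheme = "pairs"`, the per-pair maxima of disjoint
#'   sheet pairs; for `scheme = "three_sheet"`, either the list returned
#'   by [fuzzy_max_med()] or a vector `c(n_max, n_med)`.
#' @param scheme `"pairs"` or `"three_sheet"`.
#' @return the estimated total `N` (possibly fractional).
#' @examples
#' fuzzy_estimate(c(2, 0, 1), "pairs")                       # 4.5
#' fuzzy_estimate(list(n_max = 3, n_med = 2), "three_sheet") # 6
#' @export
fuzzy_estimate <- function(inputs, scheme = c("pairs", "three_sheet")) {
  scheme <- match.arg(scheme)
  if (scheme == "pairs") {
    1.5 * sum(as.numeric(inputs))
  } else {
    if (is.list(inputs)) inputs <- c(inputs$n_max, inputs$n_med)
    inputs[1] + 1.5 * inputs[2]
  }
}

#' Transdermal rate from an unpenetrated-tip count
#'
#' The transdermal rate is the fraction of tips that pierced the
#' stratum corneum: `1 - N / total_tips` (9 of 9 penetrated tips give
#' 100%, 3 of 9 give 33.3%).
#'
#' @param N (estimated) number of unpenetrated tips.
#' @param total_tips total tips in the array.
#' @return rate in `[0, 1]`; estimates exceeding `total_tips` clamp to 0
#'   with a warning.
#' @examples
#' transdermal_rate(4.5, 36)  # 0.875
#' @export
transdermal_rate <- function(N, total_tips) {
  if (N < 0) mn_error("mn_input", "N must be >= 0")
  if (N > total_tips) {
    warning("estimated unpenetrated count exceeds the tip total; rate clamped to 0",
            call. = FALSE)
    return(0)
  }
  1 - N / total_tips
}

pair_label_to_ids <- function(pair) {
  chars <- strsplit(toupper(gsub("[^A-Za-z]", "", pair)), "")[[1]]
  if (length(chars) != 2L)
    stop(sprintf("cannot parse pair label '%s'", pair), call. = FALSE)
  match(chars, LETTERS)
}

lookup_for_pair <- function(current, pair, tables) {
  ids <- pair_label_to_ids(pair)
  d <- abs(diff(ids))
  tab <- tables[[as.character(d)]]
  if (is.null(tab))
    stop(sprintf("no calibration table for pair distance %d (pair %s)",
                 d, pair), call. = FALSE)
  lookup_state(current, tab)
}

#' Decode measured inter-sheet currents into a transdermal-rate estimate
#'
#' End-to-end decoder: looks every current up in the calibration table
#' matching its pair distance, then applies the exact logic method
#' (per-sheet counts; requires one-to-one tables, i.e. 3x3 or 4x4
#' arrays) or the fuzzy logic method (three-sheet triples or disjoint
#' pairs).
#'
#' @param currents data.frame with columns `pair` (e.g. "AB") and
#'   `current_uA`.
#' @param array array label (`"3x3"`, `"4x4"`, `"6x6"`) selecting the
#'   packaged calibration, or ignored when `tables` is supplied.
#' @param method `"exact"` or `"fuzzy"`.
#' @param scheme fuzzy scheme, `"three_sheet"` or `"pairs"`.
#' @param tables optional named list of `calibration_table`s keyed by
#'   pair distance (`"1"`, `"2"`, ...); defaults to the packaged tables
#'   of `array`.
#' @param n_sheets,tips_per_sheet array dimensions; default from
#'   `array`.
#' @return an object of class `decode_result`: `per_sheet_counts`
#'   (NA where undetermined), `n_max`, `n_med`, `estimated_total`,
#'   `transdermal_rate`, `ambiguous_pairs`, `unknown_rate`, `method`.
#' @export
decode_currents <- function(currents, array = c("3x3", "4x4", "6x6"),
                            method = c("exact", "fuzzy"),
                            scheme = c("three_sheet", "pairs"),
                            tables = NULL, n_sheets = NULL,
                            tips_per_sheet = NULL) {
  method <- match.arg(method); scheme <- match.arg(scheme)
  if (is.null(tables)) {
    array <- match.arg(array)
    info <- packaged_array_info(array)
    tables <- packaged_tables(array)
    if (is.null(n_sheets)) n_sheets <- info$n_sheets
    if (is.null(tips_per_sheet)) tips_per_sheet <- info$tips
  }
  if (is.null(n_sheets) || is.null(tips_per_sheet))
    stop("'n_sheets' and 'tips_per_sheet' are required with custom tables",
         call. = FALSE)
  stopifnot(is.data.frame(currents),
            all(c("pair", "current_uA") %in% names(currents)))
  total_tips <- n_sheets * tips_per_sheet

  get_lookup <- function(pair) {
    i <- match(pair, currents$pair)
    if (is.na(i))
      stop(sprintf("currents table is missing pair %s", pair), call. = FALSE)
    lookup_for_pair(currents$current_uA[i], pair, tables)
  }

  if (method == "exact") {
    # a one-to-one table has a single state per conductive interval
    single <- all(vapply(tables, function(t) {
      cond <- !grepl("\\+$", t$states)
      all(lengths(strsplit(t$states[cond], "[;,]")) == 1L)
    }, logical(1)))
    if (!single)
      mn_error("mn_usage",
               "the exact method needs one-to-one calibration tables; this array's states are grouped")
    need <- c("AB", "BC", "AC")
    if (n_sheets > 3L)
      need <- c(need, paste0(LETTERS[3:(n_sheets - 1L)],
                             LETTERS[4:n_sheets]))
    lk <- lapply(need, get_lookup)
    names(lk) <- need
    ambiguous <- need[vapply(lk, `[[`, logical(1), "ambiguous")]
    counts <- exact_decode_chain(lk)
    N <- sum(counts)
    res <- list(per_sheet_counts = counts,
                n_max = max(counts), n_med = stats::median(counts),
                estimated_total = N,
                transdermal_rate = transdermal_rate(N, total_tips),
                ambiguous_pairs = ambiguous,
                unknown_rate = 0, method = "exact")
  } else if (scheme == "three_sheet") {
    if (n_sheets %% 3L != 0L)
      stop("the three-sheet fuzzy scheme needs a sheet count divisible by 3",
           call. = FALSE)
    ambiguous <- character(0)
    N <- 0; nmax_all <- integer(0); nmed_all <- integer(0)
    for (g in seq_len(n_sheets %/% 3L)) {
      sh <- (g - 1L) * 3L + 1:3
      prs <- c(paste0(LETTERS[sh[1]], LETTERS[sh[2]]),
               paste0(LETTERS[sh[2]], LETTERS[sh[3]]),
               paste0(LETTERS[sh[1]], LETTERS[sh[3]]))
      lk <- lapply(prs, get_lookup)
      ambiguous <- c(ambiguous,
                     prs[vapply(lk, `[[`, logical(1), "ambiguous")])
      mm <- fuzzy_max_med(lk[[1]]$n_max, lk[[2]]$n_max, lk[[3]]$n_max)
      N <- N + fuzzy_estimate(mm, "three_sheet")
      nmax_all <- c(nmax_all, mm$n_max); nmed_all <- c(nmed_all, mm$n_med)
    }
    res <- list(per_sheet_counts = rep(NA_integer_, n_sheets),
                n_max = max(nmax_all), n_med = max(nmed_all),
                estimated_total = N,
                transdermal_rate = transdermal_rate(N, total_tips),
                ambiguous_pairs = ambiguous,
                unknown_rate = 1 / 3, method = "fuzzy_three_sheet")
  } else {
    if (n_sheets %% 2L != 0L)
      stop("the disjoint-pairs fuzzy scheme needs an even sheet count",
           call. = FALSE)
    prs <- vapply(seq_len(n_sheets %/% 2L), function(g)
      paste0(LETTERS[2L * g - 1L], LETTERS[2L * g]), character(1))
    lk <- lapply(prs, get_lookup)
    ambiguous <- prs[vapply(lk, `[[`, logical(1), "ambiguous")]
    maxima <- vapply(lk, `[[`, numeric(1), "n_max")
    N <- fuzzy_estimate(maxima, "pairs")
    res <- list(per_sheet_counts = rep(NA_integer_, n_sheets),
                n_max = max(maxima), n_med = NA_real_,
                estimated_total = N,
                transdermal_rate = transdermal_rate(N, total_tips),
                ambiguous_pairs = ambiguous,
                unknown_rate = 1 / 2, method = "fuzzy_pairs")
  }
  res$n_sheets <- n_sheets
  res$tips_per_sheet <- tips_per_sheet
  class(res) <- "decode_result"
  res
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode (%s): N = %.3g of %d tips, transdermal rate %.1f%%\n",
              x$method, x$estimated_total,
              x$n_sheets * x$tips_per_sheet, 100 * x$transdermal_rate))
  if (!all(is.na(x$per_sheet_counts)))
    cat("  per-sheet unpenetrated counts:",
        paste(names(x$per_sheet_counts), x$per_sheet_counts,
              sep = "=", collapse = " "), "\n")
  if (length(x$ambiguous_pairs))
    cat("  ambiguous pairs:", paste(x$ambiguous_pairs, collapse = ", "), "\n")
  invisible(x)
}
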