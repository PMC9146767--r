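#' Microneedle array geometry
#'
#' Describes a metallic sheet microneedle array: `n_sheets` parallel metal
#' sheets, each carrying `tips_per_sheet` needle tips.  All lengths are in
#' micrometres.  Defaults describe the reference device: 100 um thick
#' sheets, 200 um wide and 800 um long needles (of which the final 200 um
#' form the tip section), 800 um tip and sheet pitch, and a 600 um
#' insertion depth.
#'
#' @param n_sheets number of microneedle sheets (rows) in the array.
#' @param tips_per_sheet number of needle tips on each sheet.
#' @param sheet_thickness sheet (metal plate) thickness, um.
#' @param tip_width needle width, um.
#' @param needle_length total needle length, um.
#' @param tip_section_length length of the tapered tip section, um.
#' @param tip_pitch centre-to-centre spacing of tips along a sheet, um.
#' @param sheet_pitch centre-to-centre spacing of adjacent sheets, um.
#' @param insertion_depth depth to which needles are inserted into the
#'   skin, um; must not exceed `needle_length`.
#' @return an object of class `array_geometry`.
#' @examples
#' geo <- array_geometry(3, 3)
#' geo$insertion_depth
#' @export
array_geometry <- function(n_sheets, tips_per_sheet,
                           sheet_thickness = 100, tip_width = 200,
                           needle_length = 800, tip_section_length = 200,
                           tip_pitch = 800, sheet_pitch = 800,
                           insertion_depth = 600) {
  n_sheets <- as.integer(n_sheets)
  tips_per_sheet <- as.integer(tips_per_sheet)
  if (is.na(n_sheets) || n_sheets < 1L)
    stop("'n_sheets' must be a positive integer", call. = FALSE)
  if (is.na(tips_per_sheet) || tips_per_sheet < 1L)
    stop("'tips_per_sheet' must be a positive integer", call. = FALSE)
  lengths <- c(sheet_thickness = sheet_thickness, tip_width = tip_width,
               needle_length = needle_length,
               tip_section_length = tip_section_length,
               tip_pitch = tip_pitch, sheet_pitch = sheet_pitch,
               insertion_depth = insertion_depth)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all geometry lengths must be positive and finite", call. = FALSE)
  if (insertion_depth > needle_length)
    stop("'insertion_depth' cannot exceed 'needle_length'", call. = FALSE)
  if (tip_section_length > needle_length)
    stop("'tip_section_length' cannot exceed 'needle_length'", call. = FALSE)
  structure(list(n_sheets = n_sheets, tips_per_sheet = tips_per_sheet,
                 sheet_thickness = sheet_thickness, tip_width = tip_width,
                 needle_length = needle_length,
                 tip_section_length = tip_section_length,
                 tip_pitch = tip_pitch, sheet_pitch = sheet_pitch,
                 insertion_depth = insertion_depth),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("microneedle array: %d sheets x %d tips\n",
              x$n_sheets, x$tips_per_sheet))
  cat(sprintf("  needle %g x %g um (tip section %g um), inserted %g um\n",
              x$tip_width, x$needle_length, x$tip_section_length,
              x$insertion_depth))
  cat(sprintf("  tip pitch %g um, sheet pitch %g um, sheet thickness %g um\n",
              x$tip_pitch, x$sheet_pitch, x$sheet_thickness))
  invisible(x)
}

#' Two-layer skin model
#'
#' Electrical description of the skin block used by the forward solver.
#' The skin is simplified to two layers: a thin, highly resistive stratum
#' corneum on top of a thick conductive layer that pools the viable
#' epidermis and dermis.  The metal/tissue interface is modelled as a thin
#' contact layer of thickness `contact_thickness` whose conductivity
#' depends on whether the tip has pierced the stratum corneum (see
#' [contact_conductivity()]).  The lateral extent of the skin block is set
#' so that the array footprint occupies `1/footprint_ratio` of the skin
#' area (default one-ninth, i.e. a 3x margin per axis).
#'
#' @param sc_thickness stratum corneum thickness, um.
#' @param sc_conductivity stratum corneum conductivity, S/m.
#' @param dermis_thickness conductive layer thickness, um.
#' @param dermis_conductivity conductive layer conductivity, S/m.
#' @param metal_conductivity sheet metal conductivity, S/m (used only for
#'   the equipotential-sheet justification; the sheets are not meshed).
#' @param contact_thickness contact-impedance layer thickness, um.
#' @param footprint_ratio skin lateral area divided by array footprint
#'   area; must be >= 1.
#' @return an object of class `skin_model`.
#' @examples
#' skin_model()$sc_conductivity
#' @export
skin_model <- function(sc_thickness = 100, sc_conductivity = 0.0005,
                       dermis_thickness = 1800, dermis_conductivity = 0.2,
                       metal_conductivity = 1e7, contact_thickness = 20,
                       footprint_ratio = 9) {
  vals <- c(sc_thickness, sc_conductivity, dermis_thickness,
            dermis_conductivity, metal_conductivity, contact_thickness,
            footprint_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all skin parameters must be positive and finite", call. = FALSE)
  if (!(sc_conductivity < dermis_conductivity &&
        dermis_conductivity < metal_conductivity))
    stop("conductivities must satisfy sc < dermis < metal", call. = FALSE)
  if (footprint_ratio < 1)
    stop("'footprint_ratio' must be >= 1", call. = FALSE)
  structure(list(sc_thickness = sc_thickness,
                 sc_conductivity = sc_conductivity,
                 dermis_thickness = dermis_thickness,
                 dermis_conductivity = dermis_conductivity,
                 metal_conductivity = metal_conductivity,
                 contact_thickness = contact_thickness,
                 footprint_ratio = footprint_ratio),
            class = "skin_model")
}

#' Per-tip penetration state
#'
#' A binary flag matrix indexed (sheet, tip): 1 marks an unpenetrated tip
#' (still resting on the stratum corneum), 0 a tip that has pierced into
#' the conductive layer.
#'
#' @param flags matrix of 0/1 flags, one row per sheet, one column per tip.
#' @return an object of class `penetration_state` (a 0/1 integer matrix).
#' @examples
#' penetration_state(rbind(c(0, 1, 0), c(0, 0, 0)))
#' @export
penetration_state <- function(flags) {
  flags <- as.matrix(flags)
  if (!all(flags %in% c(0, 1)))
    stop("penetration flags must be 0 (penetrated) or 1 (unpenetrated)",
         call. = FALSE)
  storage.mode(flags) <- "integer"
  structure(flags, class = c("penetration_state", "matrix"))
}

#' Canonical transdermal state of a sheet pair
#'
#' A transdermal state labels one pairwise current test by the two
#' unpenetrated-tip counts of the tested sheets.  The pair is unordered:
#' counts (2, 0) and (0, 2) describe the same state, canonicalised as
#' low-high ("0-2").  When either sheet is fully unpenetrated the pair is
#' electrically open (nonconductive) and is labelled with the pooled class
#' "n+" (e.g. "3+" for 3-tip sheets).
#'
#' @param a,b unpenetrated-tip counts of the two tested sheets.
#' @param n number of tips per sheet.
#' @return an object of class `transdermal_state` with fields `low`,
#'   `high`, `n` and `nonconductive`.
#' @examples
#' canonical_state(2, 0, 3)    # the "0-2" state
#' canonical_state(1, 3, 3)    # nonconductive, "3+"
#' @export
canonical_state <- function(a, b, n) {
  a <- as.integer(a); b <- as.integer(b); n <- as.integer(n)
  if (any(is.na(c(a, b, n))))
    stop("counts must be integers", call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (a < 0L || a > n || b < 0L || b > n)
    stop(sprintf("counts must lie in 0..%d", n), call. = FALSE)
  structure(list(low = min(a, b), high = max(a, b), n = n,
                 nonconductive = max(a, b) == n),
            class = "transdermal_state")
}

#' @rdname canonical_state
#' @param state a `transdermal_state`.
#' @export
state_label <- function(state) {
  stopifnot(inherits(state, "transdermal_state"))
  if (state$nonconductive) paste0(state$n, "+")
  else paste0(state$low, "-", state$high)
}

#' @export
format.transdermal_state <- function(x, ...) {
  lab <- state_label(x)
  if (x$nonconductive)
    sprintf("%s state (nonconductive; counts %d-%d of %d tips)",
            lab, x$low, x$high, x$n)
  else sprintf("%s state (%d of %d tips)", lab, x$n, x$n)
}

#' @export
print.transdermal_state <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Enumerate all pairwise penetration combinations
#'
#' Enumerates every assignment of penetrated/unpenetrated flags to the
#' `2 * n` tips of a tested sheet pair: `2^(2n)` combinations (64 for
#' 3-tip sheets, 256 for 4, 4096 for 6).  Rows follow binary counting of
#' the combination index, with sheet A's tips as the most significant
#' bits, so the ordering is deterministic and reproducible.
#'
#' @param n tips per sheet.
#' @return an integer matrix with `2^(2n)` rows and `2n` columns named
#'   `A1..An, B1..Bn`; row `k` encodes combination index `k - 1`.
#' @examples
#' nrow(enumerate_pair_states(3))  # 64
#' @export
enumerate_pair_states <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  nbits <- 2L * n
  ncomb <- 2L^nbits
  idx <- 0:(ncomb - 1L)
  m <- matrix(0L, nrow = ncomb, ncol = nbits)
  # column 1 (A1) is the most significant bit
  for (j in seq_len(nbits))
    m[, j] <- (idx %/% 2L^(nbits - j)) %% 2L
  colnames(m) <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  m
}

#' Number of tip-position assignments realising a transdermal state
#'
#' A transdermal "substate" (or event) is a position-specific assignment
#' of unpenetrated tips realising a given state over an ordered sheet
#' pair.  For counts `low != high` there are `2 * C(n, low) * C(n, high)`
#' such assignments (either sheet may carry the larger count); for
#' `low == high` there are `C(n, low)^2`.
#'
#' @param state a `transdermal_state`, or a length-2 vector of counts.
#' @param n tips per sheet (ignored when `state` is a
#'   `transdermal_state`).
#' @return integer event count.
#' @examples
#' substate_count(canonical_state(1, 2, 3))      # 18
#' substate_count(c(1, 1), 4)                    # 16
#' @export
substate_count <- function(state, n = NULL) {
  if (inherits(state, "transdermal_state")) {
    low <- state$low; high <- state$high; n <- state$n
  } else {
    if (is.null(n)) stop("'n' required when 'state' is a count pair",
                         call. = FALSE)
    low <- min(state); high <- max(state)
  }
  if (low < 0 || high > n) stop("counts out of range", call. = FALSE)
  if (low == high) choose(n, low)^2
  else 2 * choose(n, low) * choose(n, high)
}

#' @rdname substate_count
#' @details `nonconductive_count()` counts the events pooled into the
#'   "n+" class (at least one sheet fully unpenetrated):
#'   `2 * 2^n - 1`.
#' @export
nonconductive_count <- function(n) {
  2L * 2L^as.integer(n) - 1L
}

#' Rank of a transdermal state
#'
#' States are ordered by ascending `(high, low)`: the dominant factor in
#' the test current is the maximum unpenetrated-tip count on a single
#' sheet, with the smaller count breaking ties.  The fully penetrated
#' state "0-0" has rank 0; the pooled nonconductive class ranks last.
#'
#' @param state a `transdermal_state`.
#' @return integer ordinal (0-based).
#' @examples
#' state_rank(canonical_state(0, 2, 3))  # 3: after 0-0, 0-1, 1-1
#' @export
state_rank <- function(state) {
  stopifnot(inherits(state, "transdermal_state"))
  if (state$nonconductive) return((state$n * (state$n + 1L)) %/% 2L)
  (state$high * (state$high + 1L)) %/% 2L + state$low
}

#' Canonical states of a sheet pair in rank order
#'
#' Lists every canonical conductive state (low <= high < n) in
#' [state_rank()] order, followed by the pooled nonconductive class
#' "n+".
#'
#' @param n tips per sheet.
#' @param conductive_only drop the pooled "n+" row?
#' @return a data.frame with columns `low`, `high` (NA for the pooled
#'   class), `label`, `rank`, `nonconductive` and `events` (the substate
#'   count).
#' @examples
#' conductive_states(3)$label
#' @export
conductive_states <- function(n, conductive_only = FALSE) {
  n <- as.integer(n)
  grid <- expand.grid(low = 0:(n - 1L), high = 0:(n - 1L))
  grid <- grid[grid$low <= grid$high, , drop = FALSE]
  grid <- grid[order(grid$high, grid$low), , drop = FALSE]
  df <- data.frame(low = grid$low, high = grid$high,
                   label = paste0(grid$low, "-", grid$high),
                   rank = (grid$high * (grid$high + 1L)) %/% 2L + grid$low,
                   nonconductive = FALSE,
                   events = mapply(function(l, h) substate_count(c(l, h), n),
                                   grid$low, grid$high))
  if (!conductive_only) {
    df <- rbind(df, data.frame(low = NA_integer_, high = NA_integer_,
                               label = paste0(n, "+"),
                               rank = (n * (n + 1L)) %/% 2L,
                               nonconductive = TRUE,
                               events = nonconductive_count(n)))
  }
  rownames(df) <- NULL
  df
}

# canonical state of one enumerated flag row (helper shared by the sweep
# and heat-map code); returns c(low, high)
pair_counts_from_flags <- function(flags, n) {
  a <- sum(flags[seq_len(n)])
  b <- sum(flags[n + seq_len(n)])
  c(min(a, b), max(a, b))
}
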