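# Seeded synthetic-fixture generation and tabular/JSON serialization.
# Fixtures stand in for bench measurements: a random penetration truth is
# drawn and each required pairwise current is emitted from the matching
# calibration table (or from the forward solver), plus optional Gaussian
# noise.  Everything stochastic flows through one seeded RNG so a fixed
# seed reproduces a fixture bit-exactly.

#' Fixture specification
#'
#' @param array array label: `"3x3"`, `"4x4"` or `"6x6"`.
#' @param p per-tip probability of being unpenetrated, in `[0, 1]`.
#' @param noise Gaussian noise standard deviation added to each current,
#'   uA.
#' @param source `"table_means"` (representative in-interval current from
#'   the calibration table) or `"solver"` (forward-solve the truth).
#' @param seed integer RNG seed; fixes the fixture bit-exactly.
#' @param replicates number of independent truth draws.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(array = c("3x3", "4x4", "6x6"), p = 0.2,
                         noise = 0, source = c("table_means", "solver"),
                         seed = 1L, replicates = 1L) {
  array <- match.arg(array); source <- match.arg(source)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(noise) || noise < 0)
    stop("'noise' must be >= 0", call. = FALSE)
  structure(list(array = array, p = p, noise = noise, source = source,
                 seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# representative current for a state under a calibration table: the
# interval midpoint; the half-open first interval uses its boundary plus
# half the median closed-interval length
representative_current <- function(low, high, table) {
  n <- attr(table, "n")
  row <- NA_integer_
  for (r in seq_len(nrow(table))) {
    grp <- parse_state_group(table$states[r], n)
    if (any(grp$low == low & grp$high == high)) { row <- r; break }
  }
  if (is.na(row))
    stop(sprintf("state %d-%d not present in the calibration table",
                 low, high), call. = FALSE)
  lo <- table$lower_uA[row]; up <- table$upper_uA[row]
  if (is.na(up)) {
    half <- stats::median(table$upper_uA - table$lower_uA, na.rm = TRUE) / 2
    lo + half
  } else (lo + up) / 2
}

#' Generate a synthetic measurement fixture
#'
#' Draws a per-tip Bernoulli(`p`) penetration truth and emits one
#' current per sheet pair: the representative in-interval current of the
#' pair's true transdermal state under the calibration table for its
#' distance (or the forward-solved current when
#' `source = "solver"`), plus Gaussian noise.  Bit-exact reproducible
#' under a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @param tables named list of `calibration_table`s keyed by distance;
#'   defaults to the packaged tables of the array.
#' @param geometry,skin,config forward-model configuration, used only
#'   when `source = "solver"`.
#' @return a list with `truth` (list of [penetration_state()] matrices,
#'   one per replicate) and `currents` (data.frame with columns
#'   `replicate`, `pair`, `state_low`, `state_high`, `current_uA`).
#' @export
generate_fixture <- function(spec, tables = NULL, geometry = NULL,
                             skin = skin_model(),
                             config = solver_config(voxel_size = 100)) {
  stopifnot(inherits(spec, "fixture_spec"))
  info <- packaged_array_info(spec$array)
  if (is.null(tables)) tables <- packaged_tables(spec$array)
  ns <- info$n_sheets; nt <- info$tips
  if (spec$source == "solver") {
    if (is.null(geometry)) geometry <- array_geometry(ns, nt)
    grid <- discretize(geometry, skin, config)
  }
  pairs <- t(utils::combn(ns, 2L))

  with_seed(spec$seed, {
    truths <- vector("list", spec$replicates)
    rows <- vector("list", spec$replicates)
    for (rep in seq_len(spec$replicates)) {
      flags <- matrix(stats::rbinom(ns * nt, 1L, spec$p), nrow = ns)
      truth <- penetration_state(flags)
      truths[[rep]] <- truth
      cur <- numeric(nrow(pairs)); lo <- integer(nrow(pairs))
      hi <- integer(nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        a <- sum(flags[i, ]); b <- sum(flags[j, ])
        lo[k] <- min(a, b); hi[k] <- max(a, b)
        if (spec$source == "table_means") {
          tab <- tables[[as.character(j - i)]]
          if (is.null(tab))
            stop(sprintf("no calibration table for pair distance %d", j - i),
                 call. = FALSE)
          cur[k] <- representative_current(lo[k], hi[k], tab)
        } else {
          cur[k] <- solve_pair_current(grid, truth, i, j, config)$current_uA
        }
      }
      if (spec$noise > 0)
        cur <- pmax(0, cur + stats::rnorm(length(cur), 0, spec$noise))
      rows[[rep]] <- data.frame(replicate = rep,
                                pair = paste0(LETTERS[pairs[, 1L]],
                                              LETTERS[pairs[, 2L]]),
                                state_low = lo, state_high = hi,
                                current_uA = cur)
    }
    list(truth = truths, currents = do.call(rbind, rows))
  })
}

#' Tabular current I/O
#'
#' Currents (sweep results and fixtures) are serialized as plain CSV
#' with currents in uA printed to 6 significant digits; readers and
#' writers round-trip.
#'
#' @param x data.frame of currents.
#' @param path file path.
#' @name currents_io
NULL

#' @rdname currents_io
#' @export
write_currents_csv <- function(x, path) {
  stopifnot(is.data.frame(x), "current_uA" %in% names(x))
  y <- x
  y$current_uA <- signif(y$current_uA, 6)
  utils::write.csv(y, path, row.names = FALSE)
  invisible(x)
}

#' @rdname currents_io
#' @export
read_currents_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a decode result as JSON
#'
#' Per-sheet counts that the method leaves undetermined are written as
#' JSON nulls.
#'
#' @param result a `decode_result`.
#' @param path file path.
#' @return the result, invisibly.
#' @export
write_decode_result <- function(result, path) {
  stopifnot(inherits(result, "decode_result"))
  obj <- unclass(result)
  obj$per_sheet_counts <- as.list(obj$per_sheet_counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(result)
}

#' Read a run configuration
#'
#' Run configurations are YAML (or JSON) files with optional `geometry`,
#' `skin` and `solver` blocks whose field names match
#' [array_geometry()], [skin_model()] and [solver_config()], plus
#' optional `output_dir` and `log_level` entries.  Units are fixed at um
#' and S/m; no unit strings are parsed.  Unknown fields are rejected.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return a validated list of class `run_config` with constructed
#'   `geometry`, `skin` and `solver` objects.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param raw a raw configuration list.
#' @export
validate_run_config <- function(raw) {
  known <- c("geometry", "skin", "solver", "output_dir", "log_level")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown configuration fields: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  check_block <- function(block, allowed, name) {
    if (is.null(block)) return(list())
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop(sprintf("unknown %s fields: %s", name,
                   paste(extra, collapse = ", ")), call. = FALSE)
    block
  }
  geo <- check_block(raw$geometry, names(formals(array_geometry)),
                     "geometry")
  if (!all(c("n_sheets", "tips_per_sheet") %in% names(geo)))
    stop("the geometry block must set 'n_sheets' and 'tips_per_sheet'",
         call. = FALSE)
  sk <- check_block(raw$skin, names(formals(skin_model)), "skin")
  sv <- check_block(raw$solver, names(formals(solver_config)), "solver")
  structure(list(geometry = do.call(array_geometry, geo),
                 skin = do.call(skin_model, sk),
                 solver = do.call(solver_config, sv),
                 output_dir = if (is.null(raw$output_dir)) "."
                              else raw$output_dir,
                 log_level = if (is.null(raw$log_level)) "info"
                             else raw$log_level),
            class = "run_config")
}
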