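# Assembly and solution of the finite-volume current-conduction problem.
#
# Unknowns are the skin voxel potentials plus one potential per floating
# sheet; the source and ground sheets are Dirichlet nodes eliminated into
# the right-hand side.  The system is symmetric positive definite and is
# solved by sparse Cholesky factorisation (CHOLMOD via Matrix); within a
# sweep the symbolic factorisation is reused across penetration states.

build_system <- function(grid, state, source, ground, config,
                         nontested = c("floating", "absent")) {
  nontested <- match.arg(nontested)
  ns <- grid$geometry$n_sheets
  nt <- grid$geometry$tips_per_sheet
  if (!inherits(state, "penetration_state"))
    state <- penetration_state(state)
  if (!all(dim(state) == c(ns, nt)))
    stop(sprintf("penetration state must be %d x %d", ns, nt), call. = FALSE)
  source <- as.integer(source); ground <- as.integer(ground)
  if (source == ground) stop("source and ground sheets must differ",
                             call. = FALSE)
  if (source < 1L || source > ns || ground < 1L || ground > ns)
    stop("sheet id out of range", call. = FALSE)

  ct <- grid$contact
  if (nrow(ct) == 0L)
    stop("grid has no contact faces (insertion depth zero?)", call. = FALSE)
  for (s in c(source, ground))
    if (!any(ct$sheet == s))
      stop(sprintf("sheet %d has no contact faces", s), call. = FALSE)

  roles <- rep(nontested, ns)
  roles[source] <- "source"; roles[ground] <- "ground"
  keep <- roles[ct$sheet] != "absent"
  ct <- ct[keep, , drop = FALSE]

  h_m <- grid$voxel_size * 1e-6
  t_m <- grid$skin$contact_thickness * 1e-6
  xy <- state[cbind(ct$sheet, ct$tip)]
  sig_c <- contact_conductivity(xy, grid$skin)
  g_c <- sig_c * (ct$area_um2 * 1e-12) / t_m

  float_ids <- which(roles == "floating")
  n_skin <- grid$n_skin
  n_unk <- n_skin + length(float_ids)
  float_col <- integer(ns)
  float_col[float_ids] <- n_skin + seq_along(float_ids)

  V <- config$drive_voltage
  vfix <- c(source = V, ground = 0)

  # triplets: internal skin faces
  fi <- grid$faces$i; fj <- grid$faces$j; fg <- grid$faces$g
  ti <- c(fi, fj, fi, fj)
  tj <- c(fi, fj, fj, fi)
  tx <- c(fg, fg, -fg, -fg)

  b <- numeric(n_unk)
  is_fixed <- roles[ct$sheet] %in% c("source", "ground")
  # fixed-sheet contacts: diagonal + RHS
  cf <- which(is_fixed)
  if (length(cf)) {
    ti <- c(ti, ct$skin_id[cf]); tj <- c(tj, ct$skin_id[cf])
    tx <- c(tx, g_c[cf])
    vs <- ifelse(roles[ct$sheet[cf]] == "source", V, 0)
    add <- g_c[cf] * vs
    b_add <- tapply(add, ct$skin_id[cf], sum)
    b[as.integer(names(b_add))] <- b[as.integer(names(b_add))] + b_add
  }
  # floating-sheet contacts: full coupling block
  cl <- which(!is_fixed)
  if (length(cl)) {
    u <- float_col[ct$sheet[cl]]
    i2 <- ct$skin_id[cl]
    ti <- c(ti, i2, u, i2, u)
    tj <- c(tj, i2, u, u, i2)
    tx <- c(tx, g_c[cl], g_c[cl], -g_c[cl], -g_c[cl])
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_unk, n_unk))
  A <- Matrix::forceSymmetric(A, uplo = "U")
  list(A = A, b = b, contact = ct, g_c = g_c, roles = roles,
       float_col = float_col, n_unk = n_unk, V = V,
       source = source, ground = ground)
}

solve_system <- function(sys, config, chol = NULL) {
  ch <- tryCatch({
    if (is.null(chol)) Matrix::Cholesky(sys$A, LDL = FALSE, super = TRUE)
    else Matrix::update(chol, sys$A)
  }, error = function(e)
    stop("linear system is singular or ill-conditioned: ",
         conditionMessage(e), call. = FALSE))
  phi <- as.numeric(Matrix::solve(ch, sys$b))
  res <- sqrt(sum((as.numeric(sys$A %*% phi) - sys$b)^2))
  bn <- sqrt(sum(sys$b^2))
  if (bn > 0 && res / bn > config$relative_tolerance)
    stop(sprintf("solver did not reach the requested residual (%.3g > %.3g)",
                 res / bn, config$relative_tolerance), call. = FALSE)
  list(phi = phi, chol = ch)
}

sheet_currents <- function(sys, phi) {
  ns <- length(sys$roles)
  V_sheet <- numeric(ns)
  V_sheet[sys$source] <- sys$V
  V_sheet[sys$roles == "floating"] <- phi[sys$float_col[sys$roles == "floating"]]
  ct <- sys$contact
  flow <- sys$g_c * (V_sheet[ct$sheet] - phi[ct$skin_id])
  out <- tapply(flow, factor(ct$sheet, levels = seq_len(ns)), sum)
  out[is.na(out)] <- 0
  as.numeric(out)
}

#' Solve the inter-sheet current for one penetration combination
#'
#' Solves the steady current-conduction problem `div(sigma grad phi) = 0`
#' on the voxel grid with harmonic-mean face conductances.  Each contact
#' face couples its adjacent skin voxel to the owning sheet's potential
#' node through the conductance
#' `g = contact_conductivity(XY) * A_face / contact_thickness`.  The
#' source sheet is held at the drive voltage, the ground sheet at 0 V;
#' non-tested sheets are by default floating equipotential nodes carrying
#' zero net current (or can be removed entirely with
#' `nontested = "absent"`).  The returned current is the current into the
#' ground sheet, in uA.
#'
#' @param grid a `grid_model` from [discretize()].
#' @param state a [penetration_state()] matrix covering all sheets.
#' @param source,ground sheet ids (1-based) of the driven pair.
#' @param config a [solver_config()].
#' @param nontested `"floating"` (default) or `"absent"`.
#' @return a list of class `current_record`: `pair`, `current_uA`,
#'   `state` (canonical [canonical_state()] of the tested pair),
#'   `balance` (relative source/ground current mismatch),
#'   `sheet_currents_uA` (net current at every sheet).
#' @export
solve_pair_current <- function(grid, state, source, ground,
                               config = solver_config(),
                               nontested = c("floating", "absent")) {
  nontested <- match.arg(nontested)
  sys <- build_system(grid, state, source, ground, config, nontested)
  sol <- solve_system(sys, config)
  record_from_solution(grid, state, sys, sol$phi)
}

record_from_solution <- function(grid, state, sys, phi) {
  Is <- sheet_currents(sys, phi)
  i_src <- Is[sys$source]; i_gnd <- Is[sys$ground]
  balance <- abs(i_src + i_gnd) / max(abs(i_src), .Machine$double.eps)
  if (!inherits(state, "penetration_state")) state <- penetration_state(state)
  nt <- grid$geometry$tips_per_sheet
  a <- sum(state[sys$source, ]); b2 <- sum(state[sys$ground, ])
  structure(list(pair = c(sys$source, sys$ground),
                 current_uA = -i_gnd * 1e6,
                 state = canonical_state(a, b2, nt),
                 balance = balance,
                 sheet_currents_uA = Is * 1e6),
            class = "current_record")
}

#' @export
print.current_record <- function(x, ...) {
  cat(sprintf("I(%s-%s) = %.4g uA [%s state, balance %.2g]\n",
              LETTERS[x$pair[1]], LETTERS[x$pair[2]], x$current_uA,
              state_label(x$state), x$balance))
  invisible(x)
}

#' Verify the solver against a homogeneous slab
#'
#' Solves a homogeneous conductive block with full-width plate electrodes
#' on its top and bottom faces (no contact impedance) and compares the
#' computed conductance with the closed form `G = sigma * A / L`.
#'
#' @param config a [solver_config()].
#' @param sigma conductivity, S/m.
#' @param area electrode area, mm^2.
#' @param length block thickness, mm.
#' @return the relative error `|G_num - G_exact| / G_exact`, with the two
#'   conductances attached as attributes `G_num` and `G_exact` (S).
#' @examples
#' \donttest{validate_homogeneous_slab(solver_config(voxel_size = 100))}
#' @export
validate_homogeneous_slab <- function(config = solver_config(),
                                      sigma = 0.2, area = 1, length = 1) {
  h <- config$voxel_size
  side_um <- sqrt(area) * 1000
  len_um <- length * 1000
  nx <- max(1L, as.integer(round(side_um / h)))
  nz <- max(2L, as.integer(round(len_um / h)))
  h_m <- h * 1e-6
  n <- nx * nx * nz
  idx <- function(ix, iy, iz) ix + (iy - 1L) * nx + (iz - 1L) * nx * nx

  g_int <- sigma * h_m
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  pair_add <- function(i, j, g) {
    ti <<- c(ti, i, j, i, j); tj <<- c(tj, i, j, j, i)
    tx <<- c(tx, rep(g, 2 * length(i)), rep(-g, 2 * length(i)))
  }
  grd <- expand.grid(ix = seq_len(nx), iy = seq_len(nx), iz = seq_len(nz))
  ok <- grd$ix < nx
  pair_add(idx(grd$ix[ok], grd$iy[ok], grd$iz[ok]),
           idx(grd$ix[ok] + 1L, grd$iy[ok], grd$iz[ok]), g_int)
  ok <- grd$iy < nx
  pair_add(idx(grd$ix[ok], grd$iy[ok], grd$iz[ok]),
           idx(grd$ix[ok], grd$iy[ok] + 1L, grd$iz[ok]), g_int)
  ok <- grd$iz < nz
  pair_add(idx(grd$ix[ok], grd$iy[ok], grd$iz[ok]),
           idx(grd$ix[ok], grd$iy[ok], grd$iz[ok] + 1L), g_int)

  # plate electrodes via half-cell conductances on the top/bottom layers
  g_half <- 2 * sigma * h_m
  top <- idx(grd$ix[grd$iz == 1L], grd$iy[grd$iz == 1L], 1L)
  bot <- idx(grd$ix[grd$iz == nz], grd$iy[grd$iz == nz], nz)
  b <- numeric(n)
  V <- config$drive_voltage
  ti <- c(ti, top, bot); tj <- c(tj, top, bot)
  tx <- c(tx, rep(g_half, length(top) + length(bot)))
  b[top] <- b[top] + g_half * V

  A <- Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n)), "U")
  phi <- as.numeric(Matrix::solve(Matrix::Cholesky(A, LDL = FALSE,
                                                   super = TRUE), b))
  I_in <- sum(g_half * (V - phi[top]))
  G_num <- I_in / V
  G_exact <- sigma * (area * 1e-6) / (length * 1e-3)
  structure(abs(G_num - G_exact) / G_exact,
            G_num = G_num, G_exact = G_exact)
}
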