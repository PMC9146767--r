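#' Solver configuration
#'
#' Numerical settings for the forward solver.  The skin block is
#' discretised into cubic voxels of edge `voxel_size` (um); 50 um is the
#' default resolution, 100 um the coarse option used for exhaustive
#' sweeps.  A constant `drive_voltage` (1 V) is applied between the two
#' tested sheets and the terminal current is the measured quantity.  The
#' sparse symmetric positive-definite system is solved by a direct
#' Cholesky factorisation; `relative_tolerance` bounds the accepted
#' relative residual of the solution.
#'
#' @param drive_voltage terminal voltage, V.
#' @param relative_tolerance accepted relative residual of the linear
#'   solve; must lie in (0, 1e-3].
#' @param max_iterations retained for interface compatibility with
#'   iterative back-ends; unused by the direct solver.
#' @param voxel_size voxel edge length, um.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(drive_voltage = 1, relative_tolerance = 1e-8,
                          max_iterations = 10000L, voxel_size = 50) {
  if (!is.finite(drive_voltage) || drive_voltage <= 0)
    stop("'drive_voltage' must be > 0", call. = FALSE)
  if (!is.finite(relative_tolerance) || relative_tolerance <= 0 ||
      relative_tolerance > 1e-3)
    stop("'relative_tolerance' must lie in (0, 1e-3]", call. = FALSE)
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("'voxel_size' must be > 0", call. = FALSE)
  structure(list(drive_voltage = drive_voltage,
                 relative_tolerance = relative_tolerance,
                 max_iterations = as.integer(max_iterations),
                 voxel_size = voxel_size),
            class = "solver_config")
}

#' State-dependent contact conductivity
#'
#' The metal/tissue interface of each inserted needle is a thin contact
#' layer whose conductivity mixes the two skin layers according to the
#' tip's penetration flag `xy`:
#' `(1 - xy) * sigma_dermis + xy * sigma_sc`.
#' An unpenetrated tip (`xy = 1`) sees the stratum corneum conductivity,
#' a penetrated tip (`xy = 0`) the dermis conductivity.
#'
#' @param xy penetration flag(s), each 0 or 1 (vectorised).
#' @param skin a [skin_model()].
#' @return conductivity in S/m, same length as `xy`.
#' @examples
#' contact_conductivity(1, skin_model())  # 0.0005
#' contact_conductivity(0, skin_model())  # 0.2
#' @export
contact_conductivity <- function(xy, skin) {
  stopifnot(inherits(skin, "skin_model"))
  if (!all(xy %in% c(0, 1)))
    stop("penetration flags must be exactly 0 or 1; fractional penetration is not modelled",
         call. = FALSE)
  (1 - xy) * skin$dermis_conductivity + xy * skin$sc_conductivity
}

divides_within_tol <- function(value, h, tol = 1e-6) {
  r <- value / h
  abs(r - round(r)) < tol
}

#' Discretise the device/skin configuration into a voxel grid
#'
#' Builds the finite-volume grid for the forward problem.  The skin block
#' spans `sqrt(footprint_ratio)` times the array extent per lateral axis
#' with the array centred (one-ninth area ratio gives a 3x margin), and
#' the full conductive depth (stratum corneum + dermis) vertically.
#' Needle-occupied voxels are carved out of the grid down to the
#' insertion depth; every face between a carved voxel and a remaining
#' skin voxel becomes a contact face tagged with its owning (sheet, tip).
#' The metal sheets themselves are not meshed: each sheet is later
#' treated as a single equipotential node coupled to the skin through its
#' contact faces.
#'
#' @param geometry an [array_geometry()].
#' @param skin a [skin_model()].
#' @param config a [solver_config()]; its `voxel_size` must divide the
#'   tip width, pitches and (twice the) sheet thickness and must not
#'   exceed the tip width.
#' @return an object of class `grid_model` with elements `dims`,
#'   `voxel_size`, `sigma_z` (per-layer conductivity), `skin_index`,
#'   `n_skin`, `contact` (data.frame of contact faces) and precomputed
#'   internal face lists.
#' @export
discretize <- function(geometry, skin, config = solver_config()) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(skin, "skin_model"),
            inherits(config, "solver_config"))
  h <- config$voxel_size
  if (h > geometry$tip_width)
    stop("'voxel_size' must not exceed the tip width", call. = FALSE)
  if (!divides_within_tol(geometry$tip_width, h))
    stop("'voxel_size' must divide the tip width", call. = FALSE)
  if (!divides_within_tol(geometry$tip_pitch, h) ||
      !divides_within_tol(geometry$sheet_pitch, h))
    stop("'voxel_size' must divide the tip and sheet pitches", call. = FALSE)
  if (!divides_within_tol(geometry$sheet_thickness, h) &&
      !divides_within_tol(2 * geometry$sheet_thickness, h))
    stop("'voxel_size' must divide the sheet thickness (or twice it)",
         call. = FALSE)

  ns <- geometry$n_sheets; nt <- geometry$tips_per_sheet
  # array footprint extents (um): tips along x, sheets along y
  ax <- (nt - 1) * geometry$tip_pitch + geometry$tip_width
  ay <- (ns - 1) * geometry$sheet_pitch + geometry$sheet_thickness
  margin <- sqrt(skin$footprint_ratio)
  nx <- as.integer(ceiling(margin * ax / h - 1e-9))
  ny <- as.integer(ceiling(margin * ay / h - 1e-9))
  nz <- as.integer(round((skin$sc_thickness + skin$dermis_thickness) / h))
  if (nz < 1L) stop("skin depth thinner than one voxel", call. = FALSE)
  n_sc <- as.integer(round(skin$sc_thickness / h))

  # voxel-snapped array placement, centred
  ox <- as.integer(round((nx - ax / h) / 2))
  oy <- as.integer(round((ny - ay / h) / 2))
  wt <- as.integer(round(geometry$tip_width / h))        # tip width, voxels
  ws <- max(1L, as.integer(round(geometry$sheet_thickness / h)))
  px <- as.integer(round(geometry$tip_pitch / h))
  py <- as.integer(round(geometry$sheet_pitch / h))
  dz <- as.integer(round(geometry$insertion_depth / h))
  dz <- min(dz, nz)

  carved <- array(FALSE, dim = c(nx, ny, nz))
  owner_sheet <- array(0L, dim = c(nx, ny, nz))
  owner_tip <- array(0L, dim = c(nx, ny, nz))
  if (dz > 0L) {
    for (s in seq_len(ns)) {
      ys <- oy + (s - 1L) * py + seq_len(ws)
      for (t in seq_len(nt)) {
        xs <- ox + (t - 1L) * px + seq_len(wt)
        carved[xs, ys, 1:dz] <- TRUE
        owner_sheet[xs, ys, 1:dz] <- s
        owner_tip[xs, ys, 1:dz] <- t
      }
    }
  }

  skin_index <- array(0L, dim = c(nx, ny, nz))
  skin_index[!carved] <- seq_len(sum(!carved))
  n_skin <- sum(!carved)

  sigma_z <- ifelse(seq_len(nz) <= n_sc, skin$sc_conductivity,
                    skin$dermis_conductivity)
  h_m <- h * 1e-6

  # internal faces between adjacent skin voxels (insulating outer boundary:
  # faces on the domain surface simply carry no term)
  face_list <- function(axis) {
    if (axis == 1L) {
      a <- skin_index[1:(nx - 1L), , , drop = FALSE]
      b <- skin_index[2:nx, , , drop = FALSE]
      za <- array(rep(sigma_z, each = (nx - 1L) * ny), dim = dim(a))
      zb <- za
    } else if (axis == 2L) {
      a <- skin_index[, 1:(ny - 1L), , drop = FALSE]
      b <- skin_index[, 2:ny, , drop = FALSE]
      za <- array(rep(sigma_z, each = nx * (ny - 1L)), dim = dim(a))
      zb <- za
    } else {
      a <- skin_index[, , 1:(nz - 1L), drop = FALSE]
      b <- skin_index[, , 2:nz, drop = FALSE]
      za <- array(rep(sigma_z[1:(nz - 1L)], each = nx * ny), dim = dim(a))
      zb <- array(rep(sigma_z[2:nz], each = nx * ny), dim = dim(a))
    }
    keep <- a > 0L & b > 0L
    sa <- za[keep]; sb <- zb[keep]
    # harmonic-mean face conductance, SI units: g = sigma_h * A / d with
    # A = h^2, d = h (centre-to-centre)
    g <- 2 * sa * sb / (sa + sb) * h_m
    list(i = a[keep], j = b[keep], g = g)
  }
  faces <- lapply(1:3, face_list)
  faces <- list(i = c(faces[[1]]$i, faces[[2]]$i, faces[[3]]$i),
                j = c(faces[[1]]$j, faces[[2]]$j, faces[[3]]$j),
                g = c(faces[[1]]$g, faces[[2]]$g, faces[[3]]$g))

  # contact faces: carved voxel face adjacent to a skin voxel
  contact <- NULL
  if (dz > 0L) {
    shift <- function(dxi, dyi, dzi) {
      xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
      xs2 <- xs + dxi; ys2 <- ys + dyi; zs2 <- zs + dzi
      okx <- xs2 >= 1L & xs2 <= nx
      oky <- ys2 >= 1L & ys2 <= ny
      okz <- zs2 >= 1L & zs2 <= nz
      cv <- carved[okx, oky, okz, drop = FALSE]
      nb <- skin_index[xs2[okx], ys2[oky], zs2[okz], drop = FALSE]
      osh <- owner_sheet[okx, oky, okz, drop = FALSE]
      oti <- owner_tip[okx, oky, okz, drop = FALSE]
      keep <- cv & nb > 0L
      data.frame(sheet = osh[keep], tip = oti[keep], skin_id = nb[keep])
    }
    dirs <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                 c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
    contact <- do.call(rbind, lapply(dirs, function(d)
      shift(d[1L], d[2L], d[3L])))
  }
  if (is.null(contact) || nrow(contact) == 0L)
    contact <- data.frame(sheet = integer(), tip = integer(),
                          skin_id = integer())
  contact$area_um2 <- rep(h^2, nrow(contact))

  structure(list(dims = c(nx, ny, nz), voxel_size = h, n_sc = n_sc,
                 sigma_z = sigma_z, skin_index = skin_index,
                 n_skin = n_skin, carved_count = sum(carved),
                 faces = faces, contact = contact,
                 geometry = geometry, skin = skin,
                 array_extent_um = c(ax, ay),
                 skin_extent_um = c(nx * h, ny * h)),
            class = "grid_model")
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d (%g um voxels), %d skin voxels\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$n_skin))
  cat(sprintf("  %d carved needle voxels, %d contact faces over %d sheets\n",
              x$carved_count, nrow(x$contact), x$geometry$n_sheets))
  invisible(x)
}

#' Footprint ratio of a built grid
#'
#' Skin lateral area divided by the array footprint area, as realised on
#' the voxel grid.
#'
#' @param grid a `grid_model`.
#' @return dimensionless area ratio.
#' @export
grid_footprint_ratio <- function(grid) {
  stopifnot(inherits(grid, "grid_model"))
  prod(grid$skin_extent_um) / prod(grid$array_extent_um)
}
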