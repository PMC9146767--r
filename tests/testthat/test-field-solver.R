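test_that("contact conductivity mixes the two layers by the penetration flag", {
  sk <- skin_model()
  expect_equal(contact_conductivity(1, sk), 0.0005)
  expect_equal(contact_conductivity(0, sk), 0.2)
  expect_equal(contact_conductivity(c(0, 1, 0), sk), c(0.2, 0.0005, 0.2))
  expect_error(contact_conductivity(0.5, sk), "0 or 1")
})

test_that("discretisation carves the needle footprints and honours the margin", {
  geo <- array_geometry(3, 3)
  sk <- skin_model()
  g <- cached_grid_3x3()
  # 9 needle footprints, each 2 x 1 voxels wide and 6 deep at 100 um
  expect_equal(g$carved_count, 9 * 2 * 1 * 6)
  expect_equal(grid_footprint_ratio(g), 9, tolerance = 1e-12)
  expect_equal(g$dims[3], 19)             # 100 um sc + 1800 um dermis
  expect_setequal(unique(g$contact$sheet), 1:3)
  expect_setequal(unique(g$contact$tip), 1:3)

  # zero insertion: nothing carved, no contact faces, solver refuses
  g0 <- discretize(array_geometry(3, 3, insertion_depth = 1e-9), sk,
                   solver_config(voxel_size = 100))
  expect_equal(g0$carved_count, 0)
  expect_equal(nrow(g0$contact), 0)
  expect_error(solve_pair_current(g0, matrix(0L, 3, 3), 1, 2,
                                  solver_config(voxel_size = 100)),
               "contact faces")

  # doubling the footprint ratio enlarges the grid, not the carved region
  g2 <- discretize(geo, skin_model(footprint_ratio = 18),
                   solver_config(voxel_size = 100))
  expect_true(all(g2$dims[1:2] > g$dims[1:2]))
  expect_equal(g2$carved_count, g$carved_count)

  expect_error(discretize(geo, sk, solver_config(voxel_size = 300)),
               "tip width")
})

test_that("homogeneous slab conductance matches sigma*A/L and scales linearly", {
  cfg <- solver_config(voxel_size = 100)
  err <- validate_homogeneous_slab(cfg)
  expect_lt(as.numeric(err), 0.02)
  # halving the voxel size must not worsen the error
  err50 <- validate_homogeneous_slab(solver_config(voxel_size = 50))
  expect_lte(as.numeric(err50), as.numeric(err) + 1e-12)
  # linearity in sigma
  g1 <- attr(validate_homogeneous_slab(cfg, sigma = 0.2), "G_num")
  g2 <- attr(validate_homogeneous_slab(cfg, sigma = 0.4), "G_num")
  expect_equal(g2 / g1, 2, tolerance = 1e-10)
  expect_equal(attr(validate_homogeneous_slab(cfg, sigma = 0.2), "G_exact"),
               2e-4)
})

test_that("pair solves conserve current and keep floating sheets neutral", {
  cfg <- solver_config(voxel_size = 100)
  g <- cached_grid_3x3()
  st <- penetration_state(rbind(c(1L, 0L, 0L), c(0L, 1L, 1L), c(1L, 1L, 1L)))
  rec <- solve_pair_current(g, st, 1, 2, cfg)
  expect_lt(rec$balance, 1e-6)
  expect_lt(abs(rec$sheet_currents_uA[3]), 1e-6 * rec$current_uA)
  expect_gt(rec$current_uA, 0)
  # reciprocity: exchanging source and ground leaves the current unchanged
  rec2 <- solve_pair_current(g, st, 2, 1, cfg)
  expect_equal(rec2$current_uA, rec$current_uA, tolerance = 1e-10)
  # the record carries the canonical pair state
  expect_identical(state_label(rec$state), "1-2")
  expect_error(solve_pair_current(g, st, 2, 2, cfg), "differ")
})

test_that("swapping the two sheets' patterns leaves the current nearly unchanged", {
  # the state is an unordered pair: the residual asymmetry comes only from
  # the finite lateral margin and is far below the within-state spread
  cfg <- solver_config(voxel_size = 100)
  g <- cached_grid_3x3()
  pa <- c(1L, 0L, 0L); pb <- c(0L, 1L, 1L)
  r1 <- solve_pair_current(g, rbind(pa, pb, rep(1L, 3)), 1, 2, cfg)
  r2 <- solve_pair_current(g, rbind(pb, pa, rep(1L, 3)), 1, 2, cfg)
  expect_equal(r2$current_uA, r1$current_uA, tolerance = 0.01)
})

test_that("unpenetrating any single tip never increases the current", {
  cfg <- solver_config(voxel_size = 100)
  g <- cached_grid_3x3()
  base <- rbind(c(0L, 1L, 0L), c(0L, 0L, 1L), rep(1L, 3))
  I0 <- solve_pair_current(g, base, 1, 2, cfg)$current_uA
  flips <- list(c(1, 1), c(1, 3), c(2, 2))
  for (f in flips) {
    st <- base; st[f[1], f[2]] <- 1L
    I1 <- solve_pair_current(g, st, 1, 2, cfg)$current_uA
    expect_lte(I1, I0 * (1 + 1e-9))
  }
})

test_that("a fully unpenetrated pair is strongly but boundedly suppressed", {
  # the sc/dermis conductivity ratio (400) caps the contrast; the dermis
  # spreading resistance, shared by both circuits, keeps it well below
  cfg <- solver_config(voxel_size = 100)
  g <- cached_grid_3x3()
  I00 <- solve_pair_current(g, matrix(0L, 3, 3), 1, 2, cfg)$current_uA
  I33 <- solve_pair_current(g, matrix(1L, 3, 3), 1, 2, cfg)$current_uA
  ratio <- I00 / I33
  expect_gt(ratio, 10)
  expect_lt(ratio, 400)
})
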