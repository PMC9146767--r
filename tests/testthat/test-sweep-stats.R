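test_that("grouping a complete sweep by nests", {
  sw <- fake_sweep(3)
  by_total <- group_records(sw, "N_total")
  expect_equal(names(by_total), as.character(0:6))
  expect_equal(sum(lengths(by_total)), 64)

  by_state <- group_records(sw, "state")
  expect_equal(length(by_state), 10)  # all low <= high pairs over 0..3
  expect_equal(names(by_state)[1:3], c("0-0", "0-1", "1-1"))

  # N_total = 2 splits into the 1-1 and 0-2 states
  two <- sw[sw$state_low + sw$state_high == 2, ]
  expect_setequal(paste0(two$state_low, "-", two$state_high),
                  c("1-1", "0-2"))
  expect_equal(length(by_total[["2"]]),
               length(by_state[["1-1"]]) + length(by_state[["0-2"]]))

  expect_error(group_records(sw[-1, ], "N_total"), "incomplete")
})

test_that("per-state means pool the nonconductive class and keep rank order", {
  sw <- fake_sweep(3)
  sm <- state_means(sw)
  expect_equal(sm$label, c("0-0", "0-1", "1-1", "0-2", "1-2", "2-2", "3+"))
  expect_equal(sm$n_records, c(1, 6, 9, 6, 18, 9, 15))
  # the fully penetrated class is a singleton: its mean is its record
  expect_equal(sm$mean_uA[1], sw$current_uA[1])
  expect_true(all(diff(sm$mean_uA) < 0))
})

test_that("interval boundaries sit at midpoints of adjacent state means", {
  sm <- structure(data.frame(label = c("0-0", "0-1", "1+"),
                             rank = c(0, 1, 2), n_records = c(1, 2, 1),
                             mean_uA = c(100, 80, 10)),
                  n = 1L, class = c("state_means", "data.frame"))
  tab <- interval_boundaries(sm)
  expect_s3_class(tab, "calibration_table")
  expect_equal(tab$lower_uA, c(90, 45, 0))
  expect_equal(tab$upper_uA, c(NA, 90, 45))
  expect_equal(tab$length_uA, c(NA, 45, 45))
  expect_true(is.na(tab$upper_uA[1]))  # first interval is half-open above

  # tied adjacent means are a degenerate calibration
  sm$mean_uA <- c(100, 100, 10)
  expect_error(interval_boundaries(sm), "tied|monotone")

  full <- interval_boundaries(state_means(fake_sweep(3)))
  expect_equal(nrow(full), 7)
  expect_equal(full$lower_uA[nrow(full)], 0)
  # closed intervals have length upper - lower
  closed <- !is.na(full$upper_uA)
  expect_equal(full$length_uA[closed],
               full$upper_uA[closed] - full$lower_uA[closed])
})

test_that("combinatorial heat maps are exact and conserve events", {
  tab3 <- packaged_table("3x3", 1)
  hm <- heatmap_counts(tab3, axis = "state", mode = "combinatorial")
  expect_equal(hm["5", "1-2"], 18)   # interval 5 holds the 1-2 state
  expect_equal(sum(hm), 64)
  expect_equal(unname(colSums(hm)[c("0-0", "1-1", "3+")]), c(1, 9, 15))

  tab4 <- packaged_table("4x4", 1)
  hm4 <- heatmap_counts(tab4, axis = "state", mode = "combinatorial")
  expect_equal(hm4["3", "1-1"], 16)
  expect_equal(sum(hm4), 256)

  hmt <- heatmap_counts(tab3, axis = "N_total", mode = "combinatorial")
  expect_equal(sum(hmt), 64)
  expect_equal(unname(hmt["1", "0"]), 1)

  # by-current mode bins the synthetic sweep identically to its own table
  sw <- fake_sweep(3)
  ctab <- interval_boundaries(state_means(sw))
  hmc <- heatmap_counts(ctab, axis = "state", mode = "by_current",
                        records = sw)
  expect_equal(sum(hmc), 64)
  expect_equal(unname(diag(hmc[, c("0-0", "0-1", "1-1", "0-2", "1-2",
                                   "2-2", "3+")])),
               c(1, 6, 9, 6, 18, 9, 15))
  expect_error(heatmap_counts(ctab, axis = "state", mode = "by_current"),
               "records")
})

test_that("interval summaries give per-interval probabilities, mean and deviation", {
  cnt <- matrix(c(4, 4, 0, 0,
                  0, 2, 2, 0), nrow = 2, byrow = TRUE,
                dimnames = list(interval = 1:2, axis = 0:3))
  s <- interval_summary(cnt)
  p <- attr(s, "probabilities")
  expect_equal(unname(rowSums(p)), c(1, 1))
  expect_equal(s$mean, c(0.5, 1.5))   # uniform over two adjacent values
  expect_equal(s$deviation, c(0.5, 0.5))

  empty <- matrix(c(1, 0, 0, 0), nrow = 2, byrow = TRUE,
                  dimnames = list(interval = 1:2, axis = 0:1))
  se <- interval_summary(empty)
  expect_true(se$empty[2])
  expect_true(is.na(se$mean[2]))
  expect_error(interval_summary(matrix(1, 1, 1,
                                       dimnames = list(1, "0-0"))),
               "numeric axis")
})

test_that("6x6 interval summaries reproduce the first/last interval structure", {
  tab <- packaged_table("6x6", 1)
  hm <- heatmap_counts(tab, axis = "N_total", mode = "combinatorial")
  s <- interval_summary(hm)
  expect_equal(s$mean[1], 0)        # only N_total = 0 in interval 1
  expect_equal(s$deviation[1], 0)
  expect_equal(sum(hm["7", ] > 0), 7)  # N_total 6..12 in the last interval
  expect_setequal(colnames(hm)[hm["7", ] > 0], as.character(6:12))
  # intervals 1-3 and 7 hold a small minority of the 4096 events
  expect_equal(sum(hm[c("1", "2", "3", "7"), ]), 386)
})

test_that("distinct totals per interval grow as the current drops", {
  tab <- packaged_table("6x6", 1)
  d <- distinct_totals_per_interval(tab)
  expect_equal(d[1], 1)
  expect_equal(d[7], 7)
  expect_equal(d[4], 3)   # states 0-3, 2-2, 1-3, 2-3 span totals 3..5
  expect_true(all(diff(d) >= 0))
})

test_that("modal per-sheet maxima follow the table grouping", {
  tab <- packaged_table("6x6", 1)
  nm <- interval_nmax(tab)
  # interval 4 mixes maxima 2 and 3; the combinatorial mode is 3
  expect_equal(nm, c(0, 1, 2, 3, 4, 5, 6))
  tab3 <- packaged_table("3x3", 1)
  expect_equal(interval_nmax(tab3), c(0, 1, 1, 2, 2, 2, 3))
})
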