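test_that("current lookup maps into half-open intervals with overlap handling", {
  tab <- packaged_table("3x3", 1)
  expect_equal(lookup_state(250, tab)$label, "1-1")
  expect_equal(lookup_state(400, tab)$label, "0-0")
  lk50 <- lookup_state(50, tab)
  expect_equal(lk50$label, "3+")
  expect_true(lk50$nonconductive)
  # boundaries are [lower, upper)
  expect_equal(lookup_state(301, tab)$label, "0-1")
  expect_equal(lookup_state(300.999, tab)$label, "1-1")
  # the printed 171-177 overlap resolves to the higher-current interval
  lk <- lookup_state(173, tab)
  expect_equal(lk$interval, 5)
  expect_true(lk$ambiguous)
  expect_false(lookup_state(250, tab)$ambiguous)
  expect_error(lookup_state(-1, tab), "nonnegative")

  # grouped 6x6 lookup returns the state group and its modal maximum
  tab6 <- packaged_table("6x6", 1)
  lk6 <- lookup_state(500, tab6)
  expect_null(lk6$state)
  expect_equal(lk6$interval, 4)
  expect_equal(lk6$n_max, 3)
})

test_that("three-sheet exact decoding follows the branch logic", {
  expect_equal(unname(exact_decode_three(state3(1, 2), state3(1, 2),
                                         state3(2, 2))), c(2, 1, 2))
  expect_equal(unname(exact_decode_three(state3(0, 0), state3(0, 0),
                                         state3(0, 0))), c(0, 0, 0))
  expect_equal(unname(exact_decode_three(state3(1, 2), state3(2, 2),
                                         state3(1, 2))), c(1, 2, 2))
  expect_equal(unname(exact_decode_three(state3(0, 1), state3(0, 2),
                                         state3(1, 2))), c(1, 0, 2))

  # physically inconsistent measurements fail loudly, naming the pair
  expect_error(exact_decode_three(state3(1, 2), state3(1, 1), state3(0, 0)),
               class = "mn_inconsistency")
  # nonconductive input: the correspondence is lost
  expect_error(exact_decode_three(state3(3, 1), state3(0, 0), state3(0, 0)),
               class = "mn_ambiguity")
})

test_that("chain extension uses up the matched element", {
  expect_equal(exact_extend(2, state3(2, 0)), 0)
  expect_equal(exact_extend(1, state3(1, 1)), 1)
  expect_error(exact_extend(0, state3(1, 2)), class = "mn_inconsistency")

  counts <- exact_decode_chain(list(AB = state4(0, 1), BC = state4(0, 2),
                                    AC = state4(1, 2), CD = state4(2, 2)))
  expect_equal(unname(counts), c(1, 0, 2, 2))
  expect_named(counts, c("A", "B", "C", "D"))

  zero <- lapply(1:4, function(i) state3(0, 0))
  names(zero) <- c("AB", "BC", "AC", "CD")
  expect_equal(unname(exact_decode_chain(zero)), c(0, 0, 0, 0))
  expect_error(exact_decode_chain(list(AB = state3(0, 0))), "AB, BC and AC")
})

test_that("exact decoding recovers every conductive truth (exhaustive oracle)", {
  # 3 sheets, 3-tip sheets: all truths with every pairwise state conductive
  for (a in 0:2) for (b in 0:2) for (c in 0:2) {
    sAB <- canonical_state(a, b, 3)
    sBC <- canonical_state(b, c, 3)
    sAC <- canonical_state(a, c, 3)
    dec <- exact_decode_three(sAB, sBC, sAC)
    cons <- oracle_triples(sAB, sBC, sAC, 2)
    expect_equal(unname(dec), c(a, b, c))
    expect_true(any(vapply(cons, identical, logical(1),
                           y = c(a, b, c))))
  }
  # 4 sheets, 4-tip sheets, chained through CD
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    counts <- exact_decode_chain(list(AB = canonical_state(a, b, 4),
                                      BC = canonical_state(b, c, 4),
                                      AC = canonical_state(a, c, 4),
                                      CD = canonical_state(c, d, 4)))
    expect_equal(unname(counts), c(a, b, c, d))
  }
})

test_that("fuzzy max/median equals the sort oracle on all count triples", {
  for (a in 0:6) for (b in 0:6) for (c in 0:6) {
    mm <- fuzzy_max_med(max(a, b), max(b, c), max(a, c))
    srt <- sort(c(a, b, c), decreasing = TRUE)
    expect_true(mm$valid)
    expect_equal(mm$n_max, srt[1])
    expect_equal(mm$n_med, srt[2])
  }
  expect_equal(fuzzy_max_med(2, 3, 3)[c("n_max", "n_med")],
               list(n_max = 3, n_med = 2))
  expect_equal(fuzzy_max_med(0, 0, 0)[c("n_max", "n_med")],
               list(n_max = 0, n_med = 0))
  expect_warning(mm <- fuzzy_max_med(3, 2, 1), "not realisable")
  expect_false(mm$valid)
})

test_that("fuzzy totals and the transdermal rate follow their formulas", {
  expect_equal(fuzzy_estimate(c(2, 0, 1), "pairs"), 4.5)
  expect_equal(fuzzy_estimate(list(n_max = 3, n_med = 2), "three_sheet"), 6)
  expect_equal(fuzzy_estimate(c(0, 0, 0), "pairs"), 0)

  expect_equal(transdermal_rate(4.5, 36), 0.875)
  expect_equal(transdermal_rate(0, 9), 1)
  expect_equal(transdermal_rate(9, 9), 0)
  expect_warning(r <- transdermal_rate(40, 36), "clamped")
  expect_equal(r, 0)
})

test_that("the end-to-end decoder recovers truth from in-interval currents", {
  tabs <- packaged_tables("3x3")
  rep_cur <- function(a, b, d)
    mnscreen:::representative_current(min(a, b), max(a, b),
                                      tabs[[as.character(d)]])
  for (a in 0:2) for (b in 0:2) for (c in 0:2) {
    cur <- data.frame(pair = c("AB", "BC", "AC"),
                      current_uA = c(rep_cur(a, b, 1), rep_cur(b, c, 1),
                                     rep_cur(a, c, 2)))
    res <- decode_currents(cur, "3x3", method = "exact")
    expect_equal(unname(res$per_sheet_counts), c(a, b, c))
    expect_equal(res$estimated_total, a + b + c)
    expect_equal(res$transdermal_rate, 1 - (a + b + c) / 9)
    expect_equal(res$unknown_rate, 0)
  }
  # grouped tables refuse the exact method
  cur6 <- data.frame(pair = c("AB", "BC", "AC", "CD", "DE", "EF"),
                     current_uA = rep(700, 6))
  expect_error(decode_currents(cur6, "6x6", method = "exact"),
               class = "mn_usage")
})

test_that("fuzzy decoding estimates the 6x6 total from grouped intervals", {
  tabs <- packaged_tables("6x6")
  rep_cur <- function(a, b, d)
    mnscreen:::representative_current(min(a, b), max(a, b),
                                      tabs[[as.character(d)]])
  # truth counts per sheet A..F
  tr <- c(A = 2, B = 1, C = 0, D = 3, E = 1, F = 0)
  cur <- data.frame(pair = c("AB", "BC", "AC", "DE", "EF", "DF", "CD"),
                    current_uA = c(rep_cur(2, 1, 1), rep_cur(1, 0, 1),
                                   rep_cur(2, 0, 2), rep_cur(3, 1, 1),
                                   rep_cur(1, 0, 1), rep_cur(3, 0, 2),
                                   rep_cur(0, 3, 1)))
  res <- decode_currents(cur, "6x6", method = "fuzzy",
                         scheme = "three_sheet")
  # group ABC: max 2, med 1 -> 3.5; group DEF: max 3, med 1 -> 4.5
  expect_equal(res$estimated_total, 3.5 + 4.5)
  expect_equal(res$unknown_rate, 1 / 3)
  expect_true(all(is.na(res$per_sheet_counts)))
  expect_equal(res$transdermal_rate, 1 - 8 / 36)

  res2 <- decode_currents(cur[cur$pair %in% c("AB", "CD", "EF"), ],
                          "6x6", method = "fuzzy", scheme = "pairs")
  # pairwise maxima 2, 3, 1 -> N = 1.5 * 6 = 9
  expect_equal(res2$estimated_total, 9)
  expect_equal(res2$unknown_rate, 1 / 2)
})
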