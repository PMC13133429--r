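test_that("self-scan finds planted tandem units at TM ~1", {
  unit <- make_chain(fixture_spec(3, list(c("helix", 10), c("strand", 6),
                                          c("helix", 8), c("strand", 6))),
                     "unit_A")
  rep2 <- tandem_repeat(unit, 2)
  ts <- encode_chain(rep2)
  hits <- scan_chain(rep2, ts)
  expect_gt(nrow(hits), 0)
  # after consolidation the full-unit pair wins (equal TM, longer span)
  kept <- consolidate(hits)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$left_start, kept$left_end), c(0, 4))
  expect_equal(c(kept$right_start, kept$right_end), c(4, 8))
  expect_equal(kept$tm, 1.0, tolerance = 0.02)
})

test_that("scan effort matches the window-extension convention", {
  # a 19-SSE chain admits 14 extensions from the N-terminal start
  ch <- make_random_chain(77, 19)
  ts <- encode_chain(ch)
  expect_equal(length(ts), 19)
  hits <- scan_chain(ch, ts, all_starts = FALSE)
  expect_equal(attr(hits, "n_alignments_first_start"), 14L)
  expect_error(scan_chain(ch, encode_chain(make_random_chain(1, 5))),
               "too short")
})

test_that("non-repetitive chains yield no retained hits", {
  n_empty <- sum(vapply(1:8, function(s) {
    ch <- make_random_chain(400 + s, 7)
    nrow(self_scan(ch)$hits) == 0
  }, logical(1)))
  expect_gte(n_empty, 7)   # >= 90% of seeded non-repetitive fixtures
})

test_that("consolidation keeps higher TM, then longer span, and is idempotent", {
  h <- data.frame(left_start = c(0L, 0L), left_end = c(4L, 4L),
                  right_start = c(4L, 5L), right_end = c(8L, 9L),
                  tm = c(0.9, 0.8), span_residues = c(80L, 80L))
  out <- consolidate(h)
  expect_equal(nrow(out), 1)
  expect_equal(out$tm, 0.9)

  h2 <- data.frame(left_start = c(0L, 0L), left_end = c(4L, 4L),
                   right_start = c(4L, 5L), right_end = c(8L, 9L),
                   tm = c(0.60, 0.62), span_residues = c(80L, 60L))
  out2 <- consolidate(h2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$span_residues, 80L)   # delta TM < 0.05: span decides

  disjoint <- data.frame(left_start = c(0L, 8L), left_end = c(3L, 11L),
                         right_start = c(3L, 12L), right_end = c(6L, 15L),
                         tm = c(0.7, 0.9), span_residues = c(50L, 50L))
  expect_equal(nrow(consolidate(disjoint)), 2)

  expect_identical(consolidate(consolidate(h2)), consolidate(h2))
})

test_that("repeat counting follows coverage over minimal unit length", {
  # 4 x 3-SSE units, full 12-SSE coverage: three pairwise hits
  h <- data.frame(left_start = c(0L, 0L, 0L), left_end = c(3L, 3L, 3L),
                  right_start = c(3L, 6L, 9L), right_end = c(6L, 9L, 12L),
                  tm = c(0.9, 0.9, 0.9), span_residues = c(60L, 60L, 60L))
  s <- summarize_repeats("x_A", h)
  expect_equal(s$repeat_count, 4L)
  expect_equal(s$min_unit_length, 3L)

  # two repeat regions separated by a 5-SSE gap: counts add up
  h2 <- data.frame(left_start = c(0L, 11L), left_end = c(3L, 14L),
                   right_start = c(3L, 14L), right_end = c(6L, 17L),
                   tm = c(0.8, 0.8), span_residues = c(60L, 60L))
  s2 <- summarize_repeats("y_A", h2)
  expect_equal(s2$repeat_count, 4L)      # 2 + 2 over two sub-components

  s0 <- summarize_repeats("z_A", h[0, ])
  expect_equal(s0$repeat_count, 0L)

  # invariant to input hit order
  s_rev <- summarize_repeats("x_A", h[rev(seq_len(nrow(h))), ])
  expect_equal(s_rev$repeat_count, s$repeat_count)
  expect_equal(s_rev$unit_boundaries, s$unit_boundaries)
})

test_that("symmetry call is strict at TM 0.5 and needs two units", {
  h <- data.frame(left_start = 0L, left_end = 3L,
                  right_start = 3L, right_end = 6L,
                  tm = 0.5, span_residues = 60L)
  s <- summarize_repeats("x_A", h)
  expect_false(classify_symmetric(s, h))          # tm == 0.5: strictly above
  h$tm <- 0.51
  expect_true(classify_symmetric(summarize_repeats("x_A", h), h))
  expect_false(classify_symmetric(summarize_repeats("x_A", h[0, ]), h[0, ]))
})

test_that("planted k-fold tandem repeats are recovered within coarsening", {
  for (k in 2:4) {
    for (seed in c(3, 5)) {
      unit <- make_chain(fixture_spec(seed, list(c("helix", 10),
                                                 c("strand", 6),
                                                 c("helix", 8))),
                         sprintf("u%d_A", seed))
      chain <- tandem_repeat(unit, k)
      res <- self_scan(chain)
      expect_true(res$symmetric)
      expect_gte(res$summary$repeat_count, 2L)
      expect_lte(res$summary$repeat_count, k)
      # merging into double-size units is the only allowed coarsening
      expect_true(res$summary$repeat_count %in% unique(c(k, ceiling(k / 2))))
      if (k %in% 2:3)
        expect_equal(res$summary$repeat_count, k)
    }
  }
})
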