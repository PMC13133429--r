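test_that("doubled query reveals the circular-permutation seam", {
  mk <- function(toks) structure(list(chain_id = "x_A", tokens = toks,
                                      segments = data.frame()),
                                 class = "sse_tokens")
  m <- default_matrix()
  q <- mk(c("a", "b", "c", "d", "e"))
  t_ <- mk(c("d", "e", "a", "b", "c"))
  hit <- double_and_align(q, t_, m)
  expect_true(hit$crosses_seam)
  expect_equal(hit$boundary_token, 3L)   # cut before 'd': C-segment {d,e}
  expect_equal(hit$side_c, 2L)
  expect_equal(hit$side_n, 3L)
  expect_false(hit$cp_candidate)         # C side has only 2 SSEs

  # no permutation: the best hit stays on the diagonal, off the seam
  self_hit <- double_and_align(q, q, m)
  expect_false(self_hit$crosses_seam)

  expect_error(double_and_align(mk(c("a", "b", "c", "d")), t_, m),
               "below SSE-count filter")
})

test_that("indel rule flips exactly at the published thresholds", {
  cfg <- ssesym_config()
  # absolute rule: 40 residues
  expect_false(classify_indel(39, 100, 100, cfg))
  expect_true(classify_indel(40, 100, 100, cfg))
  # fractional rule: 60% of the smaller segment (below the 40-residue rule)
  expect_false(classify_indel(29, 50, 120, cfg))   # 58%
  expect_true(classify_indel(30, 50, 120, cfg))    # 60%
  # 20-30 residue gaps on typical segments are minor loop variation
  expect_false(classify_indel(20, 100, 80, cfg))
  expect_false(classify_indel(30, 100, 80, cfg))
})

test_that("equal-half permutant verifies as a circular permutation", {
  A <- make_cp_bench(11)
  B <- circular_permute(A, length(A) %/% 2)
  qt <- encode_chain(B); tt <- encode_chain(A)
  hit <- double_and_align(qt, tt)
  expect_true(hit$cp_candidate)
  rec <- rearrange_and_verify(B, A, qt, tt, hit)
  expect_equal(rec$tm_original, 0.5, tolerance = 0.08)
  expect_equal(rec$tm_rearranged, 1.0, tolerance = 0.02)
  expect_true(rec$is_cp)
  expect_false(rec$is_indel)

  # stored rearranged TM is reproducible from the serialized boundary
  b_res <- match(rec$boundary_res, B$resno) - 1L
  redo <- tm_align_sequential(circular_permute(B, b_res), A,
                              normalize_on = "shorter")
  expect_identical(redo$tm, rec$tm_rearranged)
})

test_that("identical chains forced through the seam are not CPs", {
  A <- make_cp_bench(15)
  ts <- encode_chain(A)
  hit <- double_and_align(ts, ts)
  # force a seam evaluation at the token midpoint
  forced <- hit
  forced$crosses_seam <- TRUE
  forced$boundary_token <- length(ts) %/% 2L
  forced$side_n <- length(ts) - forced$boundary_token
  forced$side_c <- forced$boundary_token
  forced$cp_candidate <- TRUE
  forced$t_img_c <- NULL; forced$t_img_n <- NULL
  rec <- rearrange_and_verify(A, A, ts, ts, forced)
  expect_lt(rec$delta_tm, 0.1)
  expect_false(rec$is_cp)
})

test_that("a 45-residue insertion between segment images flags an indel", {
  A <- make_cp_bench(11)
  B <- circular_permute(A, length(A) %/% 2)
  B45 <- apply_indel(B, length(B) %/% 2, 45, "insert")
  rec <- run_pairwise(A, B45)
  expect_equal(nrow(rec), 1)
  expect_gte(rec$gap_residues, 45)
  expect_true(rec$is_indel)
  expect_true(rec$is_cp)

  # a 20-residue insertion is minor loop variation
  B20 <- apply_indel(B, length(B) %/% 2, 20, "insert")
  rec20 <- run_pairwise(A, B20)
  expect_false(rec20$is_indel)
})

test_that("split symmetry calls tandem duplications and rejects mixed folds", {
  unit <- make_chain(fixture_spec(3, list(c("helix", 10), c("strand", 6),
                                          c("helix", 8))), "u_A")
  dup <- tandem_repeat(unit, 2)
  ts <- encode_chain(dup)
  res <- classify_symmetry_by_split(dup, ts, 3L)  # split at unit boundary
  expect_true(res$is_symmetric)
  expect_equal(res$tm, 1.0, tolerance = 0.02)

  mixed <- make_chain(fixture_spec(9, list(c("helix", 12), c("helix", 12),
                                           c("helix", 12), c("strand", 6),
                                           c("strand", 6), c("strand", 6))),
                      "mix_A")
  tsm <- encode_chain(mixed)
  resm <- classify_symmetry_by_split(mixed, tsm, 3L)
  expect_false(resm$is_symmetric)
  expect_lt(resm$tm, 0.5)

  expect_error(classify_symmetry_by_split(dup, ts, 2L), "half too short")
})

test_that("run_pairwise composes end to end", {
  A <- make_cp_bench(16)
  B <- circular_permute(A, length(A) %/% 2)
  rec <- run_pairwise(B, A)
  expect_equal(nrow(rec), 1)
  expect_true(rec$is_cp)

  # identical chains: no cross-boundary record
  rec0 <- run_pairwise(A, A)
  expect_equal(nrow(rec0), 0)

  # all-coil chain fails the SSE-count precondition
  coil <- protein_chain("c_A", make_walk_chain(9)$xyz)
  expect_error(run_pairwise(coil, A), "below SSE-count filter")
})

test_that("CP detection is involutive across role assignments", {
  for (seed in c(31, 32)) {
    A <- make_random_chain(seed, 6)
    seg <- encode_chain(A)$segments
    b_res <- seg$start_res[4]               # cut before the 4th SSE
    B <- circular_permute(A, b_res)
    r1 <- run_pairwise(B, A, both_roles = FALSE)
    r2 <- run_pairwise(A, B, both_roles = FALSE)
    expect_equal(nrow(r1), 1)
    expect_equal(nrow(r2), 1)
    expect_true(r1$is_cp)
    expect_true(r2$is_cp)
    expect_equal(r1$tm_rearranged, r2$tm_rearranged, tolerance = 0.05)
  }
})
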