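test_that("self-alignment is end-to-end with identity 1", {
  m <- default_matrix()
  for (tok in list(c("a", "b", "c", "B"), c("j", "E", "j", "G", "i", "G"))) {
    a <- smith_waterman(tok, tok, m)
    expect_equal(a$identity, 1.0)
    expect_equal(a$coverage, 1.0)
    expect_equal(a$score, sum(m$scores[cbind(tok, tok)]))
    expect_equal(a$query_range, c(0L, length(tok)))
    expect_equal(a$target_range, c(0L, length(tok)))
  }
})

test_that("all-negative scores yield the empty alignment", {
  m <- default_matrix()
  a <- smith_waterman("a", "B", m)     # helix vs strand: mismatch < 0
  expect_equal(a$score, 0)
  expect_equal(nrow(a$pairs), 0)
  expect_equal(a$identity, 0)
  expect_error(smith_waterman(character(0), "a", m), "empty")
})

test_that("alignment score is symmetric under a symmetric matrix", {
  m <- default_matrix()
  set.seed(42)
  alpha <- c("a", "c", "B", "D")
  for (k in 1:25) {
    q <- sample(alpha, sample(2:6, 1), replace = TRUE)
    t_ <- sample(alpha, sample(2:6, 1), replace = TRUE)
    expect_equal(smith_waterman(q, t_, m)$score,
                 smith_waterman(t_, q, m)$score)
  }
})

test_that("DP score equals brute-force enumeration on random short pairs", {
  m <- default_matrix()
  set.seed(7)
  alpha <- c("a", "c", "B", "D")
  for (k in 1:150) {
    q <- sample(alpha, sample(1:6, 1), replace = TRUE)
    t_ <- sample(alpha, sample(1:6, 1), replace = TRUE)
    expect_equal(smith_waterman(q, t_, m)$score,
                 brute_force_local_score(q, t_, m),
                 info = paste(paste(q, collapse = ""), "vs",
                              paste(t_, collapse = "")))
  }
})

test_that("element-specific gap penalties are charged for the skipped class", {
  # helix gaps cheap, strand gaps prohibitive: skipping the strand token
  # in the target must cost the strand penalty
  m <- default_matrix(gap_open = c(helix = -1, strand = -10),
                      gap_extend = c(helix = -0.5, strand = -5))
  q <- c("a", "a")
  t1 <- c("a", "z", "a")   # distant helix token skipped: -1 - 0.5
  t2 <- c("a", "Z", "a")   # strand token skipped: -10 - 5
  s1 <- smith_waterman(q, t1, m)$score
  s2 <- smith_waterman(q, t2, m)$score
  expect_equal(s1, 4 + 4 - 1.5)
  expect_gt(s1, s2)
  expect_equal(s2, 4)      # cheaper to keep just one match
})

test_that("default matrix orders scores by bin distance and class", {
  m <- default_matrix()
  expect_gt(m$scores["b", "b"], m$scores["b", "c"])
  expect_gt(m$scores["b", "c"], m$scores["b", "B"])
  expect_lt(m$scores["b", "B"], 0)
  expect_true(isTRUE(all.equal(m$scores, t(m$scores))))
})

test_that("matrix files round-trip and are validated", {
  m <- default_matrix()
  path <- tempfile(fileext = ".json")
  save_matrix(m, path)
  m2 <- load_matrix(path)
  expect_equal(m2$scores, m$scores)
  expect_equal(m2$gap_open, m$gap_open)
  expect_equal(m2$gap_extend, m$gap_extend)

  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$gap_open <- NULL
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE)
  expect_error(load_matrix(bad), "missing key")

  raw2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw2$scores[1, 2] <- raw2$scores[1, 2] + 1    # break symmetry
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw2, bad2, auto_unbox = TRUE)
  expect_error(load_matrix(bad2), "symmetric")
})

test_that("prescreen surrogate is calibrated and monotone in identity", {
  m <- default_matrix()
  tok <- c("a", "B", "c", "D", "e")
  self <- smith_waterman(tok, tok, m)
  expect_equal(prescreen_score(self, tok, tok, m), 1.0)

  none <- smith_waterman("a", "B", m)
  expect_equal(prescreen_score(none, "a", "B", m), 0.0)

  # monotone, non-decreasing in identity at fixed coverage and score
  base <- smith_waterman(tok, tok, m)
  grid <- seq(0, 1, by = 0.1)
  vals <- vapply(grid, function(id) {
    fake <- base
    fake$identity <- id
    prescreen_score(fake, tok, tok, m)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})
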