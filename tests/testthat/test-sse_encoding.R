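test_that("segment_ss3 extracts maximal helix/strand runs with a back-map", {
  seg <- segment_ss3("CCHHHHCCEEECC")
  expect_equal(seg$ss_type, c("helix", "strand"))
  expect_equal(seg$start_res, c(2, 8))
  expect_equal(seg$end_res, c(6, 11))
  expect_equal(seg$length, c(4, 3))

  expect_equal(nrow(segment_ss3("CCCCC")), 0)
  expect_equal(nrow(segment_ss3("HEHEH", min_segment_length = 2)), 0)
  expect_equal(nrow(segment_ss3("HEHEH", min_segment_length = 1)), 5)
})

test_that("token map hits the published anchors and the stated bin scheme", {
  expect_equal(length_to_token(2, "strand"), "A")
  expect_equal(length_to_token(3, "strand"), "B")
  expect_equal(length_to_token(3, "helix"), "b")
  expect_equal(length_to_token(10, "strand"), "I")
  # width-2 bins from 11, width-3 above 30, overflow above the cap
  expect_equal(length_to_token(11, "strand"), "J")
  expect_equal(length_to_token(12, "strand"), "J")
  expect_equal(length_to_token(13, "strand"), "K")
  expect_equal(length_to_token(30, "strand"), "S")
  expect_equal(length_to_token(31, "strand"), "T")
  expect_equal(length_to_token(33, "strand"), "T")
  expect_equal(length_to_token(34, "strand"), "U")
  expect_equal(length_to_token(48, "strand"), "Y")
  expect_equal(length_to_token(49, "strand"), "Z")
  expect_equal(length_to_token(500, "strand"), "Z")
  expect_error(length_to_token(1, "strand"), "too short")
})

test_that("tokenization is injective on (type, bin) with case encoding type", {
  lens <- 2:60
  toks_s <- vapply(lens, length_to_token, "", ss_type = "strand")
  toks_h <- vapply(lens, length_to_token, "", ss_type = "helix")
  expect_true(all(toks_s %in% LETTERS))
  expect_true(all(toks_h %in% letters))
  expect_identical(tolower(toks_s), toks_h)
  # monotone non-decreasing bin letters; distinct bins never share a token
  ab <- sse_alphabet()
  expect_identical(ab$letter, unique(toks_s))
  expect_true(all(diff(match(toks_s, LETTERS)) >= 0))
  # bins tile the lengths with no gap
  expect_true(all(ab$min_len[-1] == head(ab$max_len, -1) + 1))
})

test_that("encode_chain composes segmentation and tokenization", {
  mk <- function(ss3) protein_chain("t_A",
                                    matrix(rnorm(3 * nchar(ss3)), ncol = 3),
                                    ss3 = strsplit(ss3, "")[[1]])
  ts <- encode_chain(mk("CCHHHHCCEEECC"))
  expect_equal(ts$tokens, c("c", "B"))
  expect_equal(length(ts), nrow(ts$segments))

  expect_equal(length(encode_chain(mk("CCCCCC"))), 0)
  expect_equal(encode_chain(mk("HHH"))$tokens, "b")

  # idempotence: re-encoding the decoded segment list changes nothing
  seg <- ts$segments
  retok <- vapply(seq_len(nrow(seg)), function(i)
    length_to_token(seg$length[i], seg$ss_type[i]), "")
  expect_identical(retok, ts$tokens)

  # segments reconstruct a non-overlapping residue subsequence
  ch <- make_random_chain(31, 7)
  seg <- encode_chain(ch)$segments
  covered <- unlist(mapply(seq, seg$start_res + 1, seg$end_res,
                           SIMPLIFY = FALSE))
  expect_false(any(duplicated(covered)))
  expect_true(all(diff(covered) > 0))
})

test_that("compression ratio matches direct Shannon-entropy computation", {
  expect_equal(compression_ratio(100, 10, 4.0, 4.0), 10.0)
  expect_equal(compression_ratio(100, 100, 4.0, 4.0), 1.0)
  expect_error(compression_ratio(100, 0, 4, 4), "undefined")

  # corpus-level: empirical entropies vs a hand-rolled oracle
  chains <- lapply(1:20, function(s) make_random_chain(s, 6))
  toks <- unlist(lapply(chains, function(ch) encode_chain(ch)$tokens))
  aa_len <- sum(vapply(chains, length, integer(1)))
  # oracle entropy from first principles
  p <- as.numeric(table(toks)) / length(toks)
  h_oracle <- -sum(p * log2(p))
  expect_equal(shannon_entropy(toks), h_oracle)
  r <- compression_ratio(aa_len, length(toks),
                         aa_alphabet_entropy = log2(20),
                         token_alphabet_entropy = h_oracle)
  expect_equal(r, (aa_len * log2(20)) / (length(toks) * h_oracle))
  expect_gt(r, 1)  # the encoding must actually compress
})

test_that("token FASTA and segment TSV serialisation round-trip", {
  ch <- make_random_chain(8, 6)
  ts <- encode_chain(ch)
  fa <- tempfile(fileext = ".fasta")
  write_tokens_fasta(ts, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], paste0(">", ch$chain_id))
  expect_equal(lines[2], paste(ts$tokens, collapse = ""))
  tsv <- tempfile(fileext = ".tsv")
  write_segments_tsv(ts, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), length(ts))
  expect_equal(back$start_res, ts$segments$start_res)
})
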