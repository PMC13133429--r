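#' The variable-resolution SSE token alphabet
#'
#' Segment lengths are discretised with a resolution that decays with
#' length: lengths 2-10 get one letter each ('A' for 2, 'B' for 3, ...,
#' 'I' for 10), lengths 11-30 are binned in steps of 2, and lengths above
#' 30 in steps of 3 up to `cap`, beyond which a single overflow token is
#' used. Strands take the uppercase letter, helices the lowercase one, so
#' the case alone encodes the element type.
#'
#' @param cap largest explicitly binned length (default 48, which makes
#'   the alphabet exactly the 26 letters; larger caps would need tokens
#'   without an upper/lower-case pair and are rejected).
#' @return A data.frame with columns `letter`, `min_len`, `max_len`
#'   (the last row is the overflow bin, `max_len = Inf`).
#' @export
#' @examples
#' sse_alphabet()[1:3, ]
sse_alphabet <- function(cap = 48L) {
  cap <- as.integer(cap)
  if (cap < 33L || (cap - 30L) %% 3L != 0L)
    stop("cap must be 30 + a multiple of 3 (>= 33)")
  lo <- c(2:10, seq(11L, 29L, by = 2L), seq(31L, cap - 2L, by = 3L))
  hi <- c(2:10, seq(12L, 30L, by = 2L), seq(33L, cap, by = 3L))
  lo <- c(lo, cap + 1L)
  hi <- c(hi, Inf)
  if (length(lo) > 26L)
    stop("cap = ", cap, " needs ", length(lo),
         " tokens; only 26 case-paired letters are available (cap <= 48)")
  data.frame(letter = LETTERS[seq_along(lo)], min_len = lo, max_len = hi,
             stringsAsFactors = FALSE)
}

#' Map a segment length to its token
#'
#' @param length segment length in residues (>= 2).
#' @param ss_type `"helix"` or `"strand"`.
#' @param cap overflow cap passed to [sse_alphabet()].
#' @return A single character: uppercase for strands, lowercase for
#'   helices.
#' @export
#' @examples
#' length_to_token(3, "strand")  # "B"
#' length_to_token(3, "helix")   # "b"
length_to_token <- function(length, ss_type = c("strand", "helix"),
                            cap = 48L) {
  ss_type <- match.arg(ss_type)
  if (any(length < 2)) stop("segment too short: token map starts at length 2")
  ab <- sse_alphabet(cap)
  bin <- findInterval(length, ab$min_len)
  tok <- ab$letter[bin]
  if (ss_type == "helix") tolower(tok) else tok
}

#' Segment a 3-state string into SSE runs
#'
#' Maximal runs of H or E become segments; coil produces nothing; runs
#' shorter than `min_segment_length` are discarded (treated as coil).
#' Residue ranges are 0-based half-open indices into the chain, so the
#' token sequence keeps an exact back-map to coordinates.
#'
#' @param chain a [protein_chain()] (or a plain ss3 character string).
#' @param min_segment_length minimum run length kept (default 2).
#' @return data.frame with columns `ss_type` ("helix"/"strand"),
#'   `start_res`, `end_res` (0-based, half-open), `length`.
#' @export
segment_ss3 <- function(chain, min_segment_length = 2L) {
  ss3 <- if (inherits(chain, "protein_chain")) chain$ss3
         else strsplit(chain, "")[[1]]
  r <- rle(ss3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% c("H", "E") & r$lengths >= min_segment_length
  data.frame(
    ss_type = ifelse(r$values[keep] == "H", "helix", "strand"),
    start_res = starts[keep],
    end_res = ends[keep],
    length = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

#' Compress a chain into its SSE token sequence
#'
#' Composition of [segment_ss3()] and [length_to_token()]: one token per
#' retained helix/strand run, with the segment table as back-map.
#'
#' @inheritParams segment_ss3
#' @param cap overflow cap for the token alphabet.
#' @return An object of class `sse_tokens`: list with `chain_id`, `tokens`
#'   (character vector), and `segments` (the back-map data.frame).
#' @export
#' @examples
#' ch <- protein_chain("toy_A", matrix(rnorm(13 * 3), ncol = 3),
#'                     ss3 = strsplit("CCHHHHCCEEECC", "")[[1]])
#' encode_chain(ch)$tokens  # "c" "B"
encode_chain <- function(chain, min_segment_length = 2L, cap = 48L) {
  stopifnot(inherits(chain, "protein_chain"))
  seg <- segment_ss3(chain, min_segment_length)
  tokens <- character(nrow(seg))
  for (i in seq_len(nrow(seg)))
    tokens[i] <- length_to_token(seg$length[i], seg$ss_type[i], cap)
  structure(list(chain_id = chain$chain_id, tokens = tokens,
                 segments = seg),
            class = "sse_tokens")
}

#' @export
length.sse_tokens <- function(x) length(x$tokens)

#' @export
print.sse_tokens <- function(x, ...) {
  cat(sprintf("<sse_tokens %s: %d elements \"%s\">\n", x$chain_id,
              length(x), paste(x$tokens, collapse = "")))
  invisible(x)
}

#' Empirical Shannon entropy of a symbol stream
#'
#' @param symbols character vector of single symbols (or a single string,
#'   split into characters).
#' @return Entropy in bits per symbol.
#' @export
shannon_entropy <- function(symbols) {
  if (length(symbols) == 1 && nchar(symbols) > 1)
    symbols <- strsplit(symbols, "")[[1]]
  if (length(symbols) == 0) stop("empty symbol stream")
  p <- table(symbols) / length(symbols)
  -sum(p * log2(p))
}

#' Compression ratio of the SSE encoding
#'
#' Information-content ratio between a residue-level sequence and its SSE
#' token sequence: `(aa_length * aa_alphabet_entropy) /
#' (n_tokens * token_alphabet_entropy)`. Entropies may be computed
#' empirically from a corpus with [shannon_entropy()] or defaulted to the
#' maximal `log2(alphabet size)` (20 amino acids; 52 case-paired tokens).
#'
#' @param aa_length residue count of the original sequence.
#' @param token_seq an `sse_tokens` object (or a token count).
#' @param aa_alphabet_entropy bits per residue (default `log2(20)`).
#' @param token_alphabet_entropy bits per token (default `log2(52)`).
#' @return The compression ratio (dimensionless, > 0).
#' @export
compression_ratio <- function(aa_length, token_seq,
                              aa_alphabet_entropy = log2(20),
                              token_alphabet_entropy = log2(52)) {
  n_tok <- if (inherits(token_seq, "sse_tokens")) length(token_seq)
           else as.integer(token_seq)
  if (aa_length < 1) stop("aa_length must be >= 1")
  if (aa_alphabet_entropy <= 0 || token_alphabet_entropy <= 0)
    stop("entropies must be positive")
  if (n_tok == 0) stop("ratio undefined: empty token sequence")
  (aa_length * aa_alphabet_entropy) / (n_tok * token_alphabet_entropy)
}

#' Serialize token sequences
#'
#' Token strings are written FASTA-like (`>chain_id` + token string); the
#' residue back-map is written as TSV with one row per token.
#'
#' @param token_seqs an `sse_tokens` object or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tokens_fasta <- function(token_seqs, path) {
  if (inherits(token_seqs, "sse_tokens")) token_seqs <- list(token_seqs)
  out <- unlist(lapply(token_seqs, function(ts)
    c(paste0(">", ts$chain_id), paste(ts$tokens, collapse = ""))))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_tokens_fasta
#' @export
write_segments_tsv <- function(token_seqs, path) {
  if (inherits(token_seqs, "sse_tokens")) token_seqs <- list(token_seqs)
  rows <- do.call(rbind, lapply(token_seqs, function(ts) {
    if (length(ts) == 0) return(NULL)
    data.frame(chain_id = ts$chain_id,
               token_index = seq_along(ts$tokens) - 1L,
               token = ts$tokens, ts$segments,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chain_id = character(), token_index = integer(),
                       token = character(), ss_type = character(),
                       start_res = integer(), end_res = integer(),
                       length = integer())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
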