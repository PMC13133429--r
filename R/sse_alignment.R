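#' Substitution matrices for SSE tokens
#'
#' A substitution matrix holds a symmetric dense score matrix over the
#' token alphabet plus element-specific affine gap penalties (one
#' open/extend pair for helices, one for strands). `default_matrix()`
#' builds the shipped default: same-type tokens score `match` minus one
#' per length-bin of separation (floored at `floor_score`), and any
#' helix-vs-strand pair scores `mismatch`. The token case encodes the
#' element class, so the gap penalty charged for skipping a token is that
#' of its own class.
#'
#' @param match score of an exact token match (default 4).
#' @param floor_score lower bound of the same-type decay (default 0).
#' @param mismatch cross-class score (default -4).
#' @param gap_open,gap_extend named numeric vectors with entries `helix`
#'   and `strand`, all non-positive (defaults -4 / -1).
#' @param cap token alphabet cap, see [sse_alphabet()].
#' @return An object of class `sse_submat`: list with `tokens`, `scores`
#'   (dense symmetric matrix with dimnames), `gap_open`, `gap_extend`.
#' @export
#' @examples
#' m <- default_matrix()
#' m$scores["b", "b"] > m$scores["b", "c"]  # closer bins score higher
default_matrix <- function(match = 4, floor_score = 0, mismatch = -4,
                           gap_open = c(helix = -4, strand = -4),
                           gap_extend = c(helix = -1, strand = -1),
                           cap = 48L) {
  ab <- sse_alphabet(cap)
  up <- ab$letter
  tokens <- c(up, tolower(up))
  n_bin <- length(up)
  bin <- c(seq_len(n_bin), seq_len(n_bin))
  cls <- rep(c("strand", "helix"), each = n_bin)
  S <- matrix(mismatch, length(tokens), length(tokens),
              dimnames = list(tokens, tokens))
  same <- outer(cls, cls, "==")
  S[same] <- pmax(match - abs(outer(bin, bin, "-"))[same], floor_score)
  new_submat(tokens, S, gap_open, gap_extend)
}

new_submat <- function(tokens, scores, gap_open, gap_extend) {
  scores <- as.matrix(scores)
  dimnames(scores) <- list(tokens, tokens)
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution matrix must be symmetric")
  for (g in list(gap_open, gap_extend)) {
    if (!all(c("helix", "strand") %in% names(g)))
      stop("gap penalties need named entries 'helix' and 'strand'")
    if (any(g > 0)) stop("gap penalties must be <= 0")
  }
  structure(list(tokens = tokens, scores = scores,
                 gap_open = gap_open[c("helix", "strand")],
                 gap_extend = gap_extend[c("helix", "strand")]),
            class = "sse_submat")
}

#' @export
print.sse_submat <- function(x, ...) {
  cat(sprintf("<sse_submat: %d tokens, gap open %s / extend %s (helix, strand)>\n",
              length(x$tokens),
              paste(x$gap_open, collapse = ", "),
              paste(x$gap_extend, collapse = ", ")))
  invisible(x)
}

#' Read / write a substitution matrix
#'
#' JSON schema: `tokens` (array), `scores` (dense row-major matrix),
#' `gap_open` and `gap_extend` (objects with `helix`/`strand`).
#' Asymmetric or incomplete files are rejected.
#'
#' @param path file path.
#' @param matrix an `sse_submat` (for writing).
#' @return `load_matrix` returns an `sse_submat`; `save_matrix` returns
#'   `path` invisibly.
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("tokens", "scores", "gap_open", "gap_extend"))
    if (is.null(raw[[key]])) stop("matrix file missing key: ", key)
  sc <- as.matrix(raw$scores)
  if (nrow(sc) != length(raw$tokens) || ncol(sc) != length(raw$tokens))
    stop("scores matrix dimensions do not match the token list")
  new_submat(raw$tokens, sc, unlist(raw$gap_open), unlist(raw$gap_extend))
}

#' @rdname load_matrix
#' @export
save_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "sse_submat"))
  obj <- list(tokens = matrix$tokens,
              scores = unname(matrix$scores),
              gap_open = as.list(matrix$gap_open),
              gap_extend = as.list(matrix$gap_extend))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

token_class <- function(tokens) {
  ifelse(tokens %in% letters, "helix", "strand")
}

as_token_vector <- function(x) {
  if (inherits(x, "sse_tokens")) return(x$tokens)
  if (is.character(x) && length(x) == 1 && nchar(x) > 1)
    return(strsplit(x, "")[[1]])
  as.character(x)
}

#' Smith-Waterman local alignment of SSE token sequences
#'
#' Affine-gap local alignment where the gap penalty charged for a gap
#' column is that of the element class of the token being skipped.
#' Tie-breaking is deterministic (diagonal, then up, then left; traceback
#' from the highest-scoring cell, ties to the smallest row then column),
#' so results are bit-stable.
#'
#' @param query,target `sse_tokens` objects (or plain token strings).
#' @param matrix an `sse_submat`; defaults to [default_matrix()].
#' @return An object of class `sse_alignment`: list with `score` (>= 0),
#'   `pairs` (data.frame `qi`/`tj`, 1-based, `NA` marks a gap),
#'   `query_range`/`target_range` (0-based half-open token intervals),
#'   `identity` (fraction of aligned pairs with identical tokens) and
#'   `coverage` (aligned fraction of the shorter sequence).
#' @export
smith_waterman <- function(query, target, matrix = default_matrix()) {
  q <- as_token_vector(query)
  t_ <- as_token_vector(target)
  if (length(q) == 0 || length(t_) == 0)
    stop("empty token sequence")
  bad <- setdiff(c(q, t_), matrix$tokens)
  if (length(bad))
    stop("token(s) not covered by the substitution matrix: ",
         paste(unique(bad), collapse = ", "))
  S <- matrix$scores[q, t_, drop = FALSE]
  qc <- token_class(q); tc <- token_class(t_)
  res <- sw_affine_dp(S,
                      go_row = unname(matrix$gap_open[qc]),
                      ge_row = unname(matrix$gap_extend[qc]),
                      go_col = unname(matrix$gap_open[tc]),
                      ge_col = unname(matrix$gap_extend[tc]))
  pairs <- data.frame(qi = res$qi, tj = res$tj)
  aligned <- !is.na(pairs$qi) & !is.na(pairs$tj)
  n_aligned <- sum(aligned)
  identity <- if (n_aligned > 0)
    mean(q[pairs$qi[aligned]] == t_[pairs$tj[aligned]]) else 0
  coverage <- n_aligned / min(length(q), length(t_))
  qr <- if (n_aligned > 0)
    c(min(pairs$qi, na.rm = TRUE) - 1L, max(pairs$qi, na.rm = TRUE))
  else integer(0)
  tr <- if (n_aligned > 0)
    c(min(pairs$tj, na.rm = TRUE) - 1L, max(pairs$tj, na.rm = TRUE))
  else integer(0)
  structure(list(score = res$score, pairs = pairs,
                 query_range = qr, target_range = tr,
                 identity = identity, coverage = coverage,
                 n_query = length(q), n_target = length(t_)),
            class = "sse_alignment")
}

#' @export
print.sse_alignment <- function(x, ...) {
  cat(sprintf(
    "<sse_alignment: score %.1f, %d aligned pairs, identity %.2f, coverage %.2f>\n",
    x$score, sum(!is.na(x$pairs$qi) & !is.na(x$pairs$tj)),
    x$identity, x$coverage))
  invisible(x)
}

#' Cheap similarity surrogate used to prescreen candidates
#'
#' A monotone combination of the normalised alignment score, token
#' identity and coverage, calibrated so a self-alignment scores exactly
#' 1.0 and an empty alignment 0.0. It only gates which candidates reach
#' the exact TM-score verification: accepted hits are always re-verified,
#' so the surrogate affects recall and speed, never the correctness of
#' accepted calls.
#'
#' @param aln an `sse_alignment` from [smith_waterman()].
#' @param query,target the aligned token sequences.
#' @param matrix the substitution matrix used for the alignment.
#' @return A similarity in `[0, 1]`.
#' @export
prescreen_score <- function(aln, query, target, matrix = default_matrix()) {
  stopifnot(inherits(aln, "sse_alignment"))
  q <- as_token_vector(query)
  t_ <- as_token_vector(target)
  if (aln$score <= 0 || nrow(aln$pairs) == 0) return(0)
  self_sc <- function(tok) sum(matrix$scores[cbind(tok, tok)])
  denom <- min(self_sc(q), self_sc(t_))
  norm <- if (denom > 0) min(max(aln$score / denom, 0), 1) else 0
  0.5 * norm + 0.25 * aln$identity + 0.25 * min(aln$coverage, 1)
}
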