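#' Align a doubled query against a target
#'
#' Concatenates the query token sequence with itself and aligns it locally
#' against the target. A circularly permuted match then shows up as a
#' single contiguous alignment crossing the duplication seam (the join
#' between the two query copies); `boundary_token` is the seam position
#' mapped back into the original query (0-based), i.e. the first token of
#' the C-terminal segment. Hits that do not cross the seam are reported as
#' plain alignments with `crosses_seam = FALSE`.
#'
#' @param query,target `sse_tokens` objects.
#' @param matrix an `sse_submat`.
#' @param config an [ssesym_config()]; supplies the minimum SSE count
#'   (`min_sse`) both chains must reach and the per-side minimum
#'   (`min_unit_sse`).
#' @return A list with the `sse_alignment` (`aln`), `crosses_seam`,
#'   `boundary_token`, per-side SSE counts `side_n`/`side_c` (N- and
#'   C-terminal of the original query), `cp_candidate` (seam crossed with
#'   at least `min_unit_sse` SSEs on each side), and the aligned target
#'   token index ranges for the two sides (`t_img_c`, `t_img_n`, 0-based
#'   half-open).
#' @export
double_and_align <- function(query, target, matrix = default_matrix(),
                             config = ssesym_config()) {
  stopifnot(inherits(query, "sse_tokens"), inherits(target, "sse_tokens"))
  n <- length(query); m <- length(target)
  if (n < config$min_sse || m < config$min_sse)
    stop("below SSE-count filter: need >= ", config$min_sse,
         " SSEs per chain (query ", n, ", target ", m, ")")
  doubled <- c(query$tokens, query$tokens)
  aln <- smith_waterman(doubled, target$tokens, matrix)
  pairs <- aln$pairs
  aligned <- pairs[!is.na(pairs$qi) & !is.na(pairs$tj), , drop = FALSE]
  if (nrow(aligned) == 0)
    return(list(aln = aln, crosses_seam = FALSE, boundary_token = NA_integer_,
                side_n = 0L, side_c = 0L, cp_candidate = FALSE,
                t_img_c = NULL, t_img_n = NULL))
  qs <- min(aligned$qi); qe <- max(aligned$qi)
  crosses <- qs <= n && qe >= n + 1L
  boundary <- if (crosses) (qs - 1L) %% n else NA_integer_
  part_c <- aligned[aligned$qi <= n, , drop = FALSE]   # C-terminal segment
  part_n <- aligned[aligned$qi > n, , drop = FALSE]    # wrapped N-terminal
  side_c <- if (crosses) n - (qs - 1L) else 0L
  side_n <- if (crosses) qe - n else 0L
  img <- function(p) if (nrow(p)) c(min(p$tj) - 1L, max(p$tj)) else NULL
  list(aln = aln, crosses_seam = crosses, boundary_token = boundary,
       side_n = side_n, side_c = side_c,
       cp_candidate = crosses && side_n >= config$min_unit_sse &&
         side_c >= config$min_unit_sse,
       t_img_c = img(part_c), t_img_n = img(part_n))
}

#' Indel decision rule
#'
#' A cross-boundary pair is an indel mutant when the residue gap between
#' the target images of the two segments is at least `indel_min_gap`
#' residues (default 40) or at least `indel_frac` (default 0.6) of the
#' smaller segment's residue length. Gaps of 20-30 residues are thereby
#' treated as minor loop variation.
#'
#' @param gap_residues residue separation between segment images.
#' @param len_n,len_c residue lengths of the two query segments.
#' @param config an [ssesym_config()].
#' @return Logical.
#' @export
classify_indel <- function(gap_residues, len_n, len_c,
                           config = ssesym_config()) {
  gap_residues >= config$indel_min_gap |
    gap_residues >= config$indel_frac * pmin(len_n, len_c)
}

#' Split-symmetry classification at a duplication boundary
#'
#' Splits the chain at the residue where the given SSE starts and computes
#' the TM-score between the two halves (normalised on the shorter one);
#' the chain is symmetric when that score reaches the `sym_tm` threshold.
#'
#' @param chain a [protein_chain()].
#' @param tokens its `sse_tokens` (for the SSE-to-residue back-map).
#' @param boundary_token 0-based token index where the chain is cut.
#' @param config an [ssesym_config()].
#' @param tmalign_bin optional external TM-align executable.
#' @return List with `is_symmetric`, `tm` and the `tm_result`.
#' @export
classify_symmetry_by_split <- function(chain, tokens, boundary_token,
                                       config = ssesym_config(),
                                       tmalign_bin = config$tmalign_bin) {
  stopifnot(inherits(chain, "protein_chain"), inherits(tokens, "sse_tokens"))
  nt <- length(tokens)
  if (is.na(boundary_token) || boundary_token < 1 || boundary_token >= nt)
    stop("boundary token out of range")
  b_res <- tokens$segments$start_res[boundary_token + 1L]  # 0-based
  seg <- tokens$segments
  n1 <- sum(seg$end_res <= b_res)
  n2 <- sum(seg$start_res >= b_res)
  if (n1 < config$min_unit_sse || n2 < config$min_unit_sse)
    stop("half too short: ", n1, " / ", n2, " SSEs on either side of the split")
  half1 <- subset_chain(chain, seq_len(b_res),
                        paste0(chain$chain_id, ":N"))
  half2 <- subset_chain(chain, (b_res + 1L):length(chain),
                        paste0(chain$chain_id, ":C"))
  res <- tm_align_sequential(half1, half2, normalize_on = "shorter",
                             tmalign_bin = tmalign_bin)
  list(is_symmetric = res$tm >= config$sym_tm, tm = res$tm, tm_result = res)
}

empty_duplication_records <- function() {
  data.frame(query_id = character(), target_id = character(),
             boundary_token = integer(), boundary_res = integer(),
             seg_n_start = integer(), seg_n_end = integer(),
             seg_c_start = integer(), seg_c_end = integer(),
             gap_residues = integer(),
             tm_original = numeric(), tm_rearranged = numeric(),
             delta_tm = numeric(), prescreen = numeric(),
             is_cp = logical(), is_indel = logical(),
             is_symmetric = logical(), tm_split = numeric(),
             stringsAsFactors = FALSE)
}

#' Verify a cross-boundary hit with exact TM-scores
#'
#' Maps the duplication-seam hit back to residues, rebuilds the query with
#' its C-terminal segment moved in front of the N-terminal one, and
#' computes the TM-score to the target in both the native and rearranged
#' order. The hit is a circular permutation when the rearranged score
#' reaches `cp_tm` and improves on the native order by at least
#' `cp_delta_tm`; it is an indel mutant per [classify_indel()] on the
#' residue gap between the two segment images on the target; and the query
#' is split-symmetric per [classify_symmetry_by_split()] at the same
#' boundary (NA when a half is too short).
#'
#' @param query_chain,target_chain [protein_chain()] objects.
#' @param query_tokens,target_tokens their `sse_tokens`.
#' @param hit output of [double_and_align()] with `crosses_seam = TRUE`.
#' @param config an [ssesym_config()].
#' @param tmalign_bin optional external TM-align executable.
#' @return One-row data.frame (see [run_pairwise()] for columns).
#' @export
rearrange_and_verify <- function(query_chain, target_chain,
                                 query_tokens, target_tokens, hit,
                                 config = ssesym_config(),
                                 tmalign_bin = config$tmalign_bin) {
  if (!isTRUE(hit$crosses_seam)) stop("hit does not cross the seam")
  n <- length(query_tokens)
  b <- hit$boundary_token
  seg <- query_tokens$segments
  if (is.na(b) || b < 0 || b >= n)
    stop("internal consistency error: boundary token outside chain")
  b_res <- seg$start_res[b + 1L]                       # 0-based cut
  if (b_res <= 0 || b_res >= length(query_chain))
    stop("internal consistency error: boundary maps outside chain")

  # query segment residue ranges (0-based half-open, author order)
  last_c <- n                                           # tokens b..n-1
  seg_c <- c(seg$start_res[b + 1L], seg$end_res[last_c])
  n_tokens_n <- hit$side_n                              # tokens 0..side_n-1
  seg_n <- c(seg$start_res[1L], seg$end_res[n_tokens_n])
  len_c <- seg_c[2] - seg_c[1]
  len_n <- seg_n[2] - seg_n[1]

  # residue gap between the two segment images on the target
  tseg <- target_tokens$segments
  gap <- 0L
  if (!is.null(hit$t_img_c) && !is.null(hit$t_img_n)) {
    end_c <- tseg$end_res[hit$t_img_c[2]]               # last token of image C
    start_n <- tseg$start_res[hit$t_img_n[1] + 1L]
    gap <- max(0L, start_n - end_c)
  }

  rearranged <- circular_permute(query_chain, b_res)
  tm_o <- tm_align_sequential(query_chain, target_chain,
                              normalize_on = "shorter",
                              tmalign_bin = tmalign_bin)
  tm_r <- tm_align_sequential(rearranged, target_chain,
                              normalize_on = "shorter",
                              tmalign_bin = tmalign_bin)
  delta <- tm_r$tm - tm_o$tm
  is_cp <- hit$cp_candidate && tm_r$tm >= config$cp_tm &&
    delta >= config$cp_delta_tm

  sym <- tryCatch(
    classify_symmetry_by_split(query_chain, query_tokens, b, config,
                               tmalign_bin = tmalign_bin),
    error = function(e) list(is_symmetric = NA, tm = NA_real_))

  data.frame(query_id = query_chain$chain_id,
             target_id = target_chain$chain_id,
             boundary_token = b,
             boundary_res = query_chain$resno[b_res + 1L],
             seg_n_start = seg_n[1], seg_n_end = seg_n[2],
             seg_c_start = seg_c[1], seg_c_end = seg_c[2],
             gap_residues = gap,
             tm_original = tm_o$tm, tm_rearranged = tm_r$tm,
             delta_tm = delta,
             prescreen = NA_real_,
             is_cp = is_cp,
             is_indel = classify_indel(gap, len_n, len_c, config),
             is_symmetric = sym$is_symmetric, tm_split = sym$tm,
             stringsAsFactors = FALSE)
}

#' End-to-end circular-permutation / indel scan of a chain pair
#'
#' Composition of the whole pipeline for one unordered pair: encode both
#' chains, align the doubled query against the target in both role
#' assignments, prescreen seam-crossing hits with the cheap similarity
#' surrogate, verify survivors with exact TM-scores, and classify. The
#' record with the better rearranged TM-score is kept per pair.
#'
#' @param query,target [protein_chain()] objects with `ss3` assigned, or
#'   file paths readable by [read_chain()] (then `query_chain_id` /
#'   `target_chain_id` and `query_ss3` / `target_ss3` sidecar paths apply).
#' @param config an [ssesym_config()].
#' @param matrix an `sse_submat`.
#' @param query_chain_id,target_chain_id chain letters when reading files.
#' @param query_ss3,target_ss3 optional ss3 sidecar paths when reading
#'   files.
#' @param both_roles evaluate both role assignments and keep the better
#'   rearranged TM (default TRUE).
#' @return A data.frame with zero or one row and columns `query_id`,
#'   `target_id`, `boundary_token` (0-based, in the query as reported),
#'   `boundary_res` (author numbering), `seg_n_*`/`seg_c_*` (0-based
#'   half-open residue ranges of the N-/C-terminal query segments),
#'   `gap_residues`, `tm_original`, `tm_rearranged`, `delta_tm`,
#'   `prescreen`, `is_cp`, `is_indel`, `is_symmetric`, `tm_split`.
#' @export
run_pairwise <- function(query, target, config = ssesym_config(),
                         matrix = default_matrix(),
                         query_chain_id = "A", target_chain_id = "A",
                         query_ss3 = NULL, target_ss3 = NULL,
                         both_roles = TRUE) {
  load_side <- function(x, chain_letter, ss3_path) {
    if (inherits(x, "protein_chain")) return(x)
    ch <- read_chain(x, chain_letter)
    if (!is.null(ss3_path))
      ch <- apply_ss3_string(ch, read_ss3_sidecar(ss3_path))
    else ch <- assign_ss_geometric(ch)
    ch
  }
  qc <- load_side(query, query_chain_id, query_ss3)
  tc <- load_side(target, target_chain_id, target_ss3)
  qt <- encode_chain(qc, config$min_segment_length, config$token_cap)
  tt <- encode_chain(tc, config$min_segment_length, config$token_cap)

  roles <- list(list(qc, tc, qt, tt))
  if (both_roles) roles <- c(roles, list(list(tc, qc, tt, qt)))

  recs <- list()
  for (r in roles) {
    hit <- double_and_align(r[[3]], r[[4]], matrix, config)
    if (!hit$cp_candidate) next
    ps <- prescreen_score(hit$aln, c(r[[3]]$tokens, r[[3]]$tokens),
                          r[[4]]$tokens, matrix)
    if (ps < config$prescreen_tm) next
    rec <- rearrange_and_verify(r[[1]], r[[2]], r[[3]], r[[4]], hit,
                                config)
    rec$prescreen <- ps
    recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) return(empty_duplication_records())
  best <- recs[[which.max(vapply(recs, function(x) x$tm_rearranged,
                                 numeric(1)))]]
  # the residue gap between segment images sits on whichever chain carries
  # the inserted material, so it is a pair-level quantity: take the larger
  # gap seen across the two role assignments and re-apply the indel rule
  best$gap_residues <- max(vapply(recs, function(x) x$gap_residues,
                                  numeric(1)))
  best$is_indel <- classify_indel(best$gap_residues,
                                  best$seg_n_end - best$seg_n_start,
                                  best$seg_c_end - best$seg_c_start, config)
  best
}

#' Write duplication records as TSV
#'
#' @param records data.frame from [run_pairwise()] (rows may be bound
#'   across pairs).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
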