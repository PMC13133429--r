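#' Sliding-window self-scan for internal repeats
#'
#' Slides a window of at least 3 SSEs along the token sequence: for each
#' left start position the window grows one SSE at a time and is locally
#' aligned against the remainder of the chain, until fewer than 3 SSEs
#' remain unscanned. Each candidate segment pair (>= 3 SSEs on both
#' sides) is prescreened with the cheap similarity surrogate and then
#' verified with the exact TM-score engine on the residue correspondence
#' implied by the token alignment; hits with TM strictly above `scan_tm`
#' are retained.
#'
#' @param chain a [protein_chain()] with `ss3` assigned.
#' @param tokens its `sse_tokens` (>= 6 SSEs, room for two 3-SSE units).
#' @param matrix an `sse_submat`.
#' @param config an [ssesym_config()].
#' @param all_starts scan every left start position (default) or only the
#'   N-terminal one.
#' @return A data.frame of hits with columns `left_start`, `left_end`,
#'   `right_start`, `right_end` (0-based half-open SSE-index intervals),
#'   `tm`, `span_residues` (total residue coverage of both ranges), and
#'   attributes `n_alignments` (total window alignments performed) and
#'   `n_alignments_first_start` (those from the N-terminal start).
#' @export
scan_chain <- function(chain, tokens, matrix = default_matrix(),
                       config = ssesym_config(), all_starts = TRUE) {
  stopifnot(inherits(chain, "protein_chain"), inherits(tokens, "sse_tokens"))
  nt <- length(tokens)
  w0 <- config$min_unit_sse
  if (nt < 2 * w0)
    stop("chain too short for self-scan: ", nt, " SSEs (need >= ", 2 * w0, ")")
  seg <- tokens$segments
  hits <- list()
  seen <- character(0)
  n_aln <- 0L
  n_aln_first <- 0L
  starts <- if (all_starts) 0:(nt - 2L * w0) else 0L

  for (s in starts) {
    for (w in w0:(nt - s - w0)) {
      rem_start <- s + w
      win_tok <- tokens$tokens[(s + 1L):(s + w)]
      rem_tok <- tokens$tokens[(rem_start + 1L):nt]
      aln <- smith_waterman(win_tok, rem_tok, matrix)
      n_aln <- n_aln + 1L
      if (s == 0L) n_aln_first <- n_aln_first + 1L
      pr <- aln$pairs
      ali <- pr[!is.na(pr$qi) & !is.na(pr$tj), , drop = FALSE]
      if (nrow(ali) < w0) next
      left <- c(s + min(ali$qi) - 1L, s + max(ali$qi))        # half-open
      right <- c(rem_start + min(ali$tj) - 1L, rem_start + max(ali$tj))
      if (left[2] - left[1] < w0 || right[2] - right[1] < w0) next
      key <- paste(left[1], left[2], right[1], right[2], sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      ps <- prescreen_score(aln, win_tok, rem_tok, matrix)
      if (ps < config$prescreen_tm) next
      span_l <- seg$end_res[left[2]] - seg$start_res[left[1] + 1L]
      span_r <- seg$end_res[right[2]] - seg$start_res[right[1] + 1L]
      sub_l <- subset_chain(chain,
                            (seg$start_res[left[1] + 1L] + 1L):seg$end_res[left[2]])
      sub_r <- subset_chain(chain,
                            (seg$start_res[right[1] + 1L] + 1L):seg$end_res[right[2]])
      tm <- tryCatch(
        tm_align_sequential(sub_l, sub_r, normalize_on = "shorter")$tm,
        error = function(e) NA_real_)
      if (is.na(tm) || tm <= config$scan_tm) next
      hits[[length(hits) + 1L]] <-
        data.frame(left_start = left[1], left_end = left[2],
                   right_start = right[1], right_end = right[2],
                   tm = tm, span_residues = span_l + span_r)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(left_start = integer(), left_end = integer(),
               right_start = integer(), right_end = integer(),
               tm = numeric(), span_residues = integer())
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_alignments") <- n_aln
  attr(out, "n_alignments_first_start") <- n_aln_first
  out
}

# fraction of each hit's covered SSE set shared with another hit
hit_cover <- function(h, i) {
  c(seq(h$left_start[i], h$left_end[i] - 1L),
    seq(h$right_start[i], h$right_end[i] - 1L))
}

hits_conflict <- function(h, i, j, frac = 0.5) {
  a <- hit_cover(h, i); b <- hit_cover(h, j)
  ov <- length(intersect(a, b))
  ov > frac * length(a) || ov > frac * length(b)
}

#' Greedy consolidation of overlapping scan hits
#'
#' Sequential maximisation: candidates are processed in order of sequence
#' start position; when two hits overlap on more than half of either hit's
#' covered SSEs, the one with the clearly higher TM-score (difference >=
#' `delta`) is retained, otherwise the one with the longer total residue
#' span. The output is mutually non-redundant and the operation is
#' idempotent.
#'
#' @param hits data.frame from [scan_chain()].
#' @param delta TM difference below which span decides (default 0.05).
#' @return A filtered hits data.frame.
#' @export
consolidate <- function(hits, delta = 0.05) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(hits$left_start, hits$right_start), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    conflicts <- keep[vapply(keep, function(j) hits_conflict(hits, i, j),
                             logical(1))]
    if (!length(conflicts)) {
      keep <- c(keep, i)
      next
    }
    wins <- vapply(conflicts, function(j) {
      if (abs(hits$tm[i] - hits$tm[j]) >= delta)
        hits$tm[i] > hits$tm[j]
      else
        hits$span_residues[i] > hits$span_residues[j]
    }, logical(1))
    if (all(wins)) keep <- c(setdiff(keep, conflicts), i)
  }
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise consolidated hits into repeat units
#'
#' Builds a graph whose nodes are the hit segment ranges, with edges
#' between the two ranges of each hit (they match structurally) and
#' between ranges sharing SSEs; takes connected components, splits each
#' component where consecutive covered ranges are separated by at least
#' `gap_sse` SSEs, and computes per sub-component
#' `repeat_count = floor(total boundary coverage / minimal unit length)`.
#' The chain total is the sum over sub-components.
#'
#' @param chain_id identifier for the report.
#' @param hits consolidated hits data.frame.
#' @param gap_sse split threshold in SSEs (default 3).
#' @return An object of class `repeat_summary`: list with `chain_id`,
#'   `unit_boundaries` (matrix of 0-based half-open SSE intervals),
#'   `min_unit_length`, `repeat_count`, `mean_unit_tm`.
#' @export
summarize_repeats <- function(chain_id, hits, gap_sse = 3L) {
  if (nrow(hits) == 0)
    return(structure(list(chain_id = chain_id,
                          unit_boundaries = matrix(integer(), ncol = 2,
                                                   dimnames = list(NULL, c("start", "end"))),
                          min_unit_length = NA_integer_,
                          repeat_count = 0L, mean_unit_tm = NA_real_),
                     class = "repeat_summary"))
  ranges <- unique(rbind(
    data.frame(start = hits$left_start, end = hits$left_end),
    data.frame(start = hits$right_start, end = hits$right_end)))
  ranges <- ranges[order(ranges$start, ranges$end), , drop = FALSE]
  rownames(ranges) <- NULL
  nr <- nrow(ranges)
  # adjacency: structural partners (same hit) or SSE overlap
  adj <- matrix(FALSE, nr, nr)
  rkey <- paste(ranges$start, ranges$end)
  for (i in seq_len(nrow(hits))) {
    a <- match(paste(hits$left_start[i], hits$left_end[i]), rkey)
    b <- match(paste(hits$right_start[i], hits$right_end[i]), rkey)
    adj[a, b] <- adj[b, a] <- TRUE
  }
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (i < j && ranges$start[j] < ranges$end[i] &&
        ranges$start[i] < ranges$end[j])
      adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- connected_components(adj)

  total <- 0L
  min_unit_all <- Inf
  for (cid in unique(comp)) {
    rs <- ranges[comp == cid, , drop = FALSE]
    rs <- rs[order(rs$start), , drop = FALSE]
    # split on gaps of >= gap_sse SSEs between covered ranges
    grp <- cumsum(c(0L, diff_gap(rs, gap_sse)))
    for (g in unique(grp)) {
      sub <- rs[grp == g, , drop = FALSE]
      covered <- unique(unlist(mapply(seq, sub$start, sub$end - 1L,
                                      SIMPLIFY = FALSE)))
      min_unit <- min(sub$end - sub$start)
      total <- total + floor(length(covered) / min_unit)
      min_unit_all <- min(min_unit_all, min_unit)
    }
  }
  structure(list(chain_id = chain_id,
                 unit_boundaries = as.matrix(ranges),
                 min_unit_length = as.integer(min_unit_all),
                 repeat_count = as.integer(total),
                 mean_unit_tm = mean(hits$tm)),
            class = "repeat_summary")
}

diff_gap <- function(rs, gap_sse) {
  if (nrow(rs) <= 1) return(integer(0))
  cov_end <- cummax(rs$end)[-nrow(rs)]
  as.integer(rs$start[-1] - cov_end >= gap_sse)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary %s: %d repeat(s), min unit %s SSEs, mean TM %s>\n",
              x$chain_id, x$repeat_count,
              ifelse(is.na(x$min_unit_length), "-", x$min_unit_length),
              ifelse(is.na(x$mean_unit_tm), "-",
                     sprintf("%.3f", x$mean_unit_tm))))
  invisible(x)
}

#' Symmetry call from a repeat summary
#'
#' A chain is internally symmetric when at least one consolidated hit has
#' TM strictly above `scan_tm` with at least `min_unit_sse` SSEs in both
#' units -- equivalently, when the summarised repeat count reaches 2.
#'
#' @param summary a `repeat_summary`.
#' @param hits the consolidated hits it was built from.
#' @param config an [ssesym_config()].
#' @return Logical.
#' @export
classify_symmetric <- function(summary, hits, config = ssesym_config()) {
  if (nrow(hits) == 0) return(FALSE)
  ok <- hits$tm > config$scan_tm &
    (hits$left_end - hits$left_start) >= config$min_unit_sse &
    (hits$right_end - hits$right_start) >= config$min_unit_sse
  any(ok) && summary$repeat_count >= 2L
}

#' One-call self-scan of a chain
#'
#' Convenience wrapper: encode, scan, consolidate, summarise, classify.
#'
#' @param chain a [protein_chain()] with ss3 assigned.
#' @param config an [ssesym_config()].
#' @param matrix an `sse_submat`.
#' @return List with `hits` (consolidated), `summary` (a
#'   `repeat_summary`) and `symmetric` (logical).
#' @export
self_scan <- function(chain, config = ssesym_config(),
                      matrix = default_matrix()) {
  tokens <- encode_chain(chain, config$min_segment_length, config$token_cap)
  hits <- scan_chain(chain, tokens, matrix, config)
  hits <- consolidate(hits, config$consolidate_delta)
  summ <- summarize_repeats(chain$chain_id, hits)
  list(hits = hits, summary = summ,
       symmetric = classify_symmetric(summ, hits, config))
}
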