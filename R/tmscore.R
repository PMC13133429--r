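#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two equal-length coordinate sets. Reflections are excluded by the
#' standard determinant correction on the SVD of the covariance matrix.
#'
#' @param coords_a,coords_b numeric matrices (n x 3), n >= 3, not all
#'   collinear.
#' @return An object of class `superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3), and `rmsd` (Angstrom).
#'   The fitted transform maps `coords_a` onto `coords_b` as
#'   `coords_a %*% rotation + translation` (row-vector convention).
#' @export
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch(a, a)$rmsd  # 0
kabsch <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("coordinate sets must be equal-length n x 3 matrices")
  if (nrow(A) < 3) stop("need at least 3 points")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate input: points are (nearly) collinear")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  structure(list(rotation = R, translation = as.numeric(cB - cA %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Length-dependent TM-score distance scale
#'
#' `d0 = max(1.24 * (Lt - 15)^(1/3) - 1.8, 0.5)`; the 0.5 A floor keeps
#' the scale positive for short normalisation lengths (Lt <= 21).
#'
#' @param lt normalisation length (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(lt) {
  raw <- if (lt > 15) 1.24 * (lt - 15)^(1 / 3) - 1.8 else -Inf
  max(raw, 0.5)
}

apply_sup <- function(X, sup) {
  sweep(X %*% sup$rotation, 2, -sup$translation)
}

pair_dists <- function(A, B, sup) {
  sqrt(rowSums((apply_sup(A, sup) - B)^2))
}

#' TM-score of a fixed residue correspondence
#'
#' `TM = max over superpositions of (1/Lt) * sum_i 1 / (1 + (d_i/d0)^2)`,
#' where the maximum is searched by fragment seeding (contiguous seed
#' windows of the full, half and quarter correspondence length) followed
#' by iterative refitting on the pairs within a distance cutoff until the
#' included set is stable. `Lt` is the length of the normalisation chain,
#' not the number of aligned pairs, so unaligned residues dilute the
#' score.
#'
#' @param chain_a,chain_b [protein_chain()] objects.
#' @param pairs two-column matrix/data.frame of 1-based residue indices
#'   (a, b); at least 3 rows.
#' @param normalize_on `"shorter"`, `"a"`, `"b"`, or `"longer"`.
#' @param seed_step stride between fragment-seed start positions; 1 tries
#'   every start (the default for correspondences up to 60 pairs).
#' @return An object of class `tm_result`: `tm` in (0, 1], `d0`, `lt`,
#'   `pairs`, the best `superposition`, and per-pair `distances` under it.
#' @export
tm_score <- function(chain_a, chain_b, pairs,
                     normalize_on = c("shorter", "a", "b", "longer"),
                     seed_step = NULL) {
  stopifnot(inherits(chain_a, "protein_chain"),
            inherits(chain_b, "protein_chain"))
  normalize_on <- match.arg(normalize_on)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 aligned pairs")
  if (any(pairs[, 1] < 1 | pairs[, 1] > length(chain_a)) ||
      any(pairs[, 2] < 1 | pairs[, 2] > length(chain_b)))
    stop("pair index out of range")
  lt <- switch(normalize_on,
               shorter = min(length(chain_a), length(chain_b)),
               longer = max(length(chain_a), length(chain_b)),
               a = length(chain_a),
               b = length(chain_b))
  d0 <- tm_d0(lt)
  A <- chain_a$xyz[pairs[, 1], , drop = FALSE]
  B <- chain_b$xyz[pairs[, 2], , drop = FALSE]
  np <- nrow(pairs)
  if (is.null(seed_step)) seed_step <- max(1L, np %/% 60L)

  tm_of <- function(d) sum(1 / (1 + (d / d0)^2)) / lt

  best <- list(tm = -Inf, sup = NULL, d = NULL)
  consider <- function(sup) {
    d <- pair_dists(A, B, sup)
    tm <- tm_of(d)
    if (tm > best$tm) best <<- list(tm = tm, sup = sup, d = d)
    d
  }

  refine <- function(sel) {
    prev <- integer(0)
    for (iter in 1:20) {
      if (length(sel) < 3) break
      sup <- tryCatch(kabsch(A[sel, , drop = FALSE], B[sel, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sup)) break
      d <- consider(sup)
      d_cut <- d0
      repeat {
        new_sel <- which(d < d_cut)
        if (length(new_sel) >= 3) break
        d_cut <- d_cut + 0.5
      }
      if (identical(new_sel, sel) || identical(new_sel, prev)) break
      prev <- sel
      sel <- new_sel
    }
  }

  seed_lens <- unique(pmax(4L, c(np, np %/% 2L, np %/% 4L)))
  seed_lens <- seed_lens[seed_lens <= np]
  if (np < 4L) seed_lens <- np
  for (L in seed_lens) {
    for (s in seq(1L, np - L + 1L, by = seed_step)) {
      refine(s:(s + L - 1L))
    }
  }
  if (!is.finite(best$tm))
    stop("degenerate input: no valid superposition found")
  structure(list(tm = best$tm, d0 = d0, lt = lt, pairs = pairs,
                 superposition = best$sup, distances = best$d,
                 provenance = "internal"),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result: TM %.4f (Lt = %d, d0 = %.2f A, %d pairs, %s)>\n",
              x$tm, as.integer(x$lt), x$d0, nrow(x$pairs), x$provenance))
  invisible(x)
}

#' Sequence-order-respecting structure alignment and TM-score
#'
#' A light TM-align-style engine: initial correspondences from gapless
#' threading over all offsets, then alternation between (i) TM-score
#' superposition refinement of the current correspondence and (ii)
#' re-estimation of the correspondence by dynamic programming with free
#' end gaps on the superposed inter-residue distance score matrix
#' `1 / (1 + (d_ij/d0)^2)`. If an external TM-align executable is
#' configured (`tmalign_bin`), the computation is delegated to it and its
#' output parsed; both paths return the same shape with the provenance
#' recorded.
#'
#' @param chain_a,chain_b [protein_chain()] objects, >= 5 residues each.
#' @param normalize_on which chain length normalises the score.
#' @param tmalign_bin optional path to a TM-align executable.
#' @param max_iter maximum DP/superposition alternations per start.
#' @param n_init number of gapless-threading offsets kept as starts.
#' @return A `tm_result` (see [tm_score()]).
#' @export
tm_align_sequential <- function(chain_a, chain_b,
                                normalize_on = c("shorter", "a", "b",
                                                 "longer"),
                                tmalign_bin = NULL, max_iter = 6L,
                                n_init = 3L) {
  stopifnot(inherits(chain_a, "protein_chain"),
            inherits(chain_b, "protein_chain"))
  normalize_on <- match.arg(normalize_on)
  n <- length(chain_a); m <- length(chain_b)
  if (n < 5 || m < 5) stop("both chains must have at least 5 residues")
  if (!is.null(tmalign_bin))
    return(tm_align_external(chain_a, chain_b, normalize_on, tmalign_bin))

  lt <- switch(normalize_on, shorter = min(n, m), longer = max(n, m),
               a = n, b = m)
  d0 <- tm_d0(lt)
  Xa <- chain_a$xyz; Xb <- chain_b$xyz

  # --- gapless threading: score every offset by a single rigid fit
  offs <- seq(-(n - 4L), m - 4L)
  off_tm <- rep(-Inf, length(offs))
  for (k in seq_along(offs)) {
    i <- max(1L, 1L - offs[k]):min(n, m - offs[k])
    if (length(i) < 4) next
    j <- i + offs[k]
    sup <- tryCatch(kabsch(Xa[i, , drop = FALSE], Xb[j, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sup)) next
    d <- sqrt(rowSums((apply_sup(Xa[i, , drop = FALSE], sup) -
                         Xb[j, , drop = FALSE])^2))
    off_tm[k] <- sum(1 / (1 + (d / d0)^2)) / lt
  }
  starts <- offs[order(off_tm, decreasing = TRUE)[seq_len(min(n_init,
                                                              length(offs)))]]
  starts <- unique(c(starts, 0L))

  best <- NULL
  for (k0 in starts) {
    i <- max(1L, 1L - k0):min(n, m - k0)
    if (length(i) < 3) next
    pairs <- cbind(i, i + k0)
    prev_key <- ""
    res <- NULL
    for (iter in seq_len(max_iter)) {
      res <- tryCatch(
        tm_score(chain_a, chain_b, pairs, normalize_on,
                 seed_step = max(1L, nrow(pairs) %/% 12L)),
        error = function(e) NULL)
      if (is.null(res)) break
      sup <- res$superposition
      At <- apply_sup(Xa, sup)
      D2 <- outer(rowSums(At^2), rowSums(Xb^2), "+") - 2 * At %*% t(Xb)
      S <- 1 / (1 + pmax(D2, 0) / d0^2)
      dp <- nw_free_dp(S, gap = -0.6)
      new_pairs <- cbind(dp$qi, dp$tj)
      key <- paste(new_pairs, collapse = ",")
      if (nrow(new_pairs) < 3 || key == prev_key) break
      prev_key <- paste(pairs, collapse = ",")
      if (key == prev_key) break
      pairs <- new_pairs
    }
    if (!is.null(res) && nrow(pairs) >= 3) {
      final <- tryCatch(tm_score(chain_a, chain_b, pairs, normalize_on),
                        error = function(e) NULL)
      if (!is.null(final) && (is.null(best) || final$tm > best$tm))
        best <- final
    }
  }
  if (is.null(best)) stop("alignment failed: no valid superposition")
  best
}

# Delegate to an external TM-align binary via temporary C-alpha PDB files.
tm_align_external <- function(chain_a, chain_b, normalize_on, tmalign_bin) {
  fa <- tempfile(fileext = ".pdb"); fb <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fa, fb)), add = TRUE)
  write_chain_pdb(chain_a, fa, renumber = TRUE)
  write_chain_pdb(chain_b, fb, renumber = TRUE)
  out <- suppressWarnings(
    system2(tmalign_bin, c(fa, fb), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("external TM-align failed (exit ", status, "):\n",
         paste(tail(out, 5), collapse = "\n"))
  tm1 <- as.numeric(sub(".*TM-score= *([0-9.]+).*", "\\1",
                        grep("Chain_1", out, value = TRUE)[1]))
  tm2 <- as.numeric(sub(".*TM-score= *([0-9.]+).*", "\\1",
                        grep("Chain_2", out, value = TRUE)[1]))
  if (is.na(tm1) || is.na(tm2))
    stop("could not parse TM-align output")
  n <- length(chain_a); m <- length(chain_b)
  tm <- switch(normalize_on,
               a = tm1, b = tm2,
               shorter = if (n <= m) tm1 else tm2,
               longer = if (n >= m) tm1 else tm2)
  lt <- switch(normalize_on, shorter = min(n, m), longer = max(n, m),
               a = n, b = m)
  structure(list(tm = tm, d0 = tm_d0(lt), lt = lt, pairs = NULL,
                 superposition = NULL, distances = NULL,
                 provenance = "tmalign"),
            class = "tm_result")
}
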