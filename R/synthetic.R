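# Synthetic structure generator: ideal-geometry secondary structure
# elements joined by coil linkers, plus the rearrangement operators the
# pipeline is meant to invert. All randomness is drawn from a local RNG
# seeded from the spec, so fixtures are reproducible bit-for-bit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

random_rotation <- function() {
  # QR-based uniform random rotation, reflection corrected
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

ideal_helix <- function(len) {
  t <- 0:(len - 1)
  th <- t * 100 * pi / 180          # 100 degrees twist per residue
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * t)   # 1.5 A rise
}

ideal_strand <- function(len) {
  t <- 0:(len - 1)
  cbind(3.3 * t, 0.9 * (-1)^t, 0)   # extended zigzag, ~3.8 A Ca-Ca
}

#' Specify a synthetic structure fixture
#'
#' @param seed integer seed controlling linker geometry and element
#'   orientations.
#' @param elements list of `c(ss_type, length)` pairs (or a 2-column
#'   data.frame); `ss_type` is `"helix"` or `"strand"`, lengths in
#'   residues (>= 2).
#' @param linker_length coil residues between consecutive elements
#'   (default 4).
#' @param operators ordered list of operator descriptions applied after
#'   construction, each a list with `op` one of `"circular_permute"`
#'   (field `boundary`), `"insert"`/`"delete"` (fields `position`,
#'   `length`), `"tandem_repeat"` (field `k`).
#' @param terminal_coil coil residues appended after the last element
#'   (default 0). A terminal tail keeps the first and last elements from
#'   fusing into one SSE when the chain is circularly permuted.
#' @return An object of class `fixture_spec`.
#' @export
#' @examples
#' sp <- fixture_spec(1, list(c("helix", 12), c("strand", 6)))
#' ch <- make_chain(sp)
fixture_spec <- function(seed, elements, linker_length = 4L,
                         operators = list(), terminal_coil = 0L) {
  if (is.data.frame(elements))
    elements <- lapply(seq_len(nrow(elements)),
                       function(i) c(elements[i, 1], elements[i, 2]))
  for (e in elements) {
    if (!e[[1]] %in% c("helix", "strand"))
      stop("element type must be 'helix' or 'strand'")
    if (as.integer(e[[2]]) < 2)
      stop("spec error: element shorter than 2 residues")
  }
  structure(list(seed = as.integer(seed), elements = elements,
                 linker_length = as.integer(linker_length),
                 operators = operators,
                 terminal_coil = as.integer(terminal_coil)),
            class = "fixture_spec")
}

# self-avoiding random walk of `len` steps (3.8 A), starting adjacent to
# `from`, avoiding `existing` coordinates by >= 2.5 A. Each step resamples
# its direction up to `tries` times (with a mild outward bias in crowded
# regions); if no clash-free direction exists the least-clashing one is
# taken, so the walk always completes with finite coordinates.
coil_walk <- function(from, len, existing, step = 3.8, clash = 2.5,
                      tries = 100L) {
  if (len == 0) return(matrix(numeric(0), ncol = 3))
  pts <- matrix(NA_real_, len, 3)
  cur <- from
  cen <- if (nrow(existing)) colMeans(existing) else from
  for (i in seq_len(len)) {
    best <- NULL
    best_d <- -Inf
    pool <- rbind(existing, pts[seq_len(i - 1), , drop = FALSE])
    out <- cur - cen
    out_n <- sqrt(sum(out^2))
    for (t in seq_len(tries)) {
      dir <- stats::rnorm(3)
      if (out_n > 1e-9) dir <- dir + 0.5 * out / out_n
      cand <- cur + step * dir / sqrt(sum(dir^2))
      dmin <- if (nrow(pool) > 1)
        min(sqrt(rowSums(sweep(pool[-nrow(pool), , drop = FALSE],
                               2, cand)^2)))
      else Inf
      if (dmin >= clash) { best <- cand; break }
      if (dmin > best_d) { best_d <- dmin; best <- cand }
    }
    pts[i, ] <- best
    cur <- best
  }
  pts
}

#' Build a synthetic chain from a fixture spec
#'
#' Elements use ideal geometry (helix: 1.5 A rise, 100 degrees per
#' residue; strand: extended zigzag, ~3.8 A consecutive C-alpha spacing)
#' and are joined by seeded self-avoiding coil linkers. The 3-state
#' string is set from the construction, giving ground truth independent
#' of any assigner. Operators are applied in order after construction.
#'
#' @param spec a [fixture_spec()].
#' @param chain_id identifier for the resulting chain.
#' @return A [protein_chain()].
#' @export
make_chain <- function(spec, chain_id = sprintf("syn%04d_A", spec$seed)) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    xyz <- matrix(numeric(0), ncol = 3)
    ss3 <- character(0)
    for (k in seq_along(spec$elements)) {
      e <- spec$elements[[k]]
      len <- as.integer(e[[2]])
      local <- if (e[[1]] == "helix") ideal_helix(len) else ideal_strand(len)
      local <- local %*% random_rotation()
      if (nrow(xyz) == 0) {
        placed <- sweep(local, 2, local[1, ])
      } else {
        link <- coil_walk(xyz[nrow(xyz), ], spec$linker_length, xyz)
        from <- if (nrow(link)) link[nrow(link), ] else xyz[nrow(xyz), ]
        # try a few orientations to keep the element clash-free
        for (t in 1:100) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          start <- from + 3.8 * dir
          cand <- sweep(local, 2, local[1, ]) # element local frame at origin
          cand <- sweep(cand, 2, -start)      # translate to start
          pool <- rbind(xyz, link)
          dmin <- min(outer_dist_min(cand, pool))
          if (dmin >= 2.5) break
          local <- (if (e[[1]] == "helix") ideal_helix(len)
                    else ideal_strand(len)) %*% random_rotation()
        }
        xyz <- rbind(xyz, link)
        ss3 <- c(ss3, rep("C", nrow(link)))
        placed <- cand
      }
      xyz <- rbind(xyz, placed)
      ss3 <- c(ss3, rep(if (e[[1]] == "helix") "H" else "E", len))
    }
    tc <- spec$terminal_coil %||% 0L
    if (tc > 0) {
      tail_coil <- coil_walk(xyz[nrow(xyz), ], tc, xyz)
      xyz <- rbind(xyz, tail_coil)
      ss3 <- c(ss3, rep("C", tc))
    }
    ch <- protein_chain(chain_id, xyz, ss3 = ss3)
    for (op in spec$operators) ch <- apply_operator(ch, op, spec)
    ch
  })
}

outer_dist_min <- function(A, B) {
  if (nrow(B) == 0) return(Inf)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(min(d2), 0))
}

# coil bridge: `len` interior points from a to b along a circular arc whose
# length matches len+1 steps of `step`, so consecutive spacing stays ~3.8 A
# while both endpoints (and hence the flanking structure) stay fixed
coil_bridge <- function(a, b, len, step = 3.8) {
  chord <- sqrt(sum((b - a)^2))
  arc <- (len + 1) * step
  if (arc <= chord + 1e-6) {
    frac <- seq_len(len) / (len + 1)
    return(t(vapply(frac, function(f) a + f * (b - a), numeric(3))))
  }
  th <- stats::uniroot(function(t) 2 * sin(t / 2) / t - chord / arc,
                       c(1e-6, 2 * pi - 1e-9))$root
  r <- arc / th
  h <- r * cos(th / 2)
  u <- (b - a) / max(chord, 1e-9)
  rnd <- stats::rnorm(3)
  v <- rnd - sum(rnd * u) * u
  v <- v / sqrt(sum(v^2))
  m <- (a + b) / 2
  phi <- pi / 2 + th / 2 - seq_len(len) * th / (len + 1)
  x <- r * cos(phi)
  y <- -h + r * sin(phi)
  t(vapply(seq_len(len), function(k) m + x[k] * u + y[k] * v, numeric(3)))
}

apply_operator <- function(chain, op, spec) {
  switch(op$op,
         circular_permute = circular_permute(chain, op$boundary),
         insert = apply_indel(chain, op$position, op$length, "insert"),
         delete = apply_indel(chain, op$position, op$length, "delete"),
         tandem_repeat = tandem_repeat(chain, op$k,
                                       linker_length = spec$linker_length),
         stop("unknown operator: ", op$op))
}

#' Circularly permute a chain
#'
#' Reorders residues to `[boundary+1 .. n, 1 .. boundary]` (0-based
#' `boundary` = number of residues staying in the N-terminal block that
#' moves to the end). Coordinates are untouched; the 3-state string and
#' residue identifiers are permuted in lockstep.
#'
#' @param chain a [protein_chain()].
#' @param boundary_res 0 < boundary_res < length (0-based cut position).
#' @param chain_id optional new identifier (default appends `_cp`).
#' @return The permuted [protein_chain()].
#' @export
circular_permute <- function(chain, boundary_res,
                             chain_id = paste0(chain$chain_id, "_cp")) {
  n <- length(chain)
  if (boundary_res <= 0 || boundary_res >= n)
    stop("boundary must be strictly inside the chain")
  idx <- c((boundary_res + 1L):n, seq_len(boundary_res))
  subset_chain(chain, idx, chain_id)
}

#' Insert or delete a residue span
#'
#' `insert` splices a seeded coil walk of `length` residues after
#' 1-based residue `position` and translates the C-terminal part to
#' follow it; `delete` removes residues `position+1 .. position+length`
#' and re-joins, translating the C-terminal part so the junction gap is a
#' standard 3.8 A while preserving its internal geometry.
#'
#' @param chain a [protein_chain()].
#' @param position residue index after which to cut (1-based;
#'   0 <= position <= n for insert, position + length <= n for delete).
#' @param length residues to insert or delete.
#' @param mode `"insert"` or `"delete"`.
#' @param seed seed for the inserted coil geometry (default 1).
#' @return The modified [protein_chain()].
#' @export
apply_indel <- function(chain, position, length, mode = c("insert", "delete"),
                        seed = 1L) {
  mode <- match.arg(mode)
  n <- length(chain)
  position <- as.integer(position)
  length <- as.integer(length)
  if (mode == "insert") {
    if (position < 0 || position > n) stop("position out of range")
    with_seed(seed, {
      ins <- if (position >= 1 && position < n) {
        # interior insertion: bridge the flanking residues so neither
        # structured block moves (the gap is pure extra coil)
        coil_bridge(chain$xyz[position, ], chain$xyz[position + 1L, ],
                    length)
      } else {
        from <- if (position > 0) chain$xyz[position, ]
                else chain$xyz[1, ] - c(3.8, 0, 0)
        coil_walk(from, length, chain$xyz)
      }
      tail_idx <- if (position < n) (position + 1L):n else integer(0)
      new_xyz <- rbind(chain$xyz[seq_len(position), , drop = FALSE], ins,
                       chain$xyz[tail_idx, , drop = FALSE])
      new_ss3 <- c(chain$ss3[seq_len(position)], rep("C", length),
                   chain$ss3[tail_idx])
      protein_chain(paste0(chain$chain_id, "_ins"), new_xyz, ss3 = new_ss3)
    })
  } else {
    if (position < 0 || position + length > n)
      stop("deletion span out of range")
    if (length >= n) stop("cannot delete the whole chain")
    keep_head <- seq_len(position)
    keep_tail <- if (position + length < n) (position + length + 1L):n
                 else integer(0)
    new_xyz <- chain$xyz[keep_head, , drop = FALSE]
    if (length(keep_tail)) {
      tail_xyz <- chain$xyz[keep_tail, , drop = FALSE]
      if (length(keep_head)) {
        anchor <- new_xyz[nrow(new_xyz), ]
        dir <- tail_xyz[1, ] - anchor
        nd <- sqrt(sum(dir^2))
        dir <- if (nd > 1e-9) dir / nd else c(1, 0, 0)
        shift <- anchor + 3.8 * dir - tail_xyz[1, ]
        tail_xyz <- sweep(tail_xyz, 2, -shift)
      }
      new_xyz <- rbind(new_xyz, tail_xyz)
    }
    protein_chain(paste0(chain$chain_id, "_del"), new_xyz,
                  ss3 = chain$ss3[c(keep_head, keep_tail)])
  }
}

#' Tandem-repeat a chain
#'
#' Appends `k - 1` rigid copies of the chain, each translated along the
#' x-extent of the bounding box and joined by a straight coil linker, so
#' the units are exactly superposable.
#'
#' @param chain a [protein_chain()] (the repeat unit).
#' @param k total number of units (>= 2).
#' @param linker_length minimum coil residues between units (default 4).
#' @return A [protein_chain()] of `k` units.
#' @export
tandem_repeat <- function(chain, k, linker_length = 4L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  span <- diff(range(chain$xyz[, 1]))
  offset <- c(span + 12, 0, 0)
  xyz <- chain$xyz
  ss3 <- chain$ss3
  for (i in seq_len(k - 1)) {
    unit <- sweep(chain$xyz, 2, -offset * i)
    a <- xyz[nrow(xyz), ]; b <- unit[1, ]
    gap <- sqrt(sum((b - a)^2))
    n_link <- max(linker_length, ceiling(gap / 3.8) - 1L)
    frac <- seq_len(n_link) / (n_link + 1)
    link <- t(vapply(frac, function(f) a + f * (b - a), numeric(3)))
    xyz <- rbind(xyz, link, unit)
    ss3 <- c(ss3, rep("C", n_link), chain$ss3)
  }
  protein_chain(paste0(chain$chain_id, "_x", k), xyz, ss3 = ss3)
}
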