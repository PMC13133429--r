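# Shared fixture builders and independent oracles for the test suite.

# six-element chain with helix-rich N-half and strand-rich C-half of equal
# residue counts (38 + 38), midpoint in the inter-half linker; used for the
# equal-segment circular-permutation benchmark
make_cp_bench <- function(seed = 11) {
  make_chain(fixture_spec(seed,
                          list(c("helix", 12), c("strand", 6),
                               c("helix", 12), c("strand", 8),
                               c("helix", 10), c("strand", 8)),
                          linker_length = 4),
             chain_id = sprintf("bench%03d_A", seed))
}

# random alternating-element chain with n_elem SSEs (>= 6); element lengths
# drawn in 6..12, deterministic per seed
make_random_chain <- function(seed, n_elem = 6) {
  set.seed(seed)
  types <- rep(c("helix", "strand"), length.out = n_elem)
  lens <- sample(6:12, n_elem, replace = TRUE)
  elements <- lapply(seq_len(n_elem), function(i) c(types[i], lens[i]))
  make_chain(fixture_spec(seed, elements, terminal_coil = 4L),
             sprintf("rnd%04d_A", seed))
}

# self-avoiding random-walk chain (no secondary structure) for null models
make_walk_chain <- function(seed, n = 50) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      dir <- rnorm(3)
      cand <- xyz[i - 1, ] + 3.8 * dir / sqrt(sum(dir^2))
      if (i < 3 || min(sqrt(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE],
                                          2, cand)^2))) > 3.0) break
    }
    xyz[i, ] <- cand
  }
  protein_chain(sprintf("walk%04d_A", seed), xyz)
}

# independent superposition oracle: Horn's closed-form quaternion method
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Ac, Bc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Ac^2) + sum(Bc^2) - 2 * lam)) / n)
}

# brute-force maximal local alignment score: enumerates every monotone
# matching, charging internal gap runs with the same element-specific
# affine convention as the DP (open at the class of the first skipped
# token, extend per skipped token's own class); empty alignment scores 0
brute_force_local_score <- function(q, t, m) {
  nq <- length(q); nt <- length(t)
  cls <- function(tok) ifelse(tok %in% letters, "helix", "strand")
  run_cost <- function(tokens, from, to) {
    if (to < from) return(0)
    cl <- cls(tokens[from:to])
    m$gap_open[[cl[1]]] + sum(m$gap_extend[cl])
  }
  best <- 0
  rec <- function(i, j, sc) {
    if (sc > best) best <<- sc
    if (i < nq && j < nt) {
      for (ni in (i + 1):nq) for (nj in (j + 1):nt) {
        g <- run_cost(q, i + 1, ni - 1) + run_cost(t, j + 1, nj - 1)
        rec(ni, nj, sc + g + m$scores[q[ni], t[nj]])
      }
    }
  }
  for (i in seq_len(nq)) for (j in seq_len(nt))
    rec(i, j, m$scores[q[i], t[j]])
  best
}

# all token sequences of a given length over an alphabet
all_seqs <- function(len, alphabet) {
  if (len == 1) return(as.list(alphabet))
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len),
                    list(stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

# minimal classic-format DSSP text for one chain
write_fake_dssp <- function(path, resno, chain, ss8) {
  hdr <- c("==== Secondary Structure Definition (synthetic) ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- vapply(seq_along(resno), function(i) {
    line <- sprintf("%5d%5d %s A  ", i, resno[i], chain)
    # pad so the SS letter lands in column 17
    paste0(substr(sprintf("%-16s", line), 1, 16), ss8[i])
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
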