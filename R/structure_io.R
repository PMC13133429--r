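#' Construct a protein chain object
#'
#' The canonical internal representation: ordered C-alpha coordinates with
#' author residue numbering and a 3-state secondary-structure string
#' (H = helix, E = strand, C = coil).
#'
#' @param chain_id identifier, conventionally `"<structure>_<chain>"`.
#' @param xyz numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @param resno integer author residue numbers (defaults to `1:n`).
#' @param insert insertion codes, `""` when absent.
#' @param ss3 character vector over \{H, E, C\}; defaults to all-coil.
#' @return An object of class `protein_chain`.
#' @export
#' @examples
#' ch <- protein_chain("toy_A", cbind(c(0, 3.8, 7.6), 0, 0))
#' length(ch)
protein_chain <- function(chain_id, xyz, resno = NULL, insert = NULL,
                          ss3 = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1) stop("empty chain")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(insert)) insert <- rep("", n)
  if (is.null(ss3)) ss3 <- rep("C", n)
  ss3 <- toupper(as.character(ss3))
  if (length(resno) != n || length(ss3) != n || length(insert) != n)
    stop("resno, insert and ss3 must match the number of residues")
  if (!all(ss3 %in% c("H", "E", "C")))
    stop("ss3 letters must be H, E or C")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(chain_id = as.character(chain_id), xyz = xyz,
                 resno = as.integer(resno), insert = as.character(insert),
                 ss3 = ss3),
            class = "protein_chain")
}

#' @export
length.protein_chain <- function(x) nrow(x$xyz)

#' @export
print.protein_chain <- function(x, ...) {
  tab <- table(factor(x$ss3, levels = c("H", "E", "C")))
  cat(sprintf("<protein_chain %s: %d residues (H %d / E %d / C %d)>\n",
              x$chain_id, length(x), tab[["H"]], tab[["E"]], tab[["C"]]))
  invisible(x)
}

#' Extract a contiguous or reordered subset of residues
#'
#' @param chain a [protein_chain()].
#' @param idx 1-based residue indices, in the desired output order.
#' @param chain_id optional new identifier.
#' @return A `protein_chain` with the selected residues.
#' @export
subset_chain <- function(chain, idx, chain_id = chain$chain_id) {
  stopifnot(inherits(chain, "protein_chain"))
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > length(chain))) stop("residue index out of range")
  protein_chain(chain_id, chain$xyz[idx, , drop = FALSE],
                chain$resno[idx], chain$insert[idx], chain$ss3[idx])
}

#' Read one chain from a PDB or mmCIF file
#'
#' Only C-alpha atoms are used. For multi-model files the first model is
#' kept; alternate locations are resolved to the highest occupancy (ties go
#' to the first encountered); residues lacking a C-alpha are dropped with a
#' warning. Secondary structure is initialised to all-coil -- assignment is
#' a separate step ([apply_dssp_assignment()], [apply_ss3_string()],
#' [assign_ss_geometric()]).
#'
#' @param path PDB or mmCIF file.
#' @param chain_id chain letter as used in the file (e.g. `"A"`).
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @return A [protein_chain()] named `"<basename>_<chain>"`.
#' @export
read_chain <- function(path, chain_id, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- if (format == "mmcif") {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  }
  atoms <- pdb$atom
  if (!chain_id %in% unique(atoms$chain)) stop("chain not found: ", chain_id)
  ca <- atoms[atoms$chain == chain_id & atoms$elety == "CA" &
                atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  ca <- ca[!is.na(ca$x), , drop = FALSE]
  if (nrow(ca) == 0) stop("empty chain: no C-alpha atoms for ", chain_id)

  # resolve altlocs: within each (resno, insert) keep highest occupancy,
  # ties -> first encountered
  ins <- ca$insert
  ins[is.na(ins)] <- ""
  key <- paste(ca$resno, ins, sep = "|")
  occ <- ca$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(ii) ii[which.max(occ[ii])]),
                 use.names = FALSE)
  keep <- sort(keep)
  dropped <- nrow(ca) - length(keep)
  if (dropped > 0)
    message(dropped, " alternate-location C-alpha record(s) resolved by occupancy")
  ca <- ca[keep, , drop = FALSE]
  ins <- ins[keep]

  # report residues present in the file but lacking a CA
  res_all <- unique(paste(atoms$resno[atoms$chain == chain_id &
                                        atoms$type == "ATOM"],
                          sep = "|"))
  n_res_file <- length(res_all)
  if (n_res_file > nrow(ca))
    warning(n_res_file - nrow(ca), " residue(s) without C-alpha dropped from ",
            chain_id)

  id <- paste0(sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path),
                   ignore.case = TRUE), "_", chain_id)
  protein_chain(id, cbind(ca$x, ca$y, ca$z), ca$resno, ins)
}

#' Write a chain as a minimal PDB file
#'
#' C-alpha-only output, used to exchange rearranged structures with
#' external superposition tools. Residues are renumbered sequentially when
#' `renumber = TRUE` (required after rearrangement, where author numbering
#' is no longer monotone).
#'
#' @param chain a [protein_chain()].
#' @param path output file.
#' @param chain_letter single character chain identifier for the records.
#' @param renumber renumber residues 1..n.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, chain_letter = "A",
                            renumber = FALSE) {
  stopifnot(inherits(chain, "protein_chain"))
  resno <- if (renumber) seq_len(length(chain)) else chain$resno
  bio3d::write.pdb(file = path, xyz = as.vector(t(chain$xyz)),
                   resno = resno, chain = chain_letter,
                   resid = rep("ALA", length(chain)),
                   elety = rep("CA", length(chain)))
  invisible(path)
}

# 8-state -> 3-state reduction (DSSP letters); configurable via `table`
reduce_dssp8 <- function(letters8,
                         table = c(H = "H", G = "H", I = "H",
                                   E = "E", B = "E")) {
  out <- unname(table[letters8])
  out[is.na(out)] <- "C"
  out
}

#' Apply a DSSP assignment to a chain
#'
#' Parses classic columnar `.dssp` output and reduces the 8-state letters
#' to 3 states: \{H, G, I\} to H, \{E, B\} to E, everything else (T, S, P,
#' blank) to C. Residues absent from the DSSP record keep coil. The
#' reduction table can be overridden for non-standard schemes.
#'
#' @param chain a [protein_chain()].
#' @param dssp_path DSSP output file (classic dialect).
#' @param chain_letter chain identifier inside the DSSP file; defaults to
#'   the suffix of `chain$chain_id`.
#' @param reduction named character vector mapping 8-state letters to
#'   H/E (unlisted letters become C).
#' @return The chain with `ss3` replaced; coordinates and length untouched.
#' @export
apply_dssp_assignment <- function(chain, dssp_path, chain_letter = NULL,
                                  reduction = c(H = "H", G = "H", I = "H",
                                                E = "E", B = "E")) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!file.exists(dssp_path)) stop("DSSP file not found: ", dssp_path)
  if (is.null(chain_letter))
    chain_letter <- sub("^.*_", "", chain$chain_id)
  lines <- readLines(dssp_path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) stop("not a classic DSSP file: ", dssp_path)
  body <- lines[seq(hdr[1] + 1, length(lines))]
  body <- body[nchar(body) >= 17]
  ch <- substr(body, 12, 12)
  body <- body[ch == chain_letter]
  if (length(body) == 0) stop("assignment not found for chain ", chain_letter)
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  icode <- trimws(substr(body, 11, 11))
  ss8 <- substr(body, 17, 17)
  ok <- !is.na(resno)
  resno <- resno[ok]; icode <- icode[ok]; ss8 <- ss8[ok]
  ss3 <- reduce_dssp8(ss8, table = reduction)

  key_dssp <- paste(resno, icode, sep = "|")
  key_chain <- paste(chain$resno, chain$insert, sep = "|")
  hit <- match(key_chain, key_dssp)
  new_ss3 <- chain$ss3
  new_ss3[!is.na(hit)] <- ss3[hit[!is.na(hit)]]
  chain$ss3 <- new_ss3
  chain
}

#' Apply a precomputed 3-state string
#'
#' Sidecar files are FASTA-like: a `>chain_id` header followed by
#' one-letter-per-residue lines over \{H, E, C\}. This lets any external
#' assigner feed the pipeline.
#'
#' @param chain a [protein_chain()].
#' @param ss3 character string (or vector of single letters) of length
#'   equal to the chain.
#' @return The chain with `ss3` replaced.
#' @export
apply_ss3_string <- function(chain, ss3) {
  stopifnot(inherits(chain, "protein_chain"))
  if (length(ss3) == 1) ss3 <- strsplit(ss3, "")[[1]]
  if (length(ss3) != length(chain))
    stop("ss3 length (", length(ss3), ") does not match chain length (",
         length(chain), ")")
  chain$ss3 <- toupper(ss3)
  if (!all(chain$ss3 %in% c("H", "E", "C")))
    stop("ss3 letters must be H, E or C")
  chain
}

#' @rdname apply_ss3_string
#' @param path sidecar file path.
#' @param chain_id header to look up; defaults to the first record.
#' @export
read_ss3_sidecar <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no FASTA-like records in ", path)
  ids <- sub("^>\\s*", "", lines[heads])
  pick <- if (is.null(chain_id)) 1L else match(chain_id, ids)
  if (is.na(pick)) stop("assignment not found for ", chain_id)
  from <- heads[pick] + 1
  to <- if (pick < length(heads)) heads[pick + 1] - 1 else length(lines)
  paste(gsub("\\s", "", lines[from:to]), collapse = "")
}

#' @rdname apply_ss3_string
#' @param chains list of `protein_chain` objects to serialize.
#' @export
write_ss3_sidecar <- function(chains, path) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  out <- unlist(lapply(chains, function(ch)
    c(paste0(">", ch$chain_id), paste(ch$ss3, collapse = ""))))
  writeLines(out, path)
  invisible(path)
}

#' Assign secondary structure from C-alpha geometry
#'
#' A self-contained fallback assigner in the spirit of P-SEA: each residue
#' is classified from short-range C-alpha distances d(i,i+2), d(i,i+3) and
#' d(i,i+4), which separate helical (compact, ~5.4/5.1/6.2 A) from extended
#' (~6.6/10/13 A) geometry. Runs shorter than 3 residues are reverted to
#' coil. Deterministic for fixed coordinates. Intended for synthetic or
#' DSSP-less inputs; it is not a hydrogen-bond assigner.
#'
#' @param chain a [protein_chain()] with at least 5 residues.
#' @return The chain with `ss3` replaced (all-coil with a warning if the
#'   chain is shorter than 5 residues).
#' @export
assign_ss_geometric <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  n <- length(chain)
  if (n < 5) {
    warning("chain shorter than 5 residues: all residues assigned coil")
    chain$ss3 <- rep("C", n)
    return(chain)
  }
  X <- chain$xyz
  dk <- function(k) {
    d <- rep(NA_real_, n)
    idx <- seq_len(n - k)
    d[idx] <- sqrt(rowSums((X[idx + k, , drop = FALSE] -
                              X[idx, , drop = FALSE])^2))
    d
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)

  helix_at <- function(i) {
    !is.na(d3[i]) & d3[i] >= 4.3 & d3[i] <= 5.8 &
      !is.na(d2[i]) & d2[i] >= 4.8 & d2[i] <= 6.1 &
      (is.na(d4[i]) | (d4[i] >= 5.4 & d4[i] <= 7.2))
  }
  strand_at <- function(i) {
    !is.na(d2[i]) & d2[i] >= 6.0 & d2[i] <= 7.2 &
      !is.na(d3[i]) & d3[i] >= 8.6 & d3[i] <= 11.2 &
      (is.na(d4[i]) | d4[i] >= 11.0)
  }
  ss <- rep("C", n)
  for (i in seq_len(n)) {
    # windows starting up to 3 (helix) / 2 (strand) residues back cover i
    hs <- max(1, i - 3):min(i, n - 3)
    es <- max(1, i - 2):min(i, n - 2)
    if (length(hs) && any(helix_at(hs))) ss[i] <- "H"
    else if (length(es) && any(strand_at(es))) ss[i] <- "E"
  }
  # suppress 1-2 residue stubs
  r <- rle(ss)
  r$values[r$lengths < 3 & r$values != "C"] <- "C"
  chain$ss3 <- inverse.rle(r)
  chain
}
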