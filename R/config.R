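#' Pipeline configuration
#'
#' Collects every tunable threshold of the detection pipeline in one named
#' list. Defaults are the operating points the method was designed around:
#' a rearranged TM-score of at least 0.5 with an improvement of at least
#' 0.1 declares a circular permutation; a cross-boundary gap of at least 40
#' residues, or at least 60% of the smaller segment, declares an indel; a
#' split-half or self-scan TM-score above 0.5 declares symmetry; hits whose
#' TM-scores differ by less than 0.05 are consolidated by span rather than
#' by score; chains enter the pipeline only with at least 5 SSEs and every
#' aligned unit must contain at least 3 SSEs.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @return A named list of class `ssesym_config` with entries:
#' \describe{
#'   \item{cp_tm}{minimum rearranged TM-score for a circular permutation
#'     (default 0.5).}
#'   \item{cp_delta_tm}{minimum TM-score improvement after rearrangement
#'     (default 0.1).}
#'   \item{indel_min_gap}{residue gap declaring an indel outright
#'     (default 40).}
#'   \item{indel_frac}{fraction of the smaller segment the gap must reach
#'     to declare an indel (default 0.6).}
#'   \item{sym_tm}{split-half TM-score threshold for symmetry (default 0.5).}
#'   \item{scan_tm}{self-scan retention threshold, strict (default 0.5).}
#'   \item{consolidate_delta}{TM difference below which span wins during
#'     consolidation (default 0.05).}
#'   \item{prescreen_tm}{surrogate-similarity filter applied before exact
#'     TM verification (default 0.5).}
#'   \item{min_sse}{minimum SSE count for a chain to enter the pipeline
#'     (default 5).}
#'   \item{min_unit_sse}{minimum SSEs per aligned unit / per seam side
#'     (default 3).}
#'   \item{min_segment_length}{minimum residue run kept as an SSE
#'     (default 2).}
#'   \item{token_cap}{segment length above which the overflow token is used
#'     (default 48).}
#'   \item{gap_open, gap_extend}{affine gap penalties per element class,
#'     named vectors with entries `helix` and `strand` (defaults -4, -1).}
#'   \item{matrix_path}{optional path to a substitution-matrix JSON file.}
#'   \item{tmalign_bin}{optional path to an external TM-align executable.}
#'   \item{seed}{integer seed used wherever randomness is involved
#'     (default 42).}
#' }
#' @export
#' @examples
#' cfg <- ssesym_config(cp_delta_tm = 0.15)
#' cfg$cp_delta_tm
ssesym_config <- function(...) {
  cfg <- list(
    cp_tm = 0.5,
    cp_delta_tm = 0.1,
    indel_min_gap = 40,
    indel_frac = 0.6,
    sym_tm = 0.5,
    scan_tm = 0.5,
    consolidate_delta = 0.05,
    prescreen_tm = 0.5,
    min_sse = 5L,
    min_unit_sse = 3L,
    min_segment_length = 2L,
    token_cap = 48L,
    gap_open = c(helix = -4, strand = -4),
    gap_extend = c(helix = -1, strand = -1),
    matrix_path = NULL,
    tmalign_bin = NULL,
    seed = 42L
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all config overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_config(cfg)
  structure(cfg, class = "ssesym_config")
}

validate_config <- function(cfg) {
  chk_unit <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("config key '", key, "' must be a single value in [0, 1]")
  }
  for (key in c("cp_tm", "cp_delta_tm", "indel_frac", "sym_tm", "scan_tm",
                "consolidate_delta", "prescreen_tm")) chk_unit(key)
  if (cfg$indel_min_gap < 1) stop("indel_min_gap must be >= 1")
  if (cfg$min_sse < 1 || cfg$min_unit_sse < 1)
    stop("SSE count thresholds must be >= 1")
  if (cfg$min_segment_length < 2)
    stop("min_segment_length must be >= 2 (token map starts at length 2)")
  if (any(cfg$gap_open > 0) || any(cfg$gap_extend > 0))
    stop("gap penalties must be <= 0")
  invisible(cfg)
}

#' Read or write a pipeline configuration file
#'
#' Configuration files are YAML with the same keys as [ssesym_config()];
#' unknown keys are rejected so typos cannot silently revert a threshold to
#' its default.
#'
#' @param path file path.
#' @param cfg a config from [ssesym_config()] (for writing).
#' @return `read_config` returns a validated `ssesym_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (key in c("gap_open", "gap_extend"))
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  do.call(ssesym_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ssesym_config"))
  out <- unclass(cfg)
  out$gap_open <- as.list(out$gap_open)
  out$gap_extend <- as.list(out$gap_extend)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.ssesym_config <- function(x, ...) {
  cat("ssesym pipeline configuration\n")
  for (key in names(x)) {
    v <- x[[key]]
    if (is.null(v)) v <- "<unset>"
    cat(sprintf("  %-20s %s\n", key, paste(format(v), collapse = " / ")))
  }
  invisible(x)
}
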