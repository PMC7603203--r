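# Kyte-Doolittle transmembrane segment detection.
#
# Squalene synthases anchor to the ER membrane through a C-terminal
# transmembrane helix; its presence is classification evidence.  Detection
# uses the classical sliding-window hydropathy approach: average the
# Kyte-Doolittle index over a window (default 19 residues), flag windows
# whose mean exceeds a threshold (default 1.6, the textbook value for
# membrane-spanning segments), and report the longest run of residues
# covered by flagged windows within the C-terminal search region.

#' Kyte-Doolittle hydropathy index
#'
#' @return Named numeric vector over the 20 canonical residues. Unknown
#'   residues (`X`) are treated as neutral (0) by [detect_tm_helix()].
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Detect a C-terminal transmembrane helix
#'
#' Slides a Kyte-Doolittle hydropathy window over the C-terminal fraction of
#' the sequence and returns the maximal run of consecutive residues covered
#' by above-threshold windows.
#'
#' @param seq Amino-acid sequence.
#' @param window Window width in residues (default 19; must be >= 7).
#' @param threshold Minimum mean hydropathy for a window to count
#'   (default 1.6).
#' @param cterm_fraction Fraction of the sequence, anchored at the C-terminus,
#'   in which windows are considered (default 0.5). Windows must lie entirely
#'   inside this region.
#' @return `NULL` when no transmembrane segment is found (including sequences
#'   shorter than `window`); otherwise a list with `start` (1-based) and
#'   `length` in residues.
#' @examples
#' seq <- paste0(strrep("E", 60), strrep("A", 23), strrep("E", 17))
#' detect_tm_helix(seq)
#' @export
detect_tm_helix <- function(seq, window = 19L, threshold = 1.6,
                            cterm_fraction = 0.5) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (window < 7L) stop("hydropathy window must be >= 7 residues")
  if (cterm_fraction <= 0 || cterm_fraction > 1) {
    stop("cterm_fraction must be in (0, 1]")
  }
  n <- nchar(seq)
  if (n < window) return(NULL)
  kd <- kyte_doolittle()
  res <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  h <- unname(kd[res])
  h[is.na(h)] <- 0
  region_start <- floor((1 - cterm_fraction) * n) + 1L
  first_start <- max(1L, region_start)
  last_start <- n - window + 1L
  if (first_start > last_start) return(NULL)
  cs <- c(0, cumsum(h))
  starts <- first_start:last_start
  means <- (cs[starts + window] - cs[starts]) / window
  pass <- starts[means >= threshold]
  if (length(pass) == 0L) return(NULL)
  covered <- rep(FALSE, n)
  for (s in pass) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  list(start = ends[best] - r$lengths[best] + 1L, length = r$lengths[best])
}
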