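# Catalytic-motif grammars.
#
# The metal-binding motifs of terpene synthases are short aspartate-rich
# consensus strings (DDxxD, DxDD, DDxxE, DxDTT, ...).  We formalise the
# field's notation as a tiny grammar: plain amino-acid letters match
# themselves, 'x' matches any canonical residue, and a bracketed set such as
# [DE] matches any one of its members.  The ambiguity code 'X' in an input
# sequence is matched only by the 'x' wildcard, never by a literal: an
# unknown residue cannot certify a catalytic aspartate.

#' Compile a motif grammar
#'
#' Parses a motif consensus string into a deterministic matcher. The grammar
#' alphabet is: the 20 canonical amino-acid letters (literal match), `x`
#' (wildcard over canonical residues plus the ambiguity code `X`), and
#' bracketed alternative sets such as `[DE]`.
#'
#' @param grammar Consensus string, e.g. `"D[DE]xx[DE]"`.
#' @param name Optional motif name carried along for reporting.
#' @param fold_class One of `"class_I"`, `"class_II"`, `"accessory"`. Class I
#'   motifs mark ionization-dependent catalysis, Class II protonation-dependent
#'   catalysis; accessory motifs (e.g. QW) never influence the fold call.
#' @return An object of class `motif_pattern` with elements `name`, `grammar`,
#'   `fold_class`, `width` (match width in residues) and `regex` (the compiled
#'   matcher).
#' @examples
#' p <- compile_pattern("D[DE]xx[DE]", name = "class1")
#' p$width
#' @export
compile_pattern <- function(grammar, name = grammar,
                            fold_class = c("accessory", "class_I", "class_II")) {
  fold_class <- match.arg(fold_class)
  if (!is.character(grammar) || length(grammar) != 1L || !nzchar(grammar)) {
    stop("motif grammar must be a non-empty string")
  }
  chars <- strsplit(grammar, "", fixed = TRUE)[[1]]
  i <- 1L
  positions <- list()
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!(chars[j] %in% AA_CANONICAL)) {
          stop(sprintf("malformed motif grammar '%s': invalid residue '%s' at position %d",
                       grammar, chars[j], j))
        }
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) {
        stop(sprintf("malformed motif grammar '%s': unclosed '[' at position %d", grammar, i))
      }
      if (length(set) == 0L) {
        stop(sprintf("malformed motif grammar '%s': empty set at position %d", grammar, i))
      }
      positions[[length(positions) + 1L]] <- unique(set)
      i <- j + 1L
    } else if (ch == "x") {
      positions[[length(positions) + 1L]] <- "x"
      i <- i + 1L
    } else if (ch %in% AA_CANONICAL) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop(sprintf("malformed motif grammar '%s': unexpected character '%s' at position %d",
                   grammar, ch, i))
    }
  }
  if (length(positions) < 2L) {
    stop(sprintf("motif grammar '%s' must span at least 2 match positions", grammar))
  }
  wildcard <- paste0("[", paste(c(AA_CANONICAL, "X"), collapse = ""), "]")
  regex <- paste(vapply(positions, function(p) {
    if (identical(p, "x")) wildcard
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(
    list(name = name, grammar = grammar, fold_class = fold_class,
         width = length(positions), regex = regex),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (%s, width %d)\n",
              x$name, x$grammar, x$fold_class, x$width))
  invisible(x)
}

#' Default motif set
#'
#' The bundled motif grammars: the generic Class I aspartate-rich consensus
#' D\[DE\]xx\[DE\] and its DDxxD/DDxxE instances, the Class II DxDD and its
#' DxDTT variant, the trichodiene-synthase active-site pair (DDSRE/DDSIE and
#' the NDLFSFYKE triad), the longiborneol-synthase D\[DE\]HFD motif and its
#' partially conserved NDHFD form, the oxidosqualene-cyclase DCTAE family
#' (DCTAE/DCTSE/DCISE), the structural QW motif, and the NSD/DTE triad parts
#' of pentalenene-synthase-like proteins (encoded as the two literal
#' alternatives, flagged accessory).
#'
#' @return A data frame with columns `name`, `grammar`, `fold_class`.
#' @export
default_motifs <- function() {
  df <- data.frame(
    name = c("class1_aspartate", "ddxxd", "ddxxe", "dxdd", "dxdtt",
             "tri5_aspartate", "tri5_triad", "ddhfd", "ndhfd", "dctae",
             "qw", "nsd", "dte"),
    grammar = c("D[DE]xx[DE]", "DDxxD", "DDxxE", "DxDD", "DxDTT",
                "DDS[RI]E", "NDLFSFYKE", "D[DE]HFD", "NDHFD", "DC[TI][AS]E",
                "QW", "NSD", "DTE"),
    fold_class = c("class_I", "class_I", "class_I", "class_II", "class_II",
                   "class_I", "accessory", "class_I", "accessory", "class_II",
                   "accessory", "accessory", "accessory"),
    stringsAsFactors = FALSE
  )
  df
}

#' Read or write a motif configuration
#'
#' Motif sets are exchanged as tab-separated text with columns
#' `name`, `grammar`, `fold_class` (with header).
#'
#' @param path File path.
#' @return `read_motifs()` returns the motif table; `write_motifs()` returns
#'   `path` invisibly.
#' @export
read_motifs <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "grammar", "fold_class")
  if (!all(need %in% names(df))) {
    stop("motif config must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_motifs
#' @param motifs Motif table as returned by [default_motifs()].
#' @export
write_motifs <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

compile_motif_table <- function(motifs = default_motifs()) {
  lapply(seq_len(nrow(motifs)), function(i) {
    compile_pattern(motifs$grammar[i], name = motifs$name[i],
                    fold_class = motifs$fold_class[i])
  })
}

empty_hits <- function() {
  data.frame(pattern_name = character(), start = integer(),
             matched = character(), fold_class = character(),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence for motif matches
#'
#' Reports all matches of each motif grammar, including overlapping ones
#' (multiple instances of e.g. DDxxD on one protein are biologically
#' meaningful). Positions are 1-based inclusive.
#'
#' @param seq Amino-acid sequence (single string; `X` tolerated).
#' @param motifs Motif table (`name`, `grammar`, `fold_class`), defaults to
#'   [default_motifs()].
#' @return Data frame with columns `pattern_name`, `start`, `matched`,
#'   `fold_class`, sorted by (`start`, `pattern_name`). Empty for an empty
#'   sequence.
#' @examples
#' scan_motifs("MMDDSREMMNDLFSFYKEMM")
#' @export
scan_motifs <- function(seq, motifs = default_motifs()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(empty_hits())
  compiled <- if (is.list(motifs) && !is.data.frame(motifs)) motifs
              else compile_motif_table(motifs)
  out <- lapply(compiled, function(p) {
    m <- gregexpr(paste0("(?=", p$regex, ")"), seq, perl = TRUE)[[1]]
    starts <- as.integer(m)
    if (length(starts) == 1L && starts[1] == -1L) return(empty_hits())
    data.frame(pattern_name = p$name, start = starts,
               matched = substring(seq, starts, starts + p$width - 1L),
               fold_class = p$fold_class, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  hits <- hits[order(hits$start, hits$pattern_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Derive the Class I / Class II fold call from motif hits
#'
#' A protein carrying only Class I-tagged motif hits is called `class_I`
#' (ionization-dependent catalysis), only Class II-tagged hits `class_II`
#' (protonation-dependent), both `bifunctional`, neither `none`. Accessory
#' hits (QW, triads) never change the call.
#'
#' @param hits Hit table from [scan_motifs()].
#' @return List of class `fold_call` with elements `value` and `evidence`.
#' @export
classify_fold <- function(hits) {
  has1 <- any(hits$fold_class == "class_I")
  has2 <- any(hits$fold_class == "class_II")
  value <- if (has1 && has2) "bifunctional"
           else if (has1) "class_I"
           else if (has2) "class_II"
           else "none"
  structure(list(value = value,
                 evidence = hits[hits$fold_class != "accessory", , drop = FALSE]),
            class = "fold_call")
}

#' @export
print.fold_call <- function(x, ...) {
  cat(sprintf("<fold_call> %s (%d catalytic motif hit%s)\n", x$value,
              nrow(x$evidence), if (nrow(x$evidence) == 1L) "" else "s"))
  invisible(x)
}

#' Count QW motifs
#'
#' Number of (possibly overlapping) `QW` occurrences; oxidosqualene cyclases
#' characteristically carry five, strengthening the enzyme structure.
#'
#' @param seq Amino-acid sequence.
#' @return Integer count.
#' @export
count_qw <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(0L)
  m <- gregexpr("(?=QW)", toupper(seq), perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}
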