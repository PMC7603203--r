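# The functional taxonomy: terminal classification groups for terpene
# synthase proteins, each defined by required domain accessions (with any-of
# alternatives), required motif names, forbidden domains, an optional
# transmembrane-helix requirement, and a precedence rank.  The default
# taxonomy has 15 terminal groups; prenylation and polyprenyl-domain enzymes
# carry secondary subtype annotations (GGTase I/II, FTase; GGPP/FPP synthase,
# indole diterpene synthase, chimeric-like) rather than extra leaves.

# required_domains syntax: alternatives within one requirement are
# comma-separated; independent requirements are '|'-separated.
# "PF06330|PIRSF001388" = both required; "A,B,C" = any one of A/B/C.
parse_domain_spec <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, "|", fixed = TRUE)[[1]],
         function(alt) strsplit(alt, ",", fixed = TRUE)[[1]])
}

parse_list_spec <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, "|", fixed = TRUE)[[1]]
}

#' Default functional taxonomy
#'
#' The bundled 15-group taxonomy for fungal terpene synthases. Groups are
#' evaluated in precedence order: the HAD-like bifunctional group, the TRI5
#' superfamily (trichodiene synthase, longiborneol synthase, and two
#' uncharacterized groups), the terpene-synthase-C family
#' (presilphiperfolan-8-beta-ol synthase, pentalenene synthase, two
#' uncharacterized groups), squalene synthase (requiring the C-terminal
#' transmembrane helix), protein prenylation enzymes (subtypes GGTase I,
#' GGTase II, FTase), oxidosqualene cyclase, the SQS-PSY-domain
#' uncharacterized group, Class II diterpene synthases (CPS/KS-like), and the
#' polyprenyl-synthase superfamily (subtypes GGPP synthase, FPP synthase,
#' indole diterpene synthase, chimeric-like).
#'
#' @return An object of class `ts_taxonomy`.
#' @examples
#' tx <- default_taxonomy()
#' nrow(tx$groups)
#' @export
default_taxonomy <- function() {
  g <- function(id, name, dom, motifs = "", forb = "", tm = FALSE, prec) {
    data.frame(id = id, display_name = name, required_domains = dom,
               required_motifs = motifs, forbidden_domains = forb,
               needs_tm = tm, precedence = prec, stringsAsFactors = FALSE)
  }
  groups <- rbind(
    g("had_bifunctional", "bifunctional HAD-like TS",
      "PF13419|IPR008930", "ddxxe|dxdtt", prec = 1L),
    g("tri5", "trichodiene synthase (TRI5)",
      "PF06330|PIRSF001388", "tri5_aspartate|tri5_triad", prec = 2L),
    g("longiborneol", "longiborneol synthase",
      "PF06330", "ddhfd", prec = 3L),
    g("tri5_unchar1", "TRI5 superfamily uncharacterized group 1",
      "PF06330", "ddxxe", prec = 4L),
    g("tri5_unchar2", "TRI5 superfamily uncharacterized group 2",
      "PF06330", "ddxxd", prec = 5L),
    g("presilphiperfolanol", "presilphiperfolan-8-beta-ol synthase",
      "PF03936", "ddxxe", prec = 6L),
    g("pentalenene", "pentalenene synthase",
      "PF03936", "nsd|dte", prec = 7L),
    g("tsc_unchar3", "terpene synthase C uncharacterized group 3",
      "PF03936", "ddxxd", prec = 8L),
    g("tsc_unchar4", "terpene synthase C uncharacterized group 4",
      "PF03936", "class1_aspartate", prec = 9L),
    g("squalene_synthase", "squalene synthase (SQS)",
      "PF00494|PTHR11626:SF2|PS01044", tm = TRUE, prec = 10L),
    g("protein_prenylation", "protein prenylation enzymes",
      "PTHR11774:SF4,PTHR11774:SF11,PTHR11774:SF6", prec = 11L),
    g("oxidosqualene_cyclase", "oxidosqualene cyclase (OSC)",
      "PF13249|PF13243|PTHR11764|PS01074", "dctae|qw", prec = 12L),
    g("sqs_psy_unchar5", "SQS-PSY domain uncharacterized group 5",
      "PF00494|PTHR21181:SF13", prec = 13L),
    g("class2_diterpene", "Class II diterpene synthase (CPS/KS-like)",
      "PTHR31739:SF4", "dxdd", prec = 14L),
    g("polyprenyl_superfamily", "polyprenyl synthase superfamily",
      "PF00348", "ddxxd", prec = 15L)
  )
  subtypes <- data.frame(
    group_id = c("protein_prenylation", "protein_prenylation",
                 "protein_prenylation", "polyprenyl_superfamily",
                 "polyprenyl_superfamily", "polyprenyl_superfamily",
                 "polyprenyl_superfamily"),
    subtype = c("GGTase1", "GGTase2", "FTase",
                "GGPP_synthase", "FPP_synthase", "indole_diTS",
                "chimeric_like"),
    trigger_domains = c("PTHR11774:SF4", "PTHR11774:SF11", "PTHR11774:SF6",
                        "PTHR12001:SF47", "PTHR11525:SF0", "PF00348,PF03936",
                        ""),
    stringsAsFactors = FALSE
  )
  new_taxonomy(groups, subtypes, version = "default-15")
}

new_taxonomy <- function(groups, subtypes = NULL, version = "custom") {
  stopifnot(is.data.frame(groups))
  need <- c("id", "display_name", "required_domains", "required_motifs",
            "forbidden_domains", "needs_tm", "precedence")
  if (!all(need %in% names(groups))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(groups$id)) stop("taxonomy group ids must be unique")
  if (anyDuplicated(groups$precedence)) {
    stop("taxonomy precedence ranks must be unique")
  }
  groups <- groups[order(groups$precedence), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(groups = groups, subtypes = subtypes, version = version),
            class = "ts_taxonomy")
}

#' Load a functional taxonomy
#'
#' Reads a taxonomy configuration from tab-separated text (columns `id`,
#' `display_name`, `required_domains`, `required_motifs`,
#' `forbidden_domains`, `needs_tm`, `precedence`; `|` separates independent
#' requirements, a comma marks any-of alternatives within one requirement),
#' or returns the default taxonomy when `path` is `NULL`.
#'
#' @param path Path to a taxonomy TSV, or `NULL` for [default_taxonomy()].
#' @return A `ts_taxonomy` object.
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) return(default_taxonomy())
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = character())
  df$needs_tm <- as.logical(df$needs_tm)
  df$precedence <- as.integer(df$precedence)
  new_taxonomy(df, version = basename(path))
}

#' Write a taxonomy configuration
#'
#' @param taxonomy A `ts_taxonomy` object.
#' @param path Output TSV path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(is(taxonomy, "ts_taxonomy"))
  write.table(taxonomy$groups, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.ts_taxonomy <- function(x, ...) {
  cat(sprintf("<ts_taxonomy> %s: %d terminal groups\n",
              x$version, nrow(x$groups)))
  cat(paste0("  ", format(x$groups$precedence, width = 2), ". ",
             x$groups$id, collapse = "\n"), "\n")
  invisible(x)
}
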