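# Rule-based classification of terpene synthase proteins.
#
# A protein is assigned to the first taxonomy group (in precedence order)
# whose domain, motif, forbidden-domain and transmembrane requirements are
# all met by the observed evidence; otherwise it is reported as
# "unclassified" (never dropped).  Domain evidence comes from an
# InterProScan-style annotation table, motif evidence from scan_motifs(),
# and the TM requirement from detect_tm_helix().

satisfies_group <- function(group_row, domains, motif_names, has_tm) {
  req_dom <- parse_domain_spec(group_row$required_domains)
  for (alt in req_dom) {
    if (!any(alt %in% domains)) return(NULL)
  }
  req_mot <- parse_list_spec(group_row$required_motifs)
  if (!all(req_mot %in% motif_names)) return(NULL)
  forb <- parse_list_spec(group_row$forbidden_domains)
  if (length(forb) && any(forb %in% domains)) return(NULL)
  if (isTRUE(group_row$needs_tm) && !isTRUE(has_tm)) return(NULL)
  evidence <- c(
    vapply(req_dom, function(alt) paste0("domain:", paste(intersect(alt, domains), collapse = "/")),
           character(1)),
    if (length(req_mot)) paste0("motif:", req_mot),
    if (isTRUE(group_row$needs_tm)) "tm:C-terminal helix"
  )
  evidence
}

assign_subtype <- function(taxonomy, group_id, domains) {
  st <- taxonomy$subtypes
  if (is.null(st)) return(NA_character_)
  st <- st[st$group_id == group_id, , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    trig <- st$trigger_domains[i]
    if (!nzchar(trig)) return(st$subtype[i])  # fallback subtype
    trig <- strsplit(trig, ",", fixed = TRUE)[[1]]
    if (all(trig %in% domains)) return(st$subtype[i])
  }
  NA_character_
}

#' Classify one protein from its evidence
#'
#' Evaluates taxonomy groups in precedence order; the first group whose
#' required domains are all observed (any-of alternatives allowed), required
#' motifs all hit, forbidden domains all absent, and transmembrane
#' requirement satisfied, wins. A protein matching no group is
#' `"unclassified"`.
#'
#' @param domains Character vector of observed domain accessions.
#' @param motif_hits Hit table from [scan_motifs()] (or a character vector of
#'   motif names).
#' @param has_tm Logical: was a C-terminal TM helix detected?
#' @param taxonomy A `ts_taxonomy` object.
#' @return List of class `ts_classification` with `group_id`, `subtype`,
#'   `fold_call`, `evidence`.
#' @export
classify_protein <- function(domains, motif_hits = NULL, has_tm = FALSE,
                             taxonomy = default_taxonomy()) {
  stopifnot(is(taxonomy, "ts_taxonomy"))
  domains <- as.character(domains %||% character())
  motif_names <- if (is.data.frame(motif_hits)) unique(motif_hits$pattern_name)
                 else unique(as.character(motif_hits %||% character()))
  fold <- if (is.data.frame(motif_hits)) classify_fold(motif_hits)$value
          else NA_character_
  for (i in seq_len(nrow(taxonomy$groups))) {
    row <- taxonomy$groups[i, , drop = FALSE]
    ev <- satisfies_group(row, domains, motif_names, has_tm)
    if (!is.null(ev)) {
      return(structure(list(group_id = row$id,
                            subtype = assign_subtype(taxonomy, row$id, domains),
                            fold_call = fold, evidence = ev),
                       class = "ts_classification"))
    }
  }
  structure(list(group_id = "unclassified", subtype = NA_character_,
                 fold_call = fold, evidence = character()),
            class = "ts_classification")
}

#' @export
print.ts_classification <- function(x, ...) {
  cat(sprintf("<ts_classification> %s%s (fold: %s)\n", x$group_id,
              if (!is.na(x$subtype)) paste0(" / ", x$subtype) else "",
              x$fold_call))
  invisible(x)
}

#' Classify a protein panel
#'
#' Runs the full evidence pipeline over a set of proteins: motif scan, fold
#' call, QW count, transmembrane detection, then precedence-ordered rule
#' classification. Domain annotation rows referring to unknown proteins are
#' skipped with a warning.
#'
#' @param proteins Named character vector (or `Biostrings::AAStringSet`) of
#'   amino-acid sequences.
#' @param domains Domain annotation table with columns `protein_id`,
#'   `accession` (InterProScan-style TSV as read by [read_domains()]).
#' @param motifs Motif table (default [default_motifs()]).
#' @param taxonomy A `ts_taxonomy` (default [default_taxonomy()]).
#' @param tm_args List of arguments passed to [detect_tm_helix()].
#' @return List of class `ts_panel_classification` with elements `results`
#'   (one row per protein: `protein_id`, `group_id`, `subtype`, `fold_call`,
#'   `n_qw`, `tm_length`) and `counts` (named per-group counts including
#'   `unclassified`; counts sum to the panel size).
#' @export
classify_panel <- function(proteins, domains, motifs = default_motifs(),
                           taxonomy = default_taxonomy(), tm_args = list()) {
  if (is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  stopifnot(is.character(proteins))
  if (is.null(names(proteins)) && length(proteins) > 0L) {
    stop("proteins must be named")
  }
  domains <- domains %||% data.frame(protein_id = character(),
                                     accession = character())
  unknown <- setdiff(unique(domains$protein_id), names(proteins))
  if (length(unknown)) {
    warning("skipping domain annotations for unknown protein(s): ",
            paste(unknown, collapse = ", "))
    domains <- domains[!(domains$protein_id %in% unknown), , drop = FALSE]
  }
  compiled <- compile_motif_table(motifs)
  rows <- lapply(names(proteins), function(id) {
    seq <- proteins[[id]]
    hits <- scan_motifs(seq, compiled)
    tm <- do.call(detect_tm_helix, c(list(seq), tm_args))
    dom <- domains$accession[domains$protein_id == id]
    cls <- classify_protein(dom, hits, has_tm = !is.null(tm),
                            taxonomy = taxonomy)
    data.frame(protein_id = id, group_id = cls$group_id,
               subtype = cls$subtype, fold_call = classify_fold(hits)$value,
               n_qw = count_qw(seq),
               tm_length = if (is.null(tm)) NA_integer_ else tm$length,
               stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows)
             else data.frame(protein_id = character(), group_id = character(),
                             subtype = character(), fold_call = character(),
                             n_qw = integer(), tm_length = integer(),
                             stringsAsFactors = FALSE)
  lvls <- c(taxonomy$groups$id, "unclassified")
  counts <- table(factor(results$group_id, levels = lvls))
  structure(list(results = results, counts = counts, taxonomy = taxonomy),
            class = "ts_panel_classification")
}

#' @export
print.ts_panel_classification <- function(x, ...) {
  cat(sprintf("<ts_panel_classification> %d proteins\n", nrow(x$results)))
  nz <- x$counts[x$counts > 0]
  for (g in names(nz)) cat(sprintf("  %-24s %d\n", g, nz[[g]]))
  invisible(x)
}

#' Select expression-study candidate genes
#'
#' Applies the rule used to pick genes for qPCR follow-up from a TS gene
#' inventory: keep Class I terpene cyclases and drop Class II enzymes,
#' terpene-precursor synthases (GGPP/FPP synthase subtypes) and
#' protein-prenylation enzymes. An optional `include_override` column
#' (values `"include"` / `"exclude"`) takes precedence over the rule.
#'
#' @param inventory Data frame with columns `gene`, `group` (taxonomy group
#'   ids), optional `subtype` and `include_override`.
#' @param excluded_groups Group ids dropped by the rule.
#' @param excluded_subtypes Subtype labels dropped by the rule.
#' @return The selected subset of `inventory` rows.
#' @export
select_expression_candidates <- function(
    inventory,
    excluded_groups = c("had_bifunctional", "oxidosqualene_cyclase",
                        "class2_diterpene", "protein_prenylation"),
    excluded_subtypes = c("GGPP_synthase", "FPP_synthase")) {
  stopifnot(is.data.frame(inventory), all(c("gene", "group") %in% names(inventory)))
  subtype <- if ("subtype" %in% names(inventory)) inventory$subtype
             else rep(NA_character_, nrow(inventory))
  keep <- !(inventory$group %in% excluded_groups) &
          !(subtype %in% excluded_subtypes)
  if ("include_override" %in% names(inventory)) {
    ov <- inventory$include_override
    keep[!is.na(ov) & ov == "include"] <- TRUE
    keep[!is.na(ov) & ov == "exclude"] <- FALSE
  }
  out <- inventory[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
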