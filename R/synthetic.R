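# Deterministic synthetic fixtures: protein panels with planted group
# signatures, an anchored biosynthetic-cluster locus, and qPCR Ct tables
# with planted fold changes.
#
# Background residues are drawn uniformly from the canonical amino acids
# MINUS {D, N, Q}.  Every bundled motif grammar starts with one of those
# three letters, so planted motifs are the only motif-scan signal and
# rule-classification of an unmutated panel inverts the generator exactly
# (the round-trip invariant).  Substitutions introduced by the mutation
# model use the same alphabet, and planted signature windows are protected,
# so domain and motif evidence survive mutation by construction.

# Alphabet for background residues and substitutions: canonical minus the
# motif-initial letters D, N, Q.
AA_BACKGROUND <- setdiff(AA_CANONICAL, c("D", "N", "Q"))

# Polar residues used for the C-terminal background of proteins carrying a
# planted TM anchor: the region around a single membrane-spanning helix is
# cytosolic/lumenal and polar, which keeps the helix the only
# membrane-grade hydrophobic feature of the fixture.
AA_POLAR <- c("E", "G", "H", "K", "P", "R", "S", "T")

# Planted signature registry for the default 15-group taxonomy.  Each entry:
# concrete motif instances with fractional offsets, the domain accessions to
# emit, and whether a C-terminal TM helix block is planted.  The single
# class-defining motif sits at 60% of the protein length; secondary motifs
# at nearby fixed fractions; the TM block in the final 10%.
group_signatures <- function() {
  sig <- function(domains, motifs = character(), fracs = numeric(),
                  tm = FALSE) {
    list(domains = domains, motifs = motifs, fracs = fracs, tm = tm)
  }
  list(
    had_bifunctional = sig(c("PF13419", "PTHR43611:SF3", "IPR008930"),
                           c("DDCLE", "DIDTT"), c(0.35, 0.60)),
    tri5 = sig(c("PF06330", "PIRSF001388"),
               c("DDSRE", "NDLFSFYKE"), c(0.60, 0.70)),
    longiborneol = sig("PF06330", "DDHFD", 0.60),
    tri5_unchar1 = sig("PF06330", "DDALE", 0.60),
    tri5_unchar2 = sig("PF06330", "DDALD", 0.60),
    presilphiperfolanol = sig("PF03936", "DDGFE", 0.60),
    pentalenene = sig("PF03936", c("NSD", "DTE"), c(0.55, 0.65)),
    tsc_unchar3 = sig("PF03936", "DDRLD", 0.60),
    tsc_unchar4 = sig("PF03936", "DETAD", 0.60),
    squalene_synthase = sig(c("PF00494", "PTHR11626:SF2", "PS01044"),
                            tm = TRUE),
    protein_prenylation = sig("PTHR11774:SF4"),
    oxidosqualene_cyclase = sig(c("PF13249", "PF13243", "PTHR11764",
                                  "PS01074"),
                                c("DCTSE", "QW", "QW", "QW", "QW", "QW"),
                                c(0.60, 0.10, 0.18, 0.26, 0.34, 0.42)),
    sqs_psy_unchar5 = sig(c("PF00494", "PTHR21181:SF13")),
    class2_diterpene = sig(c("PTHR31739:SF4", "PIRSF026498"), "DVDD", 0.60),
    polyprenyl_superfamily = sig(c("PF00348", "PTHR12001:SF47", "PS00723",
                                   "PS00444"),
                                 c("DDYLD", "DDFFD"), c(0.45, 0.60))
  )
}

# TM helix block planted for squalene synthase: 23 moderately hydrophobic
# residues (alanine, Kyte-Doolittle 1.8, just above the 1.6 window
# threshold) guarded by glutamates so that only windows entirely inside the
# helix pass and the detected run is exactly 23 residues.
TM_GUARD <- 8L
TM_HELIX_LEN <- 23L
tm_block <- function() {
  paste0(strrep("E", TM_GUARD), strrep("A", TM_HELIX_LEN),
         strrep("E", TM_GUARD))
}

domain_source <- function(acc) {
  if (startsWith(acc, "PF")) "Pfam"
  else if (startsWith(acc, "PTHR")) "PANTHER"
  else if (startsWith(acc, "PIRSF")) "PIRSF"
  else if (startsWith(acc, "PS")) "PROSITE"
  else if (startsWith(acc, "IPR")) "InterPro"
  else "other"
}

#' Protein panel specification
#'
#' @param n_per_group Proteins generated per taxonomy group (>= 1).
#' @param mutation_rate Per-residue substitution probability in \[0, 1);
#'   planted signature windows are protected from mutation.
#' @param background_length Protein length in residues (default 400).
#' @param seed Integer seed; identical specifications with identical seeds
#'   produce byte-identical output.
#' @param taxonomy Target `ts_taxonomy` (default [default_taxonomy()]); every
#'   group id must have a planted-signature recipe.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_per_group = 1L, mutation_rate = 0,
                       background_length = 400L, seed = 1L,
                       taxonomy = default_taxonomy()) {
  stopifnot(n_per_group >= 1L, mutation_rate >= 0, mutation_rate < 1,
            background_length >= 100L)
  if (nrow(taxonomy$groups) == 0L) stop("taxonomy must be non-empty")
  unknown <- setdiff(taxonomy$groups$id, names(group_signatures()))
  if (length(unknown)) {
    stop("no planted-signature recipe for group(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 mutation_rate = mutation_rate,
                 background_length = as.integer(background_length),
                 seed = as.integer(seed), taxonomy = taxonomy),
            class = "panel_spec")
}

# Substitute residues at non-protected positions with probability `rate`,
# drawing replacements (different from the current residue) from `alphabet`.
# Operates on a character vector; RNG state is the caller's.
mutate_chars <- function(chars, rate, protected, alphabet = AA_BACKGROUND) {
  if (rate <= 0) return(chars)
  n <- length(chars)
  free <- setdiff(seq_len(n), protected)
  hit <- free[runif(length(free)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  chars
}

#' Mutate a protein sequence outside protected windows
#'
#' Length-preserving point substitutions at per-residue probability `rate`;
#' positions listed in `protected` are never altered. Replacement residues
#' are drawn from the background alphabet (canonical amino acids minus
#' D/N/Q) so mutation cannot fabricate aspartate-rich motif signals.
#'
#' @param seq Amino-acid sequence.
#' @param rate Substitution probability in \[0, 1).
#' @param protected Integer vector of protected 1-based positions.
#' @param seed Integer seed.
#' @return Mutated sequence of identical length.
#' @export
mutate_sequence <- function(seq, rate, protected = integer(), seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- with_seed(seed, mutate_chars(chars, rate, protected))
  paste(out, collapse = "")
}

#' Generate a protein panel with planted group signatures
#'
#' For each taxonomy group, emits `n_per_group` proteins carrying the
#' group's motif instances verbatim at fixed fractional offsets, the
#' corresponding domain-annotation rows, and (for squalene synthase) a
#' planted C-terminal transmembrane helix. Background residues are uniform
#' over the canonical amino acids minus D/N/Q; mutation applies outside
#' planted windows only.
#'
#' @param spec A [panel_spec()].
#' @return List of class `ts_panel`: `proteins` (named character),
#'   `domains` (annotation data frame), `truth` (`protein_id`, `group_id`,
#'   `subtype`), `planted` (per-protein planted motif windows), `spec`.
#' @export
generate_protein_panel <- function(spec = panel_spec()) {
  stopifnot(is(spec, "panel_spec"))
  sigs <- group_signatures()
  tx <- spec$taxonomy
  L <- spec$background_length
  proteins <- character()
  dom_rows <- list()
  truth_rows <- list()
  planted_rows <- list()
  with_seed(spec$seed, {
    for (gid in tx$groups$id) {
      sig <- sigs[[gid]]
      for (k in seq_len(spec$n_per_group)) {
        id <- sprintf("%s_%02d", gid, k)
        chars <- sample(AA_BACKGROUND, L, replace = TRUE)
        protected <- integer()
        if (length(sig$motifs)) {
          for (m in seq_along(sig$motifs)) {
            inst <- strsplit(sig$motifs[m], "", fixed = TRUE)[[1]]
            s <- max(1L, min(L - length(inst) + 1L,
                             as.integer(round(sig$fracs[m] * L))))
            idx <- s:(s + length(inst) - 1L)
            chars[idx] <- inst
            protected <- c(protected, idx)
            planted_rows[[length(planted_rows) + 1L]] <- data.frame(
              protein_id = id, motif = sig$motifs[m], start = s,
              stringsAsFactors = FALSE)
          }
        }
        if (isTRUE(sig$tm)) {
          cterm <- (floor(L / 2) + 1L):L
          chars[cterm] <- sample(AA_POLAR, length(cterm), replace = TRUE)
          block <- strsplit(tm_block(), "", fixed = TRUE)[[1]]
          s <- min(L - length(block) + 1L, as.integer(round(0.88 * L)))
          idx <- s:(s + length(block) - 1L)
          chars[idx] <- block
          protected <- c(protected, idx)
          planted_rows[[length(planted_rows) + 1L]] <- data.frame(
            protein_id = id, motif = "TM_helix", start = s + TM_GUARD,
            stringsAsFactors = FALSE)
        }
        chars <- mutate_chars(chars, spec$mutation_rate, protected)
        proteins[[id]] <- paste(chars, collapse = "")
        for (acc in sig$domains) {
          dom_rows[[length(dom_rows) + 1L]] <- data.frame(
            protein_id = id, source_db = domain_source(acc), accession = acc,
            start = 11L, end = L - 10L,
            description = tx$groups$display_name[tx$groups$id == gid],
            stringsAsFactors = FALSE)
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein_id = id, group_id = gid,
          subtype = assign_subtype(tx, gid, sig$domains),
          stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(proteins = proteins,
                 domains = do.call(rbind, dom_rows),
                 truth = do.call(rbind, truth_rows),
                 planted = do.call(rbind, planted_rows),
                 spec = spec),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("<ts_panel> %d proteins (%d groups x %d), length %d, mutation %.2f, seed %d\n",
              length(x$proteins), nrow(x$spec$taxonomy$groups),
              x$spec$n_per_group, x$spec$background_length,
              x$spec$mutation_rate, x$spec$seed))
  invisible(x)
}

#' Cluster locus layout
#'
#' The default layout mirrors a trichodiene-synthase-anchored biosynthetic
#' cluster: the anchor plus six flanking genes (a Zn2-C6 transcription
#' factor A, tailoring oxygenases B and D, an alpha-beta hydrolase C, an MFS
#' transporter E and a carbonic anhydrase F) spanning 21.2 kb.
#'
#' @param anchor_name Anchor gene id (default `"tri5"`).
#' @param member_roles Named character vector: flanking gene id -> role.
#' @param gene_order Gene ids (anchor included) in genomic order.
#' @param gene_lengths Named integer vector of gene lengths in bp.
#' @param intergenic_gaps Integer vector of gaps in bp
#'   (`length(gene_order) - 1`); all must be non-negative.
#' @param strands Strand per gene, in `gene_order`.
#' @param total_span Expected span in kb; gene lengths plus gaps must equal
#'   `total_span * 1000` within 1 bp.
#' @param contig Contig name.
#' @param origin Start coordinate (1-based) of the first gene.
#' @return List of class `cluster_layout`.
#' @export
cluster_layout <- function(
    anchor_name = "tri5",
    member_roles = c(A = "Zn2-C6 transcription factor", B = "oxygenase",
                     C = "alpha-beta hydrolase", D = "oxygenase",
                     E = "MFS transporter", F = "carbonic anhydrase"),
    gene_order = c("A", "B", "C", anchor_name, "D", "E", "F"),
    gene_lengths = c(A = 1700L, B = 1900L, C = 1300L, tri5 = 1200L,
                     D = 1800L, E = 1600L, F = 900L),
    intergenic_gaps = c(2000L, 1800L, 1500L, 2000L, 1700L, 1800L),
    strands = c("+", "-", "+", "+", "-", "+", "-"),
    total_span = 21.2, contig = "tig_1", origin = 5001L) {
  if (length(member_roles) == 0L) {
    gene_order <- anchor_name
    gene_lengths <- gene_lengths[anchor_name]
    intergenic_gaps <- integer()
    strands <- strands[1]
    total_span <- unname(gene_lengths[anchor_name]) / 1000
  }
  if (total_span <= 0) stop("total_span must be positive")
  if (any(intergenic_gaps < 0)) stop("intergenic gaps must be non-negative")
  if (sum(gene_order == anchor_name) != 1L) {
    stop("anchor must appear exactly once in the layout")
  }
  if (length(intergenic_gaps) != length(gene_order) - 1L) {
    stop("need one intergenic gap per adjacent gene pair")
  }
  if (!setequal(gene_order, c(anchor_name, names(member_roles)))) {
    stop("gene_order must contain the anchor and every member")
  }
  span_bp <- sum(gene_lengths[gene_order]) + sum(intergenic_gaps)
  if (abs(span_bp - total_span * 1000) > 1) {
    stop(sprintf("gene lengths + gaps (%d bp) do not match total_span (%g kb)",
                 span_bp, total_span))
  }
  structure(list(anchor_name = anchor_name, member_roles = member_roles,
                 gene_order = gene_order, gene_lengths = gene_lengths,
                 intergenic_gaps = intergenic_gaps, strands = strands,
                 total_span = total_span, contig = contig, origin = origin),
            class = "cluster_layout")
}

role_domains <- function(role) {
  switch(role,
    "trichodiene synthase" = c("PF06330", "trichodiene synthase"),
    "Zn2-C6 transcription factor" = c("PF00172", "Zn2-C6 fungal-type DNA-binding domain"),
    "oxygenase" = c("PF00067", "cytochrome P450 oxygenase"),
    "alpha-beta hydrolase" = c("PF12697", "alpha-beta hydrolase fold"),
    "MFS transporter" = c("PF07690", "major facilitator superfamily transporter"),
    "carbonic anhydrase" = c("PF00484", "carbonic anhydrase"),
    c("", "hypothetical protein"))
}

#' Generate an anchored cluster locus
#'
#' Lays the anchor and flanking genes on one contig with the layout's
#' lengths, gaps and strands, and emits per-gene protein sequences plus
#' domain annotations that trigger the bundled role rules.
#'
#' @param layout A [cluster_layout()].
#' @param seed Integer seed (protein sequence backgrounds).
#' @return List of class `ts_locus`: `features` (gene table),
#'   `proteins` (named character), `domains` (annotation table), `roles`
#'   (named truth roles, anchor included) and `layout`.
#' @export
generate_cluster_locus <- function(layout = cluster_layout(), seed = 1L) {
  stopifnot(is(layout, "cluster_layout"))
  roles <- c(setNames("trichodiene synthase", layout$anchor_name),
             layout$member_roles)
  pos <- layout$origin
  rows <- list()
  for (i in seq_along(layout$gene_order)) {
    gid <- layout$gene_order[i]
    len <- unname(layout$gene_lengths[gid])
    rows[[i]] <- data.frame(gene_id = gid, contig = layout$contig,
                            start = pos, end = pos + len - 1L,
                            strand = layout$strands[i],
                            stringsAsFactors = FALSE)
    if (i < length(layout$gene_order)) {
      pos <- pos + len + layout$intergenic_gaps[i]
    }
  }
  features <- do.call(rbind, rows)
  proteins <- with_seed(seed, {
    setNames(vapply(layout$gene_order, function(gid) {
      paste(sample(AA_BACKGROUND, 300L, replace = TRUE), collapse = "")
    }, character(1)), layout$gene_order)
  })
  domains <- do.call(rbind, lapply(layout$gene_order, function(gid) {
    rd <- role_domains(roles[[gid]])
    data.frame(protein_id = gid, source_db = domain_source(rd[1]),
               accession = rd[1], start = 11L, end = 290L,
               description = rd[2], stringsAsFactors = FALSE)
  }))
  structure(list(features = features, proteins = proteins, domains = domains,
                 roles = roles[layout$gene_order], layout = layout),
            class = "ts_locus")
}

#' qPCR experiment design with planted fold changes
#'
#' @param genes Target gene ids (reference gene excluded).
#' @param conditions Condition names.
#' @param basal The basal condition (its planted folds are forced to 1).
#' @param planted_fold Numeric matrix `genes x conditions` of true
#'   2^-ddCt values (default all 1); must be positive.
#' @param reference_gene Endogenous control id (default `"beta-tubulin"`).
#' @param n_bio,n_tech Biological / technical replicates (defaults 3).
#' @param noise_sd Gaussian Ct noise, in cycles (default 0).
#' @param absent Optional list of `c(gene, condition)` pairs emitted as
#'   non-detections.
#' @param seed Integer seed.
#' @return List of class `ct_design`.
#' @export
ct_design <- function(genes, conditions, basal = conditions[1],
                      planted_fold = NULL, reference_gene = "beta-tubulin",
                      n_bio = 3L, n_tech = 3L, noise_sd = 0,
                      absent = list(), seed = 1L) {
  stopifnot(length(genes) >= 1L, length(conditions) >= 1L,
            basal %in% conditions, n_bio >= 1L, n_tech >= 1L, noise_sd >= 0)
  if (is.null(planted_fold)) {
    planted_fold <- matrix(1, length(genes), length(conditions),
                           dimnames = list(genes, conditions))
  }
  planted_fold <- as.matrix(planted_fold)
  if (!setequal(rownames(planted_fold), genes) ||
      !setequal(colnames(planted_fold), conditions)) {
    stop("planted_fold must be a genes x conditions matrix")
  }
  planted_fold <- planted_fold[genes, conditions, drop = FALSE]
  if (any(planted_fold <= 0)) stop("planted folds must be positive")
  planted_fold[, basal] <- 1
  structure(list(genes = genes, conditions = conditions, basal = basal,
                 planted_fold = planted_fold, reference_gene = reference_gene,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 noise_sd = noise_sd, absent = absent,
                 seed = as.integer(seed)),
            class = "ct_design")
}

#' Generate a Ct table with planted fold changes
#'
#' Base Ct level is 20 cycles for the reference gene and 24 for targets
#' (Livak output is invariant to these bases); a target's Ct in condition c
#' is lowered by `log2(planted_fold)` so that the exact 2^-ddCt computation
#' on a zero-noise table returns the planted folds. A shared per-(condition,
#' biological replicate) Gaussian offset models biological variation and a
#' per-well offset models technical noise, both with SD `noise_sd`. Absent
#' cells carry the non-detection sentinel (`NA`, an empty field in CSV).
#'
#' @param design A [ct_design()].
#' @return Data frame `gene`, `condition`, `bio_rep`, `tech_rep`, `ct`.
#' @export
generate_ct_table <- function(design = ct_design("ts1", "MM")) {
  stopifnot(is(design, "ct_design"))
  genes <- c(design$reference_gene, design$genes)
  base_ct <- setNames(c(20, rep(24, length(design$genes))), genes)
  absent_key <- vapply(design$absent, paste, character(1), collapse = "\r")
  rows <- list()
  with_seed(design$seed, {
    for (cond in design$conditions) {
      for (b in seq_len(design$n_bio)) {
        bio_off <- rnorm(1, 0, design$noise_sd)
        for (g in genes) {
          fold <- if (g == design$reference_gene) 1
                  else design$planted_fold[g, cond]
          is_absent <- paste(g, cond, sep = "\r") %in% absent_key
          for (t in seq_len(design$n_tech)) {
            ct <- if (is_absent) NA_real_ else {
              base_ct[[g]] - log2(fold) + bio_off +
                rnorm(1, 0, design$noise_sd)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, condition = cond, bio_rep = b, tech_rep = t, ct = ct,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
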