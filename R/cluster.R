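# Biosynthetic gene cluster extraction and cross-species synteny.
#
# Cluster delineation is intergenic-gap chaining around an anchor gene
# (default max gap 3 kb): transparent, deterministic, and sufficient to
# recover a compact secondary-metabolite cluster from gene coordinates.
# Member roles are assigned from domain annotations by first-match rules;
# cluster composition is compared across genomes through reciprocal-best-hit
# orthology on percent identity, with order conservation measured as the
# absolute Kendall tau of shared members' rank orders (strand-normalized
# against the anchor).

#' Extract the gene cluster around an anchor gene
#'
#' Grows the cluster left and right from the anchor along its contig, adding
#' the next gene while the intergenic gap is at most `max_gap` base pairs.
#'
#' @param features Gene feature table (`gene_id`, `contig`, `start`, `end`,
#'   `strand`; 1-based inclusive), e.g. from [read_gff_genes()].
#' @param anchor_id Gene id of the anchor (must occur exactly once).
#' @param max_gap Maximum intergenic gap in bp (default 3000).
#' @return Object of class `ts_cluster`: `anchor_id`, `members` (feature
#'   rows sorted by `start`, with a `role` column initialized to `NA`),
#'   `span_kb` (`(max end - min start + 1)/1000`) and `contig`.
#' @export
extract_cluster <- function(features, anchor_id, max_gap = 3000) {
  stopifnot(is.data.frame(features),
            all(c("gene_id", "contig", "start", "end", "strand") %in%
                names(features)))
  hit <- which(features$gene_id == anchor_id)
  if (length(hit) == 0L) stop("anchor gene '", anchor_id, "' not found")
  if (length(hit) > 1L) stop("anchor gene '", anchor_id, "' is duplicated")
  contig <- features$contig[hit]
  f <- features[features$contig == contig, , drop = FALSE]
  f <- f[order(f$start, f$gene_id), , drop = FALSE]
  a <- which(f$gene_id == anchor_id)
  lo <- a
  while (lo > 1L && f$start[lo] - f$end[lo - 1L] - 1L <= max_gap) lo <- lo - 1L
  hi <- a
  while (hi < nrow(f) && f$start[hi + 1L] - f$end[hi] - 1L <= max_gap) hi <- hi + 1L
  members <- f[lo:hi, , drop = FALSE]
  members$role <- NA_character_
  rownames(members) <- NULL
  structure(list(anchor_id = anchor_id, members = members,
                 span_kb = (max(members$end) - min(members$start) + 1) / 1000,
                 contig = contig),
            class = "ts_cluster")
}

#' @export
print.ts_cluster <- function(x, ...) {
  cat(sprintf("<ts_cluster> %d genes around '%s' on %s, %.1f kb\n",
              nrow(x$members), x$anchor_id, x$contig, x$span_kb))
  print(x$members[, c("gene_id", "start", "end", "strand", "role")],
        row.names = FALSE)
  invisible(x)
}

#' Default role rules for cluster members
#'
#' First-match rules mapping domain accessions or description keywords to
#' the functional roles typical of a secondary-metabolite cluster: backbone
#' terpene synthase, Zn2-C6 transcription factor, tailoring oxygenases and
#' hydrolases, carbonic anhydrase, and MFS efflux transporter.
#'
#' @return Data frame with columns `role`, `accessions` (comma-separated),
#'   `keywords` (regular expression).
#' @export
default_role_rules <- function() {
  data.frame(
    role = c("trichodiene synthase", "Zn2-C6 transcription factor",
             "oxygenase", "alpha-beta hydrolase", "MFS transporter",
             "carbonic anhydrase"),
    accessions = c("PF06330", "PF00172", "PF00067", "PF12697", "PF07690",
                   "PF00484"),
    keywords = c("trichodiene", "Zn2-C6|zinc.?cluster|fungal.?specific TF",
                 "oxygenase|cytochrome P450", "alpha.?beta hydrolase",
                 "major facilitator|MFS", "carbonic anhydrase"),
    stringsAsFactors = FALSE
  )
}

#' Assign functional roles to cluster members
#'
#' For each gene, the first rule whose accession matches an observed domain
#' accession or whose keyword matches a domain description wins; genes with
#' no match are `"hypothetical protein"`.
#'
#' @param cluster A `ts_cluster`, or a character vector of gene ids.
#' @param domains Domain annotation table (`protein_id`, `accession`,
#'   `description`), protein ids matching the cluster's gene ids.
#' @param rules Role rule table (default [default_role_rules()]).
#' @return For a `ts_cluster` input, the cluster with `members$role` filled
#'   in; for a character vector, a named character vector of roles.
#' @export
assign_gene_roles <- function(cluster, domains, rules = default_role_rules()) {
  ids <- if (is(cluster, "ts_cluster")) cluster$members$gene_id
         else as.character(cluster)
  desc_col <- if ("description" %in% names(domains)) domains$description
              else rep("", nrow(domains))
  roles <- vapply(ids, function(id) {
    rows <- domains$protein_id == id
    acc <- domains$accession[rows]
    desc <- desc_col[rows]
    for (r in seq_len(nrow(rules))) {
      rule_acc <- strsplit(rules$accessions[r], ",", fixed = TRUE)[[1]]
      if (any(rule_acc %in% acc)) return(rules$role[r])
      if (nzchar(rules$keywords[r]) && length(desc) &&
          any(grepl(rules$keywords[r], desc, ignore.case = TRUE))) {
        return(rules$role[r])
      }
    }
    "hypothetical protein"
  }, character(1))
  if (is(cluster, "ts_cluster")) {
    cluster$members$role <- unname(roles)
    cluster
  } else {
    roles
  }
}

# Reciprocal best hits between two named protein sets at an identity
# threshold.  Returns a data frame (id_a, id_b, identity).
reciprocal_best_hits <- function(prot_a, prot_b, identity_threshold = 50,
                                 params = alignment_params()) {
  if (length(prot_a) == 0L || length(prot_b) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  idm <- matrix(0, length(prot_a), length(prot_b),
                dimnames = list(names(prot_a), names(prot_b)))
  for (i in seq_along(prot_a)) {
    for (j in seq_along(prot_b)) {
      idm[i, j] <- pairwise_identity(prot_a[[i]], prot_b[[j]], params)
    }
  }
  pairs <- list()
  for (i in seq_along(prot_a)) {
    j <- which.max(idm[i, ])
    if (which.max(idm[, j]) == i && idm[i, j] >= identity_threshold) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        id_a = names(prot_a)[i], id_b = names(prot_b)[j],
        identity = idm[i, j], stringsAsFactors = FALSE)
    }
  }
  if (length(pairs)) do.call(rbind, pairs)
  else data.frame(id_a = character(), id_b = character(),
                  identity = numeric(), stringsAsFactors = FALSE)
}

#' Compare two gene clusters for shared content and synteny
#'
#' Ortholog pairs are reciprocal best hits by global percent identity at or
#' above `identity_threshold`. Order conservation is the absolute Kendall
#' tau between the shared members' rank orders along the two clusters, after
#' orientation normalization: when the anchors lie on opposite strands one
#' cluster's order is reversed. With one shared pair or none, order
#' conservation is 1.
#'
#' @param cluster_a,cluster_b `ts_cluster` objects.
#' @param prot_a,prot_b Named character vectors of member protein sequences
#'   (names matching member gene ids).
#' @param identity_threshold Minimum percent identity (default 50).
#' @param params An [alignment_params()] object.
#' @return List with `shared` (data frame `id_a`, `id_b`, `identity`) and
#'   `order_conservation` in \[0, 1\].
#' @export
synteny_compare <- function(cluster_a, cluster_b, prot_a, prot_b,
                            identity_threshold = 50,
                            params = alignment_params()) {
  stopifnot(is(cluster_a, "ts_cluster"), is(cluster_b, "ts_cluster"))
  shared <- reciprocal_best_hits(prot_a, prot_b, identity_threshold, params)
  if (nrow(shared) <= 1L) {
    return(list(shared = shared, order_conservation = 1))
  }
  rank_a <- match(shared$id_a, cluster_a$members$gene_id)
  rank_b <- match(shared$id_b, cluster_b$members$gene_id)
  strand_of <- function(cl) {
    s <- cl$members$strand[cl$members$gene_id == cl$anchor_id]
    if (length(s)) s else "+"
  }
  if (strand_of(cluster_a) != strand_of(cluster_b)) {
    rank_b <- -rank_b
  }
  tau <- cor(rank_a, rank_b, method = "kendall")
  list(shared = shared, order_conservation = abs(tau))
}

#' Gene presence/absence matrix across genomes
#'
#' A query gene is present in a genome when it has a reciprocal best hit at
#' or above the identity threshold among the genome's proteins. Raising the
#' threshold can only remove presences.
#'
#' @param genomes Named list; each element a named character vector of the
#'   genome's protein sequences.
#' @param queries Named character vector of query protein sequences.
#' @param identity_threshold Minimum percent identity (default 50).
#' @param params An [alignment_params()] object.
#' @return Logical matrix, genomes x query genes.
#' @export
presence_matrix <- function(genomes, queries, identity_threshold = 50,
                            params = alignment_params()) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  out <- matrix(FALSE, length(genomes), length(queries),
                dimnames = list(names(genomes), names(queries)))
  if (length(queries) == 0L) return(out)
  for (g in seq_along(genomes)) {
    rbh <- reciprocal_best_hits(queries, genomes[[g]], identity_threshold,
                                params)
    out[g, rbh$id_a] <- TRUE
  }
  out
}
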