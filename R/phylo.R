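# Reference-guided phylogenetic assignment.
#
# Desk-scale tree machinery: p-distances from percent identity, classical
# neighbor-joining with deterministic tie-breaking, a guide-order progressive
# aligner to build the multiple alignment, nonparametric bootstrap over
# alignment columns, and clade-membership labeling of a query against
# labeled reference proteins (clades accepted at bootstrap support >= 50 by
# default).

#' Neighbor-joining tree
#'
#' Classical neighbor joining on a symmetric distance matrix. Ties in the
#' Q-criterion are broken by the lowest (row, column) index pair; negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister edge, so path lengths between the joined pair are preserved.
#'
#' @param d Square symmetric numeric matrix with zero diagonal and >= 3 taxa;
#'   row/column names are used as tip labels.
#' @param labels Optional tip labels overriding `rownames(d)`.
#' @return An unrooted `phylo` tree (package \pkg{ape}).
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (ncol(d) != n) stop("distance matrix must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  labels <- labels %||% rownames(d) %||% paste0("t", seq_len(n))
  if (anyDuplicated(labels)) stop("tip labels must be unique")
  nodes <- as.list(labels)
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newick <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], li, nodes[[j]], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newick)
    D <- D2
  }
  # closed-form star resolution for the final three nodes
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[[1]], l1, nodes[[2]], l2, nodes[[3]], l3)
  ape::read.tree(text = newick)
}

# p-distance matrix from a character matrix (rows = sequences, "-" = gap):
# proportion of differing columns among columns where both sequences are
# ungapped; 1 when there is no ungapped overlap.
pdist_from_chars <- function(M, cols = seq_len(ncol(M))) {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  sub <- M[, cols, drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- sub[i, ] != "-" & sub[j, ] != "-"
      D[i, j] <- D[j, i] <- if (!any(ok)) 1 else mean(sub[i, ok] != sub[j, ok])
    }
  }
  D
}

seqs_to_char_matrix <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must be aligned (equal length)")
  M <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(M) <- names(seqs)
  M
}

# Canonical bipartition keys of a tree: for each internal edge, the tip set
# on the side NOT containing the alphabetically first tip, sorted and joined
# with "|".  Only non-trivial bipartitions (both sides >= 2 tips) are kept.
tree_split_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(cl) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) {
      return(NA_character_)
    }
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree from p-distances over the full alignment, then
#' resamples alignment columns with replacement `n_replicates` times; the
#' support of each internal bipartition is the percentage of replicate trees
#' containing it. Leaf input order does not affect the result: taxa are
#' canonicalized alphabetically before tree building and one RNG stream,
#' seeded once, drives all resampling.
#'
#' @param alignment Named character vector of aligned (equal-length)
#'   sequences, >= 3.
#' @param n_replicates Number of bootstrap replicates (>= 1, default 100).
#' @param seed Integer seed.
#' @return A `phylo` tree whose `node.label` holds integer supports in
#'   \[0, 100\] (`NA` on trivial bipartitions), with attribute
#'   `split_support`, a named vector mapping bipartition keys to supports.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (length(alignment) < 3L) stop("need at least 3 sequences")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop("alignment must have unique names")
  }
  alignment <- alignment[order(names(alignment))]
  M <- seqs_to_char_matrix(alignment)
  main <- nj_tree(pdist_from_chars(M))
  keys <- tree_split_keys(main)
  counts <- setNames(rep(0L, length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      rep_tree <- nj_tree(pdist_from_chars(M, cols))
      rep_keys <- tree_split_keys(rep_tree)
      hit <- !is.na(keys) & keys %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- ifelse(is.na(keys), NA_integer_,
                    as.integer(round(100 * counts / n_replicates)))
  main$node.label <- support
  ss <- support[!is.na(keys)]
  names(ss) <- keys[!is.na(keys)]
  attr(main, "split_support") <- ss
  main
}

#' Progressive multiple alignment
#'
#' A simple guide-order progressive aligner: sequences are added in the tip
#' order of a preliminary NJ tree built on pairwise-identity distances, each
#' new sequence being globally aligned against the running profile's
#' consensus (most frequent non-gap residue per column, alphabetical
#' tie-break).
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param params An [alignment_params()] object.
#' @return Named character vector of gapped sequences of equal length, in
#'   the input order.
#' @export
progressive_align <- function(seqs, params = alignment_params()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  n <- length(seqs)
  if (n == 1L) return(seqs)
  ord <- if (n == 2L) names(seqs) else {
    D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- 1 - pairwise_identity(seqs[[i]], seqs[[j]],
                                                    params) / 100
      }
    }
    nj_tree(D)$tip.label
  }
  aln0 <- align_global(seqs[[ord[1]]], seqs[[ord[2]]], params)
  msa <- setNames(c(aln0$a_aln, aln0$b_aln), ord[1:2])
  for (nm in ord[-(1:2)]) {
    M <- seqs_to_char_matrix(msa)
    cons <- apply(M, 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return("A")
      tab <- sort(table(col), decreasing = TRUE)
      cands <- names(tab)[tab == tab[1]]
      sort(cands)[1]
    })
    aln <- align_global(paste(cons, collapse = ""), seqs[[nm]], params)
    ca <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
    sa <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
    newM <- matrix("-", nrow(M) + 1L, length(ca))
    w <- 0L
    for (p in seq_along(ca)) {
      if (ca[p] != "-") {
        w <- w + 1L
        newM[seq_len(nrow(M)), p] <- M[, w]
      }
      newM[nrow(M) + 1L, p] <- sa[p]
    }
    msa <- setNames(apply(newM, 1, paste, collapse = ""), c(names(msa), nm))
  }
  msa[names(seqs)]
}

#' Assign a query protein by reference-clade membership
#'
#' Builds a bootstrap-supported NJ tree on the query plus labeled reference
#' sequences; the query receives the label of the tightest reference clade it
#' nests within (all non-query members sharing one label), provided that
#' clade's bipartition has bootstrap support at or above the threshold.
#' With `support_threshold = 0` and no internal bipartition available (e.g.
#' only two references), the nearest reference's label is returned.
#'
#' @param query Query amino-acid sequence (single string).
#' @param references Named character vector of reference sequences.
#' @param labels Named character vector of functional labels, names matching
#'   `references`; at least 2 distinct labels are required.
#' @param support_threshold Minimum bootstrap support in \[0, 100\]
#'   (default 50).
#' @param n_replicates Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param params An [alignment_params()] object.
#' @return The assigned label, or `"unassigned"`.
#' @export
assign_by_reference <- function(query, references, labels,
                                support_threshold = 50, n_replicates = 100L,
                                seed = 1L, params = alignment_params()) {
  stopifnot(is.character(query), length(query) == 1L)
  if (is.null(names(references))) stop("references must be named")
  labels <- labels[names(references)]
  if (anyNA(labels)) stop("every reference needs a label")
  if (length(unique(labels)) < 2L) {
    stop("assignment needs references from at least 2 distinct labels")
  }
  qname <- "query"
  while (qname %in% names(references)) qname <- paste0(".", qname)
  seqs <- c(setNames(query, qname), references)
  if (length(unique(nchar(seqs))) != 1L) {
    seqs <- progressive_align(seqs, params)
  }
  tree <- bootstrap_support(seqs, n_replicates = n_replicates, seed = seed)
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ss <- attr(tree, "split_support")
  ref_tip <- sort(tips)[1]
  cand <- list()
  for (cl in pp) {
    side <- labs[cl]
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    qside <- if (qname %in% side) side else other
    members <- setdiff(qside, qname)
    if (!(qname %in% qside) || length(members) == 0L) next
    if (length(unique(labels[members])) != 1L) next
    key_side <- if (ref_tip %in% side) other else side
    key <- paste(sort(key_side), collapse = "|")
    cand[[length(cand) + 1L]] <- list(size = length(qside),
                                      label = unname(labels[members[1]]),
                                      support = unname(ss[key]))
  }
  if (length(cand) == 0L) {
    if (support_threshold <= 0) {
      ident <- vapply(references, function(r) pairwise_identity(query, r, params),
                      numeric(1))
      return(unname(labels[names(which.max(ident))]))
    }
    return("unassigned")
  }
  sizes <- vapply(cand, `[[`, numeric(1), "size")
  sups <- vapply(cand, function(x) x$support %||% 0, numeric(1))
  labs_c <- vapply(cand, `[[`, character(1), "label")
  ord <- order(sizes, -sups, labs_c)
  best <- cand[[ord[1]]]
  if ((best$support %||% 0) >= support_threshold) best$label else "unassigned"
}
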