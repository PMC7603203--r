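test_that("global alignment handles matches, gaps and symmetry", {
  a <- align_global("ACDE", "ACDE")
  expect_equal(a$a_aln, "ACDE")
  expect_equal(a$b_aln, "ACDE")
  b <- align_global("ACDE", "ACE")
  expect_equal(nchar(b$a_aln), 4L)
  expect_equal(sum(strsplit(b$b_aln, "")[[1]] == "-"), 1L)
  expect_equal(align_global("ACDE", "ACE")$score,
               align_global("ACE", "ACDE")$score)
  expect_error(align_global("", "ACDE"), "non-empty")
})

test_that("percent identity obeys its bounds and conventions", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  set.seed(2)
  for (i in 1:20) {
    a <- random_aa_seq(60)
    b <- random_aa_seq(60)
    id <- pairwise_identity(a, b)
    expect_true(id >= 0 && id <= 100)
    expect_equal(id, pairwise_identity(b, a))
    expect_true(pairwise_identity(a, a) == 100)
  }
  # trimmed vs full denominator differ when one sequence has a terminal
  # overhang
  a <- "MKLVACDEFGHIKLMNP"
  b <- "ACDEFGHIKLMNP"
  trimmed <- pairwise_identity(a, b)
  full <- pairwise_identity(a, b,
                            alignment_params(identity_denominator = "full"))
  expect_equal(trimmed, 100)
  expect_lt(full, 100)
})

test_that("neighbor joining recovers a known additive tree exactly", {
  # distances generated from ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(truth), tr)), 0)
  # path lengths reproduce the input distances exactly (additivity oracle)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("three taxa resolve by the closed-form star equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("Q-criterion ties break on the lowest row/column pair", {
  # fully equidistant taxa: every join is equally good; the rule must pick
  # the first pair, yielding the AB|CD split
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(truth), tr)), 0)
})

test_that("degenerate matrices are rejected", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("NJ recovers random additive trees (<= 8 taxa) and matches ape", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    t0 <- ape::rtree(n, rooted = FALSE)
    d0 <- cophenetic(t0)
    d0 <- d0[sort(rownames(d0)), sort(colnames(d0))]
    tr <- nj_tree(d0)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t0), tr)), 0)
    expect_equal(cophenetic(tr)[rownames(d0), colnames(d0)], d0,
                 tolerance = 1e-8)
    # independent implementation agrees on the topology
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ape::nj(d0)), tr)), 0)
  }
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  fam <- two_family_refs()
  aln <- c(fam$refs, q = fam$f1)
  tr1 <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  ss <- attr(tr1, "split_support")
  # the family split is preserved by every column resample
  fam_split <- paste(sort(c("s1", "s2")), collapse = "|")
  expect_equal(unname(ss[fam_split]), 100)
  tr2 <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  expect_identical(attr(tr2, "split_support"), ss)
  # a single replicate can only give 0 or 100
  tr3 <- bootstrap_support(aln, n_replicates = 1, seed = 8)
  sup <- attr(tr3, "split_support")
  expect_true(all(sup %in% c(0, 100)))
  # leaf input order does not change supports
  tr4 <- bootstrap_support(rev(aln), n_replicates = 50, seed = 4)
  expect_identical(attr(tr4, "split_support"), ss)
  expect_error(bootstrap_support(c(a = "AC", b = "ACD", c = "AC")), "aligned")
})

test_that("progressive alignment produces a consistent equal-length MSA", {
  seqs <- c(x = "MKLVACDEFG", y = "MKLVCDEFG", z = "MKLVACDEFG")
  msa <- progressive_align(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_identical(gsub("-", "", msa[["y"]]), seqs[["y"]])
  expect_identical(names(msa), names(seqs))
})

test_that("queries are assigned to the reference clade they nest within", {
  fam <- two_family_refs()
  query <- mutate_sequence(fam$f1, 0.02, seed = 99)
  expect_equal(assign_by_reference(query, fam$refs, fam$labels, seed = 6),
               "familyA")
  # renaming the labels renames the output (label-permutation equivariance)
  swapped <- c(r1 = "blue", r2 = "blue", s1 = "red", s2 = "red")
  expect_equal(assign_by_reference(query, fam$refs, swapped, seed = 6),
               "blue")
  # a threshold of zero always yields the nearest clade label
  expect_equal(assign_by_reference(query, fam$refs, fam$labels,
                                   support_threshold = 0, seed = 6),
               "familyA")
  # single reference label is undefined
  expect_error(assign_by_reference(query, fam$refs[1:2], fam$labels[1:2]),
               "2 distinct")
})

test_that("an equidistant low-support query stays unassigned", {
  set.seed(44)
  # two references from each family, query unrelated to either family
  fam <- two_family_refs(len = 80, seed = 31)
  query <- random_aa_seq(80)
  got <- assign_by_reference(query, fam$refs, fam$labels,
                             support_threshold = 101, seed = 12)
  expect_equal(got, "unassigned")
})
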