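test_that("panel generation is fully seed-deterministic", {
  p1 <- generate_protein_panel(panel_spec(seed = 7))
  p2 <- generate_protein_panel(panel_spec(seed = 7))
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p1$proteins, f1)
  write_fasta(p2$proteins, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p3 <- generate_protein_panel(panel_spec(seed = 8))
  expect_false(identical(p1$proteins, p3$proteins))
})

test_that("planted motifs appear verbatim at their recorded positions", {
  p <- generate_protein_panel(panel_spec(n_per_group = 2, mutation_rate = 0.3,
                                         seed = 13))
  for (r in seq_len(nrow(p$planted))) {
    id <- p$planted$protein_id[r]
    motif <- p$planted$motif[r]
    if (motif == "TM_helix") next
    got <- substr(p$proteins[[id]], p$planted$start[r],
                  p$planted$start[r] + nchar(motif) - 1L)
    expect_identical(got, motif)
  }
  # domain rows list exactly the group's accessions
  tri5_doms <- p$domains$accession[p$domains$protein_id == "tri5_01"]
  expect_setequal(tri5_doms, c("PF06330", "PIRSF001388"))
})

test_that("unknown taxonomy groups are a configuration error", {
  tx <- default_taxonomy()
  tx$groups$id[1] <- "mystery_group"
  expect_error(panel_spec(taxonomy = tx), "mystery_group")
})

test_that("mutation respects rate, protection and length", {
  s <- strrep("MALVKEIST", 40)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  expect_identical(mutate_sequence(s, 0.99, protected = seq_len(nchar(s)),
                                   seed = 1), s)
  m <- mutate_sequence(s, 0.5, seed = 1)
  expect_equal(nchar(m), nchar(s))
  # observed substitution fraction within the binomial 99% CI of the rate
  long <- strrep("MALVKEIST", 2000)  # 18000 residues
  rate <- 0.05
  mut <- mutate_sequence(long, rate, seed = 3)
  n_diff <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  ci <- qbinom(c(0.005, 0.995), nchar(long), rate)
  expect_true(n_diff >= ci[1] && n_diff <= ci[2])
})

test_that("label recovery is perfect at zero mutation and never improves", {
  rates <- c(0, 0.05, 0.15, 0.30)
  acc <- vapply(rates, panel_accuracy, numeric(1), n_per_group = 20, seed = 33)
  expect_equal(acc[1], 1.0)
  # non-increasing up to sampling slack: at each step the later accuracy must
  # not exceed what a one-sided binomial test at alpha = 0.01 would still
  # deem compatible with the earlier rate's accuracy
  n <- 15 * 20
  for (i in seq_len(length(rates) - 1)) {
    k_next <- round(acc[i + 1] * n)
    upper <- qbinom(0.99, n, acc[i])
    expect_lte(k_next, upper)
  }
})

test_that("the default locus matches its layout and degenerate layouts work", {
  loc <- generate_cluster_locus(cluster_layout(), seed = 1)
  expect_equal(nrow(loc$features), 7L)
  span_kb <- (max(loc$features$end) - min(loc$features$start) + 1) / 1000
  expect_equal(span_kb, 21.2)
  expect_equal(sum(loc$features$gene_id == "tri5"), 1L)
  # layout invariant: lengths + gaps = span
  lay <- loc$layout
  expect_equal(sum(lay$gene_lengths[lay$gene_order]) +
                 sum(lay$intergenic_gaps), lay$total_span * 1000)
  # anchor-only layout
  solo <- cluster_layout(member_roles = setNames(character(), character()))
  loc1 <- generate_cluster_locus(solo, seed = 1)
  expect_equal(nrow(loc1$features), 1L)
  expect_equal((loc1$features$end - loc1$features$start + 1) / 1000,
               solo$total_span)
  expect_error(cluster_layout(intergenic_gaps = c(-5L, 1800L, 1500L, 2000L,
                                                  1700L, 1800L)),
               "non-negative")
})

test_that("Ct tables plant folds exactly and carry non-detection sentinels", {
  pf <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("MM", "stress")))
  des <- ct_design(c("g1", "g2"), c("MM", "stress"), basal = "MM",
                   planted_fold = pf, noise_sd = 0, seed = 5)
  res <- run_expression_pipeline(generate_ct_table(des), basal = "MM")
  expect_true(all(abs(res$stats$fold_mean - 1) < 1e-12))
  pf["g1", "stress"] <- 18.7
  expect_error(ct_design(c("g1", "g2"), c("MM", "stress"), basal = "MM",
                         planted_fold = pf * 0), "positive")
  des2 <- ct_design(c("g1", "g2"), c("MM", "stress"), basal = "MM",
                    planted_fold = pf, noise_sd = 0, seed = 5,
                    absent = list(c("g2", "stress")))
  ct <- generate_ct_table(des2)
  expect_true(all(is.na(ct$ct[ct$gene == "g2" & ct$condition == "stress"])))
  # the sentinel round-trips through CSV as an empty field
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, tf)
  expect_true(any(grepl(",$", readLines(tf))))
  ct2 <- read_ct_table(tf)
  expect_equal(ct2$ct, ct$ct)
  res2 <- run_expression_pipeline(ct2, basal = "MM")
  g1 <- res2$stats[res2$stats$gene == "g1" & res2$stats$condition == "stress", ]
  expect_equal(g1$fold_mean, 18.7, tolerance = 1e-12)
  g2 <- res2$stats[res2$stats$gene == "g2" & res2$stats$condition == "stress", ]
  expect_true(g2$absent)
})

test_that("noisy Ct tables recover planted folds within sampling error", {
  pf <- matrix(c(1, 1, 1, 6), 2, 2,
               dimnames = list(c("gA", "gB"), c("MM", "stress")))
  des <- ct_design(c("gA", "gB"), c("MM", "stress"), basal = "MM",
                   planted_fold = pf, noise_sd = 0.1, n_bio = 50, seed = 17)
  res <- run_expression_pipeline(generate_ct_table(des), basal = "MM")
  folds <- res$folds$fold[res$folds$gene == "gB" &
                          res$folds$condition == "stress"]
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 6), 3 * se)
})
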