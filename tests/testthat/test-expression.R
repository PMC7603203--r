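ct_row <- function(gene, condition, bio, tech, ct) {
  data.frame(gene = gene, condition = condition, bio_rep = bio,
             tech_rep = tech, ct = ct, stringsAsFactors = FALSE)
}

test_that("technical replicates aggregate by mean with the majority-absent rule", {
  tab <- rbind(ct_row("g", "c", 1, 1:3, c(20, 20.5, 21)),
               ct_row("g", "c", 2, 1:3, c(20, NA, NA)),
               ct_row("g", "c", 3, 1, 25))
  agg <- aggregate_techreps(tab)
  expect_equal(agg$ct[agg$bio_rep == 1], 20.5)
  expect_true(agg$absent[agg$bio_rep == 2])
  expect_equal(agg$ct[agg$bio_rep == 3], 25)
  # under the all-absent rule the partial detection survives
  agg2 <- aggregate_techreps(tab, absent_rule = "all")
  expect_equal(agg2$ct[agg2$bio_rep == 2], 20)
})

test_that("the Livak closed form is exact", {
  # dCt = 23-20 = 3 in the condition, 25-20 = 5 in basal: ddCt = -2, fold 4
  tab <- rbind(ct_row("t", "cond", 1, 1, 23), ct_row("ref", "cond", 1, 1, 20),
               ct_row("t", "basal", 1, 1, 25), ct_row("ref", "basal", 1, 1, 20))
  folds <- livak_folds(aggregate_techreps(tab), reference_gene = "ref",
                       basal = "basal")
  expect_equal(folds$fold[folds$condition == "cond"], 4)
  expect_equal(folds$fold[folds$condition == "basal"], 1)
  expect_error(livak_folds(aggregate_techreps(tab), reference_gene = "ghost",
                           basal = "basal"), "reference gene")
})

test_that("folds are invariant to a global Ct shift and reference folds are 1", {
  pf <- matrix(c(1, 1, 1, 0.2, 1, 7), 2, 3,
               dimnames = list(c("x", "y"), c("MM", "c1", "c2")))
  des <- ct_design(c("x", "y"), c("MM", "c1", "c2"), basal = "MM",
                   planted_fold = pf, noise_sd = 0.2, seed = 3)
  ct <- generate_ct_table(des)
  r1 <- run_expression_pipeline(ct, basal = "MM")
  ct_shift <- ct
  ct_shift$ct <- ct_shift$ct + 7.3
  r2 <- run_expression_pipeline(ct_shift, basal = "MM")
  expect_equal(r1$folds$fold, r2$folds$fold, tolerance = 1e-12)
  # the reference gene never appears as a target; adding it as an explicit
  # self-normalized target gives folds of exactly 1
  expect_false("beta-tubulin" %in% r1$folds$gene)
  agg <- aggregate_techreps(ct)
  dup <- agg[agg$gene == "beta-tubulin", ]
  dup$gene <- "beta-tubulin-copy"
  folds <- livak_folds(rbind(agg, dup), basal = "MM")
  expect_true(all(abs(folds$fold[folds$gene == "beta-tubulin-copy"] - 1) <
                  1e-12))
})

test_that("zero-noise planted folds are recovered to 1e-9 relative error", {
  set.seed(6)
  genes <- paste0("g", 1:5)
  conds <- c("MM", "c1", "c2")
  pf <- matrix(2^runif(15, -6, 6), 5, 3, dimnames = list(genes, conds))
  des <- ct_design(genes, conds, basal = "MM", planted_fold = pf,
                   noise_sd = 0, seed = 4)
  res <- run_expression_pipeline(generate_ct_table(des), basal = "MM")
  pf[, "MM"] <- 1  # basal folds are forced to 1 by the design
  for (r in seq_len(nrow(res$stats))) {
    planted <- pf[res$stats$gene[r], res$stats$condition[r]]
    expect_lt(abs(res$stats$fold_mean[r] - planted) / planted, 1e-9)
  }
})

test_that("log2 fold recovery is unbiased under Ct noise", {
  pf <- matrix(c(1, 1, 1, 5), 2, 2,
               dimnames = list(c("a", "b"), c("MM", "c1")))
  des <- ct_design(c("a", "b"), c("MM", "c1"), basal = "MM",
                   planted_fold = pf, noise_sd = 0.3, n_bio = 200, seed = 8)
  res <- run_expression_pipeline(generate_ct_table(des), basal = "MM")
  l2 <- -res$folds$ddct[res$folds$gene == "b" & res$folds$condition == "c1"]
  se <- sd(l2) / sqrt(length(l2))
  expect_lt(abs(mean(l2) - log2(5)), 3 * se)
})

test_that("absent calls propagate and are never imputed", {
  des <- ct_design("g1", c("MM", "c1"), basal = "MM", noise_sd = 0, seed = 2,
                   absent = list(c("g1", "c1")))
  res <- run_expression_pipeline(generate_ct_table(des), basal = "MM")
  row <- res$stats[res$stats$condition == "c1", ]
  expect_true(row$absent)
  expect_true(is.na(row$fold_mean))
})

test_that("per-gene ANOVA with Tukey post-hoc yields the expected stars", {
  # non-overlapping groups {1,1,1} vs {4,4.1,3.9} on the ddCt scale:
  # F = (3 * 2 * (1.5)^2 / 1) / (0.02 / 4) = 2700, p << 0.001
  folds <- data.frame(gene = "g",
                      condition = rep(c("MM", "c1"), each = 3),
                      bio_rep = rep(1:3, 2),
                      ddct = c(1, 1, 1, 4, 4.1, 3.9))
  folds$fold <- 2^-folds$ddct
  folds$absent <- FALSE
  st <- fold_stats(folds, basal = "MM")
  p <- st$p_vs_basal[st$condition == "c1"]
  expect_lt(p, 0.001)
  expect_equal(st$stars[st$condition == "c1"], "***")
  # identical replicate folds across conditions: degenerate, not significant
  folds2 <- folds
  folds2$ddct <- 1
  folds2$fold <- 0.5
  st2 <- fold_stats(folds2, basal = "MM")
  expect_true(all(st2$degenerate))
  expect_true(all(st2$stars == "ns"))
  # a single condition yields descriptive output only
  st3 <- fold_stats(folds[folds$condition == "MM", ], basal = "MM")
  expect_true(is.na(st3$anova_p))
  expect_equal(st3$fold_mean, 0.5)
})

test_that("star codes follow the reporting thresholds with p = 0.05 boundary ns", {
  sc <- tpsinv:::star_code
  expect_equal(sc(0.2), "ns")
  expect_equal(sc(0.05), "ns")
  expect_equal(sc(0.049), "*")
  expect_equal(sc(0.01), "*")
  expect_equal(sc(0.009), "**")
  expect_equal(sc(0.0009), "***")
})

test_that("angular transformation and ANOVA behave on percentages", {
  expect_equal(angular_transform(0), 0)
  expect_equal(angular_transform(100), pi / 2)
  expect_error(angular_transform(101), "\\[0, 100\\]")
  # identical groups: no effect
  p_same <- angular_anova(rep(c(50, 50, 50), 2), rep(c("a", "b"), each = 3))$p
  expect_false(isTRUE(p_same < 0.05))
  # well-separated disease-severity readings are significant
  set.seed(12)
  g1 <- rnorm(3, 88.3, 1.2)
  g2 <- rnorm(3, 57.9, 4.7)
  p <- angular_anova(c(g1, g2), rep(c("high", "low"), each = 3))$p
  expect_lt(p, 0.05)
})
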