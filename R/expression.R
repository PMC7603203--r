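# Relative qPCR expression: the Livak 2^-ddCt method.
#
# Raw threshold cycles (Ct) are aggregated over technical replicates, then
# for each target gene and biological replicate:
#   dCt  = Ct(target) - Ct(reference gene), per condition
#   ddCt = dCt(condition) - dCt(basal condition)
#   fold = 2^-ddCt
# Non-detections propagate as absent, never imputed.  Per-gene statistics
# use one-way ANOVA across conditions on ddCt (the log2 scale, where
# additive Ct noise is homoscedastic) with Tukey HSD post-hoc tests, starred
# per the conventional thresholds (p >= 0.05 ns; * < 0.05; ** < 0.01;
# *** < 0.001).

#' Read and write Ct tables
#'
#' CSV with header `gene,condition,bio_rep,tech_rep,ct`; an empty `ct` field
#' is the non-detection sentinel.
#'
#' @param path CSV file path.
#' @return `read_ct_table()` returns a data frame with `ct` numeric and `NA`
#'   for non-detections.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(gene = "character", condition = "character"))
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df$ct <- suppressWarnings(as.numeric(df$ct))
  if (any(!is.na(df$ct) & df$ct <= 0)) stop("Ct values must be positive")
  key <- do.call(paste, c(df[c("gene", "condition", "bio_rep", "tech_rep")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("(gene, condition, bio_rep, tech_rep) must be unique")
  }
  df[need]
}

#' @rdname read_ct_table
#' @param ct_table Ct data frame.
#' @export
write_ct_table <- function(ct_table, path) {
  out <- ct_table[c("gene", "condition", "bio_rep", "tech_rep", "ct")]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate technical replicates
#'
#' Arithmetic mean of the detected Ct values per (gene, condition,
#' biological replicate). A cell is called absent when at least half of its
#' technical replicates are non-detections (`absent_rule = "majority"`), or
#' when all are (`"all"`).
#'
#' @param ct_table Ct data frame as from [read_ct_table()].
#' @param absent_rule `"majority"` (default) or `"all"`.
#' @return Data frame `gene`, `condition`, `bio_rep`, `ct` (NA when absent),
#'   `absent`.
#' @export
aggregate_techreps <- function(ct_table, absent_rule = c("majority", "all")) {
  absent_rule <- match.arg(absent_rule)
  sp <- split(ct_table,
              list(ct_table$gene, ct_table$condition, ct_table$bio_rep),
              drop = TRUE, sep = "\r")
  rows <- lapply(sp, function(g) {
    n_abs <- sum(is.na(g$ct))
    absent <- if (absent_rule == "majority") n_abs >= nrow(g) / 2
              else n_abs == nrow(g)
    data.frame(gene = g$gene[1], condition = g$condition[1],
               bio_rep = g$bio_rep[1],
               ct = if (absent) NA_real_ else mean(g$ct, na.rm = TRUE),
               absent = absent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$condition, out$bio_rep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Livak 2^-ddCt fold changes per biological replicate
#'
#' Normalizes each target gene's Ct to the reference gene within the same
#' condition and biological replicate, then to the basal condition of the
#' same biological replicate. Targets absent in a condition yield absent
#' folds; an absent reference or basal measurement makes the fold
#' uncomputable (also absent).
#'
#' @param agg Aggregated Ct table from [aggregate_techreps()].
#' @param reference_gene Endogenous control gene id (default
#'   `"beta-tubulin"`).
#' @param basal Basal condition (its folds are 1 by construction).
#' @return Data frame `gene`, `condition`, `bio_rep`, `ddct`, `fold`,
#'   `absent`, for every target gene (reference gene excluded).
#' @export
livak_folds <- function(agg, reference_gene = "beta-tubulin", basal) {
  if (!(reference_gene %in% agg$gene)) {
    stop("reference gene '", reference_gene, "' not in Ct table")
  }
  if (!(basal %in% agg$condition)) {
    stop("basal condition '", basal, "' not in Ct table")
  }
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  ref_ct <- setNames(ref$ct, paste(ref$condition, ref$bio_rep, sep = "\r"))
  targets <- agg[agg$gene != reference_gene, , drop = FALSE]
  dct <- targets$ct - ref_ct[paste(targets$condition, targets$bio_rep,
                                   sep = "\r")]
  base_key <- paste(targets$gene, targets$bio_rep, sep = "\r")
  basal_rows <- targets$condition == basal
  basal_dct <- setNames(dct[basal_rows], base_key[basal_rows])
  ddct <- unname(dct - basal_dct[base_key])
  out <- data.frame(gene = targets$gene, condition = targets$condition,
                    bio_rep = targets$bio_rep, ddct = ddct,
                    fold = 2^(-ddct), absent = is.na(ddct) | targets$absent,
                    stringsAsFactors = FALSE)
  out$ddct[out$absent] <- NA_real_
  out$fold[out$absent] <- NA_real_
  rownames(out) <- NULL
  out
}

star_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Per-gene fold-change statistics
#'
#' For each gene: mean and SD of the per-replicate folds by condition, a
#' one-way ANOVA across conditions on ddCt, and Tukey HSD comparisons of
#' each condition against the basal condition, starred at the conventional
#' thresholds. With fewer than two conditions (or fewer than two replicates
#' per condition) only descriptive statistics are returned. When every group
#' has zero within-condition variance and equal means, p is undefined and
#' reported as not significant with `degenerate = TRUE`.
#'
#' @param folds Fold table from [livak_folds()].
#' @param basal Basal condition name.
#' @return Data frame `gene`, `condition`, `n`, `fold_mean`, `fold_sd`,
#'   `anova_p`, `p_vs_basal`, `stars`, `absent`, `degenerate`.
#' @export
fold_stats <- function(folds, basal) {
  out <- lapply(split(folds, folds$gene), function(g) {
    conds <- unique(g$condition)
    desc <- do.call(rbind, lapply(conds, function(cn) {
      f <- g$fold[g$condition == cn]
      data.frame(gene = g$gene[1], condition = cn,
                 n = sum(!is.na(f)),
                 fold_mean = if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE),
                 fold_sd = if (sum(!is.na(f)) > 1) sd(f, na.rm = TRUE) else NA_real_,
                 absent = all(is.na(f)), stringsAsFactors = FALSE)
    }))
    ok <- g[!is.na(g$ddct), , drop = FALSE]
    tab <- table(ok$condition)
    anova_p <- NA_real_
    p_vs_basal <- setNames(rep(NA_real_, length(conds)), conds)
    degenerate <- FALSE
    if (length(tab) >= 2L && all(tab >= 2L)) {
      ok$condition <- factor(ok$condition)
      group_means <- tapply(ok$ddct, ok$condition, mean)
      resid_ss <- sum((ok$ddct - group_means[ok$condition])^2)
      if (resid_ss < 1e-12) {
        if (max(group_means) - min(group_means) < 1e-12) {
          degenerate <- TRUE  # no variance, no effect: p undefined -> ns
        } else {
          anova_p <- 0
          p_vs_basal[] <- ifelse(
            abs(group_means[conds] - group_means[[basal]]) < 1e-12, 1, 0)
        }
      } else {
        fit <- aov(ddct ~ condition, data = ok)
        anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
        tk <- TukeyHSD(fit)$condition
        cmp <- rownames(tk)
        for (cn in setdiff(levels(ok$condition), basal)) {
          row <- match(TRUE, cmp %in% c(paste0(cn, "-", basal),
                                        paste0(basal, "-", cn)))
          if (!is.na(row)) p_vs_basal[cn] <- tk[row, "p adj"]
        }
        p_vs_basal[basal] <- 1
      }
    }
    desc$anova_p <- anova_p
    desc$p_vs_basal <- unname(p_vs_basal[desc$condition])
    desc$stars <- vapply(desc$p_vs_basal, star_code, character(1))
    desc$degenerate <- degenerate
    if (degenerate) desc$stars[!is.na(desc$fold_mean)] <- "ns"
    desc
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full relative-expression pipeline
#'
#' Chains [aggregate_techreps()], [livak_folds()] and [fold_stats()].
#'
#' @param ct_table Raw Ct table (data frame or CSV path).
#' @param reference_gene Endogenous control gene id.
#' @param basal Basal condition.
#' @param absent_rule Passed to [aggregate_techreps()].
#' @return List of class `ts_expression` with `folds` (per biological
#'   replicate) and `stats` (per gene x condition).
#' @export
run_expression_pipeline <- function(ct_table, reference_gene = "beta-tubulin",
                                    basal, absent_rule = "majority") {
  if (is.character(ct_table) && length(ct_table) == 1L) {
    ct_table <- read_ct_table(ct_table)
  }
  agg <- aggregate_techreps(ct_table, absent_rule = absent_rule)
  folds <- livak_folds(agg, reference_gene = reference_gene, basal = basal)
  stats <- fold_stats(folds, basal = basal)
  structure(list(folds = folds, stats = stats, basal = basal,
                 reference_gene = reference_gene),
            class = "ts_expression")
}

#' @export
print.ts_expression <- function(x, ...) {
  cat(sprintf("<ts_expression> %d genes, basal '%s', reference '%s'\n",
              length(unique(x$stats$gene)), x$basal, x$reference_gene))
  print(x$stats[, c("gene", "condition", "fold_mean", "fold_sd", "stars",
                    "absent")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Angular (arcsine-square-root) transform
#'
#' @param x Percentages in \[0, 100\].
#' @return `asin(sqrt(x/100))`, in radians (0 maps to 0, 100 to pi/2).
#' @export
angular_transform <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]")
  }
  asin(sqrt(x / 100))
}

#' One-way ANOVA after angular transformation
#'
#' The standard analysis for percentage data such as disease severity:
#' values are arcsine-square-root transformed, then compared across groups
#' by one-way ANOVA.
#'
#' @param values Percentages in \[0, 100\].
#' @param groups Group labels, same length as `values`.
#' @return List with `p` and the fitted `aov` object.
#' @export
angular_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  y <- angular_transform(values)
  fit <- aov(y ~ factor(groups))
  list(p = summary(fit)[[1]][["Pr(>F)"]][1], fit = fit)
}
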