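# Independent oracles and small fixture builders used across the suite.

# Brute-force window matcher: checks every window position-by-position
# against the parsed grammar, independently of the regex-based scanner.
naive_scan <- function(seq, grammar) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gs <- strsplit(grammar, "", fixed = TRUE)[[1]]
  allowed <- list()
  i <- 1L
  while (i <= length(gs)) {
    if (gs[i] == "[") {
      j <- i + 1L
      set <- character()
      while (gs[j] != "]") { set <- c(set, gs[j]); j <- j + 1L }
      allowed[[length(allowed) + 1L]] <- set
      i <- j + 1L
    } else if (gs[i] == "x") {
      allowed[[length(allowed) + 1L]] <- c(LETTERS)  # any residue incl. X
      i <- i + 1L
    } else {
      allowed[[length(allowed) + 1L]] <- gs[i]
      i <- i + 1L
    }
  }
  w <- length(allowed)
  n <- length(chars)
  if (n < w) return(integer())
  starts <- integer()
  for (s in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (p in seq_len(w)) {
      if (!(chars[s + p - 1L] %in% allowed[[p]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

random_aa_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                          "I", "K", "L", "M", "N", "P", "Q",
                                          "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Panel classification accuracy against generator truth labels.
panel_accuracy <- function(mutation_rate, n_per_group, seed) {
  p <- generate_protein_panel(panel_spec(n_per_group = n_per_group,
                                         mutation_rate = mutation_rate,
                                         seed = seed))
  cl <- classify_panel(p$proteins, p$domains)
  mean(cl$results$group_id[match(p$truth$protein_id,
                                 cl$results$protein_id)] == p$truth$group_id)
}

# Round-trip locus features through an on-disk GFF3 file so cluster tests
# exercise the real I/O path.
read_gff_via_disk <- function(loc) {
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  write_gff_genes(loc$features, tf)
  read_gff_genes(tf)
}

# Divergent two-family reference set for phylogeny tests.
two_family_refs <- function(len = 100L, seed = 11L) {
  set.seed(seed)
  f1 <- random_aa_seq(len)
  f2 <- random_aa_seq(len)
  list(
    f1 = f1, f2 = f2,
    refs = c(r1 = f1,
             r2 = mutate_sequence(f1, 0.05, seed = seed + 1L),
             s1 = f2,
             s2 = mutate_sequence(f2, 0.05, seed = seed + 2L)),
    labels = c(r1 = "familyA", r2 = "familyA", s1 = "familyB", s2 = "familyB")
  )
}
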