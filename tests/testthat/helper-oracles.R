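# Shared fixtures and independent oracles.  The oracles deliberately share
# no code with the package internals: the PseAAC oracle re-derives the
# standardization and correlation sums with explicit loops, and the AUC
# oracle counts concordant positive/negative pairs directly.

rand_peptide <- function(len, prob = NULL) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = prob),
        collapse = "")
}

rand_protein_df <- function(n = 5L, len_range = c(60L, 200L),
                            prefix = "prot") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(accession = paste0(prefix, seq_len(n)),
             name = paste("synthetic protein", seq_len(n)),
             sequence = vapply(lens, rand_peptide, ""),
             length = lens, stringsAsFactors = FALSE)
}

# Synthetic stand-ins for the six bovine milk proteins, generated at the
# canonical full-entry lengths (beta-casein 224, kappa-casein 190,
# alpha-S1-casein 214, alpha-S2-casein 222, beta-lactoglobulin 178,
# alpha-lactalbumin 142).  Sequences are random: only the lengths matter
# for counting and coordinate round-trip checks.
synthetic_milk_proteins <- function(seed = 550L) {
  lens <- c(224L, 190L, 214L, 222L, 178L, 142L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(accession = paste0("synthmilk", seq_along(lens)),
             name = "synthetic milk protein stand-in",
             sequence = vapply(lens, rand_peptide, ""),
             length = lens, stringsAsFactors = FALSE)
}

# Brute-force type-II PseAAC: explicit loops over residues, lags and
# properties, starting from the RAW property matrix.
bf_pseaac <- function(sequence, raw, lambda = 1L, omega = 0.05) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  std <- raw
  for (p in seq_len(nrow(raw))) {
    m <- sum(raw[p, ]) / 20
    s <- sqrt(sum((raw[p, ] - m)^2) / 20)
    std[p, ] <- (raw[p, ] - m) / s
  }
  f <- numeric(20)
  for (u in seq_len(20)) {
    for (ch in chars) if (ch == AA_ALPHABET[u]) f[u] <- f[u] + 1
  }
  f <- f / L
  taus <- c()
  for (g in seq_len(lambda)) {
    for (p in seq_len(nrow(raw))) {
      acc <- 0
      for (j in seq_len(L - g)) {
        acc <- acc + std[p, chars[j]] * std[p, chars[j + g]]
      }
      taus <- c(taus, acc / (L - g))
    }
  }
  denom <- 1 + omega * sum(taus)
  c(f / denom, omega * taus / denom)
}

# O(n^2) pair-counting AUC with ties counted 1/2.
pair_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# A property table whose standardized values are all 1 for every residue
# and property: yields closed-form encodings (tau = 1 for every factor).
unit_property_table <- function(n_properties = 6L) {
  std <- matrix(1, n_properties, 20,
                dimnames = list(paste0("p", seq_len(n_properties)),
                                AA_ALPHABET))
  structure(list(names = rownames(std), raw = std, standardized = std,
                 provenance = rep(NA_character_, n_properties)),
            class = "property_table")
}

# Small, fast model configs for tests that exercise plumbing rather than
# the full-size training runs.
fast_config <- function(family) {
  switch(family,
    gradient_boosted_trees = model_config(family,
                                          list(n_estimators = 50L,
                                               learning_rate = 0.2)),
    random_forest = model_config(family, list(min_samples_split = 2L,
                                              min_samples_leaf = 1L,
                                              max_features = 2L)),
    model_config(family))
}

ALL_FAMILIES <- c("gradient_boosted_trees", "rbf_svm", "random_forest",
                  "knn")
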