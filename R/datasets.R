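# Run an expression with a temporary RNG seed, restoring caller state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a labelled peptide dataset
#'
#' Low-level constructor; most users will call [build_dataset()] or
#' [generate_synthetic()].  Validates the dataset contract: no sequence
#' carries both labels, no duplicate sequences within a label, and (unless
#' `allow_unbalanced`) equally many positives and negatives.
#'
#' @param peptides data frame with columns `id`, `sequence`.
#' @param labels integer vector of 1 (positive) / 0 (negative), parallel
#'   to `peptides`.
#' @param name dataset name.
#' @param provenance list describing how the dataset was built (seed,
#'   pool, generator settings).
#' @param allow_unbalanced skip the balanced-count check.
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(peptides, labels, name = "dataset",
                            provenance = list(), allow_unbalanced = FALSE) {
  stopifnot(is.data.frame(peptides),
            all(c("id", "sequence") %in% names(peptides)),
            nrow(peptides) == length(labels),
            all(labels %in% c(0L, 1L)))
  labels <- as.integer(labels)
  pos <- peptides$sequence[labels == 1L]
  neg <- peptides$sequence[labels == 0L]
  if (length(intersect(pos, neg)) > 0L) {
    stop("positive and negative sets overlap: ",
         paste(utils::head(intersect(pos, neg), 3L), collapse = ", "))
  }
  if (anyDuplicated(pos) || anyDuplicated(neg)) {
    stop("duplicate sequences within a label")
  }
  if (!allow_unbalanced && length(pos) != length(neg)) {
    stop("unbalanced dataset: ", length(pos), " positives vs ",
         length(neg), " negatives")
  }
  peptides$length <- nchar(peptides$sequence)
  structure(list(name = name, peptides = peptides, labels = labels,
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labelled peptide dataset '%s': %d peptides (%d+/%d-), lengths %d-%d\n",
              x$name, nrow(x$peptides), sum(x$labels == 1L),
              sum(x$labels == 0L), min(x$peptides$length),
              max(x$peptides$length)))
  invisible(x)
}

#' Sample negative peptides from a background protein pool
#'
#' Draws as many negatives as there are positives.  Each negative is a
#' contiguous fragment of a randomly chosen background protein whose
#' length is drawn from the empirical length distribution of the
#' positives, so the negative set matches the positives' average length.
#' Fragments equal to any positive sequence, or already drawn, are
#' rejected and resampled (up to `max_attempts` tries per negative), which
#' enforces the disjointness contract between the positive and negative
#' sets.
#'
#' @param positives data frame with a `sequence` column (deduplicated
#'   positive peptides).
#' @param background data frame of proteins with a `sequence` column (as
#'   from [read_fasta()]).
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#' @param max_attempts rejection-sampling budget per negative.
#' @return data frame with columns `id`, `sequence`, `length`.
#' @export
sample_negatives <- function(positives, background, seed,
                             max_attempts = 1000L) {
  stopifnot(is.data.frame(positives), "sequence" %in% names(positives),
            is.data.frame(background), "sequence" %in% names(background),
            nrow(positives) > 0L, nrow(background) > 0L)
  pos_seq <- unique(positives$sequence)
  pos_len <- nchar(pos_seq)
  pool_res <- sum(nchar(background$sequence))
  if (pool_res < 50L * sum(pos_len)) {
    warning("background pool holds ", pool_res, " residues; at least ",
            50L * sum(pos_len), " recommended for ", length(pos_seq),
            " positives")
  }
  prot_len <- nchar(background$sequence)
  negatives <- character(0)
  with_local_seed(seed, {
    for (i in seq_along(pos_seq)) {
      drawn <- FALSE
      for (attempt in seq_len(max_attempts)) {
        len <- sample(pos_len, 1L)
        eligible <- which(prot_len >= len)
        if (length(eligible) == 0L) next
        p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        start <- sample.int(prot_len[p] - len + 1L, 1L)
        frag <- substr(background$sequence[p], start, start + len - 1L)
        if (frag %in% pos_seq || frag %in% negatives) next
        negatives <- c(negatives, frag)
        drawn <- TRUE
        break
      }
      if (!drawn) {
        stop("negative sampling failed after ", max_attempts,
             " attempts for draw ", i, "; background pool too small or ",
             "too redundant")
      }
    }
  })
  mean_ratio <- mean(nchar(negatives)) / mean(pos_len)
  if (abs(mean_ratio - 1) > 0.10) {
    message(sprintf(
      "mean negative length deviates %.1f%% from mean positive length",
      100 * abs(mean_ratio - 1)))
  }
  data.frame(id = paste0("neg", seq_along(negatives)), sequence = negatives,
             length = nchar(negatives), stringsAsFactors = FALSE)
}

#' Build a balanced labelled dataset from positives and a protein pool
#'
#' Combines validated, deduplicated positive peptides with an equal number
#' of negatives sampled by [sample_negatives()].  The returned dataset
#' satisfies the standard benchmark contract for bioactive-peptide
#' classification: the whole set is the disjoint union of the positive and
#' negative subsets, with no sequence in both.
#'
#' @inheritParams sample_negatives
#' @param name dataset name recorded in the object.
#' @return a `labeled_dataset`.
#' @export
build_dataset <- function(positives, background, seed, name = "ACEIP") {
  stopifnot(is.data.frame(positives))
  if (nrow(positives) == 0L) stop("no positive peptides supplied")
  positives <- positives[!duplicated(positives$sequence), , drop = FALSE]
  bad <- invalid_residues(positives$sequence)
  if (!is.null(bad)) {
    stop("positive set contains non-canonical residues (first: sequence ",
         bad$index[1L], ", position ", bad$position[1L], ")")
  }
  negatives <- sample_negatives(positives, background, seed)
  peptides <- data.frame(
    id = c(if (!is.null(positives$id)) positives$id
           else paste0("pos", seq_len(nrow(positives))), negatives$id),
    sequence = c(positives$sequence, negatives$sequence),
    stringsAsFactors = FALSE)
  labeled_dataset(
    peptides,
    labels = rep(c(1L, 0L), c(nrow(positives), nrow(negatives))),
    name = name,
    provenance = list(source = "build_dataset", seed = seed,
                      n_pos = nrow(positives),
                      pool = paste0(nrow(background), " background proteins")))
}

#' Amino-acid composition profile of a dataset subset
#'
#' Fraction of each of the 20 residues among all residues of the selected
#' subset, i.e. the frequency distribution used to compare the
#' compositional signature of positive and negative peptides (typical
#' ACE-inhibitory sets are enriched in Pro and Leu and depleted in Cys,
#' Met and Trp).
#'
#' @param dataset a `labeled_dataset`.
#' @param which `"all"`, `"positive"` or `"negative"`.
#' @return list with `frequencies` (named 20-vector summing to 1),
#'   `n_peptides` and `n_residues`.
#' @export
composition_profile <- function(dataset,
                                which = c("all", "positive", "negative")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  which <- match.arg(which)
  sel <- switch(which, all = rep(TRUE, length(dataset$labels)),
                positive = dataset$labels == 1L,
                negative = dataset$labels == 0L)
  seqs <- dataset$peptides$sequence[sel]
  if (length(seqs) == 0L) stop("selected subset '", which, "' is empty")
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- tabulate(match(chars, AA_ALPHABET), nbins = 20L)
  freq <- counts / sum(counts)
  names(freq) <- AA_ALPHABET
  list(frequencies = freq, n_peptides = length(seqs),
       n_residues = sum(counts))
}

#' Configuration for the synthetic benchmark generator
#'
#' Defines the residue and length laws of a synthetic balanced dataset
#' emulating the compositional signature of ACE-inhibitory peptides.
#' Defaults: positives draw residues from a law with Pro and Leu boosted
#' to 0.12 each, Cys, Met and Trp reduced to 0.01 each and the remaining
#' mass spread uniformly over the other 15 residues; negatives draw from
#' the uniform law (0.05 per residue); lengths 2-15 with most mass on 3-8
#' residues, matching the short lengths typical of ACE-inhibitory
#' peptides.
#'
#' @param n_pos number of positive peptides (negatives are matched 1:1).
#' @param length_law named numeric vector of probabilities over lengths
#'   (names are the lengths); must sum to 1.
#' @param enrich named numeric vector of positive-law probability
#'   overrides (residue -> probability); remaining mass is spread
#'   uniformly over the residues not named.
#' @param background named numeric 20-vector of negative-law residue
#'   probabilities, summing to 1.
#' @param seed integer RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_pos = 400L,
                         length_law = NULL,
                         enrich = c(P = 0.12, L = 0.12,
                                    C = 0.01, M = 0.01, W = 0.01),
                         background = NULL,
                         seed = 1L) {
  if (is.null(length_law)) {
    length_law <- c(`2` = 0.06, `3` = 0.13, `4` = 0.15, `5` = 0.15,
                    `6` = 0.13, `7` = 0.11, `8` = 0.09, `9` = 0.06,
                    `10` = 0.04, `11` = 0.03, `12` = 0.02, `13` = 0.01,
                    `14` = 0.01, `15` = 0.01)
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(0.05, 20L), AA_ALPHABET)
  }
  if (abs(sum(length_law) - 1) > 1e-9 || any(length_law < 0)) {
    stop("length_law must be a probability vector over lengths")
  }
  if (!setequal(names(background), AA_ALPHABET) ||
      abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    stop("background must be a probability vector over the 20 residues")
  }
  if (!all(names(enrich) %in% AA_ALPHABET) || any(enrich < 0) ||
      sum(enrich) > 1) {
    stop("enrich overrides must name canonical residues, be nonnegative, ",
         "and sum to at most 1")
  }
  pos_law <- stats::setNames(rep(NA_real_, 20L), AA_ALPHABET)
  pos_law[names(enrich)] <- enrich
  rest <- setdiff(AA_ALPHABET, names(enrich))
  if (length(rest) > 0L) pos_law[rest] <- (1 - sum(enrich)) / length(rest)
  if (any(pos_law < 0) || abs(sum(pos_law) - 1) > 1e-9) {
    stop("enrichment produces an invalid positive residue law")
  }
  structure(list(n_pos = as.integer(n_pos), length_law = length_law,
                 positive_law = pos_law, background = background[AA_ALPHABET],
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic balanced benchmark dataset
#'
#' Draws `n_pos` positive peptides residue-wise from the enriched positive
#' law and `n_pos` negatives from the background law, with lengths drawn
#' from the shared length law.  Duplicates within a class and overlaps
#' between classes are removed by rejection, so the dataset satisfies the
#' same disjointness contract as [build_dataset()].  Deterministic for a
#' given config (the seed lives in the config).
#'
#' @param config a [synth_config()].
#' @return a `labeled_dataset`.
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  lens <- as.integer(names(config$length_law))
  draw_peptide <- function(law) {
    L <- sample(lens, 1L, prob = config$length_law)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = law), collapse = "")
  }
  draw_class <- function(law, n, forbidden) {
    out <- character(0)
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 200L * n) stop("synthetic rejection sampling stalled")
      s <- draw_peptide(law)
      if (s %in% out || s %in% forbidden) next
      out <- c(out, s)
    }
    out
  }
  with_local_seed(config$seed, {
    pos <- draw_class(config$positive_law, config$n_pos, character(0))
    neg <- draw_class(config$background, config$n_pos, pos)
    peptides <- data.frame(
      id = c(paste0("synthpos", seq_along(pos)),
             paste0("synthneg", seq_along(neg))),
      sequence = c(pos, neg), stringsAsFactors = FALSE)
    labeled_dataset(peptides,
                    labels = rep(c(1L, 0L), each = config$n_pos),
                    name = sprintf("synthetic_n%d_seed%d", config$n_pos,
                                   config$seed),
                    provenance = list(source = "generate_synthetic",
                                      seed = config$seed,
                                      n_pos = config$n_pos))
  })
}

#' Write / read a labelled dataset as TSV
#'
#' Serializes a dataset as a 3-column TSV (`id`, `sequence`, `label` with
#' 1 = positive, 0 = negative) plus a sidecar JSON provenance file at
#' `<path>.json`.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- data.frame(id = dataset$peptides$id,
                    sequence = dataset$peptides$sequence,
                    label = dataset$labels, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(name = dataset$name), dataset$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param name dataset name for the loaded object; defaults to the name
#'   recorded in the sidecar JSON when present.
#' @export
read_dataset <- function(path, name = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer"))
  stopifnot(all(c("id", "sequence", "label") %in% names(tab)))
  prov <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  labeled_dataset(tab[, c("id", "sequence")], tab$label,
                  name = name %||% prov$name %||% basename(path),
                  provenance = prov,
                  allow_unbalanced = TRUE)
}
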