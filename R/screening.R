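#' Digest a protein into k-mer peptides
#'
#' Exhaustive sliding-window extraction of every contiguous substring of
#' length `k_min` to `k_max` (default 2 to 9, the usual length range of
#' ACE-inhibitory peptides).  A protein of length `L >= k_max` yields
#' `sum(L - k + 1)` windows, i.e. `8L - 36` for the default k range.
#' Positions are 1-based inclusive, following UniProt convention.
#'
#' @param protein a single protein: one-row data frame (or list) with
#'   `accession` and `sequence` elements, as returned by [read_fasta()].
#' @param k_min,k_max inclusive k-mer length range.
#' @param dedupe collapse identical sequences to their first occurrence
#'   (in k-then-start order); the number removed is recorded in the
#'   `n_duplicates` attribute.
#' @return data frame with columns `sequence`, `accession`, `start`, `k`,
#'   ordered by `k` then `start`.
#' @export
kmer_cut <- function(protein, k_min = 2L, k_max = 9L, dedupe = TRUE) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    protein <- as.list(protein)
  }
  stopifnot(!is.null(protein$sequence), !is.null(protein$accession))
  seq <- protein$sequence
  L <- nchar(seq)
  empty <- data.frame(sequence = character(), accession = character(),
                      start = integer(), k = integer(),
                      stringsAsFactors = FALSE)
  if (L < k_min) {
    warning("protein ", protein$accession, " of length ", L,
            " is shorter than k_min = ", k_min, "; no k-mers emitted")
    attr(empty, "n_duplicates") <- 0L
    return(empty)
  }
  out <- lapply(seq.int(k_min, min(k_max, L)), function(k) {
    starts <- seq_len(L - k + 1L)
    data.frame(sequence = substring(seq, starts, starts + k - 1L),
               accession = protein$accession, start = starts, k = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  n_dup <- 0L
  if (dedupe) {
    dup <- duplicated(out$sequence)
    n_dup <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Assign screening bins from repeat probabilities
#'
#' Bins each k-mer from its per-repeat probabilities:
#' \itemize{
#'   \item `candidate`: every repeat probability strictly exceeds the
#'     candidate threshold (default 0.99);
#'   \item `zero_control`: every probability rounds to 0.00 at two
#'     decimals (<= 0.005);
#'   \item `mid_control`: every probability rounds to 0.50 at two
#'     decimals (within 0.50 +/- 0.005);
#'   \item `other`: anything else.
#' }
#' The two control bins reproduce the convention of reporting screening
#' probabilities at two decimals, where 0.00 and 0.50 groups serve as
#' negative controls for the high-probability candidates.
#'
#' @param probabilities numeric matrix, one row per k-mer and one column
#'   per repeat.
#' @param candidate_threshold candidate rule threshold (strict).
#' @param control_tol half-width of the control bins.
#' @return character vector of bin labels.
#' @export
screening_bin <- function(probabilities, candidate_threshold = 0.99,
                          control_tol = 0.005) {
  probabilities <- as.matrix(probabilities)
  apply(probabilities, 1L, function(p) {
    if (all(p > candidate_threshold)) "candidate"
    else if (all(p <= control_tol)) "zero_control"
    else if (all(abs(p - 0.5) <= control_tol)) "mid_control"
    else "other"
  })
}

#' Screen proteins for candidate ACE-inhibitory peptides
#'
#' Digests the proteins into k-mers, then runs `n_repeats` independent
#' train/score cycles: in each repeat the classifier is fitted afresh on
#' the full training dataset with its own seed and scores every k-mer.  A
#' k-mer is flagged as a candidate inhibitor only when its predicted
#' probability strictly exceeds `candidate_threshold` in every repeat —
#' the triple-repeat rule guards against single-fit artefacts of the
#' stochastic training families.  Records are returned candidates-first,
#' by mean probability descending.
#'
#' @param proteins data frame of proteins (as from [read_fasta()]).
#' @param train_dataset a `labeled_dataset` used to train the model.
#' @param config a [model_config()].
#' @param n_repeats number of independent train/score repeats.
#' @param candidate_threshold strict per-repeat probability threshold.
#' @param seed master seed; repeat seeds are `seed + 1..n_repeats`.
#' @param k_min,k_max,dedupe k-mer digestion settings (see [kmer_cut()]).
#' @param table,params PseAAC encoding settings.
#' @return data frame of class `screening_result` with columns `sequence`,
#'   `accession`, `start`, `k`, one `prob_rep<r>` column per repeat,
#'   `mean_prob`, `candidate`, `bin`.
#' @export
screen_proteins <- function(proteins, train_dataset, config,
                            n_repeats = 3L, candidate_threshold = 0.99,
                            seed = 1L, k_min = 2L, k_max = 9L,
                            dedupe = TRUE, table = load_property_table(),
                            params = pseaac_params()) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            inherits(train_dataset, "labeled_dataset"), n_repeats >= 1L)
  kmers <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    kmer_cut(proteins[i, , drop = FALSE], k_min = k_min, k_max = k_max,
             dedupe = dedupe)
  }))
  if (dedupe) {
    kmers <- kmers[!duplicated(kmers$sequence), , drop = FALSE]
  }
  if (is.null(kmers) || nrow(kmers) == 0L) stop("no k-mers to screen")
  encodable <- nchar(kmers$sequence) >= params$lambda + 1L
  if (any(!encodable)) {
    message(sum(!encodable), " k-mer(s) too short to encode; skipped")
    kmers <- kmers[encodable, , drop = FALSE]
  }
  if (nrow(kmers) == 0L) stop("no encodable k-mers to screen")
  kmer_feats <- pseaac_encode_batch(
    data.frame(id = paste0(kmers$accession, "_", kmers$start, "_", kmers$k),
               sequence = kmers$sequence, stringsAsFactors = FALSE),
    table = table, params = params)
  keep_train <- nchar(train_dataset$peptides$sequence) >= params$lambda + 1L
  train_x <- pseaac_encode_batch(
    train_dataset$peptides[keep_train, , drop = FALSE],
    table = table, params = params)
  train_y <- train_dataset$labels[keep_train]
  probs <- matrix(NA_real_, nrow(kmers), n_repeats)
  for (r in seq_len(n_repeats)) {
    model <- fit_model(config, train_x, train_y, seed = seed + r)
    probs[, r] <- predict_proba(model, kmer_feats)
  }
  colnames(probs) <- paste0("prob_rep", seq_len(n_repeats))
  out <- cbind(kmers, as.data.frame(probs))
  out$mean_prob <- rowMeans(probs)
  out$candidate <- apply(probs, 1L, function(p) all(p > candidate_threshold))
  out$bin <- screening_bin(probs, candidate_threshold)
  out <- out[order(-out$candidate, -out$mean_prob), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_result", class(out))
  out
}

#' Tabulate and export screening results
#'
#' Truncates a screening result to its top `top_n` records (candidates
#' first, by mean probability) and optionally writes a TSV whose header
#' comment lines carry the per-bin counts.
#'
#' @param records a `screening_result` from [screen_proteins()].
#' @param top_n number of records to keep (default: all).
#' @param path optional output TSV path.
#' @return the truncated data frame (invisibly when `path` is given).
#' @export
screening_report <- function(records, top_n = Inf, path = NULL) {
  stopifnot(inherits(records, "screening_result"), nrow(records) > 0L)
  bins <- table(factor(records$bin,
                       levels = c("candidate", "mid_control",
                                  "zero_control", "other")))
  top <- utils::head(records, top_n)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %d", names(bins), as.integer(bins)), con)
    write.table(as.data.frame(top), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(top))
  }
  attr(top, "bin_counts") <- bins
  top
}
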