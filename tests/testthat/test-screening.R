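test_that("k-mer counts follow the closed form 8L - 36", {
  set.seed(17)
  for (L in c(9L, 10L, 50L, 142L, 224L, 300L)) {
    prot <- data.frame(accession = paste0("s", L), name = "",
                       sequence = rand_peptide(L), length = L)
    km <- kmer_cut(prot, dedupe = FALSE)
    expect_equal(nrow(km), 8L * L - 36L, label = paste("L =", L))
    km_d <- kmer_cut(prot, dedupe = TRUE)
    expect_lte(nrow(km_d), nrow(km))
    expect_equal(nrow(km_d) + attr(km_d, "n_duplicates"), nrow(km))
  }
})

test_that("a length-10 protein yields 44 windows ordered by k then start", {
  prot <- data.frame(accession = "p", name = "",
                     sequence = "ACDEFGHIKL", length = 10L)
  km <- kmer_cut(prot, dedupe = FALSE)
  expect_equal(nrow(km), 44L)  # 9+8+7+6+5+4+3+2
  expect_equal(km$k, rep(2:9, times = 9:2))
  expect_equal(km$start[km$k == 2], 1:9)
  expect_equal(km$sequence[1], "AC")
})

test_that("minimal and degenerate proteins are handled", {
  km <- kmer_cut(data.frame(accession = "ac", name = "", sequence = "AC",
                            length = 2L))
  expect_equal(km$sequence, "AC")
  expect_warning(
    empty <- kmer_cut(data.frame(accession = "x", name = "",
                                 sequence = "A", length = 1L)),
    "shorter than k_min")
  expect_equal(nrow(empty), 0L)
})

test_that("every k-mer re-extracts from its recorded coordinates", {
  proteins <- synthetic_milk_proteins()
  for (i in seq_len(nrow(proteins))) {
    km <- kmer_cut(proteins[i, ], dedupe = FALSE)
    expect_equal(km$sequence,
                 substring(proteins$sequence[i], km$start,
                           km$start + km$k - 1L),
                 label = proteins$accession[i])
  }
})

test_that("screening bins are pinned on constructed probability fixtures", {
  probs <- rbind(c(0.995, 0.999, 0.992),   # all  > 0.99  -> candidate
                 c(0.995, 0.989, 0.999),   # one <= 0.99  -> other
                 c(0.000, 0.004, 0.001),   # rounds to 0.00
                 c(0.496, 0.500, 0.504),   # rounds to 0.50
                 c(0.400, 0.500, 0.500),   # one repeat off -> other
                 c(0.990, 0.990, 0.990))   # exactly at threshold -> other
  expect_equal(screening_bin(probs),
               c("candidate", "other", "zero_control", "mid_control",
                 "other", "other"))
})

test_that("screening flags candidates only when every repeat exceeds 0.99", {
  train <- generate_synthetic(synth_config(n_pos = 60L, seed = 14L))
  prots <- rand_protein_df(2L, c(30L, 40L), prefix = "scr")
  res <- suppressMessages(
    screen_proteins(prots, train, model_config("knn"), n_repeats = 3L,
                    seed = 5L, k_max = 5L))
  expect_s3_class(res, "screening_result")
  expect_true(all(c("prob_rep1", "prob_rep2", "prob_rep3", "mean_prob",
                    "candidate", "bin") %in% names(res)))
  probs <- as.matrix(res[, c("prob_rep1", "prob_rep2", "prob_rep3")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(res$candidate,
               apply(probs, 1, function(p) all(p > 0.99)))
  expect_equal(res$bin == "candidate", res$candidate)
  # candidates first, then mean probability descending
  expect_true(all(diff(res$candidate) <= 0))
  expect_true(all(diff(res$mean_prob[!res$candidate]) <= 1e-12))
})

test_that("lowering the candidate threshold never removes a candidate", {
  train <- generate_synthetic(synth_config(n_pos = 60L, seed = 14L))
  prots <- rand_protein_df(1L, c(30L, 30L), prefix = "mono")
  strict <- screen_proteins(prots, train, model_config("knn"),
                            n_repeats = 2L, candidate_threshold = 0.99,
                            seed = 5L, k_max = 4L)
  loose <- screen_proteins(prots, train, model_config("knn"),
                           n_repeats = 2L, candidate_threshold = 0.6,
                           seed = 5L, k_max = 4L)
  expect_true(all(strict$sequence[strict$candidate] %in%
                    loose$sequence[loose$candidate]))
})

test_that("screening with one repeat of a deterministic model is idempotent", {
  train <- generate_synthetic(synth_config(n_pos = 40L, seed = 3L))
  prots <- rand_protein_df(1L, c(25L, 25L), prefix = "idem")
  r1 <- screen_proteins(prots, train, model_config("knn"), n_repeats = 1L,
                        seed = 2L, k_max = 4L)
  r2 <- screen_proteins(prots, train, model_config("knn"), n_repeats = 1L,
                        seed = 2L, k_max = 4L)
  expect_identical(r1, r2)
})

test_that("screening reports truncate, count bins and write TSV", {
  train <- generate_synthetic(synth_config(n_pos = 40L, seed = 3L))
  prots <- rand_protein_df(1L, c(25L, 25L), prefix = "rep")
  res <- screen_proteins(prots, train, model_config("knn"), n_repeats = 2L,
                         seed = 2L, k_max = 4L)
  top <- screening_report(res, top_n = 2L)
  expect_equal(nrow(top), 2L)
  expect_equal(sum(attr(top, "bin_counts")), nrow(res))
  expect_equal(unname(attr(top, "bin_counts")["candidate"]),
               sum(res$candidate))
  f <- withr::local_tempfile(fileext = ".tsv")
  screening_report(res, top_n = 3L, path = f)
  lines <- readLines(f)
  expect_true(any(grepl("^# candidate:", lines)))
  body <- read.delim(f, comment.char = "#")
  expect_equal(nrow(body), 3L)
})
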