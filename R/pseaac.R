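#' PseAAC encoding parameters
#'
#' Parameters of the type-II (amphiphilic) pseudo amino acid composition
#' encoding.  With `i` property scales and correlation depth `lambda`, a
#' peptide is represented by a `20 + i * lambda` dimensional vector; at
#' the defaults (six scales, `lambda = 1`) that is 26 dimensions.
#'
#' @param lambda sequence-order correlation depth (positive integer).
#'   `lambda = 1` considers adjacent-residue interactions only.  Peptides
#'   must be at least `lambda + 1` residues long to be encodable.
#' @param omega weight factor blending the sequence-order block into the
#'   composition block (positive real, default 0.05).
#' @return object of class `pseaac_params`.
#' @export
pseaac_params <- function(lambda = 1L, omega = 0.05) {
  lambda <- as.integer(lambda)
  if (length(lambda) != 1L || is.na(lambda) || lambda < 1L) {
    stop("lambda must be a positive integer")
  }
  if (length(omega) != 1L || !is.finite(omega) || omega <= 0) {
    stop("omega must be a positive real")
  }
  structure(list(lambda = lambda, omega = omega), class = "pseaac_params")
}

#' Sequence-order correlation factor
#'
#' Type-II correlation of one standardized property along a peptide at a
#' given lag:
#' \deqn{\tau = \frac{1}{L - g} \sum_{j=1}^{L-g} H(R_j)\, H(R_{j+g})}
#' i.e. the mean product of standardized property values of residues
#' separated by `lag` positions.  The product form (rather than a squared
#' difference) is what distinguishes the amphiphilic type-II encoding.
#'
#' @param sequence a single peptide sequence (character scalar).
#' @param property_row named numeric vector of standardized property
#'   values over the 20 residues.
#' @param lag positive integer separation; requires `nchar(sequence) > lag`.
#' @return the correlation factor (numeric scalar).
#' @export
correlation_factor <- function(sequence, property_row, lag = 1L) {
  stopifnot(length(sequence) == 1L)
  lag <- as.integer(lag)
  L <- nchar(sequence)
  if (L <= lag) {
    stop("peptide of length ", L, " is too short for lag ", lag,
         " (need length > lag)")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  h <- unname(property_row[chars])
  if (anyNA(h)) stop("sequence contains residues absent from the property row")
  mean(h[seq_len(L - lag)] * h[seq_len(L - lag) + lag])
}

#' Encode one peptide as a type-II PseAAC vector
#'
#' Combines the 20 residue frequencies \eqn{f_u} with the
#' \eqn{i \times \lambda} sequence-order correlation factors
#' \eqn{\tau_1, \ldots, \tau_{i\lambda}} (ordered lag-major,
#' property-minor) into one normalized vector:
#' \deqn{x_u = \frac{f_u}{1 + \omega \sum_j \tau_j}, \quad u = 1..20}
#' \deqn{x_{20+j} = \frac{\omega\, \tau_j}{1 + \omega \sum_j \tau_j}}
#' All entries sum to 1 by construction (the composition frequencies
#' themselves sum to 1 and the blending is a common normalization).
#'
#' @param sequence a single peptide sequence.
#' @param table a `property_table` from [load_property_table()].
#' @param params a `pseaac_params` object.
#' @return named numeric vector of length `20 + n_properties * lambda`
#'   (26 at the defaults): the 20 residue codes, then
#'   `tau_lag<g>_<property>` entries.
#' @export
pseaac_encode <- function(sequence, table = load_property_table(),
                          params = pseaac_params()) {
  stopifnot(inherits(table, "property_table"),
            inherits(params, "pseaac_params"))
  L <- nchar(sequence)
  if (L < params$lambda + 1L) {
    stop("peptide of length ", L, " is too short to encode at lambda = ",
         params$lambda, " (need length >= lambda + 1)")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    stop("sequence contains non-canonical residues")
  }
  f <- tabulate(match(chars, AA_ALPHABET), nbins = 20L) / L
  # correlation block: lag-major, property-minor
  taus <- numeric(0)
  for (g in seq_len(params$lambda)) {
    for (p in seq_along(table$names)) {
      taus <- c(taus, correlation_factor(sequence, table$standardized[p, ], g))
    }
  }
  denom <- 1 + params$omega * sum(taus)
  if (abs(denom) <= 1e-8) {
    stop("degenerate encoding: |1 + omega * sum(tau)| <= 1e-8")
  }
  out <- c(f / denom, params$omega * taus / denom)
  names(out) <- c(AA_ALPHABET,
                  paste0("tau_lag",
                         rep(seq_len(params$lambda),
                             each = length(table$names)),
                         "_", rep(table$names, params$lambda)))
  out
}

#' Encode a batch of peptides into a feature matrix
#'
#' Applies [pseaac_encode()] to every peptide, preserving input order.
#' Peptides too short to encode at the requested `lambda` are omitted from
#' the matrix and reported in the `skipped` attribute (and via a message),
#' matching the convention that peptides shorter than `lambda + 1`
#' residues are excluded from training and screening.
#'
#' @param peptides data frame with columns `id` and `sequence` (as from
#'   [read_peptide_list()]), or a character vector of sequences.
#' @param table a `property_table`.
#' @param params a `pseaac_params`.
#' @return numeric matrix (n_encodable x dimension) with peptide ids as
#'   row names and attribute `skipped` (character vector of skipped ids).
#' @export
pseaac_encode_batch <- function(peptides, table = load_property_table(),
                                params = pseaac_params()) {
  if (is.character(peptides)) {
    peptides <- data.frame(id = peptides, sequence = peptides,
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  if (nrow(peptides) == 0L) stop("no peptides to encode")
  ok <- nchar(peptides$sequence) >= params$lambda + 1L
  if (!any(ok)) stop("no peptide is long enough to encode at lambda = ",
                     params$lambda)
  if (any(!ok)) {
    message(sum(!ok), " peptide(s) shorter than lambda + 1 skipped")
  }
  rows <- lapply(peptides$sequence[ok], pseaac_encode, table = table,
                 params = params)
  mat <- do.call(rbind, rows)
  rownames(mat) <- make.unique(peptides$id[ok])
  attr(mat, "skipped") <- peptides$id[!ok]
  mat
}
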