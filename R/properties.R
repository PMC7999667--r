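#' Standardize a residue property matrix
#'
#' Converts raw physicochemical property values into the zero-mean,
#' unit-variance form required by the pseudo amino acid composition
#' correlation factors:
#' \deqn{H(R) = (H_0(R) - \bar{H_0}) / \sigma_{20}(H_0)}
#' where the mean and standard deviation are taken over the 20 canonical
#' residues and \eqn{\sigma_{20}} is the population (divide-by-n) standard
#' deviation, the convention of classical PseAAC.  Using the sample SD
#' instead would rescale every downstream feature, so the choice is pinned
#' here.
#'
#' @param raw numeric matrix, properties in rows and the 20 residues in
#'   columns (column names must be the canonical one-letter codes).
#' @param provenance optional character vector, one citation per row.
#' @return an object of class `property_table`: a list with elements
#'   `names` (property labels), `raw`, `standardized` (both p x 20
#'   matrices) and `provenance`.
#' @export
standardize_properties <- function(raw, provenance = NULL) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw)) || !setequal(colnames(raw), AA_ALPHABET)) {
    stop("property matrix must have the 20 canonical residues as columns")
  }
  raw <- raw[, AA_ALPHABET, drop = FALSE]
  if (is.null(rownames(raw))) {
    rownames(raw) <- paste0("property", seq_len(nrow(raw)))
  }
  mu <- rowMeans(raw)
  sigma <- sqrt(rowMeans((raw - mu)^2))  # population SD over 20 residues
  if (any(sigma == 0)) {
    stop("zero-variance property row(s): ",
         paste(rownames(raw)[sigma == 0], collapse = ", "))
  }
  std <- (raw - mu) / sigma
  out <- list(names = rownames(raw), raw = raw, standardized = std,
              provenance = provenance %||% rep(NA_character_, nrow(raw)))
  class(out) <- "property_table"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a residue property table
#'
#' Loads a TSV of physicochemical property scales (rows = properties,
#' columns = residues in alphabetical one-letter order, with a `property`
#' label column and an optional trailing `source` citation column) and
#' standardizes it with [standardize_properties()].  The default asset
#' shipped with the package provides the six scales used for peptide
#' encoding: hydrophobicity, hydrophilicity, side-chain mass, pK1
#' (alpha-carboxyl), pK2 (alpha-amino) and pI at 25 degrees C, each
#' annotated with its literature source so alternative scales can be
#' swapped in by pointing `path` at a user file of the same layout.
#'
#' @param path path to a property TSV; defaults to the shipped asset.
#' @return a `property_table` object.
#' @export
load_property_table <- function(path = system.file("extdata", "aa_properties.tsv",
                                                   package = "aceipred")) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"property" %in% names(tab)) stop("missing 'property' column in ", path)
  prov <- if ("source" %in% names(tab)) tab$source else NULL
  raw <- as.matrix(tab[, AA_ALPHABET, drop = FALSE])
  rownames(raw) <- tab$property
  standardize_properties(raw, provenance = prov)
}

#' @export
print.property_table <- function(x, ...) {
  cat("Residue property table:", length(x$names), "properties x 20 residues\n")
  for (i in seq_along(x$names)) {
    cat(sprintf("  %-16s %s\n", x$names[i],
                ifelse(is.na(x$provenance[i]), "", x$provenance[i])))
  }
  invisible(x)
}
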