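#' The twenty canonical amino acids
#'
#' One-letter codes of the 20 canonical amino acids in alphabetical order.
#' All sequences handled by the package are validated against this
#' alphabet; ambiguity codes (B, J, O, U, X, Z) and gap characters are not
#' part of it.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate peptide/protein sequences against the canonical alphabet
#'
#' @param sequences character vector of (already uppercased) sequences.
#' @return `NULL` when everything validates; otherwise a data frame with
#'   one row per offending sequence: `index`, `position` (first offending
#'   residue) and `residue`.
#' @keywords internal
invalid_residues <- function(sequences) {
  bad <- lapply(seq_along(sequences), function(i) {
    chars <- strsplit(sequences[[i]], "", fixed = TRUE)[[1]]
    pos <- which(!chars %in% AA_ALPHABET)
    if (length(pos) == 0L) return(NULL)
    data.frame(index = i, position = pos[1L], residue = chars[pos[1L]],
               stringsAsFactors = FALSE)
  })
  bad <- do.call(rbind, bad)
  if (is.null(bad) || nrow(bad) == 0L) NULL else bad
}

#' Read protein records from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record amino-acid FASTA file.
#' The header token before the first whitespace becomes the accession, the
#' remainder of the header the name.  Sequences are uppercased; records
#' keep file order.
#'
#' @param path path to a FASTA file.
#' @param invalid how to treat records containing residues outside the
#'   20-letter canonical alphabet: `"reject"` (default) stops with an
#'   error naming the record and position; `"drop"` removes the record
#'   with a warning.
#' @return a data frame with columns `accession`, `name`, `sequence`,
#'   `length`.
#' @seealso [write_fasta()], [read_peptide_list()]
#' @export
read_fasta <- function(path, invalid = c("reject", "drop")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(accession = character(), name = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  name <- trimws(sub("^\\S+\\s*", "", headers))
  sequence <- toupper(as.character(set))
  recs <- data.frame(accession = accession, name = name,
                     sequence = sequence, length = nchar(sequence),
                     stringsAsFactors = FALSE)
  rownames(recs) <- NULL
  bad <- invalid_residues(recs$sequence)
  if (!is.null(bad)) {
    what <- sprintf("record '%s': invalid residue '%s' at position %d",
                    recs$accession[bad$index], bad$residue, bad$position)
    if (invalid == "reject") {
      stop("non-canonical residues in ", path, ": ",
           paste(what, collapse = "; "), call. = FALSE)
    }
    warning("dropping ", nrow(bad), " record(s) with non-canonical ",
            "residues: ", paste(what, collapse = "; "), call. = FALSE)
    recs <- recs[-bad$index, , drop = FALSE]
    rownames(recs) <- NULL
  }
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records data frame with columns `accession`, `sequence` and
#'   optionally `name`, as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("accession", "sequence") %in% names(records)))
  seqs <- Biostrings::BStringSet(records$sequence)
  hdr <- records$accession
  if (!is.null(records$name)) {
    hdr <- ifelse(nzchar(records$name), paste(hdr, records$name), hdr)
  }
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a peptide list
#'
#' Reads positive-training peptides from either a one-sequence-per-line
#' text file or a two-column `id TAB sequence` TSV.  The dialect is
#' auto-detected from the presence of a tab character on the first
#' non-empty line and applies to the whole file.  Duplicate sequences are
#' collapsed to their first occurrence; the number removed is reported via
#' `message()` and attached as attribute `n_duplicates`.
#'
#' @param path path to the peptide list.
#' @param invalid `"reject"` (default) errors on non-canonical residues,
#'   naming the line; `"drop"` skips the offending lines with a warning.
#' @return data frame with columns `id`, `sequence`, `length` and
#'   attribute `n_duplicates`.
#' @export
read_peptide_list <- function(path, invalid = c("reject", "drop")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("peptide list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE)
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  tsv <- grepl("\t", lines[1L], fixed = TRUE)
  if (tsv) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2L)
    if (length(short) > 0L) {
      stop("line ", lineno[short[1L]],
           ": expected two tab-separated columns (id, sequence)",
           call. = FALSE)
    }
    id <- trimws(vapply(parts, `[[`, "", 1L))
    sequence <- toupper(trimws(vapply(parts, `[[`, "", 2L)))
  } else {
    sequence <- toupper(trimws(lines))
    id <- paste0("pep", seq_along(sequence))
  }
  bad <- invalid_residues(sequence)
  if (!is.null(bad)) {
    what <- sprintf("line %d: invalid residue '%s' at position %d",
                    lineno[bad$index], bad$residue, bad$position)
    if (invalid == "reject") {
      stop("non-canonical residues in ", path, ": ",
           paste(what, collapse = "; "), call. = FALSE)
    }
    warning("dropping ", nrow(bad), " line(s): ",
            paste(what, collapse = "; "), call. = FALSE)
    drop <- bad$index
    sequence <- sequence[-drop]; id <- id[-drop]
  }
  dup <- duplicated(sequence)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    message(n_dup, " duplicate sequence(s) removed from ", path)
  }
  out <- data.frame(id = id[!dup], sequence = sequence[!dup],
                    length = nchar(sequence[!dup]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- n_dup
  out
}
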