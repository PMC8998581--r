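#' Protein sets: construction, FASTA I/O and record-level filters
#'
#' A proteome set is a plain data frame (class `proteome_set`) with one row
#' per protein and columns `id`, `sequence`, `description`, `source`.
#' Sequences are uppercase strings over the 20 standard one-letter residue
#' codes (plus X for masked ambiguity). Ids are unique within a set.
#'
#' @name proteome
NULL

#' Build a proteome set
#'
#' @param id character vector of unique record identifiers
#' @param sequence character vector of residue strings (uppercased here)
#' @param description optional free-text descriptions
#' @param source `"real"` or `"synthetic"`
#' @param provenance free-text provenance note stored as an attribute
#' @param allow_ambiguous map the non-standard codes B, Z, U, O to X
#'   instead of rejecting them. X contributes nothing to scored quantities
#'   downstream and is excluded from composition denominators.
#' @return data frame of class `proteome_set`
#' @export
proteome_set <- function(id, sequence, description = "", source = "real",
                         provenance = "", allow_ambiguous = FALSE) {
  if (length(id) != length(sequence))
    stop("id and sequence lengths differ")
  if (anyDuplicated(id))
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  source <- match.arg(source, c("real", "synthetic"))
  sequence <- toupper(sequence)
  sequence <- sub("\\*+$", "", sequence)
  if (allow_ambiguous) sequence <- chartr("BZUO", "XXXX", sequence)
  for (i in seq_along(sequence)) {
    r <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    if (length(r) == 0) stop("record '", id[i], "': empty sequence")
    bad <- which(!(r %in% aa_alphabet(with_x = TRUE)))
    if (length(bad) > 0)
      stop("record '", id[i], "': illegal residue '", r[bad[1]],
           "' at position ", bad[1])
  }
  out <- data.frame(id = as.character(id), sequence = sequence,
                    description = rep_len(as.character(description), length(id)),
                    source = rep_len(source, length(id)),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("proteome_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]. Sequences are
#' uppercased, trailing stop characters (`*`) stripped, and residues
#' validated; entry order is preserved. The FASTA id is the first
#' whitespace-delimited token of the header, the remainder the description.
#'
#' @param path FASTA file
#' @inheritParams proteome_set
#' @return a `proteome_set`
#' @export
read_fasta <- function(path, source = "real", allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("no FASTA records in ", path)
  headers <- names(aas)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  proteome_set(id = id, sequence = as.character(aas), description = desc,
               source = source, provenance = paste0("read_fasta:", path),
               allow_ambiguous = allow_ambiguous)
}

#' Write a proteome set to FASTA
#'
#' Standard FASTA with 60-column sequence wrapping; output is byte-stable
#' for identical input.
#'
#' @param set a `proteome_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "proteome_set"))
  if (nrow(set) == 0) stop("refusing to write an empty proteome set")
  aas <- Biostrings::AAStringSet(set$sequence)
  names(aas) <- ifelse(nzchar(set$description),
                       paste(set$id, set$description), set$id)
  Biostrings::writeXStringSet(aas, filepath = path, width = 60L)
  invisible(path)
}

#' Drop proteins shorter than a minimum length
#'
#' Length is counted on the residue alphabet after stop-stripping. The
#' published pipeline removes proteins of fewer than 100 amino acids
#' (359 domain-bearing candidates reduce to a final set of 318).
#'
#' @param set a `proteome_set`
#' @param min_length minimum residue count retained (default 100)
#' @param quiet suppress the removed-count message
#' @return filtered `proteome_set`
#' @export
filter_by_length <- function(set, min_length = 100, quiet = FALSE) {
  stopifnot(inherits(set, "proteome_set"), min_length >= 1)
  keep <- nchar(set$sequence) >= min_length
  if (!quiet)
    message("filter_by_length: removed ", sum(!keep), " of ", length(keep),
            " records (< ", min_length, " aa)")
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(set, "provenance")
  class(out) <- c("proteome_set", "data.frame")
  out
}
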