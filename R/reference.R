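# Trigger reference: the set of named trigger-region sequences in a pooled
# memory-strain library, including the designated positive normalization
# strain (PNS) that is constitutively memory-on and spiked into every sample.

#' Construct a trigger reference
#'
#' A trigger reference holds one nucleotide sequence per library strain
#' (the trigger promoter + RBS region that is PCR-amplified and sequenced)
#' and designates exactly one record as the positive normalization strain
#' (PNS), the constitutively memory-on spike-in against which all odds
#' ratios are normalized.
#'
#' @param ids Character vector of unique trigger identifiers.
#' @param sequences Character vector of nucleotide sequences (alphabet
#'   A, C, G, T, N), same length as `ids`. Sequences must be pairwise
#'   distinct: duplicated sequences make unique read assignment impossible.
#' @param pns_id Identifier of the positive normalization strain; must be
#'   one of `ids`.
#'
#' @return An object of class `trigger_reference`: a list with elements
#'   `ids`, `sequences` (named by id) and `pns_id`.
#' @export
trigger_reference <- function(ids, sequences, pns_id) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) == 0L)
    stop("reference is empty: at least one trigger record is required")
  if (length(ids) != length(sequences))
    stop("'ids' and 'sequences' must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate trigger ids in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("empty sequence for trigger(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence alphabet must be {A,C,G,T,N}; offending trigger(s): ",
         paste(ids[bad], collapse = ", "))
  if (anyDuplicated(sequences))
    stop("byte-identical sequences shared by multiple triggers: reads from ",
         "these records can never be assigned uniquely")
  if (length(pns_id) != 1L || !pns_id %in% ids)
    stop("pns_id '", pns_id, "' does not name a record in the reference")
  names(sequences) <- ids
  structure(list(ids = ids, sequences = sequences, pns_id = pns_id),
            class = "trigger_reference")
}

#' Load a trigger reference from a FASTA file
#'
#' Record names are taken from the FASTA header up to the first whitespace.
#'
#' @param path Path to a FASTA file with one record per trigger strain.
#' @param pns_id Identifier of the positive normalization strain record.
#'
#' @return A [trigger_reference()] object.
#' @export
load_trigger_reference <- function(path, pns_id) {
  if (!file.exists(path))
    stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("reference FASTA is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  trigger_reference(ids, as.character(seqs), pns_id)
}

#' Write a trigger reference to FASTA
#'
#' @param reference A [trigger_reference()] object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_trigger_reference <- function(reference, path) {
  stopifnot(inherits(reference, "trigger_reference"))
  dna <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @export
print.trigger_reference <- function(x, ...) {
  cat("trigger_reference:", length(x$ids), "records; PNS =", x$pns_id, "\n")
  invisible(x)
}

# reverse complement of plain character sequences (N-aware)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
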