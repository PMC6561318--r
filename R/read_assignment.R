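# Unique assignment of amplicon-like reads to trigger references.
#
# A read is assigned to the single trigger whose sequence (either strand)
# contains the read's longest exact substring of length >= min_match_len.
# Ties between triggers at the best match length are AMBIGUOUS; reads with
# no qualifying match are UNMAPPED. Only uniquely assigned reads enter any
# downstream statistic.

#' Assign one read to a trigger
#'
#' Scans substrings of the read from longest (the whole read) down to
#' `min_match_len` and reports the unique trigger containing the best one
#' on either strand. Substrings containing N are not usable as seeds, so a
#' read with an N can only be assigned through flanking N-free stretches.
#'
#' @param read_sequence A single nucleotide string.
#' @param reference A [trigger_reference()] object.
#' @param min_match_len Minimum exact-match length required for assignment
#'   (default 30).
#'
#' @return A single string: a trigger id, `"AMBIGUOUS"` (two or more
#'   triggers tie for the best match) or `"UNMAPPED"` (no match of length
#'   `>= min_match_len` in any trigger).
#' @export
assign_read <- function(read_sequence, reference, min_match_len = 30L) {
  stopifnot(inherits(reference, "trigger_reference"))
  read_sequence <- toupper(read_sequence)
  n <- nchar(read_sequence)
  if (is.na(read_sequence) || n == 0L)
    stop("empty read sequence")
  if (n < min_match_len)
    return("UNMAPPED")
  seqs <- reference$sequences
  ids <- reference$ids
  # longest-first sweep: the first length with any hit is the maximal match
  for (len in seq.int(n, min_match_len)) {
    hits <- character(0)
    for (start in seq_len(n - len + 1L)) {
      sub <- substr(read_sequence, start, start + len - 1L)
      if (grepl("N", sub, fixed = TRUE)) next
      hit <- grepl(sub, seqs, fixed = TRUE) |
        grepl(revcomp(sub), seqs, fixed = TRUE)
      if (any(hit)) hits <- union(hits, ids[hit])
      if (length(hits) > 1L) return("AMBIGUOUS")
    }
    if (length(hits) == 1L) return(hits)
  }
  "UNMAPPED"
}

# minimal 4-line FASTQ reader; quality is ignored by design, but structure
# is validated so a truncated file fails with the offending record index
read_fastq_sequences <- function(path) {
  if (!file.exists(path))
    stop("FASTQ not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(character(0))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete in ", path)
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- !startsWith(lines[idx], "@")
  if (any(bad_hdr))
    stop("malformed FASTQ record ", which(bad_hdr)[1L],
         ": header does not start with '@'")
  bad_sep <- !startsWith(lines[idx + 2L], "+")
  if (any(bad_sep))
    stop("malformed FASTQ record ", which(bad_sep)[1L],
         ": separator line does not start with '+'")
  toupper(lines[idx + 1L])
}

#' Count reads per trigger from a FASTQ file
#'
#' Assigns every read with [assign_read()] and tallies per-trigger counts;
#' ambiguous and unmapped reads are recorded but excluded from the counts
#' (and from every downstream statistic). Assignment is deterministic, so
#' read order never changes the result.
#'
#' @param fastq_path Path to a FASTQ file (4-line records; qualities are
#'   ignored).
#' @param reference A [trigger_reference()] object.
#' @param min_match_len Minimum exact-match length, see [assign_read()].
#' @param sample_id Identifier stored in the returned count vector
#'   (defaults to the file name).
#'
#' @return A `count_vector` object, see [count_vector()].
#' @export
count_reads <- function(fastq_path, reference, min_match_len = 30L,
                        sample_id = basename(fastq_path)) {
  stopifnot(inherits(reference, "trigger_reference"))
  reads <- read_fastq_sequences(fastq_path)
  counts <- stats::setNames(integer(length(reference$ids)), reference$ids)
  n_ambiguous <- 0L
  n_unmapped <- 0L
  if (length(reads)) {
    # assign each distinct read once; identical reads share the call
    tab <- table(reads)
    calls <- vapply(names(tab), assign_read, character(1),
                    reference = reference, min_match_len = min_match_len)
    for (i in seq_along(tab)) {
      k <- as.integer(tab[[i]])
      if (calls[[i]] == "AMBIGUOUS") n_ambiguous <- n_ambiguous + k
      else if (calls[[i]] == "UNMAPPED") n_unmapped <- n_unmapped + k
      else counts[[calls[[i]]]] <- counts[[calls[[i]]]] + k
    }
  }
  count_vector(sample_id, counts, n_ambiguous = n_ambiguous,
               n_unmapped = n_unmapped)
}

#' Construct a per-sample count vector
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative integer vector of uniquely assigned
#'   reads per trigger id.
#' @param n_ambiguous Number of reads tied between two or more triggers.
#' @param n_unmapped Number of reads with no qualifying match.
#'
#' @return An object of class `count_vector` with elements `sample_id`,
#'   `counts`, `total_assigned`, `n_ambiguous`, `n_unmapped`.
#' @export
count_vector <- function(sample_id, counts, n_ambiguous = 0L,
                         n_unmapped = 0L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a fully named vector (names are trigger ids)")
  counts <- round(counts)
  if (any(counts < 0))
    stop("negative count in sample '", sample_id, "'")
  storage.mode(counts) <- "integer"
  structure(list(sample_id = as.character(sample_id), counts = counts,
                 total_assigned = sum(counts),
                 n_ambiguous = as.integer(n_ambiguous),
                 n_unmapped = as.integer(n_unmapped)),
            class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat("count_vector '", x$sample_id, "': ", length(x$counts), " triggers, ",
      x$total_assigned, " assigned (", x$n_ambiguous, " ambiguous, ",
      x$n_unmapped, " unmapped)\n", sep = "")
  invisible(x)
}
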