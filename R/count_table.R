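# Sample-pair containers and the long-format count table that is the
# pipeline's canonical interchange format. Each fecal/culture sample yields
# two sequenced halves: an untreated culture and a spectinomycin-selected
# culture; the pair is the unit on which odds ratios are computed.

#' Construct a sample pair
#'
#' @param pair_id Unique identifier of the untreated/selected culture pair
#'   (one fecal or in vitro sample).
#' @param mouse_id Mouse (or replicate) identifier.
#' @param group `"control"` or `"treated"`.
#' @param timepoint Numeric time in days; 0 is the gavage baseline.
#' @param untreated,selected [count_vector()] objects for the two culture
#'   halves. Both must cover the same trigger ids.
#'
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(pair_id, mouse_id, group, timepoint,
                        untreated, selected) {
  stopifnot(inherits(untreated, "count_vector"),
            inherits(selected, "count_vector"))
  group <- match.arg(group, c("control", "treated"))
  if (!setequal(names(untreated$counts), names(selected$counts)))
    stop("pair '", pair_id, "': untreated and selected halves do not share ",
         "the same trigger reference")
  structure(list(pair_id = as.character(pair_id),
                 mouse_id = as.character(mouse_id),
                 group = group,
                 timepoint = as.numeric(timepoint),
                 untreated = untreated, selected = selected),
            class = "sample_pair")
}

count_table_columns <- c("pair_id", "mouse_id", "group", "timepoint",
                         "arm", "trigger_id", "count")

#' Write sample pairs to a long-format count TSV
#'
#' Columns: `pair_id mouse_id group timepoint arm trigger_id count`, where
#' `arm` is `untreated` or `selected`. This table is the entry point for
#' users with their own alignment-derived counts.
#'
#' @param pairs A list of [sample_pair()] objects (or a single one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(pairs, path) {
  if (inherits(pairs, "sample_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    do.call(rbind, lapply(c("untreated", "selected"), function(arm) {
      cv <- p[[arm]]
      data.frame(pair_id = p$pair_id, mouse_id = p$mouse_id,
                 group = p$group, timepoint = p$timepoint, arm = arm,
                 trigger_id = names(cv$counts),
                 count = unname(cv$counts),
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format count TSV into sample pairs
#'
#' Inverse of [write_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces the counts exactly.
#'
#' @param path Path to a count TSV.
#' @return A named list of [sample_pair()] objects (names are pair ids),
#'   ordered as first encountered in the file.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_sample_pairs(tab)
}

#' Convert a long-format count data frame to sample pairs
#'
#' @param tab Data frame with columns
#'   `pair_id mouse_id group timepoint arm trigger_id count`.
#' @return A named list of [sample_pair()] objects.
#' @export
as_sample_pairs <- function(tab) {
  missing_cols <- setdiff(count_table_columns, names(tab))
  if (length(missing_cols))
    stop("count table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(is.na(tab$count)) || any(tab$count < 0))
    stop("count table contains missing or negative counts")
  bad_arm <- setdiff(unique(tab$arm), c("untreated", "selected"))
  if (length(bad_arm))
    stop("unknown arm value(s): ", paste(bad_arm, collapse = ", "))
  pair_ids <- unique(tab$pair_id)
  pairs <- lapply(pair_ids, function(pid) {
    sub <- tab[tab$pair_id == pid, , drop = FALSE]
    arms <- lapply(c("untreated", "selected"), function(arm) {
      a <- sub[sub$arm == arm, , drop = FALSE]
      if (nrow(a) == 0L)
        stop("pair '", pid, "' is missing its '", arm, "' arm")
      if (anyDuplicated(a$trigger_id))
        stop("pair '", pid, "', arm '", arm, "': duplicated trigger rows")
      count_vector(paste0(pid, "_", arm),
                   stats::setNames(a$count, a$trigger_id))
    })
    meta <- sub[1L, ]
    sample_pair(pid, meta$mouse_id, meta$group, meta$timepoint,
                untreated = arms[[1L]], selected = arms[[2L]])
  })
  stats::setNames(pairs, pair_ids)
}
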