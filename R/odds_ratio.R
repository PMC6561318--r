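# Spike-in-normalized odds ratios and the exact one-tailed test against a
# shifted null.
#
# For one trigger in one sample pair the 2x2 table is
#
#                   trigger   PNS
#   selected arm       a       b
#   untreated arm      c       d
#
# OR = (a/b)/(c/d) = ad/bc: the trigger's selected:untreated read ratio
# relative to the constitutively memory-on positive normalization strain
# (PNS). Because each trigger is compared only with itself across the two
# arms, per-trigger amplification/length biases cancel; because both arms
# are normalized to the PNS, depth differences between arms cancel. The OR
# estimates the strain's memory-on fraction in the sample.
#
# Significance: conditional on both table margins, the count a follows
# Fisher's noncentral hypergeometric distribution with noncentrality equal
# to the odds ratio. Testing H0: OR = psi0 (default 0.02) against
# Ha: OR > psi0 gives p = P(X >= a | margins, psi0). At psi0 = 1 this is
# exactly the classical one-sided Fisher exact test.

#' Null specification for the shifted Fisher exact test and hit calling
#'
#' @param psi0 Null odds ratio for the one-tailed exact test (default 0.02,
#'   the on/off boundary established by in vitro ROC calibration).
#' @param alpha Significance level for hit calling (default 0.05).
#' @param or_cutoff Odds-ratio cutoff for hit calling (default 0.02). A hit
#'   requires both `odds_ratio >= or_cutoff` and `p_value < alpha`.
#'
#' @return An object of class `null_spec`.
#' @export
null_spec <- function(psi0 = 0.02, alpha = 0.05, or_cutoff = 0.02) {
  stopifnot(psi0 > 0, alpha > 0, alpha < 1, or_cutoff >= 0)
  structure(list(psi0 = psi0, alpha = alpha, or_cutoff = or_cutoff),
            class = "null_spec")
}

#' Spike-in-normalized odds ratio of a 2x2 read-count table
#'
#' Computes `(a/b)/(c/d) = ad/bc` with no pseudocounts. `a = 0` yields an
#' odds ratio of 0; a zero in `b` (PNS absent from the selected culture) or
#' `c` (trigger absent from the untreated culture) leaves the ratio
#' undefined and returns `NA`.
#'
#' @param a Trigger reads in the selected culture.
#' @param b PNS reads in the selected culture.
#' @param c Trigger reads in the untreated culture.
#' @param d PNS reads in the untreated culture.
#'
#' @return A non-negative number, or `NA` when undefined. Vectorized.
#' @export
compute_odds_ratio <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  # double arithmetic: integer counts at realistic depths overflow a*d
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  out <- (a * d) / (b * c)
  out[b == 0 | c == 0] <- NA_real_
  out
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

nchg_support <- function(m1, n1, N) {
  seq.int(max(0L, m1 + n1 - N), min(m1, n1))
}

# log-weights of Fisher's noncentral hypergeometric over the full support;
# unnormalized, computed in log space so margins up to ~1e7 are safe
nchg_log_weights <- function(m1, n1, N, psi) {
  x <- nchg_support(m1, n1, N)
  list(x = x,
       lw = lchoose(n1, x) + lchoose(N - n1, m1 - x) + x * log(psi))
}

#' Fisher's noncentral hypergeometric probability mass function
#'
#' Distribution of the top-left cell `x` of a 2x2 table conditional on both
#' margins when the odds ratio is `psi`:
#' `P(X = x) proportional to C(n1, x) C(N - n1, m1 - x) psi^x`, normalized
#' over the support `max(0, m1 + n1 - N) <= x <= min(m1, n1)`. At
#' `psi = 1` it reduces to the central hypergeometric distribution.
#' Computation is in log space with a running-max shift, so counts up to
#' millions of reads are handled without overflow.
#'
#' @param x Integer value(s) at which to evaluate the pmf; must lie in the
#'   support.
#' @param m1 First margin (e.g. total reads in the selected arm, `a + b`).
#' @param n1 Second margin (e.g. total trigger reads, `a + c`).
#' @param N Grand total of the table.
#' @param psi Positive noncentrality parameter (the odds ratio under which
#'   the distribution is evaluated).
#'
#' @return Probability mass at `x` (vectorized over `x`).
#' @export
nchg_pmf <- function(x, m1, n1, N, psi) {
  stopifnot(length(psi) == 1L, psi > 0, m1 >= 0, n1 >= 0, N >= m1, N >= n1)
  w <- nchg_log_weights(m1, n1, N, psi)
  if (any(x < w$x[1L] | x > w$x[length(w$x)] | x != round(x)))
    stop("x outside the support [", w$x[1L], ", ", w$x[length(w$x)], "]")
  lz <- log_sum_exp(w$lw)
  exp(w$lw[match(x, w$x)] - lz)
}

#' One-tailed exact test of H0: OR = psi0 against Ha: OR > psi0
#'
#' Conditional on both margins of the table, computes
#' `p = P(X >= a | psi = psi0)` under [nchg_pmf()], summed in log space.
#' This is the unique conditional exact test generalizing Fisher's exact
#' test to a non-unity null odds ratio; at `psi0 = 1` it equals the
#' classical one-sided ("greater") Fisher exact test.
#'
#' @param a,b,c,d Table cells as in [compute_odds_ratio()]. Requires
#'   `b > 0` and `d > 0` (PNS present in both arms); a missing PNS
#'   indicates a failed sample, handled upstream.
#' @param psi0 Null odds ratio (default 0.02).
#'
#' @return The p-value, in (0, 1].
#' @export
fisher_test_greater <- function(a, b, c, d, psi0 = 0.02) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0, psi0 > 0)
  if (b == 0 || d == 0)
    stop("PNS count is zero in one arm; the pair is invalid (PNS failure)")
  m1 <- a + b   # selected-arm total
  n1 <- a + c   # trigger total
  N <- a + b + c + d
  w <- nchg_log_weights(m1, n1, N, psi0)
  lz <- log_sum_exp(w$lw)
  p <- exp(log_sum_exp(w$lw[w$x >= a]) - lz)
  min(p, 1)
}

#' Evaluate every trigger of one sample pair
#'
#' Builds the 2x2 table of each non-PNS trigger against the PNS and
#' returns the odds ratio and one-tailed p-value, applying the coverage
#' filter: triggers with fewer than `min_untreated_reads` reads in the
#' untreated culture are not evaluated (`INSUFFICIENT_COVERAGE`; blank in
#' heat maps). A zero PNS count in either arm marks the whole pair as
#' failed (`PNS_FAILURE`).
#'
#' @param pair A [sample_pair()] object.
#' @param pns_id Trigger id of the positive normalization strain.
#' @param null A [null_spec()].
#' @param min_untreated_reads Minimum untreated-culture reads for a trigger
#'   to be evaluable (default 5, boundary inclusive).
#'
#' @return A data frame with one row per non-PNS trigger and columns
#'   `pair_id, mouse_id, group, timepoint, trigger_id, a, b, c, d,
#'   odds_ratio, p_value, status` where `status` is one of `VALID`,
#'   `INSUFFICIENT_COVERAGE`, `PNS_FAILURE`.
#' @export
evaluate_sample_pair <- function(pair, pns_id, null = null_spec(),
                                 min_untreated_reads = 5L) {
  stopifnot(inherits(pair, "sample_pair"), inherits(null, "null_spec"))
  u <- pair$untreated$counts
  s <- pair$selected$counts
  if (!pns_id %in% names(u))
    stop("PNS '", pns_id, "' absent from pair '", pair$pair_id, "'")
  b <- unname(s[[pns_id]])
  d <- unname(u[[pns_id]])
  triggers <- setdiff(names(u), pns_id)
  res <- data.frame(pair_id = pair$pair_id, mouse_id = pair$mouse_id,
                    group = pair$group, timepoint = pair$timepoint,
                    trigger_id = triggers,
                    a = unname(s[triggers]), b = b,
                    c = unname(u[triggers]), d = d,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  if (b == 0L || d == 0L) {
    res$status <- "PNS_FAILURE"
    return(res)
  }
  low <- res$c < min_untreated_reads
  res$status <- ifelse(low, "INSUFFICIENT_COVERAGE", "VALID")
  ok <- which(!low)
  res$odds_ratio[ok] <- compute_odds_ratio(res$a[ok], b, res$c[ok], d)
  res$p_value[ok] <- vapply(ok, function(i) {
    fisher_test_greater(res$a[i], b, res$c[i], d, psi0 = null$psi0)
  }, numeric(1))
  res
}

#' Evaluate a whole screen of sample pairs
#'
#' Applies [evaluate_sample_pair()] to each pair and row-binds the results.
#' Optionally applies Benjamini-Hochberg correction across all VALID
#' p-values (off by default; the hit criterion uses raw p-values).
#'
#' @param pairs List of [sample_pair()] objects (e.g. from
#'   [read_count_table()]).
#' @param pns_id Positive normalization strain id.
#' @param null A [null_spec()].
#' @param min_untreated_reads Coverage filter threshold, see
#'   [evaluate_sample_pair()].
#' @param p_adjust If `TRUE`, add a `p_adjusted` column (BH across all
#'   VALID tests).
#'
#' @return A results data frame (one row per trigger x pair).
#' @export
evaluate_screen <- function(pairs, pns_id, null = null_spec(),
                            min_untreated_reads = 5L, p_adjust = FALSE) {
  if (inherits(pairs, "sample_pair")) pairs <- list(pairs)
  res <- do.call(rbind, lapply(pairs, evaluate_sample_pair, pns_id = pns_id,
                               null = null,
                               min_untreated_reads = min_untreated_reads))
  rownames(res) <- NULL
  if (p_adjust) {
    res$p_adjusted <- NA_real_
    ok <- res$status == "VALID"
    res$p_adjusted[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  }
  res
}

#' Gavage-based trigger retention filter
#'
#' Triggers with fewer than `min_gavage_reads` untreated reads in the
#' gavage suspension are discarded from the screen, unless they register
#' strictly more than `rescue_reads` untreated reads at any later time
#' point.
#'
#' @param timecourse_counts Data frame with columns `trigger_id`,
#'   `timepoint`, `count`: untreated-arm read counts across the time
#'   course, including the gavage sample.
#' @param min_gavage_reads Retention threshold at gavage (default 5,
#'   inclusive).
#' @param rescue_reads Rescue threshold at later time points (default 20,
#'   strictly greater).
#' @param gavage_timepoint Time value identifying the gavage sample
#'   (default 0).
#'
#' @return Character vector of retained trigger ids.
#' @export
apply_gavage_filter <- function(timecourse_counts, min_gavage_reads = 5L,
                                rescue_reads = 20L, gavage_timepoint = 0) {
  stopifnot(all(c("trigger_id", "timepoint", "count") %in%
                  names(timecourse_counts)))
  gav <- timecourse_counts$timepoint == gavage_timepoint
  if (!any(gav))
    stop("no gavage sample (timepoint == ", gavage_timepoint,
         ") in the time course")
  ids <- unique(timecourse_counts$trigger_id)
  keep <- vapply(ids, function(id) {
    rows <- timecourse_counts$trigger_id == id
    g <- timecourse_counts$count[rows & gav]
    later <- timecourse_counts$count[rows & !gav]
    any(g >= min_gavage_reads) ||
      (length(later) > 0L && any(later > rescue_reads))
  }, logical(1))
  ids[keep]
}

#' Write / read an odds-ratio results table
#'
#' TSV with columns `pair_id mouse_id group timepoint trigger_id a b c d
#' odds_ratio p_value status`; undefined values are serialized as `NA`.
#'
#' @param results Results data frame from [evaluate_screen()].
#' @param path TSV path.
#' @return `path` (write) or the results data frame (read).
#' @export
write_or_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_or_results
#' @export
read_or_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
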