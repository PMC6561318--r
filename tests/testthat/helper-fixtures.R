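# Shared fixtures and independent oracles for the test suite.

# deterministic random DNA
rand_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# three-trigger reference (incl. PNS) with hand-distinct sequences
tiny_reference <- function(seed = 42, len = 120) {
  set.seed(seed)
  trigger_reference(c("trigA", "trigB", "fabR_pns"),
                    c(rand_dna(len), rand_dna(len), rand_dna(len)),
                    pns_id = "fabR_pns")
}

fasta_file <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

fastq_file <- function(reads, path = tempfile(fileext = ".fq")) {
  n <- length(reads)
  lines <- as.vector(rbind(sprintf("@r%d", seq_len(n)), reads, "+",
                           vapply(reads, function(r) strrep("I", nchar(r)),
                                  character(1))))
  writeLines(lines, path)
  path
}

# exact-arithmetic noncentral hypergeometric pmf for tiny tables
# (plain choose() products; independent of the package's log-space path)
oracle_nchg_pmf <- function(x, m1, n1, N, psi) {
  supp <- max(0, m1 + n1 - N):min(m1, n1)
  w <- choose(n1, supp) * choose(N - n1, m1 - supp) * psi^supp
  w[match(x, supp)] / sum(w)
}

# tail probability by the same direct enumeration
oracle_p_greater <- function(a, b, c, d, psi0) {
  m1 <- a + b; n1 <- a + c; N <- a + b + c + d
  supp <- max(0, m1 + n1 - N):min(m1, n1)
  w <- choose(n1, supp) * choose(N - n1, m1 - supp) * psi0^supp
  sum(w[supp >= a]) / sum(w)
}

# AUC by brute-force pairwise comparison (Mann-Whitney; ties = 1/2)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# results-frame row builder for screen-analysis unit tests
res_row <- function(trigger_id, mouse_id, group, timepoint, odds_ratio,
                    p_value, status = "VALID") {
  data.frame(pair_id = sprintf("%s_t%g", mouse_id, timepoint),
             mouse_id = mouse_id, group = group, timepoint = timepoint,
             trigger_id = trigger_id, a = 0L, b = 1L, c = 10L, d = 1L,
             odds_ratio = odds_ratio, p_value = p_value, status = status,
             stringsAsFactors = FALSE)
}
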