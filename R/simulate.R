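# Ground-truthed synthetic screens emulating the wet-lab protocol:
# a pooled library of memory strains is gavaged into mice, fecal samples
# are recovered over a time course, the constitutively memory-on positive
# normalization strain (PNS) is spiked in at 1:1,000, each sample is split
# into an untreated and a spectinomycin-selected culture, and the trigger
# regions of both halves are sequenced. The simulator reproduces this
# generative structure with known per-trigger memory-on fractions, so
# every pipeline stage can be verified against planted truth.

#' Simulation configuration
#'
#' Defaults describe a screen of the scale used for trigger discovery: a
#' 150-strain library with a handful of planted responders, three mice per
#' group sampled daily for five days after gavage, selection that recovers
#' 93% of memory-on cells and lets no memory-off cells escape, the PNS
#' spiked at 1:1,000, and half a million reads per culture half.
#'
#' @param n_triggers Number of library strains (excluding the PNS).
#' @param trigger_len Trigger-region length in nt.
#' @param responder_spec Data frame `trigger_id, condition, on_fraction`
#'   with `condition` in `always_off`, `in_vivo`, `disease_only`,
#'   `always_on`. Triggers not listed default to `always_off`. `NULL`
#'   builds a default spec: `n_in_vivo` in-vivo responders (on at
#'   `on_fraction_in_vivo` after gavage in every mouse) and `n_disease`
#'   disease-only responders (on at `on_fraction_disease`, treated group
#'   only).
#' @param n_in_vivo,n_disease Numbers of planted responders used when
#'   `responder_spec` is `NULL`.
#' @param on_fraction_in_vivo,on_fraction_disease Memory-on fractions of
#'   the default planted responders.
#' @param baseline_on_fraction Memory-on fraction of `always_off` strains
#'   (default 0: spectinomycin selection shows no spontaneous switching).
#' @param abundance_concentration Dirichlet concentration of per-mouse
#'   strain abundances (smaller = more uneven library).
#' @param dropout_per_transit Per-day probability that a strain is lost
#'   from a mouse's gut community (default 0.03, reproducing the observed
#'   ~82% strain retention over a week).
#' @param pns_spike_fraction PNS abundance after spike-in (default 1/1000).
#' @param selection_on_survival Recovery of memory-on cells under
#'   spectinomycin (default 0.93).
#' @param selection_off_escape Escape of memory-off cells through selection
#'   (default 0).
#' @param depth_untreated,depth_selected Sequencing depth of each culture
#'   half.
#' @param read_len Simulated read length (nt).
#' @param seq_error_rate Per-base substitution rate of simulated reads.
#' @param n_mice Mice per group.
#' @param timepoints Numeric days; must include the gavage baseline 0.
#' @param groups Group labels; `c("control","treated")` when disease-only
#'   responders are planted, `"control"` otherwise.
#' @param seed Mandatory integer seed; all randomness flows from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_triggers = 150L, trigger_len = 300L,
                       responder_spec = NULL,
                       n_in_vivo = 5L, n_disease = 1L,
                       on_fraction_in_vivo = 0.3,
                       on_fraction_disease = 0.5,
                       baseline_on_fraction = 0,
                       abundance_concentration = 5,
                       dropout_per_transit = 0.03,
                       pns_spike_fraction = 1 / 1000,
                       selection_on_survival = 0.93,
                       selection_off_escape = 0,
                       depth_untreated = 5e5L, depth_selected = 5e5L,
                       read_len = 50L, seq_error_rate = 0,
                       n_mice = 3L, timepoints = 0:5,
                       groups = NULL, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is required: simulations must be seeded")
  stopifnot(n_triggers >= 2L, trigger_len >= 60L,
            pns_spike_fraction > 0, pns_spike_fraction < 1,
            selection_on_survival > 0, selection_on_survival <= 1,
            selection_off_escape >= 0, selection_off_escape <= 1,
            dropout_per_transit >= 0, dropout_per_transit < 1,
            baseline_on_fraction >= 0, baseline_on_fraction <= 1,
            depth_untreated > 0, depth_selected > 0,
            0 %in% timepoints, n_mice >= 1L)
  ids <- sprintf("trig%03d", seq_len(n_triggers))
  if (is.null(responder_spec)) {
    stopifnot(n_in_vivo + n_disease <= n_triggers)
    responder_spec <- data.frame(
      trigger_id = ids[seq_len(n_in_vivo + n_disease)],
      condition = rep(c("in_vivo", "disease_only"),
                      c(n_in_vivo, n_disease)),
      on_fraction = rep(c(on_fraction_in_vivo, on_fraction_disease),
                        c(n_in_vivo, n_disease)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("trigger_id", "condition", "on_fraction") %in%
                  names(responder_spec)),
            all(responder_spec$condition %in%
                  c("always_off", "in_vivo", "disease_only", "always_on")),
            all(responder_spec$trigger_id %in% ids),
            all(responder_spec$on_fraction >= 0),
            all(responder_spec$on_fraction <= 1))
  if (is.null(groups)) {
    groups <- if (any(responder_spec$condition == "disease_only"))
      c("control", "treated") else "control"
  }
  structure(list(n_triggers = as.integer(n_triggers),
                 trigger_len = as.integer(trigger_len),
                 trigger_ids = ids, pns_id = "fabR_pns",
                 responder_spec = responder_spec,
                 baseline_on_fraction = baseline_on_fraction,
                 abundance_concentration = abundance_concentration,
                 dropout_per_transit = dropout_per_transit,
                 pns_spike_fraction = pns_spike_fraction,
                 selection_on_survival = selection_on_survival,
                 selection_off_escape = selection_off_escape,
                 depth_untreated = as.integer(depth_untreated),
                 depth_selected = as.integer(depth_selected),
                 read_len = as.integer(read_len),
                 seq_error_rate = seq_error_rate,
                 n_mice = as.integer(n_mice),
                 timepoints = sort(unique(as.numeric(timepoints))),
                 groups = groups, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Generate a random trigger reference
#'
#' Random sequences of `trigger_len` nt whose 30-mer sets (both strands)
#' are pairwise disjoint, enforced by rejection sampling, so every
#' error-free read of length >= 30 is uniquely assignable. The last record
#' is the PNS.
#'
#' @param config A [sim_config()].
#' @param k K-mer length for the uniqueness check (default 30, matching
#'   the default `min_match_len` of [assign_read()]).
#' @param max_tries Rejection-sampling retry budget per record.
#'
#' @return A [trigger_reference()].
#' @export
generate_reference <- function(config, k = 30L, max_tries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- c(config$trigger_ids, config$pns_id)
  seqs <- character(length(ids))
  seen <- character(0)
  for (i in seq_along(ids)) {
    for (try in seq_len(max_tries)) {
      s <- random_dna(1L, config$trigger_len)
      km <- c(kmer_set(s, k), kmer_set(revcomp(s), k))
      if (!any(km %in% seen)) {
        seqs[i] <- s
        seen <- c(seen, km)
        break
      }
      if (try == max_tries)
        stop("could not generate a sequence with unique ", k,
             "-mers within ", max_tries, " tries")
    }
  }
  trigger_reference(ids, seqs, config$pns_id)
}

# per-trigger memory-on fraction for one sample context
sim_on_fractions <- function(config, group, timepoint) {
  f <- rep(config$baseline_on_fraction, config$n_triggers)
  names(f) <- config$trigger_ids
  rs <- config$responder_spec
  in_gut <- timepoint > 0
  for (i in seq_len(nrow(rs))) {
    f[[rs$trigger_id[i]]] <- switch(rs$condition[i],
      always_off = config$baseline_on_fraction,
      always_on = rs$on_fraction[i],
      in_vivo = if (in_gut) rs$on_fraction[i]
                else config$baseline_on_fraction,
      disease_only = if (in_gut && group == "treated") rs$on_fraction[i]
                     else config$baseline_on_fraction)
  }
  f
}

#' Simulate the composition of one processed sample
#'
#' Returns the relative abundances entering the split cultures (library
#' strains carried through gut-passage dropout, plus the PNS spiked at
#' `pns_spike_fraction`) and the per-strain memory-on fractions implied by
#' the sample's condition. The gavage sample (timepoint 0) is pre-gut:
#' in-vivo and disease-only responders are still off.
#'
#' @param config A [sim_config()].
#' @param group Group of the mouse (`"control"` or `"treated"`).
#' @param timepoint Sample time in days (0 = gavage).
#' @param base_abundance Optional baseline library abundances (named, sums
#'   to 1 over library strains); drawn from a Dirichlet if `NULL`.
#' @param present Optional logical vector of strains still present in this
#'   mouse at this time; defaults to all present (dropout is applied by
#'   [simulate_screen()], which tracks per-mouse persistence).
#'
#' @return List with `abundance` (named, includes the PNS, sums to 1) and
#'   `on_fraction` (named, PNS fixed at 1).
#' @export
simulate_composition <- function(config, group = "control", timepoint = 0,
                                 base_abundance = NULL, present = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(base_abundance)) {
    g <- stats::rgamma(config$n_triggers,
                       shape = config$abundance_concentration)
    base_abundance <- stats::setNames(g / sum(g), config$trigger_ids)
  }
  if (is.null(present)) present <- rep(TRUE, config$n_triggers)
  ab <- base_abundance * present
  if (sum(ab) == 0)
    stop("degenerate sample: every library strain has dropped out")
  ab <- ab / sum(ab)
  spike <- config$pns_spike_fraction
  abundance <- c(ab * (1 - spike),
                 stats::setNames(spike, config$pns_id))
  on_fraction <- c(sim_on_fractions(config, group, timepoint),
                   stats::setNames(1, config$pns_id))
  list(abundance = abundance, on_fraction = on_fraction)
}

#' Simulate spectinomycin selection
#'
#' The selected culture is reweighted by each strain's expected survival,
#' `on_fraction * selection_on_survival +
#' (1 - on_fraction) * selection_off_escape`, then renormalized; the
#' untreated culture passes through unchanged (overnight growth is modeled
#' as composition-preserving). With zero escape the survival factor is
#' shared by every surviving strain and cancels in the odds ratio, which
#' is why the OR estimates the memory-on fraction itself.
#'
#' @param abundance Named, normalized strain abundances.
#' @param on_fraction Named memory-on fractions (same strains).
#' @param selection_on_survival,selection_off_escape Selection parameters.
#'
#' @return Named, normalized abundances of the selected culture.
#' @export
simulate_selection <- function(abundance, on_fraction,
                               selection_on_survival = 0.93,
                               selection_off_escape = 0) {
  stopifnot(length(abundance) == length(on_fraction))
  w <- abundance * (on_fraction * selection_on_survival +
                      (1 - on_fraction) * selection_off_escape)
  if (sum(w) == 0)
    stop("degenerate selection: no memory-on cells in the culture")
  w / sum(w)
}

#' Simulate sequencing of one culture
#'
#' A single multinomial draw of `depth` reads over the composition,
#' optionally distorted by per-strain multiplicative length-bias factors
#' (used to exercise the odds ratio's bias-cancellation property).
#'
#' @param composition Named, normalized strain abundances.
#' @param depth Number of reads.
#' @param length_bias Optional named positive factors.
#' @param sample_id Identifier for the returned count vector.
#'
#' @return A [count_vector()].
#' @export
simulate_sequencing <- function(composition, depth, length_bias = NULL,
                                sample_id = "sim") {
  p <- composition
  if (!is.null(length_bias)) {
    stopifnot(all(names(composition) %in% names(length_bias)))
    p <- p * length_bias[names(p)]
  }
  p <- p / sum(p)
  counts <- if (depth > 0)
    stats::rmultinom(1L, size = depth, prob = p)[, 1L]
  else stats::setNames(integer(length(p)), names(p))
  count_vector(sample_id, counts)
}

#' Simulate reads for a counted sample and write FASTQ
#'
#' Each counted read is a uniform-start substring of its trigger on a
#' random strand, with independent per-base substitution errors at
#' `seq_error_rate`; qualities are constant. With zero error rate,
#' re-counting the FASTQ with [count_reads()] reproduces the generating
#' counts exactly.
#'
#' @param counts A [count_vector()].
#' @param reference A [trigger_reference()].
#' @param read_len Read length (must not exceed the trigger length).
#' @param seq_error_rate Per-base substitution probability.
#' @param path Optional FASTQ output path.
#'
#' @return Character vector of read sequences (in emission order);
#'   written to `path` when given.
#' @export
simulate_reads <- function(counts, reference, read_len = 50L,
                           seq_error_rate = 0, path = NULL) {
  stopifnot(inherits(counts, "count_vector"),
            inherits(reference, "trigger_reference"))
  bases <- c("A", "C", "G", "T")
  reads <- character(0)
  for (id in names(counts$counts)) {
    k <- counts$counts[[id]]
    if (k == 0L) next
    tseq <- reference$sequences[[id]]
    tlen <- nchar(tseq)
    if (read_len > tlen)
      stop("read_len exceeds the length of trigger '", id, "'")
    starts <- sample.int(tlen - read_len + 1L, k, replace = TRUE)
    r <- substring(tseq, starts, starts + read_len - 1L)
    rc <- sample(c(TRUE, FALSE), k, replace = TRUE)
    r[rc] <- revcomp(r[rc])
    if (seq_error_rate > 0) {
      r <- vapply(r, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        err <- which(stats::runif(length(ch)) < seq_error_rate)
        for (i in err) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads <- c(reads, r)
  }
  if (!is.null(path)) {
    n <- length(reads)
    lines <- character(4L * n)
    if (n) {
      lines[seq(1L, 4L * n, 4L)] <- sprintf("@read%06d", seq_len(n))
      lines[seq(2L, 4L * n, 4L)] <- reads
      lines[seq(3L, 4L * n, 4L)] <- "+"
      lines[seq(4L, 4L * n, 4L)] <- strrep("I", read_len)
    }
    writeLines(lines, path)
  }
  invisible(reads)
}

#' Simulate a complete screen
#'
#' Full factorial mice x timepoints per group. Per mouse: baseline library
#' abundances are drawn once (Dirichlet), strains drop out cumulatively
#' (per-day Bernoulli), and each timepoint's sample is spiked with the
#' PNS, split, selected, and sequenced. The gavage sample (t = 0) is the
#' pre-gut suspension: gut- and disease-responsive triggers are still off.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `counts.tsv`,
#'   `design.tsv`, `truth.tsv` and `ref.fa` (plus per-sample FASTQs when
#'   `emit_fastq`).
#' @param emit_fastq Also simulate reads and write per-sample FASTQ files
#'   (requires `out_dir`).
#'
#' @return List with `pairs` (named list of [sample_pair()]), `counts`
#'   (long count data frame), `design` (pair metadata), `truth`
#'   (per trigger x sample: `true_abundance`, `true_on_fraction`,
#'   `expected_or`), `reference`, and `config`.
#' @export
simulate_screen <- function(config, out_dir = NULL, emit_fastq = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (emit_fastq && is.null(out_dir))
    stop("'emit_fastq' requires 'out_dir'")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(config)   # seeds the RNG from config$seed
  surv <- config$selection_on_survival
  esc <- config$selection_off_escape
  pairs <- list()
  truth <- list()
  for (group in config$groups) {
    for (m in seq_len(config$n_mice)) {
      mouse_id <- sprintf("%s_m%d", group, m)
      g <- stats::rgamma(config$n_triggers,
                         shape = config$abundance_concentration)
      base_ab <- stats::setNames(g / sum(g), config$trigger_ids)
      present <- rep(TRUE, config$n_triggers)
      prev_t <- 0
      for (t in config$timepoints) {
        if (t > prev_t && config$dropout_per_transit > 0) {
          keep_p <- (1 - config$dropout_per_transit)^(t - prev_t)
          present <- present &
            (stats::runif(config$n_triggers) < keep_p)
        }
        prev_t <- t
        comp <- simulate_composition(config, group, t,
                                     base_abundance = base_ab,
                                     present = present)
        sel <- simulate_selection(comp$abundance, comp$on_fraction,
                                  surv, esc)
        pair_id <- sprintf("%s_t%g", mouse_id, t)
        cv_u <- simulate_sequencing(comp$abundance, config$depth_untreated,
                                    sample_id = paste0(pair_id, "_untreated"))
        cv_s <- simulate_sequencing(sel, config$depth_selected,
                                    sample_id = paste0(pair_id, "_selected"))
        pairs[[pair_id]] <- sample_pair(pair_id, mouse_id, group, t,
                                        untreated = cv_u, selected = cv_s)
        f <- comp$on_fraction
        truth[[pair_id]] <- data.frame(
          pair_id = pair_id, mouse_id = mouse_id, group = group,
          timepoint = t, trigger_id = names(comp$abundance),
          true_abundance = unname(comp$abundance),
          true_on_fraction = unname(f),
          expected_or = unname((f * surv + (1 - f) * esc) / surv),
          stringsAsFactors = FALSE)
        if (emit_fastq) {
          simulate_reads(cv_u, reference, config$read_len,
                         config$seq_error_rate,
                         path = file.path(out_dir,
                                          paste0(pair_id, "_untreated.fq")))
          simulate_reads(cv_s, reference, config$read_len,
                         config$seq_error_rate,
                         path = file.path(out_dir,
                                          paste0(pair_id, "_selected.fq")))
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  design <- unique(truth[, c("pair_id", "mouse_id", "group", "timepoint")])
  rownames(design) <- NULL
  if (!is.null(out_dir)) {
    write_count_table(pairs, file.path(out_dir, "counts.tsv"))
    utils::write.table(design, file.path(out_dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_trigger_reference(reference, file.path(out_dir, "ref.fa"))
  }
  list(pairs = pairs, design = design, truth = truth,
       reference = reference, config = config)
}
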