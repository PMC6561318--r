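# The synthetic screen generator: reference generation, composition,
# selection, sequencing, read emission and the assembled screen.

test_that("generated references are deterministic with disjoint 30-mers", {
  cfg <- sim_config(n_triggers = 8, trigger_len = 200, seed = 3)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(ref1$sequences, ref2$sequences)
  expect_identical(ref1$pns_id, "fabR_pns")
  expect_length(ref1$ids, 9L)  # library strains + PNS

  # brute-force pairwise k-mer intersection across both strands
  km <- lapply(ref1$sequences, function(s) {
    n <- nchar(s); starts <- seq_len(n - 30 + 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    c(substring(s, starts, starts + 29), substring(rc, starts, starts + 29))
  })
  for (i in seq_along(km)) for (j in seq_len(i - 1L))
    expect_length(intersect(km[[i]], km[[j]]), 0L)
})

test_that("composition encodes condition-dependent memory states", {
  cfg <- sim_config(n_triggers = 10, n_in_vivo = 2, n_disease = 1,
                    baseline_on_fraction = 0, seed = 5)
  set.seed(5)
  gav <- simulate_composition(cfg, "control", 0)
  expect_equal(sum(gav$abundance), 1)
  expect_equal(unname(gav$abundance[["fabR_pns"]]), 1 / 1000)
  expect_equal(unname(gav$on_fraction[["fabR_pns"]]), 1)
  # pre-gut: every library trigger is off at gavage
  expect_true(all(gav$on_fraction[cfg$trigger_ids] == 0))

  gut_ctrl <- simulate_composition(cfg, "control", 2)
  gut_dss <- simulate_composition(cfg, "treated", 2)
  expect_equal(unname(gut_ctrl$on_fraction[["trig001"]]), 0.3)  # in_vivo
  expect_equal(unname(gut_ctrl$on_fraction[["trig003"]]), 0)    # disease_only
  expect_equal(unname(gut_dss$on_fraction[["trig003"]]), 0.5)
  expect_true(all(gut_ctrl$on_fraction[paste0("trig", sprintf("%03d", 4:10))]
                  == 0))                                        # always_off
  expect_error(simulate_composition(cfg, "control", 1,
                                    present = rep(FALSE, 10)), "degenerate")
})

test_that("selection reweights by expected survival and renormalizes", {
  ab <- c(x = 0.5, y = 0.5)
  # fully-on strains: the survival factor is uniform and cancels
  expect_equal(simulate_selection(ab, c(x = 1, y = 1)), ab)
  # a fully-off strain contributes nothing when escape is zero
  sel <- simulate_selection(ab, c(x = 1, y = 0))
  expect_equal(unname(sel[["y"]]), 0)
  # hand arithmetic: f = {1, 0.5}, survival 0.93 -> weights 0.93 : 0.465
  sel2 <- simulate_selection(ab, c(x = 1, y = 0.5),
                             selection_on_survival = 0.93)
  expect_equal(unname(sel2[["x"]] / sel2[["y"]]), 2)
  expect_error(simulate_selection(ab, c(x = 0, y = 0)), "degenerate")
})

test_that("sequencing is a seeded multinomial draw honoring length bias", {
  comp <- c(s1 = 0.7, s2 = 0.3)
  set.seed(77)
  cv <- simulate_sequencing(comp, 1e6)
  # binomial moments: observed counts within 4 sigma of expectation
  sd1 <- sqrt(1e6 * 0.7 * 0.3)
  expect_lt(abs(cv$counts[["s1"]] - 7e5), 4 * sd1)
  expect_identical(cv$total_assigned, 1000000L)

  set.seed(1)
  only <- simulate_sequencing(c(s1 = 1), 500)
  expect_identical(unname(only$counts[["s1"]]), 500L)

  empty <- simulate_sequencing(comp, 0)
  expect_identical(empty$total_assigned, 0L)

  # equal per-trigger bias in both arms leaves the odds ratio centered
  set.seed(42)
  bias <- c(s1 = 3, s2 = 0.5, pns = 1)
  comp3 <- c(s1 = 0.4995, s2 = 0.4995, pns = 0.001)
  sel3 <- simulate_selection(comp3, c(s1 = 0.5, s2 = 0.5, pns = 1))
  ors <- replicate(40, {
    u <- simulate_sequencing(comp3, 2e5, length_bias = bias)
    s <- simulate_sequencing(sel3, 2e5, length_bias = bias)
    compute_odds_ratio(s$counts[["s1"]], s$counts[["pns"]],
                       u$counts[["s1"]], u$counts[["pns"]])
  })
  expect_lt(abs(median(ors) - 0.5), 0.05)
})

test_that("simulated reads round-trip through the counter when error-free", {
  cfg <- sim_config(n_triggers = 4, trigger_len = 200, n_in_vivo = 1,
                    n_disease = 0, seed = 11)
  ref <- generate_reference(cfg)
  counts <- count_vector("sim", stats::setNames(c(60L, 25L, 0L, 10L, 5L),
                                                ref$ids))
  set.seed(13)
  fq <- tempfile(fileext = ".fq")
  simulate_reads(counts, ref, read_len = 50, seq_error_rate = 0, path = fq)
  back <- count_reads(fq, ref)
  expect_identical(back$counts, counts$counts)
  expect_identical(back$n_ambiguous, 0L)
  expect_identical(back$n_unmapped, 0L)

  # identical seed, identical FASTQ bytes
  set.seed(13)
  fq2 <- tempfile(fileext = ".fq")
  simulate_reads(counts, ref, read_len = 50, seq_error_rate = 0, path = fq2)
  expect_identical(readLines(fq), readLines(fq2))

  # read_len equal to the trigger length spans the full trigger
  set.seed(14)
  full <- simulate_reads(count_vector("x", stats::setNames(c(3L, 0L, 0L, 0L, 0L),
                                                           ref$ids)),
                         ref, read_len = 200)
  expect_true(all(nchar(full) == 200))
  expect_error(simulate_reads(counts, ref, read_len = 500), "exceeds")
})

test_that("assembled screens are schema-conformant with correct truth", {
  cfg <- sim_config(n_triggers = 12, n_in_vivo = 2, n_disease = 1,
                    n_mice = 2, timepoints = 0:2,
                    depth_untreated = 2e4, depth_selected = 2e4, seed = 23)
  out <- tempfile()
  sim <- simulate_screen(cfg, out_dir = out)
  expect_length(sim$pairs, 2 * 2 * 3)  # groups x mice x timepoints

  # written artifacts load back through the pipeline's own readers
  pairs <- read_count_table(file.path(out, "counts.tsv"))
  expect_identical(names(pairs), names(sim$pairs))
  ref <- load_trigger_reference(file.path(out, "ref.fa"), cfg$pns_id)
  expect_identical(ref$sequences, sim$reference$sequences)
  res <- evaluate_screen(pairs, cfg$pns_id)
  expect_true(all(res$status %in%
                    c("VALID", "INSUFFICIENT_COVERAGE", "PNS_FAILURE")))

  # truth: in_vivo responder expected OR is f in the gut, 0 at gavage
  tr <- sim$truth
  iv <- tr[tr$trigger_id == "trig001", ]
  expect_true(all(iv$expected_or[iv$timepoint == 0] == 0))
  expect_true(all(iv$expected_or[iv$timepoint > 0] == 0.3))
  ds <- tr[tr$trigger_id == "trig003", ]
  expect_true(all(ds$expected_or[ds$group == "control"] == 0))
  expect_true(all(ds$expected_or[ds$group == "treated" &
                                   ds$timepoint > 0] == 0.5))
  # same seed reproduces the same counts
  sim2 <- simulate_screen(cfg)
  expect_identical(sim2$pairs[[5]]$selected$counts,
                   sim$pairs[[5]]$selected$counts)
})

test_that("expected OR equals the on-fraction regardless of survival", {
  # analytic cancellation: with zero escape the selection survival factor
  # is shared between trigger and PNS, so E[OR] ~ f for any survival
  for (surv in c(0.93, 0.5)) {
    comp <- c(t1 = 0.999, pns = 0.001)
    sel <- simulate_selection(comp, c(t1 = 0.4, pns = 1),
                              selection_on_survival = surv)
    set.seed(300 + surv * 100)
    ors <- replicate(60, {
      u <- simulate_sequencing(comp, 1e5)
      s <- simulate_sequencing(sel, 1e5)
      compute_odds_ratio(s$counts[["t1"]], s$counts[["pns"]],
                         u$counts[["t1"]], u$counts[["pns"]])
    })
    expect_lt(abs(median(ors) - 0.4) / 0.4, 0.1)
  }
})

test_that("selection escape inflates odds ratios of off triggers", {
  comp <- c(t1 = 0.999, pns = 0.001)
  onf <- c(t1 = 0, pns = 1)
  med_or <- vapply(c(0, 0.01, 0.05), function(esc) {
    sel <- simulate_selection(comp, onf, selection_off_escape = esc)
    set.seed(9)
    median(replicate(20, {
      u <- simulate_sequencing(comp, 5e4)
      s <- simulate_sequencing(sel, 5e4)
      compute_odds_ratio(s$counts[["t1"]], s$counts[["pns"]],
                         u$counts[["t1"]], u$counts[["pns"]])
    }))
  }, numeric(1))
  expect_true(all(diff(med_or) > 0))
})

test_that("dropout keeps strain sets fixed when disabled", {
  cfg <- sim_config(n_triggers = 10, n_in_vivo = 1, n_disease = 0,
                    dropout_per_transit = 0, n_mice = 1, timepoints = c(0, 3, 7),
                    depth_untreated = 5e4, depth_selected = 5e4, seed = 31)
  sim <- simulate_screen(cfg)
  present <- tapply(sim$truth$true_abundance > 0, sim$truth$pair_id, sum)
  expect_true(all(present == present[[1]]))
  expect_error(sim_config(n_triggers = 10, seed = NULL), "seed")
  expect_error(sim_config(n_triggers = 10, timepoints = 1:3, seed = 1))
})
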