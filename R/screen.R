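# Screen-level aggregation: hit calling across mice and time points,
# responder classification, disease-differential scoring, ROC calibration
# of the odds-ratio cutoff, and heat-map style exports.
#
# All functions operate on the long results data frame produced by
# evaluate_screen(): one row per trigger x sample pair with columns
# pair_id, mouse_id, group, timepoint, trigger_id, a, b, c, d, odds_ratio,
# p_value, status. The gavage baseline is timepoint 0; post-gavage cells
# pooled across mice are the units of the "% positive time points" metric.

#' Call hits on odds-ratio results
#'
#' A cell is a hit when it is evaluable (`status == "VALID"`) and
#' `odds_ratio >= or_cutoff` and `p_value < alpha`. Both the cutoff and the
#' test enter the criterion: the exact test already encodes the 0.02
#' boundary as its null, and the cutoff is applied on top, mirroring the
#' conjunctive definition used for screen scoring. Non-evaluable cells
#' (insufficient coverage or PNS failure) return `NA` and are blank in heat
#' maps.
#'
#' @param results Results data frame (or any data frame with columns
#'   `odds_ratio`, `p_value`, `status`).
#' @param null A [null_spec()].
#'
#' @return Logical vector, one element per row; `NA` for non-evaluable
#'   cells.
#' @export
call_hit <- function(results, null = null_spec()) {
  stopifnot(inherits(null, "null_spec"))
  hit <- results$odds_ratio >= null$or_cutoff & results$p_value < null$alpha
  hit[results$status != "VALID"] <- NA
  hit
}

#' Per-trigger screen summary
#'
#' For each trigger, pools all evaluable post-gavage cells (mouse x time
#' point) and reports the number and fraction that are hits, plus the
#' number of mice with at least one positive time point. The gavage
#' baseline is excluded from the fraction. Triggers with zero evaluable
#' post-gavage cells get `fraction_positive = NA` and are excluded from
#' rankings.
#'
#' @param results Results data frame from [evaluate_screen()].
#' @param null A [null_spec()].
#' @param gavage_timepoint Time value of the gavage baseline (default 0).
#'
#' @return Data frame with one row per trigger: `trigger_id, n_positive,
#'   n_evaluable, fraction_positive, n_mice_positive, mean_or`, sorted by
#'   decreasing `fraction_positive` (ties: mean odds ratio, then id).
#' @export
summarize_triggers <- function(results, null = null_spec(),
                               gavage_timepoint = 0) {
  post <- results[results$timepoint != gavage_timepoint, , drop = FALSE]
  post$hit <- call_hit(post, null)
  ids <- unique(results$trigger_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- post[post$trigger_id == id, , drop = FALSE]
    ev <- sub$status == "VALID"
    n_ev <- sum(ev)
    n_pos <- sum(sub$hit[ev])
    data.frame(trigger_id = id,
               n_positive = n_pos,
               n_evaluable = n_ev,
               fraction_positive = if (n_ev > 0L) n_pos / n_ev else NA_real_,
               n_mice_positive =
                 length(unique(sub$mouse_id[ev & sub$hit])),
               mean_or = if (n_ev > 0L) mean(sub$odds_ratio[ev])
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-out$fraction_positive, -out$mean_or, out$trigger_id,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify triggers as in-vivo responders
#'
#' An in-vivo responder is off when administered and switches on in the
#' gut: every evaluable gavage cell has `odds_ratio < or_cutoff`, and at
#' least one post-gavage cell is a hit (`odds_ratio >= or_cutoff` and
#' `p_value < alpha`). Triggers with no evaluable gavage cell cannot be
#' classified and return `NA`.
#'
#' @param results Results data frame from [evaluate_screen()].
#' @param null A [null_spec()].
#' @param gavage_timepoint Time value of the gavage baseline (default 0).
#'
#' @return Named logical vector over triggers (`NA` = not evaluable).
#' @export
classify_in_vivo_responder <- function(results, null = null_spec(),
                                       gavage_timepoint = 0) {
  hit <- call_hit(results, null)
  ids <- unique(results$trigger_id)
  out <- vapply(ids, function(id) {
    rows <- results$trigger_id == id
    gav <- rows & results$timepoint == gavage_timepoint &
      results$status == "VALID"
    if (!any(gav)) return(NA)
    off_at_gavage <- all(results$odds_ratio[gav] < null$or_cutoff)
    post <- rows & results$timepoint != gavage_timepoint
    off_at_gavage && any(hit[post], na.rm = TRUE)
  }, logical(1))
  stats::setNames(out, ids)
}

#' Disease-differential response score
#'
#' For each trigger, the fraction of positive post-gavage time points in
#' the treated (e.g. DSS colitis) group minus the fraction in the control
#' group, each pooled over that group's evaluable mouse x time point cells.
#' Triggers are sorted by decreasing difference; a trigger responding only
#' under disease scores near +1. A group with zero evaluable cells leaves
#' the score `NA`.
#'
#' @param results Results data frame from [evaluate_screen()]; must contain
#'   both groups.
#' @param null A [null_spec()].
#' @param gavage_timepoint Time value of the gavage baseline (default 0).
#'
#' @return Data frame `trigger_id, fraction_treated, fraction_control,
#'   differential`, sorted by decreasing differential.
#' @export
differential_response <- function(results, null = null_spec(),
                                  gavage_timepoint = 0) {
  if (!all(c("control", "treated") %in% results$group))
    stop("differential response requires both 'control' and 'treated' groups")
  post <- results[results$timepoint != gavage_timepoint, , drop = FALSE]
  post$hit <- call_hit(post, null)
  ids <- unique(results$trigger_id)
  frac <- function(sub) {
    ev <- sub$status == "VALID"
    if (!any(ev)) return(NA_real_)
    sum(sub$hit[ev]) / sum(ev)
  }
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- post[post$trigger_id == id, , drop = FALSE]
    ft <- frac(sub[sub$group == "treated", , drop = FALSE])
    fc <- frac(sub[sub$group == "control", , drop = FALSE])
    data.frame(trigger_id = id, fraction_treated = ft,
               fraction_control = fc, differential = ft - fc,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$differential, out$trigger_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC calibration of the odds-ratio cutoff against plate-derived truth
#'
#' Sweeps thresholds over `{-Inf} U sorted unique ORs U {+Inf}` with the
#' positive-call convention `OR >= threshold`, and reports TPR/FPR per
#' threshold, the trapezoidal AUC, and the threshold maximizing Youden's
#' J = TPR - FPR. Labels come from plating individual strains on indicator
#' plates (memory-on = positive).
#'
#' @param or_values Named numeric vector of odds ratios per trigger.
#' @param labels Named logical vector (TRUE = memory-on) covering the same
#'   triggers.
#'
#' @return An object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `youden_threshold`, `labels`.
#' @export
roc_calibrate <- function(or_values, labels) {
  if (is.null(names(or_values)) || is.null(names(labels)))
    stop("'or_values' and 'labels' must be named by trigger id")
  common <- intersect(names(or_values), names(labels))
  if (length(common) < length(labels))
    stop("label(s) without a defined odds ratio: ",
         paste(setdiff(names(labels), names(or_values)), collapse = ", "))
  or_values <- or_values[common]
  labels <- as.logical(labels[common])
  if (any(is.na(or_values)))
    stop("every labeled trigger must have a defined odds ratio")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires at least one positive and one negative label")
  thresholds <- c(-Inf, sort(unique(or_values)), Inf)
  tpr <- vapply(thresholds, function(t) sum(or_values >= t & labels) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(or_values >= t & !labels) / n_neg,
                numeric(1))
  # sweep runs from all-positive (threshold -Inf) to all-negative (+Inf);
  # integrate TPR over FPR in increasing-FPR order
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  j <- tpr - fpr
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 youden_threshold = thresholds[which.max(j)],
                 labels = stats::setNames(labels, common)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC =", format(x$auc, digits = 4),
      "; Youden-optimal threshold =", format(x$youden_threshold, digits = 4),
      "\n")
  invisible(x)
}

#' Export a ranked odds-ratio heat-map table
#'
#' Rows are the top `top_k` triggers ranked by fraction of positive time
#' points (ties broken by mean odds ratio, then id); columns are mouse x
#' time point cells ordered by group, mouse, then time. Cells carry the
#' odds ratio; non-evaluable cells are `NA` (blank). Deterministic: the
#' same input always yields a byte-identical TSV.
#'
#' @param results Results data frame from [evaluate_screen()].
#' @param null A [null_spec()].
#' @param top_k Number of top-ranked triggers to export (default all).
#' @param path Optional TSV output path.
#' @param gavage_timepoint Gavage baseline time value (default 0);
#'   excluded from ranking but included as a column block.
#'
#' @return The heat-map data frame (triggers x sample cells), invisibly
#'   when `path` is given.
#' @export
render_heatmap_table <- function(results, null = null_spec(), top_k = Inf,
                                 path = NULL, gavage_timepoint = 0) {
  summ <- summarize_triggers(results, null, gavage_timepoint)
  summ <- summ[!is.na(summ$fraction_positive), , drop = FALSE]
  ids <- utils::head(summ$trigger_id, top_k)
  cells <- unique(results[, c("group", "mouse_id", "timepoint")])
  cells <- cells[order(cells$group, cells$mouse_id, cells$timepoint), ,
                 drop = FALSE]
  col_ids <- sprintf("%s_%s_d%g", cells$group, cells$mouse_id,
                     cells$timepoint)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = nrow(cells),
                dimnames = list(ids, col_ids))
  valid <- results[results$status == "VALID" &
                     results$trigger_id %in% ids, , drop = FALSE]
  ri <- match(valid$trigger_id, ids)
  ci <- match(sprintf("%s_%s_d%g", valid$group, valid$mouse_id,
                      valid$timepoint), col_ids)
  mat[cbind(ri, ci)] <- valid$odds_ratio
  out <- data.frame(trigger_id = ids,
                    fraction_positive =
                      summ$fraction_positive[match(ids, summ$trigger_id)],
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    return(invisible(out))
  }
  out
}
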