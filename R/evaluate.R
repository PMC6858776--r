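# Two-level evaluation of predicted annotations against gold annotations:
# note level (a note counts as correct only when every value of interest in
# it was extracted, with true negatives defined) and value level (each
# individual value scored; no true negative exists).  Percentile bootstrap
# over notes yields confidence intervals.

value_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sprintf("%.10g|%.10g", df$value_low, df$value_high)
}

#' Classify each note's outcome for one variable (note level)
#'
#' A note is a true positive when the predicted value multiset exactly
#' equals the non-empty gold multiset; a true negative when both are empty;
#' a false positive when any predicted value has no gold counterpart
#' (including the mixed miss-plus-spurious case, by the package's stated
#' precedence); otherwise a false negative (some gold value was missed and
#' nothing spurious was introduced).  With \code{match_counts = TRUE} a true
#' positive only requires the same number of values, not the same values.
#'
#' @param gold Gold data frame: \code{note_id}, \code{variable},
#'   \code{value_low}, \code{value_high}.
#' @param pred Predicted annotation data frame (same columns at least).
#' @param variable Variable to score.
#' @param note_ids Character vector of all note ids in the corpus (needed so
#'   that notes with neither gold nor predictions count as true negatives).
#' @param match_counts Count-only matching flag (default exact multiset).
#' @return Data frame with columns \code{note_id}, \code{outcome}
#'   (\code{"TP"/"FP"/"FN"/"TN"}).
#' @export
note_level_outcomes <- function(gold, pred, variable, note_ids,
                                match_counts = FALSE) {
  g <- gold[gold$variable == variable, , drop = FALSE]
  p <- pred[pred$variable == variable, , drop = FALSE]
  out <- character(length(note_ids))
  for (i in seq_along(note_ids)) {
    id <- note_ids[i]
    gk <- value_keys(g[g$note_id == id, , drop = FALSE])
    pk <- value_keys(p[p$note_id == id, , drop = FALSE])
    if (!length(gk) && !length(pk)) {
      out[i] <- "TN"
    } else if (match_counts) {
      out[i] <- if (length(pk) == length(gk)) "TP"
                else if (length(pk) > length(gk)) "FP" else "FN"
    } else {
      gt <- table(gk)
      pt <- table(pk)
      spurious <- any(!names(pt) %in% names(gt)) ||
        any(pt > gt[names(pt)], na.rm = TRUE)
      missed <- any(!names(gt) %in% names(pt)) ||
        any(gt > pt[names(gt)], na.rm = TRUE)
      out[i] <- if (spurious) "FP"
                else if (missed) "FN"
                else "TP"
    }
  }
  data.frame(note_id = note_ids, outcome = out, stringsAsFactors = FALSE)
}

#' Note-level confusion counts from outcomes
#'
#' @param outcomes Output of [note_level_outcomes()] (or its
#'   \code{outcome} column).
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
note_level_confusion <- function(outcomes) {
  o <- if (is.data.frame(outcomes)) outcomes$outcome else outcomes
  list(tp = sum(o == "TP"), fp = sum(o == "FP"),
       fn = sum(o == "FN"), tn = sum(o == "TN"))
}

#' Per-note value-level counts for one variable
#'
#' For each note, matched values (exact numeric equality; for ranges both
#' endpoints) are true positives, unmatched predictions false positives,
#' unmatched gold values false negatives.  No true negative is defined at
#' the value level.
#'
#' @inheritParams note_level_outcomes
#' @return Data frame with columns \code{note_id}, \code{tp}, \code{fp},
#'   \code{fn}.
#' @export
value_level_counts <- function(gold, pred, variable, note_ids) {
  g <- gold[gold$variable == variable, , drop = FALSE]
  p <- pred[pred$variable == variable, , drop = FALSE]
  tp <- fp <- fn <- integer(length(note_ids))
  for (i in seq_along(note_ids)) {
    id <- note_ids[i]
    gk <- value_keys(g[g$note_id == id, , drop = FALSE])
    pk <- value_keys(p[p$note_id == id, , drop = FALSE])
    keys <- union(gk, pk)
    gt <- vapply(keys, function(k) sum(gk == k), integer(1))
    pt <- vapply(keys, function(k) sum(pk == k), integer(1))
    tp[i] <- sum(pmin(gt, pt))
    fp[i] <- sum(pmax(pt - gt, 0L))
    fn[i] <- sum(pmax(gt - pt, 0L))
  }
  data.frame(note_id = note_ids, tp = tp, fp = fp, fn = fn,
             stringsAsFactors = FALSE)
}

#' Value-level confusion counts
#'
#' @param counts Output of [value_level_counts()].
#' @return List with \code{tp}, \code{fp}, \code{fn} (no \code{tn}).
#' @export
value_level_confusion <- function(counts) {
  list(tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn))
}

#' Point-estimate metrics from confusion counts
#'
#' Sensitivity \eqn{tp/(tp+fn)}, specificity \eqn{tn/(tn+fp)}, PPV
#' \eqn{tp/(tp+fp)}, NPV \eqn{tn/(tn+fn)}, and F1
#' \eqn{2 \cdot ppv \cdot sens / (ppv + sens)}.  A zero denominator yields
#' \code{NA}, never a silent 0/0; all-zero counts additionally warn.
#' Specificity and NPV are \code{NA} when \code{tn} is absent (value
#' level).
#'
#' @param counts List with \code{tp}, \code{fp}, \code{fn} and optionally
#'   \code{tn}.
#' @return Named numeric vector \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, \code{f1}.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tn <- if (!is.null(counts$tn)) counts$tn else NA_integer_
  if (sum(tp, fp, fn, if (is.na(tn)) 0L else tn) == 0) {
    warning("all confusion counts are zero; metrics undefined",
            call. = FALSE)
  }
  div <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

metrics_note_level <- function(outcome_labels) {
  metrics_from_counts(note_level_confusion(outcome_labels))
}

metrics_value_level <- function(counts_df) {
  m <- metrics_from_counts(value_level_confusion(counts_df))
  m[c("specificity", "npv")] <- NA_real_
  m
}

#' Percentile bootstrap confidence intervals over notes
#'
#' Resamples notes with replacement \code{B} times, recomputes the metric
#' set for each replicate, and reports the 2.5/97.5 percentiles (for the
#' default 95\% level).  Replicates where a metric is undefined are dropped
#' for that metric's percentiles.  A fixed seed gives bit-identical
#' intervals; the caller's RNG state is restored on exit.
#'
#' @param per_note Either a note-level outcome data frame
#'   ([note_level_outcomes()]) or a value-level per-note count frame
#'   ([value_level_counts()]).
#' @param level \code{"note"} or \code{"value"}.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @param conf Confidence level (default 0.95).
#' @return Matrix with rows \code{lo}, \code{hi} and one column per metric.
#' @export
bootstrap_ci <- function(per_note, level = c("note", "value"), B = 1000L,
                         seed, conf = 0.95) {
  level <- match.arg(level)
  stopifnot(B >= 1L, !missing(seed))
  n <- nrow(per_note)
  point <- if (level == "note") metrics_note_level(per_note$outcome)
           else metrics_value_level(per_note)
  if (n < 2L) {
    warning("fewer than 2 notes; bootstrap CI degenerates to the point ",
            "estimate", call. = FALSE)
    return(rbind(lo = point, hi = point))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, nrow = B, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  if (level == "note") {
    labels <- per_note$outcome
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b, ] <- suppressWarnings(metrics_note_level(labels[idx]))
    }
  } else {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b, ] <- suppressWarnings(
        metrics_value_level(per_note[idx, , drop = FALSE]))
    }
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- apply(reps, 2, function(col) {
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, probs, na.rm = TRUE, names = FALSE, type = 7)
  })
  rownames(ci) <- c("lo", "hi")
  ci
}

#' Evaluate predictions against gold at the note or value level
#'
#' The workhorse scorer: per variable, computes confusion counts, metric
#' point estimates and bootstrap confidence intervals, mirroring the
#' two-level evaluation scheme (specificity and NPV exist only at the note
#' level).
#'
#' @param gold Gold annotations (\code{note_id}, \code{variable},
#'   \code{value_low}, \code{value_high}).
#' @param pred Predicted annotations (same columns at least).
#' @param note_ids All note ids in the corpus; default is the union of ids
#'   seen in \code{gold} and \code{pred} (which loses unseen true-negative
#'   notes - pass the full list when you have it).
#' @param level \code{"note"} or \code{"value"}.
#' @param variables Variables to score; default: all in gold or pred.
#' @param B Bootstrap replicates (default 1000); \code{B = 0} skips CIs.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @param match_counts Note-level count-only matching flag.
#' @return Data frame with one row per (variable, metric):
#'   \code{variable}, \code{metric}, \code{estimate}, \code{ci_lo},
#'   \code{ci_hi}, plus the confusion counts as attributes
#'   \code{"confusion"}.
#' @export
evaluate_extraction <- function(gold, pred, note_ids = NULL,
                                level = c("note", "value"),
                                variables = NULL, B = 1000L, seed = 1L,
                                conf = 0.95, match_counts = FALSE) {
  level <- match.arg(level)
  if (is.null(note_ids)) {
    note_ids <- sort(unique(c(gold$note_id, pred$note_id)))
  }
  if (is.null(variables)) {
    variables <- sort(unique(c(gold$variable, pred$variable)))
  }
  extra <- setdiff(unique(pred$variable), unique(gold$variable))
  for (v in intersect(extra, variables)) {
    warning("variable '", v, "' present in predictions but not in gold; ",
            "scored against empty gold (all false positives)",
            call. = FALSE)
  }
  rows <- list()
  confusion <- list()
  metric_names <- if (level == "note") {
    c("sensitivity", "specificity", "ppv", "npv", "f1")
  } else {
    c("sensitivity", "ppv", "f1")
  }
  for (v in variables) {
    if (level == "note") {
      per_note <- note_level_outcomes(gold, pred, v, note_ids, match_counts)
      counts <- note_level_confusion(per_note)
      point <- suppressWarnings(metrics_note_level(per_note$outcome))
    } else {
      per_note <- value_level_counts(gold, pred, v, note_ids)
      counts <- value_level_confusion(per_note)
      point <- suppressWarnings(metrics_value_level(per_note))
    }
    ci <- if (B >= 1L) {
      suppressWarnings(bootstrap_ci(per_note, level, B, seed, conf))
    } else {
      rbind(lo = point * NA_real_, hi = point * NA_real_)
    }
    confusion[[v]] <- counts
    rows[[v]] <- data.frame(
      variable = v, metric = metric_names,
      estimate = unname(point[metric_names]),
      ci_lo = unname(ci["lo", metric_names]),
      ci_hi = unname(ci["hi", metric_names]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "confusion") <- confusion
  attr(out, "level") <- level
  out
}

#' Pretty-print an evaluation table
#'
#' One row per variable, one column per metric, each cell
#' \code{"est (lo, hi)"}, mirroring the published table layout.
#'
#' @param metrics Output of [evaluate_extraction()].
#' @param digits Digits for formatting (default 2).
#' @return The formatted data frame, invisibly printed.
#' @export
format_metrics_table <- function(metrics, digits = 2) {
  fmt <- function(e, lo, hi) {
    ifelse(is.na(e), "-",
           ifelse(is.na(lo), sprintf("%.*f", digits, e),
                  sprintf("%.*f (%.*f, %.*f)", digits, e, digits, lo,
                          digits, hi)))
  }
  vars <- unique(metrics$variable)
  mets <- unique(metrics$metric)
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (m in mets) {
    sub <- metrics[metrics$metric == m, ]
    out[[m]] <- fmt(sub$estimate[match(vars, sub$variable)],
                    sub$ci_lo[match(vars, sub$variable)],
                    sub$ci_hi[match(vars, sub$variable)])
  }
  out
}
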