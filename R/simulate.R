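# Deterministic synthetic clinical-note generator with known gold
# annotations.  Templates emulate the two documentation styles the
# extractor targets -- labeled term-value pairs ("bp 132/78",
# "ejection fraction of 10-15 percent") and unlabeled vital-sign panels
# ("97.0 100/66 98 18 98%") -- plus negative distractors: condition
# expressions ("fever > 100.4"), lab pseudo-tables, term-only and
# term-free sentences.

.TEMPLATES <- c("labeled_pair", "grouped_panel", "condition_distractor",
                "pseudo_table_distractor", "term_only", "no_term")

# words guaranteed not to collide with any default dictionary term
.SAFE_WORDS <- c("patient", "noted", "today", "stable", "exam", "overnight",
                 "currently", "remains", "comfortable", "this", "morning",
                 "without", "acute", "events", "seen", "and", "reviewed")

#' Generator configuration
#'
#' @param n_notes Number of notes to generate.
#' @param seed Integer seed (mandatory; same seed, same corpus).
#' @param weights Named template mix weights over
#'   \code{labeled_pair, grouped_panel, condition_distractor,
#'   pseudo_table_distractor, term_only, no_term}; must be non-negative and
#'   sum to 1.
#' @param variables Variables eligible for \code{labeled_pair} templates
#'   (default: the eight validated parameters).
#' @param unit_prob Probability that a labeled pair carries an explicit
#'   unit token.
#' @param colon_prob Probability that a labeled pair uses a colon separator
#'   ("t: 99.1") instead of plain whitespace.
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(n_notes, seed,
                             weights = c(labeled_pair = 0.40,
                                         grouped_panel = 0.20,
                                         condition_distractor = 0.15,
                                         pseudo_table_distractor = 0.10,
                                         term_only = 0.10,
                                         no_term = 0.05),
                             variables = c("temperature", "blood_pressure",
                                           "respiratory_rate", "heart_rate",
                                           "o2_saturation",
                                           "ejection_fraction", "hba1c",
                                           "creatinine"),
                             unit_prob = 0.3, colon_prob = 0.3) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!all(.TEMPLATES %in% names(weights))) {
    weights <- weights[.TEMPLATES]
    names(weights) <- .TEMPLATES
    weights[is.na(weights)] <- 0
  }
  weights <- weights[.TEMPLATES]
  if (any(is.na(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("template weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(n_notes = as.integer(n_notes), seed = as.integer(seed),
                 weights = weights, variables = variables,
                 unit_prob = unit_prob, colon_prob = colon_prob),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# uniform draw over the viable range shrunk by a 1-unit margin;
# boundary-behavior tests are kept separate and explicit
draw_value <- function(spec, digits = 0L) {
  lo <- spec$viable_range[1] + 1
  hi <- spec$viable_range[2] - 1
  round(stats::runif(1, lo, hi), digits)
}

unit_token <- function(variable) {
  switch(variable,
         temperature = "f", blood_pressure = "mmhg", heart_rate = "bpm",
         respiratory_rate = "", o2_saturation = "", hba1c = "%",
         ejection_fraction = "%", creatinine = "mg/dl", "")
}

# one labeled term-value pair; returns list(text, gold = c(lo, hi))
sim_labeled_pair <- function(variable, specs, cfg) {
  spec <- specs[[variable]]
  term <- sample(spec$terms, 1L)
  sep <- if (stats::runif(1) < cfg$colon_prob) ": " else " "
  unit <- if (stats::runif(1) < cfg$unit_prob) unit_token(variable) else ""
  if (variable == "blood_pressure") {
    sys <- round(stats::runif(1, 90, 180))
    dia <- round(stats::runif(1, 50, min(100, sys - 10)))
    val_str <- paste0(sys, "/", dia)
    gold <- c(sys, dia)
  } else if (variable == "ejection_fraction" && stats::runif(1) < 0.4) {
    lo <- round(stats::runif(1, 10, 60))
    hi <- lo + round(stats::runif(1, 5, 20))
    val_str <- paste0(lo, "-", hi,
                      if (stats::runif(1) < 0.5) "%" else " percent")
    unit <- ""
    gold <- c(lo, hi)
  } else {
    digits <- switch(variable, temperature = 1L, hba1c = 1L,
                     creatinine = 1L, 0L)
    v <- draw_value(spec, digits)
    if (variable == "temperature" && v == round(v)) v <- v + 0.1
    val_str <- format(v, nsmall = digits)
    if (variable == "o2_saturation" && stats::runif(1) < 0.5) {
      val_str <- paste0(val_str, "%")
    }
    gold <- c(v, v)
  }
  filler <- if (stats::runif(1) < 0.4) {
    paste(sample(.SAFE_WORDS, 2L), collapse = " ")
  } else ""
  txt <- trimws(paste0(filler, if (nzchar(filler)) " " else "",
                       term, sep, val_str,
                       if (nzchar(unit)) paste0(" ", unit) else ""))
  list(text = txt, gold = data.frame(variable = variable,
                                     value_low = gold[1],
                                     value_high = gold[2],
                                     stringsAsFactors = FALSE))
}

# unlabeled five-token vital-sign panel passing all group rules
sim_grouped_panel <- function(specs) {
  t_val <- round(stats::runif(1, 94, 109), 1)
  if (t_val == round(t_val)) t_val <- t_val + 0.1
  sys <- round(stats::runif(1, 90, 180))
  dia <- round(stats::runif(1, 50, min(100, sys - 10)))
  hr <- round(stats::runif(1, 40, 150))
  rr <- round(stats::runif(1, 8, 40))
  o2 <- round(stats::runif(1, 85, 99))
  txt <- paste0(format(t_val, nsmall = 1), " ", sys, "/", dia, " ", hr,
                " ", rr, " ", o2, "%")
  gold <- data.frame(
    variable = c("temperature", "blood_pressure", "heart_rate",
                 "respiratory_rate", "o2_saturation"),
    value_low = c(t_val, sys, hr, rr, o2),
    value_high = c(t_val, dia, hr, rr, o2),
    stringsAsFactors = FALSE)
  list(text = txt, gold = gold)
}

# "term > value" for a reject_conditions vital sign: zero gold
sim_condition_distractor <- function(specs) {
  variable <- sample(c("temperature", "heart_rate", "respiratory_rate",
                       "o2_saturation"), 1L)
  spec <- specs[[variable]]
  term <- sample(spec$terms, 1L)
  digits <- if (variable == "temperature") 1L else 0L
  v <- draw_value(spec, digits)
  cond <- sample(c(">", "<", "greater than", "less than"), 1L)
  list(text = paste(term, cond, format(v, nsmall = digits)),
       gold = NULL)
}

# number run violating at least one group rule: zero gold
sim_pseudo_table <- function() {
  variant <- sample(3L, 1L)
  txt <- switch(variant,
    # >2 decimal-pointed tokens (lab panel style)
    paste(format(round(stats::runif(sample(4:6, 1L), 0.1, 60), 1),
                 nsmall = 1), collapse = " "),
    # integers at or above 300
    paste(round(stats::runif(sample(3:5, 1L), 300, 999)), collapse = " "),
    # more than one fraction
    paste(paste0(round(stats::runif(3, 100, 180)), "/",
                 round(stats::runif(3, 50, 95))), collapse = " "))
  list(text = txt, gold = NULL)
}

sim_term_only <- function(specs, variables) {
  variable <- sample(variables, 1L)
  term <- sample(specs[[variable]]$terms, 1L)
  list(text = paste(term, sample(c("stable", "unchanged", "reviewed"), 1L)),
       gold = NULL)
}

sim_no_term <- function() {
  list(text = paste(sample(.SAFE_WORDS, sample(4:7, 1L)), collapse = " "),
       gold = NULL)
}

#' Generate a synthetic corpus with known gold annotations
#'
#' Deterministic given the config seed.  Clean templates
#' (\code{labeled_pair}, \code{grouped_panel}) carry gold annotations that
#' the extraction rules recover exactly; distractor templates carry none.
#'
#' @param config A [generator_config()].
#' @param specs Variable specifications (default [default_specs()]).
#' @return List of class \code{synthetic_corpus} with elements
#'   \code{notes} (data frame \code{note_id}, \code{text},
#'   \code{template}) and \code{gold} (data frame \code{note_id},
#'   \code{variable}, \code{value_low}, \code{value_high}).
#' @export
generate_corpus <- function(config, specs = default_specs()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_notes
    notes <- vector("list", n)
    gold <- vector("list", n)
    templates <- if (n > 0) {
      sample(.TEMPLATES, n, replace = TRUE, prob = config$weights)
    } else character(0)
    for (i in seq_len(n)) {
      sim <- switch(templates[i],
        labeled_pair = sim_labeled_pair(
          sample(config$variables, 1L), specs, config),
        grouped_panel = sim_grouped_panel(specs),
        condition_distractor = sim_condition_distractor(specs),
        pseudo_table_distractor = sim_pseudo_table(),
        term_only = sim_term_only(specs, config$variables),
        no_term = sim_no_term())
      id <- sprintf("note_%04d", i)
      notes[[i]] <- data.frame(note_id = id, text = sim$text,
                               template = templates[i],
                               stringsAsFactors = FALSE)
      if (!is.null(sim$gold) && nrow(sim$gold)) {
        gold[[i]] <- cbind(data.frame(note_id = id,
                                      stringsAsFactors = FALSE), sim$gold)
      }
    }
    gold <- gold[!vapply(gold, is.null, logical(1))]
    structure(list(
      notes = if (n > 0) do.call(rbind, notes) else
        data.frame(note_id = character(0), text = character(0),
                   template = character(0), stringsAsFactors = FALSE),
      gold = if (length(gold)) do.call(rbind, gold) else
        data.frame(note_id = character(0), variable = character(0),
                   value_low = numeric(0), value_high = numeric(0),
                   stringsAsFactors = FALSE)),
      class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$notes), "notes,", nrow(x$gold),
      "gold annotations\n")
  if (nrow(x$notes)) {
    print(table(x$notes$template))
  }
  invisible(x)
}

#' Plant an exact note-level confusion profile
#'
#' Builds gold and predicted annotation sets over \code{n = a+b+c+d} notes
#' realizing exactly \code{a} true positives, \code{b} false positives,
#' \code{c} false negatives and \code{d} true negatives for one variable,
#' to exercise the evaluation module's count recovery.
#'
#' @param a_tp,b_fp,c_fn,d_tn Requested note counts.
#' @param variable Variable to plant (default temperature).
#' @param seed Integer seed for value draws.
#' @param note_ids Optional note ids; default \code{pc_0001 ...}.
#' @return List with \code{gold}, \code{pred} (annotation-shaped data
#'   frames) and \code{note_ids}.
#' @export
plant_confusion <- function(a_tp, b_fp, c_fn, d_tn,
                            variable = "temperature", seed = 1L,
                            note_ids = NULL) {
  counts <- c(a_tp, b_fp, c_fn, d_tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (is.null(note_ids)) {
    note_ids <- sprintf("pc_%04d", seq_len(n))
  } else if (length(note_ids) != n) {
    stop("length(note_ids) must equal a+b+c+d", call. = FALSE)
  }
  with_seed(seed, {
    lab <- rep(c("TP", "FP", "FN", "TN"), counts)
    vals <- round(stats::runif(n, 94, 109), 1)
    gold <- list()
    pred <- list()
    row <- function(id, v) data.frame(
      note_id = id, variable = variable, value_low = v, value_high = v,
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      if (lab[i] == "TP") {
        gold[[length(gold) + 1L]] <- row(note_ids[i], vals[i])
        pred[[length(pred) + 1L]] <- row(note_ids[i], vals[i])
      } else if (lab[i] == "FP") {
        pred[[length(pred) + 1L]] <- row(note_ids[i], vals[i])
      } else if (lab[i] == "FN") {
        gold[[length(gold) + 1L]] <- row(note_ids[i], vals[i])
      }
    }
    empty <- data.frame(note_id = character(0), variable = character(0),
                        value_low = numeric(0), value_high = numeric(0),
                        stringsAsFactors = FALSE)
    list(gold = if (length(gold)) do.call(rbind, gold) else empty,
         pred = if (length(pred)) do.call(rbind, pred) else empty,
         note_ids = note_ids)
  })
}
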