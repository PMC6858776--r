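# Per-variable validity tests: value format, condition-symbol policy,
# viable range, unit inference.  Accepted candidates become annotations;
# rejected ones are retained with their reason for debugging.

# explicit unit tokens -> canonical labels
.UNIT_VOCAB <- c("f" = "\u00b0F", "fahrenheit" = "\u00b0F",
                 "degrees" = "\u00b0F",
                 "mmhg" = "mmHg", "bpm" = "bpm", "%" = "%", "percent" = "%",
                 "mg/dl" = "mg/dL", "kg" = "kg", "kgs" = "kg", "lb" = "lb",
                 "lbs" = "lb", "cm" = "cm", "inches" = "in")

unit_compatible <- function(spec) {
  switch(spec$name,
         weight = c("kg", "lb"),
         height = c("in", "cm"),
         spec$unit)
}

#' Resolve the unit of a candidate
#'
#' An explicit unit token adjacent to the value (a percent sign inside the
#' token, or a recognized unit word immediately after it) wins; otherwise
#' the unit implied by the viable range that matched is used (a bare 99.7
#' accepted as temperature is degrees Fahrenheit).  An explicit unit that
#' contradicts the variable's unit is a conflict.
#'
#' @param candidate One candidate row (list or 1-row data frame).
#' @param spec The matching \code{variable_spec}.
#' @return List with \code{unit} (canonical label or \code{NA}) and
#'   \code{conflict} (logical).
#' @export
resolve_unit <- function(candidate, spec) {
  explicit <- NA_character_
  if (isTRUE(candidate$has_percent)) {
    explicit <- "%"
  } else if (!is.na(candidate$next_surface)) {
    hit <- .UNIT_VOCAB[candidate$next_surface]
    if (!is.na(hit)) explicit <- unname(hit)
  }
  if (is.na(explicit)) {
    return(list(unit = spec$unit, conflict = FALSE))
  }
  if (explicit %in% unit_compatible(spec)) {
    return(list(unit = explicit, conflict = FALSE))
  }
  list(unit = explicit, conflict = TRUE)
}

#' Validity test for one candidate
#'
#' Applies, in order: value-format check against the variable's allowed
#' shapes; condition policy (an inequality between term and value
#' invalidates vital-sign pairs but is accepted and recorded for variables
#' with \code{accept_conditions}, such as ejection fraction and HbA1C);
#' decimal-form rescaling for ejection fraction (a decimal value \eqn{\le}
#' 1.0 is multiplied by 100); viable-range check (for ranges, both
#' endpoints; for blood-pressure fractions, numerator against the systolic
#' and denominator against the diastolic range); unit inference.
#'
#' @param candidate One candidate row from [extract_note()].
#' @param spec The \code{variable_spec} for the candidate's variable.
#' @return List with \code{accepted}, \code{reason} (one of \code{ok},
#'   \code{bad_format}, \code{condition_rejected}, \code{out_of_range},
#'   \code{unit_conflict}), \code{value_low}, \code{value_high} (possibly
#'   rescaled), \code{unit}.
#' @export
check_validity <- function(candidate, spec) {
  res <- function(ok, reason, lo = candidate$value_low,
                  hi = candidate$value_high, unit = NA_character_) {
    list(accepted = ok, reason = reason, value_low = lo, value_high = hi,
         unit = unit)
  }
  fmt <- if (isTRUE(candidate$is_fraction)) "fraction"
  else if (isTRUE(candidate$is_range)) "range"
  else if (isTRUE(candidate$has_percent)) "percent"
  else if (isTRUE(candidate$has_decimal)) "decimal"
  else "integer"
  if (!fmt %in% spec$formats) return(res(FALSE, "bad_format"))

  if (!identical(candidate$condition, "none") &&
      spec$condition_policy == "reject_conditions") {
    return(res(FALSE, "condition_rejected"))
  }

  lo <- candidate$value_low
  hi <- candidate$value_high
  if (spec$decimal_norm && isTRUE(candidate$has_decimal) &&
      !isTRUE(candidate$is_fraction) && max(lo, hi) <= 1.0) {
    lo <- lo * 100
    hi <- hi * 100
  }

  if (isTRUE(candidate$is_fraction)) {
    rng2 <- if (!is.null(spec$viable_range2)) spec$viable_range2
            else spec$viable_range
    if (!in_range(lo, spec$viable_range) || !in_range(hi, rng2)) {
      return(res(FALSE, "out_of_range", lo, hi))
    }
  } else {
    if (!in_range(lo, spec$viable_range) ||
        !in_range(hi, spec$viable_range)) {
      return(res(FALSE, "out_of_range", lo, hi))
    }
  }

  u <- resolve_unit(candidate, spec)
  if (u$conflict) return(res(FALSE, "unit_conflict", lo, hi, u$unit))
  res(TRUE, "ok", lo, hi, u$unit)
}

empty_annotations <- function() {
  data.frame(note_id = character(0), variable = character(0),
             value_low = numeric(0), value_high = numeric(0),
             unit = character(0), condition = character(0),
             start = integer(0), end = integer(0), source = character(0),
             stringsAsFactors = FALSE)
}

empty_rejects <- function() {
  data.frame(note_id = character(0), variable = character(0),
             value_low = numeric(0), value_high = numeric(0),
             reason = character(0), start = integer(0), end = integer(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Finalize candidates into annotations
#'
#' Runs the validity test on every candidate; accepted candidates become
#' annotation rows, rejected ones are attached as the \code{"rejected"}
#' attribute with their reasons.  Output is sorted by (note_id, start).
#'
#' @param candidates Candidate data frame from [extract_note()].
#' @param specs Variable specifications.
#' @param note_id Note identifier stamped onto the output.
#' @return Annotation data frame with columns \code{note_id},
#'   \code{variable}, \code{value_low}, \code{value_high}, \code{unit},
#'   \code{condition}, \code{start}, \code{end}, \code{source}; attribute
#'   \code{"rejected"} holds the reject log.
#' @export
finalize <- function(candidates, specs, note_id = "note") {
  ann <- empty_annotations()
  rej <- empty_rejects()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    spec <- specs[[cand$variable]]
    if (is.null(spec)) next
    v <- check_validity(cand, spec)
    if (v$accepted) {
      ann <- rbind(ann, data.frame(
        note_id = note_id, variable = cand$variable,
        value_low = v$value_low, value_high = v$value_high,
        unit = v$unit, condition = cand$condition,
        start = cand$start, end = cand$end, source = cand$source,
        stringsAsFactors = FALSE))
    } else {
      rej <- rbind(rej, data.frame(
        note_id = note_id, variable = cand$variable,
        value_low = cand$value_low, value_high = cand$value_high,
        reason = v$reason, start = cand$start, end = cand$end,
        source = cand$source, stringsAsFactors = FALSE))
    }
  }
  if (nrow(ann)) {
    ann <- ann[order(ann$note_id, ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  attr(ann, "rejected") <- rej
  ann
}

#' Extract validated annotations from notes
#'
#' End-to-end pipeline over a corpus: preprocessing, term matching,
#' term-adjacent and number-group extraction, validity testing.
#'
#' @param notes Either a character vector of note texts (ids are invented as
#'   \code{note_1 ...}), or a data frame with columns \code{note_id} and
#'   \code{text}.
#' @param specs Variable specifications (default [default_specs()]).
#' @param config An [extract_config()].
#' @param variables Optional character vector restricting output variables.
#' @return Annotation data frame (see [finalize()]); attribute
#'   \code{"rejected"} collects all rejected candidates.
#' @examples
#' extract_values("vitals: 97.0 100/66 98 18 98%")
#' @export
extract_values <- function(notes, specs = default_specs(),
                           config = extract_config(), variables = NULL) {
  if (is.character(notes)) {
    notes <- data.frame(note_id = paste0("note_", seq_along(notes)),
                        text = notes, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("note_id", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id)) {
    stop("duplicate note_id values in input", call. = FALSE)
  }
  lexicon <- build_lexicon(specs)
  out <- list()
  rej <- list()
  for (i in seq_len(nrow(notes))) {
    cand <- extract_note(notes$text[i], lexicon, specs, config)
    ann <- finalize(cand, specs, note_id = notes$note_id[i])
    out[[i]] <- ann
    rej[[i]] <- attr(ann, "rejected")
  }
  ann <- if (length(out)) do.call(rbind, out) else empty_annotations()
  if (!is.null(variables)) {
    ann <- ann[ann$variable %in% variables, , drop = FALSE]
  }
  rownames(ann) <- NULL
  attr(ann, "rejected") <- if (length(rej)) do.call(rbind, rej)
                           else empty_rejects()
  ann
}
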