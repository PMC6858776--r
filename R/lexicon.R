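# Variable specifications (dictionaries, viable ranges, format flags,
# condition policies) and the token-level prefix tree used for term matching.

.CANONICAL_VARIABLES <- c("temperature", "blood_pressure", "respiratory_rate",
                          "heart_rate", "o2_saturation", "ejection_fraction",
                          "hba1c", "creatinine", "height", "weight")

#' Construct one variable specification
#'
#' @param name Canonical variable id.
#' @param terms Character vector of dictionary terms (lowercased on load;
#'   multi-word terms are stored as token sequences).
#' @param viable_range Numeric \code{c(low, high)}; values outside are
#'   rejected by the validity test.  For blood pressure this is the systolic
#'   range and \code{viable_range2} the diastolic range.
#' @param formats Allowed value shapes, a subset of
#'   \code{c("integer","decimal","percent","fraction","range")}.
#' @param condition_policy \code{"reject_conditions"} (vital signs: an
#'   inequality between term and value invalidates the pair) or
#'   \code{"accept_conditions"} (EF/HbA1C: the bound itself is the
#'   clinically useful datum and is recorded).
#' @param unit Canonical unit label inferred when no explicit unit is
#'   present.
#' @param group_eligible Whether the variable can be filled from an
#'   unlabeled vital-sign number group.
#' @param viable_range2 Secondary (diastolic) range, blood pressure only.
#' @param decimal_norm If \code{TRUE}, a decimal value \eqn{\le} 1.0 is read
#'   as a fraction-of-one and rescaled to percent (ejection fraction).
#' @return Object of class \code{variable_spec}.
#' @export
variable_spec <- function(name, terms, viable_range, formats,
                          condition_policy = "reject_conditions",
                          unit = "", group_eligible = FALSE,
                          viable_range2 = NULL, decimal_norm = FALSE) {
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) {
    stop("variable '", name, "': term list is empty", call. = FALSE)
  }
  viable_range <- as.numeric(viable_range)
  if (length(viable_range) != 2L || !all(is.finite(viable_range)) ||
      viable_range[1] >= viable_range[2]) {
    stop("variable '", name, "': viable_range must be c(low, high) with ",
         "low < high, got [", paste(viable_range, collapse = ", "), "]",
         call. = FALSE)
  }
  if (!is.null(viable_range2)) {
    viable_range2 <- as.numeric(viable_range2)
    if (length(viable_range2) != 2L || viable_range2[1] >= viable_range2[2]) {
      stop("variable '", name, "': viable_range2 must be c(low, high) with ",
           "low < high", call. = FALSE)
    }
  }
  condition_policy <- match.arg(condition_policy,
                                c("reject_conditions", "accept_conditions"))
  formats <- match.arg(formats,
                       c("integer", "decimal", "percent", "fraction", "range"),
                       several.ok = TRUE)
  structure(list(name = name, terms = terms, viable_range = viable_range,
                 formats = formats, condition_policy = condition_policy,
                 unit = unit, group_eligible = isTRUE(group_eligible),
                 viable_range2 = viable_range2,
                 decimal_norm = isTRUE(decimal_norm)),
            class = "variable_spec")
}

# Terms pass through the same normalization as note text so that lexicon
# tokens always match note tokens ("resp." -> "resp", "B/P" -> "b/p").
normalize_term <- function(terms) {
  vapply(terms, function(tm) {
    toks <- tokenize_sentence(normalize_text(tm))
    paste(toks$surface, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Default variable specifications
#'
#' The shipped dictionaries reproduce the published term lists verbatim,
#' including idiosyncratic entries such as \code{"tear"} (temperature) and
#' the \code{"hga1c"} abbreviation whose addition repaired HbA1C recall; see
#' the package README.  Viable ranges: temperature 93--110 degrees F; EF up to 100
#' in percent form (a decimal value \eqn{\le} 1.0 is rescaled by 100);
#' HbA1C below 30 %; creatinine below 50.  Ranges the source material never
#' states (heart rate, respiratory rate, blood pressure components, oxygen
#' saturation, height, weight) are package defaults, user-overridable via
#' [load_specs()].
#'
#' @return Named list of \code{variable_spec} objects.
#' @export
default_specs <- function() {
  specs <- list(
    variable_spec("temperature",
      c("t", "fever", "t-max", "fevers", "ta", "te", "tmax", "tear", "temp",
        "tm", "tmp", "tmt", "tp", "tpr", "tr", "tre", "tt", "temperature",
        "afebrile"),
      viable_range = c(93, 110), formats = c("integer", "decimal", "range"),
      condition_policy = "reject_conditions", unit = "\u00b0F",
      group_eligible = TRUE),
    variable_spec("blood_pressure",
      c("b/p", "bps", "bp", "blood pressure", "hypertensive", "hypotensive"),
      viable_range = c(40, 300), viable_range2 = c(20, 200),
      formats = "fraction", condition_policy = "reject_conditions",
      unit = "mmHg", group_eligible = TRUE),
    variable_spec("respiratory_rate",
      c("rr", "rp", "r", "resp.", "respiratory", "respiration",
        "respirations", "tachypea", "breathing"),
      viable_range = c(4, 60), formats = c("integer", "range"),
      condition_policy = "reject_conditions", unit = "breaths/min",
      group_eligible = TRUE),
    variable_spec("heart_rate",
      c("hr", "hrt", "p", "afib", "af", "tach", "nsr", "tachy", "pulse",
        "pulses", "tachycardia", "tachycardic", "bradycardic", "sinus"),
      viable_range = c(20, 300), formats = c("integer", "range"),
      condition_policy = "reject_conditions", unit = "bpm",
      group_eligible = TRUE),
    variable_spec("o2_saturation",
      c("sat", "sats", "sating", "satting", "desat", "o2sat", "o2sats",
        "pox", "spo2", "sa", "sao2", "s", "oximetry", "o2", "saturation",
        "saturating", "saturations", "desaturation", "desaturations",
        "desaturates", "desaturate", "desaturated"),
      viable_range = c(50, 100), formats = c("integer", "percent", "range"),
      condition_policy = "reject_conditions", unit = "%",
      group_eligible = TRUE),
    variable_spec("ejection_fraction",
      c("ef", "ejection fraction", "lvef"),
      viable_range = c(1, 100),
      formats = c("integer", "decimal", "percent", "range"),
      condition_policy = "accept_conditions", unit = "%",
      decimal_norm = TRUE),
    variable_spec("hba1c",
      c("glycated haemoglobin", "glycated hemoglobins", "glycated hemoglobin",
        "glycohemoglobin a", "glycosylate haemoglobin",
        "glycosylate hemoglobin", "glycosylated haemoglobin a",
        "glycosylated haemoglobin", "glycosylated hb",
        "glycosylated hemoglobin a", "glycosylated hemoglobins",
        "glycosylated hemoglobin", "haemoglobin a1c", "hb a1a + b", "hb a1c",
        "hb a1", "hba1c", "hba1", "hemoglobin a1c", "hemoglobin glycated",
        "a1c", "a1cs", "hgba1c", "hb1c", "hga1c"),
      viable_range = c(0.5, 30),
      formats = c("integer", "decimal", "percent", "range"),
      condition_policy = "accept_conditions", unit = "%"),
    variable_spec("creatinine",
      c("creat", "crn", "cr", "creatinine", "scr", "cri", "creatinin", "ctn",
        "cre", "crea"),
      viable_range = c(0.1, 50), formats = c("integer", "decimal", "range"),
      condition_policy = "reject_conditions", unit = "mg/dL"),
    # Height and weight appear in the published dictionary but carry no
    # published viable ranges; these defaults are unvalidated package
    # inventions and should be overridden for real use.
    variable_spec("height",
      c("h", "hgt", "hh", "ht.", "height"),
      viable_range = c(36, 90), formats = c("integer", "decimal"),
      condition_policy = "reject_conditions", unit = "in"),
    variable_spec("weight",
      c("wt", "w", "wgt", "wi", "bw", "weight"),
      viable_range = c(2, 500), formats = c("integer", "decimal", "range"),
      condition_policy = "reject_conditions", unit = "kg")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Load variable specifications, optionally overridden by a config file
#'
#' With no config the shipped defaults are returned.  A YAML or JSON config
#' holds per-variable blocks that override or extend fields
#' (\code{terms}, \code{extra_terms}, \code{viable_range},
#' \code{viable_range2}, \code{formats}, \code{condition_policy},
#' \code{unit}, \code{group_eligible}); unknown variable names create new
#' specifications (which then require \code{terms} and \code{viable_range}).
#' Terms shared between two variables are kept for both, with a warning;
#' range checks downstream disambiguate.
#'
#' @param config Path to a YAML/JSON file, an already-parsed list, or
#'   \code{NULL} for the defaults.
#' @return Named list of \code{variable_spec} objects.
#' @export
load_specs <- function(config = NULL) {
  specs <- default_specs()
  if (is.null(config)) return(specs)
  cfg <- if (is.character(config)) read_config_file(config) else config
  if (!is.list(cfg)) stop("config must be a named list of variable blocks",
                          call. = FALSE)
  for (var in names(cfg)) {
    block <- cfg[[var]]
    if (!is.list(block)) {
      stop("config field '", var, "': expected a block of settings",
           call. = FALSE)
    }
    base <- specs[[var]]
    if (is.null(base)) {
      if (is.null(block$terms) || is.null(block$viable_range)) {
        stop("config field '", var, "': new variables need 'terms' and ",
             "'viable_range'", call. = FALSE)
      }
      base <- list(name = var, formats = c("integer", "decimal"),
                   condition_policy = "reject_conditions", unit = "",
                   group_eligible = FALSE, viable_range2 = NULL,
                   decimal_norm = FALSE)
    }
    terms <- if (!is.null(block$terms)) unlist(block$terms) else base$terms
    if (!is.null(block$extra_terms)) {
      terms <- c(terms, unlist(block$extra_terms))
    }
    specs[[var]] <- variable_spec(
      name = var, terms = terms,
      viable_range = pick(block, "viable_range", base$viable_range),
      formats = unlist(pick(block, "formats", base$formats)),
      condition_policy = pick(block, "condition_policy",
                              base$condition_policy),
      unit = pick(block, "unit", base$unit),
      group_eligible = pick(block, "group_eligible", base$group_eligible),
      viable_range2 = pick(block, "viable_range2", base$viable_range2),
      decimal_norm = pick(block, "decimal_norm", base$decimal_norm))
  }
  warn_shared_terms(specs)
  specs
}

pick <- function(block, field, default) {
  if (!is.null(block[[field]])) block[[field]] else default
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- tryCatch({
    if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }, error = function(e) {
    stop("malformed config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  cfg
}

warn_shared_terms <- function(specs) {
  all_terms <- unlist(lapply(specs, `[[`, "terms"), use.names = FALSE)
  owners <- rep(names(specs), vapply(specs, function(s) length(s$terms), 1L))
  dup <- unique(all_terms[duplicated(all_terms)])
  for (tm in dup) {
    warning("term '", tm, "' is shared by variables: ",
            paste(unique(owners[all_terms == tm]), collapse = ", "),
            "; both kept, range checks disambiguate", call. = FALSE)
  }
  invisible(specs)
}

#' Build a token prefix tree over all dictionary terms
#'
#' Multi-word terms are stored as token sequences; matching walks the tree
#' over whole tokens, so a term can never match inside a longer word
#' (\code{"team"} never matches \code{"te"}).
#'
#' @param specs Named list of \code{variable_spec} objects.
#' @return Object of class \code{term_lexicon}.
#' @export
build_lexicon <- function(specs) {
  stopifnot(length(specs) >= 1L)
  root <- new_trie_node()
  n_terms <- 0L
  for (spec in specs) {
    for (tm in spec$terms) {
      toks <- strsplit(tm, " ", fixed = TRUE)[[1]]
      trie_insert(root, toks, spec$name, tm)
      n_terms <- n_terms + 1L
    }
  }
  structure(list(root = root, n_terms = n_terms,
                 variables = names(specs)),
            class = "term_lexicon")
}

new_trie_node <- function() {
  node <- new.env(parent = emptyenv())
  node$children <- new.env(parent = emptyenv())
  node$terminal <- list()
  node
}

trie_insert <- function(node, tokens, variable, term) {
  for (tok in tokens) {
    child <- get0(tok, envir = node$children, inherits = FALSE)
    if (is.null(child)) {
      child <- new_trie_node()
      assign(tok, child, envir = node$children)
    }
    node <- child
  }
  node$terminal[[length(node$terminal) + 1L]] <-
    list(variable = variable, term = term)
  invisible(node)
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat("<term_lexicon>", x$n_terms, "terms across",
      length(x$variables), "variables\n")
  invisible(x)
}

#' Match dictionary terms in a token sequence
#'
#' Longest match wins at each position; matches within a sentence are
#' non-overlapping (after a match of k tokens, scanning resumes past it).
#' Matching is exact on whole tokens.  A term shared by several variables
#' yields one hit per variable over the same span.
#'
#' @param tokens Token data frame for one sentence (or a whole note; the
#'   \code{sentence} column scopes matching).
#' @param lexicon A \code{term_lexicon} from [build_lexicon()].
#' @return Data frame with columns \code{variable}, \code{term},
#'   \code{first}, \code{last} (row indices into \code{tokens}),
#'   \code{start}, \code{end} (raw-text offsets), \code{sentence}.
#' @export
match_terms <- function(tokens, lexicon) {
  empty <- data.frame(variable = character(0), term = character(0),
                      first = integer(0), last = integer(0),
                      start = integer(0), end = integer(0),
                      sentence = integer(0), stringsAsFactors = FALSE)
  if (!nrow(tokens)) return(empty)
  out <- list()
  for (sent in unique(tokens$sentence)) {
    idx <- which(tokens$sentence == sent)
    i <- 1L
    while (i <= length(idx)) {
      node <- lexicon$root
      best_len <- 0L
      best_terminal <- NULL
      j <- i
      while (j <= length(idx)) {
        child <- get0(tokens$surface[idx[j]], envir = node$children,
                      inherits = FALSE)
        if (is.null(child)) break
        node <- child
        if (length(node$terminal)) {
          best_len <- j - i + 1L
          best_terminal <- node$terminal
        }
        j <- j + 1L
      }
      if (best_len > 0L) {
        for (hit in best_terminal) {
          out[[length(out) + 1L]] <- data.frame(
            variable = hit$variable, term = hit$term,
            first = idx[i], last = idx[i + best_len - 1L],
            start = tokens$start[idx[i]],
            end = tokens$end[idx[i + best_len - 1L]],
            sentence = as.integer(sent), stringsAsFactors = FALSE)
        }
        i <- i + best_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
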