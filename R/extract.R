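# Candidate extraction: term-adjacent values/ranges (category 1) and
# unlabeled vital-sign number groups (category 2).

#' Extraction configuration
#'
#' @param window Adjacency window: how many tokens on either side of a
#'   matched term are searched for a value (default 5).
#' @param group_min Minimum run length for a number group (default 3).
#' @param group_rules Number-group filter parameters: \code{max_fraction},
#'   \code{max_percent} and \code{max_decimal} cap the slash-, percent- and
#'   decimal-pointed tokens per group; \code{int_max} is the exclusive upper
#'   bound for plain integers; plain decimals must lie strictly between
#'   \code{dec_low} and \code{dec_high} (the electronic-thermometer band).
#' @param stopwords Stop-word vector applied during preprocessing, or
#'   \code{NULL} to disable filtering.
#' @return List of class \code{extract_config}.
#' @export
extract_config <- function(window = 5L, group_min = 3L,
                           group_rules = list(max_fraction = 1L,
                                              max_percent = 1L,
                                              max_decimal = 2L,
                                              int_max = 300,
                                              dec_low = 93,
                                              dec_high = 110),
                           stopwords = default_stopwords()) {
  structure(list(window = as.integer(window),
                 group_min = as.integer(group_min),
                 group_rules = group_rules, stopwords = stopwords),
            class = "extract_config")
}

#' Condition vocabulary
#'
#' Words and symbols that signal a bound rather than a measurement when they
#' sit between a term and its value ("fever > 100.4", "ef higher than 55").
#' These are protected from stop-word removal.
#'
#' @return Character vector.
#' @export
condition_vocabulary <- function() {
  c("<", ">", "less", "greater", "higher", "lower", "than",
    "at", "least", "most")
}

# canonical condition label for the token run (from, to) exclusive of both
scan_condition <- function(surfaces) {
  i <- 1L
  while (i <= length(surfaces)) {
    s <- surfaces[i]
    nxt <- if (i < length(surfaces)) surfaces[i + 1L] else ""
    if (s == "<") return("<")
    if (s == ">") return(">")
    if (s %in% c("less", "greater", "higher", "lower")) {
      return(paste0(s, "_than"))
    }
    if (s == "at" && nxt %in% c("least", "most")) {
      return(paste0("at_", nxt))
    }
    if (s %in% c("least", "most")) return(paste0("at_", s))
    i <- i + 1L
  }
  "none"
}

#' Parse one token surface as a numeric token
#'
#' Recognized shapes: integer \code{"98"}, decimal \code{"97.0"}, percent
#' \code{"98\%"}, fraction \code{"100/66"} (blood pressure), range
#' \code{"10-15"} / \code{"35-55\%"}.  Anything else (including an inverted
#' range) returns \code{NULL}.
#'
#' @param surface Token string.
#' @return List with \code{value_low}, \code{value_high}, \code{is_fraction},
#'   \code{numerator}, \code{denominator}, \code{has_decimal},
#'   \code{has_percent}, \code{is_range}; or \code{NULL}.
#' @export
parse_numeric <- function(surface) {
  num <- "\\d+(?:\\.\\d+)?"
  mk <- function(lo, hi, fraction = FALSE, nume = NA_real_, den = NA_real_,
                 pct = FALSE, rng = FALSE) {
    list(value_low = lo, value_high = hi, is_fraction = fraction,
         numerator = nume, denominator = den,
         has_decimal = grepl(".", surface, fixed = TRUE),
         has_percent = pct, is_range = rng)
  }
  if (grepl(paste0("^(", num, ")/(", num, ")$"), surface)) {
    parts <- as.numeric(strsplit(surface, "/", fixed = TRUE)[[1]])
    return(mk(parts[1], parts[2], fraction = TRUE,
              nume = parts[1], den = parts[2]))
  }
  m <- regmatches(surface,
                  regexec(paste0("^(", num, ")-(", num, ")(%?)$"), surface))[[1]]
  if (length(m)) {
    lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
    if (lo > hi) return(NULL)
    return(mk(lo, hi, pct = m[4] == "%", rng = TRUE))
  }
  if (grepl(paste0("^", num, "%$"), surface)) {
    v <- as.numeric(sub("%$", "", surface))
    return(mk(v, v, pct = TRUE))
  }
  if (grepl(paste0("^", num, "$"), surface)) {
    v <- as.numeric(surface)
    return(mk(v, v))
  }
  NULL
}

# value shape label used against spec$formats
numeric_format <- function(nt) {
  if (nt$is_fraction) "fraction"
  else if (nt$is_range) "range"
  else if (nt$has_percent) "percent"
  else if (nt$has_decimal) "decimal"
  else "integer"
}

format_allowed <- function(nt, spec) numeric_format(nt) %in% spec$formats

# Parse all tokens once; returns a list parallel to tokens rows (NULL for
# non-numeric tokens).
parse_tokens <- function(tokens) {
  lapply(tokens$surface, parse_numeric)
}

empty_candidates <- function() {
  data.frame(variable = character(0), value_low = numeric(0),
             value_high = numeric(0), is_fraction = logical(0),
             is_range = logical(0), has_decimal = logical(0),
             has_percent = logical(0), source = character(0),
             term = character(0), condition = character(0),
             start = integer(0), end = integer(0), sentence = integer(0),
             token_index = integer(0), token_hi = integer(0),
             next_surface = character(0), stringsAsFactors = FALSE)
}

candidate_row <- function(variable, nt, source, term, condition,
                          start, end, sentence, token_index,
                          token_hi = token_index) {
  data.frame(variable = variable, value_low = nt$value_low,
             value_high = nt$value_high, is_fraction = nt$is_fraction,
             is_range = nt$is_range, has_decimal = nt$has_decimal,
             has_percent = nt$has_percent, source = source,
             term = if (is.null(term)) NA_character_ else term,
             condition = condition, start = as.integer(start),
             end = as.integer(end), sentence = as.integer(sentence),
             token_index = as.integer(token_index),
             token_hi = as.integer(token_hi),
             next_surface = NA_character_,
             stringsAsFactors = FALSE)
}

# Try to widen the numeric token at position p into a range using
# neighboring "-"/"to" separators ("10 - 15", "10 to 15"), and fold a
# trailing "%"/"percent" token.  Returns list(nt, lo, hi) of token rows
# consumed.
expand_value <- function(tokens, parsed, p) {
  idx <- tokens$sentence == tokens$sentence[p]
  nt <- parsed[[p]]
  lo_row <- p
  hi_row <- p
  if (!nt$is_fraction && !nt$is_range) {
    # forward range: p (-|to) q
    if (p + 2L <= nrow(tokens) && idx[p + 2L] &&
        tokens$surface[p + 1L] %in% c("-", "to") &&
        !is.null(parsed[[p + 2L]]) && !parsed[[p + 2L]]$is_fraction &&
        !parsed[[p + 2L]]$is_range &&
        nt$value_low <= parsed[[p + 2L]]$value_low) {
      q <- parsed[[p + 2L]]
      nt <- list(value_low = nt$value_low, value_high = q$value_low,
                 is_fraction = FALSE, numerator = NA_real_,
                 denominator = NA_real_,
                 has_decimal = nt$has_decimal || q$has_decimal,
                 has_percent = nt$has_percent || q$has_percent,
                 is_range = TRUE)
      hi_row <- p + 2L
    }
  }
  # fold trailing percent token
  if (hi_row + 1L <= nrow(tokens) &&
      tokens$sentence[hi_row + 1L] == tokens$sentence[p] &&
      tokens$surface[hi_row + 1L] %in% c("%", "percent")) {
    nt$has_percent <- TRUE
    hi_row <- hi_row + 1L
  }
  list(nt = nt, lo_row = lo_row, hi_row = hi_row)
}

# Scan one direction from a term hit for the nearest allowed-format value.
# Tokens belonging to other term hits stop the scan; non-numeric tokens are
# skipped (condition words recorded); format-mismatched numerics are skipped.
scan_direction <- function(tokens, parsed, hit, spec, window, claimed,
                           term_token, forward) {
  if (forward) {
    from <- hit$last + 1L
    to <- min(hit$last + window, nrow(tokens))
    if (from > to) return(NULL)
    rng <- from:to
  } else {
    from <- hit$first - 1L
    to <- max(hit$first - window, 1L)
    if (from < to || from < 1L) return(NULL)
    rng <- from:to
  }
  for (p in rng) {
    if (tokens$sentence[p] != hit$sentence) break
    if (term_token[p]) break
    nt <- parsed[[p]]
    if (is.null(nt)) next
    if (claimed[p]) break
    ev <- expand_value(tokens, parsed, p)
    if (!format_allowed(ev$nt, spec)) next
    between <- if (forward) {
      seq_len(max(0L, p - hit$last - 1L)) + hit$last
    } else {
      seq_len(max(0L, hit$first - ev$hi_row - 1L)) + ev$hi_row
    }
    cond <- scan_condition(tokens$surface[between])
    return(list(nt = ev$nt, lo_row = ev$lo_row, hi_row = ev$hi_row,
                condition = cond,
                distance = if (forward) p - hit$last else hit$first - p,
                forward = forward))
  }
  NULL
}

#' Extract the value adjacent to one term hit
#'
#' Searches forward from the term within the adjacency window, then
#' backward, for the nearest numeric token whose shape is allowed for the
#' variable.  Inequality words or symbols between term and value are
#' recorded as the candidate's condition, never consumed as the value; a
#' trailing \code{"percent"}/\code{"\%"} token is folded into the value.
#'
#' @param tokens Token data frame for the note.
#' @param parsed List of parsed numeric tokens (from \code{parse_numeric}),
#'   parallel to \code{tokens}.
#' @param hit One row of [match_terms()] output (as a list or 1-row frame).
#' @param spec The \code{variable_spec} for the hit's variable.
#' @param window Adjacency window in tokens.
#' @param claimed Logical vector marking tokens already consumed.
#' @param term_token Logical vector marking tokens inside any term hit.
#' @return A scan result (internal structure) or \code{NULL} when no value
#'   is found in the window.
#' @export
extract_term_adjacent <- function(tokens, parsed, hit, spec,
                                  window = 5L,
                                  claimed = rep(FALSE, nrow(tokens)),
                                  term_token = rep(FALSE, nrow(tokens))) {
  fwd <- scan_direction(tokens, parsed, hit, spec, window, claimed,
                        term_token, forward = TRUE)
  if (!is.null(fwd)) return(fwd)
  scan_direction(tokens, parsed, hit, spec, window, claimed, term_token,
                 forward = FALSE)
}

#' Find unlabeled number groups
#'
#' Maximal runs of at least \code{group_min} consecutive numeric tokens in
#' one sentence, containing no dictionary-term token and no token already
#' claimed by term-adjacent extraction.
#'
#' @inheritParams extract_term_adjacent
#' @param group_min Minimum run length (default 3).
#' @return List of integer vectors (token row indices), possibly empty.
#' @export
find_number_groups <- function(tokens, parsed,
                               claimed = rep(FALSE, nrow(tokens)),
                               term_token = rep(FALSE, nrow(tokens)),
                               group_min = 3L) {
  if (!nrow(tokens)) return(list())
  numeric_ok <- !vapply(parsed, is.null, logical(1))
  eligible <- numeric_ok & !claimed & !term_token
  groups <- list()
  i <- 1L
  n <- nrow(tokens)
  while (i <= n) {
    if (!eligible[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && eligible[j + 1L] &&
           tokens$sentence[j + 1L] == tokens$sentence[i]) {
      j <- j + 1L
    }
    if (j - i + 1L >= group_min) {
      groups[[length(groups) + 1L]] <- i:j
    }
    i <- j + 1L
  }
  groups
}

#' Decide whether a number group is a vital-sign panel
#'
#' A group passes iff (1) every token consists only of digits and the
#' characters \code{". / \%"}; (2) it has at most one fraction token, one
#' percent token, and two decimal-pointed tokens; (3) every plain integer is
#' below 300; (4) every plain decimal lies strictly inside the
#' thermometer band (93, 110).  Rule 4's published phrasing is a vacuous
#' disjunction; the conjunction is implemented and configurable.
#'
#' @param surfaces Character vector of the group's token surfaces.
#' @param parsed Parsed numeric tokens for the group (same length).
#' @param rules Rule parameters (see [extract_config()]).
#' @return Logical scalar.
#' @export
is_vital_group <- function(surfaces, parsed,
                           rules = extract_config()$group_rules) {
  # rule 1: only digits and . / % (no range hyphens)
  if (!all(grepl("^[0-9./%]+$", surfaces))) return(FALSE)
  frac <- vapply(parsed, function(p) p$is_fraction, logical(1))
  pct <- vapply(parsed, function(p) p$has_percent, logical(1))
  dec <- grepl(".", surfaces, fixed = TRUE)
  if (sum(frac) > rules$max_fraction) return(FALSE)
  if (sum(pct) > rules$max_percent) return(FALSE)
  if (sum(dec) > rules$max_decimal) return(FALSE)
  plain_int <- !frac & !pct & !dec
  ints <- vapply(parsed[plain_int], function(p) p$value_low, numeric(1))
  if (any(ints >= rules$int_max)) return(FALSE)
  plain_dec <- dec & !frac & !pct
  decs <- vapply(parsed[plain_dec], function(p) p$value_low, numeric(1))
  if (any(decs <= rules$dec_low | decs >= rules$dec_high)) return(FALSE)
  TRUE
}

#' Assign a vital-sign group's tokens to variables
#'
#' One left-to-right pass assigns signature-bearing tokens: a plain decimal
#' in the thermometer band to temperature, a fraction with components in
#' the systolic/diastolic ranges to blood pressure, a percent token in the
#' saturation range to oxygen saturation.  Remaining plain integers then
#' fill, in positional order, the first still-unfilled variable among heart
#' rate, respiratory rate, oxygen saturation whose viable range contains
#' them (the canonical T-BP-HR-RR-O2Sat panel order).  Each variable is
#' filled at most once; tokens matching nothing stay unassigned.
#'
#' @param tokens Token data frame for the note.
#' @param parsed Parsed numeric tokens parallel to \code{tokens}.
#' @param group Integer vector of token row indices (a group from
#'   [find_number_groups()]).
#' @param specs Variable specifications.
#' @param rules Group rule parameters.
#' @return Candidate data frame (source \code{"number_group"}).
#' @export
assign_group <- function(tokens, parsed, group, specs,
                         rules = extract_config()$group_rules) {
  filled <- character(0)
  out <- empty_candidates()
  add <- function(var, nt, p) {
    candidate_row(var, nt, "number_group", NULL, "none",
                  tokens$start[p], tokens$end[p], tokens$sentence[p], p)
  }
  deferred <- integer(0)
  for (p in group) {
    nt <- parsed[[p]]
    surf <- tokens$surface[p]
    is_dec <- grepl(".", surf, fixed = TRUE) && !nt$is_fraction &&
      !nt$has_percent
    if (is_dec && !is.null(specs$temperature) &&
        !("temperature" %in% filled) &&
        nt$value_low > rules$dec_low && nt$value_low < rules$dec_high) {
      out <- rbind(out, add("temperature", nt, p))
      filled <- c(filled, "temperature")
    } else if (nt$is_fraction && !is.null(specs$blood_pressure) &&
               !("blood_pressure" %in% filled) &&
               in_range(nt$numerator, specs$blood_pressure$viable_range) &&
               in_range(nt$denominator, specs$blood_pressure$viable_range2)) {
      out <- rbind(out, add("blood_pressure", nt, p))
      filled <- c(filled, "blood_pressure")
    } else if (nt$has_percent && !is.null(specs$o2_saturation) &&
               !("o2_saturation" %in% filled) &&
               in_range(nt$value_low, specs$o2_saturation$viable_range)) {
      out <- rbind(out, add("o2_saturation", nt, p))
      filled <- c(filled, "o2_saturation")
    } else if (!nt$is_fraction && !nt$has_percent && !nt$has_decimal &&
               !nt$is_range) {
      deferred <- c(deferred, p)
    }
  }
  for (p in deferred) {
    v <- parsed[[p]]$value_low
    for (var in c("heart_rate", "respiratory_rate", "o2_saturation")) {
      if (var %in% filled) next
      if (!is.null(specs[[var]]) && specs[[var]]$group_eligible &&
          in_range(v, specs[[var]]$viable_range)) {
        out <- rbind(out, add(var, parsed[[p]], p))
        filled <- c(filled, var)
        break
      }
    }
  }
  if (nrow(out)) out <- out[order(out$token_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

in_range <- function(v, rng) {
  !is.na(v) && v >= rng[1] && v <= rng[2]
}

#' Extract all candidates from one note
#'
#' Orchestrates preprocessing, term matching, term-adjacent extraction with
#' deterministic claim resolution (nearest term wins a contested value;
#' exact tie goes to the preceding term), number-group detection and
#' assignment.  Tokens consumed by a term-adjacent candidate never enter a
#' group; duplicate candidates for the same variable, value and overlapping
#' span keep the term-adjacent one.
#'
#' @param text Raw note text.
#' @param lexicon A \code{term_lexicon}; built from \code{specs} when
#'   \code{NULL}.
#' @param specs Variable specifications (default [default_specs()]).
#' @param config An [extract_config()].
#' @return Candidate data frame; pass to [finalize()] for validity testing.
#' @export
extract_note <- function(text, lexicon = NULL, specs = default_specs(),
                         config = extract_config()) {
  if (is.null(lexicon)) lexicon <- build_lexicon(specs)
  prep <- tokenize_note(text, specs, config$stopwords)
  tokens <- prep$tokens
  if (!nrow(tokens)) return(empty_candidates())
  parsed <- parse_tokens(tokens)
  hits <- match_terms(tokens, lexicon)
  term_token <- rep(FALSE, nrow(tokens))
  for (h in seq_len(nrow(hits))) {
    term_token[hits$first[h]:hits$last[h]] <- TRUE
  }
  claimed <- rep(FALSE, nrow(tokens))
  cands <- empty_candidates()

  # --- category 1: term-adjacent, with claim resolution -------------------
  if (nrow(hits)) {
    pending <- seq_len(nrow(hits))
    guard <- 0L
    while (length(pending) && guard <= nrow(hits) + 1L) {
      guard <- guard + 1L
      found <- list()
      for (h in pending) {
        spec <- specs[[hits$variable[h]]]
        if (is.null(spec)) next
        res <- extract_term_adjacent(tokens, parsed, hits[h, ], spec,
                                     config$window, claimed, term_token)
        if (!is.null(res)) found[[as.character(h)]] <- res
      }
      if (!length(found)) break
      # group contenders by first value-token row
      key <- vapply(found, function(r) r$lo_row, numeric(1))
      resolved <- integer(0)
      for (tok_row in unique(key)) {
        contenders <- as.integer(names(found)[key == tok_row])
        spans <- paste(hits$first[contenders], hits$last[contenders])
        if (length(unique(spans)) > 1L) {
          # distinct terms compete for one value: nearest wins, exact tie
          # goes to the term the value follows; shared-term hits (identical
          # span, several variables) are kept together
          dist <- vapply(as.character(contenders),
                         function(h) found[[h]]$distance, numeric(1))
          fwd <- vapply(as.character(contenders),
                        function(h) found[[h]]$forward, logical(1))
          winner_span <- spans[order(dist, !fwd)][1]
          contenders <- contenders[spans == winner_span]
        }
        win_res <- found[[as.character(contenders[1])]]
        for (h in contenders) {
          res <- found[[as.character(h)]]
          cands <- rbind(cands, candidate_row(
            hits$variable[h], res$nt, "term_adjacent", hits$term[h],
            res$condition, tokens$start[res$lo_row],
            tokens$end[res$hi_row], hits$sentence[h], res$lo_row,
            res$hi_row))
          resolved <- c(resolved, h)
        }
        claimed[win_res$lo_row:win_res$hi_row] <- TRUE
      }
      losers <- setdiff(as.integer(names(found)), resolved)
      pending <- losers
      if (!length(losers)) break
    }
  }

  # --- category 2: number groups -----------------------------------------
  groups <- find_number_groups(tokens, parsed, claimed, term_token,
                               config$group_min)
  for (g in groups) {
    if (is_vital_group(tokens$surface[g], parsed[g], config$group_rules)) {
      gc_rows <- assign_group(tokens, parsed, g, specs, config$group_rules)
      cands <- rbind(cands, gc_rows)
    }
  }

  # dedupe: same variable + same values + overlapping span, prefer
  # term_adjacent
  if (nrow(cands) > 1L) {
    pref <- order(cands$source != "term_adjacent")
    cands <- cands[pref, , drop = FALSE]
    keep <- rep(TRUE, nrow(cands))
    for (i in seq_len(nrow(cands))) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        if (cands$variable[i] == cands$variable[j] &&
            identical(cands$value_low[i], cands$value_low[j]) &&
            identical(cands$value_high[i], cands$value_high[j]) &&
            cands$start[i] < cands$end[j] && cands$start[j] < cands$end[i]) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cands <- cands[keep, , drop = FALSE]
  }
  # surface of the token following each candidate (same sentence), used by
  # unit inference downstream
  if (nrow(cands)) {
    nxt <- cands$token_hi + 1L
    ok <- nxt <= nrow(tokens) & tokens$sentence[pmin(nxt, nrow(tokens))] ==
      cands$sentence
    cands$next_surface[ok] <- tokens$surface[nxt[ok]]
  }
  cands <- cands[order(cands$start), , drop = FALSE]
  rownames(cands) <- NULL
  cands
}
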