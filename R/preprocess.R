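# Text normalization, sentence splitting, tokenization, stop-word filtering.
#
# Normalization is deliberately length-preserving: every removed punctuation
# character is replaced by exactly one space, and case folding / dash folding
# map one character to one character.  As a consequence the offset map from
# normalized text back to the raw note is the identity, and every token can
# carry raw-text offsets directly.

# Characters that carry numeric meaning and must survive normalization.
.KEEP_CHARS <- c(".", "/", "%", "-", "<", ">", ":", "!", "?")

#' Normalize raw note text
#'
#' Lowercases the text, folds Unicode dash variants to \code{"-"} and
#' less/greater-or-equal signs to \code{"<"}/\code{">"}, and replaces
#' grammatical punctuation (commas, semicolons, quotes, parentheses, and any
#' other character that is not a letter, digit, whitespace or one of
#' \code{. / \% - < > : ! ?}) with a single space.  The transformation is
#' length-preserving, so character offsets into the normalized string are
#' valid offsets into the raw text.
#'
#' @param text Character scalar; raw note text (may be empty).
#' @return Normalized character scalar of the same length as \code{text}.
#' @examples
#' normalize_text("Fever, 101.2")   # "fever  101.2"
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return("")
  x <- tolower(enc2utf8(text))
  # dash and inequality variants (one char -> one char; fixed gsub rather
  # than chartr so multibyte input survives a C locale)
  for (dash in c("\u2013", "\u2014", "\u2212")) {
    x <- gsub(dash, "-", x, fixed = TRUE)
  }
  x <- gsub("\u2264", "<", x, fixed = TRUE)
  x <- gsub("\u2265", ">", x, fixed = TRUE)
  # every char not alnum/space/keep-set becomes a single space
  x <- gsub("[^a-z0-9\\s./%<>:!?-]", " ", x, perl = TRUE)
  # normalize exotic whitespace to plain space, keep \n for sentence breaks
  x <- gsub("[^\\S\n]", " ", x, perl = TRUE)
  x
}

#' Split normalized text into sentences
#'
#' Sentence terminators are newline, \code{"!"}, \code{"?"}, and \code{"."}
#' when the period is neither flanked by digits on both sides (so clinical
#' decimals such as \code{"101.2"} are never split) nor followed by a digit
#' as the next non-space character (so abbreviation periods in constructions
#' like \code{"resp. 18"} do not separate a term from its value).
#'
#' @param normalized Character scalar produced by [normalize_text()].
#' @return Data frame with columns \code{start}, \code{end} (0-based,
#'   half-open character offsets) and \code{text}, one row per non-blank
#'   sentence.
#' @export
split_sentences <- function(normalized) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (!nzchar(normalized)) return(empty)
  chars <- strsplit(normalized, "", fixed = TRUE)[[1]]
  n <- length(chars)
  digit <- chars >= "0" & chars <= "9"
  prev_digit <- c(FALSE, digit[-n])
  next_digit <- c(digit[-1], FALSE)
  is_term <- chars %in% c("\n", "!", "?")
  for (i in which(chars == ".")) {
    if (i > 1L && i < n && digit[i - 1L] && digit[i + 1L]) next  # decimal
    j <- i + 1L
    while (j <= n && chars[j] == " ") j <- j + 1L
    if (j <= n && digit[j]) next  # "resp. 18": keep term and value together
    is_term[i] <- TRUE
  }
  bounds <- c(0L, which(is_term), n)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]            # 0-based start (char after previous terminator)
    e <- bounds[i + 1L]
    if (is_term[min(e, n)] && e <= n) e2 <- e - 1L else e2 <- e
    if (e2 <= s) next
    txt <- substr(normalized, s + 1L, e2)
    if (!grepl("[^\\s]", txt, perl = TRUE)) next
    # trim to non-whitespace extent so offsets are tight
    m <- regexpr("[^\\s]", txt, perl = TRUE)
    lead <- as.integer(m) - 1L
    trail <- nchar(txt) - {
      rev_m <- regexpr("[^\\s]\\s*$", txt, perl = TRUE)
      as.integer(rev_m)
    }
    s2 <- s + lead
    e3 <- e2 - trail
    out[[length(out) + 1L]] <- data.frame(
      start = s2, end = e3,
      text = substr(normalized, s2 + 1L, e3),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Tokenize one sentence
#'
#' Tokens are maximal runs of non-separator characters; whitespace and
#' \code{":"} separate tokens, and \code{"<"} / \code{">"} are emitted as
#' single-character tokens of their own.  Numeric composites such as
#' \code{"100/66"}, \code{"98\%"}, \code{"97.0"} and \code{"10-15\%"} survive
#' as single tokens.
#'
#' @param sentence_text Sentence string (one row of [split_sentences()]).
#' @param sentence_start 0-based offset of the sentence in the note.
#' @param sentence_index 0-based ordinal of the sentence.
#' @return Data frame with columns \code{surface}, \code{start}, \code{end}
#'   (0-based half-open raw-text offsets), \code{sentence}.
#' @export
tokenize_sentence <- function(sentence_text, sentence_start = 0L,
                              sentence_index = 0L) {
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), sentence = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(sentence_text)) return(empty)
  m <- gregexpr("[<>]|[^\\s:<>]+", sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surf <- substring(sentence_text, starts, starts + lens - 1L)
  # strip trailing bare periods left by mid-sentence abbreviations ("resp.")
  trail <- grepl("\\.$", surf) & !grepl("^[0-9.]+$", surf)
  surf[trail] <- sub("\\.+$", "", surf[trail])
  lens[trail] <- nchar(surf[trail])
  keep <- nzchar(surf)
  data.frame(surface = surf[keep],
             start = sentence_start + starts[keep] - 1L,
             end = sentence_start + starts[keep] - 1L + lens[keep],
             sentence = rep(as.integer(sentence_index), sum(keep)),
             stringsAsFactors = FALSE)
}

#' Remove stop words while protecting dictionary terms
#'
#' A token is dropped when its surface is in \code{stopwords} and not in
#' \code{protected}; offsets of surviving tokens are unchanged.  Single-letter
#' clinical abbreviations such as \code{"t"} (temperature) are typical
#' protected terms that overlap common stop-word lists.
#'
#' @param tokens Token data frame from [tokenize_sentence()].
#' @param stopwords Character vector of stop words (lowercase).
#' @param protected Character vector of terms that must never be removed.
#' @return Filtered token data frame.
#' @export
filter_stopwords <- function(tokens, stopwords, protected = character(0)) {
  if (!nrow(tokens)) return(tokens)
  drop <- tokens$surface %in% stopwords & !(tokens$surface %in% protected)
  out <- tokens[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default English stop-word list
#'
#' Returns the stop-word list shipped with the package (a standard English
#' list stored as a plain-text file, one word per line).
#'
#' @param path Optional path to an alternative stop-word file.
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "vitalex")
  }
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- tolower(trimws(words))
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Full preprocessing of one note
#'
#' Normalizes, splits into sentences, tokenizes, and (optionally) filters
#' stop words, protecting all dictionary terms of the active variable
#' specifications.
#'
#' @param text Raw note text.
#' @param specs Variable specifications (see [default_specs()]); used to
#'   build the protected-term set.
#' @param stopwords Stop-word vector, or \code{NULL} to skip filtering.
#' @return List with elements \code{normalized} (string), \code{sentences}
#'   (data frame), \code{tokens} (data frame).
#' @export
tokenize_note <- function(text, specs = default_specs(),
                          stopwords = default_stopwords()) {
  norm <- normalize_text(text)
  sents <- split_sentences(norm)
  toks <- list()
  for (i in seq_len(nrow(sents))) {
    toks[[i]] <- tokenize_sentence(sents$text[i], sents$start[i], i - 1L)
  }
  tokens <- if (length(toks)) do.call(rbind, toks) else tokenize_sentence("")
  if (!is.null(stopwords) && nrow(tokens)) {
    # protect dictionary terms plus condition/range connective words, whose
    # removal would silently change extraction semantics
    protected <- c(protected_terms(specs), condition_vocabulary(),
                   "to", "percent")
    tokens <- filter_stopwords(tokens, stopwords, protected)
  }
  list(normalized = norm, sentences = sents, tokens = tokens)
}

#' Protected-term set for stop-word filtering
#'
#' Union of all term strings across the given variable specifications, plus
#' the individual words of multi-word terms (so that filtering can never
#' break a multi-word dictionary term).
#'
#' @param specs Variable specification list.
#' @return Character vector.
#' @export
protected_terms <- function(specs) {
  terms <- unlist(lapply(specs, function(s) s$terms), use.names = FALSE)
  unique(c(terms, unlist(strsplit(terms, " ", fixed = TRUE))))
}
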