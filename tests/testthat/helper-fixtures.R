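# Shared fixtures and small assertion helpers; everything is built in code.

SPECS <- default_specs()
LEX <- build_lexicon(SPECS)

# extraction shorthand returning only the annotation frame
xv <- function(text, ...) extract_values(text, specs = SPECS, ...)

# pull the (value_low, value_high) pair for one variable out of an
# annotation frame; errors if not exactly one row
one_value <- function(ann, variable) {
  rows <- ann[ann$variable == variable, , drop = FALSE]
  stopifnot(nrow(rows) == 1L)
  c(rows$value_low, rows$value_high)
}

# tokens of a one-sentence string, without stop-word filtering
toks <- function(text) {
  tokenize_note(text, SPECS, stopwords = NULL)$tokens
}

expect_annotation <- function(ann, variable, lo, hi = lo) {
  v <- one_value(ann, variable)
  expect_equal(unname(v[1]), lo)
  expect_equal(unname(v[2]), hi)
}
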