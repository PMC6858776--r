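---
title: "Rule-based extraction of numerical clinical values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction of numerical clinical values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalex)
```

## The model

`vitalex` treats numerical clinical data extraction as a cascade of
deterministic, inspectable rules rather than a learning problem.  The
underlying assumption is that clinicians document numbers in a small set
of surface conventions:

- a **labeled pair** — a term (often an abbreviation) with the value
  right next to it: `bp 132/78`, `fever, 101.2`,
  `ejection fraction of 10-15 percent`;
- an **unlabeled panel** — a run of numbers whose *formats* identify the
  variables: `97.0 100/66 98 18 98%` can only plausibly be
  temperature, blood pressure, heart rate, respiratory rate and oxygen
  saturation, in that canonical order.

Everything else in a note is, for this task, noise — including numeric
noise such as flattened lab tables and threshold statements
(`fever > 100.4`), which the rules are designed to *exclude*.

The pipeline has four stages: normalization/tokenization, dictionary
matching over a token prefix tree, candidate extraction (two categories),
and per-variable validity testing.  Each stage is exposed as ordinary
functions so every decision can be replayed on a single sentence.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| adjacency window | 5 | tokens | how far a value may sit from its term; the source conventions say only "close", 5 keeps `ejection fraction of 10-15` reachable while bounding false pairings |
| group minimum | 3 | numeric tokens | unlabeled panels "typically consist of three or more" values; runs of 1–2 are always term-adjacent material |
| thermometer band | (93, 110) | °F | plain decimals in a panel are temperatures only inside the viable range of clinical electronic thermometers |
| integer cap (groups) | 300 | – | any plain integer ≥ 300 marks the run as non-vital (lab pseudo-table, identifiers) |
| per-group caps | 1 fraction, 1 percent, 2 decimals | tokens | a genuine vital panel has at most one BP, one saturation, and (rarely) two decimal values |
| viable ranges | per variable | native units | temperature 93–110 °F, EF 1–100 % (or ≤ 1.0 decimal), HbA1C < 30 %, creatinine < 50; HR 20–300, RR 4–60, SBP 40–300, DBP 20–200, O₂Sat 50–100 are package defaults where the source is silent, all user-overridable |
| bootstrap B | 1000 | replicates | percentile CIs over notes resampled with replacement |

All ranges, formats, term lists and condition policies live in
`variable_spec` objects (`default_specs()`, overridable through
`load_specs()` with a YAML/JSON file), because the viable range is meant
to be *specified by the user* for any new variable.

## Design choices where the design was open

**Punctuation replacement, not deletion.**  Normalization replaces every
removed character with a single space.  This makes the transformation
length-preserving, so the offset map from tokens back into the raw note
is the identity — annotations can highlight source text — and it
prevents `fever,101.2` from fusing into one token.  Characters that are
load-bearing for numerics (`. / % - < > :`) survive; Unicode dashes are
folded to `-` since both `10-15` and `10–15%` occur in the wild.

**Sentence splitting guarded for clinical decimals.**  A period is a
sentence boundary only when it is neither inside `digit.digit` nor
followed by a digit as the next non-space character.  The second guard
keeps abbreviation periods (`resp. 18`) from separating a term from its
value.  The cost is that a genuine sentence boundary directly before a
number is missed; in clinical text that construction is far more often a
term–value link, and the adjacency window bounds the damage.

**Hyphenated ranges are single tokens.**  `10-15` and `35-55%`
tokenize whole; the numeric parser also reassembles `10 to 15` and
`10 - 15` from adjacent tokens.  Whether the original tool kept ranges
as one token is unknowable from its description; one convention had to
be fixed, and the parser owns it.

**Colon is a separator.**  `t: 100.4` is a labeled pair; the colon never
carries condition meaning.

**Stop-word protection.**  The shipped stop-word list is a standard
English list; any word that is also a dictionary term (`t`, `s`, `p`,
`r` ...) or a condition/connective word (`less`, `than`, `to` ...) is
protected from removal, otherwise filtering would silently change
extraction semantics.

**Group rule 4 as a conjunction.**  The published wording — decimals
"smaller than 110 or larger than 93" — is vacuous as a disjunction
(every number qualifies).  It is implemented as the conjunction
93 < v < 110, which matches the stated temperature viable range and the
evident intent of a plausible-oral-temperature filter.  The bounds are
configurable (`extract_config()$group_rules`), so a user who disagrees
can relax them.

**Positional assignment of panel integers.**  Signature-bearing tokens
are assigned in one left-to-right pass (decimal → T, fraction → BP,
percent → O₂Sat).  Remaining plain integers then fill the first
still-unfilled variable among HR, RR, O₂Sat whose viable range contains
them, in positional order.  This reproduces both stated hand-traces:
`98.6 120/80 72` → HR = 72 with no O₂Sat, and `80 18 99` →
HR = 80, RR = 18, O₂Sat = 99.  A "last integer in 50–100 becomes
O₂Sat" rule was considered and rejected because it contradicts the
first hand-trace.  The convention is documented, not discovered: a
panel written in a non-canonical order will be mis-assigned.

**Conflict resolution between terms.**  When two terms could claim the
same value token, the nearer term wins; on an exact tie the term the
value *follows* wins (forward direction).  A losing term rescans the
window excluding claimed tokens.  This is a determinism requirement, not
a claim about the original tool.

**Term-adjacent precedence over groups.**  A numeric token consumed by a
term-adjacent candidate never enters a number group, and duplicate
(variable, value, overlapping-span) candidates keep the term-adjacent
one.  Whether the original deduplicated this way is unstated; precedence
for the labeled reading is the conservative choice.

**Condition policy.**  The condition vocabulary is `<`, `>`, `≤`, `≥`,
`less/greater/higher/lower than`, `at least/most` — the published
examples plus conservative synonyms, configurable.  Vital signs reject
conditioned pairs; EF and HbA1C accept and record them, because
`EF > 55` is itself a clinically meaningful statement.  Creatinine is
set to reject: only EF and HbA1C are ever named as condition-accepting,
and silently extending the exception seemed worse than under-extracting
`creat < 1.5`.  This is a one-line config change for users who want it.

**Blood pressure carries two numbers.**  `132/87` is one measurement;
annotations store the systolic in `value_low` and the diastolic in
`value_high` with `is_fraction` provenance.  This deliberately bends the
`value_low ≤ value_high` convention for BP rows, in gold files too; the
readers enforce the ordering invariant for every other variable.

**EF decimal form.**  A decimal EF ≤ 1.0 (`lvef 0.55`) is rescaled
×100 before the range check, so percent- and decimal-form EF compare on
one scale.  Value matching in evaluation is exact equality after this
normalization; no tolerance is applied, since none is stated for the
underlying comparison.

**Evaluation precedence.**  At the note level a note containing both a
missed gold value and a spurious prediction counts as a false positive —
the stricter reading; the definitions do not cover the mixed case.
Note-level true positives require the exact value multiset by default;
a count-only mode (`match_counts = TRUE`) exists because "identified the
same number of values" is an equally defensible reading.

**Percentile bootstrap.**  Notes are resampled with replacement B = 1000
times and the 2.5/97.5 percentiles reported.  Nothing beyond
"bootstrap, 1000 resamples" is specified, so the simplest faithful
estimator (percentile, not BCa) is used.  Replicates where a metric is
undefined (e.g. no positives drawn) are dropped from that metric's
percentiles.  A fixed seed gives bit-identical intervals, and the
caller's RNG state is restored.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws each note from one of six templates: labeled
pairs (term sampled from the real dictionaries, value uniform over the
viable range shrunk by a 1-unit margin, optional colon separator and
unit token), grouped five-value panels that pass all four group rules by
construction, condition distractors (`term > value` for
condition-rejecting vitals, hence zero gold), lab pseudo-tables that
violate at least one group rule, term-only sentences, and term-free
sentences.  The default mix is 40/20/15/10/10/5 percent.  Values are
drawn uniformly so boundary behavior is tested separately and
explicitly, not probabilistically.

This emulates the *surface formats* of clinical documentation, not its
language: there is no misspelling, no section structure, no negation
beyond condition symbols, no cross-sentence coreference, and panels are
always written in canonical order.  A green closed-loop test therefore
establishes that the rules are internally consistent — that extraction
inverts the generator on clean templates and ignores distractors — and
nothing more.  In particular it does not reproduce, and cannot be
compared against, performance figures measured on real EMR corpora,
which are private; the evaluation *machinery* is in scope, those numbers
are not.

`plant_confusion()` sidesteps text entirely: it fabricates gold/predicted
pairs realizing an exact note-level confusion profile, so the scorer's
count recovery and the bootstrap's coverage can be tested against
arithmetic rather than against the extractor.

## Numerical and degenerate-input choices

- Empty notes, whitespace-only sentences, and empty corpora flow through
  every stage as empty frames, never errors.
- An inverted textual range (`15-10`) fails numeric parsing rather than
  silently swapping endpoints.
- Range candidates require *both* endpoints inside the viable range.
- Undefined metrics (0/0) are `NA` with a warning, never 0.
- Fewer than 2 notes degrade the bootstrap CI to the point estimate with
  a warning.
- Value multiset comparison formats numbers via `%.10g`, so doubles that
  print identically compare equal, immune to sub-ulp noise.
- Seeds: every stochastic entry point (`generate_corpus`,
  `plant_confusion`, `bootstrap_ci`) takes an explicit seed and restores
  the caller's RNG state.

## Known limitations

- The dictionaries are shipped as published, typos included; they
  encode one institution's documentation habits and will need tailoring
  elsewhere.
- No Fahrenheit/Celsius conversion: a note recording `t 37.2` is outside
  the 93–110 band and will be missed by design.
- Non-canonical panel orderings and panels with fewer than three values
  are out of reach of the group rules.
- Height and weight carry invented, unvalidated viable ranges.
- The sentence splitter's digit guard merges a real sentence boundary
  that is immediately followed by a number.
- No temporal linking: repeated measurements in one note are all
  emitted, without event-time semantics.
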