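# vitalex

Rule-based extraction of numerical clinical parameters from narrative
clinical notes, in R.

## The problem

Electronic medical records bury numerical data that clinical outcomes
research needs — vital signs, left ventricular ejection fraction (EF),
glycated hemoglobin (HbA1C), serum creatinine — inside free-text notes:

```
Blood Pressure 132/87        Saturation 97% Room Air
Ejection Fraction 35-55%     fever, 101.2
97.0 100/66 98 18 98%        (an unlabeled vital-sign panel)
```

Manual chart review does not scale to tens of thousands of notes, and
general-purpose concept extractors are awkward to repurpose for numbers.
`vitalex` implements a deliberately simple, knowledge-based pipeline for
this task: no machine learning, no linguistic parsing — dictionaries,
a prefix tree, adjacency rules, and per-variable validity tests.  The
same framework extends to any numerical variable for which you can state
a term list, a viable range, and the plausible value formats.

## The method

For each note:

1. **Normalize and tokenize.** Lowercase; replace grammatical punctuation
   with spaces (length-preserving, so every token keeps raw-text offsets);
   split sentences with a rule that never breaks a decimal like `101.2`;
   filter stop words, *protecting* any word that is also a dictionary term
   (`"t"` is a stop word *and* an abbreviation for temperature).
2. **Match terms.** Per-variable dictionaries (the shipped defaults
   reproduce the published term lists verbatim — including quirks such as
   `tear` for temperature, and `hga1c`, the abbreviation whose absence
   originally cost HbA1C recall) are compiled into a token-level prefix
   tree; multi-word terms like `ejection fraction` match longest-first on
   whole tokens.
3. **Extract candidates**, two ways:
   - *Term-adjacent* (category 1): the nearest allowed-format numeric
     token within a 5-token window of a matched term, forward preferred.
     Ranges (`10-15`, `35-55%`, `10 to 15`) are one value with two
     endpoints; inequality words between term and value (`>`,
     `less than`, `higher than`) are recorded as a *condition*, never
     consumed as the value.
   - *Number groups* (category 2): a run of ≥ 3 unlabeled numeric tokens
     is screened by four rules — only `.` `/` `%` characters; at most one
     fraction, one percent, two decimal-pointed tokens; all integers
     < 300; all plain decimals inside the thermometer band (93, 110) —
     and, if it passes, assigned positionally: decimal → temperature,
     fraction → blood pressure, percent → O₂ saturation, remaining
     integers → heart rate, then respiratory rate (the canonical
     T-BP-HR-RR-O₂Sat panel order).
4. **Validity test.** Each candidate must fit the variable's value format
   and viable range (temperature 93–110 °F; EF ≤ 100 % or ≤ 1.0 in
   decimal form, rescaled ×100; HbA1C < 30 %; creatinine < 50).  A
   condition symbol invalidates a vital-sign pair (`fever > 100.4` is a
   threshold, not a measurement) but is accepted and recorded for EF and
   HbA1C, where the bound is itself the clinical datum.  Units are taken
   from an explicit adjacent token when present, else implied by the
   matched range (a bare `99.7` accepted as temperature is °F).

**Evaluation** against gold annotations is two-level, with percentile
bootstrap CIs (default B = 1000) over notes:

- *Note level*: a note is correct only if the predicted value multiset
  exactly equals the gold multiset; true negatives are notes where both
  are empty.  Sensitivity, specificity, PPV, NPV, F1.
- *Value level*: each value scored individually; no true negative exists,
  so only sensitivity, PPV, F1.

A deterministic **synthetic-note generator** produces corpora with known
gold labels over six templates (labeled pairs, grouped panels, condition
distractors, lab pseudo-tables, term-only and term-free sentences), so
the whole pipeline is testable without any real EMR data.

## Worked example

```r
library(vitalex)
extract_values("vitals: 97.0 100/66 98 18 98%")
```

```
  note_id         variable value_low value_high        unit condition start end       source
1  note_1      temperature        97         97          °F      none     8  12 number_group
2  note_1   blood_pressure       100         66        mmHg      none    13  19 number_group
3  note_1       heart_rate        98         98         bpm      none    20  22 number_group
4  note_1 respiratory_rate        18         18 breaths/min      none    23  25 number_group
5  note_1    o2_saturation        98         98           %      none    26  29 number_group
```

The unlabeled panel passed the four group rules and was assigned
positionally: 97.0 (decimal in the thermometer band) → temperature,
100/66 → blood pressure (systolic in `value_low`, diastolic in
`value_high`), 98 → heart rate, 18 → respiratory rate, 98% → O₂
saturation.  Spans are 0-based, half-open offsets into the raw note.

Condition-policy asymmetry:

```r
extract_values("fever > 100.4")            # 0 rows: threshold, not a measurement
extract_values("ejection fraction > 55")   # 1 row: EF 55, condition ">"
```

## Command line

```sh
VX=$(Rscript -e 'cat(system.file("cli", "vitalex", package = "vitalex"))')
Rscript $VX simulate --n 100 --seed 7 --out notes.jsonl --gold gold.csv
Rscript $VX extract  --input notes.jsonl --out ann.csv
Rscript $VX evaluate --pred ann.csv --gold gold.csv --notes notes.jsonl --level note
Rscript $VX validate-config --config my_variables.yaml
```

Inputs: a directory of `.txt` files, a JSONL file of
`{"note_id": ..., "text": ...}` records, or a CSV with header
`note_id,text`.  Variable dictionaries, viable ranges, formats and
condition policies are overridable via a YAML/JSON config
(`load_specs()`).

## Notes on the shipped dictionaries

The default term lists are shipped as published, including apparent
typos (`tear`, `tachypea`) and OCR/quoting artifacts in the HbA1C list;
remove or extend terms via the config file.  Height and weight have
published term lists but no published viable ranges or evaluation; their
shipped ranges are package inventions flagged as unvalidated.  To add a
new variable, the original workflow applies: collect synonyms and
abbreviations (e.g., from UMLS), review a sample of notes for extra
lexical cues, and state a viable range, unit and value formats — then
put all of that in a config block.
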