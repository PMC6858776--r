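mk_cand <- function(variable, lo, hi = lo, fraction = FALSE, range = FALSE,
                    decimal = FALSE, percent = FALSE, condition = "none",
                    next_surface = NA_character_) {
  data.frame(variable = variable, value_low = lo, value_high = hi,
             is_fraction = fraction, is_range = range,
             has_decimal = decimal, has_percent = percent,
             source = "term_adjacent", term = "x", condition = condition,
             start = 0L, end = 1L, sentence = 0L, token_index = 1L,
             token_hi = 1L, next_surface = next_surface,
             stringsAsFactors = FALSE)
}

test_that("validity enforces viable ranges on scalars and both range endpoints", {
  ok <- check_validity(mk_cand("temperature", 100.4, decimal = TRUE),
                       SPECS$temperature)
  expect_true(ok$accepted)
  bad <- check_validity(mk_cand("hba1c", 45), SPECS$hba1c)
  expect_false(bad$accepted)
  expect_equal(bad$reason, "out_of_range")
  # range with one endpoint outside is rejected
  r <- check_validity(mk_cand("ejection_fraction", 90, 120, range = TRUE),
                      SPECS$ejection_fraction)
  expect_false(r$accepted)
  expect_equal(r$reason, "out_of_range")
  # fraction checks numerator and denominator against separate ranges
  f_ok <- check_validity(mk_cand("blood_pressure", 132, 78, fraction = TRUE),
                         SPECS$blood_pressure)
  expect_true(f_ok$accepted)
  f_bad <- check_validity(mk_cand("blood_pressure", 350, 78, fraction = TRUE),
                          SPECS$blood_pressure)
  expect_equal(f_bad$reason, "out_of_range")
})

test_that("format violations are rejected", {
  v <- check_validity(mk_cand("temperature", 100, 66, fraction = TRUE),
                      SPECS$temperature)
  expect_false(v$accepted)
  expect_equal(v$reason, "bad_format")
  v2 <- check_validity(mk_cand("blood_pressure", 120), SPECS$blood_pressure)
  expect_equal(v2$reason, "bad_format")
})

test_that("condition policy is asymmetric between vitals and EF/HbA1C", {
  t_cond <- check_validity(mk_cand("temperature", 100.4, decimal = TRUE,
                                   condition = ">"), SPECS$temperature)
  expect_false(t_cond$accepted)
  expect_equal(t_cond$reason, "condition_rejected")
  ef_cond <- check_validity(mk_cand("ejection_fraction", 55,
                                    condition = ">"),
                            SPECS$ejection_fraction)
  expect_true(ef_cond$accepted)
  a1c_cond <- check_validity(mk_cand("hba1c", 8.5, decimal = TRUE,
                                     condition = "higher_than"),
                             SPECS$hba1c)
  expect_true(a1c_cond$accepted)
})

test_that("EF decimal form is rescaled to percent", {
  v <- check_validity(mk_cand("ejection_fraction", 0.55, decimal = TRUE),
                      SPECS$ejection_fraction)
  expect_true(v$accepted)
  expect_equal(v$value_low, 55)
  # end to end
  ann <- xv("lvef 0.55 on echo")
  expect_annotation(ann, "ejection_fraction", 55)
  # a decimal above 1.0 is taken at face value
  v2 <- check_validity(mk_cand("ejection_fraction", 55.5, decimal = TRUE),
                       SPECS$ejection_fraction)
  expect_equal(v2$value_low, 55.5)
})

test_that("unit inference: explicit token wins, range implies default, conflicts reject", {
  u <- resolve_unit(mk_cand("temperature", 99.7, decimal = TRUE),
                    SPECS$temperature)
  expect_equal(u$unit, "\u00b0F")
  u2 <- resolve_unit(mk_cand("ejection_fraction", 15, percent = TRUE),
                     SPECS$ejection_fraction)
  expect_equal(u2$unit, "%")
  u3 <- resolve_unit(mk_cand("temperature", 99.7, decimal = TRUE,
                             next_surface = "kg"), SPECS$temperature)
  expect_true(u3$conflict)
  v <- check_validity(mk_cand("temperature", 99.7, decimal = TRUE,
                              next_surface = "kg"), SPECS$temperature)
  expect_equal(v$reason, "unit_conflict")
  # end to end: explicit compatible unit
  ann <- xv("temp 99.7 f")
  expect_equal(ann$unit[ann$variable == "temperature"], "\u00b0F")
})

test_that("finalize splits accepted from rejected and sorts output", {
  cands <- rbind(mk_cand("temperature", 97.0, decimal = TRUE),
                 mk_cand("hba1c", 45),
                 mk_cand("ejection_fraction", 55))
  cands$start <- c(10L, 5L, 0L)
  ann <- finalize(cands, SPECS, note_id = "n1")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$start, c(0L, 10L))
  rej <- attr(ann, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$reason, "out_of_range")
  expect_equal(nrow(finalize(extract_note("", LEX, SPECS), SPECS)), 0L)
})

test_that("soundness fuzz: every emitted annotation lies in its viable range", {
  set.seed(99)
  corpus <- generate_corpus(generator_config(150, seed = 321))
  junk <- data.frame(
    note_id = paste0("junk_", 1:20),
    text = replicate(20, paste(sample(c("t", "bp", "hr", "ef", "a1c",
                                        "12", "700", "3.5", "97.2",
                                        "120/80", "45%", ">", "stable"),
                                      8, replace = TRUE), collapse = " ")),
    stringsAsFactors = FALSE)
  notes <- rbind(corpus$notes[, c("note_id", "text")], junk)
  ann <- extract_values(notes)
  expect_gt(nrow(ann), 0L)
  for (i in seq_len(nrow(ann))) {
    spec <- SPECS[[ann$variable[i]]]
    if (ann$variable[i] == "blood_pressure") {
      expect_true(ann$value_low[i] >= spec$viable_range[1] &&
                    ann$value_low[i] <= spec$viable_range[2])
      expect_true(ann$value_high[i] >= spec$viable_range2[1] &&
                    ann$value_high[i] <= spec$viable_range2[2])
    } else {
      expect_true(all(c(ann$value_low[i], ann$value_high[i]) >=
                        spec$viable_range[1]) &&
                    all(c(ann$value_low[i], ann$value_high[i]) <=
                          spec$viable_range[2]),
                  info = paste(ann$variable[i], ann$value_low[i]))
    }
  }
})

test_that("widening a viable range never loses annotations (monotonicity)", {
  corpus <- generate_corpus(generator_config(60, seed = 11))
  notes <- corpus$notes[, c("note_id", "text")]
  base <- extract_values(notes)
  wide <- load_specs(list(
    temperature = list(viable_range = c(80, 115)),
    heart_rate = list(viable_range = c(10, 350))))
  more <- extract_values(notes, specs = wide)
  expect_gte(nrow(more), nrow(base))
})
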