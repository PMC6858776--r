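gold_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(note_id = r[[1]], variable = "ef",
               value_low = as.numeric(r[[2]]),
               value_high = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}
EMPTY_G <- data.frame(note_id = character(0), variable = character(0),
                      value_low = numeric(0), value_high = numeric(0),
                      stringsAsFactors = FALSE)

test_that("note-level outcomes follow the exact-multiset definitions", {
  ids <- c("n1", "n2", "n3", "n4", "n5")
  gold <- gold_df(list("n1", 55, 55), list("n3", 55, 55), list("n3", 60, 60),
                  list("n5", 40, 40))
  pred <- gold_df(list("n1", 55, 55),               # exact -> TP
                  list("n3", 55, 55),               # missing 60 -> FN
                  list("n4", 45, 45),               # gold empty -> FP
                  list("n5", 40, 40), list("n5", 70, 70))  # mixed -> FP
  out <- note_level_outcomes(gold, pred, "ef", ids)
  expect_equal(out$outcome, c("TP", "TN", "FN", "FP", "FP"))
  cc <- note_level_confusion(out)
  expect_equal(cc, list(tp = 1L, fp = 2L, fn = 1L, tn = 1L))
  # count conservation
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, length(ids))
})

test_that("count-only matching mode relaxes value equality", {
  ids <- c("n1")
  gold <- gold_df(list("n1", 55, 55))
  pred <- gold_df(list("n1", 60, 60))
  expect_equal(note_level_outcomes(gold, pred, "ef", ids)$outcome, "FP")
  expect_equal(note_level_outcomes(gold, pred, "ef", ids,
                                   match_counts = TRUE)$outcome, "TP")
})

test_that("value-level counts match per-value definitions, no TN", {
  ids <- c("n1", "n2", "n3")
  gold <- gold_df(list("n1", 45, 45), list("n3", 55, 55), list("n3", 60, 60))
  pred <- gold_df(list("n1", 45, 45), list("n2", 45, 45), list("n3", 55, 55))
  counts <- value_level_counts(gold, pred, "ef", ids)
  cc <- value_level_confusion(counts)
  expect_equal(cc, list(tp = 2L, fp = 1L, fn = 1L))
  expect_null(cc$tn)
  # ranges match on both endpoints
  g2 <- gold_df(list("n1", 10, 15))
  p2 <- gold_df(list("n1", 10, 20))
  expect_equal(value_level_confusion(
    value_level_counts(g2, p2, "ef", "n1")),
    list(tp = 0L, fp = 1L, fn = 1L))
})

test_that("metrics arithmetic matches hand-computed values, nulls propagate", {
  m <- metrics_from_counts(list(tp = 9, fn = 1, tn = 8, fp = 0))
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 1.0)
  expect_equal(unname(m["ppv"]), 1.0)
  expect_equal(unname(m["npv"]), 8 / 9)
  expect_equal(unname(m["f1"]), 2 * 1 * 0.9 / 1.9)
  expect_true(is.na(metrics_from_counts(
    list(tp = 0, fp = 0, fn = 3, tn = 2))["ppv"]))
  perf <- metrics_from_counts(list(tp = 1, fn = 0, fp = 0, tn = 0))
  expect_equal(unname(perf["sensitivity"]), 1.0)
  expect_equal(unname(perf["f1"]), 1.0)
  expect_warning(metrics_from_counts(list(tp = 0, fp = 0, fn = 0, tn = 0)),
                 "zero")
})

test_that("planted confusion profiles are recovered exactly", {
  for (prof in list(c(5, 0, 0, 5), c(0, 0, 0, 10), c(3, 2, 1, 4))) {
    pc <- plant_confusion(prof[1], prof[2], prof[3], prof[4], seed = 5)
    out <- note_level_outcomes(pc$gold, pc$pred, "temperature", pc$note_ids)
    cc <- note_level_confusion(out)
    expect_equal(unlist(cc), c(tp = prof[1], fp = prof[2], fn = prof[3],
                               tn = prof[4]))
  }
  expect_error(plant_confusion(-1, 0, 0, 2), "non-negative")
})

test_that("evaluate_extraction produces the two-level table shapes", {
  pc <- plant_confusion(3, 2, 1, 4, seed = 9)
  note_m <- evaluate_extraction(pc$gold, pc$pred, note_ids = pc$note_ids,
                                level = "note", B = 50, seed = 2)
  expect_setequal(unique(note_m$metric),
                  c("sensitivity", "specificity", "ppv", "npv", "f1"))
  est <- function(m, name) m$estimate[m$metric == name]
  expect_equal(est(note_m, "sensitivity"), 3 / 4)
  expect_equal(est(note_m, "specificity"), 4 / 6)
  expect_equal(est(note_m, "ppv"), 3 / 5)
  expect_equal(est(note_m, "npv"), 4 / 5)
  value_m <- evaluate_extraction(pc$gold, pc$pred, note_ids = pc$note_ids,
                                 level = "value", B = 50, seed = 2)
  expect_setequal(unique(value_m$metric), c("sensitivity", "ppv", "f1"))
  # pred-only variable warns
  pred2 <- pc$pred
  pred2$variable <- "creatinine"
  expect_warning(evaluate_extraction(pc$gold, pred2,
                                     note_ids = pc$note_ids, B = 0),
                 "not in gold")
})

test_that("bootstrap CIs are deterministic given a seed and degenerate cases warn", {
  pc <- plant_confusion(30, 5, 5, 20, seed = 3)
  out <- note_level_outcomes(pc$gold, pc$pred, "temperature", pc$note_ids)
  ci1 <- bootstrap_ci(out, "note", B = 200, seed = 42)
  ci2 <- bootstrap_ci(out, "note", B = 200, seed = 42)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(out, "note", B = 200, seed = 43)
  expect_false(identical(ci1, ci3))
  expect_true(all(ci1["lo", ] <= ci1["hi", ], na.rm = TRUE))

  all_tp <- data.frame(note_id = paste0("n", 1:20), outcome = "TP",
                       stringsAsFactors = FALSE)
  ci_tp <- bootstrap_ci(all_tp, "note", B = 100, seed = 1)
  expect_equal(unname(ci_tp["lo", "sensitivity"]), 1.0)
  expect_equal(unname(ci_tp["hi", "sensitivity"]), 1.0)

  one <- data.frame(note_id = "n1", outcome = "TP", stringsAsFactors = FALSE)
  expect_warning(ci_one <- bootstrap_ci(one, "note", B = 10, seed = 1),
                 "fewer than 2")
  expect_equal(unname(ci_one["lo", "sensitivity"]), 1.0)

  # B = 1: the CI collapses onto the single replicate
  ci_b1 <- bootstrap_ci(out, "note", B = 1, seed = 7)
  expect_equal(ci_b1["lo", "sensitivity"], ci_b1["hi", "sensitivity"])
})

test_that("bootstrap CI brackets a known planted sensitivity (coverage)", {
  # 100 notes with 90 TP / 10 FN -> sensitivity 0.9; the 95% percentile CI
  # from resampled notes should cover 0.9 in >= 93 of 100 meta-repeats
  covered <- 0L
  set.seed(2026)
  fns <- stats::rbinom(100, size = 100, prob = 0.1)  # misses per repeat
  for (r in 1:100) {
    pc <- plant_confusion(100 - fns[r], 0, fns[r], 0, seed = 1000 + r)
    out <- note_level_outcomes(pc$gold, pc$pred, "temperature",
                               pc$note_ids)
    ci <- bootstrap_ci(out, "note", B = 1000, seed = 42)
    if (ci["lo", "sensitivity"] <= 0.9 && ci["hi", "sensitivity"] >= 0.9) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 93L)
})
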