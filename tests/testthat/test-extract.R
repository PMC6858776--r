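test_that("parse_numeric recognizes the five value shapes", {
  f <- parse_numeric("100/66")
  expect_true(f$is_fraction)
  expect_equal(c(f$numerator, f$denominator), c(100, 66))
  r <- parse_numeric("10-15")
  expect_true(r$is_range)
  expect_equal(c(r$value_low, r$value_high), c(10, 15))
  rp <- parse_numeric("35-55%")
  expect_true(rp$is_range && rp$has_percent)
  p <- parse_numeric("98%")
  expect_true(p$has_percent)
  expect_equal(p$value_low, 98)
  d <- parse_numeric("97.0")
  expect_true(d$has_decimal)
  expect_equal(d$value_low, 97)
  i <- parse_numeric("18")
  expect_false(i$has_decimal || i$has_percent || i$is_range || i$is_fraction)
  for (bad in c("abc", "a1c", "12a", "15-10", "", "-", "/", "%")) {
    expect_null(parse_numeric(bad), info = bad)
  }
})

test_that("term-adjacent extraction finds forward values, ranges, conditions", {
  ann <- xv("echocardiogram showed an ejection fraction of 10-15 percent")
  expect_annotation(ann, "ejection_fraction", 10, 15)

  # condition symbol recorded, not consumed
  cand <- extract_note("fever > 100.4", LEX, SPECS)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$condition, ">")
  expect_equal(cand$value_low, 100.4)

  # no numeric token in window -> nothing
  expect_equal(nrow(extract_note("afebrile overnight", LEX, SPECS)), 0L)

  # backward search: value precedes term
  ann_b <- xv("99 % sat on room air")
  expect_annotation(ann_b, "o2_saturation", 99)

  # multi-word condition
  cand2 <- extract_note("ef higher than 55", LEX, SPECS)
  expect_equal(cand2$condition, "higher_than")
})

test_that("two values for repeated terms both survive", {
  ann <- xv("temp 99.1 and later temp 100.8")
  t_rows <- ann[ann$variable == "temperature", ]
  expect_equal(sort(t_rows$value_low), c(99.1, 100.8))
  expect_equal(nrow(t_rows), 2L)
})

test_that("nearest term wins a contested value; loser rescans", {
  # value 80 sits between "bp 120/66" (claimed) and "hr"; hr gets 80
  ann <- xv("bp 120/66 hr 80")
  expect_annotation(ann, "blood_pressure", 120, 66)
  expect_annotation(ann, "heart_rate", 80)
  # flanked: "hr 88 rr" -> 88 is adjacent to both; nearest distances tie,
  # forward direction (hr) wins, rr finds nothing
  ann2 <- xv("hr 88 rr")
  expect_annotation(ann2, "heart_rate", 88)
  expect_false("respiratory_rate" %in% ann2$variable)
})

test_that("number-group detection requires three unlabeled numerics", {
  tk <- toks("97.0 100/66 98 18 98%")
  g <- find_number_groups(tk, lapply(tk$surface, parse_numeric))
  expect_length(g, 1L)
  expect_length(g[[1]], 5L)

  # a term-adjacent pair is not a group
  expect_length(find_number_groups(
    toks("1 2"), lapply(toks("1 2")$surface, parse_numeric)), 0L)
  cand <- extract_note("bp 132/78", LEX, SPECS)
  expect_equal(unique(cand$source), "term_adjacent")
})

test_that("group rules 1-4 accept the canonical panel and reject violators", {
  ok <- function(txt) {
    tk <- toks(txt)
    p <- lapply(tk$surface, parse_numeric)
    is_vital_group(tk$surface, p)
  }
  expect_true(ok("97.0 100/66 98 18 98%"))
  expect_false(ok("1.2 3.4 5.6"))       # three decimals, out of band
  expect_false(ok("350 360 370"))       # integers >= 300
  expect_false(ok("97.0 98.1 99.2"))    # three decimal-pointed tokens
  expect_false(ok("120/80 130/85 98")) # two fractions
  expect_false(ok("97% 98% 99"))       # two percents
  expect_false(ok("50.5 100/66 98"))   # decimal outside (93, 110)
  expect_false(ok("112.5 100/66 98"))  # decimal outside (93, 110)
})

test_that("group assignment follows the T-BP-HR-RR-O2Sat panel convention", {
  run <- function(txt) {
    ann <- xv(txt)
    stats::setNames(ann$value_low, ann$variable)
  }
  v <- run("97.0 100/66 98 18 98%")
  expect_equal(v[["temperature"]], 97.0)
  expect_equal(v[["blood_pressure"]], 100)
  expect_equal(v[["heart_rate"]], 98)
  expect_equal(v[["respiratory_rate"]], 18)
  expect_equal(v[["o2_saturation"]], 98)

  v2 <- run("98.6 120/80 72")
  expect_equal(v2[["temperature"]], 98.6)
  expect_equal(v2[["blood_pressure"]], 120)
  expect_equal(v2[["heart_rate"]], 72)
  expect_false("respiratory_rate" %in% names(v2))
  expect_false("o2_saturation" %in% names(v2))

  v3 <- run("80 18 99")
  expect_equal(v3[["heart_rate"]], 80)
  expect_equal(v3[["respiratory_rate"]], 18)
  expect_equal(v3[["o2_saturation"]], 99)
})

test_that("no variable is assigned twice within a group", {
  for (txt in c("97.0 100/66 98 18 98%", "80 18 99 75 20",
                "98.6 110/70 70 16 97%")) {
    ann <- xv(txt)
    expect_false(any(duplicated(ann$variable)), info = txt)
  }
})

test_that("tokens claimed by a term never join a group", {
  # "t 97.2" claims the decimal; remaining 4 unlabeled numerics group up
  ann <- xv("t 97.2 110/70 70 16 97%")
  expect_annotation(ann, "temperature", 97.2)
  expect_equal(ann$source[ann$variable == "temperature"], "term_adjacent")
  expect_annotation(ann, "blood_pressure", 110, 70)
  expect_annotation(ann, "o2_saturation", 97)
})

test_that("candidate spans slice the raw note onto the value digits", {
  raw <- "Vitals were: 97.0 100/66 98 18 98% today; EF 35-55%."
  ann <- xv(raw)
  expect_gt(nrow(ann), 0L)
  for (i in seq_len(nrow(ann))) {
    slice <- substr(raw, ann$start[i] + 1L, ann$end[i])
    digits <- gsub("\\D", "", slice)
    expect_true(grepl(gsub("\\D", "", format(ann$value_low[i])), digits,
                      fixed = TRUE))
  }
})

test_that("no numeric token yields more than one accepted candidate", {
  notes <- c("bp 120/66 hr 80", "t 99.1 pulse 85 rr 18",
             "97.0 100/66 98 18 98%", "ef 55 a1c 7.2 creat 1.1")
  for (txt in notes) {
    ann <- xv(txt)
    key <- paste(ann$start, ann$end)
    expect_false(any(duplicated(key)), info = txt)
  }
})

test_that("distractor tokens around a panel leave signature assignments unchanged", {
  set.seed(7)
  base <- c("97.0", "100/66", "98%")
  for (rep in 1:10) {
    extra <- as.character(sample(30:290, 2))  # integers, no signature clash
    panel <- c(base, extra)[sample(5)]
    ann <- xv(paste(panel, collapse = " "))
    expect_equal(ann$value_low[ann$variable == "temperature"], 97.0)
    expect_equal(ann$value_low[ann$variable == "blood_pressure"], 100)
    expect_equal(ann$value_low[ann$variable == "o2_saturation"], 98)
  }
})

test_that("empty and term-free notes yield zero candidates", {
  expect_equal(nrow(extract_note("", LEX, SPECS)), 0L)
  expect_equal(nrow(xv("")), 0L)
  expect_equal(nrow(xv("plain narrative without numbers or vitals")), 0L)
})
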