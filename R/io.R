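# Readers and writers: notes (txt directory / JSONL / CSV), annotations and
# gold files (CSV or JSONL).  CSV follows RFC 4180 with a mandatory header;
# all files are UTF-8.

#' Read a note corpus
#'
#' @param path A directory of \code{.txt} files (one note per file, the
#'   file name minus extension is the note id), a \code{.jsonl} file of
#'   records \code{{"note_id": ..., "text": ...}}, or a \code{.csv} with
#'   header \code{note_id,text}.
#' @param format \code{"auto"} (by path type/extension), \code{"txt"},
#'   \code{"jsonl"} or \code{"csv"}.
#' @return Data frame with columns \code{note_id}, \code{text}.
#' @export
read_notes <- function(path, format = c("auto", "txt", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "txt"
    else switch(tolower(tools::file_ext(path)),
                jsonl = , ndjson = , json = "jsonl",
                csv = "csv",
                txt = "txt",
                stop("cannot infer input format of '", path,
                     "'; pass format=", call. = FALSE))
  }
  if (format == "txt") {
    if (dir.exists(path)) {
      files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
      if (!length(files)) {
        return(data.frame(note_id = character(0), text = character(0),
                          stringsAsFactors = FALSE))
      }
      texts <- character(length(files))
      ok <- rep(TRUE, length(files))
      for (i in seq_along(files)) {
        txt <- tryCatch(
          suppressWarnings(
            paste(readLines(files[i], warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")),
          error = function(e) NA_character_)
        if (is.na(txt)) {
          warning("skipping unreadable note file: ", files[i],
                  call. = FALSE)
          ok[i] <- FALSE
        } else {
          texts[i] <- txt
        }
      }
      return(data.frame(
        note_id = sub("\\.txt$", "", basename(files[ok])),
        text = texts[ok], stringsAsFactors = FALSE))
    }
    return(data.frame(
      note_id = sub("\\.txt$", "", basename(path)),
      text = paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n"),
      stringsAsFactors = FALSE))
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    ok <- rep(TRUE, length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$note_id) || is.null(rec$text)) {
        warning("skipping malformed JSONL record at line ", i,
                call. = FALSE)
        ok[i] <- FALSE
      } else {
        recs[[i]] <- data.frame(note_id = as.character(rec$note_id),
                                text = as.character(rec$text),
                                stringsAsFactors = FALSE)
      }
    }
    recs <- recs[ok]
    if (!length(recs)) {
      return(data.frame(note_id = character(0), text = character(0),
                        stringsAsFactors = FALSE))
    }
    return(do.call(rbind, recs))
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("note_id", "text") %in% names(df))) {
    stop("CSV notes file must have header columns note_id,text",
         call. = FALSE)
  }
  df[, c("note_id", "text")]
}

#' Write notes as JSONL or CSV
#'
#' @param notes Data frame with \code{note_id}, \code{text}.
#' @param path Output path; extension selects the format unless
#'   \code{format} is given.
#' @param format \code{"jsonl"} or \code{"csv"}.
#' @export
write_notes <- function(notes, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(list(note_id = notes$note_id[i],
                            text = notes$text[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(notes[, c("note_id", "text")], path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write annotations
#'
#' One row per annotation: \code{note_id, variable, value_low, value_high,
#' unit, condition, start, end, source}.  Writing then reading reproduces
#' the annotation table exactly.
#'
#' @param annotations Annotation data frame from [extract_values()].
#' @param path Output path (\code{.csv} or \code{.jsonl}).
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("note_id", "variable", "value_low", "value_high", "unit",
            "condition", "start", "end", "source")
  df <- annotations[, cols, drop = FALSE]
  if (tolower(tools::file_ext(path)) %in% c("jsonl", "ndjson")) {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path Annotation file (\code{.csv} or \code{.jsonl}).
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("jsonl", "ndjson")) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty_annotations())
    df <- do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(note_id = "character"))
  }
  num <- intersect(c("value_low", "value_high", "start", "end"), names(df))
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  if ("start" %in% names(df)) df$start <- as.integer(df$start)
  if ("end" %in% names(df)) df$end <- as.integer(df$end)
  df
}

#' Read gold annotations
#'
#' @param path CSV with header \code{note_id,variable,value_low,value_high}.
#' @return Gold data frame.
#' @export
read_gold <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("note_id", "variable", "value_low", "value_high")
  if (!all(need %in% names(df))) {
    stop("gold CSV must have header columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$note_id <- as.character(df$note_id)
  df$value_low <- as.numeric(df$value_low)
  df$value_high <- as.numeric(df$value_high)
  if (any(df$value_low > df$value_high & df$variable != "blood_pressure")) {
    stop("gold file has value_low > value_high outside blood pressure",
         call. = FALSE)
  }
  df[, need]
}

#' Write gold annotations
#'
#' @param gold Gold data frame.
#' @param path Output CSV path.
#' @export
write_gold <- function(gold, path) {
  utils::write.csv(gold[, c("note_id", "variable", "value_low",
                            "value_high")], path, row.names = FALSE)
  invisible(path)
}
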