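#' Build a document corpus
#'
#' A corpus is the collection of plain-text notes that annotations refer to.
#' Character offsets in annotations index the decoded character sequence of
#' each document (0-based), not bytes.
#'
#' @param doc_id character vector of unique, non-empty document identifiers.
#' @param text character vector of document texts, same length as `doc_id`.
#' @return an `el_corpus` object: a data.frame with columns `doc_id`, `text`.
#' @export
#' @examples
#' corpus("n1", "CT head revealed no internal hemorrhage.")
corpus <- function(doc_id, text) {
  doc_id <- as.character(doc_id)
  text <- enc2utf8(as.character(text))
  if (length(doc_id) != length(text)) {
    stopf("doc_id and text must have the same length")
  }
  if (any(is.na(doc_id)) || any(!nzchar(doc_id))) {
    stopf("doc_id must be non-empty and non-missing")
  }
  if (anyDuplicated(doc_id)) {
    stopf("duplicate doc_id: %s", paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  }
  out <- data.frame(doc_id = doc_id, text = text, stringsAsFactors = FALSE)
  class(out) <- c("el_corpus", "data.frame")
  out
}

#' Read a corpus from disk
#'
#' Accepts either a directory of one plain-text file per note (filename,
#' minus an optional `.txt` extension, is the note id) or a two-column CSV
#' with header `note_id,text`.
#'
#' @param path directory or CSV file.
#' @return an [corpus()] object.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (!length(files)) stopf("no document files found under %s", path)
    ids <- sub("\\.txt$", "", basename(files))
    texts <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1))
    return(corpus(ids, texts))
  }
  if (!file.exists(path)) stopf("corpus path does not exist: %s", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("note_id", "text") %in% names(df))) {
    stopf("corpus CSV must have columns note_id,text")
  }
  corpus(df$note_id, df$text)
}

#' Write a corpus to a two-column CSV (`note_id,text`)
#'
#' @param docs an [corpus()] object.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  stopifnot(inherits(docs, "el_corpus"))
  df <- data.frame(note_id = docs$doc_id, text = docs$text, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

doc_text <- function(docs, doc_id) {
  i <- match(doc_id, docs$doc_id)
  if (anyNA(i)) stopf("unknown doc_id: %s", paste(unique(doc_id[is.na(i)]), collapse = ", "))
  docs$text[i]
}

#' Extract the text covered by annotations
#'
#' Offsets are 0-based and half-open: an annotation `[start, end)` of length
#' `end - start` covers characters `start, ..., end - 1`.
#'
#' @param docs an [corpus()] object.
#' @param anns an [annotation_set()] or any data.frame with columns
#'   `doc_id`, `start`, `end`.
#' @return character vector of covered substrings, one per annotation.
#' @export
#' @examples
#' d <- corpus("n1", "CT head revealed no internal hemorrhage.")
#' a <- annotation_set(data.frame(doc_id = "n1", start = 0, end = 7,
#'                                concept_id = "303653007"), "gold")
#' span_text(d, a)  # "CT head"
span_text <- function(docs, anns) {
  txt <- doc_text(docs, anns$doc_id)
  nch <- nchar(txt)
  bad <- which(anns$end > nch)
  if (length(bad)) {
    stopf("annotation end offset exceeds document length (first offender: %s [%d,%d) in a %d-char note)",
          anns$doc_id[bad[1]], anns$start[bad[1]], anns$end[bad[1]], nch[bad[1]])
  }
  substring(txt, anns$start + 1L, anns$end)
}
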