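#' Build a validated annotation set
#'
#' An annotation set holds the span-to-concept links produced by one source
#' (the gold standard, one system, or one annotator). Each annotation is a
#' half-open character interval `[start, end)` in one document, linked to one
#' terminology concept. Within a document, annotations from the same source
#' may not overlap (annotation guidelines for this task preclude overlapping
#' spans), so every character carries at most one concept per source.
#'
#' @param df data.frame with columns `doc_id`, `start`, `end`, `concept_id`
#'   (`note_id` is accepted as an alias for `doc_id`).
#' @param source_id identifier of the producing source (e.g. `"gold"`,
#'   a system name, an annotator code).
#' @return an `el_annotations` object: a data.frame with columns `doc_id`,
#'   `start`, `end`, `concept_id` (sorted by document then start) carrying a
#'   `source_id` attribute.
#' @export
#' @examples
#' annotation_set(
#'   data.frame(doc_id = "n1", start = 0, end = 7, concept_id = "303653007"),
#'   source_id = "gold"
#' )
annotation_set <- function(df, source_id) {
  if (!is.character(source_id) || length(source_id) != 1L || !nzchar(source_id)) {
    stopf("source_id must be a single non-empty string")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if ("note_id" %in% names(df) && !"doc_id" %in% names(df)) {
    names(df)[names(df) == "note_id"] <- "doc_id"
  }
  need <- c("doc_id", "start", "end", "concept_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$doc_id <- as.character(df$doc_id)
  df$concept_id <- as.character(df$concept_id)
  start_n <- suppressWarnings(as.numeric(df$start))
  end_n <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start_n) | is.na(end_n) | start_n != floor(start_n) | end_n != floor(end_n))
  if (length(bad)) stopf("non-integer start/end in row(s): %s", paste(bad, collapse = ", "))
  df$start <- as.integer(start_n)
  df$end <- as.integer(end_n)
  bad <- which(df$start < 0L)
  if (length(bad)) stopf("negative start offset in row(s): %s", paste(bad, collapse = ", "))
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stopf("start >= end (empty or inverted span) in row(s): %s", paste(bad, collapse = ", "))
  }
  if (nrow(df)) {
    ord <- order(df$doc_id, df$start, df$end)
    df <- df[ord, , drop = FALSE]
    same_doc <- df$doc_id[-1L] == df$doc_id[-nrow(df)]
    clash <- which(same_doc & df$start[-1L] < df$end[-nrow(df)])
    if (length(clash)) {
      k <- clash[1L]
      stopf("overlapping annotations in document '%s': [%d,%d) and [%d,%d)",
            df$doc_id[k], df$start[k], df$end[k], df$start[k + 1L], df$end[k + 1L])
    }
  }
  rownames(df) <- NULL
  attr(df, "source_id") <- source_id
  class(df) <- c("el_annotations", "data.frame")
  df
}

#' Source identifier of an annotation set
#' @param set an [annotation_set()].
#' @return the source id string.
#' @export
source_id <- function(set) attr(set, "source_id")

#' @export
print.el_annotations <- function(x, ...) {
  cat(sprintf("<annotation set '%s': %d annotations, %d documents, %d concepts>\n",
              source_id(x), nrow(x), length(unique(x$doc_id)),
              length(unique(x$concept_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Read an annotation set from the exchange CSV
#'
#' The exchange format is a UTF-8 CSV with mandatory header
#' `note_id,start,end,concept_id`; `start`/`end` are 0-based half-open
#' character offsets. Row order is not significant.
#'
#' @param path CSV file.
#' @param source_id identifier to stamp on the returned set.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, source_id) {
  if (!file.exists(path)) stopf("annotation file does not exist: %s", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("note_id", "start", "end", "concept_id")
  if (!identical(sort(intersect(need, names(df))), sort(need))) {
    stopf("%s: header must name columns note_id,start,end,concept_id", path)
  }
  start_n <- suppressWarnings(as.numeric(df$start))
  end_n <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start_n) | is.na(end_n))
  if (length(bad)) {
    # +1 for the header row: report the physical line number
    stopf("%s: malformed start/end on line %d", path, bad[1L] + 1L)
  }
  annotation_set(df[need], source_id)
}

#' Write an annotation set to the exchange CSV
#'
#' Round-trip identity holds: `read_annotations()` on the written file
#' reproduces the set exactly.
#'
#' @param set an [annotation_set()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "el_annotations"))
  df <- data.frame(note_id = set$doc_id, start = set$start, end = set$end,
                   concept_id = set$concept_id, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
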