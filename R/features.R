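#' Build a span index (span-string bags per concept and per span)
#'
#' Collects, over one or more annotation sets, the bag of normalized span
#' strings linked to each concept (`by_concept`) and its transpose, the bag
#' of concepts linked to each span string (`by_span`). These two views feed
#' the concept-entropy and annotation-entropy difficulty features.
#'
#' @param sets a single [annotation_set()] or list of them.
#' @param docs an [corpus()] resolving every annotation.
#' @param normalizer function applied to raw span strings before bagging;
#'   defaults to [normalize_span()] (lowercase, trim, collapse whitespace).
#' @return an `el_span_index`: list with `pairs` (data.frame `concept_id`,
#'   `span`, `n`), `by_concept` and `by_span` (named lists of count tables).
#' @export
build_span_index <- function(sets, docs, normalizer = normalize_span) {
  if (inherits(sets, "el_annotations")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "el_annotations")),
            inherits(docs, "el_corpus"))
  ann <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[, c("doc_id", "start", "end", "concept_id")]))
  if (!nrow(ann)) stopf("no annotations to index")
  ann$span <- normalizer(span_text(docs, ann))
  agg <- stats::aggregate(list(n = rep(1L, nrow(ann))),
                          by = list(concept_id = ann$concept_id, span = ann$span),
                          FUN = sum)
  structure(
    list(
      pairs = agg,
      by_concept = lapply(split(agg, agg$concept_id),
                          function(d) stats::setNames(d$n, d$span)),
      by_span = lapply(split(agg, agg$span),
                       function(d) stats::setNames(d$n, d$concept_id))
    ),
    class = "el_span_index"
  )
}

#' @export
print.el_span_index <- function(x, ...) {
  cat(sprintf("<span index: %d concepts, %d distinct span strings, %d annotations>\n",
              length(x$by_concept), length(x$by_span), sum(x$pairs$n)))
  invisible(x)
}

#' Concept entropy: diversity of span strings linked to a concept
#'
#' The bag of normalized span strings annotated with the concept is treated
#' as a draw from a multinomial distribution; the feature is the Shannon
#' entropy (bits) of that distribution. 0 means the concept is always
#' written the same way; log2(k) means k equally common surface forms.
#'
#' @param index an `el_span_index` from [build_span_index()].
#' @param concept_id a single concept present in the index.
#' @return entropy in bits.
#' @export
concept_entropy <- function(index, concept_id) {
  stopifnot(inherits(index, "el_span_index"))
  bag <- index$by_concept[[as.character(concept_id)]]
  if (is.null(bag)) stopf("concept '%s' not present in the index", concept_id)
  entropy_bits(bag)
}

#' Annotation entropy: ambiguity of a concept's surface forms
#'
#' For a concept C, take the set A of distinct span strings linked to C
#' anywhere in the indexed data, then the bag B of all concepts linked,
#' corpus-wide, to any string in A (with multiplicity). The feature is the
#' entropy (bits) of B: it measures how many plausible link targets a system
#' faces when it sees one of C's surface forms. 0 means C's strings are
#' linked only to C.
#'
#' @inheritParams concept_entropy
#' @param weight_by_span if `TRUE`, each string's concept counts enter B
#'   multiplied by the string's multiplicity in A, instead of once per
#'   distinct string (the default).
#' @return entropy in bits.
#' @export
annotation_entropy <- function(index, concept_id, weight_by_span = FALSE) {
  stopifnot(inherits(index, "el_span_index"))
  bag_a <- index$by_concept[[as.character(concept_id)]]
  if (is.null(bag_a)) stopf("concept '%s' not present in the index", concept_id)
  acc <- stats::setNames(numeric(0), character(0))
  for (s in names(bag_a)) {
    counts <- index$by_span[[s]]
    if (weight_by_span) counts <- counts * bag_a[[s]]
    for (cid in names(counts)) {
      acc[cid] <- (if (cid %in% names(acc)) acc[[cid]] else 0) + counts[[cid]]
    }
  }
  entropy_bits(acc)
}

#' Concept-level difficulty feature table
#'
#' Computes, for every concept observed in the reference annotation sets,
#' the feature suite used to analyze linking difficulty:
#' * `mean_span_length` — mean character length of the concept's spans
#'   (training and test pooled);
#' * `concept_entropy` — diversity of its surface forms ([concept_entropy()]),
#'   on the pooled splits;
#' * `annotation_entropy` — ambiguity of those surface forms
#'   ([annotation_entropy()]), on the pooled splits;
#' * `depth` — shortest is-a distance to the terminology root
#'   ([concept_depth()]); `NA` (with a warning) when the concept is missing
#'   from the terminology;
#' * `n_examples` — number of training-set annotations (0 for test-only
#'   concepts);
#' * `n_notes` — number of distinct training documents containing it.
#'
#' @param train gold [annotation_set()] of the training split (may be empty).
#' @param test gold [annotation_set()] of the test split.
#' @param docs an [corpus()] covering both splits.
#' @param term an [terminology()].
#' @param normalizer span normalizer passed to [build_span_index()].
#' @return an `el_feature_table`: data.frame with one row per concept.
#' @export
feature_table <- function(train, test, docs, term,
                          normalizer = normalize_span) {
  stopifnot(inherits(train, "el_annotations"), inherits(test, "el_annotations"),
            inherits(docs, "el_corpus"), inherits(term, "el_terminology"))
  index <- build_span_index(list(train, test), docs, normalizer)
  both <- rbind(as.data.frame(train)[, c("doc_id", "start", "end", "concept_id")],
                as.data.frame(test)[, c("doc_id", "start", "end", "concept_id")])
  concepts <- sort(unique(both$concept_id))

  len_by <- sum_by(both$end - both$start, both$concept_id)
  cnt_by <- table(both$concept_id)
  n_tr <- table(train$concept_id)
  notes_tr <- if (nrow(train)) {
    tapply(train$doc_id, train$concept_id, function(d) length(unique(d)))
  } else NULL

  in_term <- concepts %in% term$concept_ids
  if (any(!in_term)) {
    warnf("%d concept(s) missing from the terminology; depth recorded as NA",
          sum(!in_term))
  }
  depth <- rep(NA_integer_, length(concepts))
  if (any(in_term)) depth[in_term] <- concept_depth(term, concepts[in_term])

  out <- data.frame(
    concept_id = concepts,
    mean_span_length = as.numeric(len_by[concepts] / as.numeric(cnt_by[concepts])),
    concept_entropy = vapply(concepts, function(cc) concept_entropy(index, cc), numeric(1)),
    annotation_entropy = vapply(concepts, function(cc) annotation_entropy(index, cc), numeric(1)),
    depth = depth,
    n_examples = as.integer(ifelse(is.na(match(concepts, names(n_tr))), 0L,
                                   n_tr[concepts])),
    n_notes = as.integer(ifelse(is.na(match(concepts, names(notes_tr))), 0L,
                                notes_tr[concepts])),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("el_feature_table", "data.frame")
  out
}
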