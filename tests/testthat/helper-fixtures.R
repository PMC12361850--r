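# fixtures built in code; no files on disk

ct_doc <- function() corpus("n1", "CT head revealed no internal hemorrhage.")

anns <- function(doc_id, start, end, concept_id, source = "x") {
  annotation_set(
    data.frame(doc_id = doc_id, start = start, end = end,
               concept_id = concept_id, stringsAsFactors = FALSE),
    source
  )
}

empty_anns <- function(source = "x") {
  annotation_set(data.frame(doc_id = character(), start = integer(),
                            end = integer(), concept_id = character()), source)
}

# random non-overlapping spans in one document of length len:
# consecutive pairs from sorted distinct cut points never overlap
rand_spans_one_doc <- function(doc_id, len, max_spans, concept_pool) {
  k <- sample.int(max_spans, 1L)
  cuts <- sort(sample.int(len + 1L, min(2L * k, len + 1L)) - 1L)
  if (length(cuts) < 2L) {
    return(data.frame(doc_id = character(), start = integer(), end = integer(),
                      concept_id = character(), stringsAsFactors = FALSE))
  }
  n_pairs <- length(cuts) %/% 2L
  start <- cuts[seq(1L, by = 2L, length.out = n_pairs)]
  end <- cuts[seq(2L, by = 2L, length.out = n_pairs)]
  ok <- start < end
  data.frame(doc_id = doc_id, start = start[ok], end = end[ok],
             concept_id = sample(concept_pool, sum(ok), replace = TRUE),
             stringsAsFactors = FALSE)
}

# a random scoring instance: <= 5 docs x <= 200 chars, gold plus n_pred
# prediction sets over a small concept pool
rand_case <- function(seed, n_pred = 2L, n_concepts = 4L) {
  set.seed(seed)
  n_docs <- sample.int(5L, 1L)
  lens <- sample(40:200, n_docs, replace = TRUE)
  doc_ids <- paste0("d", seq_len(n_docs))
  docs <- corpus(doc_ids, vapply(lens, function(L)
    paste(sample(letters, L, replace = TRUE), collapse = ""), character(1)))
  pool <- paste0("c", seq_len(n_concepts))
  mk <- function(source) {
    rows <- do.call(rbind, lapply(seq_len(n_docs), function(i)
      rand_spans_one_doc(doc_ids[i], lens[i], 6L, pool)))
    annotation_set(rows, source)
  }
  list(docs = docs,
       gt = mk("gold"),
       preds = lapply(seq_len(n_pred), function(i) mk(paste0("sys", i))))
}

# plain data.frame view of an annotation set (drops class and source_id) so
# expect_equal compares content only
bare <- function(set) {
  df <- as.data.frame(set)
  attr(df, "source_id") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

zero_noise_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, p_miss = 0, p_confuse = 0, jitter = 0L,
             spur_rate = 0, ...)
}
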