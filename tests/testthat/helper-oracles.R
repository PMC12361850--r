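# brute-force reference implementations, independent of the package's
# interval arithmetic: everything here materializes explicit character sets
# or runs literal double loops over annotation rows

# character identifiers "doc:pos" linked to `concept` by a set
oracle_char_set <- function(set, concept) {
  df <- as.data.frame(set)
  df <- df[df$concept_id == concept, , drop = FALSE]
  if (!nrow(df)) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$doc_id[i], seq.int(df$start[i], df$end[i] - 1L), sep = ":")))
}

oracle_iou <- function(gt, pred, concept) {
  g <- oracle_char_set(gt, concept)
  p <- oracle_char_set(pred, concept)
  length(intersect(g, p)) / length(union(g, p))
}

oracle_precision_recall <- function(gt, pred, concept) {
  g <- oracle_char_set(gt, concept)
  p <- oracle_char_set(pred, concept)
  c(precision = if (length(p)) length(intersect(g, p)) / length(p) else NA_real_,
    recall = if (length(g)) length(intersect(g, p)) / length(g) else NA_real_)
}

# literal nested-loop error taxonomy over raw rows; returns the category
# multiset as a sorted character vector of "side|doc|start|end|concept|category"
oracle_classify <- function(gt, preds) {
  if (inherits(preds, "el_annotations")) preds <- list(preds)
  g <- as.data.frame(gt)
  s <- do.call(rbind, lapply(preds, as.data.frame))
  ov <- function(a1, a2, b1, b2) max(a1, b1) < min(a2, b2)
  out <- character(0)
  add <- function(side, row, cat) {
    c(out, paste(side, row$doc_id, row$start, row$end, row$concept_id, cat, sep = "|"))
  }
  for (i in seq_len(nrow(g))) {
    matched <- FALSE
    for (j in seq_len(nrow(s))) {
      if (g$doc_id[i] == s$doc_id[j] &&
          ov(g$start[i], g$end[i], s$start[j], s$end[j])) {
        matched <- TRUE
        if (g$concept_id[i] == s$concept_id[j]) {
          out <- add("gold", g[i, ], "Correct")
        } else {
          out <- add("gold", g[i, ], "False-Negative Link")
          out <- add("pred", s[j, ], "False-Positive Link")
        }
      }
    }
    if (!matched) out <- add("gold", g[i, ], "False-Negative Span")
  }
  for (j in seq_len(nrow(s))) {
    hit <- FALSE
    for (i in seq_len(nrow(g))) {
      if (g$doc_id[i] == s$doc_id[j] &&
          ov(g$start[i], g$end[i], s$start[j], s$end[j])) hit <- TRUE
    }
    if (!hit) out <- add("pred", s[j, ], "False-Positive Span")
  }
  sort(out)
}

ledger_as_keys <- function(ledger) {
  sort(paste(ledger$side, ledger$doc_id, ledger$start, ledger$end,
             ledger$concept_id, as.character(ledger$category), sep = "|"))
}

# per-position vote counter: returns sorted "doc:pos:concept" strings of
# strict-majority winners
oracle_vote <- function(preds) {
  n_sys <- length(preds)
  votes <- list()
  for (s in preds) {
    df <- as.data.frame(s)
    for (i in seq_len(nrow(df))) {
      for (pos in seq.int(df$start[i], df$end[i] - 1L)) {
        key <- paste(df$doc_id[i], pos, df$concept_id[i], sep = ":")
        votes[[key]] <- (votes[[key]] %||0% 0L) + 1L
      }
    }
  }
  keys <- names(votes)[vapply(votes, function(v) v > n_sys / 2, logical(1))]
  sort(keys)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

vote_as_keys <- function(set) {
  ca <- char_assignment(set)
  sort(paste(ca$doc_id, ca$pos, ca$concept_id, sep = ":"))
}

# two-pass recomputation of annotation entropy straight from raw annotations,
# bypassing build_span_index
oracle_annotation_entropy <- function(sets, docs, concept) {
  if (inherits(sets, "el_annotations")) sets <- list(sets)
  ann <- do.call(rbind, lapply(sets, as.data.frame))
  ann$span <- normalize_span(span_text(docs, ann))
  a_strings <- unique(ann$span[ann$concept_id == concept])
  b <- table(ann$concept_id[ann$span %in% a_strings])
  counts <- as.numeric(b)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}
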