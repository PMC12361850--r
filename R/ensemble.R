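#' Character-level majority-vote ensemble of prediction sets
#'
#' Combines several systems' annotation sets into one by voting at the
#' granularity the metric is defined on: each character of each document.
#' A system that annotates a character votes for that concept; a system that
#' leaves it unannotated implicitly votes for "no annotation". A character
#' receives a concept only when a strict majority of systems (votes >
#' `n_systems / 2`) agree on it; ties and sub-quorum pluralities abstain.
#' Maximal runs of consecutive characters carrying the same winning concept
#' are reassembled into spans.
#'
#' The result is idempotent (voting over copies of one set returns that set)
#' and invariant to the order of the input sets.
#'
#' @param preds list of at least two [annotation_set()] objects over a
#'   shared corpus.
#' @param source_id source id for the combined set (default `"vote"`).
#' @return an [annotation_set()] with the voted annotations.
#' @export
majority_vote <- function(preds, source_id = "vote") {
  stopifnot(is.list(preds), length(preds) >= 2L,
            all(vapply(preds, inherits, logical(1), "el_annotations")))
  n_sys <- length(preds)
  ca <- do.call(rbind, lapply(preds, function(s) as.data.frame(char_assignment(s))))
  empty <- annotation_set(
    data.frame(doc_id = character(), start = integer(), end = integer(),
               concept_id = character(), stringsAsFactors = FALSE),
    source_id
  )
  if (!nrow(ca)) return(empty)

  # votes per (doc, pos, concept); strict majority admits at most one winner
  key <- paste(ca$doc_id, ca$pos, ca$concept_id, sep = "\r")
  votes <- table(key)
  win <- names(votes)[as.numeric(votes) > n_sys / 2]
  if (!length(win)) return(empty)
  parts <- do.call(rbind, strsplit(win, "\r", fixed = TRUE))
  winners <- data.frame(doc_id = parts[, 1L],
                        pos = as.integer(parts[, 2L]),
                        concept_id = parts[, 3L],
                        stringsAsFactors = FALSE)
  winners <- winners[order(winners$doc_id, winners$pos), , drop = FALSE]

  # runs of consecutive positions with an unchanged concept become spans
  n <- nrow(winners)
  new_run <- c(TRUE, winners$doc_id[-1L] != winners$doc_id[-n] |
                 winners$pos[-1L] != winners$pos[-n] + 1L |
                 winners$concept_id[-1L] != winners$concept_id[-n])
  run_id <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, n)
  annotation_set(
    data.frame(doc_id = winners$doc_id[first],
               start = winners$pos[first],
               end = winners$pos[last] + 1L,
               concept_id = winners$concept_id[first],
               stringsAsFactors = FALSE),
    source_id
  )
}
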