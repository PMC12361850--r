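ERROR_CATEGORIES <- c("Correct", "False-Positive Link", "False-Positive Span",
                      "False-Negative Link", "False-Negative Span")

#' Classify span/link errors between gold and predicted annotations
#'
#' Applies the pairwise error taxonomy to the gold standard and the bag
#' union of one or more prediction sets. For every gold annotation `g` and
#' predicted annotation `s` in the same document with overlapping spans:
#' equal concepts yield a `(g, Correct)` record; unequal concepts yield the
#' paired `(g, False-Negative Link)` and `(s, False-Positive Link)` records
#' (one linker mistake harms two concepts). A gold annotation overlapped by
#' no prediction yields `(g, False-Negative Span)`; a prediction overlapping
#' no gold annotation yields `(s, False-Positive Span)`. The nested loops
#' are applied literally, so a gold span overlapped by several predictions
#' contributes one record per overlapping pair.
#'
#' Every record carries its own annotation's span length as `char_weight`
#' (the number of characters affected).
#'
#' @param gt gold [annotation_set()].
#' @param preds a single [annotation_set()] or a list of them; several sets
#'   are combined as a bag union (duplicates preserved).
#' @param dedupe if `TRUE`, collapse to one record per annotation: a gold
#'   annotation becomes `Correct` if any overlapping prediction agrees on
#'   the concept, else `False-Negative Link` if anything overlaps it, else
#'   `False-Negative Span`; a prediction becomes `False-Positive Link` only
#'   when everything it overlaps disagrees. Default `FALSE` (literal pairwise
#'   taxonomy).
#' @return an `el_error_ledger`: a data.frame with columns `side`
#'   (`"gold"`/`"pred"`), `source_id`, `doc_id`, `start`, `end`,
#'   `concept_id`, `category`, `char_weight`.
#' @export
classify_errors <- function(gt, preds, dedupe = FALSE) {
  stopifnot(inherits(gt, "el_annotations"))
  if (inherits(preds, "el_annotations")) preds <- list(preds)
  stopifnot(length(preds) >= 1L, all(vapply(preds, inherits, logical(1), "el_annotations")))
  bag <- do.call(rbind, lapply(preds, function(s) {
    data.frame(doc_id = s$doc_id, start = s$start, end = s$end,
               concept_id = s$concept_id,
               source_id = rep(source_id(s), nrow(s)),
               stringsAsFactors = FALSE)
  }))
  gdf <- as.data.frame(gt)[, c("doc_id", "start", "end", "concept_id")]
  ng <- nrow(gdf); ns <- nrow(bag)
  pp <- if (ng && ns) overlap_pairs(gdf, bag) else
    data.frame(i = integer(), j = integer(), overlap = integer())
  same <- if (nrow(pp)) gdf$concept_id[pp$i] == bag$concept_id[pp$j] else logical()

  rec <- function(side, src, rows_df, idx, category) {
    if (!length(idx)) return(NULL)
    data.frame(side = side, source_id = src[idx],
               doc_id = rows_df$doc_id[idx], start = rows_df$start[idx],
               end = rows_df$end[idx], concept_id = rows_df$concept_id[idx],
               category = category,
               char_weight = rows_df$end[idx] - rows_df$start[idx],
               stringsAsFactors = FALSE)
  }
  gsrc <- rep(source_id(gt), ng)

  if (!dedupe) {
    records <- list(
      rec("gold", gsrc, gdf, pp$i[same], "Correct"),
      rec("gold", gsrc, gdf, pp$i[!same], "False-Negative Link"),
      rec("pred", bag$source_id, bag, pp$j[!same], "False-Positive Link"),
      rec("gold", gsrc, gdf, setdiff(seq_len(ng), unique(pp$i)), "False-Negative Span"),
      rec("pred", bag$source_id, bag, setdiff(seq_len(ns), unique(pp$j)), "False-Positive Span")
    )
  } else {
    g_correct <- unique(pp$i[same])
    g_link <- setdiff(unique(pp$i[!same]), g_correct)
    g_miss <- setdiff(seq_len(ng), unique(pp$i))
    s_correct <- unique(pp$j[same])
    s_link <- setdiff(unique(pp$j[!same]), s_correct)
    s_spur <- setdiff(seq_len(ns), unique(pp$j))
    records <- list(
      rec("gold", gsrc, gdf, g_correct, "Correct"),
      rec("gold", gsrc, gdf, g_link, "False-Negative Link"),
      rec("pred", bag$source_id, bag, s_link, "False-Positive Link"),
      rec("gold", gsrc, gdf, g_miss, "False-Negative Span"),
      rec("pred", bag$source_id, bag, s_spur, "False-Positive Span")
    )
  }
  records <- records[!vapply(records, is.null, logical(1))]
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(side = character(), source_id = character(), doc_id = character(),
               start = integer(), end = integer(), concept_id = character(),
               category = character(), char_weight = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$category <- factor(out$category, levels = ERROR_CATEGORIES)
  class(out) <- c("el_error_ledger", "data.frame")
  out
}

#' Partition concepts into hard and easy sets by IoU threshold
#'
#' A concept is *hard* when its IoU falls below the threshold in every
#' report (system); a concept absent from a report's scored concepts counts
#' as IoU 0 there. Everything else is *easy* (IoU at or above the threshold
#' for at least one system).
#'
#' @param reports a single `el_score_report` or list of them.
#' @param threshold IoU cutoff in `(0, 1)` (default 0.1).
#' @return an `el_partition`: list with `hard`, `easy` (character vectors of
#'   concept ids) and `threshold`.
#' @export
partition_hard_easy <- function(reports, threshold = 0.1) {
  if (inherits(reports, "el_score_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "el_score_report")),
            threshold > 0, threshold < 1)
  concepts <- sort(unique(unlist(lapply(reports, function(r) r$per_concept$concept_id))))
  hard <- rep(TRUE, length(concepts))
  for (r in reports) {
    iou <- r$per_concept$iou[match(concepts, r$per_concept$concept_id)]
    iou[is.na(iou)] <- 0
    hard <- hard & (iou < threshold)
  }
  structure(list(hard = concepts[hard], easy = concepts[!hard],
                 threshold = threshold),
            class = "el_partition")
}

#' @export
print.el_partition <- function(x, ...) {
  cat(sprintf("<difficulty partition at IoU < %g: %d hard, %d easy>\n",
              x$threshold, length(x$hard), length(x$easy)))
  invisible(x)
}

#' Character-weighted error-category table by difficulty class
#'
#' For each difficulty class (hard/easy), the percentage of error-record
#' character weight falling in each of the five categories; rows sum to 100.
#' A record belongs to the class of its own annotation's concept.
#'
#' @param ledger an `el_error_ledger` from [classify_errors()].
#' @param partition an `el_partition` from [partition_hard_easy()].
#' @return data.frame with columns `class`, one column per error category
#'   (percentages), and `n_records`. A class with no records gets `NA`
#'   percentages, with a warning.
#' @export
error_table <- function(ledger, partition) {
  stopifnot(inherits(ledger, "el_error_ledger"), inherits(partition, "el_partition"))
  if (!nrow(ledger)) stopf("empty error ledger")
  cls <- ifelse(ledger$concept_id %in% partition$hard, "hard", "easy")
  out <- lapply(c("hard", "easy"), function(k) {
    sub <- ledger[cls == k, , drop = FALSE]
    if (!nrow(sub)) {
      warnf("no error records for class '%s'", k)
      pct <- stats::setNames(rep(NA_real_, length(ERROR_CATEGORIES)), ERROR_CATEGORIES)
    } else {
      w <- tapply(sub$char_weight, sub$category, sum, default = 0)
      pct <- 100 * as.numeric(w) / sum(sub$char_weight)
      names(pct) <- names(w)
      pct <- pct[ERROR_CATEGORIES]
    }
    cbind(data.frame(class = k, stringsAsFactors = FALSE),
          as.data.frame(as.list(pct), check.names = FALSE),
          data.frame(n_records = nrow(sub)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank association between per-concept IoU and difficulty features
#'
#' Kendall's tau (tau-b tie handling) between each feature column and the
#' per-concept IoU, matched on concept id.
#'
#' @param report an `el_score_report`.
#' @param features an `el_feature_table` from [feature_table()] or any
#'   data.frame with a `concept_id` column plus numeric feature columns.
#' @return data.frame with columns `feature`, `tau`, `n` (concepts used).
#'   A feature that is constant over the matched concepts gets `NA` with a
#'   warning.
#' @export
feature_associations <- function(report, features) {
  stopifnot(inherits(report, "el_score_report"))
  features <- as.data.frame(features)
  if (!"concept_id" %in% names(features)) stopf("features must have a concept_id column")
  m <- merge(report$per_concept[, c("concept_id", "iou")], features, by = "concept_id")
  if (nrow(m) < 3L) stopf("need at least 3 concepts shared between report and features")
  cols <- setdiff(names(features), "concept_id")
  cols <- cols[vapply(m[cols], is.numeric, logical(1))]
  tau <- vapply(cols, function(cl) {
    x <- m[[cl]]
    ok <- !is.na(x)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L || length(unique(m$iou[ok])) < 2L) {
      warnf("feature '%s' is constant or too sparse; tau undefined", cl)
      return(NA_real_)
    }
    stats::cor(x[ok], m$iou[ok], method = "kendall")
  }, numeric(1))
  data.frame(feature = cols, tau = as.numeric(tau),
             n = vapply(cols, function(cl) sum(!is.na(m[[cl]])), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation of per-concept IoU between two systems
#'
#' @param report_a,report_b two `el_score_report` objects; concepts are
#'   matched by id and at least 3 must be shared.
#' @return Spearman's rho.
#' @export
system_correlation <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "el_score_report"), inherits(report_b, "el_score_report"))
  m <- merge(report_a$per_concept[, c("concept_id", "iou")],
             report_b$per_concept[, c("concept_id", "iou")],
             by = "concept_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stopf("need at least 3 shared concepts")
  if (length(unique(m$iou_a)) < 2L || length(unique(m$iou_b)) < 2L) {
    warnf("constant IoU vector; rho undefined")
    return(NA_real_)
  }
  stats::cor(m$iou_a, m$iou_b, method = "spearman")
}
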