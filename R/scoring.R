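#' Character-level concept assignment of an annotation set
#'
#' Materializes the indicator view of an annotation set: one row per
#' (document, character position) covered by an annotation, with the concept
#' linked there. Because annotations from one source never overlap, each
#' position carries at most one concept, and the number of rows equals the
#' total span length of the set.
#'
#' @param set an [annotation_set()].
#' @return an `el_char_assignment` data.frame with columns `doc_id`,
#'   `pos` (0-based character position), `concept_id`.
#' @export
char_assignment <- function(set) {
  stopifnot(inherits(set, "el_annotations"))
  if (!nrow(set)) {
    out <- data.frame(doc_id = character(), pos = integer(),
                      concept_id = character(), stringsAsFactors = FALSE)
  } else {
    len <- set$end - set$start
    out <- data.frame(
      doc_id = rep(set$doc_id, len),
      pos = unlist(lapply(seq_len(nrow(set)),
                          function(i) seq.int(set$start[i], set$end[i] - 1L))),
      concept_id = rep(set$concept_id, len),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("el_char_assignment", "data.frame")
  out
}

# Per-concept character tallies for a (gold, prediction) pair, computed by
# interval arithmetic (never by materializing characters): for each concept
# the gold character count, predicted character count, their intersection,
# and the number of gold annotation instances. Covers the union of concepts
# seen in either set.
concept_char_counts <- function(gt, pred) {
  stopifnot(inherits(gt, "el_annotations"), inherits(pred, "el_annotations"))
  concepts <- union(unique(gt$concept_id), unique(pred$concept_id))
  n_gt <- n_pred <- n_int <- n_inst <- stats::setNames(numeric(length(concepts)), concepts)
  if (nrow(gt)) {
    s <- sum_by(gt$end - gt$start, gt$concept_id)
    n_gt[names(s)] <- s
    k <- table(gt$concept_id)
    n_inst[names(k)] <- as.numeric(k)
  }
  if (nrow(pred)) {
    s <- sum_by(pred$end - pred$start, pred$concept_id)
    n_pred[names(s)] <- s
  }
  # intersection: spans within each set are disjoint, so pairwise overlap
  # lengths between same-document same-concept spans sum without double count
  if (nrow(gt) && nrow(pred)) {
    pp <- overlap_pairs(gt, pred)
    if (nrow(pp)) {
      same <- gt$concept_id[pp$i] == pred$concept_id[pp$j]
      if (any(same)) {
        s <- sum_by(pp$overlap[same], gt$concept_id[pp$i[same]])
        n_int[names(s)] <- s
      }
    }
  }
  data.frame(concept_id = concepts, n_gt_chars = as.numeric(n_gt),
             n_pred_chars = as.numeric(n_pred), n_intersect_chars = as.numeric(n_int),
             n_gt_instances = as.numeric(n_inst),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_annotations_or_chars <- function(x) {
  if (inherits(x, "el_annotations")) return(x)
  stopf("expected an annotation_set")
}

#' Per-concept character-level intersection-over-union
#'
#' For one concept, the ratio of characters linked to it by both sources to
#' characters linked to it by either: `|P n G| / (|P| + |G| - |P n G|)`.
#' Boundary mistakes, missed instances, and hallucinated instances all lower
#' the value; 1 means the two character sets are identical, 0 that they are
#' disjoint.
#'
#' @param gt gold [annotation_set()].
#' @param pred predicted [annotation_set()].
#' @param concept_id a single concept identifier; it must be annotated in at
#'   least one of the two sets.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' g <- annotation_set(data.frame(doc_id = "n1", start = 0, end = 7,
#'                                concept_id = "303653007"), "gold")
#' p <- annotation_set(data.frame(doc_id = "n1", start = 0, end = 2,
#'                                concept_id = "303653007"), "sys")
#' concept_iou(g, p, "303653007")  # 2/7
concept_iou <- function(gt, pred, concept_id) {
  cc <- concept_char_counts(as_annotations_or_chars(gt), as_annotations_or_chars(pred))
  i <- match(as.character(concept_id), cc$concept_id)
  if (is.na(i)) stopf("concept '%s' appears in neither set", concept_id)
  with(cc[i, ], n_intersect_chars / (n_gt_chars + n_pred_chars - n_intersect_chars))
}

#' Per-concept character-level precision and recall
#'
#' Precision is the fraction of predicted characters that are also gold
#' (`|P n G| / |P|`, undefined when the concept is never predicted); recall
#' the fraction of gold characters recovered (`|P n G| / |G|`, undefined when
#' the concept has no gold characters). Where both are defined and positive
#' they determine the IoU through
#' `IoU = P.R / (P + R - P.R)`.
#'
#' @inheritParams concept_iou
#' @return named numeric vector `c(precision = , recall = )`; an undefined
#'   component is `NA`.
#' @export
concept_precision_recall <- function(gt, pred, concept_id) {
  cc <- concept_char_counts(as_annotations_or_chars(gt), as_annotations_or_chars(pred))
  i <- match(as.character(concept_id), cc$concept_id)
  if (is.na(i)) stopf("concept '%s' appears in neither set", concept_id)
  p <- if (cc$n_pred_chars[i] > 0) cc$n_intersect_chars[i] / cc$n_pred_chars[i] else NA_real_
  r <- if (cc$n_gt_chars[i] > 0) cc$n_intersect_chars[i] / cc$n_gt_chars[i] else NA_real_
  c(precision = p, recall = r)
}

#' Score a submission against the gold standard
#'
#' Computes the per-concept character-level IoU for every concept appearing
#' in the gold standard or the prediction (a concept predicted but absent
#' from gold scores 0 and is included, so hallucinated concepts are
#' penalized), the unweighted mean IoU over those concepts, and the
#' class-weighted mean in which each concept's IoU is weighted by its number
#' of gold annotation instances. Optionally attaches a bootstrap percentile
#' confidence interval for the mean (see [bootstrap_ci()]).
#'
#' @param gt gold [annotation_set()].
#' @param pred predicted [annotation_set()].
#' @param n_boot number of bootstrap resamples for the CI of the mean IoU;
#'   0 (default) skips the bootstrap.
#' @param seed RNG seed for the bootstrap; required when `n_boot > 0`.
#' @param weighted_ci if `TRUE` the attached CI is for the class-weighted
#'   mean rather than the unweighted mean.
#' @return an `el_score_report` (list) with elements `per_concept`
#'   (data.frame: `concept_id`, `iou`, `precision`, `recall`, `n_gt_chars`,
#'   `n_pred_chars`, `n_intersect_chars`, `n_gt_instances`), `mean_iou`,
#'   `weighted_iou`, `n_concepts`, `source_id`, and when bootstrapped
#'   `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
score_submission <- function(gt, pred, n_boot = 0L, seed = NULL,
                             weighted_ci = FALSE) {
  stopifnot(inherits(gt, "el_annotations"), inherits(pred, "el_annotations"))
  if (nrow(gt) && nrow(pred) &&
      !length(intersect(unique(gt$doc_id), unique(pred$doc_id)))) {
    warnf("gold and prediction share no documents; all scores will be zero")
  }
  cc <- concept_char_counts(gt, pred)
  if (!nrow(cc)) stopf("cannot score two empty annotation sets")
  denom <- cc$n_gt_chars + cc$n_pred_chars - cc$n_intersect_chars
  cc$iou <- cc$n_intersect_chars / denom
  cc$precision <- ifelse(cc$n_pred_chars > 0, cc$n_intersect_chars / cc$n_pred_chars, NA_real_)
  cc$recall <- ifelse(cc$n_gt_chars > 0, cc$n_intersect_chars / cc$n_gt_chars, NA_real_)
  per_concept <- cc[, c("concept_id", "iou", "precision", "recall", "n_gt_chars",
                        "n_pred_chars", "n_intersect_chars", "n_gt_instances")]
  tot_inst <- sum(per_concept$n_gt_instances)
  report <- structure(
    list(
      per_concept = per_concept,
      mean_iou = mean(per_concept$iou),
      weighted_iou = if (tot_inst > 0) {
        sum(per_concept$iou * per_concept$n_gt_instances) / tot_inst
      } else NA_real_,
      n_concepts = nrow(per_concept),
      source_id = source_id(pred)
    ),
    class = "el_score_report"
  )
  if (n_boot > 0L) {
    if (is.null(seed)) stopf("a seed is required for the bootstrap")
    ci <- bootstrap_ci(report, n_boot = n_boot, seed = seed, weighted = weighted_ci)
    report$ci_low <- ci[["low"]]
    report$ci_high <- ci[["high"]]
    report$n_boot <- as.integer(n_boot)
    report$seed <- as.integer(seed)
    report$weighted <- isTRUE(weighted_ci)
  }
  report
}

#' @export
print.el_score_report <- function(x, ...) {
  cat(sprintf("<score report%s: %d concepts>\n",
              if (!is.null(x$source_id)) paste0(" for '", x$source_id, "'") else "",
              x$n_concepts))
  cat(sprintf("  mean IoU:     %.4f\n", x$mean_iou))
  cat(sprintf("  weighted IoU: %.4f\n", x$weighted_iou))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI (%s mean, %d reps): [%.4f, %.4f]\n",
                if (isTRUE(x$weighted)) "weighted" else "unweighted",
                x$n_boot, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Bootstrap percentile confidence interval for the mean IoU
#'
#' Resamples the per-concept IoU values with replacement `n_boot` times and
#' returns the 2.5%/97.5% percentiles of the resampled mean (or, with
#' `weighted = TRUE`, of the resampled class-weighted mean, each resampled
#' concept carrying its gold instance count as weight).
#'
#' @param report an `el_score_report` from [score_submission()].
#' @param n_boot number of resamples (default 1000).
#' @param seed RNG seed; the interval is reproducible for a fixed seed.
#' @param weighted resample the class-weighted mean instead of the plain mean.
#' @return named numeric vector `c(low = , high = )`.
#' @export
bootstrap_ci <- function(report, n_boot = 1000L, seed, weighted = FALSE) {
  stopifnot(inherits(report, "el_score_report"), n_boot >= 1L)
  iou <- report$per_concept$iou
  w <- report$per_concept$n_gt_instances
  n <- length(iou)
  if (n == 0L) stopf("empty per-concept table")
  if (n == 1L && !weighted) {
    warnf("single-concept report: bootstrap interval is degenerate")
  }
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    if (weighted) {
      vapply(seq_len(n_boot), function(b) {
        i <- idx[, b]
        sw <- sum(w[i])
        if (sw > 0) sum(iou[i] * w[i]) / sw else NA_real_
      }, numeric(1))
    } else {
      colMeans(matrix(iou[idx], nrow = n))
    }
  })
  q <- stats::quantile(means, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(low = q[1L], high = q[2L])
}

#' Inter-annotator agreement (instance-level Jaccard)
#'
#' Measures whether two annotation sources found the same entities and
#' linked them to the same concepts, ignoring variation in span boundaries.
#' Candidate matches are pairs (one annotation from each set) in the same
#' document, with overlapping spans and equal concepts; pairs are ranked by
#' overlap size (ties broken by earlier position) and matched greedily
#' one-to-one. The score is `|M| / (|A| + |B| - |M|)` for `|M|` matches.
#'
#' @param a,b two [annotation_set()] objects over a shared corpus.
#' @return Jaccard agreement in `[0, 1]`.
#' @export
iaa_jaccard <- function(a, b) {
  stopifnot(inherits(a, "el_annotations"), inherits(b, "el_annotations"))
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  pp <- overlap_pairs(a, b)
  pp <- pp[a$concept_id[pp$i] == b$concept_id[pp$j], , drop = FALSE]
  m <- 0L
  if (nrow(pp)) {
    ord <- order(-pp$overlap, a$start[pp$i], b$start[pp$j], pp$i, pp$j)
    pp <- pp[ord, , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    for (k in seq_len(nrow(pp))) {
      i <- pp$i[k]; j <- pp$j[k]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        m <- m + 1L
      }
    }
  }
  m / (na + nb - m)
}

#' Histogram series of per-concept IoU scores
#'
#' Convenience export for the strongly bimodal per-concept score
#' distributions typical of this task: counts of concepts per IoU bin.
#'
#' @param report an `el_score_report`.
#' @param breaks number of equal-width bins over `[0, 1]` (default 20).
#' @return data.frame with columns `bin_low`, `bin_high`, `count`.
#' @export
iou_histogram <- function(report, breaks = 20L) {
  stopifnot(inherits(report, "el_score_report"))
  edges <- seq(0, 1, length.out = breaks + 1L)
  h <- graphics::hist(report$per_concept$iou, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
             count = h$counts)
}
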