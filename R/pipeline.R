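#' Run the full evaluation pipeline
#'
#' Orchestrates scoring, ensembling, difficulty partitioning, error
#' classification, feature computation, and rank-association reporting for
#' one gold standard and one or more prediction sets, writing all results as
#' JSON/CSV plus a manifest under `out_dir`.
#'
#' `config` is a list (or path to a flat YAML file) with fields:
#' \describe{
#'   \item{docs}{an [corpus()] or path readable by [read_corpus()].}
#'   \item{gold}{test-split gold [annotation_set()] or CSV path.}
#'   \item{gold_train}{optional training-split gold set or CSV path (used for
#'     the `n_examples`/`n_notes` features; omitted means those are 0).}
#'   \item{preds}{named list of annotation sets, or character vector of CSV
#'     paths (names become system ids).}
#'   \item{terminology}{an [terminology()] or `c(synonyms, edges)` TSV paths.}
#'   \item{root_id}{terminology root (required with TSV paths).}
#'   \item{threshold}{hard/easy IoU cutoff (default 0.1).}
#'   \item{n_boot}{bootstrap resamples per system (default 1000).}
#'   \item{seed}{seed for the bootstrap (default 1).}
#'   \item{out_dir}{output directory.}
#' }
#'
#' Outputs written: `scores.json` (per-system aggregates and CIs),
#' `per_concept_<sys>.csv`, `iou_hist_<sys>.csv`, `voted.csv` and voted
#' scores inside `scores.json`, `partition.json`, `errors.csv` (the ledger),
#' `error_table.csv`, `features.csv`, `associations.json`, and
#' `manifest.json` (package version, seeds, input digests). The manifest is
#' byte-reproducible for identical inputs and seed.
#'
#' @param config list or YAML path as described above.
#' @return invisibly, a list with every in-memory result
#'   (`scores`, `voted`, `voted_score`, `partition`, `ledger`,
#'   `error_table`, `features`, `associations`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  threshold <- config$threshold %||% 0.1
  n_boot <- config$n_boot %||% 1000L
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_files <- character(0)
  docs <- stage("load_docs", {
    if (inherits(config$docs, "el_corpus")) config$docs
    else { input_files <- c(input_files, config$docs); read_corpus(config$docs) }
  })
  gold <- stage("load_gold", {
    if (inherits(config$gold, "el_annotations")) config$gold
    else { input_files <- c(input_files, config$gold); read_annotations(config$gold, "gold") }
  })
  gold_train <- stage("load_gold_train", {
    if (is.null(config$gold_train)) {
      annotation_set(gold[0, ], "gold_train")
    } else if (inherits(config$gold_train, "el_annotations")) config$gold_train
    else { input_files <- c(input_files, config$gold_train)
           read_annotations(config$gold_train, "gold_train") }
  })
  preds <- stage("load_preds", {
    p <- config$preds
    if (is.character(p)) {
      nm <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p) else
        sub("\\.csv$", "", basename(p))
      input_files <- c(input_files, p)
      p <- stats::setNames(lapply(seq_along(p), function(i)
        read_annotations(p[[i]], nm[i])), nm)
    }
    stopifnot(is.list(p), length(p) >= 1L)
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      names(p) <- vapply(p, source_id, character(1))
    }
    p
  })
  term <- stage("load_terminology", {
    t <- config$terminology
    if (is.null(t)) NULL
    else if (inherits(t, "el_terminology")) t
    else {
      stopifnot(length(t) == 2L, !is.null(config$root_id))
      input_files <- c(input_files, t)
      read_terminology(t[[1]], t[[2]], config$root_id)
    }
  })

  scores <- stage("score", {
    lapply(preds, function(p) score_submission(gold, p, n_boot = n_boot, seed = seed))
  })

  voted <- NULL; voted_score <- NULL
  if (length(preds) >= 2L) {
    voted <- stage("vote", majority_vote(unname(preds)))
    voted_score <- stage("score_voted",
                         score_submission(gold, voted, n_boot = n_boot, seed = seed))
  }

  partition <- stage("partition", partition_hard_easy(scores, threshold))
  ledger <- stage("errors", classify_errors(gold, unname(preds)))
  etab <- stage("error_table", suppressWarnings(error_table(ledger, partition)))

  features <- NULL; assoc <- NULL
  if (!is.null(term)) {
    features <- stage("features", feature_table(gold_train, gold, docs, term))
    assoc <- stage("associations", {
      lapply(scores, function(r) {
        if (r$n_concepts >= 3L) suppressWarnings(feature_associations(r, features))
        else NULL
      })
    })
  }

  sys_cor <- NULL
  if (length(scores) >= 2L) {
    sys_cor <- stage("system_correlation", {
      nm <- names(scores)
      pairs <- utils::combn(nm, 2L, simplify = FALSE)
      do.call(rbind, lapply(pairs, function(pr) {
        data.frame(system_a = pr[1], system_b = pr[2],
                   spearman_rho = suppressWarnings(
                     system_correlation(scores[[pr[1]]], scores[[pr[2]]])),
                   stringsAsFactors = FALSE)
      }))
    })
  }

  # ---- write outputs -------------------------------------------------------
  agg <- function(r) list(mean_iou = r$mean_iou, weighted_iou = r$weighted_iou,
                          n_concepts = r$n_concepts,
                          ci_low = r$ci_low, ci_high = r$ci_high,
                          n_boot = r$n_boot, seed = r$seed)
  scores_out <- lapply(scores, agg)
  if (!is.null(voted_score)) scores_out$vote <- agg(voted_score)
  jsonlite::write_json(scores_out, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (nm in names(scores)) {
    utils::write.csv(scores[[nm]]$per_concept,
                     file.path(out_dir, paste0("per_concept_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(iou_histogram(scores[[nm]]),
                     file.path(out_dir, paste0("iou_hist_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(voted)) write_annotations(voted, file.path(out_dir, "voted.csv"))
  jsonlite::write_json(list(threshold = partition$threshold,
                            hard = partition$hard, easy = partition$easy),
                       file.path(out_dir, "partition.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(ledger), file.path(out_dir, "errors.csv"),
                   row.names = FALSE)
  utils::write.csv(etab, file.path(out_dir, "error_table.csv"), row.names = FALSE)
  if (!is.null(features)) {
    utils::write.csv(as.data.frame(features), file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  }
  if (!is.null(assoc) || !is.null(sys_cor)) {
    jsonlite::write_json(list(feature_tau = assoc, system_spearman = sys_cor),
                         file.path(out_dir, "associations.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }

  manifest <- list(
    package = "linkeval",
    version = as.character(utils::packageVersion("linkeval")),
    seed = seed, n_boot = n_boot, threshold = threshold,
    systems = names(preds),
    n_gold = nrow(gold), n_gold_train = nrow(gold_train),
    n_docs = nrow(docs),
    input_md5 = if (length(input_files)) {
      as.list(stats::setNames(unname(tools::md5sum(input_files)),
                              basename(input_files)))
    } else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scores = scores, voted = voted, voted_score = voted_score,
                 partition = partition, ledger = ledger, error_table = etab,
                 features = features, associations = assoc,
                 system_correlation = sys_cor, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
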