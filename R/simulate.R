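# fixed 7-item section list emulating the structure of discharge notes
SECTION_HEADERS <- c(
  "Chief Complaint", "History of Present Illness", "Past Medical History",
  "Physical Exam", "Laboratory Results", "Assessment and Plan",
  "Discharge Instructions"
)

LEX_ADJ <- c("acute", "chronic", "mild", "moderate", "severe", "stable",
             "elevated", "decreased", "bilateral", "left", "right",
             "recurrent", "diffuse", "focal", "intermittent", "persistent",
             "progressive", "residual", "worsening", "improving")
LEX_NOUN <- c("pain", "lesion", "fracture", "effusion", "edema", "mass",
              "stenosis", "infection", "inflammation", "hemorrhage",
              "hypertension", "nausea", "fever", "cough", "dyspnea", "rash",
              "anemia", "tachycardia", "weakness", "swelling")
LEX_SITE <- c("chest", "abdomen", "head", "neck", "knee", "shoulder", "hip",
              "spine", "pelvis", "ankle", "wrist", "elbow", "lung", "liver",
              "kidney", "bladder", "skin", "ear", "eye", "sinus")
LEX_FILLER <- c("patient", "reports", "noted", "on", "exam", "with",
                "history", "denies", "evidence", "today", "followup",
                "continues", "without", "new", "complaints", "since",
                "admission", "reviewed", "plan", "monitor", "discussed",
                "unremarkable", "tolerating", "well", "course")

#' Configuration for the synthetic benchmark generator
#'
#' Bundles every knob of the generator: the terminology shape, the corpus
#' shape, the concept frequency law, the span/concept ambiguity level, and
#' the four-channel prediction-noise process. Identical configuration and
#' seed always produce byte-identical outputs through the writers.
#'
#' Defaults emulate a desk-scale version of a clinical annotation exercise:
#' a few hundred concepts in a multi-hierarchy, a few dozen sectioned notes
#' with tens of annotations each, a heavy-tailed (Zipf) concept frequency
#' law, and moderate noise on every channel.
#'
#' @param seed integer RNG seed.
#' @param n_concepts number of concepts including the root.
#' @param branching target mean number of children per internal concept.
#' @param max_depth maximum is-a depth of any concept.
#' @param synonyms_per_concept integer range `c(min, max)` of synonym strings
#'   per concept.
#' @param multi_parent_frac fraction of eligible concepts given a second
#'   parent (multi-hierarchy).
#' @param zipf_exponent exponent `s > 0` of the concept frequency law
#'   (weight of the rank-r concept proportional to `r^-s`).
#' @param n_docs number of documents.
#' @param anns_per_doc integer range `c(min, max)` of gold annotations per
#'   document.
#' @param ambiguity fraction of synonym strings deliberately shared between
#'   at least two concepts (drives annotation entropy).
#' @param p_miss probability a gold span is dropped from a prediction
#'   (missed entity; False-Negative Span channel).
#' @param p_confuse probability a kept span is re-linked to a sibling
#'   concept (link confusion; False-Negative/False-Positive Link channel).
#' @param jitter maximum boundary extension/contraction in characters.
#' @param spur_rate expected number of spurious predicted spans per document
#'   (False-Positive Span channel).
#' @return an `el_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_concepts = 300L,
                       branching = 3,
                       max_depth = 6L,
                       synonyms_per_concept = c(1L, 4L),
                       multi_parent_frac = 0.15,
                       zipf_exponent = 1.1,
                       n_docs = 40L,
                       anns_per_doc = c(20L, 40L),
                       ambiguity = 0.2,
                       p_miss = 0.1,
                       p_confuse = 0.1,
                       jitter = 2L,
                       spur_rate = 1) {
  cfg <- list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
              branching = branching, max_depth = as.integer(max_depth),
              synonyms_per_concept = as.integer(synonyms_per_concept),
              multi_parent_frac = multi_parent_frac,
              zipf_exponent = zipf_exponent, n_docs = as.integer(n_docs),
              anns_per_doc = as.integer(anns_per_doc), ambiguity = ambiguity,
              p_miss = p_miss, p_confuse = p_confuse,
              jitter = as.integer(jitter), spur_rate = spur_rate)
  probs <- c(miss = cfg$p_miss, confuse = cfg$p_confuse,
             ambiguity = cfg$ambiguity, multi_parent = cfg$multi_parent_frac)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$zipf_exponent <= 0) stopf("zipf_exponent must be positive")
  if (cfg$n_concepts < 1L) stopf("need at least one concept (the root)")
  if (cfg$ambiguity > 0 && cfg$n_concepts < 3L) {
    stopf("ambiguity > 0 needs at least 3 concepts (root plus two to share a string)")
  }
  if (length(cfg$synonyms_per_concept) != 2L || any(cfg$synonyms_per_concept < 1L) ||
      cfg$synonyms_per_concept[1] > cfg$synonyms_per_concept[2]) {
    stopf("synonyms_per_concept must be an increasing range of positive counts")
  }
  if (length(cfg$anns_per_doc) != 2L || any(cfg$anns_per_doc < 1L) ||
      cfg$anns_per_doc[1] > cfg$anns_per_doc[2]) {
    stopf("anns_per_doc must be an increasing range of positive counts")
  }
  if (cfg$jitter < 0L || cfg$spur_rate < 0) stopf("jitter and spur_rate must be non-negative")
  structure(cfg, class = "el_sim_config")
}

# pseudo-clinical phrase, unique against `used` (an environment used as set)
make_phrase <- function(used) {
  for (attempt in 1:50) {
    pattern <- sample.int(4L, 1L)
    s <- switch(pattern,
                paste(sample(LEX_ADJ, 1L), sample(LEX_NOUN, 1L)),
                paste(sample(LEX_NOUN, 1L), "of", sample(LEX_SITE, 1L)),
                paste(sample(LEX_ADJ, 1L), sample(LEX_SITE, 1L), sample(LEX_NOUN, 1L)),
                paste(sample(LEX_SITE, 1L), sample(LEX_NOUN, 1L)))
    if (!exists(s, envir = used, inherits = FALSE)) {
      assign(s, TRUE, envir = used)
      return(s)
    }
  }
  # lexicon exhausted at this size: disambiguate deterministically
  k <- 1L
  repeat {
    s2 <- paste(s, "type", k)
    if (!exists(s2, envir = used, inherits = FALSE)) {
      assign(s2, TRUE, envir = used)
      return(s2)
    }
    k <- k + 1L
  }
}

#' Generate a synthetic terminology
#'
#' Builds a rooted acyclic is-a multi-hierarchy of `n_concepts` concepts:
#' each non-root concept gets one parent among concepts shallower than
#' `max_depth` (parents with spare child capacity relative to `branching`
#' are preferred) and a fraction of concepts at depth >= 2 receive a second,
#' strictly shallower parent. Each concept receives 1 or more pseudo-clinical
#' synonym strings, and an `ambiguity` fraction of the distinct strings is
#' additionally assigned to a sibling concept, creating the many-to-many
#' span/concept ambiguity that drives annotation entropy.
#'
#' @param config an [sim_config()].
#' @return an [terminology()] object. Deterministic for a fixed config.
#' @export
gen_terminology <- function(config) {
  stopifnot(inherits(config, "el_sim_config"))
  with_seed(config$seed, {
    n <- config$n_concepts
    ids <- c("100000000", if (n > 1L) as.character(100000000 + seq_len(n - 1L)))
    root <- ids[1L]
    depth <- stats::setNames(integer(n), ids)
    n_children <- stats::setNames(integer(n), ids)
    child <- parent <- character(0)

    if (n > 1L) {
      for (i in 2:n) {
        eligible <- ids[seq_len(i - 1L)]
        eligible <- eligible[depth[eligible] < config$max_depth]
        w <- pmax(0.1, config$branching - n_children[eligible])
        p1 <- if (length(eligible) == 1L) eligible else sample(eligible, 1L, prob = w)
        child <- c(child, ids[i]); parent <- c(parent, p1)
        depth[ids[i]] <- depth[p1] + 1L
        n_children[p1] <- n_children[p1] + 1L
      }
      # second parents: strictly shallower, so the graph stays acyclic
      for (i in 2:n) {
        if (depth[ids[i]] >= 2L && stats::runif(1) < config$multi_parent_frac) {
          shallower <- ids[depth[ids] < depth[ids[i]]]
          shallower <- setdiff(shallower, parent[child == ids[i]])
          if (length(shallower)) {
            p2 <- if (length(shallower) == 1L) shallower else sample(shallower, 1L)
            child <- c(child, ids[i]); parent <- c(parent, p2)
          }
        }
      }
    }

    used <- new.env(parent = emptyenv())
    synonyms <- lapply(seq_len(n), function(i) {
      if (i == 1L) return("clinical concept (root)")
      k <- sample_range(config$synonyms_per_concept)
      vapply(seq_len(k), function(j) make_phrase(used), character(1))
    })
    names(synonyms) <- ids

    # share a fraction of strings with a sibling (or any other concept)
    if (config$ambiguity > 0 && n > 2L) {
      all_strings <- data.frame(
        concept = rep(ids[-1L], lengths(synonyms[-1L])),
        s = unlist(synonyms[-1L], use.names = FALSE),
        stringsAsFactors = FALSE
      )
      n_share <- round(config$ambiguity * nrow(all_strings))
      if (n_share > 0L) {
        pick <- sample.int(nrow(all_strings), min(n_share, nrow(all_strings)))
        for (k in pick) {
          own <- all_strings$concept[k]
          par_k <- parent[child == own]
          sibs <- setdiff(child[parent %in% par_k], own)
          pool <- if (length(sibs)) sibs else setdiff(ids[-1L], own)
          if (!length(pool)) next
          other <- if (length(pool) == 1L) pool else sample(pool, 1L)
          if (!all_strings$s[k] %in% synonyms[[other]]) {
            synonyms[[other]] <- c(synonyms[[other]], all_strings$s[k])
          }
        }
      }
    }
    terminology(synonyms,
                data.frame(child = child, parent = parent, stringsAsFactors = FALSE),
                root)
  })
}

filler_phrase <- function() paste(sample(LEX_FILLER, sample(2:5, 1L), replace = TRUE),
                                  collapse = " ")

#' Generate a synthetic corpus with gold annotations
#'
#' Composes `n_docs` sectioned documents (a fixed 7-item header list) whose
#' free text embeds synonym mentions of terminology concepts. Concepts are
#' drawn with replacement under a Zipf law (`rank^-zipf_exponent`), so the
#' example distribution is heavy-tailed: a few very frequent concepts and a
#' long tail of rare ones. Gold offsets exactly cover the embedded mentions
#' and never overlap.
#'
#' @param term an [terminology()], typically from [gen_terminology()].
#' @param config an [sim_config()].
#' @return list with `docs` (an [corpus()]) and `gold` (an
#'   [annotation_set()] with source id `"gold"`). Deterministic for a fixed
#'   config.
#' @export
gen_corpus <- function(term, config) {
  stopifnot(inherits(term, "el_terminology"), inherits(config, "el_sim_config"))
  with_seed(config$seed + 1L, {
    mentionable <- setdiff(term$concept_ids, term$root_id)
    if (!length(mentionable)) mentionable <- term$root_id
    zipf_w <- seq_along(mentionable)^(-config$zipf_exponent)

    doc_ids <- sprintf("note%04d", seq_len(config$n_docs))
    texts <- character(config$n_docs)
    gold <- vector("list", config$n_docs)

    for (d in seq_len(config$n_docs)) {
      m <- sample_range(config$anns_per_doc)
      cids <- sample(mentionable, m, replace = TRUE, prob = zipf_w)
      mentions <- vapply(cids, function(cc) {
        syn <- term$synonyms[[cc]]
        if (length(syn) == 1L) syn else sample(syn, 1L)
      }, character(1))
      section_of <- sort(sample.int(length(SECTION_HEADERS), m, replace = TRUE))

      pieces <- character(0)
      is_mention <- logical(0)
      mention_concept <- character(0)
      for (s in seq_along(SECTION_HEADERS)) {
        pieces <- c(pieces, paste0(SECTION_HEADERS[s], ":\n"))
        is_mention <- c(is_mention, FALSE)
        mention_concept <- c(mention_concept, NA_character_)
        for (k in which(section_of == s)) {
          pieces <- c(pieces, paste0(filler_phrase(), " "), mentions[k],
                      paste0(" ", filler_phrase(), ".\n"))
          is_mention <- c(is_mention, FALSE, TRUE, FALSE)
          mention_concept <- c(mention_concept, NA_character_, cids[k], NA_character_)
        }
      }
      lens <- nchar(pieces, type = "chars")
      starts <- cumsum(c(0L, lens[-length(lens)]))
      texts[d] <- paste(pieces, collapse = "")
      gold[[d]] <- data.frame(
        doc_id = doc_ids[d],
        start = starts[is_mention],
        end = starts[is_mention] + lens[is_mention],
        concept_id = mention_concept[is_mention],
        stringsAsFactors = FALSE
      )
    }
    list(docs = corpus(doc_ids, texts),
         gold = annotation_set(do.call(rbind, gold), "gold"))
  })
}

# sibling pool of a concept: shares at least one parent; falls back to any
# other non-root concept when the concept has no sibling
sibling_pool <- function(term, concept) {
  par <- term$edges$parent[term$edges$child == concept]
  sibs <- setdiff(unique(term$edges$child[term$edges$parent %in% par]), concept)
  if (!length(sibs)) sibs <- setdiff(term$concept_ids, c(concept, term$root_id))
  sibs
}

#' Corrupt a gold annotation set into a noisy prediction set
#'
#' Applies the four-channel noise process, each channel mirroring one error
#' category of the taxonomy:
#' 1. *miss* — each gold span is independently dropped with probability
#'    `p_miss` (produces False-Negative Span errors);
#' 2. *confuse* — each surviving span is re-linked to a sibling concept with
#'    probability `p_confuse` (False-Negative Link / False-Positive Link);
#' 3. *jitter* — boundaries of surviving spans are shifted by up to
#'    `jitter` characters, clamped so spans never overlap each other or
#'    leave the document; an infeasible jitter is skipped and logged;
#' 4. *spurious* — `Poisson(spur_rate)` extra spans per document are placed
#'    on unannotated text, each carrying a real synonym string of a random
#'    concept (False-Positive Span).
#'
#' Every event is recorded in a truth log from which the expected
#' error-category totals can be recomputed exactly.
#'
#' @param gold gold [annotation_set()].
#' @param term an [terminology()] (for sibling confusion).
#' @param docs an [corpus()] (for document bounds and spurious placement).
#' @param noise list with elements `p_miss`, `p_confuse`, `jitter`,
#'   `spur_rate` (an [sim_config()] works).
#' @param seed RNG seed.
#' @param source_id source id of the returned prediction set.
#' @return list with `pred` (an [annotation_set()]) and `log` (data.frame
#'   with columns `event`, `doc_id`, `concept_id`, `new_concept_id`,
#'   `start`, `end`, `new_start`, `new_end`).
#' @export
perturb <- function(gold, term, docs, noise, seed, source_id = "sys") {
  stopifnot(inherits(gold, "el_annotations"), inherits(term, "el_terminology"),
            inherits(docs, "el_corpus"))
  p_miss <- noise$p_miss; p_confuse <- noise$p_confuse
  jit <- as.integer(noise$jitter); spur <- noise$spur_rate
  stopifnot(p_miss >= 0, p_miss <= 1, p_confuse >= 0, p_confuse <= 1,
            jit >= 0, spur >= 0)

  log_rows <- list()
  note <- function(event, doc_id, concept_id, new_concept_id = NA_character_,
                   start = NA_integer_, end = NA_integer_,
                   new_start = NA_integer_, new_end = NA_integer_) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      event = event, doc_id = doc_id, concept_id = concept_id,
      new_concept_id = new_concept_id, start = start, end = end,
      new_start = new_start, new_end = new_end, stringsAsFactors = FALSE)
  }

  pred <- with_seed(seed, {
    df <- as.data.frame(gold)[, c("doc_id", "start", "end", "concept_id")]
    n <- nrow(df)

    # channel 1: missed spans
    keep <- stats::runif(n) >= p_miss
    for (k in which(!keep)) {
      note("miss", df$doc_id[k], df$concept_id[k],
           start = df$start[k], end = df$end[k])
    }
    df <- df[keep, , drop = FALSE]

    # channel 2: link confusion towards siblings
    if (nrow(df)) {
      confuse <- stats::runif(nrow(df)) < p_confuse
      for (k in which(confuse)) {
        pool <- sibling_pool(term, df$concept_id[k])
        if (!length(pool)) next
        new_c <- if (length(pool) == 1L) pool else sample(pool, 1L)
        note("confuse", df$doc_id[k], df$concept_id[k], new_concept_id = new_c,
             start = df$start[k], end = df$end[k])
        df$concept_id[k] <- new_c
      }
    }

    # channel 3: boundary jitter, clamped to keep spans disjoint and in-bounds
    if (jit > 0L && nrow(df)) {
      df <- df[order(df$doc_id, df$start), , drop = FALSE]
      doc_len <- nchar(doc_text(docs, df$doc_id), type = "chars")
      prev_end <- 0L
      for (k in seq_len(nrow(df))) {
        if (k > 1L && df$doc_id[k] != df$doc_id[k - 1L]) prev_end <- 0L
        next_start <- if (k < nrow(df) && df$doc_id[k + 1L] == df$doc_id[k]) {
          df$start[k + 1L]
        } else doc_len[k]
        ds <- sample(seq.int(-jit, jit), 1L)
        de <- sample(seq.int(-jit, jit), 1L)
        ns <- max(df$start[k] + ds, prev_end, 0L)
        ne <- min(df$end[k] + de, next_start, doc_len[k])
        if (ns < ne && (ns != df$start[k] || ne != df$end[k])) {
          note("jitter", df$doc_id[k], df$concept_id[k],
               start = df$start[k], end = df$end[k], new_start = ns, new_end = ne)
          df$start[k] <- ns; df$end[k] <- ne
        } else if (ns >= ne) {
          note("jitter_skipped", df$doc_id[k], df$concept_id[k],
               start = df$start[k], end = df$end[k])
        }
        prev_end <- df$end[k]
      }
    }

    # channel 4: spurious spans on unannotated text
    if (spur > 0) {
      lexicon_pool <- setdiff(term$concept_ids, term$root_id)
      if (!length(lexicon_pool)) lexicon_pool <- term$concept_ids
      for (d in seq_len(nrow(docs))) {
        k_spur <- stats::rpois(1L, spur)
        if (k_spur == 0L) next
        dlen <- nchar(docs$text[d], type = "chars")
        for (j in seq_len(k_spur)) {
          occupied <- df[df$doc_id == docs$doc_id[d], , drop = FALSE]
          occupied <- occupied[order(occupied$start), , drop = FALSE]
          gap_start <- c(0L, occupied$end)
          gap_end <- c(occupied$start, dlen)
          cc <- if (length(lexicon_pool) == 1L) lexicon_pool else sample(lexicon_pool, 1L)
          syn <- term$synonyms[[cc]]
          s <- if (length(syn) == 1L) syn else sample(syn, 1L)
          len <- nchar(s, type = "chars")
          fits <- which(gap_end - gap_start >= len)
          if (!length(fits)) {
            note("spurious_skipped", docs$doc_id[d], cc)
            next
          }
          g <- if (length(fits) == 1L) fits else sample(fits, 1L)
          off_max <- gap_end[g] - len
          st <- if (off_max > gap_start[g]) {
            gap_start[g] + sample.int(off_max - gap_start[g] + 1L, 1L) - 1L
          } else gap_start[g]
          df <- rbind(df, data.frame(doc_id = docs$doc_id[d], start = st,
                                     end = st + len, concept_id = cc,
                                     stringsAsFactors = FALSE))
          note("spurious", docs$doc_id[d], cc, start = st, end = st + len)
        }
      }
    }
    df
  })

  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(event = character(), doc_id = character(), concept_id = character(),
               new_concept_id = character(), start = integer(), end = integer(),
               new_start = integer(), new_end = integer(), stringsAsFactors = FALSE)
  list(pred = annotation_set(pred, source_id), log = log_df)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Convenience wrapper: terminology, corpus, gold annotations, and
#' `n_systems` independently corrupted prediction sets, each with its truth
#' log. All randomness derives from `config$seed`, so identical
#' configurations reproduce identical bundles.
#'
#' @param config an [sim_config()].
#' @param n_systems number of noisy prediction sets to emit.
#' @return an `el_bundle`: list with `term`, `docs`, `gold`, `preds` (named
#'   list of annotation sets), `logs` (named list of truth logs), `config`.
#' @export
simulate_bundle <- function(config, n_systems = 3L) {
  stopifnot(inherits(config, "el_sim_config"), n_systems >= 1L)
  term <- gen_terminology(config)
  cg <- gen_corpus(term, config)
  preds <- logs <- list()
  for (i in seq_len(n_systems)) {
    sid <- sprintf("sys%d", i)
    p <- perturb(cg$gold, term, cg$docs, config,
                 seed = config$seed + 100L + i, source_id = sid)
    preds[[sid]] <- p$pred
    logs[[sid]] <- p$log
  }
  structure(list(term = term, docs = cg$docs, gold = cg$gold,
                 preds = preds, logs = logs, config = config),
            class = "el_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Writes `docs.csv`, `gold.csv`, one `pred_<sys>.csv` per system,
#' `synonyms.tsv` / `edges.tsv`, and `truthlog.json`.
#'
#' @param bundle an `el_bundle` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "el_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(bundle$docs, file.path(dir, "docs.csv"))
  write_annotations(bundle$gold, file.path(dir, "gold.csv"))
  for (sid in names(bundle$preds)) {
    write_annotations(bundle$preds[[sid]], file.path(dir, paste0("pred_", sid, ".csv")))
  }
  write_terminology(bundle$term, file.path(dir, "synonyms.tsv"),
                    file.path(dir, "edges.tsv"))
  jsonlite::write_json(bundle$logs, file.path(dir, "truthlog.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
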