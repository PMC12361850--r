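test_that("identical config and seed reproduce the bundle byte-for-byte", {
  cfg <- sim_config(seed = 23L, n_concepts = 60L, n_docs = 8L,
                    anns_per_doc = c(5L, 12L))
  b1 <- simulate_bundle(cfg, n_systems = 2L)
  b2 <- simulate_bundle(cfg, n_systems = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("terminology generator respects size, depth, and ambiguity bounds", {
  expect_equal(gen_terminology(sim_config(seed = 1L, n_concepts = 1L,
                                          ambiguity = 0))$concept_ids,
               "100000000")

  cfg <- sim_config(seed = 3L, n_concepts = 120L, max_depth = 3L)
  t <- gen_terminology(cfg)
  expect_length(t$concept_ids, 120L)
  expect_true(all(concept_depth(t, t$concept_ids) <= 3L))
  expect_true(igraph::is_dag(t$graph))

  # ambiguity: a sizeable set of strings is linked to >= 2 concepts
  strings <- unlist(t$synonyms[setdiff(t$concept_ids, t$root_id)])
  dup <- unique(strings[duplicated(strings)])
  expect_gt(length(dup), 0L)

  expect_error(sim_config(n_concepts = 2L, ambiguity = 0.5), "ambiguity")
  expect_error(sim_config(zipf_exponent = 0), "zipf")
  expect_error(sim_config(p_miss = 1.5), "probabilities")
})

test_that("corpus generator embeds exact, extractable, non-overlapping mentions", {
  cfg <- zero_noise_config(seed = 7L, n_concepts = 40L, n_docs = 6L,
                           anns_per_doc = c(9L, 9L))
  t <- gen_terminology(cfg)
  cg <- gen_corpus(t, cfg)
  expect_equal(nrow(cg$docs), 6L)
  # fixed annotation count per document
  expect_true(all(table(cg$gold$doc_id) == 9L))
  # every gold span extracts to a synonym of its concept (construction)
  txt <- span_text(cg$docs, cg$gold)
  ok <- vapply(seq_len(nrow(cg$gold)), function(i)
    txt[i] %in% t$synonyms[[cg$gold$concept_id[i]]], logical(1))
  expect_true(all(ok))
  # all 7 section headers present in each document
  expect_true(all(vapply(cg$docs$text, function(x)
    all(vapply(linkeval:::SECTION_HEADERS, grepl, logical(1), x, fixed = TRUE)),
    logical(1))))
})

test_that("concept frequencies follow the configured Zipf law", {
  cfg <- zero_noise_config(seed = 13L, n_concepts = 50L, n_docs = 400L,
                           anns_per_doc = c(60L, 60L), zipf_exponent = 1,
                           ambiguity = 0)
  t <- gen_terminology(cfg)
  cg <- gen_corpus(t, cfg)
  # rank-1 concept is the first non-root id by construction
  mentionable <- setdiff(t$concept_ids, t$root_id)
  n1 <- sum(cg$gold$concept_id == mentionable[1])
  n2 <- sum(cg$gold$concept_id == mentionable[2])
  # with exponent 1 the expected rank-1 : rank-2 ratio is 2
  expect_equal(n1 / n2, 2, tolerance = 0.1)
})

test_that("the noise channels act as configured at the extremes", {
  cfg <- zero_noise_config(seed = 31L, n_concepts = 40L, n_docs = 5L,
                           anns_per_doc = c(8L, 8L))
  t <- gen_terminology(cfg)
  cg <- gen_corpus(t, cfg)

  # zero noise: prediction equals gold, truth log empty
  p0 <- perturb(cg$gold, t, cg$docs, cfg, seed = 1L)
  expect_equal(bare(p0$pred), bare(cg$gold))
  expect_equal(nrow(p0$log), 0L)

  # p_miss = 1: empty prediction, every gold concept scores 0
  p1 <- perturb(cg$gold, t, cg$docs,
                list(p_miss = 1, p_confuse = 0, jitter = 0L, spur_rate = 0),
                seed = 1L)
  expect_equal(nrow(p1$pred), 0L)
  expect_true(all(p1$log$event == "miss"))
  r <- score_submission(cg$gold, p1$pred)
  expect_equal(r$mean_iou, 0)

  # confusion only: spans unchanged, concepts re-linked where logged
  p2 <- perturb(cg$gold, t, cg$docs,
                list(p_miss = 0, p_confuse = 1, jitter = 0L, spur_rate = 0),
                seed = 2L)
  expect_equal(nrow(p2$pred), nrow(cg$gold))
  expect_equal(as.data.frame(p2$pred)[, c("doc_id", "start", "end")],
               as.data.frame(cg$gold)[, c("doc_id", "start", "end")])
  expect_true(all(p2$pred$concept_id != cg$gold$concept_id))
  expect_true(all(p2$log$event == "confuse"))

  # spurious only: extra spans, all logged, none overlapping gold
  p3 <- perturb(cg$gold, t, cg$docs,
                list(p_miss = 0, p_confuse = 0, jitter = 0L, spur_rate = 2),
                seed = 3L)
  n_spur <- sum(p3$log$event == "spurious")
  expect_equal(nrow(p3$pred), nrow(cg$gold) + n_spur)
  led <- classify_errors(cg$gold, p3$pred)
  expect_equal(sum(led$category == "False-Positive Span"), n_spur)
})

test_that("the truth log recomputes expected error totals exactly (miss channel)", {
  cfg <- zero_noise_config(seed = 43L, n_concepts = 60L, n_docs = 10L,
                           anns_per_doc = c(15L, 15L))
  t <- gen_terminology(cfg)
  cg <- gen_corpus(t, cfg)
  p <- perturb(cg$gold, t, cg$docs,
               list(p_miss = 0.4, p_confuse = 0, jitter = 0L, spur_rate = 0),
               seed = 9L)
  led <- classify_errors(cg$gold, p$pred)
  fn_span <- led[led$category == "False-Negative Span", ]
  miss <- p$log[p$log$event == "miss", ]
  expect_equal(sum(fn_span$char_weight), sum(miss$end - miss$start))
  expect_equal(nrow(fn_span), nrow(miss))
})

test_that("jittered predictions never overlap and stay in bounds", {
  cfg <- sim_config(seed = 51L, n_concepts = 40L, n_docs = 8L,
                    anns_per_doc = c(10L, 15L), p_miss = 0, p_confuse = 0,
                    jitter = 4L, spur_rate = 0)
  t <- gen_terminology(cfg)
  cg <- gen_corpus(t, cfg)
  p <- perturb(cg$gold, t, cg$docs, cfg, seed = 4L)
  # annotation_set() would have thrown on overlap; check bounds explicitly
  expect_s3_class(p$pred, "el_annotations")
  lens <- nchar(cg$docs$text)[match(p$pred$doc_id, cg$docs$doc_id)]
  expect_true(all(p$pred$end <= lens))
  expect_true(all(p$pred$start >= 0L))
  # scoring a jittered-only prediction stays strictly positive
  expect_gt(score_submission(cg$gold, p$pred)$mean_iou, 0.5)
})

test_that("score_submission(gold, gold) is exactly 1 on generated bundles", {
  for (seed in c(61L, 62L)) {
    b <- simulate_bundle(zero_noise_config(seed = seed, n_concepts = 50L,
                                           n_docs = 5L,
                                           anns_per_doc = c(6L, 10L)),
                         n_systems = 1L)
    r <- score_submission(b$gold, annotation_set(as.data.frame(b$gold), "copy"))
    expect_equal(r$mean_iou, 1)
    expect_equal(r$weighted_iou, 1)
  }
})
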