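# builds the 20-occurrence surface-form bag: "stable" x15 plus four rarer
# phrasings, all linked to one concept
ambiguous_corpus <- function() {
  spans <- c(rep("stable", 15), "similar to previous examination",
             "no substantial change", rep("no notable interval change", 2),
             "no resolution of symptoms")
  sep <- " | "
  text <- paste(spans, collapse = sep)
  starts <- cumsum(c(0, head(nchar(spans) + nchar(sep), -1)))
  list(docs = corpus("n1", text),
       set = anns("n1", starts, starts + nchar(spans), rep("162498009", 20), "gold"),
       spans = spans, starts = starts)
}

test_that("span index bags normalized span strings and transposes exactly", {
  d <- ct_doc()
  idx <- build_span_index(anns("n1", 0, 7, "c", "gold"), d)
  expect_equal(idx$by_concept$c, c("ct head" = 1L))
  expect_equal(idx$by_span$`ct head`, c(c = 1L))

  ac <- ambiguous_corpus()
  idx <- build_span_index(ac$set, ac$docs)
  expect_equal(sort(unname(idx$by_concept$`162498009`)), c(1L, 1L, 1L, 2L, 15L))
  expect_equal(sum(idx$pairs$n), 20L)

  # casing/whitespace variants collapse to one key
  d2 <- corpus("m", "Stable stable  STABLE")
  idx2 <- build_span_index(anns("m", c(0, 7, 15), c(6, 13, 21), rep("c", 3)), d2)
  expect_length(idx2$by_concept$c, 1L)
  expect_equal(unname(idx2$by_concept$c), 3L)
})

test_that("transpose consistency: by_span rebuilds from by_concept", {
  for (seed in c(3, 14, 15)) {
    cs <- rand_case(seed, n_pred = 1L)
    idx <- build_span_index(list(cs$gt, cs$preds[[1]]), cs$docs)
    rebuilt <- do.call(rbind, lapply(names(idx$by_concept), function(cc)
      data.frame(concept_id = cc, span = names(idx$by_concept[[cc]]),
                 n = unname(idx$by_concept[[cc]]), stringsAsFactors = FALSE)))
    ag <- stats::aggregate(n ~ span + concept_id, data = rebuilt, FUN = sum)
    for (s in names(idx$by_span)) {
      want <- idx$by_span[[s]]
      got <- ag[ag$span == s, ]
      got_v <- stats::setNames(got$n, got$concept_id)
      expect_equal(got_v[sort(names(got_v))], want[sort(names(want))])
    }
  }
})

test_that("concept entropy: zero for one form, log2 k for k uniform forms", {
  d <- corpus("n1", "aa bb cc dd")
  idx <- build_span_index(anns("n1", c(0, 3, 6, 9), c(2, 5, 8, 11),
                               rep("c", 4)), d)
  expect_equal(concept_entropy(idx, "c"), 2)  # 4 uniform forms

  idx1 <- build_span_index(anns("n1", c(0, 3), c(2, 5), c("c", "c")),
                           corpus("n1", "aa aa"))
  expect_equal(concept_entropy(idx1, "c"), 0)

  ac <- ambiguous_corpus()
  idx <- build_span_index(ac$set, ac$docs)
  expect_equal(concept_entropy(idx, "162498009"), 1.292, tolerance = 1e-3)
  expect_error(concept_entropy(idx, "nope"), "not present")
})

test_that("annotation entropy measures corpus-wide linking ambiguity", {
  # span "stable" linked 9x to c1 and 1x to c2; c2's surface forms = {stable}
  starts <- seq(0, by = 7, length.out = 10)
  d <- corpus("n1", paste(rep("stable", 10), collapse = " "))
  set <- anns("n1", starts, starts + 6, c(rep("c1", 9), "c2"), "gold")
  idx <- build_span_index(set, d)
  expect_equal(annotation_entropy(idx, "c2"), 0.469, tolerance = 1e-3)
  expect_equal(annotation_entropy(idx, "c1"), annotation_entropy(idx, "c2"))

  # a concept whose spans are linked only to itself has zero ambiguity
  d2 <- corpus("n2", "unique phrase")
  idx2 <- build_span_index(list(set, anns("n2", 0, 13, "c3", "g2")),
                           corpus(c("n1", "n2"),
                                  c(doc_text(d, "n1"), "unique phrase")))
  expect_equal(annotation_entropy(idx2, "c3"), 0)
})

test_that("annotation entropy equals a raw two-pass recomputation", {
  for (seed in c(8, 21, 34)) {
    cs <- rand_case(seed, n_pred = 1L, n_concepts = 3L)
    sets <- list(cs$gt, cs$preds[[1]])
    idx <- build_span_index(sets, cs$docs)
    for (cc in names(idx$by_concept)) {
      expect_equal(annotation_entropy(idx, cc),
                   oracle_annotation_entropy(sets, cs$docs, cc),
                   tolerance = 1e-12)
    }
  }
})

test_that("concept depth is the shortest is-a chain to the root", {
  t <- terminology(list(R = "r", A = "a", B = "b"),
                   data.frame(child = c("A", "B"), parent = c("R", "A")), "R")
  expect_equal(concept_depth(t, "R"), 0L)
  expect_equal(concept_depth(t, "B"), 2L)

  # diamond with a 2-edge and a 3-edge path: shortest wins
  t2 <- terminology(list(R = "r", A = "a", B = "b", C = "c", D = "d"),
                    data.frame(child = c("A", "B", "C", "D", "D"),
                               parent = c("R", "A", "B", "C", "A")), "R")
  expect_equal(concept_depth(t2, "D"), 2L)

  t3 <- terminology(list(R = "r", X = "x"),
                    data.frame(child = character(), parent = character()), "R")
  expect_error(concept_depth(t3, "X"), "cannot reach")
  expect_error(concept_depth(t, "Z"), "not in terminology")
})

test_that("depth never increases when is-a edges are added", {
  cfg <- zero_noise_config(seed = 5L, n_concepts = 60L)
  t <- gen_terminology(cfg)
  base <- concept_depth(t, t$concept_ids)
  extra <- data.frame(child = t$concept_ids[base >= 2][1:5],
                      parent = t$root_id, stringsAsFactors = FALSE)
  t2 <- terminology(t$synonyms, rbind(t$edges, extra), t$root_id)
  expect_true(all(concept_depth(t2, t$concept_ids) <= base))
  expect_true(all(concept_depth(t2, extra$child) == 1L))
})

test_that("feature_table counts training examples on the train split only", {
  d <- corpus(c("n1", "n2"), c("CT head revealed no internal hemorrhage.",
                               "CT head again noted."))
  train <- anns("n1", 0, 7, "c1", "gold_train")
  test <- anns("n2", 0, 7, "c2", "gold_test")
  t <- terminology(list(R = "r", c1 = "ct head", c2 = "ct head again"),
                   data.frame(child = c("c1", "c2"), parent = c("R", "R")), "R")
  ft <- feature_table(train, test, d, t)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$n_examples[ft$concept_id == "c2"], 0L)  # test-only concept
  expect_equal(ft$n_examples[ft$concept_id == "c1"], 1L)
  expect_equal(ft$mean_span_length, c(7, 7))
  expect_true(all(ft$n_notes <= pmax(ft$n_examples, 1)))

  # concept missing from the terminology: depth NA, flagged
  t_small <- terminology(list(R = "r", c1 = "ct head"),
                         data.frame(child = "c1", parent = "R"), "R")
  expect_warning(ft2 <- feature_table(train, test, d, t_small), "missing")
  expect_true(is.na(ft2$depth[ft2$concept_id == "c2"]))
})

test_that("entropies are bounded by log2 of the distinct-form count", {
  for (seed in c(2, 9)) {
    cs <- rand_case(seed, n_pred = 1L)
    idx <- build_span_index(list(cs$gt, cs$preds[[1]]), cs$docs)
    for (cc in names(idx$by_concept)) {
      h <- concept_entropy(idx, cc)
      expect_gte(h, 0)
      expect_lte(h, log2(length(idx$by_concept[[cc]])) + 1e-12)
    }
  }
})
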