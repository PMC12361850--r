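test_that("char_assignment materializes one row per covered character", {
  ca <- char_assignment(anns("n1", 0, 7, "c"))
  expect_equal(nrow(ca), 7L)
  expect_equal(ca$pos, 0:6)
  expect_equal(unique(ca$concept_id), "c")

  expect_equal(nrow(char_assignment(empty_anns())), 0L)

  ca2 <- char_assignment(anns("n1", c(0, 5), c(2, 9), c("c", "cp")))
  expect_equal(nrow(ca2), 6L)
  expect_equal(sum(ca2$concept_id == "c"), 2L)
  expect_equal(sum(ca2$concept_id == "cp"), 4L)
})

test_that("per-concept IoU matches the worked one-sentence examples", {
  gt <- anns("n1", 0, 7, "303653007", "gold")
  expect_equal(concept_iou(gt, anns("n1", 0, 2, "303653007"), "303653007"), 2 / 7)
  expect_equal(round(concept_iou(gt, anns("n1", 0, 2, "303653007"), "303653007"), 3), 0.286)
  # identical prediction
  expect_equal(concept_iou(gt, gt, "303653007"), 1)
  # same span linked to another concept: 0 for the gold concept, and the
  # hallucinated concept is itself penalized
  wrong <- anns("n1", 0, 7, "999", "sys")
  expect_equal(concept_iou(gt, wrong, "303653007"), 0)
  expect_equal(concept_iou(gt, wrong, "999"), 0)
  # over-long span "CT head revealed": union semantics give 7/16
  expect_equal(concept_iou(gt, anns("n1", 0, 16, "303653007"), "303653007"), 7 / 16)
  expect_error(concept_iou(gt, wrong, "absent"), "neither set")
})

test_that("precision and recall follow the character sets", {
  gt <- anns("n1", 0, 7, "c", "gold")
  pr <- concept_precision_recall(gt, anns("n1", 0, 2, "c"), "c")
  expect_equal(unname(pr), c(1, 2 / 7))
  pr <- concept_precision_recall(gt, gt, "c")
  expect_equal(unname(pr), c(1, 1))
  pr <- concept_precision_recall(gt, anns("n1", 0, 16, "c"), "c")
  expect_equal(unname(pr), c(7 / 16, 1))
  # undefined sides are NA
  pr <- concept_precision_recall(gt, anns("n1", 0, 7, "other"), "c")
  expect_true(is.na(pr[["precision"]]))
  expect_equal(pr[["recall"]], 0)
})

test_that("score_submission aggregates over the union of concepts", {
  gt <- anns("n1", 0, 7, "c", "gold")
  r <- score_submission(gt, gt)
  expect_equal(r$mean_iou, 1)
  expect_equal(r$weighted_iou, 1)

  r0 <- score_submission(gt, empty_anns("sys"))
  expect_equal(r0$mean_iou, 0)

  # concept A perfect with 9 gold instances, concept B missed with 1:
  # plain mean 0.5, instance-weighted mean 0.9
  gt2 <- anns("n1", seq(0, 90, by = 10), seq(5, 95, by = 10),
              c(rep("A", 9), "B"), "gold")
  pred2 <- anns("n1", seq(0, 80, by = 10), seq(5, 85, by = 10),
                rep("A", 9), "sys")
  r2 <- score_submission(gt2, pred2)
  expect_equal(r2$n_concepts, 2L)
  expect_equal(r2$mean_iou, 0.5)
  expect_equal(r2$weighted_iou, 0.9)

  # hallucinated concepts enter the averaging domain
  r3 <- score_submission(gt, anns("n1", c(0, 10), c(7, 12), c("c", "zz"), "sys"))
  expect_equal(r3$n_concepts, 2L)
  expect_equal(r3$mean_iou, 0.5)

  expect_warning(score_submission(gt, anns("other_doc", 0, 2, "c", "sys")),
                 "share no documents")
})

test_that("bootstrap CI is seeded, degenerate on constant scores, and ordered", {
  gt <- anns("n1", seq(0, 40, by = 10), seq(5, 45, by = 10),
             paste0("c", 1:5), "gold")
  r <- score_submission(gt, gt)
  ci <- bootstrap_ci(r, n_boot = 200L, seed = 5L)
  expect_equal(unname(ci), c(1, 1))  # zero variance

  cs <- rand_case(41, n_pred = 1L)
  rr <- score_submission(cs$gt, cs$preds[[1]])
  ci1 <- bootstrap_ci(rr, n_boot = 300L, seed = 7L)
  ci2 <- bootstrap_ci(rr, n_boot = 300L, seed = 7L)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["low"]], ci1[["high"]])
  expect_gte(ci1[["low"]], 0)
  expect_lte(ci1[["high"]], 1)

  r1 <- score_submission(anns("n1", 0, 7, "c", "gold"), anns("n1", 0, 7, "c", "s"))
  expect_warning(bootstrap_ci(r1, n_boot = 10L, seed = 1L), "degenerate")

  rw <- score_submission(cs$gt, cs$preds[[1]], n_boot = 100L, seed = 3L,
                         weighted_ci = TRUE)
  expect_true(rw$ci_low <= rw$ci_high)
})

test_that("inter-annotator agreement ignores boundary variation", {
  a <- anns("n1", c(0, 10), c(7, 15), c("c1", "c2"), "ann1")
  expect_equal(iaa_jaccard(a, a), 1)
  b <- anns("n1", c(20, 30), c(25, 35), c("c1", "c2"), "ann2")
  expect_equal(iaa_jaccard(a, b), 0)
  # same entity, clipped boundary: still a full match
  expect_equal(iaa_jaccard(anns("n1", 0, 7, "c", "a"), anns("n1", 0, 2, "c", "b")), 1)
  # overlap without concept agreement is no match
  expect_equal(iaa_jaccard(anns("n1", 0, 7, "c", "a"), anns("n1", 0, 7, "d", "b")), 0)
  # one-to-one: two gold instances, one predicted overlap -> 1/(2+1-1)
  expect_equal(iaa_jaccard(anns("n1", c(0, 10), c(7, 17), c("c", "c"), "a"),
                           anns("n1", 0, 7, "c", "b")), 0.5)
  expect_equal(iaa_jaccard(empty_anns("a"), empty_anns("b")), 1)
  expect_equal(iaa_jaccard(a, empty_anns("b")), 0)
})

test_that("IoU is monotone: correct characters help, spurious characters hurt", {
  gt <- anns("n1", 0, 10, "c", "gold")
  iou_grow <- vapply(1:10, function(k)
    concept_iou(gt, anns("n1", 0, k, "c"), "c"), numeric(1))
  expect_true(all(diff(iou_grow) > 0))
  expect_equal(iou_grow[10], 1)

  iou_spur <- vapply(1:8, function(e)
    concept_iou(gt, anns("n1", c(0, 20), c(10, 20 + e), c("c", "c")), "c"),
    numeric(1))
  expect_true(all(diff(iou_spur) < 0))
  expect_true(all(iou_spur < 1))
})

test_that("iou_histogram bins cover all concepts", {
  cs <- rand_case(77, n_pred = 1L)
  r <- score_submission(cs$gt, cs$preds[[1]])
  h <- iou_histogram(r, breaks = 10L)
  expect_equal(sum(h$count), r$n_concepts)
  expect_equal(nrow(h), 10L)
})
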