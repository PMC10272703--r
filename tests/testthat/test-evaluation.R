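## brute-force span scoring oracle: set intersection over printed keys
oracle_f1 <- function(gold, pred) {
  key <- function(corpus) {
    out <- character(0)
    for (di in seq_along(corpus$documents)) {
      doc <- corpus$documents[[di]]
      for (s in seq_along(doc$sentences)) {
        sp <- decode_bio(doc$sentences[[s]]$tags)
        if (nrow(sp))
          out <- c(out, sprintf("%d|%d|%d|%d|%s", di, s, sp$start, sp$end,
                                sp$type))
      }
    }
    out
  }
  g <- key(gold); p <- key(pred)
  correct <- length(intersect(g, p))  # spans are unique within a corpus
  prec <- if (length(p)) correct / length(p) else 0
  rec <- if (length(g)) correct / length(g) else 0
  list(precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

retag <- function(corpus, f) {
  for (di in seq_along(corpus$documents))
    for (s in seq_along(corpus$documents[[di]]$sentences)) {
      sent <- corpus$documents[[di]]$sentences[[s]]
      corpus$documents[[di]]$sentences[[s]]$tags <- f(sent$tags)
    }
  conner_corpus(corpus$documents, split_name = "pred")
}

test_that("span F1 scores exact (start, end, type) matches", {
  gold <- toy_corpus()
  expect_equal(span_f1(gold, gold)[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  ## 1 of 2 gold spans found, no false positives -> P=1, R=0.5, F1=2/3
  g2 <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("a", "b", "c", "d"),
         tags = c("B-T", "I-T", "O", "B-T"))))))
  p2 <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("a", "b", "c", "d"),
         tags = c("B-T", "I-T", "O", "O"))))))
  got <- span_f1(g2, p2)
  expect_equal(got$precision, 1)
  expect_equal(got$recall, 0.5)
  expect_equal(got$f1, 2 / 3)
  ## disjoint predictions -> 0
  expect_equal(span_f1(g2, retag(g2, function(t) rep("O", length(t))))$f1, 0)
  ## misalignment is an error
  expect_error(span_f1(gold, g2), "aligned")
})

test_that("span F1 agrees with the brute-force oracle on random corpora", {
  for (seed in 1:8) {
    gold <- random_corpus(n_docs = 2, seed = seed)
    ## corrupt tags at random to get an imperfect prediction
    set.seed(seed + 100)
    pred <- retag(gold, function(tags) {
      flip <- runif(length(tags)) < 0.3
      tags[flip] <- sample(c("O", "B-Disease", "B-Chemical"), sum(flip),
                           replace = TRUE)
      repair_bio(tags)
    })
    got <- span_f1(gold, pred)
    want <- oracle_f1(gold, pred)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
  }
})

test_that("prediction consistency per length has the boundary values", {
  gold <- toy_corpus()
  curve <- prediction_consistency_by_length(gold, gold)
  expect_true(all(curve == 1))
  allO <- retag(gold, function(t) rep("O", length(t)))
  curve0 <- prediction_consistency_by_length(gold, allO)
  expect_true(all(curve0 == 0))
  ## surface occurring twice, predicted once -> contributes 0.5
  g <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("flu", "x", "flu"), tags = c("B-T", "O", "B-T"))))))
  p <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("flu", "x", "flu"), tags = c("B-T", "O", "O"))))))
  expect_equal(prediction_consistency_by_length(g, p)[["1"]], 0.5)
})

test_that("token prediction consistency is the correct-tag percentage", {
  gold <- toy_corpus()
  expect_equal(token_prediction_consistency(gold, gold, c("primary", "cancer")),
               c(primary = 100, cancer = 100))
  allO <- retag(gold, function(t) rep("O", length(t)))
  expect_equal(token_prediction_consistency(gold, allO, "cancer")[["cancer"]],
               0)
  ## 1 of 2 entity occurrences correct -> 50%
  g <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("flu", "flu"), tags = c("B-T", "B-T"))))))
  p <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = c("flu", "flu"), tags = c("B-T", "O"))))))
  expect_equal(token_prediction_consistency(g, p, "flu")[["flu"]], 50)
  expect_error(token_prediction_consistency(gold, gold, "zzz"), "not found")
})
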