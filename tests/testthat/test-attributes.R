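test_that("token consistency is the entity-occurrence fraction", {
  ## "primary": 2 occurrences, 1 inside an entity (case-insensitive)
  corp <- toy_corpus()
  tc <- token_consistency(corp, "Primary")
  expect_equal(tc$n_occurrences, 2L)
  expect_equal(tc$n_entity_occurrences, 1L)
  expect_equal(tc$tcon, 0.5)
  ## token tagged non-O in 1 of 10 occurrences -> 0.1
  docs <- list(list(doc_id = "d", sentences = list(
    list(tokens = rep("primary", 10),
         tags = c("B-Disease", rep("O", 9))))))
  expect_equal(token_consistency(conner_corpus(docs), "primary")$tcon, 0.1)
  ## single occurrence tagged B -> 1; never tagged -> 0
  expect_equal(token_consistency(corp, "tumors")$tcon, 0)
  expect_equal(token_consistency(corp, "recurred")$tcon, 0)
  one <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = "x", tags = "B-T")))))
  expect_equal(token_consistency(one, "x")$tcon, 1)
  expect_error(token_consistency(corp, "absent"), "not found")
})

test_that("entity consistency counts exactly-covered surface occurrences", {
  corp <- toy_corpus()
  ## "colorectal cancer": 3 occurrences, all annotated
  ec <- entity_consistency(corp, "colorectal cancer")
  expect_equal(ec$n_surface_occurrences, 3L)
  expect_equal(ec$econ, 1)
  ## surface occurring 4 times, 3 annotated -> 0.75
  docs <- list(list(doc_id = "d", sentences = list(
    list(tokens = rep(c("rectal", "x"), 4),
         tags = c("B-T", "O", "B-T", "O", "B-T", "O", "O", "O")))))
  expect_equal(entity_consistency(conner_corpus(docs), "rectal")$econ, 0.75)
  ## overlap with a larger annotation is not an exact cover
  docs2 <- list(list(doc_id = "d", sentences = list(
    list(tokens = c("colorectal", "cancer", "colorectal"),
         tags = c("B-T", "I-T", "O")))))
  expect_equal(entity_consistency(conner_corpus(docs2), "colorectal")$econ, 0)
  expect_error(entity_consistency(corp, "no such surface"), "not found")
})

test_that("consistency_by_length buckets mean econ by entity length", {
  corp <- toy_corpus()
  b <- consistency_by_length(corp)
  ## only length-1 ("primary", econ 1/2) and length-2 ("colorectal cancer", 1)
  expect_equal(sort(names(b)), c("1", "2"))
  expect_equal(b[["1"]], 0.5)
  expect_equal(b[["2"]], 1)
  expect_true(all(b >= 0 & b <= 1))
  ## all surfaces always annotated -> all buckets 1
  docs <- list(list(doc_id = "d", sentences = list(
    list(tokens = c("a", "b", "c"), tags = c("B-T", "O", "B-T")))))
  expect_true(all(consistency_by_length(conner_corpus(docs)) == 1))
  ## no annotations -> empty map
  empty <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = "a", tags = "O")))))
  expect_length(consistency_by_length(empty), 0)
  ## pooling: length > max_len lands in the max_len bucket
  long <- conner_corpus(list(list(doc_id = "d", sentences = list(
    list(tokens = letters[1:5], tags = c("B-T", rep("I-T", 4)))))))
  expect_equal(names(consistency_by_length(long, max_len = 3)), "3")
})

test_that("corpus statistics count documents, tokens and annotations", {
  docs <- list(list(doc_id = "d", sentences = list(
    list(tokens = c("colorectal", "cancer", "."),
         tags = c("B-Disease", "I-Disease", "O")))))
  st <- corpus_statistics(conner_corpus(docs))
  expect_equal(unlist(st), c(documents = 1, sentences = 1, tokens = 3,
                             annotations = 1, unique_annotations = 1))
  ## two identical annotations -> 2 total, 1 unique (case-insensitive)
  docs2 <- list(list(doc_id = "d", sentences = list(
    list(tokens = c("Flu", "x", "flu"), tags = c("B-D", "O", "B-D")))))
  st2 <- corpus_statistics(conner_corpus(docs2))
  expect_equal(st2$annotations, 2L)
  expect_equal(st2$unique_annotations, 1L)
})

test_that("attribute report bundles tables and validates tokens", {
  corp <- toy_corpus()
  rep <- attribute_report(corp, tokens = c("primary", "cancer"))
  expect_s3_class(rep, "conner_attribute_report")
  expect_equal(rep$token_table$token, c("primary", "cancer"))
  ## every annotated surface appears in the entity table (lowercased)
  expect_setequal(rep$entity_table$surface,
                  unique(tolower(corpus_spans(corp)$surface)))
  expect_error(attribute_report(corp, tokens = "zzz"), "not in corpus")
})

test_that("empirical tcon concentrates around the generator's rho", {
  ## binomial concentration on a moderate corpus for each rho
  for (rho in c(0.2, 0.7)) {
    sim <- simulate_corpus(sim_config(
      n_documents = 150, modifiers = c(mod = rho), seed = round(1000 * rho)))
    v <- verify_corpus(sim)
    expect_true(v$n >= 500)
    expect_true(all(v$pass))
  }
})
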