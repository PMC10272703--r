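test_that("encoding yields one d-vector per word, deterministically", {
  fit <- tiny_fit()
  doc <- list(doc_id = "t", sentences = list(
    list(tokens = c("primary", "carcinoma", "x"), tags = c("O", "O", "O"))))
  H1 <- encode_document(fit, doc)
  H2 <- encode_document(fit, doc)
  expect_equal(dim(H1), c(3L, 2L * fit$hidden_dim))
  expect_identical(H1, H2)
  expect_error(encode_document(fit, list(doc_id = "e", sentences = list())),
               "empty")
})

test_that("long documents are windowed with most-central stitching", {
  fit <- tiny_fit()
  fit$max_len <- 6L
  toks <- rep(c("primary", "carcinoma", "the", "of"), 5)  # N = 20
  x <- conner:::token_ids(fit, toks)
  H <- conner:::encode_ids(fit, x)
  expect_equal(nrow(H), 20L)
  ## oracle: recompute windows by hand and stitch by central ownership
  wl <- 6L; stride <- 3L; N <- 20L
  starts <- unique(c(seq(1L, N - wl + 1L, by = stride), N - wl + 1L))
  centers <- starts + (wl - 1) / 2
  full <- function(ids) {
    p <- fit$params
    conner:::birnn_forward(p$E[ids, , drop = FALSE], p$Wf, p$Uf, p$bf,
                           p$Wb, p$Ub, p$bb)$H
  }
  for (pos in c(1L, 7L, 13L, 20L)) {
    cand <- which(starts <= pos & pos <= starts + wl - 1L)
    w <- cand[which.min(abs(centers[cand] - pos))]
    Hw <- full(x[starts[w]:(starts[w] + wl - 1L)])
    expect_equal(H[pos, ], Hw[pos - starts[w] + 1L, ])
  }
})

test_that("classification head is affine + softmax over C classes", {
  fit <- tiny_fit()
  C <- length(fit$classes)
  doc <- list(doc_id = "t", sentences = list(
    list(tokens = c("primary", "the"), tags = c("O", "O"))))
  h <- encode_document(fit, doc)
  p <- classify_tokens(fit, h)
  expect_equal(dim(p), c(2L, C))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
  expect_true(all(p >= 0))
  ## zero-weight head -> uniform rows
  fit0 <- fit
  fit0$params$Wp[] <- 0
  fit0$params$bp[] <- 0
  expect_equal(classify_tokens(fit0, h),
               matrix(1 / C, 2, C), tolerance = 1e-12)
})

test_that("uncertainty is natural-log entropy with closed-form extremes", {
  expect_equal(token_uncertainty(matrix(1 / 3, 1, 3))[1], log(3))
  expect_equal(token_uncertainty(matrix(c(1, 0, 0), 1)), 0,
               tolerance = 1e-6)
  expect_equal(token_uncertainty(matrix(c(0.5, 0.5, 0), 1)), log(2),
               tolerance = 1e-6)
  ## permutation invariance in the class axis; uniform is the maximum
  set.seed(4)
  p <- prop.table(matrix(runif(5 * 4), 5, 4), 1)
  expect_equal(token_uncertainty(p),
               token_uncertainty(p[, c(3, 1, 4, 2)]))
  expect_true(all(token_uncertainty(p) <= log(4) + 1e-12))
})

test_that("entity mask covers exactly the span tokens", {
  expect_equal(entity_mask(5, data.frame(start = 2, end = 4, type = "D")),
               c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(entity_mask(3, NULL), rep(FALSE, 3))
  expect_equal(entity_mask(2, data.frame(start = 1, end = 3, type = "D")),
               c(TRUE, TRUE))
  expect_error(entity_mask(2, data.frame(start = 1, end = 4, type = "D")),
               "bounds")
  ## sentence-local spans offset into document coordinates
  doc <- list(sentences = list(list(tokens = c("a", "b")),
                               list(tokens = c("c", "d", "e"))))
  m <- entity_mask(doc, data.frame(sent = 2, start = 1, end = 3, type = "D"))
  expect_equal(m, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("refinement distribution is valid and deterministic", {
  fit <- tiny_fit()
  doc <- list(doc_id = "t", sentences = list(
    list(tokens = c("primary", "carcinoma", "the"), tags = rep("O", 3))))
  h <- encode_document(fit, doc)
  mask <- c(TRUE, TRUE, FALSE)
  l1 <- refine_distribution(fit, h, mask)
  l2 <- refine_distribution(fit, h, mask)
  expect_identical(l1, l2)
  expect_equal(rowSums(l1), rep(1, 3), tolerance = 1e-6)
})

test_that("combine obeys the gate laws", {
  p <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, byrow = TRUE)
  l <- matrix(c(0.6, 0.4, 0.1, 0.9), 2, byrow = TRUE)
  u <- c(1, 1)
  ## gated token: renormalized element-wise sum
  out <- combine_distributions(p, l, u, mask = c(TRUE, FALSE), gamma = 0.3)
  expect_equal(out[1, ], c(0.4, 0.6))
  expect_equal(out[2, ], p[2, ])
  expect_equal(rowSums(out), c(1, 1))
  ## gate never fires when gamma exceeds the entropy maximum log(C)
  expect_equal(combine_distributions(p, l, token_uncertainty(p),
                                     c(TRUE, TRUE), gamma = log(2) + 0.01), p)
  ## off-mask tokens never change
  expect_equal(combine_distributions(p, l, u, c(FALSE, FALSE), 0), p)
  ## one-hot p has U = 0 < gamma, never refined
  ph <- matrix(c(1, 0), 1)
  expect_equal(combine_distributions(ph, matrix(c(0.5, 0.5), 1),
                                     token_uncertainty(ph), TRUE, 0.3), ph)
  expect_error(combine_distributions(p, l, u, c(TRUE, TRUE), -1),
               "non-negative")
})

test_that("draft-label flip: combination turns an uncertain O into B", {
  ## p favors O weakly, refinement strongly favors B
  p <- matrix(c(0.55, 0.45), 1)
  l <- matrix(c(0.10, 0.90), 1)
  u <- token_uncertainty(p)
  expect_true(u >= 0.3)
  out <- combine_distributions(p, l, u, mask = TRUE, gamma = 0.3)
  expect_equal(which.max(out[1, ]), 2L)  # O -> B
})

test_that("same seed reproduces an identical fit, predictions included", {
  sim <- simulate_corpus(sim_config(n_documents = 6, seed = 5))
  f1 <- conner(sim$corpus, emb_dim = 5, hidden_dim = 3, epochs = 2, seed = 3)
  f2 <- conner(sim$corpus, emb_dim = 5, hidden_dim = 3, epochs = 2, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, sim$corpus), predict(f2, sim$corpus))
  ## only the bundled encoder kind is available
  expect_error(conner(sim$corpus, encoder = "pretrained_transformer"),
               "seam")
})
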