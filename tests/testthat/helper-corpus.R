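## shared fixtures, all built in code

toy_corpus <- function() {
  conner_corpus(list(
    list(doc_id = "d1", sentences = list(
      list(tokens = c("colorectal", "cancer", "is", "common", "."),
           tags = c("B-Disease", "I-Disease", "O", "O", "O")),
      list(tokens = c("primary", "colorectal", "cancer", "recurred"),
           tags = c("O", "B-Disease", "I-Disease", "O")))),
    list(doc_id = "d2", sentences = list(
      list(tokens = c("primary", "tumors", "and", "Colorectal", "Cancer"),
           tags = c("B-Disease", "O", "O", "B-Disease", "I-Disease"))))),
    split_name = "toy")
}

## random BIO-valid corpus via random non-overlapping spans (the oracle
## side of the encode/decode inversion property)
random_spans <- function(n, types = c("Disease", "Chemical")) {
  spans <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  covered <- logical(n)
  for (try in seq_len(5)) {
    s <- sample.int(n, 1)
    e <- min(n + 1L, s + sample.int(3, 1))
    if (any(covered[s:(e - 1L)])) next
    covered[s:(e - 1L)] <- TRUE
    spans <- rbind(spans, data.frame(start = s, end = e,
                                     type = sample(types, 1),
                                     stringsAsFactors = FALSE))
  }
  spans[order(spans$start), , drop = FALSE]
}

random_corpus <- function(n_docs = 3, seed = 1) {
  set.seed(seed)
  vocab <- c("alpha", "beta", "gamma", "delta", "EGFR", "p53", "x1")
  docs <- lapply(seq_len(n_docs), function(d) {
    sents <- lapply(seq_len(sample(1:3, 1)), function(s) {
      n <- sample(2:9, 1)
      list(tokens = sample(vocab, n, replace = TRUE),
           tags = encode_bio(n, random_spans(n)))
    })
    list(doc_id = sprintf("r%02d", d), sentences = sents)
  })
  conner_corpus(docs)
}

## small fitted model shared across op tests (cached per session)
tiny_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sim <- simulate_corpus(sim_config(n_documents = 8, seed = 42))
      fit <<- conner(sim$corpus, emb_dim = 6, hidden_dim = 4,
                     epochs = 2, seed = 7)
    }
    fit
  }
})

## numerical gradient of the total loss wrt every parameter
numeric_grads <- function(params, x, y, mask, cfg, eps = 1e-5) {
  f <- function(p) conner:::forward_doc(p, x, y, mask, cfg)$total
  lapply(stats::setNames(names(params), names(params)), function(nm) {
    g <- params[[nm]] * 0
    for (i in seq_along(g)) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      g[i] <- (f(p1) - f(p2)) / (2 * eps)
    }
    g
  })
}
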