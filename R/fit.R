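#' Fit a consistency-enhanced document tagger
#'
#' Trains a document-level BIO tagger on a corpus. Each document
#' (title + abstract) is encoded as one sequence by a bidirectional
#' recurrent encoder over token embeddings; a tag-independent affine +
#' softmax head produces the main label distribution `p` per token. With
#' `refine = TRUE` a second branch zeroes non-entity positions (gold
#' entity mask during training), runs a second bidirectional recurrent
#' layer and produces a refinement distribution `l`; tokens inside the
#' mask whose entropy of `p` reaches `gamma` are classified from the
#' renormalized sum `(p + l) / 2`. The objective is
#' `lambda[1] * L_class + lambda[2] * L_label + lambda[3] * L_distill`,
#' where `L_label` is the refinement head's cross-entropy on entity
#' tokens and `L_distill` the symmetric KL divergence pulling the two
#' heads together. Optimization is Adam, one step per document, with all
#' randomness drawn from `seed`.
#'
#' @param corpus a `conner_corpus` with gold BIO tags.
#' @param encoder encoder kind. `"toy_recurrent"` (the default, and the
#'   only kind bundled) trains embeddings and the bidirectional
#'   recurrent encoder from scratch on one CPU; `"pretrained_transformer"`
#'   names the plug-in seam for an external pretrained language model
#'   and is not shipped.
#' @param emb_dim token embedding dimension (default 16).
#' @param hidden_dim per-direction encoder width; representations have
#'   `d = 2 * hidden_dim` (default 16).
#' @param refine_dim per-direction width of the refinement layer
#'   (default `hidden_dim`).
#' @param gamma uncertainty threshold for the refinement gate, on the
#'   natural-log entropy scale (default 0.3).
#' @param lambda three non-negative loss weights (default
#'   `c(1, 0.1, 0.001)`).
#' @param refine logical; `FALSE` disables the refinement branch
#'   entirely (plain encoder + main head baseline).
#' @param refined_loss logical; if `TRUE` (default) the classification
#'   loss is taken on the gated combined distribution, otherwise on the
#'   raw main-head distribution.
#' @param epochs passes over the corpus (default 20).
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_len maximum training/encoding sequence length; longer
#'   documents are windowed (default 200).
#' @param seed integer seed governing initialization and shuffling.
#' @param verbose print per-epoch losses.
#' @return an object of class `conner`.
#' @seealso [predict.conner()], [span_f1()],
#'   [prediction_consistency_by_length()]
#' @export
conner <- function(corpus, encoder = c("toy_recurrent",
                                       "pretrained_transformer"),
                   emb_dim = 16L, hidden_dim = 16L,
                   refine_dim = hidden_dim, gamma = 0.3,
                   lambda = c(1, 0.1, 0.001), refine = TRUE,
                   refined_loss = TRUE, epochs = 20L,
                   learning_rate = 1e-3, max_len = 200L, seed = 1L,
                   verbose = FALSE) {
  stopifnot(inherits(corpus, "conner_corpus"))
  encoder <- match.arg(encoder)
  if (encoder != "toy_recurrent")
    stop("encoder '", encoder, "' is an integration seam for an external ",
         "pretrained model; this build ships the self-contained ",
         "'toy_recurrent' encoder")
  if (gamma < 0) stop("gamma must be non-negative")
  if (length(lambda) != 3 || any(lambda < 0))
    stop("lambda must be three non-negative weights")
  flat_docs <- lapply(corpus$documents, doc_flat)
  flat_docs <- Filter(function(d) length(d$tokens) > 0, flat_docs)
  if (!length(flat_docs)) stop("corpus has no tokens")
  vocab <- c("<unk>", sort(unique(tolower(unlist(lapply(flat_docs,
                                                        `[[`, "tokens"))))))
  classes <- class_labels(corpus$entity_types)
  C <- length(classes)
  cfg <- list(gamma = gamma, lambda = lambda, refine = refine,
              refined_loss = refined_loss)

  set.seed(seed)
  params <- init_params(length(vocab), C, emb_dim, hidden_dim, refine_dim)
  state <- adam_init(params)

  ## pre-index training sequences; window long documents
  seqs <- list()
  for (d in flat_docs) {
    x <- match(tolower(d$tokens), vocab)
    y <- match(d$tags, classes)
    if (anyNA(y)) stop("tag outside the corpus tag set")
    starts <- seq(1L, length(x), by = max_len)
    for (s in starts) {
      e <- min(s + max_len - 1L, length(x))
      seqs[[length(seqs) + 1L]] <-
        list(x = x[s:e], y = y[s:e], mask = d$tags[s:e] != "O")
    }
  }

  hist <- matrix(NA_real_, epochs, 4,
                 dimnames = list(NULL, c("l_class", "l_label",
                                         "l_distill", "total")))
  for (ep in seq_len(epochs)) {
    ord <- sample(length(seqs))
    acc <- c(0, 0, 0, 0)
    for (i in ord) {
      sq <- seqs[[i]]
      fw <- forward_doc(params, sq$x, sq$y, sq$mask, cfg)
      gr <- backward_doc(params, fw, sq$x, sq$y, cfg)
      st <- adam_step(params, gr, state, learning_rate)
      params <- st$params; state <- st$state
      acc <- acc + c(fw$l_class, fw$l_label, fw$l_distill, fw$total)
    }
    hist[ep, ] <- acc / length(seqs)
    if (verbose)
      message(sprintf("epoch %d: class %.4f label %.4f distill %.4f total %.4f",
                      ep, hist[ep, 1], hist[ep, 2], hist[ep, 3], hist[ep, 4]))
  }

  structure(list(params = params, vocab = vocab, classes = classes,
                 entity_types = corpus$entity_types,
                 emb_dim = emb_dim, hidden_dim = hidden_dim,
                 refine_dim = refine_dim, gamma = gamma, lambda = lambda,
                 refine = refine, refined_loss = refined_loss,
                 epochs = epochs, learning_rate = learning_rate,
                 max_len = max_len, seed = seed,
                 history = as.data.frame(hist)),
            class = "conner")
}

doc_flat <- function(doc) {
  list(doc_id = doc$doc_id,
       tokens = unlist(lapply(doc$sentences, `[[`, "tokens")) %||% character(0),
       tags = unlist(lapply(doc$sentences, `[[`, "tags")) %||% character(0),
       lens = vapply(doc$sentences, function(s) length(s$tokens), integer(1)))
}

class_labels <- function(types) {
  if (!length(types)) return("O")
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' @export
print.conner <- function(x, ...) {
  cat("<conner document tagger>\n")
  cat(sprintf("  vocab %d, classes %d (%s), d = %d\n",
              length(x$vocab), length(x$classes),
              paste(x$entity_types, collapse = ","), 2L * x$hidden_dim))
  cat(sprintf("  refinement %s (gamma = %g), lambda = (%g, %g, %g)\n",
              if (x$refine) "on" else "off", x$gamma,
              x$lambda[1], x$lambda[2], x$lambda[3]))
  n <- nrow(x$history)
  cat(sprintf("  trained %d epochs, final total loss %.4f\n",
              n, x$history$total[n]))
  invisible(x)
}

#' @export
summary.conner <- function(object, ...) {
  structure(list(model = object,
                 n_params = sum(vapply(object$params, length, integer(1))),
                 history = object$history),
            class = "summary.conner")
}

#' @export
print.summary.conner <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters\n", x$n_params))
  cat("  loss trajectory (first/last epochs):\n")
  h <- x$history
  show <- unique(c(1, nrow(h)))
  print(round(h[show, , drop = FALSE], 4))
  invisible(x)
}

#' @export
coef.conner <- function(object, ...) object$params

#' Plot the training loss trajectory
#'
#' @param x a fitted `conner` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.conner <- function(x, ...) {
  h <- as.matrix(x$history[, c("l_class", "l_label", "l_distill")])
  graphics::matplot(seq_len(nrow(h)), h, type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", colnames(h), lty = 1, col = 1:3, bty = "n")
  invisible(x)
}

#' Predict BIO tags for a corpus
#'
#' Runs the fitted model over each document of `newdata` and assigns each
#' token the argmax class of the main head's label distribution (the
#' draft label). With `refine_pass = TRUE` a second pass builds an entity
#' mask from the draft-label spans, computes the refinement distribution
#' and re-labels gated tokens from the combined distribution; the default
#' is the main head alone.
#'
#' @param object a fitted `conner` model.
#' @param newdata a `conner_corpus` (tags, if present, are ignored).
#' @param type `"corpus"` (default) returns a `conner_corpus` with
#'   predicted tags in the structure of `newdata`; `"prob"` returns a
#'   list of per-document probability matrices.
#' @param refine_pass apply inference-time refinement from draft spans.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.conner <- function(object, newdata, type = c("corpus", "prob"),
                           refine_pass = FALSE, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "conner_corpus"))
  probs <- list()
  docs <- newdata$documents
  for (di in seq_along(docs)) {
    d <- doc_flat(docs[[di]])
    if (!length(d$tokens)) { probs[[di]] <- NULL; next }
    x <- token_ids(object, d$tokens)
    H <- encode_ids(object, x)
    P <- classify_tokens(object, H)
    if (refine_pass && object$refine) {
      draft <- object$classes[max.col(P, ties.method = "first")]
      mask <- repair_bio(draft) != "O"
      if (any(mask)) {
        Lmat <- refine_distribution(object, H, mask)
        P <- combine_distributions(P, Lmat, token_uncertainty(P),
                                   mask, object$gamma)
      }
    }
    probs[[di]] <- P
    tags <- object$classes[max.col(P, ties.method = "first")]
    off <- 0L
    for (s in seq_along(docs[[di]]$sentences)) {
      n <- d$lens[s]
      docs[[di]]$sentences[[s]]$tags <-
        if (n) tags[(off + 1L):(off + n)] else character(0)
      off <- off + n
    }
  }
  if (type == "prob") return(probs)
  conner_corpus(docs, split_name = "predicted")
}
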