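check_alignment <- function(gold, pred) {
  g <- corpus_flat(gold); p <- corpus_flat(pred)
  if (nrow(g) != nrow(p) || any(g$token != p$token) ||
      any(g$sent != p$sent))
    stop("gold and predicted corpora are not token-aligned")
}

span_key <- function(sp) paste(sp$doc_id, sp$sent, sp$start, sp$end, sp$type)

#' Exact-match entity span F1
#'
#' A predicted span counts as correct iff its (sentence, start, end,
#' type) all match a gold span; precision, recall and F1 are
#' micro-averaged over all spans (and over entity types for multi-type
#' corpora).
#'
#' @param gold gold `conner_corpus`.
#' @param pred predicted `conner_corpus`, token-aligned with `gold`
#'   (e.g. from [predict.conner()]).
#' @return list with `precision`, `recall`, `f1`, `n_gold`, `n_pred`,
#'   `n_correct`.
#' @export
span_f1 <- function(gold, pred) {
  check_alignment(gold, pred)
  gs <- corpus_spans(gold); ps <- corpus_spans(pred)
  ## doc_ids may differ between the two objects; align by document index
  gs$doc_id <- match(gs$doc_id, vapply(gold$documents, `[[`, "", "doc_id"))
  ps$doc_id <- match(ps$doc_id, vapply(pred$documents, `[[`, "", "doc_id"))
  correct <- sum(span_key(ps) %in% span_key(gs))
  prec <- if (nrow(ps)) correct / nrow(ps) else 0
  rec <- if (nrow(gs)) correct / nrow(gs) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       n_gold = nrow(gs), n_pred = nrow(ps), n_correct = correct)
}

#' Prediction consistency per entity length
#'
#' For each distinct gold-entity surface (case-insensitive), the
#' fraction of its gold occurrences predicted with an identical span
#' decision (same sentence, boundaries and type). Surfaces are grouped
#' by entity length; the curve value at each length is the mean over the
#' surfaces in that bucket, lengths above `max_len` pooled. The curve is
#' constant 1 when predictions equal gold, and 0 under an all-`O`
#' prediction.
#'
#' @param gold gold `conner_corpus`.
#' @param pred aligned predicted `conner_corpus`.
#' @param max_len pooling limit for entity lengths (default 10).
#' @return named numeric vector: length bucket -> mean consistency.
#' @export
prediction_consistency_by_length <- function(gold, pred, max_len = 10L) {
  check_alignment(gold, pred)
  gs <- corpus_spans(gold); ps <- corpus_spans(pred)
  if (!nrow(gs)) return(stats::setNames(numeric(0), character(0)))
  gs$doc_id <- match(gs$doc_id, vapply(gold$documents, `[[`, "", "doc_id"))
  ps$doc_id <- match(ps$doc_id, vapply(pred$documents, `[[`, "", "doc_id"))
  gs$hit <- span_key(gs) %in% span_key(ps)
  gs$surface_lc <- tolower(gs$surface)
  gs$len <- pmin(gs$end - gs$start, max_len)
  per_surface <- tapply(gs$hit, list(gs$surface_lc, gs$len),
                        function(h) mean(h))
  ## per_surface is surfaces x lengths with NAs where absent
  buckets <- apply(per_surface, 2, function(col) mean(col, na.rm = TRUE))
  buckets[!is.nan(buckets)]
}

#' Per-token prediction consistency on gold entity occurrences
#'
#' For each listed token, the percentage of its occurrences inside gold
#' entities (gold tag non-`O`) where the predicted tag equals the gold
#' tag. This is the correct-prediction rate on modifier-token
#' occurrences within entities.
#'
#' @param gold gold `conner_corpus`.
#' @param pred aligned predicted `conner_corpus`.
#' @param tokens character vector of tokens (case-insensitive).
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
token_prediction_consistency <- function(gold, pred, tokens) {
  check_alignment(gold, pred)
  g <- corpus_flat(gold); p <- corpus_flat(pred)
  out <- numeric(length(tokens))
  names(out) <- tokens
  for (k in seq_along(tokens)) {
    idx <- which(tolower(g$token) == tolower(tokens[k]) & g$tag != "O")
    if (!length(idx)) {
      if (!any(tolower(g$token) == tolower(tokens[k])))
        stop("token '", tokens[k], "' not found in corpus")
      out[k] <- NA_real_
    } else {
      out[k] <- 100 * mean(p$tag[idx] == g$tag[idx])
    }
  }
  out
}
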