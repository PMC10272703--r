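#' Token label consistency
#'
#' The fraction of a token's corpus occurrences that carry an entity
#' (non-`O`) tag. Matching is case-insensitive; punctuation is kept.
#' A token never tagged inside an entity scores 0; a token always tagged
#' inside an entity scores 1.
#'
#' @param corpus a `conner_corpus`.
#' @param token_text token to look up.
#' @return list with `token_text`, `n_occurrences`,
#'   `n_entity_occurrences` and `tcon`.
#' @export
token_consistency <- function(corpus, token_text) {
  flat <- corpus_flat(corpus)
  hit <- tolower(flat$token) == tolower(token_text)
  if (!any(hit)) stop("token '", token_text, "' not found in corpus")
  n <- sum(hit)
  ne <- sum(hit & flat$tag != "O")
  list(token_text = tolower(token_text), n_occurrences = n,
       n_entity_occurrences = ne, tcon = ne / n)
}

## positions (sentence-local starts) of a multi-token surface in a corpus;
## returns per occurrence whether it is exactly covered by one annotation
surface_occurrences <- function(corpus, surface_tokens) {
  L <- length(surface_tokens)
  n_occ <- 0L; n_ann <- 0L
  for (doc in corpus$documents) {
    for (sent in doc$sentences) {
      toks <- tolower(sent$tokens)
      N <- length(toks)
      if (N < L) next
      cand <- which(toks == surface_tokens[1])
      cand <- cand[cand + L - 1L <= N]
      if (!length(cand)) next
      ok <- vapply(cand, function(i)
        all(toks[i:(i + L - 1L)] == surface_tokens), logical(1))
      starts <- cand[ok]
      if (!length(starts)) next
      sp <- decode_bio(sent$tags)
      for (st in starts) {
        n_occ <- n_occ + 1L
        if (nrow(sp) && any(sp$start == st & sp$end == st + L))
          n_ann <- n_ann + 1L
      }
    }
  }
  list(n_occ = n_occ, n_ann = n_ann)
}

#' Entity (surface) label consistency
#'
#' The fraction of a surface string's contiguous corpus occurrences that
#' are exactly covered by one annotated entity. An occurrence that merely
#' overlaps a larger annotation does not count as annotated. Matching is
#' case-insensitive on whitespace-tokenized surfaces.
#'
#' @param corpus a `conner_corpus`.
#' @param surface space-joined token text of the surface.
#' @return list with `surface`, `n_surface_occurrences`,
#'   `n_annotated_occurrences` and `econ`.
#' @export
entity_consistency <- function(corpus, surface) {
  stoks <- tolower(strsplit(trimws(surface), "[ ]+")[[1]])
  occ <- surface_occurrences(corpus, stoks)
  if (occ$n_occ == 0L) stop("surface '", surface, "' not found in corpus")
  list(surface = paste(stoks, collapse = " "),
       n_surface_occurrences = occ$n_occ,
       n_annotated_occurrences = occ$n_ann,
       econ = occ$n_ann / occ$n_occ)
}

#' Mean entity consistency per entity length
#'
#' Groups annotated entities by token length and reports, per length
#' bucket, the mean consistency. With `by = "surface"` (default) the mean
#' runs over the distinct lowercased surfaces in the bucket; with
#' `by = "instance"` every annotated occurrence contributes its surface's
#' score. Lengths above `max_len` are pooled into the `max_len` bucket.
#'
#' @param corpus a `conner_corpus`.
#' @param max_len pool lengths greater than this (default 10).
#' @param by averaging unit, `"surface"` or `"instance"`.
#' @return named numeric vector, names = entity lengths present.
#' @export
consistency_by_length <- function(corpus, max_len = 10L,
                                  by = c("surface", "instance")) {
  by <- match.arg(by)
  sp <- corpus_spans(corpus)
  if (!nrow(sp)) return(stats::setNames(numeric(0), character(0)))
  sp$surface_lc <- tolower(sp$surface)
  sp$len <- pmin(sp$end - sp$start, max_len)
  surfs <- unique(sp[, c("surface_lc", "len")])
  surfs$econ <- vapply(surfs$surface_lc, function(s)
    entity_consistency(corpus, s)$econ, numeric(1))
  if (by == "surface") {
    agg <- tapply(surfs$econ, surfs$len, mean)
  } else {
    sp$econ <- surfs$econ[match(paste(sp$surface_lc, sp$len),
                                paste(surfs$surface_lc, surfs$len))]
    agg <- tapply(sp$econ, sp$len, mean)
  }
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out
}

#' Corpus summary counts
#'
#' @param corpus a `conner_corpus`.
#' @return list with `documents`, `sentences`, `tokens`, `annotations`
#'   (total entity spans) and `unique_annotations` (distinct
#'   case-insensitive (surface, type) pairs).
#' @export
corpus_statistics <- function(corpus) {
  n_sent <- sum(vapply(corpus$documents,
                       function(d) length(d$sentences), integer(1)))
  n_tok <- sum(unlist(lapply(corpus$documents, function(d)
    vapply(d$sentences, function(s) length(s$tokens), integer(1)))), 0L)
  sp <- corpus_spans(corpus)
  list(documents = length(corpus$documents),
       sentences = n_sent,
       tokens = n_tok,
       annotations = nrow(sp),
       unique_annotations =
         if (nrow(sp)) nrow(unique(data.frame(s = tolower(sp$surface),
                                              t = sp$type))) else 0L)
}

#' Full attribute report
#'
#' Bundles corpus statistics, a token consistency table, an entity
#' consistency table for every distinct annotated surface, and
#' length-bucketed mean consistency.
#'
#' @param corpus a `conner_corpus`.
#' @param tokens tokens for the token table; default: every distinct
#'   token that appears at least once inside an annotation.
#' @param max_len length-bucket pooling limit.
#' @return list of class `conner_attribute_report` with elements
#'   `counts`, `token_table`, `entity_table`, `length_buckets`.
#' @export
attribute_report <- function(corpus, tokens = NULL, max_len = 10L) {
  flat <- corpus_flat(corpus)
  if (is.null(tokens)) {
    tokens <- sort(unique(tolower(flat$token[flat$tag != "O"])))
  } else {
    tokens <- tolower(tokens)
    missing <- setdiff(tokens, tolower(flat$token))
    if (length(missing))
      stop("token(s) not in corpus: ", paste(missing, collapse = ", "))
  }
  tok_tab <- do.call(rbind, lapply(tokens, function(t) {
    tc <- token_consistency(corpus, t)
    data.frame(token = tc$token_text, n = tc$n_occurrences,
               n_entity = tc$n_entity_occurrences, tcon = tc$tcon,
               stringsAsFactors = FALSE)
  })) %||% data.frame(token = character(0), n = integer(0),
                      n_entity = integer(0), tcon = numeric(0))
  sp <- corpus_spans(corpus)
  ents <- unique(tolower(sp$surface))
  ent_tab <- do.call(rbind, lapply(ents, function(s) {
    ec <- entity_consistency(corpus, s)
    data.frame(surface = ec$surface, n = ec$n_surface_occurrences,
               n_annotated = ec$n_annotated_occurrences, econ = ec$econ,
               stringsAsFactors = FALSE)
  })) %||% data.frame(surface = character(0), n = integer(0),
                      n_annotated = integer(0), econ = numeric(0))
  structure(list(counts = corpus_statistics(corpus),
                 token_table = tok_tab,
                 entity_table = ent_tab,
                 length_buckets = consistency_by_length(corpus, max_len)),
            class = "conner_attribute_report")
}

#' @export
print.conner_attribute_report <- function(x, ...) {
  cat("<attribute report>\n")
  cat(sprintf("  %d docs / %d sentences / %d tokens; %d annotations (%d unique)\n",
              x$counts$documents, x$counts$sentences, x$counts$tokens,
              x$counts$annotations, x$counts$unique_annotations))
  if (nrow(x$token_table)) {
    cat("  token consistency (tcon), head:\n")
    print(utils::head(x$token_table, 10), row.names = FALSE)
  }
  if (length(x$length_buckets)) {
    cat("  mean entity consistency by length:\n")
    print(round(x$length_buckets, 3))
  }
  invisible(x)
}
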