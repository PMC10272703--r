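TAG_RE <- "^O$|^[BI]-[A-Za-z0-9_]+$"

#' Construct a BIO-tagged corpus
#'
#' A corpus is a list of documents; each document is a list with a `doc_id`
#' and a list of sentences; each sentence holds parallel character vectors
#' `tokens` and `tags`. Tags follow the IOB2 scheme: `"O"`, `"B-<type>"`,
#' `"I-<type>"`. With T entity types the tagger's class count is 2T + 1.
#'
#' @param documents list of documents as described above.
#' @param split_name optional label for the split ("train", "dev", ...).
#' @param repair if `TRUE` (default), IOB2 violations (an `I-` tag with no
#'   valid predecessor) are rewritten to `B-`; the number of rewrites is
#'   recorded in `attr(x, "n_repaired")`.
#' @return an object of class `conner_corpus`.
#' @export
conner_corpus <- function(documents, split_name = "", repair = TRUE) {
  n_rep <- 0L
  for (d in seq_along(documents)) {
    doc <- documents[[d]]
    if (is.null(doc$doc_id)) doc$doc_id <- sprintf("doc%04d", d)
    for (s in seq_along(doc$sentences)) {
      sent <- doc$sentences[[s]]
      stopifnot(length(sent$tokens) == length(sent$tags))
      bad <- !grepl(TAG_RE, sent$tags)
      if (any(bad))
        stop("invalid tag '", sent$tags[bad][1], "' in document ",
             doc$doc_id, ", sentence ", s)
      if (repair) {
        fixed <- repair_bio(sent$tags)
        n_rep <- n_rep + sum(fixed != sent$tags)
        doc$sentences[[s]]$tags <- fixed
      }
    }
    documents[[d]] <- doc
  }
  types <- sort(unique(unlist(lapply(documents, function(doc)
    lapply(doc$sentences, function(s) tag_type(s$tags))))))
  structure(list(documents = documents,
                 entity_types = types %||% character(0),
                 split_name = split_name),
            class = "conner_corpus", n_repaired = n_rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tag_type <- function(tags) {
  t <- tags[tags != "O"]
  unique(sub("^[BI]-", "", t))
}

#' @export
print.conner_corpus <- function(x, ...) {
  st <- corpus_statistics(x)
  cat("<conner_corpus", if (nzchar(x$split_name)) paste0(" '", x$split_name, "'"),
      ">\n", sep = "")
  cat(sprintf("  %d documents, %d sentences, %d tokens\n",
              st$documents, st$sentences, st$tokens))
  cat(sprintf("  %d annotations (%d unique), entity types: %s\n",
              st$annotations, st$unique_annotations,
              if (length(x$entity_types)) paste(x$entity_types, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Repair an IOB2 tag sequence
#'
#' Rewrites any `I-<t>` whose predecessor is neither `B-<t>` nor `I-<t>`
#' to `B-<t>`. Idempotent.
#'
#' @param tags character vector of BIO tags.
#' @return repaired character vector.
#' @export
repair_bio <- function(tags) {
  if (!length(tags)) return(tags)
  out <- tags
  prev <- "O"
  for (i in seq_along(out)) {
    t <- out[i]
    if (startsWith(t, "I-")) {
      ty <- sub("^I-", "", t)
      ok <- identical(prev, paste0("B-", ty)) || identical(prev, paste0("I-", ty))
      if (!ok) out[i] <- paste0("B-", ty)
    }
    prev <- out[i]
  }
  out
}

#' Decode BIO tags into entity spans
#'
#' Spans are maximal: each `B-` opens a span, `I-` of the same type extends
#' it, and `O` or a type change closes it. Coordinates are 1-based,
#' half-open word indices, so span length equals `end - start`.
#'
#' @param tags character vector of (IOB2-valid) BIO tags.
#' @return data.frame with columns `start`, `end`, `type`.
#' @export
decode_bio <- function(tags) {
  starts <- integer(0); ends <- integer(0); types <- character(0)
  open <- FALSE; s0 <- 0L; ty0 <- ""
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "B-")) {
      if (open) { starts <- c(starts, s0); ends <- c(ends, i); types <- c(types, ty0) }
      open <- TRUE; s0 <- i; ty0 <- sub("^B-", "", t)
    } else if (startsWith(t, "I-") && open && sub("^I-", "", t) == ty0) {
      # span continues
    } else {
      if (open) { starts <- c(starts, s0); ends <- c(ends, i); types <- c(types, ty0) }
      open <- FALSE
    }
  }
  if (open) { starts <- c(starts, s0); ends <- c(ends, length(tags) + 1L); types <- c(types, ty0) }
  data.frame(start = starts, end = ends, type = types, stringsAsFactors = FALSE)
}

#' Encode entity spans as BIO tags
#'
#' Inverse of [decode_bio()] on non-overlapping in-bounds spans.
#'
#' @param n sentence length in tokens.
#' @param spans data.frame with columns `start`, `end` (1-based, half-open)
#'   and `type`.
#' @return character vector of `n` BIO tags.
#' @export
encode_bio <- function(n, spans) {
  tags <- rep("O", n)
  if (is.null(spans) || !nrow(spans)) return(tags)
  if (any(spans$start < 1L | spans$end > n + 1L | spans$start >= spans$end))
    stop("span out of bounds for sentence of length ", n)
  covered <- logical(n)
  o <- order(spans$start)
  for (k in o) {
    idx <- spans$start[k]:(spans$end[k] - 1L)
    if (any(covered[idx])) stop("overlapping spans at positions ",
                                paste(idx[covered[idx]], collapse = ","))
    covered[idx] <- TRUE
    tags[idx[1]] <- paste0("B-", spans$type[k])
    if (length(idx) > 1) tags[idx[-1]] <- paste0("I-", spans$type[k])
  }
  tags
}

#' All entity spans of a corpus
#'
#' @param corpus a `conner_corpus`.
#' @return data.frame with `doc_id`, `sent`, `start`, `end`, `type`,
#'   `surface` (space-joined original-case token texts).
#' @export
corpus_spans <- function(corpus) {
  out <- list()
  for (doc in corpus$documents) {
    for (s in seq_along(doc$sentences)) {
      sent <- doc$sentences[[s]]
      sp <- decode_bio(sent$tags)
      if (nrow(sp)) {
        sp$doc_id <- doc$doc_id
        sp$sent <- s
        sp$surface <- vapply(seq_len(nrow(sp)), function(k)
          paste(sent$tokens[sp$start[k]:(sp$end[k] - 1L)], collapse = " "),
          character(1))
        out[[length(out) + 1L]] <- sp
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0), doc_id = character(0),
                      sent = integer(0), surface = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a CoNLL-style two-column BIO corpus
#'
#' Each non-blank line is `token<TAB or space>tag`; blank lines separate
#' sentences; a line equal to `doc_marker` (any tag after it is ignored)
#' opens a new document. Without any marker the whole file is one document.
#' I/O is UTF-8. IOB2 violations are repaired (`I-` without a valid
#' predecessor becomes `B-`) and the repair count is kept in
#' `attr(x, "n_repaired")`.
#'
#' @param path file path.
#' @param doc_marker document boundary token, default `"-DOCSTART-"`.
#' @param split_name optional split label stored on the corpus.
#' @return a [conner_corpus()].
#' @export
read_conll <- function(path, doc_marker = "-DOCSTART-", split_name = "") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_sents <- list()
  cur_tok <- character(0); cur_tag <- character(0)
  n_doc_with_marker <- 0L
  saw_marker <- FALSE
  flush_sentence <- function() {
    if (length(cur_tok)) {
      cur_sents[[length(cur_sents) + 1L]] <<-
        list(tokens = cur_tok, tags = cur_tag)
      cur_tok <<- character(0); cur_tag <<- character(0)
    }
  }
  flush_document <- function() {
    flush_sentence()
    if (length(cur_sents)) {
      docs[[length(docs) + 1L]] <<-
        list(doc_id = sprintf("doc%04d", length(docs) + 1L),
             sentences = cur_sents)
      cur_sents <<- list()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush_sentence(); next }
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (fields[1] == doc_marker) { flush_document(); saw_marker <- TRUE; next }
    if (length(fields) != 2L)
      stop("line ", i, ": expected 2 columns (token, tag), got ",
           length(fields), ": '", ln, "'")
    if (!grepl(TAG_RE, fields[2]))
      stop("line ", i, ": unknown tag syntax '", fields[2], "'")
    cur_tok <- c(cur_tok, fields[1])
    cur_tag <- c(cur_tag, fields[2])
  }
  flush_document()
  conner_corpus(docs, split_name = split_name)
}

#' Write a corpus in CoNLL-style two-column format
#'
#' Documents are separated by a `doc_marker` line; sentences by a blank
#' line. [read_conll()] of the result reproduces the corpus token for
#' token and tag for tag.
#'
#' @param corpus a `conner_corpus`.
#' @param path output file path.
#' @param doc_marker document boundary token.
#' @export
write_conll <- function(corpus, path, doc_marker = "-DOCSTART-") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (doc in corpus$documents) {
    writeLines(paste(doc_marker, "O"), con)
    writeLines("", con)
    for (sent in doc$sentences) {
      if (any(grepl("[ \t]", sent$tokens)))
        stop("token with internal whitespace cannot be serialized: '",
             sent$tokens[grepl("[ \t]", sent$tokens)][1], "'")
      writeLines(paste(sent$tokens, sent$tags), con)
      writeLines("", con)
    }
  }
  invisible(NULL)
}

## flat views used throughout: one row per token
corpus_flat <- function(corpus) {
  toks <- list(); tags <- list(); did <- list(); sid <- list()
  for (doc in corpus$documents) {
    for (s in seq_along(doc$sentences)) {
      sent <- doc$sentences[[s]]
      toks[[length(toks) + 1L]] <- sent$tokens
      tags[[length(tags) + 1L]] <- sent$tags
      did[[length(did) + 1L]] <- rep(doc$doc_id, length(sent$tokens))
      sid[[length(sid) + 1L]] <- rep(s, length(sent$tokens))
    }
  }
  data.frame(doc_id = unlist(did) %||% character(0),
             sent = unlist(sid) %||% integer(0),
             token = unlist(toks) %||% character(0),
             tag = unlist(tags) %||% character(0),
             stringsAsFactors = FALSE)
}
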