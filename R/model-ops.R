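#' Encode a document into per-token representations
#'
#' Runs the fitted model's bidirectional recurrent encoder over one
#' document (all sentences concatenated, document-level context) and
#' returns one `d`-dimensional row per word position. Documents longer
#' than the model's `max_len` are encoded in overlapping windows (stride
#' `max_len / 2`); each position takes its representation from the window
#' in which it is most central. Deterministic given the fitted
#' parameters.
#'
#' @param object a fitted `conner` model.
#' @param document one document element of a `conner_corpus` (a list with
#'   `doc_id` and `sentences`).
#' @return numeric matrix, N x d.
#' @export
encode_document <- function(object, document) {
  toks <- unlist(lapply(document$sentences, `[[`, "tokens"))
  if (!length(toks)) stop("cannot encode an empty document")
  x <- token_ids(object, toks)
  encode_ids(object, x)
}

encode_ids <- function(object, x) {
  N <- length(x)
  p <- object$params
  run <- function(ids) {
    X <- p$E[ids, , drop = FALSE]
    birnn_forward(X, p$Wf, p$Uf, p$bf, p$Wb, p$Ub, p$bb)$H
  }
  if (N <= object$max_len) return(run(x))
  wl <- object$max_len
  stride <- max(1L, wl %/% 2L)
  starts <- unique(c(seq(1L, N - wl + 1L, by = stride), N - wl + 1L))
  centers <- starts + (wl - 1) / 2
  H <- matrix(0, N, 2L * object$hidden_dim)
  owner <- vapply(seq_len(N), function(pos) {
    cand <- which(starts <= pos & pos <= starts + wl - 1L)
    cand[which.min(abs(centers[cand] - pos))]
  }, integer(1))
  for (w in seq_along(starts)) {
    rows <- which(owner == w)
    if (!length(rows)) next
    idx <- starts[w]:(starts[w] + wl - 1L)
    Hw <- run(x[idx])
    H[rows, ] <- Hw[rows - starts[w] + 1L, , drop = FALSE]
  }
  H
}

token_ids <- function(object, tokens) {
  id <- match(tolower(tokens), object$vocab)
  id[is.na(id)] <- 1L  # <unk>
  id
}

#' Main-head label distribution
#'
#' Applies the fitted model's tag-independent classification head (affine
#' map + row softmax) to encoder representations. With all-zero head
#' weights every row is uniform, 1/C per class.
#'
#' @param object a fitted `conner` model.
#' @param h N x d representation matrix from [encode_document()].
#' @return N x C matrix of row-normalized class probabilities.
#' @export
classify_tokens <- function(object, h) {
  N <- nrow(h)
  softmax_rows(h %*% object$params$Wp +
                 matrix(object$params$bp, N, length(object$params$bp),
                        byrow = TRUE))
}

#' Per-token uncertainty (Shannon entropy)
#'
#' Natural-log entropy of each row of a label distribution: 0 for a
#' one-hot row, `log(C)` for a uniform row.
#'
#' @param p N x C matrix of row-normalized probabilities.
#' @return numeric vector of N entropies in `[0, log(C)]`.
#' @export
token_uncertainty <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  row_entropy(p)
}

#' Build an entity mask over a document
#'
#' Boolean vector over the document's N word positions, `TRUE` exactly on
#' tokens covered by the given spans. Spans use document-local 1-based
#' half-open coordinates (`sent` + sentence-local `start`/`end`, as
#' returned by [corpus_spans()] for a single document, or plain
#' `start`/`end` interpreted document-wide when `sent` is absent).
#'
#' @param document a document (list with `sentences`), or an integer
#'   document length.
#' @param spans data.frame of spans.
#' @return logical vector of length N.
#' @export
entity_mask <- function(document, spans) {
  if (is.numeric(document)) {
    N <- as.integer(document)
    offs <- 0L
    lens <- N
  } else {
    lens <- vapply(document$sentences, function(s) length(s$tokens), integer(1))
    N <- sum(lens)
  }
  mask <- rep(FALSE, N)
  if (is.null(spans) || !nrow(spans)) return(mask)
  off <- c(0L, cumsum(lens))
  for (k in seq_len(nrow(spans))) {
    o <- if (!is.null(spans$sent)) off[spans$sent[k]] else 0L
    a <- o + spans$start[k]; b <- o + spans$end[k] - 1L
    if (a < 1L || b > N) stop("span out of bounds for document of length ", N)
    mask[a:b] <- TRUE
  }
  mask
}

#' Refinement-head label distribution
#'
#' Zeroes non-entity positions of the representations, runs the fitted
#' model's second bidirectional recurrent layer over the masked sequence
#' and applies the refinement classification head. All N rows are valid
#' distributions; rows outside the mask are present but ignored
#' downstream.
#'
#' @param object a fitted `conner` model.
#' @param h N x d representation matrix.
#' @param mask logical entity mask of length N.
#' @return N x C matrix of row-normalized probabilities.
#' @export
refine_distribution <- function(object, h, mask) {
  stopifnot(nrow(h) == length(mask))
  p <- object$params
  Hm <- h * mask
  ref <- birnn_forward(Hm, p$Vf, p$Gf, p$cf, p$Vb, p$Gb, p$cb)
  N <- nrow(h)
  softmax_rows(ref$H %*% p$Wl + matrix(p$bl, N, length(p$bl), byrow = TRUE))
}

#' Entropy-gated combination of main and refinement distributions
#'
#' For tokens inside the entity mask whose uncertainty is at least
#' `gamma`, the output row is the renormalized element-wise sum
#' `(p + l) / 2`; every other row is `p` unchanged. Rows always sum to 1.
#' With `gamma > log(C)` the gate can never fire and the output equals
#' `p` exactly.
#'
#' @param p N x C main-head distribution.
#' @param l N x C refinement-head distribution.
#' @param u numeric vector of N token uncertainties (see
#'   [token_uncertainty()]).
#' @param mask logical entity mask of length N.
#' @param gamma non-negative uncertainty threshold (default 0.3,
#'   natural-log scale).
#' @return N x C matrix of row-normalized probabilities.
#' @export
combine_distributions <- function(p, l, u, mask, gamma = 0.3) {
  if (gamma < 0) stop("gamma must be non-negative")
  stopifnot(nrow(p) == nrow(l), nrow(p) == length(u),
            nrow(p) == length(mask))
  gate <- mask & (u >= gamma)
  out <- p
  if (any(gate)) {
    s <- p[gate, , drop = FALSE] + l[gate, , drop = FALSE]
    out[gate, ] <- s / rowSums(s)
  }
  out
}
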