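#' Classification loss (token-level cross-entropy)
#'
#' Mean over tokens of the negative log probability assigned to the gold
#' class. When label refinement is active the distribution passed in is
#' the gated combination of the two heads; the operation is the same at
#' either pipeline stage.
#'
#' @param p N x C matrix of row-normalized probabilities.
#' @param gold integer vector of N gold class indices (1-based).
#' @return non-negative scalar.
#' @export
classification_loss <- function(p, gold) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (nrow(p) != length(gold))
    stop("length mismatch: ", nrow(p), " rows vs ", length(gold), " labels")
  ce_loss(p, gold)
}

#' Label loss of the refinement head
#'
#' Cross-entropy of the refinement distribution against gold, averaged
#' over entity (masked) tokens only; 0 when the mask is empty. Non-entity
#' positions carry no signal through the entity mask, so they do not
#' enter the average.
#'
#' @param l N x C refinement-head distribution.
#' @param gold integer vector of N gold class indices.
#' @param mask logical entity mask of length N.
#' @return non-negative scalar.
#' @export
label_loss <- function(l, gold, mask) {
  if (is.null(dim(l))) l <- matrix(l, nrow = 1)
  if (nrow(l) != length(gold) || nrow(l) != length(mask))
    stop("length mismatch between distribution, gold and mask")
  masked_ce_loss(l, gold, mask)
}

#' Distillation loss (symmetric Kullback-Leibler divergence)
#'
#' `(KL(p || l) + KL(l || p)) / 2` averaged over tokens, computed on the
#' pre-combination main-head distribution. Probabilities are clamped at
#' 1e-8 inside logarithms for numerical safety. Zero iff `p == l`,
#' symmetric in its arguments, non-negative.
#'
#' @param p N x C main-head distribution.
#' @param l N x C refinement-head distribution.
#' @return non-negative scalar.
#' @export
distill_loss <- function(p, l) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (is.null(dim(l))) l <- matrix(l, nrow = 1)
  stopifnot(all(dim(p) == dim(l)))
  mean(sym_kl_rows(p, l))
}

#' Combined training objective
#'
#' `total = lambda[1] * l_class + lambda[2] * l_label + lambda[3] *
#' l_distill`. Defaults are the weights used throughout the package:
#' `lambda = c(1, 0.1, 0.001)`.
#'
#' @param l_class classification loss component.
#' @param l_label refinement label loss component.
#' @param l_distill distillation loss component.
#' @param lambda numeric vector of three non-negative weights.
#' @return list of class `conner_loss` with the three components and
#'   `total`.
#' @export
total_loss <- function(l_class, l_label, l_distill,
                       lambda = c(1, 0.1, 0.001)) {
  if (length(lambda) != 3 || any(lambda < 0))
    stop("lambda must be three non-negative weights")
  structure(list(l_class = l_class, l_label = l_label,
                 l_distill = l_distill,
                 total = lambda[1] * l_class + lambda[2] * l_label +
                   lambda[3] * l_distill,
                 lambda = lambda),
            class = "conner_loss")
}

#' @export
print.conner_loss <- function(x, ...) {
  cat(sprintf("loss: total %.4f = %g*class %.4f + %g*label %.4f + %g*distill %.4f\n",
              x$total, x$lambda[1], x$l_class, x$lambda[2], x$l_label,
              x$lambda[3], x$l_distill))
  invisible(x)
}
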