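## Internal network math for the document tagger.
##
## Architecture: token embeddings -> bidirectional Elman (tanh) encoder ->
## affine+softmax main head p. Refinement branch: entity-masked encoder
## states -> second bidirectional Elman layer -> affine+softmax head l.
## Token entropy of p gates an element-wise combination (p+l)/2 on entity
## tokens. All gradients are written out by hand and checked against
## finite differences in the test suite.

EPS_LOG <- 1e-8

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_params <- function(vocab_size, n_classes, emb_dim, hidden_dim, refine_dim) {
  d <- 2L * hidden_dim
  list(
    E  = glorot(vocab_size, emb_dim),
    Wf = glorot(emb_dim, hidden_dim), Uf = glorot(hidden_dim, hidden_dim),
    bf = numeric(hidden_dim),
    Wb = glorot(emb_dim, hidden_dim), Ub = glorot(hidden_dim, hidden_dim),
    bb = numeric(hidden_dim),
    Wp = glorot(d, n_classes), bp = numeric(n_classes),
    Vf = glorot(d, refine_dim), Gf = glorot(refine_dim, refine_dim),
    cf = numeric(refine_dim),
    Vb = glorot(d, refine_dim), Gb = glorot(refine_dim, refine_dim),
    cb = numeric(refine_dim),
    Wl = glorot(2L * refine_dim, n_classes), bl = numeric(n_classes)
  )
}

rnn_dir_forward <- function(X, W, U, b, reverse = FALSE) {
  N <- nrow(X); m <- ncol(W)
  H <- matrix(0, N, m)
  h <- numeric(m)
  ord <- if (reverse) rev(seq_len(N)) else seq_len(N)
  for (t in ord) {
    h <- tanh(drop(X[t, ] %*% W) + drop(h %*% U) + b)
    H[t, ] <- h
  }
  H
}

rnn_dir_backward <- function(X, H, W, U, dH, reverse = FALSE) {
  N <- nrow(X); m <- ncol(W)
  dW <- matrix(0, nrow(W), m); dU <- matrix(0, m, m); db <- numeric(m)
  dX <- matrix(0, N, ncol(X))
  delta <- numeric(m)
  ord <- if (reverse) seq_len(N) else rev(seq_len(N))
  for (t in ord) {
    da <- (dH[t, ] + delta) * (1 - H[t, ]^2)
    dW <- dW + outer(X[t, ], da)
    hprev <- if (reverse) {
      if (t < N) H[t + 1L, ] else numeric(m)
    } else {
      if (t > 1L) H[t - 1L, ] else numeric(m)
    }
    dU <- dU + outer(hprev, da)
    db <- db + da
    dX[t, ] <- drop(da %*% t(W))
    delta <- drop(da %*% t(U))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

birnn_forward <- function(X, W1, U1, b1, W2, U2, b2) {
  Hf <- rnn_dir_forward(X, W1, U1, b1, reverse = FALSE)
  Hb <- rnn_dir_forward(X, W2, U2, b2, reverse = TRUE)
  list(Hf = Hf, Hb = Hb, H = cbind(Hf, Hb))
}

birnn_backward <- function(X, fw, W1, U1, W2, U2, dH) {
  m <- ncol(fw$Hf)
  gf <- rnn_dir_backward(X, fw$Hf, W1, U1, dH[, seq_len(m), drop = FALSE],
                         reverse = FALSE)
  gb <- rnn_dir_backward(X, fw$Hb, W2, U2,
                         dH[, m + seq_len(m), drop = FALSE], reverse = TRUE)
  list(dW1 = gf$dW, dU1 = gf$dU, db1 = gf$db,
       dW2 = gb$dW, dU2 = gb$dU, db2 = gb$db,
       dX = gf$dX + gb$dX)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

row_entropy <- function(P) {
  -rowSums(P * log(pmax(P, EPS_LOG)))
}

## symmetric KL per row, eps-clamped inside logs and ratios
sym_kl_rows <- function(P, L) {
  Pc <- pmax(P, EPS_LOG); Lc <- pmax(L, EPS_LOG)
  0.5 * (rowSums(Pc * (log(Pc) - log(Lc))) +
         rowSums(Lc * (log(Lc) - log(Pc))))
}

## gradient of mean-over-rows sym KL wrt P and L (in probability space)
sym_kl_grad <- function(P, L) {
  N <- nrow(P)
  Pc <- pmax(P, EPS_LOG); Lc <- pmax(L, EPS_LOG)
  gP <- (log(Pc / Lc) + 1 - Lc / Pc) / (2 * N)
  gL <- (log(Lc / Pc) + 1 - Pc / Lc) / (2 * N)
  list(gP = gP, gL = gL)
}

## probability-space grad -> logit-space grad through row softmax
prob_to_logit_grad <- function(P, gP) {
  P * gP - P * rowSums(P * gP)
}

## Full forward pass over one document (one training sequence).
## x: integer token ids; y: integer class ids (may be NULL at inference);
## mask: logical entity mask; cfg: list(gamma, lambda, refine, refined_loss)
forward_doc <- function(params, x, y, mask, cfg) {
  N <- length(x)
  X <- params$E[x, , drop = FALSE]
  enc <- birnn_forward(X, params$Wf, params$Uf, params$bf,
                       params$Wb, params$Ub, params$bb)
  H <- enc$H
  P <- softmax_rows(H %*% params$Wp + matrix(params$bp, N, length(params$bp),
                                             byrow = TRUE))
  U <- row_entropy(P)
  out <- list(X = X, enc = enc, H = H, P = P, U = U, mask = mask, N = N)
  if (cfg$refine) {
    Hm <- H * mask
    ref <- birnn_forward(Hm, params$Vf, params$Gf, params$cf,
                         params$Vb, params$Gb, params$cb)
    Lmat <- softmax_rows(ref$H %*% params$Wl +
                           matrix(params$bl, N, length(params$bl), byrow = TRUE))
    gate <- mask & (U >= cfg$gamma)
    Comb <- P
    if (any(gate))
      Comb[gate, ] <- (P[gate, , drop = FALSE] + Lmat[gate, , drop = FALSE]) / 2
    out$Hm <- Hm; out$ref <- ref; out$L <- Lmat; out$gate <- gate
    out$Comb <- Comb
  } else {
    out$Comb <- P
    out$gate <- rep(FALSE, N)
  }
  if (!is.null(y)) {
    cls_target <- if (cfg$refine && cfg$refined_loss) out$Comb else P
    out$l_class <- ce_loss(cls_target, y)
    out$l_label <- if (cfg$refine) masked_ce_loss(out$L, y, mask) else 0
    out$l_distill <- if (cfg$refine) mean(sym_kl_rows(P, out$L)) else 0
    lam <- cfg$lambda
    out$total <- lam[1] * out$l_class + lam[2] * out$l_label +
      lam[3] * out$l_distill
  }
  out
}

ce_loss <- function(P, y) {
  N <- nrow(P)
  mean(-log(pmax(P[cbind(seq_len(N), y)], EPS_LOG)))
}

masked_ce_loss <- function(L, y, mask) {
  if (!any(mask)) return(0)
  idx <- which(mask)
  mean(-log(pmax(L[cbind(idx, y[idx])], EPS_LOG)))
}

## Backward pass: returns list of gradients with the same names as params.
backward_doc <- function(params, fw, x, y, cfg) {
  N <- fw$N
  C <- ncol(fw$P)
  lam <- cfg$lambda
  gP <- matrix(0, N, C)   # prob-space grads
  gL <- if (cfg$refine) matrix(0, N, C) else NULL
  iy <- cbind(seq_len(N), y)

  if (cfg$refine && cfg$refined_loss) {
    ## L_class on combined distribution; gate treated as constant
    cg <- pmax(fw$Comb[iy], EPS_LOG)
    gate <- fw$gate
    for (t in seq_len(N)) {
      gt <- -lam[1] / (N * cg[t])
      if (gate[t]) {
        gP[t, y[t]] <- gP[t, y[t]] + gt / 2
        gL[t, y[t]] <- gL[t, y[t]] + gt / 2
      } else {
        gP[t, y[t]] <- gP[t, y[t]] + gt
      }
    }
  } else {
    cg <- pmax(fw$P[iy], EPS_LOG)
    gP[iy] <- gP[iy] - lam[1] / (N * cg)
  }

  if (cfg$refine) {
    ## label loss on masked tokens
    if (any(fw$mask) && lam[2] != 0) {
      idx <- which(fw$mask)
      lg <- pmax(fw$L[cbind(idx, y[idx])], EPS_LOG)
      for (k in seq_along(idx)) {
        t <- idx[k]
        gL[t, y[t]] <- gL[t, y[t]] - lam[2] / (length(idx) * lg[k])
      }
    }
    ## distillation on pre-combination p
    if (lam[3] != 0) {
      kg <- sym_kl_grad(fw$P, fw$L)
      gP <- gP + lam[3] * kg$gP
      gL <- gL + lam[3] * kg$gL
    }
  }

  dZp <- prob_to_logit_grad(fw$P, gP)
  grads <- list()
  grads$Wp <- t(fw$H) %*% dZp
  grads$bp <- colSums(dZp)
  dH <- dZp %*% t(params$Wp)

  if (cfg$refine) {
    dZl <- prob_to_logit_grad(fw$L, gL)
    grads$Wl <- t(fw$ref$H) %*% dZl
    grads$bl <- colSums(dZl)
    dM <- dZl %*% t(params$Wl)
    gr <- birnn_backward(fw$Hm, fw$ref, params$Vf, params$Gf,
                         params$Vb, params$Gb, dM)
    grads$Vf <- gr$dW1; grads$Gf <- gr$dU1; grads$cf <- gr$db1
    grads$Vb <- gr$dW2; grads$Gb <- gr$dU2; grads$cb <- gr$db2
    dH <- dH + gr$dX * fw$mask
  } else {
    for (nm in c("Vf", "Gf", "cf", "Vb", "Gb", "cb", "Wl", "bl"))
      grads[[nm]] <- params[[nm]] * 0
  }

  ge <- birnn_backward(fw$X, fw$enc, params$Wf, params$Uf,
                       params$Wb, params$Ub, dH)
  grads$Wf <- ge$dW1; grads$Uf <- ge$dU1; grads$bf <- ge$db1
  grads$Wb <- ge$dW2; grads$Ub <- ge$dU2; grads$bb <- ge$db2
  dE <- params$E * 0
  for (t in seq_len(N)) dE[x[t], ] <- dE[x[t], ] + ge$dX[t, ]
  grads$E <- dE
  grads[names(params)]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
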