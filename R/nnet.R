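# Internal implementation of the gated dilated-convolution network.
#
# Layout: segments of length T are laid out side by side as columns of a
# C x (T*B) matrix; a dilated kernel-2 convolution is two 1x1 convolutions
# (matrix products) of the signal and a within-segment shifted copy.
# Each residual block computes tanh/sigmoid gated features, adds a 1x1
# projection back onto the residual path, and contributes to a skip sum;
# a two-layer relu head with a sigmoid output maps the skip sum to
# per-sample probabilities.

# out[, t] = X[, t + o] within each of B segments of length Tlen; zeros
# where t + o falls outside the segment.
shiftCols <- function(X, o, Tlen, B) {
  if (o == 0L) return(X)
  colt <- rep.int(seq_len(Tlen), B)
  shifted <- colt + o
  valid <- shifted >= 1L & shifted <= Tlen
  base <- rep(seq.int(0L, by = Tlen, length.out = B), each = Tlen)
  out <- matrix(0, nrow(X), ncol(X))
  out[, which(valid)] <- X[, (base + shifted)[valid]]
  out
}

blockOffsets <- function(d, mode) {
  if (mode == "causal") c(0L, -as.integer(d))
  else c(as.integer(floor(d / 2)), as.integer(floor(d / 2)) - as.integer(d))
}

initNetParams <- function(cfg, seed) {
  set.seed(seed)
  C <- cfg$channels
  him <- function(nin, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nin)), nr, nc)
  }
  # biases start at small random values rather than exactly zero so no
  # relu/gate pre-activation sits exactly on its kink at initialization
  bini <- function(k) stats::rnorm(k, sd = 0.01)
  p <- list(Wi = him(1, C, 1), bi = bini(C))
  for (b in seq_len(cfg$n_blocks)) {
    p[[paste0("Wf1_", b)]] <- him(2 * C, C, C)
    p[[paste0("Wf2_", b)]] <- him(2 * C, C, C)
    p[[paste0("bf_", b)]] <- bini(C)
    p[[paste0("Wg1_", b)]] <- him(2 * C, C, C)
    p[[paste0("Wg2_", b)]] <- him(2 * C, C, C)
    p[[paste0("bg_", b)]] <- bini(C)
    p[[paste0("Wr_", b)]] <- him(C, C, C)
    p[[paste0("br_", b)]] <- bini(C)
    p[[paste0("Ws_", b)]] <- him(C, C, C)
  }
  p$bs <- bini(C)
  p$Wh <- him(C, C, C)
  p$bh <- bini(C)
  p$wo <- him(C, 1, C)
  p$bo <- bini(1)
  p
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# x: B x T matrix of standardized segments. Returns probabilities and,
# if keepActs, the activations needed for the backward pass.
netForward <- function(params, cfg, x, keepActs = FALSE) {
  B <- nrow(x); Tlen <- ncol(x)
  xv <- matrix(as.vector(t(x)), nrow = 1)
  X <- params$Wi %*% xv + params$bi
  S <- 0
  acts <- if (keepActs) {
    list(xv = xv, X = vector("list", cfg$n_blocks),
         Fa = vector("list", cfg$n_blocks),
         Ga = vector("list", cfg$n_blocks))
  }
  for (b in seq_len(cfg$n_blocks)) {
    d <- cfg$dilations[b]
    off <- blockOffsets(d, cfg$padding_mode)
    A1 <- shiftCols(X, off[1], Tlen, B)
    A2 <- shiftCols(X, off[2], Tlen, B)
    Fa <- tanh(params[[paste0("Wf1_", b)]] %*% A1 +
                 params[[paste0("Wf2_", b)]] %*% A2 +
                 params[[paste0("bf_", b)]])
    Ga <- sigmoid(params[[paste0("Wg1_", b)]] %*% A1 +
                    params[[paste0("Wg2_", b)]] %*% A2 +
                    params[[paste0("bg_", b)]])
    H <- Fa * Ga
    S <- S + params[[paste0("Ws_", b)]] %*% H
    if (keepActs) {
      acts$X[[b]] <- X; acts$Fa[[b]] <- Fa; acts$Ga[[b]] <- Ga
    }
    X <- X + params[[paste0("Wr_", b)]] %*% H +
      params[[paste0("br_", b)]]
  }
  Spre <- S + params$bs
  R0 <- Spre * (Spre > 0)
  Z1 <- params$Wh %*% R0 + params$bh
  R1 <- Z1 * (Z1 > 0)
  z <- params$wo %*% R1 + params$bo
  p <- sigmoid(z)
  if (keepActs) {
    acts$Spre <- Spre; acts$R0 <- R0; acts$Z1 <- Z1; acts$R1 <- R1
    acts$p <- p
    list(p = p, acts = acts)
  } else {
    list(p = p)
  }
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy between predicted probabilities and 0/1
#' targets, with probabilities clamped to `[eps, 1 - eps]`.
#'
#' @param p predicted probabilities.
#' @param y targets in `{0, 1}` (same length).
#' @param eps clamping constant (default 1e-7).
#' @return scalar loss.
#' @export
bceLoss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradients of mean BCE loss wrt all parameters. y laid out like p.
netBackward <- function(params, cfg, acts, y) {
  N <- length(acts$p)
  dz <- (acts$p - y) / N                        # 1 x N
  g <- list()
  g$wo <- dz %*% t(acts$R1)
  g$bo <- sum(dz)
  dR1 <- t(params$wo) %*% dz
  dZ1 <- dR1 * (acts$Z1 > 0)
  g$Wh <- dZ1 %*% t(acts$R0)
  g$bh <- rowSums(dZ1)
  dR0 <- t(params$Wh) %*% dZ1
  dS <- dR0 * (acts$Spre > 0)
  g$bs <- rowSums(dS)
  Tlen <- attr(acts, "Tlen"); B <- attr(acts, "B")
  dX <- 0
  for (b in rev(seq_len(cfg$n_blocks))) {
    X <- acts$X[[b]]; Fa <- acts$Fa[[b]]; Ga <- acts$Ga[[b]]
    H <- Fa * Ga
    d <- cfg$dilations[b]
    off <- blockOffsets(d, cfg$padding_mode)
    A1 <- shiftCols(X, off[1], Tlen, B)
    A2 <- shiftCols(X, off[2], Tlen, B)
    # dX arrives from the residual path above this block
    dXup <- if (is.matrix(dX)) dX else matrix(0, nrow(X), ncol(X))
    g[[paste0("Wr_", b)]] <- dXup %*% t(H)
    g[[paste0("br_", b)]] <- rowSums(dXup)
    g[[paste0("Ws_", b)]] <- dS %*% t(H)
    dH <- t(params[[paste0("Wr_", b)]]) %*% dXup +
      t(params[[paste0("Ws_", b)]]) %*% dS
    dF <- dH * Ga
    dG <- dH * Fa
    dpreF <- dF * (1 - Fa^2)
    dpreG <- dG * Ga * (1 - Ga)
    g[[paste0("Wf1_", b)]] <- dpreF %*% t(A1)
    g[[paste0("Wf2_", b)]] <- dpreF %*% t(A2)
    g[[paste0("bf_", b)]] <- rowSums(dpreF)
    g[[paste0("Wg1_", b)]] <- dpreG %*% t(A1)
    g[[paste0("Wg2_", b)]] <- dpreG %*% t(A2)
    g[[paste0("bg_", b)]] <- rowSums(dpreG)
    dA1 <- t(params[[paste0("Wf1_", b)]]) %*% dpreF +
      t(params[[paste0("Wg1_", b)]]) %*% dpreG
    dA2 <- t(params[[paste0("Wf2_", b)]]) %*% dpreF +
      t(params[[paste0("Wg2_", b)]]) %*% dpreG
    dX <- dXup + shiftCols(dA1, -off[1], Tlen, B) +
      shiftCols(dA2, -off[2], Tlen, B)
  }
  g$Wi <- dX %*% t(acts$xv)
  g$bi <- rowSums(dX)
  g
}

adamInit <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# forward+backward for one minibatch; returns loss and gradients
netLossGrad <- function(params, cfg, x, y) {
  fw <- netForward(params, cfg, x, keepActs = TRUE)
  acts <- fw$acts
  attr(acts, "Tlen") <- ncol(x)
  attr(acts, "B") <- nrow(x)
  yv <- matrix(as.vector(t(y)), nrow = 1)
  loss <- bceLoss(as.vector(fw$p), as.vector(yv))
  g <- netBackward(params, cfg, acts, yv)
  list(loss = loss, grads = g)
}
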