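# Batched network kernels.
#
# All batched signals use one stacked layout: a (B * L) x C matrix
# whose rows are per-sample blocks of L positions, position index
# varying fastest. Because R matrices are column-major this layout can
# be reinterpreted as (L, B*C) or (L*B, C) without copying, which lets
# the Chebyshev basis act on a whole batch with a single matrix
# product per polynomial term.

# Add a per-column bias without sweep()'s aperm overhead.
addBias <- function(Y, b) Y + rep(b, each = nrow(Y))

# --- Chebyshev layer expansion -------------------------------------

# Expand a stacked signal into [T_0(Lt) H | ... | T_{K-1}(Lt) H], a
# (B*L) x (K*Cin) matrix with k-major column blocks. A Chebyshev
# convolution is then one product with the stacked coefficient matrix.
chebExpand <- function(H, L, B, basis) {
  cin <- ncol(H)
  K <- length(basis)
  Hr <- H
  dim(Hr) <- c(L, B * cin)
  out <- matrix(0, nrow = L * B, ncol = K * cin)
  for (k in seq_len(K)) {
    Zk <- basis[[k]] %*% Hr
    dim(Zk) <- c(L * B, cin)
    out[, ((k - 1L) * cin + 1L):(k * cin)] <- Zk
  }
  out
}

# Adjoint of chebExpand: T_k(Lt) is symmetric, so the gradient w.r.t.
# the un-expanded signal is the same transform applied blockwise.
chebExpandBackward <- function(dM, L, B, cin, basis) {
  K <- length(basis)
  dH <- matrix(0, nrow = L * B, ncol = cin)
  for (k in seq_len(K)) {
    blk <- dM[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    dim(blk) <- c(L, B * cin)
    dblk <- basis[[k]] %*% blk
    dim(dblk) <- c(L * B, cin)
    dH <- dH + dblk
  }
  dH
}

# --- Convolution layer expansion -----------------------------------

# Batched im2col on the stacked layout. rows0 indexes, for every
# sample block, the Lout window starts; offset j then shifts within
# the block, never across blocks.
convRows0 <- function(L, B, kernel) {
  Lout <- L - kernel + 1L
  as.vector(outer(seq_len(Lout), (seq_len(B) - 1L) * L, "+"))
}

convExpand <- function(H, rows0, kernel) {
  do.call(cbind, lapply(0:(kernel - 1L), function(j) {
    H[rows0 + j, , drop = FALSE]
  }))
}

convExpandBackward <- function(dM, rows0, L, B, cin, kernel) {
  dH <- matrix(0, nrow = L * B, ncol = cin)
  for (j in 0:(kernel - 1L)) {
    dH[rows0 + j, ] <- dH[rows0 + j, ] +
      dM[, (j * cin + 1L):((j + 1L) * cin), drop = FALSE]
  }
  dH
}

# Zero-pad / unpad each sample block ("same" convolution mode).
padStacked <- function(H, L, B, padLeft, padRight) {
  Lp <- L + padLeft + padRight
  Hp <- matrix(0, nrow = B * Lp, ncol = ncol(H))
  keep <- as.vector(outer(seq_len(L) + padLeft, (seq_len(B) - 1L) * Lp, "+"))
  Hp[keep, ] <- H
  Hp
}

unpadStacked <- function(dHp, L, B, padLeft, padRight) {
  Lp <- L + padLeft + padRight
  keep <- as.vector(outer(seq_len(L) + padLeft, (seq_len(B) - 1L) * Lp, "+"))
  dHp[keep, , drop = FALSE]
}

# --- Flatten --------------------------------------------------------

# (B*L) x C stacked signal -> B x (L*C) per-sample feature rows,
# channel index fastest within each position (fixed flatten order).
flattenStacked <- function(Y, L, B, C) {
  A <- Y
  dim(A) <- c(L, B, C)
  A <- aperm(A, c(3, 1, 2))
  dim(A) <- c(C * L, B)
  t(A)
}

unflattenStacked <- function(dF, L, B, C) {
  A <- t(dF)
  dim(A) <- c(C, L, B)
  A <- aperm(A, c(2, 3, 1))
  dim(A) <- c(L * B, C)
  A
}

# --- Full model forward / backward ---------------------------------

# Forward pass over a stacked one-hot batch Xb ((B*L) x 4). Returns
# probabilities and, when keepCache, every intermediate needed by the
# analytic backward pass. Dropout masks are drawn from the current RNG
# stream only when training.
nnForward <- function(params, cfg, basis, Xb, B, training = FALSE,
                      keepCache = FALSE) {
  L <- cfg$encoding$windowLength
  ab <- cfg$training$ablation
  slopeC <- cfg$chebnet$slope
  slopeN <- cfg$cnn$slope
  cache <- list(Xb = Xb, B = B)

  chebFlat <- NULL
  if (ab != "cnn_only") {
    H0 <- Xb %*% params$preW
    H0 <- addBias(H0, params$preB)
    M1 <- chebExpand(H0, L, B, basis)
    A1 <- addBias(M1 %*% params$cheb1W, params$cheb1B)
    R1 <- leakyRelu(A1, slopeC)
    M2 <- chebExpand(R1, L, B, basis)
    A2 <- addBias(M2 %*% params$cheb2W, params$cheb2B)
    R2 <- leakyRelu(A2, slopeC)
    chebFlat <- flattenStacked(R2, L, B, ncol(R2))
    if (keepCache) {
      cache$cheb <- list(M1 = M1, A1 = A1, R1 = R1, M2 = M2, A2 = A2)
    }
  }

  cnnFlat <- NULL
  if (ab != "chebnet_only") {
    kernel <- cfg$cnn$kernelSize
    same <- identical(cfg$cnn$padding, "same")
    padL <- if (same) (kernel - 1L) %/% 2L else 0L
    padR <- if (same) kernel - 1L - padL else 0L
    Hin <- if (same) padStacked(Xb, L, B, padL, padR) else Xb
    Lin1 <- L + padL + padR
    rows1 <- convRows0(Lin1, B, kernel)
    N1 <- convExpand(Hin, rows1, kernel)
    C1 <- addBias(N1 %*% params$conv1W, params$conv1B)
    S1 <- leakyRelu(C1, slopeN)
    Lout1 <- Lin1 - kernel + 1L
    Sin2 <- if (same) padStacked(S1, Lout1, B, padL, padR) else S1
    Lin2 <- Lout1 + padL + padR
    rows2 <- convRows0(Lin2, B, kernel)
    N2 <- convExpand(Sin2, rows2, kernel)
    C2 <- addBias(N2 %*% params$conv2W, params$conv2B)
    S2 <- leakyRelu(C2, slopeN)
    Lout2 <- Lin2 - kernel + 1L
    cnnFlat <- flattenStacked(S2, Lout2, B, ncol(S2))
    if (keepCache) {
      cache$cnn <- list(
        N1 = N1, C1 = C1, S1 = S1, N2 = N2, C2 = C2,
        rows1 = rows1, rows2 = rows2, Lin1 = Lin1, Lin2 = Lin2,
        Lout1 = Lout1, Lout2 = Lout2, padL = padL, padR = padR,
        same = same
      )
    }
  }

  Hf <- cbind(chebFlat, cnnFlat)
  cache$chebLen <- if (is.null(chebFlat)) 0L else ncol(chebFlat)

  slopeH <- cfg$head$slope
  keep <- 1 - cfg$head$dropout
  Z1 <- addBias(Hf %*% params$headW1, params$headB1)
  G1 <- leakyRelu(Z1, slopeH)
  D1 <- if (training && keep < 1) {
    m <- matrix(
      (stats::runif(length(G1)) < keep) / keep, nrow(G1), ncol(G1)
    )
    cache$mask1 <- m
    G1 * m
  } else {
    G1
  }
  Z2 <- addBias(D1 %*% params$headW2, params$headB2)
  G2 <- leakyRelu(Z2, slopeH)
  D2 <- if (training && keep < 1) {
    m <- matrix(
      (stats::runif(length(G2)) < keep) / keep, nrow(G2), ncol(G2)
    )
    cache$mask2 <- m
    G2 * m
  } else {
    G2
  }
  z <- addBias(D2 %*% params$headW3, params$headB3)
  p <- sigmoid(as.vector(z))

  if (keepCache) {
    cache$head <- list(Hf = Hf, Z1 = Z1, D1 = D1, Z2 = Z2, D2 = D2)
    cache$training <- training
  }
  list(p = p, cache = if (keepCache) cache else NULL)
}

# Mean binary cross-entropy of a forward pass plus the gradient of
# that mean with respect to every parameter.
nnLossGrad <- function(params, cfg, basis, Xb, y, B, training = FALSE) {
  fw <- nnForward(params, cfg, basis, Xb, B,
    training = training, keepCache = TRUE)
  p <- fw$p
  cache <- fw$cache
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  if (!is.finite(loss)) {
    stop("non-finite training loss; optimization diverged")
  }

  L <- cfg$encoding$windowLength
  slopeC <- cfg$chebnet$slope
  slopeN <- cfg$cnn$slope
  slopeH <- cfg$head$slope
  grads <- list()

  # head (sigmoid + BCE collapses to p - y at the logit)
  dz <- matrix((p - y) / B, ncol = 1)
  hd <- cache$head
  grads$headW3 <- crossprod(hd$D2, dz)
  grads$headB3 <- colSums(dz)
  dD2 <- tcrossprod(dz, params$headW3)
  if (!is.null(cache$mask2)) dD2 <- dD2 * cache$mask2
  dZ2 <- dD2 * leakyReluGrad(hd$Z2, slopeH)
  grads$headW2 <- crossprod(hd$D1, dZ2)
  grads$headB2 <- colSums(dZ2)
  dD1 <- tcrossprod(dZ2, params$headW2)
  if (!is.null(cache$mask1)) dD1 <- dD1 * cache$mask1
  dZ1 <- dD1 * leakyReluGrad(hd$Z1, slopeH)
  grads$headW1 <- crossprod(hd$Hf, dZ1)
  grads$headB1 <- colSums(dZ1)
  dHf <- tcrossprod(dZ1, params$headW1)

  chebLen <- cache$chebLen
  if (chebLen > 0L) {
    dChebFlat <- dHf[, seq_len(chebLen), drop = FALSE]
    cb <- cache$cheb
    C2 <- ncol(cb$A2)
    dR2 <- unflattenStacked(dChebFlat, L, B, C2)
    dA2 <- dR2 * leakyReluGrad(cb$A2, slopeC)
    grads$cheb2W <- crossprod(cb$M2, dA2)
    grads$cheb2B <- colSums(dA2)
    dM2 <- tcrossprod(dA2, params$cheb2W)
    dR1 <- chebExpandBackward(dM2, L, B, ncol(cb$A1), basis)
    dA1 <- dR1 * leakyReluGrad(cb$A1, slopeC)
    grads$cheb1W <- crossprod(cb$M1, dA1)
    grads$cheb1B <- colSums(dA1)
    dM1 <- tcrossprod(dA1, params$cheb1W)
    dH0 <- chebExpandBackward(dM1, L, B, ncol(params$preW), basis)
    grads$preW <- crossprod(cache$Xb, dH0)
    grads$preB <- colSums(dH0)
  }

  if (cfg$training$ablation != "chebnet_only") {
    dCnnFlat <- dHf[, (chebLen + 1L):ncol(dHf), drop = FALSE]
    cn <- cache$cnn
    kernel <- cfg$cnn$kernelSize
    F2 <- ncol(cn$C2)
    dS2 <- unflattenStacked(dCnnFlat, cn$Lout2, B, F2)
    dC2 <- dS2 * leakyReluGrad(cn$C2, slopeN)
    grads$conv2W <- crossprod(cn$N2, dC2)
    grads$conv2B <- colSums(dC2)
    dN2 <- tcrossprod(dC2, params$conv2W)
    dSin2 <- convExpandBackward(dN2, cn$rows2, cn$Lin2, B, ncol(cn$C1),
      kernel)
    dS1 <- if (cn$same) {
      unpadStacked(dSin2, cn$Lout1, B, cn$padL, cn$padR)
    } else {
      dSin2
    }
    dC1 <- dS1 * leakyReluGrad(cn$C1, slopeN)
    grads$conv1W <- crossprod(cn$N1, dC1)
    grads$conv1B <- colSums(dC1)
  }

  list(loss = loss, grads = grads, p = p)
}

# --- Adam optimizer -------------------------------------------------

adamInit <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adamStep <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
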