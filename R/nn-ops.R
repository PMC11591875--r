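# Internal neural-network primitives for the CRNN.
#
# No deep-learning runtime is assumed: convolution is im2col + GEMM (BLAS
# does the heavy lifting), batch normalization, frequency max-pooling, the
# multi-layer LSTM and Adam are implemented directly, with hand-derived
# backward passes. Activations are matrices of shape
# (channels, H*W*batch) with spatial positions ordered frequency-fastest,
# then time, then batch -- the column-major flattening of an
# (nMels, nFrames, batch) array.

# Index plan for a 3x3 same-padded convolution at a given spatial/batch
# shape. `interior` embeds/extracts the unpadded canvas; `tgt[[k]]` selects
# the shifted view of kernel tap k (and is the scatter-add target of the
# backward pass).
.convPlan <- function(H, W, B) {
    padH <- H + 2L
    HW <- H * W
    pHW <- padH * (W + 2L)
    h <- rep.int(seq_len(H), W)
    w <- rep(seq_len(W), each = H)
    interior1 <- (h + 1L) + w * padH
    nb <- matrix(0L, 9L, HW)
    k <- 0L
    for (dw in -1L:1L) for (dh in -1L:1L) {
        k <- k + 1L
        nb[k, ] <- (h + 1L + dh) + (w + dw) * padH
    }
    boff <- rep.int((seq_len(B) - 1L) * pHW, rep.int(HW, B))
    interior <- rep.int(interior1, B) + boff
    tgt <- vector("list", 9L)
    for (k in 1:9) tgt[[k]] <- rep.int(nb[k, ], B) + boff
    list(interior = interior, tgt = tgt, pHW = pHW, HW = HW, B = B)
}

.planKey <- function(H, W, B) sprintf("%d_%d_%d", H, W, B)

.getPlan <- function(plans, H, W, B) {
    key <- .planKey(H, W, B)
    if (is.null(plans[[key]])) plans[[key]] <- .convPlan(H, W, B)
    plans[[key]]
}

# 3x3 same conv forward. A: (Cin, HW*B); Wm: (Cout, Cin*9), column index
# c + Cin*(k-1). Rather than materializing an im2col matrix, the convolution
# is the sum of 9 per-tap GEMMs over shifted views of the padded canvas --
# far less memory traffic in an interpreted setting. Returns the
# pre-activation and the padded canvas for the backward pass.
.convF <- function(A, Wm, b, plan) {
    Cin <- nrow(A)
    Ap <- matrix(0, Cin, plan$pHW * plan$B)
    Ap[, plan$interior] <- A
    Y <- NULL
    for (k in 1:9) {
        Wk <- Wm[, (k - 1L) * Cin + seq_len(Cin), drop = FALSE]
        Yk <- Wk %*% Ap[, plan$tgt[[k]], drop = FALSE]
        Y <- if (is.null(Y)) Yk else Y + Yk
    }
    list(Y = Y + b, Ap = Ap)
}

.convB <- function(dY, Wm, Ap, plan, Cin) {
    dW <- matrix(0, nrow(dY), Cin * 9L)
    dAp <- matrix(0, Cin, plan$pHW * plan$B)
    for (k in 1:9) {
        cols <- plan$tgt[[k]]
        ci <- (k - 1L) * Cin + seq_len(Cin)
        dW[, ci] <- tcrossprod(dY, Ap[, cols, drop = FALSE])
        dAp[, cols] <- dAp[, cols] +
            crossprod(Wm[, ci, drop = FALSE], dY)
    }
    list(dW = dW, db = rowSums(dY), dA = dAp[, plan$interior, drop = FALSE])
}

# Per-channel batch normalization over all positions and batch entries.
.bnF <- function(A, gamma, beta, rmean, rvar, train,
                 momentum = 0.1, eps = 1e-5) {
    if (train) {
        mu <- rowMeans(A)
        v <- pmax(rowMeans(A * A) - mu^2, 0)
        rmean <- (1 - momentum) * rmean + momentum * mu
        rvar <- (1 - momentum) * rvar + momentum * v
    } else {
        mu <- rmean
        v <- rvar
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- (A - mu) * inv
    list(Y = gamma * xhat + beta, xhat = xhat, inv = inv,
         rmean = rmean, rvar = rvar)
}

.bnB <- function(dY, gamma, xhat, inv) {
    dxhat <- dY * gamma
    list(dA = (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv,
         dgamma = rowSums(dY * xhat), dbeta = rowSums(dY))
}

# 2x max pool along the frequency axis only. With frequency-fastest column
# ordering and even H, adjacent column pairs are exactly frequency pairs.
.poolF <- function(A) {
    n <- ncol(A)
    A1 <- A[, seq(1L, n, 2L), drop = FALSE]
    A2 <- A[, seq(2L, n, 2L), drop = FALSE]
    m <- A1 >= A2
    Y <- A2
    Y[m] <- A1[m]
    list(Y = Y, m = m, n = n)
}

.poolB <- function(dY, m, n) {
    d1 <- dY; d1[!m] <- 0
    d2 <- dY; d2[m] <- 0
    dA <- matrix(0, nrow(dY), n)
    dA[, seq(1L, n, 2L)] <- d1
    dA[, seq(2L, n, 2L)] <- d2
    dA
}

# Mean over the residual Hr frequency rows, turning (C, Hr*W*B) into the
# (C, W*B) sequence fed to the LSTM.
.freqMeanF <- function(A, Hr) {
    C <- nrow(A)
    N <- ncol(A) %/% Hr
    dim(A) <- c(C, Hr, N)
    S <- matrix(A[, 1L, ], C, N)
    if (Hr > 1L) for (r in 2:Hr) S <- S + matrix(A[, r, ], C, N)
    S / Hr
}

.freqMeanB <- function(dS, Hr) {
    C <- nrow(dS)
    N <- ncol(dS)
    dA <- array(0, c(C, Hr, N))
    for (r in seq_len(Hr)) dA[, r, ] <- dS / Hr
    dim(dA) <- c(C, Hr * N)
    dA
}

.sigm <- function(x) 1 / (1 + exp(-x))

# Multi-layer LSTM over Wn time steps. S: (Cin, Wn*Bn), time-fastest within
# each batch entry. Gate row order within z: input, forget, cell, output.
.lstmF <- function(S, Wn, Bn, prm, L, hid, keep = FALSE) {
    h <- lapply(seq_len(L), function(l) matrix(0, hid, Bn))
    cs <- lapply(seq_len(L), function(l) matrix(0, hid, Bn))
    caches <- if (keep) lapply(seq_len(L), function(l) vector("list", Wn))
    hSum <- matrix(0, hid, Bn)
    for (t in seq_len(Wn)) {
        xt <- S[, t + Wn * (seq_len(Bn) - 1L), drop = FALSE]
        for (l in seq_len(L)) {
            z <- prm$Wx[[l]] %*% xt + prm$Wh[[l]] %*% h[[l]] + prm$b[[l]]
            i <- .sigm(z[seq_len(hid), , drop = FALSE])
            f <- .sigm(z[hid + seq_len(hid), , drop = FALSE])
            g <- tanh(z[2L * hid + seq_len(hid), , drop = FALSE])
            o <- .sigm(z[3L * hid + seq_len(hid), , drop = FALSE])
            cNew <- f * cs[[l]] + i * g
            tc <- tanh(cNew)
            if (keep)
                caches[[l]][[t]] <- list(x = xt, hPrev = h[[l]],
                                         cPrev = cs[[l]], i = i, f = f,
                                         g = g, o = o, tc = tc)
            h[[l]] <- o * tc
            cs[[l]] <- cNew
            xt <- h[[l]]
        }
        hSum <- hSum + h[[L]]
    }
    list(hLast = h[[L]], hMean = hSum / Wn,
         caches = if (keep) caches else NULL)
}

# Backward through time. dhTop: list over t of gradients into the top-layer
# hidden state (zeros except where the head reads).
.lstmB <- function(dhTop, prm, caches, L, hid, Wn, Bn) {
    dWx <- vector("list", L)
    dWh <- vector("list", L)
    db <- vector("list", L)
    dAbove <- dhTop
    for (l in seq(L, 1L)) {
        dWx[[l]] <- prm$Wx[[l]] * 0
        dWh[[l]] <- prm$Wh[[l]] * 0
        db[[l]] <- prm$b[[l]] * 0
        dhNext <- matrix(0, hid, Bn)
        dcNext <- matrix(0, hid, Bn)
        dBelow <- vector("list", Wn)
        for (t in seq(Wn, 1L)) {
            ca <- caches[[l]][[t]]
            dh <- dAbove[[t]] + dhNext
            dov <- dh * ca$tc
            dc <- dh * ca$o * (1 - ca$tc^2) + dcNext
            dcNext <- dc * ca$f
            dz <- rbind(
                (dc * ca$g) * ca$i * (1 - ca$i),
                (dc * ca$cPrev) * ca$f * (1 - ca$f),
                (dc * ca$i) * (1 - ca$g^2),
                dov * ca$o * (1 - ca$o))
            dWx[[l]] <- dWx[[l]] + tcrossprod(dz, ca$x)
            dWh[[l]] <- dWh[[l]] + tcrossprod(dz, ca$hPrev)
            db[[l]] <- db[[l]] + rowSums(dz)
            dhNext <- crossprod(prm$Wh[[l]], dz)
            dBelow[[t]] <- crossprod(prm$Wx[[l]], dz)
        }
        dAbove <- dBelow
    }
    list(dWx = dWx, dWh = dWh, db = db, dX = dAbove)
}

.adamInit <- function(params)
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, st, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
    st$t <- st$t + 1L
    c1 <- 1 - b1^st$t
    c2 <- 1 - b2^st$t
    for (nm in names(grads)) {
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
        st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
        params[[nm]] <- params[[nm]] -
            lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    }
    list(params = params, st = st)
}
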