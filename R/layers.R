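# Neural-network layers expressed as tape operations.
#
# A layer forward takes parameter nodes plus an activation node shaped
# (C, H, W, N) (or a (F, N) matrix for dense layers) and returns a new node.
# Parameters live in flat named lists of numeric arrays; `.pnodes()` wraps
# them as differentiable tape nodes for one optimizer step.

conv_out_size <- function(s, k, stride, pad) (s + 2 * pad - k) %/% stride + 1

# convolution via im2col: weight W is (Cout, Cin*k*k), bias (Cout, 1)
nn_conv <- function(x, W, b, k, stride, pad) {
  dm <- dim(x$value)
  Ho <- conv_out_size(dm[2], k, stride, pad)
  Wo <- conv_out_size(dm[3], k, stride, pad)
  cols <- d_im2col(x, dm[1], dm[2], dm[3], dm[4], k, stride, pad)
  out <- d_matmul(W, cols)
  out <- d_add(out, d_matmul(b, dconst(matrix(1, 1, ncol(out$value)))))
  d_reshape(out, c(nrow(W$value), Ho, Wo, dm[4]))
}

# transposed convolution (adjoint geometry of nn_conv): W is (Cin, Cout*k*k)
nn_deconv <- function(x, W, b, k, stride, pad, Cout) {
  dm <- dim(x$value)
  Ho <- (dm[2] - 1) * stride - 2 * pad + k
  Wo <- (dm[3] - 1) * stride - 2 * pad + k
  xmat <- d_reshape(x, c(dm[1], dm[2] * dm[3] * dm[4]))
  cols <- d_matmul(d_t(W), xmat)
  out <- d_col2im(cols, Cout, Ho, Wo, dm[4], k, stride, pad)
  outm <- d_reshape(out, c(Cout, Ho * Wo * dm[4]))
  outm <- d_add(outm, d_matmul(b, dconst(matrix(1, 1, ncol(outm$value)))))
  d_reshape(outm, c(Cout, Ho, Wo, dm[4]))
}

# cached 0/1 expander used to take per-(channel, image) moments by matmul
.in_expander <- function(HW, N) {
  key <- paste0("E", HW, "_", N)
  E <- dsenv[[key]]
  if (is.null(E)) {
    E <- kronecker(diag(N), matrix(1, HW, 1))
    dsenv[[key]] <- E
  }
  E
}

# instance normalization over spatial positions, per channel and image
nn_instancenorm <- function(x, gamma, beta, eps = 1e-5) {
  dm <- dim(x$value)
  HW <- dm[2] * dm[3]
  N <- dm[4]
  E <- dconst(.in_expander(HW, N))
  Et <- dconst(t(.in_expander(HW, N)))
  xm <- d_reshape(x, c(dm[1], HW * N))
  mu <- d_scale(d_matmul(xm, E), 1 / HW)
  xc <- d_sub(xm, d_matmul(mu, Et))
  vr <- d_scale(d_matmul(d_square(xc), E), 1 / HW)
  inv <- d_recip(d_sqrt(d_shift(vr, eps)))
  xn <- d_mul(xc, d_matmul(inv, Et))
  ones <- dconst(matrix(1, 1, HW * N))
  y <- d_add(d_mul(xn, d_matmul(gamma, ones)), d_matmul(beta, ones))
  d_reshape(y, dm)
}

# batch normalization for (F, N) matrices; running stats live in `state`
nn_batchnorm <- function(x, gamma, beta, state, name, train, eps = 1e-5,
                         momentum = 0.1) {
  v <- x$value
  N <- ncol(v)
  if (train) {
    mu <- rowMeans(v)
    vr <- rowMeans((v - mu)^2)
    rm_key <- paste0(name, ".mean"); rv_key <- paste0(name, ".var")
    old_m <- state[[rm_key]] %||% rep(0, nrow(v))
    old_v <- state[[rv_key]] %||% rep(1, nrow(v))
    state[[rm_key]] <- (1 - momentum) * old_m + momentum * mu
    state[[rv_key]] <- (1 - momentum) * old_v + momentum * vr
    ones <- dconst(matrix(1, 1, N))
    muM <- d_matmul(x, dconst(matrix(1 / N, N, 1)))
    xc <- d_sub(x, d_matmul(muM, ones))
    vrM <- d_matmul(d_square(xc), dconst(matrix(1 / N, N, 1)))
    inv <- d_recip(d_sqrt(d_shift(vrM, eps)))
    xn <- d_mul(xc, d_matmul(inv, ones))
    d_add(d_mul(xn, d_matmul(gamma, ones)), d_matmul(beta, ones))
  } else {
    mu <- state[[paste0(name, ".mean")]] %||% rep(0, nrow(v))
    vr <- state[[paste0(name, ".var")]] %||% rep(1, nrow(v))
    sc <- 1 / sqrt(vr + eps)
    xn <- d_maskmul(d_sub(x, dconst(matrix(mu, nrow(v), N))),
                    matrix(sc, nrow(v), N))
    ones <- dconst(matrix(1, 1, N))
    d_add(d_mul(xn, d_matmul(gamma, ones)), d_matmul(beta, ones))
  }
}

nn_dense <- function(x, W, b) {
  d_add(d_matmul(W, x), d_matmul(b, dconst(matrix(1, 1, ncol(x$value)))))
}

nn_dropout <- function(x, p, train) {
  if (!train || p <= 0) return(x)
  mask <- (runif(length(x$value)) > p) / (1 - p)
  dim(mask) <- dim(x$value)
  d_maskmul(x, mask)
}

nn_flatten <- function(x) {
  dm <- dim(x$value)
  d_reshape(x, c(prod(dm[1:3]), dm[4]))
}

# spatially tile a one-hot domain code (K, N) and append as input channels
nn_tile_code <- function(x_dm, code_onehot) {
  K <- nrow(code_onehot); N <- ncol(code_onehot)
  H <- x_dm[2]; W <- x_dm[3]
  tile <- aperm(array(code_onehot, c(K, N, H, W)), c(1, 3, 4, 2))
  dconst(tile)
}

# mean log-softmax cross-entropy of logits (K, N) at 0-based labels y
nn_cross_entropy <- function(Z, y) {
  v <- Z$value
  K <- nrow(v); N <- ncol(v)
  m <- apply(v, 2, max)
  M <- dconst(matrix(m, K, N, byrow = TRUE))
  E <- d_exp(d_sub(Z, M))
  s <- d_matmul(dconst(matrix(1, 1, K)), E)
  lse <- d_add(d_log(s), dconst(matrix(m, 1, N)))
  onehot <- matrix(0, K, N)
  onehot[cbind(y + 1L, seq_len(N))] <- 1
  zy <- d_matmul(dconst(matrix(1, 1, K)), d_maskmul(Z, onehot))
  d_mean(d_sub(lse, zy))
}

# parameter initialisers ------------------------------------------------------

init_conv <- function(Cout, Cin, k, sd = 0.02) {
  matrix(rnorm(Cout * Cin * k * k, 0, sd), Cout, Cin * k * k)
}

init_deconv <- function(Cin, Cout, k, sd = 0.02) {
  matrix(rnorm(Cin * Cout * k * k, 0, sd), Cin, Cout * k * k)
}

init_dense <- function(dout, din) {
  # Glorot-uniform keeps task-net logits well-scaled at init
  r <- sqrt(6 / (din + dout))
  matrix(runif(dout * din, -r, r), dout, din)
}

.pnodes <- function(params) lapply(params, dparam)
.cnodes <- function(params) lapply(params, dconst)
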