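# Minimal reverse-mode neural-network layers on base R matrices.
#
# Every forward function returns list(out, cache); every backward function
# takes (d_out, cache) and returns list(d_in, grads) with `grads` named like
# the parameters it consumes. Analytic gradients are verified against finite
# differences in the test suite.

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(d, cache) d * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense layer -----------------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), cache = x)
}
linear_bwd <- function(d, cache, W) {
  list(d_in = d %*% t(W), dW = crossprod(cache, d), db = colSums(d))
}

# ---- 1-D convolution over N x L x C arrays ---------------------------------
# weight layout: (kernel * in_channels) x out_channels, patch features ordered
# kernel-position-major (offset 1 channels..., offset 2 channels..., ...)

conv_out_len <- function(L, kernel, stride) {
  if (L < kernel) return(0L)
  (L - kernel) %/% stride + 1L
}

conv1d_fwd <- function(x, W, b, kernel, stride) {
  dims <- dim(x)                      # N x L x C
  N <- dims[1]; L <- dims[2]; C <- dims[3]
  Lo <- conv_out_len(L, kernel, stride)
  stopifnot(Lo >= 1L, nrow(W) == kernel * C)
  starts <- seq.int(1L, by = stride, length.out = Lo)
  P <- array(0, dim = c(N, Lo, kernel * C))
  for (kk in seq_len(kernel)) {
    cols <- ((kk - 1L) * C + 1L):(kk * C)
    P[, , cols] <- x[, starts + kk - 1L, , drop = FALSE]
  }
  Pm <- matrix(P, N * Lo, kernel * C)
  out <- sweep(Pm %*% W, 2L, b, "+")
  list(out = array(out, dim = c(N, Lo, ncol(W))),
       cache = list(Pm = Pm, dims = dims, Lo = Lo, starts = starts,
                    kernel = kernel, C = C))
}

conv1d_bwd <- function(d, cache, W) {
  N <- cache$dims[1]; L <- cache$dims[2]; C <- cache$C
  Lo <- cache$Lo; kernel <- cache$kernel
  dm <- matrix(d, N * Lo, dim(d)[3])
  dW <- crossprod(cache$Pm, dm)
  db <- colSums(dm)
  dP <- array(dm %*% t(W), dim = c(N, Lo, kernel * C))
  d_in <- array(0, dim = cache$dims)
  for (kk in seq_len(kernel)) {
    cols <- ((kk - 1L) * C + 1L):(kk * C)
    idx <- cache$starts + kk - 1L
    d_in[, idx, ] <- d_in[, idx, , drop = FALSE] + dP[, , cols, drop = FALSE]
  }
  list(d_in = d_in, dW = dW, db = db)
}

# ---- max pooling (kernel = stride = 2) over N x L x C ----------------------

maxpool2_fwd <- function(x) {
  dims <- dim(x)
  Lo <- dims[2] %/% 2L
  a <- x[, seq.int(1L, by = 2L, length.out = Lo), , drop = FALSE]
  b <- x[, seq.int(2L, by = 2L, length.out = Lo), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b),
       cache = list(take_a = take_a, dims = dims, Lo = Lo))
}

maxpool2_bwd <- function(d, cache) {
  d_in <- array(0, dim = cache$dims)
  Lo <- cache$Lo
  d_in[, seq.int(1L, by = 2L, length.out = Lo), ] <- d * cache$take_a
  d_in[, seq.int(2L, by = 2L, length.out = Lo), ] <- d * !cache$take_a
  d_in
}

# ---- GRU (single direction, one layer) -------------------------------------
# Gate layout in the 3H-wide weight matrices: [reset | update | candidate].
# Two bias vectors as in the usual deep-learning convention: the candidate's
# hidden-side bias sits inside the reset gate's multiplication.

gru_fwd <- function(xs, h0, Wx, Wh, bx, bh) {
  S <- length(xs)
  H <- ncol(Wh) / 3L
  h <- h0
  hs <- vector("list", S)
  caches <- vector("list", S)
  iR <- 1:H; iZ <- (H + 1L):(2L * H); iN <- (2L * H + 1L):(3L * H)
  for (t in seq_len(S)) {
    Gx <- sweep(xs[[t]] %*% Wx, 2L, bx, "+")
    Gh <- sweep(h %*% Wh, 2L, bh, "+")
    r <- sigmoid(Gx[, iR, drop = FALSE] + Gh[, iR, drop = FALSE])
    z <- sigmoid(Gx[, iZ, drop = FALSE] + Gh[, iZ, drop = FALSE])
    n <- tanh(Gx[, iN, drop = FALSE] + r * Gh[, iN, drop = FALSE])
    h_new <- (1 - z) * n + z * h
    caches[[t]] <- list(x = xs[[t]], h_prev = h, r = r, z = z, n = n,
                        Ghn = Gh[, iN, drop = FALSE])
    h <- h_new
    hs[[t]] <- h
  }
  list(hs = hs, h_last = h, caches = caches)
}

gru_bwd <- function(d_hs, d_hlast, caches, Wx, Wh) {
  S <- length(caches)
  H <- ncol(Wh) / 3L
  iR <- 1:H; iZ <- (H + 1L):(2L * H); iN <- (2L * H + 1L):(3L * H)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dbx <- numeric(3L * H); dbh <- numeric(3L * H)
  d_xs <- vector("list", S)
  dh <- d_hlast
  for (t in rev(seq_len(S))) {
    cc <- caches[[t]]
    if (!is.null(d_hs[[t]])) dh <- dh + d_hs[[t]]
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    da_n <- dn * (1 - cc$n^2)                 # pre-tanh
    dr <- da_n * cc$Ghn
    dGhn <- da_n * cc$r
    da_r <- dr * cc$r * (1 - cc$r)            # pre-sigmoid
    da_z <- dz * cc$z * (1 - cc$z)
    dGx <- cbind(da_r, da_z, da_n)
    dGh <- cbind(da_r, da_z, dGhn)
    dWx <- dWx + crossprod(cc$x, dGx)
    dWh <- dWh + crossprod(cc$h_prev, dGh)
    dbx <- dbx + colSums(dGx)
    dbh <- dbh + colSums(dGh)
    d_xs[[t]] <- dGx %*% t(Wx)
    dh_prev <- dh_prev + dGh %*% t(Wh)
    dh <- dh_prev
  }
  list(d_xs = d_xs, d_h0 = dh, dWx = dWx, dWh = dWh, dbx = dbx, dbh = dbh)
}

# ---- parameter utilities ---------------------------------------------------

init_matrix <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -a, a), nr, nc)
}

init_vector <- function(n, fan_in) {
  a <- 1 / sqrt(fan_in)
  runif(n, -a, a)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

# Adam optimiser step on a named list of parameters
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
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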