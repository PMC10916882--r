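#' Surrogate network configuration
#'
#' Architecture hyperparameters of the convolutional-recurrent inverse
#' surrogate. Each of the six trajectories is compressed by a shared sub-CNN
#' (convolution kernel 3 stride 3 with 10 channels, max-pool 2, convolution
#' kernel 3 stride 2 with 5 channels, max-pool 2), so a 512-step window
#' becomes a 21-step sequence of 5 x 6 = 30 features. The joint sequence runs
#' through a bidirectional two-layer GRU whose hidden state is initialised
#' from the six trajectory means (FC + ReLU); an attention branch (per-step
#' FC to width 16, flattened, FC to 16) is merged with the top layer's last
#' hidden state (FC to 16) and decoded by an FC stack into 14 strictly
#' positive outputs.
#'
#' @param window_len input window length in time steps
#' @param transient_cut leading transient dropped before windowing (ms)
#' @param noise_level additive Gaussian noise, as a fraction of each
#'   trajectory's own standard deviation (training only)
#' @param gru_layers,gru_hidden GRU depth and hidden size
#' @param bidirectional run the GRU in both directions
#' @param attention_width width of the attention projections
#' @param attention_seq sequence length the attention flattening assumes;
#'   `NULL` uses the actual compressed length (sequences are zero-padded when
#'   a larger value is configured)
#' @param positivity output activation guaranteeing positive predictions:
#'   `"exp"` (log-space regression head, default), `"softplus"`, or the
#'   literal `"softmax"` (which additionally normalises the outputs to sum 1)
#' @param share_subcnn share the sub-CNN weights across the six trajectory
#'   rows
#' @param seed weight-initialisation seed (training may override)
#' @return an object of class `surrogate_config`
#' @export
surrogate_config <- function(window_len = 512L,
                             transient_cut = 75,
                             noise_level = 0.10,
                             gru_layers = 2L,
                             gru_hidden = 256L,
                             bidirectional = TRUE,
                             attention_width = 16L,
                             attention_seq = NULL,
                             positivity = c("exp", "softplus", "softmax"),
                             share_subcnn = TRUE,
                             seed = 1L) {
  positivity <- match.arg(positivity)
  cfg <- list(window_len = as.integer(window_len),
              transient_cut = transient_cut,
              noise_level = noise_level,
              conv1 = list(kernel = 3L, stride = 3L, channels = 10L),
              conv2 = list(kernel = 3L, stride = 2L, channels = 5L),
              pool_kernel = 2L,
              gru_layers = as.integer(gru_layers),
              gru_hidden = as.integer(gru_hidden),
              bidirectional = isTRUE(bidirectional),
              attention_width = as.integer(attention_width),
              attention_seq = if (is.null(attention_seq)) NULL else as.integer(attention_seq),
              output_dim = 14L,
              positivity = positivity,
              share_subcnn = isTRUE(share_subcnn),
              seed = as.integer(seed))
  if (compressed_length(cfg$window_len, cfg) < 1L) {
    abort("window_len too short for the convolution/pooling stack")
  }
  structure(cfg, class = "surrogate_config")
}

#' Compressed sequence length of the convolutional front-end
#'
#' Applies the convolution/pooling length arithmetic
#' (`floor((L - kernel)/stride) + 1` for convolutions, `floor(L/2)` for the
#' pools) through conv1 -> pool -> conv2 -> pool. A 512-step window
#' compresses to 21 steps.
#'
#' @param n_in input length in time steps
#' @param cfg a [surrogate_config()]
#' @return integer output length (0 if `n_in` is too short)
#' @export
compressed_length <- function(n_in, cfg = surrogate_config()) {
  L <- conv_out_len(n_in, cfg$conv1$kernel, cfg$conv1$stride)
  L <- L %/% cfg$pool_kernel
  L <- conv_out_len(L, cfg$conv2$kernel, cfg$conv2$stride)
  L %/% cfg$pool_kernel
}

#' Preprocess a trajectory set into a network input window
#'
#' Drops the leading transient, picks a window of `window_len` steps
#' (uniformly random in training mode, the first eligible window in
#' evaluation mode), records the pre-noise trajectory means, adds the
#' relative Gaussian noise (training only) and zero-truncates so left rows
#' stay non-positive and right rows non-negative.
#'
#' @param traj a [trajectory_set()] or a 6 x n matrix in mm
#' @param cfg a [surrogate_config()]
#' @param training training mode (random window + noise)
#' @return list with `x` (6 x window_len matrix) and `means` (length 6)
#' @export
preprocess_trajectories <- function(traj, cfg = surrogate_config(),
                                    training = FALSE) {
  v <- if (inherits(traj, "trajectory_set")) traj$values else as.matrix(traj)
  dt <- if (inherits(traj, "trajectory_set")) traj$dt else 0.25
  stopifnot(nrow(v) == 6L)
  cut <- floor(cfg$transient_cut / dt)
  if (ncol(v) < cut + cfg$window_len) {
    abort(sprintf("trajectory too short: need >= %d steps, got %d",
                  cut + cfg$window_len, ncol(v)))
  }
  v <- v[, (cut + 1L):ncol(v), drop = FALSE]
  max_start <- ncol(v) - cfg$window_len + 1L
  start <- if (training) sample.int(max_start, 1L) else 1L
  w <- v[, start:(start + cfg$window_len - 1L), drop = FALSE]
  means <- rowMeans(w)
  if (training && cfg$noise_level > 0) {
    sds <- apply(w, 1L, stats::sd)
    w <- w + matrix(rnorm(length(w)), 6L) * (cfg$noise_level * sds)
  }
  w[1:3, ] <- pmin(w[1:3, , drop = FALSE], 0)
  w[4:6, ] <- pmax(w[4:6, , drop = FALSE], 0)
  list(x = w, means = means)
}

# ---- parameter initialisation ---------------------------------------------

n_dirs <- function(cfg) if (cfg$bidirectional) 2L else 1L

att_seq_len <- function(cfg) {
  S <- compressed_length(cfg$window_len, cfg)
  if (is.null(cfg$attention_seq)) S else max(S, cfg$attention_seq)
}

init_crnn_params <- function(cfg) {
  H <- cfg$gru_hidden
  D <- n_dirs(cfg)
  S <- compressed_length(cfg$window_len, cfg)
  Satt <- att_seq_len(cfg)
  A <- cfg$attention_width
  nf <- 5L * 6L                     # features per compressed step
  DH <- D * H
  p <- list()
  n_cnn <- if (cfg$share_subcnn) 1L else 6L
  for (i in seq_len(n_cnn)) {
    sfx <- if (cfg$share_subcnn) "" else paste0("_r", i)
    p[[paste0("conv1_W", sfx)]] <- init_matrix(3L, 10L, 3)
    p[[paste0("conv1_b", sfx)]] <- init_vector(10L, 3)
    p[[paste0("conv2_W", sfx)]] <- init_matrix(30L, 5L, 30)
    p[[paste0("conv2_b", sfx)]] <- init_vector(5L, 30)
  }
  p$h0_W <- init_matrix(6L, cfg$gru_layers * D * H, 6)
  p$h0_b <- init_vector(cfg$gru_layers * D * H, 6)
  for (l in seq_len(cfg$gru_layers)) {
    d_in <- if (l == 1L) nf else DH
    for (d in seq_len(D)) {
      key <- sprintf("gru_l%d_d%d", l, d)
      p[[paste0(key, "_Wx")]] <- init_matrix(d_in, 3L * H, H)
      p[[paste0(key, "_Wh")]] <- init_matrix(H, 3L * H, H)
      p[[paste0(key, "_bx")]] <- init_vector(3L * H, H)
      p[[paste0(key, "_bh")]] <- init_vector(3L * H, H)
    }
  }
  p$att_step_W <- init_matrix(DH, A, DH)
  p$att_step_b <- init_vector(A, DH)
  p$att_flat_W <- init_matrix(Satt * A, A, Satt * A)
  p$att_flat_b <- init_vector(A, Satt * A)
  p$last_W <- init_matrix(DH, A, DH)
  p$last_b <- init_vector(A, DH)
  p$head1_W <- init_matrix(2L * A, 2L * A, 2L * A)
  p$head1_b <- init_vector(2L * A, 2L * A)
  p$head2_W <- init_matrix(2L * A, cfg$output_dim, 2L * A)
  p$head2_b <- init_vector(cfg$output_dim, 2L * A)
  p
}

# ---- forward / backward ----------------------------------------------------

# X: B x 6 x W array (preprocessed windows), M: B x 6 means
crnn_forward_cache <- function(params, X, M, cfg) {
  B <- dim(X)[1]
  H <- cfg$gru_hidden; D <- n_dirs(cfg); DH <- D * H
  S <- compressed_length(cfg$window_len, cfg)
  Satt <- att_seq_len(cfg); A <- cfg$attention_width
  stopifnot(dim(X)[3] == cfg$window_len, cfg$share_subcnn)

  # sub-CNN, shared weights: rows as independent 1-channel samples
  N <- B * 6L
  Xp <- aperm(X, c(2L, 1L, 3L))                 # 6 x B x W
  x1 <- array(matrix(Xp, N, cfg$window_len), c(N, cfg$window_len, 1L))
  c1 <- conv1d_fwd(x1, params$conv1_W, params$conv1_b, 3L, 3L)
  r1 <- relu_fwd(c1$out)
  p1 <- maxpool2_fwd(r1$out)
  c2 <- conv1d_fwd(p1$out, params$conv2_W, params$conv2_b, 3L, 2L)
  r2 <- relu_fwd(c2$out)
  p2 <- maxpool2_fwd(r2$out)                    # N x S x 5

  # regroup to per-step feature matrices B x 30 (channel fastest, then row)
  A4 <- array(p2$out, c(6L, B, S, 5L))
  F3 <- array(aperm(A4, c(2L, 4L, 1L, 3L)), c(B, 30L, S))
  xs <- lapply(seq_len(S), function(t) F3[, , t, drop = TRUE])
  if (B == 1L) xs <- lapply(xs, function(v) matrix(v, 1L))

  # hidden-state initialisation from trajectory means
  h0lin <- linear_fwd(M, params$h0_W, params$h0_b)
  h0act <- relu_fwd(h0lin$out)
  h0_slice <- function(l, d) {
    off <- ((l - 1L) * D + (d - 1L)) * H
    h0act$out[, (off + 1L):(off + H), drop = FALSE]
  }

  # GRU stack
  layer_in <- xs
  gru_caches <- list()
  for (l in seq_len(cfg$gru_layers)) {
    outs <- vector("list", D)
    for (d in seq_len(D)) {
      key <- sprintf("gru_l%d_d%d", l, d)
      seq_in <- if (d == 1L) layer_in else rev(layer_in)
      outs[[d]] <- gru_fwd(seq_in, h0_slice(l, d),
                           params[[paste0(key, "_Wx")]],
                           params[[paste0(key, "_Wh")]],
                           params[[paste0(key, "_bx")]],
                           params[[paste0(key, "_bh")]])
    }
    gru_caches[[l]] <- outs
    layer_in <- lapply(seq_len(S), function(t) {
      if (D == 2L) cbind(outs[[1L]]$hs[[t]], outs[[2L]]$hs[[S + 1L - t]])
      else outs[[1L]]$hs[[t]]
    })
  }
  Y <- layer_in                                  # S of B x DH
  top <- gru_caches[[cfg$gru_layers]]
  h_last <- if (D == 2L) cbind(top[[1L]]$h_last, top[[2L]]$h_last) else top[[1L]]$h_last

  # attention branch
  Ymat <- do.call(rbind, Y)                      # (S*B) x DH, step-major blocks
  att <- linear_fwd(Ymat, params$att_step_W, params$att_step_b)
  # flatten per sample: column index (t-1)*A + k (zero-padded past S)
  Aflat <- matrix(0, B, Satt * A)
  for (t in seq_len(S)) {
    Aflat[, ((t - 1L) * A + 1L):(t * A)] <- att$out[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
  }
  af <- linear_fwd(Aflat, params$att_flat_W, params$att_flat_b)
  lb <- linear_fwd(h_last, params$last_W, params$last_b)
  merged <- cbind(af$out, lb$out)
  hd1 <- linear_fwd(merged, params$head1_W, params$head1_b)
  hr <- relu_fwd(hd1$out)
  hd2 <- linear_fwd(hr$out, params$head2_W, params$head2_b)
  o <- hd2$out                                   # B x 14 pre-activation

  list(out = o,
       cache = list(B = B, S = S, A = A, H = H, D = D, DH = DH, Satt = Satt,
                    c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    h0lin = h0lin, h0act = h0act, gru = gru_caches,
                    att = att, af = af, lb = lb, hd1 = hd1, hr = hr,
                    hd2 = hd2, Ymat_rows = S * B))
}

crnn_backward <- function(params, d_o, cache, cfg) {
  B <- cache$B; S <- cache$S; A <- cache$A; H <- cache$H
  D <- cache$D; DH <- cache$DH; Satt <- cache$Satt
  g <- list()

  bk2 <- linear_bwd(d_o, cache$hd2$cache, params$head2_W)
  g$head2_W <- bk2$dW; g$head2_b <- bk2$db
  d_hr <- relu_bwd(bk2$d_in, cache$hr$cache)
  bk1 <- linear_bwd(d_hr, cache$hd1$cache, params$head1_W)
  g$head1_W <- bk1$dW; g$head1_b <- bk1$db
  d_af <- bk1$d_in[, 1:A, drop = FALSE]
  d_lb <- bk1$d_in[, (A + 1L):(2L * A), drop = FALSE]

  blb <- linear_bwd(d_lb, cache$lb$cache, params$last_W)
  g$last_W <- blb$dW; g$last_b <- blb$db
  d_hlast <- blb$d_in                              # B x DH

  baf <- linear_bwd(d_af, cache$af$cache, params$att_flat_W)
  g$att_flat_W <- baf$dW; g$att_flat_b <- baf$db
  d_att_out <- matrix(0, S * B, A)
  for (t in seq_len(S)) {
    d_att_out[((t - 1L) * B + 1L):(t * B), ] <-
      baf$d_in[, ((t - 1L) * A + 1L):(t * A), drop = FALSE]
  }
  batt <- linear_bwd(d_att_out, cache$att$cache, params$att_step_W)
  g$att_step_W <- batt$dW; g$att_step_b <- batt$db
  d_Y <- lapply(seq_len(S), function(t) {
    batt$d_in[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
  })

  # distribute last-hidden gradient onto the top layer's final states
  d_h0_full <- matrix(0, B, cfg$gru_layers * D * H)
  d_layer_out <- d_Y
  d_hlast_dir <- vector("list", D)
  for (d in seq_len(D)) {
    d_hlast_dir[[d]] <- d_hlast[, ((d - 1L) * H + 1L):(d * H), drop = FALSE]
  }

  for (l in rev(seq_len(cfg$gru_layers))) {
    outs <- cache$gru[[l]]
    d_in_accum <- NULL
    for (d in seq_len(D)) {
      key <- sprintf("gru_l%d_d%d", l, d)
      # gradient on this direction's per-step outputs, in its own time order
      d_hs <- vector("list", S)
      for (t in seq_len(S)) {
        dy <- d_layer_out[[t]]
        cols <- ((d - 1L) * H + 1L):(d * H)
        slice <- dy[, cols, drop = FALSE]
        tt <- if (d == 1L) t else S + 1L - t
        d_hs[[tt]] <- slice
      }
      d_last <- if (l == cfg$gru_layers) d_hlast_dir[[d]] else matrix(0, B, H)
      bk <- gru_bwd(d_hs, d_last, outs[[d]]$caches,
                    params[[paste0(key, "_Wx")]],
                    params[[paste0(key, "_Wh")]])
      g[[paste0(key, "_Wx")]] <- bk$dWx
      g[[paste0(key, "_Wh")]] <- bk$dWh
      g[[paste0(key, "_bx")]] <- bk$dbx
      g[[paste0(key, "_bh")]] <- bk$dbh
      off <- ((l - 1L) * D + (d - 1L)) * H
      d_h0_full[, (off + 1L):(off + H)] <- bk$d_h0
      # input gradients back to the layer below, in original time order
      d_xs <- if (d == 1L) bk$d_xs else rev(bk$d_xs)
      if (is.null(d_in_accum)) {
        d_in_accum <- d_xs
      } else {
        d_in_accum <- lapply(seq_len(S), function(t) d_in_accum[[t]] + d_xs[[t]])
      }
    }
    d_layer_out <- d_in_accum
  }

  # hidden-state initialisation FC
  d_h0act <- relu_bwd(d_h0_full, cache$h0act$cache)
  bh0 <- linear_bwd(d_h0act, cache$h0lin$cache, params$h0_W)
  g$h0_W <- bh0$dW; g$h0_b <- bh0$db

  # back through the regrouping into the sub-CNN
  d_F3 <- array(0, c(B, 30L, S))
  for (t in seq_len(S)) d_F3[, , t] <- d_layer_out[[t]]
  d_A4 <- aperm(array(d_F3, c(B, 5L, 6L, S)), c(3L, 1L, 4L, 2L))
  d_p2 <- array(d_A4, c(6L * B, S, 5L))

  d_r2 <- maxpool2_bwd(d_p2, cache$p2$cache)
  d_c2 <- relu_bwd(d_r2, cache$r2$cache)
  bc2 <- conv1d_bwd(d_c2, cache$c2$cache, params$conv2_W)
  g$conv2_W <- bc2$dW; g$conv2_b <- bc2$db
  d_p1 <- maxpool2_bwd(bc2$d_in, cache$p1$cache)
  d_c1 <- relu_bwd(d_p1, cache$r1$cache)
  bc1 <- conv1d_bwd(d_c1, cache$c1$cache, params$conv1_W)
  g$conv1_W <- bc1$dW; g$conv1_b <- bc1$db
  g
}

# positivity head: log-prediction and its gradient wrt the pre-activation
log_prediction <- function(o, positivity) {
  switch(positivity,
    exp = list(logq = o, dlogq_do = array(1, dim(o))),
    softplus = {
      sp <- log1p(exp(pmin(o, 30))) + pmax(o - 30, 0)
      list(logq = log(sp), dlogq_do = sigmoid(o) / sp)
    },
    softmax = {
      m <- apply(o, 1L, max)
      lse <- m + log(rowSums(exp(o - m)))
      list(logq = o - lse, softmax = exp(o - lse))
    })
}

#' Root mean square logarithmic error
#'
#' `sqrt(mean((log q - log qhat)^2))` over the components of two positive
#' vectors (natural logarithm). Scale-invariant: rescaling both arguments by
#' a common positive factor leaves the value unchanged.
#'
#' @param q_true,q_pred positive numeric vectors of equal length
#' @return scalar loss
#' @export
rmsle <- function(q_true, q_pred) {
  if (any(q_true <= 0) || any(q_pred <= 0)) {
    abort("rmsle is defined for strictly positive components only")
  }
  stopifnot(length(q_true) == length(q_pred))
  sqrt(mean((log(q_true) - log(q_pred))^2))
}

# batch loss: mean over samples of per-sample RMSLE, plus gradient wrt logq
rmsle_batch <- function(logq_pred, logq_true) {
  e <- logq_pred - logq_true
  per <- sqrt(rowMeans(e^2))
  B <- nrow(e); k <- ncol(e)
  denom <- pmax(per, 1e-12)
  d_logq <- e / (k * denom) / B
  list(loss = mean(per), d_logq = d_logq)
}

#' Training configuration
#'
#' @param lr_init initial learning rate
#' @param lr_decay_base exponential learning-rate decay per epoch
#' @param batch_size minibatch size
#' @param early_stop_patience epochs without validation improvement before
#'   stopping
#' @param val_fraction fraction split off for validation
#' @param max_epochs epoch cap
#' @param seed seed controlling the split, window rolls, noise and weight
#'   initialisation
#' @return an object of class `train_config`
#' @export
train_config <- function(lr_init = 5e-3, lr_decay_base = 0.9,
                         batch_size = 512L, early_stop_patience = 5L,
                         val_fraction = 0.10, max_epochs = 100L, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, early_stop_patience >= 1L)
  structure(list(lr_init = lr_init, lr_decay_base = lr_decay_base,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# assemble a batch of preprocessed inputs from dataset records
make_batch <- function(records, idx, scfg, training) {
  B <- length(idx)
  X <- array(0, c(B, 6L, scfg$window_len))
  M <- matrix(0, B, 6L)
  for (i in seq_len(B)) {
    pp <- preprocess_trajectories(records[[idx[i]]]$traj, scfg, training)
    X[i, , ] <- pp$x
    M[i, ] <- pp$means
  }
  list(X = X, M = M)
}

#' Train the inverse surrogate
#'
#' Splits the dataset 90/10 (seeded), trains the convolutional-recurrent
#' network with Adam under the RMSLE loss, an exponential learning-rate
#' schedule and early stopping on validation loss; training windows and
#' noise are re-rolled every epoch. The best-validation weights are kept.
#'
#' @param data a `labeled_dataset` (see [build_dataset()])
#' @param scfg a [surrogate_config()]
#' @param tcfg a [train_config()]
#' @param verbose print one line per epoch
#' @return an object of class `sixmass_surrogate`: the trained weights plus
#'   `curves` (per-epoch training/validation RMSLE), `best_val_loss`,
#'   `epochs_trained`, and `mae` (per-parameter validation MAE)
#' @export
train_surrogate <- function(data, scfg = surrogate_config(),
                            tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  N <- length(data$records)
  if (N < 10L) abort("dataset too small to split")
  set.seed(tcfg$seed)
  n_val <- max(1L, round(tcfg$val_fraction * N))
  val_idx <- sample.int(N, n_val)
  train_idx <- setdiff(seq_len(N), val_idx)
  logQ <- t(vapply(data$records, function(r) log(as.numeric(r$q)), numeric(14)))

  params <- init_crnn_params(scfg)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  curves <- list()
  patience_left <- tcfg$early_stop_patience

  eval_loss <- function(p) {
    tot <- 0; nb <- 0
    for (chunk in split(val_idx, ceiling(seq_along(val_idx) / tcfg$batch_size))) {
      b <- make_batch(data$records, chunk, scfg, training = FALSE)
      fw <- crnn_forward_cache(p, b$X, b$M, scfg)
      lp <- log_prediction(fw$out, scfg$positivity)
      tot <- tot + rmsle_batch(lp$logq, logQ[chunk, , drop = FALSE])$loss * length(chunk)
      nb <- nb + length(chunk)
    }
    tot / nb
  }

  for (epoch in seq_len(tcfg$max_epochs)) {
    lr <- tcfg$lr_init * tcfg$lr_decay_base^(epoch - 1L)
    sh <- sample(train_idx)
    batches <- split(sh, ceiling(seq_along(sh) / tcfg$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      b <- make_batch(data$records, bi, scfg, training = TRUE)
      fw <- crnn_forward_cache(params, b$X, b$M, scfg)
      lp <- log_prediction(fw$out, scfg$positivity)
      ls <- rmsle_batch(lp$logq, logQ[bi, , drop = FALSE])
      if (!is.finite(ls$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      d_o <- if (scfg$positivity == "softmax") {
        rs <- rowSums(ls$d_logq)
        ls$d_logq - lp$softmax * rs
      } else {
        ls$d_logq * lp$dlogq_do
      }
      grads <- crnn_backward(params, d_o, fw$cache, scfg)
      st <- adam_step(params, grads, opt, lr)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + ls$loss * length(bi); ep_n <- ep_n + length(bi)
    }
    vl <- eval_loss(params)
    curves[[epoch]] <- c(epoch = epoch, train_rmsle = ep_loss / ep_n,
                         val_rmsle = vl, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, ep_loss / ep_n, vl, lr))
    }
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
      patience_left <- tcfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }

  params <- best$params
  # per-parameter validation MAE (unitless)
  preds <- matrix(0, length(val_idx), 14L)
  row0 <- 0L
  for (chunk in split(val_idx, ceiling(seq_along(val_idx) / tcfg$batch_size))) {
    b <- make_batch(data$records, chunk, scfg, training = FALSE)
    fw <- crnn_forward_cache(params, b$X, b$M, scfg)
    lp <- log_prediction(fw$out, scfg$positivity)
    preds[row0 + seq_along(chunk), ] <- exp(lp$logq)
    row0 <- row0 + length(chunk)
  }
  qa <- exp(logQ[val_idx, , drop = FALSE])
  mae <- colMeans(abs(preds - qa))
  mae_tbl <- tibble(parameter = scaling_names(), mae = unname(mae))

  structure(list(
    params = params, scfg = scfg, tcfg = tcfg,
    curves = dplyr::bind_rows(lapply(curves, function(r) as_tibble(as.list(r)))),
    best_val_loss = best$loss,
    epochs_trained = length(curves),
    best_epoch = best$epoch,
    n_train = length(train_idx), n_val = length(val_idx),
    val_idx = val_idx,
    mae = mae_tbl,
    seed = tcfg$seed
  ), class = "sixmass_surrogate")
}

#' @export
print.sixmass_surrogate <- function(x, ...) {
  cat(sprintf("<sixmass_surrogate> CRNN inverse surrogate (hidden %d, %s)\n",
              x$scfg$gru_hidden,
              if (x$scfg$bidirectional) "bidirectional" else "unidirectional"))
  cat(sprintf("  trained %d epochs (best at %d), val RMSLE %.4f, %d/%d train/val samples\n",
              x$epochs_trained, x$best_epoch, x$best_val_loss,
              x$n_train, x$n_val))
  invisible(x)
}

#' Per-parameter validation MAE of a trained surrogate
#'
#' @param x a `sixmass_surrogate`
#' @param ... unused
#' @return tibble with columns `parameter`, `mae`
#' @export
tidy.sixmass_surrogate <- function(x, ...) x$mae

#' One-row training summary
#'
#' @param x a `sixmass_surrogate`
#' @param ... unused
#' @return one-row tibble
#' @export
glance.sixmass_surrogate <- function(x, ...) {
  tibble(best_val_loss = x$best_val_loss, epochs_trained = x$epochs_trained,
         best_epoch = x$best_epoch, n_train = x$n_train, n_val = x$n_val,
         gru_hidden = x$scfg$gru_hidden, seed = x$seed)
}

#' Plot training curves
#'
#' @param object a `sixmass_surrogate`
#' @param ... unused
#' @return ggplot of training/validation RMSLE per epoch
#' @export
autoplot.sixmass_surrogate <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curves, c("train_rmsle", "val_rmsle"),
                            names_to = "set", values_to = "rmsle")
  df$set <- sub("_rmsle", "", df$set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$rmsle,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "RMSLE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predict scaling vectors from trajectories
#'
#' @param object a trained `sixmass_surrogate`
#' @param newdata a `labeled_dataset`, a list of [trajectory_set()]s, a
#'   single [trajectory_set()], or a 6 x n matrix (mm)
#' @param ... unused
#' @return tibble with one row per sample and the 14 predicted scaling
#'   components as columns
#' @export
predict.sixmass_surrogate <- function(object, newdata, ...) {
  trajs <- if (inherits(newdata, "labeled_dataset")) {
    lapply(newdata$records, `[[`, "traj")
  } else if (inherits(newdata, "trajectory_set")) {
    list(newdata)
  } else if (is.matrix(newdata)) {
    list(trajectory_set(newdata))
  } else if (is.list(newdata)) {
    newdata
  } else {
    abort("unsupported newdata type")
  }
  scfg <- object$scfg
  n <- length(trajs)
  out <- matrix(0, n, 14L)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 256L))
  for (ch in chunks) {
    X <- array(0, c(length(ch), 6L, scfg$window_len))
    M <- matrix(0, length(ch), 6L)
    for (i in seq_along(ch)) {
      pp <- preprocess_trajectories(trajs[[ch[i]]], scfg, training = FALSE)
      X[i, , ] <- pp$x
      M[i, ] <- pp$means
    }
    fw <- crnn_forward_cache(object$params, X, M, scfg)
    lp <- log_prediction(fw$out, scfg$positivity)
    out[ch, ] <- exp(lp$logq)
  }
  colnames(out) <- scaling_names()
  as_tibble(as.data.frame(out))
}

#' Convert predicted scalings to metric units
#'
#' Maps unitless scaling factors to the physical quantities they scale:
#' masses in g (reciprocal factors), anchor stiffnesses in N/m, subglottal
#' pressure in Pa, collision proportionality unitless.
#'
#' @param q a 14-long scaling vector, or a tibble/matrix with the 14 scaling
#'   columns (one row per sample)
#' @param cfg a [phys_config()] supplying the defaults
#' @return tibble in long format: `sample`, `parameter`, `scaling`, `value`,
#'   `unit`
#' @export
scaling_to_metric <- function(q, cfg = phys_config()) {
  qm <- if (is.numeric(q) && is.null(dim(q))) matrix(q, 1L, dimnames = list(NULL, names(q))) else as.matrix(q)
  stopifnot(ncol(qm) == 14L)
  if (is.null(colnames(qm))) colnames(qm) <- scaling_names()
  rows <- list()
  for (i in seq_len(nrow(qm))) {
    for (nm in scaling_names()) {
      val <- unname(qm[i, nm])
      if (startsWith(nm, "inv_mass")) {
        rows[[length(rows) + 1L]] <- tibble(
          sample = i, parameter = paste0(sub("inv_mass", "mass", nm), c("_bottom", "_top")),
          scaling = val, value = c(cfg$mass_bottom, cfg$mass_top) / val, unit = "g")
      } else if (startsWith(nm, "k_a")) {
        rows[[length(rows) + 1L]] <- tibble(
          sample = i, parameter = paste0(nm, c("_bottom", "_top")),
          scaling = val, value = c(cfg$k_a_bottom, cfg$k_a_top) * val, unit = "N/m")
      } else if (nm == "p_s") {
        rows[[length(rows) + 1L]] <- tibble(sample = i, parameter = "P_S",
                                            scaling = val, value = cfg$p_s * val, unit = "Pa")
      } else {
        rows[[length(rows) + 1L]] <- tibble(sample = i, parameter = "xi_c",
                                            scaling = val, value = cfg$xi_c * val, unit = "")
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Exclude subperformant training runs
#'
#' Keeps every run whose best validation loss is within 10% of the best run.
#'
#' @param runs list of `sixmass_surrogate` objects
#' @param factor exclusion factor (default 1.10)
#' @return the kept subset (same order)
#' @export
exclude_subperformant <- function(runs, factor = 1.10) {
  stopifnot(length(runs) >= 1L)
  losses <- vapply(runs, function(r) r$best_val_loss, numeric(1))
  runs[losses <= factor * min(losses)]
}

#' Save / load a trained surrogate
#'
#' One file holding the weights, the architecture and training configuration
#' and a configuration fingerprint; the loader validates the fingerprint.
#'
#' @param model a `sixmass_surrogate`
#' @param path file path
#' @return `load_surrogate()` returns the `sixmass_surrogate`
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "sixmass_surrogate"))
  model$config_hash <- config_fingerprint(model$scfg)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sixmass_surrogate")) abort("not a surrogate artifact")
  if (!identical(model$config_hash, config_fingerprint(model$scfg))) {
    abort("surrogate artifact fingerprint mismatch")
  }
  model
}

config_fingerprint <- function(scfg) {
  paste(vapply(scfg[order(names(scfg))], function(x) paste(format(x), collapse = ","),
               character(1)), collapse = "|")
}
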