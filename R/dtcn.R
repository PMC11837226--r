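# Dilated temporal convolutional network (dTCN) for 3-class flaring
# classification from kinematic feature sequences. Sequence-to-sequence:
# two dilation blocks (each: two 1-D convolutions, filter 9, 32 channels,
# leaky-ReLU + dropout p = 0.1, residual skip), then a dense softmax head
# per time step. Trained with Adam on weighted cross-entropy (class i
# weighted N/N_i against imbalance), early-stopped on validation loss.
#
# Implemented directly on BLAS matrix products: a dilated 1-D convolution
# is a sum over taps of (C_out x C_in) %*% (C_in x T) products on
# column-shifted copies of the input, which keeps both the forward and the
# backward pass at matrix-multiplication speed without compiled code.

#' Classifier hyperparameters
#'
#' Defaults are the reference training protocol: 2 dilation blocks of 32
#' channels with 9-timestep filters and dropout 0.1, sequences of 1000
#' timesteps in batches of 8, a 90/10 train/validation split, patience of
#' 20 epochs, Adam with learning rate 1e-4. Dilation doubles per block
#' (1, 2), the canonical TCN schedule.
#'
#' @param n_blocks number of dilation blocks.
#' @param channels channels per convolution layer.
#' @param filter_size filter length in timesteps (odd).
#' @param dropout_p dropout probability.
#' @param dilations per-block dilation factors (length `n_blocks`).
#' @param seq_len training sequence length (timesteps).
#' @param batch_size sequences per batch.
#' @param train_fraction fraction of sequences used for training.
#' @param patience epochs without validation improvement before stopping.
#' @param learning_rate Adam learning rate.
#' @param n_classes number of output classes.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param seed RNG seed for init, split, shuffling and dropout.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(n_blocks = 2, channels = 32, filter_size = 9,
                            dropout_p = 0.1, dilations = 2^(seq_len(n_blocks) - 1),
                            seq_len = 1000, batch_size = 8,
                            train_fraction = 0.9, patience = 20,
                            learning_rate = 1e-4, n_classes = 3,
                            leaky_slope = 0.01, seed = 1) {
  for (nm in c("n_blocks", "channels", "filter_size", "seq_len",
               "batch_size", "patience", "n_classes"))
    assert_scalar_num(get(nm), nm, lower = 1)
  if (filter_size %% 2 == 0) stopf("`filter_size` must be odd")
  assert_scalar_num(dropout_p, "dropout_p", 0, 1, strict_upper = TRUE)
  assert_scalar_num(train_fraction, "train_fraction", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_num(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  if (length(dilations) != n_blocks) stopf("need one dilation per block")
  structure(list(n_blocks = as.integer(n_blocks), channels = as.integer(channels),
                 filter_size = as.integer(filter_size), dropout_p = dropout_p,
                 dilations = as.integer(dilations), seq_len = as.integer(seq_len),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, patience = as.integer(patience),
                 learning_rate = learning_rate, n_classes = as.integer(n_classes),
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Class weights against label imbalance
#'
#' With N total labeled frames and N_i frames of class i, class i's loss
#' weight is `N / N_i`. Classes with zero count get weight 0 (excluded
#' from the loss).
#'
#' @param label_counts per-class frame counts.
#' @return numeric weights, same length as `label_counts`.
#' @export
class_weights <- function(label_counts) {
  if (any(label_counts < 0)) stopf("counts must be non-negative")
  N <- sum(label_counts)
  if (N == 0) stopf("all class counts are zero")
  w <- ifelse(label_counts > 0, N / label_counts, 0)
  unname(w)
}

# ---- low-level ops ---------------------------------------------------

shift_cols <- function(X, s) {
  T_ <- ncol(X)
  if (s == 0L) return(X)
  if (abs(s) >= T_) return(matrix(0, nrow(X), T_))
  if (s > 0) cbind(X[, (s + 1L):T_, drop = FALSE], matrix(0, nrow(X), s))
  else cbind(matrix(0, nrow(X), -s), X[, 1:(T_ + s), drop = FALSE])
}

conv1d_fwd <- function(X, W, b, dil) {
  k <- dim(W)[3]; co <- dim(W)[1]; ci <- dim(W)[2]
  ctr <- (k + 1L) %/% 2L
  Y <- matrix(b, co, ncol(X))
  for (j in seq_len(k)) {
    Wj <- matrix(W[, , j], co, ci)
    Y <- Y + Wj %*% shift_cols(X, dil * (j - ctr))
  }
  Y
}

conv1d_bwd <- function(dY, X, W, dil) {
  k <- dim(W)[3]; co <- dim(W)[1]; ci <- dim(W)[2]
  ctr <- (k + 1L) %/% 2L
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(k)) {
    s <- dil * (j - ctr)
    dW[, , j] <- dY %*% t(shift_cols(X, s))
    dX <- dX + t(matrix(W[, , j], co, ci)) %*% shift_cols(dY, -s)
  }
  list(dW = dW, db = rowSums(dY), dX = dX)
}

leaky <- function(x, slope) x * ((x > 0) + slope * (x <= 0))
dleaky <- function(x, slope) (x > 0) + slope * (x <= 0)

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

he_init <- function(co, ci, k) {
  array(stats::rnorm(co * ci * k, 0, sqrt(2 / (ci * k))), c(co, ci, k))
}

#' Build an untrained dTCN
#'
#' @param spec a [classifier_spec()].
#' @param n_features number of input feature channels.
#' @return a `dtcn` model object (list of parameter arrays plus the spec).
#' @export
build_dtcn <- function(spec, n_features) {
  stopifnot(inherits(spec, "classifier_spec"))
  assert_scalar_num(n_features, "n_features", lower = 1)
  set.seed(spec$seed)
  ch <- spec$channels; k <- spec$filter_size
  params <- list()
  cin <- n_features
  for (bkt in seq_len(spec$n_blocks)) {
    pre <- sprintf("blk%d_", bkt)
    params[[paste0(pre, "c1_W")]] <- he_init(ch, cin, k)
    params[[paste0(pre, "c1_b")]] <- numeric(ch)
    params[[paste0(pre, "c2_W")]] <- he_init(ch, ch, k)
    params[[paste0(pre, "c2_b")]] <- numeric(ch)
    if (cin != ch) {
      # 1x1 projection so the residual path matches channel counts
      params[[paste0(pre, "p_W")]] <- matrix(stats::rnorm(ch * cin, 0, sqrt(2 / cin)), ch, cin)
      params[[paste0(pre, "p_b")]] <- numeric(ch)
    }
    cin <- ch
  }
  params$dense_W <- matrix(stats::rnorm(spec$n_classes * ch, 0, sqrt(2 / ch)),
                           spec$n_classes, ch)
  params$dense_b <- numeric(spec$n_classes)
  structure(list(spec = spec, n_features = as.integer(n_features),
                 params = params),
            class = "dtcn")
}

#' @export
print.dtcn <- function(x, ...) {
  cat(sprintf("<dtcn> %d features -> %d blocks x %d ch (filter %d, dilations %s) -> %d classes; %d parameters\n",
              x$n_features, x$spec$n_blocks, x$spec$channels,
              x$spec$filter_size, paste(x$spec$dilations, collapse = ","),
              x$spec$n_classes, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a dTCN
#' @param model a `dtcn`.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 1L))

# forward pass; train = TRUE applies (and caches) dropout masks
dtcn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  sp <- model$spec
  p <- model$params
  slope <- sp$leaky_slope
  drop_p <- if (train) sp$dropout_p else 0
  cache <- list(inputs = list(), Z1 = list(), Z2 = list(), S = list(),
                M1 = list(), M2 = list(), D1 = list())
  H <- X
  for (bkt in seq_len(sp$n_blocks)) {
    pre <- sprintf("blk%d_", bkt)
    dil <- sp$dilations[bkt]
    Xin <- H
    Z1 <- conv1d_fwd(Xin, p[[paste0(pre, "c1_W")]], p[[paste0(pre, "c1_b")]], dil)
    A1 <- leaky(Z1, slope)
    M1 <- if (drop_p > 0) (matrix(stats::runif(length(A1)), nrow(A1)) >= drop_p) / (1 - drop_p) else NULL
    D1 <- if (is.null(M1)) A1 else A1 * M1
    Z2 <- conv1d_fwd(D1, p[[paste0(pre, "c2_W")]], p[[paste0(pre, "c2_b")]], dil)
    A2 <- leaky(Z2, slope)
    M2 <- if (drop_p > 0) (matrix(stats::runif(length(A2)), nrow(A2)) >= drop_p) / (1 - drop_p) else NULL
    D2 <- if (is.null(M2)) A2 else A2 * M2
    R <- if (!is.null(p[[paste0(pre, "p_W")]]))
      p[[paste0(pre, "p_W")]] %*% Xin + p[[paste0(pre, "p_b")]] else Xin
    S <- D2 + R
    H <- leaky(S, slope)
    if (keep_cache) {
      cache$inputs[[bkt]] <- Xin; cache$Z1[[bkt]] <- Z1; cache$Z2[[bkt]] <- Z2
      cache$S[[bkt]] <- S; cache$D1[[bkt]] <- D1
      cache$M1[bkt] <- list(M1); cache$M2[bkt] <- list(M2)
    }
  }
  Z <- p$dense_W %*% H + p$dense_b
  P <- softmax_cols(Z)
  out <- list(probs = P)
  if (keep_cache) { cache$H <- H; out$cache <- cache }
  out
}

# weighted cross-entropy loss and full gradient for one sequence
dtcn_loss_grad <- function(model, X, y, w) {
  sp <- model$spec
  p <- model$params
  slope <- sp$leaky_slope
  fw <- dtcn_forward(model, X, train = TRUE, keep_cache = TRUE)
  P <- fw$probs; cache <- fw$cache
  T_ <- ncol(P)
  wt <- w[y]
  Wsum <- sum(wt)
  if (Wsum == 0) return(list(loss = 0, grads = NULL))
  iy <- cbind(y, seq_len(T_)) # (class, t) index pairs
  loss <- -sum(wt * log(pmax(P[cbind(y, seq_len(T_))], 1e-12))) / Wsum
  dZ <- P
  dZ[iy] <- dZ[iy] - 1
  dZ <- sweep(dZ, 2, wt / Wsum, "*")
  g <- list()
  g$dense_W <- dZ %*% t(cache$H)
  g$dense_b <- rowSums(dZ)
  dH <- t(p$dense_W) %*% dZ
  for (bkt in rev(seq_len(sp$n_blocks))) {
    pre <- sprintf("blk%d_", bkt)
    dil <- sp$dilations[bkt]
    dS <- dH * dleaky(cache$S[[bkt]], slope)
    dD2 <- dS
    dA2 <- if (is.null(cache$M2[[bkt]])) dD2 else dD2 * cache$M2[[bkt]]
    dZ2 <- dA2 * dleaky(cache$Z2[[bkt]], slope)
    cb2 <- conv1d_bwd(dZ2, cache$D1[[bkt]], p[[paste0(pre, "c2_W")]], dil)
    g[[paste0(pre, "c2_W")]] <- cb2$dW
    g[[paste0(pre, "c2_b")]] <- cb2$db
    dA1 <- if (is.null(cache$M1[[bkt]])) cb2$dX else cb2$dX * cache$M1[[bkt]]
    dZ1 <- dA1 * dleaky(cache$Z1[[bkt]], slope)
    cb1 <- conv1d_bwd(dZ1, cache$inputs[[bkt]], p[[paste0(pre, "c1_W")]], dil)
    g[[paste0(pre, "c1_W")]] <- cb1$dW
    g[[paste0(pre, "c1_b")]] <- cb1$db
    if (!is.null(p[[paste0(pre, "p_W")]])) {
      g[[paste0(pre, "p_W")]] <- dS %*% t(cache$inputs[[bkt]])
      g[[paste0(pre, "p_b")]] <- rowSums(dS)
      dH <- cb1$dX + t(p[[paste0(pre, "p_W")]]) %*% dS
    } else {
      dH <- cb1$dX + dS
    }
  }
  list(loss = loss, grads = g)
}

# average weighted CE loss of a set of sequences (no dropout)
dtcn_eval_loss <- function(model, Xs, ys, w) {
  tot <- 0
  for (i in seq_along(Xs)) {
    P <- dtcn_forward(model, Xs[[i]], train = FALSE)$probs
    y <- ys[[i]]
    wt <- w[y]
    tot <- tot + (-sum(wt * log(pmax(P[cbind(y, seq_along(y))], 1e-12))) /
                    max(sum(wt), .Machine$double.eps))
  }
  tot / length(Xs)
}

as_feature_matrix <- function(features) {
  if (inherits(features, "feature_series")) t(as.matrix(features$data))
  else if (is.matrix(features)) features
  else stopf("`features` must be a feature_series or a channels x time matrix")
}

chunk_sequences <- function(M, labels, seq_len) {
  T_ <- ncol(M)
  n_seq <- T_ %/% seq_len
  if (n_seq < 2) stopf("need at least 2 sequences of %d timesteps (have %d frames)",
                       seq_len, T_)
  Xs <- vector("list", n_seq); ys <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    idx <- ((i - 1L) * seq_len + 1L):(i * seq_len)
    Xs[[i]] <- M[, idx, drop = FALSE]
    ys[[i]] <- labels[idx]
  }
  list(Xs = Xs, ys = ys, dropped = T_ - n_seq * seq_len)
}

#' Train a dTCN on labeled feature sequences
#'
#' The record is chunked into fixed-length sequences (the remainder is
#' dropped), split at the sequence level into train/validation, and
#' trained with Adam on class-weighted cross-entropy. Training stops when
#' the validation loss has not improved for `spec$patience` consecutive
#' epochs (or at `max_epochs`); the returned model is the checkpoint with
#' the lowest validation loss. Fully deterministic given `spec$seed`.
#'
#' @param model a [build_dtcn()] model.
#' @param features a [feature_series()] or channels x time matrix.
#' @param labels an [ethogram()] or integer vector (0 = none, 1 = partial,
#'   2 = full) aligned with `features`.
#' @param max_epochs upper bound on epochs (default 100; 0 returns the
#'   initialization untouched).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `history` (data.frame:
#'   epoch, train_loss, val_loss), `best_epoch`, `class_weights`,
#'   `n_train`, `n_val`, `dropped_frames`.
#' @export
train_dtcn <- function(model, features, labels, max_epochs = 100,
                       verbose = FALSE) {
  stopifnot(inherits(model, "dtcn"))
  sp <- model$spec
  M <- as_feature_matrix(features)
  if (nrow(M) != model$n_features)
    stopf("model expects %d feature channels, got %d", model$n_features, nrow(M))
  y <- if (inherits(labels, "ethogram")) as.integer(unclass(labels)) else as.integer(labels) + 1L
  if (length(y) != ncol(M)) stopf("labels and features have different lengths")
  ch <- chunk_sequences(M, y, sp$seq_len)
  n_seq <- length(ch$Xs)
  set.seed(derive_seed(sp$seed, 17))
  n_val <- max(1L, round((1 - sp$train_fraction) * n_seq))
  if (n_seq - n_val < 1L) stopf("not enough sequences for a train/val split")
  val_idx <- sample.int(n_seq, n_val)
  tr_idx <- setdiff(seq_len(n_seq), val_idx)
  counts <- tabulate(unlist(ch$ys[tr_idx]), nbins = sp$n_classes)
  w <- class_weights(counts)
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  if (max_epochs == 0) {
    return(list(model = model, history = data.frame(epoch = integer(0),
                                                    train_loss = numeric(0),
                                                    val_loss = numeric(0)),
                best_epoch = 0L, class_weights = w,
                n_train = length(tr_idx), n_val = n_val,
                dropped_frames = ch$dropped))
  }
  # Adam state
  mstate <- lapply(model$params, function(x) x * 0)
  vstate <- lapply(model$params, function(x) x * 0)
  tstep <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  since_best <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / sp$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      acc <- NULL; bl <- 0
      for (i in bt) {
        lg <- dtcn_loss_grad(model, ch$Xs[[i]], ch$ys[[i]], w)
        bl <- bl + lg$loss
        if (is.null(lg$grads)) next
        if (is.null(acc)) acc <- lg$grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
      }
      if (is.null(acc)) next
      nb <- length(bt)
      tstep <- tstep + 1L
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in names(acc)) {
        gr <- acc[[nm]] / nb
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr * gr
        model$params[[nm]] <- model$params[[nm]] -
          sp$learning_rate * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
      }
      ep_loss <- ep_loss + bl
    }
    val_loss <- dtcn_eval_loss(model, ch$Xs[val_idx], ch$ys[val_idx], w)
    hist_epoch <- c(hist_epoch, ep)
    hist_train <- c(hist_train, ep_loss / length(tr_idx))
    hist_val <- c(hist_val, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                      ep_loss / length(tr_idx), val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- model$params; best_epoch <- ep
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= sp$patience) break
    }
  }
  model$params <- best_params
  list(model = model,
       history = data.frame(epoch = hist_epoch, train_loss = hist_train,
                            val_loss = hist_val),
       best_epoch = best_epoch, class_weights = w,
       n_train = length(tr_idx), n_val = n_val, dropped_frames = ch$dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict an ethogram from features
#'
#' Per-frame argmax of the class probabilities; exact ties break toward
#' the lower class index (none < partial < full).
#'
#' @param model a trained `dtcn`.
#' @param features a [feature_series()] or channels x time matrix with the
#'   channels used in training.
#' @return an [ethogram()] with provenance `"predicted"`.
#' @export
predict_ethogram <- function(model, features) {
  stopifnot(inherits(model, "dtcn"))
  M <- as_feature_matrix(features)
  if (nrow(M) != model$n_features)
    stopf("model expects %d feature channels, got %d", model$n_features, nrow(M))
  fr <- if (inherits(features, "feature_series")) features$frame_rate else 40
  P <- dtcn_forward(model, M, train = FALSE)$probs
  lab <- max.col(t(P), ties.method = "first") - 1L
  ethogram(lab, frame_rate = fr, provenance = "predicted")
}

#' Evaluate a predicted ethogram against ground truth
#'
#' Per-class precision, recall and F1 (harmonic mean of precision and
#' recall) from the 3x3 confusion matrix; classes absent from both truth
#' and prediction are reported NA and excluded from the macro average.
#' Also reports the proportion of time flaring (partial + full combined)
#' under each scoring and their absolute difference.
#'
#' @param pred,truth [ethogram()]s of equal length.
#' @return list with `confusion`, `per_class` (data.frame), `macro_f1`,
#'   `prop_flaring_pred`, `prop_flaring_truth`, `prop_flaring_diff`.
#' @export
evaluate_ethogram <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("ethogram lengths differ")
  cm <- table(factor(as.character(truth), levels = FLARE_LEVELS),
              factor(as.character(pred), levels = FLARE_LEVELS))
  per <- data.frame(class = FLARE_LEVELS, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_)
  for (i in 1:3) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    if (tp + fp + fn == 0) next # class absent everywhere -> NA
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per$precision[i] <- prec; per$recall[i] <- rec; per$f1[i] <- f1
  }
  pf_pred <- mean(binary_flaring(pred))
  pf_truth <- mean(binary_flaring(truth))
  list(confusion = unclass(cm), per_class = per,
       macro_f1 = mean(per$f1, na.rm = TRUE),
       prop_flaring_pred = pf_pred, prop_flaring_truth = pf_truth,
       prop_flaring_diff = abs(pf_pred - pf_truth))
}

#' Save / load a dTCN checkpoint as JSON
#'
#' Parameters are stored flat with their dimensions, plus the spec and
#' seed, so checkpoints are plain text and portable.
#'
#' @param model a `dtcn`.
#' @param path output path.
#' @export
write_dtcn_json <- function(model, path) {
  stopifnot(inherits(model, "dtcn"))
  pl <- lapply(model$params, function(x)
    list(dim = dim(x) %||% length(x), data = as.numeric(x)))
  jsonlite::write_json(list(spec = unclass(model$spec),
                            n_features = model$n_features, params = pl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dtcn_json
#' @export
read_dtcn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(classifier_spec, obj$spec[setdiff(names(obj$spec), NULL)])
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1) array(p$data, dim = p$dim) else as.numeric(p$data)
  })
  structure(list(spec = spec, n_features = as.integer(obj$n_features),
                 params = params),
            class = "dtcn")
}
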