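# Binary CTC/WBC classifier.
#
# Two backbones: "small-scratch-cnn", a compact 3-block convolutional
# network implemented natively (im2col convolution, ReLU, 2x2 max pooling,
# global average pooling) and trained with Adam on cross-entropy -- suitable
# for CPU training on small crops; and "pretrained-resnet50", the
# transfer-learning configuration, which requires ImageNet weights and
# raises an explicit error when they are not available. The trainable head
# is the same in both cases: fully connected + ReLU, dropout, 2-way softmax.
# Class order is fixed as [WBC, CTC].

#' Training configuration
#'
#' @param input_side classifier input side in pixels (crops are bilinearly
#'   resized from 30 to this; default 34).
#' @param backbone `"small-scratch-cnn"` or `"pretrained-resnet50"`.
#' @param freeze_backbone keep backbone weights fixed and train only the
#'   head. Default: `TRUE` for the pretrained backbone (feature extraction),
#'   `FALSE` for the scratch backbone.
#' @param head_hidden_units width of the fully connected head layer.
#' @param dropout_rate dropout rate in the head (default 0.6).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size mini-batch size (default 16).
#' @param max_epochs,patience epoch cap and early-stopping patience on
#'   validation loss.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return named list of class `ctc_train_config`.
#' @export
train_config <- function(input_side = 34L,
                         backbone = c("small-scratch-cnn", "pretrained-resnet50"),
                         freeze_backbone = NULL,
                         head_hidden_units = 256L,
                         dropout_rate = 0.6,
                         learning_rate = 1e-4,
                         batch_size = 16L,
                         max_epochs = 50L,
                         patience = 10L,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(freeze_backbone))
    freeze_backbone <- backbone == "pretrained-resnet50"
  stopifnot(dropout_rate >= 0, dropout_rate < 1, batch_size >= 1,
            input_side >= 8, max_epochs >= 1)
  structure(list(input_side = as.integer(input_side), backbone = backbone,
                 freeze_backbone = freeze_backbone,
                 head_hidden_units = as.integer(head_hidden_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ctc_train_config")
}

#' Prepare a crop as classifier input
#'
#' Bilinear resize of the (normalized) patch to `side` x `side`; when `side`
#' equals the patch side this is an exact passthrough. Grayscale is kept as
#' one channel (the scratch backbone takes one channel; a pretrained RGB
#' backbone would replicate it to three).
#'
#' @param crop a `cell_crop`.
#' @param side target side (default 34).
#' @return `side` x `side` numeric matrix.
#' @export
prepare_input <- function(crop, side = 34L) {
  p <- crop$pixels
  s0 <- nrow(p)
  if (side == s0) return(p)
  scale <- s0 / side
  g <- (seq_len(side) - 0.5) * scale - 0.5
  matrix(bilinear_sample(p, rep(g, times = side), rep(g, each = side)),
         side, side)
}

crops_to_array <- function(crops, side) {
  n <- length(crops)
  x <- array(0, dim = c(n, side, side, 1))
  for (i in seq_len(n)) x[i, , , 1] <- prepare_input(crops[[i]], side)
  x
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

# --- im2col convolution ----------------------------------------------------

im2col_index <- function(N, H, W, C, K) {
  OH <- H - K + 1L; OW <- W - K + 1L
  n_vec <- rep(seq_len(N), times = OH * OW)
  oh_vec <- rep(rep(seq_len(OH), each = N), times = OW)
  ow_vec <- rep(seq_len(OW), each = N * OH)
  idx <- matrix(0L, N * OH * OW, K * K * C)
  j <- 0L
  for (c in seq_len(C)) for (kw in seq_len(K)) for (kh in seq_len(K)) {
    j <- j + 1L
    idx[, j] <- n_vec + N * (oh_vec + kh - 2L) + (N * H) * (ow_vec + kw - 2L) +
      (N * H * W) * (c - 1L)
  }
  list(idx = idx, OH = OH, OW = OW)
}

conv_forward <- function(x, Wm, b, ii) {
  N <- dim(x)[1]
  cols <- matrix(x[ii$idx], nrow = nrow(ii$idx))
  out <- sweep(cols %*% Wm, 2, b, "+")
  dim(out) <- c(N, ii$OH, ii$OW, ncol(Wm))
  list(out = out, cols = cols)
}

conv_backward <- function(dout, cols, Wm, xdim, ii) {
  dmat <- matrix(dout, nrow = nrow(ii$idx))
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wm)
  dx <- numeric(prod(xdim))
  for (j in seq_len(ncol(dcols)))
    dx[ii$idx[, j]] <- dx[ii$idx[, j]] + dcols[, j]
  dim(dx) <- xdim
  list(dx = dx, dW = dW, db = db)
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  r1 <- seq_len(H2) * 2L - 1L; c1 <- seq_len(W2) * 2L - 1L
  a <- x[, r1, c1, , drop = FALSE];      b <- x[, r1 + 1L, c1, , drop = FALSE]
  cc <- x[, r1, c1 + 1L, , drop = FALSE]; dd <- x[, r1 + 1L, c1 + 1L, , drop = FALSE]
  mx <- pmax(a, b, cc, dd)
  # winner masks with first-wins tie-break in the fixed order a, b, c, d
  m1 <- a == mx
  m2 <- (b == mx) & !m1
  m3 <- (cc == mx) & !m1 & !m2
  m4 <- (dd == mx) & !m1 & !m2 & !m3
  list(out = mx, masks = list(m1, m2, m3, m4), r1 = r1, c1 = c1, xdim = d)
}

maxpool2_backward <- function(dout, pf) {
  dx <- array(0, dim = pf$xdim)
  r1 <- pf$r1; c1 <- pf$c1
  dx[, r1, c1, ] <- dout * pf$masks[[1]]
  dx[, r1 + 1L, c1, ] <- dout * pf$masks[[2]]
  dx[, r1, c1 + 1L, ] <- dout * pf$masks[[3]]
  dx[, r1 + 1L, c1 + 1L, ] <- dout * pf$masks[[4]]
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  x2 <- x; dim(x2) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) out[, c] <- rowMeans(x2[, , c, drop = FALSE])
  list(out = out, xdim = d)
}

gap_backward <- function(dout, gf) {
  d <- gf$xdim
  dx <- array(0, dim = d)
  per <- 1 / (d[2] * d[3])
  for (c in seq_len(d[4]))
    dx[, , , c] <- array(rep(dout[, c] * per, d[2] * d[3]), dim = d[1:3])
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- scratch backbone ------------------------------------------------------

init_scratch_backbone <- function() {
  ch <- c(1L, 8L, 16L, 32L)
  list(c1W = he_init(9 * ch[1], ch[2], 9 * ch[1]), c1b = numeric(ch[2]),
       c2W = he_init(9 * ch[2], ch[3], 9 * ch[2]), c2b = numeric(ch[3]),
       c3W = he_init(9 * ch[3], ch[4], 9 * ch[3]), c3b = numeric(ch[4]))
}

backbone_forward <- function(params, x, keep_cache = FALSE) {
  d <- dim(x)
  i1 <- im2col_index(d[1], d[2], d[3], d[4], 3L)
  cv1 <- conv_forward(x, params$c1W, params$c1b, i1)
  a1 <- pmax(cv1$out, 0)
  p1 <- maxpool2_forward(a1)
  d1 <- dim(p1$out)
  i2 <- im2col_index(d1[1], d1[2], d1[3], d1[4], 3L)
  cv2 <- conv_forward(p1$out, params$c2W, params$c2b, i2)
  a2 <- pmax(cv2$out, 0)
  p2 <- maxpool2_forward(a2)
  d2 <- dim(p2$out)
  i3 <- im2col_index(d2[1], d2[2], d2[3], d2[4], 3L)
  cv3 <- conv_forward(p2$out, params$c3W, params$c3b, i3)
  a3 <- pmax(cv3$out, 0)
  g <- gap_forward(a3)
  res <- list(features = g$out)
  if (keep_cache)
    res$cache <- list(x = x, i1 = i1, cv1 = cv1, a1 = a1, p1 = p1,
                      i2 = i2, cv2 = cv2, a2 = a2, p2 = p2,
                      i3 = i3, cv3 = cv3, a3 = a3, g = g)
  res
}

backbone_backward <- function(params, dfeat, cache) {
  da3 <- gap_backward(dfeat, cache$g)
  dz3 <- da3 * (cache$cv3$out > 0)
  b3 <- conv_backward(dz3, cache$cv3$cols, params$c3W, dim(cache$p2$out), cache$i3)
  dp2 <- b3$dx
  da2 <- maxpool2_backward(dp2, cache$p2)
  dz2 <- da2 * (cache$cv2$out > 0)
  b2 <- conv_backward(dz2, cache$cv2$cols, params$c2W, dim(cache$p1$out), cache$i2)
  dp1 <- b2$dx
  da1 <- maxpool2_backward(dp1, cache$p1)
  dz1 <- da1 * (cache$cv1$out > 0)
  b1 <- conv_backward(dz1, cache$cv1$cols, params$c1W, dim(cache$x), cache$i1)
  list(c1W = b1$dW, c1b = b1$db, c2W = b2$dW, c2b = b2$db,
       c3W = b3$dW, c3b = b3$db)
}

# --- model -----------------------------------------------------------------

#' Build an untrained classifier
#'
#' @param config a [train_config()].
#' @return a `ctc_model`: backbone + head parameters, config echo, class
#'   order `c("WBC", "CTC")`.
#' @export
build_model <- function(config = train_config()) {
  stopifnot(inherits(config, "ctc_train_config"))
  if (config$backbone == "pretrained-resnet50")
    stop_ctc("ctcscope_weights_error",
             paste0("pretrained ResNet-50 weights are not available offline; ",
                    "use backbone = \"small-scratch-cnn\""))
  with_seed(config$seed, {
    backbone <- init_scratch_backbone()
    n_feat <- 32L
    head <- list(
      W1 = he_init(n_feat, config$head_hidden_units, n_feat),
      b1 = numeric(config$head_hidden_units),
      W2 = he_init(config$head_hidden_units, 2L, config$head_hidden_units),
      b2 = numeric(2L))
    structure(list(backbone = backbone, head = head, config = config,
                   class_order = CLASS_LEVELS, history = NULL),
              class = "ctc_model")
  })
}

head_forward <- function(head, feat, dropout_rate, training) {
  z1 <- sweep(feat %*% head$W1, 2, head$b1, "+")
  h <- pmax(z1, 0)
  mask <- NULL
  if (training && dropout_rate > 0) {
    mask <- matrix(runif(length(h)) >= dropout_rate, nrow(h)) / (1 - dropout_rate)
    h <- h * mask
  }
  logits <- sweep(h %*% head$W2, 2, head$b2, "+")
  list(probs = softmax_rows(logits), z1 = z1, h = h, mask = mask)
}

head_backward <- function(head, feat, hf, y_onehot) {
  n <- nrow(feat)
  dlogits <- (hf$probs - y_onehot) / n
  dW2 <- crossprod(hf$h, dlogits)
  db2 <- colSums(dlogits)
  dh <- dlogits %*% t(head$W2)
  if (!is.null(hf$mask)) dh <- dh * hf$mask
  dz1 <- dh * (hf$z1 > 0)
  dW1 <- crossprod(feat, dz1)
  db1 <- colSums(dz1)
  dfeat <- dz1 %*% t(head$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dfeat = dfeat)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  bf <- backbone_forward(model$backbone, x, keep_cache = keep_cache)
  hf <- head_forward(model$head, bf$features, model$config$dropout_rate, training)
  list(probs = hf$probs, bf = bf, hf = hf)
}

ce_loss <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

eval_in_batches <- function(model, x, y_idx, batch = 64L) {
  n <- dim(x)[1]
  loss_sum <- 0; correct <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(n, s + batch - 1)
    xb <- x[s:e, , , , drop = FALSE]
    p <- model_forward(model, xb, training = FALSE)$probs
    loss_sum <- loss_sum + ce_loss(p, y_idx[s:e]) * (e - s + 1)
    correct <- correct + sum(max.col(p, ties.method = "first") == y_idx[s:e])
  }
  c(loss = loss_sum / n, acc = correct / n)
}

labels_to_idx <- function(crops) {
  labs <- crop_labels(crops)
  if (any(labs == "UNLABELED"))
    stop_ctc("ctcscope_class_coverage_error", "training crops must be labeled")
  match(labs, CLASS_LEVELS)
}

#' Train the classifier
#'
#' Minimizes the softmax cross-entropy with Adam over shuffled seeded
#' mini-batches; dropout is active only during training. The returned model
#' carries the parameters of the best-validation-loss epoch and the full
#' per-epoch history. With a frozen backbone, features are extracted once
#' and only the head is optimized. Train and validation sets must be
#' disjoint by `origin_id`; any overlap is a hard leakage error.
#'
#' @param model a `ctc_model` from [build_model()].
#' @param train_crops,val_crops labeled, normalized `cell_crop`s.
#' @param config optional [train_config()] override (defaults to the
#'   model's).
#' @return a trained `ctc_model` with `history` filled in.
#' @export
train_model <- function(model, train_crops, val_crops, config = NULL) {
  if (is.null(config)) config <- model$config else model$config <- config
  if (!length(val_crops))
    stop_ctc("ctcscope_parameter_error", "validation set is empty")
  ov <- intersect(origin_ids(train_crops), origin_ids(val_crops))
  if (length(ov))
    stop_ctc("ctcscope_leakage_error",
             "train/validation share origin ids: %s",
             paste(head(ov, 5), collapse = ", "))
  y_tr <- labels_to_idx(train_crops)
  if (length(unique(y_tr)) < 2)
    stop_ctc("ctcscope_class_coverage_error",
             "training set contains a single class")
  y_va <- labels_to_idx(val_crops)
  side <- config$input_side
  x_tr <- crops_to_array(train_crops, side)
  x_va <- crops_to_array(val_crops, side)
  n <- length(train_crops)

  with_seed(config$seed, {
    frozen <- isTRUE(config$freeze_backbone)
    if (frozen) {
      feat_tr <- batch_features(model, x_tr)
      feat_va <- batch_features(model, x_va)
    }
    head_state <- adam_new(model$head)
    bb_state <- if (!frozen) adam_new(model$backbone)
    best <- list(loss = Inf, head = model$head, backbone = model$backbone,
                 epoch = 0L)
    hist <- NULL
    since_best <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; correct <- 0
      for (s in seq(1, n, by = config$batch_size)) {
        e <- min(n, s + config$batch_size - 1)
        bi <- ord[s:e]
        yb <- y_tr[bi]
        y1h <- matrix(0, length(bi), 2); y1h[cbind(seq_along(bi), yb)] <- 1
        if (frozen) {
          fb <- feat_tr[bi, , drop = FALSE]
          hf <- head_forward(model$head, fb, config$dropout_rate, TRUE)
          hb <- head_backward(model$head, fb, hf, y1h)
          st <- adam_step(model$head, hb$grads, head_state,
                          config$learning_rate)
          model$head <- st$params; head_state <- st$state
          probs <- hf$probs
        } else {
          xb <- x_tr[bi, , , , drop = FALSE]
          bf <- backbone_forward(model$backbone, xb, keep_cache = TRUE)
          hf <- head_forward(model$head, bf$features, config$dropout_rate, TRUE)
          hb <- head_backward(model$head, bf$features, hf, y1h)
          bg <- backbone_backward(model$backbone, hb$dfeat, bf$cache)
          st <- adam_step(model$head, hb$grads, head_state,
                          config$learning_rate)
          model$head <- st$params; head_state <- st$state
          st <- adam_step(model$backbone, bg, bb_state, config$learning_rate)
          model$backbone <- st$params; bb_state <- st$state
          probs <- hf$probs
        }
        loss_sum <- loss_sum + ce_loss(probs, yb) * length(bi)
        correct <- correct + sum(max.col(probs, ties.method = "first") == yb)
      }
      va <- if (frozen) {
        hf <- head_forward(model$head, feat_va, 0, FALSE)
        c(loss = ce_loss(hf$probs, y_va),
          acc = mean(max.col(hf$probs, ties.method = "first") == y_va))
      } else eval_in_batches(model, x_va, y_va)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = loss_sum / n,
                                     train_acc = correct / n,
                                     val_loss = va[["loss"]],
                                     val_acc = va[["acc"]]))
      if (va[["loss"]] < best$loss) {
        best <- list(loss = va[["loss"]], head = model$head,
                     backbone = model$backbone, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
    model$head <- best$head
    model$backbone <- best$backbone
    model$history <- hist
    model$best_epoch <- best$epoch
    model$trained <- TRUE
    model
  })
}

batch_features <- function(model, x, batch = 64L) {
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    e <- min(n, s + batch - 1)
    out <- rbind(out, backbone_forward(model$backbone,
                                       x[s:e, , , , drop = FALSE])$features)
  }
  out
}

#' Predict class probabilities for crops
#'
#' Inference mode (dropout disabled, deterministic). Probabilities sum to 1;
#' the label is the argmax, with exact ties resolved to WBC (the non-rare
#' class, minimizing false CTC calls).
#'
#' @param object a trained `ctc_model`.
#' @param crops list of `cell_crop`.
#' @param ... unused.
#' @return data.frame with `crop_id`, `p_wbc`, `p_ctc`, `label`.
#' @exportS3Method stats::predict
predict.ctc_model <- function(object, crops, ...) {
  if (!isTRUE(object$trained))
    warning("predicting with an untrained model")
  x <- crops_to_array(crops, object$config$input_side)
  n <- dim(x)[1]
  probs <- NULL
  for (s in seq(1, n, by = 64L)) {
    e <- min(n, s + 63L)
    probs <- rbind(probs,
                   model_forward(object, x[s:e, , , , drop = FALSE])$probs)
  }
  # argmax with ties to WBC (class column 1)
  lab <- ifelse(probs[, 2] > probs[, 1], "CTC", "WBC")
  data.frame(crop_id = vapply(crops, `[[`, "", "crop_id"),
             p_wbc = probs[, 1], p_ctc = probs[, 2],
             label = lab, stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' RDS checkpoint plus a JSON sidecar (config echo, class order, history).
#'
#' @param model a `ctc_model`.
#' @param path checkpoint path (`.rds`); the sidecar gets `.json` appended.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config), class_order = model$class_order,
               best_epoch = model$best_epoch,
               history = model$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop_ctc("ctcscope_io_error", "missing model checkpoint: %s", path)
  readRDS(path)
}
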