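# The risk-prediction network: an 8-hidden-layer CNN over the temporal
# phenomic map -- conv(32 filters, 1 x W, same padding) -> average pool (2x2)
# -> conv(2 filters, 1 x W, same padding) -> max pool (1x3) -> flatten ->
# concatenate(age, sex) -> dense(128, LeakyReLU) -> dropout(0.3) -> sigmoid
# output -- trained with Adam on binary cross-entropy.
#
# No deep-learning backend is assumed: forward and backward passes are written
# directly on BLAS matrix products. A 1 x L temporal convolution with "same"
# padding is a banded linear map of the week axis, so a whole batch convolves
# as one matmul of the stacked (sample,row) matrix against a sparse banded
# kernel matrix rebuilt from the filter weights each step; the weight gradient
# folds the dense kernel-matrix gradient back over its bands. A ones-column /
# bias-row augmentation carries the filter biases through the same product.

#' Hyperparameter specification for the CNN
#'
#' Defaults are the published architecture and training protocol: 32 then 2
#' convolution filters spanning the full observation window, a 128-unit dense
#' layer, dropout 0.3, ReLU convolutions with a LeakyReLU dense layer and
#' sigmoid output, Adam at its conventional 1e-3 learning rate, 20 epochs,
#' batch size 64.
#'
#' @param filters1,filters2 Filter counts of the two convolutional layers.
#' @param dense_units Width of the fully connected layer.
#' @param dropout_rate Dropout probability in [0,1).
#' @param leaky_alpha Negative-slope coefficient of the LeakyReLU.
#' @param learning_rate,beta1,beta2,adam_eps Adam optimizer constants.
#' @param epochs,batch_size Training protocol.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param class_weighting If `TRUE`, weight the loss inversely to class
#'   frequency (off by default; the study reports none).
#' @param kernel_weeks Temporal extent of the convolution windows; `NULL`
#'   (default) uses the full observation width, matching the published
#'   1 x 131 filters, and shrinks proportionally with toy input shapes.
#' @return A `cnn_spec` object.
#' @export
model_spec <- function(filters1 = 32L, filters2 = 2L, dense_units = 128L,
                       dropout_rate = 0.3, leaky_alpha = 0.3,
                       learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       adam_eps = 1e-7, epochs = 20L, batch_size = 64L,
                       seed = 1L, class_weighting = FALSE,
                       kernel_weeks = NULL) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_cfg("dropout_rate", "must lie in [0, 1)")
  if (!is_count(epochs) || epochs < 1) stop_cfg("epochs", "must be positive")
  if (!is_count(batch_size) || batch_size < 1)
    stop_cfg("batch_size", "must be positive")
  structure(list(
    filters1 = as.integer(filters1), filters2 = as.integer(filters2),
    dense_units = as.integer(dense_units), dropout_rate = dropout_rate,
    leaky_alpha = leaky_alpha, learning_rate = learning_rate,
    beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), class_weighting = isTRUE(class_weighting),
    kernel_weeks = if (!is.null(kernel_weeks)) as.integer(kernel_weeks)
  ), class = "cnn_spec")
}

# Index map for a same-padded 1 x L convolution over width Tin with Cin input
# channels and F filters, expressed as a (Cin*Tin + 1) x (Tin*F) banded matrix
# (last row carries the filter biases against a ones-column in the input).
conv_indices <- function(Tin, L, F, Cin) {
  pl <- (L - 1L) %/% 2L
  tk <- CJ(t = seq_len(Tin), k = seq_len(L))
  tk[, j := t + k - 1L - pl]
  tk <- tk[j >= 1L & j <= Tin]
  nv <- nrow(tk)
  combos <- CJ(f = seq_len(F), c = seq_len(Cin))   # c fastest within f
  nc <- nrow(combos)
  rowK <- rep(tk$j, nc) + (rep(combos$c, each = nv) - 1L) * Tin
  colK <- rep(tk$t, nc) + (rep(combos$f, each = nv) - 1L) * Tin
  wpos <- rep(tk$k, nc) + (rep(combos$c, each = nv) - 1L) * L +
    (rep(combos$f, each = nv) - 1L) * L * Cin
  # bias entries
  bt <- CJ(f = seq_len(F), t = seq_len(Tin))
  rowK <- c(rowK, rep.int(Cin * Tin + 1L, nrow(bt)))
  colK <- c(colK, bt$t + (bt$f - 1L) * Tin)
  wpos <- c(wpos, L * Cin * F + bt$f)
  list(idx = cbind(rowK, colK), wpos = wpos,
       nrowK = Cin * Tin + 1L, ncolK = Tin * F,
       n_weights = L * Cin * F + F, L = L, Tin = Tin, F = F, Cin = Cin)
}

make_kernel <- function(theta, cm) {
  K <- matrix(0, cm$nrowK, cm$ncolK)
  K[cm$idx] <- theta[cm$wpos]
  K
}

fold_kernel_grad <- function(dK, cm) {
  g <- numeric(cm$n_weights)
  r <- rowsum(dK[cm$idx], cm$wpos)
  g[as.integer(rownames(r))] <- r
  g
}

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Build the (untrained) CNN
#'
#' Constructs the published layer sequence for a given map shape and
#' initializes the parameters (Glorot uniform, seeded by `spec$seed`). Exactly
#' 8 hidden layers sit between the input map and the sigmoid output; the
#' temporal convolutions use same-padding so the full-window 1 x 131 filter
#' shapes remain applicable after pooling.
#'
#' @param spec A [model_spec()].
#' @param input_shape Integer pair `(n_rows, n_weeks)` of the map.
#' @return A `tpm_cnn` model handle (untrained).
#' @export
build_model <- function(spec, input_shape) {
  stopifnot(inherits(spec, "cnn_spec"), length(input_shape) == 2L)
  R <- as.integer(input_shape[1]); Tw <- as.integer(input_shape[2])
  R2 <- R %/% 2L; T2 <- Tw %/% 2L
  if (R2 < 1L || T2 < 1L)
    stop(sprintf("input shape (%d, %d) too small for average-pooling (2x2)", R, Tw),
         call. = FALSE)
  T3 <- T2 %/% 3L
  if (T3 < 1L)
    stop(sprintf("feature width %d after average-pooling too small for max-pooling (1x3)",
                 T2), call. = FALSE)
  L <- spec$kernel_weeks %||% Tw
  F1 <- spec$filters1; F2 <- spec$filters2; H <- spec$dense_units
  D <- R2 * T3 * F2
  cm1 <- conv_indices(Tw, L, F1, 1L)
  cm2 <- conv_indices(T2, L, F2, F1)
  params <- with_seed(spec$seed, list(
    conv1 = c(glorot(L * F1, L, L * F1), rep(0, F1)),
    conv2 = c(glorot(L * F1 * F2, L * F1, L * F2), rep(0, F2)),
    dense_W = matrix(glorot((D + 2L) * H, D + 2L, H), D + 2L, H),
    dense_b = rep(0, H),
    out_W = matrix(glorot(H, H, 1L), H, 1L),
    out_b = 0
  ))
  layers <- list(
    list(type = "conv2d", filters = F1, kernel = c(1L, L), padding = "same",
         activation = "relu"),
    list(type = "average_pooling2d", size = c(2L, 2L)),
    list(type = "conv2d", filters = F2, kernel = c(1L, L), padding = "same",
         activation = "relu"),
    list(type = "max_pooling2d", size = c(1L, 3L)),
    list(type = "flatten"),
    list(type = "concatenate", inputs = c("age", "sex")),
    list(type = "dense", units = H, activation = "leaky_relu",
         alpha = spec$leaky_alpha),
    list(type = "dropout", rate = spec$dropout_rate)
  )
  structure(list(
    spec = spec, input_shape = c(R, Tw),
    dims = list(R = R, Tw = Tw, R2 = R2, T2 = T2, T3 = T3, D = D,
                F1 = F1, F2 = F2, H = H, L = L),
    cm1 = cm1, cm2 = cm2, params = params,
    layers = layers,
    output_layer = list(type = "dense", units = 1L, activation = "sigmoid"),
    trained = FALSE, history = NULL
  ), class = "tpm_cnn")
}

#' Number of hidden layers of a built model
#' @param model A `tpm_cnn`.
#' @return Integer count of layers between input and output.
#' @export
n_hidden_layers <- function(model) length(model$layers)

#' @export
print.tpm_cnn <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<tpm_cnn> input (%d x %d), %d hidden layers, %s\n",
              d$R, d$Tw, length(x$layers),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  for (l in x$layers) cat("  -", l$type,
                          if (l$type == "conv2d") sprintf("[%d @ 1x%d]", l$filters, l$kernel[2])
                          else "", "\n")
  invisible(x)
}

encode_sex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(sex == "M")
}

# Stack maps for samples `idx` into the (B*R) x T row-block matrix the
# convolution matmul expects (row (b-1)*R + r holds sample b, map row r).
stack_maps <- function(maps, idx) {
  a <- maps[, , idx, drop = FALSE]
  d <- dim(a)
  a <- aperm(a, c(1L, 3L, 2L))
  dim(a) <- c(d[1] * d[3], d[2])
  a
}

pool_row_idx <- function(B, R, R2) {
  a <- rep((seq_len(B) - 1L) * R, each = R2) +
    rep(seq.int(1L, by = 2L, length.out = R2), B)
  list(a = a, b = a + 1L)
}

pool_col_idx <- function(Tw, T2, F) {
  a <- rep((seq_len(F) - 1L) * Tw, each = T2) +
    rep(seq.int(1L, by = 2L, length.out = T2), F)
  list(a = a, b = a + 1L)
}

max_col_idx <- function(T2, T3, F) {
  a <- rep((seq_len(F) - 1L) * T2, each = T3) +
    rep(seq.int(1L, by = 3L, length.out = T3), F)
  list(c1 = a, c2 = a + 1L, c3 = a + 2L)
}

nn_forward <- function(model, Xrows, age01, sex01, train = FALSE) {
  d <- model$dims; p <- model$params
  B <- length(age01)
  X1 <- cbind(Xrows, 1)
  K1 <- make_kernel(p$conv1, model$cm1)
  A1 <- X1 %*% K1
  A1[A1 < 0] <- 0                       # ReLU in place
  pr <- pool_row_idx(B, d$R, d$R2)
  pc <- pool_col_idx(d$Tw, d$T2, d$F1)
  # keep only the two pooled row-halves; backward never needs the full
  # (B*R)-row activation again
  A1a <- A1[pr$a, , drop = FALSE]
  A1b <- A1[pr$b, , drop = FALSE]
  S <- A1a + A1b
  P1 <- (S[, pc$a, drop = FALSE] + S[, pc$b, drop = FALSE]) * 0.25
  X2 <- cbind(P1, 1)
  K2 <- make_kernel(p$conv2, model$cm2)
  A2 <- X2 %*% K2
  A2[A2 < 0] <- 0
  mx <- max_col_idx(d$T2, d$T3, d$F2)
  M1 <- A2[, mx$c1, drop = FALSE]
  M2 <- A2[, mx$c2, drop = FALSE]
  M3 <- A2[, mx$c3, drop = FALSE]
  M <- pmax(M1, M2, M3)
  tmp <- M
  dim(tmp) <- c(d$R2, B, d$T3 * d$F2)
  tmp <- aperm(tmp, c(1L, 3L, 2L))
  dim(tmp) <- c(d$D, B)
  Fl <- t(tmp)
  Zc <- cbind(Fl, age01, sex01)
  Zd <- sweep(Zc %*% p$dense_W, 2L, p$dense_b, "+")
  Ad <- Zd
  neg <- Zd < 0
  Ad[neg] <- model$spec$leaky_alpha * Zd[neg]
  mask <- NULL
  Ad2 <- Ad
  if (train && model$spec$dropout_rate > 0) {
    keep <- 1 - model$spec$dropout_rate
    mask <- (matrix(runif(B * d$H), B, d$H) < keep) / keep
    Ad2 <- Ad * mask
  }
  o <- as.vector(Ad2 %*% p$out_W) + p$out_b
  prob <- 1 / (1 + exp(-o))
  if (!train) return(prob)
  list(prob = prob, pr = pr, pc = pc, mx = mx, X1a = X1[pr$a, , drop = FALSE],
       X1b = X1[pr$b, , drop = FALSE], A1a = A1a, A1b = A1b,
       X2 = X2, K2 = K2, A2 = A2, M = M, M1 = M1, M2 = M2,
       Zc = Zc, Zd = Zd, mask = mask, Ad2 = Ad2, B = B)
}

nn_backward <- function(model, fw, y, w = NULL) {
  d <- model$dims; p <- model$params
  B <- fw$B
  dlogit <- (fw$prob - y) / B
  if (!is.null(w)) dlogit <- dlogit * w
  dlogit <- matrix(dlogit, B, 1L)
  g <- list()
  g$out_W <- crossprod(fw$Ad2, dlogit)
  g$out_b <- sum(dlogit)
  dAd2 <- dlogit %*% t(p$out_W)
  dAd <- if (is.null(fw$mask)) dAd2 else dAd2 * fw$mask
  slope <- matrix(1, B, d$H)
  slope[fw$Zd < 0] <- model$spec$leaky_alpha
  dZd <- dAd * slope
  g$dense_W <- crossprod(fw$Zc, dZd)
  g$dense_b <- colSums(dZd)
  dZc <- dZd %*% t(p$dense_W)
  dFl <- dZc[, seq_len(d$D), drop = FALSE]
  tmp <- t(dFl)
  dim(tmp) <- c(d$R2, d$T3 * d$F2, B)
  tmp <- aperm(tmp, c(1L, 3L, 2L))
  dM <- tmp
  dim(dM) <- c(d$R2 * B, d$T3 * d$F2)
  m1 <- fw$M1 == fw$M
  m2 <- (!m1) & (fw$M2 == fw$M)
  m3 <- !(m1 | m2)
  dA2 <- matrix(0, B * d$R2, d$T2 * d$F2)
  dA2[, fw$mx$c1] <- dM * m1
  dA2[, fw$mx$c2] <- dM * m2
  dA2[, fw$mx$c3] <- dM * m3
  dZ2 <- dA2 * (fw$A2 > 0)
  g$conv2 <- fold_kernel_grad(crossprod(fw$X2, dZ2), model$cm2)
  dP1 <- (dZ2 %*% t(fw$K2))[, seq_len(d$T2 * d$F1), drop = FALSE]
  dS <- matrix(0, B * d$R2, d$Tw * d$F1)
  dS[, fw$pc$a] <- dP1
  dS[, fw$pc$b] <- dP1
  dS <- dS * 0.25
  # average-pool row backward, fused with the ReLU mask and the kernel-matrix
  # gradient: fold each row-half separately instead of scattering back to the
  # full (B*R)-row matrix
  dK1 <- crossprod(fw$X1a, dS * (fw$A1a > 0)) +
    crossprod(fw$X1b, dS * (fw$A1b > 0))
  g$conv1 <- fold_kernel_grad(dK1, model$cm1)
  g
}

bce_loss <- function(prob, y, w = NULL) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (!is.null(w)) ll <- ll * w
  mean(ll)
}

#' Train the CNN
#'
#' Runs the stated protocol (default 20 epochs, batch size 64, Adam, binary
#' cross-entropy) with seeded initialization, shuffling and dropout. Maps are
#' expected normalized to [0,1]; age is scaled by 1/100 and sex encoded
#' male = 1 before concatenation.
#'
#' @param model A [build_model()] handle.
#' @param maps Array `n_rows x n_weeks x n` of normalized maps, or a
#'   normalized `tpm_set` (in which case `age`, `sex`, `y` are taken from it).
#' @param age,sex,y Auxiliary inputs (years; "M"/"F" or 0/1) and 0/1 labels.
#' @param verbose Print per-epoch loss.
#' @return The trained `tpm_cnn` (with a `history` data.frame of per-epoch
#'   training loss).
#' @export
train_cnn <- function(model, maps, age = NULL, sex = NULL, y = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "tpm_cnn"))
  if (inherits(maps, "tpm_set")) {
    age <- maps$age; sex <- maps$sex; y <- maps$y; maps <- maps$maps
  }
  dm <- dim(maps)
  if (dm[1] != model$dims$R || dm[2] != model$dims$Tw)
    stop(sprintf("maps are %d x %d but the model was built for %d x %d",
                 dm[1], dm[2], model$dims$R, model$dims$Tw), call. = FALSE)
  n <- dm[3]
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  age01 <- as.numeric(age) / 100
  sex01 <- encode_sex(sex)
  spec <- model$spec
  w_class <- NULL
  if (spec$class_weighting) {
    tab <- table(y)
    w_class <- as.numeric(n / (2 * tab[as.character(y)]))
  }
  params <- model$params
  mstate <- lapply(params, function(x) x * 0)
  vstate <- lapply(params, function(x) x * 0)
  step <- 0L
  history <- numeric(spec$epochs)
  with_seed(spec$seed, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = spec$batch_size)) {
        idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
        model$params <- params
        fw <- nn_forward(model, stack_maps(maps, idx), age01[idx], sex01[idx],
                         train = TRUE)
        wb <- if (is.null(w_class)) NULL else w_class[idx]
        g <- nn_backward(model, fw, y[idx], wb)
        step <- step + 1L
        for (nm in names(params)) {
          mstate[[nm]] <- spec$beta1 * mstate[[nm]] + (1 - spec$beta1) * g[[nm]]
          vstate[[nm]] <- spec$beta2 * vstate[[nm]] + (1 - spec$beta2) * g[[nm]]^2
          mhat <- mstate[[nm]] / (1 - spec$beta1^step)
          vhat <- vstate[[nm]] / (1 - spec$beta2^step)
          params[[nm]] <- params[[nm]] -
            spec$learning_rate * mhat / (sqrt(vhat) + spec$adam_eps)
        }
        ep_loss <- ep_loss + bce_loss(fw$prob, y[idx], wb) * length(idx)
        nb <- nb + length(idx)
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, spec$epochs,
                                   history[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(spec$epochs), loss = history)
  model
}

#' Predict PsA risk probabilities
#'
#' Deterministic inference (dropout disabled); one probability in [0,1] per
#' map.
#'
#' @param object A trained (or initialized) `tpm_cnn`.
#' @param maps Array of normalized maps, or a normalized `tpm_set`.
#' @param age,sex Auxiliary inputs when `maps` is a bare array.
#' @param batch_size Chunk size for memory control.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.tpm_cnn <- function(object, maps, age = NULL, sex = NULL,
                            batch_size = 256L, ...) {
  if (inherits(maps, "tpm_set")) {
    age <- maps$age; sex <- maps$sex; maps <- maps$maps
  }
  dm <- dim(maps)
  if (length(dm) == 2L) {
    dim(maps) <- c(dm, 1L)
    dm <- dim(maps)
  }
  if (dm[1] != object$dims$R || dm[2] != object$dims$Tw)
    stop(sprintf("maps are %d x %d but the model expects %d x %d",
                 dm[1], dm[2], object$dims$R, object$dims$Tw), call. = FALSE)
  n <- dm[3]
  age01 <- as.numeric(age) / 100
  sex01 <- encode_sex(sex)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    out[idx] <- nn_forward(object, stack_maps(maps, idx), age01[idx],
                           sex01[idx], train = FALSE)
  }
  out
}
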