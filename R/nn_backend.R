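## Minimal neural-network backend: dense layers, a 1D valid convolution and a
## gated recurrent unit (GRU), trained with Adam on binary cross-entropy.
## Written directly on BLAS matrix products; gradients are exact (verified
## against finite differences in the test suite). Dropout rates are
## fractions *dropped* (inverted dropout). All randomness (initialization,
## minibatch order, dropout masks) is drawn from the model seed, so training
## is bit-reproducible.

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Adam ---------------------------------------------------------------------

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.drop_mask <- function(dim1, dim2, rate) {
  keep <- 1 - rate
  matrix(stats::rbinom(dim1 * dim2, 1, keep) / keep, dim1, dim2)
}

## Plain feed-forward network ------------------------------------------------

#' Fit a feed-forward binary classifier
#'
#' The default geometry is three fully connected layers of 512, 64 and 1
#' units with ReLU, tanh and sigmoid activations, trained with Adam on
#' binary cross-entropy — the standard fingerprint-input architecture of the
#' ensemble.
#'
#' @param X Numeric matrix `n x d` of inputs.
#' @param y 0/1 labels.
#' @param hidden Hidden layer sizes (default `c(512, 64)`).
#' @param activations Hidden activations, `"relu"` or `"tanh"`
#'   (default `c("relu", "tanh")`).
#' @param lr,epochs,batch_size Adam learning rate, epochs, minibatch size.
#' @param seed Integer seed controlling all randomness.
#' @return An `mlp_model` (list of weights plus metadata).
#' @export
mlp_fit <- function(X, y, hidden = c(512, 64),
                    activations = c("relu", "tanh"),
                    lr = 0.001, epochs = 30, batch_size = 256, seed = 1) {
  stopifnot(length(hidden) == length(activations))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); dims <- c(ncol(X), hidden, 1L)
  with_seed(seed, {
    params <- list()
    for (l in seq_len(length(dims) - 1)) {
      params[[paste0("W", l)]] <- .glorot(dims[l], dims[l + 1])
      params[[paste0("b", l)]] <- rep(0, dims[l + 1])
    }
    st <- .adam_new(params)
    nl <- length(dims) - 1
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, n)]
        B <- length(rows)
        A <- list(X[rows, , drop = FALSE]); Z <- list()
        for (l in seq_len(nl)) {
          Z[[l]] <- sweep(A[[l]] %*% params[[paste0("W", l)]], 2,
                          params[[paste0("b", l)]], "+")
          A[[l + 1]] <- if (l == nl) .sigmoid(Z[[l]])
                        else if (activations[l] == "relu") pmax(Z[[l]], 0)
                        else tanh(Z[[l]])
        }
        g <- list()
        dZ <- (A[[nl + 1]] - y[rows]) / B
        for (l in nl:1) {
          g[[paste0("W", l)]] <- crossprod(A[[l]], dZ)
          g[[paste0("b", l)]] <- colSums(dZ)
          if (l > 1) {
            dA <- tcrossprod(dZ, params[[paste0("W", l)]])
            dZ <- if (activations[l - 1] == "relu") dA * (Z[[l - 1]] > 0)
                  else dA * (1 - tanh(Z[[l - 1]])^2)
          }
        }
        upd <- .adam_step(params, g, st, lr)
        params <- upd$params; st <- upd$state
      }
    }
    structure(list(params = params, dims = dims, activations = activations,
                   lr = lr, epochs = epochs, batch_size = batch_size,
                   seed = seed),
              class = "mlp_model")
  })
}

#' Predict probabilities from an `mlp_model`
#' @param object An `mlp_model`.
#' @param X Input matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.mlp_model <- function(object, X, ...) {
  A <- as.matrix(X); nl <- length(object$dims) - 1
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% object$params[[paste0("W", l)]], 2,
               object$params[[paste0("b", l)]], "+")
    A <- if (l == nl) .sigmoid(Z)
         else if (object$activations[l] == "relu") pmax(Z, 0)
         else tanh(Z)
  }
  as.numeric(A)
}

## CNN -> GRU sequence model --------------------------------------------------

#' Default hyperparameters of the SMILES sequence model
#'
#' One 1D convolution (384 filters of width 17, ReLU, no pooling) over the
#' `max_len x dim` one-hot grid, a many-to-many GRU of 9 units, a flatten,
#' one hidden dense layer of 64 ReLU units and a sigmoid output unit.
#' Dropout fractions: 0.9 after the convolution, 0.6 after the GRU, 0.6
#' after the first dense layer. Adam, learning rate 0.001, 120 epochs,
#' minibatch 256.
#'
#' @return Named list of hyperparameters.
#' @export
cnn_gru_default_hp <- function() {
  list(n_filters = 384L, filter_width = 17L, gru_units = 9L,
       dense_units = 64L,
       dropout = c(conv = 0.9, gru = 0.6, dense = 0.6),
       lr = 0.001, epochs = 120L, batch_size = 256L)
}

.cnn_gru_init <- function(input_dim, hp) {
  W <- hp$filter_width; F_ <- hp$n_filters; H <- hp$gru_units
  U <- hp$dense_units
  flat <- NA  # depends on max_len; dense weights sized at fit time
  p <- list(
    Wconv = .glorot(W * input_dim, F_), bconv = rep(0, F_),
    Wz = .glorot(F_, H), Uz = .glorot(H, H), bz = rep(0, H),
    Wr = .glorot(F_, H), Ur = .glorot(H, H), br = rep(0, H),
    Wc = .glorot(F_, H), Uc = .glorot(H, H), bc = rep(0, H))
  p
}

#' @noRd
.im2col <- function(X, W) {
  # X: B x L x D array -> (B*T) x (W*D) matrix, T = L - W + 1,
  # rows indexed batch-fastest within each time step.
  B <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  T_ <- L - W + 1
  M <- matrix(0, B * T_, W * D)
  for (w in seq_len(W))
    M[, ((w - 1) * D + 1):(w * D)] <- matrix(X[, w:(w + T_ - 1), , drop = FALSE],
                                             B * T_, D)
  M
}

#' @noRd
.cnn_gru_forward <- function(params, X, hp, train = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  W <- hp$filter_width; F_ <- hp$n_filters; H <- hp$gru_units
  T_ <- L - W + 1
  M <- .im2col(X, W)
  Zc <- sweep(M %*% params$Wconv, 2, params$bconv, "+")
  Ac <- pmax(Zc, 0)
  mask_c <- NULL
  if (train && hp$dropout[["conv"]] > 0) {
    mask_c <- .drop_mask(nrow(Ac), ncol(Ac), hp$dropout[["conv"]])
    Ac <- Ac * mask_c
  }
  hs <- vector("list", T_ + 1); hs[[1]] <- matrix(0, B, H)
  zs <- rs <- cs <- vector("list", T_)
  Hf <- matrix(0, B, T_ * H)
  for (t in seq_len(T_)) {
    Xt <- Ac[((t - 1) * B + 1):(t * B), , drop = FALSE]
    hprev <- hs[[t]]
    z <- .sigmoid(sweep(Xt %*% params$Wz + hprev %*% params$Uz, 2, params$bz, "+"))
    r <- .sigmoid(sweep(Xt %*% params$Wr + hprev %*% params$Ur, 2, params$br, "+"))
    cc <- tanh(sweep(Xt %*% params$Wc + (r * hprev) %*% params$Uc, 2, params$bc, "+"))
    h <- z * hprev + (1 - z) * cc
    zs[[t]] <- z; rs[[t]] <- r; cs[[t]] <- cc; hs[[t + 1]] <- h
    Hf[, ((t - 1) * H + 1):(t * H)] <- h
  }
  mask_g <- NULL
  Hfd <- Hf
  if (train && hp$dropout[["gru"]] > 0) {
    mask_g <- .drop_mask(nrow(Hf), ncol(Hf), hp$dropout[["gru"]])
    Hfd <- Hf * mask_g
  }
  Z1 <- sweep(Hfd %*% params$W1, 2, params$b1, "+")
  A1 <- pmax(Z1, 0)
  mask_d <- NULL
  A1d <- A1
  if (train && hp$dropout[["dense"]] > 0) {
    mask_d <- .drop_mask(nrow(A1), ncol(A1), hp$dropout[["dense"]])
    A1d <- A1 * mask_d
  }
  p <- .sigmoid(sweep(A1d %*% params$W2, 2, params$b2, "+"))
  list(p = as.numeric(p), M = M, Zc = Zc, Ac = Ac, hs = hs, zs = zs, rs = rs,
       cs = cs, Hfd = Hfd, Z1 = Z1, A1d = A1d,
       masks = list(conv = mask_c, gru = mask_g, dense = mask_d),
       B = B, T_ = T_)
}

#' @noRd
.cnn_gru_backward <- function(params, fw, y, hp) {
  B <- fw$B; T_ <- fw$T_; H <- hp$gru_units
  g <- lapply(params, function(p) p * 0)
  dZ2 <- matrix((fw$p - y) / B, B, 1)
  g$W2 <- crossprod(fw$A1d, dZ2); g$b2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, params$W2)
  if (!is.null(fw$masks$dense)) dA1 <- dA1 * fw$masks$dense
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$W1 <- crossprod(fw$Hfd, dZ1); g$b1 <- colSums(dZ1)
  dHf <- tcrossprod(dZ1, params$W1)
  if (!is.null(fw$masks$gru)) dHf <- dHf * fw$masks$gru
  dAc <- matrix(0, B * T_, nrow(params$Wz))
  dh_next <- matrix(0, B, H)
  for (t in T_:1) {
    dh <- dHf[, ((t - 1) * H + 1):(t * H), drop = FALSE] + dh_next
    z <- fw$zs[[t]]; r <- fw$rs[[t]]; cc <- fw$cs[[t]]; hprev <- fw$hs[[t]]
    Xt <- fw$Ac[((t - 1) * B + 1):(t * B), , drop = FALSE]
    dz <- dh * (hprev - cc)
    dc <- dh * (1 - z)
    da_c <- dc * (1 - cc^2)
    da_z <- dz * z * (1 - z)
    tmp <- tcrossprod(da_c, params$Uc)         # da_c Uc^T
    dr <- tmp * hprev
    da_r <- dr * r * (1 - r)
    dh_next <- dh * z + tcrossprod(da_z, params$Uz) +
      tcrossprod(da_r, params$Ur) + tmp * r
    g$Wz <- g$Wz + crossprod(Xt, da_z); g$Uz <- g$Uz + crossprod(hprev, da_z)
    g$bz <- g$bz + colSums(da_z)
    g$Wr <- g$Wr + crossprod(Xt, da_r); g$Ur <- g$Ur + crossprod(hprev, da_r)
    g$br <- g$br + colSums(da_r)
    g$Wc <- g$Wc + crossprod(Xt, da_c)
    g$Uc <- g$Uc + crossprod(r * hprev, da_c)
    g$bc <- g$bc + colSums(da_c)
    dAc[((t - 1) * B + 1):(t * B), ] <- tcrossprod(da_z, params$Wz) +
      tcrossprod(da_r, params$Wr) + tcrossprod(da_c, params$Wc)
  }
  if (!is.null(fw$masks$conv)) dAc <- dAc * fw$masks$conv
  dZc <- dAc * (fw$Zc > 0)
  g$Wconv <- crossprod(fw$M, dZc); g$bconv <- colSums(dZc)
  g
}

#' Fit the CNN -> GRU SMILES classifier
#'
#' End-to-end sequence model over one-hot SMILES grids: see
#' [cnn_gru_default_hp()] for the architecture. Elements of `hp` override
#' the defaults.
#'
#' @param X A `smiles_tensor` (or plain `n x max_len x dim` array).
#' @param y 0/1 labels.
#' @param hp Named list of hyperparameter overrides.
#' @param seed Integer seed.
#' @return A `cnn_gru_model`.
#' @export
cnn_gru_fit <- function(X, y, hp = list(), seed = 1) {
  hp <- utils::modifyList(cnn_gru_default_hp(), hp)
  X <- unclass(X); y <- as.numeric(y)
  n <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  T_ <- L - hp$filter_width + 1
  with_seed(seed, {
    params <- .cnn_gru_init(D, hp)
    params$W1 <- .glorot(T_ * hp$gru_units, hp$dense_units)
    params$b1 <- rep(0, hp$dense_units)
    params$W2 <- .glorot(hp$dense_units, 1)
    params$b2 <- 0
    st <- .adam_new(params)
    for (ep in seq_len(hp$epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = hp$batch_size)) {
        rows <- ord[start:min(start + hp$batch_size - 1, n)]
        fw <- .cnn_gru_forward(params, X[rows, , , drop = FALSE], hp,
                               train = TRUE)
        g <- .cnn_gru_backward(params, fw, y[rows], hp)
        upd <- .adam_step(params, g, st, hp$lr)
        params <- upd$params; st <- upd$state
      }
    }
    structure(list(params = params, hp = hp, max_len = L, input_dim = D,
                   seed = seed),
              class = "cnn_gru_model")
  })
}

#' Predict probabilities from a `cnn_gru_model`
#' @param object A `cnn_gru_model`.
#' @param X A `smiles_tensor` / array.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`.
#' @export
predict.cnn_gru_model <- function(object, X, batch_size = 512, ...) {
  X <- unclass(X); n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1, n)
    fw <- .cnn_gru_forward(object$params, X[rows, , , drop = FALSE],
                           object$hp, train = FALSE)
    out[rows] <- fw$p
  }
  out
}

#' Layer-by-layer introspection of a sequence model
#'
#' Output shapes and parameter counts are derived from the fitted (or
#' freshly initialized) weight arrays themselves, not recomputed from the
#' hyperparameters, so the summary reflects what the backend actually built.
#' With the default geometry over a 100 x 10 grid: convolution output length
#' 100 - 17 + 1 = 84, convolution parameters 10*17*384 + 384 = 65,664, and
#' flattened GRU output 84 * 9 = 756.
#'
#' @param model A `cnn_gru_model`, or `NULL` to introspect a freshly
#'   initialized default model.
#' @param max_len,input_dim Grid geometry used when `model` is `NULL`.
#' @param hp Hyperparameter overrides when `model` is `NULL`.
#' @return A data.frame with columns `layer`, `output_shape`, `n_params`.
#' @export
cnn_gru_architecture <- function(model = NULL, max_len = 100, input_dim = 10,
                                 hp = list()) {
  if (is.null(model)) {
    hp <- utils::modifyList(cnn_gru_default_hp(), hp)
    T_ <- max_len - hp$filter_width + 1
    model <- with_seed(1, {
      params <- .cnn_gru_init(input_dim, hp)
      params$W1 <- .glorot(T_ * hp$gru_units, hp$dense_units)
      params$b1 <- rep(0, hp$dense_units)
      params$W2 <- .glorot(hp$dense_units, 1); params$b2 <- 0
      list(params = params, hp = hp, max_len = max_len, input_dim = input_dim)
    })
  }
  p <- model$params; hp <- model$hp
  W <- nrow(p$Wconv) / model$input_dim           # filter width from weights
  F_ <- ncol(p$Wconv)
  T_ <- model$max_len - W + 1
  H <- ncol(p$Wz)
  gru_params <- 3 * (nrow(p$Wz) * H + H * H + H)
  data.frame(
    layer = c("input", "conv1d_relu", "gru_tanh", "flatten", "dense_relu",
              "dense_sigmoid"),
    output_shape = c(sprintf("%d x %d", model$max_len, model$input_dim),
                     sprintf("%d x %d", T_, F_),
                     sprintf("%d x %d", T_, H),
                     sprintf("%d", T_ * H),
                     sprintf("%d", ncol(p$W1)),
                     "1"),
    n_params = c(0L,
                 length(p$Wconv) + length(p$bconv),
                 as.integer(gru_params),
                 0L,
                 length(p$W1) + length(p$b1),
                 length(p$W2) + length(p$b2)),
    stringsAsFactors = FALSE)
}
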