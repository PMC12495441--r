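#' Network architecture configuration
#'
#' The affinity network is a vanilla transformer encoder-decoder: the protein
#' embedding (tokens x `protein_width`) passes through a 1D convolution that
#' projects it to `d_model` and then through `encoder_layers` encoder layers;
#' the ligand embedding (tokens x `d_model`) feeds `decoder_layers` decoder
#' layers that condition on the encoder output through encoder-decoder
#' attention. Decoder output is max-pooled over tokens and a dense layer
#' emits one real value per task (pKi, pIC50). Splitting the two sequences
#' between encoder and decoder keeps the attention cost at
#' `len_p^2 + len_m^2 + len_m*len_p` score entries instead of
#' `(len_p + len_m)^2` for a concatenated single stack.
#'
#' @param d_model Model (and ligand embedding) width; 512 matches the ligand
#'   encoder contract.
#' @param protein_width Protein embedding width; 640 matches the protein
#'   encoder contract.
#' @param encoder_layers,decoder_layers Stack depths (reference model: 1 / 6).
#' @param attention_heads Heads per attention block.
#' @param feedforward_width Inner width of the position-wise feed-forward.
#' @param dropout Dropout rate applied to each sublayer output in training.
#' @param conv_kernel Odd kernel size of the width-projecting convolution;
#'   1 = pure per-token projection.
#' @param activation Feed-forward activation (`"relu"`).
#' @param tasks Ordered output task names.
#' @return List of class `dta_network_config`.
#' @export
dta_network_config <- function(d_model = 512L, protein_width = 640L,
                               encoder_layers = 1L, decoder_layers = 6L,
                               attention_heads = 8L,
                               feedforward_width = 2048L, dropout = 0.1,
                               conv_kernel = 1L, activation = "relu",
                               tasks = c("pKi", "pIC50")) {
  stopifnot(d_model > 0, protein_width > 0, encoder_layers >= 1,
            decoder_layers >= 1, d_model %% attention_heads == 0,
            conv_kernel %% 2 == 1, dropout >= 0, dropout < 1,
            length(tasks) >= 1)
  if (activation != "relu") rlang::abort("only ReLU activation is implemented")
  structure(list(d_model = as.integer(d_model),
                 protein_width = as.integer(protein_width),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = as.integer(decoder_layers),
                 attention_heads = as.integer(attention_heads),
                 feedforward_width = as.integer(feedforward_width),
                 dropout = dropout, conv_kernel = as.integer(conv_kernel),
                 activation = activation, tasks = tasks),
            class = "dta_network_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: RAdam, learning rate 1e-4,
#' batch size 64, up to 60 epochs with early stopping on validation loss.
#'
#' @param learning_rate RAdam step size.
#' @param batch_size Examples per gradient step.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (0 = stop after the
#'   first epoch).
#' @param seed Training seed (initialization, shuffling, dropout).
#' @param use_sample_weights Whether curation weights enter the loss.
#' @return List of class `dta_train_config`.
#' @export
dta_train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                             max_epochs = 60L, patience = 5L, seed = 1L,
                             use_sample_weights = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 use_sample_weights = use_sample_weights),
            class = "dta_train_config")
}

# ---- parameter construction -------------------------------------------------

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.attn_params <- function(prefix, d) {
  p <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(prefix, ".", nm)]] <- .glorot(d, d)
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(prefix, ".", nm)]] <- numeric(d)
  p
}

.ln_params <- function(prefix, d) {
  stats::setNames(list(rep(1, d), numeric(d)),
                  paste0(prefix, c(".g", ".b")))
}

.ff_params <- function(prefix, d, dff) {
  stats::setNames(list(.glorot(d, dff), numeric(dff), .glorot(dff, d),
                       numeric(d)),
                  paste0(prefix, c(".W1", ".b1", ".W2", ".b2")))
}

#' Build an untrained affinity network
#'
#' Allocates Glorot-initialized parameters for the configured architecture.
#'
#' @param config A [dta_network_config()].
#' @param seed Initialization seed.
#' @return List of class `dta_network` with elements `config` and `params`
#'   (flat named list of matrices/vectors).
#' @export
build_network <- function(config = dta_network_config(), seed = 1L) {
  stopifnot(inherits(config, "dta_network_config"))
  d <- config$d_model; dff <- config$feedforward_width
  params <- withr::with_seed(seed, {
    p <- list()
    for (j in seq_len(config$conv_kernel)) {
      p[[paste0("conv.W", j)]] <- .glorot(config$protein_width, d)
    }
    p[["conv.b"]] <- numeric(d)
    for (l in seq_len(config$encoder_layers)) {
      pre <- paste0("enc", l)
      p <- c(p, .attn_params(paste0(pre, ".att"), d),
             .ln_params(paste0(pre, ".ln1"), d),
             .ff_params(paste0(pre, ".ff"), d, dff),
             .ln_params(paste0(pre, ".ln2"), d))
    }
    for (l in seq_len(config$decoder_layers)) {
      pre <- paste0("dec", l)
      p <- c(p, .attn_params(paste0(pre, ".self"), d),
             .ln_params(paste0(pre, ".ln1"), d),
             .attn_params(paste0(pre, ".cross"), d),
             .ln_params(paste0(pre, ".ln2"), d),
             .ff_params(paste0(pre, ".ff"), d, dff),
             .ln_params(paste0(pre, ".ln3"), d))
    }
    p[["head.W"]] <- .glorot(d, length(config$tasks))
    p[["head.b"]] <- numeric(length(config$tasks))
    p
  })
  structure(list(config = config, params = params), class = "dta_network")
}

#' Attention score entries per forward pass
#'
#' Token-count accounting of the attention cost: encoder self-attention
#' scores `len_p^2` entries per encoder layer, decoder self-attention
#' `len_m^2` and encoder-decoder attention `len_m * len_p` per decoder
#' layer. The total stays below the `(len_p + len_m)^2` per-layer cost of a
#' concatenated encoder-only design whenever both sequences are non-trivial.
#'
#' @param config A [dta_network_config()].
#' @param len_m,len_p Ligand and protein token counts.
#' @return Named vector of score-entry counts.
#' @export
attention_entry_count <- function(config, len_m, len_p) {
  c(encoder_self = config$encoder_layers * len_p^2,
    decoder_self = config$decoder_layers * len_m^2,
    cross = config$decoder_layers * len_m * len_p)
}

# ---- primitives (forward + backward) ---------------------------------------

.posenc <- function(len, d) {
  pos <- seq_len(len) - 1
  i <- seq_len(d)
  freq <- 10000^(-(2 * ((i - 1) %/% 2)) / d)
  ang <- outer(pos, freq)
  pe <- ang
  odd <- seq(1, d, by = 2)
  pe[, odd] <- sin(ang[, odd, drop = FALSE])
  if (d > 1) {
    even <- seq(2, d, by = 2)
    pe[, even] <- cos(ang[, even, drop = FALSE])
  }
  pe
}

.linear_f <- function(x, W, b) list(out = x %*% W + rep(b, each = nrow(x)),
                                    x = x)
.linear_b <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

.ln_f <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv, g = g)
}
.ln_b <- function(dy, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2, cache$g, "*")
  dx <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dg, db = db)
}

.drop_f <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) > p) / (1 - p), nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}
.drop_b <- function(dy, cache) if (is.null(cache$mask)) dy else dy * cache$mask

.mha_f <- function(xq, xkv, p, pre, H) {
  d <- ncol(xq); dk <- d %/% H; s <- 1 / sqrt(dk)
  g <- function(nm) p[[paste0(pre, ".", nm)]]
  Q <- xq %*% g("Wq") + rep(g("bq"), each = nrow(xq))
  K <- xkv %*% g("Wk") + rep(g("bk"), each = nrow(xkv))
  V <- xkv %*% g("Wv") + rep(g("bv"), each = nrow(xkv))
  O <- matrix(0, nrow(xq), d)
  A <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * s
    S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
    E <- exp(S)
    A[[h]] <- E / rowSums(E)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% g("Wo") + rep(g("bo"), each = nrow(xq))
  list(out = out, xq = xq, xkv = xkv, Q = Q, K = K, V = V, A = A, O = O,
       s = s, H = H, dk = dk)
}

.mha_b <- function(dy, cache, p, pre) {
  g <- function(nm) p[[paste0(pre, ".", nm)]]
  H <- cache$H; dk <- cache$dk; s <- cache$s
  grads <- list()
  grads[[paste0(pre, ".Wo")]] <- crossprod(cache$O, dy)
  grads[[paste0(pre, ".bo")]] <- colSums(dy)
  dO <- dy %*% t(g("Wo"))
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] * s
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) * s
  }
  grads[[paste0(pre, ".Wq")]] <- crossprod(cache$xq, dQ)
  grads[[paste0(pre, ".bq")]] <- colSums(dQ)
  grads[[paste0(pre, ".Wk")]] <- crossprod(cache$xkv, dK)
  grads[[paste0(pre, ".bk")]] <- colSums(dK)
  grads[[paste0(pre, ".Wv")]] <- crossprod(cache$xkv, dV)
  grads[[paste0(pre, ".bv")]] <- colSums(dV)
  list(dxq = dQ %*% t(g("Wq")),
       dxkv = dK %*% t(g("Wk")) + dV %*% t(g("Wv")),
       grads = grads)
}

.ff_f <- function(x, p, pre) {
  g <- function(nm) p[[paste0(pre, ".", nm)]]
  z <- x %*% g("W1") + rep(g("b1"), each = nrow(x))
  h <- pmax(z, 0)
  out <- h %*% g("W2") + rep(g("b2"), each = nrow(x))
  list(out = out, x = x, z = z, h = h)
}
.ff_b <- function(dy, cache, p, pre) {
  g <- function(nm) p[[paste0(pre, ".", nm)]]
  grads <- list()
  grads[[paste0(pre, ".W2")]] <- crossprod(cache$h, dy)
  grads[[paste0(pre, ".b2")]] <- colSums(dy)
  dh <- dy %*% t(g("W2"))
  dz <- dh * (cache$z > 0)
  grads[[paste0(pre, ".W1")]] <- crossprod(cache$x, dz)
  grads[[paste0(pre, ".b1")]] <- colSums(dz)
  list(dx = dz %*% t(g("W1")), grads = grads)
}

.conv_f <- function(x, p, k) {
  n <- nrow(x); d <- ncol(p[["conv.W1"]])
  half <- (k - 1L) %/% 2L
  out <- matrix(rep(p[["conv.b"]], each = n), n, d)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    out[ok, ] <- out[ok, , drop = FALSE] +
      x[src[ok], , drop = FALSE] %*% p[[paste0("conv.W", j)]]
  }
  list(out = out, x = x, k = k)
}
.conv_b <- function(dy, cache, p) {
  x <- cache$x; k <- cache$k; n <- nrow(x)
  half <- (k - 1L) %/% 2L
  grads <- list(conv.b = colSums(dy))
  dx <- matrix(0, n, ncol(x))
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    if (!any(ok)) {
      grads[[paste0("conv.W", j)]] <- matrix(0, ncol(x), ncol(dy))
      next
    }
    grads[[paste0("conv.W", j)]] <-
      crossprod(x[src[ok], , drop = FALSE], dy[ok, , drop = FALSE])
    dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
      dy[ok, , drop = FALSE] %*% t(p[[paste0("conv.W", j)]])
  }
  list(dx = dx, grads = grads)
}

# ---- full forward / backward -----------------------------------------------

.sublayer_f <- function(x, sub_out, ln_pre, p, dropout, training) {
  dr <- .drop_f(sub_out$out, dropout, training)
  ln <- .ln_f(x + dr$out, p[[paste0(ln_pre, ".g")]], p[[paste0(ln_pre, ".b")]])
  list(out = ln$out, dr = dr, ln = ln)
}

.forward_example <- function(params, config, Xm, Xp, training = FALSE) {
  d <- config$d_model; H <- config$attention_heads
  drp <- config$dropout
  if (ncol(Xm) != d) {
    rlang::abort(sprintf(
      "ligand embedding width %d does not match d_model %d", ncol(Xm), d))
  }
  if (ncol(Xp) != config$protein_width) {
    rlang::abort(sprintf(
      "protein embedding width %d does not match configured width %d",
      ncol(Xp), config$protein_width))
  }
  cache <- list()

  conv <- .conv_f(Xp, params, config$conv_kernel)
  x <- conv$out + .posenc(nrow(Xp), d)
  cache$conv <- conv
  cache$enc <- vector("list", config$encoder_layers)
  for (l in seq_len(config$encoder_layers)) {
    pre <- paste0("enc", l)
    att <- .mha_f(x, x, params, paste0(pre, ".att"), H)
    s1 <- .sublayer_f(x, att, paste0(pre, ".ln1"), params, drp, training)
    ff <- .ff_f(s1$out, params, paste0(pre, ".ff"))
    s2 <- .sublayer_f(s1$out, ff, paste0(pre, ".ln2"), params, drp, training)
    cache$enc[[l]] <- list(att = att, s1 = s1, ff = ff, s2 = s2)
    x <- s2$out
  }
  enc_out <- x

  x <- Xm + .posenc(nrow(Xm), d)
  cache$dec <- vector("list", config$decoder_layers)
  for (l in seq_len(config$decoder_layers)) {
    pre <- paste0("dec", l)
    self <- .mha_f(x, x, params, paste0(pre, ".self"), H)
    s1 <- .sublayer_f(x, self, paste0(pre, ".ln1"), params, drp, training)
    cross <- .mha_f(s1$out, enc_out, params, paste0(pre, ".cross"), H)
    s2 <- .sublayer_f(s1$out, cross, paste0(pre, ".ln2"), params, drp, training)
    ff <- .ff_f(s2$out, params, paste0(pre, ".ff"))
    s3 <- .sublayer_f(s2$out, ff, paste0(pre, ".ln3"), params, drp, training)
    cache$dec[[l]] <- list(self = self, s1 = s1, cross = cross, s2 = s2,
                           ff = ff, s3 = s3)
    x <- s3$out
  }
  argmax <- max.col(t(x), ties.method = "first")
  pooled <- x[cbind(argmax, seq_len(ncol(x)))]
  out <- drop(pooled %*% params[["head.W"]]) + params[["head.b"]]
  cache$pool <- list(argmax = argmax, n = nrow(x), pooled = pooled)
  cache$enc_out <- enc_out
  list(out = out, cache = cache)
}

.sublayer_b <- function(dy, x_in, sub, acc_grads, ln_pre) {
  ln <- .ln_b(dy, sub$ln)
  acc_grads[[paste0(ln_pre, ".g")]] <- ln$dg
  acc_grads[[paste0(ln_pre, ".b")]] <- ln$db
  dsub <- .drop_b(ln$dx, sub$dr)
  list(dx_res = ln$dx, dsub = dsub, grads = acc_grads)
}

.backward_example <- function(params, config, fw, dout) {
  cache <- fw$cache
  H <- config$attention_heads
  grads <- list()
  add <- function(g) for (nm in names(g)) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
  }

  pool <- cache$pool
  add(list(head.W = tcrossprod(pool$pooled, dout)[, , drop = FALSE],
           head.b = dout))
  dpooled <- params[["head.W"]] %*% dout
  dx <- matrix(0, pool$n, config$d_model)
  dx[cbind(pool$argmax, seq_along(pool$argmax))] <- dpooled

  denc_out <- matrix(0, nrow(cache$enc_out), config$d_model)
  for (l in rev(seq_len(config$decoder_layers))) {
    pre <- paste0("dec", l)
    cl <- cache$dec[[l]]
    b3 <- .sublayer_b(dx, NULL, cl$s3, list(), paste0(pre, ".ln3"))
    add(b3$grads)
    ffb <- .ff_b(b3$dsub, cl$ff, params, paste0(pre, ".ff"))
    add(ffb$grads)
    dx <- b3$dx_res + ffb$dx
    b2 <- .sublayer_b(dx, NULL, cl$s2, list(), paste0(pre, ".ln2"))
    add(b2$grads)
    crb <- .mha_b(b2$dsub, cl$cross, params, paste0(pre, ".cross"))
    add(crb$grads)
    denc_out <- denc_out + crb$dxkv
    dx <- b2$dx_res + crb$dxq
    b1 <- .sublayer_b(dx, NULL, cl$s1, list(), paste0(pre, ".ln1"))
    add(b1$grads)
    sfb <- .mha_b(b1$dsub, cl$self, params, paste0(pre, ".self"))
    add(sfb$grads)
    dx <- b1$dx_res + sfb$dxq + sfb$dxkv
  }
  # dx is now the gradient w.r.t. the decoder input (ligand embedding + PE);
  # the ligand encoder is frozen, so it is discarded.

  dx <- denc_out
  for (l in rev(seq_len(config$encoder_layers))) {
    pre <- paste0("enc", l)
    cl <- cache$enc[[l]]
    b2 <- .sublayer_b(dx, NULL, cl$s2, list(), paste0(pre, ".ln2"))
    add(b2$grads)
    ffb <- .ff_b(b2$dsub, cl$ff, params, paste0(pre, ".ff"))
    add(ffb$grads)
    dx <- b2$dx_res + ffb$dx
    b1 <- .sublayer_b(dx, NULL, cl$s1, list(), paste0(pre, ".ln1"))
    add(b1$grads)
    atb <- .mha_b(b1$dsub, cl$att, params, paste0(pre, ".att"))
    add(atb$grads)
    dx <- b1$dx_res + atb$dxq + atb$dxkv
  }
  cvb <- .conv_b(dx, cache$conv, params)
  add(cvb$grads)
  grads
}

#' Masked weighted multitask loss
#'
#' Weighted squared error over the (example, task) cells whose target is
#' present, normalized by the total weight of those cells:
#' `sum(w * (pred - target)^2) / sum(w)`. Missing cells contribute zero loss
#' and zero gradient, so training one task never perturbs parameters
#' exclusive to a task with no labels in the batch. With all targets present
#' and unit weights this is the ordinary mean squared error.
#'
#' @param predictions,targets Numeric `batch x tasks` matrices; `NA` targets
#'   mark missing cells.
#' @param weights Positive per-example weights (recycled across tasks).
#' @param gradient If `TRUE`, also return `d loss / d predictions`.
#' @return The scalar loss, or (with `gradient`) a list `loss`, `grad`.
#' @export
masked_weighted_loss <- function(predictions, targets,
                                 weights = rep(1, nrow(predictions)),
                                 gradient = FALSE) {
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  stopifnot(all(dim(predictions) == dim(targets)),
            length(weights) == nrow(predictions))
  if (any(weights <= 0)) rlang::abort("weights must be positive")
  present <- !is.na(targets)
  if (!any(present)) rlang::abort("all target cells are missing")
  W <- matrix(weights, nrow(targets), ncol(targets))
  err <- predictions - targets
  err[!present] <- 0
  wtot <- sum(W[present])
  loss <- sum(W[present] * err[present]^2) / wtot
  if (!gradient) return(loss)
  grad <- 2 * W * err / wtot
  grad[!present] <- 0
  list(loss = loss, grad = grad)
}

# Loss and accumulated gradients over a batch of embedded examples.
# batch: list of list(Xm=, Xp=); targets: n x tasks matrix; weights: n.
.batch_grads <- function(params, config, batch, targets, weights,
                         training = TRUE, compute_grads = TRUE) {
  n <- length(batch)
  preds <- matrix(NA_real_, n, length(config$tasks))
  fws <- vector("list", n)
  for (i in seq_len(n)) {
    fws[[i]] <- .forward_example(params, config, batch[[i]]$Xm, batch[[i]]$Xp,
                                 training = training)
    preds[i, ] <- fws[[i]]$out
  }
  lg <- masked_weighted_loss(preds, targets, weights, gradient = TRUE)
  if (!compute_grads) {
    return(list(loss = lg$loss, grads = NULL, predictions = preds))
  }
  grads <- NULL
  for (i in seq_len(n)) {
    if (all(lg$grad[i, ] == 0)) next
    g <- .backward_example(params, config, fws[[i]], lg$grad[i, ])
    if (is.null(grads)) grads <- g
    else for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
  }
  if (is.null(grads)) {
    grads <- lapply(params, function(x) x * 0)
  } else {
    for (nm in setdiff(names(params), names(grads))) {
      grads[[nm]] <- params[[nm]] * 0
    }
  }
  list(loss = lg$loss, grads = grads, predictions = preds)
}

#' @keywords internal
network_loss_grads <- function(net, batch, targets, weights = NULL,
                               training = FALSE) {
  if (is.null(weights)) weights <- rep(1, length(batch))
  .batch_grads(net$params, net$config, batch, as.matrix(targets), weights,
               training = training)
}

# ---- RAdam ------------------------------------------------------------------

.radam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

.radam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rho_inf <- 2 / (1 - beta2) - 1
  b2t <- beta2^t
  rho_t <- rho_inf - 2 * t * b2t / (1 - b2t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    if (rho_t > 4) {
      vhat <- sqrt(state$v[[nm]] / (1 - b2t))
      r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                  ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      params[[nm]] <- params[[nm]] - lr * r * mhat / (vhat + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * mhat
    }
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

# Embed all unique strings of a pair table once (through the shared cache).
.embed_pairs <- function(pairs, ligand_provider, protein_provider, cache) {
  lig <- lapply(stats::setNames(nm = unique(pairs$canonical_smiles)),
                function(s) embed_ligand(ligand_provider, s, cache)$values)
  pro <- lapply(stats::setNames(nm = unique(pairs$protein_sequence)),
                function(s) embed_protein(protein_provider, s, cache)$values)
  lapply(seq_len(nrow(pairs)), function(i) {
    list(Xm = lig[[pairs$canonical_smiles[i]]],
         Xp = pro[[pairs$protein_sequence[i]]])
  })
}

.targets_matrix <- function(pairs, tasks) {
  cols <- c(pKi = "p_ki", pIC50 = "p_ic50")[tasks]
  out <- vapply(cols, function(cn) {
    if (cn %in% names(pairs)) as.numeric(pairs[[cn]]) else
      rep(NA_real_, nrow(pairs))
  }, numeric(nrow(pairs)))
  matrix(out, nrow = nrow(pairs), dimnames = list(NULL, tasks))
}

#' Train one cross-validation submodel
#'
#' Optimizes the masked weighted loss with RAdam over minibatches; after each
#' epoch the loss on the validation subset (no dropout) is evaluated, the
#' best-validation parameters are retained, and training stops when the
#' validation loss has not improved for `patience` epochs or at `max_epochs`.
#'
#' @param fold List with `train` and `validation` pair tibbles (from
#'   [kfold()]); pairs carry `protein_sequence`, `canonical_smiles`,
#'   `p_ki`/`p_ic50` targets and optionally `weight`.
#' @param net_config A [dta_network_config()].
#' @param train_config A [dta_train_config()].
#' @param ligand_provider,protein_provider Embedding providers.
#' @param cache Optional shared [embedding_cache()].
#' @return List of class `dta_submodel`: `network` (best parameters),
#'   `manifest` (tibble: epoch, train_loss, val_loss), `best_epoch`,
#'   `best_val_loss`, `seed`.
#' @export
train_fold <- function(fold, net_config = dta_network_config(),
                       train_config = dta_train_config(),
                       ligand_provider, protein_provider, cache = NULL) {
  tr <- tibble::as_tibble(fold$train); va <- tibble::as_tibble(fold$validation)
  if (is.null(cache)) cache <- embedding_cache()
  batch_tr <- .embed_pairs(tr, ligand_provider, protein_provider, cache)
  batch_va <- .embed_pairs(va, ligand_provider, protein_provider, cache)
  y_tr <- .targets_matrix(tr, net_config$tasks)
  y_va <- .targets_matrix(va, net_config$tasks)
  w_tr <- if (train_config$use_sample_weights && "weight" %in% names(tr)) {
    tr$weight
  } else rep(1, nrow(tr))
  w_va <- if (train_config$use_sample_weights && "weight" %in% names(va)) {
    va$weight
  } else rep(1, nrow(va))

  net <- build_network(net_config, seed = train_config$seed)
  params <- net$params
  state <- .radam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  manifest <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                             val_loss = numeric())
  wait <- 0L
  withr::with_seed(train_config$seed + 1L, {
    for (epoch in seq_len(train_config$max_epochs)) {
      ord <- sample.int(nrow(tr))
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, length(ord), by = train_config$batch_size)) {
        idx <- ord[start:min(start + train_config$batch_size - 1L, length(ord))]
        bg <- .batch_grads(params, net_config, batch_tr[idx],
                           y_tr[idx, , drop = FALSE], w_tr[idx],
                           training = TRUE)
        if (!is.finite(bg$loss)) {
          rlang::abort(sprintf("training diverged at epoch %d (loss %g)",
                               epoch, bg$loss))
        }
        upd <- .radam_step(params, bg$grads, state, train_config$learning_rate)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bg$loss * length(idx); ep_n <- ep_n + length(idx)
      }
      val <- .batch_grads(params, net_config, batch_va, y_va, w_va,
                          training = FALSE, compute_grads = FALSE)$loss
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val))
      if (val < best$val) {
        best <- list(params = params, val = val, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (wait >= train_config$patience) break
    }
  })
  structure(list(
    network = structure(list(config = net_config, params = best$params),
                        class = "dta_network"),
    manifest = manifest, best_epoch = best$epoch, best_val_loss = best$val,
    seed = train_config$seed
  ), class = "dta_submodel")
}

#' Train a K-fold ensemble
#'
#' Splits the training pairs into K classical cross-validation folds and
#' trains one submodel per fold with identical architecture and training
#' parameters (each fold gets its own derived seed). At inference the
#' per-task outputs of all submodels are averaged.
#'
#' @param pairs Training-pair tibble.
#' @param k Number of folds/submodels.
#' @inheritParams train_fold
#' @return List of class `dta_ensemble`: `submodels`, `config`, `k`, `seed`.
#' @export
train_ensemble <- function(pairs, k = 4, net_config = dta_network_config(),
                           train_config = dta_train_config(),
                           ligand_provider, protein_provider, cache = NULL) {
  if (is.null(cache)) cache <- embedding_cache()
  folds <- kfold(pairs, k = k, seed = train_config$seed)
  submodels <- lapply(seq_len(k), function(f) {
    tc <- train_config
    tc$seed <- train_config$seed + 1000L * f
    train_fold(folds[[f]], net_config, tc, ligand_provider, protein_provider,
               cache)
  })
  structure(list(submodels = submodels, config = net_config, k = k,
                 seed = train_config$seed),
            class = "dta_ensemble")
}

#' Predict affinities with a trained ensemble
#'
#' Runs every submodel on each (ligand embedding, protein embedding) pair and
#' averages the per-task outputs arithmetically.
#'
#' @param ensemble A [train_ensemble()] result.
#' @param pairs Tibble with `protein_sequence` and `canonical_smiles`.
#' @inheritParams train_fold
#' @return Tibble: `protein_sequence`, `canonical_smiles`, `pKi_pred`,
#'   `pIC50_pred` (columns follow the configured tasks).
#' @export
predict_ensemble <- function(ensemble, pairs, ligand_provider,
                             protein_provider, cache = NULL) {
  stopifnot(inherits(ensemble, "dta_ensemble"))
  if (!length(ensemble$submodels)) rlang::abort("ensemble has no submodels")
  pairs <- tibble::as_tibble(pairs)
  if (is.null(cache)) cache <- embedding_cache()
  batch <- .embed_pairs(pairs, ligand_provider, protein_provider, cache)
  tasks <- ensemble$config$tasks
  acc <- matrix(0, nrow(pairs), length(tasks))
  for (sm in ensemble$submodels) {
    for (i in seq_along(batch)) {
      acc[i, ] <- acc[i, ] + .forward_example(sm$network$params,
                                              ensemble$config,
                                              batch[[i]]$Xm, batch[[i]]$Xp)$out
    }
  }
  acc <- acc / length(ensemble$submodels)
  out <- tibble::tibble(protein_sequence = pairs$protein_sequence,
                        canonical_smiles = pairs$canonical_smiles)
  for (j in seq_along(tasks)) out[[paste0(tasks[j], "_pred")]] <- acc[, j]
  out
}
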