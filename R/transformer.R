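# From-scratch transformer encoder over SMILES tokens. The exported
# operations mirror the classic formulation: scaled dot-product attention,
# multi-head attention (concatenated heads times an output projection) and
# the pre-LayerNorm residual block
#   z_l = x_{l-1} + MHA(LayerNorm(x_{l-1}));  x_l = z_l + MLP(LayerNorm(z_l)).
# Training (backpropagation + Adam) lives in train.R.

.LN_EPS <- 1e-5

.softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`, computed row-wise:
#' each output row is a convex combination of the rows of `V`.
#'
#' @param Q queries matrix (n_q x d_k).
#' @param K keys matrix (n_kv x d_k).
#' @param V values matrix (n_kv x d_v).
#' @param mask optional logical vector of length `n_kv`; positions with
#'   `FALSE` (e.g. padding) are excluded from the softmax.
#' @return context matrix (n_q x d_v).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop(sprintf("query width %d != key width %d", ncol(Q), ncol(K)))
  }
  if (nrow(K) != nrow(V)) {
    stop(sprintf("key rows %d != value rows %d", nrow(K), nrow(V)))
  }
  S <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(K))
    if (!any(mask)) stop("attention mask excludes every key")
    S[, !mask] <- -Inf
  }
  .softmax_rows(S) %*% V
}

#' Multi-head self-attention
#'
#' `MultiHead(X) = Concat(head_1, ..., head_n) W_o` with
#' `head_i = Attention(X W_i^Q, X W_i^K, X W_i^V)`. Projections are stored
#' stacked: `Wq`, `Wk`, `Wv` are `d_model x d_model` with head `i` occupying
#' columns `((i-1)*d_k+1):(i*d_k)`.
#'
#' @param X token-state matrix (L x d_model).
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (each d_model x d_model)
#'   and optional bias vectors `bq`, `bk`, `bv`, `bo`.
#' @param n_heads number of attention heads.
#' @param mask optional logical key mask of length L.
#' @return token-state matrix (L x d_model).
#' @export
multi_head_attention <- function(X, params, n_heads = 1L, mask = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d %% n_heads != 0L) {
    stop(sprintf("d_model %d not divisible by n_heads %d", d, n_heads))
  }
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    if (!all(dim(params[[w]]) == c(d, d))) {
      stop(sprintf("%s must be %d x %d", w, d, d))
    }
  }
  zero <- rep(0, d)
  bq <- params$bq %||% zero; bk <- params$bk %||% zero
  bv <- params$bv %||% zero; bo <- params$bo %||% zero
  Q <- sweep(X %*% params$Wq, 2L, bq, "+")
  K <- sweep(X %*% params$Wk, 2L, bk, "+")
  V <- sweep(X %*% params$Wv, 2L, bv, "+")
  dk <- d %/% n_heads
  C <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    C[, idx] <- scaled_dot_attention(Q[, idx, drop = FALSE],
                                     K[, idx, drop = FALSE],
                                     V[, idx, drop = FALSE], mask = mask)
  }
  sweep(C %*% params$Wo, 2L, bo, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.layer_norm <- function(X, g, b) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(xc^2) + .LN_EPS)
  xhat <- xc * inv_sd
  list(Y = sweep(xhat * rep(1, nrow(X)) %o% g, 2L, b, "+"),
       xhat = xhat, inv_sd = inv_sd)
}

.layer_norm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

#' One pre-LayerNorm transformer encoder block
#'
#' Applies `z = x + MHA(LayerNorm(x))` followed by
#' `x' = z + MLP(LayerNorm(z))`; normalization precedes each sublayer and the
#' two additions are plain residuals, so a block with zeroed sublayer weights
#' is the identity map. The MLP is `ReLU(h W1 + b1) W2 + b2`.
#'
#' @param x token-state matrix (L x d_model).
#' @param params list with layer-norm gains/offsets `ln1_g`, `ln1_b`,
#'   `ln2_g`, `ln2_b`, attention projections (`Wq`, `Wk`, `Wv`, `Wo` plus
#'   biases), and MLP weights `W1`, `b1`, `W2`, `b2`.
#' @param n_heads number of attention heads.
#' @param mask optional logical key mask.
#' @return token-state matrix of the same shape.
#' @export
transformer_block <- function(x, params, n_heads = 1L, mask = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite input to transformer_block")
  h <- .layer_norm(x, params$ln1_g, params$ln1_b)$Y
  z <- x + multi_head_attention(h, params, n_heads = n_heads, mask = mask)
  h2 <- .layer_norm(z, params$ln2_g, params$ln2_b)$Y
  a <- sweep(h2 %*% params$W1, 2L, params$b1, "+")
  m <- sweep(pmax(a, 0) %*% params$W2, 2L, params$b2, "+")
  z + m
}

#' Transformer model configuration
#'
#' @param d_model embedding / state width (default 64).
#' @param n_heads number of attention heads (default 2); `d_k = d_model /
#'   n_heads`.
#' @param n_layers number of encoder blocks (default 2).
#' @param d_mlp feed-forward hidden width (default 128).
#' @param max_len sequence positions including the summary token (default 128).
#' @param dropout dropout rate applied to embeddings and each sublayer output
#'   during training (default 0.1).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed governing initialization and batch order.
#' @return list of class `withdrawr_config`.
#' @export
model_config <- function(d_model = 64L, n_heads = 2L, n_layers = 2L,
                         d_mlp = 128L, max_len = 128L, dropout = 0.1,
                         lr = 1e-3, epochs = 30L, batch_size = 32L,
                         seed = 1L) {
  stopifnot(d_model >= 1L, n_heads >= 1L, n_layers >= 1L, d_mlp >= 1L,
            max_len >= 2L, dropout >= 0, dropout < 1, lr > 0,
            epochs >= 1L, batch_size >= 1L)
  if (d_model %% n_heads != 0L) {
    stop("d_model must equal n_heads * d_k for an integer d_k")
  }
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model %/% n_heads),
                 n_layers = as.integer(n_layers), d_mlp = as.integer(d_mlp),
                 max_len = as.integer(max_len), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "withdrawr_config")
}

.init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.init_transformer_params <- function(vocab_size, cfg) {
  d <- cfg$d_model
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(ln1_g = rep(1, d), ln1_b = rep(0, d),
         Wq = .init_mat(d, d), Wk = .init_mat(d, d), Wv = .init_mat(d, d),
         Wo = .init_mat(d, d),
         bq = rep(0, d), bk = rep(0, d), bv = rep(0, d), bo = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d),
         W1 = .init_mat(d, cfg$d_mlp), b1 = rep(0, cfg$d_mlp),
         W2 = .init_mat(cfg$d_mlp, d), b2 = rep(0, d))
  })
  list(emb = .init_mat(vocab_size, d), pos = .init_mat(cfg$max_len, d),
       layers = layers, lnf_g = rep(1, d), lnf_b = rep(0, d),
       w_head = rep(0, d), b_head = 0)
}

# ---- cached forward / backward for one (unpadded) id sequence ----

.seq_forward <- function(ids, params, cfg, dropmask = NULL) {
  L <- length(ids)
  X <- params$emb[ids + 1L, , drop = FALSE] +
    params$pos[seq_len(L), , drop = FALSE]
  if (!is.null(dropmask)) X <- X * dropmask$emb
  cache <- list(ids = ids, X0 = X, layers = vector("list", cfg$n_layers))
  dk <- cfg$d_k; sc <- 1 / sqrt(dk)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    lc <- list(x_in = X)
    ln1 <- .layer_norm(X, lp$ln1_g, lp$ln1_b)
    h <- ln1$Y
    Q <- sweep(h %*% lp$Wq, 2L, lp$bq, "+")
    K <- sweep(h %*% lp$Wk, 2L, lp$bk, "+")
    V <- sweep(h %*% lp$Wv, 2L, lp$bv, "+")
    C <- matrix(0, L, cfg$d_model)
    A_list <- vector("list", cfg$n_heads)
    for (hh in seq_len(cfg$n_heads)) {
      idx <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) * sc
      A <- .softmax_rows(S)
      A_list[[hh]] <- A
      C[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    O <- sweep(C %*% lp$Wo, 2L, lp$bo, "+")
    if (!is.null(dropmask)) O <- O * dropmask$attn[[l]]
    Z <- X + O
    ln2 <- .layer_norm(Z, lp$ln2_g, lp$ln2_b)
    a <- sweep(ln2$Y %*% lp$W1, 2L, lp$b1, "+")
    r <- pmax(a, 0)
    M <- sweep(r %*% lp$W2, 2L, lp$b2, "+")
    if (!is.null(dropmask)) M <- M * dropmask$mlp[[l]]
    Xn <- Z + M
    lc <- c(lc, list(ln1 = ln1, h = h, Q = Q, K = K, V = V, A = A_list,
                     C = C, Z = Z, ln2 = ln2, a = a, r = r))
    cache$layers[[l]] <- lc
    X <- Xn
  }
  lnf <- .layer_norm(X[1L, , drop = FALSE], params$lnf_g, params$lnf_b)
  u <- lnf$Y
  logit <- sum(u * params$w_head) + params$b_head
  cache$X_final <- X
  cache$lnf <- lnf
  cache$u <- u
  list(logit = logit, cache = cache)
}

.zero_like <- function(p) {
  if (is.list(p)) lapply(p, .zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else p * 0
}

.tree_add <- function(a, b) {
  if (is.list(a)) Map(.tree_add, a, b) else a + b
}

.seq_backward <- function(dlogit, cache, params, cfg, dropmask = NULL) {
  g <- .zero_like(params)
  L <- length(cache$ids)
  dk <- cfg$d_k; sc <- 1 / sqrt(dk)

  du <- dlogit * matrix(params$w_head, 1L)
  g$w_head <- as.numeric(cache$u) * dlogit
  g$b_head <- dlogit
  lnb <- .layer_norm_bwd(du, cache$lnf, params$lnf_g)
  g$lnf_g <- lnb$dg; g$lnf_b <- lnb$db
  dX <- matrix(0, L, cfg$d_model)
  dX[1L, ] <- lnb$dX

  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- g$layers[[l]]

    dM <- if (!is.null(dropmask)) dX * dropmask$mlp[[l]] else dX
    gl$W2 <- t(lc$r) %*% dM
    gl$b2 <- colSums(dM)
    dr <- dM %*% t(lp$W2)
    da <- dr * (lc$a > 0)
    gl$W1 <- t(lc$ln2$Y) %*% da
    gl$b1 <- colSums(da)
    dh2 <- da %*% t(lp$W1)
    lnb2 <- .layer_norm_bwd(dh2, lc$ln2, lp$ln2_g)
    gl$ln2_g <- lnb2$dg; gl$ln2_b <- lnb2$db
    dZ <- dX + lnb2$dX

    dO <- if (!is.null(dropmask)) dZ * dropmask$attn[[l]] else dZ
    gl$Wo <- t(lc$C) %*% dO
    gl$bo <- colSums(dO)
    dC <- dO %*% t(lp$Wo)
    dQ <- matrix(0, L, cfg$d_model)
    dK <- matrix(0, L, cfg$d_model)
    dV <- matrix(0, L, cfg$d_model)
    for (hh in seq_len(cfg$n_heads)) {
      idx <- ((hh - 1L) * dk + 1L):(hh * dk)
      A <- lc$A[[hh]]
      dCh <- dC[, idx, drop = FALSE]
      Vh <- lc$V[, idx, drop = FALSE]
      dA <- dCh %*% t(Vh)
      dV[, idx] <- t(A) %*% dCh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% lc$K[, idx, drop = FALSE] * sc
      dK[, idx] <- t(dS) %*% lc$Q[, idx, drop = FALSE] * sc
    }
    gl$Wq <- t(lc$h) %*% dQ; gl$bq <- colSums(dQ)
    gl$Wk <- t(lc$h) %*% dK; gl$bk <- colSums(dK)
    gl$Wv <- t(lc$h) %*% dV; gl$bv <- colSums(dV)
    dh <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    lnb1 <- .layer_norm_bwd(dh, lc$ln1, lp$ln1_g)
    gl$ln1_g <- lnb1$dg; gl$ln1_b <- lnb1$db
    dX <- dZ + lnb1$dX
    g$layers[[l]] <- gl
  }

  dX0 <- if (!is.null(dropmask)) dX * dropmask$emb else dX
  for (i in seq_len(L)) {
    row <- cache$ids[i] + 1L
    g$emb[row, ] <- g$emb[row, ] + dX0[i, ]
  }
  g$pos[seq_len(L), ] <- g$pos[seq_len(L), , drop = FALSE] + dX0
  g
}

.make_dropmask <- function(L, cfg) {
  if (cfg$dropout <= 0) return(NULL)
  p <- cfg$dropout
  draw <- function(nr, nc) {
    matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
  }
  list(emb = draw(L, cfg$d_model),
       attn = lapply(seq_len(cfg$n_layers), function(l) draw(L, cfg$d_model)),
       mlp = lapply(seq_len(cfg$n_layers), function(l) draw(L, cfg$d_model)))
}
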