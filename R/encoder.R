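#' Rotary position embedding of a single vector
#'
#' Splits an even-dimensional query or key vector into d/2 coordinate
#' pairs and rotates pair `i` (0-based) by the angle
#' `position * base^(-2 i / d)`. Because each pair is rotated by an angle
#' proportional to the absolute position, the dot product between a query
#' rotated at position `m` and a key rotated at position `n` depends only
#' on the relative offset `m - n` — attention becomes translation
#' invariant, which is what lets one encoder accommodate unpaired chains
#' and the roughly twice-as-long paired inputs.
#'
#' @param x Numeric vector of even length.
#' @param position Non-negative position index.
#' @param base Frequency base (canonical value 10000).
#' @return The rotated vector (same Euclidean norm as `x`).
#' @export
rope_rotate <- function(x, position, base = 10000) {
  d <- length(x)
  if (d %% 2L != 0L) stop_config("rope_rotate requires an even dimension")
  if (position < 0) stop_config("position must be >= 0")
  i <- seq_len(d / 2L) - 1L
  theta <- position * base^(-2 * i / d)
  ev <- x[2L * i + 1L]; od <- x[2L * i + 2L]
  out <- numeric(d)
  out[2L * i + 1L] <- ev * cos(theta) - od * sin(theta)
  out[2L * i + 2L] <- ev * sin(theta) + od * cos(theta)
  out
}

# cos/sin tables for positions 0..n_pos-1 and a head dimension dh.
rope_tables <- function(n_pos, dh, base = 10000) {
  i <- seq_len(dh / 2L) - 1L
  freq <- base^(-2 * i / dh)                       # dh/2
  ang <- outer(0:(n_pos - 1L), freq)               # n_pos x dh/2
  list(cos = cos(ang), sin = sin(ang))
}

# Rotate head-dimension pairs of an (n x dh) matrix whose row r sits at
# position pos[r]; cosP/sinP are (n x dh/2) tables already indexed by row.
rope_apply <- function(M, cosP, sinP) {
  dh <- ncol(M)
  odd <- seq(1L, dh, by = 2L); evn <- odd + 1L
  a <- M[, odd, drop = FALSE]; b <- M[, evn, drop = FALSE]
  out <- M
  out[, odd] <- a * cosP - b * sinP
  out[, evn] <- a * sinP + b * cosP
  out
}

#' Encoder architecture configuration
#'
#' A bidirectional (BERT-style) transformer encoder in the ESM-2 family:
#' pre-layer-norm blocks, GELU feed-forward, tied input/output embeddings,
#' and either rotary or learned absolute positional embeddings. The
#' desk-scale default (2 layers, 4 heads, hidden 64, intermediate 256) is
#' CPU-trainable in minutes; the 55M configuration (5/20/960/3840) is
#' expressible but not the default.
#'
#' @param n_layers,n_heads,hidden_size,intermediate_size Architecture
#'   sizes; `hidden_size` must be divisible by `n_heads`.
#' @param pe_type `"rope"` or `"absolute"`.
#' @param vocab_size Always 33 for this vocabulary.
#' @param max_positions Maximum input length; must be >= 320 when
#'   `pe_type = "absolute"` (rotary embeddings have no position table).
#' @param rope_base Rotary frequency base.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, n_heads = 4L, hidden_size = 64L,
                           intermediate_size = 256L,
                           pe_type = c("rope", "absolute"),
                           vocab_size = 33L, max_positions = 320L,
                           rope_base = 10000) {
  pe_type <- match.arg(pe_type)
  if (hidden_size %% n_heads != 0L) {
    stop_config("hidden_size must be divisible by n_heads")
  }
  if ((hidden_size / n_heads) %% 2L != 0L) {
    stop_config("head dimension must be even for rotary embeddings")
  }
  if (vocab_size != 33L) stop_config("vocab_size must be 33")
  if (pe_type == "absolute" && max_positions < MAX_TOKENS) {
    stop_config(sprintf("absolute positional embeddings need max_positions >= %d", MAX_TOKENS))
  }
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 hidden_size = as.integer(hidden_size),
                 intermediate_size = as.integer(intermediate_size),
                 pe_type = pe_type, vocab_size = as.integer(vocab_size),
                 max_positions = as.integer(max_positions),
                 rope_base = rope_base),
            class = "encoder_config")
}

pn <- function(l, nm) sprintf("L%d.%s", l, nm)

#' Build an initialized encoder
#'
#' Parameters are drawn N(0, 0.02^2) (layer-norm gains 1, biases 0) from
#' the given seed, so two builds with the same seed are parameter-
#' identical. The output projection is tied to the input embedding.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for initialization.
#' @return An object of class `ablm_encoder` (config + named parameter
#'   list), whose forward pass is [encoder_forward()].
#' @export
build_encoder <- function(cfg = encoder_config(), seed = 1L) {
  stopifnot(inherits(cfg, "encoder_config"))
  H <- cfg$hidden_size; I <- cfg$intermediate_size; V <- cfg$vocab_size
  with_seed(derive_seed(seed, "encoder-init"), {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list(emb = rn(V, H), out_b = numeric(V),
              lnf_g = rep(1, H), lnf_b = numeric(H))
    if (cfg$pe_type == "absolute") p$pos <- rn(cfg$max_positions, H)
    for (l in seq_len(cfg$n_layers)) {
      p[[pn(l, "ln1_g")]] <- rep(1, H); p[[pn(l, "ln1_b")]] <- numeric(H)
      p[[pn(l, "Wq")]] <- rn(H, H); p[[pn(l, "bq")]] <- numeric(H)
      p[[pn(l, "Wk")]] <- rn(H, H); p[[pn(l, "bk")]] <- numeric(H)
      p[[pn(l, "Wv")]] <- rn(H, H); p[[pn(l, "bv")]] <- numeric(H)
      p[[pn(l, "Wo")]] <- rn(H, H); p[[pn(l, "bo")]] <- numeric(H)
      p[[pn(l, "ln2_g")]] <- rep(1, H); p[[pn(l, "ln2_b")]] <- numeric(H)
      p[[pn(l, "W1")]] <- rn(H, I); p[[pn(l, "b1")]] <- numeric(I)
      p[[pn(l, "W2")]] <- rn(I, H); p[[pn(l, "b2")]] <- numeric(H)
    }
    structure(list(cfg = cfg, params = p), class = "ablm_encoder")
  })
}

#' @export
print.ablm_encoder <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<ablm_encoder> %d layers, %d heads, hidden %d, %s PE, %s parameters\n",
              x$cfg$n_layers, x$cfg$n_heads, x$cfg$hidden_size, x$cfg$pe_type,
              format(n_par, big.mark = ",")))
  invisible(x)
}

addrow <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

layernorm_f <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invsd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invsd
  y <- addrow(xhat * matrix(g, nrow(x), ncol(x), byrow = TRUE), b)
  list(y = y, xhat = xhat, invsd = invsd, g = g)
}

layernorm_b <- function(dy, cache) {
  dxhat <- dy * matrix(cache$g, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- cache$invsd * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx,
       dg = colSums(dy * cache$xhat),
       db = colSums(dy))
}

# Sigmoid-form GELU (x * sigmoid(1.702 x)), the fast approximation used
# throughout the transformer literature; exact-erf GELU costs ~10x more in
# interpreted code for an indistinguishable activation.
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

rowmax <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

# Internal forward pass over matrices.
# ids, mask: B x T (0-based ids). Returns logits ((B*T) x V, rows ordered
# by batch then position), the final hidden states, and layer caches when
# requested for backprop.
enc_forward <- function(model, ids, mask, cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  storage.mode(mask) <- "integer"
  B <- nrow(ids); Tn <- ncol(ids)
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  scale <- 1 / sqrt(dh)
  tok <- as.vector(t(ids)) + 1L                   # row-major (b, t), t fastest
  X <- p$emb[tok, , drop = FALSE]
  if (cfg$pe_type == "absolute") {
    X <- X + p$pos[rep(seq_len(Tn), B), , drop = FALSE]
  }
  use_rope <- cfg$pe_type == "rope"
  if (use_rope) {
    rt <- rope_tables(Tn, dh, cfg$rope_base)
    posidx <- rep(seq_len(Tn), B)
    cosP <- rt$cos[posidx, , drop = FALSE]
    sinP <- rt$sin[posidx, , drop = FALSE]
  }
  caches <- if (cache) vector("list", cfg$n_layers) else NULL
  head_cols <- lapply(seq_len(nh), function(hh) ((hh - 1L) * dh + 1L):(hh * dh))
  for (l in seq_len(cfg$n_layers)) {
    ln1 <- layernorm_f(X, p[[pn(l, "ln1_g")]], p[[pn(l, "ln1_b")]])
    h <- ln1$y
    Q <- addrow(h %*% p[[pn(l, "Wq")]], p[[pn(l, "bq")]])
    K <- addrow(h %*% p[[pn(l, "Wk")]], p[[pn(l, "bk")]])
    V <- addrow(h %*% p[[pn(l, "Wv")]], p[[pn(l, "bv")]])
    if (use_rope) {
      for (cols in head_cols) {
        Q[, cols] <- rope_apply(Q[, cols, drop = FALSE], cosP, sinP)
        K[, cols] <- rope_apply(K[, cols, drop = FALSE], cosP, sinP)
      }
    }
    aw <- attn_forward_cpp(Q, K, V, mask, B, Tn, nh, cache)
    O <- aw$O
    attn <- addrow(O %*% p[[pn(l, "Wo")]], p[[pn(l, "bo")]])
    X1 <- X + attn
    ln2 <- layernorm_f(X1, p[[pn(l, "ln2_g")]], p[[pn(l, "ln2_b")]])
    F1 <- addrow(ln2$y %*% p[[pn(l, "W1")]], p[[pn(l, "b1")]])
    G <- gelu(F1)
    F2 <- addrow(G %*% p[[pn(l, "W2")]], p[[pn(l, "b2")]])
    Xout <- X1 + F2
    if (cache) {
      caches[[l]] <- list(ln1 = ln1, ln2 = ln2, h = h, Q = Q, K = K, V = V,
                          A = aw$A, O = O, F1 = F1, G = G)
    }
    X <- Xout
  }
  lnf <- layernorm_f(X, p$lnf_g, p$lnf_b)
  logits <- addrow(tcrossprod(lnf$y, p$emb), p$out_b)
  list(logits = logits, hidden = lnf$y,
       caches = caches, lnf = lnf, tok = tok,
       rope = if (use_rope) list(cosP = cosP, sinP = sinP) else NULL,
       dims = c(B = B, T = Tn))
}

# Backward pass: dlogits is (B*T) x V. Returns gradients named like params.
enc_backward <- function(model, ids, mask, fwd, dlogits) {
  cfg <- model$cfg; p <- model$params
  B <- fwd$dims[["B"]]; Tn <- fwd$dims[["T"]]
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  scale <- 1 / sqrt(dh)
  head_cols <- lapply(seq_len(nh), function(hh) ((hh - 1L) * dh + 1L):(hh * dh))
  g <- list()
  g$out_b <- colSums(dlogits)
  g$emb <- crossprod(dlogits, fwd$lnf$y)           # tied-output contribution
  dHf <- dlogits %*% p$emb
  lb <- layernorm_b(dHf, fwd$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    cc <- fwd$caches[[l]]
    # FFN branch
    dF2 <- dX
    g[[pn(l, "b2")]] <- colSums(dF2)
    g[[pn(l, "W2")]] <- crossprod(cc$G, dF2)
    dG <- tcrossprod(dF2, p[[pn(l, "W2")]])
    dF1 <- dG * gelu_grad(cc$F1)
    g[[pn(l, "b1")]] <- colSums(dF1)
    g[[pn(l, "W1")]] <- crossprod(cc$ln2$y, dF1)
    dh2 <- tcrossprod(dF1, p[[pn(l, "W1")]])
    lb2 <- layernorm_b(dh2, cc$ln2)
    g[[pn(l, "ln2_g")]] <- lb2$dg; g[[pn(l, "ln2_b")]] <- lb2$db
    dX1 <- dX + lb2$dx
    # attention branch
    g[[pn(l, "bo")]] <- colSums(dX1)
    g[[pn(l, "Wo")]] <- crossprod(cc$O, dX1)
    dO <- tcrossprod(dX1, p[[pn(l, "Wo")]])
    ab <- attn_backward_cpp(dO, cc$A, cc$Q, cc$K, cc$V, B, Tn, nh)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    if (cfg$pe_type == "rope") {
      # inverse rotation: transpose of an orthogonal map
      for (cols in head_cols) {
        dQ[, cols] <- rope_apply(dQ[, cols, drop = FALSE], fwd$rope$cosP, -fwd$rope$sinP)
        dK[, cols] <- rope_apply(dK[, cols, drop = FALSE], fwd$rope$cosP, -fwd$rope$sinP)
      }
    }
    g[[pn(l, "bq")]] <- colSums(dQ); g[[pn(l, "Wq")]] <- crossprod(cc$h, dQ)
    g[[pn(l, "bk")]] <- colSums(dK); g[[pn(l, "Wk")]] <- crossprod(cc$h, dK)
    g[[pn(l, "bv")]] <- colSums(dV); g[[pn(l, "Wv")]] <- crossprod(cc$h, dV)
    dh_ <- tcrossprod(dQ, p[[pn(l, "Wq")]]) +
      tcrossprod(dK, p[[pn(l, "Wk")]]) +
      tcrossprod(dV, p[[pn(l, "Wv")]])
    lb1 <- layernorm_b(dh_, cc$ln1)
    g[[pn(l, "ln1_g")]] <- lb1$dg; g[[pn(l, "ln1_b")]] <- lb1$db
    dX <- dX1 + lb1$dx
  }
  # input embedding (and absolute position) gradients
  agg <- rowsum(dX, group = fwd$tok)
  idx <- as.integer(rownames(agg))
  g$emb[idx, ] <- g$emb[idx, , drop = FALSE] + agg
  if (cfg$pe_type == "absolute") {
    g$pos <- matrix(0, cfg$max_positions, H)
    pagg <- rowsum(dX, group = rep(seq_len(Tn), B))
    g$pos[seq_len(Tn), ] <- pagg
  }
  g
}

#' Run the encoder forward
#'
#' @param model An [build_encoder()] model.
#' @param ids Integer matrix (batch x positions) of 0-based token ids.
#' @param attention_mask Binary matrix of the same shape; 0 marks padding.
#' @return Array of per-position logits with dim `(batch, positions, 33)`.
#' @export
encoder_forward <- function(model, ids, attention_mask) {
  stopifnot(inherits(model, "ablm_encoder"))
  ids <- as.matrix(ids); attention_mask <- as.matrix(attention_mask)
  fwd <- enc_forward(model, ids, attention_mask, cache = FALSE)
  B <- nrow(ids); Tn <- ncol(ids); V <- model$cfg$vocab_size
  aperm(array(t(fwd$logits), c(V, Tn, B)), c(3, 2, 1))
}

#' Final hidden states of the encoder
#'
#' @inheritParams encoder_forward
#' @return Array `(batch, positions, hidden_size)` of post-layer-norm
#'   hidden states, the representations consumed by classification heads.
#' @export
encoder_hidden <- function(model, ids, attention_mask) {
  stopifnot(inherits(model, "ablm_encoder"))
  ids <- as.matrix(ids); attention_mask <- as.matrix(attention_mask)
  fwd <- enc_forward(model, ids, attention_mask, cache = FALSE)
  B <- nrow(ids); Tn <- ncol(ids); H <- model$cfg$hidden_size
  aperm(array(t(fwd$hidden), c(H, Tn, B)), c(3, 2, 1))
}

# ---- AdamW ---------------------------------------------------------------

adamw_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(x) x * 0)
  st$v <- lapply(params, function(x) x * 0)
  st$t <- 0L
  st
}

# Decoupled weight decay applied to weight matrices and the embedding,
# never to biases or layer-norm parameters.
adamw_decay_set <- function(names) {
  grepl("\\.(Wq|Wk|Wv|Wo|W1|W2)$", names) | names == "emb"
}

adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.98),
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  decay <- adamw_decay_set(names(params))
  for (i in seq_along(params)) {
    nm <- names(params)[i]
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr * gr
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (decay[i]) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}
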