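# Independent pure-R (double precision) forward pass of the transformer
# tower, used as the oracle for the compiled float32 implementation.

ref_ln <- function(X, g, b, eps = 1e-6) {
  g <- as.numeric(g); b <- as.numeric(b)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  xh <- xc / sqrt(v + eps)
  sweep(xh, 2, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE)
}

ref_gelu <- function(x) x * pnorm(x)   # exact GELU: x * Phi(x)

ref_softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

ref_block <- function(X, blk, H) {
  E <- ncol(X)
  Dh <- E / H
  A_in <- ref_ln(X, blk$ln1_g, blk$ln1_b)
  QKV <- A_in %*% blk$qkv_W +
    matrix(as.numeric(blk$qkv_b), nrow(X), 3 * E, byrow = TRUE)
  O <- matrix(0, nrow(X), E)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * Dh + 1):(h * Dh)
    Q <- QKV[, cols, drop = FALSE]
    K <- QKV[, E + cols, drop = FALSE]
    V <- QKV[, 2 * E + cols, drop = FALSE]
    P <- ref_softmax_rows(Q %*% t(K) / sqrt(Dh))
    O[, cols] <- P %*% V
  }
  attn <- O %*% blk$proj_W +
    matrix(as.numeric(blk$proj_b), nrow(X), E, byrow = TRUE)
  X_mid <- X + attn
  M_in <- ref_ln(X_mid, blk$ln2_g, blk$ln2_b)
  H1 <- ref_gelu(M_in %*% blk$fc1_W +
                   matrix(as.numeric(blk$fc1_b), nrow(X),
                          ncol(blk$fc1_W), byrow = TRUE))
  X_mid + H1 %*% blk$fc2_W +
    matrix(as.numeric(blk$fc2_b), nrow(X), E, byrow = TRUE)
}

ref_tower <- function(X0, params, H) {
  X <- X0
  for (blk in params$blocks) X <- ref_block(X, blk, H)
  ref_ln(X, params$norm_g, params$norm_b)
}

ref_encode_visible <- function(model, patches, mask) {
  p <- model$params$enc
  vis <- mask$visible
  Xv <- patches[vis, , drop = FALSE] %*% p$embed_W +
    matrix(as.numeric(p$embed_b), length(vis), ncol(p$embed_W),
           byrow = TRUE) +
    model$pos_enc[vis, , drop = FALSE]
  X0 <- rbind(as.numeric(p$cls), Xv)
  ref_tower(X0, p, model$enc_cfg$n_heads)
}
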