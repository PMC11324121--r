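#' Encoder size presets
#'
#' ViT encoder configuration. Presets follow the standard size ladder:
#' Tiny (192-d, depth 4, 3 heads; used throughout tests and desk-scale
#' experiments), Base (768, 12, 12), Large (1024, 24, 16) and Huge
#' (1280, 32, 16). The MLP hidden width is `mlp_ratio * embed_dim` and the
#' patch projection consumes 250-sample patches.
#'
#' @param preset One of `"tiny"`, `"base"`, `"large"`, `"huge"`, or
#'   `"custom"` (then supply the dimensions yourself).
#' @param embed_dim,depth,n_heads Transformer width, number of blocks,
#'   attention heads (`embed_dim` must be divisible by `n_heads`).
#' @param mlp_ratio Hidden-to-width ratio of the block MLPs (default 4).
#' @param patch_input_dim Samples per patch (250 = 0.5 s at 500 Hz).
#' @return An `encoder_config`.
#' @export
encoder_config <- function(preset = c("tiny", "base", "large", "huge",
                                      "custom"),
                           embed_dim = NULL, depth = NULL, n_heads = NULL,
                           mlp_ratio = 4, patch_input_dim = 250L) {
  preset <- match.arg(preset)
  dims <- switch(preset,
    tiny  = c(192L, 4L, 3L),
    base  = c(768L, 12L, 12L),
    large = c(1024L, 24L, 16L),
    huge  = c(1280L, 32L, 16L),
    custom = c(embed_dim, depth, n_heads)
  )
  if (preset != "custom") {
    embed_dim <- dims[1]; depth <- dims[2]; n_heads <- dims[3]
  }
  if (is.null(embed_dim) || is.null(depth) || is.null(n_heads)) {
    stop("custom preset requires embed_dim, depth and n_heads",
         call. = FALSE)
  }
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(list(preset = preset, embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio,
                 patch_input_dim = as.integer(patch_input_dim)),
            class = "encoder_config")
}

#' Decoder configuration
#'
#' The MAE decoder is a lighter transformer that reads the full 240-token
#' sequence (encoded visible tokens plus a learned mask token at masked
#' positions) and linearly projects each output token back to 250 voltage
#' samples. Defaults follow the original MAE decoder (512-d, depth 8, 16
#' heads); desk-scale runs use a much smaller decoder.
#'
#' @param embed_dim,depth,n_heads Decoder width/depth/heads.
#' @param mlp_ratio MLP ratio (default 4).
#' @param output_dim Samples per reconstructed patch; must equal the
#'   encoder's `patch_input_dim`.
#' @return A `decoder_config`.
#' @export
decoder_config <- function(embed_dim = 512L, depth = 8L, n_heads = 16L,
                           mlp_ratio = 4, output_dim = 250L) {
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio, output_dim = as.integer(output_dim)),
            class = "decoder_config")
}

# ---- fixed 2-D sinusoidal positional embeddings -------------------------

sincos_1d <- function(positions, dim) {
  stopifnot(dim %% 2 == 0)
  omega <- 1 / 10000^(2 * (seq_len(dim / 2) - 1) / dim)
  ang <- outer(positions, omega)
  cbind(sin(ang), cos(ang))
}

#' Fixed 2-D sinusoidal positional embedding over the patch grid
#'
#' Non-trained positional code for the 12 x 20 grid: half the channels
#' encode the time slot, half the lead index, each with the standard
#' sine/cosine frequency ladder. Rows are in lead-major patch order,
#' matching [patchify()]. The classification token carries a zero position.
#'
#' @param embed_dim Embedding width (divisible by 4).
#' @param n_lead,n_time Grid shape.
#' @return `(n_lead * n_time) x embed_dim` matrix.
#' @export
grid_pos_embed <- function(embed_dim, n_lead = 12L, n_time = 20L) {
  stopifnot(embed_dim %% 4 == 0)
  leads <- rep(seq_len(n_lead) - 1, each = n_time)
  times <- rep(seq_len(n_time) - 1, times = n_lead)
  cbind(sincos_1d(leads, embed_dim / 2), sincos_1d(times, embed_dim / 2))
}

# ---- parameter initialization -------------------------------------------

trunc_normal <- function(n, sd = 0.02) {
  # normal truncated at +/- 2 sd, via inverse-CDF sampling
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  sd * stats::qnorm(u)
}

xavier_uniform <- function(fan_in, fan_out) {
  # uniform(+/- sqrt(6 / (fan_in + fan_out))); used for the patch/token
  # projections, following the reference MAE initialization
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_block <- function(E, mlp_ratio) {
  ME <- as.integer(round(mlp_ratio * E))
  list(
    ln1_g = matrix(1, 1, E), ln1_b = matrix(0, 1, E),
    qkv_W = matrix(trunc_normal(E * 3 * E), E, 3 * E),
    qkv_b = matrix(0, 1, 3 * E),
    proj_W = matrix(trunc_normal(E * E), E, E),
    proj_b = matrix(0, 1, E),
    ln2_g = matrix(1, 1, E), ln2_b = matrix(0, 1, E),
    fc1_W = matrix(trunc_normal(E * ME), E, ME),
    fc1_b = matrix(0, 1, ME),
    fc2_W = matrix(trunc_normal(ME * E), ME, E),
    fc2_b = matrix(0, 1, E)
  )
}

init_encoder_params <- function(cfg) {
  E <- cfg$embed_dim
  list(
    embed_W = xavier_uniform(cfg$patch_input_dim, E),
    embed_b = matrix(0, 1, E),
    cls = matrix(trunc_normal(E), 1, E),
    blocks = lapply(seq_len(cfg$depth),
                    function(i) init_block(E, cfg$mlp_ratio)),
    norm_g = matrix(1, 1, E), norm_b = matrix(0, 1, E)
  )
}

init_decoder_params <- function(cfg, enc_dim) {
  D <- cfg$embed_dim
  list(
    embed_W = xavier_uniform(enc_dim, D),
    embed_b = matrix(0, 1, D),
    mask_token = matrix(trunc_normal(D), 1, D),
    blocks = lapply(seq_len(cfg$depth),
                    function(i) init_block(D, cfg$mlp_ratio)),
    norm_g = matrix(1, 1, D), norm_b = matrix(0, 1, D),
    head_W = xavier_uniform(D, cfg$output_dim),
    head_b = matrix(0, 1, cfg$output_dim)
  )
}

#' Build an MAE model
#'
#' Assembles the encoder-decoder pair with seeded initialization: the
#' patch/token projections use Xavier-uniform draws, transformer block
#' weights and the class/mask tokens a truncated normal (sd 0.02, cut at
#' two sd), biases start at zero, LayerNorm gains at one. Positional
#' embeddings are fixed (non-trained) 2-D sinusoids over the 12 x 20 grid
#' and are stored with the model.
#'
#' @param enc An [encoder_config()].
#' @param dec A [decoder_config()].
#' @param seed Integer seed; identical seeds give identical parameters.
#' @param n_lead,n_time Patch grid shape.
#' @return An `mae_model`.
#' @export
build_mae <- function(enc = encoder_config("tiny"),
                      dec = decoder_config(128L, 2L, 4L),
                      seed = 1L, n_lead = 12L, n_time = 20L) {
  stopifnot(inherits(enc, "encoder_config"), inherits(dec, "decoder_config"))
  if (dec$output_dim != enc$patch_input_dim) {
    stop("decoder output_dim must equal encoder patch_input_dim",
         call. = FALSE)
  }
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  structure(list(
    enc_cfg = enc, dec_cfg = dec, seed = as.integer(seed),
    n_lead = as.integer(n_lead), n_time = as.integer(n_time),
    params = list(enc = init_encoder_params(enc),
                  dec = init_decoder_params(dec, enc$embed_dim)),
    pos_enc = grid_pos_embed(enc$embed_dim, n_lead, n_time),
    pos_dec = grid_pos_embed(dec$embed_dim, n_lead, n_time)
  ), class = "mae_model")
}

#' @export
print.mae_model <- function(x, ...) {
  cat(sprintf("<mae_model> encoder %s (%d-d, depth %d, %d heads), decoder %d-d depth %d; %s encoder params\n",
              x$enc_cfg$preset, x$enc_cfg$embed_dim, x$enc_cfg$depth,
              x$enc_cfg$n_heads, x$dec_cfg$embed_dim, x$dec_cfg$depth,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable encoder parameters
#'
#' Sums the trainable parameter tensors of the encoder: patch projection,
#' classification token, transformer blocks and final LayerNorm. The fixed
#' sinusoidal positional embeddings are not trainable and are not counted;
#' the decoder is excluded when scoping "encoder". Accepts a built model,
#' an `encoder_config` (closed form), or a raw parameter list.
#'
#' @param x An `mae_model`, `ecg_classifier`, `encoder_config`, or
#'   parameter list.
#' @return Integer parameter count.
#' @export
count_params <- function(x) {
  if (inherits(x, "encoder_config")) {
    E <- x$embed_dim; ME <- as.integer(round(x$mlp_ratio * E))
    per_block <- (2 * E) +                       # ln1
      (E * 3 * E + 3 * E) +                      # qkv
      (E * E + E) +                              # attention projection
      (2 * E) +                                  # ln2
      (E * ME + ME) + (ME * E + E)               # mlp
    return(as.integer(x$patch_input_dim * E + E +  # patch projection
                        E +                        # cls token
                        x$depth * per_block +
                        2 * E))                    # final norm
  }
  params <- if (inherits(x, "mae_model") || inherits(x, "ecg_classifier")) {
    x$params$enc
  } else {
    x
  }
  sum(unlist(rapply(params, length, how = "list")))
}

#' Encode the visible patches of a masked record
#'
#' Runs the ViT encoder on the visible patches only (plus the
#' classification token), as in MAE pretraining: the output is a pure
#' function of the visible patches, their grid positions and the model
#' parameters — the contents of masked patches cannot affect it.
#'
#' @param model An `mae_model`.
#' @param x An [ecg_record()], an `ecg_patches` matrix, or a 240 x 250
#'   matrix.
#' @param mask An `ecg_mask` from [make_mask()].
#' @return `(n_visible + 1) x embed_dim` token matrix (row 1 is the
#'   classification token).
#' @export
encode_visible <- function(model, x, mask) {
  stopifnot(inherits(model, "mae_model"), inherits(mask, "ecg_mask"))
  patches <- if (inherits(x, "ecg_record")) patchify(x) else as.matrix(x)
  n_grid <- model$n_lead * model$n_time
  if (nrow(patches) == n_grid) {
    vis_rows <- patches[mask$visible, , drop = FALSE]
  } else if (nrow(patches) == length(mask$visible)) {
    vis_rows <- patches
  } else {
    stop(sprintf("patch count %d matches neither the grid (%d) nor the visible set (%d)",
                 nrow(patches), n_grid, length(mask$visible)), call. = FALSE)
  }
  cpp_encode(model$params$enc, model$enc_cfg$n_heads, vis_rows,
             mask$visible - 1L, model$pos_enc)
}

#' Decode a full patch sequence from encoded visible tokens
#'
#' Inserts the learned mask token at every masked grid position, restores
#' canonical (unshuffled) order, adds decoder positional embeddings, runs
#' the decoder blocks, and projects every token to 250 voltage samples.
#' The classification token is dropped from the output.
#'
#' @param model An `mae_model`.
#' @param tokens Encoder output from [encode_visible()] under the same
#'   mask.
#' @param mask The same `ecg_mask`.
#' @return 240 x 250 matrix of predicted patches in canonical grid order.
#' @export
decode_full <- function(model, tokens, mask) {
  stopifnot(inherits(model, "mae_model"), inherits(mask, "ecg_mask"))
  tokens <- as.matrix(tokens)
  if (nrow(tokens) != length(mask$visible) + 1L) {
    stop(sprintf("token count %d does not match mask (%d visible + cls)",
                 nrow(tokens), length(mask$visible)), call. = FALSE)
  }
  n_grid <- model$n_lead * model$n_time
  cpp_decode(model$params$dec, model$dec_cfg$n_heads, tokens,
             mask$visible - 1L, n_grid, model$pos_dec)
}

#' Masked-reconstruction loss
#'
#' Mean squared error between predicted and original patches, averaged over
#' the masked patches only (and over the 250 samples within each patch);
#' predictions at visible positions never contribute. With
#' `normalize_per_patch = TRUE` each target patch is centered and scaled by
#' its own mean and standard deviation before comparison (off by default:
#' records are already lead-normalized upstream).
#'
#' @param pred 240 x 250 matrix of predicted patches.
#' @param target The original `ecg_patches` (or 240 x 250 matrix).
#' @param mask The `ecg_mask` used for the prediction.
#' @param normalize_per_patch Normalize each target patch first.
#' @return Scalar loss.
#' @export
mae_loss <- function(pred, target, mask, normalize_per_patch = FALSE) {
  pred <- as.matrix(pred)
  target <- as.matrix(target)
  stopifnot(identical(dim(pred), dim(target)))
  if (length(mask$masked) == 0L) {
    stop("loss undefined: masked set is empty", call. = FALSE)
  }
  tgt <- target[mask$masked, , drop = FALSE]
  if (normalize_per_patch) {
    mu <- rowMeans(tgt)
    sd <- apply(tgt, 1, stats::sd)
    sd[sd < 1e-6] <- 1
    tgt <- (tgt - mu) / sd
  }
  d <- pred[mask$masked, , drop = FALSE] - tgt
  mean(d^2)
}

#' Reconstruct a record through the masked autoencoder
#'
#' Full encode-decode pass for one record under one mask. By the original
#' MAE visualization convention the returned composite pastes the true
#' visible patches over the decoder output, so only masked content is
#' model-generated; set `paste_visible = FALSE` for the raw decoder output
#' everywhere.
#'
#' @param model An `mae_model`.
#' @param record An [ecg_record()] (normalized upstream, as in training).
#' @param mask An `ecg_mask`.
#' @param paste_visible Paste true visible patches into the output.
#' @return List with `pred` (12 x 5000 reconstructed signal), `masked_sig`
#'   (original with masked patches blanked to `NA`), `loss`, and the inputs.
#' @export
reconstruct <- function(model, record, mask, paste_visible = TRUE) {
  patches <- patchify(record)
  tokens <- encode_visible(model, patches, mask)
  pred <- decode_full(model, tokens, mask)
  loss <- if (length(mask$masked)) mae_loss(pred, patches, mask) else NA_real_
  if (paste_visible) {
    pred[mask$visible, ] <- patches[mask$visible, ]
  }
  masked_patches <- unclass(patches)
  masked_patches[mask$masked, ] <- NA_real_
  out <- list(
    pred = unpatchify(pred, model$n_lead, model$n_time),
    masked_sig = unpatchify_na(masked_patches, model$n_lead, model$n_time),
    original = record$signal,
    loss = loss, mask = mask, record_id = record$record_id
  )
  class(out) <- "mae_reconstruction"
  out
}

# unpatchify that tolerates the NA-blanked masked panel
unpatchify_na <- function(patches, n_lead, n_time) {
  sig <- matrix(NA_real_, n_lead, n_time * 250L)
  for (l in seq_len(n_lead)) {
    for (s in seq_len(n_time)) {
      sig[l, ((s - 1L) * 250L + 1L):(s * 250L)] <-
        patches[(l - 1L) * n_time + s, ]
    }
  }
  sig
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive (RDS) holding the parameters and the configuration;
#' works for both `mae_model` and `ecg_classifier` objects.
#'
#' @param model The model object.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
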