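# ---- parameter-tree helpers ---------------------------------------------

# apply f(leaf_a, leaf_b) over two parallel nested lists of matrices,
# matching named elements by name (C++ grad lists may be ordered differently)
tree_map2 <- function(a, b, f) {
  if (is.matrix(a)) return(f(a, b))
  out <- a
  nm <- names(a)
  if (is.null(nm)) {
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
  } else {
    for (n in nm) out[[n]] <- tree_map2(a[[n]], b[[n]], f)
  }
  out
}

tree_map <- function(a, f) tree_map2(a, a, function(x, y) f(x))

tree_sum <- function(a, f) {
  if (is.matrix(a)) return(f(a))
  sum(vapply(a, tree_sum, numeric(1), f = f))
}

grad_global_norm <- function(grads) {
  sqrt(tree_sum(grads, function(g) sum(g^2)))
}

clip_grads <- function(grads, max_norm) {
  gn <- grad_global_norm(grads)
  if (is.finite(gn) && gn > max_norm) {
    grads <- tree_map(grads, function(g) g * (max_norm / gn))
  }
  grads
}

# ---- Adam / AdamW --------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0))
}

# decoupled weight decay (AdamW) when weight_decay > 0; the fused update
# runs in compiled code over the nested parameter/gradient trees
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, lr_mult = NULL) {
  state$t <- state$t + 1L
  r <- cpp_adam_update(params, grads, state$m, state$v, state$t, lr,
                       beta1, beta2, eps, weight_decay, lr_mult)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# layer-wise learning-rate multipliers for fine-tuning: the head and final
# encoder norm train at the full rate, transformer block i at
# decay^(depth + 1 - i), and the patch projection / class token at
# decay^(depth + 1) — the standard discriminative schedule for fine-tuning
# a pretrained transformer
layer_lr_mult <- function(params, decay) {
  scalar_tree <- function(x, mult) {
    if (is.matrix(x)) return(mult)
    keys <- names(x) %||% seq_along(x)
    out <- x
    for (k in keys) out[[k]] <- scalar_tree(x[[k]], mult)
    out
  }
  depth <- length(params$enc$blocks)
  enc <- params$enc
  mult <- list()
  for (nm in names(enc)) {
    mult[[nm]] <- if (nm == "blocks") {
      lapply(seq_len(depth), function(i) {
        scalar_tree(enc$blocks[[i]], decay^(depth + 1 - i))
      })
    } else if (nm %in% c("embed_W", "embed_b", "cls")) {
      scalar_tree(enc[[nm]], decay^(depth + 1))
    } else {
      # final norm moves with the top block: the pooled features feed a
      # whitening transform fitted at the start of fine-tuning, and a
      # full-rate norm would invalidate that basis
      scalar_tree(enc[[nm]], decay)
    }
  }
  list(enc = mult, head = scalar_tree(params$head, 1))
}

# ---- pretraining ---------------------------------------------------------

#' Pretraining configuration
#'
#' Defaults follow the full-scale protocol: long training with a decoupled
#' weight-decay adaptive optimizer (AdamW, betas 0.9/0.95, weight decay
#' 0.05), base learning rate `1.5e-4 * batch_size / 256`, 40-epoch linear
#' warmup then cosine decay, gradient clipping at a global norm of 1, no
#' mixed precision. Desk-scale runs shrink `epochs`, `warmup_epochs` and
#' `batch_size`.
#'
#' @param epochs Number of passes over the records.
#' @param batch_size Records per gradient step.
#' @param base_lr Base learning rate before batch scaling.
#' @param warmup_epochs Linear warmup length (epochs).
#' @param clip_norm Global gradient-norm clip (> 0).
#' @param weight_decay Decoupled weight decay.
#' @param beta1,beta2 Adam moment decays.
#' @param mask_ratio,mask_strategy Masking plan drawn fresh per record per
#'   epoch.
#' @param normalize_per_patch Per-patch target normalization flag for the
#'   loss (default off; records are lead-normalized upstream).
#' @param seed Seed driving batch order and mask draws.
#' @return A `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 1600L, batch_size = 768L,
                            base_lr = 1.5e-4, warmup_epochs = 40L,
                            clip_norm = 1.0, weight_decay = 0.05,
                            beta1 = 0.9, beta2 = 0.95,
                            mask_ratio = 0.75, mask_strategy = "random",
                            normalize_per_patch = FALSE, seed = 1L) {
  stopifnot(epochs >= 0, clip_norm > 0, batch_size >= 1)
  structure(as.list(environment()), class = "pretrain_config")
}

prepare_patches <- function(records) {
  lapply(records, function(r) {
    if (inherits(r, "ecg_record")) {
      unclass(patchify(normalize_ecg(r)))
    } else {
      as.matrix(r)
    }
  })
}

cosine_lr <- function(epoch, cfg) {
  lr_max <- cfg$base_lr * cfg$batch_size / 256
  if (cfg$warmup_epochs > 0 && epoch <= cfg$warmup_epochs) {
    return(lr_max * epoch / cfg$warmup_epochs)
  }
  denom <- max(cfg$epochs - cfg$warmup_epochs, 1L)
  lr_max * 0.5 * (1 + cos(pi * (epoch - cfg$warmup_epochs) / denom))
}

#' Pretrain an MAE on unlabeled records
#'
#' Runs masked-reconstruction pretraining: each epoch draws a fresh random
#' mask per record from a seeded stream, encodes only the visible patches,
#' decodes the full grid and takes a clipped AdamW step on the masked-only
#' mean squared error. Records are lead-normalized and patchified once up
#' front. Fully reproducible for a fixed seed on one device.
#'
#' @param model An `mae_model` from [build_mae()].
#' @param records List of [ecg_record()]s (or pre-patchified 240 x 250
#'   matrices, assumed already normalized).
#' @param cfg A [pretrain_config()].
#' @return List with `model` (trained) and `history` (tibble of epoch,
#'   loss, lr).
#' @export
pretrain <- function(model, records, cfg = pretrain_config()) {
  stopifnot(inherits(model, "mae_model"), length(records) > 0)
  patches <- prepare_patches(records)
  n <- length(patches)
  if (cfg$epochs == 0L) {
    return(list(model = model,
                history = tibble::tibble(epoch = integer(), loss = numeric(),
                                         lr = numeric())))
  }
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  params <- model$params
  opt <- adam_init(params)
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg)
    ord <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      masks <- lapply(idx, function(i) {
        make_mask(cfg$mask_ratio, cfg$mask_strategy,
                  seed = sample.int(.Machine$integer.max - 1L, 1L))
      })
      res <- cpp_mae_grad(params$enc, params$dec,
                          model$enc_cfg$n_heads, model$dec_cfg$n_heads,
                          patches[idx],
                          lapply(masks, function(m) m$visible - 1L),
                          lapply(masks, function(m) m$masked - 1L),
                          model$pos_enc, model$pos_dec,
                          cfg$normalize_per_patch, TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite pretraining loss at epoch %d (lr %.2g); reduce the learning rate",
                     epoch, lr), call. = FALSE)
      }
      grads <- clip_grads(res$grads, cfg$clip_norm)
      stepped <- adam_step(params, grads, opt, lr,
                           beta1 = cfg$beta1, beta2 = cfg$beta2,
                           weight_decay = cfg$weight_decay)
      params <- stepped$params
      opt <- stepped$state
      loss_sum <- loss_sum + res$loss * length(idx)
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = loss_sum / n,
                                    lr = lr)
  }
  model$params <- params
  list(model = model, history = dplyr::bind_rows(hist))
}

# ---- classification head -------------------------------------------------

#' Attach a classification head to an encoder
#'
#' Builds the downstream classifier: the (pre)trained encoder, a pooled
#' representation (the classification token after the final LayerNorm by
#' default — masked-reconstruction pretraining concentrates record-level
#' summary information there; mean pooling over the 240 patch tokens via
#' `pool = "mean"`), then two fully connected layers
#' (embed_dim -> 128 -> n_outputs, GELU in between) and a sigmoid per
#' output. [finetune()] optionally inserts a fixed whitening of the
#' pooled features in front of the head.
#'
#' @param x An `mae_model` (its encoder is taken over) or an
#'   `ecg_classifier` (re-headed).
#' @param n_outputs Number of labels (1 for LVSD; 71/44/19/12 for the
#'   benchmark statement tasks).
#' @param hidden Width of the intermediate layer (default 128).
#' @param pool `"cls"` or `"mean"`.
#' @param seed Seed for the head initialization.
#' @return An `ecg_classifier`.
#' @export
attach_head <- function(x, n_outputs = 1L, hidden = 128L,
                        pool = c("cls", "mean"), seed = 1L) {
  pool <- match.arg(pool)
  if (n_outputs < 1L) stop("n_outputs must be >= 1", call. = FALSE)
  enc_cfg <- x$enc_cfg
  enc_params <- x$params$enc
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  E <- enc_cfg$embed_dim
  head <- list(
    fc1_W = xavier_uniform(E, as.integer(hidden)),
    fc1_b = matrix(0, 1, hidden),
    fc2_W = xavier_uniform(as.integer(hidden), as.integer(n_outputs)),
    fc2_b = matrix(0, 1, n_outputs)
  )
  structure(list(
    enc_cfg = enc_cfg, n_outputs = as.integer(n_outputs),
    pool = pool, n_lead = x$n_lead %||% 12L, n_time = x$n_time %||% 20L,
    params = list(enc = enc_params, head = head),
    pos_enc = x$pos_enc %||% grid_pos_embed(E),
    feat_center = NULL, feat_whiten = NULL   # set by finetune()
  ), class = "ecg_classifier")
}

#' Pooled encoder features for a set of records
#'
#' Runs the classifier's encoder over full (unmasked) records and returns
#' the pooled representation each record presents to the head, before any
#' whitening: the classification token or the mean over patch tokens,
#' after the final LayerNorm.
#'
#' @param classifier An `ecg_classifier`.
#' @param x List of [ecg_record()]s or patch matrices.
#' @return Numeric matrix, records x embed_dim.
#' @export
pooled_features <- function(classifier, x) {
  patches <- prepare_patches(x)
  n_grid <- classifier$n_lead * classifier$n_time
  vis0 <- seq_len(n_grid) - 1L
  t(vapply(patches, function(p) {
    tok <- cpp_encode(classifier$params$enc, classifier$enc_cfg$n_heads,
                      p, vis0, classifier$pos_enc)
    if (classifier$pool == "cls") tok[1, ] else colMeans(tok[-1, , drop = FALSE])
  }, numeric(classifier$enc_cfg$embed_dim)))
}

# rank-truncated ZCA whitening of the pooled training features: principal
# directions with near-zero training variance are projected out rather
# than amplified
fit_whitening <- function(features, rel_floor = 1e-4) {
  pc <- stats::prcomp(features)
  keep <- which(pc$sdev > rel_floor * pc$sdev[1])
  V <- pc$rotation[, keep, drop = FALSE]
  W <- V %*% diag(1 / pc$sdev[keep], length(keep)) %*% t(V)
  list(center = matrix(pc$center, 1), whiten = W)
}

clf_whiten_args <- function(classifier) {
  if (is.null(classifier$feat_whiten)) {
    list(mu = matrix(0, 1, 1), W = matrix(0, 1, 1), use = FALSE)
  } else {
    list(mu = classifier$feat_center, W = classifier$feat_whiten,
         use = TRUE)
  }
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("<ecg_classifier> %s encoder (%d-d, depth %d) + 2-FC sigmoid head, %d output(s), %s pooling\n",
              x$enc_cfg$preset, x$enc_cfg$embed_dim, x$enc_cfg$depth,
              x$n_outputs, x$pool))
  invisible(x)
}

#' Predict per-record probabilities
#'
#' @param object An `ecg_classifier`.
#' @param x List of [ecg_record()]s or pre-patchified matrices.
#' @param ... Unused.
#' @return Numeric matrix (records x outputs); a vector when there is a
#'   single output.
#' @export
predict.ecg_classifier <- function(object, x, ...) {
  patches <- prepare_patches(x)
  wa <- clf_whiten_args(object)
  probs <- cpp_clf_predict(object$params$enc, object$params$head,
                           object$enc_cfg$n_heads, patches,
                           object$pos_enc, object$pool == "cls",
                           wa$mu, wa$W, wa$use)
  if (object$n_outputs == 1L) drop(probs) else probs
}

# ---- plateau scheduler ---------------------------------------------------

#' Initialize the plateau scheduler state
#'
#' @param lr Initial learning rate.
#' @param plateau_patience Non-improving epochs before each halving
#'   (default 3).
#' @param stop_patience Non-improving epochs before stopping (default 10).
#' @param factor Learning-rate factor at each plateau (default 1/2).
#' @return A `train_state`.
#' @export
scheduler_init <- function(lr, plateau_patience = 3L, stop_patience = 10L,
                           factor = 0.5) {
  stopifnot(plateau_patience >= 1, stop_patience >= plateau_patience)
  structure(list(epoch = 0L, best = Inf, since_improve = 0L, lr = lr,
                 plateau_patience = as.integer(plateau_patience),
                 stop_patience = as.integer(stop_patience), factor = factor,
                 improved = FALSE, stop = FALSE),
            class = "train_state")
}

#' One plateau-scheduler step
#'
#' Pure function implementing the fine-tuning schedule: a strict
#' improvement of the monitored (validation) loss resets the
#' non-improvement counter and marks the epoch's weights as best; otherwise
#' the counter increments, the learning rate is halved whenever the counter
#' reaches a positive multiple of `plateau_patience` (3), and training
#' stops when it reaches `stop_patience` (10), restoring the best weights.
#' A tie is a non-improvement under the strict `<` rule.
#'
#' @param state A `train_state` from [scheduler_init()].
#' @param epoch_val_loss The monitored loss for the epoch just finished.
#' @return Updated `train_state`; fields `improved` (snapshot weights now)
#'   and `stop` (halt and restore best) direct the training loop.
#' @export
scheduler_step <- function(state, epoch_val_loss) {
  stopifnot(inherits(state, "train_state"))
  state$epoch <- state$epoch + 1L
  if (epoch_val_loss < state$best) {
    state$best <- epoch_val_loss
    state$since_improve <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    state$since_improve <- state$since_improve + 1L
    if (state$since_improve %% state$plateau_patience == 0L) {
      state$lr <- state$lr * state$factor
    }
    if (state$since_improve >= state$stop_patience) {
      state$stop <- TRUE
    }
  }
  state
}

# ---- fine-tuning ---------------------------------------------------------

#' Fine-tuning configuration
#'
#' The downstream protocol: Adam on binary cross-entropy, batch size from
#' \{32, 64, 128, 256\}, initial learning rate from \{1e-3, 1e-4, 1e-5,
#' 1e-6\}, up to `max_epochs` epochs with the plateau rule (halve after 3
#' non-improving validation epochs, stop after 10, keep the best-epoch
#' weights).
#'
#' @param batch_size Records per step.
#' @param lr Initial learning rate.
#' @param max_epochs Maximum epochs (default 100).
#' @param plateau_patience,stop_patience,lr_factor Plateau rule parameters.
#' @param layer_decay Layer-wise learning-rate decay: the head trains at
#'   the full rate, encoder block `i` (of `depth`) at
#'   `layer_decay^(depth + 1 - i)`, the patch projection and class token
#'   at `layer_decay^(depth + 1)`. `1` disables the schedule.
#' @param whiten Fit a fixed rank-truncated ZCA whitening of the pooled
#'   training features before the head (recommended: with scarce labels
#'   the discriminative directions of a pretrained representation often
#'   carry little variance, and an unwhitened gradient-trained head
#'   cannot reach them).
#' @param freeze_encoder Train only the head on frozen pooled features
#'   (the low-label desk protocol: with very few labeled records, any
#'   practical end-to-end learning rate degrades the pretrained features
#'   faster than the head can exploit them). The encoder forward pass
#'   runs once per record; the head still trains with Adam under the
#'   plateau rule.
#' @param seed Seed for batch shuffling.
#' @return A `finetune_config`.
#' @export
finetune_config <- function(batch_size = 32L, lr = 1e-4, max_epochs = 100L,
                            plateau_patience = 3L, stop_patience = 10L,
                            lr_factor = 0.5, layer_decay = 0.75,
                            whiten = TRUE, freeze_encoder = FALSE,
                            seed = 1L) {
  stopifnot(max_epochs >= 0, plateau_patience >= 1,
            stop_patience >= plateau_patience,
            layer_decay > 0, layer_decay <= 1)
  structure(as.list(environment()), class = "finetune_config")
}

as_label_matrix <- function(labels, n) {
  lab <- if (is.matrix(labels)) labels else matrix(as.numeric(labels), ncol = 1)
  stopifnot(nrow(lab) == n)
  lab
}

clf_loss <- function(classifier, patches, labels) {
  # mean BCE over a set, computed in batches of 64
  n <- length(patches)
  wa <- clf_whiten_args(classifier)
  total <- 0
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    res <- cpp_clf_grad(classifier$params$enc, classifier$params$head,
                        classifier$enc_cfg$n_heads, patches[idx],
                        labels[idx, , drop = FALSE], classifier$pos_enc,
                        classifier$pool == "cls", wa$mu, wa$W, wa$use,
                        FALSE)
    total <- total + res$loss * length(idx)
  }
  total / n
}

#' Fine-tune a classifier with the plateau schedule
#'
#' Minimizes (multi-label) binary cross-entropy with Adam; after every
#' epoch the validation loss drives [scheduler_step()]. Returns the weights
#' of the best validation epoch, even when training runs to `max_epochs`
#' without triggering the early stop.
#'
#' @param classifier An `ecg_classifier` from [attach_head()].
#' @param train_x,val_x Lists of [ecg_record()]s (or patch matrices).
#' @param train_y,val_y Label vectors (binary) or matrices (multi-label).
#' @param cfg A [finetune_config()].
#' @return List with `classifier` (best weights), `history` tibble (epoch,
#'   train_loss, val_loss, lr, improved), `best_val_loss`, `epochs_run`.
#' @export
finetune <- function(classifier, train_x, train_y, val_x, val_y,
                     cfg = finetune_config()) {
  stopifnot(inherits(classifier, "ecg_classifier"))
  if (length(train_x) == 0L) stop("empty training set", call. = FALSE)
  train_p <- prepare_patches(train_x)
  val_p <- prepare_patches(val_x)
  train_l <- as_label_matrix(train_y, length(train_p))
  val_l <- as_label_matrix(val_y, length(val_p))
  if (length(unique(as.vector(train_l))) < 2L) {
    warning("training labels contain a single class", call. = FALSE)
  }
  if (cfg$max_epochs == 0L) {
    return(list(classifier = classifier,
                history = tibble::tibble(), best_val_loss = NA_real_,
                epochs_run = 0L))
  }
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  if (isTRUE(cfg$whiten)) {
    wt <- fit_whitening(pooled_features(classifier, train_p))
    classifier$feat_center <- wt$center
    classifier$feat_whiten <- wt$whiten
  }
  if (isTRUE(cfg$freeze_encoder)) {
    return(head_only_finetune(classifier, train_p, train_l, val_p, val_l,
                              cfg))
  }
  wa <- clf_whiten_args(classifier)
  params <- classifier$params
  opt <- adam_init(params)
  lr_mult <- if (cfg$layer_decay < 1) {
    layer_lr_mult(params, cfg$layer_decay)
  } else {
    NULL
  }
  state <- scheduler_init(cfg$lr, cfg$plateau_patience, cfg$stop_patience,
                          cfg$lr_factor)
  best_params <- params
  n <- length(train_p)
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      res <- cpp_clf_grad(params$enc, params$head,
                          classifier$enc_cfg$n_heads, train_p[idx],
                          train_l[idx, , drop = FALSE], classifier$pos_enc,
                          classifier$pool == "cls", wa$mu, wa$W, wa$use,
                          TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite fine-tuning loss at epoch %d", epoch),
             call. = FALSE)
      }
      stepped <- adam_step(params, res$grads, opt, state$lr,
                           lr_mult = lr_mult)
      params <- stepped$params
      opt <- stepped$state
      loss_sum <- loss_sum + res$loss * length(idx)
    }
    tmp <- classifier
    tmp$params <- params
    val_loss <- clf_loss(tmp, val_p, val_l)
    state <- scheduler_step(state, val_loss)
    if (state$improved) best_params <- params
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = loss_sum / n,
                                    val_loss = val_loss, lr = state$lr,
                                    improved = state$improved)
    if (state$stop) break
  }
  classifier$params <- best_params
  list(classifier = classifier, history = dplyr::bind_rows(hist),
       best_val_loss = state$best, epochs_run = state$epoch)
}

#' Fine-tune over a batch-size / learning-rate grid
#'
#' Runs [finetune()] for every combination and returns the cell with the
#' lowest best-epoch validation loss, along with a summary of the grid.
#'
#' @inheritParams finetune
#' @param batch_sizes,lrs Grid values (defaults: the studied grids).
#' @param cfg Template [finetune_config()]; batch size and learning rate
#'   are overridden per cell.
#' @return List with `best` (the winning [finetune()] result), `grid`
#'   summary tibble, `best_batch_size`, `best_lr`.
#' @export
finetune_grid <- function(classifier, train_x, train_y, val_x, val_y,
                          batch_sizes = c(32L, 64L, 128L, 256L),
                          lrs = c(1e-3, 1e-4, 1e-5, 1e-6),
                          cfg = finetune_config()) {
  cells <- expand.grid(batch_size = batch_sizes, lr = lrs)
  best <- NULL
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell_cfg <- cfg
    cell_cfg$batch_size <- cells$batch_size[[i]]
    cell_cfg$lr <- cells$lr[[i]]
    fit <- finetune(classifier, train_x, train_y, val_x, val_y, cell_cfg)
    rows[[i]] <- tibble::tibble(batch_size = cells$batch_size[[i]],
                                lr = cells$lr[[i]],
                                best_val_loss = fit$best_val_loss,
                                epochs_run = fit$epochs_run)
    if (is.null(best) || fit$best_val_loss < best$best_val_loss) {
      best <- fit
      best$batch_size <- cells$batch_size[[i]]
      best$lr <- cells$lr[[i]]
    }
  }
  list(best = best, grid = dplyr::bind_rows(rows),
       best_batch_size = best$batch_size, best_lr = best$lr)
}

#' @export
tidy.train_state <- function(x, ...) {
  tibble::tibble(epoch = x$epoch, best = x$best,
                 since_improve = x$since_improve, lr = x$lr,
                 improved = x$improved, stop = x$stop)
}

# ---- frozen-encoder (head-only) fine-tuning ------------------------------

# exact GELU and its derivative, matching the compiled head
head_gelu <- function(x) x * stats::pnorm(x)
head_gelu_deriv <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

head_forward <- function(head, Z) {
  h1pre <- sweep(Z %*% head$fc1_W, 2, head$fc1_b, "+")
  h1 <- head_gelu(h1pre)
  logits <- sweep(h1 %*% head$fc2_W, 2, head$fc2_b, "+")
  list(h1pre = h1pre, h1 = h1, logits = logits)
}

head_bce <- function(logits, labels) {
  # numerically stable mean BCE from logits
  mean(log1p(exp(-abs(logits))) + pmax(logits, 0) - logits * labels)
}

# trains the two-FC head with Adam under the plateau rule on pooled
# (optionally whitened) features extracted once through the frozen encoder
head_only_finetune <- function(classifier, train_p, train_l, val_p, val_l,
                               cfg) {
  apply_whiten <- function(F) {
    if (is.null(classifier$feat_whiten)) return(F)
    sweep(F, 2, drop(classifier$feat_center)) %*% classifier$feat_whiten
  }
  Ztr <- apply_whiten(pooled_features(classifier, train_p))
  Zva <- apply_whiten(pooled_features(classifier, val_p))
  head <- classifier$params$head
  opt <- adam_init(head)
  state <- scheduler_init(cfg$lr, cfg$plateau_patience, cfg$stop_patience,
                          cfg$lr_factor)
  best_head <- head
  n <- nrow(Ztr)
  K <- ncol(train_l)
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Z <- Ztr[idx, , drop = FALSE]
      y <- train_l[idx, , drop = FALSE]
      B <- length(idx)
      fw <- head_forward(head, Z)
      loss <- head_bce(fw$logits, y)
      dz <- (stats::plogis(fw$logits) - y) / (K * B)
      dh1 <- dz %*% t(head$fc2_W)
      dh1pre <- dh1 * head_gelu_deriv(fw$h1pre)
      grads <- list(
        fc1_W = t(Z) %*% dh1pre,
        fc1_b = matrix(colSums(dh1pre), 1),
        fc2_W = t(fw$h1) %*% dz,
        fc2_b = matrix(colSums(dz), 1)
      )
      stepped <- adam_step(head, grads, opt, state$lr)
      head <- stepped$params
      opt <- stepped$state
      loss_sum <- loss_sum + loss * B
    }
    val_loss <- head_bce(head_forward(head, Zva)$logits, val_l)
    state <- scheduler_step(state, val_loss)
    if (state$improved) best_head <- head
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = loss_sum / n,
                                    val_loss = val_loss, lr = state$lr,
                                    improved = state$improved)
    if (state$stop) break
  }
  classifier$params$head <- best_head
  list(classifier = classifier, history = dplyr::bind_rows(hist),
       best_val_loss = state$best, epochs_run = state$epoch)
}
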