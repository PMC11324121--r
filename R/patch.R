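#' Split a 12-lead record into the 12 x 20 patch grid
#'
#' Divides each lead of a 12 x 5000 record into 20 non-overlapping patches
#' of 250 contiguous samples (0.5 s at 500 Hz), giving 240 patches per
#' record. Patches are ordered lead-major: patch index
#' `(lead - 1) * 20 + time_slot`, with `time_slot` 1..20 covering samples
#' `(time_slot - 1) * 250 + 1 .. time_slot * 250` (a half-open window in
#' 0-based terms).
#'
#' @param x An [ecg_record()] or a numeric 12 x N matrix with N divisible
#'   by 250.
#' @return An `ecg_patches` matrix: 240 rows x 250 columns with grid
#'   attributes.
#' @export
patchify <- function(x) {
  sig <- if (inherits(x, "ecg_record")) x$signal else as.matrix(x)
  if (nrow(sig) != 12L) stop("signal must have 12 leads", call. = FALSE)
  if (ncol(sig) %% 250L != 0L) {
    stop("sample count not divisible by the 250-sample patch length",
         call. = FALSE)
  }
  n_time <- ncol(sig) %/% 250L
  out <- matrix(0, nrow = 12L * n_time, ncol = 250L)
  for (l in 1:12) {
    for (s in seq_len(n_time)) {
      out[(l - 1L) * n_time + s, ] <- sig[l, ((s - 1L) * 250L + 1L):(s * 250L)]
    }
  }
  structure(out, class = c("ecg_patches", "matrix", "array"),
            n_lead = 12L, n_time = n_time, patch_len = 250L)
}

#' Reassemble a signal from its patch grid
#'
#' Exact inverse of [patchify()]: `unpatchify(patchify(x))` is bitwise equal
#' to `x`.
#'
#' @param patches An `ecg_patches` matrix (rows = patches, lead-major).
#' @param n_lead,n_time Grid shape; taken from attributes when present.
#' @return Numeric `n_lead` x `n_time * 250` matrix.
#' @export
unpatchify <- function(patches, n_lead = NULL, n_time = NULL) {
  n_lead <- n_lead %||% attr(patches, "n_lead") %||% 12L
  n_time <- n_time %||% attr(patches, "n_time") %||%
    (nrow(patches) %/% n_lead)
  if (nrow(patches) != n_lead * n_time || ncol(patches) != 250L) {
    stop(sprintf("expected %d x 250 patches, got %d x %d",
                 n_lead * n_time, nrow(patches), ncol(patches)),
         call. = FALSE)
  }
  sig <- matrix(0, n_lead, n_time * 250L)
  for (l in seq_len(n_lead)) {
    for (s in seq_len(n_time)) {
      sig[l, ((s - 1L) * 250L + 1L):(s * 250L)] <-
        patches[(l - 1L) * n_time + s, ]
    }
  }
  sig
}

#' Build a masking plan over the patch grid
#'
#' Produces the visible/masked partition of the 240 patch indices under one
#' of the three strategies studied for MAE pretraining:
#'
#' * `"random"` — a seeded uniform shuffle of all 240 indices; the first
#'   `round(240 * (1 - ratio))` stay visible. All studied ratios (0.5,
#'   0.75, 0.9) give integer visible counts (120, 60, 24).
#' * `"per_lead"` — within each lead independently, `round(20 * ratio)`
#'   of the 20 patches are masked (15 per lead at ratio 0.75).
#' * `"grid"` — a regular keep-1-of-4-along-time pattern: a patch is
#'   visible iff its 0-based time slot modulo 4 equals a seed-derived
#'   phase. Defined for ratio 0.75 only.
#'
#' The returned object also records the shuffle order (visible indices
#' first, then masked) and the permutation that restores canonical order,
#' mirroring how the MAE shuffles tokens before the encoder and unshuffles
#' before the decoder.
#'
#' @param ratio Masking ratio in \[0, 1\].
#' @param strategy `"random"`, `"grid"` or `"per_lead"`.
#' @param seed Integer seed; masks are deterministic in it.
#' @param n_lead,n_time Grid shape (12 x 20 by default).
#' @return An `ecg_mask` list with 1-based `visible` and `masked` index
#'   vectors, `shuffle` and `restore` permutations, and the plan metadata.
#' @export
make_mask <- function(ratio = 0.75, strategy = c("random", "grid", "per_lead"),
                      seed = 1L, n_lead = 12L, n_time = 20L) {
  strategy <- match.arg(strategy)
  if (ratio < 0 || ratio > 1) stop("ratio must be in [0, 1]", call. = FALSE)
  n <- n_lead * n_time
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  if (strategy == "random") {
    n_vis <- round(n * (1 - ratio))
    perm <- sample.int(n)
    visible <- sort(perm[seq_len(n_vis)])
  } else if (strategy == "per_lead") {
    n_mask_per <- round(n_time * ratio)
    masked <- integer(0)
    for (l in seq_len(n_lead)) {
      slots <- sample.int(n_time, n_mask_per)
      masked <- c(masked, (l - 1L) * n_time + slots)
    }
    visible <- sort(setdiff(seq_len(n), masked))
  } else { # grid
    if (abs(ratio - 0.75) > 1e-12) {
      stop("grid masking is defined for ratio 0.75 only", call. = FALSE)
    }
    phase <- seed %% 4L
    time0 <- (seq_len(n) - 1L) %% n_time       # 0-based time slot
    visible <- which(time0 %% 4L == phase)
  }
  masked <- setdiff(seq_len(n), visible)
  shuffle <- c(visible, masked)
  restore <- order(shuffle)
  structure(list(ratio = ratio, strategy = strategy, seed = as.integer(seed),
                 n_lead = as.integer(n_lead), n_time = as.integer(n_time),
                 visible = as.integer(visible), masked = as.integer(masked),
                 shuffle = as.integer(shuffle),
                 restore = as.integer(restore)),
            class = "ecg_mask")
}

#' @export
print.ecg_mask <- function(x, ...) {
  cat(sprintf("<ecg_mask> %s, ratio %.2f: %d visible / %d masked of %d\n",
              x$strategy, x$ratio, length(x$visible), length(x$masked),
              x$n_lead * x$n_time))
  invisible(x)
}

#' Serialize / restore a masking plan as JSON
#'
#' Masks are small index sets; JSON keeps pretraining runs reproducible and
#' auditable alongside their manifests.
#'
#' @param mask An `ecg_mask`.
#' @param json A JSON string produced by `mask_to_json()`.
#' @return `mask_to_json()` a JSON string; `mask_from_json()` an `ecg_mask`.
#' @export
mask_to_json <- function(mask) {
  stopifnot(inherits(mask, "ecg_mask"))
  jsonlite::toJSON(unclass(mask), auto_unbox = TRUE, digits = NA)
}

#' @rdname mask_to_json
#' @export
mask_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(ratio = x$ratio, strategy = x$strategy,
                 seed = as.integer(x$seed),
                 n_lead = as.integer(x$n_lead), n_time = as.integer(x$n_time),
                 visible = as.integer(x$visible),
                 masked = as.integer(x$masked),
                 shuffle = as.integer(x$shuffle),
                 restore = as.integer(x$restore)),
            class = "ecg_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
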