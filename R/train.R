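# Soft-Dice training with Adam, checkpointing, and the preprocessing
# pipeline (clip -> Z-score -> crop -> optional augmentation) feeding it.

adam_init <- function(weights) {
  list(m = lapply(weights, function(a) a * 0), # keeps each parameter's exact shape
       v = lapply(weights, function(a) a * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

#' Preprocess one case for the network
#'
#' Applies the preprocessing chain in order: percentile clipping + Z-score
#' standardization over nonzero voxels, random brain-preserving crop to the
#' network input size, then (optionally) random augmentation.
#'
#' @param case list with `volume`, `labels` (or `NULL`), `spacing` as
#'   returned by [read_case()] or [generate_phantom()].
#' @param cfg a [getnet_config()]; supplies the crop size.
#' @param seed integer seed driving crop and augmentation.
#' @param augment_p per-transform augmentation probability; 0 disables
#'   augmentation.
#' @return list with `volume`, `labels`, `regions` (binary `(3, D, H, W)` or
#'   `NULL`) and `spacing`.
#' @export
preprocess_case <- function(case, cfg, seed = 1L, augment_p = 0) {
  v <- clip_and_zscore(case$volume)
  cr <- crop_to_patch(v, case$labels, size = cfg$input_size, seed = seed)
  v <- cr$volume; l <- cr$labels
  if (augment_p > 0) {
    au <- augment(v, l, seed = seed + 1L, p_apply = augment_p)
    v <- au$volume; l <- au$labels
  }
  list(volume = v, labels = l,
       regions = if (is.null(l)) NULL else labels_to_regions(l) * 1,
       spacing = case$spacing %||% c(1, 1, 1))
}

#' Train the network on a set of cases
#'
#' Plain single-case (batch size 1) Adam optimization of the soft Dice loss,
#' the recipe used at full scale (Adam, learning rate 1e-4); cases are
#' visited cyclically. With a fixed seed the loss trajectory is reproducible.
#'
#' @param cfg a [getnet_config()].
#' @param cases list of preprocessed cases (each with `volume` and
#'   `regions`); see [preprocess_case()].
#' @param steps number of optimization steps.
#' @param lr learning rate (default 1e-4).
#' @param weights optional warm-start weights; default fresh init from
#'   `seed`.
#' @param opt_state optional Adam state to resume from.
#' @param seed integer seed for the weight init.
#' @param verbose print the loss every `verbose` steps (0 = silent).
#' @return list with `weights`, `opt_state` and `history` (per-step loss).
#' @export
train_getnet <- function(cfg, cases, steps = 200L, lr = 1e-4,
                         weights = NULL, opt_state = NULL, seed = 1L,
                         verbose = 0L) {
  if (length(cases) == 0) stop_validation("no labeled cases to train on")
  for (cs in cases) if (is.null(cs$regions))
    stop_validation("training requires labeled cases")
  if (is.null(weights)) weights <- init_getnet_weights(cfg, seed = seed)
  state <- opt_state %||% adam_init(weights)
  history <- numeric(steps)
  for (it in seq_len(steps)) {
    cs <- cases[[(it - 1L) %% length(cases) + 1L]]
    lg <- getnet_loss_grad(cfg, weights, cs$volume, cs$regions)
    history[it] <- lg$loss
    up <- adam_step(weights, lg$grads, state, lr = lr)
    weights <- up$weights; state <- up$state
    if (verbose > 0 && it %% verbose == 0)
      message(sprintf("step %d loss %.4f", it, lg$loss))
  }
  list(weights = weights, opt_state = state, history = history)
}

#' Save / load a training checkpoint
#'
#' The checkpoint embeds the configuration, weights, optimizer state and
#' loss history, so training resumes exactly.
#'
#' @param path file path.
#' @param cfg,weights,opt_state,history checkpoint contents.
#' @return `load_checkpoint` returns the checkpoint list.
#' @export
save_checkpoint <- function(path, cfg, weights, opt_state = NULL, history = NULL) {
  saveRDS(list(cfg = cfg, weights = weights, opt_state = opt_state,
               history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck$cfg, "getnet_config")) stop_validation("not a checkpoint file: %s", path)
  ck
}

#' Seeded train/validation split of case directories
#'
#' Shuffle split (default 80/20, the full-scale protocol); the split seed is
#' exposed because no canonical split exists.
#'
#' @param case_dirs character vector of case directories.
#' @param train_frac training fraction.
#' @param seed split seed.
#' @return list with `train` and `val` character vectors.
#' @export
split_cases <- function(case_dirs, train_frac = 0.8, seed = 1L) {
  n <- length(case_dirs)
  idx <- with_seed(seed, sample.int(n))
  k <- floor(train_frac * n)
  list(train = case_dirs[idx[seq_len(k)]],
       val = case_dirs[idx[setdiff(seq_len(n), seq_len(k))]])
}
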