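# Dataset splitting, Adam mini-batch training with a plateau learning-rate
# schedule, and evaluation.

#' Training configuration
#'
#' Defaults follow the reference protocol: batches of 64, Adam with initial
#' learning rate 0.001 decreased by a factor of 8 on validation-loss
#' plateaus down to a floor of 1e-6, and an 80/10/10 train/validation/test
#' split.  The plateau window (`plateau_patience`) and relative improvement
#' threshold are implementation defaults.
#'
#' @param batch_size Mini-batch size.
#' @param initial_lr,lr_floor,lr_factor Learning-rate schedule.
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is multiplied by `lr_factor`.
#' @param improvement_tol Relative improvement below which an epoch does not
#'   count as progress.
#' @param max_epochs Training length.
#' @param seed Seed controlling shuffling, dropout and initialization.
#' @param weights A [loss_weights()].
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @return List of class `"train_config"`.
#' @export
train_config <- function(batch_size = 64L, initial_lr = 1e-3, lr_floor = 1e-6,
                         lr_factor = 1 / 8, plateau_patience = 20L,
                         improvement_tol = 1e-4, max_epochs = 100L, seed = 1L,
                         weights = loss_weights(),
                         split_fractions = c(0.8, 0.1, 0.1)) {
  if (abs(sum(split_fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (lr_floor >= initial_lr) stop("lr_floor must be below initial_lr")
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_floor = lr_floor, lr_factor = lr_factor,
                 plateau_patience = as.integer(plateau_patience),
                 improvement_tol = improvement_tol,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 weights = weights, split_fractions = split_fractions),
            class = "train_config")
}

#' Split frame indices into train/validation/test sets
#'
#' Disjoint, exhaustive, deterministic given the seed.  Counts are
#' `floor(fraction * n)` for train and validation; the remainder is the
#' test set.
#'
#' @param n_frames Number of frames (or any units to split).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_frames, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (n_frames < 3L) stop("need at least 3 frames to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  perm <- sample.int(n_frames)
  n_tr <- max(1L, floor(fractions[1L] * n_frames))
  n_va <- max(1L, floor(fractions[2L] * n_frames))
  list(train = sort(perm[seq_len(n_tr)]),
       val = sort(perm[n_tr + seq_len(n_va)]),
       test = sort(perm[(n_tr + n_va + 1L):n_frames]))
}

# Adam state initialized lazily per parameter tensor
.adam_new <- function() list(t = 0L, m = list(), v = list())

.adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# flatten model parameters / gradients to a named list of tensors
.model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$encoder)) {
    p[[paste0("e", i, ".W")]] <- model$encoder[[i]]$conv$W
    p[[paste0("e", i, ".b")]] <- model$encoder[[i]]$conv$b
    p[[paste0("e", i, ".g")]] <- model$encoder[[i]]$bn$gamma
    p[[paste0("e", i, ".be")]] <- model$encoder[[i]]$bn$beta
  }
  for (j in seq_along(model$decoder)) {
    p[[paste0("d", j, ".W")]] <- model$decoder[[j]]$tconv$W
    p[[paste0("d", j, ".b")]] <- model$decoder[[j]]$tconv$b
  }
  p[["f.W"]] <- model$final$W
  p[["f.b"]] <- model$final$b
  p
}

.model_grads <- function(grads, model) {
  g <- list()
  for (i in seq_along(model$encoder)) {
    g[[paste0("e", i, ".W")]] <- grads$encoder[[i]]$conv$dW
    g[[paste0("e", i, ".b")]] <- grads$encoder[[i]]$conv$db
    g[[paste0("e", i, ".g")]] <- grads$encoder[[i]]$bn$dgamma
    g[[paste0("e", i, ".be")]] <- grads$encoder[[i]]$bn$dbeta
  }
  for (j in seq_along(model$decoder)) {
    g[[paste0("d", j, ".W")]] <- grads$decoder[[j]]$tconv$dW
    g[[paste0("d", j, ".b")]] <- grads$decoder[[j]]$tconv$db
  }
  g[["f.W"]] <- grads$final$dW
  g[["f.b"]] <- grads$final$db
  g
}

.set_model_params <- function(model, p) {
  for (i in seq_along(model$encoder)) {
    model$encoder[[i]]$conv$W <- p[[paste0("e", i, ".W")]]
    model$encoder[[i]]$conv$b <- p[[paste0("e", i, ".b")]]
    model$encoder[[i]]$bn$gamma <- p[[paste0("e", i, ".g")]]
    model$encoder[[i]]$bn$beta <- p[[paste0("e", i, ".be")]]
  }
  for (j in seq_along(model$decoder)) {
    model$decoder[[j]]$tconv$W <- p[[paste0("d", j, ".W")]]
    model$decoder[[j]]$tconv$b <- p[[paste0("d", j, ".b")]]
  }
  model$final$W <- p[["f.W"]]
  model$final$b <- p[["f.b"]]
  model
}

#' Train the backmapping U-net
#'
#' Mini-batch Adam with the plateau learning-rate schedule; the checkpoint
#' with the best validation loss is retained.  Frames (not individual chain
#' samples) are partitioned into train/validation/test so chains of one
#' frame never straddle splits.
#'
#' @param model A [build_unet()] model.
#' @param data An [encode_dataset()] result.
#' @param config A [train_config()].
#' @param chain Chain topology underlying the samples (for the loss
#'   bookkeeping); defaults to the first chain of the ensemble.
#' @param Qs Optional list of per-sample bead matrices (required only for
#'   angle/dihedral loss weights).
#' @param verbose Print one line per epoch?
#' @return List with `model` (best-validation weights), `history` (data
#'   frame: epoch, lr, train/validation losses), `split`, `final_model`.
#' @export
train_backmapper <- function(model, data, config = train_config(),
                             chain = NULL, Qs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (is.null(chain)) chain <- data$chain_topology
  ctx <- loss_context(chain, data$scales)
  n_frames <- max(data$frame)
  split <- split_dataset(n_frames, config$split_fractions, config$seed)
  idx_of <- function(fr) which(data$frame %in% fr)
  tr_idx <- idx_of(split$train); va_idx <- idx_of(split$val)
  set.seed(config$seed)
  S <- model$S
  Xall <- .batch_to_mat(data$inputs)    # (n*S, C), sample-major rows
  Tall <- .batch_to_mat(data$targets)
  rows_of <- function(bi) rep((bi - 1L) * S, each = S) + seq_len(S)
  adam <- .adam_new()
  weights <- config$weights
  best_val <- Inf; best_model <- model
  hist <- vector("list", config$max_epochs)
  lr <- config$initial_lr
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; n_done <- 0L
    for (start in seq(1L, length(order_idx), by = config$batch_size)) {
      bi <- order_idx[start:min(start + config$batch_size - 1L, length(order_idx))]
      B <- length(bi)
      rows <- rows_of(bi)
      X <- Xall[rows, , drop = FALSE]
      Tm <- Tall[rows, , drop = FALSE]
      fwd <- .unet_forward_mat(model, X, B, training = TRUE)
      model <- fwd$model
      dOut <- matrix(0, nrow(fwd$Y), 3L)
      for (s in seq_len(B)) {
        rows <- (s - 1L) * S + seq_len(S)
        Q <- if (!is.null(Qs)) Qs[[bi[s]]] else NULL
        lg <- loss_and_grad(fwd$Y[rows, , drop = FALSE],
                            Tm[rows, , drop = FALSE], ctx, weights, Q)
        dOut[rows, ] <- lg$grad / B
        ep_loss <- ep_loss + lg$total
      }
      n_done <- n_done + B
      if (!is.finite(ep_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      g <- .model_grads(.unet_backward_mat(model, fwd$caches, dOut), model)
      upd <- .adam_step(adam, .model_params(model), g, lr)
      adam <- upd$state
      model <- .set_model_params(model, upd$params)
    }
    train_loss <- ep_loss / n_done
    val <- evaluate_model(model, data, va_idx, weights, ctx, Qs,
                          batch_size = config$batch_size,
                          .Xall = Xall, .Tall = Tall)
    val_loss <- val$total
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = train_loss, val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.5g  val %.5g",
                      epoch, lr, train_loss, val_loss))
    }
    if (val_loss < best_val * (1 - config$improvement_tol)) {
      best_val <- val_loss
      best_model <- model
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$plateau_patience && lr > config$lr_floor) {
        lr <- max(config$lr_floor, lr * config$lr_factor)
        stall <- 0L
      }
    }
  }
  list(model = best_model, final_model = model,
       history = do.call(rbind, hist), split = split, best_val = best_val)
}

#' Evaluate mean loss terms over a sample subset
#'
#' Deterministic (dropout off, batch-norm inference statistics).
#'
#' @param model A [build_unet()] model.
#' @param data An [encode_dataset()] result.
#' @param idx Sample indices (default: all).
#' @param weights A [loss_weights()]; angle/dihedral terms are reported only
#'   when their weight is positive or `Qs` is supplied.
#' @param ctx Optional precomputed [loss_context()].
#' @param Qs Optional list of per-sample bead matrices.
#' @param batch_size Forward batch size.
#' @param .Xall,.Tall Optional precomputed sample-major input/target
#'   matrices (internal fast path used by the training loop).
#' @return List with per-term means and `total`.
#' @export
evaluate_model <- function(model, data, idx = NULL, weights = loss_weights(),
                           ctx = NULL, Qs = NULL, batch_size = 64L,
                           .Xall = NULL, .Tall = NULL) {
  if (is.null(idx)) idx <- seq_len(dim(data$inputs)[1L])
  if (is.null(ctx)) {
    ctx <- loss_context(data$chain_topology, data$scales)
  }
  need_ang <- (weights$ba > 0 || weights$da > 0) && !is.null(Qs)
  S <- model$S
  if (is.null(.Xall)) .Xall <- .batch_to_mat(data$inputs)
  if (is.null(.Tall)) .Tall <- .batch_to_mat(data$targets)
  terms_acc <- c(bv = 0, bl = 0, ba = 0, da = 0, v0 = 0)
  have_ang <- FALSE
  n <- 0L
  for (start in seq(1L, length(idx), by = batch_size)) {
    bi <- idx[start:min(start + batch_size - 1L, length(idx))]
    B <- length(bi)
    brows <- rep((bi - 1L) * S, each = S) + seq_len(S)
    X <- .Xall[brows, , drop = FALSE]
    Tm <- .Tall[brows, , drop = FALSE]
    fwd <- .unet_forward_mat(model, X, B, training = FALSE)
    for (s in seq_len(B)) {
      rows <- (s - 1L) * S + seq_len(S)
      Q <- if (!is.null(Qs)) Qs[[bi[s]]] else NULL
      tm <- loss_terms(fwd$Y[rows, , drop = FALSE], Tm[rows, , drop = FALSE],
                       ctx, Q, need_angles = need_ang && !is.null(Q))
      for (nm in names(terms_acc)) {
        if (!is.na(tm[[nm]])) terms_acc[[nm]] <- terms_acc[[nm]] + tm[[nm]]
      }
      if (!is.na(tm[["ba"]])) have_ang <- TRUE
    }
    n <- n + B
  }
  terms <- as.list(terms_acc / n)
  if (!have_ang) terms$ba <- terms$da <- NA_real_
  total <- 0
  for (nm in names(weights)) {
    if (weights[[nm]] > 0 && !is.na(terms[[nm]])) {
      total <- total + weights[[nm]] * terms[[nm]]
    }
  }
  c(terms, list(total = total))
}
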