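# 1-D U-net: an encoder of stride-2 convolution blocks (conv -> leaky ReLU
# -> batch norm), a mirrored decoder of stride-2 transposed-convolution
# blocks (tconv -> ReLU, dropout on the first), skip connections that
# concatenate each encoder level onto the matching decoder level, and a
# final stride-1 transposed convolution with tanh onto 3 output channels.

#' U-net architecture configuration
#'
#' Defaults follow the reference architecture: five down/up levels, filters
#' starting at 64 and capped at 512, stride 2, dropout 0.5 on the first
#' up-block, tanh output.  The kernel width (4) and leaky-ReLU slope (0.2)
#' are implementation choices recorded in checkpoints.
#'
#' @param depth Number of down/up blocks.
#' @param base_filters Filters of the first encoder block; doubled per level.
#' @param max_filters Cap on filters per level.
#' @param kernel_size Convolution width.
#' @param stride Down/up-sampling factor per level.
#' @param dropout_rate Dropout rate on the first up-block.
#' @param negative_slope Leaky-ReLU slope in the encoder.
#' @param final_kernel Width of the final stride-1 transposed convolution
#'   (odd, so the length is preserved).
#' @return List of class `"unet_config"`.
#' @export
network_config <- function(depth = 5L, base_filters = 64L, max_filters = 512L,
                           kernel_size = 4L, stride = 2L, dropout_rate = 0.5,
                           negative_slope = 0.2, final_kernel = 3L) {
  stopifnot(depth >= 1L, stride >= 2L, final_kernel %% 2L == 1L)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), dropout_rate = dropout_rate,
                 negative_slope = negative_slope,
                 final_kernel = as.integer(final_kernel)),
            class = "unet_config")
}

#' Build a U-net model
#'
#' @param config A [network_config()].
#' @param k Number of monomer-type slots; input width is `k + 3`.
#' @param S Input length (a power of two divisible by `stride^depth`).
#' @param seed Optional seed for reproducible weight initialization.
#' @return List of class `"unet_model"` with `encoder`/`decoder` layer
#'   stacks, `final` layer, `config`, `k`, `S`.
#' @export
build_unet <- function(config = network_config(), k, S = 1024L, seed = NULL) {
  stopifnot(inherits(config, "unet_config"))
  if (S %% config$stride^config$depth != 0L) {
    stop("input length S = ", S, " is not divisible by stride^depth = ",
         config$stride^config$depth)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  ec <- pmin(config$base_filters * 2L^(seq_len(d) - 1L), config$max_filters)
  dc <- c(rev(ec[-d]), config$base_filters)      # decoder output channels
  encoder <- vector("list", d)
  c_prev <- k + 3L
  for (i in seq_len(d)) {
    encoder[[i]] <- list(
      conv = .layer_conv(c_prev, ec[i], config$kernel_size, config$stride, 1L),
      bn = .layer_bnorm(ec[i]))
    c_prev <- ec[i]
  }
  decoder <- vector("list", d)
  for (j in seq_len(d)) {
    # decoder level j consumes the previous decoder output concatenated with
    # the skip from encoder level d - j + 1 (none for j = 1: bottleneck)
    c_in <- if (j == 1L) ec[d] else dc[j - 1L] + ec[d - j + 1L]
    decoder[[j]] <- list(
      tconv = .layer_tconv(c_in, dc[j], config$kernel_size, config$stride, 1L),
      dropout = if (j == 1L) config$dropout_rate else 0)
  }
  fk <- config$final_kernel
  final <- .layer_tconv(dc[d] + 0L, 3L, fk, 1L, (fk - 1L) %/% 2L)
  structure(list(encoder = encoder, decoder = decoder, final = final,
                 config = config, k = as.integer(k), S = as.integer(S)),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model A [build_unet()] model.
#' @return Integer parameter count (weights, biases, batch-norm affines).
#' @export
count_parameters <- function(model) {
  n <- 0L
  for (e in model$encoder) {
    n <- n + length(e$conv$W) + length(e$conv$b) +
      length(e$bn$gamma) + length(e$bn$beta)
  }
  for (dl in model$decoder) n <- n + length(dl$tconv$W) + length(dl$tconv$b)
  n + length(model$final$W) + length(model$final$b)
}

# forward pass on a (B*S, C) matrix; returns output and (optionally) caches
.unet_forward_mat <- function(model, X, B, training = FALSE) {
  cfg <- model$config
  S <- model$S
  caches <- list(enc = list(), dec = list())
  skips <- list()
  L <- S
  A <- X
  for (i in seq_along(model$encoder)) {
    e <- model$encoder[[i]]
    cv <- .conv_fwd(e$conv, A, L, B)
    ac <- .lrelu_fwd(cv$Y, cfg$negative_slope)
    bn <- .bnorm_fwd(e$bn, ac$Y, training)
    if (training) model$encoder[[i]]$bn <- bn$layer  # running stats
    caches$enc[[i]] <- list(conv = cv$cache, act = ac$cache, bn = bn$cache)
    A <- bn$Y
    L <- cv$L_out
    skips[[i]] <- list(A = A, L = L)
  }
  for (j in seq_along(model$decoder)) {
    dl <- model$decoder[[j]]
    lvl <- length(model$encoder) - j + 1L
    if (j > 1L) {
      sk <- skips[[lvl]]
      caches$dec[[j - 1L]]$c_split <- ncol(A)
      A <- cbind(A, sk$A)
    }
    tc <- .tconv_fwd(dl$tconv, A, L, B)
    ac <- .relu_fwd(tc$Y)
    dr <- .dropout_fwd(ac$Y, dl$dropout, training)
    prev <- if (length(caches$dec) >= j) caches$dec[[j]] else NULL
    caches$dec[[j]] <- c(prev,
                         list(tconv = tc$cache, act = ac$cache, drop = dr$cache))
    A <- dr$Y
    L <- tc$L_out
  }
  fin <- .tconv_fwd(model$final, A, L, B)
  out <- tanh(fin$Y)
  caches$final <- fin$cache
  caches$out <- out
  list(Y = out, caches = caches, model = model)
}

.unet_backward_mat <- function(model, caches, dOut) {
  grads <- list(encoder = vector("list", length(model$encoder)),
                decoder = vector("list", length(model$decoder)))
  dA <- dOut * (1 - caches$out^2)
  fb <- .tconv_bwd(model$final, dA, caches$final)
  grads$final <- list(dW = fb$dW, db = fb$db)
  dA <- fb$dX
  dskip <- vector("list", length(model$encoder))
  for (j in rev(seq_along(model$decoder))) {
    cj <- caches$dec[[j]]
    dA <- .dropout_bwd(dA, cj$drop)
    dA <- .relu_bwd(dA, cj$act)
    tb <- .tconv_bwd(model$decoder[[j]]$tconv, dA, cj$tconv)
    grads$decoder[[j]] <- list(tconv = list(dW = tb$dW, db = tb$db))
    dA <- tb$dX
    if (j > 1L) {
      cs <- caches$dec[[j - 1L]]$c_split
      lvl <- length(model$encoder) - j + 1L
      dskip[[lvl]] <- dA[, -seq_len(cs), drop = FALSE]
      dA <- dA[, seq_len(cs), drop = FALSE]
    }
  }
  for (i in rev(seq_along(model$encoder))) {
    ci <- caches$enc[[i]]
    if (!is.null(dskip[[i]])) dA <- dA + dskip[[i]]
    bb <- .bnorm_bwd(model$encoder[[i]]$bn, dA, ci$bn)
    grads$encoder[[i]]$bn <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
    dA <- .lrelu_bwd(bb$dX, ci$act, model$config$negative_slope)
    cb <- .conv_bwd(model$encoder[[i]]$conv, dA, ci$conv)
    grads$encoder[[i]]$conv <- list(dW = cb$dW, db = cb$db)
    dA <- cb$dX
  }
  grads
}

.batch_to_mat <- function(a) {
  # (B, S, C) array -> (B*S, C) matrix, sample-major rows
  B <- dim(a)[1L]; S <- dim(a)[2L]; C <- dim(a)[3L]
  matrix(aperm(a, c(2L, 1L, 3L)), B * S, C)
}

.mat_to_batch <- function(m, B, S) {
  aperm(array(m, c(S, B, ncol(m))), c(2L, 1L, 3L))
}

#' Forward pass of the U-net
#'
#' @param model A [build_unet()] model.
#' @param inputs Array (B, S, k+3) or matrix (S, k+3) for a single sample.
#' @param training Use batch statistics and dropout?  Evaluation mode
#'   (default) is deterministic.
#' @return Array (B, S, 3) (or matrix (S, 3) for a single-sample matrix
#'   input) with components in (-1, 1).
#' @export
unet_forward <- function(model, inputs, training = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  single <- is.matrix(inputs)
  if (single) inputs <- array(inputs, c(1L, nrow(inputs), ncol(inputs)))
  if (dim(inputs)[2L] != model$S || dim(inputs)[3L] != model$k + 3L) {
    stop("input must be (batch, ", model$S, ", ", model$k + 3L, "); got (",
         paste(dim(inputs), collapse = ", "), ")")
  }
  B <- dim(inputs)[1L]
  out <- .unet_forward_mat(model, .batch_to_mat(inputs), B, training = training)
  Y <- .mat_to_batch(out$Y, B, model$S)
  if (single) Y[1L, , ] else Y
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights and a metadata block
#' (codec scheme version, rescale factors, `k`, composition).  Loading
#' verifies the metadata and reproduces forward outputs bitwise.
#'
#' @param model A [build_unet()] model.
#' @param path File path.
#' @param metadata List with at least `scales` (a [codec_scales()]) and
#'   `composition`.
#' @return `path` invisibly (save); list with `model` and `metadata` (load).
#' @export
save_checkpoint <- function(model, path, metadata) {
  stopifnot(inherits(model, "unet_model"))
  if (is.null(metadata$scales) || is.null(metadata$composition)) {
    stop("checkpoint metadata must carry `scales` and `composition`")
  }
  metadata$scheme <- metadata$scales$scheme
  metadata$k <- model$k
  saveRDS(list(model = model, metadata = metadata, format = "plabackmap-ckpt-1"),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_k If given, loading a checkpoint with a different number
#'   of type slots is an error.
#' @export
load_checkpoint <- function(path, expected_k = NULL) {
  x <- readRDS(path)
  if (!identical(x$format, "plabackmap-ckpt-1")) {
    stop("not a recognizable checkpoint file: ", path)
  }
  if (!identical(x$metadata$scheme, CODEC_SCHEME_VERSION)) {
    stop("checkpoint codec scheme ", x$metadata$scheme,
         " does not match this package (", CODEC_SCHEME_VERSION, ")")
  }
  if (!is.null(expected_k) && x$model$k != expected_k) {
    stop("checkpoint was trained with k = ", x$model$k,
         " monomer types; this input needs k = ", expected_k)
  }
  x
}
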