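# Minimal conv-net machinery for the DPN/PPN pair.
#
# Both networks operate on tiny 2-channel 4 x n "images" (n = 20 histogram
# bins), so the whole stack -- im2col convolutions, LeakyReLU, inverted
# dropout, dense layers, backprop and Adam -- is implemented directly on base
# R matrices. Geometry (pad-1, kernel-3, stride-1 on a fixed 4 x n grid) is
# precomputed once per bin count and cached.

.geom_cache <- new.env(parent = emptyenv())

# Precompute index maps for 'same' 3x3 convolution on a 4 x n grid.
# Spatial index s = r + 4*(c-1) (column-major); padded grid is 6 x (n+2) with
# padded index pp = rr + 6*(cc-1). Activations live channel-first as
# (C, S, B) arrays so that convolution, flattening and backprop are pure
# gathers and matrix products with no transposition.
.conv_geom <- function(n_bins) {
  key <- as.character(n_bins)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  n <- as.integer(n_bins)
  S <- 4L * n
  SP <- 6L * (n + 2L)
  r <- rep(1:4, times = n)
  cc <- rep(1:n, each = 4L)
  pos <- (r + 1L) + 6L * cc                      # location of voxel s in pad
  off <- expand.grid(dr = -1:1, dc = -1:1)       # dr fastest: column-major 3x3
  idx <- matrix(0L, nrow = 9L, ncol = S)
  for (o in 1:9) idx[o, ] <- (r + 1L + off$dr[o]) + 6L * (cc + off$dc[o])
  src <- matrix(match(idx, pos, nomatch = 0L), nrow = 9L)  # 0 = zero padding
  g <- list(n = n, S = S, SP = SP, pos = pos, idx = idx, src = src)
  .geom_cache[[key]] <- g
  g
}

.leaky <- function(x, slope) x * ((x > 0) + slope * (x <= 0))
.dleaky <- function(x, slope) (x > 0) + slope * (x <= 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward one conv layer. x: array (C_in, S, B). Returns the pre-activation
# (C_out, S, B) plus the im2col matrix kept for the backward pass.
.conv_fwd <- function(x, W, b, g, return_xc = TRUE) {
  B <- dim(x)[3]
  r <- .conv_fwd_cpp(x, dim(x), W, b, g$src, return_xc)
  dim(r$y) <- c(nrow(W), g$S, B)
  r
}

# Weight/bias gradients of one conv layer. dy: (C_out, S, B).
.conv_bwd <- function(dy, xc, g) {
  C_out <- dim(dy)[1]; B <- dim(dy)[3]
  dy2 <- dy
  dim(dy2) <- c(C_out, g$S * B)
  list(dW = tcrossprod(dy2, xc), db = rowSums(dy2))
}

# Input gradient of a conv layer = convolution of dy with the flipped,
# transposed kernel (offset o maps to 10 - o under negation).
.conv_dx <- function(dy, W, C_in, g) {
  C_out <- nrow(W)
  arr <- array(W, dim = c(C_out, 9L, C_in))
  arr <- arr[, 9:1, , drop = FALSE]
  Wt <- aperm(arr, c(3, 2, 1))                   # (C_in, 9, C_out), tiny
  dim(Wt) <- c(C_in, 9L * C_out)
  .conv_fwd(dy, Wt, numeric(C_in), g, return_xc = FALSE)$y
}

# Architecture descriptor ---------------------------------------------------

#' Network architecture descriptor
#'
#' Describes the shared DPN/PPN architecture: four 3x3 'same' convolutions
#' (each followed by LeakyReLU and, in training mode, dropout), a flatten, and
#' two dense layers. The PPN head ends in a sigmoid (probability); the DPN
#' head ends in a LeakyReLU over four outputs (per-fraction EQD2). Input
#' scaling constants are recorded here so checkpoints are self-describing:
#' anatomy rows enter as fractions, total-course doses are divided by
#' `dose_scale` (Gy), prescriptions by `rx_scale` (Gy), and DPN outputs are in
#' units of `out_scale` Gy.
#'
#' @param head `"ppn"` or `"dpn"`.
#' @param n_bins histogram bins per structure (default 20).
#' @param channels conv channel widths (default `c(16, 32, 32, 16)`).
#' @param dense_width hidden dense width (default 64).
#' @param dropout dropout rate in the conv trunk (default 0.5).
#' @param dropout_mode `"channel"` (default; one Bernoulli draw per feature
#'   map per sample, the standard form after 2D convolutions) or
#'   `"element"`.
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @param dense_act insert a LeakyReLU between the two dense layers
#'   (default `TRUE`).
#' @param dose_scale,rx_scale,out_scale input/output scaling constants in Gy.
#' @return list of class `network_descriptor`.
#' @export
network_descriptor <- function(head = c("ppn", "dpn"), n_bins = 20L,
                               channels = c(16L, 32L, 32L, 16L),
                               dense_width = 64L, dropout = 0.5,
                               dropout_mode = c("channel", "element"),
                               leaky_slope = 0.2, dense_act = TRUE,
                               dose_scale = 100, rx_scale = 10, out_scale = 10) {
  head <- match.arg(head)
  dropout_mode <- match.arg(dropout_mode)
  structure(list(head = head, n_bins = as.integer(n_bins),
                 channels = as.integer(channels),
                 dense_width = as.integer(dense_width), dropout = dropout,
                 dropout_mode = dropout_mode,
                 leaky_slope = leaky_slope, dense_act = isTRUE(dense_act),
                 dose_scale = dose_scale, rx_scale = rx_scale,
                 out_scale = out_scale, version = 1L),
            class = "network_descriptor")
}

#' Initialize network parameters
#'
#' He-style Gaussian initialization using the current RNG state (set a seed
#' for reproducibility). Biases start at zero.
#'
#' @param descriptor a [network_descriptor()].
#' @param init_scale multiplier on the He standard deviations (default 1).
#' @return list of class `network_params` carrying the weight tensors and the
#'   descriptor.
#' @export
init_network <- function(descriptor, init_scale = 1) {
  d <- descriptor
  S <- 4L * d$n_bins
  chans <- c(2L, d$channels)
  conv <- vector("list", length(d$channels))
  for (l in seq_along(d$channels)) {
    fan_in <- 9L * chans[l]
    conv[[l]] <- list(
      W = matrix(rnorm(chans[l + 1] * fan_in, sd = init_scale * sqrt(2 / fan_in)),
                 nrow = chans[l + 1]),
      b = numeric(chans[l + 1]))
  }
  flat <- S * d$channels[length(d$channels)]
  n_out <- if (d$head == "ppn") 1L else 4L
  params <- list(
    conv = conv,
    dense1 = list(W = matrix(rnorm(d$dense_width * flat,
                                   sd = init_scale * sqrt(2 / flat)),
                             nrow = d$dense_width),
                  b = numeric(d$dense_width)),
    dense2 = list(W = matrix(rnorm(n_out * d$dense_width,
                                   sd = init_scale * sqrt(1 / d$dense_width)),
                             nrow = n_out),
                  b = numeric(n_out)),
    descriptor = d)
  class(params) <- "network_params"
  params
}

# Parameter container with all tensors zero, no RNG involvement.
.empty_params <- function(descriptor) {
  d <- descriptor
  S <- 4L * d$n_bins
  chans <- c(2L, d$channels)
  conv <- vector("list", length(d$channels))
  for (l in seq_along(d$channels)) {
    conv[[l]] <- list(W = matrix(0, nrow = chans[l + 1], ncol = 9L * chans[l]),
                      b = numeric(chans[l + 1]))
  }
  flat <- S * d$channels[length(d$channels)]
  n_out <- if (d$head == "ppn") 1L else 4L
  params <- list(conv = conv,
                 dense1 = list(W = matrix(0, d$dense_width, flat),
                               b = numeric(d$dense_width)),
                 dense2 = list(W = matrix(0, n_out, d$dense_width),
                               b = numeric(n_out)),
                 descriptor = d)
  class(params) <- "network_params"
  params
}

#' Set all weights and biases to zero (diagnostic configuration)
#' @param params `network_params`.
#' @return `network_params` with every tensor zeroed.
#' @export
zero_params <- function(params) {
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$W[] <- 0; params$conv[[l]]$b[] <- 0
  }
  params$dense1$W[] <- 0; params$dense1$b[] <- 0
  params$dense2$W[] <- 0; params$dense2$b[] <- 0
  params
}

#' Number of trainable parameters
#' @param params `network_params`.
#' @return integer count.
#' @export
count_parameters <- function(params) {
  n <- 0L
  for (l in seq_along(params$conv)) {
    n <- n + length(params$conv[[l]]$W) + length(params$conv[[l]]$b)
  }
  n + length(params$dense1$W) + length(params$dense1$b) +
    length(params$dense2$W) + length(params$dense2$b)
}

# Core forward pass. x0: array (2, S, B). mode "train" activates dropout
# (drawn from the current RNG). Returns list(out, cache).
.net_forward <- function(params, x0, mode = "eval") {
  d <- params$descriptor
  g <- .conv_geom(d$n_bins)
  slope <- d$leaky_slope
  train <- identical(mode, "train")
  B <- dim(x0)[3]
  tf <- .trunk_fwd_cpp(x0, dim(x0), lapply(params$conv, `[[`, "W"),
                       lapply(params$conv, `[[`, "b"), g$src, slope,
                       d$dropout, train,
                       identical(d$dropout_mode, "channel"))
  cache <- list(trunk = tf, xdim = dim(x0))
  C_last <- d$channels[length(d$channels)]
  flat <- tf$out
  dim(flat) <- c(C_last * g$S, B)
  z1 <- params$dense1$W %*% flat + params$dense1$b
  a1 <- if (d$dense_act) .leaky(z1, slope) else z1
  z2 <- params$dense2$W %*% a1 + params$dense2$b
  out <- if (d$head == "ppn") .sigmoid(as.vector(z2)) else .leaky(z2, slope)
  if (any(!is.finite(out))) stop("non-finite network activation", call. = FALSE)
  cache$flat <- flat; cache$z1 <- z1; cache$a1 <- a1; cache$z2 <- z2; cache$B <- B
  list(out = out, cache = cache)
}

# Backward pass. dout: gradient of the loss w.r.t. the network OUTPUT
# (probability for PPN, post-LeakyReLU vector for DPN); shape B or (4, B).
# Returns list(grads, dvec) where dvec (4 x B) is the gradient w.r.t. the
# tiled channel-2 input vector (needed to chain through the PPN into the DPN).
.net_backward <- function(params, cache, dout, need_dinput = FALSE) {
  d <- params$descriptor
  g <- .conv_geom(d$n_bins)
  slope <- d$leaky_slope
  B <- cache$B
  if (d$head == "ppn") {
    p <- .sigmoid(as.vector(cache$z2))
    dz2 <- matrix(as.vector(dout) * p * (1 - p), nrow = 1L)
  } else {
    dz2 <- dout * .dleaky(cache$z2, slope)
  }
  gr <- list(conv = vector("list", length(params$conv)))
  gr$dense2 <- list(W = tcrossprod(dz2, cache$a1), b = rowSums(dz2))
  da1 <- crossprod(params$dense2$W, dz2)
  dz1 <- if (d$dense_act) da1 * .dleaky(cache$z1, slope) else da1
  gr$dense1 <- list(W = tcrossprod(dz1, cache$flat), b = rowSums(dz1))
  dflat <- crossprod(params$dense1$W, dz1)
  tf <- cache$trunk
  bw <- .trunk_bwd_cpp(dflat, lapply(params$conv, `[[`, "W"), tf$xc, tf$pre,
                       tf$mask, g$src, cache$xdim, slope, need_dinput)
  for (l in seq_along(params$conv)) {
    gr$conv[[l]] <- list(W = bw$dW[[l]], b = bw$db[[l]])
  }
  list(grads = gr, dvec = if (need_dinput) bw$dvec else NULL)
}

# Input assembly ------------------------------------------------------------

# Stack anatomy (4 x n matrix, (4, n, B) array, or list of matrices) with a
# tiled 4-vector channel into the channel-first (2, S, B) network input.
.make_input <- function(anatomy, vec, n_bins) {
  if (is.list(anatomy) && !is.array(anatomy)) {
    anatomy <- array(unlist(anatomy), dim = c(4L, n_bins, length(anatomy)))
  } else if (is.matrix(anatomy)) {
    anatomy <- array(as.numeric(anatomy), dim = c(4L, n_bins, 1L))
  }
  stopifnot(dim(anatomy)[1] == 4L, dim(anatomy)[2] == n_bins)
  B <- dim(anatomy)[3]
  vec <- if (is.matrix(vec)) vec else matrix(vec, nrow = 4L, ncol = B)
  stopifnot(nrow(vec) == 4L, ncol(vec) == B)
  S <- 4L * n_bins
  x0 <- array(0, dim = c(2L, S, B))
  dim(anatomy) <- c(S, B)
  x0[1L, , ] <- anatomy
  x0[2L, , ] <- vec[rep(1:4, times = n_bins), , drop = FALSE]
  x0
}

#' PPN forward pass: probability of plan approval
#'
#' Scores the probability that a plan, expressed as the total-course EQD2 of
#' the four structures, would be approved given the patient anatomy. In
#' `"train"` mode dropout is active (stochastic, uses the current RNG); in
#' `"eval"` mode the pass is deterministic.
#'
#' @param params PPN `network_params`.
#' @param anatomy 4 x n histogram matrix, `(4, n, B)` array, or list of
#'   matrices (rows normalized to fractions).
#' @param total_dose total-course EQD2 in Gy: 4-vector or `4 x B` matrix,
#'   order `r paste(STRUCTURES, collapse = ", ")`.
#' @param mode `"eval"` (default) or `"train"`.
#' @return numeric vector of probabilities in `(0, 1)`, length B.
#' @export
ppn_forward <- function(params, anatomy, total_dose, mode = "eval") {
  d <- params$descriptor
  if (d$head != "ppn") stop("params are not a PPN checkpoint", call. = FALSE)
  if (any(total_dose < 0)) stop("doses must be >= 0", call. = FALSE)
  x0 <- .make_input(anatomy, total_dose / d$dose_scale, d$n_bins)
  .forward_chunked(params, x0, mode)
}

# Evaluate the network in manageable chunks so large-batch scoring keeps a
# small memory footprint (the im2col buffers scale with batch size).
.forward_chunked <- function(params, x0, mode, chunk = 256L) {
  B <- dim(x0)[3]
  if (identical(mode, "train") || B <= chunk) {
    return(.net_forward(params, x0, mode)$out)
  }
  starts <- seq(1L, B, by = chunk)
  parts <- lapply(starts, function(s) {
    e <- min(s + chunk - 1L, B)
    .net_forward(params, x0[, , s:e, drop = FALSE], mode)$out
  })
  if (params$descriptor$head == "ppn") unlist(parts) else do.call(cbind, parts)
}

#' DPN forward pass: predicted per-fraction EQD2
#'
#' Predicts the four dosimetric measures (CTV D90%, bladder/rectum/sigmoid
#' D2cc) of an approvable plan for the current fraction, from the anatomy and
#' the HDRBT prescription dose.
#'
#' @param params DPN `network_params`.
#' @param anatomy as in [ppn_forward()].
#' @param prescription prescription dose in Gy per fraction (scalar or
#'   length-B vector).
#' @param mode `"eval"` or `"train"`.
#' @return `4 x B` matrix of per-fraction EQD2 in Gy, rows
#'   `r paste(STRUCTURES, collapse = ", ")`.
#' @export
dpn_forward <- function(params, anatomy, prescription, mode = "eval") {
  d <- params$descriptor
  if (d$head != "dpn") stop("params are not a DPN checkpoint", call. = FALSE)
  B <- if (is.array(anatomy) && length(dim(anatomy)) == 3L) dim(anatomy)[3]
       else if (is.list(anatomy) && !is.array(anatomy)) length(anatomy) else 1L
  rx <- rep(prescription, length.out = B)
  vec <- matrix(rep(rx, each = 4L), nrow = 4L) / d$rx_scale
  x0 <- .make_input(anatomy, vec, d$n_bins)
  out <- .forward_chunked(params, x0, mode)
  out <- matrix(out, nrow = 4L, dimnames = list(STRUCTURES, NULL))
  out * d$out_scale
}

# Adam optimizer ------------------------------------------------------------

.tensor_paths <- function(params) {
  p <- list()
  for (l in seq_along(params$conv)) {
    p[[sprintf("conv%d.W", l)]] <- c("conv", l, "W")
    p[[sprintf("conv%d.b", l)]] <- c("conv", l, "b")
  }
  p[["dense1.W"]] <- c("dense1", "W"); p[["dense1.b"]] <- c("dense1", "b")
  p[["dense2.W"]] <- c("dense2", "W"); p[["dense2.b"]] <- c("dense2", "b")
  p
}

.get_tensor <- function(x, path) {
  if (path[1] == "conv") x$conv[[as.integer(path[2])]][[path[3]]]
  else x[[path[1]]][[path[2]]]
}

.set_tensor <- function(x, path, value) {
  if (path[1] == "conv") x$conv[[as.integer(path[2])]][[path[3]]] <- value
  else x[[path[1]]][[path[2]]] <- value
  x
}

.adam_init <- function(params) {
  paths <- .tensor_paths(params)
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(paths)) {
    tn <- .get_tensor(params, paths[[nm]])
    st$m[[nm]] <- tn * 0
    st$v[[nm]] <- tn * 0
  }
  st
}

# One Adam step with decoupled-from-nothing classic L2 (added to gradients).
.adam_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  paths <- .tensor_paths(params)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(paths)) {
    pth <- paths[[nm]]
    g <- .get_tensor(grads, pth)
    w <- .get_tensor(params, pth)
    if (weight_decay > 0 && pth[length(pth)] == "W") g <- g + weight_decay * w
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    w <- w - lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params <- .set_tensor(params, pth, w)
  }
  list(params = params, state = state)
}

# Checkpoint IO --------------------------------------------------------------

# FNV-1a hash over a character string, as a hex digest (corruption check).
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save network parameters to a JSON checkpoint
#'
#' The checkpoint stores the architecture descriptor, every weight tensor at
#' full double precision, and a content hash; [load_checkpoint()] verifies the
#' hash and restores a bit-identical forward pass.
#'
#' @param params `network_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  paths <- .tensor_paths(params)
  # doubles are serialized as %.17g strings: decimal -> binary parsing at 17
  # significant digits restores every value bit-exactly
  tensors <- lapply(paths, function(p) {
    tn <- .get_tensor(params, p)
    list(dim = if (is.matrix(tn)) dim(tn) else length(tn),
         data = sprintf("%.17g", as.vector(tn)))
  })
  payload <- paste(unlist(lapply(tensors, `[[`, "data")), collapse = ",")
  obj <- list(format = "brachynet-checkpoint",
              descriptor = unclass(params$descriptor),
              checksum = .fnv1a(payload),
              tensors = tensors)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load network parameters from a JSON checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @param descriptor optional `network_descriptor` the checkpoint must match;
#'   a mismatch is an error.
#' @return `network_params`.
#' @export
load_checkpoint <- function(path, descriptor = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "brachynet-checkpoint")) {
    stop("not a brachynet checkpoint", call. = FALSE)
  }
  payload <- paste(unlist(lapply(obj$tensors, `[[`, "data")), collapse = ",")
  if (!identical(.fnv1a(payload), obj$checksum)) {
    stop("checkpoint checksum mismatch (corrupted file)", call. = FALSE)
  }
  tensors <- lapply(obj$tensors, function(t) {
    list(dim = as.integer(t$dim), data = as.numeric(t$data))
  })
  dsc <- do.call(network_descriptor, obj$descriptor[
    setdiff(names(obj$descriptor), "version")])
  if (!is.null(descriptor) && !identical(unclass(dsc), unclass(descriptor))) {
    stop("checkpoint descriptor does not match the requested architecture",
         call. = FALSE)
  }
  params <- .empty_params(dsc)
  for (nm in names(.tensor_paths(params))) {
    t <- tensors[[nm]]
    tn <- if (length(t$dim) == 2L) matrix(t$data, nrow = t$dim[1]) else t$data
    params <- .set_tensor(params, .tensor_paths(params)[[nm]], tn)
  }
  params
}
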