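#' Network configuration
#'
#' The reconstruction network is a stack of stride-1, circularly padded 5x5
#' convolutions over the 16 x 16 EIM (no pooling anywhere; layer
#' normalization after each convolution), followed by a dense head shared
#' across the 16 injection rows: the final feature map is reshaped to 16
#' rows of `16 * channels_final` features, each row passes through the same
#' two dense layers (`head_widths`, dropout between them), and each row's
#' 4096-vector is read as a 64 x 64 canonical map in log1p-conductivity
#' space, rotated by its injection angle (k * 22.5 degrees) and averaged.
#'
#' With `canonicalize_rows` each row's 16 column blocks are cyclically
#' unrotated by the row index before the head, which makes the head inputs
#' permute cleanly under diagonal EIM shifts; combined with the
#' `rotate_sum` aggregation the full network is then exactly equivariant to
#' shifts by multiples of 4 (90-degree image rotations).
#'
#' @param conv_channels Output channels of each conv layer. The default five
#'   5x5 layers give the stack a 21 x 21 receptive field, deliberately larger
#'   than the 16 x 16 map so boundary cells are seen as often as central ones.
#' @param kernel Kernel side length(s), recycled over layers.
#' @param head_widths Widths of the two shared dense layers; the second must
#'   be 4096 so each row emits a full 64 x 64 canonical image.
#' @param dropout Dropout rate between the two dense layers.
#' @param aggregation `"rotate_sum"` (rotate each row map by its injection
#'   angle, then average) or `"mean"` (plain average).
#' @param canonicalize_rows See above; default TRUE.
#' @param grid_size Output image side (64).
#' @param lrelu_slope Negative slope of the leaky rectifier.
#' @param input_scale_feature Feed the EIM as a scale-free channel plus a
#'   constant log-magnitude channel, so the absolute voltage scale (which
#'   encodes the absolute conductivity level) survives the per-sample layer
#'   normalizations.
#' @return Object of class `net_config`.
#' @export
net_config <- function(conv_channels = c(32L, 64L, 128L, 128L, 128L),
                       kernel = 5L,
                       head_widths = c(2048L, 4096L),
                       dropout = 0.1,
                       aggregation = c("rotate_sum", "mean"),
                       canonicalize_rows = TRUE,
                       grid_size = 64L,
                       lrelu_slope = 0.01,
                       input_scale_feature = TRUE) {
  aggregation <- match.arg(aggregation)
  kernel <- rep_len(as.integer(kernel), length(conv_channels))
  if (any(kernel %% 2L != 1L)) stop("kernels must be odd")
  if (head_widths[2L] != grid_size^2)
    stop("second head width must equal grid_size^2 (one canonical map per row)")
  cfg <- structure(list(
    conv_channels = as.integer(conv_channels), kernel = kernel,
    head_widths = as.integer(head_widths), dropout = dropout,
    aggregation = aggregation, canonicalize_rows = canonicalize_rows,
    grid_size = as.integer(grid_size), lrelu_slope = lrelu_slope,
    input_scale_feature = input_scale_feature,
    rows = 16L,
    row_feature_width = 16L * as.integer(conv_channels[length(conv_channels)])
  ), class = "net_config")
  cfg
}

#' Reduced configuration for quick CPU training runs
#'
#' Same topology (five 5x5 circular convolutions, receptive field 21, shared
#' two-layer head, 64 x 64 output) with fewer channels, sized so a
#' 500-sample, 50-epoch run completes in minutes on one core.
#'
#' @param ... Overrides passed to [net_config()].
#' @return A `net_config`.
#' @export
net_config_small <- function(...) {
  net_config(conv_channels = c(8L, 12L, 12L, 12L, 12L),
             head_widths = c(128L, 4096L), ...)
}

#' Receptive field of the convolutional front end
#'
#' For a stride-1 stack this is `1 + sum(kernel - 1)`; the default
#' configuration gives 21.
#'
#' @param config A `net_config`.
#' @return Integer side length of the square receptive field.
#' @export
receptive_field <- function(config) {
  stopifnot(inherits(config, "net_config"))
  1L + sum(config$kernel - 1L)
}

#' Initialize network parameters
#'
#' He-scaled Gaussian weights, zero biases, unit layer-norm gains; fully
#' deterministic given `seed`.
#'
#' @param config A `net_config`.
#' @param seed Integer seed.
#' @return Object of class `net_params` (list of conv and dense parameters;
#'   carries the config).
#' @export
init_network <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  cin <- if (config$input_scale_feature) 2L else 1L
  conv <- vector("list", length(config$conv_channels))
  for (l in seq_along(conv)) {
    cout <- config$conv_channels[l]
    fan <- config$kernel[l]^2 * cin
    conv[[l]] <- list(
      W = matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout),
      b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout))
    cin <- cout
  }
  rw <- config$row_feature_width
  h1 <- config$head_widths[1L]; h2 <- config$head_widths[2L]
  params <- list(
    conv = conv,
    W1 = matrix(stats::rnorm(rw * h1, 0, sqrt(2 / rw)), rw, h1),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, 0, sqrt(1 / h1)), h1, h2),
    b2 = numeric(h2),
    config = config, seed = seed)
  class(params) <- "net_params"
  params
}

#' @export
print.net_params <- function(x, ...) {
  cen <- param_census(x)
  cat(sprintf("net_params: %d conv layers + %d shared dense layers, %d parameters\n",
              cen$n_conv, cen$n_dense, cen$n_parameters))
  invisible(x)
}

#' Parameter census
#'
#' @param params A `net_params`.
#' @return List: `n_conv`, `n_dense` (dense layers, shared across the 16
#'   rows), `n_pooling` (always 0 by construction), `shared_rows`,
#'   `n_parameters`.
#' @export
param_census <- function(params) {
  stopifnot(inherits(params, "net_params"))
  n <- sum(vapply(params$conv, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1))) +
    length(params$W1) + length(params$b1) + length(params$W2) + length(params$b2)
  list(n_conv = length(params$conv), n_dense = 2L, n_pooling = 0L,
       shared_rows = 16L, n_parameters = n)
}

## ---- internal geometry tables -------------------------------------------

.model_cache <- new.env(parent = emptyenv())

# 256 x k^2 circular gather table: P[p, o] is the pixel index of the
# neighbour at kernel offset o of pixel p (p = k + 16*(j-1), column-major)
.conv_offsets <- function(kernel) {
  key <- sprintf("P%d", kernel)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  half <- (kernel - 1L) %/% 2L
  k <- as.vector(matrix(0:15, 16, 16))        # EIM row index per pixel
  j <- as.vector(matrix(0:15, 16, 16, byrow = TRUE))
  P <- matrix(0L, 256L, kernel^2)
  o <- 0L
  for (dj in -half:half) for (dk in -half:half) {
    o <- o + 1L
    P[, o] <- ((k + dk) %% 16L) + 16L * ((j + dj) %% 16L) + 1L
  }
  .model_cache[[key]] <- P
  P
}

# (16B) x 16 row-gather table: entry [(b-1)*16 + k, jj] is the feature-matrix
# row of pixel (k, j') of sample b, with j' = jj + (k-1)*canon (mod 16)
.row_gather <- function(B, canon) {
  key <- sprintf("R%d_%d", B, canon)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  k <- rep(rep(1:16, times = B), times = 1L)          # (16B)
  b <- rep(seq_len(B), each = 16L)
  R <- matrix(0L, 16L * B, 16L)
  for (jj in 1:16) {
    jprime <- if (canon) ((jj - 1L + (k - 1L)) %% 16L) + 1L else rep(jj, 16L * B)
    R[, jj] <- (b - 1L) * 256L + k + 16L * (jprime - 1L)
  }
  .model_cache[[key]] <- R
  R
}

.lrelu <- function(x, slope) { x[x < 0] <- x[x < 0] * slope; x }

## ---- forward / backward -------------------------------------------------

# Stack a list of EIMs (or a 16 x 16 x B array) into the (256B) x Cin input
# feature matrix.
.net_input <- function(eims, config) {
  if (is.list(eims)) {
    B <- length(eims)
    X <- vapply(eims, function(e) as.vector(unclass(e)), numeric(256))
  } else if (is.array(eims) && length(dim(eims)) == 3L) {
    B <- dim(eims)[3L]
    X <- matrix(eims, 256L, B)
  } else {
    B <- 1L
    X <- matrix(as.vector(unclass(eims)), 256L, 1L)
  }
  if (any(!is.finite(X))) stop("non-finite EIM input")
  if (config$input_scale_feature) {
    rms <- sqrt(colSums(X^2) / 208)
    rms_safe <- pmax(rms, 1e-30)
    ch1 <- sweep(X, 2L, rms_safe, "/")
    ch2 <- matrix(rep(log10(rms_safe) / 5, each = 256L), 256L, B)
    F0 <- cbind(as.vector(ch1), as.vector(ch2))   # (256B) x 2
  } else {
    F0 <- matrix(as.vector(X), ncol = 1L)
  }
  list(F0 = F0, B = B)
}

# weights rearranged for the transpose convolution: the gradient wrt the
# input of a circular convolution is a circular convolution of the output
# gradient with the spatially flipped kernel, channels transposed
.flip_weights <- function(W, K2, cin, cout) {
  Wa <- array(W, c(cin, K2, cout))
  Wf <- Wa[, K2:1, , drop = FALSE]            # opposite spatial offsets
  matrix(aperm(Wf, c(3L, 2L, 1L)), K2 * cout, cin)
}

# circular im2col gather: F (256B x C) -> (256B) x (k^2 C), done as one
# vectorized index into F (the flat index table is cached per shape)
.conv_gather <- function(F, P, B) {
  n <- nrow(F); C <- ncol(F); K <- ncol(P)
  key <- sprintf("G_%d_%d_%d", B, C, K)
  big <- .model_cache[[key]]
  if (is.null(big)) {
    base <- rep.int(seq.int(0L, by = 256L, length.out = B),
                    rep.int(256L, B))
    big <- matrix(0L, n, K * C)
    for (o in seq_len(K)) {
      ridx <- base + P[, o]
      for (cc in seq_len(C))
        big[, (o - 1L) * C + cc] <- ridx + n * (cc - 1L)
    }
    .model_cache[[key]] <- big
  }
  matrix(F[big], n, K * C)
}

# full forward pass on a batch; returns prediction in log1p space (B x 4096)
# plus caches for the backward pass when train = TRUE
.net_forward <- function(params, eims, train = FALSE, rng_dropout = TRUE) {
  cfg <- params$config
  inp <- .net_input(eims, cfg)
  F <- inp$F0; B <- inp$B
  grp <- rep(seq_len(B), each = 256L)
  caches <- if (train) vector("list", length(params$conv))
  for (l in seq_along(params$conv)) {
    P <- .conv_offsets(cfg$kernel[l])
    lay <- params$conv[[l]]
    Xc <- .conv_gather(F, P, B)
    Z <- Xc %*% lay$W
    Z <- sweep(Z, 2L, lay$b, "+")
    ## layer norm over all (spatial x channel) features of the sample
    nfeat <- 256L * ncol(Z)
    s1 <- rowsum(Z, grp, reorder = TRUE)
    s2 <- rowsum(Z * Z, grp, reorder = TRUE)
    mu <- rowSums(s1) / nfeat
    va <- rowSums(s2) / nfeat - mu^2
    sd_ <- sqrt(va + 1e-6)
    Zh <- (Z - mu[grp]) / sd_[grp]
    A <- sweep(sweep(Zh, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
    H <- .lrelu(A, cfg$lrelu_slope)
    if (train)
      caches[[l]] <- list(Xc = Xc, Zh = Zh, sd = sd_, A = A)
    F <- H
  }
  ## rows + shared head
  RI <- .row_gather(B, cfg$canonicalize_rows)
  Cf <- ncol(F)
  Hin <- matrix(0, 16L * B, 16L * Cf)
  for (jj in 1:16)
    Hin[, ((jj - 1L) * Cf + 1L):(jj * Cf)] <- F[RI[, jj], , drop = FALSE]
  Z1 <- sweep(Hin %*% params$W1, 2L, params$b1, "+")
  H1 <- .lrelu(Z1, cfg$lrelu_slope)
  drop_mask <- NULL
  if (train && cfg$dropout > 0 && rng_dropout) {
    drop_mask <- matrix(stats::rbinom(length(H1), 1L, 1 - cfg$dropout) /
                          (1 - cfg$dropout), nrow(H1), ncol(H1))
    H1 <- H1 * drop_mask
  }
  Z2 <- sweep(H1 %*% params$W2, 2L, params$b2, "+")   # (16B) x 4096 row maps
  ## aggregation
  N2 <- cfg$grid_size^2
  if (cfg$aggregation == "rotate_sum") {
    # row order k + 16(b-1) makes t(Z2) exactly the (pixel + N2*k) x batch
    # stack; one sparse product applies all 16 rotations, then average
    V <- matrix(t(Z2), 16L * N2, B)
    S <- t(as.matrix(rot_operator_cat(cfg$grid_size) %*% V)) / 16
  } else {
    S <- rowsum(Z2, rep(seq_len(B), each = 16L), reorder = TRUE) / 16
  }
  out <- list(S = S, B = B)
  if (train)
    out$cache <- list(conv = caches, F_last = F, Hin = Hin, Z1 = Z1,
                      H1 = H1, drop_mask = drop_mask, Z2 = Z2, grp = grp,
                      RI = RI)
  out
}

# backward pass: dS is dLoss/dS (B x 4096, log1p space); returns gradient
# list with the same shape as params (conv W/b/gamma/beta, W1/b1/W2/b2)
.net_backward <- function(params, fwd, dS) {
  cfg <- params$config
  cache <- fwd$cache
  B <- fwd$B
  ## aggregation backward
  N2 <- cfg$grid_size^2
  if (cfg$aggregation == "rotate_sum") {
    dV <- as.matrix(Matrix::crossprod(rot_operator_cat(cfg$grid_size),
                                      t(dS))) / 16
    dZ2 <- t(matrix(dV, N2, 16L * B))
  } else {
    dZ2 <- (dS / 16)[rep(seq_len(B), each = 16L), , drop = FALSE]
  }
  gW2 <- crossprod(cache$H1, dZ2)
  gb2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, params$W2)
  if (!is.null(cache$drop_mask)) dH1 <- dH1 * cache$drop_mask
  slope <- cfg$lrelu_slope
  dZ1 <- dH1 * (slope + (1 - slope) * (cache$Z1 > 0))
  gW1 <- crossprod(cache$Hin, dZ1)
  gb1 <- colSums(dZ1)
  dHin <- tcrossprod(dZ1, params$W1)
  ## scatter rows back to the feature map (bijective gather)
  Cf <- ncol(cache$F_last)
  dF <- matrix(0, 256L * B, Cf)
  for (jj in 1:16)
    dF[cache$RI[, jj], ] <- dHin[, ((jj - 1L) * Cf + 1L):(jj * Cf), drop = FALSE]
  ## conv stack backward
  grp <- cache$grp
  gconv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    lay <- params$conv[[l]]
    cc <- cache$conv[[l]]
    dH <- dF
    dA <- dH * (slope + (1 - slope) * (cc$A > 0))
    ggamma <- colSums(dA * cc$Zh)
    gbeta <- colSums(dA)
    dZh <- sweep(dA, 2L, lay$gamma, "*")
    nfeat <- 256L * ncol(dZh)
    m1 <- rowSums(rowsum(dZh, grp, reorder = TRUE)) / nfeat
    m2 <- rowSums(rowsum(dZh * cc$Zh, grp, reorder = TRUE)) / nfeat
    dZ <- (dZh - m1[grp] - cc$Zh * m2[grp]) / cc$sd[grp]
    P <- .conv_offsets(cfg$kernel[l])
    gW <- crossprod(cc$Xc, dZ)
    gb <- colSums(dZ)
    Cin <- ncol(cc$Xc) %/% ncol(P)
    Wb <- .flip_weights(lay$W, ncol(P), Cin, ncol(dZ))
    dF <- .conv_gather(dZ, P, B) %*% Wb
    gconv[[l]] <- list(W = gW, b = gb, gamma = ggamma, beta = gbeta)
  }
  list(conv = gconv, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Forward pass: reconstruct an image from one EIM (or a batch)
#'
#' Runs the network in evaluation mode (no dropout) and returns the
#' conductivity image(s): the aggregated log1p-space map passed through
#' `expm1`, guaranteeing predictions greater than -1 across the whole
#' dynamic range.
#'
#' @param params A `net_params`.
#' @param eim A 16 x 16 EIM, a list of EIMs, or a 16 x 16 x B array.
#' @return A 64 x 64 matrix (single input) or a 64 x 64 x B array.
#' @export
forward_pass <- function(params, eim) {
  stopifnot(inherits(params, "net_params"))
  fwd <- .net_forward(params, eim, train = FALSE)
  N <- params$config$grid_size
  img <- expm1(fwd$S)
  if (fwd$B == 1L) return(matrix(img[1L, ], N, N))
  array(t(img), dim = c(N, N, fwd$B))
}

#' Convolutional front-end features
#'
#' Runs only the circularly padded conv stack (with its layer norms and
#' activations) and returns the 16 x 16 x C feature map of a single EIM.
#' Because every stage is either pointwise, a circular convolution, or a
#' spatially invariant normalization, these features are exactly equivariant
#' to diagonal cyclic shifts of the input.
#'
#' @param params A `net_params`.
#' @param eim A 16 x 16 EIM.
#' @return 16 x 16 x C array (EIM row, EIM column, channel).
#' @export
conv_features <- function(params, eim) {
  stopifnot(inherits(params, "net_params"))
  cfg <- params$config
  inp <- .net_input(eim, cfg)
  F <- inp$F0
  grp <- rep(1L, 256L)
  for (l in seq_along(params$conv)) {
    P <- .conv_offsets(cfg$kernel[l])
    lay <- params$conv[[l]]
    Xc <- .conv_gather(F, P, 1L)
    Z <- sweep(Xc %*% lay$W, 2L, lay$b, "+")
    nfeat <- 256L * ncol(Z)
    mu <- sum(Z) / nfeat
    sd_ <- sqrt(sum((Z - mu)^2) / nfeat + 1e-6)
    Zh <- (Z - mu) / sd_
    A <- sweep(sweep(Zh, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
    F <- .lrelu(A, cfg$lrelu_slope)
  }
  array(F, dim = c(16L, 16L, ncol(F)))
}

## ---- losses -------------------------------------------------------------

#' Loss weights of the composite objective
#'
#' The composite loss is `w2_weight * Lw2 + tv_weight * LTV +
#' msle_weight * LMSLE`. The `"printed"` preset uses the published weighting
#' (Lw2 weight 1, TV 0.1, MSLE 1e-6); the `"sane"` preset inverts the
#' regularizer/data-term roles (MSLE 1, TV 0.1, w2 1e-6), which is the
#' weighting that actually drives reconstruction during training.
#'
#' @param preset `"printed"` or `"sane"`; or pass explicit weights.
#' @param w2_weight,tv_weight,msle_weight Explicit non-negative weights
#'   (override the preset).
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(preset = c("printed", "sane"),
                         w2_weight = NULL, tv_weight = NULL,
                         msle_weight = NULL) {
  preset <- match.arg(preset)
  w <- if (preset == "printed") c(w2 = 1, tv = 0.1, msle = 1e-6)
       else c(w2 = 1e-6, tv = 0.1, msle = 1)
  if (!is.null(w2_weight)) w["w2"] <- w2_weight
  if (!is.null(tv_weight)) w["tv"] <- tv_weight
  if (!is.null(msle_weight)) w["msle"] <- msle_weight
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(list(w2_weight = unname(w["w2"]), tv_weight = unname(w["tv"]),
                 msle_weight = unname(w["msle"]), preset = preset),
            class = "loss_weights")
}

#' Weight regularization term
#'
#' Default: sum of squared weight-matrix entries (biases and normalization
#' parameters excluded). `squared = FALSE` gives the plain sum of weights
#' (the literal published form, kept for comparison; it is sign-indefinite).
#'
#' @param params A `net_params`, or a plain numeric vector of weights.
#' @param squared Use the squared form (default).
#' @return Scalar.
#' @export
loss_w2 <- function(params, squared = TRUE) {
  w <- if (inherits(params, "net_params"))
    c(unlist(lapply(params$conv, function(l) as.numeric(l$W))),
      as.numeric(params$W1), as.numeric(params$W2))
  else as.numeric(params)
  if (squared) sum(w^2) else sum(w)
}

#' Anisotropic total variation of an image
#'
#' `sum |Y[i+1,j] - Y[i,j]| + |Y[i,j+1] - Y[i,j]|` over all pixels whose
#' forward neighbour exists (no wraparound).
#'
#' @param image Numeric matrix.
#' @return Scalar TV.
#' @export
loss_tv <- function(image) {
  stopifnot(is.matrix(image))
  dv <- image[-1L, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  dh <- image[, -1L, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  sum(abs(dv)) + sum(abs(dh))
}

#' Mean squared logarithmic error
#'
#' Mean over all pixels of the squared difference of log1p-transformed
#' values; order-of-magnitude insensitive, which suits conductivities
#' spanning five decades. Both inputs must exceed -1 everywhere.
#'
#' @param pred,target Numeric matrices of equal dimension.
#' @return Scalar MSLE (>= 0, zero iff pred == target).
#' @export
loss_msle <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  if (any(pred <= -1) || any(target <= -1))
    stop("MSLE requires all values > -1")
  mean((log1p(pred) - log1p(target))^2)
}

#' Composite training loss
#'
#' `w2_weight * Lw2 + tv_weight * LTV + msle_weight * LMSLE` for the given
#' weights (see [loss_weights()]).
#'
#' @param params A `net_params` (for the weight term).
#' @param pred Predicted image.
#' @param target Ground-truth image.
#' @param weights A `loss_weights`.
#' @param components Optional named vector `c(w2=, tv=, msle=)` of
#'   pre-computed component values; when given, `params`/`pred`/`target`
#'   are ignored and the weighted sum of the components is returned.
#' @return Scalar total loss.
#' @export
loss_total <- function(params = NULL, pred = NULL, target = NULL,
                       weights = loss_weights("printed"), components = NULL) {
  stopifnot(inherits(weights, "loss_weights"))
  if (is.null(components))
    components <- c(w2 = loss_w2(params), tv = loss_tv(pred),
                    msle = loss_msle(pred, target))
  weights$w2_weight * components[["w2"]] +
    weights$tv_weight * components[["tv"]] +
    weights$msle_weight * components[["msle"]]
}
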