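#' Training configuration
#'
#' @param epochs Number of epochs.
#' @param batch_size Samples per Adam step.
#' @param lr Initial learning rate.
#' @param lr_factor Multiplier applied to the learning rate at a plateau
#'   (0.3: a 70 percent reduction).
#' @param patience Epochs without validation improvement before the
#'   learning-rate drop.
#' @param weights A [loss_weights()] preset; the training objective uses its
#'   three weights with the TV term averaged over neighbour pairs (so the
#'   weight is resolution-independent) and MSLE/w2 as defined.
#' @param alpha_blend Blend each batch with a second, independently shuffled
#'   batch (per-item alpha uniform on `[0, 1]`).
#' @param seed Seed governing shuffling, blending and dropout; a run is
#'   bit-reproducible given (params, dataset, config).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 25L, lr = 1e-3,
                         lr_factor = 0.3, patience = 10L,
                         weights = loss_weights("sane"),
                         alpha_blend = TRUE, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0,
            lr_factor > 0, lr_factor < 1, inherits(weights, "loss_weights"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_factor = lr_factor, patience = as.integer(patience),
                 weights = weights, alpha_blend = isTRUE(alpha_blend),
                 seed = as.integer(seed)),
            class = "train_config")
}

# flat iteration over the parameter list for the optimizer
.param_names <- function(params) {
  c(unlist(lapply(seq_along(params$conv), function(l)
    paste0("conv", l, ".", c("W", "b", "gamma", "beta")))),
    "W1", "b1", "W2", "b2")
}
.param_get <- function(params, name) {
  if (grepl("^conv", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
    params$conv[[as.integer(sub("conv", "", parts[1L]))]][[parts[2L]]]
  } else params[[name]]
}
.param_set <- function(params, name, value) {
  if (grepl("^conv", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
    params$conv[[as.integer(sub("conv", "", parts[1L]))]][[parts[2L]]] <- value
  } else params[[name]] <- value
  params
}
.grad_get <- function(grads, name) {
  if (grepl("^conv", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
    grads$conv[[as.integer(sub("conv", "", parts[1L]))]][[parts[2L]]]
  } else grads[[name]]
}

# loss + gradient wrt S (log1p-space batch output) for one batch
.batch_loss_grad <- function(params, fwd, Tlog, weights) {
  cfg <- params$config
  N <- cfg$grid_size
  B <- fwd$B
  S <- fwd$S
  ## MSLE in log space: mean over batch of per-image means
  dif <- S - Tlog
  msle <- mean(dif^2)
  dS <- weights$msle_weight * 2 * dif / length(dif)
  ## TV on the conductivity image, averaged over neighbour pairs
  tv <- 0
  if (weights$tv_weight > 0) {
    npair <- 2L * N * (N - 1L)
    arr <- array(t(expm1(S)), c(N, N, B))
    dv <- arr[-1L, , , drop = FALSE] - arr[-N, , , drop = FALSE]
    dh <- arr[, -1L, , drop = FALSE] - arr[, -N, , drop = FALSE]
    tv <- (sum(abs(dv)) + sum(abs(dh))) / npair / B
    g <- array(0, c(N, N, B))
    sv <- sign(dv); sh <- sign(dh)
    g[-1L, , ] <- g[-1L, , , drop = FALSE] + sv
    g[-N, , ] <- g[-N, , , drop = FALSE] - sv
    g[, -1L, ] <- g[, -1L, , drop = FALSE] + sh
    g[, -N, ] <- g[, -N, , drop = FALSE] - sh
    dTV <- t(matrix(g, N * N, B)) / npair
    dS <- dS + weights$tv_weight * (dTV / B) * exp(S)
  }
  w2 <- loss_w2(params)
  loss <- weights$msle_weight * msle + weights$tv_weight * tv +
    weights$w2_weight * w2
  list(loss = loss, msle = msle, dS = dS)
}

# validation MSLE (evaluation mode, no dropout)
.val_msle <- function(params, eims, Tlog, chunk = 64L) {
  n <- length(eims)
  tot <- 0
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    fwd <- .net_forward(params, eims[idx], train = FALSE)
    tot <- tot + sum((fwd$S - Tlog[idx, , drop = FALSE])^2) / ncol(Tlog)
  }
  tot / n
}

#' Train the reconstruction network
#'
#' Adam updates on the composite loss, with per-epoch random batch pairing
#' and alpha-blending, and a plateau learning-rate schedule: when the
#' validation MSLE has not improved for `patience` epochs the learning rate
#' is multiplied by `lr_factor`. Fully reproducible given the config seed.
#'
#' @param params Initial `net_params` (see [init_network()]).
#' @param samples List of `eit_sample` training samples.
#' @param val_samples List of `eit_sample` held-out samples used for the
#'   validation curve and the plateau detector.
#' @param config A `train_config`.
#' @return List with `params` (trained), `history` (data.frame: epoch, lr,
#'   train_loss, val_msle, best_val_msle -- the best-so-far sequence is
#'   non-increasing by construction), and `val_msle0` (pre-training value).
#' @export
train_network <- function(params, samples, val_samples,
                          config = train_config()) {
  stopifnot(inherits(params, "net_params"), length(samples) >= 2L,
            inherits(config, "train_config"))
  set.seed(config$seed)
  cfg <- params$config
  weights <- config$weights
  eims <- lapply(samples, `[[`, "eim")
  Tlog <- t(vapply(samples, function(s) log1p(as.vector(s$target)),
                   numeric(cfg$grid_size^2)))
  veims <- lapply(val_samples, `[[`, "eim")
  VTlog <- t(vapply(val_samples, function(s) log1p(as.vector(s$target)),
                    numeric(cfg$grid_size^2)))
  n <- length(samples)
  bs <- min(config$batch_size, n)

  ## Adam state
  pn <- .param_names(params)
  mstate <- vstate <- stats::setNames(vector("list", length(pn)), pn)
  for (nm in pn) {
    z <- .param_get(params, nm); z[] <- 0
    mstate[[nm]] <- z; vstate[[nm]] <- z
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- config$lr

  val0 <- .val_msle(params, veims, VTlog)
  best <- val0; best_epoch <- 0L; last_drop <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ord2 <- sample.int(n)        # blending partners
    ep_loss <- 0; nb <- 0L
    for (i0 in seq(1L, n - bs + 1L, by = bs)) {
      idx <- ord[i0:(i0 + bs - 1L)]
      bat_e <- eims[idx]
      bat_t <- Tlog[idx, , drop = FALSE]
      if (config$alpha_blend) {
        jdx <- ord2[i0:(i0 + bs - 1L)]
        al <- stats::runif(bs)
        v <- eim_valid_mask()
        U1 <- vapply(bat_e, function(e) unclass(e)[v], numeric(208))
        U2 <- vapply(eims[jdx], function(e) unclass(e)[v], numeric(208))
        alr <- rep(al, each = 208L)
        Ub <- matrix(blend_voltages(as.vector(U1), as.vector(U2), alr),
                     208L, bs)
        for (b in seq_len(bs)) {
          e1 <- unclass(bat_e[[b]])
          e1[v] <- Ub[, b]
          bat_e[[b]] <- structure(e1, class = c("eim", "matrix", "array"))
        }
        bat_t <- log1p(al * expm1(bat_t) + (1 - al) * expm1(Tlog[jdx, ]))
      }
      fwd <- .net_forward(params, bat_e, train = TRUE)
      lg <- .batch_loss_grad(params, fwd, bat_t, weights)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d)",
                     epoch, i0))
      grads <- .net_backward(params, fwd, lg$dS)
      if (weights$w2_weight > 0) {     # decay on weight matrices only
        for (l in seq_along(grads$conv))
          grads$conv[[l]]$W <- grads$conv[[l]]$W +
            2 * weights$w2_weight * params$conv[[l]]$W
        grads$W1 <- grads$W1 + 2 * weights$w2_weight * params$W1
        grads$W2 <- grads$W2 + 2 * weights$w2_weight * params$W2
      }
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in pn) {
        g <- .grad_get(grads, nm)
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g * g
        upd <- lr * (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + eps)
        params <- .param_set(params, nm, .param_get(params, nm) - upd)
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vm <- .val_msle(params, veims, VTlog)
    if (vm < best) { best <- vm; best_epoch <- epoch }
    if (epoch - max(best_epoch, last_drop) >= config$patience) {
      lr <- lr * config$lr_factor
      last_drop <- epoch
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / max(nb, 1L),
                                val_msle = vm, best_val_msle = best)
  }
  list(params = params, history = do.call(rbind, hist), val_msle0 = val0)
}
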