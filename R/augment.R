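#' Training sample: EIM plus ground-truth target
#'
#' @param eim A 16 x 16 `eim`.
#' @param target 64 x 64 ground-truth conductivity raster (S/m).
#' @param provenance Named list (phantom id, applied augmentations).
#' @return Object of class `eit_sample`.
#' @export
eit_sample <- function(eim, target, provenance = list()) {
  .eim_check(unclass(eim))
  stopifnot(is.matrix(target), all(dim(target) == c(64L, 64L)))
  structure(list(eim = eim, target = target, provenance = provenance),
            class = "eit_sample")
}

#' Thermal/jitter measurement noise
#'
#' Multiplies every valid EIM entry by an independent Normal(1, std) draw;
#' the amplitude-proportional noise of the acquisition chain. Structural
#' zeros are untouched. Study default std 1e-6.
#'
#' @param eim A 16 x 16 EIM.
#' @param std Non-negative standard deviation.
#' @return The perturbed EIM.
#' @export
apply_thermal_jitter <- function(eim, std = 1e-6) {
  stopifnot(std >= 0)
  if (std == 0) return(eim)
  v <- eim_valid_mask()
  out <- unclass(eim)
  out[v] <- out[v] * stats::rnorm(sum(v), 1, std)
  structure(out, class = class(eim))
}

#' Quantization measurement noise
#'
#' Adds independent Normal(0, std) noise to every valid EIM entry;
#' signal-level-independent digitization noise. Study default std 1e-8.
#'
#' @inheritParams apply_thermal_jitter
#' @return The perturbed EIM.
#' @export
apply_quantization <- function(eim, std = 1e-8) {
  stopifnot(std >= 0)
  if (std == 0) return(eim)
  v <- eim_valid_mask()
  out <- unclass(eim)
  out[v] <- out[v] + stats::rnorm(sum(v), 0, std)
  structure(out, class = class(eim))
}

#' Per-channel gain noise
#'
#' One multiplicative gain draw per measurement row (16 draws), each applied
#' to all valid entries of that row: different acquisition channels have
#' different multiplexer gains. Gains are drawn from Normal(1, std); setting
#' `mean_zero = TRUE` uses Normal(0, std) instead (a literal reading of the
#' gain model that would null out whole rows, kept for comparison).
#'
#' @inheritParams apply_thermal_jitter
#' @param mean_zero Use a zero-mean gain distribution instead of unit-mean.
#' @return The perturbed EIM.
#' @export
apply_channel_gain <- function(eim, std = 1e-6, mean_zero = FALSE) {
  stopifnot(std >= 0)
  if (std == 0 && !mean_zero) return(eim)
  gains <- stats::rnorm(16L, mean = if (mean_zero) 0 else 1, sd = std)
  out <- unclass(eim)
  out <- out * gains            # row k scaled by gains[k] (column-major recycle)
  structure(out, class = class(eim))
}

#' Alpha-blend two training samples
#'
#' Creates a new sample as a convex combination of two: conductivities (and
#' hence targets and admittances) combine linearly, so under constant
#' injection current the voltages combine harmonically,
#' `U = (alpha/U1 + (1-alpha)/U2)^-1`. Valid entries where the harmonic
#' denominator nearly cancels (adjacent voltages can carry opposite signs)
#' fall back to the linear blend; structural zeros remain zero.
#'
#' @param a,b `eit_sample`s sharing the structural-zero pattern.
#' @param alpha Blend weight in `[0, 1]` (1 returns `a`, 0 returns `b`).
#' @return The blended `eit_sample`.
#' @export
alpha_blend <- function(a, b, alpha) {
  stopifnot(inherits(a, "eit_sample"), inherits(b, "eit_sample"),
            alpha >= 0, alpha <= 1)
  if (alpha == 1) return(a)
  if (alpha == 0) return(b)
  v <- eim_valid_mask()
  U1 <- unclass(a$eim)[v]; U2 <- unclass(b$eim)[v]
  out <- unclass(a$eim)
  out[v] <- blend_voltages(U1, U2, alpha)
  eit_sample(structure(out, class = class(a$eim)),
             alpha * a$target + (1 - alpha) * b$target,
             provenance = list(blend = list(alpha = alpha,
                                            a = a$provenance, b = b$provenance)))
}

#' Harmonic voltage blend
#'
#' @param U1,U2 Voltage vectors.
#' @param alpha Blend weight in `[0, 1]`.
#' @return Blended voltages `(alpha/U1 + (1-alpha)/U2)^-1`, with a linear
#'   fallback where the denominator nearly cancels or an input is zero.
#' @export
blend_voltages <- function(U1, U2, alpha) {
  lin <- alpha * U1 + (1 - alpha) * U2
  den <- alpha / U1 + (1 - alpha) / U2
  harm <- 1 / den
  guard <- !is.finite(harm) |
    abs(den) < 1e-12 / pmax(pmin(abs(U1), abs(U2)), 1e-300)
  harm[guard] <- lin[guard]
  harm
}

#' Expand one sample into its 16 rotations
#'
#' Returns the original plus 15 samples in which the EIM is diagonally
#' shifted by n and the target rotated by `2*pi*n/16` (n = 1..15) using the
#' composed rotation operators of [rot_image()] (exact pixel permutations at
#' multiples of 90 degrees). Rotation costs no new forward simulation.
#'
#' @param s An `eit_sample`.
#' @return List of 16 `eit_sample`s; element n+1 carries shift n.
#' @export
expand_rotations <- function(s) {
  stopifnot(inherits(s, "eit_sample"))
  out <- vector("list", 16L)
  out[[1L]] <- s
  for (n in 1:15) {
    prov <- s$provenance
    prov$rotation <- n
    out[[n + 1L]] <- eit_sample(shift_eim(s$eim, n),
                                rot_image(s$target, n),
                                provenance = prov)
  }
  out
}
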