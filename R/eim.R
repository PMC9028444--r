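#' The electrical impedance map (EIM)
#'
#' A 16 x 16 matrix holding one adjacent-adjacent frame: row k (1-based
#' index k+1) is the injection pair (k, k+1 mod 16), column j the measurement
#' pair (j, j+1 mod 16). Entries where the measurement pair shares an
#' electrode with the injection pair -- j in \{k-1, k, k+1\} mod 16 -- are
#' structural zeros: a circular band of 48 cells around the diagonal, leaving
#' 16 x 13 = 208 informative entries.
#'
#' @name eim
NULL

# 16x16 logical mask of the 208 valid (non-structural-zero) positions
eim_valid_mask <- function() {
  k <- matrix(0:15, 16, 16)         # row index (injection)
  j <- matrix(0:15, 16, 16, byrow = TRUE)
  d <- (j - k) %% 16
  d != 0 & d != 1 & d != 15
}

.eim_check <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(16L, 16L)))
    stop("an EIM is a 16 x 16 matrix")
  if (any(m[!eim_valid_mask()] != 0))
    stop("corrupted EIM: structural-zero positions carry nonzero values")
  invisible(m)
}

#' Pack a voltage frame into an EIM
#'
#' @param frame A `voltage_frame` (208 values in canonical order) or a bare
#'   numeric vector of length 208.
#' @return 16 x 16 numeric matrix of class `eim`.
#' @export
build_eim <- function(frame) {
  v <- as.numeric(frame)
  if (length(v) != 208L) stop("a voltage frame has exactly 208 entries")
  pat <- adjacent_pattern()
  m <- matrix(0, 16L, 16L)
  m[cbind(pat$inj + 1L, pat$meas + 1L)] <- v
  structure(m, class = c("eim", "matrix", "array"))
}

#' Unpack an EIM into the canonical 208-entry voltage frame
#'
#' Inverse of [build_eim()]. Errors if any structural-zero position is
#' nonzero (a corrupted map).
#'
#' @param eim A 16 x 16 EIM.
#' @return A `voltage_frame`.
#' @export
flatten_eim <- function(eim) {
  .eim_check(unclass(eim))
  pat <- adjacent_pattern()
  voltage_frame(eim[cbind(pat$inj + 1L, pat$meas + 1L)])
}

#' Diagonal cyclic shift of an EIM
#'
#' Shifts both row and column indices cyclically by `n`. A shift by `n`
#' corresponds to a counter-clockwise rotation of the underlying conductivity
#' by `2*pi*n/16`: injection pair k on the rotated medium sees what pair
#' k - n saw on the original. The structural-zero band is invariant, and the
#' operation is an exact group action of Z/16.
#'
#' @param eim A 16 x 16 EIM.
#' @param n Any integer (reduced mod 16).
#' @return The shifted EIM.
#' @export
shift_eim <- function(eim, n) {
  m <- unclass(eim)
  if (!is.matrix(m) || !all(dim(m) == c(16L, 16L)))
    stop("an EIM is a 16 x 16 matrix")
  n <- ((as.integer(n) %% 16L) + 16L) %% 16L
  if (n == 0L) return(eim)
  idx <- ((0:15 - n) %% 16L) + 1L   # new index k holds old index k - n
  structure(m[idx, idx], class = class(eim))
}

#' @export
print.eim <- function(x, ...) {
  cat("eim: 16 x 16 electrical impedance map (208 valid entries)\n")
  print(signif(unclass(x), 3))
  invisible(x)
}
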