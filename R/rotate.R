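#' Image rotation by multiples of one electrode pitch (22.5 degrees)
#'
#' The reconstruction grid is rotated by `n * 2*pi/16` counter-clockwise in
#' world coordinates (the same sense as [shift_eim()] and
#' [rotate_element_field()]). Each of the 16 operators is a fixed sparse
#' linear map on the 4096-pixel vector, composed as
#' (exact 90-degree permutation)^f  o  (bilinear base rotation by r * 22.5),
#' with `n = 4 f + r`. Because the 90-degree factor is an exact pixel
#' permutation, composing any operator with a multiple of 90 degrees is
#' exact; this is what makes the network's rotation aggregation exactly
#' equivariant at n in \{4, 8, 12\}. Preimage coordinates falling outside
#' the grid are clamped to the border (edge-replicating fill), which also
#' commutes with the square's 90-degree symmetry.
#'
#' @param img N x N matrix (row = y downwards, column = x rightwards).
#' @param n Integer number of pitches (reduced mod 16).
#' @return Rotated N x N matrix; exact pixel permutation when n is a
#'   multiple of 4.
#' @export
rot_image <- function(img, n) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  op <- rot_operator(nrow(img), n)
  matrix(as.numeric(op %*% as.vector(img)), nrow(img), ncol(img))
}

.rot_cache <- new.env(parent = emptyenv())

# all 16 operators stacked column-wise: N^2 x (16 N^2); one sparse product
# applies every pitch rotation at once (used by the network aggregation)
rot_operator_cat <- function(N) {
  key <- sprintf("cat%d", N)
  if (!is.null(.rot_cache[[key]])) return(.rot_cache[[key]])
  op <- do.call(cbind, lapply(0:15, function(n) rot_operator(N, n)))
  op <- methods::as(op, "CsparseMatrix")
  .rot_cache[[key]] <- op
  op
}

#' Sparse rotation operator for one pitch multiple
#'
#' @param N Image side length.
#' @param n Integer pitches (mod 16).
#' @return A sparse `Matrix` of dimension N^2 x N^2 acting on column-major
#'   image vectors.
#' @export
rot_operator <- function(N, n) {
  n <- ((as.integer(n) %% 16L) + 16L) %% 16L
  key <- sprintf("N%d_n%d", N, n)
  if (!is.null(.rot_cache[[key]])) return(.rot_cache[[key]])
  f <- n %/% 4L; r <- n %% 4L
  P <- .rot_base(N, 4L)        # exact 90-degree permutation
  op <- .rot_base(N, r)        # bilinear 0/22.5/45/67.5
  if (f > 0L) for (i in seq_len(f)) op <- P %*% op
  op <- methods::as(op, "CsparseMatrix")
  .rot_cache[[key]] <- op
  op
}

# single-stage rotation operator by n * 22.5 degrees CCW (n in 0..4),
# bilinear with border clamp; exact permutation at n = 0 and n = 4
.rot_base <- function(N, n) {
  if (n == 0L) return(Matrix::Diagonal(N * N))
  phi <- 2 * pi * n / 16
  c0 <- (N - 1) / 2
  ix <- as.vector(matrix(0:(N - 1L), N, N, byrow = TRUE))
  iy <- as.vector(matrix(0:(N - 1L), N, N))
  x <- ix - c0; y <- c0 - iy             # world coords of output pixels
  # preimage: rotate by -phi
  xs <- cos(phi) * x + sin(phi) * y
  ys <- -sin(phi) * x + cos(phi) * y
  pxs <- pmin(pmax(xs + c0, 0), N - 1)   # border clamp
  pys <- pmin(pmax(c0 - ys, 0), N - 1)
  x0 <- floor(pxs + 1e-9); y0 <- floor(pys + 1e-9)
  fx <- pxs - x0; fy <- pys - y0
  fx[abs(fx) < 1e-9] <- 0; fy[abs(fy) < 1e-9] <- 0
  x1 <- pmin(x0 + 1, N - 1); y1 <- pmin(y0 + 1, N - 1)
  out <- seq_len(N * N)
  idx <- function(py, px) py + N * px + 1L   # column-major, row = y
  i <- rep(out, 4L)
  j <- c(idx(y0, x0), idx(y0, x1), idx(y1, x0), idx(y1, x1))
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  keep <- w != 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                       dims = c(N * N, N * N))
}
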