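#' Gauss-Newton reconstruction configuration
#'
#' @param lambda Regularization weight (> 0). Scaled internally by the mean
#'   diagonal of the first Gauss-Newton normal matrix, so useful values sit
#'   around 1e-3 .. 1 regardless of the voltage scale.
#' @param prior `"tikhonov"` (identity) or `"laplace"` (element-adjacency
#'   graph Laplacian); the penalty is about the homogeneous starting
#'   estimate, so the infinite-regularization limit returns the start.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param step_tol Stop when the relative conductivity update falls below
#'   this.
#' @return Object of class `gn_config`.
#' @export
gn_config <- function(lambda = 0.03, prior = c("tikhonov", "laplace"),
                      max_iter = 10L, step_tol = 1e-4) {
  prior <- match.arg(prior)
  stopifnot(lambda > 0, max_iter >= 1L)
  structure(list(lambda = lambda, prior = prior,
                 max_iter = as.integer(max_iter), step_tol = step_tol),
            class = "gn_config")
}

# element-adjacency graph Laplacian (elements sharing an edge)
.elem_laplacian <- function(mesh) {
  tri <- mesh$tri
  ed <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  ed <- t(apply(ed, 1L, sort))
  el <- rep(seq_len(nrow(tri)), 3L)
  key <- paste(ed[, 1L], ed[, 2L])
  sp <- split(el, key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) == 2L], function(x) x))
  A <- Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                            j = c(pairs[, 2L], pairs[, 1L]), x = 1,
                            dims = c(mesh$n_elem, mesh$n_elem))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# adjoint-method Jacobian dV/dsigma (208 x n_elem) at the given solution:
# the sensitivity of measurement (k, j) to element e is
# -grad(u_k) . grad(u_j) * area_e (both fields are adjacent-pair solves)
.gn_jacobian <- function(mesh, u) {
  n <- mesh$n_nodes
  m <- mesh$n_elem
  rows <- rep(seq_len(m), 3L)
  Bx <- Matrix::sparseMatrix(i = rows, j = as.vector(mesh$tri),
                             x = as.vector(mesh$gb), dims = c(m, n))
  By <- Matrix::sparseMatrix(i = rows, j = as.vector(mesh$tri),
                             x = as.vector(mesh$gc), dims = c(m, n))
  GX <- as.matrix(Bx %*% u); GY <- as.matrix(By %*% u)
  pat <- adjacent_pattern()
  J <- -(GX[, pat$inj + 1L] * GX[, pat$meas + 1L] +
         GY[, pat$inj + 1L] * GY[, pat$meas + 1L]) * mesh$area
  t(J)
}

# best-fit homogeneous conductivity: 1-D minimization of the data misfit
.fit_homogeneous <- function(frame, mesh, electrodes) {
  v <- as.numeric(frame)
  obj <- function(lc) {
    f <- forward_solve(mesh, rep(10^lc, mesh$n_elem), electrodes)$frame
    sum((as.numeric(f) - v)^2)
  }
  opt <- stats::optimize(obj, c(-6, 1), tol = 1e-4)
  10^opt$minimum
}

# nearest-element lookup for every pixel centre inside the disc
.mesh_pixel_map <- function(mesh, grid_size = 64L) {
  N <- as.integer(grid_size)
  scale <- 2 * mesh$radius / N
  ix <- as.vector(matrix(0:(N - 1L), N, N, byrow = TRUE))
  iy <- as.vector(matrix(0:(N - 1L), N, N))
  x <- (ix - (N - 1) / 2) * scale
  y <- ((N - 1) / 2 - iy) * scale
  inside <- x^2 + y^2 <= mesh$radius^2
  d2 <- outer(x^2 + y^2, rep(1, mesh$n_elem)) -
    2 * cbind(x, y) %*% t(mesh$centroid)
  d2 <- sweep(d2, 2L, rowSums(mesh$centroid^2), "+")
  elem <- max.col(-d2, ties.method = "first")
  elem[!inside] <- NA_integer_
  list(elem = elem, inside = inside, N = N)
}

#' Rasterize a per-element field with the target-image convention
#'
#' Nearest-element sampling at pixel centres; pixels outside the circular
#' domain take `fill`.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element values.
#' @param fill Value for pixels outside the domain.
#' @param grid_size Image side (64).
#' @return `grid_size` x `grid_size` matrix.
#' @export
rasterize_elements <- function(mesh, sigma, fill = NA_real_, grid_size = 64L) {
  pm <- .mesh_pixel_map(mesh, grid_size)
  img <- rep(fill, pm$N^2)
  img[pm$inside] <- sigma[pm$elem[pm$inside]]
  matrix(img, pm$N, pm$N)
}

#' Absolute Gauss-Newton reconstruction
#'
#' Iteratively minimizes the regularized data misfit
#' `0.5 ||F(sigma) - V||^2 + 0.5 lambda ||L (sigma - sigma0)||^2`
#' from the best-fit homogeneous start `sigma0`, with an adjoint-method
#' Jacobian, a backtracking line search (the accepted objective sequence is
#' non-increasing), and positivity clamping. The element solution is
#' rasterized with the target-image convention, pixels outside the domain
#' filled with the homogeneous estimate.
#'
#' @param frame A `voltage_frame` (the measured data).
#' @param mesh The inversion `eit_mesh` (use a coarser mesh than the one
#'   that simulated `frame` to avoid the inverse crime).
#' @param config A `gn_config`.
#' @param electrodes The `electrode_model` assumed in the inversion.
#' @param grid_size Output image side (64).
#' @return 64 x 64 image with attributes `sigma` (element solution),
#'   `sigma0` (homogeneous start), `objective` (accepted objective values),
#'   `flagged` (TRUE when the line search stalled and the best iterate was
#'   returned).
#' @export
gn_reconstruct <- function(frame, mesh, config = gn_config(),
                           electrodes = electrode_model(), grid_size = 64L) {
  stopifnot(inherits(config, "gn_config"), config$lambda > 0)
  v <- as.numeric(frame)
  sigma0 <- .fit_homogeneous(frame, mesh, electrodes)
  Rm <- if (config$prior == "tikhonov") Matrix::Diagonal(mesh$n_elem)
        else { L <- .elem_laplacian(mesh); Matrix::crossprod(L) }
  sigma <- rep(sigma0, mesh$n_elem)
  lam <- NULL
  objective <- function(sig, resid)
    0.5 * sum(resid^2) +
      0.5 * lam_eff * sum(as.numeric(Rm %*% (sig - sigma0)) * (sig - sigma0))
  fs <- forward_solve(mesh, sigma, electrodes)
  resid <- v - as.numeric(fs$frame)
  lam_eff <- NA_real_
  obj_hist <- numeric(0)
  flagged <- FALSE
  for (it in seq_len(config$max_iter)) {
    J <- .gn_jacobian(mesh, fs$u)
    H <- crossprod(J)
    if (is.na(lam_eff))                  # scale-free lambda
      lam_eff <- config$lambda * mean(Matrix::diag(H))
    if (it == 1L) obj_hist <- objective(sigma, resid)
    g <- crossprod(J, resid) - lam_eff * as.numeric(Rm %*% (sigma - sigma0))
    delta <- as.numeric(solve(H + lam_eff * as.matrix(Rm), g))
    step <- 1; accepted <- FALSE
    for (ls in 1:8) {
      cand <- pmax(sigma + step * delta, 1e-8)
      fs_c <- forward_solve(mesh, cand, electrodes)
      res_c <- v - as.numeric(fs_c$frame)
      if (objective(cand, res_c) < obj_hist[length(obj_hist)]) {
        accepted <- TRUE
        rel_step <- max(abs(cand - sigma)) / max(abs(sigma))
        sigma <- cand; fs <- fs_c; resid <- res_c
        obj_hist <- c(obj_hist, objective(sigma, resid))
        break
      }
      step <- step / 2
    }
    if (!accepted) { flagged <- TRUE; break }
    if (rel_step < config$step_tol) break
  }
  img <- rasterize_elements(mesh, sigma, fill = sigma0, grid_size = grid_size)
  attr(img, "sigma") <- sigma
  attr(img, "sigma0") <- sigma0
  attr(img, "objective") <- obj_hist
  attr(img, "flagged") <- flagged
  img
}

#' Sweep the Gauss-Newton regularization weight
#'
#' Runs [gn_reconstruct()] for every lambda in the grid, evaluates the
#' figures of merit against the supplied ground truth, and reports the
#' lambda minimizing the position error.
#'
#' @param frame A `voltage_frame`.
#' @param mesh The inversion mesh.
#' @param lambdas Numeric grid (length >= 1).
#' @param truth_px `c(tx, ty)` ground-truth target position in pixels.
#' @param target_sign Passed to [figures_of_merit()].
#' @param config Base `gn_config` (its lambda is replaced per run).
#' @param electrodes The assumed `electrode_model`.
#' @return data.frame (lambda, AR, PE, RNG), one row per lambda, with
#'   attribute `best_lambda` (argmin PE).
#' @export
sweep_lambda <- function(frame, mesh, lambdas, truth_px,
                         target_sign = "below", config = gn_config(),
                         electrodes = electrode_model()) {
  stopifnot(length(lambdas) >= 1L)
  rows <- lapply(lambdas, function(lam) {
    cfg <- config; cfg$lambda <- lam
    img <- gn_reconstruct(frame, mesh, cfg, electrodes)
    fom <- figures_of_merit(img, truth_px, target_sign)
    data.frame(lambda = lam, AR = as.numeric(fom$AR),
               PE = as.numeric(fom$PE), RNG = as.numeric(fom$RNG))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_lambda") <- out$lambda[which.min(out$PE)]
  out
}
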