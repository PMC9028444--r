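#' Electrode model for the complete electrode model (CEM)
#'
#' @param n_elec Number of electrodes (16).
#' @param contact_impedance Per-electrode contact impedance (Ohm m^2, one
#'   value recycled or a length-16 vector). Default 1e-2 in model units.
#' @return Object of class `electrode_model`.
#' @export
electrode_model <- function(n_elec = 16L, contact_impedance = 1e-2) {
  z <- rep_len(contact_impedance, n_elec)
  if (any(!is.finite(z)) || any(z <= 0))
    stop("contact impedances must be strictly positive and finite")
  structure(list(n_elec = as.integer(n_elec), z = z),
            class = "electrode_model")
}

#' Adjacent-adjacent measurement index table
#'
#' For each injection pair k = 0..15 (electrodes k, k+1 mod 16) the 13 valid
#' measurement pairs j (electrodes j, j+1 mod 16) with
#' j not in \{k-1, k, k+1\} (mod 16), j ascending. Row order of the table is
#' the canonical order of the 208-entry voltage frame.
#'
#' @return data.frame with 0-based columns `inj` and `meas` (208 rows).
#' @export
adjacent_pattern <- function() {
  rows <- lapply(0:15, function(k) {
    j <- setdiff(0:15, c((k - 1) %% 16, k, (k + 1) %% 16))
    data.frame(inj = k, meas = sort(j))
  })
  do.call(rbind, rows)
}

# assemble the CEM system matrix and current RHS for all 16 adjacent
# injections; returns the grounded sparse SPD system
.cem_system <- function(mesh, sigma, electrodes) {
  n <- mesh$n_nodes
  L <- electrodes$n_elec
  z <- electrodes$z

  ## volume stiffness: sum_e sigma_e * K_e
  ii <- as.vector(t(mesh$tri[, rep(1:3, each = 3L)]))
  jj <- as.vector(t(mesh$tri[, rep(1:3, times = 3L)]))
  xx <- as.vector(t(mesh$k_local * sigma))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + L, n + L))

  ## electrode boundary terms
  ti <- tj <- integer(0); tx <- numeric(0)
  for (l in seq_len(L)) {
    ed <- mesh$electrodes[[l]]
    n1 <- ed[, 1L]; n2 <- ed[, 2L]
    h <- sqrt(rowSums((mesh$nodes[n1, , drop = FALSE] -
                       mesh$nodes[n2, , drop = FALSE])^2))
    w <- 1 / z[l]
    # edge mass matrix h/6 * [2 1; 1 2] scaled by 1/z_l
    ti <- c(ti, n1, n2, n1, n2)
    tj <- c(tj, n1, n2, n2, n1)
    tx <- c(tx, w * h / 3, w * h / 3, w * h / 6, w * h / 6)
    # coupling -1/z_l * int phi_i over electrode
    ti <- c(ti, n1, n2)
    tj <- c(tj, rep.int(n + l, 2L * length(h)))
    tx <- c(tx, -w * h / 2, -w * h / 2)
    ti <- c(ti, rep.int(n + l, 2L * length(h)))
    tj <- c(tj, n1, n2)
    tx <- c(tx, -w * h / 2, -w * h / 2)
    # electrode diagonal |E_l| / z_l
    ti <- c(ti, n + l); tj <- c(tj, n + l); tx <- c(tx, w * sum(h))
  }
  A <- A + Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n + L, n + L))

  ## unit adjacent current patterns: +1 at electrode k, -1 at k+1 (0-based k)
  rhs <- matrix(0, n + L, L)
  for (k in 0:(L - 1L)) {
    rhs[n + k + 1L, k + 1L] <- 1
    rhs[n + (k + 1L) %% L + 1L, k + 1L] <- -1
  }

  ## ground by pinning the centre node (potentials defined up to a constant;
  ## four-probe differences are invariant to the choice)
  keep <- setdiff(seq_len(n + L), 1L)
  list(A = A[keep, keep], rhs = rhs[keep, , drop = FALSE], keep = keep,
       n = n, L = L)
}

#' Solve the CEM forward problem for all 16 adjacent injections
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity (S/m), strictly positive.
#' @param electrodes An `electrode_model`.
#' @return List with `U` (16 x 16 electrode potentials, columns = injection
#'   patterns), `u` (nodes x 16 interior potentials) and `frame` (the
#'   208-entry `voltage_frame`).
#' @export
forward_solve <- function(mesh, sigma, electrodes = electrode_model()) {
  if (length(sigma) == 1L) sigma <- rep_len(sigma, mesh$n_elem)
  stopifnot(length(sigma) == mesh$n_elem)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivities must be strictly positive and finite")
  sys <- .cem_system(mesh, sigma, electrodes)
  sol <- tryCatch(
    as.matrix(Matrix::solve(sys$A, sys$rhs)),
    error = function(e) stop("singular CEM system: ", conditionMessage(e)))
  full <- matrix(0, sys$n + sys$L, sys$L)
  full[sys$keep, ] <- sol
  U <- full[sys$n + seq_len(sys$L), , drop = FALSE]
  u <- full[seq_len(sys$n), , drop = FALSE]
  list(U = U, u = u, frame = .frame_from_U(U))
}

# four-probe differences V(k, j) = U_j - U_{j+1} under injection k, in
# canonical frame order
.frame_from_U <- function(U) {
  pat <- adjacent_pattern()
  L <- nrow(U)
  v <- U[cbind(pat$meas + 1L, pat$inj + 1L)] -
       U[cbind((pat$meas + 1L) %% L + 1L, pat$inj + 1L)]
  voltage_frame(v)
}

#' Voltage frame constructor
#'
#' A frame is the 208 adjacent-adjacent four-probe voltages of one phantom,
#' ordered by injection pair k = 0..15, then by ascending measurement pair.
#'
#' @param values Numeric vector of length 208, all finite.
#' @param meta Optional named list carried along (phantom id, noise applied).
#' @return Object of class `voltage_frame` (numeric with attributes).
#' @export
voltage_frame <- function(values, meta = list()) {
  values <- as.numeric(values)
  if (length(values) != 208L) stop("a voltage frame has exactly 208 entries")
  if (any(!is.finite(values))) stop("voltage frame entries must be finite")
  structure(values, meta = meta, class = "voltage_frame")
}

#' @export
print.voltage_frame <- function(x, ...) {
  cat(sprintf("voltage_frame: 208 values, range [%.3g, %.3g]\n",
              min(x), max(x)))
  invisible(x)
}

#' Simulate an adjacent-adjacent voltage frame for a phantom
#'
#' Convenience wrapper around [forward_solve()] returning only the frame.
#'
#' @param mesh An `eit_mesh`.
#' @param phantom A `conductivity_phantom` (or a bare per-element sigma).
#' @param electrodes An `electrode_model`.
#' @return A `voltage_frame`.
#' @export
simulate_voltages <- function(mesh, phantom, electrodes = electrode_model()) {
  sigma <- if (inherits(phantom, "conductivity_phantom")) phantom$sigma else phantom
  fs <- forward_solve(mesh, sigma, electrodes)
  fs$frame
}

#' Sample perturbed per-electrode contact impedances
#'
#' Each electrode's impedance is the base value times an independent draw
#' from Normal(mean = 1, sd = std), clamped to stay strictly positive.
#' The three std levels model well-, moderately- and poorly-attached
#' electrode sets.
#'
#' @param base Base contact impedance (Ohm m^2), > 0.
#' @param std One of 1e-5, 1e-3, 1e-1 (other non-negative values accepted).
#' @param n_elec Number of electrodes.
#' @return Numeric vector of length `n_elec`.
#' @export
sample_contact_impedance <- function(base = 1e-2, std = 1e-3, n_elec = 16L) {
  stopifnot(base > 0, std >= 0)
  mult <- stats::rnorm(n_elec, mean = 1, sd = std)
  pmax(base * mult, base * 1e-6)
}

#' Add white Gaussian noise at a target SNR to a voltage frame
#'
#' Amplitude SNR convention: the per-entry noise standard deviation is
#' `||v||_2 / (sqrt(208) * 10^(snr_db/20))`, i.e. the RMS signal over the
#' RMS noise equals `10^(snr_db/20)`.
#'
#' @param frame A `voltage_frame`.
#' @param snr_db Target signal-to-noise ratio in dB (finite).
#' @return A `voltage_frame` with noise applied and `meta$snr_db` recorded.
#' @export
add_awgn_snr <- function(frame, snr_db) {
  stopifnot(inherits(frame, "voltage_frame"), is.finite(snr_db))
  v <- as.numeric(frame)
  sd_n <- sqrt(sum(v^2)) / (sqrt(length(v)) * 10^(snr_db / 20))
  meta <- attr(frame, "meta")
  meta$snr_db <- snr_db
  voltage_frame(v + stats::rnorm(length(v), 0, sd_n), meta = meta)
}
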