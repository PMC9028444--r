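#' Build a 16-fold rotationally symmetric disc mesh
#'
#' Constructs a structured triangular mesh of a circular 2D domain with
#' `n_elec` equidistant boundary electrodes. The mesh is built ring by ring
#' (ring `i` carries `n_elec * i` nodes at radius `i/rings * radius`), so a
#' rotation by one electrode pitch (`2*pi/n_elec`) maps the node, element and
#' electrode sets onto themselves up to a permutation. This exact discrete
#' symmetry is what makes the rotation/diagonal-shift identities of the
#' electrical impedance map hold to solver precision rather than to mesh
#' accuracy.
#'
#' @param radius Domain radius in model units.
#' @param rings Number of concentric node rings; the element count is
#'   `n_elec * rings^2` (default 14 rings, 3136 elements).
#' @param n_elec Number of boundary electrodes (16; the measurement protocol
#'   and the EIM layout assume this value).
#' @param elec_width Electrode arc length in model units. Realized as the
#'   nearest even number of boundary edges centred on the electrode's centre
#'   node. Default half the electrode pitch.
#' @return An object of class `eit_mesh`: list with `nodes` (n x 2), `tri`
#'   (m x 3 node indices, counter-clockwise), `radius`, `rings`, `n_elec`,
#'   per-element geometry (`area`, `centroid`, gradient coefficients `gb`,
#'   `gc`), electrode edge lists, and the node/element permutations realizing
#'   a rotation by one electrode pitch.
#' @export
build_mesh <- function(radius = 1, rings = 14L, n_elec = 16L,
                       elec_width = radius * pi / n_elec) {
  stopifnot(radius > 0, rings >= 2L)
  n_elec <- as.integer(n_elec)
  rings <- as.integer(rings)
  if (n_elec != 16L)
    stop("the adjacent-adjacent protocol implemented here assumes 16 electrodes")

  ## nodes: centre + rings i = 1..rings with n_elec*i nodes each
  ring_n <- n_elec * seq_len(rings)
  ring_start <- c(2L, 2L + cumsum(ring_n)[-rings])  # first node index per ring
  n_nodes <- 1L + sum(ring_n)
  nodes <- matrix(0, n_nodes, 2L)
  for (i in seq_len(rings)) {
    th <- 2 * pi * (seq_len(ring_n[i]) - 1L) / ring_n[i]
    r <- radius * i / rings
    idx <- ring_start[i] + seq_len(ring_n[i]) - 1L
    nodes[idx, 1L] <- r * cos(th)
    nodes[idx, 2L] <- r * sin(th)
  }

  node_at <- function(ring, j) {
    # ring 0 -> centre; j is 0-based angular index, wrapped
    if (ring == 0L) return(rep.int(1L, length(j)))
    ring_start[ring] + (j %% ring_n[ring])
  }

  ## triangulation: between ring i (inner) and i+1 (outer), per sector s
  tris <- vector("list", rings)
  for (i in 0:(rings - 1L)) {
    outer <- i + 1L
    s <- rep(0:(n_elec - 1L), each = 2L * i + 1L)        # sector index
    if (i == 0L) {
      k <- rep(0L, n_elec)
      a <- node_at(0L, k)
      b <- node_at(1L, s)
      d <- node_at(1L, s + 1L)
      tris[[outer]] <- cbind(a, b, d)
    } else {
      # sector-local strip: inner chain u_0..u_i, outer chain w_0..w_{i+1}
      tA <- lapply(0:i, function(k) cbind(k, k, k + 1L, 1L))       # (u_k, w_k, w_k+1)
      tB <- if (i >= 1L) lapply(0:(i - 1L), function(k)
        cbind(k, k + 1L, k + 1L, 2L)) else list()                  # (u_k, w_k+1, u_k+1)
      loc <- do.call(rbind, c(tA, tB))
      # replicate across sectors
      ss <- rep(0:(n_elec - 1L), each = nrow(loc))
      loc <- loc[rep(seq_len(nrow(loc)), n_elec), , drop = FALSE]
      u <- node_at(i, ss * i + loc[, 1L])
      w1 <- node_at(outer, ss * outer + loc[, 2L])
      w2 <- if (i >= 1L) ifelse(loc[, 4L] == 1L,
                                node_at(outer, ss * outer + loc[, 3L]),
                                node_at(i, ss * i + loc[, 3L]))
            else node_at(outer, ss * outer + loc[, 3L])
      tris[[outer]] <- cbind(u, w1, w2)
    }
  }
  tri <- do.call(rbind, tris)
  dimnames(tri) <- NULL

  ## orient counter-clockwise
  x <- matrix(nodes[tri, 1L], ncol = 3L)
  y <- matrix(nodes[tri, 2L], ncol = 3L)
  det2 <- (x[, 2L] - x[, 1L]) * (y[, 3L] - y[, 1L]) -
          (x[, 3L] - x[, 1L]) * (y[, 2L] - y[, 1L])
  flip <- det2 < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]

  geom <- .tri_geometry(nodes, tri)

  ## boundary ring and electrodes
  nb <- ring_n[rings]                     # boundary node count
  bstart <- ring_start[rings]
  edge_ang <- 2 * pi / nb
  n_edge <- max(2L, 2L * round((elec_width / radius) / (2 * edge_ang)))
  if (n_edge >= nb %/% n_elec)
    stop("electrode width leaves no gap between electrodes; refine the mesh")
  pitch_edges <- nb %/% n_elec            # = rings
  electrodes <- vector("list", n_elec)
  for (l in 0:(n_elec - 1L)) {
    c0 <- l * pitch_edges                 # centre boundary node (0-based)
    e0 <- c0 - n_edge %/% 2L              # first covered edge start
    js <- (e0 + 0:(n_edge - 1L)) %% nb
    electrodes[[l + 1L]] <- cbind(bstart + js, bstart + (js + 1L) %% nb)
  }
  elec_len <- n_edge * 2 * radius * sin(edge_ang / 2)  # chord-summed arc length

  ## rotation by one pitch: node permutation (node -> rotated node)
  perm <- integer(n_nodes); perm[1L] <- 1L
  for (i in seq_len(rings)) {
    j <- 0:(ring_n[i] - 1L)
    perm[node_at(i, j)] <- node_at(i, j + i)   # ring i advances by i nodes
  }
  rot_tri <- matrix(perm[tri], ncol = 3L)
  key <- function(m) apply(m, 1L, function(r) paste(sort(r), collapse = "-"))
  elem_perm <- match(key(rot_tri), key(tri))
  if (anyNA(elem_perm))
    stop("internal error: mesh is not rotationally symmetric")

  structure(list(
    nodes = nodes, tri = tri, radius = radius, rings = rings,
    n_elec = n_elec, n_nodes = n_nodes, n_elem = nrow(tri),
    area = geom$area, centroid = geom$centroid,
    gb = geom$gb, gc = geom$gc, k_local = geom$k_local,
    electrodes = electrodes, elec_len = elec_len,
    boundary_start = bstart, boundary_n = nb,
    node_perm = perm, elem_perm = elem_perm
  ), class = "eit_mesh")
}

# per-element P1 geometry: areas, centroids, shape-function gradients and the
# 3x3 local stiffness coefficients (to be scaled by the element conductivity)
.tri_geometry <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1L], ncol = 3L)
  y <- matrix(nodes[tri, 2L], ncol = 3L)
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L])
  c_ <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L])
  area <- 0.5 * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  # grad(phi_i) = (b_i, c_i) / (2A); K_ij = (b_i b_j + c_i c_j) / (4A)
  k_local <- matrix(0, nrow(tri), 9L)
  for (i in 1:3) for (j in 1:3)
    k_local[, (i - 1L) * 3L + j] <- (b[, i] * b[, j] + c_[, i] * c_[, j]) / (4 * area)
  list(area = area,
       centroid = cbind(rowMeans(x), rowMeans(y)),
       gb = b / (2 * area), gc = c_ / (2 * area),
       k_local = k_local)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("eit_mesh: %d nodes, %d elements, radius %g, %d electrodes\n",
              x$n_nodes, x$n_elem, x$radius, x$n_elec))
  invisible(x)
}

#' Rotate a per-element field by a multiple of the electrode pitch
#'
#' Uses the mesh's exact element permutation: the returned field at element
#' `e` is the input field at the element that maps onto `e` under a rigid
#' counter-clockwise rotation by `n * 2*pi/16`.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element values.
#' @param n Integer number of electrode pitches (any integer, reduced mod 16).
#' @return Rotated per-element vector.
#' @export
rotate_element_field <- function(mesh, sigma, n) {
  stopifnot(length(sigma) == mesh$n_elem)
  n <- ((as.integer(n) %% mesh$n_elec) + mesh$n_elec) %% mesh$n_elec
  out <- sigma
  for (i in seq_len(n)) {
    prev <- out
    out[mesh$elem_perm] <- prev   # element e moves onto elem_perm[e]
  }
  out
}
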