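#' Shape specification for a conductivity enclosure
#'
#' A basic unit shape (sphere, cube or octahedron, each of size 1 centred at
#' the origin) placed into the model by a translation `t`, an intrinsic
#' z-y-x rotation `euler`, and a per-axis scaling `s`, with a dimensionless
#' conductivity `contrast` multiplying the background.
#'
#' @param kind One of "sphere", "cube", "octahedron".
#' @param t Length-3 translation (model units); `(t[1], t[2])` must lie
#'   strictly inside the domain of radius `radius` if `radius` is given.
#' @param s Length-3 scaling (model units), each component in
#'   `[0.1, 0.8] * radius` when `radius` is given; no zero components.
#' @param euler Length-3 rotation angles (rad), each in `[0, 2*pi)`.
#' @param contrast Conductivity multiplier in `[1e-2, 1e2]`.
#' @param radius Optional model radius used to validate `t` and `s`.
#' @return Object of class `shape_spec`.
#' @export
shape_spec <- function(kind, t = c(0, 0, 0), s = c(1, 1, 1),
                       euler = c(0, 0, 0), contrast = 1, radius = NULL) {
  kind <- match.arg(kind, c("sphere", "cube", "octahedron"))
  t <- as.numeric(t); s <- as.numeric(s); euler <- as.numeric(euler)
  stopifnot(length(t) == 3L, length(s) == 3L, length(euler) == 3L)
  if (any(s == 0)) stop("invalid shape spec: zero scaling component")
  if (contrast < 1e-2 || contrast > 1e2)
    stop("contrast must lie in [1e-2, 1e2]")
  if (!is.null(radius)) {
    if (sqrt(t[1]^2 + t[2]^2) >= radius)
      stop("enclosure centre must lie strictly inside the domain boundary")
    if (any(abs(s) < 0.1 * radius - 1e-12) || any(abs(s) > 0.8 * radius + 1e-12))
      stop("scaling components must lie in [0.1, 0.8] * radius")
  }
  structure(list(kind = kind, t = t, s = s,
                 euler = euler %% (2 * pi), contrast = contrast),
            class = "shape_spec")
}

# intrinsic z-y-x rotation matrix from euler = (about-x, about-y, about-z)
.euler_matrix <- function(e) {
  cx <- cos(e[1]); sx <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cz <- cos(e[3]); sz <- sin(e[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# matrix -> euler (z-y-x convention), inverse of .euler_matrix away from
# the gimbal singularity
.matrix_euler <- function(M) {
  ey <- -asin(max(-1, min(1, M[3, 1])))
  if (abs(abs(M[3, 1]) - 1) > 1e-9) {
    ex <- atan2(M[3, 2], M[3, 3])
    ez <- atan2(M[2, 1], M[1, 1])
  } else {                       # gimbal: fold everything into x
    ex <- atan2(-M[2, 3], M[2, 2])
    ez <- 0
  }
  c(ex, ey, ez) %% (2 * pi)
}

#' Map points into an enclosure's unit-shape frame
#'
#' Applies `v' = (R (v - t)) / s` componentwise: translation first, then the
#' shape's rotation, then elementwise division by the scaling vector. Points
#' with `v'` inside the unit shape are inside the enclosure.
#'
#' @param points N x 3 matrix of model coordinates.
#' @param spec A `shape_spec`.
#' @return N x 3 matrix of transformed coordinates.
#' @export
inverse_transform <- function(points, spec) {
  stopifnot(inherits(spec, "shape_spec"))
  points <- rbind(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  if (any(spec$s == 0)) stop("invalid shape spec: zero scaling component")
  R <- .euler_matrix(spec$euler)
  v <- sweep(points, 2L, spec$t)
  v <- v %*% t(R)
  sweep(v, 2L, spec$s, "/")
}

#' Unit-shape membership test
#'
#' Evaluates the unit-shape inequality in the transformed frame:
#' sphere `x^2+y^2+z^2 <= 1`, cube `max(|x|,|y|,|z|) <= 1`, octahedron
#' `|x|+|y|+|z| <= 1`.
#'
#' @param kind One of "sphere", "cube", "octahedron".
#' @param points N x 3 matrix of transformed coordinates
#'   (output of [inverse_transform()]).
#' @return Logical vector of length N.
#' @export
shape_mask <- function(kind, points) {
  points <- rbind(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  switch(match.arg(kind, c("sphere", "cube", "octahedron")),
    sphere = rowSums(points^2) <= 1,
    cube = pmax(abs(points[, 1L]), abs(points[, 2L]), abs(points[, 3L])) <= 1,
    octahedron = abs(points[, 1L]) + abs(points[, 2L]) + abs(points[, 3L]) <= 1)
}

#' Draw a random enclosure specification
#'
#' Translation components are uniform on `[-0.8, 0.8] * radius`, resampled
#' until the in-plane centre lies within `0.8 * radius` of the axis; scaling
#' components uniform on `[0.1, 0.8] * radius`; euler angles uniform on
#' `[0, 2*pi)`; contrast log-uniform on `[1e-2, 1e2]`; shape kind uniform
#' over the three basic shapes.
#'
#' @param radius Model radius (> 0).
#' @param planar If TRUE, force the out-of-plane translation component to 0
#'   (every sampled enclosure then intersects the imaging plane).
#' @return A `shape_spec`.
#' @export
sample_enclosure <- function(radius, planar = FALSE) {
  stopifnot(radius > 0)
  repeat {
    t <- stats::runif(3, -0.8 * radius, 0.8 * radius)
    if (planar) t[3] <- 0
    if (sqrt(t[1]^2 + t[2]^2) <= 0.8 * radius) break
  }
  shape_spec(kind = sample(c("sphere", "cube", "octahedron"), 1L),
             t = t,
             s = stats::runif(3, 0.1 * radius, 0.8 * radius),
             euler = stats::runif(3, 0, 2 * pi),
             contrast = 10^stats::runif(1, -2, 2),
             radius = radius)
}

#' Draw a background conductivity
#'
#' Log-uniform on `[1e-5, 1]` S/m: wide enough to cover the tissue
#' conductivities met in thoracic imaging with a generalization margin on
#' both sides.
#'
#' @return Scalar conductivity (S/m).
#' @export
sample_background <- function() {
  10^stats::runif(1, -5, 0)
}

#' Multiplicative Gaussian perturbation of a conductivity field
#'
#' Each value is multiplied by an independent draw from Normal(1, std),
#' modelling within-tissue inhomogeneity; the result is clamped to stay
#' strictly positive.
#'
#' @param values Per-element conductivities.
#' @param std Non-negative standard deviation (study range `[1e-8, 1e-2]`).
#' @return Perturbed values, same length.
#' @export
perturb_field <- function(values, std) {
  if (!is.numeric(std) || std < 0) stop("perturbation std must be >= 0")
  if (std == 0) return(values)
  mult <- stats::rnorm(length(values), 1, std)
  values * pmax(mult, 1e-8)
}

#' Phantom specification
#'
#' @param sigma_bg Background conductivity (S/m) in `[1e-5, 1]`.
#' @param enclosures List of `shape_spec`s.
#' @param perturb_std Per-conductivity-value multiplicative perturbation std;
#'   `NA` (default) samples an independent std log-uniform on `[1e-8, 1e-2]`
#'   for each conductivity value when the phantom is built; 0 disables.
#' @param contact_std Contact-impedance perturbation std (one of 1e-5, 1e-3,
#'   1e-1 in the study design).
#' @param seed RNG seed recorded for provenance.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(sigma_bg, enclosures = list(), perturb_std = NA_real_,
                         contact_std = 1e-3, seed = NA_integer_) {
  if (sigma_bg < 1e-5 || sigma_bg > 1)
    stop("sigma_bg must lie in [1e-5, 1] S/m")
  if (!is.na(perturb_std) && (perturb_std < 0 || perturb_std > 1e-2))
    stop("perturb_std must lie in [0, 1e-2]")
  stopifnot(all(vapply(enclosures, inherits, logical(1), "shape_spec")))
  structure(list(sigma_bg = sigma_bg, enclosures = enclosures,
                 perturb_std = perturb_std, contact_std = contact_std,
                 seed = seed),
            class = "phantom_spec")
}

#' Draw a full random phantom specification
#'
#' @param radius Model radius.
#' @param n_enclosures Number of enclosures; `NA` samples uniformly 1..4.
#' @param planar Passed to [sample_enclosure()].
#' @param contact_std Contact-impedance std; `NA` samples uniformly from
#'   \{1e-5, 1e-3, 1e-1\}.
#' @return A `phantom_spec`.
#' @export
sample_phantom_spec <- function(radius, n_enclosures = NA_integer_,
                                planar = FALSE, contact_std = NA_real_) {
  if (is.na(n_enclosures)) n_enclosures <- sample.int(4L, 1L)
  if (is.na(contact_std)) contact_std <- sample(c(1e-5, 1e-3, 1e-1), 1L)
  phantom_spec(
    sigma_bg = sample_background(),
    enclosures = replicate(n_enclosures, sample_enclosure(radius, planar),
                           simplify = FALSE),
    contact_std = contact_std)
}

#' Build a conductivity phantom on a mesh
#'
#' Assigns the background conductivity everywhere, then for each enclosure in
#' order sets the elements whose centroid (at z = 0) falls inside the
#' transformed shape to `sigma_bg * contrast`; later enclosures overwrite
#' earlier ones where they overlap. Finally each conductivity value's element
#' group is perturbed multiplicatively (see [perturb_field()]), with an
#' independent std per value when `spec$perturb_std` is `NA`.
#'
#' @param mesh An `eit_mesh`.
#' @param spec A `phantom_spec`.
#' @return Object of class `conductivity_phantom`: list with `sigma`
#'   (per-element, strictly positive), `spec`, and `mesh_key`.
#' @export
build_phantom <- function(mesh, spec) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(spec, "phantom_spec"))
  pts <- cbind(mesh$centroid, 0)
  sigma <- rep(spec$sigma_bg, mesh$n_elem)
  group <- rep.int(0L, mesh$n_elem)      # which conductivity value
  for (i in seq_along(spec$enclosures)) {
    enc <- spec$enclosures[[i]]
    inside <- shape_mask(enc$kind, inverse_transform(pts, enc))
    if (!any(inside))
      warning(sprintf("enclosure %d covers zero mesh elements", i))
    sigma[inside] <- spec$sigma_bg * enc$contrast
    group[inside] <- i
  }
  for (g in unique(group)) {
    std <- spec$perturb_std
    if (is.na(std)) std <- 10^stats::runif(1, -8, -2)
    idx <- group == g
    sigma[idx] <- perturb_field(sigma[idx], std)
  }
  structure(list(sigma = sigma, spec = spec,
                 mesh_key = sprintf("r%g-n%d-e%d", mesh$radius, mesh$rings,
                                    mesh$n_elec)),
            class = "conductivity_phantom")
}

#' @export
print.conductivity_phantom <- function(x, ...) {
  cat(sprintf("conductivity_phantom: %d elements, sigma in [%.3g, %.3g] S/m, %d enclosure(s)\n",
              length(x$sigma), min(x$sigma), max(x$sigma),
              length(x$spec$enclosures)))
  invisible(x)
}

#' Rasterize the ground-truth conductivity of a phantom spec
#'
#' Samples the ideal (unperturbed) conductivity at pixel centres on the
#' z = 0 plane. Pixel (0,0) is top-left; x increases rightwards, y downwards;
#' the domain centre sits at pixel centre ((N-1)/2, (N-1)/2) and the domain
#' diameter spans the N pixels. Pixels outside the circular domain are set to
#' the background conductivity.
#'
#' @param spec A `phantom_spec` (or a `conductivity_phantom`, whose spec is
#'   used).
#' @param radius Model radius the spec was sampled for.
#' @param grid_size Image side length in pixels (64).
#' @return `grid_size` x `grid_size` matrix (row = y, column = x) of
#'   conductivities (S/m).
#' @export
rasterize_target <- function(spec, radius, grid_size = 64L) {
  if (inherits(spec, "conductivity_phantom")) spec <- spec$spec
  stopifnot(inherits(spec, "phantom_spec"), radius > 0)
  N <- as.integer(grid_size)
  scale <- 2 * radius / N
  ix <- matrix(0:(N - 1L), N, N, byrow = TRUE)
  iy <- matrix(0:(N - 1L), N, N)
  x <- (ix - (N - 1) / 2) * scale
  y <- ((N - 1) / 2 - iy) * scale       # raster y-down -> world y-up
  pts <- cbind(as.vector(x), as.vector(y), 0)
  img <- rep(spec$sigma_bg, N * N)
  inside_domain <- pts[, 1L]^2 + pts[, 2L]^2 <= radius^2
  for (enc in spec$enclosures) {
    m <- shape_mask(enc$kind, inverse_transform(pts, enc)) & inside_domain
    img[m] <- spec$sigma_bg * enc$contrast
  }
  matrix(img, N, N)
}

#' Convert a model-space position to raster pixel coordinates
#'
#' @param t Length-2 or 3 position in model units (z ignored).
#' @param radius Model radius.
#' @param grid_size Image side (64).
#' @return c(tx, ty): 0-based pixel coordinates (x rightwards, y downwards).
#' @export
position_to_pixels <- function(t, radius, grid_size = 64L) {
  N <- as.integer(grid_size)
  scale <- 2 * radius / N
  c(tx = t[1] / scale + (N - 1) / 2,
    ty = (N - 1) / 2 - t[2] / scale)
}

#' Rotate a shape spec about the domain axis
#'
#' Returns the spec of the enclosure rigidly rotated counter-clockwise by
#' `n * 2*pi/16` about z: the translation rotates with the shape and the
#' shape's rotation matrix absorbs the extra turn.
#'
#' @param spec A `shape_spec`.
#' @param n Integer number of electrode pitches.
#' @return A `shape_spec`.
#' @export
rotate_shape_spec <- function(spec, n) {
  phi <- 2 * pi * n / 16
  cz <- cos(phi); sz <- sin(phi)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  M <- .euler_matrix(spec$euler) %*% t(Rz)    # R_new = R %*% Rz(-phi)
  out <- spec
  out$t <- as.numeric(Rz %*% spec$t)
  out$euler <- .matrix_euler(M)
  out
}

#' Rotate every enclosure of a phantom spec about the domain axis
#'
#' @param spec A `phantom_spec`.
#' @param n Integer number of electrode pitches.
#' @return A `phantom_spec`.
#' @export
rotate_phantom_spec <- function(spec, n) {
  out <- spec
  out$enclosures <- lapply(spec$enclosures, rotate_shape_spec, n = n)
  out
}

#' Serialize / deserialize phantom specs as YAML
#'
#' @param spec A `phantom_spec`.
#' @param file Optional path; if `NULL` the YAML string is returned.
#' @return `phantom_spec_to_yaml`: the YAML string (invisibly if written to
#'   file). `phantom_spec_from_yaml`: a `phantom_spec`.
#' @export
phantom_spec_to_yaml <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$enclosures <- lapply(lst$enclosures, unclass)
  txt <- yaml::as.yaml(lst, precision = 15L)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' @rdname phantom_spec_to_yaml
#' @param yaml_text YAML string (alternative to `file`).
#' @export
phantom_spec_from_yaml <- function(file = NULL, yaml_text = NULL) {
  lst <- if (!is.null(file)) yaml::read_yaml(file) else yaml::yaml.load(yaml_text)
  encs <- lapply(lst$enclosures, function(e)
    shape_spec(e$kind, unlist(e$t), unlist(e$s), unlist(e$euler), e$contrast))
  phantom_spec(sigma_bg = lst$sigma_bg, enclosures = encs,
               perturb_std = if (is.null(lst$perturb_std)) NA_real_ else lst$perturb_std,
               contact_std = lst$contact_std,
               seed = if (is.null(lst$seed)) NA_integer_ else lst$seed)
}
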