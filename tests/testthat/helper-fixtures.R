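# shared fixtures, built once per test run

# coarse mesh for fast forward solves
mesh_coarse <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_mesh(radius = 28, rings = 6)
    m
  }
})

# study-scale symmetric mesh for the physics property tests
mesh_fine <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_mesh(radius = 28, rings = 14)
    m
  }
})

# a reproducible valid EIM with random entries
random_eim <- function(seed = 1) {
  set.seed(seed)
  v <- eim_valid_mask()
  m <- matrix(0, 16, 16)
  m[v] <- rnorm(208)
  structure(m, class = c("eim", "matrix", "array"))
}

# a tiny network configuration for fast structural tests
tiny_config <- function(..., dropout = 0) {
  net_config(conv_channels = c(3L, 4L), head_widths = c(8L, 4096L),
             dropout = dropout, ...)
}

# single off-centre low-conductivity target phantom on the fine mesh
single_target_phantom <- function(t_xy = c(11, 0), contrast = 0.1,
                                  sigma_bg = 0.1, size = 6) {
  enc <- shape_spec("sphere", t = c(t_xy, 0), s = rep(size, 3),
                    contrast = contrast, radius = 28)
  phantom_spec(sigma_bg, list(enc), perturb_std = 0)
}
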