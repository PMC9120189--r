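# shared test helpers: tiny particles, morphologies and fields built in code

spion <- function(T = 300) particle_preset("spion", temperature = T)
menp12 <- function() particle_preset("menp", r_core_nm = 12)

# three-node soma-axon-dendrite SWC fixture written to a temp file
write_tiny_swc <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c("# tiny fixture",
               "1 1 0 0 0 10 -1",
               "2 2 0 -50 0 1 1",
               "3 3 0 40 30 1.5 1"), path)
  path
}

# a magnetization_field with constant value per half-space, on a small grid
two_zone_field <- function(val_lo = 1e-6, val_hi = 5e-6) {
  g <- field_grid(c(40, 40, 40), 10)
  n <- nrow(g$coords)
  dM <- matrix(val_lo, n, 3)
  dM[g$coords[, 2] > 20, ] <- val_hi
  structure(list(coords = g$coords, t = c(0, 1, 2), dM = dM,
                 dims = g$dims, spacing = g$spacing,
                 h_hat = c(1, 0, 0), convention = "signed_projection"),
            class = "magnetization_field")
}

# uniform-value magnetization field over a lattice
uniform_field <- function(value, dims = c(100, 700, 100), spacing = 50,
                          t = 0:4) {
  g <- field_grid(dims, spacing)
  structure(list(coords = g$coords, t = t,
                 dM = matrix(value, nrow(g$coords), length(t)),
                 dims = g$dims, spacing = g$spacing,
                 h_hat = c(1, 0, 0), convention = "signed_projection"),
            class = "magnetization_field")
}
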