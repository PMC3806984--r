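# Shared fixtures. The full default ear solve is expensive, so it is
# computed once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

coarse_params <- function(...) ear_params(mesh_size = 1.0, ...)

default_mesh <- function() cached("default_mesh", build_ear_mesh())

default_system <- function() {
  cached("default_system", assemble_ear(default_mesh()))
}

# Default-model UDTF on a moderately dense grid (shared by the response
# and acceptance tests).
default_udtf <- function() {
  cached("default_udtf", {
    compute_udtf(system = default_system(),
                 freqs = udtf_freq_grid(200, 10000, 20))
  })
}

# Flat circular plate built from the shell mesher (cone depth ~ 0),
# clamped at the rim, for bending verification.
plate_system <- function(radius = 10, mesh_size = 10 / 12, thickness = 0.2,
                         E = 7e10, rho = 2700, loss = 0) {
  p <- list(tm_radius = radius, annulus_width = radius / 12,
            annulus_thickness = thickness, tm_tension = 0,
            mesh_size = mesh_size, flaccida_sector_deg = 60,
            tm_cone_depth = 1e-9, manubrium_fraction = 0.6,
            tm_thickness_tensa = thickness, tm_thickness_flaccida = thickness,
            ossicle_dims = list(manubrium_thickness = thickness))
  sh <- otomech:::cone_shell_mesh(p)
  mesh <- structure(list(
    nodes = sh$nodes, shell = sh$elements,
    solid = tibble::tibble(n1 = integer(0), n2 = integer(0),
                           n3 = integer(0), n4 = integer(0),
                           region = character(0)),
    connectors = empty_connectors(),
    tags = list(
      annulus_boundary = which(abs(sqrt(sh$nodes[, 1]^2 + sh$nodes[, 2]^2) -
                                     radius) < 1e-6),
      tm_lateral_surface = seq_len(nrow(sh$elements))),
    params = p), class = "ear_mesh")
  reg <- material_registry()
  for (r in c("tympanic_membrane_tensa", "tympanic_membrane_flaccida",
              "manubrium", "tympanic_annular_ligament")) {
    reg <- apply_overrides(reg, stats::setNames(list(list(
      youngs_modulus = E, density = rho, loss_factor = loss)), r))
  }
  list(mesh = mesh, system = assemble_ear(mesh, reg))
}

empty_connectors <- function() {
  tibble::tibble(kind = character(0), region = character(0),
                 node = integer(0), dir_x = numeric(0), dir_y = numeric(0),
                 dir_z = numeric(0), k = numeric(0), c = numeric(0),
                 area_mm2 = numeric(0), length_mm = numeric(0))
}

sdof_system <- function(f0 = 10, m = 1, eta = 0) {
  k <- (2 * pi * f0)^2 * m
  fe_system_raw(K = matrix(k), M = matrix(m),
                Kloss = if (eta > 0) matrix(k * eta) else NULL)
}

# Rectangular shell strip (beam-like, nu = 0) clamped at both x-ends.
strip_system <- function(L = 100, b = 10, t = 2, nx = 20, ny = 2,
                         E = 2.1e11, rho = 7800) {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, b, length.out = ny + 1)
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  nodes <- cbind(grid$x, grid$y, 0)
  nid <- function(ix, iy) (iy - 1L) * (nx + 1L) + ix
  tris <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    a <- nid(ix, iy); bb <- nid(ix + 1L, iy)
    cc <- nid(ix + 1L, iy + 1L); d <- nid(ix, iy + 1L)
    tris[[length(tris) + 1L]] <- rbind(c(a, bb, cc), c(a, cc, d))
  }
  conn <- do.call(rbind, tris)
  shell <- tibble::tibble(n1 = conn[, 1], n2 = conn[, 2], n3 = conn[, 3],
                          region = "tympanic_membrane_tensa",
                          thickness_mm = t, tension_n_per_m = 0)
  mesh <- structure(list(
    nodes = nodes, shell = shell,
    solid = tibble::tibble(n1 = integer(0), n2 = integer(0),
                           n3 = integer(0), n4 = integer(0),
                           region = character(0)),
    connectors = empty_connectors(),
    tags = list(annulus_boundary = which(nodes[, 1] %in% c(0, L)),
                tm_lateral_surface = seq_len(nrow(shell))),
    params = list()), class = "ear_mesh")
  reg <- apply_overrides(material_registry(), list(
    tympanic_membrane_tensa = list(youngs_modulus = E, density = rho,
                                   poisson = 0, loss_factor = 0)))
  assemble_ear(mesh, reg)
}

# Sum one translational component of a free-dof load vector over all nodes.
sum_load_component <- function(system, load, comp) {
  n_nodes <- length(system$ndof_node)
  total <- 0
  for (nn in seq_len(n_nodes)) {
    i <- otomech:::free_dof_index(system, nn, comp)
    if (!is.na(i)) total <- total + load[i]
  }
  total
}

new_spectrum_for_test <- function(freqs, mags) {
  otomech:::new_udtf_spectrum(tibble::tibble(
    frequency_hz = freqs, magnitude_mm_per_pa = mags,
    phase_rad = 0), excitation = "synthetic test spectrum")
}
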