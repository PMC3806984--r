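test_that("linear tetrahedron passes rigid-body, patch and mass checks", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 0.01
  E <- 1e7; nu <- 0.3; rho <- 1000
  em <- otomech:::tet_element(X, E, nu, rho)
  # rigid-body translation: zero strain energy
  u_rigid <- rep(c(1e-3, -2e-3, 5e-4), 4)
  expect_lt(abs(t(u_rigid) %*% em$K %*% u_rigid), 1e-12 * max(abs(em$K)))
  # uniform-strain patch: energy matches the closed-form density exactly
  A <- matrix(c(1e-3, 2e-4, 0, -1e-4, 5e-4, 3e-4, 0, 1e-4, -2e-4), 3, 3)
  u_lin <- as.vector(A %*% t(X))
  eps <- 0.5 * (A + t(A))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  W <- (0.5 * lam * sum(diag(eps))^2 + mu * sum(eps * eps)) * em$volume
  expect_equal(as.numeric(0.5 * t(u_lin) %*% em$K %*% u_lin), W,
               tolerance = 1e-10)
  # consistent mass integrates the density exactly
  expect_equal(sum(em$M) / 3, rho * em$volume, tolerance = 1e-12)
  # inverted element rejected
  expect_error(otomech:::tet_element(X[c(2, 1, 3, 4), ], E, nu, rho),
               "Jacobian")
})

test_that("assembled mass conserves the density-volume sum", {
  mesh <- build_ear_mesh(coarse_params())
  reg <- material_registry()
  sys <- assemble_ear(mesh, reg)
  # rigid unit-z motion of every free node recovers the full structural
  # mass except what was clamped away with the annulus boundary ring
  v <- numeric(sys$n_free)
  for (nn in seq_len(nrow(mesh$nodes))) {
    i <- otomech:::free_dof_index(sys, nn, 3L)
    if (!is.na(i)) v[i] <- 1
  }
  m_fe <- as.numeric(t(v) %*% (sys$M %*% v))
  vols <- otomech:::tet_volumes(mesh$nodes, mesh$solid) * 1e-9
  rho_s <- vapply(mesh$solid$region, function(r)
    material_lookup(reg, r)$density, numeric(1))
  areas <- otomech:::tri_areas(mesh$nodes, mesh$shell) * 1e-6
  rho_sh <- vapply(mesh$shell$region, function(r)
    material_lookup(reg, r)$density, numeric(1))
  shell_mass <- rho_sh * areas * mesh$shell$thickness_mm * 1e-3
  # shell mass is lumped per node: the clamped ring takes its share away
  clamped <- mesh$tags$annulus_boundary
  lost <- 0
  for (e in seq_len(nrow(mesh$shell))) {
    nds <- unlist(mesh$shell[e, c("n1", "n2", "n3")])
    lost <- lost + shell_mass[e] / 3 * sum(nds %in% clamped)
  }
  expected <- sum(rho_s * vols) + sum(shell_mass) - lost
  expect_equal(m_fe, unname(expected), tolerance = 1e-9)
})

test_that("flat shell decouples membrane and bending and scales with thickness", {
  X <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(0.4, 1.8, 0)) * 1e-3
  se1 <- otomech:::shell_element(X, E = 1e7, nu = 0.3, t = 1e-4, rho = 1200)
  se2 <- otomech:::shell_element(X, E = 1e7, nu = 0.3, t = 2e-4, rho = 1200)
  # rigid-body modes carry no energy
  rb <- function(tr, om) unlist(lapply(1:3, function(i)
    c(tr + otomech:::cross3(om, X[i, ]), om)))
  modes <- rbind(rb(c(1, 0, 0), c(0, 0, 0)), rb(c(0, 1, 0), c(0, 0, 0)),
                 rb(c(0, 0, 1), c(0, 0, 0)), rb(c(0, 0, 0), c(1, 0, 0)),
                 rb(c(0, 0, 0), c(0, 1, 0)), rb(c(0, 0, 0), c(0, 0, 1)))
  en <- apply(modes, 1, function(u) abs(t(u) %*% se1$K %*% u))
  expect_lt(max(en), 1e-10 * max(abs(se1$K)))
  # in-plane stretch excites membrane energy only, and doubles with t
  stretch <- unlist(lapply(1:3, function(i) c(X[i, 1], 0, 0, 0, 0, 0)))
  e_m1 <- as.numeric(t(stretch) %*% se1$K %*% stretch)
  e_m2 <- as.numeric(t(stretch) %*% se2$K %*% stretch)
  expect_gt(e_m1, 0)
  expect_equal(e_m2 / e_m1, 2, tolerance = 1e-10)
  # transverse quadratic field excites bending, scaling with t^3
  bend <- unlist(lapply(1:3, function(i)
    c(0, 0, -0.5 * X[i, 1]^2, 0, X[i, 1], 0)))
  e_b1 <- as.numeric(t(bend) %*% se1$K %*% bend)
  e_b2 <- as.numeric(t(bend) %*% se2$K %*% bend)
  expect_gt(e_b1, 0)
  expect_equal(e_b2 / e_b1, 8, tolerance = 1e-6)
  expect_error(otomech:::shell_element(X, 1e7, 0.3, 0, 1200),
               "thickness")
})

test_that("clamped circular plate fundamental matches the Kirchhoff closed form", {
  ps <- cached("plate12", plate_system(mesh_size = 10 / 12))
  f1 <- modal_frequencies(ps$system, 1)
  a <- 0.01; t <- 2e-4
  D <- 7e10 * t^3 / (12 * (1 - 0.3^2))
  f_exact <- 10.2158 / (2 * pi * a^2) * sqrt(D / (2700 * t))
  expect_lt(abs(f1 - f_exact) / f_exact, 0.02)
})

test_that("clamped-plate modal error decreases monotonically under refinement", {
  a <- 0.01; t <- 2e-4
  D <- 7e70 * 0; D <- 7e10 * t^3 / (12 * (1 - 0.3^2))
  f_exact <- 10.2158 / (2 * pi * a^2) * sqrt(D / (2700 * t))
  errs <- vapply(c(10 / 6, 10 / 9, 10 / 12), function(h) {
    f1 <- modal_frequencies(plate_system(mesh_size = h)$system, 1)
    abs(f1 - f_exact) / f_exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("clamped beam strip matches the Euler-Bernoulli closed form", {
  sys <- strip_system()
  f1 <- modal_frequencies(sys, 1)
  L <- 0.1; t <- 2e-3
  f_exact <- 22.373 / (2 * pi * L^2) * t * sqrt(2.1e11 / (12 * 7800))
  expect_lt(abs(f1 - f_exact) / f_exact, 0.02)
})

test_that("grounded connectors add rank-one blocks where placed", {
  mesh <- build_ear_mesh(coarse_params())
  base <- assemble_ear(mesh)
  # 42 springs totalling 70 on one node along +z: diagonal gains 70
  m2 <- mesh
  nn <- m2$tags$footplate[1]
  m2$connectors <- dplyr::bind_rows(
    m2$connectors,
    tibble::tibble(kind = "spring", region = "stapedial_annular_ligament",
                   node = nn, dir_x = 0, dir_y = 0, dir_z = 1,
                   k = 70 / 42, c = 0, loss_factor = 0,
                   area_mm2 = NA_real_, length_mm = NA_real_)[rep(1, 42), ])
  sys2 <- assemble_ear(m2)
  iz <- otomech:::free_dof_index(base, nn, 3L)
  expect_equal(sys2$K[iz, iz] - base$K[iz, iz], 70, tolerance = 1e-6)
  ix <- otomech:::free_dof_index(base, nn, 1L)
  expect_equal(sys2$K[ix, ix], base$K[ix, ix], tolerance = 1e-9)
  # zero damping leaves C untouched
  expect_equal(Matrix::nnzero(sys2$C), Matrix::nnzero(base$C))
})

test_that("harmonic solve reproduces single-dof closed forms exactly", {
  sys <- sdof_system(f0 = 10)
  k <- (2 * pi * 10)^2
  expect_equal(Mod(harmonic_solve(sys, 1, 0)$u[1, 1]), 1 / k,
               tolerance = 1e-10)
  eta <- 0.02
  sysd <- sdof_system(f0 = 10, eta = eta)
  expect_equal(Mod(harmonic_solve(sysd, 1, 10)$u[1, 1]), 1 / (k * eta),
               tolerance = 1e-10)
  expect_error(harmonic_solve(sys, 1, 10), "singular")
  expect_error(harmonic_solve(sys, c(1, 2), 5), "length")
})

test_that("sparse augmented solve agrees with a dense complex oracle", {
  K <- matrix(c(100, -40, 0, -40, 130, -30, 0, -30, 80), 3, 3)
  M <- diag(c(1, 2, 0.5)); C <- 0.05 * K; Kl <- 0.03 * K
  sys <- fe_system_raw(K, M, C, Kl)
  load <- c(1, 0, 2i)
  freqs <- c(0.3, 1.1, 2.7, 4.2, 9.9)
  sol <- harmonic_solve(sys, load, freqs)
  for (i in seq_along(freqs)) {
    w <- 2 * pi * freqs[i]
    ud <- solve(K + 1i * Kl + 1i * w * C - w^2 * M, load)
    expect_lt(max(Mod(sol$u[, i] - ud)) / max(Mod(ud)), 1e-10)
  }
  # linearity in complex amplitude
  a <- 2 - 3i
  sol2 <- harmonic_solve(sys, a * load, freqs)
  expect_lt(max(Mod(sol2$u - a * sol$u)) / max(Mod(sol$u)), 1e-12)
  # reciprocity: transfer i->j equals j->i
  e1 <- c(1, 0, 0); e3 <- c(0, 0, 1)
  t13 <- harmonic_solve(sys, e1, 5)$u[3, 1]
  t31 <- harmonic_solve(sys, e3, 5)$u[1, 1]
  expect_equal(t13, t31, tolerance = 1e-12)
  # velocity accessor
  expect_equal(solution_velocity(sol)[, 2],
               2i * pi * freqs[2] * sol$u[, 2], tolerance = 1e-12)
})

test_that("damped response stays finite across a resonance sweep", {
  sysd <- sdof_system(f0 = 100, eta = 0.05)
  mags <- Mod(harmonic_solve(sysd, 1, seq(50, 200, by = 1))$u[1, ])
  expect_true(all(is.finite(mags)))
  expect_lt(max(mags), 1 / ((2 * pi * 100)^2 * 0.05) * 1.01)
})

test_that("modal extraction handles rigid modes and reduced systems", {
  sys <- sdof_system(10)
  expect_equal(modal_frequencies(sys, 1), 10, tolerance = 1e-9)
  # free-free two-mass spring: one rigid mode at ~0 Hz
  k <- 100
  free2 <- fe_system_raw(K = matrix(c(k, -k, -k, k), 2),
                         M = diag(2))
  f <- modal_frequencies(free2, 2)
  expect_lt(f[1], 1e-3)
  expect_equal(f[2], sqrt(2 * k) / (2 * pi), tolerance = 1e-9)
  expect_error(modal_frequencies(sys, 5), "free dofs")
})

test_that("system matrices satisfy the structural invariants", {
  sys <- cached("coarse_system", assemble_ear(build_ear_mesh(coarse_params())))
  relsym <- function(A) {
    max(abs(A - Matrix::t(A))) / max(abs(A))
  }
  expect_lt(relsym(sys$K), 1e-9)
  expect_lt(relsym(sys$M), 1e-9)
  expect_lt(relsym(sys$C), 1e-9)
  expect_true(all(Matrix::diag(sys$M) > 0))
  expect_true(all(Matrix::diag(sys$C) >= 0))
  # MatrixMarket dump round-trips through the Matrix reader
  dir <- tempfile(); paths <- export_system_mtx(sys, dir)
  back <- Matrix::readMM(file.path(dir, "K.mtx"))
  expect_equal(dim(back), dim(sys$K))
})
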