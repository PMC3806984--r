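# Element matrices for the harmonic structural core: linear-tetrahedron
# isotropic elasticity, flat-facet triangular shell (constant-strain
# membrane + discrete-Kirchhoff bending + stabilized drilling rotation),
# and grounded / two-node spring, damper and bar connectors.
# All element routines work in SI units (m, kg, Pa).

# ---- linear tetrahedron --------------------------------------------------

# X: 4x3 node coordinates (m). Returns K (12x12), M (12x12), volume.
tet_element <- function(X, E, nu, rho) {
  V6 <- det(cbind(1, X))            # 6*V (signed)
  V <- V6 / 6
  if (V <= 0) abort("inverted solid element (negative Jacobian)")
  Cinv <- solve(cbind(1, X))        # rows: coefficients of 1, x, y, z
  g <- Cinv[2:4, , drop = FALSE]    # g[, i] = grad N_i
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    c0 <- 3 * (i - 1)
    bx <- g[1, i]; by <- g[2, i]; bz <- g[3, i]
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(0, 3), rep(mu, 3)))
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  K <- crossprod(B, D %*% B) * V
  Mm <- matrix(0, 12, 12)
  for (i in 1:4) for (j in 1:4) {
    m <- rho * V / 20 * (1 + (i == j))
    ii <- 3 * (i - 1); jj <- 3 * (j - 1)
    Mm[ii + 1, jj + 1] <- Mm[ii + 1, jj + 1] + m
    Mm[ii + 2, jj + 2] <- Mm[ii + 2, jj + 2] + m
    Mm[ii + 3, jj + 3] <- Mm[ii + 3, jj + 3] + m
  }
  list(K = K, M = Mm, volume = V)
}

# ---- discrete-Kirchhoff triangle bending --------------------------------

# Quadratic shape functions on the unit triangle and their derivatives.
dkt_N <- function(xi, eta) {
  lam <- 1 - xi - eta
  c(2 * lam * (lam - 0.5), xi * (2 * xi - 1), eta * (2 * eta - 1),
    4 * xi * eta, 4 * eta * lam, 4 * xi * lam)
}
dkt_dNdxi <- function(xi, eta) {
  lam <- 1 - xi - eta
  c(1 - 4 * lam, 4 * xi - 1, 0, 4 * eta, -4 * eta, 4 * (lam - xi))
}
dkt_dNdeta <- function(xi, eta) {
  lam <- 1 - xi - eta
  c(1 - 4 * lam, 0, 4 * eta - 1, 4 * xi, 4 * (lam - eta), -4 * xi)
}

# Rotation-field coefficient rows for beta_x and beta_y given side
# geometry coefficients (Batoz construction). Returns the 9-vectors of
# coefficients multiplying the quadratic shape function vector N (6).
dkt_H_coeff <- function(x, y) {
  # sides 4:(2,3)  5:(3,1)  6:(1,2)
  si <- c(2, 3, 1); sj <- c(3, 1, 2)
  xij <- x[si] - x[sj]; yij <- y[si] - y[sj]
  l2 <- xij^2 + yij^2
  a <- -xij / l2
  b <- 0.75 * xij * yij / l2
  cc <- (0.25 * xij^2 - 0.5 * yij^2) / l2
  d <- -yij / l2
  e <- (0.25 * yij^2 - 0.5 * xij^2) / l2
  # index helpers: k=1 -> side 4, k=2 -> side 5, k=3 -> side 6
  Hx <- matrix(0, 9, 6); Hy <- matrix(0, 9, 6)
  # node 1 block (dofs w1, tx1, ty1); mid-side funcs: N4=4, N5=5, N6=6
  Hx[1, 6] <- 1.5 * a[3];  Hx[1, 5] <- -1.5 * a[2]
  Hx[2, 5] <- b[2];        Hx[2, 6] <- b[3]
  Hx[3, 1] <- 1;           Hx[3, 5] <- -cc[2]; Hx[3, 6] <- -cc[3]
  Hx[4, 4] <- 1.5 * a[1];  Hx[4, 6] <- -1.5 * a[3]
  Hx[5, 6] <- b[3];        Hx[5, 4] <- b[1]
  Hx[6, 2] <- 1;           Hx[6, 6] <- -cc[3]; Hx[6, 4] <- -cc[1]
  Hx[7, 5] <- 1.5 * a[2];  Hx[7, 4] <- -1.5 * a[1]
  Hx[8, 4] <- b[1];        Hx[8, 5] <- b[2]
  Hx[9, 3] <- 1;           Hx[9, 4] <- -cc[1]; Hx[9, 5] <- -cc[2]

  Hy[1, 6] <- 1.5 * d[3];  Hy[1, 5] <- -1.5 * d[2]
  Hy[2, 1] <- -1;          Hy[2, 5] <- e[2];  Hy[2, 6] <- e[3]
  Hy[3, 5] <- -b[2];       Hy[3, 6] <- -b[3]
  Hy[4, 4] <- 1.5 * d[1];  Hy[4, 6] <- -1.5 * d[3]
  Hy[5, 2] <- -1;          Hy[5, 6] <- e[3];  Hy[5, 4] <- e[1]
  Hy[6, 6] <- -b[3];       Hy[6, 4] <- -b[1]
  Hy[7, 5] <- 1.5 * d[2];  Hy[7, 4] <- -1.5 * d[1]
  Hy[8, 3] <- -1;          Hy[8, 4] <- e[1];  Hy[8, 5] <- e[2]
  Hy[9, 4] <- -b[1];       Hy[9, 5] <- -b[2]
  list(Hx = Hx, Hy = Hy)
}

# x, y: local node coordinates (length 3). Db: 3x3 plate rigidity.
# Dofs (w, theta_x, theta_y) per node with theta_x = dw/dy, theta_y = -dw/dx.
dkt_bending <- function(x, y, Db) {
  H <- dkt_H_coeff(x, y)
  x31 <- x[3] - x[1]; x12 <- x[1] - x[2]
  y31 <- y[3] - y[1]; y12 <- y[1] - y[2]
  A2 <- x31 * y12 - x12 * y31         # 2*area
  K <- matrix(0, 9, 9)
  pts <- rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  for (q in 1:3) {
    xi <- pts[q, 1]; eta <- pts[q, 2]
    dNx <- dkt_dNdxi(xi, eta); dNe <- dkt_dNdeta(xi, eta)
    Hx_xi <- H$Hx %*% dNx; Hx_eta <- H$Hx %*% dNe
    Hy_xi <- H$Hy %*% dNx; Hy_eta <- H$Hy %*% dNe
    B <- rbind(
      t(y31 * Hx_xi + y12 * Hx_eta),
      t(-x31 * Hy_xi - x12 * Hy_eta),
      t(-x31 * Hx_xi - x12 * Hx_eta + y31 * Hy_xi + y12 * Hy_eta)
    ) / A2
    K <- K + crossprod(B, Db %*% B)
  }
  K * A2 / 6
}

# ---- flat shell: CST membrane + DKT bending + drilling -------------------

# X: 3x3 global node coordinates (m). Returns 18x18 global K and lumped M.
# `tension` is an isotropic in-surface resting tension (N/m) adding the
# membrane geometric stiffness T * int(grad N . grad N) dA on the
# transverse deflection dofs.
shell_element <- function(X, E, nu, t, rho, drill_scale = 1e-6,
                          tension = 0) {
  if (t <= 0) abort("shell element with non-positive thickness")
  e1 <- X[2, ] - X[1, ]
  nvec <- cross3(e1, X[3, ] - X[1, ])
  A <- 0.5 * sqrt(sum(nvec^2))
  if (A <= 1e-18) abort("degenerate shell triangle")
  e1 <- e1 / sqrt(sum(e1^2))
  e3 <- nvec / sqrt(sum(nvec^2))
  e2 <- cross3(e3, e1)
  R <- rbind(e1, e2, e3)              # global -> local
  xl <- (X - matrix(X[1, ], 3, 3, byrow = TRUE)) %*% t(R)
  x <- xl[, 1]; y <- xl[, 2]

  # membrane (CST, plane stress)
  x32 <- x[3] - x[2]; x13 <- x[1] - x[3]; x21 <- x[2] - x[1]
  y23 <- y[2] - y[3]; y31 <- y[3] - y[1]; y12 <- y[1] - y[2]
  Bm <- matrix(0, 3, 6)
  Bm[1, c(1, 3, 5)] <- c(y23, y31, y12)
  Bm[2, c(2, 4, 6)] <- c(x32, x13, x21)
  Bm[3, c(1, 3, 5)] <- c(x32, x13, x21)
  Bm[3, c(2, 4, 6)] <- c(y23, y31, y12)
  Bm <- Bm / (2 * A)
  Dm <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  Km <- t * A * crossprod(Bm, Dm %*% Bm)

  Db <- (E * t^3 / (12 * (1 - nu^2))) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  Kb <- dkt_bending(x, y, Db)

  if (tension > 0) {
    G <- rbind(c(y23, y31, y12), c(x32, x13, x21)) / (2 * A)
    Kt <- tension * A * crossprod(G)
    Kb[c(1, 4, 7), c(1, 4, 7)] <- Kb[c(1, 4, 7), c(1, 4, 7)] + Kt
  }

  Kl <- matrix(0, 18, 18)
  mem <- c(1, 2, 7, 8, 13, 14)
  ben <- c(3, 4, 5, 9, 10, 11, 15, 16, 17)
  drl <- c(6, 12, 18)
  Kl[mem, mem] <- Km
  Kl[ben, ben] <- Kb
  # drilling stabilization: penalizes deviation from the mean drilling
  # rotation only (null vector (1,1,1) keeps rigid rotations stress-free)
  kd <- drill_scale * E * t * A
  Kl[drl, drl] <- kd * (diag(3) - matrix(1 / 3, 3, 3))

  Tm <- matrix(0, 18, 18)
  for (b in 0:5) Tm[b * 3 + 1:3, b * 3 + 1:3] <- R
  Kg <- crossprod(Tm, Kl %*% Tm)

  mt <- rho * t * A / 3
  mr <- mt * t^2 / 12                  # lumped rotary inertia (keeps M > 0)
  # drilling inertia far below the bending rotary inertia: the drilling
  # stiffness is a weak stabilization, and matching inertia would park
  # artifact modes inside the audio band
  Ml <- diag(rep(c(mt, mt, mt, mr, mr, mr * 1e-4), 3))
  Mg <- crossprod(Tm, Ml %*% Tm)
  list(K = Kg, M = Mg, area = A, normal = e3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- connectors ----------------------------------------------------------

# Grounded connector: k * d d^T on the translational block of one node.
connector_block <- function(k, dvec) {
  k * tcrossprod(dvec)
}
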