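#' Build the idealized middle-ear mesh
#'
#' Discretizes the parametric geometry of [ear_params()] into an
#' `ear_mesh`: a conical shell membrane (pars tensa / pars flaccida /
#' annular-ligament ring / manubrium strip) on a structured polar grid of
#' flat triangles, a solid-tetrahedron ossicular chain running medially
#' (-z) from the umbo apex, and the connector set (42 vertical cochlear
#' spring-dampers plus lateral springs on the footplate, the stapedial
#' annular-ligament springs, and grounded ligament/tendon bars).
#'
#' Coordinate convention: the annulus ring lies in the `z = 0` plane with
#' the cone apex (umbo) at `z = -tm_cone_depth`; the ossicular chain and
#' the footplate extend further in `-z`, so the footplate normal is the
#' `z` axis ("vertical" direction of the cochlear springs). Coordinates
#' are in mm; assembly converts to SI.
#'
#' @param params An [ear_params()] object.
#' @param springs A [spring_registry()] giving the cochlear, annular and
#'   lateral spring/damper constants placed on the footplate.
#' @return An object of class `ear_mesh` with fields `nodes` (n x 3 matrix,
#'   mm), `shell` / `solid` element tables with region labels, `connectors`,
#'   `tags` (named node/element sets: `tm_lateral_surface`,
#'   `annulus_boundary`, `footplate`, `umbo_region`), `point_attachments`,
#'   and the originating `params`.
#' @examples
#' mesh <- build_ear_mesh(ear_params(mesh_size = 1.0))
#' nrow(mesh$shell)
#' sum(mesh$connectors$kind == "spring_damper")
#' @export
build_ear_mesh <- function(params = ear_params(), springs = spring_registry()) {
  validate_ear_params(params)

  shell <- cone_shell_mesh(params)
  chain <- ossicle_chain_mesh(params, node_offset = nrow(shell$nodes))

  nodes <- rbind(shell$nodes, chain$nodes)
  mesh <- list(
    nodes = nodes,
    shell = shell$elements,
    solid = chain$elements,
    tags = list(),
    point_attachments = list(),
    params = params
  )
  mesh <- merge_coincident_nodes(mesh)

  apex <- apex_node(mesh, params)
  d <- sqrt(rowSums((mesh$nodes -
                       matrix(mesh$nodes[apex, ], nrow(mesh$nodes), 3,
                              byrow = TRUE))^2))
  shell_nodes <- sort(unique(unlist(mesh$shell[, c("n1", "n2", "n3")])))
  umbo <- intersect(which(d <= params$umbo_radius + 1e-9), shell_nodes)
  if (!length(umbo)) umbo <- apex

  ring_r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  boundary <- which(abs(ring_r - params$tm_radius) < 1e-6 &
                      abs(mesh$nodes[, 3]) < 1e-6)
  footplate <- footplate_nodes(mesh)

  mesh$tags <- list(
    tm_lateral_surface = seq_len(nrow(mesh$shell)),
    annulus_boundary = boundary,
    footplate = footplate,
    umbo_region = umbo
  )
  mesh$connectors <- build_connectors(mesh, params, springs)
  mesh$point_attachments <- c(
    list(footplate = footplate),
    split(mesh$connectors$node[mesh$connectors$kind == "bar"],
          mesh$connectors$region[mesh$connectors$kind == "bar"])
  )
  class(mesh) <- "ear_mesh"
  mesh <- check_mesh_validity(mesh)
  mesh
}

# ---- conical membrane on a structured polar grid -------------------------

cone_shell_mesh <- function(params) {
  R <- params$tm_radius
  Ri <- R - params$annulus_width
  h <- params$mesh_size
  nr <- max(3L, round(Ri / h))
  na <- max(12L, ceiling(2 * pi * R / h))
  if (360 / na > params$flaccida_sector_deg) {
    abort("mesh_size too coarse to resolve the flaccida sector")
  }
  radii <- c(seq(0, Ri, length.out = nr + 1L), R) # last band = annulus
  nring <- length(radii) - 1L
  ang <- 2 * pi * (seq_len(na) - 1L) / na

  idx <- function(ring, i) 1L + (ring - 1L) * na + ((i - 1L) %% na) + 1L
  nodes <- matrix(0, 1L + nring * na, 3L)
  for (j in seq_len(nring)) {
    r <- radii[j + 1L]
    nodes[idx(j, seq_len(na)), 1L] <- r * cos(ang)
    nodes[idx(j, seq_len(na)), 2L] <- r * sin(ang)
  }
  r_all <- sqrt(nodes[, 1L]^2 + nodes[, 2L]^2)
  nodes[, 3L] <- -params$tm_cone_depth * (1 - r_all / R)

  tri <- vector("list", nring)
  fan <- cbind(1L, idx(1L, seq_len(na)), idx(1L, seq_len(na) + 1L))
  for (j in seq_len(nring - 1L)) {
    a <- idx(j, seq_len(na)); b <- idx(j, seq_len(na) + 1L)
    cc <- idx(j + 1L, seq_len(na) + 1L); d <- idx(j + 1L, seq_len(na))
    tri[[j]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  conn <- rbind(fan, do.call(rbind, tri))
  colnames(conn) <- c("n1", "n2", "n3")

  cx <- rowMeans(matrix(nodes[conn, 1L], nrow(conn), 3L))
  cy <- rowMeans(matrix(nodes[conn, 2L], nrow(conn), 3L))
  rc <- sqrt(cx^2 + cy^2)
  tc <- (atan2(cy, cx) * 180 / pi) %% 360

  strip_half <- 1.1 * 360 / na
  region <- rep("tympanic_membrane_tensa", nrow(conn))
  thick <- rep(params$tm_thickness_tensa, nrow(conn))

  fla <- ang_dist(tc, 90) <= params$flaccida_sector_deg / 2 &
    rc <= Ri & rc >= 0.6 * Ri    # flaccida is a rim-adjacent patch
  region[fla] <- "tympanic_membrane_flaccida"
  thick[fla] <- params$tm_thickness_flaccida

  man <- ang_dist(tc, 270) <= strip_half &
    rc <= params$manubrium_fraction * Ri
  region[man] <- "manubrium"
  thick[man] <- params$ossicle_dims$manubrium_thickness

  annu <- rc > Ri
  region[annu] <- "tympanic_annular_ligament"
  thick[annu] <- params$annulus_thickness

  # resting tension carried by the taut regions (pars tensa and the
  # manubrium strip riding on it); the flaccida and the annular ring
  # are slack
  tension <- ifelse(region %in% c("tympanic_membrane_tensa", "manubrium"),
                    params$tm_tension, 0)

  list(nodes = nodes,
       elements = tibble(n1 = conn[, 1L], n2 = conn[, 2L], n3 = conn[, 3L],
                         region = region, thickness_mm = thick,
                         tension_n_per_m = tension))
}

ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# ---- ossicular chain as a structured block of 6-tet hexes ----------------

chain_segments <- function(params) {
  seg <- c("malleus_handle", "malleus_neck", "malleus_head",
           "incudomalleolar_joint", "incus_body", "incus_short_process",
           "incus_long_process", "incudostapedial_joint", "stapes")
  len <- unlist(params$ossicle_dims[seg])
  tibble(region = seg, length_mm = unname(len))
}

ossicle_chain_mesh <- function(params, node_offset) {
  a <- sqrt(params$ossicle_dims$cross_section_mm2 %||% params$footplate_area)
  segs <- chain_segments(params)
  # z-breaks: each segment subdivided to keep layers near cubic
  zb <- -params$tm_cone_depth
  layer_region <- character(0)
  for (i in seq_len(nrow(segs))) {
    nzk <- max(1L, round(segs$length_mm[i] / (a / 2)))
    z_new <- zb[length(zb)] - segs$length_mm[i] * seq_len(nzk) / nzk
    zb <- c(zb, z_new)
    layer_region <- c(layer_region, rep(segs$region[i], nzk))
  }
  nz <- length(zb)           # node layers
  xs <- c(-a / 2, 0, a / 2)
  grid <- expand.grid(x = xs, y = xs, KEEP.OUT.ATTRS = FALSE)
  nodes <- do.call(rbind, lapply(zb, function(z) cbind(grid$x, grid$y, z)))

  nid <- function(ix, iy, iz) node_offset + (iz - 1L) * 9L + (iy - 1L) * 3L + ix
  tets <- list()
  regions <- character(0)
  # Freudenthal 6-tet split on the v0->v6 main diagonal: face diagonals
  # agree between neighbouring cells, so shared faces are conforming.
  tet_pat <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                   c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  for (cz in seq_len(nz - 1L)) {
    for (cyy in 1:2) {
      for (cxx in 1:2) {
        v <- c(nid(cxx, cyy, cz), nid(cxx + 1L, cyy, cz),
               nid(cxx + 1L, cyy + 1L, cz), nid(cxx, cyy + 1L, cz),
               nid(cxx, cyy, cz + 1L), nid(cxx + 1L, cyy, cz + 1L),
               nid(cxx + 1L, cyy + 1L, cz + 1L), nid(cxx, cyy + 1L, cz + 1L))
        tets[[length(tets) + 1L]] <- matrix(v[tet_pat], 6L, 4L)
        regions <- c(regions, rep(layer_region[cz], 6L))
      }
    }
  }
  conn <- do.call(rbind, tets)
  colnames(conn) <- c("n1", "n2", "n3", "n4")
  list(nodes = nodes,
       elements = tibble(n1 = conn[, 1L], n2 = conn[, 2L], n3 = conn[, 3L],
                         n4 = conn[, 4L], region = regions))
}

# ---- node merging and validity -------------------------------------------

merge_coincident_nodes <- function(mesh, tol = 1e-7) {
  key <- apply(round(mesh$nodes / tol) * tol, 1L, paste, collapse = "/")
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  keep <- which(first)
  remap <- integer(nrow(mesh$nodes))
  remap[keep] <- seq_along(keep)
  new_id <- remap[keep][new_id]

  mesh$nodes <- mesh$nodes[keep, , drop = FALSE]
  for (col in c("n1", "n2", "n3")) mesh$shell[[col]] <- new_id[mesh$shell[[col]]]
  for (col in c("n1", "n2", "n3", "n4")) {
    mesh$solid[[col]] <- new_id[mesh$solid[[col]]]
  }
  mesh
}

apex_node <- function(mesh, params) {
  target <- c(0, 0, -params$tm_cone_depth)
  which.min(colSums((t(mesh$nodes) - target)^2))
}

footplate_nodes <- function(mesh) {
  zmin <- min(mesh$nodes[, 3L])
  sort(which(abs(mesh$nodes[, 3L] - zmin) < 1e-9))
}

tet_volumes <- function(nodes, solid) {
  p1 <- nodes[solid$n1, , drop = FALSE]; p2 <- nodes[solid$n2, , drop = FALSE]
  p3 <- nodes[solid$n3, , drop = FALSE]; p4 <- nodes[solid$n4, , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; cc <- p4 - p1
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

tri_areas <- function(nodes, shell) {
  p1 <- nodes[shell$n1, , drop = FALSE]; p2 <- nodes[shell$n2, , drop = FALSE]
  p3 <- nodes[shell$n3, , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

check_mesh_validity <- function(mesh) {
  vol <- tet_volumes(mesh$nodes, mesh$solid)
  neg <- which(vol < 0)
  if (length(neg)) {  # reorient rather than fail: orientation is bookkeeping
    tmp <- mesh$solid$n3[neg]
    mesh$solid$n3[neg] <- mesh$solid$n4[neg]
    mesh$solid$n4[neg] <- tmp
    vol <- tet_volumes(mesh$nodes, mesh$solid)
  }
  if (any(vol <= 1e-9)) abort("degenerate (zero-volume) solid element")
  if (any(tri_areas(mesh$nodes, mesh$shell) <= 1e-6)) {
    abort("degenerate (zero-area) shell element")
  }
  if (!length(mesh$tags$umbo_region)) abort("empty umbo region")
  invisible(mesh)
}

# ---- connectors ----------------------------------------------------------

build_connectors <- function(mesh, params, springs) {
  fp <- mesh$tags$footplate
  kc <- per_spring_constants(springs)
  n <- params$n_cochlear_springs
  cochlear <- tibble(
    kind = "spring_damper",
    region = "cochlear_fluid",
    node = fp[((seq_len(n) - 1L) %% length(fp)) + 1L],
    dir_x = 0, dir_y = 0, dir_z = 1,
    k = kc$k_each, c = kc$c_each,
    area_mm2 = NA_real_, length_mm = NA_real_
  )

  # stapedial annular ligament: total k shared over footplate rim nodes
  center <- colMeans(mesh$nodes[fp, , drop = FALSE])
  rim <- fp[sqrt((mesh$nodes[fp, 1] - center[1])^2 +
                   (mesh$nodes[fp, 2] - center[2])^2) > 1e-9]
  if (!length(rim)) rim <- fp
  seal_loss <- springs$seal_loss %||% 0
  annular <- tibble(
    kind = "spring", region = "stapedial_annular_ligament",
    node = rim, dir_x = 0, dir_y = 0, dir_z = 1,
    k = springs$stapedius_annular_k / length(rim), c = 0,
    loss_factor = seal_loss,
    area_mm2 = NA_real_, length_mm = NA_real_
  )

  # lateral footplate constraint springs at rim nodes
  nl <- params$n_lateral_springs
  dirs <- cbind(cos(2 * pi * (seq_len(nl) - 1) / nl),
                sin(2 * pi * (seq_len(nl) - 1) / nl), 0)
  corner <- rim[order(-((mesh$nodes[rim, 1] - center[1])^2 +
                          (mesh$nodes[rim, 2] - center[2])^2))]
  lateral <- tibble(
    kind = "spring", region = "footplate_lateral",
    node = corner[((seq_len(nl) - 1L) %% length(corner)) + 1L],
    dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
    k = springs$lateral_k, c = 0, loss_factor = seal_loss,
    area_mm2 = NA_real_, length_mm = NA_real_
  )

  bars <- ligament_bars(mesh, params)
  out <- bind_rows(cochlear, annular, lateral, bars)
  nrm <- sqrt(out$dir_x^2 + out$dir_y^2 + out$dir_z^2)
  out$dir_x <- out$dir_x / nrm; out$dir_y <- out$dir_y / nrm
  out$dir_z <- out$dir_z / nrm
  out
}

ligament_bars <- function(mesh, params) {
  lig <- params$ligaments
  node <- integer(nrow(lig))
  for (i in seq_len(nrow(lig))) {
    seg_el <- mesh$solid[mesh$solid$region == lig$segment[i], ]
    if (!nrow(seg_el)) abort(paste0("no solid elements for ligament segment ",
                                    lig$segment[i]))
    cand <- unique(unlist(seg_el[, c("n1", "n2", "n3", "n4")]))
    xy <- mesh$nodes[cand, 1:2, drop = FALSE]
    zc <- mesh$nodes[cand, 3]
    # anchor at the outermost node (toward the pull direction) at mid-height
    proj <- xy[, 1] * sign(lig$dir_x[i] + 1e-12) * (abs(lig$dir_x[i]) >=
                                                      abs(lig$dir_y[i])) +
      xy[, 2] * sign(lig$dir_y[i] + 1e-12) * (abs(lig$dir_x[i]) <
                                                abs(lig$dir_y[i]))
    best <- cand[order(-proj, abs(zc - mean(zc)))][1]
    node[i] <- best
  }
  tibble(
    kind = "bar", region = lig$region, node = node,
    dir_x = lig$dir_x, dir_y = lig$dir_y, dir_z = lig$dir_z,
    k = NA_real_, c = 0,                 # k resolved as E*A/L at assembly
    area_mm2 = lig$area_mm2, length_mm = lig$length_mm
  )
}

#' @exportS3Method print ear_mesh
print.ear_mesh <- function(x, ...) {
  cat("<ear_mesh>\n")
  cat(sprintf("  nodes: %d   shell tris: %d   solid tets: %d   connectors: %d\n",
              nrow(x$nodes), nrow(x$shell), nrow(x$solid),
              nrow(x$connectors)))
  cat(sprintf("  regions: %s\n",
              paste(sort(unique(c(x$shell$region, x$solid$region))),
                    collapse = ", ")))
  invisible(x)
}

#' Total mass of each mesh region
#'
#' Density x volume (solids) or density x thickness x area (shells) per
#' region, using the material registry densities. Useful for checking that
#' the surrogate ossicle blocks land at literature-typical masses (the
#' stapes is conventionally about 3 mg).
#'
#' @param mesh An `ear_mesh`.
#' @param registry A [material_registry()].
#' @return A tibble with `region` and `mass_mg`.
#' @export
region_masses <- function(mesh, registry = material_registry()) {
  vol <- tet_volumes(mesh$nodes, mesh$solid) * 1e-9      # mm^3 -> m^3
  area <- tri_areas(mesh$nodes, mesh$shell) * 1e-6       # mm^2 -> m^2
  rho <- function(region) map_dbl(region, function(r) {
    material_lookup(registry, r)$density
  })
  solid <- tibble(region = mesh$solid$region,
                  mass = rho(mesh$solid$region) * vol)
  shell <- tibble(region = mesh$shell$region,
                  mass = rho(mesh$shell$region) * area *
                    mesh$shell$thickness_mm * 1e-3)
  bind_rows(solid, shell) |>
    group_by(.data$region) |>
    summarise(mass_mg = 1e6 * sum(.data$mass), .groups = "drop")
}
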