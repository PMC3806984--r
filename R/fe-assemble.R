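#' Assemble the damped harmonic structural system for an ear mesh
#'
#' Builds the reduced (free-dof) operators of the damped harmonic problem
#' `[K (1 + i eta) + i w C - w^2 M] u = f`: real symmetric stiffness `K`,
#' its hysteretic companion `Kloss = sum(eta_region * K_element)` (the
#' structural loss factors enter the complex stiffness element-wise by
#' region, not as proportional damping), consistent/lumped mass `M`, and
#' viscous damping `C` from the connector dampers. Shell nodes carry 6
#' degrees of freedom (3 translations + 3 rotations), solid-only nodes 3;
#' the annulus boundary ring is clamped by row/column elimination.
#'
#' @param mesh An [build_ear_mesh()] result.
#' @param registry A [material_registry()] covering every mesh region.
#' @param drill_scale Relative stiffness of the shell drilling-rotation
#'   stabilization.
#' @return An object of class `fe_system` with sparse `K`, `Kloss`, `M`,
#'   `C` on the free dofs, plus the dof map needed to place loads and read
#'   responses.
#' @export
assemble_ear <- function(mesh, registry = material_registry(),
                         drill_scale = 1e-6) {
  stopifnot(inherits(mesh, "ear_mesh"))
  dm <- dof_map(mesh)
  acc <- triplet_accumulator()

  nodes_m <- mesh$nodes * 1e-3                      # mm -> m

  # solids
  for (e in seq_len(nrow(mesh$solid))) {
    el <- mesh$solid[e, ]
    mat <- material_lookup(registry, el$region)
    nd <- c(el$n1, el$n2, el$n3, el$n4)
    em <- tet_element(nodes_m[nd, , drop = FALSE], mat$youngs_modulus,
                      mat$poisson, mat$density)
    gd <- as.vector(vapply(nd, function(n) dm$offset[n] + 1:3, integer(3)))
    acc$add("K", gd, em$K)
    acc$add("Kloss", gd, em$K * mat$loss_factor)
    acc$add("M", gd, em$M)
  }

  # shells
  for (e in seq_len(nrow(mesh$shell))) {
    el <- mesh$shell[e, ]
    mat <- material_lookup(registry, el$region)
    nd <- c(el$n1, el$n2, el$n3)
    tension <- if ("tension_n_per_m" %in% names(mesh$shell)) {
      el$tension_n_per_m
    } else {
      0
    }
    em <- shell_element(nodes_m[nd, , drop = FALSE], mat$youngs_modulus,
                        mat$poisson, el$thickness_mm * 1e-3, mat$density,
                        drill_scale, tension = tension)
    gd <- as.vector(vapply(nd, function(n) dm$offset[n] + 1:6, integer(6)))
    acc$add("K", gd, em$K)
    acc$add("Kloss", gd, em$K * mat$loss_factor)
    acc$add("M", gd, em$M)
  }

  # connectors (grounded)
  con <- resolve_connector_constants(mesh$connectors, registry)
  for (i in seq_len(nrow(con))) {
    dvec <- c(con$dir_x[i], con$dir_y[i], con$dir_z[i])
    gd <- dm$offset[con$node[i]] + 1:3
    if (con$k[i] > 0) {
      blk <- connector_block(con$k[i], dvec)
      acc$add("K", gd, blk)
      if (con$loss_factor[i] > 0) acc$add("Kloss", gd, blk * con$loss_factor[i])
    }
    if (con$c[i] > 0) acc$add("C", gd, connector_block(con$c[i], dvec))
  }

  mats <- acc$build(dm$ndof)
  fixed <- unlist(lapply(mesh$tags$annulus_boundary,
                         function(n) dm$offset[n] + seq_len(dm$ndof_node[n])))
  free <- setdiff(seq_len(dm$ndof), fixed)

  structure(list(
    K = mats$K[free, free], Kloss = mats$Kloss[free, free],
    M = mats$M[free, free], C = mats$C[free, free],
    n_free = length(free), free = free, ndof = dm$ndof,
    dof_offset = dm$offset, ndof_node = dm$ndof_node,
    connectors = con, mesh = mesh
  ), class = "fe_system")
}

# Fill bar stiffnesses from the registry (k = E * A / L) and attach the
# structural loss factor of the connector's soft-tissue region.
resolve_connector_constants <- function(con, registry) {
  if (!"loss_factor" %in% names(con)) con$loss_factor <- 0
  con$loss_factor[is.na(con$loss_factor)] <- 0
  bars <- which(con$kind == "bar")
  for (i in bars) {
    mat <- material_lookup(registry, con$region[i])
    con$k[i] <- mat$youngs_modulus * (con$area_mm2[i] * 1e-6) /
      (con$length_mm[i] * 1e-3)
    con$loss_factor[i] <- mat$loss_factor
  }
  con$k[is.na(con$k)] <- 0
  con
}

dof_map <- function(mesh) {
  n <- nrow(mesh$nodes)
  shell_nodes <- unique(unlist(mesh$shell[, c("n1", "n2", "n3")]))
  ndof_node <- rep(3L, n)
  ndof_node[shell_nodes] <- 6L
  offset <- c(0L, cumsum(ndof_node))[seq_len(n)]
  list(offset = offset, ndof_node = ndof_node, ndof = sum(ndof_node))
}

triplet_accumulator <- function() {
  store <- list(K = list(), Kloss = list(), M = list(), C = list())
  add <- function(which, gdofs, block) {
    nb <- length(gdofs)
    store[[which]][[length(store[[which]]) + 1L]] <<- list(
      i = rep(gdofs, times = nb), j = rep(gdofs, each = nb),
      x = as.vector(block))
  }
  build <- function(ndof) {
    out <- lapply(store, function(parts) {
      if (!length(parts)) {
        return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(ndof, ndof)))
      }
      i <- unlist(lapply(parts, `[[`, "i"), use.names = FALSE)
      j <- unlist(lapply(parts, `[[`, "j"), use.names = FALSE)
      x <- unlist(lapply(parts, `[[`, "x"), use.names = FALSE)
      keep <- x != 0
      Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                           dims = c(ndof, ndof))
    })
    out
  }
  list(add = add, build = build)
}

#' Wrap raw matrices as an `fe_system`
#'
#' Convenience constructor for small hand-built systems (single-dof
#' oscillators, chains, plates assembled elsewhere); all dofs are free.
#'
#' @param K,M Stiffness and mass matrices (dense or sparse).
#' @param C Viscous damping matrix (default zero).
#' @param Kloss Hysteretic stiffness `sum(eta * K_e)` (default zero; pass
#'   `eta * K` for a uniform loss factor).
#' @return An `fe_system`.
#' @export
fe_system_raw <- function(K, M, C = NULL, Kloss = NULL) {
  K <- Matrix::Matrix(K, sparse = TRUE)
  n <- nrow(K)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                               x = numeric(0), dims = c(n, n))
  structure(list(
    K = K, Kloss = if (is.null(Kloss)) zero else Matrix::Matrix(Kloss, sparse = TRUE),
    M = Matrix::Matrix(M, sparse = TRUE),
    C = if (is.null(C)) zero else Matrix::Matrix(C, sparse = TRUE),
    n_free = n, free = seq_len(n), ndof = n,
    dof_offset = NULL, ndof_node = NULL, connectors = NULL, mesh = NULL
  ), class = "fe_system")
}

#' @exportS3Method print fe_system
print.fe_system <- function(x, ...) {
  cat("<fe_system>\n")
  cat(sprintf("  free dofs: %d (of %d)   nnz(K): %d\n",
              x$n_free, x$ndof, Matrix::nnzero(x$K)))
  invisible(x)
}

# Map a (node, component) pair to its index in the reduced system, or NA
# if constrained. Components 1:3 translations, 4:6 rotations.
free_dof_index <- function(system, node, comp) {
  full <- system$dof_offset[node] + comp
  idx <- match(full, system$free)
  idx
}

#' Export assembled operators in MatrixMarket format
#'
#' Dumps `K`, `Kloss`, `M`, `C` as `.mtx` files for external inspection.
#'
#' @param system An `fe_system`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
export_system_mtx <- function(system, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("K", "Kloss", "M", "C")) {
    p <- file.path(dir, paste0(nm, ".mtx"))
    Matrix::writeMM(as(system[[nm]], "generalMatrix"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
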