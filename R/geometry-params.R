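#' Default parametric geometry for the idealized middle ear
#'
#' Returns the full parameter set describing the idealized middle-ear
#' geometry: a conical tympanic membrane (pars tensa / pars flaccida
#' sectors plus a peripheral annular-ligament ring) meshed with flat
#' triangular shell facets, an embedded manubrium strip, an ossicular
#' chain (malleus, incudomalleolar joint, incus, incudostapedial joint,
#' stapes) built from solid tetrahedra, and the spring-damper cochlear
#' boundary on the stapes footplate.
#'
#' None of these dimensions is reported by middle-ear response studies
#' that work from subject-specific imaging; every default here is a
#' literature-typical, explicitly non-anatomical surrogate value stored in
#' configuration. The only counts fixed by the modelling convention are
#' the 42 vertical cochlear spring-dampers on the footplate and the
#' lateral footplate springs.
#'
#' @param ... Named overrides for any field of the parameter set (see
#'   Details). Unknown names are an error.
#'
#' @details Fields (lengths in mm unless noted):
#' \describe{
#'   \item{tm_radius}{Tympanic-membrane radius (annulus outer edge).}
#'   \item{tm_cone_depth}{Depth of the membrane cone; the umbo apex sits
#'     at `z = -tm_cone_depth` with the annulus ring in the `z = 0` plane.}
#'   \item{tm_thickness_tensa, tm_thickness_flaccida}{Shell thicknesses of
#'     the pars tensa and pars flaccida.}
#'   \item{flaccida_sector_deg}{Angular extent of the pars flaccida sector
#'     (degrees, centred superiorly).}
#'   \item{annulus_width}{Radial width of the tympanic annular ligament
#'     ring at the membrane rim.}
#'   \item{manubrium_fraction}{Radial extent (0-1) of the manubrium shell
#'     strip, from the apex outwards.}
#'   \item{ossicle_dims}{Named list of chain-segment lengths (mm) plus the
#'     manubrium strip thickness; segment cross-section equals
#'     `footplate_area`. Lengths are calibrated so density x volume gives
#'     literature-typical ossicle masses (stapes about 3 mg).}
#'   \item{footplate_area}{Stapes footplate area (mm^2); also the chain
#'     cross-section.}
#'   \item{n_cochlear_springs}{Count of vertical cochlear spring-damper
#'     connectors on the footplate (42 by convention).}
#'   \item{n_lateral_springs}{Count of lateral grounded footplate springs.}
#'   \item{umbo_radius}{Radius (mm) around the cone apex defining the
#'     umbo region over which responses are averaged.}
#'   \item{mesh_size}{Target element edge length (mm).}
#'   \item{ligaments}{Data frame of grounded bar connectors (anterior
#'     malleal ligament, posterior incudal ligament, tensor tympani,
#'     stapedius muscle): attachment segment, cross-section area (mm^2),
#'     length (mm) and direction. Axial stiffness is `E * A / L` with `E`
#'     from the material registry, so material presets act on them.}
#' }
#'
#' @return An object of class `ear_geometry_params` (a named list).
#' @examples
#' p <- ear_params()
#' p$n_cochlear_springs
#' ear_params(mesh_size = 0.8)$mesh_size
#' @export
ear_params <- function(...) {
  defaults <- list(
    tm_radius = 4.5,
    tm_cone_depth = 1.5,
    tm_thickness_tensa = 0.074,
    tm_thickness_flaccida = 0.1,
    flaccida_sector_deg = 60,
    annulus_width = 0.1,
    annulus_thickness = 1.2,
    tm_tension = 150,
    manubrium_fraction = 0.95,
    ossicle_dims = list(
      malleus_handle = 0.3,
      malleus_neck = 0.2,
      malleus_head = 0.85,
      incudomalleolar_joint = 0.15,
      incus_body = 1.0,
      incus_short_process = 0.5,
      incus_long_process = 0.2,
      incudostapedial_joint = 0.1,
      stapes = 0.215,
      cross_section_mm2 = 6.4,
      manubrium_thickness = 0.35
    ),
    footplate_area = 3.2,
    n_cochlear_springs = 42L,
    n_lateral_springs = 4L,
    umbo_radius = 0.3,
    mesh_size = 0.6,
    ligaments = default_ligaments()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown geometry parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  p <- modifyList(defaults, over)
  p$n_cochlear_springs <- as.integer(p$n_cochlear_springs)
  p$n_lateral_springs <- as.integer(p$n_lateral_springs)
  class(p) <- "ear_geometry_params"
  validate_ear_params(p)
  p
}

# Grounded bar connectors standing in for the suspensory soft tissues.
# Directions are oblique unit vectors (normalized at build time); the
# z-components give the ligaments an axial (piston-direction) stiffness
# share, standing in for the rotation-axis suspension of the real chain.
default_ligaments <- function() {
  tibble(
    region = c("anterior_malleal_ligament", "posterior_incudal_ligament",
               "tensor_tympani_muscle", "stapedius_muscle"),
    segment = c("malleus_head", "incus_short_process",
                "malleus_neck", "stapes"),
    area_mm2 = c(3.2, 0.40, 0.30, 0.20),
    length_mm = c(2.0, 1.5, 2.0, 1.5),
    dir_x = c(0.70711, 0, 0.70711, 0),
    dir_y = c(0, 0.70711, 0, 0.70711),
    dir_z = c(0.70711, 0.70711, 0.70711, 0.70711)
  )
}

validate_ear_params <- function(p) {
  stopifnot(inherits(p, "ear_geometry_params"))
  len_fields <- c("tm_radius", "tm_cone_depth", "tm_thickness_tensa",
                  "tm_thickness_flaccida", "annulus_width",
                  "annulus_thickness", "umbo_radius",
                  "mesh_size", "footplate_area")
  for (f in len_fields) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      abort(paste0("geometry parameter '", f, "' must be a positive scalar"))
    }
  }
  if (p$flaccida_sector_deg <= 0 || p$flaccida_sector_deg >= 90) {
    abort("flaccida_sector_deg must lie in (0, 90)")
  }
  if (p$manubrium_fraction <= 0 || p$manubrium_fraction > 1) {
    abort("manubrium_fraction must lie in (0, 1]")
  }
  if (p$n_cochlear_springs < 1L) abort("n_cochlear_springs must be >= 1")
  if (p$umbo_radius >= p$tm_radius) abort("umbo_radius must be < tm_radius")
  if (p$mesh_size >= p$tm_radius / 4) {
    abort("mesh_size must be < tm_radius / 4 to resolve the membrane")
  }
  if (p$annulus_width >= p$tm_radius / 2) {
    abort("annulus_width too large for tm_radius")
  }
  if (any(unlist(p$ossicle_dims) <= 0)) {
    abort("all ossicle_dims must be positive")
  }
  if (p$tm_tension < 0) abort("tm_tension must be >= 0")
  invisible(p)
}

#' @exportS3Method print ear_geometry_params
print.ear_geometry_params <- function(x, ...) {
  cat("<ear_geometry_params>\n")
  cat(sprintf("  membrane: radius %.3g mm, cone depth %.3g mm, tensa %.3g mm\n",
              x$tm_radius, x$tm_cone_depth, x$tm_thickness_tensa))
  cat(sprintf("  cochlear springs: %d (+%d lateral), mesh size %.3g mm\n",
              x$n_cochlear_springs, x$n_lateral_springs, x$mesh_size))
  invisible(x)
}

#' Read / write geometry configuration files
#'
#' Geometry parameters are stored under a `geometry` section whose keys are
#' exactly the [ear_params()] field names; YAML and JSON are supported
#' (chosen by file extension).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_ear_config()` returns an `ear_geometry_params`;
#'   `write_ear_config()` invisibly returns `path`.
#' @export
read_ear_config <- function(path) {
  cfg <- read_config_file(path)
  geo <- cfg$geometry %||% abort("config file has no 'geometry' section")
  if (!is.null(geo$ligaments)) {
    geo$ligaments <- as_tibble(as.data.frame(
      lapply(geo$ligaments, unlist),
      stringsAsFactors = FALSE))
  }
  do.call(ear_params, geo)
}

#' @rdname read_ear_config
#' @param params An `ear_geometry_params` object.
#' @export
write_ear_config <- function(params, path) {
  validate_ear_params(params)
  x <- unclass(params)
  x$ligaments <- as.list(as.data.frame(x$ligaments))
  obj <- list(geometry = x)
  write_config_file(obj, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config_file <- function(obj, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
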