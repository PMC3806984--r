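#' Material property registry for the middle-ear model
#'
#' The standard isotropic property set used in human middle-ear
#' finite-element work: Young's modulus, density and Poisson's ratio per
#' structural region, plus a structural loss factor (hysteretic damping
#' coefficient eta multiplying the stiffness as `1 + i*eta`). Moduli and
#' densities are the published consensus values for this model family;
#' the loss factors are not published and default to 0.05 for mineralized
#' regions (ossicles, manubrium) and 0.15 for membrane, joints and other
#' soft tissue — both exposed for override.
#'
#' @param loss_bone,loss_soft,loss_annulus Default structural loss factors
#'   for mineralized regions, soft tissue, and the tympanic annular
#'   ligament ring. Loss factors are not published for this property set;
#'   the defaults are calibrated so the assembled model reproduces the
#'   strongly damped, flat-then-resonant umbo response characteristic of
#'   the intact middle ear, and are fully config-exposed.
#' @return A tibble of class `material_registry` with columns `region`,
#'   `youngs_modulus` (N/m^2), `density` (kg/m^3), `poisson`,
#'   `loss_factor`.
#' @examples
#' reg <- material_registry()
#' material_lookup(reg, "stapes")$density
#' @export
material_registry <- function(loss_bone = 0.05, loss_soft = 0.7,
                              loss_annulus = 1.2) {
  rows <- tibble(
    region = c(
      "tympanic_membrane_tensa", "tympanic_membrane_flaccida",
      "malleus_head", "malleus_neck", "malleus_handle",
      "incus_body", "incus_short_process", "incus_long_process",
      "stapes", "incudomalleolar_joint", "incudostapedial_joint",
      "anterior_malleal_ligament", "posterior_incudal_ligament",
      "tensor_tympani_muscle", "manubrium", "stapedius_muscle",
      "tympanic_annular_ligament"
    ),
    youngs_modulus = c(
      3.34e7, 1.11e7,
      1.2e10, 1.2e10, 1.2e10,
      1.2e10, 1.2e10, 1.2e10,
      1.2e10, 1.2e10, 6.0e5,
      2.1e7, 6.5e5,
      2.6e5, 4.7e9, 5.2e5,
      6.0e5
    ),
    density = c(
      1.2e3, 1.2e3,
      2.55e3, 4.53e3, 3.70e3,
      2.36e3, 2.26e3, 5.08e3,
      2.2e3, 3.2e3, 1.2e3,
      2.5e3, 2.5e3,
      2.5e3, 1.0e3, 2.5e3,
      2.5e3
    ),
    poisson = 0.3
  )
  soft <- c("tympanic_membrane_tensa", "tympanic_membrane_flaccida",
            "incudostapedial_joint", "anterior_malleal_ligament",
            "posterior_incudal_ligament", "tensor_tympani_muscle",
            "stapedius_muscle", "tympanic_annular_ligament",
            "incudomalleolar_joint")
  rows$loss_factor <- ifelse(rows$region %in% soft, loss_soft, loss_bone)
  rows$loss_factor[rows$region == "tympanic_annular_ligament"] <- loss_annulus
  structure(rows, class = c("material_registry", class(rows)))
}

#' Spring and damper constants of the discrete boundary elements
#'
#' The cochlear-fluid load on the stapes footplate is a bank of
#' `cochlear_n` vertical elastic springs and viscous dampers whose
#' stiffnesses and damping sum to `cochlear_total_k` and
#' `cochlear_total_c`; the stapedial annular ligament is a further total
#' stiffness around the footplate rim, and the lateral footplate motion
#' is constrained by linear springs of stiffness `lateral_k` each
#' (defaulting to the per-spring vertical stiffness).
#'
#' @param cochlear_total_k Total cochlear spring stiffness, N/m.
#' @param cochlear_n Number of cochlear spring-dampers.
#' @param cochlear_total_c Total cochlear viscous damping, N s/m.
#' @param stapedius_annular_k Stapedial annular-ligament stiffness, N/m.
#' @param lateral_k Per-spring lateral footplate stiffness, N/m. The
#'   default reflects the in-plane (transverse-to-piston) stiffness of the
#'   oval-window annular seal, order 1e3 N/m in total: unlike the vertical
#'   cochlear-fluid load it is not a published constant.
#' @param seal_loss Structural loss factor of the annular-seal springs
#'   (stapedial annular ligament and lateral footplate constraints): the
#'   oval-window seal is hysteretic soft tissue. The vertical cochlear
#'   bank keeps its viscous damper and no structural loss.
#' @param per_spring If `TRUE`, interpret `cochlear_total_k` and
#'   `cochlear_total_c` as per-spring values instead of totals.
#' @return An object of class `spring_registry`.
#' @export
spring_registry <- function(cochlear_total_k = 70,
                            cochlear_n = 42L,
                            cochlear_total_c = 0.054,
                            stapedius_annular_k = 9,
                            lateral_k = 5000,
                            seal_loss = 0.7,
                            per_spring = FALSE) {
  if (cochlear_n < 1L) abort("cochlear_n must be >= 1")
  if (per_spring) {
    cochlear_total_k <- cochlear_total_k * cochlear_n
    cochlear_total_c <- cochlear_total_c * cochlear_n
  }
  out <- list(cochlear_total_k = cochlear_total_k,
              cochlear_n = as.integer(cochlear_n),
              cochlear_total_c = cochlear_total_c,
              stapedius_annular_k = stapedius_annular_k,
              lateral_k = lateral_k,
              seal_loss = seal_loss)
  if (any(unlist(out) < 0)) abort("spring constants must be >= 0")
  structure(out, class = "spring_registry")
}

#' Per-spring constants of the cochlear spring-damper bank
#'
#' Divides the total cochlear stiffness and damping evenly over the
#' spring count, so the bank reproduces the totals exactly.
#'
#' @param springs A [spring_registry()].
#' @return A list with `k_each` (N/m) and `c_each` (N s/m).
#' @examples
#' per_spring_constants(spring_registry())$k_each  # 70/42
#' @export
per_spring_constants <- function(springs) {
  if (springs$cochlear_n < 1L) abort("cochlear_n must be >= 1")
  list(k_each = springs$cochlear_total_k / springs$cochlear_n,
       c_each = springs$cochlear_total_c / springs$cochlear_n)
}

#' Look up one region's material record
#'
#' @param registry A [material_registry()].
#' @param region Region label.
#' @return A one-row tibble.
#' @export
material_lookup <- function(registry, region) {
  row <- registry[registry$region == region, ]
  if (!nrow(row)) abort(paste0("unknown material region: ", region))
  row
}

#' Override material properties, including the published presets
#'
#' `apply_overrides()` returns a registry differing from its input only at
#' the overridden entries. `material_preset()` returns the registry under
#' one of two shipped presets reflecting a table-versus-text conflict in
#' the source property set: `"table"` keeps the tabulated values
#' (incudostapedial joint E = 6.0e5 N/m^2, anterior malleal ligament
#' E = 2.1e7 N/m^2), while `"text_update"` applies the cadaver-derived
#' stiffness updates at stretch ratio 1.1 (incudostapedial joint
#' 0.43 MPa, anterior malleal ligament 0.46 MPa).
#'
#' @param registry A [material_registry()].
#' @param overrides Named list: `region = list(field = value, ...)`.
#' @return A `material_registry`.
#' @examples
#' r <- material_preset("text_update")
#' material_lookup(r, "incudostapedial_joint")$youngs_modulus  # 4.3e5
#' @export
apply_overrides <- function(registry, overrides = list()) {
  if (!length(overrides)) return(registry)
  bad <- setdiff(names(overrides), registry$region)
  if (length(bad)) {
    abort(paste0("unknown override region(s): ", paste(bad, collapse = ", ")))
  }
  for (region in names(overrides)) {
    fields <- overrides[[region]]
    badf <- setdiff(names(fields),
                    c("youngs_modulus", "density", "poisson", "loss_factor"))
    if (length(badf)) {
      abort(paste0("unknown material field(s): ", paste(badf, collapse = ", ")))
    }
    i <- which(registry$region == region)
    for (f in names(fields)) registry[[f]][i] <- fields[[f]]
  }
  registry
}

#' @rdname apply_overrides
#' @param preset `"table"` or `"text_update"`.
#' @export
material_preset <- function(preset = c("table", "text_update"),
                            registry = material_registry()) {
  preset <- match.arg(preset)
  if (preset == "table") return(registry)
  apply_overrides(registry, list(
    incudostapedial_joint = list(youngs_modulus = 0.43e6),
    anterior_malleal_ligament = list(youngs_modulus = 0.46e6)
  ))
}

#' Serialize / load a material registry
#'
#' Stored under `materials.<region>` sections (YAML or JSON by file
#' extension), with `springs` as its own section.
#'
#' @param registry A [material_registry()].
#' @param springs A [spring_registry()].
#' @param path Output path.
#' @export
write_material_config <- function(registry, path,
                                  springs = spring_registry()) {
  mats <- lapply(seq_len(nrow(registry)), function(i) {
    as.list(registry[i, c("youngs_modulus", "density", "poisson",
                          "loss_factor")])
  })
  names(mats) <- registry$region
  write_config_file(list(materials = mats, springs = unclass(springs)), path)
  invisible(path)
}

#' @rdname write_material_config
#' @export
read_material_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$materials)) abort("config has no 'materials' section")
  reg <- material_registry()
  reg <- reg[reg$region %in% names(cfg$materials), ]
  overrides <- lapply(cfg$materials, function(m) m)
  reg <- apply_overrides(reg, overrides)
  springs <- if (!is.null(cfg$springs)) {
    do.call(spring_registry, cfg$springs)
  } else {
    spring_registry()
  }
  list(materials = reg, springs = springs)
}
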