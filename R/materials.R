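#' Convert Hounsfield units to apparent density
#'
#' Linear calibration of CT attenuation to apparent (wet) bone density,
#' evaluated in kg/m^3 as published and returned in g/cm^3, the unit all
#' downstream power laws expect. Values are clamped below at 0.001 g/cm^3:
#' fatty marrow voxels (HU below about -42) would otherwise map to
#' non-physical non-positive densities that the stiffness and strength
#' power laws cannot accept.
#'
#' @param hu numeric vector of Hounsfield units.
#' @return apparent density in g/cm^3, same length as `hu`.
#' @examples
#' hu_to_apparent_density(c(0, 1000))
#' @export
hu_to_apparent_density <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("`hu` must be finite numeric")
  rho_kgm3 <- 47 + 1.122 * hu
  pmax(rho_kgm3 / 1000, 0.001)
}

#' Convert apparent density to ash density
#'
#' @param rho_app apparent density, g/cm^3 (non-negative).
#' @return ash density, g/cm^3 (0.6 times the apparent density).
#' @export
apparent_to_ash <- function(rho_app) {
  if (!is.numeric(rho_app) || any(!is.finite(rho_app)) || any(rho_app < 0))
    stop("`rho_app` must be finite and non-negative")
  0.6 * rho_app
}

## Fixed anisotropy ratios of the vertebral constitutive model.
## z is the superior-inferior (axial) direction.
.elastic_ratios <- list(
  Ex_over_Ez = 0.333, G_xy_over_Ez = 0.121, G_xz_over_Ez = 0.157,
  nu_xy = 0.381, nu_xz = 0.104
)

#' Transversely isotropic elastic constants from apparent density
#'
#' Axial modulus follows the density power law E_z = 4730 * rho_app^1.56
#' (rho_app in g/cm^3, E in MPa); transverse and shear moduli and the
#' Poisson ratios are fixed multiples of E_z:
#' E_x = E_y = 0.333 E_z, G_xy = 0.121 E_z, G_xz = G_yz = 0.157 E_z,
#' nu_xy = 0.381, nu_xz = nu_yz = 0.104.
#'
#' @param rho_app apparent density, g/cm^3, strictly positive.
#' @return data.frame with columns E_z, E_x, E_y, G_xy, G_xz, G_yz,
#'   nu_xy, nu_xz, nu_yz (moduli in MPa).
#' @export
elastic_card <- function(rho_app) {
  if (!is.numeric(rho_app) || any(!is.finite(rho_app)) || any(rho_app <= 0))
    stop("`rho_app` must be finite and strictly positive")
  E_z <- 4730 * rho_app^1.56
  r <- .elastic_ratios
  data.frame(
    E_z = E_z, E_x = r$Ex_over_Ez * E_z, E_y = r$Ex_over_Ez * E_z,
    G_xy = r$G_xy_over_Ez * E_z, G_xz = r$G_xz_over_Ez * E_z,
    G_yz = r$G_xz_over_Ez * E_z,
    nu_xy = r$nu_xy, nu_xz = r$nu_xz, nu_yz = r$nu_xz
  )
}

#' Strength and failure-strain constants from ash density
#'
#' Maximum principal stress limit uses a two-branch power law with the
#' branch point at 0.317 g/cm^3 (the lower branch is used at exactly
#' 0.317, where the two branches agree to within 0.05 MPa):
#' sigma_max = 137 rho_ash^1.88 below, 114 rho_ash^1.72 above.
#' Minimum principal stress limit sigma_min = 65.1 rho_ash^1.93.
#' The post-yield strain limit eps_AB = -0.00315 + 0.0728 rho_ash is
#' clamped at zero (the affine form goes negative below
#' rho_ash ~ 0.0433 g/cm^3, meaningless as a strain limit).
#'
#' @param rho_ash ash density, g/cm^3, non-negative.
#' @return data.frame with columns sigma_max, sigma_min (MPa) and
#'   eps_AB (dimensionless).
#' @export
strength_card <- function(rho_ash) {
  if (!is.numeric(rho_ash) || any(!is.finite(rho_ash)) || any(rho_ash < 0))
    stop("`rho_ash` must be finite and non-negative")
  sigma_max <- ifelse(rho_ash <= 0.317,
                      137 * rho_ash^1.88,
                      114 * rho_ash^1.72)
  data.frame(
    sigma_max = sigma_max,
    sigma_min = 65.1 * rho_ash^1.93,
    eps_AB = pmax(-0.00315 + 0.0728 * rho_ash, 0)
  )
}

#' Full material card from Hounsfield units
#'
#' Composes the HU-to-density calibration, the density-to-stiffness
#' power law and the strength relations into one per-element record.
#'
#' @param hu numeric vector of Hounsfield units (one per element).
#' @return data.frame of class `material_cards` with densities, the
#'   transversely isotropic elastic constants, strength limits and the
#'   post-yield strain limit, one row per input value.
#' @export
material_card <- function(hu) {
  rho_app <- hu_to_apparent_density(hu)
  rho_ash <- apparent_to_ash(rho_app)
  out <- cbind(
    data.frame(hu = hu, rho_app = rho_app, rho_ash = rho_ash),
    elastic_card(rho_app),
    strength_card(rho_ash)
  )
  class(out) <- c("material_cards", "data.frame")
  out
}

#' Map CT attenuation onto mesh elements
#'
#' Each element's HU is the arithmetic mean of the HU of voxels whose
#' centers fall inside the element; an element containing no voxel
#' center falls back to the HU of the voxel nearest its centroid. For
#' meshes built by [mask_to_mesh()] the voxel-center-to-tetrahedron
#' assignment is exact (it uses the Kuhn cell subdivision directly).
#'
#' @param ct a `ct_volume` (see [make_vertebra_phantom()]).
#' @param mesh a `tet_mesh` from [mask_to_mesh()].
#' @return a `material_cards` data.frame with one row per element.
#' @export
map_elements <- function(ct, mesh) {
  stopifnot(inherits(ct, "ct_volume"), inherits(mesh, "tet_mesh"))
  hu <- element_hu(ct, mesh)
  material_card(hu)
}

## Mean HU over voxel centers per element, with centroid fallback.
element_hu <- function(ct, mesh) {
  sp <- ct$spacing
  dims <- dim(ct$data)
  nel <- nrow(mesh$elements)
  centroid_hu <- function(els) {
    cx <- (mesh$nodes[mesh$elements[els, 1], , drop = FALSE] +
           mesh$nodes[mesh$elements[els, 2], , drop = FALSE] +
           mesh$nodes[mesh$elements[els, 3], , drop = FALSE] +
           mesh$nodes[mesh$elements[els, 4], , drop = FALSE]) / 4
    ii <- pmin(pmax(ceiling(cx[, 1] / sp[1]), 1L), dims[1])
    jj <- pmin(pmax(ceiling(cx[, 2] / sp[2]), 1L), dims[2])
    kk <- pmin(pmax(ceiling(cx[, 3] / sp[3]), 1L), dims[3])
    ct$data[cbind(ii, jj, kk)]
  }
  if (!is.null(mesh$voxel_assignment)) {
    va <- mesh$voxel_assignment  # element index per voxel center, 0 = none
    keep <- va > 0L
    sums <- rowsum(ct$data[keep], va[keep])
    cnts <- tabulate(va[keep], nbins = nel)
    hu <- rep(NA_real_, nel)
    hu[as.integer(rownames(sums))] <- sums[, 1] /
      cnts[as.integer(rownames(sums))]
    miss <- which(!is.finite(hu))
    if (length(miss)) hu[miss] <- centroid_hu(miss)
  } else {
    hu <- centroid_hu(seq_len(nel))
  }
  if (any(!is.finite(hu)))
    stop("element(s) outside the CT volume: ",
         paste(which(!is.finite(hu))[1:3], collapse = ", "))
  hu
}

#' Export material cards as CSV
#'
#' @param cards a `material_cards` data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_material_csv <- function(cards, path) {
  utils::write.csv(as.data.frame(cards), path, row.names = FALSE)
  invisible(path)
}

#' Export mesh materials as an Abaqus INP material block
#'
#' Elements are binned by axial modulus into `n_bins` discrete
#' materials (the usual discrete-material workflow of CT-based FE
#' pipelines), each written as an *ELSET plus an isotropic-equivalent
#' *MATERIAL/*ELASTIC block using the bin-mean axial modulus and the
#' in-plane Poisson ratio, for cross-checking against external solvers.
#'
#' @param cards a `material_cards` data.frame.
#' @param path output file path.
#' @param n_bins number of material bins (default 100).
#' @return the path, invisibly.
#' @export
write_material_inp <- function(cards, path, n_bins = 100) {
  E <- cards$E_z
  brk <- seq(min(E), max(E), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9; brk[n_bins + 1] <- brk[n_bins + 1] + 1e-9
  bin <- cut(E, brk, labels = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  for (b in sort(unique(bin))) {
    els <- which(bin == b)
    writeLines(sprintf("*ELSET, ELSET=MAT%03d", b), con)
    writeLines(paste(strwrap(paste(els, collapse = ", "), 72),
                     collapse = "\n"), con)
    writeLines(c(sprintf("*MATERIAL, NAME=MAT%03d", b), "*ELASTIC",
                 sprintf("%.6g, %.4g", mean(E[els]), cards$nu_xy[1])), con)
  }
  invisible(path)
}
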