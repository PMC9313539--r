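#' Phantom ground-truth description
#'
#' Parameters of a synthetic vertebral-body phantom: an elliptic
#' cylinder with a dense cortical shell (including endplates) and a
#' stochastic trabecular interior, surrounded by air. The default HU
#' profiles place the osteoporotic interior at Normal(80, 30) HU and
#' the diffusely sclerotic (osteoblastic) interior at Normal(600, 150)
#' HU with a 1200 HU shell -- values chosen to straddle typical
#' trabecular and sclerotic attenuation ranges; they are configurable,
#' not measured quantities.
#'
#' @param condition `"osteoporotic"` or `"osteoblastic"`.
#' @param trabecular_hu_mean,trabecular_hu_sd interior HU distribution.
#' @param shell_hu cortical shell HU (must exceed the interior mean).
#' @param semi_axis_x,semi_axis_y outer semi-axes of the elliptic
#'   cross-section, mm.
#' @param height_mm body height along the superior-inferior (z) axis, mm.
#' @param shell_mm shell thickness, mm.
#' @param spacing_mm isotropic voxel size, mm.
#' @param margin_mm air margin around the body, mm.
#' @param psf_fwhm_mm full width at half maximum of the isotropic
#'   Gaussian scanner point-spread function applied to the HU volume
#'   (0 disables). Clinical bone-kernel CT reconstructions have an
#'   effective resolution of roughly 1-2 mm; leaving sub-voxel-sharp
#'   edges unblurred would make the phantom sharper than any scanner.
#' @param seed integer RNG seed.
#' @return a `phantom_truth` list.
#' @export
phantom_truth <- function(condition = c("osteoporotic", "osteoblastic"),
                          trabecular_hu_mean = NULL, trabecular_hu_sd = NULL,
                          shell_hu = 1200,
                          semi_axis_x = 17, semi_axis_y = 12,
                          height_mm = 27, shell_mm = 0.5,
                          spacing_mm = 0.5, margin_mm = 2,
                          psf_fwhm_mm = 1.5, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(trabecular_hu_mean))
    trabecular_hu_mean <- if (condition == "osteoporotic") 80 else 600
  if (is.null(trabecular_hu_sd))
    trabecular_hu_sd <- if (condition == "osteoporotic") 30 else 150
  stopifnot(shell_hu > trabecular_hu_mean, trabecular_hu_sd >= 0,
            semi_axis_x > 0, semi_axis_y > 0, height_mm > 0,
            shell_mm > 0, spacing_mm > 0)
  structure(list(condition = condition,
                 trabecular_hu_mean = trabecular_hu_mean,
                 trabecular_hu_sd = trabecular_hu_sd,
                 shell_hu = shell_hu,
                 semi_axis_x = semi_axis_x, semi_axis_y = semi_axis_y,
                 height_mm = height_mm, shell_mm = shell_mm,
                 spacing_mm = spacing_mm, margin_mm = margin_mm,
                 psf_fwhm_mm = psf_fwhm_mm,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Generate a vertebral-body CT phantom and its segmentation mask
#'
#' Builds a Hounsfield-unit volume containing one elliptic-cylindrical
#' vertebral body: cortical shell (side wall and endplates) at
#' `shell_hu`, trabecular interior drawn i.i.d. from
#' Normal(`trabecular_hu_mean`, `trabecular_hu_sd`), background air at
#' -1000 HU. All HU are clamped to the CT range [-1024, 3071]. The
#' returned mask labels the whole solid as label 1 (level L1).
#' Deterministic for a given `truth$seed`.
#'
#' @param truth a [phantom_truth()] description.
#' @return list with elements `ct` (class `ct_volume`: `data`,
#'   `spacing`, `affine`, `axis_convention`) and `mask` (class
#'   `seg_mask`: `labels`, `level_map`).
#' @export
make_vertebra_phantom <- function(truth = phantom_truth()) {
  stopifnot(inherits(truth, "phantom_truth"))
  sp <- truth$spacing_mm
  nx <- ceiling((2 * truth$semi_axis_x + 2 * truth$margin_mm) / sp)
  ny <- ceiling((2 * truth$semi_axis_y + 2 * truth$margin_mm) / sp)
  nz <- ceiling((truth$height_mm + 2 * truth$margin_mm) / sp)
  if (2 * truth$semi_axis_x > nx * sp || 2 * truth$semi_axis_y > ny * sp ||
      truth$height_mm > nz * sp)
    stop("phantom geometry exceeds the voxel grid")
  cx <- nx * sp / 2; cy <- ny * sp / 2
  z0 <- (nz * sp - truth$height_mm) / 2
  xs <- (seq_len(nx) - 0.5) * sp
  ys <- (seq_len(ny) - 0.5) * sp
  zs <- (seq_len(nz) - 0.5) * sp
  ex <- outer((xs - cx) / truth$semi_axis_x, rep(1, ny))^2 +
    outer(rep(1, nx), (ys - cy) / truth$semi_axis_y)^2
  in_xy <- ex <= 1
  t <- truth$shell_mm
  core_xy <- (outer((xs - cx) / (truth$semi_axis_x - t), rep(1, ny))^2 +
              outer(rep(1, nx), (ys - cy) / (truth$semi_axis_y - t))^2) <= 1
  in_z <- zs >= z0 & zs <= z0 + truth$height_mm
  core_z <- zs >= z0 + t & zs <= z0 + truth$height_mm - t
  solid <- outer(in_xy, in_z) > 0      # nx x ny x nz logical
  core <- outer(core_xy, core_z) > 0
  data <- array(-1000, dim = c(nx, ny, nz))
  data[solid] <- truth$shell_hu
  n_core <- sum(core)
  hu_core <- with_seed(truth$seed, {
    truth$trabecular_hu_mean +
      truth$trabecular_hu_sd * stats::rnorm(n_core)
  })
  data[core] <- hu_core
  if (truth$psf_fwhm_mm > 0)
    data <- gauss_blur3(data, truth$psf_fwhm_mm / 2.3548 / sp)
  data[] <- pmin(pmax(data, -1024), 3071)
  affine <- diag(c(sp, sp, sp, 1))
  ct <- structure(list(data = data, spacing = rep(sp, 3), affine = affine,
                       axis_convention = "z-superior"),
                  class = "ct_volume")
  mask <- structure(list(labels = array(as.integer(solid), dim = dim(data)),
                         level_map = c(L1 = 1L)),
                    class = "seg_mask")
  list(ct = ct, mask = mask, truth = truth)
}

## Separable 3D Gaussian blur (scanner PSF emulation). Edge-renormalized
## truncated kernel: constants are preserved exactly everywhere.
gauss_blur3 <- function(arr, sigma_vox) {
  blur1 <- function(mat, n, sigma) {
    if (sigma <= 0) return(mat)
    h <- max(1L, ceiling(3 * sigma))
    w <- stats::dnorm(-h:h, sd = sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, pmin(n, i + (-h:h)))
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
    }
    (K / rowSums(K)) %*% mat
  }
  d <- dim(arr)
  a <- blur1(matrix(arr, d[1]), d[1], sigma_vox)
  a <- aperm(array(a, d), c(2, 3, 1))
  a <- blur1(matrix(a, d[2]), d[2], sigma_vox)
  a <- aperm(array(a, d[c(2, 3, 1)]), c(2, 3, 1))
  a <- blur1(matrix(a, d[3]), d[3], sigma_vox)
  aperm(array(a, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Default six-echo timing
#'
#' First echo at 1.12 ms with a 0.96 ms spacing, six echoes.
#'
#' @param n_echoes number of echoes.
#' @param te_min_ms first echo time, ms.
#' @param delta_te_ms echo spacing, ms.
#' @return echo times in ms.
#' @export
default_echo_times <- function(n_echoes = 6, te_min_ms = 1.12,
                               delta_te_ms = 0.96) {
  te_min_ms + delta_te_ms * (seq_len(n_echoes) - 1)
}

#' Simulate chemical-shift-encoded multi-echo signals
#'
#' Forward-simulates the complex water-fat signal of [forward_signal()]
#' voxel-wise: water and fat magnitudes sum to one with fat fraction
#' given by `pdff_truth`, phase evolves with the local field offset,
#' and magnitude decays with a single effective R2*. Optional complex
#' Gaussian noise is added per voxel per echo; SNR is defined as the
#' voxel's first-echo magnitude divided by the complex noise standard
#' deviation (each real/imaginary component has sd `|s(TE1)|/snr/sqrt(2)`).
#'
#' @param pdff_truth array of true fat fractions in \[0, 1\].
#' @param r2star array of R2* values, 1/s (same shape).
#' @param field_map array of field offsets, Hz (same shape).
#' @param echo_times_ms echo times, ms, strictly increasing.
#' @param spectrum a [fat_spectrum()].
#' @param snr positive scalar signal-to-noise ratio, or `NULL` for
#'   noiseless signals.
#' @param seed RNG seed for the noise draw.
#' @return an `echo_series`: list with `signal` (complex array, last
#'   axis = echo), `echo_times_ms`, `spectrum`, `dim`.
#' @export
make_cse_echoes <- function(pdff_truth, r2star, field_map,
                            echo_times_ms = default_echo_times(),
                            spectrum = fat_spectrum(), snr = NULL,
                            seed = 1L) {
  pdff_truth <- as.array(pdff_truth)
  r2star <- as.array(r2star); field_map <- as.array(field_map)
  if (!identical(dim(pdff_truth), dim(r2star)) ||
      !identical(dim(pdff_truth), dim(field_map)))
    stop("pdff_truth, r2star and field_map must share the same shape")
  if (any(diff(echo_times_ms) <= 0))
    stop("echo times must be strictly increasing")
  dims <- dim(pdff_truth)
  sig <- forward_signal(rho_W = 1 - c(pdff_truth), rho_F = c(pdff_truth),
                        psi_hz = c(field_map), r2star_s = c(r2star),
                        spectrum = spectrum, echo_times_ms = echo_times_ms)
  if (!is.null(snr)) {
    stopifnot(is.numeric(snr), snr > 0)
    sd_vox <- Mod(sig[, 1]) / snr / sqrt(2)
    n <- length(sig)
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    })
    sig <- sig + noise * sd_vox  # sd recycled down columns (per voxel)
  }
  structure(list(signal = array(sig, dim = c(dims, length(echo_times_ms))),
                 echo_times_ms = echo_times_ms, spectrum = spectrum,
                 dim = dims),
            class = "echo_series")
}

#' Effect profile for synthetic cohorts
#'
#' Group-specific lognormal location/scale parameters for per-vertebra
#' PDFF, failure displacement and failure load. The default medians are
#' the pooled group medians of the packaged measurement fixture
#' (metastasis vs osteoporosis: PDFF 11.9 / 43.8 %, displacement
#' 0.874 / 0.348 mm, load 29589 / 3095 N), with log-scale spreads
#' matched to the fixture's pooled IQRs. `effect = 0` collapses both
#' groups onto their common geometric mean (null configuration);
#' `effect = 1` is the full default contrast.
#'
#' @param effect scalar in \[0, 1\] scaling the log-median group gap.
#' @return a list of per-measure `medians` (2-vector metastasis,
#'   osteoporosis) and `sdlog` values.
#' @export
cohort_effect_profile <- function(effect = 1) {
  med <- list(pdff_percent = c(metastasis = 11.9, osteoporosis = 43.8),
              failure_displacement_mm = c(metastasis = 0.874,
                                          osteoporosis = 0.348),
              failure_load_N = c(metastasis = 29589, osteoporosis = 3095))
  sdlog <- list(pdff_percent = c(metastasis = 0.60, osteoporosis = 0.10),
                failure_displacement_mm = c(metastasis = 0.13,
                                            osteoporosis = 0.35),
                failure_load_N = c(metastasis = 0.43, osteoporosis = 0.30))
  med <- lapply(med, function(m) {
    g <- mean(log(m)); exp(g + effect * (log(m) - g))
  })
  list(medians = med, sdlog = sdlog, effect = effect)
}

#' Generate a synthetic cohort table
#'
#' Draws per-vertebra PDFF, failure displacement and failure load for
#' `n_metastasis` + `n_osteoporosis` patients (four lumbar levels each)
#' from group-specific lognormal distributions centred on the profile
#' medians. All fracture flags are `FALSE` (fracture status is an input
#' in this pipeline, never simulated). Deterministic given `seed`.
#'
#' @param n_metastasis,n_osteoporosis patient counts (>= 1).
#' @param effect_profile a [cohort_effect_profile()].
#' @param seed RNG seed.
#' @return a `cohort_table` data.frame with columns `patient_id`,
#'   `group`, `level`, `fractured`, `pdff_percent`,
#'   `failure_displacement_mm`, `failure_load_N`.
#' @export
make_cohort <- function(n_metastasis = 3, n_osteoporosis = 4,
                        effect_profile = cohort_effect_profile(),
                        seed = 1L) {
  stopifnot(n_metastasis >= 1, n_osteoporosis >= 1)
  n_pat <- n_metastasis + n_osteoporosis
  group <- rep(c("metastasis", "osteoporosis"),
               c(n_metastasis, n_osteoporosis))
  tab <- data.frame(
    patient_id = rep(seq_len(n_pat), each = 4),
    group = rep(group, each = 4),
    level = rep(c("L1", "L2", "L3", "L4"), n_pat),
    fractured = FALSE, stringsAsFactors = FALSE
  )
  gi <- ifelse(tab$group == "metastasis", 1L, 2L)
  vals <- with_seed(seed, {
    lapply(names(effect_profile$medians), function(m) {
      stats::rlnorm(nrow(tab),
                    meanlog = log(effect_profile$medians[[m]][gi]),
                    sdlog = effect_profile$sdlog[[m]][gi])
    })
  })
  names(vals) <- names(effect_profile$medians)
  tab$pdff_percent <- pmin(vals$pdff_percent, 100)
  tab$failure_displacement_mm <- vals$failure_displacement_mm
  tab$failure_load_N <- vals$failure_load_N
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Packaged per-vertebra lumbar measurement fixture
#'
#' The seven-patient reference cohort shipped with the package: per
#' vertebra (L1-L4) PDFF, failure displacement and failure load, with
#' group membership (3 metastasis, 4 osteoporosis) and fracture flags
#' (patient 4: L2 and L3; patient 5: L4; patient 6: L2 and L4) -- 28
#' rows, 5 of them fractured.
#'
#' @return a `cohort_table` data.frame.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_lumbar_measurements.csv",
                      package = "spinefea", mustWork = TRUE)
  read_cohort(path)
}
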