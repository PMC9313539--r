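#' Multi-peak fat spectrum
#'
#' A precalibrated marrow-type fat spectrum: spectral peak positions in
#' ppm relative to the water resonance (negative = lower frequency)
#' with relative amplitudes summing to one. The default seven peaks are
#' a standard published bone-marrow parameterization (olefinic peak
#' above water, dominant methylene peak at -3.40 ppm); it ships as
#' editable configuration because acquisition-specific calibrations
#' vary by a percentage point or two of PDFF.
#'
#' @param ppm peak offsets from water, ppm.
#' @param amplitude relative amplitudes (positive; normalized to sum 1).
#' @param field_T main field strength, Tesla (sets Hz per ppm).
#' @return a `fat_spectrum`: data.frame-ish list with `ppm`,
#'   `amplitude`, `freq_hz`, `field_T`.
#' @export
fat_spectrum <- function(ppm = c(0.59, -0.50, -1.95, -2.46, -2.68,
                                 -3.40, -3.80),
                         amplitude = c(0.047, 0.039, 0.006, 0.058,
                                       0.062, 0.700, 0.088),
                         field_T = 3) {
  stopifnot(length(ppm) == length(amplitude), all(amplitude > 0))
  amplitude <- amplitude / sum(amplitude)
  hz_per_ppm <- 42.577 * field_T   # proton gyromagnetic ratio, MHz/T
  structure(list(ppm = ppm, amplitude = amplitude,
                 freq_hz = ppm * hz_per_ppm, field_T = field_T),
            class = "fat_spectrum")
}

## Complex fat modulation c_F(t) = sum_p alpha_p exp(i 2 pi f_p t)
## for echo times in seconds; returns length(t) complex vector.
fat_modulation <- function(spectrum, t_s) {
  colSums(spectrum$amplitude *
            exp(1i * 2 * pi * outer(spectrum$freq_hz, t_s)))
}

#' Forward chemical-shift-encoded signal model
#'
#' s(t) = (rho_W + rho_F * sum_p alpha_p e^{i 2 pi f_p t})
#'        e^{i 2 pi psi t} e^{-R2* t},
#' with echo times in ms (converted to seconds internally), the field
#' offset psi in Hz and R2* in 1/s. Vectorized over voxels.
#'
#' @param rho_W,rho_F water and fat magnitudes (vectors).
#' @param psi_hz field-map offset, Hz.
#' @param r2star_s effective transverse relaxation rate, 1/s.
#' @param spectrum a [fat_spectrum()].
#' @param echo_times_ms echo times, ms.
#' @return complex matrix, voxels x echoes.
#' @export
forward_signal <- function(rho_W, rho_F, psi_hz = 0, r2star_s = 0,
                           spectrum = fat_spectrum(),
                           echo_times_ms = default_echo_times()) {
  n <- max(length(rho_W), length(rho_F), length(psi_hz),
           length(r2star_s))
  rho_W <- rep_len(rho_W, n); rho_F <- rep_len(rho_F, n)
  psi_hz <- rep_len(psi_hz, n); r2star_s <- rep_len(r2star_s, n)
  stopifnot(all(is.finite(rho_W)), all(is.finite(rho_F)),
            all(is.finite(psi_hz)), all(is.finite(r2star_s)))
  t_s <- echo_times_ms * 1e-3
  cF <- fat_modulation(spectrum, t_s)              # echoes
  base <- outer(rho_W, rep(1 + 0i, length(t_s))) +
    outer(rho_F, cF)
  phase <- exp(outer(1i * 2 * pi * psi_hz, t_s))
  decay <- exp(outer(-r2star_s, t_s))
  base * phase * decay
}

#' Fit the water-fat model to voxel signals by variable projection
#'
#' For every candidate (psi, R2*) pair on a grid, the complex water and
#' fat amplitudes are obtained in closed form by linear least squares
#' and the candidate with the smallest residual is kept; an optional
#' Nelder-Mead refinement then polishes (psi, R2*) with the linear
#' solve nested inside. PDFF is computed from the magnitudes of the
#' fitted complex amplitudes: 100 |rho_F| / (|rho_W| + |rho_F|).
#'
#' @param signal complex matrix (voxels x echoes) or a single voxel's
#'   complex vector.
#' @param echo_times_ms echo times, ms (>= 4 echoes).
#' @param spectrum a [fat_spectrum()].
#' @param psi_grid_hz field-map search grid, Hz.
#' @param r2_grid_s R2* search grid, 1/s.
#' @param refine logical: polish (psi, R2*) per voxel after the grid
#'   search.
#' @return data.frame of class `voxel_fit` with columns `rho_W`,
#'   `rho_F`, `psi_hz`, `r2star_s`, `residual`, `pdff_percent`,
#'   `degenerate` (all-zero signal).
#' @export
fit_voxels <- function(signal, echo_times_ms = default_echo_times(),
                       spectrum = fat_spectrum(),
                       psi_grid_hz = seq(-150, 150, by = 2),
                       r2_grid_s = seq(0, 300, by = 20),
                       refine = TRUE) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  ne <- ncol(signal)
  stopifnot(ne >= 4, length(echo_times_ms) == ne)
  t_s <- echo_times_ms * 1e-3
  cF <- fat_modulation(spectrum, t_s)
  nv <- nrow(signal)
  energy <- rowSums(Mod(signal)^2)
  degenerate <- energy < .Machine$double.eps
  best_res <- rep(Inf, nv)
  best_psi <- numeric(nv); best_r2 <- numeric(nv)
  cand <- expand.grid(psi = psi_grid_hz, r2 = r2_grid_s)
  for (i in seq_len(nrow(cand))) {
    w <- exp((1i * 2 * pi * cand$psi[i] - cand$r2[i]) * t_s)
    A <- cbind(w, cF * w)
    qr_ <- qr(A)
    Q <- qr.Q(qr_)                      # ne x 2, orthonormal
    proj <- Mod(signal %*% Conj(Q))^2   # |Q^H s|^2 per column
    res <- pmax(energy - rowSums(proj), 0)
    better <- res < best_res
    if (any(better)) {
      best_res[better] <- res[better]
      best_psi[better] <- cand$psi[i]
      best_r2[better] <- cand$r2[i]
    }
  }
  solve_amp <- function(psi, r2, s) {
    w <- exp((1i * 2 * pi * psi - r2) * t_s)
    A <- cbind(w, cF * w)
    x <- qr.solve(A, s)
    r <- s - A %*% x
    list(x = x, res = sum(Mod(r)^2))
  }
  rho_W <- numeric(nv); rho_F <- numeric(nv)
  for (v in seq_len(nv)) {
    if (degenerate[v]) { rho_W[v] <- rho_F[v] <- 0; next }
    s <- signal[v, ]
    if (refine) {
      obj <- function(p) solve_amp(p[1], max(p[2], 0), s)$res
      opt <- stats::optim(c(best_psi[v], best_r2[v]), obj,
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 500))
      best_psi[v] <- opt$par[1]; best_r2[v] <- max(opt$par[2], 0)
    }
    fit <- solve_amp(best_psi[v], best_r2[v], s)
    rho_W[v] <- Mod(fit$x[1]); rho_F[v] <- Mod(fit$x[2])
    best_res[v] <- fit$res
  }
  pdff <- ifelse(rho_W + rho_F > 0, 100 * rho_F / (rho_W + rho_F),
                 NA_real_)
  pdff[degenerate] <- NA_real_
  out <- data.frame(rho_W = rho_W, rho_F = rho_F, psi_hz = best_psi,
                    r2star_s = best_r2, residual = sqrt(best_res),
                    pdff_percent = pdff, degenerate = degenerate)
  class(out) <- c("voxel_fit", "data.frame")
  out
}

#' @rdname fit_voxels
#' @export
fit_voxel <- function(signal, ...) fit_voxels(rbind(signal), ...)

#' Compute a PDFF map from a multi-echo series
#'
#' Runs [fit_voxels()] on every masked voxel and assembles PDFF, R2*
#' and field maps; unmasked voxels and degenerate fits are `NA`.
#'
#' @param echoes an `echo_series` (see [make_cse_echoes()]).
#' @param mask a `seg_mask` co-registered with the series, or `NULL`
#'   to fit every voxel.
#' @param ... passed to [fit_voxels()] (grids, `refine`).
#' @return a `pdff_map`: list of 3D arrays `pdff` (percent), `r2star`
#'   (1/s), `psi` (Hz), plus `n_degenerate`.
#' @export
map_volume <- function(echoes, mask = NULL, ...) {
  stopifnot(inherits(echoes, "echo_series"))
  dims <- echoes$dim
  sig <- matrix(echoes$signal, nrow = prod(dims))
  sel <- if (is.null(mask)) rep(TRUE, prod(dims)) else {
    stopifnot(identical(dim(mask$labels), dims))
    c(mask$labels > 0)
  }
  if (!any(sel)) {
    warning("empty mask: returning empty map")
    empty <- array(NA_real_, dims)
    return(structure(list(pdff = empty, r2star = empty, psi = empty,
                          n_degenerate = 0L), class = "pdff_map"))
  }
  fit <- fit_voxels(sig[sel, , drop = FALSE],
                    echo_times_ms = echoes$echo_times_ms,
                    spectrum = echoes$spectrum, ...)
  mk <- function(v) { a <- array(NA_real_, dims); a[sel] <- v; a }
  nd <- sum(fit$degenerate)
  if (nd > 0) message(nd, " degenerate voxel fit(s) marked missing")
  structure(list(pdff = mk(fit$pdff_percent), r2star = mk(fit$r2star_s),
                 psi = mk(fit$psi_hz), n_degenerate = nd),
            class = "pdff_map")
}

#' @export
print.pdff_map <- function(x, ...) {
  v <- x$pdff[is.finite(x$pdff)]
  cat(sprintf("PDFF map: %s voxels fitted, %d degenerate\n",
              format(length(v)), x$n_degenerate))
  if (length(v))
    cat(sprintf("  PDFF %% median %.2f  range [%.2f, %.2f]\n",
                stats::median(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.pdff_map <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$pdff)[3] / 2)
  graphics::image(x$pdff[, , slice], zlim = c(0, 100), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("PDFF %% (slice %d)", slice), ...)
  invisible(x)
}

#' Per-vertebra PDFF
#'
#' Mean PDFF over a labelled vertebra's voxels (the conventional ROI
#' statistic), excluding missing voxels.
#'
#' @param map a `pdff_map`.
#' @param mask a `seg_mask`.
#' @param level vertebral level name present in `mask$level_map`.
#' @return scalar PDFF in percent.
#' @export
vertebra_pdff <- function(map, mask, level = "L1") {
  stopifnot(inherits(map, "pdff_map"), inherits(mask, "seg_mask"))
  if (!level %in% names(mask$level_map))
    stop("level ", level, " not present in mask")
  lab <- mask$level_map[[level]]
  vals <- map$pdff[mask$labels == lab]
  mean(vals[is.finite(vals)])
}
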