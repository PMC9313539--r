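## Linear tetrahedral (C3D4) finite elements with transversely
## isotropic elasticity, displacement-controlled compression,
## principal-stress yield with secant stiffness reduction, and element
## kill at the post-yield strain limit.

## Voigt order used throughout: (xx, yy, zz, xy, xz, yz),
## engineering shear strains.

#' Transversely isotropic compliance matrix
#'
#' Builds the 6x6 compliance from the per-element elastic constants.
#' The given minor Poisson ratios are read with the load axis first
#' (`"load-first"`: nu_xz couples a load along x to strain along z, so
#' S\[z,x\] = -nu_xz / E_x); the `"load-second"` alternative reads them
#' with the load along the second axis. Either way the matrix is
#' symmetrized before inversion.
#'
#' @param card one row of a `material_cards` data.frame (or any list
#'   with E_x, E_y, E_z, G_xy, G_xz, G_yz, nu_xy, nu_xz, nu_yz).
#' @param convention Poisson-ratio reading, see above.
#' @return 6x6 symmetric compliance matrix (1/MPa).
#' @export
compliance_matrix <- function(card,
                              convention = c("load-first", "load-second")) {
  convention <- match.arg(convention)
  S <- diag(c(1 / card$E_x, 1 / card$E_y, 1 / card$E_z,
              1 / card$G_xy, 1 / card$G_xz, 1 / card$G_yz))
  S[1, 2] <- S[2, 1] <- -card$nu_xy / card$E_x
  if (convention == "load-first") {
    S[1, 3] <- S[3, 1] <- -card$nu_xz / card$E_x
    S[2, 3] <- S[3, 2] <- -card$nu_yz / card$E_y
  } else {
    S[1, 3] <- S[3, 1] <- -card$nu_xz / card$E_z
    S[2, 3] <- S[3, 2] <- -card$nu_yz / card$E_z
  }
  (S + t(S)) / 2
}

#' Isotropic override material card
#'
#' A single-material card with E_x = E_y = E_z and G = E / (2(1 + nu)),
#' used for analytic verification problems where closed-form solutions
#' exist (uniform cuboids under uniaxial compression).
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio.
#' @param sigma_max,sigma_min principal-stress limits, MPa (`Inf`
#'   keeps the element elastic).
#' @param eps_AB post-yield strain limit.
#' @param n number of identical rows to produce.
#' @return a `material_cards` data.frame.
#' @export
isotropic_card <- function(E, nu = 0, sigma_max = Inf, sigma_min = Inf,
                           eps_AB = Inf, n = 1) {
  out <- data.frame(
    hu = NA_real_, rho_app = NA_real_, rho_ash = NA_real_,
    E_z = E, E_x = E, E_y = E,
    G_xy = E / (2 * (1 + nu)), G_xz = E / (2 * (1 + nu)),
    G_yz = E / (2 * (1 + nu)),
    nu_xy = nu, nu_xz = nu, nu_yz = nu,
    sigma_max = sigma_max, sigma_min = sigma_min, eps_AB = eps_AB
  )[rep(1, n), ]
  rownames(out) <- NULL
  class(out) <- c("material_cards", "data.frame")
  out
}

## Strain-displacement matrices for all elements.
## Returns list(B = 6 x 12 x nel array, vol = element volumes).
element_B <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  x1 <- n[e[, 1], , drop = FALSE]
  J1 <- n[e[, 2], , drop = FALSE] - x1
  J2 <- n[e[, 3], , drop = FALSE] - x1
  J3 <- n[e[, 4], , drop = FALSE] - x1
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cross(J2, J3); c31 <- cross(J3, J1); c12 <- cross(J1, J2)
  detJ <- rowSums(J1 * c23)
  if (any(detJ <= 0)) stop("element(s) with non-positive volume")
  ## gradients of shape functions 2..4 are the rows of J^-T, i.e. the
  ## columns of adj(J)/det; gradient of shape function 1 is minus their sum
  g2 <- c23 / detJ; g3 <- c31 / detJ; g4 <- c12 / detJ
  g1 <- -(g2 + g3 + g4)
  nel <- nrow(e)
  B <- array(0, dim = c(6, 12, nel))
  glist <- list(g1, g2, g3, g4)
  for (a in 1:4) {
    g <- glist[[a]]
    cx <- 3 * (a - 1) + 1
    B[1, cx, ] <- g[, 1]; B[2, cx + 1, ] <- g[, 2]; B[3, cx + 2, ] <- g[, 3]
    B[4, cx, ] <- g[, 2]; B[4, cx + 1, ] <- g[, 1]
    B[5, cx, ] <- g[, 3]; B[5, cx + 2, ] <- g[, 1]
    B[6, cx + 1, ] <- g[, 3]; B[6, cx + 2, ] <- g[, 2]
  }
  list(B = B, vol = detJ / 6)
}

## Per-element stiffness (D) matrices, exploiting that cards sharing
## the same dimensionless shape (ratios to E_z and Poisson ratios)
## differ only by the scalar E_z.
element_D <- function(cards, convention = "load-first") {
  sig <- paste(signif(cards$E_x / cards$E_z, 12),
               signif(cards$G_xy / cards$E_z, 12),
               signif(cards$G_xz / cards$E_z, 12),
               signif(cards$nu_xy, 12), signif(cards$nu_xz, 12))
  nel <- nrow(cards)
  D <- array(0, dim = c(6, 6, nel))
  for (s in unique(sig)) {
    i <- which(sig == s)[1]
    unit <- cards[i, ]
    sc <- unit$E_z
    unit[c("E_x", "E_y", "E_z", "G_xy", "G_xz", "G_yz")] <-
      unit[c("E_x", "E_y", "E_z", "G_xy", "G_xz", "G_yz")] / sc
    S <- compliance_matrix(unit, convention)
    Du <- solve(S)
    Du <- (Du + t(Du)) / 2
    ev <- eigen(Du, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("non-positive-definite material at element ", i)
    idx <- which(sig == s)
    D[, , idx] <- outer(c(Du), cards$E_z[idx])
  }
  D
}

## Precompute everything assembly needs.
fe_prep <- function(mesh, cards, convention = "load-first") {
  stopifnot(nrow(cards) == nrow(mesh$elements))
  bb <- element_B(mesh)
  D <- element_D(cards, convention)
  nel <- nrow(mesh$elements)
  Kel <- matrix(0, 144, nel)
  for (e in seq_len(nel)) {
    Be <- bb$B[, , e]
    Kel[, e] <- c(bb$vol[e] * crossprod(Be, D[, , e] %*% Be))
  }
  ## dof columns interleaved per node: (n1x, n1y, n1z, n2x, ...)
  dof <- matrix(0L, nel, 12)
  for (a in 1:4) {
    dof[, 3 * a - 2] <- 3L * mesh$elements[, a] - 2L
    dof[, 3 * a - 1] <- 3L * mesh$elements[, a] - 1L
    dof[, 3 * a] <- 3L * mesh$elements[, a]
  }
  ii <- matrix(0L, 144, nel); jj <- matrix(0L, 144, nel)
  for (e in seq_len(nel)) {
    d <- dof[e, ]
    ii[, e] <- rep(d, times = 12)
    jj[, e] <- rep(d, each = 12)
  }
  list(Kel = Kel, ii = ii, jj = jj, B = bb$B, vol = bb$vol, D = D,
       dof = dof, ndof = 3 * nrow(mesh$nodes))
}

## Precompute the triplet-to-slot maps for the free/free (upper
## triangle, symmetric) and free/constrained blocks so repeated
## assemblies only recompute group sums and assign @x in place.
fe_partition <- function(prep, free, constrained) {
  ndof <- prep$ndof
  posf <- integer(ndof); posf[free] <- seq_along(free)
  posc <- integer(ndof); posc[constrained] <- seq_along(constrained)
  nfree <- length(free)
  ii <- c(prep$ii); jj <- c(prep$jj)
  fi <- posf[ii]; fj <- posf[jj]; cj <- posc[jj]
  sel <- which(fi > 0L & fj > 0L & fi <= fj)
  key <- (fj[sel] - 1) * as.numeric(nfree) + fi[sel]
  o <- order(key); sel_ff <- sel[o]; ko <- key[o]
  g_ff <- cumsum(c(1, diff(ko) > 0))
  Tup <- Matrix::sparseMatrix(i = fi[sel], j = fj[sel], x = 1,
                              dims = c(nfree, nfree))
  Kff <- Matrix::forceSymmetric(Tup, uplo = "U")
  stopifnot(length(Kff@x) == g_ff[length(g_ff)])
  sel2 <- which(fi > 0L & cj > 0L)
  key2 <- (cj[sel2] - 1) * as.numeric(nfree) + fi[sel2]
  o2 <- order(key2); sel_fp <- sel2[o2]; ko2 <- key2[o2]
  g_fp <- cumsum(c(1, diff(ko2) > 0))
  Kfp <- Matrix::sparseMatrix(i = fi[sel2], j = cj[sel2], x = 1,
                              dims = c(nfree, length(constrained)))
  stopifnot(length(Kfp@x) == g_fp[length(g_fp)])
  list(Kff = Kff, Kfp = Kfp, sel_ff = sel_ff, g_ff = g_ff,
       sel_fp = sel_fp, g_fp = g_fp)
}

assemble_from_prep <- function(prep, scale = NULL) {
  x <- if (is.null(scale)) c(prep$Kel)
       else c(prep$Kel) * rep(scale, each = 144)
  K <- Matrix::sparseMatrix(i = c(prep$ii), j = c(prep$jj), x = x,
                            dims = c(prep$ndof, prep$ndof))
  Matrix::forceSymmetric(K, uplo = "U")
}

#' Assemble the global stiffness matrix
#'
#' Symmetric sparse stiffness of the whole mesh: each element
#' contributes vol * B' D B built from its transversely isotropic
#' constants, scaled by its current stiffness scale factor (1 for
#' elastic elements).
#'
#' @param mesh a `tet_mesh`.
#' @param cards `material_cards`, one row per element.
#' @param states optional element states (see [run_compression()]); only
#'   the `scale` component is used. `NULL` means all elastic.
#' @param convention Poisson-ratio convention, see [compliance_matrix()].
#' @return a symmetric sparse matrix (3 * n_nodes square).
#' @export
assemble <- function(mesh, cards, states = NULL,
                     convention = "load-first") {
  prep <- fe_prep(mesh, cards, convention)
  scale <- if (is.null(states)) NULL else states$scale
  assemble_from_prep(prep, scale)
}

## Principal stresses of row-wise Voigt stress vectors
## (xx, yy, zz, xy, xz, yz). Returns nel x 3, descending.
principal_stresses <- function(sig) {
  m <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  dx <- sig[, 1] - m; dy <- sig[, 2] - m; dz <- sig[, 3] - m
  xy <- sig[, 4]; xz <- sig[, 5]; yz <- sig[, 6]
  J2 <- 0.5 * (dx^2 + dy^2 + dz^2) + xy^2 + xz^2 + yz^2
  J3 <- dx * (dy * dz - yz^2) - xy * (xy * dz - yz * xz) +
    xz * (xy * yz - dy * xz)
  r <- sqrt(pmax(J2 / 3, 0))
  arg <- ifelse(r > 0, J3 / 2 / pmax(r^3, .Machine$double.xmin), 0)
  arg <- pmin(pmax(arg, -1), 1)
  theta <- acos(arg) / 3
  ## theta in [0, pi/3] makes the three roots already descending
  s1 <- m + 2 * r * cos(theta)
  s2 <- m + 2 * r * cos(theta - 2 * pi / 3)
  s3 <- m + 2 * r * cos(theta + 2 * pi / 3)
  hi <- pmax(s1, s2, s3); lo <- pmin(s1, s2, s3)
  cbind(hi, s1 + s2 + s3 - hi - lo, lo)
}

#' Quasi-static displacement-controlled compression
#'
#' Fixes the inferior surface, prescribes a downward axial displacement
#' on the superior surface (in-plane translations free unless
#' `bonded = TRUE`), and advances in equal displacement increments. At
#' each increment the element states are iterated to self-consistency:
#' elements whose maximum principal stress exceeds `sigma_max` or whose
#' minimum principal stress falls below `-sigma_min` yield and have
#' their secant stiffness scaled so the stress returns to the limit
#' surface; yielded elements accumulate post-yield axial strain and are
#' killed (stiffness scale `kill_scale`) once it reaches `eps_AB`.
#' State transitions are forward-only. The run stops at the prescribed
#' maximum displacement or once the total reaction force drops below
#' half its running peak.
#'
#' @param mesh a `tet_mesh` with non-empty inferior/superior node sets.
#' @param cards `material_cards`, one row per element.
#' @param max_displacement_mm final prescribed axial displacement, mm.
#' @param n_increments number of equal displacement increments (>= 10).
#' @param bonded if `TRUE`, superior-surface in-plane translations are
#'   also fixed (rigid-bonded platen).
#' @param kill_scale residual stiffness fraction of failed elements.
#' @param kill_ref_length_mm crack-band regularization reference
#'   length: the post-yield strain limit of each element is scaled by
#'   `kill_ref_length_mm / h_e` (h_e the element's parent-cell edge),
#'   which keeps the energy dissipated by a localizing failure band
#'   independent of the mesh size. The default, 2 mm, is the element
#'   size the constitutive strain limit is referred to. `NULL`
#'   disables the scaling.
#' @param max_state_iter cap on state iterations per increment.
#' @param yield_tol relative stress overshoot tolerated before an
#'   element is (re)scaled.
#' @param convention Poisson-ratio convention, see [compliance_matrix()].
#' @return an object of class `fea_result`: the load-displacement
#'   curve (with per-increment surface reactions), `failure_load` (N),
#'   `failure_displacement` (mm), `failure_reached`, and an element
#'   state summary.
#' @export
run_compression <- function(mesh, cards, max_displacement_mm,
                            n_increments = 40, bonded = FALSE,
                            kill_scale = 1e-3,
                            kill_ref_length_mm = 2,
                            max_state_iter = 50,
                            yield_tol = 1e-3,
                            convention = "load-first") {
  stopifnot(inherits(mesh, "tet_mesh"),
            length(mesh$boundary$inferior) > 0,
            length(mesh$boundary$superior) > 0)
  nel <- nrow(mesh$elements)
  curve0 <- data.frame(displacement_mm = 0, force_N = 0,
                       reaction_inferior_N = 0, reaction_superior_N = 0)
  if (max_displacement_mm <= 0) {
    return(structure(list(curve = curve0, failure_load = NA_real_,
                          failure_displacement = NA_real_,
                          failure_reached = FALSE,
                          states = data.frame(status = rep("elastic", nel),
                                              scale = 1, acc_strain = 0),
                          n_elements = nel),
                     class = "fea_result"))
  }
  stopifnot(n_increments >= 10)
  prep <- fe_prep(mesh, cards, convention)
  ndof <- prep$ndof
  inf_nodes <- mesh$boundary$inferior
  sup_nodes <- mesh$boundary$superior
  fixed <- c(3 * inf_nodes - 2, 3 * inf_nodes - 1, 3 * inf_nodes)
  sup_z <- 3 * sup_nodes
  presc <- sup_z
  if (bonded) presc <- c(presc, 3 * sup_nodes - 2, 3 * sup_nodes - 1)
  constrained <- c(fixed, presc)
  free <- setdiff(seq_len(ndof), constrained)
  asm <- fe_partition(prep, free, constrained)
  status <- integer(nel)          # 0 elastic, 1 yielded, 2 failed
  scale <- rep(1, nel)
  acc <- numeric(nel)
  eps_z_prev <- numeric(nel)
  sigma_max <- cards$sigma_max; sigma_min <- cards$sigma_min
  eps_AB <- cards$eps_AB
  if (!is.null(kill_ref_length_mm)) {
    h_e <- (6 * tet_volumes(mesh))^(1 / 3)   # parent-cell edge length
    eps_AB <- eps_AB * kill_ref_length_mm / h_e
  }
  curve <- curve0
  peak <- 0
  factor <- NULL; scale_at_factor <- NULL
  Kff <- asm$Kff; Kfp <- asm$Kfp
  d_steps <- seq_len(n_increments) * max_displacement_mm / n_increments
  up <- numeric(length(constrained))
  zsel <- match(sup_z, constrained)
  u <- numeric(ndof)
  dof_flat <- c(t(prep$dof))
  dof_ids <- sort(unique(dof_flat))
  for (k in seq_along(d_steps)) {
    d <- d_steps[k]
    converged <- FALSE
    for (it in seq_len(max_state_iter)) {
      if (is.null(factor) || !identical(scale_at_factor, scale)) {
        xs <- c(prep$Kel) * rep(scale, each = 144)
        Kff@x <- c(rowsum(xs[asm$sel_ff], asm$g_ff, reorder = FALSE))
        Kfp@x <- c(rowsum(xs[asm$sel_fp], asm$g_fp, reorder = FALSE))
        factor <- if (is.null(factor))
          Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
        else Matrix::update(factor, Kff)
        scale_at_factor <- scale
      }
      up[zsel] <- -d
      uf <- as.numeric(Matrix::solve(factor, -Kfp %*% up))
      u[] <- 0; u[free] <- uf; u[constrained] <- up
      ## element strains and secant stresses
      ue <- matrix(u[dof_flat], nrow = 12)
      eps <- matrix(0, 6, nel)
      for (r in 1:6)
        eps[r, ] <- colSums(prep$B[r, , ] * ue)
      sig <- matrix(0, 6, nel)
      for (r in 1:6)
        sig[r, ] <- colSums(prep$D[r, , ] * eps) * scale
      ps <- principal_stresses(t(sig))
      viol <- pmax(ifelse(is.finite(sigma_max), ps[, 1] / sigma_max, 0),
                   ifelse(is.finite(sigma_min), -ps[, 3] / sigma_min, 0))
      yield_now <- viol > 1 + yield_tol & status < 2L
      eps_z <- eps[3, ]
      acc_cand <- acc + ifelse(status == 1L, abs(eps_z - eps_z_prev), 0)
      fail_now <- status == 1L & acc_cand >= eps_AB
      if (!any(yield_now) && !any(fail_now)) {
        converged <- TRUE
        acc <- acc_cand
        eps_z_prev <- eps_z
        break
      }
      scale[yield_now] <- scale[yield_now] / viol[yield_now]
      status[yield_now] <- pmax(status[yield_now], 1L)
      scale[fail_now] <- kill_scale
      status[fail_now] <- 2L
    }
    if (!converged)
      stop("element state iteration did not converge at increment ", k)
    ## nodal internal forces f = sum_e vol_e B_e' sigma_e (reactions at
    ## constrained dofs; ~0 at free dofs by equilibrium)
    fel <- matrix(0, 12, nel)
    for (a in 1:12)
      fel[a, ] <- prep$vol * colSums(prep$B[, a, ] * sig)
    r_all <- c(rowsum(c(fel), dof_flat, reorder = TRUE))
    r_of <- function(dofs) sum(r_all[match(dofs, dof_ids)], na.rm = TRUE)
    r_sup <- r_of(sup_z)
    r_inf <- r_of(3 * inf_nodes)
    Fk <- -r_sup
    curve <- rbind(curve, data.frame(displacement_mm = d, force_N = Fk,
                                     reaction_inferior_N = r_inf,
                                     reaction_superior_N = r_sup))
    peak <- max(peak, Fk)
    if (Fk < 0.5 * peak) break
  }
  fl <- tryCatch(extract_failure(curve), error = function(e) NULL)
  structure(list(
    curve = curve,
    failure_load = if (is.null(fl)) NA_real_ else fl[["failure_load"]],
    failure_displacement = if (is.null(fl)) NA_real_
                           else fl[["failure_displacement"]],
    failure_reached = !is.null(fl) && any(
      curve$force_N < (1 - 0.01) * cummax(curve$force_N)),
    states = data.frame(status = c("elastic", "yielded",
                                   "failed")[status + 1L],
                        scale = scale, acc_strain = acc),
    n_elements = nel, bonded = bonded,
    elastic_slope = if (nrow(curve) >= 2)
      curve$force_N[2] / curve$displacement_mm[2] else NA_real_
  ), class = "fea_result")
}

#' Extract the failure point from a load-displacement curve
#'
#' The failure point is the first local force maximum followed by a
#' drop exceeding `drop_frac` of that maximum; if the force never drops
#' that much, the global maximum is taken.
#'
#' @param curve data.frame with columns `displacement_mm`, `force_N`
#'   (at least two points).
#' @param drop_frac relative force drop that qualifies a peak.
#' @return named vector `failure_load` (N), `failure_displacement` (mm).
#' @export
extract_failure <- function(curve, drop_frac = 0.01) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 2)
  f <- curve$force_N; d <- curve$displacement_mm
  if (max(f) <= 0) stop("degenerate curve: no positive force recorded")
  runpeak <- cummax(f)
  drop_at <- which(f < (1 - drop_frac) * runpeak)
  idx <- if (length(drop_at)) {
    ## first attainment of that peak (tolerant to fp plateau jitter)
    which(f >= runpeak[drop_at[1]] * (1 - 1e-12))[1]
  } else {
    which(f >= max(f) * (1 - 1e-12))[1]
  }
  c(failure_load = f[idx], failure_displacement = d[idx])
}

#' @export
print.fea_result <- function(x, ...) {
  cat("Vertebral compression FE result\n")
  cat(sprintf("  elements: %d  increments recorded: %d\n",
              x$n_elements, nrow(x$curve) - 1))
  if (is.finite(x$failure_load))
    cat(sprintf("  failure load: %.1f N at %.4f mm%s\n", x$failure_load,
                x$failure_displacement,
                if (x$failure_reached) "" else " (peak not followed by drop)"))
  else cat("  failure point: not reached\n")
  invisible(x)
}

#' @export
summary.fea_result <- function(object, ...) {
  st <- table(factor(object$states$status,
                     levels = c("elastic", "yielded", "failed")))
  out <- list(failure_load = object$failure_load,
              failure_displacement = object$failure_displacement,
              failure_reached = object$failure_reached,
              elastic_slope = object$elastic_slope,
              element_states = st, curve = object$curve)
  class(out) <- "summary.fea_result"
  out
}

#' @export
print.summary.fea_result <- function(x, ...) {
  cat("Failure load:        ", format(x$failure_load), "N\n")
  cat("Failure displacement:", format(x$failure_displacement), "mm\n")
  cat("Elastic slope:       ", format(x$elastic_slope), "N/mm\n")
  cat("Element states:\n"); print(x$element_states)
  invisible(x)
}

#' @export
coef.fea_result <- function(object, ...) {
  c(failure_load_N = object$failure_load,
    failure_displacement_mm = object$failure_displacement)
}

#' @export
plot.fea_result <- function(x, ...) {
  graphics::plot(x$curve$displacement_mm, x$curve$force_N, type = "b",
                 xlab = "applied displacement (mm)",
                 ylab = "reaction force (N)", ...)
  if (is.finite(x$failure_load))
    graphics::points(x$failure_displacement, x$failure_load, pch = 19,
                     col = "red")
  invisible(x)
}
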