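## Kuhn (Freudenthal) subdivision of a cube into 6 tetrahedra, one per
## permutation of the axes. Every tetrahedron shares the main diagonal
## (0,0,0)-(1,1,1); using the same orientation in every cell makes the
## subdivision conform across cell faces without parity alternation.
.kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

## Local corner index (1..8) of offset (dx,dy,dz).
.corner_id <- function(d) 1L + d[1] + 2L * d[2] + 4L * d[3]

## 4 local corner ids per Kuhn tet, orientation-corrected to positive
## volume for positive axis-aligned cells.
.kuhn_tets <- local({
  out <- matrix(0L, 6, 4)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, 1:3]
  for (p in 1:6) {
    pi <- .kuhn_perms[p, ]
    v0 <- c(0, 0, 0)
    v1 <- v0; v1[pi[1]] <- 1
    v2 <- v1; v2[pi[2]] <- 1
    v3 <- c(1, 1, 1)
    vs <- rbind(v0, v1, v2, v3)
    if (det(rbind(vs[2, ] - vs[1, ], vs[3, ] - vs[1, ],
                  vs[4, ] - vs[1, ])) < 0)
      vs <- vs[c(1, 2, 4, 3), ]
    out[p, ] <- apply(vs, 1, .corner_id)
  }
  out
})

## Kuhn tet index (1..6) of fractional coordinates within a cell,
## ties broken toward the lower axis index (deterministic).
.kuhn_tet_of <- function(u1, u2, u3) {
  ge12 <- u1 >= u2; ge13 <- u1 >= u3; ge23 <- u2 >= u3
  out <- integer(length(u1))
  out[ge12 & ge23] <- 1L                      # x >= y >= z
  out[ge12 & !ge23 & ge13] <- 2L              # x >= z > y
  out[ge12 & !ge23 & !ge13] <- 5L             # z > x >= y
  out[!ge12 & ge13] <- 3L                     # y > x >= z
  out[!ge12 & !ge13 & ge23] <- 4L             # y >= z > x
  out[!ge12 & !ge13 & !ge23] <- 6L            # z > y > x
  out
}

#' Convert a segmentation mask to a conforming linear tetrahedral mesh
#'
#' Voxels are aggregated into cubic cells whose side is the nearest
#' integer multiple of the voxel spacing to `edge_length_mm`; every
#' cell with at least `occupancy` masked volume fraction is split into
#' six linear tetrahedra by the Kuhn subdivision with a globally
#' consistent diagonal orientation, which guarantees face conformity.
#' Node sets on the lowest and highest occupied z-planes are tagged as
#' the inferior and superior loading surfaces.
#'
#' @param mask a `seg_mask`; all nonzero labels are meshed.
#' @param ct the companion `ct_volume` (supplies voxel spacing).
#' @param edge_length_mm target element edge length, mm; must be at
#'   least the largest voxel spacing.
#' @param occupancy minimum masked volume fraction for a cell to be
#'   meshed (default 0.5).
#' @return a `tet_mesh`: `nodes` (n x 3, mm), `elements` (m x 4 node
#'   indices, positively oriented), `boundary` (`inferior`/`superior`
#'   node index sets), `cell_mm`, and the voxel-center-to-element
#'   assignment used for material mapping.
#' @export
mask_to_mesh <- function(mask, ct, edge_length_mm, occupancy = 0.5) {
  stopifnot(inherits(mask, "seg_mask"), inherits(ct, "ct_volume"))
  sp <- ct$spacing
  dims <- dim(mask$labels)
  if (sum(mask$labels > 0) == 0) stop("empty segmentation mask")
  if (edge_length_mm < max(sp) * (1 - 1e-9))
    stop("edge length must be at least the voxel spacing")
  m <- pmax(1L, as.integer(round(edge_length_mm / sp)))
  cell_mm <- m * sp
  ## anchor the cell grid at the mask bounding-box corner so the
  ## specimen's load-bearing extreme layers align with cell boundaries
  ## regardless of the chosen edge length
  occ_any <- which(mask$labels > 0, arr.ind = TRUE)
  imin <- apply(occ_any, 2, min)
  axis_cells <- function(n, m1, i0) {
    cc <- floor((seq_len(n) - i0) / m1)
    cc - min(cc)
  }
  cix <- axis_cells(dims[1], m[1], imin[1])
  ciy <- axis_cells(dims[2], m[2], imin[2])
  ciz <- axis_cells(dims[3], m[3], imin[3])
  nc <- c(max(cix), max(ciy), max(ciz)) + 1L
  ## physical origin of cell (0,0,0) per axis
  grid_origin <- (imin - 1 + floor((1 - imin) / m) * m) * sp
  cell_of <- 1L + outer(outer(cix, ciy * nc[1], "+"),
                        ciz * (nc[1] * nc[2]), "+")
  inside <- c(mask$labels > 0)
  counts <- tabulate(cell_of[inside], nbins = prod(nc))
  occ <- counts / prod(m) >= occupancy
  ## trim partial cell layers along the loading (z) axis: an end layer
  ## extending past the mask would otherwise form a weak half-covered
  ## load path whose composition depends on the edge length
  n_z <- (max(occ_any[, 3]) - imin[3] + 1L) %/% m[3]
  if (n_z < 1) stop("mask thinner than one cell along z")
  occ <- occ & rep(seq_len(nc[3]) - 1L < n_z, each = nc[1] * nc[2])
  if (!any(occ)) stop("no cell reaches the occupancy threshold")
  cell_rank <- integer(prod(nc)); cell_rank[occ] <- seq_len(sum(occ))
  occ_idx <- which(occ) - 1L
  ocx <- occ_idx %% nc[1]
  ocy <- (occ_idx %/% nc[1]) %% nc[2]
  ocz <- occ_idx %/% (nc[1] * nc[2])
  ## global corner lattice ids for the 8 corners of each occupied cell
  ld <- nc + 1L
  gid <- function(i, j, k) 1L + i + ld[1] * (j + ld[2] * k)
  corners8 <- sapply(0:7, function(l) {
    d <- c(l %% 2, (l %/% 2) %% 2, l %/% 4)
    gid(ocx + d[1], ocy + d[2], ocz + d[3])
  })
  if (!is.matrix(corners8)) corners8 <- matrix(corners8, nrow = 1)
  ncell <- length(occ_idx)
  ## element id = (cell - 1) * 6 + tet
  elements_g <- matrix(0L, ncell * 6L, 4L)
  for (p in 1:6)
    elements_g[seq(p, by = 6L, length.out = ncell), ] <-
      corners8[, .kuhn_tets[p, ], drop = FALSE]
  used <- sort(unique(as.vector(elements_g)))
  node_map <- integer(max(used)); node_map[used] <- seq_along(used)
  elements <- matrix(node_map[elements_g], ncol = 4)
  u0 <- used - 1L
  nix <- u0 %% ld[1]
  niy <- (u0 %/% ld[1]) %% ld[2]
  niz <- u0 %/% (ld[1] * ld[2])
  nodes <- cbind(grid_origin[1] + nix * cell_mm[1],
                 grid_origin[2] + niy * cell_mm[2],
                 grid_origin[3] + niz * cell_mm[3])
  ## voxel-center -> element assignment (exact for the Kuhn split)
  vx <- (seq_len(dims[1]) - 0.5) * sp[1]
  vy <- (seq_len(dims[2]) - 0.5) * sp[2]
  vz <- (seq_len(dims[3]) - 0.5) * sp[3]
  u1 <- (vx - grid_origin[1] - cix * cell_mm[1]) / cell_mm[1]
  u2 <- (vy - grid_origin[2] - ciy * cell_mm[2]) / cell_mm[2]
  u3 <- (vz - grid_origin[3] - ciz * cell_mm[3]) / cell_mm[3]
  U1 <- array(u1, dims); U2 <- aperm(array(u2, dims[c(2, 1, 3)]), c(2, 1, 3))
  U3 <- aperm(array(u3, dims[c(3, 1, 2)]), c(2, 3, 1))
  crk <- cell_rank[cell_of]
  sel <- crk > 0L
  tet <- integer(prod(dims))
  tet[sel] <- .kuhn_tet_of(U1[sel], U2[sel], U3[sel])
  voxel_assignment <- integer(prod(dims))
  voxel_assignment[sel] <- (crk[sel] - 1L) * 6L + tet[sel]
  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  structure(list(
    nodes = nodes, elements = elements,
    element_material = seq_len(nrow(elements)),
    boundary = list(inferior = which(abs(nodes[, 3] - zmin) < 1e-9),
                    superior = which(abs(nodes[, 3] - zmax) < 1e-9)),
    cell_mm = cell_mm, edge_length_mm = edge_length_mm,
    voxel_assignment = voxel_assignment, grid_dim = dims
  ), class = "tet_mesh")
}

#' Signed tetrahedron volumes
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector of element volumes (mm^3), positive for a
#'   consistently oriented mesh.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  a <- n[e[, 2], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  b <- n[e[, 3], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  c_ <- n[e[, 4], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

## Face multiset of a mesh: each face as a sorted node triple.
mesh_faces <- function(mesh) {
  e <- mesh$elements
  f <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)],
             e[, c(1, 3, 4)], e[, c(2, 3, 4)])
  t(apply(f, 1, sort))
}

#' Mesh convergence study
#'
#' Meshes the same masked volume at a sequence of target edge lengths,
#' runs the full material mapping and compression solve at each, and
#' reports failure load/displacement with the relative change between
#' successive levels.
#'
#' @param ct a `ct_volume`.
#' @param mask a `seg_mask`.
#' @param edge_lengths_mm numeric vector of edge lengths, mm.
#' @param max_disp_frac prescribed displacement as a fraction of
#'   specimen height (default 0.02).
#' @param n_increments loading increments per solve.
#' @param ... further arguments passed to [run_compression()].
#' @return data.frame with columns `edge_length_mm`, `n_elements`,
#'   `failure_load_N`, `failure_displacement_mm`, `rel_change_load`.
#' @export
convergence_study <- function(ct, mask,
                              edge_lengths_mm = c(1.0, 1.5, 2.0, 2.5, 3.0),
                              max_disp_frac = 0.02, n_increments = 40,
                              ...) {
  rows <- lapply(edge_lengths_mm, function(el) {
    mesh <- mask_to_mesh(mask, ct, el)
    cards <- map_elements(ct, mesh)
    height <- diff(range(mesh$nodes[, 3]))
    res <- tryCatch(
      run_compression(mesh, cards,
                      max_displacement_mm = max_disp_frac * height,
                      n_increments = n_increments, ...),
      error = function(e) stop("solve failed at edge length ", el, " mm: ",
                               conditionMessage(e)))
    data.frame(edge_length_mm = el, n_elements = nrow(mesh$elements),
               failure_load_N = res$failure_load,
               failure_displacement_mm = res$failure_displacement)
  })
  out <- do.call(rbind, rows)
  out$rel_change_load <- c(NA, abs(diff(out$failure_load_N)) /
                             out$failure_load_N[-nrow(out)])
  out
}

#' Export a mesh as ASCII VTK unstructured grid (.vtu)
#'
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @export
write_mesh_vtu <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">'),
    con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  writeLines(c('</DataArray></Points>', '<Cells>',
    '<DataArray type="Int64" Name="connectivity" format="ascii">'), con)
  writeLines(apply(mesh$elements - 1L, 1, paste, collapse = " "), con)
  writeLines('</DataArray>', con)
  writeLines('<DataArray type="Int64" Name="offsets" format="ascii">', con)
  writeLines(paste(seq_len(m) * 4L, collapse = " "), con)
  writeLines(c('</DataArray>',
    '<DataArray type="UInt8" Name="types" format="ascii">',
    paste(rep(10L, m), collapse = " "),
    '</DataArray>', '</Cells>', '</Piece>',
    '</UnstructuredGrid>', '</VTKFile>'), con)
  invisible(path)
}

#' Export a mesh as Abaqus INP (nodes, C3D4 elements, surface node sets)
#'
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @export
write_mesh_inp <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.6f, %.6f, %.6f", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4]), con)
  for (s in c("inferior", "superior")) {
    writeLines(sprintf("*NSET, NSET=%s_surface", toupper(s)), con)
    writeLines(paste(strwrap(paste(mesh$boundary[[s]], collapse = ", "), 72),
                     collapse = "\n"), con)
  }
  invisible(path)
}
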