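test_that("compliance matrices are symmetric positive definite over the
          physiological density range under both Poisson conventions", {
  rho <- c(0.01, 0.05, 0.137, 0.3, 0.6, 1.0, 1.4)
  for (conv in c("load-first", "load-second")) {
    cards <- material_card((rho * 1000 - 47) / 1.122)
    for (i in seq_along(rho)) {
      S <- compliance_matrix(cards[i, ], conv)
      expect_equal(S, t(S))
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("a free-floating mesh has exactly six rigid-body modes", {
  ct <- make_uniform_ct(c(4, 4, 4), hu = 500)
  mesh <- mask_to_mesh(make_full_mask(c(4, 4, 4)), ct, 2)
  cards <- map_elements(ct, mesh)
  K <- as.matrix(assemble(mesh, cards))
  ev <- sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(ev[1:6])), 1e-8 * ev[7])
  expect_gt(ev[7], 0)
})

test_that("stiffness is linear in the moduli", {
  ct <- make_uniform_ct(c(4, 4, 4), hu = 500)
  mesh <- mask_to_mesh(make_full_mask(c(4, 4, 4)), ct, 2)
  cards <- map_elements(ct, mesh)
  K1 <- assemble(mesh, cards)
  cards2 <- cards
  cards2[c("E_x", "E_y", "E_z", "G_xy", "G_xz", "G_yz")] <-
    2 * cards2[c("E_x", "E_y", "E_z", "G_xy", "G_xz", "G_yz")]
  K2 <- assemble(mesh, cards2)
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-12)
})

test_that("one-element stiffness matches an independently assembled
          textbook linear-tet matrix", {
  ## single tetrahedron, isotropic E = 1000 MPa, nu = 0.3
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mesh <- structure(list(nodes = nodes,
                         elements = matrix(1:4, 1),
                         boundary = list(inferior = 1:3, superior = 4L),
                         voxel_assignment = NULL), class = "tet_mesh")
  card <- isotropic_card(1000, 0.3)
  K <- as.matrix(assemble(mesh, card))
  ## independent route: shape gradients from the 4x4 coordinate matrix
  M <- cbind(1, nodes)
  C <- solve(M)              # rows 2..4 are d/dx, d/dy, d/dz of N_j
  V <- abs(det(M)) / 6
  B <- matrix(0, 6, 12)
  for (j in 1:4) {
    g <- C[2:4, j]
    B[1, 3 * j - 2] <- g[1]; B[2, 3 * j - 1] <- g[2]; B[3, 3 * j] <- g[3]
    B[4, 3 * j - 2] <- g[2]; B[4, 3 * j - 1] <- g[1]
    B[5, 3 * j - 2] <- g[3]; B[5, 3 * j] <- g[1]
    B[6, 3 * j - 1] <- g[3]; B[6, 3 * j] <- g[2]
  }
  E <- 1000; nu <- 0.3
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam, 3), rep(0, 3))) + diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- lam + diag(rep(2 * mu, 3))
  Kref <- V * t(B) %*% D %*% B
  expect_equal(K, unname(Kref), tolerance = 1e-10)
})

test_that("closed-form principal stresses agree with eigen decomposition", {
  set.seed(7)
  for (i in 1:200) {
    v <- rnorm(6, sd = 10)
    S <- matrix(c(v[1], v[4], v[5],
                  v[4], v[2], v[6],
                  v[5], v[6], v[3]), 3, 3)
    ref <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    got <- spinefea:::principal_stresses(matrix(v, 1))
    expect_equal(as.numeric(got), ref, tolerance = 1e-8)
  }
})

test_that("a homogeneous cuboid reproduces the uniaxial closed forms", {
  ct <- make_uniform_ct()
  mesh <- mask_to_mesh(make_full_mask(), ct, 2)
  cards <- isotropic_card(1000, 0, sigma_max = Inf, sigma_min = 10,
                          eps_AB = 0.005, n = nrow(mesh$elements))
  res <- run_compression(mesh, cards, max_displacement_mm = 0.2,
                         n_increments = 40)
  ## elastic slope E A / L = 1000 * 100 / 10
  expect_equal(res$elastic_slope, 10000, tolerance = 0.02)
  ## failure load sigma_min * A
  expect_equal(unname(res$failure_load), 1000, tolerance = 0.05)
  expect_true(res$failure_reached)
})

test_that("reaction forces balance between surfaces at every increment", {
  ph <- make_vertebra_phantom(phantom_truth("osteoporotic", seed = 5))
  mesh <- mask_to_mesh(ph$mask, ph$ct, 2.5)
  cards <- map_elements(ph$ct, mesh)
  res <- run_compression(mesh, cards, max_displacement_mm = 0.2,
                         n_increments = 10, max_state_iter = 500)
  cv <- res$curve[-1, ]
  rel <- abs(cv$reaction_inferior_N + cv$reaction_superior_N) /
    pmax(abs(cv$reaction_superior_N), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("the elastic slope is independent of increment size", {
  ct <- make_uniform_ct()
  mesh <- mask_to_mesh(make_full_mask(), ct, 2)
  cards <- isotropic_card(800, 0.25, n = nrow(mesh$elements))
  r1 <- run_compression(mesh, cards, 0.05, n_increments = 10)
  r2 <- run_compression(mesh, cards, 0.05, n_increments = 20)
  expect_equal(r1$elastic_slope, r2$elastic_slope, tolerance = 1e-3)
})

test_that("scaling all moduli and strengths scales the failure load", {
  ct <- make_uniform_ct()
  mesh <- mask_to_mesh(make_full_mask(), ct, 2)
  n <- nrow(mesh$elements)
  base <- isotropic_card(1000, 0.1, sigma_max = Inf, sigma_min = 8,
                         eps_AB = 0.004, n = n)
  scaled <- isotropic_card(3000, 0.1, sigma_max = Inf, sigma_min = 24,
                           eps_AB = 0.004, n = n)
  r1 <- run_compression(mesh, base, 0.2, n_increments = 40,
                        max_state_iter = 200)
  r2 <- run_compression(mesh, scaled, 0.2, n_increments = 40,
                        max_state_iter = 200)
  expect_equal(r2$failure_load / r1$failure_load, 3, tolerance = 0.01)
  expect_equal(r2$failure_displacement, r1$failure_displacement,
               tolerance = 0.01)
})

test_that("a rigid-bonded platen is at least as stiff as the free platen", {
  ct <- make_uniform_ct()
  mesh <- mask_to_mesh(make_full_mask(), ct, 2)
  cards <- isotropic_card(1000, 0.3, n = nrow(mesh$elements))
  free <- run_compression(mesh, cards, 0.05, n_increments = 10)
  bonded <- run_compression(mesh, cards, 0.05, n_increments = 10,
                            bonded = TRUE)
  expect_gte(bonded$elastic_slope, free$elastic_slope * (1 - 1e-9))
})

test_that("failure extraction follows the first-peak-with-drop rule", {
  inc <- data.frame(displacement_mm = 0:4 / 10, force_N = c(0, 1, 2, 3, 4))
  expect_equal(unname(extract_failure(inc)), c(4, 0.4))  # no drop: last
  pk <- data.frame(displacement_mm = c(0, 0.25, 0.5, 0.75),
                   force_N = c(0, 600, 1000, 900))
  expect_equal(unname(extract_failure(pk)), c(1000, 0.5))
  two <- data.frame(displacement_mm = seq(0, 0.5, by = 0.1),
                    force_N = c(0, 500, 800, 700, 1100, 1200))
  expect_equal(unname(extract_failure(two)), c(800, 0.2))  # first peak wins
  flat0 <- data.frame(displacement_mm = c(0, 0.1), force_N = c(0, 0))
  expect_error(extract_failure(flat0), "degenerate")
})

test_that("zero prescribed displacement reports failure as not reached", {
  ct <- make_uniform_ct(c(4, 4, 4))
  mesh <- mask_to_mesh(make_full_mask(c(4, 4, 4)), ct, 2)
  cards <- isotropic_card(1000, 0, n = nrow(mesh$elements))
  res <- run_compression(mesh, cards, 0)
  expect_equal(nrow(res$curve), 1)
  expect_true(is.na(res$failure_load))
  expect_false(res$failure_reached)
})
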