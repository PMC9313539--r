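test_that("phantom generation is deterministic given the seed", {
  t1 <- phantom_truth("osteoporotic", seed = 9)
  a <- make_vertebra_phantom(t1)
  b <- make_vertebra_phantom(t1)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$mask$labels, b$mask$labels)
  c_ <- make_vertebra_phantom(phantom_truth("osteoporotic", seed = 10))
  expect_false(identical(a$ct$data, c_$ct$data))
})

## voxel selector for the deep interior, clear of the shell and of the
## scanner-blur transition band
deep_interior <- function(ph, clear_mm = 3) {
  tr <- ph$truth; sp <- tr$spacing_mm
  d <- dim(ph$ct$data)
  xs <- (seq_len(d[1]) - 0.5) * sp; ys <- (seq_len(d[2]) - 0.5) * sp
  zs <- (seq_len(d[3]) - 0.5) * sp
  cx <- d[1] * sp / 2; cy <- d[2] * sp / 2
  z0 <- (d[3] * sp - tr$height_mm) / 2
  rx <- tr$semi_axis_x - tr$shell_mm - clear_mm
  ry <- tr$semi_axis_y - tr$shell_mm - clear_mm
  inxy <- outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, "+") <= 1
  inz <- zs >= z0 + tr$shell_mm + clear_mm &
    zs <= z0 + tr$height_mm - tr$shell_mm - clear_mm
  outer(inxy, inz, "&")
}

test_that("the deep trabecular interior has the requested HU distribution", {
  ph <- make_vertebra_phantom(phantom_truth("osteoporotic", seed = 2))
  interior <- ph$ct$data[deep_interior(ph)]
  expect_gt(length(interior), 20^3)
  expect_lt(abs(mean(interior) - 80), 3)   # law of large numbers
  ## degenerate noise: exactly constant deep interior (the scanner
  ## blur preserves constants away from gradients)
  flat <- make_vertebra_phantom(
    phantom_truth("osteoporotic", trabecular_hu_sd = 0, seed = 2))
  expect_equal(max(abs(flat$ct$data[deep_interior(flat)] - 80)), 0)
})

test_that("phantom HU stay in CT range and the mask covers the solid", {
  for (cond in c("osteoporotic", "osteoblastic")) {
    ph <- make_vertebra_phantom(phantom_truth(cond, seed = 4))
    expect_true(all(ph$ct$data >= -1024 & ph$ct$data <= 3071))
    ## far-field air is untouched; solid voxels always exceed air
    expect_equal(ph$ct$data[1, 1, 1], -1000)
    expect_true(all(ph$ct$data[ph$mask$labels > 0] > -1000))
    ## the mask is exactly the geometric solid, independent of blur
    sharp <- make_vertebra_phantom(
      phantom_truth(cond, seed = 4, psf_fwhm_mm = 0))
    expect_identical(ph$mask$labels, sharp$mask$labels)
    expect_true(all(sharp$ct$data[sharp$mask$labels == 0] == -1000))
  }
})

test_that("oversized geometry is rejected", {
  expect_error(make_vertebra_phantom(
    phantom_truth(shell_hu = 1200, trabecular_hu_mean = 80,
                  semi_axis_x = -1)), "semi_axis_x")
})

test_that("echo generation covers the pure-water and pure-fat limits", {
  z <- array(0, c(2, 2, 1))
  water <- make_cse_echoes(z, z, z)
  expect_equal(apply(Mod(water$signal), 1:3, stats::sd),
               array(0, c(2, 2, 1)))
  fat <- make_cse_echoes(array(1, dim(z)), z, z)
  spec <- fat$spectrum
  cF <- colSums(spec$amplitude *
                  exp(1i * 2 * pi * outer(spec$freq_hz,
                                          fat$echo_times_ms * 1e-3)))
  expect_equal(as.numeric(Mod(fat$signal[1, 1, 1, ])), Mod(cF))
  expect_true(all(Mod(fat$signal) <= 1 + 1e-12))
})

test_that("echo magnitudes decay at the closed-form R2* rate", {
  z <- array(0, c(1, 1, 1))
  es <- make_cse_echoes(z, array(50, dim(z)), z)
  ratio <- Mod(es$signal[1, 1, 1, 6]) / Mod(es$signal[1, 1, 1, 1])
  expect_equal(ratio, exp(-0.05 * (5.92 - 1.12)), tolerance = 1e-12)
})

test_that("echo generator validates shapes and is seed-deterministic", {
  z <- array(0.3, c(2, 2, 2))
  expect_error(make_cse_echoes(z, array(0, c(2, 2, 1)), z), "shape")
  e1 <- make_cse_echoes(z, z * 0, z * 0, snr = 30, seed = 5)
  e2 <- make_cse_echoes(z, z * 0, z * 0, snr = 30, seed = 5)
  expect_identical(e1$signal, e2$signal)
  e3 <- make_cse_echoes(z, z * 0, z * 0, snr = 30, seed = 6)
  expect_false(identical(e1$signal, e3$signal))
})

test_that("the packaged fixture matches its reference rows", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 28)
  expect_equal(sum(tab$fractured), 5)
  r11 <- tab[tab$patient_id == 1 & tab$level == "L1", ]
  expect_equal(r11$pdff_percent, 24.1)
  expect_equal(r11$failure_displacement_mm, 1.027)
  expect_equal(r11$failure_load_N, 19735)
  r62 <- tab[tab$patient_id == 6 & tab$level == "L2", ]
  expect_equal(r62$pdff_percent, 8.1)
  expect_true(r62$fractured)
  expect_equal(sort(tab$level[tab$patient_id == 4 & tab$fractured]),
               c("L2", "L3"))
  expect_equal(tab$level[tab$patient_id == 5 & tab$fractured], "L4")
})

test_that("synthetic cohorts are deterministic and carry the group effect", {
  c1 <- make_cohort(3, 4, seed = 1)
  c2 <- make_cohort(3, 4, seed = 1)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 28)
  ## null profile: group medians differ only by sampling noise
  null <- make_cohort(40, 40, cohort_effect_profile(effect = 0), seed = 3)
  md <- tapply(null$pdff_percent, null$group, median)
  expect_lt(abs(log(md[[1]] / md[[2]])), 0.25)
  ## default profile: direction of effect stable across seeds
  hits <- 0
  for (s in 1:100) {
    co <- make_cohort(10, 10, seed = s)
    md <- tapply(co$pdff_percent, co$group, median)
    if (md[["metastasis"]] < md[["osteoporosis"]]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("noiseless generated echoes invert to the true fat fraction", {
  ## round-trip between the generator and the voxel fitter
  dims <- c(3, 3, 1)
  pdff <- array(seq(0.05, 0.85, length.out = 9), dims)
  r2 <- array(35, dims); fm <- array(-20, dims)
  es <- make_cse_echoes(pdff, r2, fm)
  fit <- fit_voxels(matrix(es$signal, prod(dims)),
                    es$echo_times_ms, es$spectrum)
  expect_lt(max(abs(fit$pdff_percent - 100 * c(pdff))), 1e-6)
})
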