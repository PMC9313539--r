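## Shared fixtures: small deterministic volumes built in code.

make_uniform_ct <- function(dims = c(10, 10, 10), hu = 500,
                            spacing = c(1, 1, 1)) {
  structure(list(data = array(hu, dims), spacing = spacing,
                 affine = diag(c(spacing, 1)),
                 axis_convention = "z-superior"),
            class = "ct_volume")
}

make_full_mask <- function(dims = c(10, 10, 10)) {
  structure(list(labels = array(1L, dims), level_map = c(L1 = 1L)),
            class = "seg_mask")
}

## random blocky mask: union of a base slab plus random cuboids
make_random_mask <- function(dims = c(12, 12, 12), seed = 1) {
  set.seed(seed)
  lab <- array(0L, dims)
  lab[3:10, 3:10, 2:11] <- 1L
  for (i in 1:3) {
    lo <- pmax(1, floor(runif(3) * (dims - 4)))
    hi <- pmin(dims, lo + 2 + floor(runif(3) * 4))
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  }
  structure(list(labels = lab, level_map = c(L1 = 1L)), class = "seg_mask")
}

## Mann-Whitney U by brute-force pair counting (independent oracle)
brute_force_U <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

## Spearman rho via the exact rank-difference formula (no ties)
brute_force_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x)^3 - length(x))
}
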