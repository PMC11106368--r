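# Shared fixtures, built once per test run. The cohorts are small phantom
# sets under fixed seeds; heavy models are trained only in the acceptance
# file.

.fx <- new.env()

fixture_case <- function(seed = 1L, site = "A") {
  key <- sprintf("case_%d_%s", seed, site)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- makePhantom(phantomSpec(seed = seed, site = site))
  .fx[[key]]
}

fixture_cohort <- function(n = 6L, baseSeed = 7L, site = "A") {
  key <- sprintf("cohort_%d_%d_%s", n, baseSeed, site)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- makeCohort(n, baseSeed, site)
  .fx[[key]]
}

# A small volume with deterministic content on a given grid
tiny_volume <- function(d = c(8, 8, 8), vox = 1, seed = 99) {
  set.seed(seed)
  BrainVolume(array(stats::rnorm(prod(d)), d), voxelSize = vox)
}

# Build a binary mask from voxel index triples (1-based)
mask_from_idx <- function(d, idx, vox = 1) {
  a <- array(0, d)
  a[idx] <- 1
  BinaryMask(a, voxelSize = vox)
}

# The brainstem scoring window used for ELV experiments on phantoms
phantom_elv_window <- function() c(-9, 9, -9, 1, -14, 10)
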