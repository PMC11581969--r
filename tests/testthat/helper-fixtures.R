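# Shared fixtures: small cohort specs and toy volumes built in code.

# small, fast spec for unit tests (not the study-condition defaults)
small_spec <- function(seed = 1L, n = 4L, ...) {
  cohort_spec(n_patients = n, volume_shape = c(32L, 32L, 32L),
              tumor_radius_range = c(7, 9), seed = seed, ...)
}

# a deterministic random volume + all-ones mask
toy_volume <- function(dm = c(6L, 5L, 4L), spacing = c(1, 1, 1), seed = 42L,
                       phase = "ACE") {
  set.seed(seed)
  image_volume(array(rnorm(prod(dm), 50, 30), dm), spacing, phase = phase)
}

# axis-aligned solid cuboid mask inside a volume
cuboid_mask <- function(dm, from, to, spacing = c(1, 1, 1)) {
  m <- array(0L, dm)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  roi_mask(m, spacing)
}

# a ball mask of radius r (in mm) centered in the volume
ball_mask <- function(dm, r, spacing = c(1, 1, 1)) {
  ax <- lapply(1:3, function(i) ((seq_len(dm[i]) - 1) * spacing[i]) -
                 (dm[i] - 1) * spacing[i] / 2)
  d <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  roi_mask(array(as.integer(d <= r), dm), spacing)
}
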