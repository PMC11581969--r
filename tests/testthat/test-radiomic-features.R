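# IBSI-style feature extraction: degenerate fields, geometry, texture
# oracles, fusion accounting, invariances.

cfg <- feature_config()

test_that("constant regions give zero variance / contrast and defined
           limiting texture values", {
  dm <- c(12L, 12L, 12L)
  v <- normalize_intensity(image_volume(array(50, dm)))
  m <- cuboid_mask(dm, c(3, 3, 3), c(9, 9, 9))
  f <- extract_region_features(v, m, cfg)
  expect_equal(unname(f["firstorder__variance"]), 0)
  expect_equal(unname(f["glcm__contrast"]), 0)
  expect_equal(unname(f["glcm__joint_entropy"]), 0)
  expect_equal(unname(f["glcm__energy"]), 1)
  expect_equal(unname(f["ngtdm__contrast"]), 0)
  expect_false(anyNA(f))
})

test_that("shape features match analytic values on a 10 mm cube", {
  dm <- c(16L, 16L, 16L)
  v <- normalize_intensity(image_volume(array(rnorm(prod(dm), 50, 10), dm)))
  m <- cuboid_mask(dm, c(4, 4, 4), c(13, 13, 13))   # 10x10x10 voxels at 1 mm
  f <- extract_region_features(v, m, cfg)
  expect_equal(unname(f["shape__volume_mm3"]), 1000)
  expect_equal(unname(f["shape__surface_area_mm2"]), 600)
  expect_equal(unname(f["shape__sphericity"]),
               (36 * pi * 1000^2)^(1 / 3) / 600, tolerance = 1e-9)
  expect_equal(unname(f["shape__maximum_3d_diameter"]), sqrt(3 * 81),
               tolerance = 1e-9)
  # elongation/flatness of a cube: 1 (all eigenvalues equal)
  expect_equal(unname(f["shape__elongation"]), 1, tolerance = 1e-9)
})

test_that("GLCM joint entropy matches a brute-force co-occurrence oracle on
           a checkerboard slice", {
  # 4x4 checkerboard embedded as a single-slice 3D region
  dm <- c(6L, 6L, 3L)
  vals <- array(0, dm)
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)   # 0/1 pattern
  vals[2:5, 2:5, 2] <- ifelse(cb == 1, 100, -100)
  v <- normalize_intensity(image_volume(vals))
  m <- array(0L, dm); m[2:5, 2:5, 2] <- 1L
  f <- extract_region_features(v, roi_mask(m), cfg)
  # oracle: enumerate symmetric co-occurrences over the same 13 directions
  g <- array(0L, dm)
  g[m == 1L] <- habitatrad:::quantize_gray(v$values[m == 1L], cfg)
  dirs <- habitatrad:::direction_offsets_13()
  pairs <- c()
  for (x in 1:6) for (y in 1:6) for (z in 1:3) {
    if (g[x, y, z] == 0) next
    for (r in seq_len(nrow(dirs))) {
      q <- c(x, y, z) + dirs[r, ]
      if (any(q < 1) || any(q > dm)) next
      if (g[q[1], q[2], q[3]] == 0) next
      pairs <- c(pairs, paste(g[x, y, z], g[q[1], q[2], q[3]]),
                 paste(g[q[1], q[2], q[3]], g[x, y, z]))
    }
  }
  pr <- table(pairs) / length(pairs)
  oracle_entropy <- -sum(pr * log2(pr))
  expect_equal(unname(f["glcm__joint_entropy"]), oracle_entropy,
               tolerance = 1e-9)
})

test_that("GLRLM run counts match a line-walking oracle", {
  set.seed(50)
  dm <- c(5L, 5L, 3L)
  g <- array(sample(0:3, prod(dm), replace = TRUE), dm)  # 0 = outside
  cfgl <- feature_config()
  R <- habitatrad:::glrlm_matrix(g, cfgl)
  # oracle: walk every line in every direction, voxel by voxel
  dirs <- habitatrad:::direction_offsets_13()
  oracle <- matrix(0, cfgl$n_levels, max(dm))
  inb <- function(q) all(q >= 1) && all(q <= dm)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    for (x in 1:5) for (y in 1:5) for (z in 1:3) {
      p0 <- c(x, y, z)
      gv <- g[x, y, z]
      if (gv == 0) next
      prev <- p0 - d
      if (inb(prev) && g[prev[1], prev[2], prev[3]] == gv) next  # not a start
      len <- 1L; q <- p0 + d
      while (inb(q) && g[q[1], q[2], q[3]] == gv) {
        len <- len + 1L; q <- q + d
      }
      oracle[gv, len] <- oracle[gv, len] + 1
    }
  }
  expect_equal(R, oracle)
})

test_that("GLSZM zones match a flood-fill oracle", {
  set.seed(51)
  dm <- c(6L, 6L, 4L)
  g <- array(sample(0:2, prod(dm), replace = TRUE, prob = c(0.3, 0.4, 0.3)),
             dm)
  z <- habitatrad:::glszm_zones(g)
  # oracle: stack-based flood fill with 26-connectivity per gray level
  visited <- array(FALSE, dm)
  offs <- habitatrad:::neighbor_offsets(26L)
  zones <- data.frame(gray = integer(), size = integer())
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z0 in 1:dm[3]) {
    if (g[x, y, z0] == 0 || visited[x, y, z0]) next
    gv <- g[x, y, z0]
    stack <- list(c(x, y, z0)); visited[x, y, z0] <- TRUE; size <- 0L
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- q + offs[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (visited[nb[1], nb[2], nb[3]]) next
        if (g[nb[1], nb[2], nb[3]] != gv) next
        visited[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
    zones <- rbind(zones, data.frame(gray = gv, size = size))
  }
  key <- function(df) sort(paste(df$gray, df$size))
  expect_equal(key(z), key(zones))
})

test_that("NGTDM size/sums match a direct neighborhood oracle", {
  set.seed(52)
  dm <- c(5L, 5L, 4L)
  g <- array(sample(0:3, prod(dm), replace = TRUE), dm)
  f <- habitatrad:::ngtdm_features(g, feature_config())
  # oracle coarseness via explicit loops
  offs <- habitatrad:::neighbor_offsets(26L)
  diffs <- c(); grays <- c()
  for (x in 1:5) for (y in 1:5) for (z in 1:4) {
    if (g[x, y, z] == 0) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (any(q < 1) || any(q > dm)) next
      if (g[q[1], q[2], q[3]] > 0) nb <- c(nb, g[q[1], q[2], q[3]])
    }
    if (length(nb)) {
      diffs <- c(diffs, abs(g[x, y, z] - mean(nb)))
      grays <- c(grays, g[x, y, z])
    }
  }
  nvp <- length(grays)
  s_i <- tapply(diffs, grays, sum)
  p_i <- as.vector(table(grays)) / nvp
  oracle_coarseness <- 1 / sum(p_i * s_i)
  expect_equal(unname(f["coarseness"]), oracle_coarseness, tolerance = 1e-9)
})

test_that("whole-voxel translation leaves intensity and texture features
           unchanged; shape is identical between phases", {
  dm <- c(20L, 20L, 20L)
  set.seed(53)
  block <- array(rnorm(6 * 5 * 4, 60, 25), c(6, 5, 4))
  v1 <- array(-80, dm); v1[3:8, 4:8, 5:8] <- block
  m1 <- array(0L, dm); m1[3:8, 4:8, 5:8] <- 1L
  v2 <- array(-80, dm); v2[9:14, 8:12, 10:13] <- block
  m2 <- array(0L, dm); m2[9:14, 8:12, 10:13] <- 1L
  f1 <- extract_region_features(normalize_intensity(image_volume(v1)),
                                roi_mask(m1), cfg)
  f2 <- extract_region_features(normalize_intensity(image_volume(v2)),
                                roi_mask(m2), cfg)
  expect_equal(f1, f2, tolerance = 1e-12)
  # same region, different phases: shape block identical
  vv <- normalize_intensity(image_volume(v1 + 10, phase = "VCE"))
  fv <- extract_region_features(vv, roi_mask(m1), cfg)
  sh <- grep("^shape__", names(f1), value = TRUE)
  expect_equal(f1[sh], fv[sh], tolerance = 1e-12)
})

test_that("table extraction: identical columns across patients, correct
           accounting, averaged mode equals the manual habitat mean", {
  sp <- small_spec(seed = 60, n = 2L)
  pats <- lapply(1:2, function(i) generate_patient(sp, i))
  pre <- lapply(pats, function(p) {
    pp <- preprocess_patient(p$ace_volume, p$vce_volume, p$roi)
    list(id = p$patient_id, ace = pp$ace, vce = pp$vce, roi = pp$roi)
  })
  maps <- lapply(pre, function(pp) {
    segment_patient(pp$ace, pp$vce, pp$roi, seed = 1)
  })
  maps <- remap_labels(maps)$maps
  rad <- extract_rad_table(pre, cfg)
  expect_equal(nrow(rad), 2L)
  f_per <- length(extract_region_features(pre[[1]]$ace, pre[[1]]$roi, cfg))
  expect_equal(ncol(rad), rad_feature_count(f_per))
  hab <- extract_habitat_table(pre, maps, k = 3, config = cfg)
  expect_equal(ncol(hab), habitat_feature_count(f_per, 3, 2))
  avg <- extract_habitat_table(pre, maps, k = 3, mode = "averaged",
                               config = cfg)
  expect_equal(ncol(avg), rad_feature_count(f_per))
  # manual mean over habitats equals averaged mode, elementwise
  feat <- sub("^ACE__habitatmean__", "", colnames(avg)[1])
  manual <- rowMeans(hab[, paste0("ACE__habitat", 1:3, "__", feat)])
  expect_equal(unname(avg[, paste0("ACE__habitatmean__", feat)]),
               unname(manual), tolerance = 1e-12)
  # identical feature value in all habitats -> averaged equals that value
  one <- hab[1, paste0("ACE__habitat", 1:3, "__", feat)]
  if (length(unique(one)) > 1) {
    expect_equal(unname(avg[1, paste0("ACE__habitatmean__", feat)]),
                 mean(one), tolerance = 1e-12)
  }
})

test_that("fusion machinery reproduces the published feature accounting at
           F = 1834", {
  f <- 1834L
  blocks <- list()
  for (ph in c("ACE", "VCE")) {
    for (h in 1:3) {
      blocks[[paste0(ph, "__habitat", h)]] <-
        setNames(rep(0, f), paste0("fam__f", seq_len(f)))
    }
  }
  fused <- fuse_early(blocks)
  expect_equal(length(fused), 11004L)
  expect_equal(habitat_feature_count(f, 3, 2), 11004L)
  expect_equal(rad_feature_count(f, 2), 3668L)
  expect_error(fuse_early(list(A = c(x = 1), A2 = c(x = 2))), NA)
  expect_error(fuse_early(list(A = c(x = 1, x = 2))), "unique")
})
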