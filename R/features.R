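# IBSI-style radiomic features: first-order, 3D shape, and texture matrices
# (GLCM, GLRLM, GLSZM, NGTDM) computed on quantized normalized intensities,
# for whole-ROI ("Rad") and per-habitat ("Habitat") extraction with early
# fusion across phases.

#' Radiomic extraction configuration
#'
#' Fixes gray-level quantization and the feature families to extract, so a
#' table's feature count F per region and phase is fully determined by the
#' config.
#'
#' @param bin_width gray-level bin width applied after rescaling.
#' @param rescale factor mapping normalized \[0,1\] intensities onto the
#'   quantization scale; the default (500, bin width 25) yields 20 gray
#'   levels.
#' @param families feature families to extract.
#' @param max_boundary_points cap on boundary voxels used for the exact
#'   maximum-3D-diameter scan (larger surfaces are deterministically
#'   subsampled).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(bin_width = 25, rescale = 500,
                           families = c("firstorder", "shape", "glcm",
                                        "glrlm", "glszm", "ngtdm"),
                           max_boundary_points = 600L) {
  families <- match.arg(families, several.ok = TRUE)
  if (bin_width <= 0 || rescale <= 0) stop("bin_width and rescale must be > 0")
  structure(list(bin_width = bin_width, rescale = rescale,
                 families = families,
                 n_levels = as.integer(ceiling(rescale / bin_width)),
                 max_boundary_points = as.integer(max_boundary_points)),
            class = "feature_config")
}

quantize_gray <- function(x, cfg) {
  g <- floor(x * cfg$rescale / cfg$bin_width) + 1
  as.integer(pmin(pmax(g, 1L), cfg$n_levels))
}

fo_features <- function(x, cfg) {
  n <- length(x)
  g <- quantize_gray(x, cfg)
  p <- tabulate(g, cfg$n_levels) / n
  p <- p[p > 0]
  c(mean = mean(x), median = median(x), minimum = min(x), maximum = max(x),
    range = max(x) - min(x),
    p10 = unname(quantile(x, 0.10, type = 7)),
    p90 = unname(quantile(x, 0.90, type = 7)),
    iqr = unname(IQR(x, type = 7)),
    variance = mean((x - mean(x))^2),
    skewness = sample_skewness(x),
    kurtosis = sample_kurtosis(x),
    mad = mean(abs(x - mean(x))),
    rms = sqrt(mean(x^2)),
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2))
}

shape_features <- function(msk, spacing, cfg) {
  n <- sum(msk)
  vol <- n * prod(spacing)
  dm <- dim(msk)
  # surface area from exposed voxel faces
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    for (sgn in c(1L, -1L)) {
      nb <- array_shift(msk, sgn * d)
      nb[is.na(nb)] <- FALSE
      area <- area + sum(msk & !nb) * face_area[ax]
    }
  }
  co <- arrayInd(which(msk), dm)
  coords <- sweep(co, 2, spacing, `*`)
  if (n > 1L) {
    cc <- sweep(coords, 2, colMeans(coords))
    ev <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # exact max diameter over boundary voxels (subsampled when very large)
  inner <- msk
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    for (sgn in c(1L, -1L)) {
      nb <- array_shift(msk, sgn * d)
      nb[is.na(nb)] <- FALSE
      inner <- inner & nb
    }
  }
  bidx <- which(msk & !inner)
  if (!length(bidx)) bidx <- which(msk)
  if (length(bidx) > cfg$max_boundary_points) {
    bidx <- bidx[seq(1L, length(bidx),
                     length.out = cfg$max_boundary_points)]
  }
  bc <- sweep(arrayInd(bidx, dm), 2, spacing, `*`)
  maxdiam <- if (nrow(bc) > 1L) {
    sqrt(max(as.vector(stats::dist(bc))^2))
  } else 0
  sphericity <- if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 0
  c(volume_mm3 = vol,
    surface_area_mm2 = area,
    surface_volume_ratio = if (vol > 0) area / vol else 0,
    sphericity = sphericity,
    compactness = if (area > 0) 36 * pi * vol^2 / area^3 else 0,
    maximum_3d_diameter = maxdiam,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# symmetric co-occurrence counts merged over the 13 unique directions
glcm_matrix <- function(g, cfg) {
  ng <- cfg$n_levels
  counts <- matrix(0, ng, ng)
  dirs <- direction_offsets_13()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    nb <- array_shift(g, d)
    ok <- which(g > 0L & !is.na(nb) & nb > 0L)
    if (!length(ok)) next
    i <- g[ok]; j <- nb[ok]
    tab <- tabulate(i + (j - 1L) * ng, ng * ng)
    counts <- counts + matrix(tab, ng, ng)
  }
  counts + t(counts)
}

glcm_features <- function(g, cfg) {
  M <- glcm_matrix(g, cfg)
  tot <- sum(M)
  nm <- c("joint_maximum", "joint_average", "joint_variance", "joint_entropy",
          "contrast", "dissimilarity", "inverse_difference", "idm",
          "inverse_variance", "correlation", "autocorrelation",
          "cluster_tendency", "cluster_shade", "cluster_prominence",
          "energy", "sum_average", "sum_entropy", "difference_average",
          "difference_entropy")
  if (tot == 0) {
    warning("region too small for co-occurrence pairs; GLCM features missing")
    return(setNames(rep(NA_real_, length(nm)), nm))
  }
  P <- M / tot
  ng <- nrow(P)
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)
  J <- t(I)
  px <- rowSums(P)
  mu <- sum(iv * px)       # symmetric: mu_x == mu_y
  sig2 <- sum((iv - mu)^2 * px)
  pd <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))  # |i-j| = 0..
  dlev <- sort(unique(as.vector(abs(I - J))))
  ps <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  slev <- sort(unique(as.vector(I + J)))
  nz <- P > 0
  corr <- if (sig2 > 0) sum((I - mu) * (J - mu) * P) / sig2 else 1
  c(joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sum((I - mu)^2 * P),
    joint_entropy = -sum(P[nz] * log2(P[nz])),
    contrast = sum((I - J)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    inverse_difference = sum(P / (1 + abs(I - J))),
    idm = sum(P / (1 + (I - J)^2)),
    inverse_variance = sum(P[I != J] / (I - J)[I != J]^2),
    correlation = corr,
    autocorrelation = sum(I * J * P),
    cluster_tendency = sum((I + J - 2 * mu)^2 * P),
    cluster_shade = sum((I + J - 2 * mu)^3 * P),
    cluster_prominence = sum((I + J - 2 * mu)^4 * P),
    energy = sum(P^2),
    sum_average = sum(slev * ps),
    sum_entropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    difference_average = sum(dlev * pd),
    difference_entropy = -sum(pd[pd > 0] * log2(pd[pd > 0])))
}

# run-length counts merged over the 13 directions: matrix gray x run length
glrlm_matrix <- function(g, cfg) {
  dm <- dim(g)
  idx <- which(g > 0L)
  co <- arrayInd(idx, dm)
  gv <- g[idx]
  ng <- cfg$n_levels
  maxlen <- max(dm)
  R <- matrix(0, ng, maxlen)
  dirs <- direction_offsets_13()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    ax <- which(d != 0)[1]
    tpos <- co[, ax] * d[ax]
    key <- co - tpos %*% t(d) + maxlen   # shift keys to be strictly positive
    M <- 3 * maxlen + 2
    keyid <- key[, 1] + key[, 2] * M + key[, 3] * M^2
    ord <- order(keyid, tpos)
    ko <- keyid[ord]; to <- tpos[ord]; go <- gv[ord]
    n <- length(ord)
    newrun <- c(TRUE, ko[-1] != ko[-n] | to[-1] != to[-n] + 1L |
                  go[-1] != go[-n])
    rid <- cumsum(newrun)
    len <- tabulate(rid)
    gray <- go[newrun]
    tb <- tabulate(gray + (len - 1L) * ng, ng * maxlen)
    R <- R + matrix(tb, ng, maxlen)
  }
  R
}

glrlm_features <- function(g, cfg) {
  R <- glrlm_matrix(g, cfg)
  nr <- sum(R)
  np <- sum(g > 0L)
  ng <- nrow(R)
  jl <- seq_len(ncol(R))
  il <- seq_len(ng)
  p <- R / nr
  ri <- rowSums(R)  # per gray level
  rj <- colSums(R)  # per run length
  mu_i <- sum(il * rowSums(p))
  mu_j <- sum(jl * colSums(p))
  c(short_run_emphasis = sum(sweep(p, 2, jl^2, `/`)),
    long_run_emphasis = sum(sweep(p, 2, jl^2, `*`)),
    gray_level_nonuniformity = sum(ri^2) / nr,
    gray_level_nonuniformity_normalized = sum(ri^2) / nr^2,
    run_length_nonuniformity = sum(rj^2) / nr,
    run_length_nonuniformity_normalized = sum(rj^2) / nr^2,
    run_percentage = nr / (np * nrow(direction_offsets_13())),
    gray_level_variance = sum(sweep(p, 1, (il - mu_i)^2, `*`)),
    run_length_variance = sum(sweep(p, 2, (jl - mu_j)^2, `*`)),
    run_entropy = {pp <- p[p > 0]; -sum(pp * log2(pp))},
    low_gray_level_run_emphasis = sum(sweep(p, 1, il^2, `/`)),
    high_gray_level_run_emphasis = sum(sweep(p, 1, il^2, `*`)),
    short_run_low_gray_level_emphasis =
      sum(p / outer(il^2, jl^2)),
    short_run_high_gray_level_emphasis =
      sum(p * outer(il^2, 1 / jl^2)),
    long_run_low_gray_level_emphasis =
      sum(p * outer(1 / il^2, jl^2)),
    long_run_high_gray_level_emphasis =
      sum(p * outer(il^2, jl^2)))
}

# zones: connected components (26-connectivity) of constant gray level;
# returns per-zone gray level and size
glszm_zones <- function(g) {
  comp <- label_components(g, connectivity = 26L)
  ncmp <- max(comp)
  if (ncmp == 0L) return(data.frame(gray = integer(), size = integer()))
  size <- tabulate(comp[comp > 0], ncmp)
  gray <- g[match(seq_len(ncmp), comp)]
  data.frame(gray = as.integer(gray), size = size)
}

glszm_features <- function(g, cfg) {
  z <- glszm_zones(g)
  nz <- nrow(z)
  np <- sum(g > 0L)
  i <- z$gray; s <- z$size
  ngl <- as.vector(table(i))           # zones per gray level present
  nsz <- as.vector(table(s))           # zones per distinct size
  mu_i <- mean(i)
  mu_s <- mean(s)
  # joint cell counts for zone entropy
  key <- as.numeric(i) * 1e9 + as.numeric(s)
  cell <- as.vector(table(key)) / nz
  c(small_area_emphasis = mean(1 / s^2),
    large_area_emphasis = mean(s^2),
    gray_level_nonuniformity = sum(ngl^2) / nz,
    gray_level_nonuniformity_normalized = sum(ngl^2) / nz^2,
    size_zone_nonuniformity = sum(nsz^2) / nz,
    size_zone_nonuniformity_normalized = sum(nsz^2) / nz^2,
    zone_percentage = nz / np,
    gray_level_variance = mean((i - mu_i)^2),
    zone_size_variance = mean((s - mu_s)^2),
    zone_entropy = -sum(cell * log2(cell)),
    low_gray_level_zone_emphasis = mean(1 / i^2),
    high_gray_level_zone_emphasis = mean(i^2),
    small_area_low_gray_level_emphasis = mean(1 / (i^2 * s^2)),
    small_area_high_gray_level_emphasis = mean(i^2 / s^2),
    large_area_low_gray_level_emphasis = mean(s^2 / i^2),
    large_area_high_gray_level_emphasis = mean(i^2 * s^2))
}

ngtdm_features <- function(g, cfg) {
  inreg <- g > 0L
  nsum <- array(0, dim(g))
  ncnt <- array(0, dim(g))
  offs <- neighbor_offsets(26L)
  for (r in seq_len(nrow(offs))) {
    nb <- array_shift(g, offs[r, ])
    ok <- !is.na(nb) & nb > 0L
    nsum[ok] <- nsum[ok] + nb[ok]
    ncnt <- ncnt + ok
  }
  valid <- inreg & ncnt > 0
  nvp <- sum(valid)
  gi <- g[valid]
  diffs <- abs(gi - nsum[valid] / ncnt[valid])
  ng <- cfg$n_levels
  n_i <- tabulate(gi, ng)
  s_i <- as.vector(rowsum(diffs, gi))
  s_full <- numeric(ng)
  s_full[sort(unique(gi))] <- s_i
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  ii <- present
  pi_ <- p_i[present]; si_ <- s_full[present]
  denom_coars <- sum(pi_ * si_)
  coarseness <- if (denom_coars > 0) 1 / denom_coars else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(ii, ii, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(si_) / nvp)
  } else 0
  busy_den <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
  busyness <- if (busy_den > 0) sum(pi_ * si_) / busy_den else 0
  PI <- outer(pi_, rep(1, ngp)); PJ <- t(PI)
  SI <- outer(si_, rep(1, ngp)); SJ <- t(SI)
  DIJ <- abs(outer(ii, ii, `-`))
  complexity <- sum(DIJ * (PI * SI + PJ * SJ) / (PI + PJ)) / nvp
  strength_den <- sum(si_)
  strength <- if (strength_den > 0) {
    sum((PI + PJ) * DIJ^2) / strength_den
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Extract radiomic features from one region of one phase
#'
#' Computes first-order intensity statistics, 3D shape descriptors and
#' texture features (GLCM, GLRLM, GLSZM, NGTDM, each aggregated over the 13
#' unique 3D directions / 26-connectivity) on the quantized normalized
#' intensities of the region. Deterministic for fixed inputs and config.
#' Degenerate regions (a single gray level) yield the defined limiting values
#' (zero contrast/entropy, correlation 1); regions too small to form any
#' voxel pair yield `NA` texture values with a warning, never silent NaNs.
#'
#' @param v a normalized [image_volume()].
#' @param region a [roi_mask()] or a logical/integer array on the same grid
#'   (nonzero voxels define the region, e.g. `habitat_map$labels == k`).
#' @param config a [feature_config()].
#' @param shape_values optional precomputed shape block for this region
#'   (named as returned by this function): shape depends only on the region
#'   geometry, so the block computed on one phase can be reused on the other.
#' @return Named numeric vector; names are `<family>__<feature>`.
#' @export
extract_region_features <- function(v, region, config = feature_config(),
                                    shape_values = NULL) {
  stopifnot(inherits(v, "image_volume"), inherits(config, "feature_config"))
  msk <- if (inherits(region, "roi_mask")) region$labels > 0 else region != 0
  if (!all(dim(msk) == dim(v$values))) stop("region and volume grids differ")
  if (!any(msk)) stop("empty region")
  rng <- bbox_ranges(msk, margin = 1L)
  m <- crop_to(msk, rng)
  x <- crop_to(v$values, rng)
  xv <- x[m]
  g <- array(0L, dim(m))
  g[m] <- quantize_gray(xv, config)
  out <- numeric(0)
  add <- function(out, fam, vals) {
    c(out, setNames(vals, paste0(fam, "__", names(vals))))
  }
  for (fam in config$families) {
    vals <- switch(fam,
      firstorder = fo_features(xv, config),
      shape = if (!is.null(shape_values)) {
        setNames(unname(shape_values),
                 sub("^shape__", "", names(shape_values)))
      } else shape_features(m, v$spacing, config),
      glcm = glcm_features(g, config),
      glrlm = glrlm_features(g, config),
      glszm = glszm_features(g, config),
      ngtdm = ngtdm_features(g, config))
    out <- add(out, fam, vals)
  }
  out
}

#' Early fusion of per-region, per-phase feature blocks
#'
#' Concatenates named feature vectors into one row, prefixing each feature
#' with its block name (`<phase>__<region>`), the package's fused
#' `<phase>__<region>__<family>__<feature>` naming.
#'
#' @param blocks named list of named numeric vectors; block names like
#'   `"ACE__whole"` or `"VCE__habitat2"`.
#' @return Single named numeric vector; errors if fused names collide.
#' @export
fuse_early <- function(blocks) {
  stopifnot(is.list(blocks), !is.null(names(blocks)), all(names(blocks) != ""))
  out <- unlist(lapply(names(blocks), function(b) {
    v <- blocks[[b]]
    setNames(as.numeric(v), paste0(b, "__", names(v)))
  }))
  if (anyDuplicated(names(out))) stop("fused feature names are not unique")
  out
}

#' Feature-count accounting
#'
#' Column counts implied by a per-region, per-phase feature count F: the
#' whole-ROI (Rad) table has `F * n_phases` columns; the per-habitat fused
#' table has `F * k * n_phases` (e.g. F = 1834, k = 3, two phases gives
#' 3668 and 11004).
#'
#' @param f features per region and phase.
#' @param k number of habitats.
#' @param n_phases number of imaging phases.
#' @return Integer column count.
#' @export
habitat_feature_count <- function(f, k = 3L, n_phases = 2L) {
  as.integer(f) * as.integer(k) * as.integer(n_phases)
}

#' @rdname habitat_feature_count
#' @export
rad_feature_count <- function(f, n_phases = 2L) {
  as.integer(f) * as.integer(n_phases)
}

cohort_phase_volumes <- function(patient) {
  list(ACE = patient$ace, VCE = patient$vce)
}

#' Whole-ROI (Rad) feature table
#'
#' One row per patient: whole-ROI features of both phases, early-fused. A
#' patient missing a phase is excluded with a message.
#'
#' @param cohort list of preprocessed patients, each
#'   `list(id = , ace = , vce = , roi = )` with normalized volumes.
#' @param config a [feature_config()].
#' @return Numeric matrix, rownames = patient ids, identical columns for all
#'   patients.
#' @export
extract_rad_table <- function(cohort, config = feature_config()) {
  rows <- list()
  for (p in cohort) {
    if (is.null(p$ace) || is.null(p$vce)) {
      message("extract_rad_table: patient ", p$id, " missing a phase; excluded")
      next
    }
    blocks <- list()
    shp <- NULL
    for (ph in c("ACE", "VCE")) {
      v <- if (ph == "ACE") p$ace else p$vce
      fv <- extract_region_features(v, p$roi, config, shape_values = shp)
      if (is.null(shp)) shp <- fv[grep("^shape__", names(fv))]
      blocks[[paste0(ph, "__whole")]] <- fv
    }
    rows[[p$id]] <- fuse_early(blocks)
  }
  do.call(rbind, rows)
}

#' Per-habitat (Habitat) feature table
#'
#' `mode = "per_habitat"` keeps each harmonized habitat's features as its own
#' columns (F x K x 2 phases); `mode = "averaged"` averages each feature over
#' the K habitats within a phase (F x 2). Habitats absent for a patient
#' (dropped by filtering) yield `NA` columns in per-habitat mode and are
#' skipped by the average (logged); nothing is imputed silently.
#'
#' @param cohort as in [extract_rad_table()].
#' @param habitat_maps list of harmonized `habitat_map`s aligned with
#'   `cohort`.
#' @param k habitat count used for column layout.
#' @param mode `"per_habitat"` or `"averaged"`.
#' @param config a [feature_config()].
#' @return Numeric matrix, one row per patient.
#' @export
extract_habitat_table <- function(cohort, habitat_maps, k = 3L,
                                  mode = c("per_habitat", "averaged"),
                                  config = feature_config()) {
  mode <- match.arg(mode)
  stopifnot(length(cohort) == length(habitat_maps))
  rows <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    hm <- habitat_maps[[i]]
    blocks <- list()
    feat_names <- NULL
    shp <- vector("list", k)
    for (ph in c("ACE", "VCE")) {
      v <- if (ph == "ACE") p$ace else p$vce
      per_hab <- vector("list", k)
      for (h in seq_len(k)) {
        reg <- hm$labels == h
        if (!any(reg)) {
          message("patient ", p$id, ": habitat ", h,
                  " absent; features flagged missing")
        } else {
          per_hab[[h]] <- extract_region_features(v, reg, config,
                                                  shape_values = shp[[h]])
          if (is.null(shp[[h]])) {
            shp[[h]] <- per_hab[[h]][grep("^shape__", names(per_hab[[h]]))]
          }
          if (is.null(feat_names)) feat_names <- names(per_hab[[h]])
        }
      }
      if (mode == "per_habitat") {
        for (h in seq_len(k)) {
          vals <- per_hab[[h]]
          if (is.null(vals)) vals <- setNames(rep(NA_real_,
                                                  length(feat_names)),
                                              feat_names)
          blocks[[paste0(ph, "__habitat", h)]] <- vals
        }
      } else {
        mat <- do.call(rbind, per_hab[!vapply(per_hab, is.null, TRUE)])
        blocks[[paste0(ph, "__habitatmean")]] <- colMeans(mat)
      }
    }
    rows[[p$id]] <- fuse_early(blocks)
  }
  do.call(rbind, rows)
}
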