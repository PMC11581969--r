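# Habitat generation: SLIC superpixels on the joint two-phase image inside
# the ROI, K-means on superpixel intensity profiles, small-region filtering,
# and cross-patient label harmonization (ReMap).

check_aligned <- function(ace, vce, roi) {
  stopifnot(inherits(ace, "image_volume"), inherits(vce, "image_volume"),
            inherits(roi, "roi_mask"))
  if (!all(dim(ace$values) == dim(vce$values)) ||
      !all(dim(ace$values) == dim(roi$labels))) {
    stop("ACE, VCE and ROI must share the same grid")
  }
}

habitat_stats <- function(labels, ace, vce) {
  sel <- labels > 0
  l <- labels[sel]
  labs <- sort(unique(l))
  cnt <- as.vector(rowsum(rep(1L, length(l)), l))
  data.frame(label = labs,
             mean_ace = as.vector(rowsum(ace$values[sel], l)) / cnt,
             mean_vce = as.vector(rowsum(vce$values[sel], l)) / cnt,
             n_voxels = cnt)
}

# reassign non-largest connected components of each label to the most
# frequent adjacent different label (keeps superpixels/habitats connected)
absorb_stray_components <- function(labels) {
  offs <- neighbor_offsets(6L)
  for (pass in 1:5) {
    comp <- label_components(labels)
    nc <- max(comp)
    if (nc == 0L) break
    csize <- tabulate(comp[comp > 0], nc)
    firsts <- match(seq_len(nc), comp)
    clab <- labels[firsts]
    # largest component per label is kept
    keep <- rep(FALSE, nc)
    for (lv in unique(clab)) {
      members <- which(clab == lv)
      keep[members[which.max(csize[members])]] <- TRUE
    }
    stray <- which(!keep)
    if (!length(stray)) break
    changed <- FALSE
    for (ci in stray) {
      vox <- which(comp == ci)
      co <- arrayInd(vox, dim(labels))
      neigh <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(co, 2, offs[r, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dim(labels)[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim(labels)[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim(labels)[3]
        if (!any(ok)) next
        li <- nb[ok, 1] + (nb[ok, 2] - 1) * dim(labels)[1] +
          (nb[ok, 3] - 1) * dim(labels)[1] * dim(labels)[2]
        nl <- labels[li]
        neigh <- c(neigh, nl[nl > 0 & nl != labels[vox[1]]])
      }
      if (length(neigh)) {
        tt <- table(neigh)
        labels[vox] <- as.integer(names(tt)[which.max(tt)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' SLIC superpixels within a tumor ROI
#'
#' Runs Simple Linear Iterative Clustering on the two-channel (ACE, VCE)
#' normalized image restricted to the ROI. The distance balances intensity
#' similarity against spatial proximity: D^2 = dc^2 + m^2 * ds^2 / S^2 with
#' compactness m and grid interval S (voxels). Superpixels are made spatially
#' connected by absorbing stray components into their neighbors.
#'
#' @param ace,vce normalized (\[0,1\]) [image_volume()]s on the same grid.
#' @param roi the [roi_mask()].
#' @param n_segments target superpixel count; default
#'   `max(16, round(ROI voxels / 50))`, i.e. superpixels of roughly 50 voxels.
#' @param compactness spatial-vs-intensity weight `m` (on normalized
#'   intensities).
#' @param seed kept for interface symmetry; the algorithm is deterministic.
#' @param max_iter Lloyd iterations.
#' @return A `superpixel_map`: full-size label array (0 outside ROI, 1..S
#'   inside) and a per-superpixel profile table (mean intensity per phase,
#'   voxel count, centroid).
#' @export
slic_superpixels <- function(ace, vce, roi, n_segments = NULL,
                             compactness = 0.1, seed = 1L, max_iter = 5L) {
  check_aligned(ace, vce, roi)
  nvox <- sum(roi$labels)
  if (nvox == 0L) stop("empty ROI")
  if (is.null(n_segments)) n_segments <- max(16L, round(nvox / 50))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (nvox < n_segments) {
    stop("ROI has only ", nvox, " voxels; lower n_segments (requested ",
         n_segments, ")")
  }
  full_dm <- dim(roi$labels)
  if (n_segments == 1L) {
    labels <- array(0L, full_dm)
    labels[roi$labels > 0] <- 1L
    sel <- roi$labels > 0
    co <- arrayInd(which(sel), full_dm)
    prof <- data.frame(superpixel = 1L, mean_ace = mean(ace$values[sel]),
                       mean_vce = mean(vce$values[sel]), n_voxels = nvox,
                       cx = mean(co[, 1]), cy = mean(co[, 2]),
                       cz = mean(co[, 3]))
    return(structure(list(labels = labels, profiles = prof,
                          spacing = roi$spacing), class = "superpixel_map"))
  }
  rng <- bbox_ranges(roi$labels, margin = 0L)
  msk <- crop_to(roi$labels, rng) > 0
  f1 <- crop_to(ace$values, rng)
  f2 <- crop_to(vce$values, rng)
  dm <- dim(msk)
  S <- (nvox / n_segments)^(1 / 3)
  roi_idx <- which(msk)
  co_all <- arrayInd(roi_idx, dm)
  row_of <- array(0L, dm)
  row_of[roi_idx] <- seq_along(roi_idx)
  # grid initialization, snapped to the nearest ROI voxel in each cell
  grid_ax <- lapply(1:3, function(a) seq(S / 2 + 0.5, dm[a] + 0.4, by = S))
  g <- as.matrix(expand.grid(grid_ax[[1]], grid_ax[[2]], grid_ax[[3]]))
  centers <- NULL
  for (i in seq_len(nrow(g))) {
    w <- lapply(1:3, function(a) {
      abs(co_all[, a] - g[i, a])
    })
    inside <- w[[1]] <= S / 2 & w[[2]] <= S / 2 & w[[3]] <= S / 2
    if (!any(inside)) next
    d2 <- (co_all[inside, 1] - g[i, 1])^2 + (co_all[inside, 2] - g[i, 2])^2 +
      (co_all[inside, 3] - g[i, 3])^2
    pick <- which(inside)[which.min(d2)]
    centers <- rbind(centers, c(co_all[pick, ], f1[roi_idx[pick]],
                                f2[roi_idx[pick]]))
  }
  if (is.null(centers) || nrow(centers) < 1L) stop("SLIC initialization failed")
  m2s2 <- compactness^2 / S^2
  lab_v <- integer(length(roi_idx))
  for (it in seq_len(max_iter)) {
    dist_v <- rep(Inf, length(roi_idx))
    lab_v <- integer(length(roi_idx))
    for (j in seq_len(nrow(centers))) {
      cc <- centers[j, ]
      xi <- max(1L, floor(cc[1] - S)):min(dm[1], ceiling(cc[1] + S))
      yi <- max(1L, floor(cc[2] - S)):min(dm[2], ceiling(cc[2] + S))
      zi <- max(1L, floor(cc[3] - S)):min(dm[3], ceiling(cc[3] + S))
      nx <- length(xi); ny <- length(yi); nz <- length(zi)
      li <- rep.int(xi, ny * nz) +
        rep(rep.int((yi - 1L) * dm[1], rep.int(nx, ny)), nz) +
        rep((zi - 1L) * dm[1] * dm[2], rep.int(nx * ny, nz))
      sd2 <- rep.int((xi - cc[1])^2, ny * nz) +
        rep(rep.int((yi - cc[2])^2, rep.int(nx, ny)), nz) +
        rep((zi - cc[3])^2, rep.int(nx * ny, nz))
      rw <- row_of[li]
      ok <- rw > 0L
      if (!any(ok)) next
      li <- li[ok]; rw <- rw[ok]
      d2 <- (f1[li] - cc[4])^2 + (f2[li] - cc[5])^2 + m2s2 * sd2[ok]
      upd <- d2 < dist_v[rw]
      if (any(upd)) {
        dist_v[rw[upd]] <- d2[upd]
        lab_v[rw[upd]] <- j
      }
    }
    orphans <- which(lab_v == 0L)
    if (length(orphans)) {
      for (oi in orphans) {
        d2 <- (centers[, 1] - co_all[oi, 1])^2 +
          (centers[, 2] - co_all[oi, 2])^2 + (centers[, 3] - co_all[oi, 3])^2
        lab_v[oi] <- which.min(d2)
      }
    }
    new_centers <- centers
    sums <- rowsum(cbind(co_all, f1[roi_idx], f2[roi_idx]), lab_v)
    cnt <- tabulate(lab_v, nrow(centers))
    present <- sort(unique(lab_v))
    new_centers[present, ] <- sums / cnt[present]
    move <- sqrt(rowSums((new_centers[present, 1:3, drop = FALSE] -
                            centers[present, 1:3, drop = FALSE])^2))
    centers <- new_centers[present, , drop = FALSE]
    lab_v <- match(lab_v, present)
    if (max(move) < 0.25) break
  }
  lab_crop <- array(0L, dm)
  lab_crop[roi_idx] <- lab_v
  lab_crop <- absorb_stray_components(lab_crop)
  # consecutive labels
  present <- sort(unique(lab_crop[lab_crop > 0]))
  lab_crop[lab_crop > 0] <- match(lab_crop[lab_crop > 0], present)
  labels <- array(0L, full_dm)
  labels[rng[[1]], rng[[2]], rng[[3]]] <- lab_crop
  lv <- labels[labels > 0]
  co <- arrayInd(which(labels > 0), full_dm)
  ns <- max(lv)
  cnt <- tabulate(lv, ns)
  prof <- data.frame(
    superpixel = seq_len(ns),
    mean_ace = as.vector(rowsum(ace$values[labels > 0], lv)) / cnt,
    mean_vce = as.vector(rowsum(vce$values[labels > 0], lv)) / cnt,
    n_voxels = cnt,
    cx = as.vector(rowsum(co[, 1], lv)) / cnt,
    cy = as.vector(rowsum(co[, 2], lv)) / cnt,
    cz = as.vector(rowsum(co[, 3], lv)) / cnt)
  structure(list(labels = labels, profiles = prof, spacing = roi$spacing),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d superpixels over %d voxels\n",
              nrow(x$profiles), sum(x$profiles$n_voxels)))
  invisible(x)
}

#' Cluster superpixels into habitats by K-means
#'
#' K-means (Lloyd/Hartigan-Wong via [stats::kmeans()]) on standardized
#' per-superpixel profiles (mean ACE, mean VCE normalized intensity); every
#' superpixel's voxels inherit its cluster, yielding a raw (un-harmonized)
#' habitat map.
#'
#' @param sp a `superpixel_map`.
#' @param k number of habitats (default 3).
#' @param seed RNG seed for the K-means restarts.
#' @param n_init number of random restarts.
#' @return A `habitat_map` with raw labels 1..k, per-habitat intensity stats
#'   and voxel counts.
#' @export
kmeans_habitats <- function(sp, k = 3L, seed = 1L, n_init = 10L) {
  stopifnot(inherits(sp, "superpixel_map"))
  k <- as.integer(k)
  ns <- nrow(sp$profiles)
  if (ns < k) stop("fewer superpixels (", ns, ") than clusters (", k, ")")
  P <- as.matrix(sp$profiles[, c("mean_ace", "mean_vce")])
  Ps <- scale(P)
  Ps[, apply(P, 2, sd) == 0] <- 0
  if (nrow(unique(Ps)) < k) {
    # duplicate profiles: break ties deterministically with a tiny
    # index-based ramp so K-means still partitions reproducibly
    Ps[, 1] <- Ps[, 1] + seq_len(ns) * 1e-9
  }
  set.seed(seed)
  if (k == 1L) {
    cl <- rep(1L, ns)
  } else {
    km <- suppressWarnings(
      kmeans(Ps, centers = k, nstart = n_init, iter.max = 100L))
    cl <- km$cluster
  }
  labels <- sp$labels
  labels[labels > 0] <- cl[labels[labels > 0]]
  w <- sp$profiles$n_voxels
  stats <- data.frame(
    label = seq_len(k),
    mean_ace = as.vector(rowsum(P[, 1] * w, cl)) / as.vector(rowsum(w, cl)),
    mean_vce = as.vector(rowsum(P[, 2] * w, cl)) / as.vector(rowsum(w, cl)),
    n_voxels = as.vector(rowsum(w, cl)))
  structure(list(labels = labels, k = k, stats = stats,
                 spacing = sp$spacing, provenance = NULL,
                 dropped = integer(0)),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> k = %d, voxels per habitat: %s\n",
              nrow(x$stats), paste(x$stats$n_voxels, collapse = ", ")))
  invisible(x)
}

#' Filter small habitat subregions
#'
#' Connected components of a habitat smaller than `min_voxels` are reassigned
#' to the habitat label of their largest adjacent region; the total ROI voxel
#' count is conserved. If every region of a habitat is absorbed, the habitat
#' is dropped and the effective K reduced (logged via a message).
#'
#' @param h a `habitat_map`.
#' @param min_voxels minimum component size to keep.
#' @param ace,vce optional normalized volumes used to recompute per-habitat
#'   intensity stats exactly after reassignment.
#' @return The filtered `habitat_map`.
#' @export
filter_small_regions <- function(h, min_voxels = 64L, ace = NULL, vce = NULL) {
  stopifnot(inherits(h, "habitat_map"))
  labels <- h$labels
  if (min_voxels > 1L) {
    dm <- dim(labels)
    for (pass in 1:20) {
      comp <- label_components(labels)
      ncmp <- max(comp)
      if (ncmp == 0L) break
      csize <- tabulate(comp[comp > 0], ncmp)
      small <- which(csize < min_voxels)
      if (!length(small)) break
      small <- small[order(csize[small])]
      offs <- neighbor_offsets(26L)
      changed <- FALSE
      for (ci in small) {
        vox <- which(comp == ci)
        if (labels[vox[1]] == 0L) next
        adj_comp <- integer(0)
        co <- arrayInd(vox, dm)
        for (r in seq_len(nrow(offs))) {
          nb <- sweep(co, 2, offs[r, ], `+`)
          ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
            nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
          if (!any(ok)) next
          li <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] +
            (nb[ok, 3] - 1) * dm[1] * dm[2]
          cc <- comp[li]
          adj_comp <- c(adj_comp, cc[cc > 0 & cc != ci])
        }
        adj_comp <- unique(adj_comp)
        if (!length(adj_comp)) next
        target <- adj_comp[which.max(csize[adj_comp])]
        labels[vox] <- labels[which(comp == target)[1]]
        comp[vox] <- target
        csize[target] <- csize[target] + length(vox)
        changed <- TRUE
      }
      if (!changed) break
    }
  }
  present <- sort(unique(labels[labels > 0]))
  dropped <- setdiff(h$stats$label, present)
  if (length(dropped)) {
    message("filter_small_regions: habitat(s) ",
            paste(dropped, collapse = ", "),
            " absorbed entirely; K reduced to ", length(present))
  }
  h$labels <- labels
  h$dropped <- dropped
  if (!is.null(ace) && !is.null(vce)) {
    h$stats <- habitat_stats(labels, ace, vce)
  } else {
    cnt <- tabulate(labels[labels > 0], max(present))
    h$stats <- h$stats[h$stats$label %in% present, , drop = FALSE]
    h$stats$n_voxels <- cnt[h$stats$label]
    if (min_voxels > 1L) attr(h$stats, "stale_means") <- TRUE
  }
  h$k <- length(present)
  h
}

#' Harmonize habitat labels across patients (ReMap)
#'
#' Unsupervised clustering gives arbitrary label order per patient. Within
#' each patient the raw clusters are sorted by mean ACE normalized intensity
#' (ascending; ties broken by mean VCE, then by voxel count descending) and
#' relabeled 1..K, so harmonized label k carries the same physical meaning —
#' the k-th least arterially enhancing habitat — in every patient.
#'
#' @param maps list of `habitat_map`s produced with the same k.
#' @return `list(maps = , rules = )`; each rule is a data.frame with columns
#'   raw, harmonized and the ordering statistic.
#' @export
remap_labels <- function(maps) {
  if (inherits(maps, "habitat_map")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, TRUE, "habitat_map")))
  rules <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    h <- maps[[i]]
    st <- h$stats
    if (anyDuplicated(st$mean_ace)) {
      message("remap_labels: ACE-mean tie in patient ", i,
              "; broken by VCE mean, then voxel count")
    }
    ord <- order(st$mean_ace, st$mean_vce, -st$n_voxels)
    raw <- st$label[ord]
    rule <- data.frame(raw = raw, harmonized = seq_along(raw),
                       mean_ace = st$mean_ace[ord])
    lut <- integer(max(st$label))
    lut[raw] <- seq_along(raw)
    labels <- h$labels
    labels[labels > 0] <- lut[labels[labels > 0]]
    h$labels <- labels
    h$stats <- data.frame(label = seq_along(raw),
                          mean_ace = st$mean_ace[ord],
                          mean_vce = st$mean_vce[ord],
                          n_voxels = st$n_voxels[ord])
    h$provenance <- rule
    maps[[i]] <- h
    rules[[i]] <- rule
  }
  list(maps = maps, rules = rules)
}

#' Segment one patient into habitats
#'
#' Convenience wrapper: SLIC superpixels, K-means habitats, small-region
#' filtering, with exact per-habitat stats. Labels are raw; harmonize across
#' the cohort with [remap_labels()].
#'
#' @inheritParams slic_superpixels
#' @inheritParams kmeans_habitats
#' @inheritParams filter_small_regions
#' @return A `habitat_map`.
#' @export
segment_patient <- function(ace, vce, roi, k = 3L, n_segments = NULL,
                            compactness = 0.1, min_voxels = 64L,
                            seed = 1L, n_init = 10L) {
  sp <- slic_superpixels(ace, vce, roi, n_segments = n_segments,
                         compactness = compactness, seed = seed)
  h <- kmeans_habitats(sp, k = k, seed = seed, n_init = n_init)
  filter_small_regions(h, min_voxels = min_voxels, ace = ace, vce = vce)
}
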