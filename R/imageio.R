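# NIfTI IO, intensity windowing, isotropic resampling.

#' Construct a 3D image volume
#'
#' Container for one CT phase: a 3D scalar grid plus voxel spacing, world
#' origin and phase tag (arterial `"ACE"` or venous `"VCE"`).
#'
#' @param values 3D numeric array.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param origin world coordinates of the first voxel (mm), length 3.
#' @param phase `"ACE"` or `"VCE"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         phase = c("ACE", "VCE")) {
  phase <- match.arg(phase)
  if (length(dim(values)) != 3L) stop("expected 3D volume")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' @param labels 3D array with values in \{0, 1\}.
#' @param spacing,origin geometry, as in [image_volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("expected 3D volume")
  if (!all(labels %in% c(0, 1))) stop("ROI mask labels must be in {0, 1}")
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n", x$phase,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d foreground\n",
              paste(dim(x$labels), collapse = "x"), sum(x$labels)))
  invisible(x)
}

nifti_geometry <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  list(spacing = as.numeric(pd[1:3]), origin = as.numeric(xf[1:3, 4]))
}

#' Read a 3D NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param phase phase tag to attach, `"ACE"` or `"VCE"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, phase = c("ACE", "VCE")) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume, got ",
                                   length(dim(img)), "D")
  geo <- nifti_geometry(img)
  image_volume(array(as.numeric(img), dim(img)), geo$spacing, geo$origin, phase)
}

#' Read a binary ROI mask from NIfTI
#'
#' @inheritParams read_volume
#' @return A [roi_mask()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume, got ",
                                   length(dim(img)), "D")
  vals <- array(as.numeric(img), dim(img))
  if (!all(vals %in% c(0, 1))) stop("mask labels outside {0, 1}")
  geo <- nifti_geometry(img)
  roi_mask(vals, geo$spacing, geo$origin)
}

nifti_with_geometry <- function(values, spacing, origin, datatype) {
  vals <- values
  attr(vals, "pixdim") <- spacing
  img <- RNifti::asNifti(vals, datatype = datatype)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  img
}

#' Write an image volume or ROI mask to NIfTI-1
#'
#' Volumes are stored as 64-bit float, masks as unsigned 8-bit. Spacing and
#' origin are preserved through the qform/sform affine.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "image_volume")) {
    img <- nifti_with_geometry(x$values, x$spacing, x$origin, "double")
  } else if (inherits(x, "roi_mask")) {
    img <- nifti_with_geometry(x$labels, x$spacing, x$origin, "uint8")
  } else stop("x must be an image_volume or roi_mask")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Window and rescale CT intensities
#'
#' Clips voxel values to a fixed Hounsfield window (default -200 to 300 HU)
#' and maps the window linearly onto \[0, 1\]. The window is fixed, not
#' per-image, so normalized intensities are comparable across patients.
#'
#' @param v an [image_volume()].
#' @param low,high window bounds in HU; `low < high`.
#' @return An [image_volume()] with values in \[0, 1\].
#' @export
normalize_intensity <- function(v, low = -200, high = 300) {
  stopifnot(inherits(v, "image_volume"))
  if (low >= high) stop("low must be smaller than high")
  x <- pmin(pmax(v$values, low), high)
  v$values <- (x - low) / (high - low)
  v
}

#' Resample a volume and its mask to isotropic spacing
#'
#' Trilinear interpolation for the image, nearest neighbor for the mask, on
#' a voxel-node grid that preserves the physical extent. The default target
#' is 1 mm isotropic.
#'
#' @param v an [image_volume()].
#' @param m the aligned [roi_mask()].
#' @param target_mm isotropic target spacing in mm.
#' @return `list(volume = , mask = )` at the target spacing.
#' @export
resample_isotropic <- function(v, m, target_mm = 1.0) {
  stopifnot(inherits(v, "image_volume"), inherits(m, "roi_mask"))
  if (!all(dim(v$values) == dim(m$labels)) ||
      max(abs(v$spacing - m$spacing)) > 1e-9) {
    stop("volume and mask must share grid and spacing")
  }
  dm <- dim(v$values)
  sp <- v$spacing
  if (max(abs(sp - target_mm)) < 1e-9) {
    return(list(volume = v, mask = m))
  }
  new_dm <- pmax(2L, as.integer(round((dm - 1L) * sp / target_mm)) + 1L)
  # fractional source indices for each target node, per axis
  src <- lapply(1:3, function(ax) {
    s <- (seq_len(new_dm[ax]) - 1) * target_mm / sp[ax] + 1
    pmin(pmax(s, 1), dm[ax])
  })
  i0 <- lapply(1:3, function(ax) pmin(floor(src[[ax]]), dm[ax] - 1L))
  w <- lapply(1:3, function(ax) src[[ax]] - i0[[ax]])
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  gx0 <- rep(i0[[1]], times = new_dm[2] * new_dm[3])
  gy0 <- rep(rep(i0[[2]], each = new_dm[1]), times = new_dm[3])
  gz0 <- rep(i0[[3]], each = new_dm[1] * new_dm[2])
  wx <- rep(w[[1]], times = new_dm[2] * new_dm[3])
  wy <- rep(rep(w[[2]], each = new_dm[1]), times = new_dm[3])
  wz <- rep(w[[3]], each = new_dm[1] * new_dm[2])
  vals <- v$values
  corner <- function(dx, dy, dz) {
    vals[(gx0 + dx) + (gy0 + dy - 1) * nx + (gz0 + dz - 1) * nxy]
  }
  out <- corner(0, 0, 0) * (1 - wx) * (1 - wy) * (1 - wz) +
    corner(1, 0, 0) * wx * (1 - wy) * (1 - wz) +
    corner(0, 1, 0) * (1 - wx) * wy * (1 - wz) +
    corner(0, 0, 1) * (1 - wx) * (1 - wy) * wz +
    corner(1, 1, 0) * wx * wy * (1 - wz) +
    corner(1, 0, 1) * wx * (1 - wy) * wz +
    corner(0, 1, 1) * (1 - wx) * wy * wz +
    corner(1, 1, 1) * wx * wy * wz
  new_vals <- array(out, new_dm)
  # nearest neighbor for the mask
  nn <- lapply(1:3, function(ax) pmin(pmax(round(src[[ax]]), 1L), dm[ax]))
  gx <- rep(nn[[1]], times = new_dm[2] * new_dm[3])
  gy <- rep(rep(nn[[2]], each = new_dm[1]), times = new_dm[3])
  gz <- rep(nn[[3]], each = new_dm[1] * new_dm[2])
  new_mask <- array(m$labels[gx + (gy - 1) * nx + (gz - 1) * nxy], new_dm)
  if (sum(new_mask) == 0L) stop("ROI vanished after resampling")
  sp3 <- rep(target_mm, 3)
  list(volume = image_volume(new_vals, sp3, v$origin, v$phase),
       mask = roi_mask(new_mask, sp3, m$origin))
}

#' Preprocess one patient's two-phase study
#'
#' Resamples both phases and the ROI to isotropic spacing, then applies the
#' fixed-window intensity normalization. Resampling precedes normalization so
#' interpolation happens on the HU scale.
#'
#' @param ace,vce raw-HU [image_volume()]s, co-registered.
#' @param roi the shared [roi_mask()].
#' @param target_mm isotropic spacing (mm).
#' @param low,high normalization window (HU).
#' @return `list(ace = , vce = , roi = )`, normalized at `target_mm`.
#' @export
preprocess_patient <- function(ace, vce, roi, target_mm = 1.0,
                               low = -200, high = 300) {
  ra <- resample_isotropic(ace, roi, target_mm)
  rv <- resample_isotropic(vce, roi, target_mm)
  list(ace = normalize_intensity(ra$volume, low, high),
       vce = normalize_intensity(rv$volume, low, high),
       roi = ra$mask)
}
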