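# Two-photon z-stack processing: z-resampling to isotropic voxels,
# coherence-enhancing diffusion (CED) filtering, hysteresis segmentation with
# size filters, domain area from the mask projection, and leaflet
# volume-fraction (VF) estimation from soma-plane line profiles.

#' Construct an image stack
#'
#' @param voxels 3D numeric array indexed `[z, y, x]`, finite and >= 0.
#' @param lateral_res Lateral resolution in micrometers per pixel (default 0.2).
#' @param z_step Axial step in micrometers (default 1, before resampling).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, lateral_res = 0.2, z_step = 1.0) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array (z, y, x)")
  if (lateral_res <= 0 || z_step <= 0) stop("resolutions must be > 0")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and >= 0")
  structure(list(voxels = voxels, lateral_res = lateral_res, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), %.3g um/px, z-step %.3g um\n",
              d[1], d[2], d[3], x$lateral_res, x$z_step))
  invisible(x)
}

#' Resample the z-axis to the lateral resolution
#'
#' Each (y, x) column is interpolated along z with a natural cubic spline so
#' that the axial step equals the lateral pixel size; the z-extent in
#' micrometers is preserved. The interpolation is applied as a single linear
#' map (spline interpolation is linear in the data), so all columns share one
#' precomputed operator.
#'
#' @param stack An [image_stack()] with `z_step > lateral_res`.
#' @return An `image_stack` with `z_step == lateral_res`.
#' @export
resample_z <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  nz <- d[1]
  if (nz < 2) stop("cannot interpolate a single z-plane")
  z_old <- (seq_len(nz) - 1) * stack$z_step
  z_new <- seq(0, z_old[nz], by = stack$lateral_res)
  # interpolation matrix: column j = spline through unit vector e_j
  M <- vapply(seq_len(nz), function(j) {
    e <- numeric(nz); e[j] <- 1
    stats::splinefun(z_old, e, method = "natural")(z_new)
  }, numeric(length(z_new)))
  flat <- matrix(stack$voxels, nrow = nz)       # nz x (ny*nx)
  out <- M %*% flat
  out[out < 0] <- 0                              # spline undershoot clipped
  image_stack(array(out, dim = c(length(z_new), d[2], d[3])),
              lateral_res = stack$lateral_res, z_step = stack$lateral_res)
}

# Separable Gaussian blur with replicated borders.
gauss_blur2d <- function(u, sigma) {
  if (sigma <= 0) return(u)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[i] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(u, TRUE), FALSE)
}

# Central differences with replicated borders.
grad2d <- function(u) {
  n1 <- nrow(u); n2 <- ncol(u)
  up <- u[pmin(seq_len(n1) + 1L, n1), , drop = FALSE]
  dn <- u[pmax(seq_len(n1) - 1L, 1L), , drop = FALSE]
  rt <- u[, pmin(seq_len(n2) + 1L, n2), drop = FALSE]
  lf <- u[, pmax(seq_len(n2) - 1L, 1L), drop = FALSE]
  list(d1 = (up - dn) / 2, d2 = (rt - lf) / 2)
}

# One plane of coherence-enhancing diffusion (structure-tensor steered,
# explicit scheme). Diffusivity across coherent structures is small (alpha);
# along them it grows with the tensor's eigenvalue contrast via
# exp(-C / (mu1 - mu2)^2).
ced_plane <- function(u, n_iter, contrast_param, rho, alpha, dt) {
  for (it in seq_len(n_iter)) {
    g <- grad2d(u)
    j11 <- gauss_blur2d(g$d1 * g$d1, rho)
    j12 <- gauss_blur2d(g$d1 * g$d2, rho)
    j22 <- gauss_blur2d(g$d2 * g$d2, rho)
    tr2 <- (j11 + j22) / 2
    disc <- sqrt(((j11 - j22) / 2)^2 + j12^2)
    mu1 <- tr2 + disc                       # across-structure eigenvalue
    # unit eigenvector of mu1: (mu1 - j22, j12), falling back to axis-aligned
    v1a <- mu1 - j22
    v1b <- j12
    nv <- sqrt(v1a^2 + v1b^2)
    deg <- nv < 1e-12
    v1a[deg] <- 1; v1b[deg] <- 0; nv[deg] <- 1
    v1a <- v1a / nv; v1b <- v1b / nv
    coh <- (2 * disc)^2                     # (mu1 - mu2)^2
    c1 <- alpha                             # across structures
    c2 <- alpha + (1 - alpha) * exp(-contrast_param / pmax(coh, 1e-30))
    # D = c1 v1 v1' + c2 v2 v2', with v2 perpendicular to v1
    d11 <- c1 * v1a^2 + c2 * v1b^2
    d22 <- c1 * v1b^2 + c2 * v1a^2
    d12 <- (c1 - c2) * v1a * v1b
    f1 <- d11 * g$d1 + d12 * g$d2
    f2 <- d12 * g$d1 + d22 * g$d2
    div <- grad2d(f1)$d1 + grad2d(f2)$d2
    u <- u + dt * div
  }
  u
}

#' Coherence-enhancing diffusion filter
#'
#' Enhances the contrast of anisotropic structures (astrocytic processes) by
#' diffusing intensity preferentially along locally coherent orientations,
#' plane by plane. The intensity range of the output is clamped to the input
#' range.
#'
#' @param stack An [image_stack()].
#' @param n_iter Number of diffusion steps (default 20).
#' @param contrast_param Coherence contrast parameter (squared-gradient units);
#'   default `(0.05 * intensity range)^2`. Must be > 0.
#' @param rho Structure-tensor smoothing scale in pixels (default 1).
#' @param dt Explicit time step (default 0.15).
#' @param alpha Baseline isotropic diffusivity (default 0.01).
#' @return A filtered `image_stack`.
#' @export
ced_filter <- function(stack, n_iter = 20, contrast_param = NULL,
                       rho = 1, dt = 0.15, alpha = 0.01) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_iter < 0) stop("n_iter must be >= 0")
  v <- stack$voxels
  rng <- range(v)
  if (is.null(contrast_param)) {
    contrast_param <- (0.05 * max(diff(rng), 1e-12))^2
  }
  if (contrast_param <= 0) stop("contrast_param must be > 0")
  if (n_iter == 0) return(stack)
  out <- v
  for (z in seq_len(dim(v)[1])) {
    out[z, , ] <- ced_plane(v[z, , ], n_iter, contrast_param, rho, alpha, dt)
  }
  out[out < rng[1]] <- rng[1]
  out[out > rng[2]] <- rng[2]
  res <- stack
  res$voxels <- out
  res
}

# Connected-component labeling of a logical array; connectivity 26 in 3D is
# 8-connectivity when one dimension is singleton.
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  lab <- .cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
  array(lab, dim = dim(mask))
}

#' Segment a dye-filled astrocyte from a filtered stack
#'
#' Within each z-plane a hysteresis threshold is applied with high level
#' `mean + 3 SD` and low level `mean + 1 SD` of that plane's brightness
#' (8-connectivity): low-threshold components are kept only if they contain a
#' high-threshold pixel. In-plane components smaller than `min_px` pixels are
#' removed, the planes are combined into a 3D mask, and 3D components
#' (26-connectivity) smaller than `min_voxels` voxels are removed.
#'
#' @param stack A filtered/resampled [image_stack()].
#' @param high_k,low_k SD multipliers for the high and low thresholds
#'   (defaults 3 and 1).
#' @param min_px Minimum in-plane component size in pixels (default 9).
#' @param min_voxels Minimum 3D component size in voxels (default 100).
#' @return An object of class `segmentation_mask` with fields `mask` (3D
#'   logical, same shape), `lateral_res`, `z_step` and `provenance`.
#' @export
segment_astrocyte <- function(stack, high_k = 3, low_k = 1,
                              min_px = 9, min_voxels = 100) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  mask <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) {
    plane <- v[z, , ]
    mu <- mean(plane); s <- stats::sd(as.vector(plane))
    if (!is.finite(s) || s == 0) {
      warning(sprintf("z-plane %d has zero brightness variance (saturated?)", z))
      next
    }
    low <- plane > mu + low_k * s
    if (!any(low)) next
    lab <- label_components(low, 26)
    high <- plane > mu + high_k * s
    keep_lab <- unique(lab[high & low])
    keep_lab <- setdiff(keep_lab, 0L)
    if (length(keep_lab) == 0) next
    sizes <- tabulate(lab[lab > 0L])
    keep_lab <- keep_lab[sizes[keep_lab] >= min_px]
    if (length(keep_lab) == 0) next
    mask[z, , ] <- lab %in% keep_lab
  }
  if (any(mask)) {
    lab3 <- label_components(mask, 26)
    sizes <- tabulate(lab3[lab3 > 0L])
    keep <- which(sizes >= min_voxels)
    mask <- array(lab3 %in% keep, dim = d)
  }
  structure(
    list(mask = mask, lateral_res = stack$lateral_res, z_step = stack$z_step,
         provenance = list(high_k = high_k, low_k = low_k, min_px = min_px,
                           min_voxels = min_voxels,
                           connectivity_2d = 8, connectivity_3d = 26)),
    class = "segmentation_mask"
  )
}

#' Astrocyte domain area from a segmentation mask
#'
#' Max-projects the 3D mask along z and returns the projected area:
#' (number of occupied (y, x) columns) times the pixel area.
#'
#' @param mask A [segment_astrocyte()] result (or 3D logical array plus
#'   `lateral_res`).
#' @param lateral_res Lateral resolution, taken from `mask` when available.
#' @return Area in square micrometers.
#' @export
domain_area_from_mask <- function(mask, lateral_res = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    if (is.null(lateral_res)) lateral_res <- mask$lateral_res
    mask <- mask$mask
  }
  if (is.null(lateral_res)) stop("lateral_res is required")
  proj <- apply(mask, c(2, 3), any)
  n <- sum(proj)
  if (n == 0) stop("empty mask: no occupied columns to project")
  n * lateral_res^2
}

# Bilinear interpolation of plane (matrix, [y, x]) at fractional (y, x).
bilinear <- function(plane, y, x) {
  ny <- nrow(plane); nx <- ncol(plane)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y0 <- pmin(pmax(y0, 1L), ny); x0 <- pmin(pmax(x0, 1L), nx)
  y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  plane[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    plane[cbind(y1, x0)] * fy * (1 - fx) +
    plane[cbind(y0, x1)] * (1 - fy) * fx +
    plane[cbind(y1, x1)] * fy * fx
}

# Excise branch-crossing excursions from a soma-normalized radial profile:
# runs where the profile exceeds a moving-median baseline by more than
# `excess_pp` percentage points for longer than `max_run_um` are bridged by
# linear interpolation.
excise_fluctuations <- function(vf, step_um, excess_pp = 10, max_run_um = 0.5,
                                median_window_um = 7) {
  n <- length(vf)
  if (n < 3) return(vf)
  k <- max(3L, 2L * floor(median_window_um / step_um / 2) + 1L)
  if (k > n) k <- if (n %% 2 == 1) n else n - 1L
  base <- stats::runmed(vf, k, endrule = "median")
  mark <- (vf - base) > excess_pp
  r <- rle(mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- vf
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    run_um <- r$lengths[i] * step_um
    if (run_um <= max_run_um) next
    a <- max(1L, starts[i] - 1L)          # dilate by one sample: run edges
    b <- min(n, ends[i] + 1L)             # sit below threshold but are mixed
    lo <- if (a > 1) out[a - 1] else out[min(b + 1, n)]
    hi <- if (b < n) out[b + 1] else lo
    out[a:b] <- lo + (hi - lo) * seq_len(b - a + 1) / (b - a + 2)
  }
  out
}

#' Leaflet volume fraction from soma-plane line profiles
#'
#' In the z-plane containing the soma, five fluorescence cross-sections are
#' drawn through the soma center, 72 degrees apart (10 half-rays at 36 degree
#' spacing). Each half-ray profile is normalized to the mean soma intensity
#' (soma = 100 percent) so that unresolved-leaflet fluorescence reads directly
#' as a volume fraction. Sharp excursions from resolvable branches (more than
#' 10 percentage points above a moving-median baseline for runs longer than
#' 0.5 um) are excised and bridged. The characteristic VF is the mean
#' normalized intensity in the 30-40 um band beyond the soma boundary,
#' averaged over usable half-rays.
#'
#' @param stack An [image_stack()].
#' @param soma_center Numeric `(y, x)` pixel coordinates of the soma center.
#' @param soma_z Index of the soma-containing z-plane; default the plane with
#'   the highest mean intensity.
#' @param soma_boundary_radius Soma radius in micrometers; default the
#'   half-maximum radius of the radial soma intensity profile.
#' @param band Distances beyond the soma boundary over which the
#'   characteristic VF is averaged (um, default `c(30, 40)`).
#' @param excess_pp,max_run_um,median_window_um Excision parameters: threshold
#'   in percentage points, minimum run length in um and baseline moving-median
#'   window in um.
#' @return An object of class `vf_result`: `characteristic_vf` (percent),
#'   `per_ray_vf`, `radial_profiles` (list of data frames with distance,
#'   raw and excised normalized intensity), `soma_mean`,
#'   `soma_boundary_radius`.
#' @export
leaflet_vf <- function(stack, soma_center, soma_z = NULL,
                       soma_boundary_radius = NULL, band = c(30, 40),
                       excess_pp = 10, max_run_um = 0.5,
                       median_window_um = 7) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  res <- stack$lateral_res
  if (is.null(soma_z))
    soma_z <- which.max(apply(v, 1, mean))
  plane <- v[soma_z, , ]
  cy <- soma_center[1]; cx <- soma_center[2]

  # mean soma intensity within the soma radius (est. from half-max if absent)
  prof_r <- seq(0, min(nrow(plane), ncol(plane)) * res / 2, by = res)
  radial_mean <- vapply(prof_r, function(r) {
    if (r == 0) return(bilinear(plane, cy, cx))
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    mean(bilinear(plane, cy + r / res * sin(th), cx + r / res * cos(th)))
  }, numeric(1))
  if (is.null(soma_boundary_radius)) {
    half <- radial_mean[1] / 2
    below <- which(radial_mean < half)
    soma_boundary_radius <- if (length(below)) prof_r[below[1]] else prof_r[2]
  }
  # mean over an eroded soma core: the boundary annulus mixes soma and
  # background by partial volume and would dilute the normalization
  core_r <- max(soma_boundary_radius - 1, soma_boundary_radius / 2)
  soma_mean <- mean(radial_mean[prof_r <= core_r])
  if (!is.finite(soma_mean) || soma_mean <= 0)
    stop("soma mean intensity <= 0: cannot normalize")

  r_needed <- soma_boundary_radius + band[2]
  angles <- (0:9) * 36 * pi / 180
  profiles <- list()
  per_ray <- numeric(0)
  for (a in angles) {
    dy <- sin(a); dx <- cos(a)
    # distance to image border along this half-ray
    tmax_y <- if (dy > 0) (nrow(plane) - cy) / dy else if (dy < 0) (1 - cy) / dy else Inf
    tmax_x <- if (dx > 0) (ncol(plane) - cx) / dx else if (dx < 0) (1 - cx) / dx else Inf
    r_avail <- min(tmax_y, tmax_x) * res
    if (r_avail < r_needed) {
      warning(sprintf("half-ray at %.0f deg leaves the image before %g um; excluded",
                      a * 180 / pi, r_needed))
      next
    }
    s <- seq(0, r_avail, by = res)
    raw <- 100 * bilinear(plane, cy + s / res * dy, cx + s / res * dx) / soma_mean
    cleaned <- excise_fluctuations(raw, res, excess_pp, max_run_um,
                                   median_window_um)
    sel <- s >= soma_boundary_radius + band[1] & s <= soma_boundary_radius + band[2]
    per_ray <- c(per_ray, mean(cleaned[sel]))
    profiles[[length(profiles) + 1L]] <-
      data.frame(distance_um = s, vf_raw = raw, vf = cleaned)
  }
  if (length(per_ray) == 0)
    stop("all half-rays leave the image before the measurement band")
  structure(
    list(characteristic_vf = mean(per_ray), per_ray_vf = per_ray,
         radial_profiles = profiles, soma_mean = soma_mean,
         soma_boundary_radius = soma_boundary_radius, soma_z = soma_z),
    class = "vf_result"
  )
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are taken as z-planes in order.
#'
#' @param path TIFF file path.
#' @param lateral_res,z_step Voxel sizes in micrometers.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, lateral_res = 0.2, z_step = 1.0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  image_stack(arr, lateral_res = lateral_res, z_step = z_step)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` for storage.
#'
#' @param stack An [image_stack()] or `segmentation_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- if (inherits(stack, "segmentation_mask")) stack$mask * 1 else stack$voxels
  vmax <- max(v)
  if (vmax > 0) v <- v / vmax
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path)
  invisible(path)
}
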