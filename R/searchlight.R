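# Searchlight mapping: decode at every in-mask voxel using the voxels
# inside a spherical neighborhood, producing a map of excess accuracy.

#' Integer voxel offsets of a spherical searchlight
#'
#' All integer grid offsets (i, j, k) whose physical distance
#' `spacing * sqrt(i^2 + j^2 + k^2)` is at most `radius_mm` (boundary
#' inclusive), center included. A 10 mm-diameter searchlight on a 1.5 mm
#' grid yields 171 offsets.
#'
#' @param radius_mm Sphere radius in mm (>= 0).
#' @param spacing_mm Isotropic voxel spacing in mm (> 0).
#' @return Integer matrix (n_offsets x 3).
#' @export
#' @examples
#' nrow(sphere_offsets(5, 1.5))  # 171
sphere_offsets <- function(radius_mm = 5, spacing_mm = 1.5) {
  check_param(radius_mm >= 0, "`radius_mm` must be >= 0")
  check_param(spacing_mm > 0, "`spacing_mm` must be > 0")
  r <- floor(radius_mm / spacing_mm)
  g <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  g[rowSums(g^2) * spacing_mm^2 <= radius_mm^2 + 1e-12, , drop = FALSE]
}

#' Searchlight map of excess decoding accuracy
#'
#' For every in-mask voxel, decodes the condition using the voxels inside
#' the sphere intersected with the mask (running-index folds, linear SVM)
#' and subtracts the center-specific permutation chance mean. A center
#' whose sphere contains no other in-mask voxel still uses its own voxel.
#'
#' @param B Trials x voxels matrix (retained trials, z-scored rows align
#'   with `labels`).
#' @param coords Integer voxel grid coordinates, one row per column of `B`.
#' @param labels Binary class labels per row of `B`.
#' @param radius_mm Searchlight radius in mm (10 mm diameter by default).
#' @param spacing_mm Voxel spacing in mm.
#' @param n_perm Permutations per center for the local chance level
#'   (reduced relative to region-of-interest analyses for tractability).
#' @param seed Integer seed.
#' @param cost SVM cost parameter.
#' @param centers Optional subset of voxel indices to use as centers
#'   (default: all).
#' @return A `data.frame` of class `"fc_searchlight"`: coordinates,
#'   `n_voxels` in each sphere, `raw_accuracy`, `chance_mean`,
#'   `excess_accuracy`.
#' @export
run_searchlight <- function(B, coords, labels, radius_mm = 5, spacing_mm = 1.5,
                            n_perm = 100L, seed = 1L, cost = 1,
                            centers = seq_len(ncol(B))) {
  coords <- as.matrix(coords)
  check_param(nrow(coords) == ncol(B), "`coords` must have one row per voxel")
  check_param(length(centers) >= 1, "mask is empty: no centers to map")
  offs <- sphere_offsets(radius_mm, spacing_mm)
  # hash occupied grid positions for O(1) sphere lookup
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  kk <- key(coords)
  for (v in seq_len(ncol(B))) assign(kk[v], v, envir = lookup)
  folds <- make_running_index_folds(labels)
  seeds <- spawn_seeds(seed, length(centers))

  rows <- lapply(seq_along(centers), function(ci) {
    cen <- centers[ci]
    neigh_keys <- key(sweep(offs, 2, coords[cen, ], "+"))
    vox <- unlist(lapply(neigh_keys, function(k)
      if (exists(k, envir = lookup, inherits = FALSE)) get(k, envir = lookup)),
      use.names = FALSE)
    Bs <- B[, vox, drop = FALSE]
    raw <- decode_condition(Bs, labels, folds, cost)
    ch <- permutation_chance(Bs, labels, n_perm = n_perm, seed = seeds[ci],
                             cost = cost)
    data.frame(x = coords[cen, 1], y = coords[cen, 2], z = coords[cen, 3],
               n_voxels = length(vox), raw_accuracy = raw,
               chance_mean = ch$chance_mean,
               excess_accuracy = raw - ch$chance_mean)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fc_searchlight", "data.frame")
  attr(out, "radius_mm") <- radius_mm
  attr(out, "spacing_mm") <- spacing_mm
  out
}

#' Render a searchlight map as a 3-D volume array
#'
#' @param map An `"fc_searchlight"` data frame.
#' @param dims Volume dimensions; default the map's bounding box.
#' @param value Column to render.
#' @param fill Value outside the mapped voxels.
#' @return A 3-D numeric array.
#' @export
searchlight_volume <- function(map, dims = c(max(map$x), max(map$y), max(map$z)),
                               value = "excess_accuracy", fill = NA_real_) {
  vol <- array(fill, dim = dims)
  vol[cbind(map$x, map$y, map$z)] <- map[[value]]
  vol
}

#' Gaussian smoothing of a volume map
#'
#' Separable Gaussian filter parameterized by full width at half maximum,
#' as used to smooth group-space accuracy maps before inspection. `NA`
#' voxels (outside the mask) are ignored with local kernel renormalization.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Full width at half maximum in mm.
#' @param spacing_mm Voxel spacing in mm.
#' @return Smoothed array of the same dimensions (`NA` pattern preserved).
#' @export
smooth_volume <- function(vol, fwhm_mm = 8, spacing_mm = 1.5) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  mask <- !is.na(vol)
  x <- vol
  x[!mask] <- 0
  w <- array(as.numeric(mask), dim = dim(vol))
  conv_axis <- function(a, axis) {
    out <- array(0, dim = dim(a))
    for (s in -r:r) {
      shifted <- shift_array(a, s, axis)
      out <- out + k[s + r + 1] * shifted
    }
    out
  }
  for (axis in 1:3) {
    x <- conv_axis(x, axis)
    w <- conv_axis(w, axis)
  }
  out <- x / w
  out[!mask] <- NA_real_
  out
}

# Shift a 3-D array by s along one axis, zero-padding.
shift_array <- function(a, s, axis) {
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- if (s >= 0) (1 + s):n else 1:(n + s)
  idx_src <- idx_dst <- list(quote(expr =), quote(expr =), quote(expr =))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  out
}
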