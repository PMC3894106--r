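#' Build the analysis region of interest
#'
#' Applies the ROI rules in order: start from the volume's `inside_mask`
#' (dosimeter material; channel and source already excluded), drop voxels
#' with zero or negative intensity, then binary-erode the surviving mask
#' with a Euclidean ball of the given radius.  Because the non-positive
#' exclusion runs before the erosion, a shell is also removed around every
#' imperfection, not just around the dosimeter surface.
#'
#' @param volume A [dose_volume()] with an `inside_mask`.
#' @param erosion_mm Ball structuring-element radius in mm (>= 0);
#'   default 1.5 mm (3 voxels at 0.5 mm spacing).
#' @return An object of class `roi_mask`: list with `mask` (logical array)
#'   and `provenance` (voxels removed by each rule).
#' @export
build_roi <- function(volume, erosion_mm = 1.5) {
  if (is.null(volume$inside_mask)) stopf("volume has no inside_mask")
  if (erosion_mm < 0) stopf("erosion radius must be >= 0")
  m0 <- volume$inside_mask
  n_total <- length(m0)
  n_inside <- sum(m0)
  if (n_inside == 0L) stopf("inside_mask is empty")

  m1 <- m0 & volume$intensity > 0
  n_pos <- sum(m1)
  if (n_pos == 0L) stopf("no voxels with positive intensity inside the mask")

  m2 <- erode_ball(m1, erosion_mm, volume$spacing_mm)
  n_final <- sum(m2)
  if (n_final == 0L) {
    stopf("erosion with radius %.3g mm removed every voxel; reduce the radius",
          erosion_mm)
  }
  structure(list(mask = m2,
                 provenance = c(outside_or_channel = n_total - n_inside,
                                nonpositive = n_inside - n_pos,
                                erosion = n_pos - n_final),
                 erosion_mm = erosion_mm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d voxels retained (erosion radius %.3g mm)\n",
              sum(x$mask), x$erosion_mm))
  p <- x$provenance
  cat(sprintf("  removed: %d outside/channel, %d non-positive, %d by erosion\n",
              p[["outside_or_channel"]], p[["nonpositive"]], p[["erosion"]]))
  invisible(x)
}

#' Binary erosion with a Euclidean ball
#'
#' A voxel survives iff every voxel whose center lies within `radius_mm` of
#' it (Euclidean distance in physical units) is also in the mask; voxels
#' beyond the array border count as background.  Implemented as an AND over
#' shifted copies of the mask, one per structuring-element offset.
#'
#' @param mask Logical 3D array.
#' @param radius_mm Ball radius in mm.
#' @param spacing_mm Voxel spacing per axis in mm (length 1 or 3).
#' @return Logical array of the same dimension.
#' @export
erode_ball <- function(mask, radius_mm, spacing_mm) {
  if (radius_mm == 0) return(mask)
  spacing_mm <- rep_len(spacing_mm, 3L)
  dims <- dim(mask)
  ## a ball wider than the array reaches past the (background) border from
  ## every voxel: nothing survives
  if (any(floor(radius_mm / spacing_mm) >= dims)) {
    return(array(FALSE, dims))
  }
  off <- ball_offsets(radius_mm, spacing_mm)
  out <- mask
  for (q in seq_len(nrow(off))) {
    o <- off[q, ]
    if (all(o == 0L)) next
    out <- out & shift_mask(mask, o, dims)
    if (!any(out)) break
  }
  out
}

ball_offsets <- function(radius_mm, spacing_mm) {
  nmax <- floor(radius_mm / spacing_mm)
  g <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2], k = -nmax[3]:nmax[3])
  d2 <- (g$i * spacing_mm[1])^2 + (g$j * spacing_mm[2])^2 + (g$k * spacing_mm[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

## mask shifted by offset o, padded with FALSE: result[v] = mask[v + o]
shift_mask <- function(mask, o, dims) {
  out <- array(FALSE, dims)
  if (any(abs(o) >= dims)) return(out)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (o[a] >= 0) {
      dst[[a]] <- seq_len(dims[a] - o[a])
      src[[a]] <- seq_len(dims[a] - o[a]) + o[a]
    } else {
      dst[[a]] <- seq_len(dims[a] + o[a]) - o[a]
      src[[a]] <- seq_len(dims[a] + o[a])
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}
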