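#' Voxelized dose volume
#'
#' A 3D scalar intensity grid (Gy, or any unit linear in dose) with isotropic
#' or per-axis spacing, a physical origin, and a boolean `inside_mask`
#' marking dosimeter material (excluding surrounding air, the drilled source
#' channel and the source itself).  Coordinate contract: the center of voxel
#' with 0-based index (i, j, k) lies at `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param intensity 3D numeric array.
#' @param spacing_mm Voxel spacing per axis in mm (length 1 or 3).
#' @param origin_mm Physical position (mm) of the center of voxel (0, 0, 0).
#' @param inside_mask Logical array of the same dimension (or NULL).
#' @return An object of class `dose_volume`.
#' @export
dose_volume <- function(intensity, spacing_mm, origin_mm = c(0, 0, 0),
                        inside_mask = NULL) {
  if (length(dim(intensity)) != 3L) stopf("intensity must be a 3D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stopf("spacing must be positive")
  if (!is.null(inside_mask)) {
    if (!identical(dim(inside_mask), dim(intensity))) {
      stopf("inside_mask dimensions must match intensity")
    }
    storage.mode(inside_mask) <- "logical"
  }
  structure(list(intensity = intensity,
                 spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L),
                 inside_mask = inside_mask),
            class = "dose_volume")
}

#' @export
print.dose_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("dose_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  if (!is.null(x$inside_mask)) {
    cat(sprintf("  inside mask: %d voxels (%.1f%%)\n", sum(x$inside_mask),
                100 * mean(x$inside_mask)))
  }
  invisible(x)
}

#' Physical voxel-center coordinates (cm) for linear indices
#' @noRd
voxel_coords_cm <- function(volume, idx) {
  ai <- arrayInd(idx, dim(volume$intensity))
  sweep(sweep((ai - 1), 2L, volume$spacing_mm, `*`),
        2L, volume$origin_mm, `+`) / 10
}

#' Source pose
#'
#' Position of the active-length midpoint (cm) and the unit long-axis
#' direction, pointing from the channel opening toward the channel tip.
#'
#' @param center_cm Numeric length-3, cm.
#' @param axis Numeric length-3 direction (normalized internally).
#' @return An object of class `source_pose`.
#' @export
source_pose <- function(center_cm, axis) {
  structure(list(center_cm = as.numeric(center_cm), axis = unit3(as.numeric(axis))),
            class = "source_pose")
}

#' @export
print.source_pose <- function(x, ...) {
  cat(sprintf("source_pose: center (%.4f, %.4f, %.4f) cm, axis (%.4f, %.4f, %.4f)\n",
              x$center_cm[1], x$center_cm[2], x$center_cm[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Write / read a source pose as JSON
#' @param pose A [source_pose()].
#' @param path Output path (`.json`).
#' @export
write_pose <- function(pose, path) {
  jsonlite::write_json(list(center_cm = pose$center_cm, axis = pose$axis),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  source_pose(p$center_cm, p$axis)
}

#' Write a dose volume to disk
#'
#' Format is inferred from the extension: `.nii` / `.nii.gz` (NIfTI-1, via
#' RNifti; spacing goes to pixdim and the origin into the qform/sform
#' translation) or `.mhd` (MetaImage header + `.raw` little-endian payload).
#' The inside mask, when present, is written alongside as
#' `<stem>_mask.<ext>` (uint8).
#'
#' @param volume A [dose_volume()].
#' @param path Output path.
#' @param write_mask Write the companion mask file if the volume has one.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, write_mask = TRUE) {
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    write_nifti_array(volume$intensity, volume$spacing_mm, volume$origin_mm, path)
  } else {
    write_mhd_array(volume$intensity, volume$spacing_mm, volume$origin_mm, path,
                    element_type = "MET_DOUBLE")
  }
  if (write_mask && !is.null(volume$inside_mask)) {
    mpath <- mask_path_for(path)
    m <- volume$inside_mask
    storage.mode(m) <- "integer"
    if (fmt == "nifti") {
      write_nifti_array(m, volume$spacing_mm, volume$origin_mm, mpath,
                        datatype = "uint8")
    } else {
      write_mhd_array(m, volume$spacing_mm, volume$origin_mm, mpath,
                      element_type = "MET_UCHAR")
    }
  }
  invisible(path)
}

#' Read a dose volume from disk
#'
#' @param path `.nii`, `.nii.gz` or `.mhd` file written by [write_volume()]
#'   (or any file with spacing recorded in its header).
#' @param mask_path Optional companion mask file; defaults to
#'   `<stem>_mask.<ext>` if that file exists.
#' @return A [dose_volume()].
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  fmt <- volume_format(path)
  vol <- if (fmt == "nifti") read_nifti_array(path) else read_mhd_array(path)
  if (is.null(mask_path)) {
    cand <- mask_path_for(path)
    if (file.exists(cand)) mask_path <- cand
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- if (volume_format(mask_path) == "nifti") read_nifti_array(mask_path)
         else read_mhd_array(mask_path)
    mask <- m$data != 0
  }
  dose_volume(vol$data, vol$spacing_mm, vol$origin_mm, mask)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return("mhd")
  stopf("unsupported volume format: %s (use .nii, .nii.gz or .mhd)", path)
}

mask_path_for <- function(path) {
  sub("(\\.nii\\.gz|\\.nii|\\.mhd)$", "_mask\\1", path, ignore.case = TRUE)
}

write_nifti_array <- function(arr, spacing_mm, origin_mm, path, datatype = "double") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  aff <- rbind(cbind(diag(spacing_mm), origin_mm), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  sp <- hdr$pixdim[2:4]
  if (any(sp <= 0)) stopf("NIfTI header of %s has no valid spacing", path)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  list(data = array(as.numeric(img), dim = dim(img)[1:3]),
       spacing_mm = as.numeric(sp), origin_mm = as.numeric(org))
}

## --- Minimal MetaImage (MHD/RAW) support ------------------------------------
## Plain key = value text header plus a raw binary payload; element types
## restricted to what this package writes (double / uchar), little-endian.

write_mhd_array <- function(arr, spacing_mm, origin_mm, path,
                            element_type = "MET_DOUBLE") {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
           sprintf("ElementSpacing = %s", paste(format(spacing_mm, digits = 17),
                                                collapse = " ")),
           sprintf("Offset = %s", paste(format(origin_mm, digits = 17),
                                        collapse = " ")),
           sprintf("ElementType = %s", element_type),
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (element_type == "MET_DOUBLE") {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  } else if (element_type == "MET_UCHAR") {
    writeBin(as.raw(as.integer(arr)), con)
  } else {
    stopf("unsupported MetaImage element type %s", element_type)
  }
  invisible(path)
}

read_mhd_array <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  getv <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stopf("MetaImage header %s missing key %s", path, k)
    vals[i]
  }
  dims <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing"), "\\s+")[[1]])
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("MetaImage header %s has invalid ElementSpacing", path)
  }
  offset <- if ("Offset" %in% keys) {
    as.numeric(strsplit(getv("Offset"), "\\s+")[[1]])
  } else c(0, 0, 0)
  etype <- getv("ElementType")
  datafile <- file.path(dirname(path), getv("ElementDataFile"))
  n <- prod(dims)
  con <- file(datafile, "rb")
  on.exit(close(con))
  data <- if (etype == "MET_DOUBLE") {
    readBin(con, "numeric", n = n, size = 8L, endian = "little")
  } else if (etype == "MET_UCHAR") {
    as.numeric(readBin(con, "raw", n = n))
  } else {
    stopf("unsupported MetaImage element type %s", etype)
  }
  list(data = array(data, dim = dims), spacing_mm = spacing, origin_mm = offset)
}
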