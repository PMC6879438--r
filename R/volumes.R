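#' PET volume in SUV units
#'
#' A 3D grid of body-weight-normalized standardized uptake values together
#' with its physical voxel spacing. Values must be finite and non-negative.
#' Voxel indexing follows R array conventions (x fastest); on disk, seed
#' tables use 0-based indices (see [read_seeds()]).
#'
#' @param grid numeric 3D array of SUV.
#' @param spacing_mm positive numeric vector of length 3 (mm), default the
#'   scanner voxel size 5.5 x 5.5 x 3.3 mm.
#' @param patient_id identifier carried through feature tables.
#' @return an object of class `pet_volume`.
#' @export
pet_volume <- function(grid, spacing_mm = c(5.5, 5.5, 3.3), patient_id = "P1") {
  if (!is.array(grid) || length(dim(grid)) != 3)
    stop_ctx("grid must be a 3D array")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop_ctx("SUV values must be finite and >= 0")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_ctx("spacing_mm must be 3 positive numbers")
  structure(list(grid = grid, spacing_mm = spacing_mm,
                 patient_id = as.character(patient_id)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume %s: %s voxels @ %s mm, SUV range [%.2f, %.2f]>\n",
              x$patient_id, paste(dim(x$grid), collapse = "x"),
              paste(x$spacing_mm, collapse = "x"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

voxel_volume_ml <- function(volume) prod(volume$spacing_mm) / 1000

#' Read a PET volume from a NIfTI file
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param patient_id identifier; defaults to the file stem.
#' @return a [pet_volume()].
#' @export
load_volume <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3)
    stop_ctx("expected a 3D volume, got ", length(dm), "D: ", path)
  arr <- array(as.numeric(img), dm)   # plain array, no header attributes
  # header pixdim is float32; round to its 7 significant decimal digits
  sp <- signif(RNifti::pixdim(img)[seq_len(3)], 7)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop_ctx("missing or invalid voxel spacing in header: ", path)
  if (any(arr < 0)) stop_ctx("negative SUV values in ", path)
  pid <- patient_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  pet_volume(arr, sp, pid)
}

#' Write a PET volume (or mask) to NIfTI
#'
#' @param volume a [pet_volume()] or `tmtv_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "tmtv_mask")) {
    arr <- array(as.numeric(volume$mask), dim(volume$mask))
    sp <- volume$spacing_mm
  } else {
    arr <- volume$grid
    sp <- volume$spacing_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a seed-point table
#'
#' Seed CSVs store 0-based voxel indices (`patient_id,x,y,z`); this returns
#' 1-based indices for use with R arrays.
#'
#' @param path CSV path.
#' @return data.frame with columns patient_id, x, y, z (1-based).
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "x", "y", "z")
  if (!all(need %in% names(df))) stop_ctx("seed CSV needs columns ", paste(need, collapse = ", "))
  df$x <- df$x + 1L; df$y <- df$y + 1L; df$z <- df$z + 1L
  df
}

#' Segment a single lesion by fixed-fraction SUVmax region growing
#'
#' Grows a region from a seed voxel: the threshold is
#' `threshold_fraction` times the current region's maximum SUV, the region is
#' the connected component (default 26-connectivity) of voxels at or above
#' the threshold, and the procedure is iterated to a fixed point so that the
#' result does not depend on where inside the lesion the seed was placed.
#' The default fraction 0.41 is the recommended 41% SUVmax threshold for
#' lymphoma metabolic tumour volumes.
#'
#' @param volume a [pet_volume()].
#' @param seed integer vector of length 3, 1-based voxel index.
#' @param threshold_fraction fraction of the region maximum, default 0.41.
#' @param connectivity 26 (default) or 6.
#' @param background_floor seeds with SUV below this are rejected as
#'   background (default 1.0).
#' @param max_iter fixed-point iteration cap.
#' @return logical 3D array marking the lesion.
#' @export
segment_lesion <- function(volume, seed, threshold_fraction = 0.41,
                           connectivity = 26, background_floor = 1.0,
                           max_iter = 100) {
  suv <- volume$grid
  dm <- dim(suv)
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > dm))
    stop_ctx("seed outside the grid")
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 || threshold_fraction > 1)
    stop_ctx("threshold_fraction must be in (0, 1]")
  if (suv[seed[1], seed[2], seed[3]] < background_floor)
    stop_ctx(sprintf("seed (%d,%d,%d) lies on background (SUV %.3g < floor %.3g)",
                     seed[1], seed[2], seed[3], suv[seed[1], seed[2], seed[3]], background_floor))
  region <- array(FALSE, dm)
  region[seed[1], seed[2], seed[3]] <- TRUE
  cur_max <- suv[seed[1], seed[2], seed[3]]
  grow_from <- seed
  for (i in seq_len(max_iter)) {
    thr <- threshold_fraction * cur_max
    cand <- suv >= thr
    # grow from the current region's hottest voxel (always a candidate),
    # making the fixed point independent of the original seed position
    new_region <- flood_fill(cand, grow_from, connectivity)
    if (identical(new_region, region)) break
    region <- new_region
    cur_max <- max(suv[region])
    grow_from <- idx_to_vox(which(region)[which.max(suv[region])], dm)[1, ]
  }
  region
}

#' Build a total metabolic tumour volume (TMTV) mask
#'
#' Union of per-seed region-growing segmentations; overlapping or touching
#' lesions merge, and lesion labels are reassigned by connected-component
#' labelling of the union. Total volume is voxel count times voxel volume.
#'
#' @inheritParams segment_lesion
#' @param seeds matrix/data.frame of 1-based voxel indices, one seed per row
#'   (columns x, y, z).
#' @return an object of class `tmtv_mask` with elements `mask` (logical
#'   array), `component_labels` (integer array), `n_components`,
#'   `volume_ml` and `spacing_mm`.
#' @export
build_tmtv <- function(volume, seeds, threshold_fraction = 0.41,
                       connectivity = 26, background_floor = 1.0) {
  seeds <- as.matrix(seeds)
  if (nrow(seeds) < 1) stop_ctx("at least one seed is required")
  mask <- array(FALSE, dim(volume$grid))
  for (i in seq_len(nrow(seeds))) {
    mask <- mask | segment_lesion(volume, seeds[i, seq_len(3)],
                                  threshold_fraction = threshold_fraction,
                                  connectivity = connectivity,
                                  background_floor = background_floor)
  }
  if (!any(mask)) stop_ctx("empty TMTV: no voxel passed the threshold")
  labels <- label_components(mask, connectivity)
  structure(list(mask = mask,
                 component_labels = labels,
                 n_components = max(labels),
                 volume_ml = sum(mask) * voxel_volume_ml(volume),
                 spacing_mm = volume$spacing_mm),
            class = "tmtv_mask")
}

#' @export
print.tmtv_mask <- function(x, ...) {
  cat(sprintf("<tmtv_mask: %d voxels, %d lesion component(s), %.2f mL>\n",
              sum(x$mask), x$n_components, x$volume_ml))
  invisible(x)
}

#' Wrap an externally supplied lesion mask as a TMTV mask
#'
#' Alternate input path for cohorts where lesions were delineated manually:
#' accepts any logical array aligned to the volume.
#'
#' @param volume a [pet_volume()].
#' @param mask logical array of the same shape.
#' @param connectivity 26 (default) or 6, for component labelling.
#' @return a `tmtv_mask`.
#' @export
as_tmtv_mask <- function(volume, mask, connectivity = 26) {
  if (!identical(dim(mask), dim(volume$grid))) stop_ctx("mask shape must match the volume")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop_ctx("mask is empty")
  labels <- label_components(mask, connectivity)
  structure(list(mask = mask, component_labels = labels,
                 n_components = max(labels),
                 volume_ml = sum(mask) * voxel_volume_ml(volume),
                 spacing_mm = volume$spacing_mm),
            class = "tmtv_mask")
}
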