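#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(..., call. = FALSE)

#' Neighbour offsets for a 3D connectivity scheme
#'
#' @param connectivity 26 (vertex/edge/face neighbours) or 6 (face neighbours).
#' @return integer matrix, one offset per row.
#' @keywords internal
conn_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    stop_ctx("connectivity must be 6 or 26")
  }
}

# Flat indices <-> voxel coordinates (1-based, x fastest)
vox_to_idx <- function(v, dm) v[, 1] + (v[, 2] - 1L) * dm[1] + (v[, 3] - 1L) * dm[1] * dm[2]

idx_to_vox <- function(idx, dm) {
  idx0 <- idx - 1L
  cbind(idx0 %% dm[1] + 1L,
        (idx0 %/% dm[1]) %% dm[2] + 1L,
        idx0 %/% (dm[1] * dm[2]) + 1L)
}

#' Flood fill: connected component of a candidate set containing a seed
#'
#' Breadth-first search over a logical 3D array with 6- or 26-connectivity.
#' Returns an all-FALSE array if the seed itself is not a candidate.
#'
#' @param candidate logical 3D array.
#' @param seed integer vector of length 3 (1-based voxel index).
#' @param connectivity 6 or 26.
#' @return logical array of the same shape marking the component.
#' @keywords internal
flood_fill <- function(candidate, seed, connectivity = 26) {
  dm <- dim(candidate)
  out <- array(FALSE, dm)
  if (!candidate[seed[1], seed[2], seed[3]]) return(out)
  offs <- conn_offsets(connectivity)
  k <- nrow(offs)
  out[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(as.integer(seed), nrow = 1)
  while (nrow(frontier) > 0) {
    n <- nrow(frontier)
    nb <- frontier[rep(seq_len(n), each = k), , drop = FALSE] +
      offs[rep(seq_len(k), times = n), , drop = FALSE]
    keep <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
      nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) == 0) break
    idx <- vox_to_idx(nb, dm)
    ok <- candidate[idx] & !out[idx]
    idx <- unique(idx[ok])
    if (length(idx) == 0) break
    out[idx] <- TRUE
    frontier <- idx_to_vox(idx, dm)
  }
  out
}

#' Label connected components of a 3D logical mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array: 0 outside the mask, 1..k per component.
#' @keywords internal
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  labels <- array(0L, dm)
  remaining <- mask
  lab <- 0L
  while (any(remaining)) {
    seed_idx <- which(remaining)[1]
    seed <- idx_to_vox(seed_idx, dm)[1, ]
    comp <- flood_fill(remaining, seed, connectivity)
    lab <- lab + 1L
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  labels
}

# Cache for FFTs of smoothing kernels, keyed by (dim, sigma in voxels)
.kernel_cache <- new.env(parent = emptyenv())

gaussian_kernel_fft <- function(dm, sigma_vox) {
  key <- paste(c(dm, signif(sigma_vox, 6)), collapse = "_")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- function(n, s) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
    if (s <= 0) as.numeric(d == 0) else exp(-0.5 * (d / s)^2)
  }
  k <- outer(outer(ax(dm[1], sigma_vox[1]), ax(dm[2], sigma_vox[2])), ax(dm[3], sigma_vox[3]))
  k <- k / sum(k)
  fk <- fft(k)
  .kernel_cache[[key]] <- fk
  fk
}

#' Spatially correlated Gaussian random field
#'
#' White noise smoothed by a periodic Gaussian kernel (FFT convolution) and
#' standardized to zero mean / unit variance over the grid. An infinite
#' correlation length yields an exactly constant (all-zero) field.
#'
#' @param dm grid dimensions (length 3).
#' @param spacing_mm voxel spacing in mm (length 3).
#' @param corr_length_mm correlation length in mm (may be `Inf`).
#' @return numeric 3D array.
#' @keywords internal
gaussian_random_field <- function(dm, spacing_mm, corr_length_mm) {
  if (is.infinite(corr_length_mm)) return(array(0, dm))
  w <- array(rnorm(prod(dm)), dm)
  if (corr_length_mm <= 0) {
    f <- w
  } else {
    fk <- gaussian_kernel_fft(dm, corr_length_mm / spacing_mm)
    f <- Re(fft(fft(w) * fk, inverse = TRUE)) / prod(dm)
  }
  s <- stats::sd(f)
  if (s < 1e-12) return(array(0, dm))
  (f - mean(f)) / s
}
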