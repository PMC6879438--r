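#' The 16 co-occurrence texture feature names
#'
#' Order used throughout feature tables.
#' @export
TEXTURE_FEATURES <- c(
  "entropy", "homogeneity", "contrast", "correlation",
  "angular_second_moment", "difference_entropy", "difference_variance",
  "inverse_difference_moment", "sum_average", "sum_entropy", "sum_variance",
  "cluster_prominence", "cluster_shade", "maximum_probability", "imc1", "imc2"
)

#' First-order SUV features over a tumour mask
#'
#' SUVmax/SUVmean over masked voxels; TMTV in mL; TLG as the exact product
#' TMTV x SUVmean; SUVpeak as the maximum, over masked voxels, of the mean
#' SUV in a 1 mL sphere centred on the voxel (voxel-centre inclusion rule,
#' clipped to the grid).
#'
#' @param volume a [pet_volume()].
#' @param mask a `tmtv_mask` or logical array.
#' @param peak_volume_ml sphere volume for SUVpeak (default 1 mL).
#' @return data.frame with suv_max, suv_mean, suv_peak, tmtv_ml, tlg.
#' @export
first_order <- function(volume, mask, peak_volume_ml = 1) {
  m <- if (inherits(mask, "tmtv_mask")) mask$mask else mask
  if (!any(m)) stop_ctx("empty mask")
  suv <- volume$grid
  vals <- suv[m]
  tmtv_ml <- sum(m) * voxel_volume_ml(volume)
  suv_mean <- mean(vals)
  data.frame(
    suv_max = max(vals),
    suv_mean = suv_mean,
    suv_peak = suv_peak(volume, m, peak_volume_ml),
    tmtv_ml = tmtv_ml,
    tlg = tmtv_ml * suv_mean
  )
}

#' Voxel offsets whose centres fall within a sphere of given volume
#' @keywords internal
sphere_offsets <- function(spacing_mm, volume_ml = 1) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  n <- ceiling(r / spacing_mm)
  g <- as.matrix(expand.grid(x = -n[1]:n[1], y = -n[2]:n[2], z = -n[3]:n[3]))
  d2 <- (g[, 1] * spacing_mm[1])^2 + (g[, 2] * spacing_mm[2])^2 + (g[, 3] * spacing_mm[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

suv_peak <- function(volume, mask, peak_volume_ml = 1) {
  suv <- volume$grid
  dm <- dim(suv)
  offs <- sphere_offsets(volume$spacing_mm, peak_volume_ml)
  centres <- idx_to_vox(which(mask), dm)
  sums <- numeric(nrow(centres))
  counts <- numeric(nrow(centres))
  for (i in seq_len(nrow(offs))) {
    nb <- centres + matrix(offs[i, ], nrow(centres), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    idx <- vox_to_idx(nb[ok, , drop = FALSE], dm)
    sums[ok] <- sums[ok] + suv[idx]
    counts[ok] <- counts[ok] + 1
  }
  max(sums / counts)
}

#' Fixed-bin-number grey-level quantization over a mask
#'
#' Discretizes masked SUV values to integer levels 1..`n_bins` over the
#' masked range: `level = min(G, floor(G * (x - min)/(max - min)) + 1)`.
#' A constant region maps entirely to level 1.
#'
#' @param volume a [pet_volume()].
#' @param mask a `tmtv_mask` or logical array.
#' @param n_bins number of grey levels G (default 64).
#' @return object of class `quantized_volume`: integer array (`NA` outside
#'   the mask), `n_bins`, and the masked `range` used.
#' @export
quantize <- function(volume, mask, n_bins = 64) {
  m <- if (inherits(mask, "tmtv_mask")) mask$mask else mask
  if (!any(m)) stop_ctx("empty mask")
  if (n_bins < 2) stop_ctx("n_bins must be >= 2")
  suv <- volume$grid
  vals <- suv[m]
  lo <- min(vals); hi <- max(vals)
  q <- array(NA_integer_, dim(suv))
  if (hi - lo <= 0) {
    q[m] <- 1L
  } else {
    q[m] <- pmin.int(n_bins, floor(n_bins * (vals - lo) / (hi - lo)) + 1L)
  }
  structure(list(levels = q, n_bins = as.integer(n_bins), range = c(lo, hi),
                 binning = "fixed bin number over masked range"),
            class = "quantized_volume")
}

#' The 13 canonical 3D co-occurrence directions
#'
#' Unique neighbour offsets up to sign (half of the 26 neighbours).
#' @return 13 x 3 integer matrix.
#' @export
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep one of each +-pair: first nonzero component positive
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(g[keep, , drop = FALSE])
}

#' 3D grey-level co-occurrence matrices
#'
#' For each of the 13 canonical directions, counts ordered voxel pairs
#' separated by `distance` times the offset with both endpoints inside the
#' mask, then symmetrizes by adding the transpose. A direction is valid when
#' its (unsymmetrized) pair count reaches `min_pairs` (default 20 pairs).
#'
#' @param q a [quantize()]d volume.
#' @param distance interpixel distance in voxels (default 1).
#' @param min_pairs minimum pair count for a direction to be usable.
#' @return object of class `glcm_set`: per-direction symmetric count
#'   matrices, pair counts and validity flags.
#' @export
glcm_3d <- function(q, distance = 1, min_pairs = 20) {
  if (distance < 1) stop_ctx("distance must be >= 1")
  lv <- q$levels
  G <- q$n_bins
  dm <- dim(lv)
  dirs <- glcm_directions() * as.integer(distance)
  mats <- vector("list", nrow(dirs))
  pairs <- integer(nrow(dirs))
  safe_seq <- function(lo, hi) if (lo > hi) integer(0) else lo:hi
  for (d in seq_len(nrow(dirs))) {
    o <- dirs[d, ]
    # source block A and shifted block B such that B = A + offset
    ax <- safe_seq(max(1, 1 - o[1]), min(dm[1], dm[1] - o[1]))
    ay <- safe_seq(max(1, 1 - o[2]), min(dm[2], dm[2] - o[2]))
    az <- safe_seq(max(1, 1 - o[3]), min(dm[3], dm[3] - o[3]))
    if (length(ax) == 0 || length(ay) == 0 || length(az) == 0) {
      mats[[d]] <- matrix(0, G, G); next
    }
    a <- lv[ax, ay, az, drop = FALSE]
    b <- lv[ax + o[1], ay + o[2], az + o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    av <- a[ok]; bv <- b[ok]
    cnt <- matrix(tabulate((av - 1L) * G + bv, nbins = G * G), G, G, byrow = TRUE)
    pairs[d] <- length(av)
    mats[[d]] <- cnt + t(cnt)
  }
  structure(list(matrices = mats, pair_counts = pairs,
                 valid = pairs >= min_pairs, directions = dirs,
                 n_bins = G, distance = distance, min_pairs = min_pairs),
            class = "glcm_set")
}

# Static per-G index structures, cached (feature extraction is called once
# per patient and direction over a fixed bin count)
.haralick_cache <- new.env(parent = emptyenv())

haralick_indices <- function(G) {
  key <- as.character(G)
  hit <- .haralick_cache[[key]]
  if (!is.null(hit)) return(hit)
  I <- matrix(seq_len(G), G, G)
  J <- t(I)
  out <- list(I = I, J = J, IJ = I * J, IpJ = I + J,
              ImJ2 = (I - J)^2, absImJ = abs(I - J))
  .haralick_cache[[key]] <- out
  out
}

# All 16 Haralick features from one normalized symmetric GLCM.
# Entropies in log base `log_base`; zero-probability cells are omitted
# (the exact p*log p -> 0 limit), never epsilon-padded.
haralick_features <- function(P, log_base = 2) {
  G <- nrow(P)
  lg <- function(x) log(x, base = log_base)
  ix <- haralick_indices(G)
  I <- ix$I; J <- ix$J
  pos <- P > 0
  entropy <- -sum(P[pos] * lg(P[pos]))
  asm <- sum(P^2)
  maxprob <- max(P)
  contrast <- sum(ix$ImJ2 * P)
  homogeneity <- sum(P / (1 + ix$absImJ))
  idm <- sum(P / (1 + ix$ImJ2))
  px <- rowSums(P)                      # symmetric: px == py
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  correlation <- if (sig2 > 0) (sum(ix$IJ * P) - mu^2) / sig2 else 1
  # p_{x+y}, k = 2..2G ; p_{x-y}, k = 0..G-1 (accumulated along diagonals)
  ks <- 2:(2 * G); kd <- 0:(G - 1)
  psum <- as.numeric(rowsum(as.vector(P), as.vector(ix$IpJ)))
  pdiff <- as.numeric(rowsum(as.vector(P), as.vector(ix$absImJ)))
  sum_average <- sum(ks * psum)
  sum_entropy <- -sum(psum[psum > 0] * lg(psum[psum > 0]))
  sum_variance <- sum((ks - sum_average)^2 * psum)
  diff_average <- sum(kd * pdiff)
  difference_entropy <- -sum(pdiff[pdiff > 0] * lg(pdiff[pdiff > 0]))
  difference_variance <- sum((kd - diff_average)^2 * pdiff)
  dev <- ix$IpJ - 2 * mu
  cluster_shade <- sum(dev^3 * P)
  cluster_prominence <- sum(dev^4 * P)
  hx <- -sum(px[px > 0] * lg(px[px > 0]))
  pxy <- outer(px, px)
  hxy1 <- -sum(P[pos] * lg(pxy[pos]))
  posm <- pxy > 0
  hxy2 <- -sum(pxy[posm] * lg(pxy[posm]))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy) * log(log_base))))
  c(entropy = entropy, homogeneity = homogeneity, contrast = contrast,
    correlation = correlation, angular_second_moment = asm,
    difference_entropy = difference_entropy,
    difference_variance = difference_variance,
    inverse_difference_moment = idm, sum_average = sum_average,
    sum_entropy = sum_entropy, sum_variance = sum_variance,
    cluster_prominence = cluster_prominence, cluster_shade = cluster_shade,
    maximum_probability = maxprob, imc1 = imc1, imc2 = imc2)
}

#' Direction-averaged co-occurrence texture features
#'
#' Computes the 16 Haralick features per valid direction from the normalized
#' symmetric matrix and returns their arithmetic mean over valid directions;
#' directions with fewer than `min_pairs` pairs are excluded from the mean.
#'
#' @param glcms a [glcm_3d()] result.
#' @param min_pairs override of the validity rule (default: as recorded).
#' @param log_base base for all entropies (default 2; the Entropy scale, and
#'   hence any absolute Entropy cutoff, depends on this choice).
#' @return named numeric vector of the 16 features, with attributes
#'   `n_valid_directions`.
#' @export
texture_features <- function(glcms, min_pairs = NULL, log_base = 2) {
  min_pairs <- min_pairs %||% glcms$min_pairs
  valid <- glcms$pair_counts >= min_pairs
  if (!any(valid))
    stop_ctx("no direction satisfies the minimum of ", min_pairs,
             " pixel pairs; texture features undefined")
  feats <- vapply(which(valid), function(d) {
    M <- glcms$matrices[[d]]
    haralick_features(M / sum(M), log_base = log_base)
  }, numeric(16))
  out <- rowMeans(feats)
  attr(out, "n_valid_directions") <- sum(valid)
  out
}

#' Extract the full radiomic feature vector for one patient
#'
#' Composes [first_order()] with [quantize()] -> [glcm_3d()] ->
#' [texture_features()].
#'
#' @inheritParams first_order
#' @param n_bins grey levels for quantization (default 64).
#' @param distance co-occurrence interpixel distance (default 1).
#' @param min_pairs per-direction pair minimum (default 20).
#' @param log_base entropy log base (default 2).
#' @return one-row data.frame: patient_id, first-order features, and the 16
#'   texture features.
#' @export
extract_all <- function(volume, mask, n_bins = 64, distance = 1,
                        min_pairs = 20, log_base = 2) {
  fo <- first_order(volume, mask)
  q <- quantize(volume, mask, n_bins)
  tx <- texture_features(glcm_3d(q, distance, min_pairs),
                         min_pairs = min_pairs, log_base = log_base)
  cbind(data.frame(patient_id = volume$patient_id, stringsAsFactors = FALSE),
        fo, as.data.frame(as.list(tx)))
}
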