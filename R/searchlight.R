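#' Sphere neighborhood offsets on a voxel grid
#'
#' Integer offsets `(dx, dy, dz)` with Euclidean length at most
#' `radius_voxels` (center included, distance in voxel units, boundary
#' inclusive).
#'
#' @param radius_voxels sphere radius in voxels (>= 1).
#' @return Integer matrix `n_offsets x 3`.
#' @export
sphere_offsets <- function(radius_voxels = 4) {
  if (radius_voxels < 1) stop("radius_voxels must be at least 1")
  r <- floor(radius_voxels)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- sqrt(g$dx^2 + g$dy^2 + g$dz^2) <= radius_voxels
  as.matrix(g[keep, , drop = FALSE])
}

#' Synthesize voxel-grid pattern volumes for searchlight analyses
#'
#' Builds per-run, per-condition t-value-like volumes on a voxel grid. Voxels
#' inside `signal_region` carry the planted letter codes (with hand-dependence
#' `mix`, see [synthesize_roi_patterns]); all other in-mask voxels carry pure
#' noise.
#'
#' @param dim grid dimensions `c(nx, ny, nz)`.
#' @param mask logical array of grid shape (default: all voxels in-mask).
#' @param signal_region logical array marking the signal-carrying voxels.
#' @param spec an [effect_spec].
#' @param n_runs number of runs (>= 5).
#' @param mix hand-dependence of the planted code in the signal region.
#' @param noise_sd voxel noise SD.
#' @return List: `data` (runs x 16 x n_vox), `voxels` (n_vox x 3 integer
#'   coordinates of in-mask voxels), `dim`, `mask`.
#' @export
synthesize_volume_patterns <- function(dim, mask = NULL, signal_region = NULL,
                                       spec = effect_spec(), n_runs = 10L,
                                       mix = 0.5, noise_sd = 1) {
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(all(base::dim(mask) == dim))
  if (n_runs < 5L) stop("n_runs must be at least 5 to form 5 pseudo-runs")
  vox <- which(mask, arr.ind = TRUE)
  n_vox <- nrow(vox)
  in_signal <- if (is.null(signal_region)) rep(FALSE, n_vox) else signal_region[vox]
  ct <- condition_table()
  pat <- draw_condition_patterns(spec, n_features = max(1L, sum(in_signal)))
  mean_pat <- matrix(0, 16, n_vox)
  if (any(in_signal)) {
    planted <- mix * spec$sensory_snr * pat$sensory +
      (1 - mix) * spec$perceptual_snr *
        pat$perceptual[match(ct$letter, braille_letters()), , drop = FALSE]
    mean_pat[, in_signal] <- planted
  }
  with_seed(split_seed(spec$seed, "volume_noise"), {
    data <- array(rnorm(n_runs * 16 * n_vox, sd = noise_sd),
                  dim = c(n_runs, 16, n_vox))
    for (cond in 1:16) {
      data[, cond, ] <- data[, cond, ] +
        matrix(mean_pat[cond, ], n_runs, n_vox, byrow = TRUE)
    }
    list(data = data, voxels = vox, dim = dim, mask = mask)
  })
}

#' Volumetric searchlight decoding
#'
#' For every in-mask voxel, decodes letter pairs from the t-patterns of the
#' in-mask voxels within a sphere of `radius_voxels` around it (neighborhoods
#' are truncated at the grid and mask boundary; no out-of-grid access) and
#' stores the pair-averaged accuracy at the center voxel. Runs are averaged
#' into 5 pseudo-runs once, with the same random assignment for every voxel,
#' since runs are reassigned as wholes.
#'
#' @param volume_patterns output of [synthesize_volume_patterns] (or the same
#'   structure built from real data).
#' @param radius_voxels searchlight sphere radius (voxels).
#' @param seed RNG seed for the pseudo-run assignment.
#' @param schemes which schemes to map (default across-hand, optionally also
#'   within-hand).
#' @param C SVM cost parameter.
#' @return An `accuracy_map`: list with per-scheme 3D arrays (`NaN` outside
#'   the mask, % accuracy inside) and the grid metadata.
#' @export
volume_searchlight <- function(volume_patterns, radius_voxels = 4, seed = NULL,
                               schemes = c("across", "within"), C = 1) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  vp <- volume_patterns
  if (nrow(vp$voxels) == 0) stop("mask is empty")
  pseudo <- bin_pseudoruns(vp$data, seed = seed)  # 16 x 5 x n_vox
  lin <- array(NA_integer_, vp$dim)
  lin[vp$voxels] <- seq_len(nrow(vp$voxels))
  offs <- sphere_offsets(radius_voxels)
  maps <- lapply(schemes, function(s) array(NaN, vp$dim))
  names(maps) <- schemes
  for (v in seq_len(nrow(vp$voxels))) {
    ctr <- vp$voxels[v, ]
    nb <- sweep(offs, 2, ctr, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= vp$dim[1] &
      nb[, 2] >= 1 & nb[, 2] <= vp$dim[2] &
      nb[, 3] >= 1 & nb[, 3] <= vp$dim[3]
    ids <- lin[nb[ok, , drop = FALSE]]
    ids <- ids[!is.na(ids)]
    res <- cpp_pairwise_set(pseudo_to_matrix(pseudo[, , ids, drop = FALSE]),
                            C = C,
                            do_within = "within" %in% schemes,
                            do_across = "across" %in% schemes)
    if ("across" %in% schemes) maps$across[ctr[1], ctr[2], ctr[3]] <- mean(res$across)
    if ("within" %in% schemes) maps$within[ctr[1], ctr[2], ctr[3]] <- mean(res$within)
  }
  structure(list(maps = maps, dim = vp$dim, mask = vp$mask,
                 radius_voxels = radius_voxels),
            class = "accuracy_map")
}

#' Nearest-channel neighborhoods of a montage
#'
#' For each channel, the `k` closest other channels by Euclidean distance in
#' montage space. "Surrounding" is read literally: the center channel itself
#' is excluded unless `include_center` is set.
#'
#' @param montage data.frame with `x`, `y`, `z`.
#' @param k neighbors per channel (`k < n_channels`).
#' @param include_center include the center channel in its own neighborhood.
#' @return List of channel index vectors, one per channel.
#' @export
knn_channels <- function(montage, k = 4, include_center = FALSE) {
  n <- nrow(montage)
  if (k >= n) stop("k must be smaller than the number of channels")
  d <- as.matrix(stats::dist(montage[, c("x", "y", "z")]))
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    if (include_center) c(i, nb) else nb
  })
}

#' Sensor-space searchlight decoding, time-resolved
#'
#' For each channel, runs the time-resolved pairwise decoding on the channel's
#' `k` nearest neighbors, stores the pair/hand-averaged accuracy at that
#' channel, and mean-pools the per-sample accuracies into `bin_ms` bins after
#' decoding.
#'
#' @param epochs a (preprocessed) [braille_epochs] object.
#' @param k nearest channels per neighborhood.
#' @param bin_ms temporal bin width (ms) for post-decoding downsampling.
#' @param include_center include the center channel in its neighborhood.
#' @param n_iterations pseudo-trial assignment repetitions.
#' @param seed RNG seed.
#' @param schemes which schemes to map.
#' @param C SVM cost parameter.
#' @return An `accuracy_map`: per scheme a `channels x bins` matrix,
#'   plus `bin_start_ms` and channel names.
#' @export
sensor_searchlight <- function(epochs, k = 4, bin_ms = 10,
                               include_center = FALSE, n_iterations = 1,
                               seed = NULL, schemes = c("within", "across"),
                               C = 1) {
  stopifnot(inherits(epochs, "braille_epochs"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  nbs <- knn_channels(epochs$montage, k = k, include_center = include_center)
  n_ch <- length(nbs)
  step <- diff(epochs$time_ms[1:2])
  per_bin <- max(1L, round(bin_ms / step))
  n_bins <- floor(length(epochs$time_ms) / per_bin)
  maps <- lapply(schemes, function(s) {
    matrix(NA_real_, n_ch, n_bins, dimnames = list(epochs$montage$name, NULL))
  })
  names(maps) <- schemes
  for (ch in seq_len(n_ch)) {
    sub <- braille_epochs(epochs$data[, nbs[[ch]], , drop = FALSE],
                          epochs$time_ms,
                          epochs$montage[nbs[[ch]], , drop = FALSE],
                          epochs$labels)
    dec <- time_resolved_decode(sub, n_iterations = n_iterations,
                                seed = split_seed(if (is.null(seed)) 0L else seed, ch),
                                C = C, schemes = schemes)
    for (s in schemes) {
      curve <- colMeans(hand_average(dec[[s]]))
      pooled <- vapply(seq_len(n_bins), function(b) {
        mean(curve[((b - 1) * per_bin + 1):(b * per_bin)])
      }, numeric(1))
      maps[[s]][ch, ] <- pooled
    }
  }
  bin_start <- epochs$time_ms[seq(1, by = per_bin, length.out = n_bins)]
  structure(list(maps = maps, bin_start_ms = bin_start, bin_ms = bin_ms,
                 channels = epochs$montage$name, k = k,
                 include_center = include_center),
            class = "sensor_accuracy_map")
}

#' Write a volumetric accuracy map as NIfTI
#'
#' One float32 NIfTI file per scheme, `NaN` outside the mask, with a diagonal
#' affine from the voxel size.
#'
#' @param map an `accuracy_map` from [volume_searchlight].
#' @param path_prefix output prefix; files are `<prefix>_<scheme>.nii.gz`.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @return Named character vector of written paths, invisibly.
#' @export
write_accuracy_map_nifti <- function(map, path_prefix, voxel_size_mm = 3) {
  stopifnot(inherits(map, "accuracy_map"))
  paths <- vapply(names(map$maps), function(s) {
    arr <- map$maps[[s]]
    attr(arr, "pixdim") <- rep(voxel_size_mm, 3)
    img <- RNifti::asNifti(arr, datatype = "float")
    p <- paste0(path_prefix, "_", s, ".nii.gz")
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a sensor-space accuracy map as tidy TSV
#'
#' Columns: scheme, channel, bin_start_ms, accuracy.
#'
#' @param map a `sensor_accuracy_map` from [sensor_searchlight].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_map <- function(map, path) {
  stopifnot(inherits(map, "sensor_accuracy_map"))
  rows <- do.call(rbind, lapply(names(map$maps), function(s) {
    m <- map$maps[[s]]
    data.frame(scheme = s,
               channel = rep(rownames(m), times = ncol(m)),
               bin_start_ms = rep(map$bin_start_ms, each = nrow(m)),
               accuracy = as.vector(m))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster-forming threshold report for a volumetric map
#'
#' Labels face-connected clusters of voxels exceeding `threshold` and reports
#' their sizes and peak values. This is a descriptive report, not an
#' FWE-corrected inference.
#'
#' @param volume 3D accuracy (or statistic) array, `NaN`/`NA` ignored.
#' @param threshold cluster-forming threshold.
#' @return data.frame with one row per cluster: `cluster`, `n_voxels`,
#'   `peak`, `peak_x`, `peak_y`, `peak_z`.
#' @export
threshold_clusters <- function(volume, threshold) {
  supra <- !is.na(volume) & volume > threshold
  dims <- dim(volume)
  labels <- array(0L, dims)
  nxt <- 0L
  res <- list()
  idx <- which(supra, arr.ind = TRUE)
  nb6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    start <- idx[r, ]
    if (labels[start[1], start[2], start[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(start)
    labels[start[1], start[2], start[3]] <- nxt
    members <- matrix(start, 1)
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(6)) {
        w <- v + nb6[d, ]
        if (any(w < 1) || any(w > dims)) next
        if (supra[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
          members <- rbind(members, w)
        }
      }
    }
    vals <- volume[members]
    pk <- members[which.max(vals), ]
    res[[nxt]] <- data.frame(cluster = nxt, n_voxels = nrow(members),
                             peak = max(vals),
                             peak_x = pk[1], peak_y = pk[2], peak_z = pk[3])
  }
  if (length(res) == 0) {
    return(data.frame(cluster = integer(0), n_voxels = integer(0),
                      peak = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0)))
  }
  do.call(rbind, res)
}
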