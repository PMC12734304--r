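#' Volumetric image with metadata
#'
#' A single-channel 3D intensity grid together with voxel spacing, a binary
#' class label and a subject identifier. Intensities are expected to lie in
#' \[0, 1\] after preprocessing.
#'
#' @param data numeric 3D array (depth x height x width).
#' @param spacing positive numeric vector of length 3, voxel size in mm.
#' @param label integer class index, 0 or 1 (NA allowed for unlabeled data).
#' @param subject_id character scalar.
#' @return An object of class `slim3d_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), label = NA_integer_,
                   subject_id = "S0000") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume intensities must all be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive reals")
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("`label` must be 0 or 1")
  structure(list(data = data, spacing = as.numeric(spacing),
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 subject_id = as.character(subject_id)),
            class = "slim3d_volume")
}

#' @export
print.slim3d_volume <- function(x, ...) {
  cat(sprintf("<slim3d_volume %s  %s  label=%s  range=[%.3f, %.3f]>\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              ifelse(is.na(x$label), "NA", x$label),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Specification of a synthetic brain phantom
#'
#' Describes the generative model for a two-class phantom cohort: an
#' ellipsoidal "brain" with smoothed random texture, where the disease class
#' (label 1) has the intensity of a fixed subregion of an axial slice slab
#' reduced by a multiplicative factor `1 - effect_size`. Axial slices are
#' indexed 0-based, inferior to superior, and slice windows are half-open.
#'
#' @param shape integer vector (depth, height, width); default 73 x 96 x 96.
#' @param effect_size fractional intensity reduction in the signal region for
#'   class 1; `0` makes the two class-conditional distributions identical.
#' @param signal_slab half-open axial slice interval `[lo, hi)` holding the
#'   class signal.
#' @param noise_sd standard deviation of the Gaussian texture field.
#' @param smoothing_sigma Gaussian smoothing of the texture, in voxels.
#' @param spacing voxel size in mm.
#' @param seed master seed; each sample uses a substream derived from
#'   `(seed, draw)`.
#' @return An object of class `slim3d_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(73, 96, 96), effect_size = 0,
                         signal_slab = c(20, 40), noise_sd = 0.05,
                         smoothing_sigma = 1.5, spacing = c(1, 1, 1),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three positive integers, got (",
         paste(shape, collapse = ", "), ")")
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0")
  if (length(signal_slab) != 2L || signal_slab[1] < 0 ||
      signal_slab[2] > shape[1] || signal_slab[1] >= signal_slab[2])
    stop("`signal_slab` must be a half-open interval inside [0, depth)")
  structure(list(shape = shape, effect_size = effect_size,
                 signal_slab = as.integer(signal_slab), noise_sd = noise_sd,
                 smoothing_sigma = smoothing_sigma,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "slim3d_phantom_spec")
}

# Separable Gaussian smoothing of a 3D array via banded row-normalized
# smoothing matrices (edges renormalized, so constants are preserved).
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  smat <- function(n) {
    r <- ceiling(3 * sigma)
    idx <- seq_len(n)
    m <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
    })
    m / rowSums(m)
  }
  d <- dim(a)
  s1 <- smat(d[1]); s2 <- smat(d[2]); s3 <- smat(d[3])
  x <- s1 %*% matrix(a, d[1], d[2] * d[3])
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  x <- s2 %*% matrix(x, d[2], d[1] * d[3])
  dim(x) <- d[c(2, 1, 3)]
  x <- aperm(x, c(3, 2, 1))
  x <- s3 %*% matrix(x, d[3], d[2] * d[1])
  dim(x) <- d[c(3, 2, 1)]
  aperm(x, c(3, 2, 1))
}

# Masks for the phantom geometry, deterministic given the shape.
phantom_masks <- function(spec) {
  d <- spec$shape
  ctr <- (d + 1) / 2
  ax <- 0.42 * d
  g <- function(i, n) (i - ctr[n]) / ax[n]
  dd <- g(seq_len(d[1]), 1); hh <- g(seq_len(d[2]), 2); ww <- g(seq_len(d[3]), 3)
  r2 <- outer(outer(dd^2, hh^2, `+`), ww^2, `+`)
  brain <- r2 <= 1
  # signal subregion: in-plane disc of radius 0.25*min(H,W) centered on the
  # brain, restricted to the signal slab (0-based, half-open)
  slab <- seq_len(d[1]) - 1L
  in_slab <- slab >= spec$signal_slab[1] & slab < spec$signal_slab[2]
  rad <- 0.25 * min(d[2], d[3])
  hh2 <- (seq_len(d[2]) - ctr[2])^2
  ww2 <- (seq_len(d[3]) - ctr[3])^2
  disc <- outer(hh2, ww2, `+`) <= rad^2
  signal <- array(FALSE, d)
  signal[in_slab, , ] <- rep(disc, each = sum(in_slab))
  signal <- signal & brain
  list(brain = brain, signal = signal)
}

#' Generate a synthetic brain phantom volume
#'
#' Draws one phantom from the generative model in [phantom_spec()]: an
#' ellipsoidal brain region at base intensity 0.7 with an additive smoothed
#' Gaussian texture, zero background. For `label = 1` every voxel of the
#' fixed signal subregion is multiplied by `1 - effect_size`. The result is
#' clipped to \[0, 1\]. The voxel grid is a pure function of
#' `(spec$seed, draw, label)`; with `effect_size = 0` it does not depend on
#' the label at all.
#'
#' @param label class index 0 (control) or 1 (disease-like).
#' @param spec a [phantom_spec()].
#' @param draw non-negative integer substream index of this sample.
#' @param subject_id identifier stored in the volume.
#' @return A [volume()].
#' @export
generate_phantom <- function(label, spec, draw = 0L,
                             subject_id = sprintf("S%04d", draw)) {
  stopifnot(inherits(spec, "slim3d_phantom_spec"))
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1")
  if (draw < 0) stop("`draw` must be >= 0")
  masks <- phantom_masks(spec)
  d <- spec$shape
  base <- array(0, d)
  base[masks$brain] <- 0.7
  if (spec$noise_sd > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(derive_seed(spec$seed, draw))
    tex <- array(rnorm(prod(d), 0, spec$noise_sd), d)
    tex <- gauss_smooth3d(tex, spec$smoothing_sigma)
    base[masks$brain] <- base[masks$brain] + tex[masks$brain]
  }
  if (label == 1 && spec$effect_size > 0)
    base[masks$signal] <- base[masks$signal] * (1 - spec$effect_size)
  base <- pmin(pmax(base, 0), 1)
  dim(base) <- d
  volume(base, spacing = spec$spacing, label = as.integer(label),
         subject_id = subject_id)
}

# save/restore the global RNG state so generators with their own seeding do
# not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Additive Gaussian noise augmentation
#'
#' Adds independent zero-mean Gaussian noise to every voxel, then clips the
#' result back to \[0, 1\].
#'
#' @param v a [volume()].
#' @param sd noise standard deviation on the \[0, 1\] intensity scale.
#' @param seed integer seed for the perturbation.
#' @return A [volume()] with perturbed intensities.
#' @export
augment_gaussian_noise <- function(v, sd = 0.01, seed = 1L) {
  stopifnot(inherits(v, "slim3d_volume"))
  if (sd < 0) stop("`sd` must be >= 0")
  if (sd == 0) return(v)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(as.integer(seed))
  out <- v$data + array(rnorm(length(v$data), 0, sd), dim(v$data))
  v$data <- pmin(pmax(out, 0), 1)
  v
}

#' Gamma-correction augmentation
#'
#' Maps every voxel intensity `x` in \[0, 1\] to `x^gamma`. `gamma = 1` is the
#' identity; the map is strictly monotone, so voxel ordering is preserved.
#'
#' @param v a [volume()].
#' @param gamma positive exponent.
#' @return A [volume()].
#' @export
augment_gamma <- function(v, gamma) {
  stopifnot(inherits(v, "slim3d_volume"))
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (min(v$data) < 0 || max(v$data) > 1)
    stop("gamma correction expects intensities in [0, 1]")
  v$data <- v$data^gamma
  v
}

#' Oversample the minority class to balance a cohort
#'
#' Returns record indices forming a class-balanced multiset: every
#' majority-class record appears exactly once, every minority-class record at
#' least once, and the remaining minority slots are filled by seeded sampling
#' with replacement.
#'
#' @param manifest data frame with at least a `label` column of 0/1.
#' @param seed integer seed for the resampling.
#' @return Integer vector of row indices into `manifest`.
#' @export
oversample_balance <- function(manifest, seed = 1L) {
  labs <- manifest$label
  tab <- table(factor(labs, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present to balance a cohort")
  n_max <- max(tab)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(as.integer(seed))
  idx <- integer(0)
  for (cl in c(0, 1)) {
    rows <- which(labs == cl)
    extra <- n_max - length(rows)
    if (extra > 0)
      rows <- c(rows, rows[sample.int(length(rows), extra, replace = TRUE)])
    idx <- c(idx, rows)
  }
  idx
}

#' Simulate a phantom cohort
#'
#' Generates `n_per_class` phantoms per class under `spec`. Each sample uses
#' its own substream, so the cohort is a pure function of
#' `(spec, n_per_class)` and generation order does not matter.
#'
#' @param n_per_class number of subjects per class.
#' @param spec a [phantom_spec()].
#' @return An object of class `slim3d_cohort`: a list with `volumes` (list of
#'   [volume()]) and `manifest` (data frame `subject_id`, `label`, `path`).
#' @export
simulate_cohort <- function(n_per_class, spec) {
  stopifnot(inherits(spec, "slim3d_phantom_spec"))
  vols <- vector("list", 2L * n_per_class)
  ids <- character(2L * n_per_class)
  labs <- integer(2L * n_per_class)
  i <- 0L
  for (cl in c(0L, 1L)) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    draw <- (cl * n_per_class) + j - 1L
    ids[i] <- sprintf("S%03d", draw)
    labs[i] <- cl
    vols[[i]] <- generate_phantom(cl, spec, draw = draw, subject_id = ids[i])
  }
  structure(list(volumes = vols,
                 manifest = data.frame(subject_id = ids, label = labs,
                                       path = NA_character_,
                                       stringsAsFactors = FALSE)),
            class = "slim3d_cohort")
}

#' @export
print.slim3d_cohort <- function(x, ...) {
  cat(sprintf("<slim3d_cohort  %d volumes  (%d / %d per class)>\n",
              nrow(x$manifest), sum(x$manifest$label == 0),
              sum(x$manifest$label == 1)))
  invisible(x)
}

#' Write a cohort to NIfTI files plus a CSV manifest
#'
#' Volumes are written as 32-bit float `.nii.gz` files and the manifest as
#' `manifest.csv` with columns `subject_id,label,path`.
#'
#' @param cohort a `slim3d_cohort`.
#' @param dir output directory (created if missing).
#' @return The manifest data frame with file paths filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "slim3d_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$volumes)) {
    v <- cohort$volumes[[i]]
    path <- file.path(dir, sprintf("%s.nii.gz", v$subject_id))
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    RNifti::writeNifti(img, path, datatype = "float")
    man$path[i] <- path
  }
  if (anyDuplicated(man$path)) stop("file paths in the manifest must be unique")
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort from a directory or manifest CSV
#'
#' @param x a directory containing `manifest.csv`, or a manifest CSV path.
#' @return A `slim3d_cohort`.
#' @export
read_cohort <- function(x) {
  csv <- if (dir.exists(x)) file.path(x, "manifest.csv") else x
  if (!file.exists(csv)) {
    warning("no manifest found at ", csv, "; returning an empty cohort")
    return(structure(list(volumes = list(),
                          manifest = data.frame(subject_id = character(),
                                                label = integer(),
                                                path = character())),
                     class = "slim3d_cohort"))
  }
  man <- read.csv(csv, stringsAsFactors = FALSE)
  vols <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) stop("cohort volume file missing: ", p)
    img <- RNifti::readNifti(p)
    dat <- as.array(img)
    attributes(dat) <- list(dim = dim(dat))   # strip NIfTI metadata attrs
    vols[[i]] <- volume(dat,
                        spacing = RNifti::pixdim(img)[1:3],
                        label = as.integer(man$label[i]),
                        subject_id = as.character(man$subject_id[i]))
  }
  structure(list(volumes = vols, manifest = man), class = "slim3d_cohort")
}
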