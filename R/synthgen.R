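## Synthetic cohorts with planted ground truth.
##
## The generator emulates the structure of a resting-state acquisition:
## spatially independent network maps with temporally coherent
## low-frequency (< 0.1 Hz) time courses, additive Gaussian noise,
## tissue probability volumes, and a multiplicative group effect on the
## amplitude of designated networks. Connectivity-profile cohorts emulate
## seed-by-region streamline visitation counts with planted cluster
## structure, with Poisson count noise.

#' Default desk-scale grid for synthetic cohorts
#'
#' 20 x 24 x 18 voxels of 3 x 3 x 4 mm at TR = 3 s, a scaled-down version
#' of a typical resting-state raster that keeps full pipeline runs fast.
#'
#' @return A [GridSpec-class].
#' @export
defaultGrid <- function() gridSpec(c(20L, 24L, 18L), c(3, 3, 4), TR = 3)

## Split nNetworks blob sites over a coarse lattice of cells covering the
## grid, returning one centre (voxel coords) and an isotropic sd (voxels)
## per network. Deterministic given the grid and count.
network_sites <- function(dims, n) {
  splits <- c(1L, 1L, 1L)
  while (prod(splits) < n) {
    ax <- which.max(dims / splits)
    splits[ax] <- splits[ax] + 1L
  }
  cell <- dims / splits
  if (min(cell) < 3) {
    stop("infeasible geometry: grid too small to host the requested networks",
         call. = FALSE)
  }
  centres <- as.matrix(expand.grid(
    x = (seq_len(splits[1L]) - 0.5) * cell[1L],
    y = (seq_len(splits[2L]) - 0.5) * cell[2L],
    z = (seq_len(splits[3L]) - 0.5) * cell[3L]
  ))[seq_len(n), , drop = FALSE]
  list(centres = centres, sigma = max(1, min(cell) / 5))
}

## Gaussian blob (peak 1) at `centre` (voxel coords) with sd `sigma` voxels.
blob_volume <- function(dims, centre, sigma) {
  gx <- exp(-((seq_len(dims[1L]) - centre[1L])^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(dims[2L]) - centre[2L])^2) / (2 * sigma^2))
  gz <- exp(-((seq_len(dims[3L]) - centre[3L])^2) / (2 * sigma^2))
  outer(outer(gx, gy), gz)
}

## Band-limited unit-variance time courses: white Gaussian noise filtered
## to `band` in the FFT domain, with a 1/f amplitude envelope inside the
## band (resting-state fluctuations have 1/f-like spectra, so most power
## sits at the low end of the band), then standardised per column.
bandlimited_timecourses <- function(T_, k, TR, band) {
  tc <- matrix(stats::rnorm(T_ * k), T_, k)
  gain <- bandpass_gain(T_, TR, band[1L], band[2L])
  f <- attr(gain, "freq")
  env <- gain * pmin(1, band[1L] / pmax(f, 1e-12))
  tc <- Re(stats::mvfft(stats::mvfft(tc) * env, inverse = TRUE)) / T_
  sweep(sweep(tc, 2L, colMeans(tc)), 2L, apply(tc, 2L, stats::sd), "/")
}

#' Generate a synthetic resting-state fMRI cohort with planted networks
#'
#' Each subject's 4D series is a sum of spatially fixed network maps
#' (Gaussian blobs at well-separated sites, so that maps are spatially
#' independent by construction) weighted by subject-specific band-limited
#' time courses, plus white Gaussian noise. A multiplicative group effect
#' scales the amplitude of designated networks in the second group.
#' Optional confound components are confined to the CSF compartment and
#' fluctuate above the analysis pass band; they exercise the component
#' selection criteria.
#'
#' Tissue priors are derived from the same geometry: grey matter follows
#' the network sites, CSF occupies a dedicated corner block plus the volume
#' boundary shell, and white matter fills the remainder; per-voxel prior
#' sums never exceed 1.
#'
#' @param grid a [GridSpec-class] (default [defaultGrid()]).
#' @param nTimepoints number of volumes per subject (default 100).
#' @param nSubjectsPerGroup integer(2), subjects in groups A and B.
#' @param nNetworks number of planted networks (>= 2).
#' @param groupEffect numeric vector of per-network multiplicative
#'   amplitude factors applied to group B; default 1.5 on network 1 and
#'   1 elsewhere.
#' @param noiseSd Gaussian noise sd in units of the peak-voxel signal sd.
#' @param amplitude base network amplitude (signal units).
#' @param nConfounds number of CSF-confined high-frequency confound
#'   components added to every subject.
#' @param band frequency band (Hz) of the network time courses.
#' @param confoundBand frequency band (Hz) of the confound time courses.
#' @param subjectAmplitudes optional (total subjects) x nNetworks matrix
#'   overriding the per-subject network amplitudes (before group effect).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return A list with elements `images` (list of [Image4D-class]),
#'   `truth` (planted maps, per-subject time courses and amplitudes,
#'   tissue priors, group labels, confound flags) and `grid`.
#' @export
makeRsfmriCohort <- function(grid = defaultGrid(), nTimepoints = 100L,
                             nSubjectsPerGroup = c(6L, 6L), nNetworks = 6L,
                             groupEffect = NULL, noiseSd = 0.5, amplitude = 1,
                             nConfounds = 0L, band = c(0.01, 0.08),
                             confoundBand = c(0.10, 0.15),
                             subjectAmplitudes = NULL, seed = 1L) {
  stopifnot_count(nNetworks, "nNetworks", min = 2L)
  stopifnot_count(nTimepoints, "nTimepoints", min = 64L)
  if (length(nSubjectsPerGroup) != 2L || any(nSubjectsPerGroup < 1)) {
    stop("nSubjectsPerGroup must be two positive counts", call. = FALSE)
  }
  if (noiseSd < 0) stop("noiseSd must be nonnegative", call. = FALSE)
  if (is.null(groupEffect)) {
    groupEffect <- rep(1, nNetworks)
    groupEffect[1L] <- 1.5
  }
  stopifnot(length(groupEffect) == nNetworks)
  dims <- grid@dims
  nTotal <- nNetworks + nConfounds
  sites <- network_sites(dims, nTotal + 1L)  # last cell reserved for CSF block
  maps <- lapply(seq_len(nTotal), function(k) {
    blob_volume(dims, sites$centres[k, ], sites$sigma)
  })
  isConfound <- c(rep(FALSE, nNetworks), rep(TRUE, nConfounds))

  ## tissue priors from the same geometry
  gm <- Reduce(`+`, maps[!isConfound])
  gm <- pmin(gm, 1) * 0.95
  csf_centre <- sites$centres[nTotal + 1L, ]
  csf <- blob_volume(dims, csf_centre, sites$sigma) * 0.9
  shell <- array(0, dims)
  shell[c(1L, dims[1L]), , ] <- 1
  shell[, c(1L, dims[2L]), ] <- 1
  shell[, , c(1L, dims[3L])] <- 1
  csf <- pmin(csf + 0.8 * shell, 0.95)
  csf <- pmin(csf, 0.98 - gm)                 # keep per-voxel sums <= 1
  wm <- pmax(0, 0.97 - gm - csf) * 0.95
  if (nConfounds > 0L) {
    ## confounds live in CSF space: relocate their blobs into the CSF block,
    ## with small offsets so distinct confounds stay distinguishable
    conf_idx <- which(isConfound)
    for (i in seq_along(conf_idx)) {
      off <- c((i - 1) %% 2, (i - 1) %/% 2, 0) * sites$sigma
      maps[[conf_idx[i]]] <- blob_volume(dims, csf_centre + off, sites$sigma * 0.8)
    }
  }

  nSub <- sum(nSubjectsPerGroup)
  group <- rep(c("A", "B"), nSubjectsPerGroup)
  with_seed(seed, {
    amps <- matrix(amplitude, nSub, nTotal)
    if (!is.null(subjectAmplitudes)) {
      stopifnot(nrow(subjectAmplitudes) == nSub,
                ncol(subjectAmplitudes) == nNetworks)
      amps[, seq_len(nNetworks)] <- subjectAmplitudes
    }
    for (k in seq_len(nNetworks)) {
      amps[group == "B", k] <- amps[group == "B", k] * groupEffect[k]
    }
    images <- vector("list", nSub)
    tcs <- vector("list", nSub)
    nvox <- prod(dims)
    map_mat <- vapply(maps, as.vector, numeric(nvox))  # nvox x nTotal
    for (s in seq_len(nSub)) {
      tc <- matrix(0, nTimepoints, nTotal)
      tc[, !isConfound] <- bandlimited_timecourses(
        nTimepoints, nNetworks, grid@TR, band)
      if (nConfounds > 0L) {
        tc[, isConfound] <- bandlimited_timecourses(
          nTimepoints, nConfounds, grid@TR, confoundBand)
      }
      sig <- tcrossprod(sweep(tc, 2L, amps[s, ], "*"), map_mat)  # T x nvox
      if (noiseSd > 0) {
        sig <- sig + matrix(stats::rnorm(length(sig), sd = noiseSd),
                            nTimepoints, nvox)
      }
      motion <- abs(stats::rnorm(1L, mean = 0.5, sd = 0.15))
      images[[s]] <- image4D(array(t(sig), c(dims, nTimepoints)), grid,
                             subjectId = sprintf("%s%02d", group[s], s),
                             meanMotion = motion)
      tcs[[s]] <- tc
    }
    list(
      images = images,
      truth = list(
        maps = maps, timecourses = tcs, amplitudes = amps,
        groupEffect = groupEffect, noiseSd = noiseSd,
        priors = list(gm = gm, wm = wm, csf = csf),
        group = group, isConfound = isConfound, band = band,
        confoundBand = confoundBand
      ),
      grid = grid
    )
  })
}

#' Generate synthetic seed-by-region connectivity-profile cohorts
#'
#' Each group carries a planted number of clusters. Cluster archetypes
#' have disjoint region support; a seed of cluster j draws Poisson counts
#' with rate `baseRate + separation` on the archetype's regions and
#' `baseRate` elsewhere. `separation = 0` therefore yields exchangeable
#' profiles with no cluster structure.
#'
#' @param nSeedsPerSubject seeds per subject (per group).
#' @param nSubjects subjects per group.
#' @param nRegions atlas regions (columns); default 48, the size of a
#'   standard cortical atlas.
#' @param plantedK integer vector, one planted cluster count per group.
#' @param separation nonnegative rate increment on archetype regions.
#' @param baseRate background Poisson rate per region.
#' @param regionsPerCluster archetype support size (regions per cluster).
#' @param seed integer RNG seed.
#' @return A list with `profiles` (one [ProfileMatrix-class] per group,
#'   rows carrying subject provenance and true labels) and `truth`
#'   (archetype rate matrices and planted cluster counts).
#' @export
makeProfileCohort <- function(nSeedsPerSubject = 10L, nSubjects = 6L,
                              nRegions = 48L, plantedK = c(2L, 4L),
                              separation = 8, baseRate = 1,
                              regionsPerCluster = 4L, seed = 1L) {
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  stopifnot_count(nRegions, "nRegions")
  stopifnot_count(nSeedsPerSubject, "nSeedsPerSubject")
  stopifnot_count(nSubjects, "nSubjects")
  plantedK <- as.integer(plantedK)
  if (any(plantedK < 1L)) stop("plantedK must be positive", call. = FALSE)
  nSeeds <- nSeedsPerSubject * nSubjects
  if (any(plantedK > nSeeds)) {
    stop("plantedK must not exceed the number of seeds", call. = FALSE)
  }
  if (max(plantedK) * regionsPerCluster > nRegions) {
    stop("not enough regions for disjoint cluster archetypes", call. = FALSE)
  }
  regions <- sprintf("region%02d", seq_len(nRegions))
  with_seed(seed, {
    groups <- lapply(seq_along(plantedK), function(g) {
      k <- plantedK[g]
      rates <- matrix(baseRate, k, nRegions, dimnames = list(NULL, regions))
      for (j in seq_len(k)) {
        sup <- ((j - 1L) * regionsPerCluster + 1L):(j * regionsPerCluster)
        rates[j, sup] <- baseRate + separation
      }
      counts <- matrix(0, nSeeds, nRegions, dimnames = list(NULL, regions))
      lab <- integer(nSeeds)
      subj <- character(nSeeds)
      row <- 0L
      for (s in seq_len(nSubjects)) {
        ## iid labels: per-subject seed counts per cluster vary naturally
        lab_s <- sample.int(k, nSeedsPerSubject, replace = TRUE)
        for (i in seq_len(nSeedsPerSubject)) {
          row <- row + 1L
          lab[row] <- lab_s[i]
          subj[row] <- sprintf("g%d_s%02d", g, s)
          counts[row, ] <- stats::rpois(nRegions, rates[lab_s[i], ])
        }
      }
      pm <- profileMatrix(
        counts,
        seedInfo = data.frame(subject = subj, roi = "roi", hemisphere = "",
                              trueLabel = lab, stringsAsFactors = FALSE)
      )
      list(profile = pm, rates = rates)
    })
    list(
      profiles = lapply(groups, `[[`, "profile"),
      truth = list(rates = lapply(groups, `[[`, "rates"),
                   plantedK = plantedK, separation = separation,
                   baseRate = baseRate)
    )
  })
}

#' Monte-Carlo toy streamline tracker
#'
#' Propagates streamlines from each seed along a 3D orientation field,
#' perturbing the direction at every step by a random rotation with the
#' given angular standard deviation. A streamline stops when it leaves the
#' volume or exceeds `maxSteps` steps. The output per seed is a visitation
#' count volume: the number of streamlines that entered each voxel.
#'
#' @param orientationField 4D array (x, y, z, 3) of unit direction vectors.
#' @param seeds a [SeedSet-class]; all seeds must lie inside the volume.
#' @param nSamples streamlines per seed.
#' @param step step length in mm.
#' @param angleSd angular perturbation sd in degrees (0 = deterministic).
#' @param maxSteps maximum steps per streamline.
#' @param seed integer RNG seed.
#' @return A list of 3D integer count arrays, one per seed.
#' @export
toyTracker <- function(orientationField, seeds, nSamples = 100L, step = 2,
                       angleSd = 10, maxSteps = 200L, seed = 1L) {
  stopifnot(is(seeds, "SeedSet"))
  d <- dim(orientationField)
  stopifnot(length(d) == 4L, d[4L] == 3L)
  dims <- d[1:3]
  if (step <= 0) stop("step must be positive", call. = FALSE)
  coords <- seeds@coords
  if (nrow(coords) == 0L) stop("invalid seed: empty seed set", call. = FALSE)
  if (any(coords < 1L) ||
      any(coords > matrix(dims, nrow(coords), 3L, byrow = TRUE))) {
    stop("invalid seed: outside the orientation field", call. = FALSE)
  }
  vox <- seeds@grid@voxelSize
  rad <- angleSd * pi / 180
  with_seed(seed, {
    lapply(seq_len(nrow(coords)), function(si) {
      counts <- array(0L, dims)
      for (n in seq_len(nSamples)) {
        pos <- as.numeric(coords[si, ])      # continuous voxel coordinates
        visited <- integer(0)
        for (stp in seq_len(maxSteps)) {
          iv <- round(pos)
          if (any(iv < 1) || any(iv > dims)) break
          lin <- iv[1L] + (iv[2L] - 1L) * dims[1L] +
            (iv[3L] - 1L) * dims[1L] * dims[2L]
          if (!(lin %in% visited)) {
            visited <- c(visited, lin)
          }
          v <- orientationField[iv[1L], iv[2L], iv[3L], ]
          nv <- sqrt(sum(v^2))
          if (nv < 1e-12) break
          v <- v / nv
          if (rad > 0) {
            g <- stats::rnorm(3L)
            p <- g - sum(g * v) * v
            np <- sqrt(sum(p^2))
            if (np > 1e-12) {
              theta <- stats::rnorm(1L, 0, rad)
              v <- cos(theta) * v + sin(theta) * p / np
            }
          }
          pos <- pos + step * v / vox        # mm step in voxel units
        }
        counts[visited] <- counts[visited] + 1L
      }
      counts
    })
  })
}

#' Downsample a count volume by integer-factor block summation
#'
#' Emulates saving tractography visitation counts at a coarser resolution
#' before regional aggregation; counts are conserved exactly when the
#' factor divides the volume dimensions.
#'
#' @param vol 3D numeric array.
#' @param factor integer downsampling factor per axis.
#' @return 3D array of dimension `ceiling(dim(vol) / factor)`.
#' @export
downsampleCounts <- function(vol, factor = 2L) {
  factor <- stopifnot_count(factor, "factor")
  if (factor == 1L) return(vol)
  d <- dim(vol)
  nd <- as.integer(ceiling(d / factor))
  out <- array(0, nd)
  idx <- lapply(d, function(n) ((seq_len(n) - 1L) %/% factor) + 1L)
  for (z in seq_len(d[3L])) {
    sl <- vol[, , z]
    agg <- rowsum(t(rowsum(sl, idx[[1L]])), idx[[2L]])  # coarse y x coarse x
    out[, , idx[[3L]][z]] <- out[, , idx[[3L]][z]] + t(agg)
  }
  out
}

#' Downsample a label volume by block majority vote
#'
#' Each coarse voxel takes the most frequent label among the fine voxels
#' it covers (ties broken toward the smaller label; background 0 counts).
#'
#' @param atlas 3D integer label array.
#' @param factor integer downsampling factor per axis.
#' @return 3D integer array of coarse labels.
#' @export
downsampleLabels <- function(atlas, factor = 2L) {
  factor <- stopifnot_count(factor, "factor")
  if (factor == 1L) return(atlas)
  d <- dim(atlas)
  nd <- as.integer(ceiling(d / factor))
  out <- array(0L, nd)
  for (i in seq_len(nd[1L])) for (j in seq_len(nd[2L])) for (k in seq_len(nd[3L])) {
    xs <- ((i - 1L) * factor + 1L):min(i * factor, d[1L])
    ys <- ((j - 1L) * factor + 1L):min(j * factor, d[2L])
    zs <- ((k - 1L) * factor + 1L):min(k * factor, d[3L])
    tab <- table(atlas[xs, ys, zs])
    out[i, j, k] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}
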