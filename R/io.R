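## NIfTI-1 input/output and pipeline orchestration.

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file; 4D images become [Image4D-class] objects (the
#' grid is taken from the header: matrix size, pixel dimensions, TR),
#' 3D images are returned as plain arrays with a `grid` attribute.
#'
#' @param path file path (.nii or .nii.gz).
#' @param subjectId,meanMotion metadata attached to 4D images.
#' @return An [Image4D-class] or a 3D array.
#' @export
readNiftiImage <- function(path, subjectId = NULL, meanMotion = 0) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pix <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4L]
  if (length(d) == 4L) {
    hdr <- RNifti::niftiHeader(img)
    TR <- hdr$pixdim[5L]
    if (!is.finite(TR) || TR <= 0) TR <- 1
    grid <- gridSpec(d[1:3], abs(pix[1:3]), TR = TR, origin = origin)
    if (is.null(subjectId)) {
      subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
    }
    image4D(array(as.numeric(img), d), grid, subjectId = subjectId,
            meanMotion = meanMotion)
  } else if (length(d) == 3L) {
    arr <- array(as.numeric(img), d)
    attr(arr, "grid") <- gridSpec(d, abs(pix[1:3]), TR = 1, origin = origin)
    arr
  } else {
    stop("format error: expected a 3D or 4D NIfTI volume", call. = FALSE)
  }
}

#' Write a volume as NIfTI-1
#'
#' Writes an [Image4D-class] or a 3D array with its [GridSpec-class]
#' affine (diagonal voxel sizes plus origin translation); data and affine
#' survive a write/read round trip.
#'
#' @param obj an [Image4D-class], or a 3D/4D array.
#' @param path output file path.
#' @param grid a [GridSpec-class] (required for plain arrays).
#' @return Invisibly, `path`.
#' @export
writeNiftiImage <- function(obj, path, grid = NULL) {
  if (is(obj, "Image4D")) {
    grid <- obj@grid
    arr <- obj@data
  } else {
    arr <- obj
    if (is.null(grid)) grid <- attr(arr, "grid")
    if (is.null(grid)) stop("grid required to write a plain array", call. = FALSE)
  }
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  pd <- c(grid@voxelSize, if (nd == 4L) grid@TR else numeric(0))
  RNifti::pixdim(img) <- pd
  aff <- diag(c(grid@voxelSize, 1))
  aff[1:3, 4L] <- grid@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that a cohort of images shares one grid
#'
#' @param images list of [Image4D-class] objects.
#' @return Invisibly TRUE; errors on mismatched grids.
#' @export
checkAlignment <- function(images) {
  ref <- images[[1L]]@grid
  for (img in images[-1L]) {
    g <- img@grid
    if (!identical(g@dims, ref@dims) ||
        max(abs(g@voxelSize - ref@voxelSize)) > 1e-6 ||
        max(abs(g@origin - ref@origin)) > 1e-6) {
      stop(sprintf("alignment error: subject %s is on a different grid",
                   img@subjectId), call. = FALSE)
    }
  }
  invisible(TRUE)
}

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "rsnparc_out",
    synth = list(n_subjects_per_group = c(6L, 6L), n_networks = 6L,
                 n_timepoints = 100L, noise_sd = 0.5, n_confounds = 1L,
                 group_effect_network = 1L, group_effect = 1.5),
    preprocess = list(band = c(0.01, 0.08), fwhm = 6),
    gica = list(K = 12L, C = 12L),
    stability = list(n_runs = 5L, bootstrap = TRUE),
    selection = list(lowband = c(0.01, 0.05), power_fraction_min = 0.5,
                     gm_corr_min = 0.15),
    rsn_stats = list(p_primary = 0.001, k_min = 5L, alpha_fwe = 0.05,
                     n_perm = 500L),
    parcellate = list(planted_k = c(2L, 4L), n_seeds_per_subject = 10L,
                      n_subjects = 6L, n_regions = 48L, separation = 8,
                      k_range = 2:15, n_restarts = 20L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates generation, preprocessing, group ICA, stability
#' assessment, component selection, voxelwise group statistics and
#' connectivity-based parcellation from a single configuration (an R
#' list, or the path of a YAML/JSON file). Every stage parameter has a
#' default; the effective configuration is logged. Outputs are written
#' under `out_dir`: a JSON report (selected components, significant
#' clusters, chosen number of clusters per group), CSV tables, NIfTI
#' statistic volumes and a parameter log.
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return Invisibly, the report list (also written as JSON).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- merge_config(default_config(), config)
  grid <- defaultGrid()
  nyq <- 1 / (2 * grid@TR)
  if (cfg$preprocess$band[2L] >= nyq) {
    stop(sprintf("config error: preprocess$band high edge (%g Hz) must be below Nyquist (%g Hz)",
                 cfg$preprocess$band[2L], nyq), call. = FALSE)
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "parameters.json")
  jsonlite::write_json(cfg, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  ## --- synthesis -----------------------------------------------------
  ge <- rep(1, cfg$synth$n_networks)
  ge[cfg$synth$group_effect_network] <- cfg$synth$group_effect
  cohort <- makeRsfmriCohort(
    grid = grid, nTimepoints = cfg$synth$n_timepoints,
    nSubjectsPerGroup = cfg$synth$n_subjects_per_group,
    nNetworks = cfg$synth$n_networks, groupEffect = ge,
    noiseSd = cfg$synth$noise_sd, nConfounds = cfg$synth$n_confounds,
    seed = cfg$seed)
  checkAlignment(cohort$images)
  motion <- vapply(cohort$images, meanMotion, numeric(1))
  utils::write.csv(
    data.frame(subject = vapply(cohort$images, subjectId, character(1)),
               group = cohort$truth$group, mean_motion = motion),
    file.path(out_dir, "covariates.csv"), row.names = FALSE)

  ## --- preprocessing -------------------------------------------------
  pre <- lapply(cohort$images, function(img) {
    smoothGaussian(detrendBandpass(img, cfg$preprocess$band),
                   cfg$preprocess$fwhm)
  })

  ## --- group ICA + stability + selection -----------------------------
  cset <- runGroupICA(pre, K = cfg$gica$K, C = cfg$gica$C,
                      seed = derive_seed(cfg$seed, 2))
  cset <- assessStability(cset, pre, nRuns = cfg$stability$n_runs,
                          seed = derive_seed(cfg$seed, 3),
                          bootstrap = cfg$stability$bootstrap)
  crit <- selectionCriteria(lowband = cfg$selection$lowband,
                            powerFractionMin = cfg$selection$power_fraction_min,
                            gmCorrMin = cfg$selection$gm_corr_min)
  sel <- selectComponents(cset, cohort$truth$priors, crit)
  utils::write.csv(sel, file.path(out_dir, "component_selection.csv"),
                   row.names = FALSE)

  ## --- group statistics on the best-matching planted network ---------
  truth_map <- as.numeric(cohort$truth$maps[[cfg$synth$group_effect_network]])
  match_r <- abs(row_cor(cset@groupMaps, matrix(truth_map, 1L)))
  kbest <- which.max(match_r)
  subj_maps <- t(vapply(cset@subjectMaps, function(m) m[kbest, ],
                        numeric(ncol(cset@groupMaps))))
  grp <- cohort$truth$group
  mapsA <- subj_maps[grp == "A", , drop = FALSE]
  mapsB <- subj_maps[grp == "B", , drop = FALSE]
  os <- list(oneSampleT(mapsA, motion[grp == "A"], grid, cset@mask),
             oneSampleT(mapsB, motion[grp == "B"], grid, cset@mask))
  gmask <- suppressWarnings(groupMask(os, pThresh = cfg$rsn_stats$p_primary))
  stat <- clusterThreshold(
    mapsA, mapsB, motion, grid, cset@mask,
    pPrimary = cfg$rsn_stats$p_primary, kMin = cfg$rsn_stats$k_min,
    alphaFwe = cfg$rsn_stats$alpha_fwe, nPerm = cfg$rsn_stats$n_perm,
    seed = derive_seed(cfg$seed, 4))
  writeNiftiImage(stat@tValues, file.path(out_dir, "group_t.nii.gz"), grid)
  writeNiftiImage(array(as.numeric(gmask), grid@dims),
                  file.path(out_dir, "group_mask.nii.gz"), grid)
  utils::write.csv(clusterTable(stat), file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)

  ## --- parcellation --------------------------------------------------
  pc <- makeProfileCohort(
    nSeedsPerSubject = cfg$parcellate$n_seeds_per_subject,
    nSubjects = cfg$parcellate$n_subjects,
    nRegions = cfg$parcellate$n_regions,
    plantedK = cfg$parcellate$planted_k,
    separation = cfg$parcellate$separation,
    seed = derive_seed(cfg$seed, 5))
  res <- lapply(seq_along(pc$profiles), function(g) {
    chooseK(pc$profiles[[g]], kRange = cfg$parcellate$k_range,
            nRestarts = cfg$parcellate$n_restarts,
            seed = derive_seed(cfg$seed, 10 + g),
            group = c("A", "B")[g])
  })
  cmp <- compareCentroids(res[[1L]], res[[2L]])
  scs <- seedCountStats(res[[1L]], res[[2L]], matches = cmp$matches)
  utils::write.csv(cmp$report, file.path(out_dir, "centroid_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(scs$tests, file.path(out_dir, "seed_count_tests.csv"),
                   row.names = FALSE)

  report <- list(
    n_subjects = length(pre),
    K = cset@K,
    stability_range = range(stabilityIndex(cset), na.rm = TRUE),
    n_selected = sum(sel$keep),
    significant_clusters = sum(clusterTable(stat)$significant),
    chosen_k = lapply(res, function(r) {
      if (r@noStructure) NA else chosenK(r)
    })
  )
  names(report$chosen_k) <- c("A", "B")[seq_along(res)]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
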