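## Voxelwise group statistics on back-reconstructed Z maps:
## one/two-sample general linear models with a motion covariate,
## intersection masking, cluster-extent thresholding with permutation
## family-wise-error correction, and clinical correlations with
## small-volume correction.

## Vectorised GLM: fit Y (n x V) on design X (n x p), return the t map of
## coefficient `coef` with its degrees of freedom.
glm_t <- function(Y, X, coef) {
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, Y)              # p x V
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[coef, coef])
  t <- B[coef, ] / se
  t[!is.finite(t)] <- 0
  list(t = t, df = df)
}

## Fold a per-voxel t vector into a StatMap; p-values per `alternative`.
make_statmap <- function(t, df, grid, mask, alternative = "two.sided") {
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              greater = stats::pt(t, df, lower.tail = FALSE))
  tvol <- vectorToVolume(t, grid, mask, fill = 0)
  pvol <- vectorToVolume(p, grid, mask, fill = 1)
  new("StatMap", tValues = tvol, pValues = pvol,
      clusterLabels = array(0L, grid@dims),
      clusters = data.frame(label = integer(), extent = integer(),
                            peak_x = numeric(), peak_y = numeric(),
                            peak_z = numeric(), peak_t = numeric(),
                            p_fwe = numeric(), sign = integer(),
                            significant = logical()),
      grid = grid, df = as.numeric(df))
}

#' One-sample voxelwise t test with an optional covariate
#'
#' Tests the mean map against zero at every voxel, optionally adjusting
#' for a per-subject confound (mean head motion). P-values are one-sided
#' for positive effects, the convention for within-group network maps.
#'
#' @param maps subjects x voxels matrix of in-mask map values.
#' @param covariate optional per-subject scalar confound.
#' @param grid a [GridSpec-class].
#' @param mask 3D logical array the columns of `maps` live on.
#' @return A [StatMap-class] with one-sided p-values.
#' @export
oneSampleT <- function(maps, covariate = NULL, grid, mask) {
  n <- nrow(maps)
  X <- if (is.null(covariate)) matrix(1, n, 1L) else {
    cbind(1, covariate - mean(covariate))
  }
  fit <- glm_t(maps, X, coef = 1L)
  make_statmap(fit$t, fit$df, grid, mask, alternative = "greater")
}

#' Two-sample voxelwise t test with a confounding covariate
#'
#' Per-voxel general linear model with an intercept, a group indicator
#' and the covariate; the reported t is for the group contrast (B minus
#' A) with `nA + nB - 3` degrees of freedom. Errors when the covariate is
#' collinear with the group indicator.
#'
#' @param mapsA,mapsB subjects x voxels matrices for the two groups.
#' @param covariate per-subject scalar, ordered as `rbind(mapsA, mapsB)`.
#' @param grid a [GridSpec-class].
#' @param mask 3D logical array matching the map columns.
#' @return A [StatMap-class] with two-sided p-values.
#' @export
twoSampleTCov <- function(mapsA, mapsB, covariate = NULL, grid, mask) {
  nA <- nrow(mapsA)
  nB <- nrow(mapsB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group", call. = FALSE)
  Y <- rbind(mapsA, mapsB)
  g <- c(rep(0, nA), rep(1, nB))
  ## a constant covariate contributes nothing to the model: drop it
  if (!is.null(covariate) && stats::sd(covariate) == 0) covariate <- NULL
  X <- if (is.null(covariate)) cbind(1, g) else cbind(1, g, covariate)
  if (qr(X)$rank < ncol(X)) {
    stop("rank deficiency: covariate collinear with the group indicator",
         call. = FALSE)
  }
  fit <- glm_t(Y, X, coef = 2L)
  make_statmap(fit$t, fit$df, grid, mask, alternative = "two.sided")
}

#' Intersection mask from per-group one-sample maps
#'
#' A voxel enters the mask when it is suprathreshold (p below
#' `pThresh`) in the one-sample map of every group; the intersection of
#' within-group network extents then restricts the between-group
#' comparison. An empty intersection gives a warning and an empty mask.
#'
#' @param oneSampleMaps list of [StatMap-class] objects, one per group.
#' @param pThresh primary threshold (default 0.001).
#' @return 3D logical array.
#' @export
groupMask <- function(oneSampleMaps, pThresh = 0.001) {
  dims <- lapply(oneSampleMaps, function(m) m@grid@dims)
  if (length(unique(dims)) != 1L) {
    stop("maps must share a voxel space", call. = FALSE)
  }
  masks <- lapply(oneSampleMaps, function(m) m@pValues < pThresh)
  out <- Reduce(`&`, masks)
  if (!any(out)) warning("empty intersection mask", call. = FALSE)
  out
}

## Suprathreshold cluster extents of a t map, by sign, 6-face connectivity.
## Returns list(labels pos/neg arrays, table of clusters).
t_clusters <- function(tvol, tcrit) {
  lab_pos <- label_components_6(tvol >= tcrit)
  lab_neg <- label_components_6(tvol <= -tcrit)
  rows <- list()
  for (sgn in c(1L, -1L)) {
    lab <- if (sgn == 1L) lab_pos else lab_neg
    if (max(lab) == 0L) next
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      tv <- tvol[idx]
      pk <- idx[which.max(abs(tv))]
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sgn, id = cl, extent = length(idx),
        peak_idx = pk, peak_t = tv[which.max(abs(tv))]
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sign = integer(), id = integer(), extent = integer(),
               peak_idx = integer(), peak_t = numeric())
  }
  list(pos = lab_pos, neg = lab_neg, table = tab)
}

#' Cluster-extent thresholding with permutation FWE correction
#'
#' Thresholds the two-sample t map at the primary level `pPrimary`
#' (two-sided), labels suprathreshold clusters by 6-face connectivity,
#' and corrects their extents for family-wise error with a max-statistic
#' permutation scheme: group labels are shuffled, the model (including
#' the covariate) refit, and the largest suprathreshold extent recorded
#' per permutation. A cluster is reported significant when its extent
#' reaches `kMin` voxels and its FWE-corrected p is below `alphaFwe`.
#'
#' Permutation-based correction replaces parametric random-field cluster
#' inference; it is assumption-light and exactly calibrated under
#' exchangeability of the group labels.
#'
#' @param mapsA,mapsB subjects x voxels matrices for the two groups.
#' @param covariate per-subject scalar confound (may be NULL).
#' @param grid a [GridSpec-class].
#' @param mask 3D logical array matching the map columns.
#' @param pPrimary primary (uncorrected) threshold, default 0.001.
#' @param kMin minimum cluster extent in voxels, default 5.
#' @param alphaFwe family-wise error level at the cluster level, default 0.05.
#' @param nPerm number of permutations (default 1000; below 100 warns).
#' @param seed integer RNG seed for the permutations.
#' @return A [StatMap-class] with `clusterLabels` and a populated cluster
#'   table (extents, peak world coordinates, FWE-corrected p, flags).
#' @export
clusterThreshold <- function(mapsA, mapsB, covariate = NULL, grid, mask,
                             pPrimary = 0.001, kMin = 5L, alphaFwe = 0.05,
                             nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) warning("fewer than 100 permutations", call. = FALSE)
  nA <- nrow(mapsA)
  nB <- nrow(mapsB)
  Y <- rbind(mapsA, mapsB)
  obs <- twoSampleTCov(mapsA, mapsB, covariate, grid, mask)
  tcrit <- stats::qt(1 - pPrimary / 2, obs@df)
  cl <- t_clusters(obs@tValues, tcrit)

  ## permutation null of the maximum suprathreshold extent
  max_ext <- with_seed(seed, {
    vapply(seq_len(nPerm), function(p) {
      pi_ <- sample.int(nA + nB)
      g <- c(rep(0, nA), rep(1, nB))[pi_]
      X <- if (is.null(covariate)) cbind(1, g) else cbind(1, g, covariate)
      ft <- glm_t(Y, X, coef = 2L)
      tv <- vectorToVolume(ft$t, grid, mask, fill = 0)
      supra <- abs(tv) >= tcrit
      if (!any(supra)) return(0L)
      lab <- label_components_6(supra)
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
  })

  tab <- cl$table
  labels <- array(0L, grid@dims)
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$extent, function(e) {
      (1 + sum(max_ext >= e)) / (nPerm + 1)
    }, numeric(1))
    tab$significant <- tab$extent >= kMin & tab$p_fwe < alphaFwe
    pk <- arrayInd(tab$peak_idx, grid@dims)
    w <- voxelToWorld(grid, pk)
    tab$peak_x <- w[, 1L]; tab$peak_y <- w[, 2L]; tab$peak_z <- w[, 3L]
    ## relabel clusters 1..n across both signs
    tab$label <- seq_len(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      src <- if (tab$sign[i] == 1L) cl$pos else cl$neg
      labels[src == tab$id[i]] <- tab$label[i]
    }
    tab <- tab[, c("label", "extent", "peak_x", "peak_y", "peak_z",
                   "peak_t", "p_fwe", "sign", "significant")]
  } else {
    tab <- data.frame(label = integer(), extent = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_t = numeric(),
                      p_fwe = numeric(), sign = integer(),
                      significant = logical())
  }
  new("StatMap", tValues = obs@tValues, pValues = obs@pValues,
      clusterLabels = labels, clusters = tab, grid = grid, df = obs@df)
}

#' Clinical correlations with small-volume correction
#'
#' For each a-priori peak, correlates the map value with a clinical score
#' at every voxel of a sphere of radius `svcRadius` (mm, world space)
#' around the peak, reports the strongest in-sphere correlation, and
#' Bonferroni-corrects its p-value over the number of in-sphere voxels
#' (the small-volume correction). A radius of 0 tests the peak voxel
#' alone, with no correction factor.
#'
#' @param maps subjects x voxels matrix.
#' @param score per-subject clinical score (non-constant).
#' @param peaks n x 3 matrix of peak world coordinates (mm).
#' @param grid a [GridSpec-class].
#' @param mask 3D logical array matching the map columns.
#' @param svcRadius sphere radius in mm (default 10).
#' @param method "pearson" (default) or "spearman".
#' @param alpha significance level after correction (default 0.05).
#' @return data.frame per peak: best r, in-sphere voxel count,
#'   uncorrected and SVC-corrected p, significance flag.
#' @export
clinicalCorrelation <- function(maps, score, peaks, grid, mask,
                                svcRadius = 10, method = "pearson",
                                alpha = 0.05) {
  if (nrow(maps) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (stats::sd(score) == 0) {
    stop("undefined correlation: constant score", call. = FALSE)
  }
  peaks <- rbind_coords(peaks)
  keep <- which(as.logical(mask))
  vox_idx <- arrayInd(keep, grid@dims)
  world <- voxelToWorld(grid, vox_idx)
  n <- nrow(maps)
  if (method == "spearman") {
    maps <- apply(maps, 2L, rank)
    score <- rank(score)
  }
  out <- data.frame(peak = seq_len(nrow(peaks)), r = NA_real_,
                    nVoxels = NA_integer_, p = NA_real_, p_svc = NA_real_,
                    significant = NA)
  for (i in seq_len(nrow(peaks))) {
    d2 <- rowSums(sweep(world, 2L, peaks[i, ])^2)
    inside <- which(d2 <= svcRadius^2 + 1e-9)
    if (!length(inside)) next
    r <- suppressWarnings(stats::cor(score, maps[, inside, drop = FALSE]))
    r[!is.finite(r)] <- 0
    best <- which.max(abs(r))
    rb <- r[best]
    tstat <- rb * sqrt((n - 2) / max(1e-12, 1 - rb^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    out$r[i] <- rb
    out$nVoxels[i] <- length(inside)
    out$p[i] <- p
    out$p_svc[i] <- min(1, p * length(inside))
    out$significant[i] <- out$p_svc[i] < alpha
  }
  out
}
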