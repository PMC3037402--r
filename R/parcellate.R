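## Connectivity-based parcellation: seed extraction at the GM/WM
## boundary, profile aggregation over atlas regions, silhouette-guided
## k-means, centroid-profile comparison, and seed-count statistics.

## 2D Sobel gradient magnitude of a matrix, replicate-padded borders.
sobel2d <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  pad <- rbind(sl[1L, , drop = FALSE], sl, sl[nr, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dx, dy) pad[(2L + dx):(nr + 1L + dx), (2L + dy):(nc + 1L + dy)]
  gx <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gy <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  sqrt(gx^2 + gy^2)
}

#' Extract seed voxels at the GM/WM boundary of a region
#'
#' Applies a 2D Sobel filter per axial slice to the (non-binarised) grey
#' matter probability map; voxels whose gradient magnitude reaches
#' `gradThreshFrac` of the slice maximum and whose region probability is
#' at least `roiThresh` become candidate seeds. Seeds facing the CSF
#' (own or any 6-neighbour CSF probability above `csfCutoff`) are removed.
#'
#' @param gmProb,csfProb,roiProb 3D probability arrays in a shared space.
#' @param grid the [GridSpec-class] of the volumes.
#' @param roiThresh region-probability threshold (default 0.5).
#' @param gradThreshFrac gradient threshold as a fraction of the slice
#'   maximum (default 0.25).
#' @param csfCutoff CSF probability above which a neighbour disqualifies
#'   a seed (default 0.5).
#' @param roiName,subjectId,hemisphere seed-set metadata.
#' @return A [SeedSet-class]; errors when no seed survives.
#' @export
extractSeeds <- function(gmProb, csfProb, roiProb, grid, roiThresh = 0.5,
                         gradThreshFrac = 0.25, csfCutoff = 0.5,
                         roiName = "roi", subjectId = "s1", hemisphere = "") {
  d <- dim(gmProb)
  stopifnot(identical(d, dim(csfProb)), identical(d, dim(roiProb)),
            identical(as.integer(d), grid@dims))
  keep <- array(FALSE, d)
  for (z in seq_len(d[3L])) {
    g <- sobel2d(gmProb[, , z])
    mx <- max(g)
    if (mx <= 0) next
    keep[, , z] <- g >= gradThreshFrac * mx
  }
  keep <- keep & (roiProb >= roiThresh)
  ## drop seeds inside or adjacent (6-face) to CSF
  csf_hi <- csfProb > csfCutoff
  near_csf <- csf_hi
  near_csf[-d[1L], , ] <- near_csf[-d[1L], , ] | csf_hi[-1L, , ]
  near_csf[-1L, , ] <- near_csf[-1L, , ] | csf_hi[-d[1L], , ]
  near_csf[, -d[2L], ] <- near_csf[, -d[2L], ] | csf_hi[, -1L, ]
  near_csf[, -1L, ] <- near_csf[, -1L, ] | csf_hi[, -d[2L], ]
  near_csf[, , -d[3L]] <- near_csf[, , -d[3L]] | csf_hi[, , -1L]
  near_csf[, , -1L] <- near_csf[, , -1L] | csf_hi[, , -d[3L]]
  keep <- keep & !near_csf
  if (!any(keep)) stop("empty ROI: no boundary seeds found", call. = FALSE)
  new("SeedSet", roiName = roiName, coords = arrayInd(which(keep), d),
      subjectId = subjectId, hemisphere = hemisphere, grid = grid)
}

#' Aggregate visitation counts into seed-by-region profiles
#'
#' Sums each seed's streamline visitation counts within the regions of a
#' label atlas: entry (s, r) is the total number of visits of seed s in
#' voxels labelled r. Count volumes and the atlas are first downsampled
#' to a coarser raster (block summation for counts, label majority for
#' the atlas), emulating tractography output saved at reduced resolution.
#' Seed-containing regions (`excludeRegions`) and regions in the
#' contralateral hemisphere are dropped from the columns.
#'
#' @param visitCounts list of 3D count arrays, one per seed.
#' @param atlas 3D integer label array (0 = background), same space.
#' @param regionInfo data.frame with columns `id`, `name`, `hemisphere`
#'   describing the atlas labels.
#' @param excludeRegions character names (or integer ids) of regions to
#'   drop, typically those containing the starting seeds.
#' @param seedHemisphere "L" or "R"; regions with the opposite
#'   hemisphere label are excluded ("" disables the rule).
#' @param seedInfo optional data.frame of per-seed provenance.
#' @param downsample integer downsampling factor (default 1 = native).
#' @return A [ProfileMatrix-class].
#' @export
aggregateProfiles <- function(visitCounts, atlas, regionInfo,
                              excludeRegions = character(),
                              seedHemisphere = "", seedInfo = NULL,
                              downsample = 1L) {
  stopifnot(is.list(visitCounts), length(visitCounts) >= 1L)
  if (is.numeric(excludeRegions)) {
    bad <- setdiff(excludeRegions, regionInfo$id)
    if (length(bad)) stop("unknown region id in exclusions", call. = FALSE)
    excludeRegions <- regionInfo$name[match(excludeRegions, regionInfo$id)]
  } else {
    bad <- setdiff(excludeRegions, regionInfo$name)
    if (length(bad)) {
      stop(sprintf("unknown region in exclusions: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (downsample > 1L) {
    atlas <- downsampleLabels(atlas, downsample)
    visitCounts <- lapply(visitCounts, downsampleCounts, factor = downsample)
  }
  lab <- as.integer(atlas)
  counts <- t(vapply(visitCounts, function(v) {
    vapply(regionInfo$id, function(id) sum(v[lab == id]), numeric(1))
  }, numeric(nrow(regionInfo))))
  colnames(counts) <- regionInfo$name
  drop_ <- regionInfo$name %in% excludeRegions
  if (nzchar(seedHemisphere)) {
    contra <- regionInfo$hemisphere != "" &
      regionInfo$hemisphere != seedHemisphere
    drop_ <- drop_ | contra
  }
  profileMatrix(counts[, !drop_, drop = FALSE], seedInfo = seedInfo,
                regionInfo = regionInfo[!drop_, c("name", "hemisphere")])
}

## Row-normalise profiles (L1: each row divided by its total count);
## all-zero rows are left at zero.
normalize_profiles <- function(x, normalize = TRUE) {
  m <- if (is(x, "ProfileMatrix")) x@counts else as.matrix(x)
  if (!normalize) return(m)
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m / tot
}

#' Mean silhouette index of a clustering
#'
#' Standard silhouette in its dissimilarity form: for seed i with mean
#' intra-cluster distance a(i) and smallest mean distance to another
#' cluster b(i), `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; seeds in
#' singleton clusters score 0. The mean over seeds is returned. A
#' literal similarity-ratio variant (mean intra-cluster similarity over
#' the maximum similarity to seeds of other clusters, with similarity
#' `1 / (1 + d)`) is available via `variant = "ratio"`.
#'
#' @param profiles a [ProfileMatrix-class] or numeric matrix (rows: seeds).
#' @param labels integer cluster assignment (>= 2 nonempty clusters).
#' @param normalize L1-normalise rows first (default TRUE).
#' @param metric "euclidean" (default) or "correlation" (1 - r).
#' @param variant "rousseeuw" (default) or "ratio".
#' @return Mean index; in [-1, 1] for the default variant.
#' @export
silhouetteMean <- function(profiles, labels, normalize = TRUE,
                           metric = c("euclidean", "correlation"),
                           variant = c("rousseeuw", "ratio")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  m <- normalize_profiles(profiles, normalize)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(m))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (all(sizes == 1L)) {
    stop("undefined silhouette: all clusters are singletons", call. = FALSE)
  }
  D <- as.matrix(if (metric == "euclidean") stats::dist(m) else {
    stats::as.dist(1 - stats::cor(t(m)))
  })
  cl_ids <- as.integer(names(sizes))
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own)
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(same, i)])
    if (variant == "rousseeuw") {
      b <- min(vapply(cl_ids[cl_ids != own], function(cl) {
        mean(D[i, labels == cl])
      }, numeric(1)))
      s[i] <- (b - a) / max(a, b)
    } else {
      S <- 1 / (1 + D)
      a_sim <- mean(S[i, setdiff(same, i)])
      b_sim <- max(S[i, labels != own])
      s[i] <- a_sim / b_sim
    }
  }
  mean(s)
}

## k-means++ initial centres (rows of m), deterministic under the caller's
## RNG state.
kmeanspp_centres <- function(m, k) {
  n <- nrow(m)
  centres <- matrix(0, k, ncol(m))
  idx <- sample.int(n, 1L)
  centres[1L, ] <- m[idx, ]
  d2 <- rowSums(sweep(m, 2L, centres[1L, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centres[j, ] <- m[idx, ]
    d2 <- pmin(d2, rowSums(sweep(m, 2L, centres[j, ])^2))
  }
  centres
}

#' Silhouette-guided selection of the number of clusters
#'
#' Runs k-means (k-means++ initialisation, `nRestarts` restarts, best
#' within-cluster sum of squares kept) on the L1-normalised profiles for
#' every candidate k, scores each solution by its mean silhouette, and
#' selects the k with the maximum mean silhouette (ties broken toward
#' the smaller k). Cohorts whose best mean silhouette stays below
#' `noStructureCutoff` - the conventional boundary below which a
#' silhouette indicates no substantial structure - are flagged
#' `noStructure`, with `chosenK` undefined; degenerate all-identical
#' profiles are flagged directly. Groups are intended to be processed
#' separately, one call per cohort.
#'
#' @param profiles a [ProfileMatrix-class] (or numeric matrix).
#' @param kRange candidate cluster numbers (default 2:15).
#' @param nRestarts k-means restarts per k (default 20).
#' @param seed integer RNG seed.
#' @param normalize L1-normalise rows (default TRUE).
#' @param metric silhouette metric, see [silhouetteMean()].
#' @param noStructureCutoff minimum acceptable mean silhouette (default 0.25).
#' @param group cohort label stored in the result.
#' @return A [ParcellationResult-class].
#' @export
chooseK <- function(profiles, kRange = 2:15, nRestarts = 20L, seed = 1L,
                    normalize = TRUE, metric = "euclidean",
                    noStructureCutoff = 0.25, group = "A") {
  m <- normalize_profiles(profiles, normalize)
  si <- if (is(profiles, "ProfileMatrix")) profiles@seedInfo else NULL
  n <- nrow(m)
  kRange <- kRange[kRange >= 2L & kRange < n]
  if (!length(kRange)) stop("no admissible k in kRange", call. = FALSE)
  nd <- nrow(unique(m))
  if (nd == 1L) {
    return(new("ParcellationResult", labels = integer(), centroids = matrix(0, 0, ncol(m)),
               silhouetteCurve = stats::setNames(numeric(0), character(0)),
               chosenK = NA_integer_, noStructure = TRUE,
               seedCounts = matrix(0, 0, 0), group = group))
  }
  with_seed(seed, {
    sil <- stats::setNames(rep(NA_real_, length(kRange)), kRange)
    fits <- vector("list", length(kRange))
    for (j in seq_along(kRange)) {
      k <- kRange[j]
      if (nd < k) next
      best <- NULL
      for (r in seq_len(nRestarts)) {
        cen <- kmeanspp_centres(m, k)
        fit <- tryCatch(
          stats::kmeans(m, centers = cen, iter.max = 100L,
                        algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) {
            tryCatch(suppressWarnings(
              stats::kmeans(m, centers = cen, iter.max = 100L,
                            algorithm = "Lloyd")), error = function(e) NULL)
          })
        if (is.null(fit) || length(unique(fit$cluster)) < k) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      if (is.null(best)) next
      fits[[j]] <- best
      sil[j] <- silhouetteMean(m, best$cluster, normalize = FALSE,
                               metric = metric)
    }
    ok <- which(is.finite(sil))
    if (!length(ok) || max(sil[ok]) < noStructureCutoff) {
      return(new("ParcellationResult", labels = integer(),
                 centroids = matrix(0, 0, ncol(m)),
                 silhouetteCurve = sil, chosenK = NA_integer_,
                 noStructure = TRUE, seedCounts = matrix(0, 0, 0),
                 group = group))
    }
    jbest <- ok[which.max(sil[ok])]        # which.max takes the first max: smaller k
    fit <- fits[[jbest]]
    k <- kRange[jbest]
    cen <- fit$centers
    colnames(cen) <- colnames(m)
    counts <- if (!is.null(si)) {
      tab <- table(si$subject, factor(fit$cluster, levels = seq_len(k)))
      mat <- matrix(as.integer(tab), nrow(tab), k,
                    dimnames = list(rownames(tab), seq_len(k)))
      mat
    } else {
      matrix(table(factor(fit$cluster, levels = seq_len(k))), 1L, k,
             dimnames = list("all", seq_len(k)))
    }
    new("ParcellationResult", labels = as.integer(fit$cluster),
        centroids = cen, silhouetteCurve = sil, chosenK = as.integer(k),
        noStructure = FALSE, seedCounts = counts, group = group)
  })
}

#' Compare cluster-centroid profiles between two parcellations
#'
#' Matches clusters across the two groups by maximal centroid correlation
#' (optimal one-to-one assignment); with unequal cluster counts the
#' unmatched clusters are reported as group-unique. For every matched
#' cluster each region is classified by peak presence and amplitude:
#' `present-in-A-only`, `present-in-B-only`, `increased` (B over A by at
#' least `ampRatio`), `decreased`, or `unchanged`. Regions below
#' `peakThresh` in both centroids are omitted from the report. The
#' comparison is symmetric: swapping the arguments mirrors the report.
#'
#' @param resA,resB [ParcellationResult-class] objects over the same
#'   region columns.
#' @param peakThresh centroid value above which a region counts as a
#'   peak (default 0.05 on normalised profiles).
#' @param ampRatio amplitude ratio defining increased/decreased
#'   (default 1.5).
#' @return List: `matches` (data.frame clusterA, clusterB, r),
#'   `unmatchedA`, `unmatchedB` (integer cluster ids), `report`
#'   (data.frame clusterA, clusterB, region, valueA, valueB, status).
#' @export
compareCentroids <- function(resA, resB, peakThresh = 0.05, ampRatio = 1.5) {
  cA <- resA@centroids
  cB <- resB@centroids
  if (!identical(colnames(cA), colnames(cB))) {
    stop("parcellations must share region columns", call. = FALSE)
  }
  R <- row_cor(cA, cB)
  R[is.na(R)] <- 0
  asg <- hungarian_match(R)
  matches <- data.frame(clusterA = which(!is.na(asg)),
                        clusterB = asg[!is.na(asg)])
  matches$r <- R[cbind(matches$clusterA, matches$clusterB)]
  rows <- list()
  for (i in seq_len(nrow(matches))) {
    a <- cA[matches$clusterA[i], ]
    b <- cB[matches$clusterB[i], ]
    for (rgn in seq_along(a)) {
      pa <- a[rgn] >= peakThresh
      pb <- b[rgn] >= peakThresh
      if (!pa && !pb) next
      status <- if (pa && !pb) "present-in-A-only"
      else if (!pa && pb) "present-in-B-only"
      else if (b[rgn] / a[rgn] >= ampRatio) "increased"
      else if (a[rgn] / b[rgn] >= ampRatio) "decreased"
      else "unchanged"
      rows[[length(rows) + 1L]] <- data.frame(
        clusterA = matches$clusterA[i], clusterB = matches$clusterB[i],
        region = colnames(cA)[rgn], valueA = unname(a[rgn]),
        valueB = unname(b[rgn]), status = status)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(clusterA = integer(), clusterB = integer(),
               region = character(), valueA = numeric(),
               valueB = numeric(), status = character())
  }
  list(matches = matches,
       unmatchedA = setdiff(seq_len(nrow(cA)), matches$clusterA),
       unmatchedB = setdiff(seq_len(nrow(cB)), matches$clusterB),
       report = report)
}

#' Group statistics on per-subject seed counts
#'
#' For every matched cluster pair, compares the per-subject number of
#' seeds assigned to the cluster between groups with Welch's t test, and
#' correlates the counts with clinical scores by Spearman rank
#' correlation within each group that has scores.
#'
#' @param resA,resB [ParcellationResult-class] objects with per-subject
#'   seed counts.
#' @param scoresA,scoresB optional data.frames of per-subject clinical
#'   scores (rows aligned with the rows of the seed-count matrices).
#' @param matches optional match table from [compareCentroids()];
#'   computed when omitted.
#' @return List: `tests` (per matched cluster: means, t, df, p),
#'   `correlations` (group, cluster, score, rho, p).
#' @export
seedCountStats <- function(resA, resB, scoresA = NULL, scoresB = NULL,
                           matches = NULL) {
  if (is.null(matches)) matches <- compareCentroids(resA, resB)$matches
  tests <- data.frame(clusterA = matches$clusterA, clusterB = matches$clusterB,
                      meanA = NA_real_, meanB = NA_real_, t = NA_real_,
                      df = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(matches))) {
    a <- resA@seedCounts[, matches$clusterA[i]]
    b <- resB@seedCounts[, matches$clusterB[i]]
    tests$meanA[i] <- mean(a)
    tests$meanB[i] <- mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      ## degenerate variance: identical means are a null result, different
      ## means a deterministic difference
      d <- mean(b) - mean(a)
      tests$t[i] <- if (d == 0) 0 else sign(d) * Inf
      tests$df[i] <- length(a) + length(b) - 2
      tests$p[i] <- if (d == 0) 1 else 0
    } else {
      tt <- stats::t.test(b, a)            # Welch; positive t = more in B
      tests$t[i] <- unname(tt$statistic)
      tests$df[i] <- unname(tt$parameter)
      tests$p[i] <- tt$p.value
    }
  }
  cors <- list()
  add_cors <- function(res, scores, grp, cluster_col) {
    if (is.null(scores)) return()
    for (i in seq_len(nrow(matches))) {
      cl <- matches[[cluster_col]][i]
      cnt <- res@seedCounts[, cl]
      for (sc in colnames(scores)) {
        ct <- suppressWarnings(
          stats::cor.test(cnt, scores[[sc]], method = "spearman"))
        cors[[length(cors) + 1L]] <<- data.frame(
          group = grp, cluster = cl, score = sc,
          rho = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  add_cors(resA, scoresA, "A", "clusterA")
  add_cors(resB, scoresB, "B", "clusterB")
  correlations <- if (length(cors)) do.call(rbind, cors) else {
    data.frame(group = character(), cluster = integer(),
               score = character(), rho = numeric(), p = numeric())
  }
  list(tests = tests, correlations = correlations)
}
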