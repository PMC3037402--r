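## ICASSO-style reliability of the ICA decomposition.

#' ICASSO stability assessment of Infomax components
#'
#' Runs Infomax `nRuns` times with different random initial conditions
#' (and, optionally, bootstrap-resampled data: time-rows of the
#' concatenated matrix drawn with replacement), pools all estimated
#' spatial maps, clusters them agglomeratively on the dissimilarity
#' `1 - |spatial correlation|` (single linkage: reliably re-estimated
#' components form tight cliques that merge first, while chaining is
#' confined to the diffuse unstable pool), and scores each of the K
#' clusters with the stability index
#' `mean intra-cluster similarity - mean extra-cluster similarity`,
#' which lies in `[-1, 1]` and approaches 1 for components re-estimated
#' identically in every run. The centrotype of a cluster is its member
#' with the largest within-cluster similarity sum.
#'
#' @param X M x N concatenated data matrix (see [concatenateReduced()]).
#' @param K number of components per run (and pooled clusters).
#' @param nRuns number of Infomax runs (default 10, >= 2).
#' @param seed integer RNG seed; per-run seeds are derived from it.
#' @param bootstrap logical; resample the M rows with replacement per run.
#' @param runSeeds optional integer vector of per-run seeds (length
#'   `nRuns`), overriding the seeds derived from `seed`; identical run
#'   seeds with `bootstrap = FALSE` reproduce the same decomposition in
#'   every run.
#' @param ... further arguments passed to [runInfomax()].
#' @return List: `index` (numeric K, per-cluster stability),
#'   `centrotypes` (K x N matrix of canonical maps), `membership`
#'   (integer per pooled component), `similarity` (pooled |r| matrix),
#'   `runs` (list of per-run map matrices).
#' @export
icasso <- function(X, K, nRuns = 10L, seed = 1L, bootstrap = TRUE,
                   runSeeds = NULL, ...) {
  nRuns <- stopifnot_count(nRuns, "nRuns", min = 2L)
  M <- nrow(X)
  if (K * nRuns < 4L) stop("pool of K x nRuns components too small", call. = FALSE)
  if (!is.null(runSeeds)) stopifnot(length(runSeeds) == nRuns)
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    run_seed <- if (is.null(runSeeds)) derive_seed(seed, r) else runSeeds[r]
    Xr <- if (bootstrap) {
      rows <- with_seed(derive_seed(seed, 1000 + r),
                        sample.int(M, M, replace = TRUE))
      X[rows, , drop = FALSE]
    } else {
      X
    }
    runs[[r]] <- suppressWarnings(
      runInfomax(Xr, K = K, seed = run_seed, ...)$maps
    )
  }
  pool <- do.call(rbind, runs)               # (nRuns K) x N
  sim <- abs(row_cor(pool, pool))
  sim[!is.finite(sim)] <- 0
  diag(sim) <- 1
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
  memb <- stats::cutree(hc, k = K)
  index <- numeric(K)
  centro <- matrix(0, K, ncol(pool))
  for (cl in seq_len(K)) {
    inside <- which(memb == cl)
    outside <- which(memb != cl)
    intra <- if (length(inside) > 1L) {
      S <- sim[inside, inside]
      mean(S[upper.tri(S)])
    } else 1          # singleton cluster: perfectly self-similar
    extra <- if (length(outside)) mean(sim[inside, outside, drop = FALSE]) else 0
    index[cl] <- intra - extra
    within_sums <- rowSums(sim[inside, inside, drop = FALSE])
    centro[cl, ] <- pool[inside[which.max(within_sums)], ]
  }
  list(index = index, centrotypes = centro, membership = memb,
       similarity = sim, runs = runs)
}

#' Stability assessment for a fitted ComponentSet
#'
#' Re-runs the group decomposition `nRuns` times on the concatenated
#' reduced data of `images`, matches each ICASSO cluster centrotype to
#' the components of `cset` by greatest absolute spatial correlation, and
#' stores the per-component stability index in the object.
#'
#' @param cset a [ComponentSet-class] from [runGroupICA()].
#' @param images the input list of [Image4D-class] objects.
#' @param nRuns number of Infomax runs.
#' @param seed integer RNG seed.
#' @param bootstrap logical, bootstrap the concatenated rows.
#' @param ... passed to [runInfomax()].
#' @return The [ComponentSet-class] with its `stability` slot filled.
#' @export
assessStability <- function(cset, images, nRuns = 10L, seed = 1L,
                            bootstrap = TRUE, ...) {
  red <- pcaReduce(images, C = cset@reducedDim, mask = cset@mask)
  X <- concatenateReduced(red)
  ic <- icasso(X, K = cset@K, nRuns = nRuns, seed = seed,
               bootstrap = bootstrap, ...)
  r <- abs(row_cor(cset@groupMaps, ic$centrotypes))
  m <- greedy_match(r)
  st <- rep(NA_real_, cset@K)
  st[m$row] <- ic$index[m$col]
  stabilityIndex(cset) <- st
  cset
}

#' Spatial similarity of two component decompositions
#'
#' Pearson correlation between all pairs of Z-scored group maps of two
#' decompositions in the same voxel space, with a greedy one-to-one
#' matching by descending absolute correlation (the cross-cohort
#' similarity check performed between per-group and whole-group ICAs).
#'
#' @param setA,setB [ComponentSet-class] objects on the same voxel grid.
#' @return List: `correlation` (K_A x K_B matrix), `matches`
#'   (data.frame with columns row, col, value).
#' @export
crossCohortSimilarity <- function(setA, setB) {
  if (ncol(setA@groupMaps) != ncol(setB@groupMaps)) {
    stop("invalid space: decompositions have different voxel counts",
         call. = FALSE)
  }
  R <- row_cor(setA@groupMaps, setB@groupMaps)
  list(correlation = R, matches = greedy_match(R))
}
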