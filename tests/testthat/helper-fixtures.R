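## Shared fixtures, built in code at test time.

tiny_grid <- function(dims = c(4L, 4L, 3L), voxelSize = c(3, 3, 4), TR = 3) {
  gridSpec(dims, voxelSize, TR)
}

## Image4D holding a single voxel time series replicated over a 2x2x2 grid.
series_image <- function(x, TR = 3, voxelSize = c(3, 3, 4)) {
  T_ <- length(x)
  arr <- aperm(array(x %o% rep(1, 8), c(T_, 2, 2, 2)), c(2, 3, 4, 1))
  image4D(arr, gridSpec(c(2L, 2L, 2L), voxelSize, TR))
}

## Analytic GM/WM slab: GM = 1 for y < y0, WM = 1 for y >= y0 (1-based:
## GM rows 1..y0, WM rows y0+1..). Returns gm, wm, csf arrays.
slab_volumes <- function(dims = c(12L, 20L, 6L), y0 = 10L) {
  gm <- array(0, dims)
  wm <- array(0, dims)
  gm[, seq_len(y0), ] <- 1
  wm[, (y0 + 1L):dims[2L], ] <- 1
  list(gm = gm, wm = wm, csf = array(0, dims))
}

## Build a ComponentSet directly from generator truth (maps + per-subject
## time courses), bypassing ICA; used to exercise selection criteria on
## known components.
truth_component_set <- function(cohort) {
  maps <- t(vapply(cohort$truth$maps, as.vector,
                   numeric(prod(gridDims(cohort$grid)))))
  K <- nrow(maps)
  nSub <- length(cohort$images)
  new("ComponentSet",
      groupMaps = zscoreMaps(maps),
      mixing = matrix(0, nSub * K, K),
      timecourses = cohort$truth$timecourses,
      subjectMaps = list(),
      K = as.integer(K), reducedDim = as.integer(K),
      subjects = vapply(cohort$images, subjectId, character(1)),
      stability = rep(NA_real_, K),
      grid = cohort$grid, mask = array(TRUE, gridDims(cohort$grid)),
      converged = TRUE)
}

## Independent brute-force silhouette oracle (double loop, no shared code
## with the implementation).
silhouette_bruteforce <- function(m, labels) {
  n <- nrow(m)
  d <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) d(i, j), numeric(1)))
    bs <- vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(vapply(which(labels == cl), function(j) d(i, j), numeric(1)))
    }, numeric(1))
    b <- min(bs)
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## Best label agreement between two assignments over all permutations of
## the (small) label set of `b`.
label_agreement <- function(a, b) {
  la <- sort(unique(a))
  lb <- sort(unique(b))
  if (length(la) != length(lb)) return(0)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(lb)) {
    rel <- p[match(b, lb)]
    best <- max(best, mean(a == rel))
  }
  best
}
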