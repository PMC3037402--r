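## Group spatial ICA: subject-level PCA reduction, temporal concatenation,
## Infomax unmixing, back-reconstruction, Z-scoring.

#' Per-subject PCA reduction of the temporal dimension
#'
#' Projects each subject's time-by-voxel matrix onto the top-C principal
#' directions of its temporal covariance. Each time point's spatial mean
#' is removed first. The retained basis has orthonormal columns, and the
#' reconstruction error equals the sum of the discarded eigenvalues.
#'
#' @param matrices list of time x N matrices (one per subject), or a list
#'   of [Image4D-class] objects together with `mask`.
#' @param C retained temporal dimensionality (<= each time length).
#' @param mask optional 3D logical array applied when `matrices` holds
#'   [Image4D-class] objects.
#' @return A `ReducedData` list: `reduced` (list of C x N matrices),
#'   `basis` (list of time x C orthonormal matrices), `eigenvalues`
#'   (per-subject full eigenvalue vectors), `C`, and `subjects`.
#' @export
pcaReduce <- function(matrices, C, mask = NULL) {
  if (is(matrices[[1L]], "Image4D")) {
    subjects <- vapply(matrices, subjectId, character(1))
    matrices <- lapply(matrices, flattenImage, mask = mask)
  } else {
    subjects <- sprintf("s%02d", seq_along(matrices))
    if (!is.null(names(matrices))) subjects <- names(matrices)
  }
  Tmin <- min(vapply(matrices, nrow, integer(1)))
  if (C > Tmin) stop("invalid dimension: C exceeds the time length", call. = FALSE)
  red <- vector("list", length(matrices))
  bases <- vector("list", length(matrices))
  evs <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    X <- matrices[[i]]
    X <- X - rowMeans(X)              # remove each volume's spatial mean
    Ct <- tcrossprod(X) / ncol(X)     # temporal covariance, T x T
    eg <- eigen(Ct, symmetric = TRUE)
    E <- eg$vectors[, seq_len(C), drop = FALSE]
    red[[i]] <- crossprod(E, X)       # C x N
    bases[[i]] <- E
    evs[[i]] <- eg$values
  }
  structure(list(reduced = red, basis = bases, eigenvalues = evs,
                 C = as.integer(C), subjects = subjects),
            class = "ReducedData")
}

#' Concatenate reduced subject matrices into the multi-subject matrix
#'
#' Stacks the C x N reduced matrices vertically in subject order, giving
#' the M x N matrix with M = subjects x C (e.g. 26 subjects x 40
#' components = 1,040 rows) that enters Infomax.
#'
#' @param reduced a `ReducedData` list from [pcaReduce()].
#' @return M x N matrix with attributes `subjects` and `C` recording the
#'   block structure.
#' @export
concatenateReduced <- function(reduced) {
  Ns <- vapply(reduced$reduced, ncol, integer(1))
  if (length(unique(Ns)) != 1L) {
    stop("invalid shape: subjects disagree on voxel count N", call. = FALSE)
  }
  X <- do.call(rbind, reduced$reduced)
  attr(X, "subjects") <- reduced$subjects
  attr(X, "C") <- reduced$C
  X
}

#' Infomax independent component estimation
#'
#' Estimates K maximally independent spatial sources from an M x N matrix
#' by the natural-gradient Infomax rule with a logistic nonlinearity,
#' which favours the super-Gaussian (spatially sparse) sources typical of
#' network maps. The data are whitened internally to K dimensions. The
#' learning rate is annealed, and halved with a restart whenever the
#' weights blow up. Non-convergence within `maxIter` passes yields a
#' warning, not an error.
#'
#' @param X M x N data matrix (rows: concatenated reduced time courses).
#' @param K number of components (<= M).
#' @param seed integer RNG seed for the random orthogonal initialisation
#'   and the per-pass column permutations.
#' @param maxIter maximum number of passes over the data (default 512).
#' @param tol convergence tolerance on the squared weight change.
#' @param lrate initial learning rate; default `0.01 / log(K)`.
#' @param blockSize natural-gradient block size; default
#'   `ceiling(min(N / 10, 5 + sqrt(N)))`.
#' @return List: `maps` (K x N source estimates), `mixing` (M x K),
#'   `unmixing` (K x M), `converged`, `iterations`.
#' @export
runInfomax <- function(X, K, seed = 1L, maxIter = 512L, tol = 1e-6,
                       lrate = NULL, blockSize = NULL) {
  M <- nrow(X)
  N <- ncol(X)
  if (K > M) stop("invalid dimension: K exceeds the number of rows", call. = FALSE)
  if (is.null(lrate)) lrate <- 0.01 / log(max(K, 3))
  if (is.null(blockSize)) blockSize <- ceiling(min(N / 10, 5 + sqrt(N)))
  Xc <- X - rowMeans(X)
  ## whiten to K dimensions
  Cm <- tcrossprod(Xc) / N
  eg <- eigen(Cm, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(K)], 1e-12)
  E <- eg$vectors[, seq_len(K), drop = FALSE]
  wh <- diag(1 / sqrt(ev), K) %*% t(E)       # K x M
  dewh <- E %*% diag(sqrt(ev), K)            # M x K
  Xw <- wh %*% Xc
  with_seed(seed, {
    W0 <- qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
    W <- W0
    lr <- lrate
    old_change <- Inf
    converged <- FALSE
    iter <- 0L
    IK <- diag(K)
    while (iter < maxIter) {
      iter <- iter + 1L
      W_old <- W
      perm <- sample.int(N)
      starts <- seq(1L, N, by = blockSize)
      bad <- FALSE
      for (s in starts) {
        idx <- perm[s:min(s + blockSize - 1L, N)]
        B <- length(idx)
        u <- W %*% Xw[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        W <- W + lr * ((B * IK + (1 - 2 * y) %*% t(u)) %*% W) / B
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) { bad <- TRUE; break }
      }
      if (bad) {
        lr <- lr * 0.5
        W <- W0
        old_change <- Inf
        next
      }
      change <- sum((W - W_old)^2)
      if (change < tol) { converged <- TRUE; break }
      if (change > old_change) lr <- lr * 0.98
      old_change <- change
    }
    if (!converged) {
      warning(sprintf("Infomax did not converge in %d passes (change %.2e)",
                      iter, old_change), call. = FALSE)
    }
    Wtot <- W %*% wh                         # K x M unmixing
    maps <- Wtot %*% Xc                      # K x N sources
    mixing <- dewh %*% solve(W)              # M x K, X ~ mixing %*% maps
    ## canonical sign: nonnegative spatial skewness per component
    fl <- vapply(seq_len(K), function(k) skewness_(maps[k, ]) < 0, logical(1))
    maps[fl, ] <- -maps[fl, , drop = FALSE]
    mixing[, fl] <- -mixing[, fl, drop = FALSE]
    Wtot[fl, ] <- -Wtot[fl, , drop = FALSE]
    list(maps = maps, mixing = mixing, unmixing = Wtot,
         converged = converged, iterations = iter)
  })
}

#' Back-reconstruct per-subject maps and time courses
#'
#' Partitions the group mixing matrix into per-subject C x K blocks.
#' Subject time courses are the subject's PCA basis times its mixing
#' block; subject maps are the (pseudo)inverse of the block applied to
#' the subject's reduced data. With a single subject this degenerates to
#' ordinary ICA: subject maps equal the group maps up to scale.
#'
#' @param mixing M x K group mixing matrix from [runInfomax()].
#' @param reduced the `ReducedData` list the concatenated matrix was built
#'   from (supplies the bases and the block order).
#' @return List: `timecourses` (per subject, time x K), `maps` (per
#'   subject, K x N).
#' @export
backReconstruct <- function(mixing, reduced) {
  nSub <- length(reduced$reduced)
  C <- reduced$C
  if (nrow(mixing) != nSub * C) {
    stop("invalid partition: mixing rows do not match subjects x C", call. = FALSE)
  }
  tcs <- vector("list", nSub)
  maps <- vector("list", nSub)
  for (i in seq_len(nSub)) {
    rows <- ((i - 1L) * C + 1L):(i * C)
    Ai <- mixing[rows, , drop = FALSE]       # C x K
    tcs[[i]] <- reduced$basis[[i]] %*% Ai    # time x K
    maps[[i]] <- MASS::ginv(Ai) %*% reduced$reduced[[i]]  # K x N
  }
  names(tcs) <- names(maps) <- reduced$subjects
  list(timecourses = tcs, maps = maps)
}

#' Z-score component maps
#'
#' Standardises each row (spatial map) to zero mean and unit population
#' standard deviation over its voxels, making voxel values comparable
#' across subjects. Zero-variance rows cannot be standardised; they are
#' left at zero and flagged in the `degenerate` attribute.
#'
#' @param maps K x N matrix of spatial maps.
#' @return K x N matrix with attribute `degenerate` (logical per row).
#' @export
zscoreMaps <- function(maps) {
  mu <- rowMeans(maps)
  cen <- maps - mu
  sdv <- sqrt(rowMeans(cen^2))
  degen <- sdv <= 0
  out <- cen
  out[!degen, ] <- cen[!degen, , drop = FALSE] / sdv[!degen]
  out[degen, ] <- 0
  attr(out, "degenerate") <- degen
  out
}

#' Run the full group spatial ICA
#'
#' Convenience wrapper: PCA-reduce each subject to C dimensions,
#' concatenate, run Infomax for K components, back-reconstruct subject
#' maps and time courses, and Z-score all spatial maps.
#'
#' Following the arithmetic of a 26-subject, 40-component analysis
#' (M = 26 x 40 = 1,040 concatenated rows), `C` defaults to `K`.
#'
#' @param images list of [Image4D-class] objects (or time x N matrices).
#' @param K number of group components.
#' @param C per-subject retained dimensionality (default `K`).
#' @param mask optional 3D logical analysis mask; default all voxels.
#' @param seed integer RNG seed.
#' @param grid [GridSpec-class]; taken from the images when omitted.
#' @param ... further arguments passed to [runInfomax()].
#' @return A [ComponentSet-class].
#' @export
runGroupICA <- function(images, K = 40L, C = K, mask = NULL, seed = 1L,
                        grid = NULL, ...) {
  if (is(images[[1L]], "Image4D")) {
    grid <- images[[1L]]@grid
  } else if (is.null(grid)) {
    stop("grid must be supplied when inputs are plain matrices", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, grid@dims)
  red <- pcaReduce(images, C = C, mask = mask)
  X <- concatenateReduced(red)
  im <- runInfomax(X, K = K, seed = seed, ...)
  br <- backReconstruct(im$mixing, red)
  new("ComponentSet",
      groupMaps = zscoreMaps(im$maps),
      mixing = im$mixing,
      timecourses = br$timecourses,
      subjectMaps = lapply(br$maps, zscoreMaps),
      K = as.integer(K), reducedDim = as.integer(C), subjects = red$subjects,
      stability = rep(NA_real_, K), grid = grid, mask = mask,
      converged = im$converged)
}
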