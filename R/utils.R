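## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
## All exported stochastic operations funnel through this so that a given
## `seed` argument yields bit-identical results regardless of the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministically derive a child seed from a parent seed and a stream index,
## staying inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

## Pearson correlation between rows of A and rows of B (kA x n, kB x n),
## returned as a kA x kB matrix.  Degenerate (zero-variance) rows give NA.
row_cor <- function(A, B) {
  a <- A - rowMeans(A)
  b <- B - rowMeans(B)
  sa <- sqrt(rowSums(a^2))
  sb <- sqrt(rowSums(b^2))
  r <- (a %*% t(b)) / outer(sa, sb)
  r[!is.finite(r)] <- NA_real_
  r
}

## Greedy one-to-one matching by descending |value| of a score matrix.
## Returns a data.frame(row, col, value) with min(nrow, ncol) matches.
greedy_match <- function(score) {
  sc <- abs(score)
  sc[is.na(sc)] <- -Inf
  n <- min(nrow(score), ncol(score))
  out <- data.frame(row = integer(n), col = integer(n), value = numeric(n))
  for (i in seq_len(n)) {
    idx <- arrayInd(which.max(sc), dim(sc))
    out$row[i] <- idx[1L]
    out$col[i] <- idx[2L]
    out$value[i] <- score[idx[1L], idx[2L]]
    sc[idx[1L], ] <- -Inf
    sc[, idx[2L]] <- -Inf
  }
  out
}

## Hungarian algorithm (O(n^3), rectangular via padding) maximising total
## `score`.  Returns integer vector: for each row, the matched column or NA.
hungarian_match <- function(score) {
  nr <- nrow(score)
  nc <- ncol(score)
  n <- max(nr, nc)
  ## convert to a square cost matrix for minimisation
  big <- max(abs(score[is.finite(score)]), 1)
  cost <- matrix(2 * big, n, n)
  cost[seq_len(nr), seq_len(nc)] <- -score
  cost[!is.finite(cost)] <- 2 * big
  ## Jonker-style potentials with augmenting paths
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  res <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    if (p[j + 1L] >= 1L && p[j + 1L] <= nr && j <= nc) res[p[j + 1L]] <- j
  }
  res
}

## 6-face-connected component labelling of a 3D logical array.
## Returns an integer array; 0 = background, clusters numbered 1..n.
label_components_6 <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nxt <- 0L
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  nxy <- nx * ny
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      y <- rem %/% nx
      x <- rem %% nx
      nbr <- c(
        if (x > 0L) v - 1L, if (x < nx - 1L) v + 1L,
        if (y > 0L) v - nx, if (y < ny - 1L) v + nx,
        if (z > 0L) v - nxy, if (z < nz - 1L) v + nxy
      )
      for (w in nbr) {
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

## Skewness (population moment form) of a numeric vector.
skewness_ <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) return(0)
  mean(x^3) / s2^1.5
}
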