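test_that("PCA reduction spans the top-variance subspace", {
  set.seed(10)
  ## exact rank-3 input is reconstructed losslessly at C = 3
  A <- matrix(rnorm(20 * 3), 20) %*% matrix(rnorm(3 * 50), 3)
  red <- pcaReduce(list(A), C = 3L)
  recon <- red$basis[[1L]] %*% red$reduced[[1L]]
  Ac <- A - rowMeans(A)
  expect_lt(max(abs(recon - Ac)), 1e-9)
  expect_equal(crossprod(red$basis[[1L]]), diag(3), tolerance = 1e-12)

  ## explained variance equals the top-C eigenvalue sum (dense oracle)
  X <- matrix(rnorm(30 * 200), 30)
  red5 <- pcaReduce(list(X), C = 5L)
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)$values
  got <- sum(red5$reduced[[1L]]^2) / ncol(X)
  expect_equal(got, sum(ev[1:5]), tolerance = 1e-8)
  ## reconstruction error equals the discarded eigenvalue sum
  resid <- Xc - red5$basis[[1L]] %*% red5$reduced[[1L]]
  expect_equal(sum(resid^2) / ncol(X), sum(ev[-(1:5)]), tolerance = 1e-8)

  expect_error(pcaReduce(list(X), C = 31L), "dimension")
})

test_that("concatenation preserves block order, shape and retained variance", {
  set.seed(11)
  mats <- lapply(1:3, function(i) matrix(rnorm(8 * 10), 8))
  red <- pcaReduce(mats, C = 2L)
  X <- concatenateReduced(red)
  expect_equal(dim(X), c(6L, 10L))
  expect_identical(X[3:4, ], red$reduced[[2L]])
  expect_equal(sum(X^2), sum(vapply(red$reduced, function(m) sum(m^2),
                                    numeric(1))), tolerance = 1e-10)

  one <- concatenateReduced(pcaReduce(mats[1L], C = 2L))
  expect_equal(dim(one), c(2L, 10L))

  bad <- pcaReduce(list(mats[[1L]], matrix(rnorm(8 * 9), 8)), C = 2L)
  expect_error(concatenateReduced(bad), "shape|N")
})

test_that("Infomax separates super-Gaussian sources mixed by a known matrix", {
  set.seed(12)
  N <- 2000
  S <- rbind(rexp(N) * sign(rnorm(N)), rexp(N) * sign(rnorm(N)))  # sparse
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  X <- A %*% S
  fit <- runInfomax(X, K = 2L, seed = 5)
  R <- abs(rsnparc:::row_cor(fit$maps, S))
  m <- rsnparc:::greedy_match(R)
  expect_true(all(abs(m$value) > 0.99))
  ## mixing reconstructs the data
  expect_lt(max(abs(fit$mixing %*% fit$maps - (X - rowMeans(X)))), 1e-6)

  ## determinism: same seed, same output
  fit2 <- runInfomax(X, K = 2L, seed = 5)
  expect_identical(fit$maps, fit2$maps)

  ## identity-mixed independent sources: unmixing ~ permuted scaled identity
  fit3 <- runInfomax(S, K = 2L, seed = 7)
  P <- abs(rsnparc:::row_cor(fit3$maps, S))
  expect_true(all(abs(rsnparc:::greedy_match(P)$value) > 0.99))

  expect_error(runInfomax(X, K = 3L), "dimension")
})

test_that("component sign canonicalisation gives nonnegative skewness and is idempotent", {
  set.seed(13)
  S <- rbind(-rexp(1000), rexp(1000))      # one negatively skewed source
  X <- matrix(rnorm(4 * 2), 4) %*% S
  fit <- runInfomax(X, K = 2L, seed = 1)
  sk <- apply(fit$maps, 1L, rsnparc:::skewness_)
  expect_true(all(sk >= 0))
})

test_that("back-reconstruction recovers subject structure", {
  ## single subject: subject maps equal group maps up to scale/sign
  co <- makeRsfmriCohort(nSubjectsPerGroup = c(1L, 1L), nNetworks = 2L,
                         nTimepoints = 80L, noiseSd = 0.2, seed = 31)
  cs1 <- runGroupICA(co$images[1L], K = 3L, C = 3L, seed = 2)
  r11 <- abs(rsnparc:::row_cor(subjectMaps(cs1)[[1L]], componentMaps(cs1)))
  expect_true(all(diag(r11) > 0.999))

  ## planted cohort: subject maps track the group map of each network
  co2 <- makeRsfmriCohort(nSubjectsPerGroup = c(3L, 3L), nNetworks = 3L,
                          nTimepoints = 100L, noiseSd = 0.1, seed = 32)
  cs <- runGroupICA(co2$images, K = 4L, C = 4L, seed = 3)
  truth <- t(vapply(co2$truth$maps, as.vector,
                    numeric(prod(gridDims(co2$grid)))))
  match <- rsnparc:::greedy_match(rsnparc:::row_cor(truth, componentMaps(cs)))
  for (i in seq_len(nrow(match))) {
    comp <- match$col[i]
    for (s in seq_along(co2$images)) {
      r <- abs(stats::cor(subjectMaps(cs)[[s]][comp, ],
                          componentMaps(cs)[comp, ]))
      expect_gt(r, 0.8)
    }
  }

  ## a subject with zero amplitude on one network shows ~no time-course
  ## energy for that component
  amps <- matrix(1, 6, 3)
  amps[1L, 2L] <- 0
  co3 <- makeRsfmriCohort(nSubjectsPerGroup = c(3L, 3L), nNetworks = 3L,
                          nTimepoints = 100L, noiseSd = 0.2,
                          groupEffect = c(1, 1, 1),
                          subjectAmplitudes = amps, seed = 33)
  cs3 <- runGroupICA(co3$images, K = 4L, C = 4L, seed = 4)
  truth3 <- matrix(as.vector(co3$truth$maps[[2L]]), 1L)
  comp <- which.max(abs(rsnparc:::row_cor(truth3, componentMaps(cs3))))
  tcsd <- vapply(timecourses(cs3), function(tc) stats::sd(tc[, comp]),
                 numeric(1))
  ## the silent subject carries almost none of that component's energy
  expect_lt(tcsd[1L], 0.1 * mean(tcsd[-1L]))
  expect_lt(tcsd[1L], min(tcsd[-1L]))

  red <- pcaReduce(lapply(co3$images, flattenImage), C = 4L)
  expect_error(backReconstruct(matrix(0, 7, 4), red), "partition")
})

test_that("Z-scoring standardises rows and flags degenerate components", {
  z <- zscoreMaps(matrix(c(1, 2, 3), 1L))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  m <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 4, 6, 8))
  z2 <- zscoreMaps(m)
  expect_identical(attr(z2, "degenerate"), c(FALSE, TRUE, FALSE))
  expect_true(all(z2[2L, ] == 0))
  expect_equal(rowMeans(z2[c(1, 3), ]), c(0, 0), tolerance = 1e-12)
  ## scale invariance: doubling a row leaves its Z-scores unchanged
  expect_equal(z2[1L, ], zscoreMaps(2 * m)[1L, ], tolerance = 1e-12)
})
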