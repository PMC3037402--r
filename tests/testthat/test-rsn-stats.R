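null_grid <- function() gridSpec(c(10L, 10L, 10L), c(3, 3, 4), 3)

test_that("two-sample GLM t matches the closed-form least-squares oracle", {
  g <- null_grid(); mask <- array(TRUE, c(10, 10, 10))

  ## identical groups with a zero covariate give t = 0 everywhere
  set.seed(1)
  A <- matrix(rnorm(3 * 1000), 3)
  sm0 <- twoSampleTCov(A, A, covariate = rep(0, 6), g, mask)
  expect_lt(max(abs(statValues(sm0))), 1e-8)

  ## hand-computable 3+3 design against lm() at a single voxel
  yA <- c(1.2, 0.7, 1.9); yB <- c(2.4, 3.1, 2.2)
  cov <- c(0.3, 0.5, 0.1, 0.6, 0.2, 0.4)
  mA <- matrix(rep(yA, 1000), 3); mB <- matrix(rep(yB, 1000), 3)
  sm <- twoSampleTCov(mA, mB, cov, g, mask)
  fit <- stats::lm(c(yA, yB) ~ grp + cv,
                   data = data.frame(grp = c(0, 0, 0, 1, 1, 1), cv = cov))
  t_oracle <- summary(fit)$coefficients["grp", "t value"]
  expect_equal(statValues(sm)[1, 1, 1], t_oracle, tolerance = 1e-10)
  expect_equal(sm@df, 3)                       # nA + nB - 3

  expect_error(twoSampleTCov(mA, mB, c(0, 0, 0, 1, 1, 1), g, mask),
               "rank")
  expect_error(twoSampleTCov(mA[1, , drop = FALSE], mB, cov[-1], g, mask),
               "2 subjects")
})

test_that("null simulation is calibrated at the primary threshold", {
  g <- null_grid(); mask <- array(TRUE, c(10, 10, 10))
  set.seed(7)
  hits <- 0; total <- 0
  for (r in 1:20) {
    A <- matrix(rnorm(12 * 1000), 12)
    B <- matrix(rnorm(12 * 1000), 12)
    sm <- twoSampleTCov(A, B, rnorm(24), g, mask)
    tcrit <- stats::qt(1 - 0.001 / 2, sm@df)
    hits <- hits + sum(abs(statValues(sm)) > tcrit)
    total <- total + 1000
  }
  rate <- hits / total
  se <- sqrt(0.001 * 0.999 / total)
  expect_lt(rate, 0.001 + 4 * se + 1e-4)
  expect_gt(rate, 0.001 - 4 * se - 1e-4)
})

test_that("intersection mask requires suprathreshold evidence in every group", {
  g <- null_grid(); mask <- array(TRUE, c(10, 10, 10))
  set.seed(3)
  base <- matrix(rnorm(8 * 1000), 8)
  base[, 1:50] <- base[, 1:50] + 5          # shared activation
  osA <- oneSampleT(base, NULL, g, mask)
  osB <- oneSampleT(base + matrix(rnorm(8000, sd = 0.1), 8), NULL, g, mask)

  ## identical groups: mask equals the thresholded map
  mAA <- groupMask(list(osA, osA), 0.001)
  expect_identical(mAA, osA@pValues < 0.001)

  ## disjoint activations: empty intersection warns
  C1 <- matrix(rnorm(8 * 1000), 8); C1[, 1:20] <- C1[, 1:20] + 8
  C2 <- matrix(rnorm(8 * 1000), 8); C2[, 101:120] <- C2[, 101:120] + 8
  osC1 <- oneSampleT(C1, NULL, g, mask)
  osC2 <- oneSampleT(C2, NULL, g, mask)
  expect_warning(mEmpty <- groupMask(list(osC1, osC2), 1e-6), "empty")
  expect_false(any(mEmpty))

  ## planted shared network: mask covers >= 80% of its support
  ## (amplitude 1 under the generator's default noise sd of 0.5)
  set.seed(4)
  support <- 1:60
  mkgrp <- function(n) {
    m <- matrix(rnorm(n * 1000, sd = 0.5), n)
    m[, support] <- m[, support] + 1
    m
  }
  osG <- lapply(list(mkgrp(13), mkgrp(13)), oneSampleT,
                covariate = NULL, grid = g, mask = mask)
  gm <- groupMask(osG, 0.001)
  expect_gte(sum(which(gm) %in% support) / length(support), 0.8)
})

test_that("cluster-extent permutation correction finds planted clusters and honours k >= 5", {
  g <- null_grid(); mask <- array(TRUE, c(10, 10, 10))
  set.seed(5)
  ## a compact 20-voxel block effect (4 x 5 x 1 in x-fastest order)
  eff <- array(FALSE, c(10, 10, 10)); eff[3:6, 3:7, 5] <- TRUE
  effcols <- which(as.vector(eff))
  A <- matrix(rnorm(12 * 1000), 12)
  B <- matrix(rnorm(12 * 1000), 12)
  B[, effcols] <- B[, effcols] + 3
  sm <- clusterThreshold(A, B, rnorm(24), g, mask, nPerm = 300L, seed = 9)
  tab <- clusterTable(sm)
  sig <- tab[tab$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_gte(sig$extent, 15L)               # covers most of the 20 voxels
  lab <- sm@clusterLabels
  expect_gte(sum(lab[eff] == sig$label) / 20, 0.75)

  ## no suprathreshold voxels -> empty report
  sm0 <- clusterThreshold(A, A + matrix(rnorm(12000, sd = 0.01), 12),
                          rnorm(24), g, mask, nPerm = 200L, seed = 2)
  expect_equal(sum(clusterTable(sm0)$significant), 0L)

  ## a 4-voxel effect can be highly significant voxelwise but is
  ## excluded by the extent rule
  eff4 <- array(FALSE, c(10, 10, 10)); eff4[2:5, 2, 2] <- TRUE
  B4 <- matrix(rnorm(12 * 1000), 12)
  B4[, which(as.vector(eff4))] <- B4[, which(as.vector(eff4))] + 10
  sm4 <- clusterThreshold(A, B4, rnorm(24), g, mask, nPerm = 200L, seed = 3)
  tab4 <- clusterTable(sm4)
  four <- tab4[tab4$extent == 4L, ]
  expect_gte(nrow(four), 1L)
  expect_false(any(four$significant))

  expect_warning(
    clusterThreshold(A, B, rnorm(24), g, mask, nPerm = 50L, seed = 1),
    "100 permutations")
})

test_that("reported peak coordinates round-trip through the affine", {
  g <- gridSpec(c(10L, 10L, 10L), c(3, 3, 4), 3, origin = c(-12, -15, -20))
  mask <- array(TRUE, c(10, 10, 10))
  set.seed(6)
  eff <- array(FALSE, c(10, 10, 10)); eff[4:8, 4:6, 3:4] <- TRUE
  A <- matrix(rnorm(10 * 1000), 10)
  B <- matrix(rnorm(10 * 1000), 10)
  B[, which(as.vector(eff))] <- B[, which(as.vector(eff))] + 3
  sm <- clusterThreshold(A, B, NULL, g, mask, nPerm = 200L, seed = 4)
  tab <- clusterTable(sm)
  for (i in seq_len(nrow(tab))) {
    v <- worldToVoxel(g, c(tab$peak_x[i], tab$peak_y[i], tab$peak_z[i]))
    expect_identical(v, round(v))           # exact integer voxel index
    expect_true(all(v >= 1 & v <= 10))
  }
})

test_that("clinical correlations with small-volume correction behave", {
  g <- null_grid(); mask <- array(TRUE, c(10, 10, 10))
  set.seed(8)
  n <- 13
  blob <- array(0, c(10, 10, 10)); blob[5:7, 5:7, 5] <- 1
  amp <- rnorm(n, 1, 0.5)
  maps <- amp %o% as.vector(blob) + matrix(rnorm(n * 1000, sd = 0.1), n)
  peak <- voxelToWorld(g, c(6, 6, 5))

  ## score equal to the planted amplitude is recovered at the peak
  cc <- clinicalCorrelation(maps, amp, peak, g, mask, svcRadius = 10)
  expect_gt(abs(cc$r), 0.9)
  expect_true(cc$significant)

  ## radius 0: single voxel, no correction factor
  cc0 <- clinicalCorrelation(maps, amp, peak, g, mask, svcRadius = 0)
  expect_equal(cc0$nVoxels, 1L)
  expect_equal(cc0$p_svc, cc0$p)

  ## permuted scores: significance no more often than nominal
  hits <- 0
  for (r in 1:100) {
    cc_p <- clinicalCorrelation(maps, sample(amp), peak, g, mask,
                                svcRadius = 10)
    hits <- hits + cc_p$significant
  }
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lte(hits / 100, 0.05 + 2 * se)

  ## spearman option reproduces rank-based correlation at the peak voxel
  ccS <- clinicalCorrelation(maps, amp, peak, g, mask, svcRadius = 0,
                             method = "spearman")
  col <- 6 + (6 - 1) * 10 + (5 - 1) * 100   # x-fastest linear index of (6,6,5)
  expect_equal(ccS$r, stats::cor(amp, maps[, col], method = "spearman"),
               tolerance = 1e-9)

  expect_error(clinicalCorrelation(maps, rep(1, n), peak, g, mask), "constant")
  expect_error(clinicalCorrelation(maps[1:4, ], amp[1:4], peak, g, mask),
               "5 subjects")
})
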