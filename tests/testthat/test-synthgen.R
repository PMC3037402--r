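test_that("noiseless cohorts are exactly low-rank and deterministic", {
  co <- makeRsfmriCohort(nSubjectsPerGroup = c(1L, 1L), nNetworks = 2L,
                         nTimepoints = 64L, noiseSd = 0, seed = 7)
  mat <- flattenImage(co$images[[1L]])
  sv <- svd(mat, nu = 0, nv = 0)$d
  expect_lt(sv[3L] / sv[1L], 1e-10)   # rank <= number of networks
  expect_gt(sv[2L] / sv[1L], 1e-6)

  co2 <- makeRsfmriCohort(nSubjectsPerGroup = c(1L, 1L), nNetworks = 2L,
                          nTimepoints = 64L, noiseSd = 0, seed = 7)
  expect_identical(imgData(co$images[[2L]]), imgData(co2$images[[2L]]))
  expect_identical(co$truth$amplitudes, co2$truth$amplitudes)
})

test_that("multiplicative group effect raises variance on the target network", {
  co <- makeRsfmriCohort(nSubjectsPerGroup = c(13L, 13L), nNetworks = 3L,
                         nTimepoints = 100L, noiseSd = 0.3,
                         groupEffect = c(1.5, 1, 1), seed = 21)
  net1 <- co$truth$maps[[1L]] > 0.5
  varByGroup <- vapply(seq_along(co$images), function(s) {
    mat <- flattenImage(co$images[[s]], mask = net1)
    mean(apply(mat, 2L, stats::var))
  }, numeric(1))
  grp <- co$truth$group
  expect_gt(mean(varByGroup[grp == "B"]), mean(varByGroup[grp == "A"]))
  ## untouched network shows no comparable difference
  net2 <- co$truth$maps[[2L]] > 0.5
  v2 <- vapply(seq_along(co$images), function(s) {
    mean(apply(flattenImage(co$images[[s]], mask = net2), 2L, stats::var))
  }, numeric(1))
  expect_lt(abs(mean(v2[grp == "B"]) - mean(v2[grp == "A"])),
            mean(varByGroup[grp == "B"]) - mean(varByGroup[grp == "A"]))
})

test_that("planted maps are spatially independent and time courses band-limited", {
  co <- makeRsfmriCohort(nSubjectsPerGroup = c(1L, 1L), nNetworks = 6L,
                         nTimepoints = 100L, noiseSd = 0, seed = 3)
  maps <- t(vapply(co$truth$maps, as.vector, numeric(prod(gridDims(co$grid)))))
  R <- abs(rsnparc:::row_cor(maps, maps))
  diag(R) <- 0
  expect_lt(max(R), 0.2)
  ## all time-course power below 0.1 Hz
  for (k in seq_len(6L)) {
    frac <- spectralPowerFraction(co$truth$timecourses[[1L]][, k], TR = 3,
                                  lowband = c(0.001, 0.1))
    expect_gt(frac, 0.99)
  }
  ## priors are probabilities with per-voxel sums <= 1
  pr <- co$truth$priors
  expect_true(all(pr$gm >= 0 & pr$wm >= 0 & pr$csf >= 0))
  expect_lte(max(pr$gm + pr$wm + pr$csf), 1 + 1e-9)
})

test_that("generator rejects invalid arguments and infeasible geometry", {
  expect_error(makeRsfmriCohort(nNetworks = 1L), "nNetworks")
  expect_error(makeRsfmriCohort(nSubjectsPerGroup = c(0L, 2L)), "positive")
  expect_error(
    makeRsfmriCohort(grid = gridSpec(c(4L, 4L, 3L), c(3, 3, 4), 3),
                     nNetworks = 10L, nTimepoints = 64L),
    "infeasible")
  expect_error(makeProfileCohort(separation = -1), "nonnegative")
})

test_that("profile cohorts plant recoverable cluster structure", {
  pc <- makeProfileCohort(plantedK = c(2L, 4L), separation = 8, seed = 5)
  expect_length(pc$profiles, 2L)
  cnt <- profileCounts(pc$profiles[[2L]])
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_identical(sort(unique(seedInfo(pc$profiles[[2L]])$trueLabel)), 1:4)

  ## at high separation with disjoint support, k-means at the true k
  ## recovers the planted labels exactly (up to label permutation)
  pc2 <- makeProfileCohort(plantedK = 3L, separation = 30, baseRate = 0.2,
                           seed = 11)
  pm <- pc2$profiles[[1L]]
  res <- chooseK(pm, kRange = 3L, seed = 2)
  agree <- label_agreement(seedInfo(pm)$trueLabel, clusterAssignments(res))
  expect_equal(agree, 1)

  ## separation 0: archetypes identical, rates all equal
  pc0 <- makeProfileCohort(plantedK = 2L, separation = 0, seed = 9)
  expect_true(all(pc0$truth$rates[[1L]] == pc0$truth$rates[[1L]][1L]))
})

test_that("toy tracker is deterministic in the zero-noise limit and scales with samples", {
  dims <- c(10L, 6L, 4L)
  g <- gridSpec(dims, c(2, 2, 2), 3)
  field <- array(0, c(dims, 3L))
  field[, , , 1L] <- 1                      # straight +x field
  seeds <- new("SeedSet", roiName = "r", subjectId = "s", hemisphere = "L",
               coords = matrix(c(2L, 3L, 2L), 1L), grid = g)
  counts <- toyTracker(field, seeds, nSamples = 25L, step = 2, angleSd = 0,
                       seed = 1)[[1L]]
  ## every streamline traces the same straight voxel path
  expect_true(all(counts[2:10, 3L, 2L] == 25L))
  expect_equal(sum(counts), 9L * 25L)

  ## doubling samples approximately doubles stochastic counts
  c1 <- toyTracker(field, seeds, nSamples = 200L, step = 2, angleSd = 25,
                   seed = 3)[[1L]]
  c2 <- toyTracker(field, seeds, nSamples = 400L, step = 2, angleSd = 25,
                   seed = 4)[[1L]]
  vox <- which(c1 >= 50)                    # well-visited voxels only
  ratio <- sum(c2[vox]) / sum(c1[vox])
  se <- sqrt(1 / sum(c1[vox]) + 1 / sum(c2[vox]))  # log-scale SE
  expect_lt(abs(log(ratio / 2)), 3 * se + 0.05)

  ## a seed valid on a larger grid but outside this orientation field
  gBig <- gridSpec(c(12L, 8L, 4L), c(2, 2, 2), 3)
  expect_error(
    toyTracker(field, new("SeedSet", roiName = "r", subjectId = "s",
                          hemisphere = "L",
                          coords = matrix(c(11L, 7L, 4L), 1L), grid = gBig),
               seed = 1),
    "outside")
})

test_that("count and label downsampling conserve mass and take majorities", {
  vol <- array(1, c(4L, 4L, 2L))
  dn <- downsampleCounts(vol, 2L)
  expect_equal(dim(dn), c(2L, 2L, 1L))
  expect_equal(sum(dn), sum(vol))
  expect_true(all(dn == 8))
  atlas <- array(1L, c(4L, 4L, 2L))
  atlas[1:3, 1:2, ] <- 2L
  coarse <- downsampleLabels(atlas, 2L)
  expect_equal(coarse[1L, 1L, 1L], 2L)      # 2 is the block majority
  expect_equal(coarse[2L, 2L, 1L], 1L)
})
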