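test_that("seed extraction finds the analytic GM/WM slab boundary exactly", {
  dims <- c(12L, 20L, 6L)
  g <- gridSpec(dims, c(2, 2, 2), 3)
  sv <- slab_volumes(dims, y0 = 10L)
  roi <- array(0, dims); roi[4:9, , 2:5] <- 1

  seeds <- extractSeeds(sv$gm, sv$csf, roi, g, roiName = "slab")
  got <- seedCoords(seeds)
  ## hand-derived: the 2D Sobel of a unit step in y is nonzero exactly on
  ## the two rows flanking the interface (y = 10 and y = 11, 1-based)
  expected <- as.matrix(expand.grid(x = 4:9, y = 10:11, z = 2:5))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(got), key(expected))

  ## uniform GM: no boundary anywhere -> empty-roi error
  expect_error(
    extractSeeds(array(1, dims), sv$csf, roi, g),
    "empty ROI")

  ## a CSF-filled notch removes exactly the notch-adjacent seeds
  csf2 <- sv$csf
  csf2[6L, 9:12, 3L] <- 1      # notch crossing the interface
  seeds2 <- extractSeeds(sv$gm, csf2, roi, g)
  removed <- setdiff(key(got), key(seedCoords(seeds2)))
  ## exactly the boundary voxels inside or 6-adjacent to the notch disappear
  is_adj_notch <- function(x, y, z) {
    any(vapply(9:12, function(ny) {
      sum(abs(c(x, y, z) - c(6L, ny, 3L))) <= 1L
    }, logical(1)))
  }
  exp_removed <- expected[mapply(is_adj_notch, expected[, 1], expected[, 2],
                                 expected[, 3]), , drop = FALSE]
  expect_identical(sort(removed), key(exp_removed))
})

test_that("profile aggregation sums counts within regions and drops exclusions", {
  dims <- c(6L, 6L, 2L)
  atlas <- array(0L, dims)
  atlas[1:3, , ] <- 1L
  atlas[4:6, 1:3, ] <- 2L
  atlas[4:6, 4:6, ] <- 3L
  rinfo <- data.frame(id = 1:3, name = c("regA", "regB", "regC"),
                      hemisphere = c("L", "L", "R"),
                      stringsAsFactors = FALSE)

  v1 <- array(0, dims); v1[2, 2, 1] <- 7; v1[3, 5, 2] <- 2   # all in regA
  v2 <- array(0, dims); v2[5, 2, 1] <- 4; v2[5, 5, 1] <- 6   # regB + regC

  pm <- aggregateProfiles(list(v1, v2), atlas, rinfo)
  expect_equal(unname(profileCounts(pm)),
               rbind(c(9, 0, 0), c(0, 4, 6)))

  ## excluded (seed-containing) region column is absent
  pm2 <- aggregateProfiles(list(v1, v2), atlas, rinfo,
                           excludeRegions = "regA")
  expect_identical(regionNames(pm2), c("regB", "regC"))

  ## contralateral exclusion drops the right-hemisphere column
  pm3 <- aggregateProfiles(list(v1, v2), atlas, rinfo,
                           seedHemisphere = "L")
  expect_identical(regionNames(pm3), c("regA", "regB"))

  expect_error(
    aggregateProfiles(list(v1), atlas, rinfo, excludeRegions = "nope"),
    "unknown region")

  ## downsampling aggregates at the coarse resolution, conserving counts
  pm4 <- aggregateProfiles(list(v1, v2), atlas, rinfo, downsample = 2L)
  expect_equal(sum(profileCounts(pm4)), sum(v1) + sum(v2))
})

test_that("silhouette equals the brute-force oracle and the reference implementation", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * 6), n) + 2 * matrix(rnorm(k * 6), k)[
      sample(k, n, TRUE), ]
    lab <- stats::kmeans(m, k)$cluster
    got <- silhouetteMean(m, lab, normalize = FALSE)
    expect_equal(got, silhouette_bruteforce(m, lab), tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE)) {
      ref <- mean(cluster::silhouette(lab, stats::dist(m))[, "sil_width"])
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }

  ## two well-separated clouds, correct labels: mean > 0.9
  m2 <- rbind(matrix(rnorm(40, sd = 0.05), 20),
              matrix(rnorm(40, sd = 0.05) + 5, 20))
  expect_gt(silhouetteMean(m2, rep(1:2, each = 20), normalize = FALSE), 0.9)

  ## random labels on one cloud: mean near 0
  set.seed(21)
  m3 <- matrix(rnorm(200), 50)
  sil_rand <- replicate(20, silhouetteMean(m3, sample(1:2, 50, TRUE),
                                           normalize = FALSE))
  expect_lt(abs(mean(sil_rand)), 0.1)

  expect_error(silhouetteMean(m3, rep(1, 50), normalize = FALSE), "2 clusters")
  expect_error(silhouetteMean(m3[1:2, ], 1:2, normalize = FALSE),
               "singleton")

  ## similarity-ratio variant: larger for good clusterings too
  good <- silhouetteMean(m2, rep(1:2, each = 20), normalize = FALSE,
                         variant = "ratio")
  bad <- silhouetteMean(m2, rep(1:2, 20), normalize = FALSE,
                        variant = "ratio")
  expect_gt(good, bad)
})

test_that("chooseK selects the planted number of clusters and flags null structure", {
  pc <- makeProfileCohort(plantedK = 4L, separation = 8, seed = 30)
  res <- chooseK(pc$profiles[[1L]], seed = 1)
  expect_equal(chosenK(res), 4L)
  expect_false(res@noStructure)
  expect_equal(names(which.max(silhouetteCurve(res))), "4")
  expect_true(all(clusterAssignments(res) %in% 1:4))
  ## per-subject seed counts sum to the seeds per subject
  expect_true(all(rowSums(seedCounts(res)) == 10))

  ## invariance to row permutation and global count scaling
  pm <- pc$profiles[[1L]]
  perm <- sample(nrow(profileCounts(pm)))
  pmP <- profileMatrix(profileCounts(pm)[perm, ],
                       seedInfo = seedInfo(pm)[perm, ])
  expect_equal(chosenK(chooseK(pmP, seed = 1)), 4L)
  pmS <- profileMatrix(profileCounts(pm) * 3, seedInfo = seedInfo(pm))
  resS <- chooseK(pmS, seed = 1)
  expect_identical(clusterAssignments(resS), clusterAssignments(res))
  expect_identical(chosenK(resS), chosenK(res))

  ## separation 0: no structure, chosen k undefined
  pc0 <- makeProfileCohort(plantedK = 3L, separation = 0, seed = 31)
  res0 <- chooseK(pc0$profiles[[1L]], seed = 2)
  expect_true(res0@noStructure)
  expect_true(is.na(chosenK(res0)))

  ## degenerate all-identical profiles flagged directly
  resD <- chooseK(profileMatrix(matrix(1, 30, 8)), seed = 3)
  expect_true(resD@noStructure)
})

test_that("centroid comparison classifies region differences and mirrors", {
  k <- 2L; p <- 6L
  cen <- rbind(c(0.5, 0.3, 0, 0.2, 0, 0),
               c(0, 0, 0.6, 0, 0.4, 0))
  colnames(cen) <- sprintf("r%d", 1:p)
  mk <- function(cen, counts) {
    new("ParcellationResult", labels = rep(seq_len(nrow(cen)), 5),
        centroids = cen, silhouetteCurve = c(`2` = 0.8),
        chosenK = nrow(cen), noStructure = FALSE,
        seedCounts = counts, group = "g")
  }
  cnt <- matrix(5, 4, k)
  resA <- mk(cen, cnt)

  ## identical parcellations: everything unchanged
  same <- compareCentroids(resA, resA)
  expect_true(all(same$report$status == "unchanged"))
  expect_identical(same$matches$clusterA, same$matches$clusterB)

  ## amplitude doubled on one region: increased; new peak: B-only
  cenB <- cen
  cenB[1L, 1L] <- 1.0            # doubled
  cenB[2L, 6L] <- 0.3            # new peak
  resB <- mk(cenB, cnt)
  cmp <- compareCentroids(resA, resB)
  rep1 <- cmp$report
  expect_equal(rep1$status[rep1$region == "r1"], "increased")
  expect_equal(rep1$status[rep1$region == "r6"], "present-in-B-only")

  ## symmetry: swapping the arguments mirrors the report
  cmp2 <- compareCentroids(resB, resA)
  rep2 <- cmp2$report
  expect_equal(rep2$status[rep2$region == "r1"], "decreased")
  expect_equal(rep2$status[rep2$region == "r6"], "present-in-A-only")

  ## unequal k: surplus clusters are group-unique
  cenC <- rbind(cenB, c(0.2, 0, 0, 0.7, 0, 0.1))
  resC <- mk(cenC, matrix(5, 4, 3))
  cmp3 <- compareCentroids(resA, resC)
  expect_length(cmp3$unmatchedB, 1L)
  expect_length(cmp3$unmatchedA, 0L)
})

test_that("a 2-vs-4 planted group design reproduces a group difference in chosen k", {
  pc <- makeProfileCohort(plantedK = c(2L, 4L), separation = 8, seed = 40)
  resA <- chooseK(pc$profiles[[1L]], seed = 1, group = "controls")
  resB <- chooseK(pc$profiles[[2L]], seed = 2, group = "patients")
  expect_equal(chosenK(resA), 2L)
  expect_equal(chosenK(resB), 4L)
})

test_that("seed-count statistics match hand-computed oracles", {
  mk <- function(counts) {
    k <- ncol(counts)
    cen <- matrix(seq_len(2 * k), k, 2)
    colnames(cen) <- c("r1", "r2")
    new("ParcellationResult", labels = rep(seq_len(k), 3),
        centroids = cen, silhouetteCurve = c(`2` = 0.5),
        chosenK = k, noStructure = FALSE, seedCounts = counts, group = "g")
  }
  matches <- data.frame(clusterA = 1:2, clusterB = 1:2)

  cntA <- cbind(c(4, 6, 5, 7), c(10, 12, 9, 11))
  resA <- mk(cntA)

  ## identical groups: t = 0
  st0 <- seedCountStats(resA, mk(cntA), matches = matches)
  expect_true(all(st0$tests$t == 0 | abs(st0$tests$t) < 1e-12))

  ## a constant shift in group B sets the t sign
  stUp <- seedCountStats(resA, mk(cntA + 3), matches = matches)
  expect_true(all(stUp$tests$t > 0))
  stDn <- seedCountStats(resA, mk(cntA - 3), matches = matches)
  expect_true(all(stDn$tests$t < 0))
  ## Welch t agrees with t.test directly
  tt <- stats::t.test(cntA[, 1] + 3, cntA[, 1])
  expect_equal(stUp$tests$t[1], unname(tt$statistic), tolerance = 1e-12)

  ## 3-subject Spearman against the rank-formula oracle (no ties)
  cntB3 <- cbind(c(2, 9, 5), c(1, 2, 3))
  resB3 <- mk(cntB3)
  scores <- data.frame(prnfl = c(55, 40, 70))
  st <- seedCountStats(mk(cbind(c(1, 2, 3), c(3, 2, 1))), resB3,
                       scoresB = scores, matches = matches)
  got <- st$correlations
  d <- rank(cntB3[, 1]) - rank(scores$prnfl)
  rho_oracle <- 1 - 6 * sum(d^2) / (3 * (3^2 - 1))
  expect_equal(got$rho[got$cluster == 1 & got$group == "B"], rho_oracle,
               tolerance = 1e-12)
})
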