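test_that("TPM normalisation matches hand computation and sums to 1e6", {
  tpm <- computeTpm(cbind(s1 = c(10, 90)), geneLengths = c(1000, 1000))
  expect_equal(unname(tpm[, 1]), c(1e5, 9e5))
  tpm2 <- computeTpm(cbind(s1 = c(10, 10)), geneLengths = c(1000, 2000))
  expect_equal(unname(tpm2[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(3)
  m <- matrix(rpois(50, 40), 10, 5)
  t3 <- computeTpm(m, geneLengths = sample(500:2000, 10))
  expect_equal(unname(colSums(t3)), rep(1e6, 5), tolerance = 1e-6)
  expect_error(computeTpm(cbind(c(0, 0)), geneLengths = c(1, 1)),
               "zero total")
})

test_that("DEG calls apply the FC and expression thresholds symmetrically", {
  wt <- c(a = 4, b = 0.5, c = 8, d = 100)
  ko <- c(a = 8, b = 1.0, c = 4, d = 101)
  res <- callDegs(ko, wt)
  expect_identical(upGenes(res), "a")     # FC ~2, expressed
  expect_identical(downGenes(res), "c")   # symmetric
  # b: FC 2 but log2(max) = 0 <= 1 -> expression floor blocks the call
  expect_false("b" %in% c(upGenes(res), downGenes(res)))
  # antisymmetry: swapping the conditions swaps the sets exactly
  swapped <- callDegs(wt, ko)
  expect_identical(upGenes(swapped), downGenes(res))
  expect_identical(downGenes(swapped), upGenes(res))
})

test_that("sign-pattern clustering recovers forced patterns", {
  expr <- rbind(
    down = 2^c(5, 4, 3, 2, 1),
    flat = 2^c(3, 3, 3, 3, 3),
    up = 2^c(1, 2, 3, 4, 5))
  pcs <- clusterProfiles(expr, nTop = 8, pseudocount = 0)
  expect_identical(clusterMembers(pcs, "----"), "down")
  expect_identical(clusterMembers(pcs, "0000"), "flat")
  expect_identical(clusterMembers(pcs, "++++"), "up")
  expect_equal(coveredFraction(pcs), 1)
  expect_warning(clusterMembers(pcs, "+-+-"), "no cluster")
})

test_that("clustering partitions the gene universe deterministically", {
  sim <- simulateExpressionTimecourse(nGenes = 300, seed = 4)
  se <- computeTpm(sim$se)
  pcs <- clusterProfiles(se, nTop = 1000)  # retain everything
  members <- unlist(pcs@clusters, use.names = FALSE)
  expect_equal(sort(members), sort(rownames(se)))
  expect_equal(coveredFraction(pcs), 1)
  # permuting gene order changes nothing about the memberships
  tpm <- SummarizedExperiment::assay(se, "tpm")
  cd <- SummarizedExperiment::colData(se)
  wtMeans <- vapply(sort(unique(cd$timepoint_h)), function(tp)
    rowMeans(tpm[, cd$condition == "WT" & cd$timepoint_h == tp,
                 drop = FALSE]), numeric(nrow(tpm)))
  perm <- sample(nrow(wtMeans))
  p1 <- clusterProfiles(wtMeans, nTop = 1000)
  p2 <- clusterProfiles(wtMeans[perm, ], nTop = 1000)
  expect_identical(lapply(p1@clusters, sort), lapply(p2@clusters, sort))
})

test_that("planted monotone-down genes land in the all-down cluster", {
  sim <- simulateExpressionTimecourse(nGenes = 1000, noiseSigma = 0.2,
                                      seed = 5)
  se <- computeTpm(sim$se)
  pcs <- clusterProfiles(se)
  down <- degradationCluster(pcs)
  planted <- sim$truth$gene[sim$truth$cluster == "down"]
  recovered <- mean(planted %in% down)
  expect_gte(recovered, 0.95)
  jaccard <- length(intersect(down, planted)) /
    length(union(down, planted))
  expect_gte(jaccard, 0.9)
})

test_that("planted KO-stabilised genes surface in the late up sets", {
  sim <- simulateExpressionTimecourse(nGenes = 1000, nStabilized = 100,
                                      seed = 6)
  se <- computeTpm(sim$se)
  degs <- degsByTimepoint(se)
  stab <- sim$truth$gene[sim$truth$stabilized]
  expect_gte(mean(stab %in% upGenes(degs[["24"]])), 0.9)
  expect_gte(mean(stab %in% upGenes(degs[["48"]])), 0.95)
  # and they do not appear as upregulated before induction
  expect_lte(length(upGenes(degs[["0"]])), 0.02 * 1000)
})

test_that("PCA projection behaves on planted structure", {
  set.seed(8)
  grad <- seq(0, 1, length.out = 20)
  mat <- outer(rnorm(100), grad) + matrix(rnorm(2000, 0, 0.01), 100, 20)
  rownames(mat) <- paste0("g", 1:100)
  colnames(mat) <- paste0("s", 1:20)
  p <- pcaProjection(mat)
  ord <- order(p$coords$PC1)
  expect_true(identical(ord, 1:20) || identical(ord, 20:1))
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  # identical samples project to identical coordinates
  two <- cbind(a = mat[, 1], b = mat[, 1], c = mat[, 5])
  p2 <- pcaProjection(two)
  expect_equal(p2$coords$PC1[1], p2$coords$PC1[2], tolerance = 1e-9)
  expect_error(pcaProjection(matrix(1, 5, 3)), "degenerate")
})

test_that("ratio reporting rounds to one decimal", {
  expect_equal(summarizeRatio(1236, 4161), 29.7)
  expect_equal(summarizeRatio(12667, 13428), 94.3)
  expect_equal(summarizeRatio(0, 10), 0)
  expect_error(summarizeRatio(1, 0), "> 0")
})
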