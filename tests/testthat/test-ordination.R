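test_that("PCoA round-trips explicit coordinate configurations", {
  withr::local_seed(61)
  X <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(sprintf("u%02d", 1:15), NULL))
  d <- as.matrix(dist(X))
  pc <- pcoa(d)
  expect_lt(procrustes_error(X, pc$coordinates[, 1:4]), 1e-8)
  # eigenvalues descending; proportions over positive eigenvalues sum to 1
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_equal(sum(pc$prop_explained), 1)
  # agreement with classical scaling (cmdscale) up to sign
  cs <- cmdscale(d, k = 4)
  expect_lt(procrustes_error(cs, pc$coordinates[, 1:4]), 1e-8)
  # 3 collinear points: one positive axis carries all inertia
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  pc3 <- pcoa(d3)
  expect_equal(pc3$prop_explained[1], 1)
  # equilateral triple: two equal positive eigenvalues
  de <- matrix(1, 3, 3, dimnames = dimnames(d3)); diag(de) <- 0
  pce <- pcoa(de)
  expect_equal(pce$eigenvalues[1], pce$eigenvalues[2], tolerance = 1e-10)
  expect_error(pcoa(d[1:2, 1:2]), "at least 3")
  expect_error(pcoa(matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3)), "symmetric")
})

test_that("negative eigenvalues are reported and Lingoes correction removes them", {
  # a non-Euclidean dissimilarity: sqrt of squared distances plus distortion
  withr::local_seed(62)
  d <- random_distance_matrix(10, seed = 62)
  d[1, 2] <- d[2, 1] <- d[1, 2] * 3     # break the triangle inequality
  pc <- pcoa(d)
  expect_gt(pc$negative$n, 0)
  pcl <- pcoa(d, correction = "lingoes")
  expect_equal(pcl$negative$n, 0)
})

test_that("marginal DistLM pseudo-F matches the classical univariate F oracle", {
  # on Euclidean distances of raw data, tr-based pseudo-F equals the
  # univariate regression F statistics summed over response columns
  withr::local_seed(63)
  n <- 20
  Y <- matrix(rnorm(n * 3), n, 3)
  x <- rnorm(n)
  d <- as.matrix(dist(Y))
  rownames(d) <- colnames(d) <- sprintf("u%02d", 1:n)
  out <- distlm_marginal(d, data.frame(x = x), n_perm = 99, seed = 1)
  Yc <- scale(Y, scale = FALSE)
  ssr <- sum(vapply(1:3, function(j) {
    f <- lm(Yc[, j] ~ x); sum(fitted(f)^2) - n * mean(Yc[, j])^2
  }, numeric(1)))
  sse <- sum(vapply(1:3, function(j) sum(resid(lm(Yc[, j] ~ x))^2),
                    numeric(1)))
  f_oracle <- ssr / (sse / (n - 2))
  expect_equal(out$pseudo_F, f_oracle, tolerance = 1e-8)
  expect_equal(out$prop_explained, ssr / (ssr + sse), tolerance = 1e-8)
  expect_error(distlm_marginal(d, data.frame(k = rep(1, n))), "constant")
})

test_that("DistLM marginal test has correct size and detects structure", {
  # the first PCoA axis is the best single-axis predictor of its own distances
  d <- withr::with_seed(64, {
    pts <- matrix(rnorm(25 * 4), 25, 4)
    dd <- as.matrix(dist(pts))
    dimnames(dd) <- list(sprintf("u%02d", 1:25), sprintf("u%02d", 1:25))
    dd
  })
  pc <- pcoa(d)
  preds <- as.data.frame(pc$coordinates[, 1:3])
  out <- distlm_marginal(d, preds, n_perm = 199, seed = 2)
  expect_equal(which.max(out$pseudo_F), 1L)
  expect_true(all(diff(out$pseudo_F) < 0))
  # null predictors on structureless distances: rejection rate near alpha
  hits <- vapply(seq_len(25), function(r) {
    dr <- random_distance_matrix(16, seed = 800 + r)
    x <- withr::with_seed(900 + r, rnorm(16))
    distlm_marginal(dr, data.frame(x = x), n_perm = 99, seed = r)$p <= 0.05
  }, logical(1))
  expect_lte(sum(hits), 5)
})

test_that("forward selection orders planted effects and skips collinear ones", {
  withr::local_seed(65)
  n <- 30
  a <- rnorm(n); bx <- rnorm(n)
  Y <- cbind(3 * a + rnorm(n, 0, 0.3), 1.5 * bx + rnorm(n, 0, 0.3),
             rnorm(n, 0, 0.3))
  d <- as.matrix(dist(Y)); rownames(d) <- colnames(d) <- sprintf("u%02d", 1:n)
  preds <- data.frame(a = a, a_dup = a, b = bx, noise = rnorm(n))
  sel <- distlm_forward(d, preds, n_perm = 199, seed = 3)
  picked <- sel$predictor[sel$selected %in% TRUE]
  expect_identical(picked[1:2], c("a", "b"))
  expect_identical(sel$flag[sel$predictor == "a_dup"], "collinear")
  expect_false("noise" %in% picked)
  expect_true(all(diff(na.omit(sel$cumulative_prop)) > -1e-12))
  # pure noise predictors: usually nothing selected at alpha = 0.05
  spurious <- vapply(seq_len(12), function(r) {
    dr <- random_distance_matrix(16, seed = 950 + r)
    pr <- withr::with_seed(990 + r, data.frame(x = rnorm(16), y = rnorm(16)))
    sum(distlm_forward(dr, pr, n_perm = 99, seed = r)$selected)
  }, numeric(1))
  expect_lte(mean(spurious > 0), 0.25)
})

test_that("Storey q-values match the hand step-up example and are monotone", {
  # pi0 forced to 1 (m < 20 fallback), p = (.01,.02,.03,.04) -> all q = .04
  expect_warning(q4 <- storey_qvalues(c(0.01, 0.02, 0.03, 0.04)), "pi0")
  expect_equal(q4, rep(0.04, 4))
  expect_warning(q1 <- storey_qvalues(rep(1, 5)))
  expect_equal(q1, rep(1, 5))
  # uniform null p: pi0 ~ 1 and q ~ BH
  withr::local_seed(66)
  p <- runif(1000)
  q <- storey_qvalues(p)
  bh <- p.adjust(p, "BH")
  expect_lt(max(abs(q - bh)), 0.25)
  expect_gt(cor(q, bh), 0.99)
  # monotone nondecreasing in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1 + 1e-12))
  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
})

test_that("RDA with forward selection finds a planted habitat-tracking variable", {
  sim <- simulate_dataset(sim_params(n_aflp = 200, n_msap = 10, seed = 67))
  rr <- rda_forward(sim$aflp, sim$soil, n_perm = 199, seed = 4)
  expect_lt(rr$global$p, 0.05)
  expect_gt(rr$global$adj_r_squared, 0)
  sel <- rr$selection$predictor[rr$selection$selected %in% TRUE]
  expect_gt(length(sel), 0)
  # pure-noise soil on structureless markers: global test not significant
  b0 <- null_band_matrix(n = 60, n_loci = 150, n_groups = 12, seed = 68)
  soil0 <- withr::with_seed(69, tibble::tibble(
    site = sort(unique(b0$samples$site)),
    v1 = rnorm(12), v2 = rnorm(12), v3 = rnorm(12), v4 = rnorm(12)))
  rr0 <- rda_forward(b0, soil0, n_perm = 199, seed = 5)
  expect_gt(rr0$global$p, 0.05)
  expect_lt(abs(rr0$global$adj_r_squared), 0.08)
})

test_that("UPGMA agglomerates by average linkage with locus bootstrap support", {
  # 3 taxa: d(A,B) = 1, d(A,C) = d(B,C) = 4 -> ((A,B),C), heights 0.5 and 2
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d, n_boot = 0)
  expect_s3_class(tr, "phylo")
  # A and B join first; root-to-tip height 2, A/B cherry at height 0.5
  cherry <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "B")))
  expect_setequal(cherry$tip.label, c("A", "B"))
  heights <- ape::node.depth.edgelength(tr)
  expect_equal(max(heights), 2)
  expect_equal(unname(heights[1:3]), c(2, 2, 2))  # ultrametric
  edge_to_A <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(edge_to_A, 0.5)
  # ultrametric input from clustered binary data: full bootstrap support
  v <- rbind(a1 = rep(0L, 40), a2 = rep(0L, 40),
             b1 = rep(1L, 40), b2 = rep(1L, 40),
             c1 = c(rep(1L, 20), rep(0L, 20)))
  colnames(v) <- sprintf("L%02d", 1:40)
  b <- band_matrix(v, habitat = rep("H", 5), site = rep("s", 5))
  db <- sqrt(squared_distance_matrix(b))
  trb <- upgma(db, b = b, n_boot = 100, seed = 6)
  expect_true(all(as.numeric(trb$node.label) >= 0))
  expect_true(any(as.numeric(trb$node.label) == 100))
  # two identical individuals join at height 0
  expect_equal(min(db["a1", "a2"]), 0)
  expect_error(upgma(d[1:2, 1:2]), "at least 3")
})
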