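test_that("squared distances count mismatches and rescale for missingness", {
  v <- matrix(c(0L, 0L, 0L,
                1L, 1L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("L1", "L2", "L3")))
  b <- band_matrix(v, c("H1", "H1"), c("s1", "s1"))
  expect_equal(squared_distance_matrix(b)["a", "b"], 3)
  # identical profiles -> 0
  v2 <- rbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L))
  colnames(v2) <- c("L1", "L2", "L3")
  b2 <- band_matrix(v2, c("H1", "H1"), c("s1", "s1"))
  expect_equal(squared_distance_matrix(b2)["a", "b"], 0)
  # 4 loci, 2 mutually observed, 1 mismatch -> 4 * (1/2) = 2
  v3 <- rbind(a = c(1L, 0L, NA, NA), b = c(1L, 1L, 1L, NA))
  colnames(v3) <- paste0("L", 1:4)
  b3 <- band_matrix(v3, c("H1", "H1"), c("s1", "s1"))
  expect_equal(squared_distance_matrix(b3)["a", "b"], 2)
  # no shared loci is an error naming the pair
  v4 <- rbind(a = c(1L, NA), b = c(NA, 1L))
  colnames(v4) <- c("L1", "L2")
  b4 <- band_matrix(v4, c("H1", "H1"), c("s1", "s1"))
  expect_error(squared_distance_matrix(b4), "share no observed loci")
})

test_that("one-level AMOVA matches the hand-computed toy exactly", {
  # two groups of 2: within d2 = 0, across d2 = 2
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  res <- amova(d, c("g1", "g1", "g2", "g2"), n_perm = 0)
  expect_equal(res$table$SS, c(2, 0, 2))
  expect_equal(res$table$df, c(1, 2, 3))
  expect_equal(res$table$sigma2[1], 1)
  expect_equal(res$phi$value, 1)
  # all individuals identical -> PhiPT reported 0 with the degenerate flag
  d0 <- matrix(0, 4, 4, dimnames = dimnames(d))
  res0 <- amova(d0, c("g1", "g1", "g2", "g2"), n_perm = 19)
  expect_equal(res0$phi$value, 0)
  expect_true(res0$degenerate)
})

test_that("SS and df are additive and results are order-invariant", {
  b <- bn_band_matrix(n_loci = 80, seed = 3)
  d <- squared_distance_matrix(b)
  g <- b$samples$habitat; s <- b$samples$site
  res <- amova(d, g, subgroups = s, n_perm = 0)
  expect_equal(sum(res$table$SS[1:3]), res$table$SS[4], tolerance = 1e-10)
  expect_equal(sum(res$table$df[1:3]), nrow(d) - 1)
  # permuting samples (with their labels) and loci changes nothing
  perm <- withr::with_seed(4, sample(nrow(d)))
  lperm <- withr::with_seed(5, sample(n_loci(b)))
  d_p <- squared_distance_matrix(b[perm, lperm])
  res_p <- amova(d_p, g[perm], subgroups = s[perm], n_perm = 0)
  expect_equal(res_p$phi$value, res$phi$value, tolerance = 1e-12)
  expect_equal(res_p$table$SS, res$table$SS, tolerance = 1e-10)
})

test_that("variance components equal a direct nested ANOVA on balanced designs", {
  # oracle: per-locus univariate nested ANOVA mean squares, summed over loci,
  # converted with the balanced-design coefficients
  b <- bn_band_matrix(n_habitats = 3, sites_per_habitat = 2,
                      individuals_per_site = 5, n_loci = 40, seed = 7)
  X <- b$values
  g <- factor(b$samples$habitat); s <- factor(b$samples$site)
  n_i <- 5; n_sites_per_g <- 2
  ms <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::aov(X[, j] ~ g / s)
    suppressWarnings(stats::anova(fit)[["Mean Sq"]])
  }, numeric(3))
  ms_sum <- rowSums(ms)
  sigma_c <- ms_sum[3]
  sigma_b <- (ms_sum[2] - sigma_c) / n_i
  sigma_a <- (ms_sum[1] - ms_sum[2]) / (n_i * n_sites_per_g)
  res <- amova(squared_distance_matrix(b), g, subgroups = s, n_perm = 0)
  expect_equal(res$table$sigma2[1:3], c(sigma_a, sigma_b, sigma_c),
               tolerance = 1e-10)
  # one-level agreement too
  ms1 <- vapply(seq_len(ncol(X)), function(j) {
    suppressWarnings(stats::anova(stats::aov(X[, j] ~ g))[["Mean Sq"]])
  }, numeric(2))
  s1 <- rowSums(ms1)
  res1 <- amova(squared_distance_matrix(b), g, n_perm = 0)
  expect_equal(res1$table$sigma2[2], s1[2], tolerance = 1e-10)
  expect_equal(res1$table$sigma2[1], (s1[1] - s1[2]) / (n_i * n_sites_per_g),
               tolerance = 1e-10)
})

test_that("two-level AMOVA recovers the planted intraclass correlations", {
  b <- bn_band_matrix(n_habitats = 4, sites_per_habitat = 3,
                      individuals_per_site = 7, n_loci = 2000,
                      theta_habitat = 0.10, theta_site = 0.05, seed = 11)
  res <- amova(squared_distance_matrix(b), b$samples$habitat,
               subgroups = b$samples$site, n_perm = 0)
  phi <- setNames(res$phi$value, res$phi$statistic)
  expect_lt(abs(phi["PhiCT"] - 0.10), 0.03)
  expect_lt(abs(phi["PhiSC"] - 0.05), 0.03)
})

test_that("permutation p-values behave under null and structured data", {
  # structureless data: p roughly uniform; type-I close to nominal
  reps <- 24
  ps <- vapply(seq_len(reps), function(r) {
    b <- null_band_matrix(n = 24, n_loci = 60, n_groups = 3, seed = 100 + r)
    amova(squared_distance_matrix(b), b$samples$habitat, n_perm = 199,
          seed = r)$phi$p
  }, numeric(1))
  expect_gt(mean(ps > 0.2), 0.5)           # not concentrated at small p
  expect_lte(sum(ps <= 0.05), 5)           # ~1.2 expected at alpha = 0.05
  # structured data: small p
  b <- bn_band_matrix(n_loci = 300, theta_habitat = 0.15, seed = 12)
  res <- amova(squared_distance_matrix(b), b$samples$habitat, n_perm = 199,
               seed = 1)
  expect_lt(res$phi$p, 0.02)
})

test_that("pairwise AMOVA flags the distinct group and is order-invariant", {
  # groups A and B identical profiles, C maximally distinct
  v <- rbind(a1 = rep(0L, 6), a2 = rep(0L, 6),
             b1 = rep(0L, 6), b2 = rep(0L, 6),
             c1 = rep(1L, 6), c2 = rep(1L, 6))
  colnames(v) <- paste0("L", 1:6)
  b <- band_matrix(v, habitat = rep(c("A", "B", "C"), each = 2),
                   site = rep(c("A", "B", "C"), each = 2))
  d <- squared_distance_matrix(b)
  pw <- pairwise_amova(d, b$samples$habitat, n_perm = 39, seed = 1)
  expect_equal(pw$phi["A", "B"], 0)
  expect_equal(pw$phi["A", "C"], 1)
  expect_equal(pw$phi["B", "C"], 1)
  expect_equal(pw$phi, t(pw$phi))
  # relabelled group order gives the same matrices
  pw2 <- pairwise_amova(d, b$samples$habitat, n_perm = 39, seed = 1)
  expect_equal(pw2$phi, pw$phi)
  # planted ordering: stronger theta gives larger pairwise Phi
  sim <- simulate_dataset(sim_params(n_aflp = 600, n_msap = 10, seed = 24))
  dsim <- squared_distance_matrix(sim$aflp)
  pws <- pairwise_amova(dsim, sim$aflp$samples$habitat, n_perm = 0)
  expect_true(all(pws$phi[lower.tri(pws$phi)] > 0))
})

test_that("locus-by-locus AMOVA isolates differentiated loci", {
  # one locus fixed between groups, one monomorphic, some noise loci
  withr::local_seed(31)
  X <- cbind(fixed = rep(c(0L, 1L), each = 10),
             mono = rep(1L, 20),
             matrix(rbinom(20 * 18, 1, 0.5), 20, 18,
                    dimnames = list(NULL, sprintf("n%02d", 1:18))))
  rownames(X) <- sprintf("i%02d", 1:20)
  b <- band_matrix(X, habitat = rep(c("A", "B"), each = 10),
                   site = rep(c("A", "B"), each = 10))
  out <- locus_by_locus_amova(b, "habitat", n_perm = 199, alpha = 0.01,
                              seed = 2)
  expect_equal(out$phi[out$locus == "fixed"], 1)
  expect_equal(out$p[out$locus == "fixed"], 1 / 200)
  expect_true(out$significant[out$locus == "fixed"])
  expect_identical(out$flag[out$locus == "mono"], "monomorphic")
  expect_true(is.na(out$p[out$locus == "mono"]))
  # neutral loci: significant fraction near the nominal alpha
  bnull <- null_band_matrix(n = 48, n_loci = 800, n_groups = 4, seed = 32)
  nul <- locus_by_locus_amova(bnull, "habitat", n_perm = 199, alpha = 0.05,
                              seed = 3)
  rate <- mean(nul$significant[nul$flag == ""])
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / sum(nul$flag == "")) + 0.02)
})

test_that("tidy and glance return the expected tabular views", {
  b <- bn_band_matrix(n_loci = 50, seed = 13)
  res <- amova(squared_distance_matrix(b), b$samples$habitat,
               subgroups = b$samples$site, n_perm = 19, seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("source", "df", "SS", "MS", "sigma2", "pct_variation"))
  gl <- glance(res)
  expect_true(all(c("value_PhiCT", "p_PhiST", "n_perm") %in% names(gl)))
})
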