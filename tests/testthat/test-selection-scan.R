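test_that("per-locus fst and het follow the He-based definitions", {
  # two groups with band-presence allele frequencies 0.3 and 0.7, rendered as
  # exact phenotype fractions so the sqrt estimator returns them exactly
  n <- 100
  mk_col <- function(p) {
    x0 <- round((1 - p)^2 * n)
    c(rep(0L, x0), rep(1L, n - x0))
  }
  v <- cbind(L1 = c(mk_col(0.3), mk_col(0.7)),
             L2 = c(mk_col(0.5), mk_col(0.5)),       # equal freqs -> fst 0
             L3 = c(rep(0L, n), rep(1L, n)),         # opposite fixation
             L4 = rep(1L, 2 * n))                    # monomorphic: excluded
  rownames(v) <- sprintf("i%03d", seq_len(2 * n))
  b <- band_matrix(v, habitat = rep(c("A", "B"), each = n),
                   site = rep(c("A", "B"), each = n))
  rec <- fst_het_per_locus(b, "habitat")
  expect_setequal(rec$locus, c("L1", "L2", "L3"))
  r1 <- rec[rec$locus == "L1", ]
  expect_equal(r1$fst, (0.5 - (0.42 + 0.42) / 2) / 0.5, tolerance = 1e-6)
  expect_equal(r1$fst, 0.16, tolerance = 1e-6)
  expect_equal(r1$het, 0.5, tolerance = 1e-6)
  expect_equal(rec$fst[rec$locus == "L2"], 0)
  expect_equal(rec$fst[rec$locus == "L3"], 1)
  expect_equal(rec$het[rec$locus == "L3"], 0.5)
  # 0/1 relabeling: the dominant sqrt estimator is anchored to the
  # band-absent class, so fst shifts slightly but stays the same order;
  # monomorphic and symmetric loci are unaffected
  v_flip <- v; v_flip[, "L1"] <- 1L - v_flip[, "L1"]
  b_flip <- band_matrix(v_flip, habitat = rep(c("A", "B"), each = n),
                        site = rep(c("A", "B"), each = n))
  rec_flip <- fst_het_per_locus(b_flip, "habitat")
  expect_gt(rec_flip$fst[rec_flip$locus == "L1"], 0.05)
  expect_equal(rec_flip$fst[rec_flip$locus == "L2"], 0)
  expect_equal(rec_flip$fst[rec_flip$locus == "L3"], 1)
})

test_that("the neutral envelope is calibrated and has the advertised coverage", {
  # with large groups the estimator chain is nearly unbiased, so the mean
  # simulated fst approaches target * (K-1)/K (unweighted-Ht convention)
  env <- suppressWarnings(
    fdist_null_envelope(4, 500, 0.10, n_sim = 8000, het_bins = 1, seed = 1))
  expect_lt(abs(attr(env, "mean_fst") - 0.10 * 3 / 4), 0.015)
  # ~1% of a fresh neutral simulation falls outside a (0.005, 0.995) envelope
  env2 <- suppressWarnings(
    fdist_null_envelope(4, 20, 0.10, n_sim = 20000, seed = 2))
  rec <- tibble::tibble(locus = sprintf("S%d", seq_len(5000)),
                        fst = numeric(5000), het = numeric(5000))
  # reconstruct fresh per-locus draws via a small direct simulation
  withr::local_seed(4)
  draws <- replicate(5000, {
    pb <- runif(1, 0.01, 0.99)
    repeat {
      pg <- rbeta(4, pb * 0.9 / 0.1, (1 - pb) * 0.9 / 0.1)
      x0 <- rbinom(4, 20, (1 - pg)^2) / 20
      if (any(x0 < 1) && any(x0 > 0)) break
    }
    q <- sqrt(x0); p <- 1 - q
    ht <- 2 * mean(p) * (1 - mean(p))
    c(fst = (ht - mean(2 * p * q)) / ht, het = ht)
  })
  rec$fst <- draws["fst", ]; rec$het <- draws["het", ]
  rec <- rec[rec$het > 0, ]
  flagged <- fdist_outliers(rec, env2)
  out_rate <- mean(flagged$flag != "none")
  expect_lt(abs(out_rate - 0.01), 0.01)
  # degenerate limit: tiny target collapses the envelope toward fst 0
  env3 <- suppressWarnings(
    fdist_null_envelope(4, 500, 0.002, n_sim = 3000, het_bins = 1, seed = 5))
  expect_lt(env3$upper, 0.05)
  expect_error(fdist_null_envelope(4, 20, 0), "target_fst")
})

test_that("outlier flags respect the envelope and extrapolation is marked", {
  env <- tibble::tibble(bin = 1:2, het_lo = c(0, 0.25), het_hi = c(0.25, 0.5),
                        lower = c(0.01, 0.02), upper = c(0.3, 0.4),
                        n_sim = c(1000L, 1000L))
  class(env) <- c("fdist_envelope", class(env))
  rec <- tibble::tibble(locus = c("a", "b", "c", "d"),
                        fst = c(0.5, 0.005, 0.2, 0.45),
                        het = c(0.3, 0.1, 0.2, 0.6))
  fl <- fdist_outliers(rec, env)
  expect_identical(fl$flag, c("directional_candidate", "balancing_candidate",
                              "none", "directional_candidate"))
  expect_identical(fl$het_extrapolated, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("the full scan flags planted outliers far above the neutral rate", {
  sim <- simulate_dataset(sim_params(n_aflp = 1200, n_msap = 10,
                                     n_outliers = 40, outlier_theta = 0.5,
                                     seed = 41))
  scan <- suppressWarnings(
    fdist_scan(sim$aflp, groups = "habitat", n_sim = 8000, seed = 42))
  rec <- tidy(scan)
  planted <- rec$locus %in% sim$truth$outlier_loci
  hit <- mean(rec$flag[planted] == "directional_candidate")
  fp <- mean(rec$flag[!planted] == "directional_candidate")
  expect_gt(hit, 0.1)
  expect_lt(fp, 0.03)
  expect_gt(hit / max(fp, 1e-3), 10)   # strong enrichment of planted loci
  # calibrated neutral target stays near the planted background theta scale
  expect_lt(scan$target_fst, 0.3)
  # determinism under a fixed seed
  scan2 <- suppressWarnings(
    fdist_scan(sim$aflp, groups = "habitat", n_sim = 8000, seed = 42))
  expect_identical(tidy(scan2), rec)
})

test_that("logistic scan computes G and Wald per locus x variable", {
  withr::local_seed(51)
  n <- 80
  z <- rep(seq(-1.5, 1.5, length.out = 8), each = 10)
  site <- rep(sprintf("s%d", 1:8), each = 10)
  # strong cline locus, null locus
  y1 <- rbinom(n, 1, plogis(-0.5 + 3 * z))
  y2 <- rbinom(n, 1, 0.5)
  v <- cbind(cline = as.integer(y1), nullL = as.integer(y2))
  rownames(v) <- sprintf("i%02d", 1:n)
  b <- band_matrix(v, habitat = rep(c("H1", "H2"), each = 40), site = site)
  s <- tibble::tibble(site = sprintf("s%d", 1:8),
                      grad = seq(-1.5, 1.5, length.out = 8))
  out <- env_logistic_scan(b, s, alpha = 0.05)
  expect_equal(nrow(out), 2L)
  cl <- out[out$locus == "cline", ]
  # oracle: glm() fit of the same model
  or <- glm(y1 ~ z, family = binomial())
  expect_equal(cl$beta, unname(coef(or)[2]), tolerance = 1e-6)
  expect_equal(cl$g_stat, unname(or$null.deviance - or$deviance),
               tolerance = 1e-6)
  expect_equal(cl$wald_stat,
               unname((coef(or)[2] / sqrt(vcov(or)[2, 2]))^2),
               tolerance = 1e-3)
  expect_true(cl$significant)   # both tests below 0.05 / (2 x 1)
  expect_false(out$significant[out$locus == "nullL"])
  # G and Wald agree asymptotically: large n, local effect size
  withr::local_seed(52)
  nb <- 1000
  zb <- rep(seq(-1.5, 1.5, length.out = 10), each = nb / 10)
  yb <- rbinom(nb, 1, plogis(0.1 * zb))
  vb <- cbind(mild = as.integer(yb))
  rownames(vb) <- sprintf("j%04d", seq_len(nb))
  sb <- rep(sprintf("t%02d", 1:10), each = nb / 10)
  bb <- band_matrix(vb, habitat = rep("H", nb), site = sb)
  tab <- tibble::tibble(site = sprintf("t%02d", 1:10),
                        grad = seq(-1.5, 1.5, length.out = 10))
  ob <- env_logistic_scan(bb, tab)
  expect_lt(abs(ob$p_g - ob$p_wald), 0.01)
  # constant variable is an error
  s0 <- tibble::tibble(site = sprintf("s%d", 1:8), flat = rep(1, 8))
  expect_error(env_logistic_scan(b, s0), "flat")
})

test_that("perfect separation is flagged and Wald suppressed", {
  v <- cbind(sep = rep(c(0L, 1L), each = 20))
  rownames(v) <- sprintf("i%02d", 1:40)
  site <- rep(c("s1", "s2"), each = 20)
  b <- band_matrix(v, habitat = site, site = site)
  s <- tibble::tibble(site = c("s1", "s2"), grad = c(-1, 1))
  out <- env_logistic_scan(b, s)
  expect_identical(out$flag, "separation")
  expect_true(is.na(out$wald_stat))
  expect_gt(out$g_stat, 0)
})

test_that("familywise error of the corrected scan is near alpha under the null", {
  hits <- vapply(seq_len(20), function(r) {
    b <- null_band_matrix(n = 60, n_loci = 50, n_groups = 6, seed = 600 + r)
    s <- withr::with_seed(700 + r,
      tibble::tibble(site = unique(b$samples$site), v1 = rnorm(6), v2 = rnorm(6)))
    out <- env_logistic_scan(b, s, alpha = 0.05)
    any(out$significant)
  }, logical(1))
  # nominal familywise rate 0.05: allow 2x the binomial CI around 1/20
  expect_lte(sum(hits), 4)
})
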