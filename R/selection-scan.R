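# FDIST-style Fst-outlier detection for dominant markers against a
# Balding-Nichols beta-binomial island-model neutral envelope, plus
# univariate logistic environmental association (landscape-genomics scan).

#' Per-locus Fst and heterozygosity
#'
#' Allele frequencies per group come from the dominant-marker estimator;
#' per locus, Hs is the mean within-group expected heterozygosity 2pq, Ht
#' the expected heterozygosity at the unweighted mean allele frequency, and
#' fst = (Ht - Hs)/Ht. Loci monomorphic across all groups (Ht = 0) are
#' excluded.
#'
#' @param b A [band_matrix].
#' @param groups Per-sample labels or `"site"`/`"habitat"`.
#' @param freq_method Allele-frequency estimator (see
#'   [estimate_allele_frequencies()]).
#' @return A tibble: locus, fst, het (= Ht), flag (`"none"` initially).
#' @export
fst_het_per_locus <- function(b, groups = "habitat",
                              freq_method = c("sqrt", "lynch_milligan",
                                              "bayes_uniform")) {
  freq_method <- match.arg(freq_method)
  g <- resolve_grouping(b, groups)
  if (nlevels(g) < 2) abort("need at least two groups")
  freqs <- estimate_allele_frequencies(b, g, freq_method)
  wide <- tidyr::pivot_wider(
    dplyr::select(freqs, "pop", "locus", "p"),
    names_from = "pop", values_from = "p")
  P <- as.matrix(wide[, -1])
  pbar <- rowMeans(P, na.rm = TRUE)
  hs <- rowMeans(2 * P * (1 - P), na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  keep <- is.finite(ht) & ht > 0
  tibble::tibble(locus = wide$locus[keep],
                 fst = (ht[keep] - hs[keep]) / ht[keep],
                 het = ht[keep],
                 flag = "none")
}

# multilocus Fst: sum(Ht - Hs) / sum(Ht) over loci
multilocus_fst <- function(records) {
  sum(records$fst * records$het) / sum(records$het)
}

# mean estimated multilocus fst of neutral loci simulated at model theta
# (same sampling + estimator chain as the envelope)
simulate_mean_fst <- function(n_groups, group_sizes, theta, n_sim, freq_method) {
  env <- fdist_null_envelope(n_groups, group_sizes, theta, n_sim = n_sim,
                             het_bins = 1, freq_method = freq_method)
  attr(env, "mean_fst")
}

# The finite-sample estimator chain (dominant phenotypes + frequency
# estimator) inflates multilocus fst, most strongly for small groups; feeding
# the raw data estimate to the null model would double-count that bias.
# Calibrate the model theta so that neutral simulations reproduce the
# observed multilocus fst on the estimation scale (standard FDIST practice).
calibrate_target_fst <- function(observed, n_groups, group_sizes, n_sim,
                                 freq_method, max_iter = 4) {
  theta <- max(min(observed, 0.95), 1e-3)
  for (it in seq_len(max_iter)) {
    m <- simulate_mean_fst(n_groups, group_sizes, theta, n_sim, freq_method)
    if (!is.finite(m) || m <= 0) break
    theta <- max(min(theta * observed / m, 0.95), 1e-3)
  }
  theta
}

#' Neutral Fst-heterozygosity envelope
#'
#' Simulates neutral dominant loci under a Balding-Nichols island-model
#' surrogate: ancestral band-presence allele frequency uniform on
#' (0.01, 0.99), group frequencies Beta-distributed around it with
#' dispersion `target_fst`, dominant phenotypes sampled per group under HWE,
#' and fst/het recomputed with the same estimator as the empirical scan.
#' Conditional quantiles per heterozygosity bin form the envelope; bins with
#' fewer than 200 simulated loci are merged with a neighbour (warning).
#'
#' @param n_groups Number of groups.
#' @param group_sizes Integer vector of per-group sample sizes (recycled to
#'   `n_groups`).
#' @param target_fst Dispersion (Fst) of the neutral model, in (0, 1).
#' @param n_sim Number of simulated polymorphic loci (default 20000).
#' @param quantiles Lower/upper envelope quantiles (default 0.005, 0.995).
#' @param het_bins Number of equal-width heterozygosity bins (default 20).
#' @param freq_method Estimator used to recompute frequencies.
#' @param seed Optional RNG seed.
#' @return An object of class `fdist_envelope`: tibble with columns bin,
#'   het_lo, het_hi, lower, upper, n_sim; attributes keep the simulation
#'   settings.
#' @export
fdist_null_envelope <- function(n_groups, group_sizes, target_fst,
                                n_sim = 20000, quantiles = c(0.005, 0.995),
                                het_bins = 20,
                                freq_method = c("sqrt", "lynch_milligan",
                                                "bayes_uniform"),
                                seed = NULL) {
  freq_method <- match.arg(freq_method)
  if (!(target_fst > 0 && target_fst < 1)) abort("`target_fst` must be in (0, 1)")
  group_sizes <- rep_len(as.integer(group_sizes), n_groups)
  if (any(group_sizes < 2)) abort("group sizes must be >= 2")
  local_seed_if(seed)
  est_q <- function(x0, n) {
    switch(freq_method,
      sqrt = sqrt(x0),
      lynch_milligan = {
        qs <- sqrt(x0)
        vx <- x0 * (1 - x0) / n
        ifelse(x0 > 3 / n & x0 > 0, qs / (1 + vx / (8 * x0^2)), qs)
      },
      bayes_uniform = sqrt((x0 * n + 1) / (n + 2)))
  }
  fst_all <- het_all <- numeric(0)
  todo <- n_sim
  while (todo > 0) {
    m <- ceiling(todo * 1.3) + 100
    pbar <- runif(m, 0.01, 0.99)
    shp1 <- pbar * (1 - target_fst) / target_fst
    shp2 <- (1 - pbar) * (1 - target_fst) / target_fst
    X0 <- matrix(0, m, n_groups)
    for (k in seq_len(n_groups)) {
      pg <- rbeta(m, shp1, shp2)
      X0[, k] <- rbinom(m, group_sizes[k], (1 - pg)^2) / group_sizes[k]
    }
    poly <- rowSums(X0 == 1) < n_groups & rowSums(X0 == 0) < n_groups
    Q <- matrix(0, m, n_groups)
    for (k in seq_len(n_groups)) Q[, k] <- est_q(X0[, k], group_sizes[k])
    P <- 1 - Q
    pbar_hat <- rowMeans(P)
    hs <- rowMeans(2 * P * Q)
    ht <- 2 * pbar_hat * (1 - pbar_hat)
    ok <- poly & ht > 0
    fst_all <- c(fst_all, ((ht - hs) / ht)[ok])
    het_all <- c(het_all, ht[ok])
    todo <- n_sim - length(fst_all)
  }
  fst_all <- fst_all[seq_len(n_sim)]
  het_all <- het_all[seq_len(n_sim)]
  breaks <- seq(0, 0.5, length.out = het_bins + 1)
  bin <- pmin(pmax(findInterval(het_all, breaks, rightmost.closed = TRUE), 1),
              het_bins)
  counts <- tabulate(bin, het_bins)
  merged <- FALSE
  while (any(counts > 0 & counts < 200) && sum(counts > 0) > 1) {
    i <- which(counts > 0 & counts < 200)[1]
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= length(counts) & counts[nb] > 0]
    if (length(nb) == 0) break
    j <- nb[which.min(counts[nb])]
    lo <- min(i, j); hi <- max(i, j)
    bin[bin == hi] <- lo
    breaks <- breaks[-(lo + 1)]
    bin[bin > hi] <- bin[bin > hi] - 1L
    counts <- tabulate(bin, length(breaks) - 1)
    merged <- TRUE
  }
  if (merged) warn("heterozygosity bins with < 200 simulations were widened")
  nb <- length(breaks) - 1
  env <- purrr::map_dfr(seq_len(nb), function(i) {
    f <- fst_all[bin == i]
    if (length(f) == 0) return(NULL)
    qs <- quantile(f, probs = quantiles, names = FALSE, type = 8)
    tibble::tibble(bin = i, het_lo = breaks[i], het_hi = breaks[i + 1],
                   lower = qs[1], upper = qs[2], n_sim = length(f))
  })
  structure(env, class = c("fdist_envelope", class(env)),
            target_fst = target_fst, quantiles = quantiles,
            group_sizes = group_sizes, freq_method = freq_method,
            mean_fst = sum(fst_all * het_all) / sum(het_all))
}

#' Flag Fst outliers against a neutral envelope
#'
#' A locus is a directional-selection candidate when its fst exceeds the
#' upper envelope quantile of its heterozygosity bin, and a
#' balancing-selection candidate when it falls below the lower quantile.
#' Records outside the envelope's het range use the nearest bin and are
#' flagged.
#'
#' @param records Tibble from [fst_het_per_locus()].
#' @param envelope An `fdist_envelope`.
#' @return `records` with the `flag` column set to `directional_candidate`,
#'   `balancing_candidate` or `none`, plus `het_extrapolated`.
#' @export
fdist_outliers <- function(records, envelope) {
  stopifnot(inherits(envelope, "fdist_envelope"))
  breaks <- c(envelope$het_lo, envelope$het_hi[nrow(envelope)])
  idx <- findInterval(records$het, breaks, rightmost.closed = TRUE)
  extrap <- idx < 1 | idx > nrow(envelope)
  idx <- pmin(pmax(idx, 1), nrow(envelope))
  lo <- envelope$lower[idx]
  hi <- envelope$upper[idx]
  dplyr::mutate(records,
    flag = dplyr::case_when(.data$fst > hi ~ "directional_candidate",
                            .data$fst < lo ~ "balancing_candidate",
                            TRUE ~ "none"),
    het_extrapolated = extrap)
}

#' Full FDIST-style outlier scan
#'
#' Computes per-locus fst/het, builds a neutral envelope at the trimmed
#' multilocus fst (one trimming pass: provisional outliers from a first
#' envelope are removed before the target fst of the final envelope is
#' computed), and flags outliers.
#'
#' @inheritParams fst_het_per_locus
#' @inheritParams fdist_null_envelope
#' @param target_fst Neutral-model fst; default `NULL` uses the trimmed
#'   multilocus fst of the data.
#' @return A list of class `fdist_scan`: `records` (flagged tibble),
#'   `envelope`, `target_fst`.
#' @export
fdist_scan <- function(b, groups = "habitat", target_fst = NULL,
                       n_sim = 20000, quantiles = c(0.005, 0.995),
                       het_bins = 20,
                       freq_method = c("sqrt", "lynch_milligan",
                                       "bayes_uniform"),
                       seed = NULL) {
  freq_method <- match.arg(freq_method)
  g <- resolve_grouping(b, groups)
  records <- fst_het_per_locus(b, g, freq_method)
  sizes <- as.vector(table(g))
  local_seed_if(seed)
  if (is.null(target_fst)) {
    n_cal <- max(4000, n_sim %/% 4)
    obs0 <- multilocus_fst(records)
    theta0 <- calibrate_target_fst(obs0, nlevels(g), sizes, n_cal, freq_method)
    env0 <- suppressWarnings(
      fdist_null_envelope(nlevels(g), sizes, theta0, n_sim = n_cal,
                          quantiles = quantiles, het_bins = het_bins,
                          freq_method = freq_method))
    prov <- fdist_outliers(records, env0)
    keep <- prov$flag == "none"
    obs1 <- multilocus_fst(records[keep, ])
    target_fst <- calibrate_target_fst(obs1, nlevels(g), sizes, n_cal,
                                       freq_method)
  }
  env <- fdist_null_envelope(nlevels(g), sizes, target_fst, n_sim = n_sim,
                             quantiles = quantiles, het_bins = het_bins,
                             freq_method = freq_method)
  structure(list(records = fdist_outliers(records, env), envelope = env,
                 target_fst = target_fst),
            class = "fdist_scan")
}

#' @export
print.fdist_scan <- function(x, ...) {
  tab <- table(x$records$flag)
  cat(sprintf("<fdist_scan> %d loci, neutral fst = %.4f\n",
              nrow(x$records), x$target_fst))
  print(tab)
  invisible(x)
}

#' @method tidy fdist_scan
#' @export
tidy.fdist_scan <- function(x, ...) x$records

# log-likelihood of a fitted Bernoulli vector
bern_ll <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Univariate logistic environmental association scan
#'
#' For every polymorphic locus and every soil variable, fits band-presence ~
#' intercept + variable by maximum likelihood (individuals inherit their
#' site's mean value) and reports the likelihood-ratio G statistic and the
#' Wald statistic with chi-square (df = 1) p-values. A model is significant
#' when both tests pass the multiplicity-corrected threshold
#' alpha / (n_loci x n_variables). Perfect separation is flagged and the
#' Wald test suppressed (G retained).
#'
#' @param b A [band_matrix].
#' @param s Soil table (site rows).
#' @param assignment Sample-to-site map; defaults to the band matrix's own
#'   site labels.
#' @param variables Which soil variables to test (default: all non-site
#'   columns).
#' @param alpha Familywise significance level before correction.
#' @param threshold Override the corrected per-test threshold.
#' @return A tibble: locus, variable, beta, g_stat, wald_stat, p_g, p_wald,
#'   threshold, significant, flag.
#' @export
env_logistic_scan <- function(b, s, assignment = NULL, variables = NULL,
                              alpha = 0.05, threshold = NULL) {
  stopifnot(inherits(b, "band_matrix"))
  if (is.null(assignment)) {
    assignment <- stats::setNames(b$samples$site, b$samples$sample)
  } else if (is.data.frame(assignment)) {
    assignment <- stats::setNames(as.character(assignment$site),
                                  assignment$sample)
  }
  if (is.null(variables)) variables <- setdiff(names(s), "site")
  site_rows <- match(assignment[b$samples$sample], s$site)
  if (anyNA(site_rows)) abort("sample site(s) missing from soil table")
  env <- as.matrix(s[site_rows, variables, drop = FALSE])
  const <- apply(env, 2, function(z) length(unique(z)) == 1)
  if (any(const)) {
    abort(sprintf("constant environmental variable(s): %s",
                  paste(variables[const], collapse = ", ")))
  }
  X <- b$values
  poly <- colSums(X == 1, na.rm = TRUE) > 0 & colSums(X == 0, na.rm = TRUE) > 0
  loci <- b$loci$locus[poly]
  n_tests <- length(loci) * length(variables)
  if (is.null(threshold)) threshold <- alpha / n_tests
  res <- vector("list", n_tests)
  k <- 0
  for (li in which(poly)) {
    y_all <- X[, li]
    obs <- !is.na(y_all)
    y <- y_all[obs]
    for (vi in seq_along(variables)) {
      z <- env[obs, vi]
      Xd <- cbind(1, z)
      fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
      mu <- fit$fitted.values
      beta <- unname(fit$coefficients[2])
      g <- 2 * (bern_ll(y, mu) - bern_ll(y, mean(y)))
      g <- max(g, 0)
      sep <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
        !is.finite(beta) || abs(beta) > 15
      wald <- NA_real_
      if (!sep) {
        w <- mu * (1 - mu)
        info <- crossprod(Xd * sqrt(w))
        se2 <- tryCatch(solve(info)[2, 2], error = function(e) NA_real_)
        if (is.finite(se2) && se2 > 0) wald <- beta^2 / se2
      }
      p_g <- stats::pchisq(g, 1, lower.tail = FALSE)
      p_w <- if (is.na(wald)) NA_real_ else stats::pchisq(wald, 1, lower.tail = FALSE)
      k <- k + 1
      res[[k]] <- tibble::tibble(
        locus = b$loci$locus[li], variable = variables[vi],
        beta = beta, g_stat = g, wald_stat = wald, p_g = p_g, p_wald = p_w,
        threshold = threshold,
        significant = !is.na(p_w) && p_g < threshold && p_w < threshold,
        flag = if (sep) "separation" else "")
    }
  }
  dplyr::bind_rows(res)
}
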