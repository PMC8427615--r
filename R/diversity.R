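# POPGENE/AFLPSURV-style diversity statistics for dominant markers,
# Nei distance/identity between populations, and a rank-sum comparison
# utility for MSL-vs-NML Shannon diversity.
#
# Dominant markers hide heterozygotes, so the recessive (band-absent)
# allele frequency q is estimated from the band-absent phenotype fraction
# x0: under HWE x0 = q^2. Estimators: sqrt (q = sqrt(x0), POPGENE's
# classical assumption), lynch_milligan (bias-corrected sqrt), and
# bayes_uniform (q = sqrt of the posterior mean of q^2 under a uniform
# prior, the AFLPSURV-style Bayesian estimator).

resolve_grouping <- function(b, grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% c("site", "habitat")) {
    factor(b$samples[[grouping]])
  } else {
    align_labels(grouping, b$samples$sample, "grouping")
  }
}

#' Estimate allele frequencies per population
#'
#' @param b A [band_matrix].
#' @param grouping `"site"` (default), `"habitat"`, or a per-sample label
#'   vector defining the populations.
#' @param method `"sqrt"`, `"lynch_milligan"` or `"bayes_uniform"`.
#' @return A tibble with one row per population x locus: pop, locus, n
#'   (non-missing individuals), x0 (band-absent fraction), q (recessive
#'   allele frequency), p = 1 - q, method. Loci with no data in a population
#'   carry `NA` frequencies.
#' @export
estimate_allele_frequencies <- function(b, grouping = "site",
                                        method = c("sqrt", "lynch_milligan",
                                                   "bayes_uniform")) {
  method <- match.arg(method)
  g <- resolve_grouping(b, grouping)
  purrr::map_dfr(levels(g), function(lev) {
    v <- b$values[g == lev, , drop = FALSE]
    n <- colSums(!is.na(v))
    k0 <- colSums(v == 0L, na.rm = TRUE)
    x0 <- ifelse(n > 0, k0 / n, NA_real_)
    q <- switch(method,
      sqrt = sqrt(x0),
      lynch_milligan = {
        qs <- sqrt(x0)
        vx <- x0 * (1 - x0) / pmax(n, 1)
        corr <- ifelse(x0 > 3 / pmax(n, 1) & x0 > 0,
                       1 / (1 + vx / (8 * x0^2)), 1)
        qs * corr
      },
      bayes_uniform = sqrt((k0 + 1) / (n + 2))
    )
    q <- unname(pmin(pmax(q, 0), 1))
    tibble::tibble(pop = lev, locus = b$loci$locus,
                   n = unname(as.integer(n)), x0 = unname(x0),
                   q = q, p = 1 - q, method = method)
  })
}

#' Per-population diversity indices for dominant markers
#'
#' Per locus: Na = number of observed band states; Ne = 1/(p^2 + q^2) under
#' the biallelic model; He = 2pq (Nei's gene diversity); the Shannon index
#' I = -(f log f + (1-f) log(1-f)) is computed on the band-state (phenotype)
#' frequency f, natural logs. Population values are across-locus means; P is
#' the percentage of loci with both band states observed and P5 the
#' percentage with estimated minor allele frequency >= 0.05. Across
#' populations, Gst = (Ht - Hs)/Ht (He-based, locus totals) and
#' Nm = 0.5 (1 - Gst)/Gst.
#'
#' @inheritParams estimate_allele_frequencies
#' @param level `"population"` (one row per population) or `"locus"` (one
#'   row per population x locus).
#' @return A tibble. For `level = "population"` the attributes `gst` and
#'   `nm` carry the across-population statistics (`NA` with a single
#'   population).
#' @export
diversity_indices <- function(b, grouping = "site",
                              method = c("sqrt", "lynch_milligan",
                                         "bayes_uniform"),
                              level = c("population", "locus")) {
  level <- match.arg(level)
  method <- match.arg(method)
  freqs <- estimate_allele_frequencies(b, grouping, method)
  per_locus <- dplyr::mutate(
    freqs,
    f = 1 - .data$x0,                       # band-presence phenotype frequency
    na_states = (.data$x0 > 0 & .data$x0 < 1) + 1,
    ne = 1 / (.data$p^2 + .data$q^2),
    he = 2 * .data$p * .data$q,
    shannon = ifelse(.data$f <= 0 | .data$f >= 1, 0,
                     -(.data$f * log(.data$f) + (1 - .data$f) * log(1 - .data$f)))
  )
  if (level == "locus") {
    return(dplyr::select(per_locus, "pop", "locus", "n", "x0", "p", "q",
                         "na_states", "ne", "he", "shannon"))
  }
  pop_tab <- per_locus |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(
      n_loci = sum(!is.na(.data$x0)),
      Na = mean(.data$na_states, na.rm = TRUE),
      Ne = mean(.data$ne, na.rm = TRUE),
      P = 100 * mean(.data$x0 > 0 & .data$x0 < 1, na.rm = TRUE),
      P5 = 100 * mean(pmin(.data$p, .data$q) >= 0.05, na.rm = TRUE),
      He = mean(.data$he, na.rm = TRUE),
      I = mean(.data$shannon, na.rm = TRUE),
      .groups = "drop"
    )
  gst <- nm <- NA_real_
  if (length(unique(freqs$pop)) >= 2) {
    wide_p <- per_locus |>
      dplyr::select("pop", "locus", "p", "he") |>
      tidyr::pivot_wider(names_from = "pop", values_from = c("p", "he"))
    pcols <- grep("^p_", names(wide_p))
    hcols <- grep("^he_", names(wide_p))
    pbar <- rowMeans(as.matrix(wide_p[pcols]), na.rm = TRUE)
    hs <- rowMeans(as.matrix(wide_p[hcols]), na.rm = TRUE)
    ht <- 2 * pbar * (1 - pbar)
    keep <- is.finite(ht) & is.finite(hs)
    if (sum(ht[keep]) > 0) {
      gst <- (sum(ht[keep]) - sum(hs[keep])) / sum(ht[keep])
      nm <- if (gst > 0) 0.5 * (1 - gst) / gst else Inf
    }
  }
  attr(pop_tab, "gst") <- gst
  attr(pop_tab, "nm") <- nm
  pop_tab
}

#' Nei's genetic identity and distance between populations
#'
#' For each pair of populations, Jxy is the across-locus mean of
#' (px py + qx qy), Jx and Jy analogously; identity I = Jxy / sqrt(Jx Jy)
#' and distance D = -log(I). Loci with missing frequencies in either
#' population are dropped pairwise. A degenerate identity (I <= 0) yields an
#' infinite distance.
#'
#' @param freqs Allele-frequency table from [estimate_allele_frequencies()]
#'   covering at least two populations.
#' @return A list with symmetric matrices `identity` and `distance`.
#' @export
nei_distance <- function(freqs) {
  pops <- unique(freqs$pop)
  if (length(pops) < 2) abort("need at least two populations")
  loci <- unique(freqs$locus)
  P <- matrix(NA_real_, length(loci), length(pops),
              dimnames = list(loci, pops))
  P[cbind(match(freqs$locus, loci), match(freqs$pop, pops))] <- freqs$p
  Q <- 1 - P
  k <- length(pops)
  I <- matrix(1, k, k, dimnames = list(pops, pops))
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(P[, i]) & !is.na(P[, j])
      if (!any(ok)) abort(sprintf("no shared loci between %s and %s",
                                  pops[i], pops[j]))
      jxy <- mean(P[ok, i] * P[ok, j] + Q[ok, i] * Q[ok, j])
      jx <- mean(P[ok, i]^2 + Q[ok, i]^2)
      jy <- mean(P[ok, j]^2 + Q[ok, j]^2)
      Iij <- jxy / sqrt(jx * jy)
      I[i, j] <- I[j, i] <- Iij
      D[i, j] <- D[j, i] <- if (Iij <= 0) Inf else -log(Iij)
    }
  }
  list(identity = I, distance = D)
}

#' Wilcoxon rank-sum comparison of two sets of per-locus values
#'
#' Wraps the two-sided rank-sum test (exact for small untied samples,
#' otherwise a tie-corrected normal approximation with continuity
#' correction) and reports the rank-sum statistic of the first sample plus
#' summary statistics.
#'
#' @param a,b Numeric vectors (e.g. per-locus Shannon indices of MSL and
#'   NML loci).
#' @return A one-row tibble: W (rank sum of `a`), p, n and mean/sd of each
#'   sample.
#' @export
rank_sum_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  n1 <- length(a)
  if (length(unique(c(a, b))) == 1L) {
    w <- n1 * (n1 + length(b) + 1) / 2
    p <- 1
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    w <- unname(ht$statistic) + n1 * (n1 + 1) / 2
    p <- min(1, ht$p.value)
  }
  tibble::tibble(W = w, p = p, n_a = n1, n_b = length(b),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b))
}
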