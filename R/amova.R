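# Analysis of molecular variance on squared Euclidean distances of binary
# band profiles: one-level (PhiPT) and two-level nested (PhiCT, PhiSC,
# PhiST) designs with unequal-size coefficients, permutation tests,
# pairwise AMOVA between groups, and vectorised locus-by-locus AMOVA.

#' Squared Euclidean distance matrix from binary profiles
#'
#' For individuals i and j, d2 = (L / Lij) * sum over mutually observed loci
#' of (xi - xj)^2, where Lij counts the mutually observed loci and L the
#' total number of loci (standard missing-data rescaling for AMOVA input).
#'
#' @param b A [band_matrix].
#' @return A symmetric matrix of squared distances with sample-id dimnames.
#' @export
squared_distance_matrix <- function(b) {
  stopifnot(inherits(b, "band_matrix"))
  if (n_samples(b) < 2) abort("need at least two samples")
  sq_dist_from_values(b$values)
}

# core computation on a raw 0/1/NA matrix (also used by the locus bootstrap)
sq_dist_from_values <- function(X) {
  O <- !is.na(X)
  Xz <- X; Xz[!O] <- 0L
  storage.mode(Xz) <- "double"
  storage.mode(O) <- "double"
  Lij <- O %*% t(O)
  if (any(offdiag(Lij) == 0)) {
    ij <- which(Lij == 0 & lower.tri(Lij), arr.ind = TRUE)[1, ]
    abort(sprintf("samples '%s' and '%s' share no observed loci",
                  rownames(X)[ij[1]], rownames(X)[ij[2]]))
  }
  # mismatches over mutually observed loci (x binary: (xi-xj)^2 = xi + xj - 2 xi xj)
  XO <- Xz %*% t(O)
  mism <- XO + t(XO) - 2 * (Xz %*% t(Xz))
  d2 <- (ncol(X) / Lij) * mism
  diag(d2) <- 0
  d2 <- (d2 + t(d2)) / 2
  dimnames(d2) <- list(rownames(X), rownames(X))
  d2
}

# within-unit sum-of-squares term: sum over units of (1/n_k) sum_{i<j in k} d2
ss_within_units <- function(d2, f) {
  tot <- 0
  for (lev in levels(f)) {
    i <- which(f == lev)
    if (length(i) > 1) {
      tot <- tot + sum(d2[i, i][lower.tri(diag(length(i)))]) / length(i)
    }
  }
  tot
}

amova_onelevel_stats <- function(d2, g) {
  N <- nrow(d2)
  K <- nlevels(g)
  nk <- as.vector(table(g))
  ss_t <- sum(offdiag(d2)) / N
  ss_w <- ss_within_units(d2, g)
  ss_a <- ss_t - ss_w
  df_a <- K - 1
  df_w <- N - K
  ms_a <- ss_a / df_a
  ms_w <- if (df_w > 0) ss_w / df_w else 0
  n0 <- (N - sum(nk^2) / N) / (K - 1)
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  tot <- sigma_a + sigma_w
  phi <- if (tot <= 0) 0 else sigma_a / tot
  list(ss = c(among = ss_a, within = ss_w, total = ss_t),
       df = c(df_a, df_w), ms = c(ms_a, ms_w),
       sigma = c(among = sigma_a, within = sigma_w),
       phi = phi, degenerate = tot <= 0)
}

amova_twolevel_stats <- function(d2, g, s) {
  N <- nrow(d2)
  G <- nlevels(g)
  pops <- droplevels(interaction(g, s, drop = TRUE))
  P <- nlevels(pops)
  ss_t <- sum(offdiag(d2)) / N
  ss_wp <- ss_within_units(d2, pops)
  ss_wg <- ss_within_units(d2, g)
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  ms <- c(ss_ag, ss_ap, ss_wp) / df
  np <- as.vector(table(pops))
  Ng <- as.vector(table(g))
  pop_grp <- tapply(as.character(g), pops, function(x) x[1])
  Sg <- tapply(np, pop_grp[levels(pops)], sum)           # not squared; see below
  Sg2 <- tapply(np^2, pop_grp[levels(pops)], sum)
  n_c <- (N - sum(Sg2 / Ng[match(names(Sg2), levels(g))])) / (P - G)
  n_b <- (sum(Sg2 / Ng[match(names(Sg2), levels(g))]) - sum(np^2) / N) / (G - 1)
  n_a <- (N - sum(Ng^2) / N) / (G - 1)
  sigma_c <- unname(ms[3])
  sigma_b <- unname((ms[2] - sigma_c) / n_c)
  sigma_a <- unname((ms[1] - sigma_c - n_b * sigma_b) / n_a)
  tot <- sigma_a + sigma_b + sigma_c
  degenerate <- tot <= 0
  phi_ct <- if (degenerate) 0 else sigma_a / tot
  phi_sc <- if (sigma_b + sigma_c <= 0) 0 else sigma_b / (sigma_b + sigma_c)
  phi_st <- if (degenerate) 0 else (sigma_a + sigma_b) / tot
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within_pops = ss_wp,
              total = ss_t),
       df = df, ms = ms,
       sigma = c(among_groups = sigma_a, among_pops = sigma_b,
                 within_pops = sigma_c),
       phi = c(PhiCT = phi_ct, PhiSC = phi_sc, PhiST = phi_st),
       degenerate = degenerate)
}

#' Analysis of molecular variance (AMOVA)
#'
#' One-level AMOVA partitions squared distances among and within groups and
#' reports PhiPT; the two-level nested design (groups and subgroups, e.g.
#' habitats and sites) additionally separates among-subgroups-within-groups
#' variance and reports PhiCT, PhiSC and PhiST. Variance components use the
#' standard unequal-size coefficients. Permutation p-values follow the
#' add-one rule: PhiPT/PhiST permute individuals among all units, PhiSC
#' permutes individuals among subgroups within their group, and PhiCT
#' permutes whole subgroups among groups.
#'
#' Negative variance components are retained when computing Phi, but the
#' percentage-of-variation column truncates them to zero and renormalises
#' (the raw components stay in the table).
#'
#' @param d Symmetric matrix of squared Euclidean distances (e.g. from
#'   [squared_distance_matrix()]); a `dist` is accepted.
#' @param groups Per-individual group labels (vector aligned with the
#'   matrix ids, or named by them).
#' @param subgroups Optional nested subgroup labels for the two-level design.
#' @param n_perm Number of permutations (0 skips the tests).
#' @param seed Optional RNG seed for the permutations.
#' @return An object of class `amova_result` with a variance-partition
#'   `table` (tibble), a `phi` tibble (statistic, value, p) and bookkeeping
#'   fields. `tidy()` returns the table, `glance()` the Phi statistics.
#' @export
amova <- function(d, groups, subgroups = NULL, n_perm = 999, seed = NULL) {
  d2 <- as_square_matrix(d)
  ids <- rownames(d2)
  g <- align_labels(groups, ids, "groups")
  if (nlevels(g) < 2) abort("all individuals are in one group")
  if (any(table(g) < 2)) {
    warn("group(s) with a single individual present")
  }
  local_seed_if(seed)
  N <- nrow(d2)
  if (is.null(subgroups)) {
    obs <- amova_onelevel_stats(d2, g)
    p_phi <- NA_real_
    if (n_perm > 0) {
      perms <- vapply(seq_len(n_perm), function(r) {
        amova_onelevel_stats(d2, g[sample.int(N)])$phi
      }, numeric(1))
      p_phi <- perm_pvalue(obs$phi, perms, "upper")
    }
    sig <- obs$sigma
    sig_t <- pmax(sig, 0)
    pct <- if (sum(sig_t) > 0) 100 * sig_t / sum(sig_t) else c(0, 0)
    table <- tibble::tibble(
      source = c("Among groups", "Within groups", "Total"),
      df = c(obs$df, N - 1),
      SS = unname(obs$ss),
      MS = c(obs$ms, NA),
      sigma2 = c(unname(sig), sum(sig)),
      pct_variation = c(pct, 100)
    )
    phi <- tibble::tibble(statistic = "PhiPT", value = unname(obs$phi),
                          p = p_phi)
  } else {
    s <- align_labels(subgroups, ids, "subgroups")
    chk <- tapply(as.character(g), s, function(x) length(unique(x)))
    if (any(chk > 1)) abort("subgroups must be nested within groups")
    obs <- amova_twolevel_stats(d2, g, s)
    p <- c(PhiCT = NA_real_, PhiSC = NA_real_, PhiST = NA_real_)
    if (n_perm > 0) {
      pops <- droplevels(interaction(g, s, drop = TRUE))
      perm_st <- perm_sc <- perm_ct <- numeric(n_perm)
      pop_of <- levels(pops)
      grp_of_pop <- tapply(as.character(g), pops, function(x) x[1])[pop_of]
      for (r in seq_len(n_perm)) {
        pr <- sample.int(N)
        perm_st[r] <- amova_twolevel_stats(d2, g[pr], s[pr])$phi["PhiST"]
        # individuals among subgroups within groups
        s_sc <- as.character(s)
        for (lev in levels(g)) {
          i <- which(g == lev)
          s_sc[i] <- s_sc[i][sample.int(length(i))]
        }
        perm_sc[r] <- amova_twolevel_stats(d2, g, factor(s_sc))$phi["PhiSC"]
        # whole subgroups among groups
        g_ct_map <- stats::setNames(sample(grp_of_pop), pop_of)
        g_ct <- factor(g_ct_map[as.character(pops)], levels = levels(g))
        perm_ct[r] <- amova_twolevel_stats(d2, g_ct, s)$phi["PhiCT"]
      }
      p <- c(PhiCT = perm_pvalue(obs$phi["PhiCT"], perm_ct, "upper"),
             PhiSC = perm_pvalue(obs$phi["PhiSC"], perm_sc, "upper"),
             PhiST = perm_pvalue(obs$phi["PhiST"], perm_st, "upper"))
    }
    sig <- obs$sigma
    sig_t <- pmax(sig, 0)
    pct <- if (sum(sig_t) > 0) 100 * sig_t / sum(sig_t) else rep(0, 3)
    table <- tibble::tibble(
      source = c("Among groups", "Among subgroups within groups",
                 "Within subgroups", "Total"),
      df = c(unname(obs$df), N - 1),
      SS = unname(obs$ss),
      MS = c(unname(obs$ms), NA),
      sigma2 = c(unname(sig), sum(sig)),
      pct_variation = c(unname(pct), 100)
    )
    phi <- tibble::tibble(statistic = names(obs$phi),
                          value = unname(obs$phi),
                          p = unname(p[names(obs$phi)]))
  }
  structure(
    list(table = table, phi = phi, n_perm = n_perm,
         degenerate = obs$degenerate,
         design = if (is.null(subgroups)) "one-level" else "two-level"),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("<amova_result> %s design, %d permutations%s\n", x$design,
              x$n_perm, if (x$degenerate) " [degenerate: no variance]" else ""))
  print(as.data.frame(x$table), row.names = FALSE, digits = 5)
  print(as.data.frame(x$phi), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @method tidy amova_result
#' @export
tidy.amova_result <- function(x, ...) x$table

#' @method glance amova_result
#' @export
glance.amova_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$phi, names_from = "statistic",
                             values_from = c("value", "p"))
  dplyr::mutate(wide, n_perm = x$n_perm, degenerate = x$degenerate)
}

#' Pairwise AMOVA between groups
#'
#' Runs the one-level AMOVA on every pair of groups and collects the PhiPT
#' and permutation-p matrices.
#'
#' @inheritParams amova
#' @return An object of class `pairwise_amova`: list with symmetric `phi`
#'   and `p` matrices. `tidy()` gives one row per pair.
#' @export
pairwise_amova <- function(d, groups, n_perm = 999, seed = NULL) {
  d2 <- as_square_matrix(d)
  ids <- rownames(d2)
  g <- align_labels(groups, ids, "groups")
  if (nlevels(g) < 2) abort("need at least two groups")
  local_seed_if(seed)
  levs <- levels(g)
  k <- length(levs)
  phi <- matrix(0, k, k, dimnames = list(levs, levs))
  pm <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sel <- g %in% levs[c(i, j)]
      res <- amova(d2[sel, sel], droplevels(g[sel]), n_perm = n_perm)
      phi[i, j] <- phi[j, i] <- res$phi$value
      pm[i, j] <- pm[j, i] <- res$phi$p
    }
  }
  structure(list(phi = phi, p = pm, n_perm = n_perm),
            class = "pairwise_amova")
}

#' @export
print.pairwise_amova <- function(x, ...) {
  cat(sprintf("<pairwise_amova> %d groups, %d permutations\n",
              nrow(x$phi), x$n_perm))
  print(round(x$phi, 5))
  invisible(x)
}

#' @method tidy pairwise_amova
#' @export
tidy.pairwise_amova <- function(x, ...) {
  levs <- rownames(x$phi)
  idx <- which(lower.tri(x$phi), arr.ind = TRUE)
  tibble::tibble(group1 = levs[idx[, 2]], group2 = levs[idx[, 1]],
                 phi = x$phi[idx], p = x$p[idx])
}

#' Locus-by-locus AMOVA
#'
#' One-level AMOVA per locus on 0/1 band scores (squared distance between
#' individuals is the mismatch indicator). Monomorphic loci are excluded
#' with a flag. Permutations shuffle individuals among groups jointly across
#' loci.
#'
#' @param b A [band_matrix].
#' @param groups Per-sample group labels, or `"site"`/`"habitat"`.
#' @param n_perm Permutations for the per-locus p-values.
#' @param alpha Significance level for the `significant` flag (default 0.01).
#' @param seed Optional RNG seed.
#' @return A tibble: locus, phi, p, significant, flag.
#' @export
locus_by_locus_amova <- function(b, groups, n_perm = 999, alpha = 0.01,
                                 seed = NULL) {
  stopifnot(inherits(b, "band_matrix"))
  g <- resolve_grouping(b, groups)
  if (nlevels(g) < 2) abort("need at least two groups")
  local_seed_if(seed)
  X <- b$values
  O <- (!is.na(X)) * 1
  Xz <- X; Xz[is.na(X)] <- 0L
  storage.mode(Xz) <- "double"
  Gm <- t(stats::model.matrix(~ g - 1))            # K x N indicator
  locus_phi <- function(ones_k, ns_k) {
    Ntot <- colSums(ns_k)
    n1 <- colSums(ones_k)
    zeros_k <- ns_k - ones_k
    K_l <- colSums(ns_k > 0)
    ss_t <- ifelse(Ntot > 0, n1 * (Ntot - n1) / Ntot, NA_real_)
    ss_w <- colSums(ifelse(ns_k > 0, ones_k * zeros_k / ns_k, 0))
    ss_a <- ss_t - ss_w
    df_a <- K_l - 1
    df_w <- Ntot - K_l
    ms_a <- ss_a / df_a
    ms_w <- ifelse(df_w > 0, ss_w / df_w, 0)
    n0 <- (Ntot - colSums(ns_k^2) / Ntot) / pmax(df_a, 1)
    sigma_a <- (ms_a - ms_w) / n0
    tot <- sigma_a + ms_w
    phi <- ifelse(tot <= 0, 0, sigma_a / tot)
    ifelse(df_a >= 1 & df_w >= 1, phi, NA_real_)
  }
  ones_obs <- Gm %*% Xz
  ns_obs <- Gm %*% O
  phi_obs <- locus_phi(ones_obs, ns_obs)
  n1 <- colSums(Xz)
  n_obs_tot <- colSums(O)
  mono <- n1 == 0 | n1 == n_obs_tot
  hits <- rep(0, ncol(X))
  if (n_perm > 0) {
    for (r in seq_len(n_perm)) {
      pr <- sample.int(nrow(X))
      phi_p <- locus_phi(Gm %*% Xz[pr, , drop = FALSE],
                         Gm %*% O[pr, , drop = FALSE])
      hits <- hits + as.numeric(!is.na(phi_p) & !is.na(phi_obs) &
                                  phi_p >= phi_obs - 1e-12)
    }
  }
  p <- (hits + 1) / (n_perm + 1)
  phi_obs <- as.vector(phi_obs)
  mono <- as.vector(mono)
  p <- as.vector(p)
  tibble::tibble(
    locus = b$loci$locus,
    phi = phi_obs,
    p = ifelse(mono | is.na(phi_obs), NA_real_, p),
    significant = !mono & !is.na(phi_obs) & p < alpha,
    flag = dplyr::case_when(mono ~ "monomorphic",
                            is.na(phi_obs) ~ "undefined",
                            TRUE ~ "")
  )
}
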