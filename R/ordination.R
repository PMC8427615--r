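# Principal coordinate analysis, distance-based linear models (DistLM /
# dbRDA) with marginal and forward-selection permutation tests, Storey
# q-values, RDA with forward selection of soil variables, and UPGMA with
# locus bootstrap.

gower_center <- function(d) {
  A <- -0.5 * d * d
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Principal coordinate analysis (PCoA)
#'
#' Gower double-centering of -0.5 * D^2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are reported and excluded from the
#' proportion-explained denominator; a Lingoes correction is available.
#'
#' @param d Distance matrix (symmetric, zero diagonal). Note: actual
#'   distances, not squared distances - take `sqrt()` of the output of
#'   [squared_distance_matrix()] first.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return An object of class `pcoa_result`: `coordinates` (n x k matrix),
#'   `eigenvalues` (all, descending), `prop_explained` (over positive
#'   eigenvalues), `negative` (summary list), `correction`.
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_square_matrix(d)
  if (nrow(d) < 3) abort("need at least 3 units")
  G <- gower_center(d)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (correction == "lingoes" && min(e$values) < 0) {
    cc <- abs(min(e$values))
    d2 <- d * d + 2 * cc
    diag(d2) <- 0
    G <- gower_center(sqrt(d2))
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  }
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  neg <- e$values[e$values < -tol]
  structure(
    list(coordinates = coords,
         eigenvalues = e$values,
         prop_explained = e$values[pos] / sum(e$values[pos]),
         negative = list(n = length(neg),
                         most_negative = if (length(neg)) min(neg) else 0,
                         sum = sum(neg)),
         correction = correction),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d units, %d positive axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
                    collapse = ", ")))
  if (x$negative$n > 0) {
    cat(sprintf("  %d negative eigenvalues (min %.4g, correction: %s)\n",
                x$negative$n, x$negative$most_negative, x$correction))
  }
  invisible(x)
}

#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample")
}

#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$coordinates),
                 prop_axis1 = x$prop_explained[1],
                 prop_axis2 = if (length(x$prop_explained) > 1)
                   x$prop_explained[2] else NA_real_,
                 n_negative = x$negative$n,
                 correction = x$correction)
}

# trace-based pseudo-F machinery; H must be symmetric idempotent
hat_matrix <- function(x) {
  X <- cbind(1, as.matrix(x))
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Marginal DistLM tests of individual predictors
#'
#' Distance-based linear model: the Gower-centered distance matrix G is
#' regressed on each predictor alone; pseudo-F = tr(HGH) / [tr((I-H)G(I-H)) /
#' (n-2)] with the permutation null obtained by permuting the units of the
#' distance matrix. Storey q-values are appended across predictors.
#'
#' @param d Distance matrix over the units.
#' @param predictors Data frame (or matrix) of per-unit variables, rows
#'   aligned with the ids of `d`.
#' @param n_perm Permutations per predictor (default 9999).
#' @param seed Optional RNG seed.
#' @return A tibble: predictor, pseudo_F, prop_explained, p, q.
#' @export
distlm_marginal <- function(d, predictors, n_perm = 9999, seed = NULL) {
  d <- as_square_matrix(d)
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != nrow(d)) {
    abort("`predictors` must have one row per unit of `d`")
  }
  n <- nrow(d)
  G <- gower_center(d)
  trG <- sum(diag(G))
  local_seed_if(seed)
  purrr::map_dfr(names(predictors), function(v) {
    x <- predictors[[v]]
    if (length(unique(x)) == 1) abort(sprintf("constant predictor '%s'", v))
    H <- hat_matrix(x)
    trGH <- sum(G * H)
    f_obs <- trGH / ((trG - trGH) / (n - 2))
    perms <- vapply(seq_len(n_perm), function(r) {
      pr <- sample.int(n)
      Gp_H <- sum(G[pr, pr] * H)
      Gp_H / ((trG - Gp_H) / (n - 2))
    }, numeric(1))
    tibble::tibble(predictor = v, pseudo_F = f_obs,
                   prop_explained = trGH / trG,
                   p = perm_pvalue(f_obs, perms, "upper"))
  }) |>
    dplyr::mutate(q = suppressWarnings(storey_qvalues(.data$p)))
}

#' Forward selection DistLM
#'
#' Greedy forward selection of predictors by added proportion of the total
#' sum of squares; at each step the sequential pseudo-F of the best
#' candidate is tested by permuting the residualised (reduced-model) Gower
#' matrix. Selection stops when no candidate reaches `stop_alpha`. Candidates
#' adding less than 1e-12 proportion (collinear) are skipped with a flag.
#'
#' @inheritParams distlm_marginal
#' @param stop_alpha Stop when the best candidate's p >= this (default 0.05).
#' @return A tibble path: step, predictor, added_prop, cumulative_prop,
#'   pseudo_F, p, selected, flag.
#' @export
distlm_forward <- function(d, predictors, n_perm = 9999, stop_alpha = 0.05,
                           seed = NULL) {
  d <- as_square_matrix(d)
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != nrow(d)) {
    abort("`predictors` must have one row per unit of `d`")
  }
  n <- nrow(d)
  G <- gower_center(d)
  trG <- sum(diag(G))
  local_seed_if(seed)
  remaining <- names(predictors)
  selected <- character(0)
  skipped <- character(0)
  path <- list()
  step <- 0
  repeat {
    H_sel <- hat_matrix(
      if (length(selected)) predictors[selected] else matrix(0, n, 0))
    trGH_sel <- sum(G * H_sel)
    cand <- setdiff(remaining, skipped)
    if (length(cand) == 0) break
    added <- vapply(cand, function(v) {
      (sum(G * hat_matrix(predictors[c(selected, v)])) - trGH_sel) / trG
    }, numeric(1))
    collinear <- added < 1e-12
    if (any(collinear)) {
      for (v in cand[collinear]) {
        path[[length(path) + 1]] <- tibble::tibble(
          step = NA_integer_, predictor = v, added_prop = added[v],
          cumulative_prop = NA_real_, pseudo_F = NA_real_, p = NA_real_,
          selected = FALSE, flag = "collinear")
      }
      skipped <- c(skipped, cand[collinear])
      cand <- cand[!collinear]
      if (length(cand) == 0) break
      added <- added[!collinear]
    }
    best <- cand[which.max(added)]
    H_full <- hat_matrix(predictors[c(selected, best)])
    k_full <- length(selected) + 2          # intercept + predictors
    R <- diag(n) - H_sel
    Gr <- R %*% G %*% R
    f_of <- function(Gm) {
      num <- sum(Gm * H_full) - sum(Gm * H_sel)
      den <- (sum(diag(Gm)) - sum(Gm * H_full)) / (n - k_full)
      num / den
    }
    f_obs <- f_of(Gr)
    perms <- vapply(seq_len(n_perm), function(r) {
      pr <- sample.int(n)
      f_of(Gr[pr, pr])
    }, numeric(1))
    p <- perm_pvalue(f_obs, perms, "upper")
    sel <- p < stop_alpha
    step <- step + 1
    path[[length(path) + 1]] <- tibble::tibble(
      step = step, predictor = best, added_prop = unname(added[best]),
      cumulative_prop = (trGH_sel + unname(added[best]) * trG) / trG,
      pseudo_F = f_obs, p = p, selected = sel, flag = "")
    if (!sel) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(setdiff(remaining, skipped)) == 0) break
  }
  dplyr::bind_rows(path)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the lambda grid 0.05..0.95 with a
#' cubic-polynomial smoother evaluated at lambda = 0.95 (clamped to (0, 1]),
#' then applies the step-up transformation q(p_(i)) = min_{j >= i}
#' pi0 * m * p_(j) / j. With fewer than 20 p-values pi0 is fixed at 1
#' (Benjamini-Hochberg fallback) with a warning.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @return Vector of q-values, monotone nondecreasing in p.
#' @export
storey_qvalues <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  if (m < 20) {
    warn("fewer than 20 p-values: pi0 fixed at 1 (BH fallback)")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- stats::lm(pi0_l ~ poly(lambda, 3))
    pi0 <- stats::predict(fit, newdata = data.frame(lambda = 0.95))
    pi0 <- min(max(unname(pi0), .Machine$double.eps), 1)
  }
  o <- order(pvals)
  ps <- pvals[o]
  q <- pi0 * m * ps / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' RDA of binary markers on soil variables, with forward selection
#'
#' Redundancy analysis implemented through the DistLM machinery on Euclidean
#' distances of the column-centered binary matrix (the two are equivalent).
#' Reports the global Monte-Carlo test (all variables) and a forward
#' selection with the double stopping rule: a candidate must pass
#' `stop_alpha` and the cumulative adjusted R^2 must not exceed the global
#' adjusted R^2.
#'
#' @param b A [band_matrix]; missing cells are mean-imputed per locus for
#'   the ordination.
#' @param s Soil table.
#' @param assignment Sample-to-site map (default: the band matrix's sites).
#' @param n_perm Permutations for the global test and each selection step
#'   (default 999).
#' @param stop_alpha Forward-selection alpha (default 0.05).
#' @param seed Optional RNG seed.
#' @return A list of class `rda_forward_result`: `global` (one-row tibble:
#'   pseudo_F, p, r_squared, adj_r_squared) and `selection` (path tibble).
#' @export
rda_forward <- function(b, s, assignment = NULL, n_perm = 999,
                        stop_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(b, "band_matrix"))
  if (is.null(assignment)) {
    assignment <- stats::setNames(b$samples$site, b$samples$sample)
  } else if (is.data.frame(assignment)) {
    assignment <- stats::setNames(as.character(assignment$site),
                                  assignment$sample)
  }
  vars <- setdiff(names(s), "site")
  site_rows <- match(assignment[b$samples$sample], s$site)
  if (anyNA(site_rows)) abort("sample site(s) missing from soil table")
  env <- as.data.frame(s[site_rows, vars, drop = FALSE])
  rownames(env) <- b$samples$sample
  env <- env[, vapply(env, function(z) length(unique(z)) > 1, logical(1)),
             drop = FALSE]
  if (ncol(env) < 1) abort("no non-constant soil variables")
  Y <- b$values
  storage.mode(Y) <- "double"
  cm <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx) > 0) Y[idx] <- cm[idx[, 2]]
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  d <- as.matrix(stats::dist(Yc))
  n <- nrow(d)
  m <- ncol(env)
  G <- gower_center(d)
  trG <- sum(diag(G))
  H <- hat_matrix(env)
  trGH <- sum(G * H)
  r2 <- trGH / trG
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  f_glob <- (trGH / m) / ((trG - trGH) / (n - m - 1))
  local_seed_if(seed)
  perms <- vapply(seq_len(n_perm), function(r) {
    pr <- sample.int(n)
    tg <- sum(G[pr, pr] * H)
    (tg / m) / ((trG - tg) / (n - m - 1))
  }, numeric(1))
  p_glob <- perm_pvalue(f_glob, perms, "upper")
  sel <- distlm_forward(d, env, n_perm = n_perm, stop_alpha = stop_alpha)
  # double stopping rule: truncate once cumulative adjusted R2 passes global
  if (nrow(sel) > 0) {
    ksel <- cumsum(!is.na(sel$step) & sel$selected)
    adj <- 1 - (1 - sel$cumulative_prop) * (n - 1) / (n - ksel - 1)
    over <- !is.na(adj) & adj > adj_r2 & sel$selected
    if (any(over)) {
      first <- which(over)[1]
      sel$selected[sel$selected & seq_len(nrow(sel)) >= first] <- FALSE
      sel$flag[first] <- "exceeds_global_adj_r2"
      sel <- sel[seq_len(first), ]
    }
  }
  structure(
    list(global = tibble::tibble(pseudo_F = f_glob, p = p_glob,
                                 r_squared = r2, adj_r_squared = adj_r2,
                                 n_variables = m, n_perm = n_perm),
         selection = sel),
    class = "rda_forward_result"
  )
}

#' @export
print.rda_forward_result <- function(x, ...) {
  cat(sprintf("<rda_forward_result> global F = %.4f, p = %.4g, adj R2 = %.4f\n",
              x$global$pseudo_F, x$global$p, x$global$adj_r_squared))
  sel <- x$selection[x$selection$selected %in% TRUE, ]
  cat(sprintf("  selected: %s\n",
              if (nrow(sel)) paste(sel$predictor, collapse = ", ") else "(none)"))
  invisible(x)
}

#' @method tidy rda_forward_result
#' @export
tidy.rda_forward_result <- function(x, ...) x$selection

#' @method glance rda_forward_result
#' @export
glance.rda_forward_result <- function(x, ...) x$global

#' UPGMA dendrogram with locus bootstrap
#'
#' Average-linkage agglomeration of a distance matrix; when a band matrix is
#' supplied, loci (columns) are resampled with replacement `n_boot` times,
#' the distance matrix and tree rebuilt, and each internal bipartition's
#' support reported as the percentage of replicates containing it (stored as
#' node labels).
#'
#' @param d Distance matrix (actual distances; take `sqrt()` of squared
#'   distances first).
#' @param b Optional [band_matrix] for the bootstrap (must cover the same
#'   samples).
#' @param n_boot Bootstrap replicates (default 1000; 0 disables).
#' @param seed Optional RNG seed.
#' @return An `ape::phylo` tree; node labels carry bootstrap support (%).
#' @export
upgma <- function(d, b = NULL, n_boot = 1000, seed = NULL) {
  d <- as_square_matrix(d)
  if (nrow(d) < 3) abort("need at least 3 taxa")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(b) && n_boot > 0) {
    stopifnot(inherits(b, "band_matrix"))
    if (!setequal(b$samples$sample, rownames(d))) {
      abort("`b` must cover the same samples as `d`")
    }
    local_seed_if(seed)
    L <- n_loci(b)
    boots <- vector("list", n_boot)
    for (r in seq_len(n_boot)) {
      cols <- sample.int(L, L, replace = TRUE)
      dstar <- sqrt(sq_dist_from_values(b$values[, cols, drop = FALSE]))
      dstar <- dstar[rownames(d), rownames(d)]
      boots[[r]] <- ape::as.phylo(
        stats::hclust(stats::as.dist(dstar), method = "average"))
    }
    support <- ape::prop.clades(tree, boots, rooted = TRUE)
    support[is.na(support)] <- 0
    tree$node.label <- round(100 * support / n_boot, 1)
  }
  tree
}
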