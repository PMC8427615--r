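# Mantel and partial Mantel permutation tests, soil-difference matrices,
# off-diagonal (SPSS-style) correlation of pairwise statistic matrices, and
# the 2x2 chi-square association test.

check_same_ids <- function(A, B, argA, argB) {
  if (!identical(rownames(A), rownames(B))) {
    if (setequal(rownames(A), rownames(B))) {
      B <- B[rownames(A), rownames(A)]
    } else {
      abort(sprintf("`%s` and `%s` must cover the same ids", argA, argB))
    }
  }
  B
}

#' Mantel test
#'
#' Pearson correlation of the off-diagonal entries of two distance matrices,
#' with a permutation null obtained by jointly permuting rows and columns of
#' `B`. For n <= 7, `exact = TRUE` enumerates all n! permutations instead of
#' sampling; Monte-Carlo p-values use the add-one rule.
#'
#' @param A,B Symmetric matrices over the same ids.
#' @param n_perm Number of random permutations (default 10000).
#' @param tail `"upper"` (default: positive association), `"lower"` or
#'   `"two"`.
#' @param seed Optional RNG seed.
#' @param exact Enumerate all permutations (n <= 7 only).
#' @return An object of class `mantel_result` (also a one-row tibble):
#'   r, p, n_perm, tail, method.
#' @export
mantel <- function(A, B, n_perm = 10000, tail = c("upper", "lower", "two"),
                   seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  A <- as_square_matrix(A, "A", check_nonneg = FALSE)
  B <- as_square_matrix(B, "B", check_nonneg = FALSE)
  B <- check_same_ids(A, B, "A", "B")
  n <- nrow(A)
  if (n < 4) abort("need at least 4 units")
  a <- offdiag(A); b <- offdiag(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("constant off-diagonal entries: Mantel r is undefined")
  }
  r <- stats::cor(a, b)
  if (exact) {
    if (n > 7) abort("exact enumeration is limited to n <= 7")
    pm <- all_perms(n)
    rp <- vapply(seq_len(nrow(pm)), function(k) {
      stats::cor(a, offdiag(B[pm[k, ], pm[k, ]]))
    }, numeric(1))
    tol <- 1e-12
    p <- switch(tail,
      upper = mean(rp >= r - tol),
      lower = mean(rp <= r + tol),
      two   = mean(abs(rp) >= abs(r) - tol))
    method <- "exact"
    n_used <- nrow(pm)
  } else {
    local_seed_if(seed)
    rp <- vapply(seq_len(n_perm), function(k) {
      pr <- sample.int(n)
      stats::cor(a, offdiag(B[pr, pr]))
    }, numeric(1))
    p <- perm_pvalue(r, rp, tail)
    method <- "permutation"
    n_used <- n_perm
  }
  out <- tibble::tibble(r = r, p = p, n_perm = n_used, tail = tail,
                        method = method)
  class(out) <- c("mantel_result", class(out))
  out
}

#' Partial Mantel test
#'
#' Correlation between the off-diagonals of `A` and `B` after residualising
#' both on `C` by simple linear regression (the partial correlation
#' r_AB.C). The null permutes rows and columns of the residualised `A`
#' matrix (residual-permutation scheme).
#'
#' @inheritParams mantel
#' @param C Conditioning matrix over the same ids. A constant `C`
#'   degenerates to the simple Mantel test with a warning.
#' @return A `mantel_result` tibble with an extra `flag` column
#'   (`"degenerate"` when the residuals are essentially constant).
#' @export
partial_mantel <- function(A, B, C, n_perm = 100000,
                           tail = c("upper", "lower", "two"), seed = NULL) {
  tail <- match.arg(tail)
  A <- as_square_matrix(A, "A", check_nonneg = FALSE)
  B <- as_square_matrix(B, "B", check_nonneg = FALSE)
  C <- as_square_matrix(C, "C", check_nonneg = FALSE)
  B <- check_same_ids(A, B, "A", "B")
  C <- check_same_ids(A, C, "A", "C")
  n <- nrow(A)
  if (n < 5) abort("need at least 5 units")
  a <- offdiag(A); b <- offdiag(B); cc <- offdiag(C)
  if (stats::sd(cc) == 0) {
    warn("conditioning matrix is constant; falling back to the simple Mantel test")
    return(mantel(A, B, n_perm = n_perm, tail = tail, seed = seed))
  }
  res_on <- function(y) stats::lm.fit(cbind(1, cc), y)$residuals
  ra <- res_on(a); rb <- res_on(b)
  if (stats::sd(ra) < 1e-12 || stats::sd(rb) < 1e-12) {
    out <- tibble::tibble(r = NA_real_, p = NA_real_, n_perm = 0L,
                          tail = tail, method = "residual-permutation",
                          flag = "degenerate")
    class(out) <- c("mantel_result", class(out))
    return(out)
  }
  r <- stats::cor(ra, rb)
  RA <- matrix(0, n, n, dimnames = dimnames(A))
  RA[lower.tri(RA)] <- ra
  RA <- RA + t(RA)
  local_seed_if(seed)
  rp <- vapply(seq_len(n_perm), function(k) {
    pr <- sample.int(n)
    stats::cor(offdiag(RA[pr, pr]), rb)
  }, numeric(1))
  out <- tibble::tibble(r = r, p = perm_pvalue(r, rp, tail),
                        n_perm = n_perm, tail = tail,
                        method = "residual-permutation", flag = "")
  class(out) <- c("mantel_result", class(out))
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.4g (%s, tail = %s, n = %d)\n",
              x$r, x$p, x$method, x$tail, x$n_perm))
  invisible(x)
}

#' Soil-difference matrix between individuals
#'
#' Entry (i, j) is the absolute difference of the site means of one soil
#' variable between the sites of individuals i and j (zero within a site);
#' individuals inherit their site's mean value.
#'
#' @param s Soil table (tibble with a `site` column, e.g. from
#'   [read_soil_table()]).
#' @param variable Name of the soil variable.
#' @param assignment Sample-to-site assignment: a named character vector
#'   (names = sample ids) or a data frame with columns `sample` and `site`.
#' @return A symmetric matrix over the samples.
#' @export
soil_difference_matrix <- function(s, variable, assignment) {
  if (!variable %in% names(s)) {
    abort(sprintf("soil variable '%s' not found", variable))
  }
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(as.character(assignment$site),
                                  assignment$sample)
  }
  miss <- setdiff(unique(assignment), s$site)
  if (length(miss) > 0) {
    abort(sprintf("site(s) missing from soil table: %s",
                  paste(miss, collapse = ", ")))
  }
  v <- stats::setNames(s[[variable]], s$site)[assignment]
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(names(assignment), names(assignment))
  d
}

#' Off-diagonal correlation of two pairwise-statistic matrices
#'
#' Ordinary Pearson correlation of the off-diagonal vectors with a two-sided
#' t-test p-value (no permutation) - the descriptive correlation typically
#' reported between, e.g., AFLP and MSAP pairwise Phi matrices.
#'
#' @param A,B Symmetric matrices over the same ids.
#' @return A one-row tibble: r, r_squared, p, n_pairs.
#' @export
offdiag_correlation <- function(A, B) {
  A <- as_square_matrix(A, "A", check_nonneg = FALSE, check_diag = FALSE)
  B <- as_square_matrix(B, "B", check_nonneg = FALSE, check_diag = FALSE)
  B <- check_same_ids(A, B, "A", "B")
  a <- offdiag(A); b <- offdiag(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("constant off-diagonal vector: correlation undefined")
  }
  ct <- stats::cor.test(a, b)
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n_pairs = length(a))
}

#' Chi-square test of association for a 2x2 table
#'
#' Pearson chi-square (no continuity correction) or the likelihood-ratio
#' G-statistic, both on 1 degree of freedom.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @param method `"pearson"` (default) or `"likelihood_ratio"`.
#' @return A one-row tibble: statistic, df, p, method.
#' @export
chi2_2x2 <- function(counts, method = c("pearson", "likelihood_ratio")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    abort("`counts` must be a nonnegative 2x2 matrix")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero marginal total: test undefined")
  }
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- if (method == "pearson") {
    sum((counts - E)^2 / E)
  } else {
    terms <- ifelse(counts > 0, counts * log(counts / E), 0)
    2 * sum(terms)
  }
  tibble::tibble(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = method)
}
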