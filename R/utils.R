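# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor pchisq pnorm quantile rbeta rbinom rnorm runif sd var
NULL

# lower-triangle (off-diagonal) vector of a square matrix
offdiag <- function(m) m[lower.tri(m)]

# validate / coerce a square symmetric nonnegative zero-diagonal matrix
as_square_matrix <- function(d, arg = "d", check_nonneg = TRUE,
                             check_diag = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    abort(sprintf("`%s` must be a square numeric matrix or a 'dist' object", arg))
  }
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    abort(sprintf("`%s` must be symmetric", arg))
  }
  if (check_diag && any(abs(diag(d)) > 1e-10)) {
    abort(sprintf("`%s` must have a zero diagonal", arg))
  }
  if (check_nonneg && any(d < -1e-12)) {
    abort(sprintf("`%s` must be nonnegative", arg))
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("u", seq_len(nrow(d)))
  }
  d
}

# set the RNG locally when a seed is supplied; no-op otherwise
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# deterministic sub-stream seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + k * 10007) %% 2147483629 + 1)
}

# add-one permutation p-value
perm_pvalue <- function(obs, perms, tail = c("upper", "lower", "two")) {
  tail <- match.arg(tail)
  perms <- perms[is.finite(perms)]
  tol <- 1e-12
  hits <- switch(tail,
    upper = sum(perms >= obs - tol),
    lower = sum(perms <= obs + tol),
    two   = sum(abs(perms) >= abs(obs) - tol)
  )
  (hits + 1) / (length(perms) + 1)
}

# align a per-sample label vector (possibly named) against sample ids
align_labels <- function(x, ids, arg = "groups") {
  if (is.factor(x)) x <- as.character(x)
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0) {
      abort(sprintf("`%s` has no entry for sample(s): %s", arg,
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    abort(sprintf("`%s` must have one label per sample (%d needed, %d given)",
                  arg, length(ids), length(x)))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing labels", arg))
  factor(as.character(x))
}

# all permutations of 1:n (used for exact Mantel enumeration, n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}
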