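# Shared fixtures, built in code.

# tiny hand-checkable band matrix
toy_band_matrix <- function() {
  x <- matrix(c(0L, 1L, 1L, 0L,
                1L, 1L, 0L, 0L,
                1L, 0L, NA, 1L,
                0L, 0L, 1L, 1L), nrow = 4, byrow = TRUE,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("L1", "L2", "L3", "L4")))
  band_matrix(x, habitat = c("HA", "HA", "HB", "HB"),
              site = c("sA", "sA", "sB", "sB"),
              fragment_size_bp = c(160L, 220L, 300L, 480L))
}

# band matrix with nested Balding-Nichols structure where the binary scores
# themselves follow the model (theta is their intraclass correlation)
bn_band_matrix <- function(n_habitats = 4, sites_per_habitat = 3,
                           individuals_per_site = 7, n_loci = 500,
                           theta_habitat = 0.10, theta_site = 0.05,
                           seed = 1) {
  withr::with_seed(seed, {
    hab <- rep(sprintf("H%d", seq_len(n_habitats)),
               each = sites_per_habitat * individuals_per_site)
    site <- rep(sprintf("s%02d", seq_len(n_habitats * sites_per_habitat)),
                each = individuals_per_site)
    pbar <- runif(n_loci, 0.05, 0.95)
    X <- matrix(0L, length(hab), n_loci)
    for (h in unique(hab)) {
      ph <- rbeta(n_loci, pbar * (1 - theta_habitat) / theta_habitat,
                  (1 - pbar) * (1 - theta_habitat) / theta_habitat)
      for (s in unique(site[hab == h])) {
        ps <- rbeta(n_loci, ph * (1 - theta_site) / theta_site,
                    (1 - ph) * (1 - theta_site) / theta_site)
        rows <- which(site == s)
        X[rows, ] <- matrix(rbinom(length(rows) * n_loci, 1,
                                   rep(ps, each = length(rows))),
                            nrow = length(rows))
      }
    }
    rownames(X) <- sprintf("i%03d", seq_len(nrow(X)))
    colnames(X) <- sprintf("L%04d", seq_len(n_loci))
    band_matrix(X, habitat = hab, site = site)
  })
}

# structureless binary data (panmixia null)
null_band_matrix <- function(n = 40, n_loci = 200, n_groups = 4, seed = 1) {
  withr::with_seed(seed, {
    f <- runif(n_loci, 0.2, 0.8)
    X <- matrix(rbinom(n * n_loci, 1, rep(f, each = n)), nrow = n)
    rownames(X) <- sprintf("i%03d", seq_len(n))
    colnames(X) <- sprintf("L%04d", seq_len(n_loci))
    g <- rep(sprintf("g%d", seq_len(n_groups)), length.out = n)
    band_matrix(X[order(g), , drop = FALSE], habitat = sort(g),
                site = sort(g))
  })
}

# random symmetric distance matrix from points in the plane
random_distance_matrix <- function(n, seed = 1, ids = sprintf("u%02d", seq_len(n))) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(2 * n), n, 2)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(ids, ids)
    d
  })
}

# Procrustes distance after optimal rotation/reflection/translation
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  k <- min(ncol(Xc), ncol(Yc))
  Xc <- Xc[, seq_len(k), drop = FALSE]
  Yc <- Yc[, seq_len(k), drop = FALSE]
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Xc - Yc %*% R)^2))
}
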