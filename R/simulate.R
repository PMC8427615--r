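# Synthetic AFLP + MSAP datasets with known ground truth: nested
# Balding-Nichols genetic structure (habitats, sites within habitats),
# planted selection outliers, methylation-susceptible loci of the obligate /
# facilitated / pure kinds, habitat-linked soil gradients, and scoring
# error. Every component draws from its own deterministic sub-stream of the
# master seed, so changing the number of loci does not reshuffle the soil
# draws.

#' Default per-habitat soil profile
#'
#' Habitat means for the fourteen soil variables, emulating a mosaic of a
#' seasonally waterlogged low-lying meadow (H1, pH ~8.2, moist,
#' nutrient-rich), strongly alkalinised saline patches (H2, pH >10, high EC
#' and ions), typical meadow steppe (H3) and an aerated sandy habitat (H4,
#' low ions).
#'
#' @return A tibble: habitat plus one column per variable in
#'   [soil_variables].
#' @export
default_soil_profile <- function() {
  tibble::tibble(
    habitat = c("H1", "H2", "H3", "H4"),
    moisture = c(25, 8, 15, 10),          # %
    pH = c(8.2, 10.3, 8.8, 8.3),
    EC = c(0.4, 2.5, 0.8, 0.3),           # mS/cm
    total_P = c(0.50, 0.30, 0.45, 0.35),  # g/kg
    total_N = c(1.8, 0.6, 1.5, 0.8),      # g/kg
    organic_matter = c(35, 10, 28, 12),   # g/kg
    NO3_N = c(12, 4, 9, 5),               # mg/kg
    NH4_N = c(8, 3, 6, 4),                # mg/kg
    Cl = c(30, 220, 60, 25),              # mg/L
    SO4 = c(40, 260, 80, 35),             # mg/L
    Na = c(80, 600, 150, 70),             # mg/L
    K = c(25, 35, 28, 20),                # mg/L
    Mg = c(45, 90, 55, 40),               # mg/L
    Ca = c(120, 180, 140, 160)            # mg/L
  )
}

#' Simulation parameters
#'
#' Defaults reproduce the study design the generator emulates: 4 habitats x
#' 3 sites x 6-8 individuals (80 total), 2,478 AFLP and 2,884 MSAP loci with
#' about two-thirds of the MSAP loci methylation-susceptible, moderate
#' nested differentiation, ~1% planted selection outliers, and a per-cell
#' scoring error of 1% (which makes the expected HpaII/MspI mismatch rate
#' due to error about 2%, a realistic duplicate-discordance figure).
#'
#' @param n_habitats,sites_per_habitat Design dimensions.
#' @param individuals_per_site Per-site sample sizes (recycled; default is
#'   the 6/7/7, 7/6/7, 7/6/7, 6/6/8 layout).
#' @param n_aflp,n_msap Locus counts.
#' @param msl_fraction Fraction of MSAP loci that are methylation-susceptible.
#' @param theta_habitat,theta_site Balding-Nichols Fst among habitats and
#'   among sites within habitats.
#' @param n_outliers,outlier_theta Count and dispersion of planted AFLP
#'   selection outliers.
#' @param epilocus_mix Proportions of obligate / facilitated / pure MSL.
#' @param env_effect Logistic slope (per SD of the driving soil variable)
#'   for pure epiloci.
#' @param env_driver Fix the driving soil variable of pure epiloci (default:
#'   drawn per locus).
#' @param facilitation P(methylated | underlying genotype = 1) for
#'   facilitated epiloci (the complement applies when the genotype is 0).
#' @param p_internal P((0,1) internal-methylation pattern | methylated);
#'   hemimethylated (1,0) otherwise.
#' @param error_rate Per-cell flip probability applied independently to both
#'   enzyme matrices.
#' @param soil_profile Habitat-mean soil table (see [default_soil_profile()]).
#' @param soil_sd_frac Within-habitat, between-site SD as a fraction of the
#'   habitat mean.
#' @param seed Master seed (integer).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_habitats = 4, sites_per_habitat = 3,
                       individuals_per_site = c(6, 7, 7, 7, 6, 7, 7, 6, 7, 6, 6, 8),
                       n_aflp = 2478, n_msap = 2884, msl_fraction = 2 / 3,
                       theta_habitat = 0.10, theta_site = 0.05,
                       n_outliers = 25, outlier_theta = 0.5,
                       epilocus_mix = c(obligate = 1 / 3, facilitated = 1 / 3,
                                        pure = 1 / 3),
                       env_effect = 2, env_driver = NULL, facilitation = 0.8,
                       p_internal = 0.5, error_rate = 0.01,
                       soil_profile = default_soil_profile(),
                       soil_sd_frac = 0.08, seed = 1L) {
  n_sites <- n_habitats * sites_per_habitat
  individuals_per_site <- rep_len(as.integer(individuals_per_site), n_sites)
  stopifnot(
    n_habitats >= 2, sites_per_habitat >= 1,
    all(individuals_per_site >= 2),
    n_aflp >= 1, n_msap >= 1,
    msl_fraction >= 0, msl_fraction <= 1,
    theta_habitat > 0, theta_habitat < 1, theta_site > 0, theta_site < 1,
    n_outliers >= 0, outlier_theta > 0, outlier_theta < 1,
    all(epilocus_mix >= 0), abs(sum(epilocus_mix) - 1) < 1e-8,
    facilitation >= 0, facilitation <= 1,
    p_internal >= 0, p_internal <= 1,
    error_rate >= 0, error_rate < 1,
    soil_sd_frac >= 0
  )
  if (nrow(soil_profile) < n_habitats) {
    abort("`soil_profile` must have one row per habitat")
  }
  structure(
    list(n_habitats = n_habitats, sites_per_habitat = sites_per_habitat,
         individuals_per_site = individuals_per_site,
         n_aflp = n_aflp, n_msap = n_msap, msl_fraction = msl_fraction,
         theta_habitat = theta_habitat, theta_site = theta_site,
         n_outliers = n_outliers, outlier_theta = outlier_theta,
         epilocus_mix = epilocus_mix, env_effect = env_effect,
         env_driver = env_driver, facilitation = facilitation,
         p_internal = p_internal, error_rate = error_rate,
         soil_profile = soil_profile, soil_sd_frac = soil_sd_frac,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Balding-Nichols draw of daughter frequencies around parent frequencies
bn_draw <- function(parent, theta) {
  if (theta < 1e-9) return(parent)
  rbeta(length(parent), parent * (1 - theta) / theta,
        (1 - parent) * (1 - theta) / theta)
}

# simulate a dominant band block with nested structure; returns values plus
# the realised site-level presence-allele frequencies
simulate_band_block <- function(meta, n_loci, theta_locus_habitat, theta_site,
                                pbar_range = c(0.05, 0.95)) {
  sites <- unique(meta$site)
  habitats_of_site <- meta$habitat[match(sites, meta$site)]
  habitats <- unique(meta$habitat)
  pbar <- runif(n_loci, pbar_range[1], pbar_range[2])
  ph <- matrix(NA_real_, n_loci, length(habitats),
               dimnames = list(NULL, habitats))
  th <- rep_len(theta_locus_habitat, n_loci)   # may vary per locus (outliers)
  for (h in habitats) {
    ph[, h] <- rbeta(n_loci, pbar * (1 - th) / th, (1 - pbar) * (1 - th) / th)
  }
  ps <- matrix(NA_real_, n_loci, length(sites), dimnames = list(NULL, sites))
  for (s in sites) ps[, s] <- bn_draw(ph[, habitats_of_site[sites == s]],
                                      theta_site)
  vals <- matrix(NA_integer_, nrow(meta), n_loci)
  for (s in sites) {
    i <- which(meta$site == s)
    pres <- 1 - (1 - ps[, s])^2           # dominant phenotype under HWE
    vals[i, ] <- matrix(rbinom(length(i) * n_loci, 1,
                               rep(pres, each = length(i))),
                        nrow = length(i), ncol = n_loci)
  }
  list(values = vals, site_freqs = ps, ancestral = pbar)
}

#' Simulate a joint AFLP + MSAP dataset with known truth
#'
#' Generates (i) AFLP bands with nested Balding-Nichols structure and
#' planted high-dispersion outlier loci; (ii) MSAP loci split into NML
#' (ordinary dominant bands, concordant across enzymes) and MSL whose
#' methylation indicator is obligate (deterministic in an underlying
#' genotype), facilitated (probabilistic given that genotype) or pure
#' (logistic in a soil variable); methylated cells render as (1,0) or (0,1),
#' unmethylated as (1,1), and scoring error flips each cell of both enzyme
#' matrices independently; (iii) a site-level soil table drawn around
#' habitat means; and (iv) a truth record for recovery tests.
#'
#' @param p A [sim_params] object.
#' @return A list of class `msapop_simulation`: `aflp` ([band_matrix]),
#'   `msap` ([msap_pair]), `soil` (tibble), `truth` (list: outlier_loci,
#'   msl_loci, epiloci tibble, thetas, error_rate, seed).
#' @export
simulate_dataset <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  n_sites <- p$n_habitats * p$sites_per_habitat
  habitat <- rep(sprintf("H%d", seq_len(p$n_habitats)),
                 each = p$sites_per_habitat)
  site <- sprintf("%s_s%d", habitat, rep(seq_len(p$sites_per_habitat),
                                         p$n_habitats))
  meta <- tibble::tibble(
    habitat = rep(habitat, p$individuals_per_site),
    site = rep(site, p$individuals_per_site))
  meta$sample <- sprintf("%s_i%02d", meta$site,
                         unlist(lapply(p$individuals_per_site, seq_len)))
  # --- soil (own sub-stream; drawn first because pure epiloci depend on it)
  withr::local_seed(derive_seed(p$seed, 3))
  prof <- p$soil_profile[seq_len(p$n_habitats), ]
  vars <- intersect(soil_variables, names(prof))
  soil <- purrr::map_dfr(seq_len(n_sites), function(si) {
    hmean <- prof[prof$habitat == habitat[si], vars]
    draws <- vapply(vars, function(v) {
      mu <- as.numeric(hmean[[v]])
      rnorm(1, mu, p$soil_sd_frac * abs(mu) + 1e-8)
    }, numeric(1))
    tibble::as_tibble(c(list(site = site[si]), as.list(draws)))
  })
  # --- AFLP (own sub-stream)
  withr::local_seed(derive_seed(p$seed, 1))
  outlier_idx <- if (p$n_outliers > 0) {
    sort(sample.int(p$n_aflp, min(p$n_outliers, p$n_aflp)))
  } else integer(0)
  theta_vec <- rep(p$theta_habitat, p$n_aflp)
  theta_vec[outlier_idx] <- p$outlier_theta
  aflp_block <- simulate_band_block(meta, p$n_aflp, theta_vec, p$theta_site)
  aflp_ids <- sprintf("A%04d", seq_len(p$n_aflp))
  sizes_aflp <- sample(150:500, p$n_aflp, replace = TRUE)
  vals <- aflp_block$values
  dimnames(vals) <- list(meta$sample, aflp_ids)
  aflp <- band_matrix(vals, habitat = meta$habitat, site = meta$site,
                      fragment_size_bp = sizes_aflp)
  # --- MSAP (own sub-stream)
  withr::local_seed(derive_seed(p$seed, 2))
  n_msl <- round(p$msl_fraction * p$n_msap)
  msl_idx <- sort(sample.int(p$n_msap, n_msl))
  nml_idx <- setdiff(seq_len(p$n_msap), msl_idx)
  msap_ids <- sprintf("M%04d", seq_len(p$n_msap))
  hpa <- msp <- matrix(NA_integer_, nrow(meta), p$n_msap,
                       dimnames = list(meta$sample, msap_ids))
  # NML: ordinary dominant bands, concordant across digests
  if (length(nml_idx) > 0) {
    nml_block <- simulate_band_block(meta, length(nml_idx), p$theta_habitat,
                                     p$theta_site)
    hpa[, nml_idx] <- nml_block$values
    msp[, nml_idx] <- nml_block$values
  }
  # MSL: methylation indicator by epilocus category
  categories <- sample(names(p$epilocus_mix), n_msl, replace = TRUE,
                       prob = p$epilocus_mix)
  geno_block <- simulate_band_block(meta, n_msl, p$theta_habitat, p$theta_site,
                                    pbar_range = c(0.2, 0.8))
  site_z <- scale(as.matrix(soil[vars]))   # site x variable, standardised
  rownames(site_z) <- soil$site
  drivers <- if (is.null(p$env_driver)) {
    sample(vars, n_msl, replace = TRUE)
  } else rep(p$env_driver, n_msl)
  slopes <- p$env_effect * sample(c(-1, 1), n_msl, replace = TRUE)
  baselines <- runif(n_msl, 0.3, 0.7)
  meth <- matrix(NA_integer_, nrow(meta), n_msl)
  for (k in seq_len(n_msl)) {
    g <- geno_block$values[, k]
    meth[, k] <- switch(categories[k],
      obligate = g,
      facilitated = rbinom(nrow(meta), 1,
                           ifelse(g == 1, p$facilitation, 1 - p$facilitation)),
      pure = {
        z <- site_z[meta$site, drivers[k]]
        rbinom(nrow(meta), 1,
               stats::plogis(stats::qlogis(baselines[k]) + slopes[k] * z))
      })
  }
  internal <- matrix(rbinom(length(meth), 1, p$p_internal), nrow(meth))
  hpa_msl <- ifelse(meth == 1, ifelse(internal == 1, 0L, 1L), 1L)
  msp_msl <- ifelse(meth == 1, ifelse(internal == 1, 1L, 0L), 1L)
  hpa[, msl_idx] <- hpa_msl
  msp[, msl_idx] <- msp_msl
  sizes_msap <- sample(150:500, p$n_msap, replace = TRUE)
  # --- scoring error (own sub-stream): independent per-cell flips
  withr::local_seed(derive_seed(p$seed, 4))
  if (p$error_rate > 0) {
    flip_h <- matrix(rbinom(length(hpa), 1, p$error_rate), nrow(hpa)) == 1
    flip_m <- matrix(rbinom(length(msp), 1, p$error_rate), nrow(msp)) == 1
    hpa[flip_h] <- 1L - hpa[flip_h]
    msp[flip_m] <- 1L - msp[flip_m]
  }
  pair <- msap_pair(
    band_matrix(hpa, habitat = meta$habitat, site = meta$site,
                fragment_size_bp = sizes_msap),
    band_matrix(msp, habitat = meta$habitat, site = meta$site,
                fragment_size_bp = sizes_msap))
  truth <- list(
    outlier_loci = aflp_ids[outlier_idx],
    msl_loci = msap_ids[msl_idx],
    nml_loci = msap_ids[nml_idx],
    epiloci = tibble::tibble(locus = msap_ids[msl_idx],
                             category = categories,
                             driver = ifelse(categories == "pure", drivers,
                                             NA_character_),
                             slope = ifelse(categories == "pure", slopes,
                                            NA_real_),
                             baseline = ifelse(categories == "pure", baselines,
                                               NA_real_)),
    theta_habitat = p$theta_habitat, theta_site = p$theta_site,
    outlier_theta = p$outlier_theta, error_rate = p$error_rate,
    aflp_site_freqs = aflp_block$site_freqs,
    seed = p$seed
  )
  structure(list(aflp = aflp, msap = pair, soil = soil, truth = truth,
                 params = p),
            class = "msapop_simulation")
}

#' @export
print.msapop_simulation <- function(x, ...) {
  cat(sprintf("<msapop_simulation> %d individuals (%d habitats x %d sites), %d AFLP + %d MSAP loci\n",
              n_samples(x$aflp), length(unique(x$aflp$samples$habitat)),
              length(unique(x$aflp$samples$site)), n_loci(x$aflp),
              n_loci(x$msap$hpa)))
  cat(sprintf("  planted: %d outliers, %d MSL (of which %d pure)\n",
              length(x$truth$outlier_loci), length(x$truth$msl_loci),
              sum(x$truth$epiloci$category == "pure")))
  invisible(x)
}

#' Simulate phenotypes driven by epiallele states
#'
#' trait = intercept + sum of coefficient x methylation indicator at the
#' chosen epiloci + Normal(0, noise_sd) noise.
#'
#' @param sim A `msapop_simulation`.
#' @param coefficients Named numeric vector (names = MSAP locus ids);
#'   default: -1.5 on up to five pure epiloci.
#' @param intercept Trait baseline (default 10).
#' @param noise_sd Residual SD (default 1).
#' @param seed Optional RNG seed.
#' @return A tibble: sample, habitat, site, trait.
#' @export
simulate_phenotypes <- function(sim, coefficients = NULL, intercept = 10,
                                noise_sd = 1, seed = NULL) {
  stopifnot(inherits(sim, "msapop_simulation"))
  scored <- score_methylation_states(sim$msap)
  if (is.null(coefficients)) {
    pure <- sim$truth$epiloci$locus[sim$truth$epiloci$category == "pure"]
    if (length(pure) == 0) abort("no pure epiloci; supply `coefficients`")
    pure <- utils::head(pure, 5)
    coefficients <- stats::setNames(rep(-1.5, length(pure)), pure)
  }
  miss <- setdiff(names(coefficients), scored$loci$locus)
  if (length(miss) > 0) abort(sprintf("unknown locus id(s): %s",
                                      paste(miss, collapse = ", ")))
  M <- scored$binary[, names(coefficients), drop = FALSE]
  M[is.na(M)] <- 0L
  local_seed_if(seed)
  trait <- intercept + as.vector(M %*% coefficients) +
    rnorm(nrow(M), 0, noise_sd)
  dplyr::mutate(scored$samples, trait = trait)
}
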