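# MSAP methylation-state scoring, error-rate estimation, MSL/NML
# classification and band filtering.
#
# Per individual and locus the (HpaII, MspI) band pattern maps to one of
# four states: (1,1) unmethylated, (1,0) hemimethylated (CHG methylation of
# the external cytosine), (0,1) internal cytosine (CG) methylation, (0,0)
# uninformative (full methylation or absence of the target). The binary
# view collapses these to unmethylated (0) / methylated (1) / missing.

#' @name methylation_states
#' @title Methylation state codes
#' @description Integer codes used in the `states` matrix of a
#'   `methylation_matrix`: 1 unmethylated, 2 hemimethylated, 3 internal
#'   cytosine methylation, 4 uninformative.
NULL

state_labels <- c("unmethylated", "hemimethylated",
                  "internal_methylated", "uninformative")

#' Score methylation states from a HpaII/MspI pair
#'
#' @param pair An aligned [msap_pair].
#' @return An object of class `methylation_matrix`: `states` (integer matrix,
#'   codes 1-4), `binary` (0 = unmethylated, 1 = methylated, `NA` otherwise),
#'   `observed` (logical matrix, both enzyme scores present) plus the sample
#'   and locus tables. A cell with a missing score in either digest is
#'   uninformative; an observed (0,0) is also uninformative for the binary
#'   view but still counts as a concordant observation when classifying loci.
#' @export
score_methylation_states <- function(pair) {
  if (!inherits(pair, "msap_pair")) abort("`pair` must be an msap_pair")
  h <- pair$hpa$values
  m <- pair$msp$values
  observed <- !is.na(h) & !is.na(m)
  states <- matrix(4L, nrow(h), ncol(h), dimnames = dimnames(h))
  states[observed & h == 1 & m == 1] <- 1L
  states[observed & h == 1 & m == 0] <- 2L
  states[observed & h == 0 & m == 1] <- 3L
  binary <- matrix(NA_integer_, nrow(h), ncol(h), dimnames = dimnames(h))
  binary[states == 1L] <- 0L
  binary[states == 2L | states == 3L] <- 1L
  structure(
    list(states = states, binary = binary, observed = observed,
         samples = pair$hpa$samples, loci = pair$hpa$loci),
    class = "methylation_matrix"
  )
}

#' @export
print.methylation_matrix <- function(x, ...) {
  tab <- table(factor(state_labels[x$states], levels = state_labels))
  cat(sprintf("<methylation_matrix> %d samples x %d loci\n",
              nrow(x$states), ncol(x$states)))
  print(round(tab / length(x$states), 3))
  invisible(x)
}

#' Proportions of the four methylation states
#'
#' @param m A `methylation_matrix`.
#' @param by Optional per-sample grouping label (`"habitat"`, `"site"`, or a
#'   vector); `NULL` pools all individuals.
#' @return A tibble of state proportions (per group when `by` is given).
#' @export
methylation_state_profile <- function(m, by = NULL) {
  stopifnot(inherits(m, "methylation_matrix"))
  grp <- if (is.null(by)) {
    rep("all", nrow(m$states))
  } else if (is.character(by) && length(by) == 1 && by %in% c("habitat", "site")) {
    m$samples[[by]]
  } else {
    as.character(align_labels(by, m$samples$sample, "by"))
  }
  purrr::map_dfr(split(seq_len(nrow(m$states)), grp), function(i) {
    tab <- tabulate(m$states[i, , drop = FALSE], nbins = 4)
    tibble::tibble(state = state_labels, proportion = tab / sum(tab))
  }, .id = "group")
}

#' Duplicate-based scoring error rate
#'
#' Pools discordant cells over repeated, independent runs of the same
#' individuals: `epsilon` is the per-individual, per-locus probability that
#' two runs disagree, the natural scale for the MSL classification threshold.
#'
#' @param replicate_pairs A list; each element is a list or pair of two
#'   [band_matrix] objects over identical samples and loci.
#' @return A list of class `error_rate_estimate` with `epsilon`,
#'   `n_duplicate_pairs` and `n_comparisons`.
#' @export
estimate_error_rate <- function(replicate_pairs) {
  if (inherits(replicate_pairs, "band_matrix")) {
    abort("`replicate_pairs` must be a list of pairs of band matrices")
  }
  if (inherits(replicate_pairs[[1]], "band_matrix")) {
    replicate_pairs <- list(replicate_pairs)
  }
  mismatches <- 0L
  comparisons <- 0L
  for (rp in replicate_pairs) {
    a <- rp[[1]]; b <- rp[[2]]
    stopifnot(inherits(a, "band_matrix"), inherits(b, "band_matrix"))
    if (!identical(dimnames(a$values), dimnames(b$values))) {
      abort("replicate pair has mismatched sample or locus ids")
    }
    ok <- !is.na(a$values) & !is.na(b$values)
    mismatches <- mismatches + sum(a$values[ok] != b$values[ok])
    comparisons <- comparisons + sum(ok)
  }
  if (comparisons == 0) abort("no comparable (mutually observed) cells")
  structure(
    list(epsilon = mismatches / comparisons,
         n_duplicate_pairs = length(replicate_pairs),
         n_comparisons = comparisons),
    class = "error_rate_estimate"
  )
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("<error_rate_estimate> epsilon = %.4g (%d pairs, %d comparisons)\n",
              x$epsilon, x$n_duplicate_pairs, x$n_comparisons))
  invisible(x)
}

#' Classify loci as methylation-susceptible (MSL) or nonmethylated (NML)
#'
#' A locus is MSL when its discordance - the fraction of individuals with
#' mismatched HpaII/MspI scores among individuals where both scores were
#' observed - strictly exceeds `epsilon`, the expected per-individual
#' mismatch probability due to scoring error. An observed (0,0) pattern is a
#' legitimate concordant score and stays in the denominator; only cells with
#' a missing input score are dropped.
#'
#' @param m A `methylation_matrix` from [score_methylation_states()].
#' @param epsilon Mismatch-probability threshold; either a number or an
#'   `error_rate_estimate`. When omitted, 0.05 is used and announced loudly.
#' @return A tibble with one row per locus: locus, discordance,
#'   n_informative, label (`"MSL"`/`"NML"`), threshold_used, flag
#'   (`"no_informative"` for loci with no observed individuals).
#' @export
classify_loci <- function(m, epsilon = NULL) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(epsilon)) {
    inform("classify_loci(): no error rate supplied; using default epsilon = 0.05")
    epsilon <- 0.05
  }
  if (inherits(epsilon, "error_rate_estimate")) epsilon <- epsilon$epsilon
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon >= 1) {
    abort("`epsilon` must be in [0, 1)")
  }
  disc <- m$states == 2L | m$states == 3L
  n_inf <- colSums(m$observed)
  n_disc <- colSums(disc & m$observed)
  discordance <- ifelse(n_inf > 0, n_disc / n_inf, 0)
  tibble::tibble(
    locus = m$loci$locus,
    discordance = unname(discordance),
    n_informative = unname(as.integer(n_inf)),
    label = unname(ifelse(n_inf > 0 & discordance > epsilon, "MSL", "NML")),
    threshold_used = epsilon,
    flag = unname(ifelse(n_inf == 0, "no_informative", ""))
  )
}

#' Split scored MSAP data into MSL and NML band matrices
#'
#' MSL loci are carried forward as the binary methylated/unmethylated view;
#' NML loci behave as ordinary dominant bands and are taken from the MspI
#' profile.
#'
#' @param pair The [msap_pair] that was scored.
#' @param m The `methylation_matrix` from [score_methylation_states()].
#' @param classification Output of [classify_loci()].
#' @param msl_source `"binary"` (default) or `"hpa"` to use the raw HpaII
#'   banding for MSL loci instead of the methylation indicator.
#' @return A list with [band_matrix] elements `msl` and `nml`.
#' @export
split_msap <- function(pair, m, classification, msl_source = c("binary", "hpa")) {
  msl_source <- match.arg(msl_source)
  msl_ids <- classification$locus[classification$label == "MSL"]
  nml_ids <- classification$locus[classification$label == "NML"]
  msl_vals <- if (msl_source == "binary") {
    m$binary[, msl_ids, drop = FALSE]
  } else {
    pair$hpa$values[, msl_ids, drop = FALSE]
  }
  sizes <- pair$hpa$loci$size_bp
  size_of <- function(ids) {
    if (all(is.na(sizes))) NULL else sizes[match(ids, pair$hpa$loci$locus)]
  }
  list(
    msl = band_matrix(msl_vals, habitat = m$samples$habitat,
                      site = m$samples$site, fragment_size_bp = size_of(msl_ids)),
    nml = band_matrix(pair$msp$values[, nml_ids, drop = FALSE],
                      habitat = m$samples$habitat, site = m$samples$site,
                      fragment_size_bp = size_of(nml_ids))
  )
}

#' Apply standard band filters
#'
#' Removes loci outside the scorable fragment-size window, loci carried by
#' fewer than `min_carriers` individuals, and loci where exactly one
#' individual deviates from the consensus state (singletons). The first rule
#' triggered is recorded per removed locus.
#'
#' @param b A [band_matrix].
#' @param min_carriers Minimum number of presence calls (default 4).
#' @param size_range Two-element bp window (default 150-500); skipped with a
#'   warning when fragment sizes are unknown.
#' @param drop_singleton_nonconsensus Drop single-deviant loci (default TRUE).
#' @return The filtered [band_matrix]; removed loci and reasons are in
#'   `attr(, "filter_log")` (tibble: locus, reason).
#' @export
apply_band_filters <- function(b, min_carriers = 4, size_range = c(150, 500),
                               drop_singleton_nonconsensus = TRUE) {
  stopifnot(inherits(b, "band_matrix"))
  reason <- rep(NA_character_, n_loci(b))
  if (!is.null(size_range)) {
    if (all(is.na(b$loci$size_bp))) {
      warn("fragment sizes unknown; size-range filter skipped")
    } else {
      out <- !is.na(b$loci$size_bp) &
        (b$loci$size_bp < size_range[1] | b$loci$size_bp > size_range[2])
      reason[out & is.na(reason)] <- "size_range"
    }
  }
  carriers <- colSums(b$values == 1L, na.rm = TRUE)
  reason[carriers < min_carriers & is.na(reason)] <- "min_carriers"
  if (isTRUE(drop_singleton_nonconsensus)) {
    n_obs <- colSums(!is.na(b$values))
    n_one <- colSums(b$values == 1L, na.rm = TRUE)
    n_zero <- n_obs - n_one
    singleton <- (n_one == 1L & n_zero > 1L) | (n_zero == 1L & n_one > 1L)
    reason[singleton & is.na(reason)] <- "singleton"
  }
  drop <- !is.na(reason)
  if (all(drop)) abort("all loci removed by band filters")
  log <- tibble::tibble(locus = b$loci$locus[drop], reason = reason[drop])
  out <- b[, !drop]
  attr(out, "filter_log") <- log
  out
}
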