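#' Band-presence matrix for dominant markers
#'
#' The universal unit of analysis: an individuals-by-loci matrix of binary
#' band scores (0 = absent, 1 = present, `NA` = missing), together with the
#' habitat and site label of every individual and, optionally, per-locus
#' fragment sizes in base pairs.
#'
#' @param values Integer or numeric matrix with entries in \{0, 1, `NA`\};
#'   rownames are sample ids, colnames are locus ids (generated when absent).
#' @param habitat Per-sample habitat labels (recycled names checked against
#'   sample ids when named).
#' @param site Per-sample site labels; each site must belong to exactly one
#'   habitat.
#' @param fragment_size_bp Optional per-locus fragment size (bp).
#'
#' @return An object of class `band_matrix`: a list with elements `values`
#'   (the scored matrix), `samples` (tibble: sample, habitat, site) and
#'   `loci` (tibble: locus, size_bp).
#' @export
#'
#' @examples
#' x <- matrix(c(0, 1, 1, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("L1", "L2")))
#' band_matrix(x, habitat = c("H1", "H1"), site = c("s1", "s1"))
band_matrix <- function(values, habitat, site, fragment_size_bp = NULL) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (nrow(values) < 1 || ncol(values) < 1) abort("empty band matrix")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("L%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(rownames(values)[duplicated(rownames(values))]),
                        collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) abort("duplicate locus ids")
  bad <- !(values %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    ij <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1, ]
    abort(sprintf("invalid band score at sample '%s', locus '%s' (only 0, 1, missing allowed)",
                  rownames(values)[ij[1]], colnames(values)[ij[2]]))
  }
  ids <- rownames(values)
  habitat <- as.character(align_labels(habitat, ids, "habitat"))
  site <- as.character(align_labels(site, ids, "site"))
  s2h <- tapply(habitat, site, function(h) length(unique(h)))
  if (any(s2h > 1)) {
    abort(sprintf("site(s) %s span more than one habitat",
                  paste(names(s2h)[s2h > 1], collapse = ", ")))
  }
  if (!is.null(fragment_size_bp)) {
    if (length(fragment_size_bp) != ncol(values)) {
      abort("`fragment_size_bp` must have one entry per locus")
    }
    fragment_size_bp <- as.integer(fragment_size_bp)
  }
  structure(
    list(
      values = values,
      samples = tibble::tibble(sample = ids, habitat = habitat, site = site),
      loci = tibble::tibble(
        locus = colnames(values),
        size_bp = if (is.null(fragment_size_bp)) NA_integer_ else fragment_size_bp
      )
    ),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("<band_matrix> %d samples x %d loci\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  habitats: %s\n", paste(unique(x$samples$habitat), collapse = ", ")))
  cat(sprintf("  sites: %d; missing cells: %d (%.2f%%)\n",
              length(unique(x$samples$site)), sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!all(is.na(x$loci$size_bp))) cat("  fragment sizes: recorded\n")
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$values)

#' Number of samples / loci in a band matrix
#' @param b A [band_matrix].
#' @return Integer count.
#' @export
n_samples <- function(b) nrow(b$values)

#' @rdname n_samples
#' @export
n_loci <- function(b) ncol(b$values)

#' Subset a band matrix
#'
#' @param x A [band_matrix].
#' @param i Sample index (ids, logical or integer).
#' @param j Locus index.
#' @param ... Unused.
#' @return A [band_matrix] restricted to the selected samples and loci.
#' @export
`[.band_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  keep_s <- match(rownames(v), x$samples$sample)
  keep_l <- match(colnames(v), x$loci$locus)
  band_matrix(v,
              habitat = x$samples$habitat[keep_s],
              site = x$samples$site[keep_s],
              fragment_size_bp = if (all(is.na(x$loci$size_bp))) NULL
                                 else x$loci$size_bp[keep_l])
}

#' Long-format view of a band matrix
#'
#' @param x A [band_matrix].
#' @param ... Unused.
#' @return A tibble with one row per sample-locus cell: sample, habitat,
#'   site, locus, score.
#' @method as_tibble band_matrix
#' @export
as_tibble.band_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "locus", values_to = "score")
  dplyr::left_join(long, x$samples, by = "sample") |>
    dplyr::select("sample", "habitat", "site", "locus", "score")
}

#' Paired HpaII/MspI MSAP profiles
#'
#' Binds the two methylation-sensitive digests of the same individuals into
#' one aligned object. Samples and loci are matched by id (order-independent);
#' the HpaII ordering is kept.
#'
#' @param hpa [band_matrix] from the EcoRI/HpaII digests.
#' @param msp [band_matrix] from the EcoRI/MspI digests.
#' @return An object of class `msap_pair` with aligned `hpa` and `msp`.
#' @export
msap_pair <- function(hpa, msp) {
  stopifnot(inherits(hpa, "band_matrix"), inherits(msp, "band_matrix"))
  only_h <- setdiff(hpa$samples$sample, msp$samples$sample)
  only_m <- setdiff(msp$samples$sample, hpa$samples$sample)
  if (length(only_h) + length(only_m) > 0) {
    abort(sprintf(
      "sample sets differ between digests: only in hpa: %s; only in msp: %s",
      paste(only_h, collapse = ", "), paste(only_m, collapse = ", ")))
  }
  if (!setequal(hpa$loci$locus, msp$loci$locus)) {
    abort("locus sets differ between the HpaII and MspI matrices")
  }
  msp <- msp[hpa$samples$sample, hpa$loci$locus]
  structure(list(hpa = hpa, msp = msp), class = "msap_pair")
}

#' @export
print.msap_pair <- function(x, ...) {
  cat(sprintf("<msap_pair> %d samples x %d loci (HpaII + MspI digests)\n",
              n_samples(x$hpa), n_loci(x$hpa)))
  invisible(x)
}
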