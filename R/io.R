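# Readers and writers for scored marker tables and soil data.
#
# Wide CSV layout: header `sample,habitat,site,<locus ids...>`, one row per
# individual, scores in {0,1} with "?", "NA" or an empty cell for missing.
# An optional `#size` row directly after the header carries per-locus
# fragment sizes (bp). GenAlEx-style CSV (two numeric/label header rows,
# columns sample,pop,<loci>) is supported read-only.

#' The canonical soil variables
#'
#' Names of the fourteen site-level soil variables used throughout the
#' package: moisture, pH, electrical conductivity, total phosphorus, total
#' nitrogen, organic matter, nitrate and ammonium nitrogen, and the major
#' ions.
#' @export
soil_variables <- c(
  "moisture", "pH", "EC", "total_P", "total_N", "organic_matter",
  "NO3_N", "NH4_N", "Cl", "SO4", "Na", "K", "Mg", "Ca"
)

default_missing_codes <- c("?", "NA", "")

read_csv_strict <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = ",", quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2) abort(sprintf("empty or header-only file: %s", path))
  if (length(unique(nf)) != 1) {
    abort(sprintf("ragged rows in %s: rows have %s fields", path,
                  paste(unique(nf), collapse = "/")))
  }
  utils::read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
}

parse_scores <- function(raw, sample_ids, locus_ids, missing_codes, path) {
  m <- as.matrix(raw)
  m[m %in% missing_codes] <- NA_character_
  bad <- !is.na(m) & !(m %in% c("0", "1"))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "invalid token '%s' at sample '%s', locus '%s' in %s (allowed: 0, 1, %s)",
      m[ij[1], ij[2]], sample_ids[ij[1]], locus_ids[ij[2]], path,
      paste(shQuote(setdiff(missing_codes, "")), collapse = ", ")))
  }
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(sample_ids, locus_ids))
  out
}

#' Read a scored band matrix
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` (default; sample,habitat,site + loci columns,
#'   optional `#size` row) or `"genalex"` (GenAlEx export with two extra
#'   header rows and a `pop` column; the habitat is taken as the part of the
#'   pop label before the first `_` or `-`, or the whole label).
#' @param missing_codes Cell tokens treated as missing.
#' @return A [band_matrix].
#' @export
read_band_matrix <- function(path, dialect = c("wide", "genalex"),
                             missing_codes = default_missing_codes) {
  dialect <- match.arg(dialect)
  raw <- read_csv_strict(path)
  if (dialect == "wide") {
    header <- as.character(raw[1, ])
    if (length(header) < 4 || !identical(tolower(header[1:3]),
                                         c("sample", "habitat", "site"))) {
      abort(sprintf("%s: wide dialect needs columns sample,habitat,site then loci", path))
    }
    loci <- header[-(1:3)]
    body <- raw[-1, , drop = FALSE]
    sizes <- NULL
    if (nrow(body) > 0 && body[1, 1] == "#size") {
      sv <- as.character(body[1, -(1:3)])
      sv[sv %in% missing_codes] <- NA_character_
      sizes <- as.integer(sv)
      body <- body[-1, , drop = FALSE]
    }
    if (nrow(body) == 0) abort(sprintf("no data rows in %s", path))
    ids <- as.character(body[, 1])
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate sample id(s) in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    vals <- parse_scores(body[, -(1:3), drop = FALSE], ids, loci,
                         missing_codes, path)
    band_matrix(vals, habitat = as.character(body[, 2]),
                site = as.character(body[, 3]), fragment_size_bp = sizes)
  } else {
    if (nrow(raw) < 4) abort(sprintf("%s: too short for a GenAlEx file", path))
    header <- as.character(raw[3, ])
    if (length(header) < 3) abort(sprintf("%s: GenAlEx layout needs sample,pop,loci", path))
    loci <- header[-(1:2)]
    body <- raw[-(1:3), , drop = FALSE]
    ids <- as.character(body[, 1])
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate sample id(s) in %s", path))
    }
    pop <- as.character(body[, 2])
    habitat <- sub("[_-].*$", "", pop)
    vals <- parse_scores(body[, -(1:2), drop = FALSE], ids, loci,
                         missing_codes, path)
    band_matrix(vals, habitat = habitat, site = pop)
  }
}

#' Write a band matrix as wide CSV
#'
#' Missing scores are written as `?`; fragment sizes, when recorded, go into
#' a `#size` row after the header so that `read_band_matrix()` round-trips
#' the object (and the file) exactly.
#'
#' @param b A [band_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(b, path) {
  stopifnot(inherits(b, "band_matrix"))
  v <- matrix(as.character(b$values), nrow(b$values))
  v[is.na(v)] <- "?"
  lines <- c(
    paste(c("sample", "habitat", "site", b$loci$locus), collapse = ","),
    if (!all(is.na(b$loci$size_bp))) {
      paste(c("#size", "", "", ifelse(is.na(b$loci$size_bp), "?",
                                      b$loci$size_bp)), collapse = ",")
    },
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(b$samples$sample[i], b$samples$habitat[i], b$samples$site[i],
              v[i, ]), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read paired HpaII/MspI matrices
#'
#' Samples and loci are matched by id, so file row/column order is
#' irrelevant; a sample or locus present in only one file is an alignment
#' error naming the offenders.
#'
#' @param hpa_path,msp_path CSV paths for the two digests.
#' @inheritParams read_band_matrix
#' @return An [msap_pair].
#' @export
read_msap_pair <- function(hpa_path, msp_path, dialect = c("wide", "genalex"),
                           missing_codes = default_missing_codes) {
  dialect <- match.arg(dialect)
  hpa <- read_band_matrix(hpa_path, dialect, missing_codes)
  msp <- read_band_matrix(msp_path, dialect, missing_codes)
  msap_pair(hpa, msp)
}

#' Read a site-by-variable soil table
#'
#' Accepts one row per site or one row per replicate sample (replicates are
#' averaged by site). Variable names are normalised to [soil_variables] by a
#' case/punctuation-insensitive match; unknown variables are kept under their
#' given name with a warning.
#'
#' @param path CSV path with a `site` column and one column per variable.
#' @return A tibble with one row per site.
#' @export
read_soil_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df)[1] <- trimws(names(df)[1])
  if (!"site" %in% tolower(names(df))) {
    abort(sprintf("%s: no 'site' column", path))
  }
  names(df)[tolower(names(df)) == "site"][1] <- "site"
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  canon <- stats::setNames(soil_variables, norm(soil_variables))
  # common aliases seen in field tables
  canon <- c(canon,
             electricalconductivity = "EC", conductivity = "EC",
             totalphosphorus = "total_P", totalp = "total_P",
             totalnitrogen = "total_N", totaln = "total_N",
             organicmatter = "organic_matter",
             no3nitrogen = "NO3_N", no3n = "NO3_N",
             nh4nitrogen = "NH4_N", nh4n = "NH4_N",
             cl = "Cl", so4 = "SO4", na = "Na", k = "K", mg = "Mg", ca = "Ca",
             ph = "pH", moisture = "moisture")
  vars <- setdiff(names(df), "site")
  mapped <- canon[norm(vars)]
  unknown <- vars[is.na(mapped)]
  if (length(unknown) > 0) {
    warn(sprintf("unrecognised soil variable(s) kept as given: %s",
                 paste(unknown, collapse = ", ")))
  }
  names(df)[match(vars, names(df))] <- ifelse(is.na(mapped), vars, mapped)
  for (v in setdiff(names(df), "site")) df[[v]] <- as.numeric(df[[v]])
  if (anyNA(df[setdiff(names(df), "site")])) {
    abort(sprintf("%s: non-numeric or missing soil values", path))
  }
  df$site <- as.character(df$site)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$site),
    dplyr::across(dplyr::everything(), mean), .groups = "drop")
  out
}

#' @importFrom rlang .data
NULL
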