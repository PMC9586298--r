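# Tabular readers/writers.  TSV for count matrices, sample sheets, BGC
# catalogs and result tables; CSV for the LC-MS feature table (the
# upstream feature extractor's convention).  Sample ids are the join key
# everywhere; nothing is joined positionally.

#' Read a gene count matrix
#'
#' Expects a TSV whose first column holds gene ids (namespaced as
#' `genome:gene`) and whose remaining columns are samples.  All counts
#' must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix (genes x samples) with dimnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: expected gene id column plus >=1 sample", path),
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicated gene id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp)) {
    stop(sprintf("%s: duplicated sample id(s) in header", path), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-integer or negative count '%s' at row %d (gene %s), column %s",
                   path, m[bad[1], j], bad[1], ids[bad[1]], samp[j]),
           call. = FALSE)
    }
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, samp)
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Integer matrix with gene-id rownames and sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a sample sheet into a study design
#'
#' Expects a TSV with columns `sample_id`, `condition`, `genotype`,
#' `replicate` and optionally `series`.  Conditions are letter-set strings
#' over `"BFK"` (order-insensitive) or `"media"`.
#'
#' @param path Path to a TSV file.
#' @return A [study_design()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "genotype", "replicate")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  series <- if ("series" %in% colnames(df)) df$series else NULL
  tryCatch(
    study_design(df$sample_id, df$condition, df$genotype, df$replicate, series),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Write a study design as a sample sheet TSV
#'
#' @param design A [study_design()].
#' @param path Output path.
#' @export
write_sample_sheet <- function(design, path) {
  .write_tsv(design[, c("sample_id", "condition", "genotype",
                        "replicate", "series")], path)
}

#' Construct an LC-MS molecular feature table
#'
#' @param areas Numeric matrix of peak areas (features x samples),
#'   non-negative, with feature rownames and sample colnames.
#' @param mw Optional numeric vector of calculated molecular weights
#'   (Daltons) per feature; `NA` allowed.
#' @param rt Optional numeric vector of retention times (minutes); `NA`
#'   allowed.
#' @return A `feature_table` (list with elements `areas`, `mw`, `rt`).
#' @export
feature_table <- function(areas, mw = NULL, rt = NULL) {
  stopifnot(is.matrix(areas), !is.null(rownames(areas)),
            !is.null(colnames(areas)))
  if (anyDuplicated(rownames(areas))) {
    stop("duplicated feature id(s)", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("peak areas must be finite and >= 0", call. = FALSE)
  }
  n <- nrow(areas)
  if (is.null(mw)) mw <- rep(NA_real_, n)
  if (is.null(rt)) rt <- rep(NA_real_, n)
  stopifnot(length(mw) == n, length(rt) == n)
  structure(list(areas = areas, mw = as.numeric(mw), rt = as.numeric(rt)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  invisible(x)
}

#' Read an LC-MS feature table
#'
#' Expects a CSV with columns `feature_id`, `mw`, `rt`, then one column of
#' peak areas per sample.  Missing `mw`/`rt` are allowed; missing or
#' negative areas are an error (the upstream feature extractor gap-fills).
#'
#' @param path Path to a CSV file.
#' @param design Optional [study_design()]; when supplied, sample columns
#'   not present in the design raise an error naming them.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, design = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("feature_id", "mw", "rt")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ids <- df$feature_id
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicated feature id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  samp <- setdiff(colnames(df), need)
  if (length(samp) == 0) stop(sprintf("%s: no sample columns", path),
                              call. = FALSE)
  if (!is.null(design)) {
    unknown <- setdiff(samp, design$sample_id)
    if (length(unknown) > 0) {
      stop(sprintf("%s: sample column(s) not in the study design: %s",
                   path, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  areas <- matrix(NA_real_, nrow(df), length(samp),
                  dimnames = list(ids, samp))
  for (j in seq_along(samp)) {
    raw <- df[[samp[j]]]
    empty <- which(is.na(raw) | raw == "")
    if (length(empty) > 0) {
      stop(sprintf("%s: empty area cell at row %d (feature %s), column %s",
                   path, empty[1], ids[empty[1]], samp[j]), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric area '%s' at row %d (feature %s), column %s",
                   path, raw[bad[1]], bad[1], ids[bad[1]], samp[j]),
           call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      stop(sprintf("%s: negative area %s at row %d (feature %s), column %s",
                   path, raw[neg[1]], neg[1], ids[neg[1]], samp[j]),
           call. = FALSE)
    }
    areas[, j] <- v
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  feature_table(areas, mw = num_or_na(df$mw), rt = num_or_na(df$rt))
}

#' Write a feature table to CSV
#'
#' @param ft A [feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(feature_id = rownames(ft$areas),
                   mw = .fmt_num(ft$mw), rt = .fmt_num(ft$rt),
                   apply(ft$areas, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a BGC region catalog
#'
#' Expects a TSV with columns `region_id`, `genome`, `product_label`,
#' `gene_id` — one row per member gene, grouped into regions preserving
#' gene order.  A gene may belong to at most one region.  An empty file
#' yields an empty catalog.
#'
#' @param path Path to a TSV file.
#' @return A `bgc_catalog` data frame (columns as above).
#' @export
read_bgc_catalog <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    df <- data.frame(region_id = character(0), genome = character(0),
                     product_label = character(0), gene_id = character(0),
                     stringsAsFactors = FALSE)
    class(df) <- c("bgc_catalog", "data.frame")
    return(df)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "genome", "product_label", "gene_id")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bgc_catalog(df)
}

#' Construct/validate a BGC catalog
#'
#' @param df Data frame with columns `region_id`, `genome`,
#'   `product_label`, `gene_id` (one row per member gene).
#' @return A validated `bgc_catalog`.
#' @export
bgc_catalog <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    two <- unique(df$region_id[df$gene_id %in% dup])
    stop(sprintf("gene(s) %s listed under more than one region (%s)",
                 paste(unique(dup), collapse = ", "),
                 paste(two, collapse = ", ")), call. = FALSE)
  }
  per_region_genome <- tapply(df$genome, df$region_id,
                              function(g) length(unique(g)))
  if (any(per_region_genome > 1)) {
    stop("a region must belong to a single genome", call. = FALSE)
  }
  class(df) <- c("bgc_catalog", "data.frame")
  df
}

#' Write a BGC catalog to TSV
#' @param catalog A `bgc_catalog`.
#' @param path Output path.
#' @export
write_bgc_catalog <- function(catalog, path) {
  .write_tsv(as.data.frame(catalog), path)
}

#' Write a result table to TSV
#'
#' Numeric columns are written with 6 significant digits; re-reading
#' reproduces values to that precision.  An empty table writes a
#' header-only file.
#'
#' @param table A data frame.
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  .write_tsv(as.data.frame(table), path)
}

#' Read a result table written by [write_table()]
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.fmt_num <- function(x) {
  out <- as.character(signif(x, 6))
  out[is.na(x)] <- NA_character_
  out
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

# Flat key-value run configuration -------------------------------------

#' Default generator/pipeline configuration
#'
#' Returns the flat key-value configuration with every tunable used across
#' the pipeline.  See the package vignette for the rationale behind each
#' default.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    # study layout
    n_replicates = 5,
    # molecular features
    n_features = 1000,
    n_media = 100,
    n_pair_only = 75,
    n_triple_only = 18,
    n_kec_dependent = 20,
    effect_presence = 3,
    p_background_effect = 0.1,
    background_effect_sd = 0.5,
    baseline_meanlog = 11.5,
    baseline_sdlog = 1,
    noise_sigma = 0.5,
    detection_floor = 1000,
    # transcriptome
    n_genes = 500,
    n_bgc = 5,
    bgc_size = 10,
    gene_baseline_meanlog = 4,
    gene_baseline_sdlog = 1,
    nb_dispersion = 0.1,
    library_size = 1e6,
    library_size_spread = 0.5,
    # analysis tunables
    cpm_method = "total",
    lfc_input = "counts",
    lfc_prior = 0.5,
    lfc_center = FALSE,
    filter_percentile = 2.5,
    coding = "containment",
    baseline = "include",
    log_offset = 1,
    tail_percentile = 2.5,
    presence_rule = "median",
    pca_scale = "unit_variance",
    linkage = "average"
  )
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Keys not in
#' [default_config()] are an error (config drift detection); keys not
#' present keep their defaults.
#'
#' @param path Path to a config file.
#' @return Named list merging the file over [default_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  allowed <- c(names(cfg), "planted_lfc", "planted_lfc_condition",
               "planted_lfc_genome")
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("%s: cannot parse line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% allowed) {
      stop(sprintf("%s: unknown configuration key '%s'", path, key),
           call. = FALSE)
    }
    pieces <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(pieces))
    cfg[[key]] <- if (!anyNA(num)) num
                  else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                  else val
  }
  cfg
}
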