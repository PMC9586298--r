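# BGC-level expression quantification: CPM, per-genome low-expression
# filtering, pseudocount (Psi) log2 fold changes, BGC-wise aggregation,
# and wild-type vs knockout comparisons.
#
# Gene ids are namespaced "genome:gene"; in this pipeline genomes are
# named by their species letter (B, F, K), so per-genome library sizes and
# coculture-vs-monoculture contrasts can be derived directly from the
# count matrix and the study design.

#' Genome of each gene in a count matrix
#' @param gene_ids Character vector of `genome:gene` ids.
#' @return Character vector of genome names.
#' @export
gene_genome <- function(gene_ids) {
  out <- sub(":.*$", "", gene_ids)
  if (any(out == gene_ids)) {
    stop("gene ids must be namespaced as genome:gene; offending id(s): ",
         paste(utils::head(gene_ids[out == gene_ids], 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Counts per million
#'
#' Scales each sample column of a count matrix to counts per million:
#' `cpm[g, s] = counts[g, s] / colsum(s) * 1e6`.  Plain library-size
#' scaling; no between-sample normalisation factors.
#'
#' @param counts Integer matrix (genes x samples).
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total counts: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Remove genes with very low expression
#'
#' For each genome, takes every gene's maximum CPM across all samples and
#' removes genes whose maximum falls strictly below the given empirical
#' percentile (linear interpolation between order statistics) of the
#' genome's maxima.  With the default 2.5 this trims the noisiest tail of
#' each genome's expression distribution.
#'
#' @param expr CPM matrix (genes x samples), e.g. from [cpm()].
#' @param percentile Percentile in `[0, 100)`; default 2.5.
#' @param groups Optional character vector mapping each gene to a genome;
#'   by default derived from the `genome:gene` id prefix.
#' @return List with `expr` (retained matrix), `removed` (gene ids) and
#'   `thresholds` (named per genome).
#' @export
low_expression_filter <- function(expr, percentile = 2.5, groups = NULL) {
  stopifnot(percentile >= 0, percentile < 100)
  if (is.null(groups)) groups <- gene_genome(rownames(expr))
  if (length(groups) != nrow(expr)) {
    stop("groups must map every gene to a genome", call. = FALSE)
  }
  maxima <- apply(expr, 1, max)
  removed <- character(0)
  thresholds <- c()
  for (g in unique(groups)) {
    idx <- groups == g
    if (!any(idx)) stop("empty genome group: ", g, call. = FALSE)
    thr <- stats::quantile(maxima[idx], percentile / 100, names = FALSE,
                           type = 7)
    thresholds[g] <- thr
    removed <- c(removed, rownames(expr)[idx][maxima[idx] < thr])
  }
  list(expr = expr[!rownames(expr) %in% removed, , drop = FALSE],
       removed = removed, thresholds = thresholds)
}

#' Pseudocount effect-size log2 fold change (Psi estimator)
#'
#' Posterior-mean log2 fold change between two count observations with a
#' Jeffreys-type pseudocount prior:
#' `(digamma(kA + prior) - digamma(kB + prior)) / ln 2 - log2(libA / libB)`.
#' Finite for all non-negative counts, including `kA = kB = 0`, and
#' converging to the naive `log2((kA/libA) / (kB/libB))` for large counts.
#'
#' @param kA,kB Non-negative counts (vectorised).
#' @param libA,libB Positive library sizes.
#' @param prior Pseudocount prior (default 0.5).
#' @return Numeric log2 fold change(s) of A over B.
#' @export
psi_effect_lfc <- function(kA, kB, libA, libB, prior = 0.5) {
  if (any(kA < 0) || any(kB < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(libA <= 0) || any(libB <= 0)) stop("library sizes must be > 0",
                                             call. = FALSE)
  if (prior <= 0) stop("prior must be > 0", call. = FALSE)
  (digamma(kA + prior) - digamma(kB + prior)) / log(2) - log2(libA / libB)
}

#' Coculture-vs-monoculture Psi log2 fold changes
#'
#' For every gene (or, given a catalog, every BGC region) of a genome,
#' computes the Psi log2 fold change of each coculture condition
#' containing that genome's species against the species' monoculture.
#' Counts are summed across replicates within each condition (and across
#' member genes for BGC units); library sizes are the genome's total
#' counts summed over the same samples.
#'
#' @param counts Integer count matrix (genes x samples, `genome:gene` ids).
#' @param design A [study_design()]; only samples of `series` are used.
#' @param catalog Optional `bgc_catalog`; when supplied, units are BGC
#'   regions instead of genes.
#' @param series Genotype series to use (default `"wt"`).
#' @param center Subtract the per-contrast median LFC across the genome's
#'   units (default `FALSE`).
#' @param prior Pseudocount prior passed to [psi_effect_lfc()].
#' @return Data frame with columns `unit`, `genome`, `condition`,
#'   `contrast`, `psi_lfc`.
#' @export
lfc_table <- function(counts, design, catalog = NULL, series = "wt",
                      center = FALSE, prior = 0.5) {
  stopifnot(inherits(design, "study_design"))
  d <- design_series(design, series)
  d <- d[d$sample_id %in% colnames(counts), , drop = FALSE]
  genomes <- gene_genome(rownames(counts))
  if (is.null(catalog)) {
    units <- data.frame(unit = rownames(counts), genome = genomes,
                        stringsAsFactors = FALSE)
    members <- split(rownames(counts), rownames(counts))
  } else {
    missing <- setdiff(catalog$gene_id, rownames(counts))
    if (length(missing) > 0) {
      stop("catalog gene(s) absent from the count matrix: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
    units <- unique(data.frame(unit = catalog$region_id,
                               genome = catalog$genome,
                               stringsAsFactors = FALSE))
    members <- split(catalog$gene_id, catalog$region_id)
  }
  out <- list()
  for (g in unique(units$genome)) {
    species <- if (g %in% SPECIES) g else
      stop(sprintf("genome '%s' is not a species letter (B/F/K)", g),
           call. = FALSE)
    mono_samples <- d$sample_id[d$condition == species]
    if (length(mono_samples) == 0) {
      stop(sprintf("monoculture condition '%s' missing from the design",
                   species), call. = FALSE)
    }
    cocult <- setdiff(unique(d$condition[grepl(species, d$condition) &
                                           !d$is_media]), species)
    genome_genes <- rownames(counts)[genomes == g]
    lib_mono <- sum(counts[genome_genes, mono_samples, drop = FALSE])
    uni <- units[units$genome == g, , drop = FALSE]
    for (cond in cocult) {
      co_samples <- d$sample_id[d$condition == cond]
      lib_co <- sum(counts[genome_genes, co_samples, drop = FALSE])
      kA <- vapply(uni$unit, function(u)
        sum(counts[members[[u]], co_samples, drop = FALSE]), numeric(1))
      kB <- vapply(uni$unit, function(u)
        sum(counts[members[[u]], mono_samples, drop = FALSE]), numeric(1))
      lfc <- psi_effect_lfc(kA, kB, lib_co, lib_mono, prior = prior)
      if (center) lfc <- lfc - stats::median(lfc)
      out[[length(out) + 1L]] <- data.frame(
        unit = uni$unit, genome = g, condition = cond,
        contrast = sprintf("%s_vs_%s", cond, species),
        psi_lfc = unname(lfc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' BGC-wide expression
#'
#' BGC-wide expression in each sample is the sum of the CPM values of the
#' region's member genes.  Member genes removed by the low-expression
#' filter contribute zero and are counted per region; a region with no
#' surviving member genes is reported with value 0 and a warning.
#'
#' @param expr CPM matrix (genes x samples), possibly post-filter.
#' @param catalog A `bgc_catalog`.
#' @return List with `expression` (regions x samples matrix),
#'   `n_filtered` (named integer per region), `product_label` (named
#'   character per region).
#' @export
bgc_expression <- function(expr, catalog) {
  regions <- unique(catalog$region_id)
  mat <- matrix(0, length(regions), ncol(expr),
                dimnames = list(regions, colnames(expr)))
  n_filtered <- stats::setNames(integer(length(regions)), regions)
  for (r in regions) {
    genes <- catalog$gene_id[catalog$region_id == r]
    present <- intersect(genes, rownames(expr))
    n_filtered[r] <- length(genes) - length(present)
    if (length(present) == 0) {
      warning(sprintf("region %s has no surviving member genes", r),
              call. = FALSE)
    } else {
      mat[r, ] <- colSums(expr[present, , drop = FALSE])
    }
  }
  labels <- vapply(regions, function(r)
    catalog$product_label[catalog$region_id == r][1], character(1))
  list(expression = mat, n_filtered = n_filtered, product_label = labels)
}

#' Percent change of mutant-series vs wild-type-series expression
#'
#' The "X% higher" convention:
#' `(value_mut - value_wt) / value_wt * 100`.
#'
#' @param value_mut Non-negative value in the mutant series.
#' @param value_wt Positive value in the wild-type series.
#' @return Percent change (vectorised).
#' @export
percent_change <- function(value_mut, value_wt) {
  if (any(value_mut < 0)) stop("values must be >= 0", call. = FALSE)
  if (any(value_wt <= 0)) stop("wild-type value must be > 0", call. = FALSE)
  (value_mut - value_wt) / value_wt * 100
}

#' Wild-type vs knockout BGC expression comparison
#'
#' For each BGC region and each condition present in both genotype
#' series, computes the mean BGC-wide CPM per series and the percent
#' change of the knockout series over the wild type.
#'
#' @param bgc A [bgc_expression()] result.
#' @param design A [study_design()].
#' @param conditions Conditions to compare (default: all non-media
#'   conditions present in both series).
#' @return Data frame with columns `region_id`, `product_label`,
#'   `condition`, `mean_wt`, `mean_kec`, `pct_change`.
#' @export
series_percent_change <- function(bgc, design, conditions = NULL) {
  stopifnot(inherits(design, "study_design"))
  d <- design[design$sample_id %in% colnames(bgc$expression), , drop = FALSE]
  if (is.null(conditions)) {
    conditions <- intersect(unique(d$condition[d$series == "wt"]),
                            unique(d$condition[d$series == "kec"]))
  }
  out <- list()
  for (r in rownames(bgc$expression)) {
    for (cond in conditions) {
      wt <- d$sample_id[d$series == "wt" & d$condition == cond]
      mu <- d$sample_id[d$series == "kec" & d$condition == cond]
      if (length(wt) == 0 || length(mu) == 0) next
      m_wt <- mean(bgc$expression[r, wt])
      m_mu <- mean(bgc$expression[r, mu])
      out[[length(out) + 1L]] <- data.frame(
        region_id = r, product_label = unname(bgc$product_label[r]),
        condition = cond, mean_wt = m_wt, mean_kec = m_mu,
        pct_change = if (m_wt > 0) percent_change(m_mu, m_wt) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
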