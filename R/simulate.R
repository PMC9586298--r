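# Synthetic multi-omics community study generator.
#
# Emulates the statistical structure the analysis assumes: 7 culture
# conditions (B, F, K, BF, BK, FK, BFK) plus media blanks, five
# replicates each, a parallel koreenceine-null (kec) series, log-normal
# molecular-feature abundances with planted main/pairwise/three-way
# effects, and negative-binomial gene counts with planted BGC-level
# condition effects.  Planted ground truth is returned alongside the data
# for parameter-recovery tests.

#' Validate and complete a generator configuration
#'
#' @param config Named list of overrides over [default_config()].
#' @return The completed configuration.
#' @export
sim_config <- function(config = list()) {
  cfg <- default_config()
  unknown <- setdiff(names(config), c(names(cfg), "planted_lfc",
                                      "planted_lfc_condition",
                                      "planted_lfc_genome"))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$planted_lfc <- c(-2, 1, 3)
  cfg$planted_lfc_condition <- "BK"
  cfg$planted_lfc_genome <- "B"
  cfg[names(config)] <- config
  if (!"planted_lfc" %in% names(config)) {
    cfg$planted_lfc <- utils::head(cfg$planted_lfc, cfg$n_bgc)
  }
  counts <- c("n_features", "n_media", "n_pair_only", "n_triple_only",
              "n_kec_dependent", "n_genes", "n_bgc", "bgc_size",
              "n_replicates")
  for (k in counts) {
    if (cfg[[k]] < 0 || cfg[[k]] != floor(cfg[[k]])) {
      stop(sprintf("configuration error: %s must be a non-negative integer",
                   k), call. = FALSE)
    }
  }
  if (cfg$n_features <= 0) stop("configuration error: n_features must be > 0",
                                call. = FALSE)
  planted <- cfg$n_media + cfg$n_pair_only + cfg$n_triple_only +
    cfg$n_kec_dependent
  if (planted > cfg$n_features) {
    stop("configuration error: planted feature classes exceed n_features",
         call. = FALSE)
  }
  if (cfg$noise_sigma < 0) stop("configuration error: noise_sigma must be >= 0",
                                call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("configuration error: nb_dispersion must be > 0",
                                   call. = FALSE)
  if (cfg$detection_floor <= 0) stop("configuration error: detection_floor must be > 0",
                                     call. = FALSE)
  if (cfg$library_size <= 0) stop("configuration error: library_size must be > 0",
                                  call. = FALSE)
  if (length(cfg$planted_lfc) > cfg$n_bgc) {
    stop("configuration error: more planted BGC LFCs than regions",
         call. = FALSE)
  }
  cfg
}

#' Plant the synthetic ground truth
#'
#' Assigns every molecular feature to a class (media-derived,
#' pairwise-emergent, triple-only, koreenceine-dependent, or background),
#' draws per-feature model-term effect sizes, gene baselines, BGC
#' membership, planted BGC-level condition fold changes, and per-sample
#' library sizes.  Deterministic for fixed `(config, seed)`.
#'
#' Feature classes encode presence patterns through the containment-coded
#' model: a class with planted effect `e` on term `T` and intercept
#' `log(floor/10) + e` sits at the detection floor/10 in every condition
#' not containing all species of `T`, and `floor/10 * exp(2e)` where `T`
#' is contained — e.g. triple-only features are seen only in the
#' three-member community.  The first three koreenceine-dependent
#' features stand in for koreenceine A, B and C and anchor the detection
#' baseline.  Planted BGC fold changes are koreenceine-mediated: they
#' apply in the wild-type series only.
#'
#' @param config Named list of overrides over [default_config()].
#' @param seed Integer seed.
#' @return A `planted_effects` list; see Details in the vignette.
#' @export
planted_truth <- function(config = list(), seed = 1) {
  cfg <- sim_config(config)
  design <- study_layout(cfg$n_replicates)
  set.seed(seed)
  n <- cfg$n_features
  ids <- sprintf("F%05d", seq_len(n))
  shuffled <- sample(ids)
  take <- function(k) {
    out <- utils::head(shuffled, k)
    shuffled <<- utils::tail(shuffled, length(shuffled) - k)
    out
  }
  media_ids <- take(cfg$n_media)
  triple_ids <- take(cfg$n_triple_only)
  pair_ids <- take(cfg$n_pair_only)
  kec_ids <- take(cfg$n_kec_dependent)
  background_ids <- shuffled

  floor_log <- log(cfg$detection_floor / 10)
  eff <- cfg$effect_presence
  terms <- matrix(0, n, 8, dimnames = list(ids, MODEL_TERMS))
  terms[media_ids, "intercept"] <-
    stats::rnorm(length(media_ids), cfg$baseline_meanlog, cfg$baseline_sdlog)
  terms[triple_ids, "intercept"] <- floor_log + eff
  terms[triple_ids, "B:F:K"] <- eff
  pair_terms <- rep(c("B:F", "B:K", "F:K"), length.out = length(pair_ids))
  for (i in seq_along(pair_ids)) {
    terms[pair_ids[i], "intercept"] <- floor_log + eff
    terms[pair_ids[i], pair_terms[i]] <- eff
  }
  terms[kec_ids, "intercept"] <- floor_log + eff
  terms[kec_ids, "K"] <- eff
  nb <- length(background_ids)
  terms[background_ids, "intercept"] <-
    stats::rnorm(nb, cfg$baseline_meanlog, cfg$baseline_sdlog)
  # background effects touch main and pairwise terms only; the three-way
  # term carries planted community features alone, so its nonzero count
  # is forced by the configuration
  for (term in MODEL_TERMS[2:7]) {
    hit <- stats::runif(nb) < cfg$p_background_effect
    terms[background_ids[hit], term] <-
      stats::rnorm(sum(hit), 0, cfg$background_effect_sd)
  }

  gene_ids <- as.vector(vapply(SPECIES, function(g)
    sprintf("%s:g%04d", g, seq_len(cfg$n_genes)), character(cfg$n_genes)))
  gene_baseline <- stats::setNames(
    stats::rlnorm(length(gene_ids), cfg$gene_baseline_meanlog,
                  cfg$gene_baseline_sdlog), gene_ids)

  catalog <- do.call(rbind, lapply(SPECIES, function(g) {
    do.call(rbind, lapply(seq_len(cfg$n_bgc), function(i) {
      first <- (i - 1) * cfg$bgc_size + 1
      data.frame(region_id = sprintf("%s_region%02d", g, i),
                 genome = g,
                 product_label = sprintf("product_%s%02d", g, i),
                 gene_id = sprintf("%s:g%04d", g,
                                   seq(first, first + cfg$bgc_size - 1)),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (cfg$n_bgc * cfg$bgc_size > cfg$n_genes) {
    stop("configuration error: BGC regions exceed the gene complement",
         call. = FALSE)
  }
  catalog <- bgc_catalog(catalog)

  conds <- c("B", "F", "K", "BF", "BK", "FK", "BFK")
  lfc <- matrix(0, length(gene_ids), length(conds),
                dimnames = list(gene_ids, conds))
  for (i in seq_along(cfg$planted_lfc)) {
    region <- sprintf("%s_region%02d", cfg$planted_lfc_genome, i)
    genes <- catalog$gene_id[catalog$region_id == region]
    lfc[genes, cfg$planted_lfc_condition] <- cfg$planted_lfc[i]
  }

  non_media <- design$sample_id[!design$is_media]
  lib <- stats::setNames(
    round(cfg$library_size *
            stats::runif(length(non_media),
                         1 - cfg$library_size_spread / 2,
                         1 + cfg$library_size_spread / 2)), non_media)
  if (any(lib <= 0)) stop("configuration error: zero library size",
                          call. = FALSE)

  structure(list(design = design, feature_ids = ids, feature_terms = terms,
                 media_features = media_ids, triple_only = triple_ids,
                 pair_only = pair_ids, kec_dependent = kec_ids,
                 anchor_features = utils::head(kec_ids, 3),
                 detection_floor = cfg$detection_floor,
                 noise_sigma = cfg$noise_sigma,
                 gene_ids = gene_ids, gene_baseline = gene_baseline,
                 gene_condition_lfc = lfc, catalog = catalog,
                 planted_lfc = stats::setNames(
                   cfg$planted_lfc,
                   sprintf("%s_region%02d", cfg$planted_lfc_genome,
                           seq_along(cfg$planted_lfc))),
                 planted_lfc_condition = cfg$planted_lfc_condition,
                 nb_dispersion = cfg$nb_dispersion, library_sizes = lib,
                 config = cfg),
            class = "planted_effects")
}

#' Generate a synthetic LC-MS molecular feature table
#'
#' Log-abundance of feature m in sample i is
#' `intercept_m + sum_term effect_{m,term} * code(term, condition_i) +
#' Normal(0, noise_sigma)` under containment coding, with media blanks
#' entering as the all-absent design point, so every feature is
#' model-consistent at every design point and a noiseless fit recovers
#' the planted effects exactly.  Media-derived features draw from their
#' media baseline term in every sample.  "Absent" cells — a
#' presence-pattern feature's conditions lacking its planted term, and
#' koreenceine-dependent features in every koreenceine-null sample — are
#' pinned at exactly `detection_floor / 10` (the class construction makes
#' this equal the model mean there, so the pinning is mean-preserving; it
#' mimics an LC-MS detector floor rather than log-normal biology).  Peak
#' areas are the exponentiated values, non-negative.
#'
#' @param design A [study_design()].
#' @param truth A [planted_truth()] result.
#' @param seed Integer seed.
#' @return A [feature_table()].
#' @export
generate_feature_table <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth, "planted_effects"))
  set.seed(seed)
  ids <- truth$feature_ids
  n <- length(ids)
  ns <- nrow(design)
  codes <- vapply(design$condition, encode_condition, numeric(8))
  M <- truth$feature_terms %*% codes          # n x ns log-means
  colnames(M) <- design$sample_id
  # media-derived features: media baseline term everywhere
  M[truth$media_features, ] <- truth$feature_terms[truth$media_features,
                                                   "intercept"]
  E <- matrix(stats::rnorm(n * ns, 0, truth$noise_sigma), n, ns)
  A <- exp(M + E)
  dimnames(A) <- list(ids, design$sample_id)
  # detector floor: absent cells of presence-pattern features sit exactly
  # at floor/10 (= their model mean there, by construction)
  floor_val <- truth$detection_floor / 10
  floor_log <- log(floor_val)
  pattern <- c(truth$triple_only, truth$pair_only, truth$kec_dependent)
  if (length(pattern) > 0) {
    absent <- abs(M[pattern, , drop = FALSE] - floor_log) < 1e-9
    A[pattern, ][absent] <- floor_val
  }
  kec_cols <- design$series == "kec"
  if (any(kec_cols) && length(truth$kec_dependent) > 0) {
    A[truth$kec_dependent, kec_cols] <- floor_val
  }
  mw <- stats::runif(n, 150, 1500)
  rt <- stats::runif(n, 0.5, 20)
  feature_table(A, mw = mw, rt = rt)
}

#' Generate a synthetic gene count matrix
#'
#' Counts for gene g of genome G in a (non-media) sample whose condition
#' contains G's species are drawn negative-binomially with mean
#' `baseline_g * 2^lfc / sum(baselines of G) * library_share`, where
#' `lfc` is the planted BGC-level log2 fold change for the sample's
#' condition (wild-type series only; planted effects are
#' koreenceine-mediated) and the sample's library size is split evenly
#' across the species present.  Genes of absent species get zero counts.
#'
#' @param design A [study_design()]; media samples are ignored (no
#'   transcriptome is simulated for blanks).
#' @param truth A [planted_truth()] result providing baselines, planted
#'   fold changes, library sizes and the dispersion.
#' @param seed Integer seed.
#' @return Integer count matrix (genes x samples).
#' @export
generate_counts <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth, "planted_effects"))
  set.seed(seed)
  d <- design[!design$is_media, , drop = FALSE]
  missing <- setdiff(d$sample_id, names(truth$library_sizes))
  if (length(missing) > 0) {
    stop("no library size planted for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(truth$library_sizes[d$sample_id] <= 0)) {
    stop("configuration error: zero library size", call. = FALSE)
  }
  genes <- truth$gene_ids
  genomes <- gene_genome(genes)
  counts <- matrix(0L, length(genes), nrow(d),
                   dimnames = list(genes, d$sample_id))
  size <- 1 / truth$nb_dispersion
  sp_list <- condition_species(d$condition)
  for (j in seq_len(nrow(d))) {
    sp <- sp_list[[j]]
    lib_share <- truth$library_sizes[d$sample_id[j]] / length(sp)
    for (g in sp) {
      idx <- genomes == g
      w <- truth$gene_baseline[genes[idx]]
      lfc <- if (d$series[j] == "wt")
        truth$gene_condition_lfc[genes[idx], d$condition[j]] else 0
      mu <- w * 2^lfc / sum(w) * lib_share
      counts[idx, j] <- stats::rnbinom(sum(idx), mu = mu, size = size)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a complete synthetic study
#'
#' Composes [planted_truth()], [generate_counts()] and
#' [generate_feature_table()] under one master seed (component calls use
#' `seed`, `seed + 1`, `seed + 2` respectively, in that documented
#' order).  The default layout yields 2 x 7 x 5 + 5 = 75 feature-table
#' samples: wild-type and koreenceine-null series of all 7 conditions,
#' plus shared media blanks.
#'
#' @param config Named list of overrides over [default_config()].
#' @param seed Integer master seed.
#' @return A `synthetic_study`: list with `design`, `counts`, `features`,
#'   `truth`, `seed`.
#' @export
generate_study <- function(config = list(), seed = 1) {
  truth <- planted_truth(config, seed)
  counts <- generate_counts(truth$design, truth, seed + 1)
  features <- generate_feature_table(truth$design, truth, seed + 2)
  structure(list(design = truth$design, counts = counts,
                 features = features, truth = truth, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study (seed %d): %d samples, %d genes, ",
                     "%d molecular features\n"),
              x$seed, nrow(x$design), nrow(x$counts), nrow(x$features$areas)))
  invisible(x)
}

#' Write a synthetic study to standard pipeline input files
#'
#' Writes the counts TSV, sample sheet TSV, feature CSV and BGC catalog
#' TSV consumed by the readers, plus a `truth.tsv` (feature class and
#' per-term effect sizes) for test harnesses.
#'
#' @param study A [generate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             samples = file.path(outdir, "samples.tsv"),
             features = file.path(outdir, "features.csv"),
             catalog = file.path(outdir, "bgc_catalog.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_count_matrix(study$counts, paths["counts"])
  write_sample_sheet(study$design, paths["samples"])
  write_feature_table(study$features, paths["features"])
  write_bgc_catalog(study$truth$catalog, paths["catalog"])
  tr <- study$truth
  cls <- rep("background", length(tr$feature_ids))
  names(cls) <- tr$feature_ids
  cls[tr$media_features] <- "media"
  cls[tr$pair_only] <- "pair_only"
  cls[tr$triple_only] <- "triple_only"
  cls[tr$kec_dependent] <- "kec_dependent"
  truth_df <- data.frame(feature_id = tr$feature_ids,
                         class = unname(cls[tr$feature_ids]),
                         tr$feature_terms, check.names = FALSE,
                         stringsAsFactors = FALSE)
  write_table(truth_df, paths["truth"])
  invisible(paths)
}
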