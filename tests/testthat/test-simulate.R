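test_that("planted truth honours the configured class counts exactly", {
  truth <- planted_truth(list(n_features = 100, n_media = 10,
                              n_pair_only = 6, n_triple_only = 3,
                              n_kec_dependent = 4), seed = 2)
  expect_length(truth$media_features, 10)
  expect_length(truth$pair_only, 6)
  expect_length(truth$triple_only, 3)
  expect_length(truth$kec_dependent, 4)
  expect_length(truth$feature_ids, 100)
  # classes are disjoint and conserved
  all_planted <- c(truth$media_features, truth$pair_only,
                   truth$triple_only, truth$kec_dependent)
  expect_equal(anyDuplicated(all_planted), 0L)
  # exactly n_triple_only nonzero three-way effects at the planted size
  expect_equal(sum(truth$feature_terms[, "B:F:K"] != 0), 3)
  expect_equal(unname(truth$feature_terms[truth$triple_only, "B:F:K"]),
               rep(3, 3))

  expect_identical(truth, planted_truth(list(n_features = 100, n_media = 10,
                                             n_pair_only = 6,
                                             n_triple_only = 3,
                                             n_kec_dependent = 4), seed = 2))
  expect_error(planted_truth(list(noise_sigma = -1)), "noise_sigma")
  expect_error(planted_truth(list(nb_dispersion = 0)), "nb_dispersion")
  expect_error(planted_truth(list(n_features = 10, n_media = 20)),
               "exceed n_features")
})

test_that("feature tables follow the planted factorial model", {
  # zero noise, no planted effects: non-media features constant everywhere
  cfg0 <- list(n_features = 30, n_media = 5, n_pair_only = 0,
               n_triple_only = 0, n_kec_dependent = 0,
               p_background_effect = 0, noise_sigma = 0)
  truth0 <- planted_truth(cfg0, seed = 1)
  ft0 <- generate_feature_table(truth0$design, truth0, seed = 2)
  non_media <- setdiff(truth0$feature_ids, truth0$media_features)
  culture <- truth0$design$sample_id[!truth0$design$is_media]
  spread <- apply(ft0$areas[non_media, culture], 1,
                  function(x) max(x) - min(x))
  expect_equal(unname(spread), rep(0, length(non_media)))

  # a large positive three-way feature peaks in BFK
  cfg <- list(n_features = 50, n_media = 5, n_pair_only = 5,
              n_triple_only = 2, n_kec_dependent = 3)
  truth <- planted_truth(cfg, seed = 3)
  ft <- generate_feature_table(truth$design, truth, seed = 4)
  d <- truth$design
  cond_mean <- function(f, cond) {
    mean(ft$areas[f, d$sample_id[d$condition == cond & d$series == "wt"]])
  }
  for (f in truth$triple_only) {
    bfk <- cond_mean(f, "BFK")
    others <- vapply(c("B", "F", "K", "BF", "BK", "FK"), cond_mean,
                     numeric(1), f = f)
    expect_true(all(bfk > others))
  }
  # koreenceine-dependent features sit at the floor in every kec sample
  floor_val <- truth$detection_floor / 10
  kec_samples <- d$sample_id[d$series == "kec"]
  expect_true(all(ft$areas[truth$kec_dependent, kec_samples] == floor_val))

  expect_identical(ft, generate_feature_table(truth$design, truth, seed = 4))
  ft_b <- generate_feature_table(truth$design, truth, seed = 5)
  expect_true(any(ft_b$areas != ft$areas))
})

test_that("counts are reproducible negative-binomial draws around the planted means", {
  # near-zero dispersion at mean 50: 10,000 draws within 1% of the mean
  cfg <- list(n_genes = 2000, n_bgc = 5, bgc_size = 10,
              gene_baseline_sdlog = 0, library_size = 3 * 2000 * 50 / 3,
              library_size_spread = 0, nb_dispersion = 1e-8,
              n_features = 10, n_media = 1, n_pair_only = 0,
              n_triple_only = 0, n_kec_dependent = 1,
              planted_lfc = numeric(0))
  truth <- planted_truth(cfg, seed = 8)
  counts <- generate_counts(truth$design, truth, seed = 9)
  b_mono <- truth$design$sample_id[truth$design$condition == "B"]
  draws <- counts[gene_genome(rownames(counts)) == "B", b_mono]
  expect_gte(length(draws), 10000)
  expect_lt(abs(mean(draws) - 50) / 50, 0.01)

  expect_identical(counts, generate_counts(truth$design, truth, seed = 9))
  # genes of absent species are zero
  f_mono <- truth$design$sample_id[truth$design$condition == "F"]
  expect_true(all(counts[gene_genome(rownames(counts)) == "B", f_mono] == 0L))
})

test_that("a gene with no planted fold change has equal condition means", {
  # conditions with equal library share for the genome (BF vs BK for B genes)
  cfg <- list(n_genes = 60, n_bgc = 2, bgc_size = 5,
              library_size_spread = 0, planted_lfc = numeric(0),
              n_features = 10, n_media = 1, n_pair_only = 0,
              n_triple_only = 0, n_kec_dependent = 1)
  pvals <- vapply(1:20, function(s) {
    truth <- planted_truth(cfg, seed = s)
    counts <- generate_counts(truth$design, truth, seed = s + 50)
    d <- truth$design
    g <- "B:g0001"
    a <- counts[g, d$sample_id[d$condition == "BF" & d$series == "wt"]]
    b <- counts[g, d$sample_id[d$condition == "BK" & d$series == "wt"]]
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("generate_study composes the default layout deterministically", {
  st <- generate_study(list(n_features = 60, n_media = 6, n_pair_only = 6,
                            n_triple_only = 3, n_kec_dependent = 3,
                            n_genes = 40, n_bgc = 2, bgc_size = 5),
                       seed = 12)
  expect_equal(ncol(st$features$areas), 2 * 7 * 5 + 5)
  expect_true(all(c("wt", "kec") %in%
                    st$design$series[st$design$condition == "BFK"]))
  st2 <- generate_study(list(n_features = 60, n_media = 6, n_pair_only = 6,
                             n_triple_only = 3, n_kec_dependent = 3,
                             n_genes = 40, n_bgc = 2, bgc_size = 5),
                        seed = 12)
  expect_identical(st$features$areas, st2$features$areas)
  expect_identical(st$counts, st2$counts)
  st3 <- generate_study(list(n_features = 60, n_media = 6, n_pair_only = 6,
                             n_triple_only = 3, n_kec_dependent = 3,
                             n_genes = 40, n_bgc = 2, bgc_size = 5),
                        seed = 13)
  expect_true(any(st3$features$areas != st$features$areas))
})

test_that("written studies round-trip through the standard readers", {
  st <- generate_study(list(n_features = 40, n_media = 4, n_pair_only = 3,
                            n_triple_only = 2, n_kec_dependent = 3,
                            n_genes = 20, n_bgc = 2, bgc_size = 4),
                       seed = 30)
  outdir <- withr::local_tempdir()
  paths <- write_study(st, outdir)
  expect_identical(read_count_matrix(paths["counts"]), st$counts)
  expect_equal(read_sample_sheet(paths["samples"]), st$design)
  back <- read_feature_table(paths["features"], st$design)
  expect_equal(back$areas, st$features$areas, tolerance = 1e-5)
  expect_equal(nrow(read_bgc_catalog(paths["catalog"])),
               nrow(st$truth$catalog))
  truth_tab <- read_table(paths["truth"])
  expect_equal(sum(truth_tab$class == "triple_only"), 2)
})
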