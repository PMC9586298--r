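test_that("condition encoding follows the containment and product rules", {
  expect_equal(unname(encode_condition("B")),
               c(1, 1, -1, -1, -1, -1, -1, -1))
  expect_equal(unname(encode_condition("BFK")), rep(1, 8))
  expect_equal(unname(encode_condition("BFK", coding = "product")), rep(1, 8))
  # the codings differ exactly where some but not all members are present
  b_cont <- encode_condition("B")
  b_prod <- encode_condition("B", coding = "product")
  expect_equal(unname(b_prod["F:K"]), 1)   # (-1)(-1)
  expect_equal(unname(b_cont["F:K"]), -1)
  expect_equal(b_cont[c("intercept", "B", "F", "K")],
               b_prod[c("intercept", "B", "F", "K")])
  # media is the all-absent design point
  m <- encode_condition("media")
  expect_equal(unname(m), c(1, rep(-1, 7)))
})

test_that("7 non-media conditions give rank 7 with the stated null vector; media gives rank 8", {
  d <- tiny_design(2)
  v <- c(1, -1, -1, -1, 1, 1, 1, -1)
  for (coding in c("containment", "product")) {
    dm7 <- build_design(d, coding = coding, include_baseline = FALSE)
    expect_equal(dm7$rank, 7)
    expect_equal(max(abs(dm7$X %*% v)), 0)
    expect_equal(ncol(dm7$null_space), 1)
    ns <- dm7$null_space[, 1]
    expect_equal(unname(ns / ns[1]), v, tolerance = 1e-10)
    dm8 <- build_design(d, coding = coding, include_baseline = TRUE)
    expect_equal(dm8$rank, 8)
    expect_null(dm8$null_space)
  }
  one_cond <- study_design(c("a", "b"), c("B", "B"),
                           rep("not_applicable", 2), 1:2)
  expect_error(build_design(one_cond), "at least 2 distinct conditions")
})

test_that("fit_feature matches the brute-force normal-equations oracle", {
  set.seed(42)
  for (i in 1:25) {
    coding <- sample(c("containment", "product"), 1)
    inst <- random_instance(coding)
    dm <- as_design_matrix(inst$X, coding)
    fit <- fit_feature(inst$y, dm)
    ora <- oracle_ls(inst$X, inst$y)
    expect_equal(unname(fit$coefficients), unname(ora$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(ora$se), tolerance = 1e-8)
    expect_equal(unname(fit$t), unname(ora$t), tolerance = 1e-8)
    expect_equal(fit$df, ora$df)
  }
})

test_that("noiseless responses interpolate exactly with infinite t", {
  set.seed(7)
  inst <- random_instance()
  dm <- as_design_matrix(inst$X)
  y <- drop(inst$X %*% inst$beta)
  fit <- fit_feature(y, dm)
  expect_equal(unname(fit$coefficients), inst$beta, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-16)
  expect_true(fit$exact_fit)
  expect_true(all(is.infinite(fit$t[inst$beta != 0])))
  expect_error(fit_feature(c(y[1], NA, y[-(1:2)]), dm), "non-finite")
})

test_that("balanced full-factorial fits match the orthogonal closed form", {
  # 8 conditions x r reps under product coding: X'X = nI, so
  # beta_j = mean(x_j * y) and Var(beta_j) = s^2 / n.
  set.seed(11)
  r <- 3
  conds <- rep(c("B", "F", "K", "BF", "BK", "FK", "BFK", "media"), each = r)
  X <- t(vapply(conds, encode_condition, numeric(8), coding = "product"))
  rownames(X) <- sprintf("s%02d", seq_along(conds))
  y <- rnorm(nrow(X), mean = drop(X %*% c(5, 1, 0, -1, 0.5, 0, 0, 2)))
  dm <- as_design_matrix(X, "product")
  fit <- fit_feature(y, dm)
  n <- nrow(X)
  beta_closed <- colMeans(X * y)
  s2 <- sum((y - X %*% beta_closed)^2) / (n - 8)
  expect_equal(unname(fit$coefficients), unname(beta_closed),
               tolerance = 1e-8)
  expect_equal(unname(fit$t), unname(beta_closed / sqrt(s2 / n)),
               tolerance = 1e-8)
})

test_that("rank-deficient designs alias the trailing term in entry order", {
  d <- tiny_design(2)
  dm7 <- build_design(d, include_baseline = FALSE)
  y <- rnorm(nrow(dm7$X))
  fit <- fit_feature(y, dm7)
  expect_true(fit$aliased[["B:F:K"]])
  expect_false(any(fit$aliased[1:7]))
  expect_true(is.na(fit$t[["B:F:K"]]))
  ens <- fit_ensemble(ft_from(matrix(exp(y), 1, length(y),
                                     dimnames = list("F1", rownames(dm7$X)))),
                      dm7)
  expect_error(tail_select(ens, "B:F:K"), "aliased")
})

test_that("null features have per-term t medians near zero", {
  # model-consistent null: intercept-only features from the generator
  cfg <- list(n_features = 100, n_media = 0, n_pair_only = 0,
              n_triple_only = 0, n_kec_dependent = 0,
              p_background_effect = 0, noise_sigma = 0.5)
  truth <- planted_truth(cfg, seed = 5)
  ft <- generate_feature_table(truth$design, truth, seed = 6)
  dm <- build_design(truth$design, include_baseline = TRUE, series = "wt")
  ens <- fit_ensemble(ft, dm)
  expect_equal(nrow(ens$t), 100)
  meds <- ens$summary$median[ens$summary$term != "intercept"]
  expect_true(all(abs(meds) < 0.5))
})

test_that("a single-feature table yields a one-row ensemble", {
  d <- tiny_design(2)
  dm <- build_design(d, include_baseline = TRUE)
  areas <- matrix(runif(nrow(dm$X), 10, 20), 1,
                  dimnames = list("F1", rownames(dm$X)))
  ens <- fit_ensemble(ft_from(areas), dm)
  expect_equal(dim(ens$t), c(1L, 8L))
})

test_that("a dominant planted three-way feature tops the ensemble", {
  cfg <- list(n_features = 200, n_media = 20, n_pair_only = 10,
              n_triple_only = 1, n_kec_dependent = 5, effect_presence = 4,
              noise_sigma = 0.3)
  truth <- planted_truth(cfg, seed = 3)
  ft <- generate_feature_table(truth$design, truth, seed = 4)
  dm <- build_design(truth$design, include_baseline = TRUE, series = "wt")
  ens <- fit_ensemble(ft, dm)
  expect_equal(rownames(ens$t)[which.max(ens$t[, "B:F:K"])],
               truth$triple_only)
})

test_that("tail selection counts and tie handling follow the quantile rule", {
  d <- tiny_design(2)
  dm <- build_design(d, include_baseline = TRUE)
  mk_ens <- function(tvals) {
    ens <- structure(list(t = matrix(tvals, ncol = 1,
                                     dimnames = list(sprintf("F%04d",
                                                             seq_along(tvals)),
                                                     "B:F:K")),
                          aliased = c(`B:F:K` = FALSE)),
                     class = "ensemble_result")
    ens
  }
  sel <- tail_select(mk_ens(as.numeric(1:1000)), "B:F:K", 2.5)
  expect_length(sel$upper, 25)
  expect_length(sel$lower, 25)
  sel40 <- tail_select(mk_ens(as.numeric(1:40)), "B:F:K", 2.5)
  expect_length(sel40$upper, 1)  # threshold 39.025, only the maximum
  tie <- tail_select(mk_ens(rep(2, 10)), "B:F:K", 2.5)
  expect_length(tie$upper, 10)
  expect_length(tie$lower, 10)
  expect_error(tail_select(mk_ens(1:10), "B:F:K", 50), "percentile")
})

test_that("permuting sample labels destroys planted tail enrichment", {
  cfg <- list(n_features = 300, n_media = 30, n_pair_only = 20,
              n_triple_only = 10, n_kec_dependent = 5)
  overlaps <- vapply(1:5, function(s) {
    truth <- planted_truth(cfg, seed = s)
    ft <- generate_feature_table(truth$design, truth, seed = s + 100)
    perm_ft <- ft
    set.seed(s + 200)
    colnames(perm_ft$areas) <- sample(colnames(perm_ft$areas))
    dm <- build_design(truth$design, include_baseline = TRUE, series = "wt")
    ens <- fit_ensemble(perm_ft, dm)
    sel <- tail_select(ens, "B:F:K", 2.5)
    length(intersect(sel$upper, truth$triple_only))
  }, numeric(1))
  # expected overlap under chance is ~0.025 * 10 per seed
  expect_lt(mean(overlaps), 2.5)
})
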