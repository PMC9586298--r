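# Sample-level ordination and clustering reports over molecular-feature
# tables: principal components with unit normalization, and hierarchical
# clustering of replicates on Spearman correlation distance.

#' Principal component analysis of sample metabolome profiles
#'
#' Features are centred and (by default) scaled to unit variance before
#' the decomposition; zero-variance features are dropped first and
#' reported.  Loadings are returned per feature so that components can be
#' interrogated for their discriminating features.
#'
#' @param ft A [feature_table()].
#' @param scale `"unit_variance"` (per-feature z-scaling, default) or
#'   `"none"`.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings` (features x components), `var_explained` (percent per
#'   component, summing to 100), `dropped` (zero-variance feature ids).
#' @export
pca_profiles <- function(ft, scale = c("unit_variance", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(ft, "feature_table"))
  X <- t(ft$areas)                       # samples x features
  if (nrow(X) < 2) stop("need at least 2 samples for PCA", call. = FALSE)
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  X <- X[, v > 0, drop = FALSE]
  if (ncol(X) == 0) stop("all features have zero variance", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = (scale == "unit_variance"))
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, dropped = dropped, scale = scale),
            class = "pca_result")
}

#' Top discriminating features of one principal component
#' @param pca A [pca_profiles()] result.
#' @param component Component index (default 1).
#' @param n Number of features (default 10).
#' @return Data frame of feature ids and loadings, by absolute loading.
#' @export
top_loadings <- function(pca, component = 1, n = 10) {
  stopifnot(inherits(pca, "pca_result"))
  l <- pca$loadings[, component]
  ord <- order(abs(l), decreasing = TRUE)
  head_n <- utils::head(ord, n)
  data.frame(feature_id = rownames(pca$loadings)[head_n],
             loading = unname(l[head_n]), stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples on Spearman correlation
#'
#' Pairwise sample distance is `1 - rho` where `rho` is the Spearman rank
#' correlation of the two samples' feature abundances; samples are then
#' clustered agglomeratively (average linkage by default).  Distances are
#' invariant under strictly monotone per-sample transforms of the areas.
#'
#' @param ft A [feature_table()].
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List with `hclust` (an `hclust` object), `dist` (the distance
#'   object), `rho` (the Spearman correlation matrix).
#' @export
spearman_linkage <- function(ft, method = "average") {
  stopifnot(inherits(ft, "feature_table"))
  A <- ft$areas
  if (ncol(A) < 2) stop("need at least 2 samples", call. = FALSE)
  const <- colnames(A)[apply(A, 2, function(x) max(x) == min(x))]
  if (length(const) > 0) {
    stop("constant profile (Spearman correlation undefined) for sample(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  rho <- stats::cor(A, method = "spearman")
  d <- stats::as.dist(1 - rho)
  list(hclust = stats::hclust(d, method = method), dist = d, rho = rho)
}

#' Cut a sample tree and report cluster membership by condition
#' @param linkage A [spearman_linkage()] result.
#' @param design A [study_design()].
#' @param k Number of clusters.
#' @return Data frame with `sample_id`, `condition`, `cluster`.
#' @export
cluster_membership <- function(linkage, design, k) {
  cl <- stats::cutree(linkage$hclust, k = k)
  idx <- match(names(cl), design$sample_id)
  data.frame(sample_id = names(cl),
             condition = design$condition[idx],
             cluster = unname(cl), stringsAsFactors = FALSE)
}
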