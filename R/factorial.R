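# Per-feature 2^3 factorial model of species presence.
#
# For molecular feature m and sample i the model is
#   log(y_im) = b0m + sum_j b_jm x_ij + sum_j' b_j'm x_ij' + b_BFKm x_iBFK
# where the x are +/-1 indicators of species (or species-set) presence.
# Two codings of the interaction indicators are supported:
#   containment: x for term {j'} is +1 iff ALL species of the term are
#     present in the sample (a subset indicator), -1 otherwise;
#   product:     x for an interaction is the product of its members'
#     main-effect entries (classical full-factorial effect coding).
# The two differ exactly in samples where some but not all species of an
# interaction are present.

MODEL_TERMS <- c("intercept", "B", "F", "K", "B:F", "B:K", "F:K", "B:F:K")

.term_members <- list(intercept = character(0),
                      B = "B", F = "F", K = "K",
                      `B:F` = c("B", "F"), `B:K` = c("B", "K"),
                      `F:K` = c("F", "K"), `B:F:K` = c("B", "F", "K"))

#' Encode one condition as a factorial design row
#'
#' @param condition A condition string (`"B"`, `"BFK"`, `"media"`, ...).
#' @param coding `"containment"` (subset indicators; default) or
#'   `"product"` (effect coding).
#' @return Named numeric vector of length 8 over
#'   `intercept, B, F, K, B:F, B:K, F:K, B:F:K` with values in {-1, +1}
#'   (intercept always +1).
#' @examples
#' encode_condition("B")                      # FK entry -1
#' encode_condition("B", coding = "product")  # FK entry +1
#' @export
encode_condition <- function(condition, coding = c("containment", "product")) {
  coding <- match.arg(coding)
  sp <- condition_species(condition)[[1]]
  main <- vapply(SPECIES, function(s) if (s %in% sp) 1 else -1, numeric(1))
  row <- numeric(8)
  names(row) <- MODEL_TERMS
  row["intercept"] <- 1
  row[c("B", "F", "K")] <- main
  for (term in MODEL_TERMS[5:8]) {
    mem <- .term_members[[term]]
    row[term] <- if (coding == "containment") {
      if (all(mem %in% sp)) 1 else -1
    } else {
      prod(main[mem])
    }
  }
  row
}

#' Build the factorial design matrix for one genotype series
#'
#' Assembles the per-sample +/-1 design over all 8 model terms for the
#' samples of one series, optionally including the media blanks as the
#' all-absent design point.  Without that baseline row the 7 non-media
#' conditions span only 7 of the 8 terms (the matrix is rank-deficient
#' with null vector proportional to `(1, -1, -1, -1, 1, 1, 1, -1)`); the
#' matrix is returned anyway, flagged, with its null-space basis.
#'
#' @param design A [study_design()].
#' @param coding `"containment"` or `"product"`; see [encode_condition()].
#' @param include_baseline Include media blanks as all-absent rows
#'   (default `TRUE`, which makes all 8 terms identifiable).
#' @param series Which genotype series to model (`"wt"` default, or
#'   `"kec"`).
#' @return A `design_matrix`: list with elements `X` (samples x 8 matrix),
#'   `coding`, `rank`, `null_space` (basis matrix or `NULL`), `samples`.
#' @export
build_design <- function(design, coding = c("containment", "product"),
                         include_baseline = TRUE, series = "wt") {
  coding <- match.arg(coding)
  stopifnot(inherits(design, "study_design"))
  d <- design_series(design, series, include_media = include_baseline)
  if (length(unique(d$condition)) < 2) {
    stop("need at least 2 distinct conditions to build a design matrix",
         call. = FALSE)
  }
  conds <- unique(d$condition)
  rows <- t(vapply(conds, encode_condition, numeric(8), coding = coding))
  X <- rows[match(d$condition, conds), , drop = FALSE]
  dimnames(X) <- list(d$sample_id, MODEL_TERMS)
  qr_x <- qr(X)
  rank <- qr_x$rank
  null_space <- NULL
  if (rank < ncol(X)) {
    sv <- svd(X, nu = 0, nv = ncol(X))
    null_space <- sv$v[, (rank + 1):ncol(X), drop = FALSE]
    rownames(null_space) <- MODEL_TERMS
  }
  structure(list(X = X, coding = coding, rank = rank,
                 null_space = null_space, samples = d$sample_id),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d samples x %d terms (%s coding), rank %d%s\n",
              nrow(x$X), ncol(x$X), x$coding, x$rank,
              if (x$rank < ncol(x$X)) " [rank-deficient]" else ""))
  invisible(x)
}

# Shared least-squares machinery.  The same design is reused across
# thousands of features, so the pivoting/normal-equation work is done once
# and applied to a whole response matrix.
.ls_prepare <- function(X) {
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  Xk <- X[, keep, drop = FALSE]
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  list(keep = keep, Xk = Xk, XtXinv = XtXinv,
       H = tcrossprod(XtXinv, Xk),  # (X'X)^-1 X'
       rank = length(keep), n = nrow(X), p = ncol(X))
}

# Fit a response matrix (samples x features) against a prepared design.
.ls_fit <- function(prep, Y) {
  n <- prep$n
  df <- n - prep$rank
  B <- prep$H %*% Y                      # rank x m coefficients
  R <- Y - prep$Xk %*% B
  rss <- colSums(R^2)
  exact <- rss <= 1e-12 * pmax(1, colSums(Y^2))
  s2 <- rss / df
  se <- sqrt(outer(diag(prep$XtXinv), s2)) # rank x m
  Tm <- B / se
  Tm[, exact] <- sign(B[, exact, drop = FALSE]) * Inf
  list(coefficients = B, se = se, t = Tm, rss = rss, df = df,
       exact = exact)
}

#' Least-squares fit of one molecular feature
#'
#' Ordinary least squares of a log-abundance response on a factorial
#' design.  If the design is rank-deficient, coefficients are fit on the
#' maximal independent column subset in term order (intercept, mains,
#' pairs, triple) and the trailing dependent terms are flagged aliased
#' (`NA` coefficients, no t value).  A perfect fit (zero residual) yields
#' infinite t statistics, flagged via `exact_fit`.
#'
#' @param y Numeric response vector (one value per design sample).
#' @param dm A [build_design()] result.
#' @return List with `coefficients`, `se`, `t` (length-8 named vectors,
#'   `NA` for aliased terms), `df` (residual degrees of freedom), `rss`,
#'   `aliased` (logical per term), `exact_fit`.
#' @export
fit_feature <- function(y, dm) {
  stopifnot(inherits(dm, "design_matrix"))
  X <- dm$X
  if (length(y) != nrow(X)) {
    stop(sprintf("response length %d does not match %d design samples",
                 length(y), nrow(X)), call. = FALSE)
  }
  if (any(!is.finite(y))) stop("non-finite response value(s)", call. = FALSE)
  prep <- .ls_prepare(X)
  if (prep$n - prep$rank < 1) stop("saturated model: residual degrees of freedom = 0",
                                   call. = FALSE)
  fit <- .ls_fit(prep, matrix(y, ncol = 1))
  full <- function(v) {
    out <- rep(NA_real_, ncol(X)); names(out) <- colnames(X)
    out[prep$keep] <- v
    out
  }
  aliased <- rep(TRUE, ncol(X)); names(aliased) <- colnames(X)
  aliased[prep$keep] <- FALSE
  list(coefficients = full(fit$coefficients[, 1]),
       se = full(fit$se[, 1]),
       t = full(fit$t[, 1]),
       df = fit$df, rss = fit$rss[1],
       aliased = aliased, exact_fit = fit$exact[1])
}

#' Fit the factorial model across all molecular features
#'
#' Applies `y = log(area + offset)` per feature (natural log) and fits
#' every feature against the shared design, assembling the t-statistic
#' ensemble and per-term distribution summaries (median and interquartile
#' range, as visualised in per-term box/frequency displays).
#'
#' @param ft A [feature_table()].
#' @param dm A [build_design()] result; all design samples must be present
#'   in the feature table.
#' @param offset Additive offset before the log transform (default 1,
#'   keeps zero areas finite).
#' @return An `ensemble_result`: list with `t` (features x terms matrix),
#'   `coefficients`, `se` (same shape), `df`, `summary` (per-term data
#'   frame: median, q25, q75, iqr), `aliased` (logical per term),
#'   `failures` (feature ids with non-finite responses, fitted as `NA`
#'   rows), `offset`.
#' @export
fit_ensemble <- function(ft, dm, offset = 1) {
  stopifnot(inherits(ft, "feature_table"), inherits(dm, "design_matrix"))
  missing <- setdiff(rownames(dm$X), colnames(ft$areas))
  if (length(missing) > 0) {
    stop("design sample(s) missing from the feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  A <- ft$areas[, rownames(dm$X), drop = FALSE]
  Y <- t(log(A + offset))                     # samples x features
  prep <- .ls_prepare(dm$X)
  if (prep$n - prep$rank < 1) stop("saturated model: residual degrees of freedom = 0",
                                   call. = FALSE)
  bad <- colnames(Y)[!apply(is.finite(Y), 2, all)]
  ok <- setdiff(colnames(Y), bad)
  p <- ncol(dm$X)
  m <- nrow(ft$areas)
  tmat <- matrix(NA_real_, m, p, dimnames = list(rownames(ft$areas),
                                                 colnames(dm$X)))
  bmat <- tmat; semat <- tmat
  if (length(ok) > 0) {
    fit <- .ls_fit(prep, Y[, ok, drop = FALSE])
    tmat[ok, prep$keep] <- t(fit$t)
    bmat[ok, prep$keep] <- t(fit$coefficients)
    semat[ok, prep$keep] <- t(fit$se)
  }
  aliased <- rep(TRUE, p); names(aliased) <- colnames(dm$X)
  aliased[prep$keep] <- FALSE
  summ <- do.call(rbind, lapply(colnames(tmat), function(term) {
    v <- tmat[, term]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      data.frame(term = term, median = NA_real_, q25 = NA_real_,
                 q75 = NA_real_, iqr = NA_real_, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      data.frame(term = term, median = q[2], q25 = q[1], q75 = q[3],
                 iqr = q[3] - q[1], stringsAsFactors = FALSE)
    }
  }))
  structure(list(t = tmat, coefficients = bmat, se = semat,
                 df = prep$n - prep$rank, summary = summ,
                 aliased = aliased, failures = bad, offset = offset),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d features x %d terms, residual df %d\n",
              nrow(x$t), ncol(x$t), x$df))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select tail features by per-term t statistic
#'
#' Flags the molecular features whose t statistic for one model term falls
#' in the upper or lower tail of the ensemble distribution.  Quantiles use
#' linear interpolation between order statistics; ties at a threshold are
#' included (so a degenerate all-equal ensemble selects every feature in
#' both tails).
#'
#' @param ens An [fit_ensemble()] result.
#' @param term Model term name (e.g. `"B:F:K"`).
#' @param percentile Tail size in percent, in (0, 50); default 2.5.
#' @return List with `upper` and `lower` character vectors of feature ids
#'   and the two `thresholds`.
#' @export
tail_select <- function(ens, term, percentile = 2.5) {
  stopifnot(inherits(ens, "ensemble_result"))
  if (!term %in% colnames(ens$t)) stop("unknown term: ", term, call. = FALSE)
  if (ens$aliased[[term]]) {
    stop(sprintf("term '%s' is aliased in this design; no t statistics",
                 term), call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 50) {
    stop("percentile must be in (0, 50)", call. = FALSE)
  }
  tv <- ens$t[, term]
  use <- tv[!is.na(tv)]
  lo <- stats::quantile(use, percentile / 100, names = FALSE, type = 7)
  hi <- stats::quantile(use, 1 - percentile / 100, names = FALSE, type = 7)
  list(upper = names(tv)[!is.na(tv) & tv >= hi],
       lower = names(tv)[!is.na(tv) & tv <= lo],
       thresholds = c(lower = lo, upper = hi))
}
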