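# Presence/absence accounting for molecular features: a detection
# baseline anchored on analytes known to be absent from the knockout
# series (koreenceine A, B, C in the published design), media-blank
# subtraction, per-condition presence calls, and condition-unique /
# shared tallies.

#' Knockout-anchored detection baseline
#'
#' The presence/absence intensity threshold is the maximum peak area the
#' known-absent analytes reach in samples where they cannot occur
#' biologically (e.g. koreenceine features in koreenceine-null samples):
#' any signal they show there is noise by construction.
#'
#' @param ft A [feature_table()].
#' @param absent_ids Feature ids of the known-absent analytes.
#' @param samples Sample ids restricted to conditions where the analytes
#'   are absent.
#' @return The threshold, in peak-area units.
#' @export
detection_baseline <- function(ft, absent_ids, samples) {
  stopifnot(inherits(ft, "feature_table"))
  if (length(absent_ids) == 0) stop("absent_ids must be non-empty",
                                    call. = FALSE)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  missing <- setdiff(absent_ids, rownames(ft$areas))
  if (length(missing) > 0) {
    stop("absent analyte(s) not in the feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  missing_s <- setdiff(samples, colnames(ft$areas))
  if (length(missing_s) > 0) {
    stop("sample(s) not in the feature table: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  max(ft$areas[absent_ids, samples, drop = FALSE])
}

.presence_call <- function(areas_row, threshold, rule) {
  switch(rule,
         median = stats::median(areas_row) > threshold,
         any = any(areas_row > threshold),
         all = all(areas_row > threshold),
         stop("unknown presence rule: ", rule, call. = FALSE))
}

#' Features present in media blanks
#'
#' Returns the features called present in the sterile media blanks (per
#' the replicate rule); downstream tallies operate on their complement,
#' the nonmedia molecular features.
#'
#' @param ft A [feature_table()].
#' @param design A [study_design()] containing media samples.
#' @param threshold Peak-area threshold, e.g. from [detection_baseline()].
#' @param rule Replicate rule: `"median"` (default), `"any"`, or `"all"`.
#' @return Character vector of media feature ids.
#' @export
media_features <- function(ft, design, threshold, rule = "median") {
  stopifnot(inherits(ft, "feature_table"), inherits(design, "study_design"))
  media_samples <- intersect(design$sample_id[design$is_media],
                             colnames(ft$areas))
  if (length(media_samples) == 0) stop("no media samples in the design",
                                       call. = FALSE)
  A <- ft$areas[, media_samples, drop = FALSE]
  present <- apply(A, 1, .presence_call, threshold = threshold, rule = rule)
  rownames(ft$areas)[present]
}

#' Per-condition presence calls
#'
#' Calls each feature present or absent in each non-media condition of one
#' genotype series, per the replicate rule over the condition's samples
#' (default: median replicate area strictly above the threshold).
#'
#' @param ft A [feature_table()].
#' @param design A [study_design()].
#' @param threshold Peak-area threshold.
#' @param rule `"median"` (default), `"any"`, or `"all"`.
#' @param series Genotype series (default `"wt"`).
#' @return A `presence_calls`: list with `calls` (logical features x
#'   conditions matrix), `threshold`, `rule`, `series`.
#' @export
presence_matrix <- function(ft, design, threshold, rule = "median",
                            series = "wt") {
  stopifnot(inherits(ft, "feature_table"), inherits(design, "study_design"))
  d <- design_series(design, series)
  d <- d[d$sample_id %in% colnames(ft$areas), , drop = FALSE]
  conds <- unique(d$condition)
  if (length(conds) == 0) stop("no samples for series ", series, call. = FALSE)
  calls <- matrix(FALSE, nrow(ft$areas), length(conds),
                  dimnames = list(rownames(ft$areas), conds))
  for (cond in conds) {
    s <- d$sample_id[d$condition == cond]
    calls[, cond] <- apply(ft$areas[, s, drop = FALSE], 1, .presence_call,
                           threshold = threshold, rule = rule)
  }
  structure(list(calls = calls, threshold = threshold, rule = rule,
                 series = series),
            class = "presence_calls")
}

#' Condition-unique and shared feature tallies
#'
#' Per genotype series, tallies the nonmedia features only seen when two
#' or more members are cultured together (absent from every monoculture)
#' and those only seen in the three-member community.  Given a second
#' series, also compares matched conditions: shared, unique-to-first and
#' unique-to-second counts with percentages of the per-comparison
#' nonmedia union.
#'
#' Media features must be removed from the calls before tallying (see
#' [media_features()]).
#'
#' @param calls A [presence_matrix()] result.
#' @param calls_other Optional second series' [presence_matrix()] over the
#'   same feature universe.
#' @return List with `n_detected` (features present in >=1 condition),
#'   `coculture_only` / `triple_only` (feature id vectors),
#'   `pct_coculture_only` / `pct_triple_only` (percent of detected
#'   features), and — when `calls_other` is given — `comparison`, a data
#'   frame with per-condition `shared`, `unique_first`, `unique_second`
#'   counts and percentages of the union.
#' @export
condition_tallies <- function(calls, calls_other = NULL) {
  stopifnot(inherits(calls, "presence_calls"))
  M <- calls$calls
  conds <- colnames(M)
  mono <- conds[nchar(conds) == 1]
  multi <- conds[nchar(conds) >= 2]
  triple <- conds[nchar(conds) == 3]
  detected <- rownames(M)[rowSums(M) > 0]
  cocult_only <- rownames(M)[rowSums(M[, multi, drop = FALSE]) > 0 &
                               rowSums(M[, mono, drop = FALSE]) == 0]
  triple_only <- if (length(triple) == 1) {
    rownames(M)[M[, triple] & rowSums(M[, setdiff(conds, triple),
                                        drop = FALSE]) == 0]
  } else character(0)
  out <- list(n_detected = length(detected),
              coculture_only = cocult_only,
              triple_only = triple_only,
              pct_coculture_only = 100 * length(cocult_only) /
                max(1, length(detected)),
              pct_triple_only = 100 * length(triple_only) /
                max(1, length(detected)))
  if (!is.null(calls_other)) {
    stopifnot(inherits(calls_other, "presence_calls"))
    N <- calls_other$calls
    if (!identical(sort(rownames(M)), sort(rownames(N)))) {
      stop("the two series cover different feature universes", call. = FALSE)
    }
    N <- N[rownames(M), , drop = FALSE]
    shared_conds <- intersect(colnames(M), colnames(N))
    comp <- do.call(rbind, lapply(shared_conds, function(cond) {
      a <- M[, cond]; b <- N[, cond]
      union_n <- sum(a | b)
      data.frame(condition = cond,
                 shared = sum(a & b),
                 unique_first = sum(a & !b),
                 unique_second = sum(!a & b),
                 union = union_n,
                 pct_shared = 100 * sum(a & b) / max(1, union_n),
                 pct_unique_first = 100 * sum(a & !b) / max(1, union_n),
                 pct_unique_second = 100 * sum(!a & b) / max(1, union_n),
                 stringsAsFactors = FALSE)
    }))
    out$comparison <- comp
  }
  out
}

#' Drop features from a presence-calls object
#' @param calls A [presence_matrix()] result.
#' @param drop_ids Feature ids to remove (e.g. media features).
#' @return The reduced `presence_calls`.
#' @export
drop_features <- function(calls, drop_ids) {
  stopifnot(inherits(calls, "presence_calls"))
  calls$calls <- calls$calls[!rownames(calls$calls) %in% drop_ids, ,
                             drop = FALSE]
  calls
}
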