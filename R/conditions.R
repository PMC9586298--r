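#' @keywords internal
"_PACKAGE"

# The three community members are denoted by single letters throughout:
# B = Bacillus cereus, F = Flavobacterium johnsoniae, K = Pseudomonas
# koreensis.  A culture condition is the set of members present, written as
# a letter-set string ("B", "BF", "BFK", ...); sterile medium is "media".

SPECIES <- c("B", "F", "K")

#' Parse a condition string into the set of species present
#'
#' Condition strings are order-insensitive subsets of `"BFK"` (e.g. `"KFB"`
#' and `"BFK"` denote the same three-member community); `"media"` denotes a
#' sterile media blank (no species present).
#'
#' @param condition Character vector of condition strings.
#' @return A list (one element per input) of character vectors of species
#'   letters, sorted in B, F, K order; `character(0)` for media.
#' @examples
#' condition_species(c("KFB", "media", "F"))
#' @export
condition_species <- function(condition) {
  lapply(condition, function(cond) {
    if (identical(tolower(cond), "media")) return(character(0))
    letters <- strsplit(cond, "")[[1]]
    bad <- setdiff(letters, SPECIES)
    if (length(bad) > 0 || length(letters) == 0) {
      stop(sprintf("invalid condition '%s': unknown species letter(s) %s",
                   cond, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    if (anyDuplicated(letters)) {
      stop(sprintf("invalid condition '%s': repeated species letter", cond),
           call. = FALSE)
    }
    SPECIES[SPECIES %in% letters]
  })
}

#' Canonical form of a condition string
#'
#' @param condition Character vector of condition strings.
#' @return Character vector with species letters sorted in B, F, K order
#'   (`"media"` is passed through lower-cased).
#' @export
normalize_condition <- function(condition) {
  vapply(condition_species(condition), function(sp) {
    if (length(sp) == 0) "media" else paste(sp, collapse = "")
  }, character(1))
}

GENOTYPES <- c("wild_type", "kec_null", "not_applicable")

#' Construct a study design
#'
#' A study design records, per sample, the culture condition (which
#' community members are present), the genotype of the *P. koreensis*
#' inoculum (`wild_type` or koreenceine-null `kec_null`; `not_applicable`
#' when K is absent and for media blanks), the replicate number, and the
#' experimental series the sample belongs to (`"wt"`, `"kec"`, or
#' `"media"` for shared blanks).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param condition Character vector of condition strings over `"BFK"`, or
#'   `"media"`.
#' @param genotype One of `"wild_type"`, `"kec_null"`, `"not_applicable"`
#'   per sample.  Must be `not_applicable` whenever K is absent.
#' @param replicate Positive integer replicate index per sample.
#' @param series Optional series label per sample (`"wt"`, `"kec"`,
#'   `"media"`).  When `NULL` it is derived from the genotype: `kec_null`
#'   samples form the `"kec"` series, media blanks the `"media"` series,
#'   and everything else the `"wt"` series.
#' @return A `study_design`: a data frame with columns `sample_id`,
#'   `condition` (canonical form), `genotype`, `replicate`, `series`,
#'   `is_media`.
#' @export
study_design <- function(sample_id, condition, genotype, replicate,
                         series = NULL) {
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  condition <- normalize_condition(condition)
  sp <- condition_species(condition)
  is_media <- lengths(sp) == 0
  bad_gt <- setdiff(genotype, GENOTYPES)
  if (length(bad_gt) > 0) {
    stop("unknown genotype value(s): ", paste(bad_gt, collapse = ", "),
         call. = FALSE)
  }
  has_k <- vapply(sp, function(s) "K" %in% s, logical(1))
  if (any(genotype == "kec_null" & !has_k)) {
    offenders <- sample_id[genotype == "kec_null" & !has_k]
    stop("genotype kec_null requires K in the condition; offending sample(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  if (any(genotype != "not_applicable" & !has_k)) {
    offenders <- sample_id[genotype != "not_applicable" & !has_k]
    stop("genotype must be not_applicable when K is absent (and for media); ",
         "offending sample(s): ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate) | replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (is.null(series)) {
    series <- ifelse(is_media, "media",
                     ifelse(genotype == "kec_null", "kec", "wt"))
  }
  if (any(is_media & series != "media")) {
    stop("media blanks must carry series 'media'", call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    condition = condition,
                    genotype = genotype,
                    replicate = replicate,
                    series = as.character(series),
                    is_media = is_media,
                    stringsAsFactors = FALSE)
  class(out) <- c("study_design", "data.frame")
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d conditions, series: %s\n",
              nrow(x), length(unique(x$condition)),
              paste(unique(x$series), collapse = ", ")))
  NextMethod()
}

#' Restrict a design to one genotype series
#'
#' @param design A `study_design`.
#' @param series Series label (`"wt"` or `"kec"`).
#' @param include_media Whether to keep the shared media blanks.
#' @return The filtered `study_design`.
#' @export
design_series <- function(design, series, include_media = FALSE) {
  stopifnot(inherits(design, "study_design"))
  keep <- design$series == series | (include_media & design$is_media)
  out <- design[keep, , drop = FALSE]
  class(out) <- c("study_design", "data.frame")
  out
}

#' Default coculture study layout
#'
#' Builds the study design the pipeline's synthetic generator emulates: all
#' seven non-media conditions (three monocultures, three pairwise
#' cocultures, and the three-member community) in two parallel genotype
#' series (wild-type *P. koreensis* and the koreenceine-null mutant), plus
#' shared media blanks, with `n_replicates` replicates each.  The default
#' of 5 replicates per condition gives 2 x 7 x 5 + 5 = 75 samples.
#'
#' @param n_replicates Replicates per condition (default 5).
#' @return A [study_design()].
#' @export
study_layout <- function(n_replicates = 5) {
  stopifnot(n_replicates >= 1)
  conds <- c("B", "F", "K", "BF", "BK", "FK", "BFK")
  rows <- list()
  for (ser in c("wt", "kec")) {
    for (cond in conds) {
      has_k <- grepl("K", cond)
      gt <- if (!has_k) "not_applicable"
            else if (ser == "kec") "kec_null" else "wild_type"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", ser, cond, seq_len(n_replicates)),
        condition = cond, genotype = gt,
        replicate = seq_len(n_replicates), series = ser,
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = sprintf("media_%d", seq_len(n_replicates)),
    condition = "media", genotype = "not_applicable",
    replicate = seq_len(n_replicates), series = "media",
    stringsAsFactors = FALSE)
  d <- do.call(rbind, rows)
  study_design(d$sample_id, d$condition, d$genotype, d$replicate, d$series)
}
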