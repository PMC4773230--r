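# Warrick visual HRCT score: severity points per abnormality type, extent
# points per number of bronchopulmonary segments involved, total 0-30.

.warrick_points <- c(ground_glass = 1L, irregular_pleural_margins = 2L,
                     septal_subpleural_lines = 3L, honeycombing = 4L,
                     subpleural_cysts = 5L)

#' The five Warrick abnormality types and their severity points
#'
#' @return A named integer vector: ground-glass appearance 1, irregular
#'   pleural margins 2, septal/subpleural lines 3, honeycombing 4,
#'   subpleural cysts 5.
#' @export
warrick_abnormalities <- function() .warrick_points

#' Bronchopulmonary segment atlas
#'
#' The fixed 18-segment atlas used as the universe for extent scoring:
#' 10 right segments and 8 left (apicoposterior and anteromedial-basal
#' fused, as is anatomically conventional).
#'
#' @return A character vector of 18 segment codes.
#' @export
warrick_segments <- function() {
  c("R_apical", "R_posterior", "R_anterior", "R_lateral", "R_medial",
    "R_superior", "R_medial_basal", "R_anterior_basal", "R_lateral_basal",
    "R_posterior_basal",
    "L_apicoposterior", "L_anterior", "L_superior_lingula",
    "L_inferior_lingula", "L_superior", "L_anteromedial_basal",
    "L_lateral_basal", "L_posterior_basal")
}

#' Severity points for an abnormality type
#'
#' @param abnormality character vector of abnormality codes (see
#'   [warrick_abnormalities]).
#' @return Integer severity points in 1..5.
#' @export
severity_points <- function(abnormality) {
  bad <- setdiff(abnormality, names(.warrick_points))
  if (length(bad) > 0)
    stop("unknown abnormality: ", paste(bad, collapse = ", "))
  unname(.warrick_points[abnormality])
}

#' Extent points for a segment count
#'
#' Maps the number of bronchopulmonary segments involved to extent points:
#' 0 segments scores 0, 1-3 scores 1, 4-9 scores 2, more than 9 scores 3.
#'
#' @param n_segments integer vector of segment counts, each in 0..18.
#' @return Integer extent points in 0..3.
#' @export
extent_points <- function(n_segments) {
  if (any(n_segments < 0) || any(n_segments > 18))
    stop("segment counts must lie in 0..18")
  unname(c(0L, 1L, 2L, 3L)[findInterval(n_segments, c(0, 1, 4, 10))])
}

#' A single reader finding
#'
#' @param abnormality one abnormality code.
#' @param segments non-empty character vector of involved segment codes
#'   drawn from [warrick_segments()]; duplicates are collapsed.
#' @return A `warrick_finding` object.
#' @export
warrick_finding <- function(abnormality, segments) {
  severity_points(abnormality)        # validates the code
  segments <- unique(as.character(segments))
  if (length(segments) == 0) stop("'segments' must be non-empty")
  bad <- setdiff(segments, warrick_segments())
  if (length(bad) > 0)
    stop("unknown segment code: ", paste(bad, collapse = ", "))
  structure(list(abnormality = abnormality, segments = segments),
            class = "warrick_finding")
}

#' One reader's assessment of one study
#'
#' @param reader_id reader identifier.
#' @param findings list of [warrick_finding] objects, at most one per
#'   abnormality type.
#' @return A `reader_assessment` object.
#' @export
reader_assessment <- function(reader_id, findings = list()) {
  if (inherits(findings, "warrick_finding")) findings <- list(findings)
  ab <- vapply(findings, function(f) f$abnormality, character(1))
  if (anyDuplicated(ab))
    stop("duplicate abnormality entries: ",
         paste(unique(ab[duplicated(ab)]), collapse = ", "))
  structure(list(reader_id = as.character(reader_id), findings = findings),
            class = "reader_assessment")
}

#' Warrick score triple
#'
#' @param severity,extent,total score components; `total` must equal
#'   `severity + extent`, severity and extent each at most 15 so the total
#'   ranges 0-30.
#' @return A `warrick_score` object.
#' @export
warrick_score <- function(severity, extent, total = severity + extent) {
  if (severity < 0 || severity > 15 || extent < 0 || extent > 15)
    stop("severity and extent must lie in 0..15")
  if (!isTRUE(all.equal(total, severity + extent)))
    stop("total must equal severity + extent")
  structure(list(severity = severity, extent = extent, total = total),
            class = "warrick_score")
}

#' @export
print.warrick_score <- function(x, ...) {
  cat(sprintf("<warrick_score> severity %g + extent %g = total %g (0-30)\n",
              x$severity, x$extent, x$total))
  invisible(x)
}

#' Score one reader assessment
#'
#' Severity is the sum of point values over the abnormality types present;
#' extent is the sum, over all five abnormality types, of the extent points
#' for the number of segments involved (0 for an absent type).
#'
#' @param a a [reader_assessment].
#' @return A [warrick_score].
#' @export
score_assessment <- function(a) {
  stopifnot(inherits(a, "reader_assessment"))
  sev <- 0L; ext <- 0L
  for (f in a$findings) {
    sev <- sev + severity_points(f$abnormality)
    ext <- ext + extent_points(length(f$segments))
  }
  warrick_score(sev, ext)
}

#' Combine the scores of two independent readers
#'
#' @param a1,a2 [warrick_score] objects for the same study.
#' @param mode `"mean"` takes the component-wise arithmetic mean (the
#'   final score used in analyses); `"consensus"` returns a third,
#'   adjudicated assessment supplied by the caller — disagreement
#'   resolution is a data question, not a computation.
#' @param adjudicated a [warrick_score] from the consensus read; required
#'   for `mode = "consensus"`.
#' @return A list with numeric `severity`, `extent`, `total`.
#' @export
aggregate_readers <- function(a1, a2, mode = c("mean", "consensus"),
                              adjudicated = NULL) {
  stopifnot(inherits(a1, "warrick_score"), inherits(a2, "warrick_score"))
  mode <- match.arg(mode)
  if (mode == "mean")
    return(list(severity = (a1$severity + a2$severity) / 2,
                extent = (a1$extent + a2$extent) / 2,
                total = (a1$total + a2$total) / 2))
  if (is.null(adjudicated))
    stop("consensus mode requires an adjudicated assessment")
  stopifnot(inherits(adjudicated, "warrick_score"))
  list(severity = adjudicated$severity, extent = adjudicated$extent,
       total = adjudicated$total)
}

#' Read a findings table
#'
#' Flat interchange format: one row per (study, reader, abnormality,
#' segment).
#'
#' @param path CSV file with columns `study_id`, `reader_id`,
#'   `abnormality`, `segment_code`.
#' @return A data frame with those four character columns.
#' @export
read_warrick_findings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "reader_id", "abnormality", "segment_code")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("findings table lacks columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Score a findings table
#'
#' Aggregates per-segment rows into per-reader assessments, scores each,
#' and (when every study has exactly two readers) appends the aggregated
#' final score.
#'
#' @param findings data frame as returned by [read_warrick_findings].
#' @param aggregate aggregation mode passed to [aggregate_readers] when
#'   two readers are present, or `"none"` to skip.
#' @return A data frame with one row per (study, reader) — columns
#'   `study_id`, `reader_id`, `severity`, `extent`, `total` — plus rows
#'   with `reader_id = "<mean>"` holding the aggregated scores.
#' @export
score_warrick_table <- function(findings, aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  out <- list()
  for (sid in unique(findings$study_id)) {
    fs <- findings[findings$study_id == sid, ]
    scores <- list()
    for (rid in unique(fs$reader_id)) {
      fr <- fs[fs$reader_id == rid, ]
      fl <- lapply(unique(fr$abnormality), function(ab)
        warrick_finding(ab, fr$segment_code[fr$abnormality == ab]))
      sc <- score_assessment(reader_assessment(rid, fl))
      scores[[rid]] <- sc
      out[[length(out) + 1L]] <-
        data.frame(study_id = sid, reader_id = rid, severity = sc$severity,
                   extent = sc$extent, total = sc$total)
    }
    if (aggregate == "mean" && length(scores) == 2L) {
      m <- aggregate_readers(scores[[1]], scores[[2]], "mean")
      out[[length(out) + 1L]] <-
        data.frame(study_id = sid, reader_id = "<mean>",
                   severity = m$severity, extent = m$extent, total = m$total)
    }
  }
  do.call(rbind, out)
}
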