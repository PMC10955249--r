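.REVIEW_STARS <- c(
  "practice guideline" = 4L,
  "reviewed by expert panel" = 3L,
  "criteria provided, multiple submitters, no conflicts" = 2L,
  "criteria provided, conflicting classifications" = 1L,
  "criteria provided, conflicting interpretations" = 1L,
  "criteria provided, single submitter" = 1L,
  "no assertion criteria provided" = 0L,
  "no classification provided" = 0L,
  "no assertion provided" = 0L
)

.canonStatus <- function(status) {
  s <- tolower(trimws(gsub("_", " ", status)))
  gsub(",(\\S)", ", \\1", s)  # VCF style omits the space after commas
}

#' Stars from a ClinVar review status
#'
#' Maps ClinVar review-status strings to the 0-4 star confidence rating.
#' Both the variant_summary spelling (spaces) and the VCF CLNREVSTAT
#' spelling (underscores) are accepted. Unrecognized statuses are a hard
#' error rather than a silent zero-star downgrade, so that new ClinVar
#' vocabulary has to be added deliberately.
#'
#' @param status Character vector of review-status strings.
#' @return Integer vector of star counts (0-4).
#' @examples
#' starsFromReviewStatus("reviewed by expert panel")  # 3
#' @export
starsFromReviewStatus <- function(status) {
  s <- .canonStatus(status)
  stars <- .REVIEW_STARS[s]
  if (anyNA(stars)) {
    bad <- unique(status[is.na(stars)])
    stop("unrecognized ClinVar review status: ",
         paste(sQuote(bad), collapse = ", "),
         "; known statuses must be extended deliberately")
  }
  unname(stars)
}

.isConflictingStatus <- function(status) {
  grepl("conflicting", .canonStatus(status), fixed = TRUE)
}

#' Normalize a ClinVar significance string to the five-level scale
#'
#' Case-insensitive total mapping of ClinVar clinical-significance strings
#' (variant_summary or VCF CLNSIG spelling) onto P/LP/VUS/LB/B. The
#' combined aggregates map to the weaker assertion:
#' "Pathogenic/Likely pathogenic" to LP and "Benign/Likely benign" to LB.
#' Everything else - risk factor, drug response, Affects, association,
#' protective, conflicting aggregates, compound strings with modifiers -
#' returns `"non_standard"` and is treated as no ClinVar classification.
#'
#' @param raw Character vector of significance strings.
#' @return Character vector over `c(callLevels(), "non_standard")`.
#' @examples
#' normalizeSignificance("Likely benign")        # "LB"
#' normalizeSignificance("Affects|risk_factor")  # "non_standard"
#' @export
normalizeSignificance <- function(raw) {
  s <- tolower(trimws(gsub("_", " ", as.character(raw))))
  map <- c("pathogenic" = "P",
           "likely pathogenic" = "LP",
           "uncertain significance" = "VUS",
           "likely benign" = "LB",
           "benign" = "B",
           "pathogenic/likely pathogenic" = "LP",
           "benign/likely benign" = "LB")
  out <- map[s]
  out[is.na(out)] <- "non_standard"
  unname(out)
}

#' Options controlling 1-star conflict resolution
#'
#' @param concept_ids Optional character vector of MedGen Concept IDs;
#'   when given, conflict resolution only considers submissions whose
#'   reported conditions intersect this set. `NULL` (absent) disables the
#'   filter and is distinct from an empty set.
#' @param tiebreak `"latest"` (default: call of the most recently evaluated
#'   submission) or `"most_severe"` (maximum-severity call) when no
#'   majority exists.
#' @return A `ResolutionOptions` list.
#' @export
resolutionOptions <- function(concept_ids = NULL,
                              tiebreak = c("latest", "most_severe")) {
  tiebreak <- match.arg(tiebreak)
  if (!is.null(concept_ids)) {
    concept_ids <- unique(as.character(concept_ids))
    if (length(concept_ids) == 0L)
      stop("concept_ids must be NULL (no filtering) or a non-empty set")
  }
  structure(list(concept_ids = concept_ids, tiebreak = tiebreak),
            class = "ResolutionOptions")
}

#' Filter submissions by MedGen Concept IDs
#'
#' Keeps the submissions whose reported-condition Concept IDs intersect the
#' given set; order is preserved.
#'
#' @param submissions Submission data.frame (see [readClinvarFiles()]) with
#'   a `concept_ids` list-column.
#' @param ids Non-empty character vector of Concept IDs.
#' @return The filtered submission data.frame.
#' @export
filterByConceptIds <- function(submissions, ids) {
  if (length(ids) == 0L) stop("ids must be a non-empty set of Concept IDs")
  keep <- vapply(submissions$concept_ids,
                 function(cc) length(intersect(cc, ids)) > 0L, logical(1))
  submissions[keep, , drop = FALSE]
}

#' Resolve a 1-star conflicting-interpretation variant
#'
#' The multi-step decision tree applied to the submissions of one variant
#' flagged "criteria provided, conflicting interpretations/classifications":
#' (1) submissions without assertion criteria are excluded; (2) submissions
#' whose significance is not expressible on the five-level scale are
#' excluded; (3) if a Concept ID list is supplied, submissions are
#' restricted to those reporting a matching condition; (4) if nothing
#' remains the variant is unresolved (`excluded_all`); (5) a unique
#' strictly-most-frequent call wins (`majority`); (6) otherwise the
#' configured tiebreak decides: `latest` takes the call of the maximum
#' last-evaluated date (dateless submissions rank lowest; ties at the
#' maximum date - including the all-dateless case - are broken by
#' [severityMax()]), `most_severe` takes [severityMax()] of the remaining
#' calls.
#'
#' @param submissions Submission data.frame for a single variation ID, with
#'   columns `significance`, `date_last_evaluated` (`Date`, `NA` allowed),
#'   `assertion_criteria_provided` (logical) and list-column `concept_ids`.
#' @param options A [resolutionOptions()] object.
#' @return List with `call` (a call or `NA` if unresolved), `method`
#'   (`majority`, `latest`, `most_severe` or `excluded_all`) and
#'   `n_considered`.
#' @export
resolveConflict <- function(submissions, options = resolutionOptions()) {
  if (is.null(submissions) || nrow(submissions) == 0L)
    stop("resolveConflict() requires at least one submission; ",
         "only call it for variants flagged as conflicting")
  subs <- submissions[submissions$assertion_criteria_provided, , drop = FALSE]
  if (nrow(subs) > 0L) {
    calls <- normalizeSignificance(subs$significance)
    subs <- subs[calls != "non_standard", , drop = FALSE]
  }
  if (!is.null(options$concept_ids) && nrow(subs) > 0L)
    subs <- filterByConceptIds(subs, options$concept_ids)
  if (nrow(subs) == 0L)
    return(list(call = NA_character_, method = "excluded_all",
                n_considered = 0L))

  calls <- normalizeSignificance(subs$significance)
  tab <- table(calls)
  top <- max(tab)
  if (sum(tab == top) == 1L) {
    return(list(call = names(tab)[which.max(tab)], method = "majority",
                n_considered = nrow(subs)))
  }
  if (options$tiebreak == "most_severe") {
    return(list(call = severityMax(calls), method = "most_severe",
                n_considered = nrow(subs)))
  }
  dates <- subs$date_last_evaluated
  if (all(is.na(dates))) {
    latest <- rep(TRUE, nrow(subs))
  } else {
    latest <- !is.na(dates) & dates == max(dates, na.rm = TRUE)
  }
  list(call = severityMax(calls[latest]), method = "latest",
       n_considered = nrow(subs))
}

#' Select the usable subset of ClinVar classifications
#'
#' Applies the star-aware retention policy to every ClinVar assertion:
#' two-or-more-star assertions and 1-star single-submitter assertions with
#' a standard five-level call are retained directly; 1-star
#' conflicting-interpretation assertions are resolved through
#' [resolveConflict()]; zero-star assertions, non-standard aggregate
#' calls, and conflicts whose submissions were all excluded yield no
#' ClinVar classification (the variant falls through to the modified
#' InterVar classifier).
#'
#' @param assertions Assertion data.frame from [readClinvarFiles()] with
#'   columns `vid`, `variation_id`, `significance`, `review_status`,
#'   `stars`.
#' @param submissions_by_id List of submission data.frames keyed by
#'   variation ID (as character).
#' @param options A [resolutionOptions()] object.
#' @return Data.frame keyed by `vid` with columns `variation_id`, `call`
#'   (`NA` when ClinVar yields no classification), `stars`,
#'   `resolution_method` (`direct`, `majority`, `latest`, `most_severe` or
#'   `NA`), `n_considered` and `note` (absence reason: `zero_star`,
#'   `non_standard`, `conflict_excluded_all`, `conflict_non_standard`).
#' @export
selectClinvarSubset <- function(assertions, submissions_by_id,
                                options = resolutionOptions()) {
  n <- nrow(assertions)
  out <- data.frame(
    vid = assertions$vid,
    variation_id = assertions$variation_id,
    call = NA_character_,
    stars = assertions$stars,
    resolution_method = NA_character_,
    n_considered = NA_integer_,
    note = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    stars <- assertions$stars[i]
    status <- assertions$review_status[i]
    if (.isConflictingStatus(status)) {
      subs <- submissions_by_id[[as.character(assertions$variation_id[i])]]
      if (is.null(subs) || nrow(subs) == 0L) {
        out$note[i] <- "conflict_excluded_all"
        next
      }
      res <- resolveConflict(subs, options)
      if (is.na(res$call)) {
        out$note[i] <- "conflict_excluded_all"
      } else {
        out$call[i] <- res$call
        out$resolution_method[i] <- res$method
        out$n_considered[i] <- res$n_considered
      }
      next
    }
    if (stars == 0L) {
      out$note[i] <- "zero_star"
      next
    }
    call <- normalizeSignificance(assertions$significance[i])
    if (call == "non_standard") {
      out$note[i] <- "non_standard"
      next
    }
    out$call[i] <- call
    out$resolution_method[i] <- "direct"
  }
  out
}

#' Write the resolved ClinVar subset
#'
#' Persists the pre-step artifact (one row per ClinVar assertion, with the
#' resolved call, method and number of submissions considered) as a TSV.
#'
#' @param resolved Data.frame from [selectClinvarSubset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeResolvedSubset <- function(resolved, path) {
  cols <- c("variation_id", "call", "resolution_method", "n_considered")
  utils::write.table(resolved[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
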