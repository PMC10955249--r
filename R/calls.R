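#' The five-level pathogenicity scale
#'
#' Calls are plain character values on the standard five-level germline
#' pathogenicity scale, ordered from benign to pathogenic:
#' `B < LB < VUS < LP < P`.
#'
#' @return Character vector of the five call labels in increasing severity.
#' @examples
#' callLevels()
#' @export
callLevels <- function() .CALL_LEVELS

.CALL_LEVELS <- c("B", "LB", "VUS", "LP", "P")

.assertCalls <- function(calls) {
  bad <- setdiff(unique(calls), .CALL_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown call value(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.CALL_LEVELS, collapse = ", "), ")")
  }
  invisible(calls)
}

#' Severity rank of calls
#'
#' @param calls Character vector of calls (see [callLevels()]).
#' @return Integer rank, 1 = B (least severe) to 5 = P (most severe).
#' @export
severityRank <- function(calls) {
  .assertCalls(calls)
  match(calls, .CALL_LEVELS)
}

#' Most severe call in a set
#'
#' Returns the call ranked highest under P > LP > VUS > LB > B. This is the
#' reduction used by the `most_severe` conflict tiebreak.
#'
#' @param calls Non-empty character vector of calls.
#' @return A single call.
#' @examples
#' severityMax(c("LB", "VUS", "LP"))
#' @export
severityMax <- function(calls) {
  if (length(calls) == 0L) stop("severityMax() requires a non-empty set of calls")
  .CALL_LEVELS[max(severityRank(calls))]
}
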