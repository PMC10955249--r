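#' @import methods
NULL

.STRENGTH_LEVELS <- c("Unmet", "Supporting", "Moderate", "Strong", "VeryStrong")

#' PVS1 strength vocabulary
#'
#' The graded strengths at which the loss-of-function PVS1 criterion can be
#' applied, ordered `Unmet < Supporting < Moderate < Strong < VeryStrong`.
#'
#' @return Character vector of strength labels in increasing order.
#' @export
strengthLevels <- function() .STRENGTH_LEVELS

.CRITERIA_NAMES <- c(
  paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

#' CriteriaVector: the ACMG-AMP evidence state of one variant
#'
#' Holds the PVS1 strength (graded: Unmet/Supporting/Moderate/Strong/
#' VeryStrong) plus boolean flags for the positional criteria families:
#' PS1-PS4, PM1-PM6, PP1-PP5, BA1, BS1-BS4, BP1-BP7. The PP5 and BP6
#' positions exist so that their removal by [stripPP5BP6()] is observable.
#'
#' @slot pvs1 Character scalar, one of [strengthLevels()].
#' @slot ps Logical(4), PS1-PS4.
#' @slot pm Logical(6), PM1-PM6.
#' @slot pp Logical(5), PP1-PP5.
#' @slot ba1 Logical(1).
#' @slot bs Logical(4), BS1-BS4.
#' @slot bp Logical(7), BP1-BP7.
#' @name CriteriaVector-class
#' @aliases CriteriaVector
#' @exportClass CriteriaVector
setClass("CriteriaVector",
  representation(pvs1 = "character", ps = "logical", pm = "logical",
                 pp = "logical", ba1 = "logical", bs = "logical",
                 bp = "logical"),
  prototype(pvs1 = "Unmet", ps = logical(4), pm = logical(6),
            pp = logical(5), ba1 = FALSE, bs = logical(4), bp = logical(7))
)

setValidity("CriteriaVector", function(object) {
  msg <- character()
  if (length(object@pvs1) != 1L || !(object@pvs1 %in% .STRENGTH_LEVELS))
    msg <- c(msg, paste0("pvs1 must be one of ",
                         paste(.STRENGTH_LEVELS, collapse = ", ")))
  arity <- c(ps = 4L, pm = 6L, pp = 5L, ba1 = 1L, bs = 4L, bp = 7L)
  for (nm in names(arity)) {
    v <- slot(object, nm)
    if (length(v) != arity[[nm]] || anyNA(v))
      msg <- c(msg, paste0(nm, " must be logical(", arity[[nm]], ") without NA"))
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Construct a CriteriaVector
#'
#' @param set Character vector of criterion names to flag, from
#'   `PS1..PS4, PM1..PM6, PP1..PP5, BA1, BS1..BS4, BP1..BP7`.
#' @param pvs1 PVS1 strength, one of [strengthLevels()]; `"VeryStrong"`
#'   corresponds to full-strength PVS1.
#' @return A [CriteriaVector-class] object.
#' @examples
#' criteriaVector(c("PS1", "PM2"), pvs1 = "VeryStrong")
#' @export
criteriaVector <- function(set = character(), pvs1 = "Unmet") {
  bad <- setdiff(set, .CRITERIA_NAMES)
  if (length(bad) > 0L)
    stop("unknown criterion name(s): ", paste(bad, collapse = ", "))
  cv <- new("CriteriaVector", pvs1 = pvs1)
  cv@ps <- paste0("PS", 1:4) %in% set
  cv@pm <- paste0("PM", 1:6) %in% set
  cv@pp <- paste0("PP", 1:5) %in% set
  cv@ba1 <- "BA1" %in% set
  cv@bs <- paste0("BS", 1:4) %in% set
  cv@bp <- paste0("BP", 1:7) %in% set
  validObject(cv)
  cv
}

#' @describeIn CriteriaVector-class names of the flagged boolean criteria
#'   (PVS1 strength is reported separately by [pvs1Strength()]).
#' @param cv A `CriteriaVector`.
#' @export
criteriaNames <- function(cv) {
  stopifnot(is(cv, "CriteriaVector"))
  flags <- c(cv@ps, cv@pm, cv@pp, cv@ba1, cv@bs, cv@bp)
  .CRITERIA_NAMES[flags]
}

#' PVS1 strength accessor
#'
#' @param cv A [CriteriaVector-class].
#' @return The PVS1 strength label.
#' @export
pvs1Strength <- function(cv) {
  stopifnot(is(cv, "CriteriaVector"))
  cv@pvs1
}

#' @rdname pvs1Strength
#' @param value New strength, one of [strengthLevels()].
#' @export
`pvs1Strength<-` <- function(cv, value) {
  cv@pvs1 <- value
  validObject(cv)
  cv
}

setMethod("show", "CriteriaVector", function(object) {
  set <- criteriaNames(object)
  cat("CriteriaVector: PVS1=", object@pvs1,
      if (length(set)) paste0("; ", paste(set, collapse = " ")) else "; no other criteria",
      "\n", sep = "")
})

# serialize back to InterVar's printed evidence layout (fixture generation
# and round-trip tests); call is the verbatim InterVar call string
.formatInterVarEvidence <- function(call, cv) {
  fmt <- function(x, pad) {
    v <- as.integer(c(x, logical(pad - length(x))))
    paste0("[", paste(v, collapse = ", "), "]")
  }
  paste0("InterVar: ", call,
         " PVS1=", as.integer(cv@pvs1 != "Unmet"),
         " PS=", fmt(cv@ps, 5L),
         " PM=", fmt(cv@pm, 7L),
         " PP=", fmt(cv@pp, 6L),
         " BA1=", as.integer(cv@ba1),
         " BS=", fmt(cv@bs, 5L),
         " BP=", fmt(cv@bp, 8L))
}

#' Parse an InterVar evidence cell
#'
#' InterVar prints its call and the full criteria state in one cell of the
#' `.intervar` table, e.g.
#' `"InterVar: Uncertain significance PVS1=1 PS=[0, 0, 0, 0, 0] PM=[0, 1, 0,
#' 0, 0, 0, 0] PP=[0, 0, 0, 0, 0, 0] BA1=0 BS=[0, 0, 0, 0, 0]
#' BP=[0, 0, 0, 0, 0, 0, 0, 0]"`. Bracketed lists are positional and
#' 1-based (PS slot 1 = PS1, ...); InterVar reserves surplus trailing slots
#' beyond the named criteria, which are ignored. Values greater than 1
#' (user-upgraded evidence) count as set. `PVS1=1` maps to strength
#' `VeryStrong`, `PVS1=0` to `Unmet`.
#'
#' @param cell The combined "InterVar and Evidence" cell.
#' @return A list with `call` (InterVar's printed call, verbatim) and
#'   `criteria` (a [CriteriaVector-class]).
#' @export
parseInterVarEvidence <- function(cell) {
  rx <- paste0("^\\s*InterVar:\\s*(.+?)\\s+PVS1=(\\d+)\\s+",
               "PS=\\[([^]]*)\\]\\s+PM=\\[([^]]*)\\]\\s+PP=\\[([^]]*)\\]\\s+",
               "BA1=(\\d+)\\s+BS=\\[([^]]*)\\]\\s+BP=\\[([^]]*)\\]\\s*$")
  m <- regmatches(cell, regexec(rx, cell))[[1L]]
  if (length(m) == 0L) {
    stop("InterVar evidence cell does not match the expected ",
         "'InterVar: <call> PVS1=.. PS=[..] PM=[..] PP=[..] BA1=.. BS=[..] ",
         "BP=[..]' layout: ", cell)
  }
  parseList <- function(s, want, family) {
    if (!nzchar(trimws(s))) return(logical(want))
    v <- suppressWarnings(as.integer(trimws(strsplit(s, ",", fixed = TRUE)[[1L]])))
    if (anyNA(v)) stop("non-integer entry in ", family, " list of cell: ", cell)
    if (length(v) < want)
      stop(family, " list has ", length(v), " slots, expected at least ",
           want, " in cell: ", cell)
    if (length(v) > want && any(v[(want + 1L):length(v)] > 0L))
      message("ignoring set flag in surplus ", family, " slot(s) beyond ",
              family, want)
    v[seq_len(want)] > 0L
  }
  cv <- new("CriteriaVector",
            pvs1 = if (as.integer(m[3L]) > 0L) "VeryStrong" else "Unmet",
            ps = parseList(m[4L], 4L, "PS"),
            pm = parseList(m[5L], 6L, "PM"),
            pp = parseList(m[6L], 5L, "PP"),
            ba1 = as.integer(m[7L]) > 0L,
            bs = parseList(m[8L], 4L, "BS"),
            bp = parseList(m[9L], 7L, "BP"))
  validObject(cv)
  list(call = m[2L], criteria = cv)
}

#' Remove the deprecated PP5 and BP6 criteria
#'
#' PP5 ("reputable source reports pathogenic") and BP6 (its benign mirror)
#' double-count ClinVar evidence in this workflow and current guidance
#' recommends excluding them, so they are cleared before re-combination.
#' All other flags are untouched; the operation is idempotent.
#'
#' @param cv A [CriteriaVector-class].
#' @return The vector with PP5 and BP6 set to `FALSE`.
#' @export
stripPP5BP6 <- function(cv) {
  stopifnot(is(cv, "CriteriaVector"))
  cv@pp[5L] <- FALSE
  cv@bp[6L] <- FALSE
  cv
}

#' Re-weight PVS1 to its graded strength
#'
#' InterVar applies PVS1 at full strength to every putative loss-of-function
#' variant in a LOF-intolerant gene; refined guidance grades PVS1 as
#' VeryStrong/Strong/Moderate/Supporting (or Unmet) per variant. When
#' InterVar set PVS1 and a graded strength is available, PVS1 is replaced by
#' that strength (possibly `Unmet`). The adjustment is demote-only: if
#' InterVar did not flag PVS1 it is never introduced, and if no graded
#' strength is available the original strength is kept with a warning.
#'
#' @param cv A [CriteriaVector-class] parsed from InterVar.
#' @param strength Graded PVS1 strength (one of [strengthLevels()]), or
#'   `NULL`/`NA` when no grading is available for this variant.
#' @return The adjusted [CriteriaVector-class].
#' @export
applyPVS1Strength <- function(cv, strength = NULL) {
  stopifnot(is(cv, "CriteriaVector"))
  if (cv@pvs1 == "Unmet") return(cv)
  if (is.null(strength) || length(strength) == 0L || is.na(strength)) {
    warning("variant has PVS1 set but no graded PVS1 strength available; ",
            "keeping strength ", cv@pvs1)
    return(cv)
  }
  if (!(strength %in% .STRENGTH_LEVELS))
    stop("unknown PVS1 strength: ", strength)
  cv@pvs1 <- strength
  cv
}

#' Evidence counts for the combining rules
#'
#' Collapses a [CriteriaVector-class] to the bucket counts the ACMG-AMP
#' combining rules operate on. PVS1 contributes to the bucket named by its
#' strength (VeryStrong is the only source of the very-strong bucket;
#' Strong joins the PS count, Moderate the PM count, Supporting the PP
#' count). PS criteria are strong, PM moderate, PP supporting; BA1 is the
#' standalone benign criterion, BS strong benign, BP supporting benign.
#'
#' @param cv A [CriteriaVector-class].
#' @return Named integer vector with elements `very_strong`, `strong`,
#'   `moderate`, `supporting`, `standalone_benign`, `strong_benign`,
#'   `supporting_benign`.
#' @export
evidenceCounts <- function(cv) {
  stopifnot(is(cv, "CriteriaVector"))
  c(very_strong = as.integer(cv@pvs1 == "VeryStrong"),
    strong = sum(cv@ps) + as.integer(cv@pvs1 == "Strong"),
    moderate = sum(cv@pm) + as.integer(cv@pvs1 == "Moderate"),
    supporting = sum(cv@pp) + as.integer(cv@pvs1 == "Supporting"),
    standalone_benign = as.integer(cv@ba1),
    strong_benign = sum(cv@bs),
    supporting_benign = sum(cv@bp))
}

#' ACMG-AMP combining rules over evidence counts
#'
#' Vectorized implementation of the standard combining table. Pathogenic
#' fires for 1 VeryStrong with (>=1 Strong, or >=2 Moderate, or 1 Moderate +
#' 1 Supporting, or >=2 Supporting), for >=2 Strong, or for 1 Strong with
#' (>=3 Moderate, or 2 Moderate + >=2 Supporting, or 1 Moderate + >=4
#' Supporting). Likely pathogenic fires for 1 VeryStrong + 1 Moderate,
#' 1 Strong + 1-2 Moderate, 1 Strong + >=2 Supporting, >=3 Moderate,
#' 2 Moderate + >=2 Supporting, or 1 Moderate + >=4 Supporting. Benign fires
#' for BA1 or >=2 strong-benign; likely benign for 1 strong-benign + >=1
#' supporting-benign, or >=2 supporting-benign. If a pathogenic-group rule
#' and a benign-group rule both fire the evidence is contradictory and the
#' result is VUS; if no rule fires the result is VUS.
#'
#' @param very_strong 0/1 per variant (PVS1 at full strength).
#' @param strong,moderate,supporting Non-negative pathogenic-side counts.
#' @param standalone_benign 0/1 per variant (BA1).
#' @param strong_benign,supporting_benign Non-negative benign-side counts.
#' @return Character vector of calls, one per input tuple.
#' @examples
#' combineCounts(1, 1, 0, 0, 0, 0, 0)  # "P"
#' combineCounts(1, 0, 1, 0, 0, 0, 0)  # "LP"
#' @export
combineCounts <- function(very_strong, strong, moderate, supporting,
                          standalone_benign, strong_benign,
                          supporting_benign) {
  n <- max(length(very_strong), length(strong), length(moderate),
           length(supporting), length(standalone_benign),
           length(strong_benign), length(supporting_benign))
  vs <- rep_len(as.integer(very_strong), n)
  s <- rep_len(as.integer(strong), n)
  m <- rep_len(as.integer(moderate), n)
  su <- rep_len(as.integer(supporting), n)
  ba <- rep_len(as.integer(standalone_benign), n)
  bsn <- rep_len(as.integer(strong_benign), n)
  bpn <- rep_len(as.integer(supporting_benign), n)

  all_counts <- c(vs, s, m, su, ba, bsn, bpn)
  if (anyNA(all_counts) || any(all_counts < 0L))
    stop("evidence counts must be non-negative integers")
  if (any(vs > 1L) || any(ba > 1L))
    stop("very_strong and standalone_benign are 0/1 counts")

  p_fire <- (vs == 1L & (s >= 1L | m >= 2L | (m == 1L & su == 1L) | su >= 2L)) |
    s >= 2L |
    (s == 1L & (m >= 3L | (m == 2L & su >= 2L) | (m == 1L & su >= 4L)))
  lp_fire <- (vs == 1L & m == 1L) |
    (s == 1L & (m == 1L | m == 2L)) |
    (s == 1L & su >= 2L) |
    m >= 3L |
    (m == 2L & su >= 2L) |
    (m == 1L & su >= 4L)
  b_fire <- ba == 1L | bsn >= 2L
  lb_fire <- (bsn == 1L & bpn >= 1L) | bpn >= 2L

  path_group <- p_fire | lp_fire
  benign_group <- b_fire | lb_fire

  out <- rep("VUS", n)
  out[path_group & !benign_group & p_fire] <- "P"
  out[path_group & !benign_group & !p_fire] <- "LP"
  out[benign_group & !path_group & b_fire] <- "B"
  out[benign_group & !path_group & !b_fire] <- "LB"
  out
}

#' Combine a CriteriaVector into a five-level call
#'
#' @param cv A [CriteriaVector-class] (post-modification).
#' @return A single call from [callLevels()].
#' @export
acmgCombine <- function(cv) {
  ct <- evidenceCounts(cv)
  combineCounts(ct[["very_strong"]], ct[["strong"]], ct[["moderate"]],
                ct[["supporting"]], ct[["standalone_benign"]],
                ct[["strong_benign"]], ct[["supporting_benign"]])
}

# human-readable trace of the rule groups that fired, for the full output's
# provenance column
.acmgRuleTrace <- function(cv) {
  ct <- evidenceCounts(cv)
  call <- acmgCombine(cv)
  counts <- paste0("VS=", ct[["very_strong"]], ",S=", ct[["strong"]],
                   ",M=", ct[["moderate"]], ",SU=", ct[["supporting"]],
                   ",BA1=", ct[["standalone_benign"]],
                   ",BS=", ct[["strong_benign"]],
                   ",BP=", ct[["supporting_benign"]])
  path <- combineCounts(ct[["very_strong"]], ct[["strong"]], ct[["moderate"]],
                        ct[["supporting"]], 0, 0, 0)
  benign <- combineCounts(0, 0, 0, 0, ct[["standalone_benign"]],
                          ct[["strong_benign"]], ct[["supporting_benign"]])
  lab <- if (call == "VUS" && path != "VUS" && benign != "VUS") {
    "contradictory"
  } else if (call == "VUS") "none" else call
  paste0(lab, "(", counts, ")")
}

#' Modified-InterVar classification of one variant
#'
#' The complete re-scoring pipeline applied to a raw InterVar evidence
#' vector: strip PP5/BP6, re-weight PVS1 to its graded strength
#' (demote-only), and re-derive the call from the combining rules.
#'
#' @param cv A raw [CriteriaVector-class] parsed from InterVar.
#' @param strength Graded PVS1 strength, or `NULL` when unavailable.
#' @return List with `call`, `criteria` (the modified vector) and `rule`
#'   (trace of the rule group that fired).
#' @export
intervarModifiedCall <- function(cv, strength = NULL) {
  mod <- applyPVS1Strength(stripPP5BP6(cv), strength)
  list(call = acmgCombine(mod), criteria = mod, rule = .acmgRuleTrace(mod))
}
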