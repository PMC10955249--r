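#' VepVcf: a VEP-annotated VCF in memory
#'
#' Container for the variant universe of one run: the fixed VCF columns,
#' per-record parsed CSQ (per-transcript) annotation entries, the genotype
#' matrix, header field declarations, and the normalized variant keys used
#' to join all other tables.
#'
#' @slot fix Data.frame with the fixed VCF columns (CHROM, POS, ID, REF,
#'   ALT, QUAL, FILTER, INFO) plus normalized key columns `contig`, `npos`,
#'   `nref`, `nalt` and the string key `vid`.
#' @slot csq List (one element per record) of character matrices; columns
#'   are the CSQ fields declared in the header, rows the transcript
#'   annotations of that record.
#' @slot csqFields Character vector: the CSQ field names, exactly as
#'   declared by the header's `Format:` clause.
#' @slot gt Character matrix of the VCF FORMAT/sample columns (or a
#'   0-column matrix when absent).
#' @slot infoMeta,formatMeta Data.frames of header INFO/FORMAT declarations
#'   (`ID`, `Type`).
#' @slot chrStyle `"chr"` if the input VCF used chr-prefixed contigs,
#'   otherwise `""`; outputs re-emit contigs in this style.
#' @name VepVcf-class
#' @aliases VepVcf
#' @exportClass VepVcf
setClass("VepVcf",
  representation(fix = "data.frame", csq = "list", csqFields = "character",
                 gt = "matrix", infoMeta = "data.frame",
                 formatMeta = "data.frame", chrStyle = "character"))

setValidity("VepVcf", function(object) {
  if (length(object@csq) != nrow(object@fix))
    return("one CSQ entry list is required per VCF record")
  TRUE
})

setMethod("show", "VepVcf", function(object) {
  cat("VepVcf with", nrow(object@fix), "variant record(s),",
      length(object@csqFields), "CSQ fields,",
      max(0L, ncol(object@gt) - 1L), "sample(s)\n")
})

#' Number of records in a VepVcf
#' @param x A [VepVcf-class].
#' @export
setMethod("length", "VepVcf", function(x) nrow(x@fix))

#' Normalized variant keys of a VepVcf
#' @param x A [VepVcf-class].
#' @return Data.frame with `contig`, `pos`, `ref`, `alt`, `vid`.
#' @export
variantKeys <- function(x) {
  stopifnot(is(x, "VepVcf"))
  data.frame(contig = x@fix$contig, pos = x@fix$npos, ref = x@fix$nref,
             alt = x@fix$nalt, vid = x@fix$vid, stringsAsFactors = FALSE)
}

#' FILTER column of a VepVcf
#' @param x A [VepVcf-class].
#' @export
filterStatus <- function(x) {
  stopifnot(is(x, "VepVcf"))
  x@fix$FILTER
}

#' CSQ entries of one record
#' @param x A [VepVcf-class].
#' @param i Record index.
#' @return Character matrix, one row per transcript annotation.
#' @export
csqEntries <- function(x, i) {
  stopifnot(is(x, "VepVcf"))
  x@csq[[i]]
}

# header INFO/FORMAT declarations from vcfR meta lines
.parseHeaderMeta <- function(meta, kind) {
  rx <- paste0("^##", kind, "=<")
  lines <- grep(rx, meta, value = TRUE)
  ids <- sub('^.*[<,]ID=([^,>]+).*$', "\\1", lines)
  types <- ifelse(grepl("Type=", lines),
                  sub('^.*Type=([^,>]+).*$', "\\1", lines), NA_character_)
  data.frame(ID = ids, Type = types, stringsAsFactors = FALSE)
}

.extractInfoField <- function(info, field) {
  rx <- paste0("(?:^|;)", field, "=([^;]*)")
  m <- regmatches(info, regexec(rx, info))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read a VEP-annotated VCF
#'
#' Accepts plain or gzipped VCF. The header must declare the CSQ INFO field
#' with its `Format:` clause; each data row must carry at least one CSQ
#' transcript annotation (the transcript-selection step needs one).
#'
#' @param path Path to the `*VEP.vcf(.gz)` file.
#' @return A [VepVcf-class] object; records keep the file order.
#' @export
readVepVcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  csqLine <- grep("^##INFO=<ID=CSQ[,>]", meta, value = TRUE)
  if (length(csqLine) == 0L)
    stop("VCF header does not declare the CSQ INFO field; ",
         "a VEP-annotated VCF (with ##INFO=<ID=CSQ,...Format: ...>) is required")
  fmt <- regmatches(csqLine[1L], regexec("Format:\\s*([A-Za-z0-9_|]+)", csqLine[1L]))[[1L]]
  if (length(fmt) < 2L)
    stop("CSQ INFO declaration lacks a 'Format:' field list")
  csqFields <- strsplit(fmt[2L], "|", fixed = TRUE)[[1L]]

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (!is.null(v@gt) && length(dim(v@gt)) == 2L && ncol(v@gt) > 0L)
    v@gt else matrix(character(), nrow = nrow(fix), ncol = 0L)

  if (nrow(fix) > 0L && anyNA(fix$FILTER))
    fix$FILTER[is.na(fix$FILTER)] <- "."

  keys <- if (nrow(fix) > 0L) {
    tryCatch(
      normalizeVariant(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
      error = function(e) stop("malformed VCF record among data rows 1-",
                               nrow(fix), ": ", conditionMessage(e)))
  } else {
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  }
  fix$contig <- keys$contig
  fix$npos <- keys$pos
  fix$nref <- keys$ref
  fix$nalt <- keys$alt
  fix$vid <- variantId(keys)

  csq <- vector("list", nrow(fix))
  if (nrow(fix) > 0L) {
    raw <- .extractInfoField(fix$INFO, "CSQ")
    for (i in seq_len(nrow(fix))) {
      if (is.na(raw[i]) || !nzchar(raw[i]))
        stop("VCF data row ", i, " has no CSQ transcript annotation; ",
             "every record must carry at least one")
      entries <- strsplit(raw[i], ",", fixed = TRUE)[[1L]]
      m <- matrix("", nrow = length(entries), ncol = length(csqFields),
                  dimnames = list(NULL, csqFields))
      for (j in seq_along(entries)) {
        parts <- strsplit(entries[j], "|", fixed = TRUE)[[1L]]
        if (length(parts) > length(csqFields))
          stop("VCF data row ", i, ": CSQ entry has ", length(parts),
               " fields but the header declares ", length(csqFields))
        m[j, seq_along(parts)] <- parts
      }
      csq[[i]] <- m
    }
  }

  chrStyle <- if (nrow(fix) > 0L && any(grepl("^chr", fix$CHROM))) "chr" else ""
  new("VepVcf", fix = fix, csq = csq, csqFields = csqFields, gt = gt,
      infoMeta = .parseHeaderMeta(meta, "INFO"),
      formatMeta = .parseHeaderMeta(meta, "FORMAT"),
      chrStyle = chrStyle)
}

.readTsv <- function(path, comment.char = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = comment.char,
                    colClasses = "character")
}

#' Read an InterVar output table
#'
#' Parses the `*multianno.txt.intervar` TSV. The combined
#' `InterVar: InterVar and Evidence` column is parsed into the printed call
#' and a [CriteriaVector-class] via [parseInterVarEvidence()]. Coordinates
#' are InterVar's ANNOVAR-style Chr/Start/End/Ref/Alt (indels use `-`
#' alleles); the pipeline maps them back to VCF keys through the multianno
#' bridge.
#'
#' @param path Path to the InterVar output file.
#' @return Data.frame with columns `Chr`, `Start`, `End`, `Ref`, `Alt`,
#'   `gene`, `original_call`, `evidence` (the verbatim cell) and
#'   list-column `criteria`.
#' @export
readIntervar <- function(path) {
  d <- .readTsv(path)
  evCol <- grep("InterVar.*Evidence", names(d))
  if (length(evCol) == 0L)
    stop("InterVar table lacks the combined 'InterVar: InterVar and ",
         "Evidence' column: ", path)
  evCol <- evCol[1L]
  chrCol <- if ("#Chr" %in% names(d)) "#Chr" else "Chr"
  geneCol <- if ("Ref.Gene" %in% names(d)) "Ref.Gene" else
    grep("Gene", names(d), value = TRUE)[1L]
  n <- nrow(d)
  parsed <- lapply(seq_len(n), function(i) parseInterVarEvidence(d[[evCol]][i]))
  data.frame(
    Chr = if (n) sub("^chr", "", d[[chrCol]]) else character(),
    Start = if (n) as.integer(d$Start) else integer(),
    End = if (n) as.integer(d$End) else integer(),
    Ref = if (n) d$Ref else character(),
    Alt = if (n) d$Alt else character(),
    gene = if (n && !is.na(geneCol)) d[[geneCol]] else rep("", n),
    original_call = vapply(parsed, `[[`, character(1), "call"),
    evidence = if (n) d[[evCol]] else character(),
    criteria = I(lapply(parsed, `[[`, "criteria")),
    stringsAsFactors = FALSE
  )
}

#' Read an AutoPVS1 output table
#'
#' Parses the `*autopvs1.txt` TSV: one row per variant graded for PVS1,
#' with the variant (`chrom-pos-ref-alt` string), the transcript the
#' grading applies to, the consequence, the decision-path criterion code
#' and the graded strength. Strength tokens are normalized to the
#' five-level vocabulary (a `Strength.` prefix is tolerated; `NA`, empty or
#' `Unset` map to `Unmet`). Variants absent from the file simply yield no
#' record.
#'
#' @param path Path to the AutoPVS1 output file.
#' @return Data.frame with columns `vid`, `transcript`, `consequence`,
#'   `criterion`, `strength`.
#' @export
readAutopvs1 <- function(path) {
  d <- .readTsv(path)
  vcol <- intersect(c("variant_id", "vcf_id", "variant"), names(d))
  if (length(vcol) == 0L)
    stop("AutoPVS1 table lacks a variant identifier column ",
         "(variant_id/vcf_id/variant): ", path)
  vcol <- vcol[1L]
  tcol <- intersect(c("trans_name", "transcript"), names(d))[1L]
  n <- nrow(d)
  if (n == 0L)
    return(data.frame(vid = character(), transcript = character(),
                      consequence = character(), criterion = character(),
                      strength = character(), stringsAsFactors = FALSE))

  raw <- sub("^Strength\\.", "", trimws(d$strength))
  raw[is.na(raw) | raw %in% c("", "NA", "Unset")] <- "Unmet"
  ok <- c("VeryStrong", "Strong", "Moderate", "Supporting", "Unmet")
  if (!all(raw %in% ok))
    stop("unrecognized AutoPVS1 strength token(s): ",
         paste(sQuote(unique(raw[!(raw %in% ok)])), collapse = ", "),
         "; accepted: Strength.VeryStrong/Strong/Moderate/Supporting, ",
         "Unmet, Unset, NA")
  strength <- raw

  parts <- strsplit(d[[vcol]], "-", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L)
    stop("AutoPVS1 row ", bad[1L], ": variant identifier ",
         sQuote(d[[vcol]][bad[1L]]), " is not chrom-pos-ref-alt")
  keys <- normalizeVariant(vapply(parts, `[[`, "", 1L),
                           as.integer(vapply(parts, `[[`, "", 2L)),
                           vapply(parts, `[[`, "", 3L),
                           vapply(parts, `[[`, "", 4L))
  data.frame(
    vid = variantId(keys),
    transcript = if (!is.na(tcol)) d[[tcol]] else rep("", n),
    consequence = if ("consequence" %in% names(d)) d$consequence else rep("", n),
    criterion = if ("criterion" %in% names(d)) d$criterion else rep("", n),
    strength = strength,
    stringsAsFactors = FALSE
  )
}

#' Read an ANNOVAR multianno table (pass-through annotations)
#'
#' The multianno table produced with ANNOVAR's `--vcfinput` flag carries
#' the original VCF columns in trailing `Otherinfo` columns; the variant
#' key is re-derived from those (Otherinfo4-8 = CHROM, POS, ID, REF, ALT)
#' rather than from ANNOVAR's indel-shifted Start/End. The table is used
#' only for pass-through annotation columns and for bridging InterVar's
#' ANNOVAR-style coordinates back to VCF keys; classification never depends
#' on it.
#'
#' @param path Path to the `*_multianno.txt` file.
#' @return Data.frame of the original columns plus `vid` (normalized key)
#'   and `annovar_key` (`Chr:Start:End:Ref:Alt`, for the InterVar bridge).
#' @export
readAnnovarMultianno <- function(path) {
  d <- .readTsv(path)
  need <- paste0("Otherinfo", 4:8)
  if (!all(need %in% names(d)))
    stop("multianno table lacks the original-VCF Otherinfo columns ",
         "(Otherinfo4..Otherinfo8 = CHROM, POS, ID, REF, ALT); ",
         "run ANNOVAR with --vcfinput: ", path)
  n <- nrow(d)
  if (n == 0L) {
    d$vid <- character()
    d$annovar_key <- character()
    return(d)
  }
  keys <- normalizeVariant(d$Otherinfo4, as.integer(d$Otherinfo5),
                           d$Otherinfo7, d$Otherinfo8)
  d$vid <- variantId(keys)
  d$annovar_key <- paste(sub("^chr", "", d$Chr), d$Start, d$End, d$Ref,
                         d$Alt, sep = ":")
  d
}

.parseConceptIds <- function(reported) {
  lapply(strsplit(as.character(reported), ";", fixed = TRUE), function(parts) {
    ids <- sub(":.*$", "", trimws(parts))
    unique(ids[grepl("^C[N]?\\d+$", ids)])
  })
}

.parseSubmissionDate <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso])
  mon <- grepl("^[A-Za-z]{3} \\d{1,2}, \\d{4}$", x)
  if (any(mon)) {
    lc <- Sys.getlocale("LC_TIME")
    on.exit(suppressWarnings(Sys.setlocale("LC_TIME", lc)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_TIME", "C"))
    out[mon] <- as.Date(x[mon], format = "%b %d, %Y")
  }
  out
}

#' Read the three ClinVar distribution files
#'
#' Loads `clinvar.vcf.gz` (key-to-VariationID map), `variant_summary.txt.gz`
#' (per-assembly aggregate significance and review status; rows for other
#' assemblies are dropped) and `submission_summary.txt.gz` (per-submitter
#' assertions, grouped by VariationID). Aggregate significance and review
#' status are taken from variant_summary, the per-build authority; when a
#' VariationID in the ClinVar VCF has no variant_summary row for the
#' requested build, the VCF's own CLNSIG/CLNREVSTAT are used and a message
#' is emitted. Variation IDs with no submissions resolve to an empty
#' submission list.
#'
#' @param vcf_path Path to the ClinVar VCF (plain or gzip).
#' @param variant_summary_path Path to variant_summary.txt(.gz).
#' @param submission_summary_path Path to submission_summary.txt(.gz);
#'   leading `#` comment lines are tolerated.
#' @param build Genome build tag, `"GRCh38"` (default) or `"GRCh37"`.
#' @return List with `assertions` (data.frame: `vid`, `variation_id`,
#'   `significance`, `review_status`, `stars`) and `submissions_by_id`
#'   (list of data.frames keyed by VariationID: `variation_id`,
#'   `significance`, `date_last_evaluated`, `assertion_criteria_provided`,
#'   `concept_ids` list-column, `submitter`).
#' @export
readClinvarFiles <- function(vcf_path, variant_summary_path,
                             submission_summary_path,
                             build = c("GRCh38", "GRCh37")) {
  build <- match.arg(build)

  cv <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(cv@fix, stringsAsFactors = FALSE)
  if (nrow(fix) > 0L) {
    keys <- normalizeVariant(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
    vcfMap <- data.frame(
      vid = variantId(keys),
      variation_id = as.integer(fix$ID),
      vcf_sig = gsub("_", " ", .extractInfoField(fix$INFO, "CLNSIG")),
      vcf_rev = gsub("_", " ", .extractInfoField(fix$INFO, "CLNREVSTAT")),
      stringsAsFactors = FALSE
    )
  } else {
    vcfMap <- data.frame(vid = character(), variation_id = integer(),
                         vcf_sig = character(), vcf_rev = character(),
                         stringsAsFactors = FALSE)
  }

  vs <- .readTsv(variant_summary_path)
  names(vs)[1L] <- sub("^#", "", names(vs)[1L])
  vs <- vs[vs$Assembly == build, , drop = FALSE]
  idx <- match(vcfMap$variation_id, as.integer(vs$VariationID))

  significance <- ifelse(is.na(idx), vcfMap$vcf_sig,
                         vs$ClinicalSignificance[idx])
  review <- ifelse(is.na(idx), vcfMap$vcf_rev, vs$ReviewStatus[idx])
  if (anyNA(idx) && nrow(vcfMap) > 0L)
    message(sum(is.na(idx)), " ClinVar VCF variant(s) without a ", build,
            " variant_summary row; using the VCF's CLNSIG/CLNREVSTAT")
  disagree <- !is.na(idx) & !is.na(vcfMap$vcf_sig) &
    tolower(vcfMap$vcf_sig) != tolower(significance)
  if (any(disagree))
    message(sum(disagree), " variant(s) where ClinVar VCF CLNSIG disagrees ",
            "with variant_summary; variant_summary wins")

  assertions <- data.frame(
    vid = vcfMap$vid,
    variation_id = vcfMap$variation_id,
    significance = significance,
    review_status = review,
    stars = if (nrow(vcfMap) > 0L) starsFromReviewStatus(review) else integer(),
    stringsAsFactors = FALSE
  )

  # submission summary: real files carry leading '#' comment lines and a
  # '#'-prefixed header line; locate the header ourselves
  con <- gzfile(submission_summary_path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  hdr <- grep("VariationID", lines)[1L]
  if (is.na(hdr)) stop("submission summary has no VariationID header line: ",
                       submission_summary_path)
  body <- lines[hdr:length(lines)]
  body[1L] <- sub("^#", "", body[1L])
  ss <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  sigCol <- intersect(c("ClinicalSignificance", "SubmittedClinicalSignificance"),
                      names(ss))[1L]
  if (is.na(sigCol))
    stop("submission summary lacks a ClinicalSignificance column")
  submissions <- data.frame(
    variation_id = as.integer(ss$VariationID),
    significance = ss[[sigCol]],
    date_last_evaluated = .parseSubmissionDate(ss$DateLastEvaluated),
    assertion_criteria_provided =
      !grepl("no (assertion|classification)", tolower(ss$ReviewStatus)),
    submitter = if ("Submitter" %in% names(ss)) ss$Submitter else "",
    stringsAsFactors = FALSE
  )
  submissions$concept_ids <- .parseConceptIds(ss$ReportedPhenotypeInfo)

  list(assertions = assertions,
       submissions_by_id = split(submissions, submissions$variation_id))
}

#' Read a MedGen Concept ID list
#'
#' @param path Plain-text file, one Concept ID per line; blank lines and
#'   `#` comments are ignored.
#' @return Character vector of Concept IDs.
#' @export
readConceptIds <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
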