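#' Parse a filter-criteria string
#'
#' Grammar: comma-separated `FIELD OP VALUE` tokens, e.g.
#' `"DP>=10,AF<0.001"`. `FIELD` is a VCF INFO or FORMAT key; `OP` is one of
#' `<, <=, >, >=, ==, !=`; `VALUE` is a number or a bare string. All
#' criteria are conjunctive (a record must satisfy every one).
#'
#' @param spec The criteria string; `""` or `NULL` means no extra criteria.
#' @return List of criteria, each `list(field, op, value)`.
#' @export
parseFilterCriteria <- function(spec) {
  if (is.null(spec) || !nzchar(trimws(spec))) return(list())
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
  lapply(tokens[nzchar(tokens)], function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z0-9_.]+)\\s*(<=|>=|==|!=|<|>)\\s*(.+)$", tok))[[1L]]
    if (length(m) != 4L)
      stop("cannot parse filter criterion ", sQuote(tok),
           "; expected FIELD OP VALUE with OP in <, <=, >, >=, ==, !=")
    val <- suppressWarnings(as.numeric(m[4L]))
    list(field = m[2L], op = m[3L],
         value = if (is.na(val)) m[4L] else val)
  })
}

.compareOp <- function(x, op, value) {
  switch(op,
         "<" = x < value, "<=" = x <= value,
         ">" = x > value, ">=" = x >= value,
         "==" = x == value, "!=" = x != value,
         stop("unknown operator ", op))
}

# per-record value of a FORMAT field on the single germline sample
.formatFieldValues <- function(vep, field) {
  gt <- vep@gt
  if (ncol(gt) < 2L)
    stop("filter criterion on FORMAT field ", field,
         " but the VCF carries no sample column")
  if (ncol(gt) > 2L)
    stop("FORMAT-field filters require a single-sample VCF; found ",
         ncol(gt) - 1L, " samples")
  keys <- strsplit(gt[, 1L], ":", fixed = TRUE)
  vals <- strsplit(gt[, 2L], ":", fixed = TRUE)
  vapply(seq_along(keys), function(i) {
    j <- match(field, keys[[i]])
    if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
  }, character(1))
}

#' Filter VCF records
#'
#' Keeps records whose FILTER is exactly `"PASS"` and which satisfy every
#' user criterion. Criteria referencing a field the header does not declare
#' are an error before any record is processed. A record where a criterion's
#' field is missing (or not numeric for a numeric comparison) fails that
#' criterion and is dropped; drop counts per reason are returned.
#'
#' @param vep A [VepVcf-class].
#' @param criteria List from [parseFilterCriteria()].
#' @return List with `vep` (the filtered [VepVcf-class], order preserved)
#'   and `dropped` (named integer vector of drop counts per reason).
#' @export
applyFilters <- function(vep, criteria = list()) {
  stopifnot(is(vep, "VepVcf"))
  for (cr in criteria) {
    if (!(cr$field %in% vep@infoMeta$ID) &&
        !(cr$field %in% vep@formatMeta$ID))
      stop("filter criterion references field ", sQuote(cr$field),
           " which the VCF header declares neither as INFO nor FORMAT")
  }
  n <- length(vep)
  keep <- filterStatus(vep) == "PASS"
  dropped <- c(not_pass = sum(!keep))
  for (cr in criteria) {
    raw <- if (cr$field %in% vep@infoMeta$ID) {
      .extractInfoField(vep@fix$INFO, cr$field)
    } else {
      .formatFieldValues(vep, cr$field)
    }
    ok <- if (is.numeric(cr$value)) {
      v <- suppressWarnings(as.numeric(raw))
      !is.na(v) & .compareOp(v, cr$op, cr$value)
    } else {
      !is.na(raw) & .compareOp(raw, cr$op, cr$value)
    }
    reason <- paste0("fail_", cr$field, cr$op, cr$value)
    dropped[reason] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- vep
  out@fix <- vep@fix[keep, , drop = FALSE]
  out@csq <- vep@csq[keep]
  out@gt <- vep@gt[keep, , drop = FALSE]
  validObject(out)
  list(vep = out, dropped = dropped)
}

.stripVersion <- function(x) sub("\\.\\d+$", "", x)

#' Select the primary transcript annotation for one record
#'
#' The variant is annotated to a single transcript: the CSQ entry whose
#' `Feature` matches the transcript graded for PVS1 (version-insensitive);
#' when no such entry exists, the entry flagged `CANONICAL`/`PICK`, else the
#' first entry. All other entries are retained for the `csq_vep` output
#' column.
#'
#' @param vep A [VepVcf-class].
#' @param i Record index.
#' @param autopvs1_transcript Transcript identifier from the AutoPVS1 row
#'   for this variant, or `NA`/`NULL` when absent.
#' @return List with `primary` (named character vector, the chosen CSQ
#'   entry) and `retained` (character matrix of the remaining entries).
#' @export
selectTranscript <- function(vep, i, autopvs1_transcript = NULL) {
  m <- csqEntries(vep, i)
  if (is.null(m) || nrow(m) == 0L)
    stop("record ", i, " has no CSQ entries")
  pick <- NA_integer_
  if (!is.null(autopvs1_transcript) && length(autopvs1_transcript) == 1L &&
      !is.na(autopvs1_transcript) && nzchar(autopvs1_transcript) &&
      "Feature" %in% colnames(m)) {
    hit <- which(.stripVersion(m[, "Feature"]) ==
                   .stripVersion(autopvs1_transcript))
    if (length(hit) > 0L) pick <- hit[1L]
  }
  if (is.na(pick) && "CANONICAL" %in% colnames(m)) {
    hit <- which(toupper(m[, "CANONICAL"]) == "YES")
    if (length(hit) > 0L) pick <- hit[1L]
  }
  if (is.na(pick) && "PICK" %in% colnames(m)) {
    hit <- which(m[, "PICK"] == "1")
    if (length(hit) > 0L) pick <- hit[1L]
  }
  if (is.na(pick)) pick <- 1L
  list(primary = m[pick, ],
       retained = m[-pick, , drop = FALSE])
}

#' Run configuration
#'
#' @param vep_vcf,multianno,intervar,autopvs1 Paths to the per-cohort
#'   inputs: VEP-annotated VCF, ANNOVAR multianno table (`--vcfinput`
#'   layout), InterVar output table, AutoPVS1 output table.
#' @param clinvar_vcf,variant_summary,submission_summary Paths to the three
#'   ClinVar distribution files.
#' @param concept_list Optional path to a MedGen Concept ID list.
#' @param tiebreak `"latest"` or `"most_severe"` (see
#'   [resolutionOptions()]).
#' @param filter_criteria Filter string (see [parseFilterCriteria()]).
#' @param out_prefix Output path prefix; the run writes
#'   `<prefix>.abridged.tsv`, `<prefix>.full.tsv`,
#'   `<prefix>.clinvar_subset.tsv` and `<prefix>.summary.log`.
#' @param build Genome build, `"GRCh38"` (default) or `"GRCh37"`.
#' @return A validated `RunConfig` list.
#' @export
runConfig <- function(vep_vcf, multianno, intervar, autopvs1, clinvar_vcf,
                      variant_summary, submission_summary,
                      concept_list = NULL,
                      tiebreak = c("latest", "most_severe"),
                      filter_criteria = "", out_prefix,
                      build = c("GRCh38", "GRCh37")) {
  tiebreak <- match.arg(tiebreak)
  build <- match.arg(build)
  paths <- c(vep_vcf = vep_vcf, multianno = multianno, intervar = intervar,
             autopvs1 = autopvs1, clinvar_vcf = clinvar_vcf,
             variant_summary = variant_summary,
             submission_summary = submission_summary)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = "; "))
  if (!is.null(concept_list) && !file.exists(concept_list))
    stop("concept list not found: ", concept_list)
  structure(list(vep_vcf = vep_vcf, multianno = multianno,
                 intervar = intervar, autopvs1 = autopvs1,
                 clinvar_vcf = clinvar_vcf, variant_summary = variant_summary,
                 submission_summary = submission_summary,
                 concept_list = concept_list, tiebreak = tiebreak,
                 filter_criteria = filter_criteria, out_prefix = out_prefix,
                 build = build),
            class = "RunConfig")
}

#' Classify the variants of a filtered VCF
#'
#' The per-variant decision: a variant with a usable ClinVar classification
#' (see [selectClinvarSubset()]) takes it (source `ClinVar`); otherwise the
#' modified InterVar classification applies (source `InterVar`, resolution
#' method `not_in_clinvar`, with the ClinVar absence reason in the note). A
#' variant with neither an InterVar row nor a ClinVar call is emitted as
#' VUS with a `no_evidence` note and a warning, never silently dropped.
#'
#' @param vep Filtered [VepVcf-class].
#' @param clinvarSubset Data.frame from [selectClinvarSubset()].
#' @param intervar Data.frame from [readIntervar()], with a `vid` column
#'   already attached (see [runPipeline()] for the multianno bridge).
#' @param autopvs1 Data.frame from [readAutopvs1()].
#' @return Data.frame, one row per record: `vid`, `final_call`,
#'   `call_source`, `clinvar_stars`, `resolution_method`, `variation_id`,
#'   `intervar_call`, `intervar_rule`, `note`.
#' @export
classifyVariants <- function(vep, clinvarSubset, intervar, autopvs1) {
  n <- length(vep)
  vids <- vep@fix$vid
  cvIdx <- match(vids, clinvarSubset$vid)
  ivIdx <- match(vids, intervar$vid)
  apIdx <- match(vids, autopvs1$vid)

  out <- data.frame(
    vid = vids,
    final_call = NA_character_,
    call_source = NA_character_,
    clinvar_stars = NA_integer_,
    resolution_method = NA_character_,
    variation_id = NA_integer_,
    intervar_call = NA_character_,
    intervar_rule = NA_character_,
    note = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ci <- cvIdx[i]
    clinvar_note <- NA_character_
    if (!is.na(ci)) {
      out$variation_id[i] <- clinvarSubset$variation_id[ci]
      if (!is.na(clinvarSubset$call[ci])) {
        out$final_call[i] <- clinvarSubset$call[ci]
        out$call_source[i] <- "ClinVar"
        out$clinvar_stars[i] <- clinvarSubset$stars[ci]
        out$resolution_method[i] <- clinvarSubset$resolution_method[ci]
        next
      }
      clinvar_note <- clinvarSubset$note[ci]
    }
    ii <- ivIdx[i]
    if (is.na(ii)) {
      warning("variant ", vids[i], " absent from the InterVar table and ",
              "unclassified by ClinVar; emitting VUS (no_evidence)")
      out$final_call[i] <- "VUS"
      out$call_source[i] <- "InterVar"
      out$resolution_method[i] <- "not_in_clinvar"
      out$note[i] <- paste(stats::na.omit(c(clinvar_note, "no_evidence")),
                           collapse = ";")
      next
    }
    strength <- if (!is.na(apIdx[i])) autopvs1$strength[apIdx[i]] else NULL
    mod <- intervarModifiedCall(intervar$criteria[[ii]], strength)
    out$final_call[i] <- mod$call
    out$call_source[i] <- "InterVar"
    out$resolution_method[i] <- "not_in_clinvar"
    out$intervar_call[i] <- intervar$original_call[ii]
    out$intervar_rule[i] <- mod$rule
    out$note[i] <- if (is.na(clinvar_note)) "not_in_clinvar" else clinvar_note
  }
  out
}

# map InterVar's ANNOVAR-style rows to VCF keys: primary route is the
# multianno bridge (same ANNOVAR coordinates, carries the original VCF
# columns); rows with plain ACGT alleles fall back to direct normalization
.attachIntervarVids <- function(intervar, multianno) {
  if (nrow(intervar) == 0L) {
    intervar$vid <- character()
    return(intervar)
  }
  akey <- paste(intervar$Chr, intervar$Start, intervar$End, intervar$Ref,
                intervar$Alt, sep = ":")
  vid <- multianno$vid[match(akey, multianno$annovar_key)]
  direct <- is.na(vid) & grepl("^[ACGTN]+$", intervar$Ref) &
    grepl("^[ACGTN]+$", intervar$Alt)
  if (any(direct)) {
    keys <- normalizeVariant(intervar$Chr[direct], intervar$Start[direct],
                             intervar$Ref[direct], intervar$Alt[direct])
    vid[direct] <- variantId(keys)
  }
  if (anyNA(vid))
    message(sum(is.na(vid)), " InterVar row(s) could not be mapped to a ",
            "VCF key (no multianno bridge, non-sequence alleles); ignored")
  intervar$vid <- vid
  intervar[!is.na(vid), , drop = FALSE]
}

#' Run the full classification pipeline
#'
#' End-to-end composition: read the seven inputs, filter to PASS (plus user
#' criteria), select the usable ClinVar subset, classify every surviving
#' variant, pick its primary transcript, and write the abridged and full
#' output tables plus a machine-readable summary log
#' (`key=value` lines with per-branch counts) and the resolved ClinVar
#' subset TSV. Input record order is preserved; repeated runs are
#' byte-identical.
#'
#' @param config A [runConfig()] object.
#' @return Invisibly, a list with `results` (the merged classified table),
#'   `counts` (named integer vector of branch/drop counts) and `paths`
#'   (output file paths).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))

  vep <- readVepVcf(config$vep_vcf)
  multianno <- readAnnovarMultianno(config$multianno)
  intervar <- .attachIntervarVids(readIntervar(config$intervar), multianno)
  autopvs1 <- readAutopvs1(config$autopvs1)
  clinvar <- readClinvarFiles(config$clinvar_vcf, config$variant_summary,
                              config$submission_summary, config$build)
  concept_ids <- if (!is.null(config$concept_list))
    readConceptIds(config$concept_list) else NULL
  options <- resolutionOptions(concept_ids, config$tiebreak)

  n_input <- length(vep)
  filtered <- applyFilters(vep, parseFilterCriteria(config$filter_criteria))
  vep <- filtered$vep

  clinvarSubset <- selectClinvarSubset(clinvar$assertions,
                                       clinvar$submissions_by_id, options)
  calls <- classifyVariants(vep, clinvarSubset, intervar, autopvs1)

  apIdx <- match(vep@fix$vid, autopvs1$vid)
  primary <- character(0); retained <- character(0)
  gene <- character(0); transcript <- character(0)
  if (length(vep) > 0L) {
    sel <- lapply(seq_len(length(vep)), function(i) {
      tr <- if (!is.na(apIdx[i])) autopvs1$transcript[apIdx[i]] else NULL
      selectTranscript(vep, i, tr)
    })
    gene <- vapply(sel, function(s)
      if ("SYMBOL" %in% names(s$primary)) s$primary[["SYMBOL"]] else "",
      character(1))
    transcript <- vapply(sel, function(s)
      if ("Feature" %in% names(s$primary)) s$primary[["Feature"]] else "",
      character(1))
    primary <- vapply(sel, function(s) paste(s$primary, collapse = "|"),
                      character(1))
    retained <- vapply(sel, function(s)
      paste(apply(s$retained, 1L, paste, collapse = "|"), collapse = ","),
      character(1))
  }
  # gene fallback for records whose CSQ lacks a symbol
  ivIdx <- match(vep@fix$vid, intervar$vid)
  noGene <- !nzchar(gene) & !is.na(ivIdx)
  gene[noGene] <- intervar$gene[ivIdx[noGene]]

  results <- data.frame(
    chr = paste0(vep@chrStyle, vep@fix$contig),
    start = vep@fix$npos,
    ref = vep@fix$nref,
    alt = vep@fix$nalt,
    gene = gene,
    transcript = transcript,
    final_call = calls$final_call,
    call_source = calls$call_source,
    clinvar_stars = calls$clinvar_stars,
    resolution_method = calls$resolution_method,
    stringsAsFactors = FALSE
  )

  maIdx <- match(vep@fix$vid, multianno$vid)
  annovarCols <- setdiff(names(multianno),
                         c("vid", "annovar_key",
                           grep("^Otherinfo", names(multianno), value = TRUE)))
  full <- cbind(
    results,
    data.frame(
      variation_id = calls$variation_id,
      qual = vep@fix$QUAL,
      filter = vep@fix$FILTER,
      info = vep@fix$INFO,
      intervar_call = calls$intervar_call,
      intervar_evidence = ifelse(is.na(ivIdx), NA_character_,
                                 intervar$evidence[ivIdx]),
      intervar_rule = calls$intervar_rule,
      autopvs1_strength = ifelse(is.na(apIdx), NA_character_,
                                 autopvs1$strength[apIdx]),
      autopvs1_criterion = ifelse(is.na(apIdx), NA_character_,
                                  autopvs1$criterion[apIdx]),
      csq_primary = primary,
      csq_vep = retained,
      note = calls$note,
      stringsAsFactors = FALSE
    )
  )
  for (col in annovarCols) {
    full[[paste0("annovar_", col)]] <-
      ifelse(is.na(maIdx), NA_character_, multianno[[col]][maIdx])
  }

  paths <- writeOutputs(results, full, config$out_prefix)
  paths$clinvar_subset <- paste0(config$out_prefix, ".clinvar_subset.tsv")
  writeResolvedSubset(clinvarSubset, paths$clinvar_subset)

  counts <- c(
    n_input = n_input,
    filtered$dropped,
    n_classified = nrow(results),
    n_clinvar_direct = sum(calls$call_source == "ClinVar" &
                             calls$resolution_method == "direct"),
    n_clinvar_majority = sum(calls$call_source == "ClinVar" &
                               calls$resolution_method == "majority"),
    n_clinvar_latest = sum(calls$call_source == "ClinVar" &
                             calls$resolution_method == "latest"),
    n_clinvar_most_severe = sum(calls$call_source == "ClinVar" &
                                  calls$resolution_method == "most_severe"),
    n_intervar = sum(calls$call_source == "InterVar"),
    n_no_evidence = sum(!is.na(calls$note) &
                          grepl("no_evidence", calls$note))
  )
  paths$summary <- paste0(config$out_prefix, ".summary.log")
  writeLines(paste0(names(counts), "=", counts), paths$summary)

  invisible(list(results = full, counts = counts, paths = paths))
}
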