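# Session-cached fixture bundle and pipeline runs so the end-to-end tests
# generate and classify the default catalog once each.

.cache <- new.env(parent = emptyenv())

getBundle <- function() {
  if (is.null(.cache$bundle)) {
    dir <- file.path(tempdir(), "gvclass-bundle")
    .cache$bundle <- generateBundle(scenarioCatalog(), seed = 7L,
                                    out_dir = dir)
  }
  .cache$bundle
}

getRun <- function(tiebreak = "latest", concept = FALSE,
                   filter_criteria = "") {
  key <- paste(tiebreak, concept, filter_criteria, sep = "/")
  if (is.null(.cache$runs)) .cache$runs <- list()
  if (is.null(.cache$runs[[key]])) {
    b <- getBundle()
    out <- file.path(tempdir(),
                     paste0("gvclass-run-",
                            gsub("[^a-z0-9]+", "_", tolower(key))))
    cfg <- runConfig(
      b$paths$vep_vcf, b$paths$multianno, b$paths$intervar,
      b$paths$autopvs1, b$paths$clinvar_vcf, b$paths$variant_summary,
      b$paths$submission_summary,
      concept_list = if (concept) b$paths$concept_ids else NULL,
      tiebreak = tiebreak, filter_criteria = filter_criteria,
      out_prefix = out)
    .cache$runs[[key]] <- suppressWarnings(suppressMessages(runPipeline(cfg)))
    .cache$runs[[key]]$out_prefix <- out
  }
  .cache$runs[[key]]
}

# small in-code submission set constructor for conflict-resolution tests
makeSubs <- function(sigs, dates = NA, crit = TRUE, concepts = "C0000001") {
  n <- length(sigs)
  df <- data.frame(
    variation_id = rep_len(1L, n),
    significance = sigs,
    date_last_evaluated = as.Date(as.character(rep_len(dates, n))),
    assertion_criteria_provided = rep_len(crit, n),
    submitter = sprintf("Lab%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  df$concept_ids <- rep_len(if (is.list(concepts)) concepts else
    list(concepts), n)
  df
}
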