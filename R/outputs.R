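#' Write the abridged and full output tables
#'
#' Both tables are UTF-8, LF-terminated, tab-separated with a mandatory
#' header row, in input order. The abridged table carries the minimal
#' coordinate / gene / classification columns; the full table additionally
#' carries the raw VCF INFO, ANNOVAR pass-through columns, InterVar call
#' and evidence, the PVS1 grading columns, the primary CSQ entry and the
#' retained extra transcript annotations (`csq_vep`, entries joined with
#' `","` and fields with `"|"`, mirroring the VEP encoding).
#'
#' @param abridged Data.frame of the abridged columns (chr, start, ref,
#'   alt, gene, transcript, final_call, call_source, clinvar_stars,
#'   resolution_method).
#' @param full Data.frame of the full columns (`NULL` to derive from
#'   `abridged` alone).
#' @param out_prefix Path prefix; writes `<prefix>.abridged.tsv` and
#'   `<prefix>.full.tsv`.
#' @return List with elements `abridged` and `full` (the file paths).
#' @export
writeOutputs <- function(abridged, full = NULL, out_prefix) {
  if (is.null(full)) full <- abridged
  paths <- list(abridged = paste0(out_prefix, ".abridged.tsv"),
                full = paste0(out_prefix, ".full.tsv"))
  for (p in paths) {
    dir <- dirname(p)
    if (!dir.exists(dir))
      stop("output directory does not exist: ", dir)
  }
  .writeTsv <- function(d, p) {
    con <- file(p, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", eol = "\n")
  }
  .writeTsv(abridged, paths$abridged)
  .writeTsv(full, paths$full)
  paths
}
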