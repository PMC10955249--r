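#' Normalize a variant to its minimal representation
#'
#' Produces the canonical join key used to match rows across the VEP VCF,
#' ANNOVAR multianno, InterVar and AutoPVS1 tables: the `chr` prefix is
#' stripped, alleles are uppercased, and the (ref, alt) pair is reduced to
#' minimal representation by right-trimming the shared suffix and then
#' left-trimming the shared prefix, advancing the position one base per
#' trimmed leading base. Coordinates are 1-based (VCF convention).
#'
#' Symbolic alleles (`<DEL>`, breakends) and multi-allelic composites
#' (comma-separated ALT) are rejected: inputs must be pre-split upstream,
#' since silently splitting here could desynchronize the annotation tables.
#'
#' @param contig Chromosome name(s), with or without a `chr` prefix.
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings over A, C, G, T, N.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`, one row
#'   per input variant.
#' @examples
#' normalizeVariant("chr7", 100, "AT", "A")
#' normalizeVariant("1", 1000, "CAG", "CAA")  # trims to 1:1002 G>A
#' @export
normalizeVariant <- function(contig, pos, ref, alt) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  if (anyNA(pos) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1")
  }
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic ALT (comma-separated) rejected: split records ",
         "into one alternate allele per row before running this pipeline")
  }
  if (any(grepl("[<>\\[\\]*.]", ref)) || any(grepl("[<>\\[\\]*.]", alt))) {
    stop("symbolic or breakend alleles (e.g. <DEL>, [, ], *) are not ",
         "supported; only explicit sequence alleles can be normalized")
  }
  if (any(!grepl("^[ACGTN]+$", ref)) || any(!grepl("^[ACGTN]+$", alt))) {
    stop("alleles must be non-empty strings over A, C, G, T, N")
  }
  if (any(ref == alt)) {
    i <- which(ref == alt)[1L]
    stop("ref and alt alleles are identical (", contig[i], ":", pos[i],
         " ", ref[i], ">", alt[i], "); not a variant")
  }

  contig <- sub("^chr", "", contig, ignore.case = TRUE)

  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # right-trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # left-trim shared prefix, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }

  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' String form of a normalized variant key
#'
#' @param key A data.frame as returned by [normalizeVariant()].
#' @return Character vector `"contig:pos:ref:alt"`, one element per row.
#' @export
variantId <- function(key) {
  sprintf("%s:%d:%s:%s", key$contig, key$pos, key$ref, key$alt)
}
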