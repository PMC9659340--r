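#' Construct a variant catalog
#'
#' A variant catalog is the population collection underlying all frequency and
#' cooccurrence statistics: one record per sequenced individual, each carrying
#' a haplogroup label and a set of substitution tokens.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param haplogroup Character vector of haplogroup labels (NA allowed).
#' @param variants List of character vectors of variant tokens (one element per
#'   sample; empty vectors allowed).
#' @return An object of class `variant_catalog`: a data frame with columns
#'   `sample_id`, `haplogroup` and list-column `variants`, plus attribute `N`.
#' @examples
#' cat <- variant_catalog(c("s1", "s2"), c("H7", "J"),
#'                        list("m.13708G>A", c("m.13708G>A", "m.10398A>G")))
#' nrow(cat)  # 2
#' @export
variant_catalog <- function(sample_id, haplogroup = NA_character_, variants = list()) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) {
    dup <- sample_id[duplicated(sample_id)][1]
    stop(sprintf("duplicate sample_id: '%s'", dup), call. = FALSE)
  }
  haplogroup <- rep_len(as.character(haplogroup), n)
  if (length(variants) == 0L) variants <- rep(list(character(0)), n)
  if (length(variants) != n) stop("variants list length must match sample_id", call. = FALSE)
  variants <- lapply(variants, normalize_tokens)
  out <- data.frame(sample_id = sample_id, haplogroup = haplogroup,
                    stringsAsFactors = FALSE)
  out$variants <- variants
  class(out) <- c("variant_catalog", "data.frame")
  out
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat(sprintf("variant_catalog: %d records, %d haplogroup labels, %d distinct variants\n",
              nrow(x), length(unique(x$haplogroup[!is.na(x$haplogroup)])),
              length(unique(unlist(x$variants)))))
  invisible(x)
}

#' Read a variant catalog from TSV
#'
#' Expected format: tab-delimited with mandatory header columns `sample_id`,
#' `haplogroup`, `variants`; the variants column holds comma-separated
#' "m.<pos><ref>><alt>" tokens, or `"."` for none/unknown. Malformed rows are
#' rejected with the offending line number, never silently coerced.
#'
#' @param path File path.
#' @return A [variant_catalog()].
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "haplogroup", "variants")
  if (!all(need %in% names(df))) {
    stop(sprintf("catalog header must contain columns: %s (found: %s)",
                 paste(need, collapse = ", "), paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  vars <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    raw <- df$variants[i]
    toks <- if (raw == "." || raw == "") character(0) else strsplit(raw, ",", fixed = TRUE)[[1]]
    vars[[i]] <- tryCatch(normalize_tokens(trimws(toks)),
      error = function(e) {
        stop(sprintf("line %d (sample '%s'): %s", i + 1L, df$sample_id[i],
                     conditionMessage(e)), call. = FALSE)
      })
  }
  hg <- df$haplogroup
  hg[hg == "." | hg == ""] <- NA_character_
  variant_catalog(df$sample_id, hg, vars)
}

#' Write a variant catalog to TSV
#'
#' Inverse of [read_catalog()]: `read_catalog(write_catalog(x, p))` returns a
#' catalog equal to `x`.
#'
#' @param catalog A `variant_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "variant_catalog"))
  vtxt <- vapply(catalog$variants, function(v) {
    if (length(v) == 0L) "." else paste(v, collapse = ",")
  }, character(1))
  hg <- catalog$haplogroup
  hg[is.na(hg)] <- "."
  df <- data.frame(sample_id = catalog$sample_id, haplogroup = hg,
                   variants = vtxt, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mtDNA variants from a VCF into a catalog
#'
#' Reads a VCF restricted to the mitochondrial contig (`chrM` or `MT`); each
#' sample column becomes one catalog record. Biallelic SNVs with any
#' non-reference genotype count as presence (mtDNA treated as haploid);
#' indels and multiallelic records are skipped with counts reported in the
#' `skipped` attribute.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A [variant_catalog()] with attribute `skipped` =
#'   `c(indel = n1, multiallelic = n2)`.
#' @export
read_vcf_chrm <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) > 0 && is.null(dim(vcfR::getFIX(v)))) {
    fix <- as.data.frame(t(vcfR::getFIX(v)), stringsAsFactors = FALSE)
  }
  on_mt <- fix$CHROM %in% c("chrM", "MT", "chrMT", "M")
  if (!any(on_mt)) stop("no records on a chrM/MT contig found in VCF", call. = FALSE)
  fix <- fix[on_mt, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[on_mt, , drop = FALSE]

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% .BASES & fix$ALT %in% .BASES & !multi
  skipped <- c(indel = sum(!snv & !multi), multiallelic = sum(multi))

  samples <- colnames(gt)
  if (is.null(samples)) stop("VCF has no sample genotype columns", call. = FALSE)
  vars <- lapply(samples, function(s) {
    g <- gt[snv, s]
    present <- !is.na(g) & g != "0" & g != "0/0" & g != "0|0" & g != "./." & g != "."
    normalize_tokens(variant_token(as.integer(fix$POS[snv][present]),
                                   fix$REF[snv][present], fix$ALT[snv][present]))
  })
  out <- variant_catalog(samples, NA_character_, vars)
  attr(out, "skipped") <- skipped
  out
}

#' Test equality of two catalogs
#'
#' @param a,b `variant_catalog` objects.
#' @return Logical scalar.
#' @export
catalogs_equal <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$sample_id, b$sample_id) &&
    identical(a$haplogroup, b$haplogroup) &&
    all(mapply(identical, a$variants, b$variants))
}
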