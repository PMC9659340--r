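#' @importFrom stats median optimize optim p.adjust pbinom phyper rnorm
#'   rpois runif
#' @importFrom utils read.delim write.table combn
NULL

#' Length of the revised Cambridge Reference Sequence (rCRS)
#'
#' The human mtDNA coordinate reference spans positions 1..16569.
#' @export
RCRS_LENGTH <- 16569L

.BASES <- c("A", "C", "G", "T")

#' Parse an mtDNA substitution token
#'
#' Parses variant tokens in the standard "m.<pos><ref>><alt>" nomenclature
#' (e.g. `"m.13708G>A"`) against rCRS coordinates. Only single-nucleotide
#' substitutions are modelled; insertion/deletion syntax is rejected with a
#' distinct error so callers can distinguish "malformed" from "unsupported".
#'
#' @param token Character scalar, e.g. `"m.13708G>A"`.
#' @param gene Optional region/gene label carried along (e.g. `"ND5"`).
#' @param aa_change Optional amino-acid change annotation.
#' @return An object of class `mt_variant`: a list with `position`, `ref`,
#'   `alt`, and optional `gene` and `aa_change` fields.
#' @examples
#' v <- parse_variant_token("m.13708G>A")
#' v$position  # 13708
#' format(v)   # "m.13708G>A"
#' @export
parse_variant_token <- function(token, gene = NA_character_, aa_change = NA_character_) {
  if (!is.character(token) || length(token) != 1L || is.na(token) || !nzchar(token)) {
    stop("variant token must be a non-empty character scalar", call. = FALSE)
  }
  if (grepl("ins|del|dup|_", token, ignore.case = TRUE)) {
    stop(sprintf("indel syntax is not supported: '%s' (only substitutions are modelled)", token),
         call. = FALSE)
  }
  m <- regmatches(token, regexec("^m\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", token))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("malformed variant token: '%s' (expected m.<pos><ref>><alt>)", token),
         call. = FALSE)
  }
  pos <- as.integer(m[2])
  ref <- toupper(m[3])
  alt <- toupper(m[4])
  if (is.na(pos) || pos < 1L || pos > RCRS_LENGTH) {
    stop(sprintf("position %s outside rCRS range [1, %d] in token '%s'", m[2], RCRS_LENGTH, token),
         call. = FALSE)
  }
  if (ref == alt) {
    stop(sprintf("ref and alt are identical in token '%s'", token), call. = FALSE)
  }
  structure(
    list(position = pos, ref = ref, alt = alt, gene = gene, aa_change = aa_change),
    class = "mt_variant"
  )
}

#' Format an mtDNA variant as a token
#'
#' @param x An `mt_variant` object.
#' @param ... Unused.
#' @return The canonical "m.<pos><ref>><alt>" token.
#' @export
format.mt_variant <- function(x, ...) {
  sprintf("m.%d%s>%s", x$position, x$ref, x$alt)
}

#' @export
print.mt_variant <- function(x, ...) {
  cat(format(x))
  if (!is.na(x$gene)) cat(" [", x$gene, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Build a variant token from components
#'
#' @param position 1-based rCRS position.
#' @param ref,alt Reference and alternate nucleotides (A/C/G/T).
#' @return Canonical token string.
#' @export
variant_token <- function(position, ref, alt) {
  sprintf("m.%d%s>%s", as.integer(position), ref, alt)
}

# Normalize a vector of tokens: validate each and re-format canonically.
# Returns a position-sorted, de-duplicated character vector. Duplicate
# (position, alt) pairs with differing ref are rejected. Vectorized so that
# catalogs with thousands of variants per record stay fast; falls back to
# parse_variant_token() for the precise error message on the first bad token.
normalize_tokens <- function(tokens) {
  tokens <- tokens[!is.na(tokens) & nzchar(tokens) & tokens != "."]
  if (length(tokens) == 0L) return(character(0))
  ok <- grepl("^m\\.[0-9]+[ACGTacgt]>[ACGTacgt]$", tokens)
  pos <- suppressWarnings(as.integer(sub("^m\\.([0-9]+).*$", "\\1", tokens)))
  ref <- toupper(substr(sub("^m\\.[0-9]+", "", tokens), 1L, 1L))
  alt <- toupper(sub("^.*>", "", tokens))
  ok <- ok & !is.na(pos) & pos >= 1L & pos <= RCRS_LENGTH & ref != alt
  if (!all(ok)) parse_variant_token(tokens[!ok][1])  # raises the precise error
  out <- sprintf("m.%d%s>%s", pos, ref, alt)
  dup <- duplicated(out)
  out <- out[!dup]
  key <- paste(pos[!dup], alt[!dup])
  if (anyDuplicated(key)) {
    stop("duplicate (position, alt) pair with conflicting ref alleles", call. = FALSE)
  }
  out[order(pos[!dup], out)]
}

token_positions <- function(tokens) {
  as.integer(sub("^m\\.([0-9]+).*$", "\\1", tokens))
}
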