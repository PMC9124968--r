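#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   pairwiseAlignment nucleotideSubstitutionMatrix mismatchTable
#'   alignedPattern alignedSubject readDNAStringSet
#'   readQualityScaledDNAStringSet
#' @importFrom S4Vectors mcols
#' @importFrom methods is
#' @importFrom stats sd runif setNames
#' @importFrom utils write.table read.delim head tail
NULL

STOP_AA <- "*"

#' Reverse complement of a DNA string
#'
#' @param x character scalar of A/C/G/T/N (IUPAC allowed).
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return("")
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

## codon -> amino acid lookup (standard genetic code, built once)
codon_table <- function() {
  if (is.null(.igj_utils_cache$codons)) {
    .igj_utils_cache$codons <- Biostrings::GENETIC_CODE
  }
  .igj_utils_cache$codons
}
.igj_utils_cache <- new.env(parent = emptyenv())

#' Translate a DNA string in a given frame
#'
#' Trailing partial codons are dropped; `*` marks stop codons; codons with
#' ambiguous bases translate to `X`.
#'
#' @param x character scalar (DNA).
#' @param frame 0, 1 or 2 (offset in nucleotides).
#' @return character scalar of amino acids.
#' @keywords internal
translate_frame <- function(x, frame = 0L) {
  n <- nchar(x) - frame
  n <- n - n %% 3L
  if (n < 3L) return("")
  s <- substr(x, frame + 1L, frame + n)
  cods <- substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(codon_table()[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## split into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Hamming distance between equal-length strings
hamming <- function(a, b) sum(chars(a) != chars(b))

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## does concrete base b match IUPAC code p?
iupac_match <- function(b, p) {
  vapply(seq_along(b), function(i) b[i] %in% IUPAC_MAP[[p[i]]], logical(1L))
}

## IUPAC pattern -> regex character classes
iupac_regex <- function(pat) {
  paste0(vapply(chars(pat), function(p) {
    alt <- IUPAC_MAP[[p]]
    if (length(alt) == 1L) alt else paste0("[", paste(alt, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

assert_dna <- function(x, what = "sequence", iupac = FALSE) {
  ok <- if (iupac) grepl("^[ACGTRYSWKMBDHVN]*$", x) else grepl("^[ACGTN]*$", x)
  if (!all(ok)) {
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(utils::head(x[!ok], 3L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

## normalize sequences: uppercase, RNA U -> T
normalize_dna <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)

## population standard deviation (denominator n)
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

## longest common substring between two strings by dynamic programming.
## Returns list(len, a_start, b_start) with 1-based starts of the first
## (leftmost in `a`, then leftmost in `b`) maximal match, or len = 0.
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(list(len = 0L, a_start = NA_integer_, b_start = NA_integer_))
  av <- chars(a); bv <- chars(b)
  best <- 0L; besta <- NA_integer_; bestb <- NA_integer_
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- av[i] == bv
    cur[hit] <- c(0L, prev[-nb])[hit] + 1L
    mx <- max(cur)
    if (mx > best) {
      best <- mx
      j <- which(cur == mx)[1L]
      besta <- i - mx + 1L
      bestb <- j - mx + 1L
    } else if (mx == best && best > 0L) {
      j <- which(cur == mx)[1L]
      ai <- i - mx + 1L
      if (ai < besta || (ai == besta && (j - mx + 1L) < bestb)) {
        besta <- ai; bestb <- j - mx + 1L
      }
    }
    prev <- cur
  }
  list(len = best, a_start = besta, b_start = bestb)
}
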