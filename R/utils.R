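#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows count distinct filter group_by
#'   left_join mutate n pull rename row_number select slice summarise ungroup
#'   first if_else across all_of anti_join semi_join lead lag desc
#' @importFrom rlang .data .env abort warn
#' @importFrom stats median pbinom rbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that works
#' on plain character vectors, which is how sequences travel through this
#' package's tibbles.
#'
#' @param x Character vector of ACGTN sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGCC"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## random sequence with given GC content; vector of single bases pasted
random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

## split a sequence string into a character vector of bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## all k-length substrings of each string in x, concatenated
kmers_of <- function(x, k) {
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    n <- nchar(s)
    if (n < k) next
    out[[i]] <- substring(s, 1:(n - k + 1), k:n)
  }
  unlist(out, use.names = FALSE)
}

## substitute bases at selected 1-based positions (used for error injection
## and haplotype construction); pos/base vectors refer to one sequence
apply_substitutions <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  ch <- seq_chars(seq)
  ch[pos] <- base
  paste(ch, collapse = "")
}

## draw substituting bases distinct from the originals
other_base <- function(orig) {
  vapply(orig, function(b) sample(setdiff(BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

is_odd <- function(x) x %% 2 == 1

`%||%` <- function(a, b) if (is.null(a)) b else a
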