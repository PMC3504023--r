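#' Locate restriction-enzyme recognition sites
#'
#' Scans a nucleotide sequence for every occurrence of a recognition sequence,
#' counting overlapping occurrences separately. For non-palindromic
#' recognition sequences the reverse-complement strand is also scanned and
#' hits are reported in forward-strand coordinates. Ambiguous bases (`N`)
#' never match.
#'
#' The default recognition sequence is that of EagI (`CGGCCG`), the enzyme
#' used to build the RAD library this pipeline models. EagI's site is its own
#' reverse complement, so for the default only one strand needs scanning.
#'
#' @param sequence A single nucleotide sequence (character scalar).
#' @param recognition Recognition sequence, uppercase ACGT.
#' @return Sorted integer vector of 0-based start offsets.
#' @export
#' @examples
#' find_sites("AACGGCCGTT")          # 2
#' find_sites("CGGCCGGCCG")          # 0, 4 (overlap counted)
find_sites <- function(sequence, recognition = "CGGCCG") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!grepl("^[ACGT]+$", recognition)) {
    abort("`recognition` must be a non-empty uppercase ACGT string.")
  }
  if (is.na(sequence) || nchar(sequence) < nchar(recognition)) {
    return(integer(0))
  }
  subj <- Biostrings::DNAString(sequence)
  hit0 <- function(pat) {
    Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = TRUE)) - 1L
  }
  pos <- hit0(recognition)
  rc <- revcomp(recognition)
  if (!identical(rc, recognition)) pos <- union(pos, hit0(rc))
  sort(unique(as.integer(pos)))
}

#' Expected number of recognition sites in a random sequence
#'
#' Closed-form expectation under an i.i.d. base model with a given GC content:
#' every window of the recognition length matches independently with
#' probability equal to the product of per-base probabilities, where
#' `p(G) = p(C) = gc/2` and `p(A) = p(T) = (1 - gc)/2`. This is the standard
#' in-silico prediction of RAD cut-site counts from genome size and GC
#' content; real genomes (for example CpG-depleted mammalian genomes scanned
#' for CGGCCG) can depart considerably from it, which is why [find_sites()]
#' on an actual sequence is exposed alongside.
#'
#' @param length Sequence length in bases.
#' @param gc GC content, a fraction in `[0, 1]`.
#' @param recognition Recognition sequence, uppercase ACGT.
#' @return Expected site count (double). Zero when `length` is shorter than
#'   the recognition sequence.
#' @export
#' @examples
#' expected_site_count(1e6, 0.5)   # (1e6 - 5) * 0.25^6 ~= 244.14
expected_site_count <- function(length, gc, recognition = "CGGCCG") {
  stopifnot(gc >= 0, gc <= 1, length >= 0)
  m <- nchar(recognition)
  if (length < m) return(0)
  p_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p_site <- prod(p_base[seq_chars(recognition)])
  (length - m + 1) * unname(p_site)
}

#' Extract RAD tags flanking each cut site
#'
#' The enzyme cuts after the first base of the recognition sequence
#' (`C*GGCCG`), and each cut releases up to two sequenceable tags: the
#' `tag_length` bases immediately left of the cut, reverse-complemented so
#' they read toward the cut, and the `tag_length` bases immediately right of
#' it. Directions with insufficient flanking sequence are skipped, so interior
#' sites contribute two tags and edge sites fewer.
#'
#' @param sequence A single nucleotide sequence.
#' @param sites 0-based site offsets, as returned by [find_sites()].
#' @param tag_length Tag length in bases (the forward-read length).
#' @param cut_offset Cut position within the recognition site (bases after its
#'   first base; 1 for EagI's `C*GGCCG`).
#' @return Tibble with columns `site` (0-based site offset), `direction`
#'   (`"up"`/`"down"`) and `seq`.
#' @export
extract_rad_tags <- function(sequence, sites, tag_length = 40,
                             cut_offset = 1L) {
  stopifnot(tag_length >= 1)
  n <- nchar(sequence)
  if (length(sites) == 0) {
    return(tibble(site = integer(0), direction = character(0),
                  seq = character(0)))
  }
  cut <- as.integer(sites) + as.integer(cut_offset)  # 0-based, cut before it
  up <- tibble(site = as.integer(sites), direction = "up",
               start = cut - tag_length, end = cut)
  down <- tibble(site = as.integer(sites), direction = "down",
                 start = cut, end = cut + tag_length)
  tags <- bind_rows(up, down) %>%
    filter(.data$start >= 0, .data$end <= n) %>%
    mutate(seq = substring(.env$sequence, .data$start + 1, .data$end)) %>%
    mutate(seq = if_else(.data$direction == "up", revcomp(.data$seq),
                         .data$seq)) %>%
    arrange(.data$site, .data$direction) %>%
    select("site", "direction", "seq")
  tags
}

#' Summarise an in-silico digest
#'
#' Runs [find_sites()] and [extract_rad_tags()] on one sequence and pairs the
#' observed site count with the random-sequence expectation at the sequence's
#' own GC content.
#'
#' @inheritParams extract_rad_tags
#' @param recognition Recognition sequence.
#' @return One-row tibble: `n_sites`, `n_tags`, `expected_sites`, `gc`.
#' @export
digest_summary <- function(sequence, recognition = "CGGCCG",
                           tag_length = 40) {
  sites <- find_sites(sequence, recognition)
  tags <- extract_rad_tags(sequence, sites, tag_length)
  ch <- seq_chars(sequence)
  gc <- mean(ch %in% c("G", "C"))
  tibble(
    n_sites = length(sites),
    n_tags = nrow(tags),
    expected_sites = expected_site_count(nchar(sequence), gc, recognition),
    gc = gc
  )
}
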