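#' Canonical form of a microsatellite motif
#'
#' The lexicographically least string among all rotations of the motif and
#' all rotations of its reverse complement, so that for example `TG`, `GT`,
#' `CA` and `AC` all canonicalise to `AC`.
#'
#' @param motif Character vector of motifs.
#' @return Character vector of canonical motifs.
#' @export
#' @examples
#' canonical_motif(c("TG", "GAT"))
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    p <- nchar(m)
    rot <- function(x) {
      vapply(seq_len(p), function(i)
        paste0(substr(x, i, p), substr(x, 1, i - 1)), character(1))
    }
    min(c(rot(m), rot(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

default_min_repeats <- function() c(`1` = 6L, `2` = 3L, `3` = 3L, `4` = 3L)

#' Find perfect microsatellites (SSRs)
#'
#' Detects maximal perfect tandem runs of 1-4 bp motifs meeting a per-class
#' minimum repeat count. A run whose motif is itself periodic (for example
#' `ATAT` as a 4-mer) is reported at its smallest period only. Runs are
#' perfect: a single interruption terminates a run. Overlapping runs of
#' different periods are resolved by keeping the longer run (ties: smaller
#' start).
#'
#' @param sequence One nucleotide sequence.
#' @param min_repeats Named integer vector mapping motif length (`"1"` to
#'   `"4"`) to the minimum repeat count for that class.
#' @return Tibble `start`, `end` (0-based half-open), `motif` (as it occurs),
#'   `canonical` (canonical motif), `motif_length`, `repeats`, with
#'   `end - start == motif_length * repeats`.
#' @export
#' @examples
#' find_ssrs("GGACACACACGG")  # one (AC)4 locus
find_ssrs <- function(sequence, min_repeats = default_min_repeats()) {
  stopifnot(all(c("1", "2", "3", "4") %in% names(min_repeats)))
  n <- nchar(sequence)
  empty <- tibble(start = integer(0), end = integer(0), motif = character(0),
                  canonical = character(0), motif_length = integer(0),
                  repeats = integer(0))
  if (n < 2) return(empty)
  ch <- seq_chars(sequence)
  cand <- list()
  ci <- 0
  for (p in 1:4) {
    if (n < 2 * p) next
    eq <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    for (i in w) {
      m <- r$lengths[i]
      reps <- (m + p) %/% p
      if (reps < min_repeats[[as.character(p)]]) next
      s1 <- starts[i]                       # 1-based start of the run
      motif <- substr(sequence, s1, s1 + p - 1)
      if (grepl("[^ACGT]", motif)) next
      if (minimal_period(motif) != p) next  # reported at smaller period
      ci <- ci + 1
      cand[[ci]] <- tibble(start = s1 - 1L, end = s1 - 1L + reps * p,
                           motif = motif, motif_length = p,
                           repeats = as.integer(reps))
    }
  }
  if (ci == 0) return(empty)
  cand <- bind_rows(cand) %>%
    mutate(span = .data$end - .data$start) %>%
    arrange(desc(.data$span), .data$start, .data$motif_length)
  # overlap resolution: longer run wins, ties to the smaller start
  kept <- logical(nrow(cand))
  occupied_start <- integer(0)
  occupied_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (!any(s < occupied_end & e > occupied_start)) {
      kept[i] <- TRUE
      occupied_start <- c(occupied_start, s)
      occupied_end <- c(occupied_end, e)
    }
  }
  cand %>%
    filter(kept) %>%
    mutate(canonical = canonical_motif(.data$motif)) %>%
    arrange(.data$start) %>%
    select("start", "end", "motif", "canonical", "motif_length", "repeats")
}

#' Find SSRs on every contig of a set
#'
#' @param contigs Contig tibble (`contig_id`, `seq`).
#' @inheritParams find_ssrs
#' @return [find_ssrs()] output with a leading `contig_id` column.
#' @export
find_ssrs_contigs <- function(contigs, min_repeats = default_min_repeats()) {
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    out <- find_ssrs(contigs$seq[i], min_repeats)
    if (nrow(out) == 0) return(out)
    mutate(out, contig_id = contigs$contig_id[i], .before = 1)
  })
}

#' Mark compound microsatellites
#'
#' Adjacent SSRs on the same contig separated by at most `max_gap` bases are
#' both marked compound.
#'
#' @param ssrs SSR tibble (with `contig_id`, `start`, `end`), sorted or not.
#' @param max_gap Maximum gap in bases between members of a compound.
#' @return The input, sorted by contig and start, with a logical `compound`
#'   column.
#' @export
classify_compound <- function(ssrs, max_gap = 10) {
  if (nrow(ssrs) == 0) return(mutate(ssrs, compound = logical(0)))
  if (!"contig_id" %in% names(ssrs)) ssrs$contig_id <- "seq1"
  ssrs %>%
    arrange(.data$contig_id, .data$start) %>%
    group_by(.data$contig_id) %>%
    mutate(
      gap_prev = .data$start - lag(.data$end),
      gap_next = lead(.data$start) - .data$end,
      compound = (!is.na(.data$gap_prev) & .data$gap_prev <= max_gap) |
        (!is.na(.data$gap_next) & .data$gap_next <= max_gap)) %>%
    ungroup() %>%
    select(-"gap_prev", -"gap_next")
}

#' Flag potentially amplifiable loci (PAL)
#'
#' An SSR is a PAL when at least `min_flank` unambiguous bases (no `N`)
#' flank the run on each side within its contig and the run has at least
#' `min_repeats_pal` repeats. A stricter `primer_candidate` flag additionally
#' requires `min_repeats_primer` repeats, the subset for which primers would
#' actually be designed.
#'
#' @param ssrs SSR tibble with `contig_id`, `start`, `end`, `repeats`.
#' @param contigs Contig tibble (`contig_id`, `seq`).
#' @param min_flank Minimum clean flank on each side, in bases.
#' @param min_repeats_pal,min_repeats_primer Repeat-count thresholds.
#' @return The input with logical `pal` and `primer_candidate` columns.
#' @export
classify_pal <- function(ssrs, contigs, min_flank = 30,
                         min_repeats_pal = 3, min_repeats_primer = 4) {
  if (nrow(ssrs) == 0) {
    return(mutate(ssrs, pal = logical(0), primer_candidate = logical(0)))
  }
  idx <- match(ssrs$contig_id, contigs$contig_id)
  if (anyNA(idx)) abort("SSRs reference unknown contigs.")
  cseq <- contigs$seq[idx]
  clen <- nchar(cseq)
  left <- substring(cseq, pmax(1, ssrs$start - min_flank + 1), ssrs$start)
  right <- substring(cseq, ssrs$end + 1, pmin(clen, ssrs$end + min_flank))
  flank_ok <- ssrs$start >= min_flank &
    (clen - ssrs$end) >= min_flank &
    !grepl("N", left, fixed = TRUE) & !grepl("N", right, fixed = TRUE)
  ssrs %>%
    mutate(pal = flank_ok & .data$repeats >= min_repeats_pal,
           primer_candidate = .data$pal &
             .data$repeats >= min_repeats_primer)
}

#' Summarise an SSR scan
#'
#' Counts loci by motif class (mono- to tetra-nucleotide), totals them, and
#' reports the PAL count and percentage among di-, tri- and tetra-nucleotide
#' loci (the classes scorable by fragment-length variation), to one decimal.
#'
#' @param ssrs SSR tibble with `motif_length` and (optionally) `pal`
#'   columns, e.g. from [classify_pal()].
#' @return Object of class `ssr_summary`: list with `per_class` (tibble
#'   `class`, `motif_length`, `n`, `n_pal`) and `totals` (one-row tibble
#'   `n_total`, `n_di_plus`, `n_pal_di_plus`, `pal_pct`).
#' @export
summarize_ssrs <- function(ssrs) {
  if (!"pal" %in% names(ssrs)) ssrs$pal <- NA
  class_names <- c("mono", "di", "tri", "tetra")
  per_class <- tibble(motif_length = 1:4,
                      class = factor(class_names, levels = class_names)) %>%
    left_join(
      ssrs %>% group_by(.data$motif_length) %>%
        summarise(n = n(), n_pal = sum(.data$pal, na.rm = TRUE),
                  .groups = "drop"),
      by = "motif_length") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n)),
           n_pal = ifelse(is.na(.data$n_pal), 0L, as.integer(.data$n_pal))) %>%
    select("class", "motif_length", "n", "n_pal")
  n_di_plus <- sum(per_class$n[per_class$motif_length >= 2])
  n_pal_di_plus <- sum(per_class$n_pal[per_class$motif_length >= 2])
  totals <- tibble(
    n_total = sum(per_class$n),
    n_di_plus = n_di_plus,
    n_pal_di_plus = n_pal_di_plus,
    # one decimal, truncated: 1706/9038 reports as 18.8
    pal_pct = if (n_di_plus > 0)
      floor(1000 * n_pal_di_plus / n_di_plus) / 10 else NA_real_)
  structure(list(per_class = per_class, totals = totals),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("<ssr_summary>\n")
  print(x$per_class)
  print(x$totals)
  invisible(x)
}
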