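#' Demultiplex barcoded RAD read pairs
#'
#' Assigns each read pair to the unique sample whose barcode exactly matches
#' the forward-read prefix, strips the barcode, and counts non-matching
#' pairs. Demultiplexing uses the in-line prefix, not the read header.
#'
#' @param pairs Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (as produced by [simulate_rad_library()] or [read_fastq_pairs()]).
#' @param barcode_map Named character vector, sample id -> barcode. Barcodes
#'   must be equal length and pairwise distinct.
#' @return List with `pairs` (input rows that matched, with a `sample` column
#'   and barcodes stripped from `seq1`/`qual1`) and `n_rejected`.
#' @export
demultiplex <- function(pairs, barcode_map) {
  if (anyDuplicated(barcode_map) > 0) {
    abort("Duplicate barcodes in `barcode_map`.")
  }
  if (length(unique(nchar(barcode_map))) > 1) {
    abort("Barcodes must be equal length.")
  }
  bl <- nchar(barcode_map[1])
  prefix <- substr(pairs$seq1, 1, bl)
  idx <- match(prefix, unname(barcode_map))
  keep <- !is.na(idx)
  out <- pairs[keep, , drop = FALSE]
  out$sample <- names(barcode_map)[idx[keep]]
  out$seq1 <- substr(out$seq1, bl + 1, nchar(out$seq1))
  out$qual1 <- substr(out$qual1, bl + 1, nchar(out$qual1))
  list(pairs = as_tibble(out), n_rejected = sum(!keep))
}

#' Cluster forward reads into unitags
#'
#' A unitag is a unique RAD single-end (forward-read) sequence; reads
#' clustering is exact-match. Clusters with depth outside
#' `[min_cov, max_cov]` are removed; surviving clusters carry their paired
#' reverse reads for local assembly.
#'
#' @param pairs Demultiplexed pair tibble (columns `sample`, `seq1`, `seq2`,
#'   `read_id`). A single sample's reads may also be given without the
#'   `sample` column.
#' @param min_cov,max_cov Depth bounds for retaining a cluster.
#' @return Tibble with `sample`, `unitag`, `depth`, and list-columns
#'   `read_ids` and `rev_seqs` (reverse reads in sequencing orientation).
#' @export
build_unitags <- function(pairs, min_cov = 5, max_cov = 500) {
  if (!"sample" %in% names(pairs)) pairs$sample <- "s1"
  if (nrow(pairs) > 0 && length(unique(nchar(pairs$seq1))) > 1) {
    abort("Forward reads must be equal length for unitag clustering.")
  }
  pairs %>%
    group_by(.data$sample, unitag = .data$seq1) %>%
    summarise(depth = n(),
              read_ids = list(.data$read_id),
              rev_seqs = list(.data$seq2), .groups = "drop") %>%
    filter(.data$depth >= min_cov, .data$depth <= max_cov) %>%
    arrange(.data$sample, .data$unitag)
}

#' Locally assemble one unitag cluster
#'
#' Builds a single-k de Bruijn graph from the unitag plus all paired reverse
#' reads (reverse-complemented into template orientation) and reports maximal
#' majority-resolved paths of at least `min_contig_length` bases. The path
#' containing the unitag is flagged as the locus contig; under the paired-end
#' geometry modelled here the reverse-read cloud cannot overlap the unitag in
#' k-mer space (inserts are at least the summed read lengths), so when no
#' path contains the unitag the longest contig is flagged instead.
#'
#' @param unitag Unitag sequence (40 bp forward read).
#' @param rev_seqs Character vector of the cluster's reverse reads in
#'   sequencing orientation.
#' @param k Odd k-mer size, at most the reverse-read length.
#' @param min_contig_length Shortest reported contig.
#' @return Tibble `contig_id`, `seq`, `length`, `mean_depth`,
#'   `is_locus_contig`; zero rows when no path reaches `min_contig_length`.
#' @export
assemble_locus <- function(unitag, rev_seqs, k = 31, min_contig_length = 150) {
  stopifnot(k > 1, k <= min(nchar(rev_seqs)))
  contigs <- debruijn_assemble(c(unitag, revcomp(rev_seqs)), k = k,
                               min_contig_length = min_contig_length)
  if (nrow(contigs) == 0) return(mutate(contigs, is_locus_contig = logical(0)))
  has_unitag <- stringr::str_detect(contigs$seq, stringr::fixed(unitag))
  if (!any(has_unitag)) has_unitag[1] <- TRUE  # longest contig stands in
  mutate(contigs, is_locus_contig = has_unitag)
}

#' Assemble every unitag cluster of every sample
#'
#' Maps [assemble_locus()] over a unitag table and assigns contig ids of the
#' form `sample.locus.counter`.
#'
#' @param unitags Output of [build_unitags()].
#' @inheritParams assemble_locus
#' @return Tibble with `sample`, `unitag`, `contig_id`, `seq`, `length`,
#'   `mean_depth`, `is_locus_contig`. Clusters yielding no contig are dropped
#'   (logged via the returned attribute `n_dropped`).
#' @export
assemble_sample <- function(unitags, k = 31, min_contig_length = 150) {
  res <- vector("list", nrow(unitags))
  dropped <- 0
  for (i in seq_len(nrow(unitags))) {
    ctg <- assemble_locus(unitags$unitag[i], unitags$rev_seqs[[i]], k = k,
                          min_contig_length = min_contig_length)
    if (nrow(ctg) == 0) {
      dropped <- dropped + 1
      next
    }
    ctg$sample <- unitags$sample[i]
    ctg$unitag <- unitags$unitag[i]
    ctg$locus_index <- i
    res[[i]] <- ctg
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(sample = character(0), unitag = character(0),
                  contig_id = character(0), seq = character(0),
                  length = integer(0), mean_depth = double(0),
                  is_locus_contig = logical(0))
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  out <- out %>%
    group_by(.data$sample) %>%
    mutate(cluster_serial = match(.data$locus_index,
                                  unique(.data$locus_index))) %>%
    group_by(.data$sample, .data$locus_index) %>%
    mutate(contig_id = sprintf("%s.%04d.%d", .data$sample,
                               .data$cluster_serial, row_number())) %>%
    ungroup() %>%
    select("sample", "unitag", "contig_id", "seq", "length", "mean_depth",
           "is_locus_contig")
  attr(out, "n_dropped") <- dropped
  out
}

#' Filter assemblies by relative coverage
#'
#' Removes contigs whose mean depth falls outside
#' `[lower x median, upper x median]` of the per-sample median mean-depth —
#' too-high coverage indicates collapsed repetitive regions, too-low
#' coverage unreliable assemblies.
#'
#' @param contigs Contig tibble with `sample` and `mean_depth` columns.
#' @param lower,upper Multiples of the per-sample median mean-depth.
#' @return The retained contigs, with attribute `removed` holding the
#'   filtered-out rows.
#' @export
filter_assemblies <- function(contigs, lower = 0.25, upper = 4) {
  if (nrow(contigs) == 0) abort("`contigs` must contain at least one contig.")
  flagged <- contigs %>%
    group_by(.data$sample) %>%
    mutate(.med = median(.data$mean_depth),
           .keep_row = .data$mean_depth >= lower * .data$.med &
             .data$mean_depth <= upper * .data$.med) %>%
    ungroup()
  kept <- flagged %>% filter(.data$.keep_row) %>%
    select(-".med", -".keep_row")
  removed <- flagged %>% filter(!.data$.keep_row) %>%
    select(-".med", -".keep_row")
  attr(kept, "removed") <- removed
  kept
}

#' Select the mini-reference sample
#'
#' Returns the sample with the most assembled contigs; ties are broken by
#' total assembled bases, then by the lexicographically smallest sample id.
#'
#' @param contigs Contig tibble with `sample` and `length` columns.
#' @return A sample id (character scalar).
#' @export
#' @examples
#' x <- tibble::tibble(
#'   sample = rep(c("s2", "s3", "s4", "s7"), c(3, 4, 5, 2)),
#'   length = 200)
#' select_reference_sample(x)  # "s4"
select_reference_sample <- function(contigs) {
  if (nrow(contigs) == 0) abort("No sample has any contigs.")
  contigs %>%
    group_by(.data$sample) %>%
    summarise(n_contigs = n(), total_bp = sum(.data$length),
              .groups = "drop") %>%
    arrange(desc(.data$n_contigs), desc(.data$total_bp), .data$sample) %>%
    slice(1) %>%
    pull("sample")
}

#' N50 of a set of contig lengths
#'
#' The weighted median length: sorting lengths in decreasing order, the
#' length at which the cumulative sum first reaches at least half the total
#' assembly.
#'
#' @param lengths Positive contig lengths.
#' @return A single length (same type as the input).
#' @export
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("`lengths` must be non-empty.")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Per-sample assembly summary statistics
#'
#' The contig-level row set reported for each sample: contig count, total
#' assembled bases, mean length, N50, and length range.
#'
#' @param contigs Contig tibble with `sample` and `length` columns.
#' @return Tibble with one row per sample.
#' @export
assembly_stats <- function(contigs) {
  contigs %>%
    group_by(.data$sample) %>%
    summarise(n_contigs = n(),
              total_bp = sum(.data$length),
              mean_length = mean(.data$length),
              n50 = n50(.data$length),
              min_length = min(.data$length),
              max_length = max(.data$length),
              .groups = "drop")
}
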