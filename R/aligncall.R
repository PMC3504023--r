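## number of differing characters between two equal-length strings
str_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(charToRaw(a) != charToRaw(b))
}

## seed index: every `seed_len`-mer of every contig -> encoded (contig, offset)
build_seed_index <- function(contigs, seed_len = 20) {
  stopifnot(nrow(contigs) > 0)
  big <- 1e7  # double arithmetic: contig_idx * big exceeds 32-bit range
  entries <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$seq[i]
    n <- nchar(s)
    if (n < seed_len) next
    off <- 0:(n - seed_len)
    entries[[i]] <- tibble(kmer = substring(s, off + 1, off + seed_len),
                           code = as.numeric(i) * big + off)
  }
  tab <- bind_rows(entries)
  idx <- split(tab$code, tab$kmer)
  list(env = list2env(idx, hash = TRUE, size = length(idx) * 2L),
       big = big, seed_len = seed_len)
}

## candidate (read, contig, start, strand) placements from exact seed hits
seed_candidates <- function(seqs, index, seed_offsets) {
  hits <- list()
  h <- 0
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") seqs else revcomp(seqs)
    for (o in seed_offsets) {
      ok <- nchar(oriented) >= o + index$seed_len - 1
      if (!any(ok)) next
      sd <- substring(oriented[ok], o, o + index$seed_len - 1)
      got <- mget(sd, envir = index$env, ifnotfound = list(NULL))
      lens <- lengths(got)
      if (sum(lens) == 0) next
      code <- as.numeric(unlist(got, use.names = FALSE))
      h <- h + 1
      hits[[h]] <- tibble(
        read_idx = rep(which(ok), lens),
        strand = strand,
        start = as.integer(code %% index$big) - (o - 1L),
        contig_idx = as.integer(code %/% index$big))
    }
  }
  if (h == 0) {
    return(tibble(read_idx = integer(0), contig_idx = integer(0),
                  start = integer(0), strand = character(0)))
  }
  bind_rows(hits) %>%
    distinct(.data$read_idx, .data$contig_idx, .data$start, .data$strand)
}

#' Map reads to contigs
#'
#' Seed-and-extend read placement against a contig set, in one of two modes.
#' `rad` mode is ungapped: exact 20-mer seeds propose placements, the full
#' read is compared to the contig, placements with more than `max_mismatch`
#' substitutions are rejected, and a read is reported only when it has a
#' unique best placement (ambiguous reads are counted and dropped).
#' `shotgun` mode extends seeds with a semi-global pairwise alignment
#' permitting gaps (`band` extra bases of contig on each side) and reports
#' the best-scoring unique placement together with its indel operations.
#' Both strands are scanned.
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `sample`.
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param mode `"rad"` or `"shotgun"`.
#' @param max_mismatch Maximum substitutions accepted in rad mode.
#' @param seed_len Exact seed length.
#' @param band Extra contig bases allowed around a shotgun placement.
#' @return Tibble of alignments: `read_id`, `sample`, `contig_id`, `start`
#'   (0-based), `strand`, `n_mismatch`, `aligned_seq` (read in contig
#'   orientation), and in shotgun mode list-column `indels` (per-alignment
#'   tibble of `pos`, `type`, `len`, `seq`). Attributes `n_unmapped` and
#'   `n_ambiguous` carry the rejection counters.
#' @export
map_reads <- function(reads, contigs, mode = c("rad", "shotgun"),
                      max_mismatch = 4, seed_len = 20, band = 10) {
  mode <- match.arg(mode)
  if (!"sample" %in% names(reads)) reads$sample <- NA_character_
  index <- build_seed_index(contigs, seed_len)
  rl <- nchar(reads$seq)
  seed_offsets <- if (mode == "rad") {
    unique(pmax(1L, c(1L, min(rl) - seed_len + 1L,
                      (min(rl) - seed_len) %/% 2L + 1L)))
  } else {
    unique(c(1L, 51L, 101L, 151L))
  }
  cand <- seed_candidates(reads$seq, index, seed_offsets)
  clen <- nchar(contigs$seq)

  if (mode == "rad") {
    cand <- cand %>%
      mutate(len = rl[.data$read_idx]) %>%
      filter(.data$start >= 0,
             .data$start + .data$len <= clen[.data$contig_idx])
    n <- nrow(cand)
    mm <- integer(n)
    oriented <- ifelse(cand$strand == "+", reads$seq[cand$read_idx],
                       revcomp(reads$seq[cand$read_idx]))
    refs <- substring(contigs$seq[cand$contig_idx], cand$start + 1,
                      cand$start + cand$len)
    for (i in seq_len(n)) mm[i] <- str_mismatches(oriented[i], refs[i])
    cand$n_mismatch <- mm
    cand$aligned_seq <- oriented
    cand <- cand %>% filter(.data$n_mismatch <= max_mismatch)
    best <- cand %>%
      group_by(.data$read_idx) %>%
      filter(.data$n_mismatch == min(.data$n_mismatch)) %>%
      mutate(.n_best = n()) %>%
      ungroup()
    ambiguous <- best %>% filter(.data$.n_best > 1) %>%
      distinct(.data$read_idx)
    aln <- best %>% filter(.data$.n_best == 1)
    out <- tibble(
      read_id = reads$read_id[aln$read_idx],
      sample = reads$sample[aln$read_idx],
      contig_id = contigs$contig_id[aln$contig_idx],
      start = aln$start, strand = aln$strand,
      n_mismatch = aln$n_mismatch, aligned_seq = aln$aligned_seq)
    attr(out, "n_ambiguous") <- nrow(ambiguous)
    attr(out, "n_unmapped") <- nrow(reads) - nrow(out) - nrow(ambiguous)
    return(out)
  }

  ## shotgun: banded semi-global extension via pairwise alignment.
  ## Seeds from different read offsets imply slightly different starts when
  ## the read spans an indel; collapse each start cluster to one candidate.
  cand <- cand %>%
    mutate(len = rl[.data$read_idx]) %>%
    arrange(.data$read_idx, .data$contig_idx, .data$strand, .data$start) %>%
    group_by(.data$read_idx, .data$contig_idx, .data$strand) %>%
    mutate(.cluster = cumsum(c(1L, diff(.data$start) > 2L * band))) %>%
    group_by(.data$read_idx, .data$contig_idx, .data$strand,
             .data$.cluster) %>%
    summarise(start = min(.data$start), len = .data$len[1],
              .groups = "drop") %>%
    mutate(win_start = pmax(0L, .data$start - band),
           win_end = pmin(clen[.data$contig_idx],
                          .data$start + .data$len + band)) %>%
    filter(.data$win_end - .data$win_start >= .data$len - band) %>%
    distinct(.data$read_idx, .data$contig_idx, .data$strand,
             .data$win_start, .data$win_end)
  n <- nrow(cand)
  if (n == 0) {
    out <- tibble(read_id = character(0), sample = character(0),
                  contig_id = character(0), start = integer(0),
                  strand = character(0), n_mismatch = integer(0),
                  aligned_seq = character(0), indels = list())
    attr(out, "n_ambiguous") <- 0L
    attr(out, "n_unmapped") <- nrow(reads)
    return(out)
  }
  oriented <- ifelse(cand$strand == "+", reads$seq[cand$read_idx],
                     revcomp(reads$seq[cand$read_idx]))
  wins <- substring(contigs$seq[cand$contig_idx], cand$win_start + 1,
                    cand$win_end)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  n <- nrow(cand)
  score_v <- double(n)
  pat_al_v <- character(n)
  sub_al_v <- character(n)
  sub_start_v <- integer(n)
  # fast path: a read occurring verbatim in its window needs no alignment
  exact_at <- vapply(seq_len(n), function(j)
    regexpr(oriented[j], wins[j], fixed = TRUE)[1], integer(1))
  for (j in seq_len(n)) {
    if (exact_at[j] > 0) {
      score_v[j] <- nchar(oriented[j])
      pat_al_v[j] <- oriented[j]
      sub_al_v[j] <- oriented[j]
      sub_start_v[j] <- exact_at[j]
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      oriented[j], wins[j], type = "global-local",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 2)
    score_v[j] <- Biostrings::score(pa)
    pat_al_v[j] <- as.character(Biostrings::alignedPattern(pa))
    sub_al_v[j] <- as.character(Biostrings::alignedSubject(pa))
    sub_start_v[j] <- Biostrings::start(Biostrings::subject(pa))
  }
  cand$score <- score_v
  best_idx <- cand %>%
    mutate(.row = row_number()) %>%
    group_by(.data$read_idx) %>%
    filter(.data$score == max(.data$score)) %>%
    mutate(.n_best = n()) %>%
    ungroup()
  ambiguous <- best_idx %>% filter(.data$.n_best > 1) %>%
    distinct(.data$read_idx)
  keep <- best_idx %>% filter(.data$.n_best == 1)
  rows <- keep$.row
  pat_al <- pat_al_v[rows]
  sub_al <- sub_al_v[rows]
  sub_start <- sub_start_v[rows]  # 1-based in window
  aln_list <- vector("list", length(rows))
  mm <- integer(length(rows))
  starts <- integer(length(rows))
  for (j in seq_along(rows)) {
    parsed <- parse_gapped_alignment(pat_al[j], sub_al[j])
    base0 <- keep$win_start[j] + sub_start[j] - 1L  # 0-based contig coord
    parsed$indels$pos <- parsed$indels$pos + base0
    aln_list[[j]] <- parsed$indels
    mm[j] <- parsed$n_mismatch
    starts[j] <- base0
  }
  out <- tibble(
    read_id = reads$read_id[keep$read_idx],
    sample = reads$sample[keep$read_idx],
    contig_id = contigs$contig_id[keep$contig_idx],
    start = starts, strand = keep$strand, n_mismatch = mm,
    aligned_seq = vapply(seq_along(rows),
                         function(j) gsub("-", "", pat_al[j], fixed = TRUE),
                         character(1)),
    gapped_pattern = pat_al, gapped_subject = sub_al,
    indels = aln_list)
  attr(out, "n_ambiguous") <- nrow(ambiguous)
  attr(out, "n_unmapped") <- nrow(reads) - nrow(out) - nrow(ambiguous)
  out
}

## walk a gapped alignment (pattern = read, subject = contig window); returns
## substitution count and indel events with 0-based positions relative to the
## first aligned subject base, anchored on the base left of the event
parse_gapped_alignment <- function(pat, sub) {
  p <- seq_chars(pat)
  s <- seq_chars(sub)
  sub_pos <- cumsum(s != "-") - 1L  # 0-based subject coord per column
  is_ins <- s == "-"                 # insertion relative to the contig
  is_del <- p == "-"                 # deletion of contig bases in the read
  n_mismatch <- sum(!is_ins & !is_del & p != s)
  indels <- tibble(pos = integer(0), type = character(0), len = integer(0),
                   seq = character(0))
  if (any(is_ins)) {
    r <- rle(is_ins)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    w <- which(r$values)
    indels <- bind_rows(indels, tibble(
      pos = sub_pos[pmax(starts[w] - 1, 1)],
      type = "ins", len = r$lengths[w],
      seq = vapply(w, function(i)
        paste(p[starts[i]:ends[i]], collapse = ""), character(1))))
  }
  if (any(is_del)) {
    r <- rle(is_del)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    w <- which(r$values)
    indels <- bind_rows(indels, tibble(
      pos = sub_pos[pmax(starts[w] - 1, 1)],
      type = "del", len = r$lengths[w],
      seq = vapply(w, function(i)
        paste(s[starts[i]:ends[i]], collapse = ""), character(1))))
  }
  list(n_mismatch = n_mismatch, indels = indels)
}

#' Build a per-site, per-sample pileup from alignments
#'
#' Expands every alignment into per-position base observations and counts
#' them by contig, position, sample and base. In shotgun mode insertion and
#' deletion events are recorded against the base to their left, as rows with
#' `base` of the form `"I:<seq>"` or `"D:<len>"`.
#'
#' @param alignments Output of [map_reads()].
#' @param contigs Contig tibble (`contig_id`, `seq`).
#' @return Tibble `contig_id`, `pos` (0-based), `sample`, `base`, `n`.
#' @export
pileup <- function(alignments, contigs) {
  if (!all(alignments$contig_id %in% contigs$contig_id)) {
    abort("Alignments reference unknown contigs.")
  }
  if (nrow(alignments) == 0) {
    return(tibble(contig_id = character(0), pos = integer(0),
                  sample = character(0), base = character(0), n = integer(0)))
  }
  has_gaps <- "gapped_pattern" %in% names(alignments)
  seqs <- if (has_gaps) {
    # drop read bases that are insertions relative to the contig, so that
    # remaining bases advance contig coordinates one by one
    vapply(seq_len(nrow(alignments)), function(j) {
      p <- seq_chars(alignments$gapped_pattern[j])
      s <- seq_chars(alignments$gapped_subject[j])
      paste(p[s != "-"], collapse = "")
    }, character(1))
  } else {
    alignments$aligned_seq
  }
  lens <- nchar(seqs)
  bases <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  rows <- rep(seq_len(nrow(alignments)), lens)
  pos <- rep(alignments$start, lens) + sequence(lens) - 1L
  obs <- tibble(contig_id = alignments$contig_id[rows], pos = pos,
                sample = alignments$sample[rows], base = bases) %>%
    filter(.data$base != "-")
  if (has_gaps) {
    ind <- alignments %>%
      select("contig_id", "sample", "indels") %>%
      tidyr::unnest("indels")
    if (nrow(ind) > 0) {
      obs <- bind_rows(obs, tibble(
        contig_id = ind$contig_id, pos = as.integer(ind$pos),
        sample = ind$sample,
        base = ifelse(ind$type == "ins", paste0("I:", ind$seq),
                      paste0("D:", ind$len))))
    }
  }
  obs %>%
    count(.data$contig_id, .data$pos, .data$sample, .data$base,
          name = "n") %>%
    arrange(.data$contig_id, .data$pos, .data$sample, .data$base)
}

#' Threshold-model genotype call
#'
#' The count-based caller: with `depth = ref_count + alt_count`, a site is
#' `missing` below `min_depth`; otherwise the alternate allele fraction
#' `f = alt_count / depth` is compared with the threshold `t` (default 7.5%
#' alternate allele frequency): `f < t` is `hom_ref`, `f > 1 - t` is
#' `hom_alt`, anything in between (boundaries included) is `het`.
#'
#' @param ref_count,alt_count Non-negative allele counts (vectorised).
#' @param t Alternate-allele-frequency threshold.
#' @param min_depth Minimum depth for a call.
#' @return Character vector in `{"hom_ref", "het", "hom_alt", "missing"}`.
#' @export
#' @examples
#' call_genotype_threshold(20, 1)   # hom_ref (f ~ 0.048)
#' call_genotype_threshold(10, 10)  # het
#' call_genotype_threshold(0, 20)   # hom_alt
call_genotype_threshold <- function(ref_count, alt_count, t = 0.075,
                                    min_depth = 5) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0))
  depth <- ref_count + alt_count
  f <- ifelse(depth > 0, alt_count / depth, 0)
  out <- ifelse(depth < min_depth, "missing",
                ifelse(f < t, "hom_ref",
                       ifelse(f > 1 - t, "hom_alt", "het")))
  out
}

#' Phred-scaled site quality from allele counts
#'
#' A binomial-tail surrogate for an aligner's SNP quality score:
#' `Q = min(60, -10 log10 P(X >= alt_count))` with
#' `X ~ Binomial(ref_count + alt_count, error_rate)` — the probability that
#' sequencing error alone produces at least the observed alternate support.
#' `alt_count = 0` yields `Q = 0`.
#'
#' @param ref_count,alt_count Non-negative counts (vectorised).
#' @param error_rate Assumed per-base error probability.
#' @return Numeric Phred-scaled qualities capped at 60.
#' @export
site_quality <- function(ref_count, alt_count, error_rate = 0.01) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0))
  depth <- ref_count + alt_count
  tail_p <- pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
  q <- -10 * log10(pmax(tail_p, 1e-12))
  ifelse(alt_count == 0, 0, pmin(60, q))
}

## shared engine for site calling; returns the long calls table
call_sites_engine <- function(pile, contigs, t, min_depth, error_rate,
                              tri_min_frac) {
  sub <- pile %>% filter(.data$base %in% BASES)
  if (nrow(sub) == 0) {
    return(empty_calls())
  }
  pooled <- sub %>%
    group_by(.data$contig_id, .data$pos, .data$base) %>%
    summarise(n = sum(.data$n), .groups = "drop")
  ref_base <- pooled %>%
    distinct(.data$contig_id, .data$pos) %>%
    mutate(ref = substring(
      contigs$seq[match(.data$contig_id, contigs$contig_id)],
      .data$pos + 1, .data$pos + 1))
  pooled <- pooled %>% left_join(ref_base, by = c("contig_id", "pos"))
  nonref <- pooled %>% filter(.data$base != .data$ref)
  if (nrow(nonref) == 0) return(empty_calls())
  site_alt <- nonref %>%
    group_by(.data$contig_id, .data$pos, .data$ref) %>%
    summarise(
      alt = .data$base[which.max(.data$n)],
      alt_n = max(.data$n),
      extra_n = sum(.data$n) - max(.data$n),
      n_alleles = n() + 1L, .groups = "drop")
  site_depth <- pooled %>%
    group_by(.data$contig_id, .data$pos) %>%
    summarise(depth = sum(.data$n),
              ref_n = sum(.data$n[.data$base == .data$ref[1]]),
              .groups = "drop")
  sites <- site_alt %>%
    left_join(site_depth, by = c("contig_id", "pos")) %>%
    mutate(
      tri_allelic = .data$n_alleles > 2 &
        .data$extra_n >= tri_min_frac * .data$depth,
      quality = site_quality(.data$ref_n, .data$alt_n, error_rate))
  per_sample <- sub %>%
    semi_join(sites, by = c("contig_id", "pos")) %>%
    left_join(sites %>% select("contig_id", "pos", "ref", "alt"),
              by = c("contig_id", "pos")) %>%
    group_by(.data$contig_id, .data$pos, .data$sample) %>%
    summarise(ref_count = sum(.data$n[.data$base == .data$ref[1]]),
              alt_count = sum(.data$n[.data$base == .data$alt[1]]),
              .groups = "drop") %>%
    mutate(genotype = call_genotype_threshold(
      .data$ref_count, .data$alt_count, t = t, min_depth = min_depth))
  sites %>%
    select("contig_id", "pos", "ref", "alt", "quality", "tri_allelic") %>%
    mutate(is_indel = FALSE) %>%
    left_join(per_sample, by = c("contig_id", "pos"))
}

empty_calls <- function() {
  tibble(contig_id = character(0), pos = integer(0), ref = character(0),
         alt = character(0), quality = double(0), tri_allelic = logical(0),
         is_indel = logical(0), sample = character(0),
         ref_count = integer(0), alt_count = integer(0),
         genotype = character(0))
}

#' Call variant sites from a RAD pileup
#'
#' Applies the threshold model at every covered position and reports sites
#' where at least one sample is called heterozygous or homozygous-alternate.
#' Tri-allelic sites (a second non-reference allele with pooled frequency at
#' least `tri_min_frac`) keep the two most frequent alleles and carry a flag
#' consumed by assay design.
#'
#' @param pile A [pileup()] result.
#' @param contigs The contig tibble the pileup refers to.
#' @param t,min_depth Threshold-model parameters
#'   ([call_genotype_threshold()]).
#' @param error_rate Error model for [site_quality()].
#' @param tri_min_frac Minimum pooled frequency for a third allele to flag a
#'   site as tri-allelic.
#' @return Long calls tibble: site columns (`contig_id`, `pos`, `ref`,
#'   `alt`, `quality`, `tri_allelic`, `is_indel`) repeated for each `sample`
#'   with `ref_count`, `alt_count`, `genotype`.
#' @export
call_sites_rad <- function(pile, contigs, t = 0.075, min_depth = 5,
                           error_rate = 0.01, tri_min_frac = 0.075) {
  calls <- call_sites_engine(pile, contigs, t, min_depth, error_rate,
                             tri_min_frac)
  variable <- calls %>%
    group_by(.data$contig_id, .data$pos) %>%
    filter(any(.data$genotype %in% c("het", "hom_alt"))) %>%
    ungroup()
  variable
}

#' Call SNPs and indels from a shotgun pileup
#'
#' Substitution sites are reported when their Phred-scaled quality is at
#' least `snp_q_min`; indel events (pileup rows `I:`/`D:`) when theirs is at
#' least `indel_q_min`. Substitution sites also receive threshold-model
#' genotypes per sample; indel genotypes use indel-supporting versus
#' reference-spanning counts. Only variable sites are reported.
#'
#' @inheritParams call_sites_rad
#' @param snp_q_min,indel_q_min Class-specific quality gates.
#' @return Long calls tibble as in [call_sites_rad()], with `is_indel`
#'   marking indel records (whose `alt` is `I:<seq>` or `D:<len>`).
#' @export
call_sites_shotgun <- function(pile, contigs, t = 0.075, min_depth = 5,
                               error_rate = 0.01, snp_q_min = 20,
                               indel_q_min = 50, tri_min_frac = 0.075) {
  snp <- call_sites_engine(pile, contigs, t, min_depth, error_rate,
                           tri_min_frac) %>%
    group_by(.data$contig_id, .data$pos) %>%
    filter(any(.data$genotype %in% c("het", "hom_alt"))) %>%
    ungroup() %>%
    filter(.data$quality >= snp_q_min)

  ind_rows <- pile %>% filter(!.data$base %in% BASES)
  ind <- empty_calls()
  if (nrow(ind_rows) > 0) {
    depth_at <- pile %>%
      filter(.data$base %in% BASES) %>%
      group_by(.data$contig_id, .data$pos, .data$sample) %>%
      summarise(span_n = sum(.data$n), .groups = "drop")
    ind_site <- ind_rows %>%
      group_by(.data$contig_id, .data$pos, .data$base) %>%
      summarise(alt_n = sum(.data$n), .groups = "drop")
    ind_depth <- depth_at %>%
      group_by(.data$contig_id, .data$pos) %>%
      summarise(tot = sum(.data$span_n), .groups = "drop")
    ind_site <- ind_site %>%
      left_join(ind_depth, by = c("contig_id", "pos")) %>%
      mutate(tot = ifelse(is.na(.data$tot), .data$alt_n, .data$tot),
             quality = site_quality(pmax(.data$tot - .data$alt_n, 0),
                                    .data$alt_n, error_rate)) %>%
      filter(.data$quality >= indel_q_min)
    if (nrow(ind_site) > 0) {
      per_sample <- ind_rows %>%
        semi_join(ind_site, by = c("contig_id", "pos", "base")) %>%
        rename(alt_count = "n") %>%
        left_join(depth_at, by = c("contig_id", "pos", "sample")) %>%
        mutate(span_n = ifelse(is.na(.data$span_n), .data$alt_count,
                               .data$span_n),
               ref_count = pmax(.data$span_n - .data$alt_count, 0L))
      all_samples <- unique(pile$sample)
      full <- tidyr::expand_grid(
        ind_site %>% select("contig_id", "pos", "base", "quality"),
        sample = all_samples) %>%
        left_join(per_sample %>%
                    select("contig_id", "pos", "base", "sample",
                           "ref_count", "alt_count"),
                  by = c("contig_id", "pos", "base", "sample")) %>%
        left_join(depth_at, by = c("contig_id", "pos", "sample")) %>%
        mutate(
          alt_count = ifelse(is.na(.data$alt_count), 0L, .data$alt_count),
          ref_count = ifelse(is.na(.data$ref_count),
                             ifelse(is.na(.data$span_n), 0L, .data$span_n),
                             .data$ref_count))
      ind <- full %>%
        mutate(
          ref = substring(
            contigs$seq[match(.data$contig_id, contigs$contig_id)],
            .data$pos + 1, .data$pos + 1),
          alt = .data$base, tri_allelic = FALSE, is_indel = TRUE,
          genotype = call_genotype_threshold(.data$ref_count,
                                             .data$alt_count,
                                             t = t, min_depth = min_depth)) %>%
        select("contig_id", "pos", "ref", "alt", "quality", "tri_allelic",
               "is_indel", "sample", "ref_count", "alt_count", "genotype")
    }
  }
  bind_rows(snp, ind) %>%
    arrange(.data$contig_id, .data$pos, .data$sample)
}

#' Summarise a call set
#'
#' Classifies each variant site as heterozygous (at least one sample called
#' het) or homozygous, and tabulates substitutions by unordered base pair
#' (A-G, C-T, A-C, G-T, A-T, C-G).
#'
#' @param calls A long calls tibble ([call_sites_rad()] /
#'   [call_sites_shotgun()]).
#' @return An object of class `variant_summary`: list with `totals` (one-row
#'   tibble: `n_sites`, `n_het`, `n_hom`, `het_pct`) and `classes` (tibble
#'   `pair`, `n`, `class`).
#' @export
summarize_variants <- function(calls) {
  if (nrow(calls) == 0) abort("`calls` must be non-empty.")
  snp <- calls %>% filter(!.data$is_indel)
  site <- snp %>%
    group_by(.data$contig_id, .data$pos, .data$ref, .data$alt) %>%
    summarise(het = any(.data$genotype == "het"), .groups = "drop")
  totals <- tibble(
    n_sites = nrow(site),
    n_het = sum(site$het),
    n_hom = sum(!site$het),
    het_pct = if (nrow(site) > 0) round(100 * mean(site$het)) else NA_real_)
  classes <- site %>%
    mutate(pair = paste(pmin(.data$ref, .data$alt),
                        pmax(.data$ref, .data$alt), sep = "-")) %>%
    count(.data$pair, name = "n") %>%
    mutate(class = ifelse(.data$pair %in% c("A-G", "C-T"),
                          "transition", "transversion"))
  structure(list(totals = totals, classes = classes),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("<variant_summary>\n")
  print(x$totals)
  print(x$classes)
  invisible(x)
}
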