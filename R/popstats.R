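#' Consensus genotype from replicate observations
#'
#' An allele enters the consensus when it is observed in at least two
#' replicates. Exactly two accepted alleles give a heterozygous consensus,
#' one gives a homozygous consensus, none (every allele observed once,
#' conflicting) gives no consensus, and an all-missing replicate set is
#' missing.
#'
#' @param obs_a1,obs_a2 Character vectors of replicate allele observations
#'   (NA for a failed replicate).
#' @return List with `a1`, `a2` (NA unless a consensus was reached) and
#'   `status` in `{"het", "hom", "no_consensus", "missing"}`.
#' @export
#' @examples
#' consensus_genotype(c("A", "A", "A"), c("B", "B", "A"))  # het A/B
consensus_genotype <- function(obs_a1, obs_a2) {
  ok <- !is.na(obs_a1) & !is.na(obs_a2)
  if (!any(ok)) {
    return(list(a1 = NA_character_, a2 = NA_character_, status = "missing"))
  }
  support <- table(unlist(lapply(which(ok), function(i)
    unique(c(obs_a1[i], obs_a2[i])))))
  accepted <- sort(names(support)[support >= 2])
  if (length(accepted) == 2) {
    list(a1 = accepted[1], a2 = accepted[2], status = "het")
  } else if (length(accepted) == 1) {
    list(a1 = accepted[1], a2 = accepted[1], status = "hom")
  } else {
    list(a1 = NA_character_, a2 = NA_character_, status = "no_consensus")
  }
}

#' Consensus genotypes for a whole replicate table
#'
#' Applies [consensus_genotype()] to every sample x locus group.
#'
#' @param replicates Replicate tibble with columns `sample`, `locus`,
#'   `obs_a1`, `obs_a2` (e.g. from [simulate_replicates()]).
#' @return Tibble `sample`, `locus`, `a1`, `a2`, `status`, `n_positive`,
#'   `n_attempted`.
#' @export
consensus_genotypes <- function(replicates) {
  replicates %>%
    group_by(.data$sample, .data$locus) %>%
    summarise(
      .cons = list(consensus_genotype(.data$obs_a1, .data$obs_a2)),
      n_positive = sum(!is.na(.data$obs_a1)),
      n_attempted = n(), .groups = "drop") %>%
    mutate(a1 = purrr::map_chr(.data$.cons, "a1"),
           a2 = purrr::map_chr(.data$.cons, "a2"),
           status = purrr::map_chr(.data$.cons, "status")) %>%
    select("sample", "locus", "a1", "a2", "status", "n_positive",
           "n_attempted")
}

#' Genotyping error rates from replicate data
#'
#' Estimates, against the consensus genotypes: the allelic-dropout rate
#' (positive amplifications of heterozygous-consensus entries that show only
#' one consensus allele, over all positive amplifications of those entries),
#' the false-allele rate (positive amplifications showing at least one
#' allele absent from the consensus, over all positive amplifications of
#' consensus-resolved entries), and the positive-PCR rate (positive over
#' attempted amplifications). Zero denominators report as `NA`.
#'
#' @param replicates Replicate tibble (`sample`, `locus`, `obs_a1`,
#'   `obs_a2`, optionally grouping columns such as `plex`).
#' @param by Optional character vector of grouping columns (e.g. `"sample"`
#'   or `"plex"`); the default reports a single overall row.
#' @return Tibble with `ado_rate`, `fa_rate`, `positive_pcr_rate` and their
#'   numerators/denominators, one row per group.
#' @export
error_rates <- function(replicates, by = NULL) {
  cons <- consensus_genotypes(replicates)
  dat <- replicates %>%
    left_join(cons %>% select("sample", "locus", "a1", "a2", "status"),
              by = c("sample", "locus")) %>%
    mutate(
      positive = !is.na(.data$obs_a1),
      resolved = .data$status %in% c("het", "hom"),
      obs_hom = .data$positive & .data$obs_a1 == .data$obs_a2,
      ado_event = .data$positive & .data$status == "het" & .data$obs_hom &
        (.data$obs_a1 == .data$a1 | .data$obs_a1 == .data$a2),
      fa_event = .data$positive & .data$resolved &
        (!.data$obs_a1 %in% c(.data$a1, .data$a2) |
           !.data$obs_a2 %in% c(.data$a1, .data$a2)))
  grouped <- if (is.null(by)) dat else group_by(dat, across(all_of(by)))
  grouped %>%
    summarise(
      n_attempted = n(),
      n_positive = sum(.data$positive),
      het_positive = sum(.data$positive & .data$status == "het"),
      ado_events = sum(.data$ado_event),
      fa_events = sum(.data$fa_event),
      resolved_positive = sum(.data$positive & .data$resolved),
      .groups = "drop") %>%
    mutate(
      ado_rate = ifelse(.data$het_positive > 0,
                        .data$ado_events / .data$het_positive, NA_real_),
      fa_rate = ifelse(.data$resolved_positive > 0,
                       .data$fa_events / .data$resolved_positive, NA_real_),
      positive_pcr_rate = ifelse(.data$n_attempted > 0,
                                 .data$n_positive / .data$n_attempted,
                                 NA_real_))
}

#' Observed heterozygosity per individual
#'
#' `Ho(i)` is the fraction of an individual's non-missing genotyped loci at
#' which it is heterozygous.
#'
#' @param genotypes Tibble with `sample`, `locus`, `a1`, `a2` (NA alleles =
#'   missing genotype).
#' @return List with `per_individual` (tibble `sample`, `n_genotyped`,
#'   `n_het`, `ho`; `ho` is NA for individuals with no genotyped loci) and
#'   `mean_ho` (mean over individuals with data).
#' @export
observed_heterozygosity <- function(genotypes) {
  per <- genotypes %>%
    group_by(.data$sample) %>%
    summarise(
      n_genotyped = sum(!is.na(.data$a1) & !is.na(.data$a2)),
      n_het = sum(!is.na(.data$a1) & !is.na(.data$a2) &
                    .data$a1 != .data$a2),
      .groups = "drop") %>%
    mutate(ho = ifelse(.data$n_genotyped > 0,
                       .data$n_het / .data$n_genotyped, NA_real_))
  list(per_individual = per, mean_ho = mean(per$ho, na.rm = TRUE))
}

#' Mean number of alleles per locus (MNA)
#'
#' @inheritParams observed_heterozygosity
#' @return Mean over loci of the number of distinct alleles observed among
#'   non-missing genotypes.
#' @export
mna <- function(genotypes) {
  per_locus <- genotypes %>%
    filter(!is.na(.data$a1), !is.na(.data$a2)) %>%
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") %>%
    group_by(.data$locus) %>%
    summarise(k = dplyr::n_distinct(.data$allele), .groups = "drop")
  if (nrow(per_locus) == 0) abort("No genotyped loci.")
  mean(per_locus$k)
}

#' Fraction of polymorphic loci
#'
#' A locus is polymorphic when at least two distinct alleles are observed
#' among non-missing genotypes.
#'
#' @inheritParams observed_heterozygosity
#' @return List with `fraction` and `percent` (rounded to a whole number).
#' @export
#' @examples
#' # 33 polymorphic of 194 -> 17%
polymorphic_fraction <- function(genotypes) {
  per_locus <- genotypes %>%
    group_by(.data$locus) %>%
    summarise(k = dplyr::n_distinct(
      c(.data$a1[!is.na(.data$a1)], .data$a2[!is.na(.data$a2)])),
      .groups = "drop")
  if (nrow(per_locus) == 0) abort("No loci.")
  frac <- mean(per_locus$k >= 2)
  list(fraction = frac, percent = round(100 * frac))
}

#' Transition/transversion summary
#'
#' Classifies unordered substitution base pairs into transitions (A-G, C-T)
#' and transversions (A-C, G-T, A-T, C-G) and reports the ts/tv ratio,
#' rounded to two decimals (`NA` when there are no transversions).
#'
#' @param substitutions Either a character vector of unordered base pairs
#'   (`"A-G"`, `"G-A"`, ... in any orientation), or a tibble with columns
#'   `pair` and `n`.
#' @return One-row tibble `n_transitions`, `n_transversions`, `ratio`, with
#'   the per-class count table in attribute `"classes"`.
#' @export
#' @examples
#' tstv(tibble::tibble(
#'   pair = c("A-G", "C-T", "A-C", "G-T", "A-T", "C-G"),
#'   n = c(380, 404, 132, 115, 61, 178)))  # ratio 1.61
tstv <- function(substitutions) {
  if (is.character(substitutions)) {
    substitutions <- tibble(pair = substitutions) %>%
      count(.data$pair, name = "n")
  }
  parts <- stringr::str_split_fixed(substitutions$pair, stringr::fixed("-"), 2)
  if (!all(parts %in% BASES)) abort("Invalid base pair in `substitutions`.")
  canon <- paste(pmin(parts[, 1], parts[, 2]),
                 pmax(parts[, 1], parts[, 2]), sep = "-")
  classes <- tibble(pair = canon, n = substitutions$n) %>%
    group_by(.data$pair) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(class = ifelse(.data$pair %in% c("A-G", "C-T"),
                          "transition", "transversion"))
  ts <- sum(classes$n[classes$class == "transition"])
  tv <- sum(classes$n[classes$class == "transversion"])
  out <- tibble(n_transitions = ts, n_transversions = tv,
                ratio = if (tv > 0) round(ts / tv, 2) else NA_real_)
  attr(out, "classes") <- classes
  out
}

#' SNP density
#'
#' SNPs per base of screened contig sequence, reported to two significant
#' figures.
#'
#' @param n_snps SNP count.
#' @param total_contig_bases Total bases of the contigs screened for SNPs.
#' @return A single density value.
#' @export
snp_density <- function(n_snps, total_contig_bases) {
  if (total_contig_bases <= 0) abort("`total_contig_bases` must be > 0.")
  signif(n_snps / total_contig_bases, 2)
}

#' Replicate-genotyping quality-control report
#'
#' Bundles consensus genotypes, error rates (overall and per sample) and
#' diversity statistics (Ho, MNA, polymorphic fraction) for a replicate
#' table — the per-sample row set of a genotyping validation report.
#'
#' @param replicates Replicate tibble (`sample`, `locus`, `obs_a1`,
#'   `obs_a2`, optional `plex`).
#' @return Object of class `genotyping_qc`: list with `consensus`,
#'   `overall`, `per_sample` (error-rate tibbles), `ho`, `mna_value`,
#'   `polymorphic`.
#' @export
genotyping_qc <- function(replicates) {
  cons <- consensus_genotypes(replicates)
  genotypes <- cons %>% select("sample", "locus", "a1", "a2")
  per_sample <- error_rates(replicates, by = "sample")
  overall <- error_rates(replicates)
  per_plex <- if ("plex" %in% names(replicates)) {
    error_rates(replicates, by = "plex")
  } else NULL
  ho <- observed_heterozygosity(genotypes)
  structure(list(
    consensus = cons, overall = overall, per_sample = per_sample,
    per_plex = per_plex, ho = ho, mna_value = mna(genotypes),
    polymorphic = polymorphic_fraction(genotypes)), class = "genotyping_qc")
}

#' @export
print.genotyping_qc <- function(x, ...) {
  cat("<genotyping_qc>\n")
  cat(sprintf("  %d sample x locus entries; mean Ho %.4f; MNA %.3f; %d%% polymorphic\n",
              nrow(x$consensus), x$ho$mean_ho, x$mna_value,
              x$polymorphic$percent))
  print(x$overall)
  invisible(x)
}
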