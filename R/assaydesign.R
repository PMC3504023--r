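#' Filter candidate SNPs to assayable markers
#'
#' Applies the genotyping-assay design rules to a site table: a SNP is
#' assayable when (a) no other polymorphism (SNP, indel or tri-allelic
#' residue) lies within `window` bases up- or downstream, (b) at least
#' `edge` bases of contig flank it on both sides, and (c) it is not
#' tri-allelic. Among survivors on one contig only the SNP with the highest
#' site quality is kept (ties go to the leftmost), since one SNP is selected
#' per contig. A transparent `design_score` — the fraction of rules passed —
#' stands in for proprietary designability scores.
#'
#' @param sites Site-level tibble with columns `contig_id`, `pos`,
#'   `quality`, `tri_allelic`, `is_indel` (one row per variant site; a long
#'   calls table is collapsed automatically).
#' @param contigs Contig tibble (`contig_id`, `seq`) giving contig lengths.
#' @param window Exclusion window for neighbouring polymorphisms (bases).
#' @param edge Minimum distance to either contig end (bases).
#' @param keep_all Return every candidate with its rule flags instead of
#'   only the assayable survivors.
#' @return Marker tibble: input site columns plus `rule_window`,
#'   `rule_edge`, `rule_biallelic`, `rule_unique`, `design_score`,
#'   `assayable`. With the default `keep_all = FALSE` only rows with
#'   `assayable == TRUE` are returned, which makes the operation idempotent.
#' @export
filter_assayable <- function(sites, contigs, window = 60, edge = 30,
                             keep_all = FALSE) {
  site_cols <- intersect(
    c("contig_id", "pos", "ref", "alt", "quality", "tri_allelic",
      "is_indel"), names(sites))
  sites <- sites %>% distinct(across(all_of(site_cols)))
  if (!"is_indel" %in% names(sites)) sites$is_indel <- FALSE
  if (!"tri_allelic" %in% names(sites)) sites$tri_allelic <- FALSE
  if (!"quality" %in% names(sites)) sites$quality <- NA_real_
  clen <- setNames(nchar(contigs$seq), contigs$contig_id)
  out <- sites %>%
    group_by(.data$contig_id) %>%
    mutate(rule_window = vapply(seq_len(n()), function(i) {
      d <- abs(.data$pos[-i] - .data$pos[i])
      length(d) == 0 || all(d > window)
    }, logical(1))) %>%
    ungroup() %>%
    mutate(
      .len = unname(clen[.data$contig_id]),
      rule_edge = .data$pos >= edge & (.data$.len - .data$pos - 1) >= edge,
      rule_biallelic = !.data$tri_allelic & !.data$is_indel)
  survivors <- out %>%
    filter(.data$rule_window, .data$rule_edge, .data$rule_biallelic) %>%
    group_by(.data$contig_id) %>%
    arrange(desc(.data$quality), .data$pos, .by_group = TRUE) %>%
    mutate(rule_unique = row_number() == 1) %>%
    ungroup()
  out <- out %>%
    left_join(survivors %>% select("contig_id", "pos", "rule_unique"),
              by = c("contig_id", "pos")) %>%
    mutate(
      rule_unique = !is.na(.data$rule_unique) & .data$rule_unique,
      design_score = (.data$rule_window + .data$rule_edge +
                        .data$rule_biallelic + .data$rule_unique) / 4,
      assayable = .data$design_score == 1) %>%
    select(-".len") %>%
    arrange(.data$contig_id, .data$pos)
  if (keep_all) out else filter(out, .data$assayable)
}

#' Group markers into multiplex assays
#'
#' Assigns markers to consecutive plexes of at most `cap` markers, in input
#' order; the number of plexes is `ceiling(n / cap)`.
#'
#' @param markers Marker tibble (any rows).
#' @param cap Maximum markers per plex.
#' @return The input with an integer `plex` column.
#' @export
#' @examples
#' group_multiplexes(tibble::tibble(id = 1:85))$plex |> table()  # 40, 40, 5
group_multiplexes <- function(markers, cap = 40) {
  stopifnot(cap >= 1)
  markers %>% mutate(plex = as.integer((row_number() - 1) %/% cap + 1))
}

#' Flag loci showing fixed heterozygosity
#'
#' A locus where every genotyped individual is heterozygous is the signature
#' of two co-amplifying monomorphic paralogous loci collapsed into one
#' assay. Loci are flagged when all non-missing genotypes are `het` and at
#' least `min_genotyped` genotypes are non-missing.
#'
#' @param genotypes Long genotype tibble with columns `locus`, `sample`,
#'   `gt` (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`/`NA`).
#' @param min_genotyped Minimum non-missing genotypes before the flag is
#'   trusted.
#' @return Tibble `locus`, `n_genotyped`, `n_het`, `fixed_het`.
#' @export
flag_fixed_heterozygotes <- function(genotypes, min_genotyped = 2) {
  genotypes %>%
    mutate(gt = ifelse(is.na(.data$gt), "missing", .data$gt)) %>%
    group_by(.data$locus) %>%
    summarise(
      n_genotyped = sum(.data$gt != "missing"),
      n_het = sum(.data$gt == "het"),
      .groups = "drop") %>%
    mutate(fixed_het = .data$n_genotyped >= min_genotyped &
             .data$n_het == .data$n_genotyped)
}

#' Split fixed-heterozygous loci into co-amplified pairs
#'
#' Each flagged locus is replaced by two monomorphic loci, one per
#' co-amplifying allele; unflagged loci pass through unchanged. The output
#' has `n - f + 2f` rows for `n` input loci of which `f` are flagged.
#'
#' @param loci Tibble with a `locus` column (one row per locus).
#' @param flagged Character vector of flagged locus ids (must be a subset of
#'   `loci$locus`).
#' @return Tibble with columns of `loci` plus `parent_locus` and
#'   `co_allele` (`NA` for unsplit loci, `"a"`/`"b"` for split pairs);
#'   `locus` of split rows is suffixed `.a` / `.b`.
#' @export
#' @examples
#' split_duplicated_loci(tibble::tibble(locus = as.character(1:161)),
#'                       as.character(1:33)) |> nrow()  # 194
split_duplicated_loci <- function(loci, flagged) {
  if (!all(flagged %in% loci$locus)) {
    abort("`flagged` must be a subset of `loci$locus`.")
  }
  keep <- loci %>% filter(!.data$locus %in% flagged) %>%
    mutate(parent_locus = .data$locus, co_allele = NA_character_)
  split_a <- loci %>% filter(.data$locus %in% flagged) %>%
    mutate(parent_locus = .data$locus, co_allele = "a",
           locus = paste0(.data$locus, ".a"))
  split_b <- loci %>% filter(.data$locus %in% flagged) %>%
    mutate(parent_locus = .data$locus, co_allele = "b",
           locus = paste0(.data$locus, ".b"))
  bind_rows(keep, split_a, split_b) %>% arrange(.data$parent_locus)
}

#' Count private alleles per individual
#'
#' A locus contributes to an individual's private-allele count when that
#' individual is heterozygous there and every other non-missing genotype is
#' homozygous for the major allele (the minor allele is observed in exactly
#' one heterozygous individual).
#'
#' @inheritParams flag_fixed_heterozygotes
#' @return Tibble `sample`, `n_private` (zeros included).
#' @export
private_alleles <- function(genotypes) {
  g <- genotypes %>%
    mutate(gt = ifelse(is.na(.data$gt), "missing", .data$gt))
  per_locus <- g %>%
    group_by(.data$locus) %>%
    summarise(
      n_het = sum(.data$gt == "het"),
      het_sample = if (sum(.data$gt == "het") == 1)
        .data$sample[.data$gt == "het"] else NA_character_,
      others_hom_same = {
        o <- .data$gt[.data$gt != "missing" & .data$gt != "het"]
        length(o) > 0 && length(unique(o)) == 1
      },
      .groups = "drop") %>%
    filter(.data$n_het == 1, .data$others_hom_same)
  g %>%
    distinct(.data$sample) %>%
    left_join(per_locus %>% count(sample = .data$het_sample,
                                  name = "n_private"),
              by = "sample") %>%
    mutate(n_private = ifelse(is.na(.data$n_private), 0L,
                              as.integer(.data$n_private))) %>%
    arrange(.data$sample)
}
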