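## long calls -> genotype tibble in code form (locus = contig:pos)
calls_to_gt <- function(calls) {
  calls %>%
    mutate(locus = paste0(.data$contig_id, ":", .data$pos),
           gt = .data$genotype) %>%
    select("locus", "sample", "gt")
}

## long calls -> genotype tibble in allele form (a1/a2)
calls_to_alleles <- function(calls) {
  calls %>%
    mutate(locus = paste0(.data$contig_id, ":", .data$pos),
           a1 = dplyr::case_when(
             .data$genotype == "hom_ref" ~ .data$ref,
             .data$genotype == "het" ~ .data$ref,
             .data$genotype == "hom_alt" ~ .data$alt,
             TRUE ~ NA_character_),
           a2 = dplyr::case_when(
             .data$genotype == "hom_ref" ~ .data$ref,
             .data$genotype == "het" ~ .data$alt,
             .data$genotype == "hom_alt" ~ .data$alt,
             TRUE ~ NA_character_)) %>%
    select("locus", "sample", "a1", "a2")
}

stage_row <- function(stage, n, t0) {
  tibble(stage = stage, n_records = as.integer(n),
         elapsed_s = round(as.numeric(Sys.time()) - t0, 2))
}

#' Run the RAD marker-discovery pipeline end to end
#'
#' Simulate (optionally against a supplied truth set) -> demultiplex ->
#' unitag clustering -> local assembly -> coverage filtering ->
#' mini-reference selection -> mapping of all samples' reverse reads ->
#' threshold genotype calling -> assay-design filtering and multiplex
#' grouping -> paralog (fixed-heterozygote) flagging and private-allele
#' counts -> summary statistics.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-built [simulate_reference()] truth set (must
#'   match `config`).
#' @param k,min_contig_length Assembler parameters.
#' @param min_cov,max_cov Unitag depth bounds.
#' @param t,min_depth Threshold-caller parameters.
#' @param window,edge,plex_cap Assay-design parameters.
#' @return Object of class `rad_run`: list with the stage outputs (`truth`,
#'   `demux_rejected`, `unitags`, `contigs`, `reference_sample`, `calls`,
#'   `markers`, `fixed_het`, `private`, `variant_summary`, `sample_summary`,
#'   `manifest`).
#' @export
run_rad_pipeline <- function(config, truth = NULL, k = 31,
                             min_contig_length = 150, min_cov = 5,
                             max_cov = 500, t = 0.075, min_depth = 5,
                             window = 60, edge = 30, plex_cap = 40) {
  manifest <- list()
  t0 <- as.numeric(Sys.time())
  if (is.null(truth)) truth <- simulate_reference(config)
  lib <- simulate_rad_library(truth, config)
  manifest$sim <- stage_row("simulate", nrow(lib$pairs), t0)

  t0 <- as.numeric(Sys.time())
  dm <- demultiplex(lib$pairs, config$barcodes)
  if (nrow(dm$pairs) + dm$n_rejected != nrow(lib$pairs)) {
    abort("Stage demultiplex: record counts do not reconcile.")
  }
  manifest$demux <- stage_row("demultiplex", nrow(dm$pairs), t0)

  t0 <- as.numeric(Sys.time())
  unitags <- build_unitags(dm$pairs, min_cov = min_cov, max_cov = max_cov)
  manifest$unitags <- stage_row("unitags", nrow(unitags), t0)

  t0 <- as.numeric(Sys.time())
  contigs_all <- bind_rows(lapply(
    split(unitags, unitags$sample), assemble_sample, k = k,
    min_contig_length = min_contig_length))
  manifest$assemble <- stage_row("assemble", nrow(contigs_all), t0)

  t0 <- as.numeric(Sys.time())
  contigs <- filter_assemblies(contigs_all)
  refsamp <- select_reference_sample(
    contigs %>% filter(.data$is_locus_contig))
  mini_ref <- contigs %>%
    filter(.data$sample == refsamp, .data$is_locus_contig) %>%
    select("contig_id", "seq", "unitag")
  manifest$filter <- stage_row("filter_assemblies", nrow(contigs), t0)

  t0 <- as.numeric(Sys.time())
  reads2 <- dm$pairs %>%
    select("read_id", "sample", seq = "seq2")
  aln <- map_reads(reads2, mini_ref, mode = "rad")
  manifest$map <- stage_row("map", nrow(aln), t0)

  t0 <- as.numeric(Sys.time())
  pile <- pileup(aln, mini_ref)
  calls <- call_sites_rad(pile, mini_ref, t = t, min_depth = min_depth)
  manifest$call <- stage_row("call", nrow(calls), t0)

  t0 <- as.numeric(Sys.time())
  markers <- filter_assayable(calls, mini_ref, window = window,
                              edge = edge) %>%
    group_multiplexes(cap = plex_cap)
  gt <- calls_to_gt(calls)
  fixed <- flag_fixed_heterozygotes(gt)
  priv <- private_alleles(gt)
  vsum <- if (nrow(calls) > 0) summarize_variants(calls) else NULL
  manifest$markers <- stage_row("assay_design", nrow(markers), t0)

  per_sample_reads <- dm$pairs %>%
    group_by(.data$sample) %>%
    summarise(n_pairs = n(),
              mb = sum(nchar(.data$seq1) + nchar(.data$seq2)) / 1e6,
              .groups = "drop")
  per_sample_tags <- unitags %>% count(.data$sample, name = "n_tags")
  astats <- assembly_stats(contigs)
  ratio <- if (!is.null(vsum)) tstv(vsum$classes %>%
                                      select("pair", "n")) else NULL
  total_ref_bp <- sum(nchar(mini_ref$seq))
  sample_summary <- per_sample_reads %>%
    left_join(per_sample_tags, by = "sample") %>%
    left_join(astats, by = "sample") %>%
    mutate(
      putative_snps = if (!is.null(vsum)) vsum$totals$n_sites else 0L,
      het_pct = if (!is.null(vsum)) vsum$totals$het_pct else NA_real_,
      tstv_ratio = if (!is.null(ratio)) ratio$ratio else NA_real_,
      density = if (!is.null(vsum) && total_ref_bp > 0)
        snp_density(vsum$totals$n_sites, total_ref_bp) else NA_real_)

  structure(list(
    config = config, truth = truth,
    demux_rejected = dm$n_rejected, unitags = unitags,
    contigs = contigs, reference_sample = refsamp, mini_ref = mini_ref,
    alignments_attr = list(n_unmapped = attr(aln, "n_unmapped"),
                           n_ambiguous = attr(aln, "n_ambiguous")),
    calls = calls, markers = markers, fixed_het = fixed, private = priv,
    variant_summary = vsum, tstv = ratio,
    sample_summary = sample_summary,
    manifest = bind_rows(manifest)), class = "rad_run")
}

#' @export
print.rad_run <- function(x, ...) {
  cat("<rad_run>\n")
  cat(sprintf("  %d read pairs; %d unitag clusters; %d contigs; mini-reference %s\n",
              sum(x$sample_summary$n_pairs), nrow(x$unitags),
              nrow(x$contigs), x$reference_sample))
  nsites <- if (!is.null(x$variant_summary))
    x$variant_summary$totals$n_sites else 0
  cat(sprintf("  %d variant sites; %d assayable markers in %d plexes\n",
              nsites, nrow(x$markers),
              if (nrow(x$markers)) max(x$markers$plex) else 0L))
  invisible(x)
}

#' Run the shotgun marker-discovery pipeline end to end
#'
#' Simulates long single-end reads for the configured samples, assembles one
#' combined contig set from the pooled reads, maps the reads back, calls
#' quality-gated SNPs and indels, and scans the contigs for microsatellites
#' with PAL classification.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-built truth set.
#' @param n_reads Reads per sample.
#' @param k,min_contig_length Assembler parameters (contigs over 100 bp are
#'   kept by default, matching long-read shotgun practice).
#' @param snp_q_min,indel_q_min Quality gates for substitution and indel
#'   calls.
#' @param min_repeats Per-class SSR minima ([find_ssrs()]).
#' @return Object of class `shotgun_run`: list with `contigs`, `calls`,
#'   `ssrs`, `ssr_summary`, `variant_summary`, `assembly`, `manifest`.
#' @export
run_shotgun_pipeline <- function(config, truth = NULL, n_reads = 1500,
                                 k = 31, min_contig_length = 100,
                                 snp_q_min = 20, indel_q_min = 50,
                                 min_repeats = default_min_repeats()) {
  manifest <- list()
  t0 <- as.numeric(Sys.time())
  if (is.null(truth)) truth <- simulate_reference(config)
  sg <- simulate_shotgun(truth, config, n_reads = n_reads)
  manifest$sim <- stage_row("simulate", nrow(sg$reads), t0)

  t0 <- as.numeric(Sys.time())
  contigs <- debruijn_assemble(sg$reads$seq, k = k,
                               min_contig_length = min_contig_length,
                               dedupe_revcomp = TRUE) %>%
    mutate(contig_id = sprintf("ctg%05d", row_number()))
  manifest$assemble <- stage_row("assemble", nrow(contigs), t0)

  t0 <- as.numeric(Sys.time())
  aln <- map_reads(sg$reads, contigs, mode = "shotgun")
  manifest$map <- stage_row("map", nrow(aln), t0)

  t0 <- as.numeric(Sys.time())
  pile <- pileup(aln, contigs)
  calls <- call_sites_shotgun(pile, contigs, snp_q_min = snp_q_min,
                              indel_q_min = indel_q_min)
  manifest$call <- stage_row("call", nrow(calls), t0)

  t0 <- as.numeric(Sys.time())
  ssrs <- find_ssrs_contigs(contigs, min_repeats = min_repeats)
  if (nrow(ssrs) > 0) {
    ssrs <- ssrs %>% classify_compound() %>% classify_pal(contigs)
  }
  ssum <- summarize_ssrs(ssrs)
  manifest$ssr <- stage_row("ssr", nrow(ssrs), t0)

  vsum <- if (nrow(calls) > 0) summarize_variants(calls) else NULL
  assembly <- contigs %>% mutate(sample = "combined") %>% assembly_stats()

  structure(list(
    config = config, truth = truth, reads = sg$manifest,
    contigs = contigs, calls = calls, ssrs = ssrs, ssr_summary = ssum,
    variant_summary = vsum, assembly = assembly,
    manifest = bind_rows(manifest)), class = "shotgun_run")
}

#' @export
print.shotgun_run <- function(x, ...) {
  cat("<shotgun_run>\n")
  cat(sprintf("  %d contigs (N50 %d bp); %d call records; %d SSRs\n",
              nrow(x$contigs), x$assembly$n50[1], nrow(x$calls),
              nrow(x$ssrs)))
  invisible(x)
}

## ---- truth-linked evaluation ---------------------------------------------

## contig -> truth locus assignment for the mini-reference, via the unitag
mini_ref_locus_map <- function(run) {
  truth <- run$truth
  tags <- vapply(seq_len(nrow(truth$loci)), function(i)
    substr(locus_template(truth, truth$loci$locus_id[i],
                          run$reference_sample, 1), 1,
           run$config$read_lengths[1]),
    character(1))
  tibble(locus_id = truth$loci$locus_id, tag = tags,
         is_paralog = truth$loci$is_paralog)
}

#' Planted-locus recovery of a RAD run
#'
#' For every planted non-paralogous locus, checks whether the mini-reference
#' sample's locus contig is an exact substring of the planted locus span on
#' at least one haplotype of that sample (every assembled base correct, with
#' the extent set by the random shear coverage). Paralogous loci are
#' excluded: they collapse into one cluster by design and are evaluated via
#' [evaluate_fixed_het()].
#'
#' @param run A [run_rad_pipeline()] result with its embedded truth.
#' @return List: `n_loci`, `n_recovered`, `recovery` (fraction), and the
#'   per-locus tibble `detail`.
#' @export
evaluate_locus_recovery <- function(run) {
  truth <- run$truth
  lmap <- mini_ref_locus_map(run) %>% filter(!.data$is_paralog)
  ctg <- run$mini_ref
  detail <- lmap
  detail$contig_seq <- ctg$seq[match(detail$tag, ctg$unitag)]
  detail$recovered <- vapply(seq_len(nrow(detail)), function(i) {
    cs <- detail$contig_seq[i]
    if (is.na(cs)) return(FALSE)
    t1 <- locus_truth_seq(truth, detail$locus_id[i], run$reference_sample, 1)
    t2 <- locus_truth_seq(truth, detail$locus_id[i], run$reference_sample, 2)
    grepl(cs, t1, fixed = TRUE) || grepl(cs, t2, fixed = TRUE)
  }, logical(1))
  list(n_loci = nrow(detail), n_recovered = sum(detail$recovered),
       recovery = mean(detail$recovered), detail = detail)
}

#' Planted-genotype concordance of a RAD run
#'
#' Locates every planted variant on the mini-reference contigs and compares
#' threshold-model calls with the planted genotypes, allele-aware: when the
#' mini-reference carries the alternate allele the call's reference and
#' alternate states are swapped before comparison. Variants whose site was
#' never reported are concordant for exactly the samples that are truly
#' homozygous-reference. Counted over planted variant x sample pairs at
#' recovered (non-paralogous) loci.
#'
#' @param run A [run_rad_pipeline()] result.
#' @return List: `n_genotypes`, `n_concordant`, `concordance`, `detail`.
#' @export
evaluate_genotype_concordance <- function(run) {
  truth <- run$truth
  lmap <- mini_ref_locus_map(run) %>% filter(!.data$is_paralog)
  ctg <- run$mini_ref %>%
    mutate(locus_id = lmap$locus_id[match(.data$unitag, lmap$tag)])
  v <- truth$variants %>%
    filter(.data$type == "snp") %>%
    left_join(ctg %>% select("locus_id", "contig_id", cseq = "seq"),
              by = "locus_id") %>%
    filter(!is.na(.data$contig_id))
  if (nrow(v) == 0) {
    return(list(n_genotypes = 0L, n_concordant = 0L, concordance = NA_real_,
                detail = tibble()))
  }
  # contig offset of each variant: position of the contig inside the
  # template of the haplotype the contig was assembled from
  v$cpos <- vapply(seq_len(nrow(v)), function(i) {
    for (hap in 1:2) {
      tpl <- locus_template(truth, v$locus_id[i], run$reference_sample, hap)
      p <- regexpr(v$cseq[i], tpl, fixed = TRUE)[1]
      if (p > 0) return(as.integer(v$offset[i] - (p - 1)))
    }
    NA_integer_
  }, integer(1))
  v <- v %>% filter(!is.na(.data$cpos), .data$cpos >= 0,
                    .data$cpos < nchar(.data$cseq))
  truth_gt <- truth$genotypes %>%
    mutate(truth_code = c("hom_ref", "het", "hom_alt")[.data$h1 + .data$h2
                                                       + 1L])
  v$contig_base <- substring(v$cseq, v$cpos + 1, v$cpos + 1)
  detail <- tidyr::expand_grid(
    v %>% select("variant_id", "contig_id", "cpos", "ref_locus",
                 "alt_locus", "contig_base"),
    sample = names(run$config$barcodes)) %>%
    left_join(truth_gt %>% select("variant_id", "sample", "truth_code"),
              by = c("variant_id", "sample")) %>%
    left_join(run$calls %>%
                select("contig_id", "pos", "ref", "alt", "sample",
                       "genotype"),
              by = c("contig_id", cpos = "pos", "sample")) %>%
    mutate(
      called = !is.na(.data$genotype),
      # orient the call into truth-allele space
      oriented = dplyr::case_when(
        # site absent: every sample matches the mini-reference allele
        !.data$called & .data$contig_base == .data$ref_locus ~ "hom_ref",
        !.data$called ~ "hom_alt",
        .data$ref == .data$ref_locus ~ .data$genotype,
        .data$ref == .data$alt_locus & .data$genotype == "hom_ref"
        ~ "hom_alt",
        .data$ref == .data$alt_locus & .data$genotype == "hom_alt"
        ~ "hom_ref",
        .data$ref == .data$alt_locus ~ .data$genotype,
        TRUE ~ "foreign_allele"),
      concordant = .data$oriented == .data$truth_code)
  list(n_genotypes = nrow(detail),
       n_concordant = sum(detail$concordant),
       concordance = mean(detail$concordant), detail = detail)
}

#' Fixed-heterozygote flags versus planted paralogs
#'
#' Compares the fixed-heterozygosity flags of a run with the planted
#' duplicated-segment truth: the divergent site of every collapsed paralog
#' pair should be flagged, and nothing else.
#'
#' @param run A [run_rad_pipeline()] result.
#' @return List: `n_planted`, `n_flagged`, `n_true_flags`,
#'   `n_false_flags`, `all_planted_found` (logical).
#' @export
evaluate_fixed_het <- function(run) {
  truth <- run$truth
  flags <- run$fixed_het %>% filter(.data$fixed_het)
  # paralog clusters: their unitag occurs at both source and copy loci
  par_loci <- truth$loci %>% filter(.data$is_paralog)
  par_tags <- vapply(seq_len(nrow(par_loci)), function(i)
    substr(locus_template(truth, par_loci$locus_id[i],
                          run$reference_sample, 1), 1,
           run$config$read_lengths[1]), character(1))
  par_contigs <- run$mini_ref$contig_id[run$mini_ref$unitag %in% par_tags]
  flag_contig <- sub(":.*$", "", flags$locus)
  n_true <- sum(flag_contig %in% par_contigs)
  list(n_planted = nrow(truth$duplicated_segments),
       n_flagged = nrow(flags), n_true_flags = n_true,
       n_false_flags = nrow(flags) - n_true,
       all_planted_found = length(unique(flag_contig[
         flag_contig %in% par_contigs])) == nrow(truth$duplicated_segments))
}
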