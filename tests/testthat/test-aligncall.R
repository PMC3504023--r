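mini_contigs <- function() {
  set.seed(61)
  tibble::tibble(contig_id = c("cA", "cB"),
                 seq = c(rand_dna(300), rand_dna(300)))
}

test_that("rad mapping: exact, mismatch-capped, unique-best placement", {
  ctg <- mini_contigs()
  read_ok <- substr(ctg$seq[1], 101, 180)
  read_bad <- read_ok
  for (p in c(30, 40, 50, 60, 70)) substr(read_bad, p, p) <- "N"
  reads <- tibble::tibble(read_id = c("r1", "r2"), sample = "s1",
                          seq = c(read_ok, read_bad))
  aln <- map_reads(reads, ctg, mode = "rad")
  expect_equal(nrow(aln), 1)
  expect_equal(aln$contig_id, "cA")
  expect_equal(aln$start, 100L)
  expect_equal(aln$n_mismatch, 0L)
  expect_equal(attr(aln, "n_unmapped"), 1L)
})

test_that("rad mapping: reads matching two contigs equally are ambiguous", {
  set.seed(62)
  shared <- rand_dna(120)
  ctg <- tibble::tibble(contig_id = c("c1", "c2"),
                        seq = c(paste0(shared, rand_dna(100)),
                                paste0(rand_dna(100), shared)))
  reads <- tibble::tibble(read_id = "r1", sample = "s1",
                          seq = substr(shared, 11, 90))
  aln <- map_reads(reads, ctg, mode = "rad")
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "n_ambiguous"), 1L)
})

test_that("rad mapping places reverse-strand reads in forward coordinates", {
  ctg <- mini_contigs()
  reads <- tibble::tibble(read_id = "r1", sample = "s1",
                          seq = rc_chr(substr(ctg$seq[2], 51, 130)))
  aln <- map_reads(reads, ctg, mode = "rad")
  expect_equal(aln$contig_id, "cB")
  expect_equal(aln$start, 50L)
  expect_equal(aln$strand, "-")
})

test_that("pileup depths are per-position, additive, manifest-consistent", {
  ctg <- mini_contigs()[1, ]
  r <- substr(ctg$seq, 1, 80)
  reads <- tibble::tibble(read_id = c("r1", "r2"), sample = "s1",
                          seq = c(r, substr(ctg$seq, 41, 120)))
  aln <- map_reads(reads, ctg, mode = "rad")
  pile <- pileup(aln, ctg)
  depth <- tapply(pile$n, pile$pos, sum)
  expect_true(all(depth[as.character(0:39)] == 1))
  expect_true(all(depth[as.character(40:79)] == 2))
  expect_true(all(depth[as.character(80:119)] == 1))
})

test_that("pileup counts equal a truth-based recount on simulated data", {
  run <- small_run()
  lib <- small_library()
  # recount: every mapped read contributes its full length in observations
  ctg <- run$mini_ref
  reads2 <- demultiplex(lib$pairs, small_config()$barcodes)$pairs
  aln <- map_reads(
    tibble::tibble(read_id = reads2$read_id, sample = reads2$sample,
                   seq = reads2$seq2), ctg, mode = "rad")
  pile <- pileup(aln, ctg)
  expect_equal(sum(pile$n), nrow(aln) * 80L)
})

test_that("threshold caller follows the 7.5% rule with boundaries", {
  expect_equal(call_genotype_threshold(20, 1), "hom_ref")
  expect_equal(call_genotype_threshold(10, 10), "het")
  expect_equal(call_genotype_threshold(0, 20), "hom_alt")
  expect_equal(call_genotype_threshold(2, 1), "missing")  # below min_depth
  # f exactly t calls het (alternate evidence at the threshold counts)
  expect_equal(call_genotype_threshold(37, 3), "het")      # f = 0.075
  expect_equal(call_genotype_threshold(3, 37), "het")      # f = 0.925
  expect_equal(
    call_genotype_threshold(c(20, 10, 0), c(1, 10, 20)),
    c("hom_ref", "het", "hom_alt"))
})

test_that("site quality is a capped binomial tail", {
  expect_equal(site_quality(10, 0), 0)
  expect_equal(site_quality(5, 5, error_rate = 0.01), 60)
  q <- site_quality(rep(20, 10), 0:9, error_rate = 0.01)
  expect_true(all(diff(q) >= 0))
  # independent check at moderate support
  expect_equal(site_quality(18, 2, 0.01),
               min(60, -10 * log10(pbinom(1, 20, 0.01, lower.tail = FALSE))))
})

test_that("shotgun gates: q20 for substitutions, q50 for indels", {
  set.seed(63)
  ctg <- tibble::tibble(contig_id = "c1", seq = rand_dna(400))
  base_at <- function(p) substr(ctg$seq, p + 1, p + 1)
  other <- setdiff(c("A", "C", "G", "T"), base_at(200))[1]
  # hand-built pileups: a variable site below q20 vs a clear one
  weak <- tibble::tibble(
    contig_id = "c1", pos = 200L, sample = "sA",
    base = c(base_at(200), other), n = c(4L, 1L))
  expect_equal(call_genotype_threshold(4, 1), "het")   # variable, but...
  expect_lt(site_quality(4, 1), 20)                    # ...below the gate
  strong <- dplyr::mutate(weak, n = c(12L, 8L))
  expect_equal(nrow(call_sites_shotgun(weak, ctg)), 0)
  out <- call_sites_shotgun(strong, ctg)
  expect_equal(nrow(out), 1)
  expect_false(out$is_indel)
  # indel with quality between 20 and 50 is suppressed
  ind_weak <- tibble::tibble(
    contig_id = "c1", pos = 100L, sample = "sA",
    base = c(base_at(100), "I:ACG"), n = c(60L, 4L))
  expect_equal(nrow(call_sites_shotgun(ind_weak, ctg)), 0)
  q_weak <- site_quality(60, 4)
  expect_true(q_weak >= 20 && q_weak < 50)
  ind_strong <- tibble::tibble(
    contig_id = "c1", pos = 100L, sample = "sA",
    base = c(base_at(100), "I:ACG"), n = c(20L, 10L))
  out2 <- call_sites_shotgun(ind_strong, ctg)
  expect_equal(nrow(out2), 1)
  expect_true(out2$is_indel)
  expect_equal(out2$alt, "I:ACG")
  expect_equal(out2$genotype, "het")
})

test_that("error-free shotgun calls equal the carried planted variants", {
  cfg <- sim_config(genome_length = 4e4, n_sites = 5, n_duplicated_loci = 0,
                    n_individuals = 2, insert_range = c(120, 300),
                    snp_density = 0.002, n_indels = 2,
                    n_private_per_individual = 0, seed = 11)
  # ~11x per haplotype: a heterozygous indel (a quarter of reads) needs
  # this much depth for its support to clear the q50 gate
  sr <- run_shotgun_pipeline(cfg, n_reads = 2500)
  truth <- sr$truth
  carried <- dplyr::summarise(
    dplyr::group_by(truth$genotypes, variant_id),
    carried = sum(h1 + h2) > 0)
  v <- merge(truth$variants, carried, by = "variant_id")
  n_carried_snps <- sum(v$carried & v$type == "snp")
  n_carried_indels <- sum(v$carried & v$type != "snp")
  called_snps <- dplyr::distinct(
    dplyr::filter(sr$calls, !is_indel), contig_id, pos)
  called_indels <- dplyr::distinct(
    dplyr::filter(sr$calls, is_indel), contig_id, pos, alt)
  # every carried variant is recovered; nothing spurious appears
  expect_equal(nrow(called_snps), n_carried_snps)
  expect_equal(nrow(called_indels), n_carried_indels)
})

test_that("variant summary tabulates het sites and substitution classes", {
  calls <- tibble::tibble(
    contig_id = rep(c("c1", "c1", "c2"), each = 2),
    pos = rep(c(10L, 80L, 5L), each = 2),
    ref = rep(c("A", "C", "A"), each = 2),
    alt = rep(c("G", "T", "T"), each = 2),
    quality = 60, tri_allelic = FALSE, is_indel = FALSE,
    sample = rep(c("s1", "s2"), 3),
    ref_count = 10L, alt_count = 10L,
    genotype = c("het", "hom_ref", "hom_alt", "hom_alt", "het", "het"))
  vs <- summarize_variants(calls)
  expect_equal(vs$totals$n_sites, 3)
  expect_equal(vs$totals$n_het, 2)
  expect_equal(vs$totals$n_hom, 1)
  cls <- tidy(vs)
  expect_equal(cls$n[cls$pair == "A-G"], 1)
  expect_equal(cls$n[cls$pair == "A-T"], 1)
  expect_equal(cls$n[cls$pair == "C-T"], 1)
})

test_that("calls are invariant to read input order", {
  lib <- small_library()
  cfg <- small_config()
  dm <- demultiplex(lib$pairs, cfg$barcodes)
  run <- small_run()
  reads <- tibble::tibble(read_id = dm$pairs$read_id,
                          sample = dm$pairs$sample, seq = dm$pairs$seq2)
  set.seed(1)
  shuffled <- reads[sample(nrow(reads)), ]
  a1 <- map_reads(reads, run$mini_ref, mode = "rad")
  a2 <- map_reads(shuffled, run$mini_ref, mode = "rad")
  c1 <- call_sites_rad(pileup(a1, run$mini_ref), run$mini_ref)
  c2 <- call_sites_rad(pileup(a2, run$mini_ref), run$mini_ref)
  expect_identical(c1, c2)
})
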