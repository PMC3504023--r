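mk_sites <- function(pos, contig = "c1", quality = 60, tri = FALSE,
                     indel = FALSE) {
  tibble::tibble(contig_id = contig, pos = as.integer(pos),
                 ref = "A", alt = "G", quality = quality,
                 tri_allelic = tri, is_indel = indel)
}

ctg300 <- tibble::tibble(contig_id = "c1", seq = strrep("A", 300))

test_that("assayability rules: window, edge, tri-allelic, one per contig", {
  # two SNPs 30 bp apart both fail the 60 bp window
  both <- filter_assayable(mk_sites(c(100, 130)), ctg300)
  expect_equal(nrow(both), 0)
  # close to the contig start fails the edge rule
  expect_equal(nrow(filter_assayable(mk_sites(20), ctg300)), 0)
  # a lone mid-contig SNP passes
  lone <- filter_assayable(mk_sites(150), ctg300)
  expect_equal(nrow(lone), 1)
  expect_equal(lone$design_score, 1)
  # tri-allelic and indel sites never pass
  expect_equal(nrow(filter_assayable(mk_sites(150, tri = TRUE), ctg300)), 0)
  expect_equal(nrow(filter_assayable(mk_sites(150, indel = TRUE),
                                     ctg300)), 0)
  # an indel neighbour knocks out an otherwise clean SNP
  s <- dplyr::bind_rows(mk_sites(150), mk_sites(190, indel = TRUE))
  expect_equal(nrow(filter_assayable(s, ctg300)), 0)
})

test_that("one SNP per contig: highest quality wins, ties to leftmost", {
  s <- dplyr::bind_rows(mk_sites(80, quality = 40), mk_sites(200,
                                                             quality = 55))
  out <- filter_assayable(s, ctg300)
  expect_equal(out$pos, 200L)
  s2 <- dplyr::bind_rows(mk_sites(80), mk_sites(200))
  expect_equal(filter_assayable(s2, ctg300)$pos, 80L)
})

test_that("filter_assayable is idempotent", {
  set.seed(71)
  s <- mk_sites(sort(sample(40:260, 6)))
  once <- filter_assayable(s, ctg300)
  twice <- filter_assayable(once, ctg300)
  expect_equal(once, twice)
})

test_that("multiplex grouping fills consecutive plexes of at most the cap", {
  m <- tibble::tibble(id = 1:85)
  px <- group_multiplexes(m, cap = 40)
  expect_equal(as.integer(table(px$plex)), c(40L, 40L, 5L))
  expect_equal(nrow(group_multiplexes(m[0, ], cap = 40)), 0)
  expect_equal(max(group_multiplexes(m[1:40, ], cap = 40)$plex), 1)
  expect_equal(sum(table(px$plex)), nrow(m))
})

test_that("fixed-heterozygote flagging requires all-het, min 2 genotyped", {
  g <- tibble::tibble(
    locus = rep(c("L1", "L2", "L3"), each = 7),
    sample = rep(paste0("s", 1:7), 3),
    gt = c(rep("het", 7),
           c(rep("het", 6), "hom_ref"),
           c("het", rep("missing", 6))))
  fl <- flag_fixed_heterozygotes(g)
  expect_true(fl$fixed_het[fl$locus == "L1"])
  expect_false(fl$fixed_het[fl$locus == "L2"])
  expect_false(fl$fixed_het[fl$locus == "L3"])  # only one genotyped
})

test_that("splitting fixed-het loci doubles them and conserves the rest", {
  loci <- tibble::tibble(locus = as.character(1:161))
  out <- split_duplicated_loci(loci, as.character(1:33))
  expect_equal(nrow(out), 194)
  expect_equal(sum(is.na(out$co_allele)), 128)
  expect_equal(nrow(split_duplicated_loci(loci, character(0))), 161)
  expect_equal(nrow(split_duplicated_loci(loci[1:5, ],
                                          as.character(1:5))), 10)
  expect_error(split_duplicated_loci(loci, "not-a-locus"), "subset")
})

test_that("private alleles: single het against a homozygous background", {
  g <- tibble::tibble(
    locus = rep(c("L1", "L2", "L3"), each = 3),
    sample = rep(c("i1", "i2", "i3"), 3),
    gt = c("hom_ref", "het", "hom_ref",     # private to i2
           "het", "het", "hom_ref",         # two hets: private to nobody
           "hom_alt", "hom_alt", "het"))    # private to i3 (major = alt)
  pa <- private_alleles(g)
  expect_equal(pa$n_private[pa$sample == "i1"], 0L)
  expect_equal(pa$n_private[pa$sample == "i2"], 1L)
  expect_equal(pa$n_private[pa$sample == "i3"], 1L)
})

test_that("simulated private variants are found at the configured count", {
  run <- small_run()
  truth <- run$truth
  # evaluate directly against planted genotypes (caller-independent)
  gt <- dplyr::mutate(
    truth$genotypes,
    locus = variant_id,
    gt = c("hom_ref", "het", "hom_alt")[h1 + h2 + 1])
  pa <- private_alleles(gt[, c("locus", "sample", "gt")])
  k <- small_config()$n_private_per_individual
  # HWE variants can create extra private-pattern loci; planted ones are a
  # floor, and restricted to the planted subset the count is exact
  expect_true(all(pa$n_private >= k))
  priv_ids <- truth$variants$variant_id[!is.na(truth$variants$private_to)]
  pa2 <- private_alleles(gt[gt$locus %in% priv_ids,
                            c("locus", "sample", "gt")])
  expect_true(all(pa2$n_private == k))
})
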