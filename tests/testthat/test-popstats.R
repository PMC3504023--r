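test_that("consensus follows the two-replicate support rule", {
  expect_equal(consensus_genotype(c("A", "A", "A"), c("B", "B", "A")),
               list(a1 = "A", a2 = "B", status = "het"))
  expect_equal(consensus_genotype(c("A", "A", "A"), c("A", "A", "B")),
               list(a1 = "A", a2 = "A", status = "hom"))
  expect_equal(consensus_genotype(c("A", "B"), c("A", "B"))$status,
               "no_consensus")
  expect_equal(consensus_genotype(c(NA, NA), c(NA, NA))$status, "missing")
  # order-invariance in the replicate list
  expect_equal(consensus_genotype(c("A", "A", "B"), c("B", "A", "B")),
               consensus_genotype(c("B", "A", "A"), c("B", "B", "A")))
})

test_that("error-rate arithmetic matches the worked example", {
  # 2 het loci x 4 replicates, all positive, one dropout observation
  reps <- tibble::tibble(
    sample = "s1",
    locus = rep(c("L1", "L2"), each = 4),
    obs_a1 = c("A", "A", "A", "A", "C", "C", "C", "C"),
    obs_a2 = c("B", "B", "B", "A", "D", "D", "D", "D"))
  er <- error_rates(reps)
  expect_equal(er$ado_rate, 1 / 8)
  expect_equal(er$fa_rate, 0)
  expect_equal(er$positive_pcr_rate, 1)
  # no heterozygous consensus: ADO undefined
  hom <- tibble::tibble(sample = "s1", locus = rep("L1", 3),
                        obs_a1 = "A", obs_a2 = "A")
  expect_true(is.na(error_rates(hom)$ado_rate))
})

test_that("a spurious allele counts as a false-allele event", {
  reps <- tibble::tibble(
    sample = "s1", locus = rep("L1", 4),
    obs_a1 = c("A", "A", "A", "A"),
    obs_a2 = c("A", "A", "A", "X"))
  er <- error_rates(reps)
  expect_equal(er$fa_rate, 1 / 4)
})

test_that("ADO/FA estimators recover simulated rates within 0.02", {
  cfg <- sim_config(ado_rate = 0.2, fa_rate = 0.01, fail_rate = 0,
                    n_replicates = 4, seed = 1234,
                    insert_range = c(120, 300))
  g <- dplyr::bind_rows(
    tibble::tibble(sample = rep(paste0("s", 1:5), each = 100),
                   locus = rep(paste0("H", 1:100), 5),
                   a1 = "A", a2 = "B"),
    tibble::tibble(sample = rep(paste0("s", 1:5), each = 200),
                   locus = rep(paste0("M", 1:200), 5),
                   a1 = "A", a2 = "A"))
  reps <- simulate_replicates(g, cfg)
  er <- error_rates(reps)
  expect_lt(abs(er$ado_rate - 0.2), 0.02)
  expect_lt(abs(er$fa_rate - 0.01), 0.02)
  expect_equal(er$positive_pcr_rate, 1)
})

test_that("observed heterozygosity is the per-individual het fraction", {
  g <- tibble::tibble(
    sample = rep("s1", 194), locus = paste0("L", 1:194),
    a1 = "A", a2 = c(rep("B", 10), rep("A", 184)))
  ho <- observed_heterozygosity(g)
  expect_equal(ho$per_individual$ho, 10 / 194)
  all_hom <- tibble::tibble(sample = "s1", locus = c("L1", "L2"),
                            a1 = "A", a2 = "A")
  expect_equal(observed_heterozygosity(all_hom)$per_individual$ho, 0)
  none <- tibble::tibble(sample = "s1", locus = "L1",
                         a1 = NA_character_, a2 = NA_character_)
  expect_true(is.na(observed_heterozygosity(none)$per_individual$ho))
})

test_that("simulated per-individual Ho tracks the configured target", {
  cfg <- sim_config(target_het = 0.057, seed = 99, insert_range = c(120, 300))
  truth <- simulate_reference(cfg)
  n_loci <- 1000
  p <- (1 - sqrt(1 - 2 * 0.057)) / 2
  set.seed(7)
  h1 <- rbinom(n_loci, 1, p)
  h2 <- rbinom(n_loci, 1, p)
  g <- tibble::tibble(sample = "s1", locus = paste0("L", 1:n_loci),
                      a1 = ifelse(h1 == 1, "B", "A"),
                      a2 = ifelse(h2 == 1, "B", "A"))
  ho <- observed_heterozygosity(g)$mean_ho
  se <- sqrt(0.057 * (1 - 0.057) / n_loci)
  expect_lt(abs(ho - 0.057), 3 * se)
  # and the generator's own genotypes match the target too
  tg <- truth$genotypes[is.na(truth$variants$private_to[
    match(truth$genotypes$variant_id, truth$variants$variant_id)]), ]
  if (nrow(tg) > 200) {
    emp <- mean(tg$h1 + tg$h2 == 1)
    expect_lt(abs(emp - 0.057), 3 * sqrt(0.057 * 0.943 / nrow(tg)))
  }
})

test_that("MNA and polymorphic fraction count observed alleles", {
  g <- tibble::tibble(
    sample = rep(c("i1", "i2"), 3),
    locus = rep(c("L1", "L2", "L3"), each = 2),
    a1 = c("A", "A", "A", "B", "A", "B"),
    a2 = c("A", "A", "A", "B", "C", "C"))
  expect_equal(mna(g), mean(c(1, 2, 3)))
  expect_equal(polymorphic_fraction(g)$fraction, 2 / 3)
  mono <- tibble::tibble(sample = "i1", locus = c("L1", "L2"),
                         a1 = "A", a2 = "A")
  expect_equal(mna(mono), 1)
  expect_equal(polymorphic_fraction(mono)$percent, 0)
  # 33 of 194 polymorphic reports 17%
  g194 <- tibble::tibble(
    sample = "i1", locus = paste0("L", 1:194),
    a1 = "A", a2 = c(rep("B", 33), rep("A", 161)))
  expect_equal(polymorphic_fraction(g194)$percent, 17)
})

test_that("ts/tv classification reproduces the published class counts", {
  rad <- tstv(tibble::tibble(
    pair = c("A-G", "C-T", "A-C", "G-T", "A-T", "C-G"),
    n = c(380, 404, 132, 115, 61, 178)))
  expect_equal(rad$n_transitions, 784)
  expect_equal(rad$n_transversions, 486)
  expect_equal(rad$ratio, 1.61)
  shot <- tstv(tibble::tibble(
    pair = c("A-G", "C-T", "A-C", "G-T", "A-T", "C-G"),
    n = c(2020, 2010, 680, 628, 463, 886)))
  expect_equal(shot$n_transitions, 4030)
  expect_equal(shot$n_transversions, 2657)
  expect_equal(shot$ratio, 1.52)
  # orientation invariance and conservation
  flip <- tstv(c("G-A", "A-G", "T-C"))
  expect_equal(flip$n_transitions, 3)
  expect_true(is.na(tstv("A-G")$ratio))
  expect_error(tstv("A-Z"), "Invalid")
})

test_that("snp_density divides and reports 2 significant figures", {
  expect_equal(snp_density(100, 1e6), 1e-4)
  expect_equal(snp_density(0, 1e6), 0)
  expect_equal(snp_density(14724, 18172839), signif(14724 / 18172839, 2))
  expect_error(snp_density(10, 0), "total_contig_bases")
})

test_that("genotyping_qc bundles a coherent report", {
  cfg <- sim_config(ado_rate = 0.1, fa_rate = 0.01, fail_rate = 0.1,
                    n_replicates = 4, seed = 77, insert_range = c(120, 300))
  g <- tibble::tibble(sample = rep(paste0("s", 1:3), each = 50),
                      locus = rep(paste0("L", 1:50), 3),
                      a1 = "A",
                      a2 = rep(c("B", rep("A", 9)), 15))
  qc <- genotyping_qc(simulate_replicates(g, cfg))
  expect_s3_class(qc, "genotyping_qc")
  expect_equal(nrow(qc$per_sample), 3)
  gl <- glance(qc)
  expect_true(gl$positive_pcr_rate > 0.8 && gl$positive_pcr_rate < 1)
  expect_true(gl$mean_ho >= 0 && gl$mean_ho <= 0.2)
  p <- autoplot(qc)
  expect_s3_class(p, "ggplot")
})
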