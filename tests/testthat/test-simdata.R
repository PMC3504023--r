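test_that("sim_config validates geometry and rates", {
  expect_s3_class(small_config(), "sim_config")
  expect_error(sim_config(insert_range = c(100, 300)), "read pairs")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(error_rate = -0.1), "rates")
  expect_error(sim_config(barcodes = c(s1 = "AAAAAA", s2 = "AAAAAA")),
               "distinct")
})

test_that("simulated reference is deterministic and digest-exact", {
  cfg <- small_config()
  t1 <- simulate_reference(cfg)
  t2 <- simulate_reference(cfg)
  expect_identical(t1, t2)
  # planted-feature recall: an in-silico digest finds exactly what was planted
  expect_identical(find_sites(t1$reference, cfg$enzyme_site), t1$sites)
})

test_that("gc_content = 0 puts no G/C outside planted features", {
  cfg <- sim_config(genome_length = 2e4, gc_content = 0, n_sites = 3,
                    n_duplicated_loci = 0, n_individuals = 2,
                    n_private_per_individual = 0,
                    ssr_spec = tibble::tibble(motif_length = integer(0),
                                              repeat_count = integer(0),
                                              copies = integer(0)),
                    insert_range = c(120, 300), seed = 3)
  truth <- simulate_reference(cfg)
  ch <- strsplit(truth$reference, "")[[1]]
  planted <- unlist(lapply(truth$sites, function(p) (p + 1):(p + 6)))
  expect_true(all(ch[-planted] %in% c("A", "T")))
})

test_that("background GC content lands within 3 binomial SD of target", {
  cfg <- sim_config(genome_length = 1e6, gc_content = 0.41, n_sites = 10,
                    n_duplicated_loci = 0, n_private_per_individual = 1,
                    insert_range = c(120, 300), seed = 1)
  truth <- simulate_reference(cfg)
  ch <- strsplit(truth$reference, "")[[1]]
  planted <- unlist(lapply(truth$sites, function(p) (p + 1):(p + 6)))
  bg <- ch[-planted]
  phat <- mean(bg %in% c("G", "C"))
  se <- sqrt(0.41 * 0.59 / length(bg))
  expect_lt(abs(phat - 0.41), 3 * se)
})

test_that("feature packing beyond the genome is a sizing error", {
  expect_error(
    simulate_reference(sim_config(genome_length = 1e4, n_sites = 50,
                                  insert_range = c(120, 300))),
    "genome_length")
})

test_that("rad library geometry, counts and manifest are exact", {
  cfg <- small_config()
  truth <- small_truth()
  lib <- small_library()
  n_clusters <- nrow(truth$loci)
  expect_equal(nrow(lib$pairs), n_clusters * cfg$n_individuals * cfg$coverage)
  expect_identical(sort(lib$pairs$read_id), sort(lib$manifest$read_id))
  expect_equal(anyDuplicated(lib$manifest$read_id), 0L)
  # forward read = barcode + 40 cut-anchored bases
  expect_true(all(nchar(lib$pairs$seq1) == 6 + cfg$read_lengths[1]))
  expect_true(all(nchar(lib$pairs$seq2) == cfg$read_lengths[2]))
  # error-free: every forward read (sans barcode) is an exact substring of
  # the reference or its reverse complement, adjacent to a site
  idx <- sample(nrow(lib$pairs), 50)
  for (i in idx) {
    fwd <- substr(lib$pairs$seq1[i], 7, 46)
    hit <- grepl(fwd, truth$reference, fixed = TRUE) ||
      grepl(fwd, revcomp(truth$reference), fixed = TRUE)
    expect_true(hit)
  }
})

test_that("rad library reproduces a planted het at ~50% alt fraction", {
  truth <- small_truth()
  cfg <- small_config()
  lib <- small_library()
  # among het planted genotypes, use the one whose variant is best covered
  # by that individual's reverse reads
  gt <- dplyr::filter(truth$genotypes, h1 + h2 == 1)
  expect_gt(nrow(gt), 0)
  r2 <- cfg$read_lengths[2]
  best <- NULL
  for (j in seq_len(nrow(gt))) {
    g_j <- gt[j, ]
    v_j <- truth$variants[truth$variants$variant_id == g_j$variant_id, ]
    man_j <- dplyr::filter(lib$manifest, sample == g_j$sample,
                           locus_id == v_j$locus_id)
    cov_j <- sum(man_j$insert - r2 <= v_j$offset & man_j$insert > v_j$offset)
    if (is.null(best) || cov_j > best$cov) {
      best <- list(g = g_j, v = v_j, man = man_j, cov = cov_j)
    }
  }
  g <- best$g
  v <- best$v
  man <- best$man
  pairs <- lib$pairs[match(man$read_id, lib$pairs$read_id), ]
  covers <- man$insert - r2 <= v$offset & man$insert > v$offset
  expect_gte(sum(covers), 10)
  # base at the variant offset within the oriented reverse read
  tpl_off <- v$offset - (man$insert - r2)
  base <- substring(revcomp(pairs$seq2), tpl_off + 1, tpl_off + 1)
  alt_frac <- mean(base[covers] == v$alt_locus)
  n <- sum(covers)
  expect_lt(abs(alt_frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("same seed gives byte-identical library and shotgun streams", {
  cfg <- small_config(seed = 12)
  tr <- simulate_reference(cfg)
  expect_identical(simulate_rad_library(tr, cfg),
                   simulate_rad_library(tr, cfg))
  expect_identical(simulate_shotgun(tr, cfg, n_reads = 200),
                   simulate_shotgun(tr, cfg, n_reads = 200))
})

test_that("shotgun read lengths have the configured mean and bounds", {
  truth <- small_truth()
  cfg <- small_config()
  sg <- simulate_shotgun(truth, cfg, n_reads = 5000,
                         samples = names(cfg$barcodes)[1])
  expect_equal(nrow(simulate_shotgun(truth, cfg, n_reads = 0)$reads), 0)
  lens <- nchar(sg$reads$seq)
  expect_true(all(lens >= 100 & lens <= 800))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - cfg$shotgun_mean_len), 3 * se)
  # error-free reads are exact substrings of one haplotype (either strand)
  hp <- truth$haplotypes[[sg$reads$sample[1]]]
  for (i in sample(nrow(sg$reads), 25)) {
    s <- sg$reads$seq[i]
    expect_true(grepl(s, hp[[1]]$seq, fixed = TRUE) ||
                  grepl(s, hp[[2]]$seq, fixed = TRUE) ||
                  grepl(revcomp(s), hp[[1]]$seq, fixed = TRUE) ||
                  grepl(revcomp(s), hp[[2]]$seq, fixed = TRUE))
  }
})

test_that("replicate simulation honours its event model", {
  cfg0 <- sim_config(ado_rate = 0, fa_rate = 0, fail_rate = 0, seed = 5,
                     insert_range = c(120, 300))
  g <- tibble::tibble(sample = rep(c("s1", "s2"), each = 4),
                      locus = rep(paste0("L", 1:4), 2),
                      a1 = c("A", "A", "C", "G", "A", "A", "C", "G"),
                      a2 = c("B", "A", "C", "T", "B", "A", "C", "T"))
  reps <- simulate_replicates(g, cfg0)
  expect_equal(nrow(reps), nrow(g) * cfg0$n_replicates)
  merged <- merge(reps, g, by = c("sample", "locus"))
  expect_true(all(merged$obs_a1 == merged$a1 & merged$obs_a2 == merged$a2))

  cfg1 <- sim_config(ado_rate = 1, fa_rate = 0, fail_rate = 0, seed = 5,
                     insert_range = c(120, 300))
  reps1 <- simulate_replicates(g[g$a1 != g$a2, ], cfg1)
  expect_true(all(reps1$obs_a1 == reps1$obs_a2))
})

test_that("empirical dropout fraction tracks ado_rate", {
  cfg <- sim_config(ado_rate = 0.2, fa_rate = 0, fail_rate = 0,
                    n_replicates = 4, seed = 21, insert_range = c(120, 300))
  g <- tibble::tibble(sample = "s1", locus = paste0("L", 1:500),
                      a1 = "A", a2 = "B")
  reps <- simulate_replicates(g, cfg)
  drop_frac <- mean(reps$event %in% c("ado", "ado+fa"))
  n <- nrow(reps)
  expect_lt(abs(drop_frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})
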