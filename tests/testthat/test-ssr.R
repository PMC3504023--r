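test_that("find_ssrs detects runs, canonicalises motifs, honours minima", {
  out <- find_ssrs("ACACACAC", min_repeats = c(`1` = 6, `2` = 3, `3` = 3,
                                               `4` = 3))
  expect_equal(nrow(out), 1)
  expect_equal(out$motif, "AC")
  expect_equal(out$repeats, 4L)
  expect_equal(out$end - out$start, 8L)
  # canonical form collapses rotations and the reverse complement
  tg <- find_ssrs("TGTGTGTG")
  expect_equal(tg$canonical, "AC")
  expect_equal(canonical_motif(c("TG", "GT", "CA", "AC")),
               rep("AC", 4))
  # below the class minimum: nothing
  expect_equal(nrow(find_ssrs("AAAAA",
                              min_repeats = c(`1` = 6, `2` = 3, `3` = 3,
                                              `4` = 3))), 0)
  expect_equal(nrow(find_ssrs("GGAAAAAAGG")), 1)  # (A)6 at mono-min 6
})

test_that("periodic motifs report at the smallest period only", {
  out <- find_ssrs("GGATATATATGG")
  expect_equal(nrow(out), 1)
  expect_equal(out$motif_length, 2L)
  expect_equal(out$motif, "AT")
})

test_that("a single interruption terminates a perfect run", {
  # (AC)3 then interruption then (AC)3: two runs, not one
  out <- find_ssrs("TTACACACGACACACTT",
                   min_repeats = c(`1` = 6, `2` = 3, `3` = 3, `4` = 3))
  expect_equal(nrow(out), 2)
  expect_true(all(out$repeats == 3))
})

test_that("find_ssrs equals the brute-force enumerator on random 2 kb", {
  set.seed(81)
  mins <- c(`1` = 6, `2` = 3, `3` = 3, `4` = 3)
  for (i in 1:30) {
    s <- rand_dna(2000, gc = runif(1, 0.3, 0.7))
    got <- as.data.frame(
      find_ssrs(s, mins)[, c("start", "end", "motif", "motif_length",
                             "repeats")])
    want <- naive_find_ssrs(s, mins)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("raising a class minimum never increases that class's count", {
  set.seed(82)
  seqs <- replicate(20, rand_dna(1500))
  for (cls in c("1", "2", "3", "4")) {
    counts <- vapply(3:6, function(m) {
      mins <- c(`1` = 3, `2` = 3, `3` = 3, `4` = 3)
      mins[cls] <- m
      sum(vapply(seqs, function(s) {
        out <- find_ssrs(s, mins)
        sum(out$motif_length == as.integer(cls))
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("planted SSRs are recovered with exact span and motif", {
  truth <- small_truth()
  found <- find_ssrs(truth$reference,
                     min_repeats = c(`1` = 4, `2` = 3, `3` = 3, `4` = 3))
  for (i in seq_len(nrow(truth$ssr_loci))) {
    p <- truth$ssr_loci[i, ]
    hit <- found[found$start == p$start & found$end == p$end, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$motif, p$motif)
  }
})

test_that("compound classification joins runs within the gap", {
  ssrs <- tibble::tibble(
    contig_id = "c1",
    start = c(10L, 23L, 100L), end = c(20L, 31L, 112L),
    motif = c("AC", "AG", "AT"), motif_length = 2L,
    repeats = c(5L, 4L, 6L))
  out <- classify_compound(ssrs, max_gap = 10)
  expect_equal(out$compound, c(TRUE, TRUE, FALSE))
  far <- classify_compound(dplyr::mutate(ssrs[c(1, 3), ]), max_gap = 10)
  expect_false(any(far$compound))
  expect_false(classify_compound(ssrs[1, ])$compound)
})

test_that("PAL needs clean flanks and 3 repeats; primers need 4", {
  ctg <- tibble::tibble(
    contig_id = c("long", "short", "enn"),
    seq = c(strrep("A", 200), strrep("A", 50),
            paste0(strrep("N", 40), strrep("A", 160))))
  ssrs <- tibble::tibble(
    contig_id = c("long", "long", "short", "enn"),
    start = c(100L, 60L, 10L, 100L), end = c(110L, 66L, 20L, 110L),
    motif = "AC", motif_length = 2L, repeats = c(5L, 3L, 5L, 5L))
  out <- classify_pal(ssrs, ctg)
  expect_equal(out$pal, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$primer_candidate, c(TRUE, FALSE, FALSE, TRUE))
  # N inside the flank kills PAL
  ssr_n <- tibble::tibble(contig_id = "enn", start = 50L, end = 60L,
                          motif = "AC", motif_length = 2L, repeats = 5L)
  expect_false(classify_pal(ssr_n, ctg)$pal)
})

test_that("SSR summary reproduces per-class totals and PAL percentage", {
  counts <- c(18188L, 7241L, 1471L, 326L)
  ssrs <- tibble::tibble(
    motif_length = rep(1:4, counts),
    pal = FALSE)
  # 1,706 PAL among the di+tri+tetra loci
  di_plus <- which(ssrs$motif_length >= 2)
  ssrs$pal[di_plus[seq_len(1706)]] <- TRUE
  sm <- summarize_ssrs(ssrs)
  expect_equal(sm$totals$n_total, 27226L)
  expect_equal(sm$totals$n_di_plus, 9038L)
  expect_equal(sm$totals$pal_pct, 18.8)
  expect_equal(tidy(sm)$n, counts)
  # empty input: zeros
  sm0 <- summarize_ssrs(ssrs[0, ])
  expect_equal(sm0$totals$n_total, 0L)
  expect_true(is.na(sm0$totals$pal_pct))
})
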