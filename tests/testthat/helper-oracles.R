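## Independent brute-force oracles used across the suite. These deliberately
## avoid the implementation's code paths (and Biostrings) so they can serve
## as cross-checks.

BASES4 <- c("A", "C", "G", "T")

rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## naive O(n * m) site scan, both strands, forward coordinates, overlaps kept
naive_find_sites <- function(sequence, recognition) {
  n <- nchar(sequence)
  m <- nchar(recognition)
  pats <- unique(c(recognition, rc_chr(recognition)))
  hits <- integer(0)
  if (n >= m) {
    for (i in 0:(n - m)) {
      w <- substr(sequence, i + 1, i + m)
      if (w %in% pats) hits <- c(hits, i)
    }
  }
  hits
}

## exhaustive N50: smallest k such that the k largest contigs hold >= half
## the assembly; returns the k-th largest length
naive_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  for (k in seq_along(s)) {
    if (sum(s[seq_len(k)]) >= half) return(s[k])
  }
}

## minimal period of a motif, independently
naive_min_period <- function(m) {
  p <- nchar(m)
  for (d in seq_len(p)) {
    if (p %% d == 0) {
      unit <- substr(m, 1, d)
      if (paste(rep(unit, p / d), collapse = "") == m) return(d)
    }
  }
  p
}

## O(n^2) tandem-run enumerator: every maximal perfect run of an aperiodic
## 1-4 bp motif meeting its class minimum, then the same longest-wins
## overlap resolution
naive_find_ssrs <- function(sequence, min_repeats) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  cand <- list()
  ci <- 0
  for (p in 1:4) {
    for (s0 in 0:(n - 2 * p)) {
      # maximal: the run must not extend backwards
      if (s0 > 0 && s0 + p <= n && ch[s0] == ch[s0 + p]) next
      motif <- substr(sequence, s0 + 1, s0 + p)
      if (grepl("[^ACGT]", motif)) next
      if (naive_min_period(motif) != p) next
      r <- 1
      while (s0 + (r + 1) * p <= n &&
             substr(sequence, s0 + r * p + 1, s0 + (r + 1) * p) == motif) {
        r <- r + 1
      }
      if (r < min_repeats[[as.character(p)]]) next
      ci <- ci + 1
      cand[[ci]] <- data.frame(start = s0, end = s0 + r * p,
                               motif = motif, motif_length = p,
                               repeats = r, stringsAsFactors = FALSE)
    }
  }
  if (ci == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_length = integer(0),
                      repeats = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start,
                     cand$motif_length), ]
  kept <- rep(FALSE, nrow(cand))
  occ_s <- integer(0)
  occ_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < occ_e & cand$end[i] > occ_s)) {
      kept[i] <- TRUE
      occ_s <- c(occ_s, cand$start[i])
      occ_e <- c(occ_e, cand$end[i])
    }
  }
  out <- cand[kept, ]
  out[order(out$start), ]
}

## random ACGT string at uniform base frequencies
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES4, n, replace = TRUE, prob = p), collapse = "")
}
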