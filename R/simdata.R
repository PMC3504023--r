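#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every simulator
#' in the package. The defaults encode the library design this pipeline
#' models: EagI (`CGGCCG`) restriction sites, barcoded asymmetric paired-end
#' RAD reads of 40 x 80 bp with sheared inserts gel-selected to 300-800 bp,
#' long shotgun reads averaging 348 bp, a low-heterozygosity SNP spectrum
#' (target per-individual observed heterozygosity 0.057) and replicate PCR
#' genotyping with allelic-dropout / false-allele / amplification-failure
#' events.
#'
#' @param genome_length Reference length in bases.
#' @param gc_content GC fraction of the background sequence, in `[0, 1]`.
#' @param enzyme_site Restriction recognition sequence (uppercase ACGT).
#' @param n_individuals Number of diploid individuals.
#' @param n_sites Number of restriction sites planted at spaced positions
#'   (paralog copies add further sites on top of this).
#' @param coverage RAD read pairs simulated per locus per individual.
#' @param snp_density Per-base probability of planting a SNP inside the
#'   sequenced span of a RAD locus.
#' @param target_het Expected per-individual heterozygosity at planted
#'   variant sites.
#' @param n_private_per_individual Number of planted variants private to each
#'   individual (minor allele carried, heterozygously, by that individual
#'   only).
#' @param n_duplicated_loci Number of RAD loci duplicated elsewhere in the
#'   genome with exactly one fixed difference (the paralog model).
#' @param ssr_spec Tibble/data frame with columns `motif_length` (1-4),
#'   `repeat_count` and `copies` describing planted perfect microsatellites.
#' @param n_indels Number of small (1-3 bp) indel variants planted outside
#'   RAD locus spans; used by the shotgun path only.
#' @param insert_range Length-2 integer vector, min/max sheared insert size.
#'   Must satisfy `insert_range[1] >= sum(read_lengths)`.
#' @param read_lengths Length-2 integer vector: forward (cut-anchored) and
#'   reverse (sheared-end) read lengths.
#' @param shotgun_mean_len,shotgun_sd_len Mean and sd of the truncated-normal
#'   shotgun read-length distribution (truncation at 100-800 bp).
#' @param error_rate Per-base substitution error probability for simulated
#'   reads.
#' @param barcodes Named character vector mapping sample id to an in-line
#'   forward-read barcode. `NULL` generates `n_individuals` distinct 6-mers.
#' @param ado_rate,fa_rate,fail_rate Replicate-genotyping event
#'   probabilities: allelic dropout (per heterozygous amplification), false
#'   allele (per homozygous observation) and amplification failure (per
#'   replicate).
#' @param n_replicates Replicate PCRs per sample x locus.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(genome_length = 2e5,
                       gc_content = 0.41,
                       enzyme_site = "CGGCCG",
                       n_individuals = 8,
                       n_sites = 60,
                       coverage = 30,
                       snp_density = 0.001,
                       target_het = 0.057,
                       n_private_per_individual = 2,
                       n_duplicated_loci = 3,
                       ssr_spec = default_ssr_spec(),
                       n_indels = 0,
                       insert_range = c(300L, 800L),
                       read_lengths = c(40L, 80L),
                       shotgun_mean_len = 348,
                       shotgun_sd_len = 60,
                       error_rate = 0,
                       barcodes = NULL,
                       ado_rate = 0.05,
                       fa_rate = 0.002,
                       fail_rate = 0.1,
                       n_replicates = 4,
                       seed = 1L) {
  insert_range <- as.integer(insert_range)
  read_lengths <- as.integer(read_lengths)
  if (gc_content < 0 || gc_content > 1) {
    abort("`gc_content` must lie in [0, 1].")
  }
  if (!grepl("^[ACGT]+$", enzyme_site)) {
    abort("`enzyme_site` must be a non-empty uppercase ACGT string.")
  }
  if (length(insert_range) != 2 || insert_range[1] > insert_range[2]) {
    abort("`insert_range` must be c(min, max) with min <= max.")
  }
  if (insert_range[1] < sum(read_lengths)) {
    abort("insert_range[1] must be >= sum(read_lengths): read pairs must not overlap.")
  }
  rates <- c(error_rate = error_rate, ado_rate = ado_rate, fa_rate = fa_rate,
             fail_rate = fail_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("All rates must lie in [0, 1].")
  }
  if (target_het < 0 || target_het > 0.5) {
    abort("`target_het` must lie in [0, 0.5] (heterozygosity under HWE).")
  }
  if (is.null(barcodes)) {
    barcodes <- default_barcodes(n_individuals)
  }
  if (anyDuplicated(barcodes) > 0) {
    abort("Barcodes must be pairwise distinct.")
  }
  if (length(unique(nchar(barcodes))) > 1) {
    abort("Barcodes must be equal length.")
  }
  if (is.null(names(barcodes))) {
    names(barcodes) <- paste0("s", seq_along(barcodes))
  }
  cfg <- list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    enzyme_site = enzyme_site, n_individuals = as.integer(n_individuals),
    n_sites = as.integer(n_sites), coverage = as.integer(coverage),
    snp_density = snp_density, target_het = target_het,
    n_private_per_individual = as.integer(n_private_per_individual),
    n_duplicated_loci = as.integer(n_duplicated_loci),
    ssr_spec = as_tibble(ssr_spec), n_indels = as.integer(n_indels),
    insert_range = insert_range, read_lengths = read_lengths,
    shotgun_mean_len = shotgun_mean_len, shotgun_sd_len = shotgun_sd_len,
    error_rate = error_rate, barcodes = barcodes,
    ado_rate = ado_rate, fa_rate = fa_rate, fail_rate = fail_rate,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome %s bp, GC %.2f, %d individuals, %d sites, seed %d\n",
              format(x$genome_length, big.mark = ","), x$gc_content,
              x$n_individuals, x$n_sites, x$seed))
  cat(sprintf("  enzyme %s, reads %dx%d bp, inserts %d-%d bp, coverage %dx\n",
              x$enzyme_site, x$read_lengths[1], x$read_lengths[2],
              x$insert_range[1], x$insert_range[2], x$coverage))
  invisible(x)
}

#' Packaged end-to-end evaluation scenario
#'
#' The configuration used by the package's own truth-linked evaluation: 8
#' barcoded individuals, 120 planted restriction sites (240 single-direction
#' RAD loci once paralog copies are excluded), 3 duplicated loci, 30
#' error-free read pairs per locus per individual, SNPs at a density of
#' 0.001 per base of locus span with target heterozygosity 0.057, and 2
#' private variants per individual. Inserts are drawn from 120-300 bp so
#' that 30 pairs tile each ~260 bp locus span densely enough for exact local
#' assembly; the resulting contig lengths match the 250-290 bp contigs this
#' pipeline is designed around.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
study_config <- function(seed = 1) {
  sim_config(genome_length = 1e5, gc_content = 0.41, n_individuals = 8,
             n_sites = 120, n_duplicated_loci = 3, coverage = 30,
             snp_density = 0.001, target_het = 0.057,
             n_private_per_individual = 2, insert_range = c(120L, 300L),
             error_rate = 0, seed = seed)
}

#' Default planted microsatellite specification
#'
#' One small panel per repeat class: mono-, di-, tri- and tetra-nucleotide
#' perfect repeats, at repeat counts comfortably above the detection minima.
#'
#' @return Tibble with columns `motif_length`, `repeat_count`, `copies`.
#' @export
default_ssr_spec <- function() {
  tibble(
    motif_length = c(1L, 2L, 3L, 4L),
    repeat_count = c(8L, 6L, 5L, 4L),
    copies = c(3L, 4L, 3L, 2L)
  )
}

default_barcodes <- function(n) {
  base4 <- function(i, width = 6) {
    d <- integer(width)
    for (j in seq_len(width)) {
      d[j] <- i %% 4
      i <- i %/% 4
    }
    paste(BASES[rev(d) + 1], collapse = "")
  }
  # indices spaced so single substitutions rarely convert one barcode into
  # another
  bc <- vapply((seq_len(n) - 1) * 37 + 5, base4, character(1))
  setNames(bc, paste0("s", seq_len(n)))
}

## genome layout bookkeeping: where sites, paralog copies, SSRs and indels go
sim_layout <- function(config) {
  imax <- config$insert_range[2]
  gap <- 100L
  slot_w <- 2L * imax + gap
  n_slots <- config$n_sites + config$n_duplicated_loci
  margin <- 100L
  site_region_end <- margin + n_slots * slot_w
  ssr <- config$ssr_spec
  ssr_pad <- 80L
  ssr_lens <- if (nrow(ssr) > 0) {
    rep(ssr$motif_length * ssr$repeat_count, times = ssr$copies)
  } else integer(0)
  ssr_region_len <- sum(ssr_lens + ssr_pad)
  indel_region_len <- config$n_indels * 50L
  needed <- site_region_end + ssr_region_len + indel_region_len + margin
  if (needed > config$genome_length) {
    abort(sprintf(
      "Planted features need %d bp but genome_length is only %d bp; increase genome_length or reduce features.",
      needed, config$genome_length))
  }
  cuts <- margin + (seq_len(n_slots) - 1L) * slot_w + imax  # 0-based cut coords
  list(
    cuts = as.integer(cuts), slot_gap = gap,
    site_cuts = as.integer(cuts[seq_len(config$n_sites)]),
    copy_cuts = as.integer(tail(cuts, config$n_duplicated_loci)),
    ssr_region_start = as.integer(site_region_end),
    ssr_lens = as.integer(ssr_lens), ssr_pad = ssr_pad,
    indel_region_start = as.integer(site_region_end + ssr_region_len)
  )
}

## motif helpers for SSR planting ------------------------------------------

minimal_period <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 &&
        motif == strrep(substr(motif, 1, d), p / d)) {
      return(d)
    }
  }
  p
}

random_ssr_motif <- function(len, recognition) {
  repeat {
    m <- paste(sample(BASES, len, replace = TRUE), collapse = "")
    if (minimal_period(m) != len) next
    run <- strrep(m, ceiling(nchar(recognition) / len) + 2)
    if (grepl(recognition, run, fixed = TRUE)) next
    if (grepl(revcomp(recognition), run, fixed = TRUE)) next
    return(m)
  }
}

#' Simulate a reference genome with known ground truth
#'
#' Generates an i.i.d. background sequence at the configured GC content, then
#' plants, at spaced positions: restriction sites (verbatim), perfect
#' microsatellites (with boundaries fixed so the planted run is maximal),
#' duplicated RAD loci carrying exactly one fixed difference (the mechanism
#' that creates apparent fixed heterozygosity in collapsed assemblies), SNP
#' variants inside the sequenced span of each locus (allele frequencies set
#' so expected per-individual heterozygosity equals `target_het`, plus the
#' configured number of private variants per individual) and, optionally,
#' small indels outside the RAD spans. Accidental occurrences of the
#' recognition sequence in the background are removed, so an in-silico
#' digest recovers exactly the planted sites. Per-individual haplotype pairs
#' are materialised. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `truth_set`: a list with elements `config`,
#'   `reference`, `sites`, `loci`, `variants`, `genotypes`, `ssr_loci`,
#'   `duplicated_segments` and `haplotypes` (per individual, two strings).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 10 * config$insert_range[2]) {
    abort("genome_length must be at least 10 x insert_range max.")
  }
  set.seed(config$seed)
  lay <- sim_layout(config)
  rec <- config$enzyme_site
  r1 <- config$read_lengths[1]
  r2 <- config$read_lengths[2]
  imin <- config$insert_range[1]
  imax <- config$insert_range[2]
  span_lo <- imin - r2   # locus truth span, offsets from the cut
  span_hi <- imax
  # planted polymorphism window: inside the span, away from its thinly
  # covered edges so calls reach min_depth at realistic coverages
  snp_lo <- span_lo + as.integer(ceiling(0.75 * r2))
  snp_hi <- span_lo + as.integer(floor(0.70 * (span_hi - span_lo)))

  genome <- seq_chars(random_seq(config$genome_length, config$gc_content))

  ## -- plant SSRs ----------------------------------------------------------
  ssr_rows <- list()
  pos <- lay$ssr_region_start + lay$ssr_pad %/% 2
  spec <- config$ssr_spec
  k_ssr <- 0
  protected <- rep(FALSE, config$genome_length)  # 1-based mask
  if (nrow(spec) > 0) {
    for (i in seq_len(nrow(spec))) {
      for (cp in seq_len(spec$copies[i])) {
        p <- spec$motif_length[i]
        reps <- spec$repeat_count[i]
        motif <- random_ssr_motif(p, rec)
        run <- seq_chars(strrep(motif, reps))
        s0 <- pos  # 0-based start
        genome[(s0 + 1):(s0 + length(run))] <- run
        # enforce maximality of the planted run
        last_m <- substr(motif, p, p)
        first_m <- substr(motif, 1, 1)
        if (genome[s0] == last_m) {
          genome[s0] <- sample(setdiff(BASES, c(last_m, first_m)), 1)
        }
        after <- s0 + length(run) + 1
        if (genome[after] == first_m) {
          genome[after] <- sample(setdiff(BASES, c(first_m, last_m)), 1)
        }
        protected[s0:(s0 + length(run) + 1)] <- TRUE
        k_ssr <- k_ssr + 1
        ssr_rows[[k_ssr]] <- tibble(
          start = s0, end = s0 + length(run), motif = motif,
          motif_length = p, repeats = reps)
        pos <- pos + length(run) + lay$ssr_pad
      }
    }
  }
  ssr_loci <- if (k_ssr > 0) bind_rows(ssr_rows) else
    tibble(start = integer(0), end = integer(0), motif = character(0),
           motif_length = integer(0), repeats = integer(0))

  ## -- plant restriction sites --------------------------------------------
  rec_ch <- seq_chars(rec)
  for (cut in lay$site_cuts) {
    p <- cut - 1L  # site starts one base before the cut (C*GGCCG)
    genome[(p + 1):(p + length(rec_ch))] <- rec_ch
    protected[(p + 1):(p + length(rec_ch))] <- TRUE
  }

  ## -- scrub accidental recognition occurrences ---------------------------
  planted_sites <- lay$site_cuts - 1L
  for (iter in 1:20) {
    hits <- find_sites(paste(genome, collapse = ""), rec)
    extra <- setdiff(hits, planted_sites)
    if (length(extra) == 0) break
    for (h in extra) {
      cand <- (h + 1):(h + nchar(rec))
      cand <- cand[!protected[cand]]
      if (length(cand) == 0) next  # overlaps planted features only; hopeless
      j <- cand[ceiling(length(cand) / 2)]
      genome[j] <- sample(setdiff(BASES, genome[j]), 1)
    }
    if (iter == 20) abort("Failed to scrub accidental restriction sites.")
  }

  ## -- duplicated (paralog) loci ------------------------------------------
  dup_rows <- list()
  if (config$n_duplicated_loci > 0) {
    if (config$n_sites < config$n_duplicated_loci) {
      abort("n_duplicated_loci cannot exceed n_sites.")
    }
    src_cuts <- sort(sample(lay$site_cuts, config$n_duplicated_loci))
    for (g in seq_len(config$n_duplicated_loci)) {
      c_src <- src_cuts[g]
      c_cpy <- lay$copy_cuts[g]
      seg <- genome[c_src:(c_src + imax)]  # site base + down template
      genome[c_cpy:(c_cpy + imax)] <- seg
      protected[c_cpy:(c_cpy + nchar(rec))] <- TRUE
      d <- sample(seq(snp_lo, snp_hi - 1L), 1)
      div_pos <- c_cpy + d  # 0-based ref position in the copy
      old <- genome[div_pos + 1]
      repeat {
        newb <- sample(setdiff(BASES, old), 1)
        genome[div_pos + 1] <- newb
        win <- paste(genome[max(1, div_pos - 6):(div_pos + 7)], collapse = "")
        if (!grepl(rec, win, fixed = TRUE) &&
            !grepl(revcomp(rec), win, fixed = TRUE)) break
      }
      dup_rows[[g]] <- tibble(
        group = g, source_cut = c_src, copy_cut = c_cpy,
        source_start = c_src, source_end = c_src + imax,
        copy_start = c_cpy, copy_end = c_cpy + imax,
        offset = d, diverged_pos = div_pos,
        source_base = old, copy_base = newb)
    }
  }
  duplicated_segments <- if (length(dup_rows) > 0) bind_rows(dup_rows) else
    tibble(group = integer(0), source_cut = integer(0), copy_cut = integer(0),
           source_start = integer(0), source_end = integer(0),
           copy_start = integer(0), copy_end = integer(0), offset = integer(0),
           diverged_pos = integer(0), source_base = character(0),
           copy_base = character(0))

  ## final scrub pass (copies and divergence could not create new sites, but
  ## verify planted-site exactness before committing the reference)
  ref <- paste(genome, collapse = "")
  all_cuts <- lay$cuts
  sites <- sort(as.integer(all_cuts - 1L))
  hits <- find_sites(ref, rec)
  if (!identical(hits, sites)) {
    abort("Internal error: digest of the simulated reference does not equal the planted site set.")
  }

  ## -- locus table ---------------------------------------------------------
  paralog_cuts <- c(duplicated_segments$source_cut,
                    duplicated_segments$copy_cut)
  paralog_grp <- c(duplicated_segments$group, duplicated_segments$group)
  loci <- bind_rows(
    tibble(site = sites, cut = as.integer(all_cuts), direction = "down"),
    tibble(site = sites, cut = as.integer(all_cuts), direction = "up")
  ) %>%
    arrange(.data$cut, .data$direction) %>%
    mutate(
      locus_id = sprintf("L%04d_%s", match(.data$cut, sort(unique(.data$cut))),
                         ifelse(.data$direction == "down", "d", "u")),
      span_lo = span_lo, span_hi = span_hi,
      is_paralog = .data$direction == "down" & .data$cut %in% paralog_cuts,
      paralog_group = ifelse(.data$is_paralog,
                             paralog_grp[match(.data$cut, paralog_cuts)], NA)
    ) %>%
    select("locus_id", "site", "cut", "direction", "span_lo", "span_hi",
           "is_paralog", "paralog_group")

  ## -- variants ------------------------------------------------------------
  # SNPs land inside the well-covered part of each non-paralog locus span
  callable <- loci %>% filter(!.data$is_paralog)
  var_rows <- list()
  vi <- 0
  if (snp_hi > snp_lo && nrow(callable) > 0 && config$snp_density > 0) {
    for (i in seq_len(nrow(callable))) {
      nsnp <- rbinom(1, snp_hi - snp_lo,
                     min(1, config$snp_density *
                           (span_hi - span_lo) / (snp_hi - snp_lo)))
      if (nsnp == 0) next
      offs <- sort(sample(seq(snp_lo, snp_hi - 1), min(nsnp, 3)))
      offs <- offs[c(TRUE, diff(offs) >= 5)]
      for (o in offs) {
        vi <- vi + 1
        var_rows[[vi]] <- tibble(
          locus_id = callable$locus_id[i], offset = o, type = "snp",
          private_to = NA_character_)
      }
    }
  }
  # private variants: one per chosen locus, individual fixed
  samples <- names(config$barcodes)
  if (config$n_private_per_individual > 0 && nrow(callable) > 0) {
    used <- if (vi > 0) bind_rows(var_rows)$locus_id else character(0)
    free <- setdiff(callable$locus_id, used)
    need <- config$n_private_per_individual * length(samples)
    if (length(free) < need) {
      abort("Not enough variant-free loci for the requested private alleles; increase n_sites.")
    }
    chosen <- sample(free, need)
    idx <- 0
    for (s in samples) {
      for (j in seq_len(config$n_private_per_individual)) {
        idx <- idx + 1
        vi <- vi + 1
        var_rows[[vi]] <- tibble(
          locus_id = chosen[idx],
          offset = sample(seq(snp_lo, snp_hi - 1), 1),
          type = "snp", private_to = s)
      }
    }
  }
  variants <- if (vi > 0) bind_rows(var_rows) else
    tibble(locus_id = character(0), offset = integer(0), type = character(0),
           private_to = character(0))

  # map locus offsets to reference coordinates and draw alleles
  if (nrow(variants) > 0) {
    variants <- variants %>%
      left_join(loci, by = "locus_id") %>%
      mutate(pos = ifelse(.data$direction == "down",
                          .data$cut + .data$offset,
                          .data$cut - 1L - .data$offset)) %>%
      mutate(ref = substring(.env$ref, .data$pos + 1, .data$pos + 1)) %>%
      mutate(ref_locus = ifelse(.data$direction == "down", .data$ref,
                                revcomp(.data$ref))) %>%
      mutate(alt_locus = other_base(.data$ref_locus)) %>%
      mutate(alt = ifelse(.data$direction == "down", .data$alt_locus,
                          revcomp(.data$alt_locus))) %>%
      mutate(variant_id = sprintf("V%04d", row_number())) %>%
      select("variant_id", "locus_id", "offset", "pos", "ref", "alt",
             "ref_locus", "alt_locus", "type", "private_to")
  } else {
    variants <- tibble(variant_id = character(0), locus_id = character(0),
                       offset = integer(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       ref_locus = character(0), alt_locus = character(0),
                       type = character(0), private_to = character(0))
  }

  ## indels (shotgun path); planted in the dedicated region outside RAD spans
  if (config$n_indels > 0) {
    istart <- lay$indel_region_start + 20L
    for (j in seq_len(config$n_indels)) {
      p <- istart + (j - 1L) * 50L
      is_ins <- runif(1) < 0.5
      len <- sample(1:3, 1)
      if (is_ins) {
        refb <- substring(ref, p + 1, p + 1)
        altb <- paste0(refb, random_seq(len, 0.5))
      } else {
        refb <- substring(ref, p + 1, p + 1 + len)
        altb <- substring(ref, p + 1, p + 1)
      }
      variants <- bind_rows(variants, tibble(
        variant_id = sprintf("I%04d", j), locus_id = NA_character_,
        offset = NA_integer_, pos = p, ref = refb, alt = altb,
        ref_locus = refb, alt_locus = altb,
        type = ifelse(is_ins, "ins", "del"), private_to = NA_character_))
    }
  }

  ## -- genotypes ------------------------------------------------------------
  h <- config$target_het
  p_alt <- (1 - sqrt(1 - 2 * h)) / 2
  geno <- tidyr::expand_grid(variant_id = variants$variant_id,
                             sample = samples)
  if (nrow(geno) > 0) {
    priv <- variants$private_to[match(geno$variant_id, variants$variant_id)]
    h1 <- rbinom(nrow(geno), 1, p_alt)
    h2 <- rbinom(nrow(geno), 1, p_alt)
    is_priv <- !is.na(priv)
    h1[is_priv] <- ifelse(priv[is_priv] == geno$sample[is_priv], 1L, 0L)
    h2[is_priv] <- 0L
    # indels are planted to exercise the indel caller: guarantee each one is
    # carried, heterozygously, by one individual
    vtype <- variants$type[match(geno$variant_id, variants$variant_id)]
    is_ind <- vtype != "snp"
    if (any(is_ind)) {
      h1[is_ind] <- 0L
      h2[is_ind] <- 0L
      for (vid in unique(geno$variant_id[is_ind])) {
        rows <- which(geno$variant_id == vid)
        h1[sample(rows, 1)] <- 1L
      }
    }
    geno$h1 <- as.integer(h1)
    geno$h2 <- as.integer(h2)
  } else {
    geno <- tibble(variant_id = character(0), sample = character(0),
                   h1 = integer(0), h2 = integer(0))
  }

  ## -- haplotypes -----------------------------------------------------------
  haplotypes <- build_haplotypes(ref, variants, geno, samples)

  structure(list(
    config = config, reference = ref, sites = sites, loci = loci,
    variants = variants, genotypes = geno, ssr_loci = ssr_loci,
    duplicated_segments = duplicated_segments, haplotypes = haplotypes
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>\n")
  cat(sprintf("  reference %s bp; %d sites; %d loci (%d paralogous); %d variants; %d SSRs\n",
              format(nchar(x$reference), big.mark = ","), length(x$sites),
              nrow(x$loci), sum(x$loci$is_paralog), nrow(x$variants),
              nrow(x$ssr_loci)))
  invisible(x)
}

## apply a sample's variant alleles to the reference, one string per
## haplotype; returns list(sample -> list(seq = c(h1, h2), shift tables))
build_haplotypes <- function(ref, variants, genotypes, samples) {
  out <- vector("list", length(samples))
  names(out) <- samples
  for (s in samples) {
    g <- genotypes %>% filter(.data$sample == s)
    pair <- vector("list", 2)
    for (hap in 1:2) {
      carried <- g$variant_id[if (hap == 1) g$h1 == 1 else g$h2 == 1]
      v <- variants %>% filter(.data$variant_id %in% carried) %>%
        arrange(.data$pos)
      seqs <- ref
      shift <- tibble(pos = integer(0), delta = integer(0))
      if (nrow(v) > 0) {
        subs <- v %>% filter(.data$type == "snp")
        seqs <- apply_substitutions(seqs, subs$pos + 1L, subs$alt)
        ind <- v %>% filter(.data$type != "snp") %>% arrange(desc(.data$pos))
        for (i in seq_len(nrow(ind))) {
          p <- ind$pos[i]
          seqs <- paste0(substr(seqs, 1, p), ind$alt[i],
                         substr(seqs, p + 1 + nchar(ind$ref[i]),
                                nchar(seqs)))
        }
        ind2 <- v %>% filter(.data$type != "snp") %>% arrange(.data$pos) %>%
          mutate(delta = nchar(.data$alt) - nchar(.data$ref))
        shift <- ind2 %>% select("pos", "delta")
      }
      pair[[hap]] <- list(seq = seqs, shift = shift)
    }
    out[[s]] <- pair
  }
  out
}

## map a 0-based reference coordinate onto a haplotype coordinate
ref_to_hap <- function(pos, shift) {
  if (nrow(shift) == 0) return(pos)
  vapply(pos, function(x) x + sum(shift$delta[shift$pos < x]), numeric(1))
}

## forward-oriented template of a locus on one haplotype: the insert_max
## bases read away from the cut (reverse-complemented for "up" loci)
locus_template <- function(truth, locus_id, sample, hap = 1) {
  l <- truth$loci[truth$loci$locus_id == locus_id, ]
  stopifnot(nrow(l) == 1)
  hp <- truth$haplotypes[[sample]][[hap]]
  cut <- ref_to_hap(l$cut, hp$shift)
  imax <- l$span_hi
  if (l$direction == "down") {
    substr(hp$seq, cut + 1, cut + imax)
  } else {
    revcomp(substr(hp$seq, cut - imax + 1, cut))
  }
}

## the planted locus truth sequence (the reverse-read-covered span) on one
## haplotype of one individual
locus_truth_seq <- function(truth, locus_id, sample, hap = 1) {
  l <- truth$loci[truth$loci$locus_id == locus_id, ]
  tpl <- locus_template(truth, locus_id, sample, hap)
  substr(tpl, l$span_lo + 1, l$span_hi)
}

## inject substitution errors into reads; returns list(seq, qual)
inject_errors <- function(seqs, error_rate, q_hi = "?", q_lo = "+") {
  lens <- nchar(seqs)
  quals <- strrep(q_hi, lens)
  if (error_rate > 0 && length(seqs) > 0) {
    n_err <- rbinom(length(seqs), lens, error_rate)
    idx <- which(n_err > 0)
    for (i in idx) {
      pos <- sample.int(lens[i], n_err[i])
      ch <- seq_chars(seqs[i])
      ch[pos] <- other_base(ch[pos])
      seqs[i] <- paste(ch, collapse = "")
      qc <- seq_chars(quals[i])
      qc[pos] <- q_lo
      quals[i] <- paste(qc, collapse = "")
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate a barcoded paired-end RAD library
#'
#' Every read pair originates at a restriction cut on one haplotype of one
#' individual. The forward read is the sample barcode followed by the
#' cut-anchored tag; the reverse read is the `read_lengths[2]` bases at the
#' randomly sheared end of an insert drawn uniformly from `insert_range`,
#' reported in sequencing orientation (reverse complement of the template).
#' Substitution errors are injected at `error_rate`; base qualities are
#' constant Phred 30, lowered to Phred 10 at error-injected positions. In
#' fixed-count mode each locus x individual receives exactly `coverage`
#' pairs.
#'
#' @param truth A [simulate_reference()] result.
#' @param config The same [sim_config()]; `config$coverage` pairs are drawn
#'   per locus per individual.
#' @return List with `pairs` (tibble: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `manifest` (tibble mapping `read_id` to `sample`,
#'   `locus_id`, `haplotype`, `insert`).
#' @export
simulate_rad_library <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  if (any(truth$variants$type != "snp")) {
    abort("RAD simulation requires a SNP-only truth set (indels are modelled on the shotgun path).")
  }
  if (length(truth$sites) == 0 || nrow(truth$loci) == 0) {
    warn("Truth set has no restriction sites; returning empty read streams.")
    empty <- tibble(read_id = character(0), seq1 = character(0),
                    qual1 = character(0), seq2 = character(0),
                    qual2 = character(0))
    return(list(pairs = empty,
                manifest = tibble(read_id = character(0),
                                  sample = character(0),
                                  locus_id = character(0),
                                  haplotype = integer(0),
                                  insert = integer(0))))
  }
  set.seed(config$seed + 104729L)
  r1 <- config$read_lengths[1]
  r2 <- config$read_lengths[2]
  imin <- config$insert_range[1]
  imax <- config$insert_range[2]
  samples <- names(config$barcodes)
  cov <- config$coverage
  loci <- truth$loci

  blocks <- vector("list", nrow(loci) * length(samples))
  b <- 0
  serial <- 0
  for (s in samples) {
    bc <- config$barcodes[[s]]
    for (i in seq_len(nrow(loci))) {
      hap <- sample(1:2, cov, replace = TRUE)
      ins <- sample(seq(imin, imax), cov, replace = TRUE)
      tpl1 <- locus_template(truth, loci$locus_id[i], s, 1)
      tpl2 <- locus_template(truth, loci$locus_id[i], s, 2)
      tpl <- ifelse(hap == 1, tpl1, tpl2)
      fwd <- substr(tpl, 1, r1)
      rev_tpl <- substring(tpl, ins - r2 + 1, ins)
      b <- b + 1
      blocks[[b]] <- tibble(
        read_id = sprintf("r%07d", serial + seq_len(cov)),
        sample = s, locus_id = loci$locus_id[i],
        haplotype = as.integer(hap), insert = as.integer(ins),
        fwd = fwd, rev_tpl = rev_tpl, barcode = bc)
      serial <- serial + cov
    }
  }
  reads <- bind_rows(blocks)
  e1 <- inject_errors(reads$fwd, config$error_rate)
  e2 <- inject_errors(revcomp(reads$rev_tpl), config$error_rate)
  bq <- strrep("?", nchar(reads$barcode[1]))
  pairs <- tibble(
    read_id = reads$read_id,
    seq1 = paste0(reads$barcode, e1$seq),
    qual1 = paste0(bq, e1$qual),
    seq2 = e2$seq, qual2 = e2$qual)
  manifest <- reads %>%
    select("read_id", "sample", "locus_id", "haplotype", "insert")
  list(pairs = pairs, manifest = manifest)
}

#' Simulate long single-end shotgun reads
#'
#' Read lengths follow a normal distribution with the configured mean and sd,
#' truncated to 100-800 bp (a positive distribution with a long right tail,
#' as long-read shotgun data shows). Start positions are uniform; the
#' haplotype and strand of each read are chosen uniformly.
#'
#' @param truth A [simulate_reference()] result.
#' @param config A [sim_config()].
#' @param n_reads Number of reads per sample.
#' @param samples Samples to draw reads for (default: all configured).
#' @return List with `reads` (tibble: `read_id`, `sample`, `seq`, `qual`) and
#'   `manifest` (tibble adding `haplotype`, `start`, `length`, `strand`).
#' @export
simulate_shotgun <- function(truth, config = truth$config, n_reads = 1000,
                             samples = names(config$barcodes)) {
  stopifnot(inherits(truth, "truth_set"), n_reads >= 0)
  set.seed(config$seed + 224737L)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    if (n_reads == 0) {
      out[[si]] <- tibble(read_id = character(0), sample = character(0),
                          haplotype = integer(0), start = integer(0),
                          length = integer(0), strand = character(0),
                          seq = character(0))
      next
    }
    lens <- round(rnorm(n_reads, config$shotgun_mean_len,
                        config$shotgun_sd_len))
    lens <- pmin(pmax(lens, 100L), 800L)
    hap <- sample(1:2, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    hlen <- vapply(1:2, function(h) nchar(truth$haplotypes[[s]][[h]]$seq),
                   numeric(1))
    start <- floor(runif(n_reads) * (hlen[hap] - lens))
    seqs <- character(n_reads)
    for (h in 1:2) {
      idx <- which(hap == h)
      if (length(idx) == 0) next
      seqs[idx] <- substring(truth$haplotypes[[s]][[h]]$seq,
                             start[idx] + 1, start[idx] + lens[idx])
    }
    neg <- strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    out[[si]] <- tibble(
      read_id = sprintf("g%s_%06d", s, seq_len(n_reads)), sample = s,
      haplotype = as.integer(hap), start = as.integer(start),
      length = as.integer(lens), strand = strand, seq = seqs)
  }
  all <- bind_rows(out)
  err <- inject_errors(all$seq, config$error_rate)
  reads <- tibble(read_id = all$read_id, sample = all$sample,
                  seq = err$seq, qual = err$qual)
  manifest <- all %>% select("read_id", "sample", "haplotype", "start",
                             "length", "strand")
  list(reads = reads, manifest = manifest)
}

#' Simulate replicate PCR genotypes with injected errors
#'
#' For each sample x locus genotype, `n_replicates` independent replicate
#' observations are generated. Each replicate fails (missing) with
#' `fail_rate`; if the true genotype is heterozygous, one allele (chosen at
#' random) drops out with `ado_rate`, yielding a homozygous observation; any
#' observation that is homozygous after the dropout step gains a spurious
#' allele with `fa_rate`. Events are logged per replicate.
#'
#' @param genotypes Tibble with columns `sample`, `locus`, `a1`, `a2` (true
#'   diploid genotypes; allele labels are arbitrary strings).
#' @param config A [sim_config()]; uses `ado_rate`, `fa_rate`, `fail_rate`,
#'   `n_replicates` and `seed`.
#' @return Tibble with columns `sample`, `locus`, `replicate`, `obs_a1`,
#'   `obs_a2` (NA when failed) and `event` (`"ok"`, `"fail"`, `"ado"`,
#'   `"fa"`, or `"ado+fa"`).
#' @export
simulate_replicates <- function(genotypes, config) {
  stopifnot(all(c("sample", "locus", "a1", "a2") %in% names(genotypes)))
  set.seed(config$seed + 350377L)
  reps <- tidyr::expand_grid(genotypes,
                             replicate = seq_len(config$n_replicates))
  n <- nrow(reps)
  if (n == 0) {
    return(tibble(sample = character(0), locus = character(0),
                  replicate = integer(0), obs_a1 = character(0),
                  obs_a2 = character(0), event = character(0)))
  }
  fail <- runif(n) < config$fail_rate
  is_het <- reps$a1 != reps$a2
  ado <- !fail & is_het & runif(n) < config$ado_rate
  keep_first <- runif(n) < 0.5
  obs1 <- reps$a1
  obs2 <- reps$a2
  obs1[ado & !keep_first] <- reps$a2[ado & !keep_first]
  obs2[ado & keep_first] <- reps$a1[ado & keep_first]
  hom_now <- obs1 == obs2
  fa <- !fail & hom_now & runif(n) < config$fa_rate
  if (any(fa)) {
    locus_alleles <- genotypes %>%
      tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") %>%
      distinct(.data$locus, .data$allele)
    for (i in which(fa)) {
      cand <- setdiff(
        locus_alleles$allele[locus_alleles$locus == reps$locus[i]], obs1[i])
      spur <- if (length(cand) > 0) sample(cand, 1) else
        sample(setdiff(BASES, obs1[i]), 1)
      obs2[i] <- spur
    }
  }
  obs1[fail] <- NA_character_
  obs2[fail] <- NA_character_
  event <- rep("ok", n)
  event[ado] <- "ado"
  event[fa] <- ifelse(event[fa] == "ado", "ado+fa", "fa")
  event[fail] <- "fail"
  tibble(sample = reps$sample, locus = reps$locus,
         replicate = as.integer(reps$replicate),
         obs_a1 = obs1, obs_a2 = obs2, event = event)
}
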