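#' Read and write FASTA contig sets
#'
#' Thin wrappers around Biostrings keeping sequences in the tibble shape the
#' rest of the package uses.
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param path File path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns
#'   a contig tibble.
#' @export
write_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$contig_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig_id = names(x), seq = unname(as.character(x)))
}

#' Read and write FASTQ read sets
#'
#' Four-line FASTQ records with Phred+33 qualities. Paired reads use two
#' files (`_1` / `_2` suffixes inserted before the extension).
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path File path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a read
#'   tibble.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign internal coercion notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}

pair_paths <- function(path) {
  stem <- sub("(\\.[^.]+)$", "", path)
  ext <- sub(sprintf("^%s", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
  c(paste0(stem, "_1", ext), paste0(stem, "_2", ext))
}

#' @rdname write_fastq
#' @param pairs Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
write_fastq_pairs <- function(pairs, path) {
  p <- pair_paths(path)
  write_fastq(tibble(read_id = pairs$read_id, seq = pairs$seq1,
                     qual = pairs$qual1), p[1])
  write_fastq(tibble(read_id = pairs$read_id, seq = pairs$seq2,
                     qual = pairs$qual2), p[2])
  invisible(p)
}

#' @rdname write_fastq
#' @export
read_fastq_pairs <- function(path) {
  p <- pair_paths(path)
  r1 <- read_fastq(p[1])
  r2 <- read_fastq(p[2])
  stopifnot(identical(r1$read_id, r2$read_id))
  tibble(read_id = r1$read_id, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual)
}

gt_code_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                    missing = "./.")

#' Write calls as VCF 4.2
#'
#' One record per variant site with per-sample `GT` and `DP` fields and
#' `##contig` header lines. Internal 0-based positions become 1-based VCF
#' positions. Indel records (`alt` of the form `I:<seq>` / `D:<len>`) are
#' emitted with the standard left-anchored REF/ALT encoding.
#'
#' @param calls Long calls tibble ([call_sites_rad()] and friends).
#' @param contigs Contig tibble the calls refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contigs, path) {
  if (nrow(calls) > 0 && !all(calls$contig_id %in% contigs$contig_id)) {
    abort("Calls reference unknown contigs.")
  }
  samples <- sort(unique(calls$sample))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$contig_id,
            nchar(contigs$seq)),
    "##INFO=<ID=TRI,Number=0,Type=Flag,Description=\"Tri-allelic site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    sites <- calls %>%
      distinct(.data$contig_id, .data$pos, .data$ref, .data$alt,
               .data$quality, .data$tri_allelic, .data$is_indel) %>%
      arrange(.data$contig_id, .data$pos, .data$alt)
    cseq <- setNames(contigs$seq, contigs$contig_id)
    enc <- function(i) {
      s <- lapply(sites[i, ], unname)
      if (!s$is_indel) {
        c(pos1 = s$pos + 1L, ref = s$ref, alt = s$alt)
      } else if (startsWith(s$alt, "I:")) {
        anchor <- substring(cseq[[s$contig_id]], s$pos + 1, s$pos + 1)
        c(pos1 = s$pos + 1L, ref = anchor,
          alt = paste0(anchor, sub("^I:", "", s$alt)))
      } else {
        len <- as.integer(sub("^D:", "", s$alt))
        anchor_plus <- substring(cseq[[s$contig_id]], s$pos + 1,
                                 s$pos + 1 + len)
        c(pos1 = s$pos + 1L, ref = anchor_plus,
          alt = substring(anchor_plus, 1, 1))
      }
    }
    gt <- calls %>%
      mutate(
        gt_str = paste0(gt_code_to_vcf[.data$genotype], ":",
                        .data$ref_count + .data$alt_count))
    for (i in seq_len(nrow(sites))) {
      e <- enc(i)
      g <- gt %>%
        filter(.data$contig_id == sites$contig_id[i],
               .data$pos == sites$pos[i], .data$alt == sites$alt[i])
      cells <- g$gt_str[match(samples, g$sample)]
      cells[is.na(cells)] <- "./.:0"
      body <- c(body, paste(c(
        sites$contig_id[i], e[["pos1"]], ".", e[["ref"]], e[["alt"]],
        sprintf("%g", sites$quality[i]), "PASS",
        if (isTRUE(sites$tri_allelic[i])) "TRI" else ".",
        "GT:DP", cells), collapse = "\t"))
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a long genotype tibble
#'
#' Parses with `vcfR` and returns one row per site x sample with the fields
#' this pipeline retains: positions return to 0-based, `GT` strings decode
#' to the genotype codes used throughout, and `DP` becomes `depth`.
#'
#' @param path VCF path.
#' @return Tibble `contig_id`, `pos`, `ref`, `alt`, `quality`,
#'   `tri_allelic`, `sample`, `gt`, `genotype`, `depth`.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) abort(sprintf(
                  "Malformed VCF at %s: %s", path, conditionMessage(e))))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    return(tibble(contig_id = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  quality = double(0), tri_allelic = logical(0),
                  sample = character(0), gt = character(0),
                  genotype = character(0), depth = integer(0)))
  }
  info <- vcfR::getINFO(v)
  gt_m <- vcfR::extract.gt(v, element = "GT")
  dp_m <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  samples <- colnames(gt_m)
  decode <- setNames(names(gt_code_to_vcf), unname(gt_code_to_vcf))
  out <- tidyr::expand_grid(site = seq_len(n), sample = samples) %>%
    mutate(
      contig_id = fix$CHROM[.data$site],
      pos = as.integer(fix$POS[.data$site]) - 1L,
      ref = fix$REF[.data$site],
      alt = fix$ALT[.data$site],
      quality = as.numeric(fix$QUAL[.data$site]),
      tri_allelic = grepl("TRI", info[.data$site]),
      gt = gt_m[cbind(.data$site, match(.data$sample, samples))],
      depth = as.integer(dp_m[cbind(.data$site, match(.data$sample,
                                                      samples))])) %>%
    mutate(gt = ifelse(is.na(.data$gt), "./.", .data$gt),
           genotype = unname(decode[.data$gt])) %>%
    select("contig_id", "pos", "ref", "alt", "quality", "tri_allelic",
           "sample", "gt", "genotype", "depth") %>%
    arrange(.data$contig_id, .data$pos, .data$sample)
  out
}
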