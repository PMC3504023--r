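#' Single-k de Bruijn assembly of a read set
#'
#' Minimal local assembler: builds the k-mer multiset of the input sequences
#' and walks greedy majority-resolved paths. At a branch the successor with
#' the strictly highest k-mer count is taken, so a heterozygous site inside a
#' locus is represented by its majority base rather than breaking the contig;
#' exact ties, dead ends and merges into already-assembled sequence stop the
#' walk. Paths are seeded from unvisited k-mers in decreasing count order
#' (ties broken lexicographically), which makes the output deterministic and
#' independent of read input order.
#'
#' @param seqs Character vector of reads (all in a consistent orientation,
#'   unless `dedupe_revcomp` is set).
#' @param k Odd k-mer size, `1 < k <= min(nchar(seqs))` of the reads used.
#' @param min_contig_length Shortest contig reported.
#' @param dedupe_revcomp For unstranded libraries: drop contigs that mostly
#'   re-assemble already-kept sequence on the opposite strand.
#' @return Tibble with `contig_id`, `seq`, `length`, `mean_depth` (mean
#'   k-mer count along the path), ordered by decreasing length.
#' @export
debruijn_assemble <- function(seqs, k = 31, min_contig_length = 150,
                              dedupe_revcomp = FALSE) {
  stopifnot(k > 1, is_odd(k))
  seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
  empty <- tibble(contig_id = character(0), seq = character(0),
                  length = integer(0), mean_depth = double(0))
  if (length(seqs) == 0) return(empty)
  km <- kmers_of(seqs, k)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(empty)
  cnt <- table(km)
  keys <- names(cnt)
  counts <- as.integer(cnt)
  e <- list2env(setNames(as.list(counts), keys), hash = TRUE,
                size = length(keys) * 2L)
  visited <- new.env(hash = TRUE, size = length(keys) * 2L)

  get_cnt <- function(ks) {
    unlist(mget(ks, envir = e, ifnotfound = 0L), use.names = FALSE)
  }
  pick <- function(cands) {
    cn <- get_cnt(cands)
    m <- max(cn)
    if (m == 0) return(NA_character_)
    w <- which(cn == m)
    if (length(w) > 1) return(NA_character_)  # ambiguous: stop
    cands[w]
  }
  walk <- function(start) {
    path_fwd <- character(0)
    cur <- start
    repeat {
      nxt <- pick(paste0(substr(cur, 2, k), BASES))
      if (is.na(nxt) || !is.null(visited[[nxt]])) break
      assign(nxt, TRUE, envir = visited)
      path_fwd <- c(path_fwd, nxt)
      cur <- nxt
      if (length(path_fwd) > 2e6) break
    }
    path_bwd <- character(0)
    cur <- start
    repeat {
      prv <- pick(paste0(BASES, substr(cur, 1, k - 1)))
      if (is.na(prv) || !is.null(visited[[prv]])) break
      assign(prv, TRUE, envir = visited)
      path_bwd <- c(path_bwd, prv)
      cur <- prv
      if (length(path_bwd) > 2e6) break
    }
    c(rev(path_bwd), start, path_fwd)
  }

  ord <- order(-counts, keys)
  contigs <- list()
  ci <- 0
  for (i in ord) {
    kk <- keys[i]
    if (!is.null(visited[[kk]])) next
    assign(kk, TRUE, envir = visited)
    path <- walk(kk)
    len <- k + length(path) - 1L
    if (len < min_contig_length) next
    seqc <- paste0(path[1],
                   paste(substr(path[-1], k, k), collapse = ""))
    ci <- ci + 1
    contigs[[ci]] <- tibble(
      seq = seqc, length = nchar(seqc),
      mean_depth = mean(get_cnt(path)))
  }
  if (ci == 0) return(empty)
  out <- bind_rows(contigs) %>%
    arrange(desc(.data$length), .data$seq) %>%
    mutate(contig_id = sprintf("c%03d", row_number())) %>%
    select("contig_id", "seq", "length", "mean_depth")
  if (dedupe_revcomp && nrow(out) > 1) out <- drop_revcomp_duplicates(out, k)
  out
}

## drop contigs that re-assemble already-kept sequence on the opposite
## strand (reads from an unstranded library build each region's k-mer graph
## twice, once per orientation)
drop_revcomp_duplicates <- function(contigs, k, max_shared = 0.5) {
  seen <- new.env(hash = TRUE)
  keep <- logical(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    km <- kmers_of(contigs$seq[i], k)
    canon <- pmin(km, revcomp(km))
    shared <- mean(vapply(canon, function(x) !is.null(seen[[x]]),
                          logical(1)))
    if (shared <= max_shared) {
      keep[i] <- TRUE
      for (x in canon) assign(x, TRUE, envir = seen)
    }
  }
  contigs[keep, , drop = FALSE] %>%
    mutate(contig_id = sprintf("c%03d", row_number()))
}
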