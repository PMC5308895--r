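#' Sense-strand k-mer at a TSS
#'
#' Returns the k bases read in transcription direction starting at the TSS
#' base: the forward genomic k-mer on plus strand, the reverse complement of
#' the k bases ending at the TSS on minus strand.
#'
#' @param genome named `DNAStringSet` (or named character vector)
#' @param chrom contig name
#' @param pos 0-based TSS position
#' @param strand `"+"` or `"-"`
#' @param k k-mer length
#' @return character k-mer
#' @export
context_at <- function(genome, chrom, pos, strand, k) {
  seqs <- if (is.character(genome)) genome else
    setNames(as.character(genome), names(genome))
  if (!chrom %in% names(seqs)) stop(sprintf("no contig '%s' in genome", chrom))
  len <- nchar(seqs[[chrom]])
  if (strand == "+") {
    if (pos < 0L || pos + k > len)
      stop(sprintf("k-mer at %s:%d(+) runs off the contig", chrom, pos))
    substr(seqs[[chrom]], pos + 1L, pos + k)
  } else {
    if (pos - k + 1L < 0L || pos >= len)
      stop(sprintf("k-mer at %s:%d(-) runs off the contig", chrom, pos))
    fwd <- substr(seqs[[chrom]], pos - k + 2L, pos + 1L)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  }
}

#' Classify TOP promoters from the summit 5-mer
#'
#' A promoter carries a 5' terminal oligopyrimidine (TOP) element when its
#' summit-initiated transcript starts with C followed by four pyrimidines
#' (CYYYY, Y in {C,T}).
#'
#' @param kmer character vector of sense-strand summit k-mers (k >= 5; only
#'   the first five bases are inspected)
#' @return logical vector
#' @export
classify_top <- function(kmer) {
  if (any(nchar(kmer) < 5L)) stop("summit k-mer must have at least 5 bases")
  ok <- substr(kmer, 1L, 1L) == "C"
  for (i in 2:5) ok <- ok & substr(kmer, i, i) %in% c("C", "T")
  ok
}

#' Initiating-nucleotide contexts for a TSS table
#'
#' @param genome named `DNAStringSet` or character vector
#' @param tss `data.table`/data.frame with columns `chrom`, `pos` (0-based),
#'   `strand`; extra columns are carried through
#' @return the table with `first_nt`, `trinucleotide` and `pentamer`
#'   sense-strand columns appended
#' @export
tss_contexts <- function(genome, tss) {
  out <- as.data.table(tss)
  out[, pentamer := vapply(seq_len(.N), function(i)
    context_at(genome, chrom[i], pos[i], strand[i], 5L), "")]
  out[, `:=`(first_nt = substr(pentamer, 1L, 1L),
             trinucleotide = substr(pentamer, 1L, 3L))]
  out[]
}

#' Stratify RO effects by initiating-nucleotide context
#'
#' Groups log2 RO effects of supported TSSs by first nucleotide and by
#' initiating trinucleotide and summarizes each group by its median and
#' 5/95 percentiles, alongside the overall median.
#'
#' @param tss_stats `data.table` with columns `first_nt`, `trinucleotide`,
#'   `ro_effect` and `mass` (read support per TSS)
#' @param min_reads minimum read support for a TSS to be included
#' @return list with `by_nt` and `by_trinucleotide` summary tables (columns
#'   `group`, `n`, `median_log2`, `q05`, `q95`) and `overall_median_log2`
#' @export
stratify_ro_by_context <- function(tss_stats, min_reads = 50) {
  dt <- as.data.table(tss_stats)[mass >= min_reads]
  summarize <- function(d, col) {
    s <- d[, .(n = .N,
               median_log2 = median(log2(ro_effect)),
               q05 = quantile(log2(ro_effect), 0.05, names = FALSE),
               q95 = quantile(log2(ro_effect), 0.95, names = FALSE)),
           by = c(col)]
    setnames(s, col, "group")
    setorder(s, group)[]
  }
  list(by_nt = summarize(dt, "first_nt"),
       by_trinucleotide = summarize(dt, "trinucleotide"),
       overall_median_log2 = median(log2(dt$ro_effect)))
}

#' Pool coverage tracks by summing masses
#' @param tracks list of [coverage_track()]
#' @return a single [coverage_track()]
#' @export
pool_tracks <- function(tracks) {
  as_coverage_track(rbindlist(tracks))
}

#' Metagene profile around TSSs
#'
#' For each TSS a strand-oriented window of offsets `-window..window`
#' (downstream positive) is cut from the coverage track. Regions with fewer
#' than `min_covered` nonzero positions, or zero variance, are excluded;
#' each remaining region is normalized to mean 0 and standard deviation 1
#' and the normalized vectors are summed across regions.
#'
#' @param track a [coverage_track()] (pool samples first with
#'   [pool_tracks()] if desired)
#' @param tss table with columns `chrom`, `pos` (0-based), `strand`
#' @param window half-width in nt (profile length `2*window + 1`)
#' @param min_covered minimum nonzero positions per region
#' @return a `metagene_profile`: list with `offsets`, `profile` (summed
#'   z-scores per offset) and `n_regions_used`
#' @export
metagene <- function(track, tss, window = 200, min_covered = 10) {
  tss <- as.data.table(tss)
  stopifnot(nrow(tss) > 0L)
  offs <- seq.int(-window, window)
  acc <- numeric(length(offs))
  used <- 0L
  tr <- as.data.table(track)
  for (i in seq_len(nrow(tss))) {
    p <- if (tss$strand[i] == "+") tss$pos[i] + offs else tss$pos[i] - offs
    q <- data.table(chrom = tss$chrom[i], strand = tss$strand[i], pos = p)
    v <- tr[q, mass, on = c("chrom", "strand", "pos")]
    v[is.na(v)] <- 0
    if (sum(v > 0) < min_covered) next
    s <- sd(v)
    if (s == 0) next
    acc <- acc + (v - mean(v)) / s
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TSS regions for the metagene profile")
  structure(list(offsets = offs, profile = acc, n_regions_used = used),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d offsets (%d..%d), %d regions used, peak at offset %d\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              x$n_regions_used, x$offsets[which.max(x$profile)]))
  invisible(x)
}
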