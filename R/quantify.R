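#' Spike-in normalization
#'
#' Each sample's scale factor is derived from the reads mapping to the
#' exogenous capped spikes (GFP, luciferase) added in known amounts to every
#' fraction pool: per spike, factor = input mass / observed reads; per
#' sample, the geometric mean over its spikes; then all factors are rescaled
#' so their geometric mean across samples is 1. Tracks are multiplied by
#' their sample's factor.
#'
#' @param experiment a [capseq_experiment()]
#' @param fraction_factors optional named positive multipliers per fraction
#'   (`free`, `light`, `heavy`), applied on top of the spike factors for
#'   gradients whose pools were not loaded in equivalent volumes; default
#'   is 1 for every fraction
#' @return the experiment with `norm_factors` set (named numeric, one per
#'   sample; geometric mean 1 before `fraction_factors`) and tracks scaled
#' @export
spike_normalize <- function(experiment, fraction_factors = NULL) {
  sp <- merge(experiment$spikes,
              data.table(spike_id = names(experiment$spike_truth),
                         input_mass = unname(experiment$spike_truth)),
              by = "spike_id")
  if (nrow(sp) == 0L)
    stop("no spike read counts match the spike truth table")
  zero <- sp[reads <= 0]
  if (nrow(zero))
    stop(sprintf("sample '%s' has zero reads for spike '%s'",
                 zero$sample_id[1L], zero$spike_id[1L]))
  f <- sp[, .(factor = exp(mean(log(input_mass / reads)))), by = sample_id]
  missing <- setdiff(experiment$samples$sample_id, f$sample_id)
  if (length(missing))
    stop(sprintf("sample '%s' has no spike counts", missing[1L]))
  factors <- setNames(f$factor, f$sample_id)
  factors <- factors / exp(mean(log(factors)))   # anchor geometric mean at 1
  factors <- factors[experiment$samples$sample_id]
  if (!is.null(fraction_factors)) {
    if (!all(experiment$samples$fraction %in% names(fraction_factors)) ||
        any(!is.finite(fraction_factors)) || any(fraction_factors <= 0))
      stop("fraction_factors must be finite positive values named per fraction")
    factors <- factors * fraction_factors[experiment$samples$fraction]
    names(factors) <- experiment$samples$sample_id
  }
  experiment$tracks <- Map(scale_track, experiment$tracks,
                           as.list(factors[names(experiment$tracks)]))
  experiment$norm_factors <- factors
  experiment
}

#' Count 5'-end read mass inside an interval
#'
#' Sums the mass at positions in `[start, end)` on the matching strand only.
#'
#' @param track a [coverage_track()]
#' @param chrom chromosome
#' @param start,end 0-based half-open bounds
#' @param strand `"+"` or `"-"`
#' @return numeric read mass
#' @export
count_interval <- function(track, chrom, start, end, strand) {
  stopifnot(start < end)
  ch <- chrom; st <- strand
  sum(track[chrom == ch & strand == st & pos >= start & pos < end, mass])
}

#' Count 5'-end read mass at a single TSS position
#' @inheritParams count_interval
#' @param pos 0-based position
#' @return numeric read mass
#' @export
count_tss <- function(track, chrom, pos, strand) {
  count_interval(track, chrom, pos, pos + 1L, strand)
}

#' Find a promoter's summit
#'
#' The summit is the position with maximal total mass summed over all
#' samples' tracks; ties go to the 5'-most position (smallest coordinate on
#' plus strand, largest on minus).
#'
#' @param tracks list of [coverage_track()]
#' @param chrom,start,end,strand promoter interval
#' @return 0-based summit position
#' @export
find_summit <- function(tracks, chrom, start, end, strand) {
  ch <- chrom; st <- strand
  pooled <- rbindlist(lapply(tracks, function(tr)
    tr[chrom == ch & strand == st & pos >= start & pos < end,
       .(pos, mass)]))
  if (nrow(pooled) == 0L)
    stop(sprintf("promoter %s:%d-%d(%s) has no reads", chrom, start, end, strand))
  tot <- pooled[, .(mass = sum(mass)), by = pos]
  top <- tot[mass == max(mass), pos]
  if (strand == "+") min(top) else max(top)
}

#' Quantify promoters across all samples of an experiment
#'
#' Counts normalized 5'-end mass per promoter per sample and locates each
#' promoter's summit over the pooled tracks.
#'
#' @param experiment a [capseq_experiment()] (normalize first with
#'   [spike_normalize()] unless tracks are already comparable)
#' @param promoters promoter table as from [read_promoters()]
#' @return a `promoter_quant`: long `data.table` with columns `promoter_id`,
#'   `gene_id`, `condition`, `fraction`, `replicate`, `count`, plus a
#'   `summits` attribute (`data.table` of `promoter_id`, `chrom`, `summit`,
#'   `strand`; `NA` summit for read-free promoters)
#' @export
quantify_promoters <- function(experiment, promoters) {
  promoters <- as.data.table(promoters)
  samples <- experiment$samples
  counts <- rbindlist(lapply(seq_len(nrow(samples)), function(i) {
    tr <- experiment$tracks[[samples$sample_id[i]]]
    cnt <- vapply(seq_len(nrow(promoters)), function(j)
      count_interval(tr, promoters$chrom[j], promoters$start[j],
                     promoters$end[j], promoters$strand[j]), 0)
    data.table(promoter_id = promoters$promoter_id,
               gene_id = promoters$gene_id,
               condition = samples$condition[i],
               fraction = samples$fraction[i],
               replicate = samples$replicate[i],
               count = cnt)
  }))
  summit <- vapply(seq_len(nrow(promoters)), function(j)
    tryCatch(find_summit(experiment$tracks, promoters$chrom[j],
                         promoters$start[j], promoters$end[j],
                         promoters$strand[j]),
             error = function(e) NA_integer_),
    0L)
  setattr(counts, "summits",
          data.table(promoter_id = promoters$promoter_id,
                     chrom = promoters$chrom, summit = summit,
                     strand = promoters$strand))
  setattr(counts, "class", c("promoter_quant", class(counts)))
  counts[]
}

#' Reshape promoter counts to one row per (promoter, condition, replicate)
#' @param counts a `promoter_quant` from [quantify_promoters()]
#' @return `data.table` with columns `promoter_id`, `gene_id`, `condition`,
#'   `replicate`, `free`, `light`, `heavy`
#' @export
fraction_matrix <- function(counts) {
  wide <- dcast(as.data.table(counts),
                promoter_id + gene_id + condition + replicate ~ fraction,
                value.var = "count", fill = 0)
  for (fr in c("free", "light", "heavy"))
    if (!fr %in% names(wide)) wide[, (fr) := 0]
  setcolorder(wide, c("promoter_id", "gene_id", "condition", "replicate",
                      "free", "light", "heavy"))
  wide[]
}

#' Expression threshold on promoters
#'
#' A replicate passes when its total normalized mass, summed over the three
#' fractions and both conditions, is at least `min_reads` (inclusive). A
#' promoter is retained only if every replicate passes.
#'
#' @param fracs output of [fraction_matrix()]
#' @param min_reads minimum normalized reads per promoter per replicate
#' @return `data.table` with `promoter_id`, `replicate`, `total`, `pass`,
#'   and a logical `keep` (same for all rows of a promoter)
#' @export
apply_threshold <- function(fracs, min_reads = 500) {
  per_rep <- fracs[, .(total = sum(free + light + heavy)),
                   by = .(promoter_id, replicate)]
  per_rep[, pass := total >= min_reads]
  per_rep[, keep := all(pass), by = promoter_id]
  per_rep[]
}

#' Drop promoters failing the expression threshold
#' @inheritParams apply_threshold
#' @return filtered [fraction_matrix()] table
#' @export
filter_expressed <- function(fracs, min_reads = 500) {
  th <- apply_threshold(fracs, min_reads)
  fracs[promoter_id %in% th[keep == TRUE, unique(promoter_id)]]
}

#' Average fraction counts over replicates
#' @param fracs output of [fraction_matrix()]
#' @return `data.table` with one row per (promoter, condition): arithmetic
#'   mean of `free`, `light`, `heavy` over replicates
#' @export
mean_replicates <- function(fracs) {
  fracs[, .(free = mean(free), light = mean(light), heavy = mean(heavy)),
        by = .(promoter_id, gene_id, condition)]
}
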