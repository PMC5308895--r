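#' Ribosome occupancy of a promoter
#'
#' RO is the ratio of the polysomal (light + heavy) read mass to the
#' polysome-free mass, with a pseudo-count added to each fraction count so
#' the ratio stays finite and positive for empty fractions:
#' `((light + pc) + (heavy + pc)) / (free + pc)`.
#'
#' @param free,light,heavy normalized read mass per fraction (vectorized)
#' @param pseudocount added to each fraction count; 0 disables it
#' @return numeric RO
#' @export
compute_ro <- function(free, light, heavy, pseudocount = 0.5) {
  if (any(c(free, light, heavy) < 0)) stop("fraction counts must be >= 0")
  ((light + pseudocount) + (heavy + pseudocount)) / (free + pseudocount)
}

#' RO effect of stress
#' @param ro_stress,ro_control ribosome occupancies (vectorized)
#' @return `ro_stress / ro_control`
#' @export
compute_ro_effect <- function(ro_stress, ro_control) ro_stress / ro_control

#' mRNA level change under stress
#'
#' Ratio of total (free + light + heavy) mass under stress to control, each
#' fraction count pseudo-counted.
#'
#' @param free_stress,light_stress,heavy_stress stress fraction counts
#' @param free_control,light_control,heavy_control control fraction counts
#' @param pseudocount added to each fraction count
#' @return numeric ratio
#' @export
compute_mrna_change <- function(free_stress, light_stress, heavy_stress,
                                free_control, light_control, heavy_control,
                                pseudocount = 0.5) {
  if (any(c(free_stress, light_stress, heavy_stress,
            free_control, light_control, heavy_control) < 0))
    stop("fraction counts must be >= 0")
  (free_stress + light_stress + heavy_stress + 3 * pseudocount) /
    (free_control + light_control + heavy_control + 3 * pseudocount)
}

#' Per-replicate ribosome occupancies
#' @param fracs output of [fraction_matrix()]
#' @inheritParams compute_ro
#' @return `data.table` with `promoter_id`, `gene_id`, `condition`,
#'   `replicate`, `ro`
#' @export
replicate_ro <- function(fracs, pseudocount = 0.5) {
  fracs[, .(promoter_id, gene_id, condition, replicate,
            ro = compute_ro(free, light, heavy, pseudocount))]
}

#' Promoter-level translation statistics
#'
#' Computes, per promoter, RO in each condition (from replicate-mean
#' fraction counts), the RO effect (stress / control) and the mRNA level
#' change, with log2 versions; per-replicate RO effects and mRNA changes
#' ride along in the `"replicates"` attribute for the both-repeats calls.
#'
#' @param fracs output of [fraction_matrix()]; must contain both conditions
#' @inheritParams compute_ro
#' @return `data.table` with columns `promoter_id`, `gene_id`,
#'   `ro_control`, `ro_stress`, `ro_effect`, `mrna_change`,
#'   `log2_ro_effect`, `log2_mrna_change`
#' @export
translation_stats <- function(fracs, pseudocount = 0.5) {
  stopifnot(all(c("control", "stress") %in% fracs$condition))
  per_cond <- function(dt) {
    w <- dcast(dt, promoter_id + gene_id + replicate ~ condition,
               value.var = c("free", "light", "heavy"))
    w[, `:=`(
      ro_control = compute_ro(free_control, light_control, heavy_control,
                              pseudocount),
      ro_stress = compute_ro(free_stress, light_stress, heavy_stress,
                             pseudocount),
      mrna_change = compute_mrna_change(free_stress, light_stress,
                                        heavy_stress, free_control,
                                        light_control, heavy_control,
                                        pseudocount))]
    w[, ro_effect := compute_ro_effect(ro_stress, ro_control)]
    w
  }
  reps <- per_cond(fracs)[, .(promoter_id, gene_id, replicate,
                              ro_control, ro_stress, ro_effect, mrna_change)]
  means <- mean_replicates(fracs)
  means[, replicate := 1L]
  main <- per_cond(means)[, .(promoter_id, gene_id, ro_control, ro_stress,
                              ro_effect, mrna_change)]
  main[, `:=`(log2_ro_effect = log2(ro_effect),
              log2_mrna_change = log2(mrna_change))]
  setattr(main, "replicates", reps)
  main[]
}

#' Call translationally affected promoters
#'
#' A promoter is `repressed` when its RO effect is at most `1/fold` in every
#' replicate, `induced` when at least `fold` in every replicate (both
#' inclusive), otherwise `unaffected`.
#'
#' @param stats output of [translation_stats()] (its per-replicate attribute
#'   is used), or a `data.table` with `promoter_id`, `replicate`, `ro_effect`
#' @param fold fold-change threshold (default two-fold in both repeats)
#' @return `data.table` with `promoter_id`, `direction`, `fold`
#' @export
call_affected <- function(stats, fold = 2) {
  reps <- attr(stats, "replicates", exact = TRUE)
  if (is.null(reps)) reps <- as.data.table(stats)
  out <- reps[, .(direction =
    if (all(ro_effect <= 1 / fold)) "repressed"
    else if (all(ro_effect >= fold)) "induced"
    else "unaffected"), by = promoter_id]
  out[, fold := fold]
  out[]
}

#' Call differentially translated alternative-promoter pairs
#'
#' Every unordered pair of promoters of the same gene is compared. For each
#' condition independently, the pair is flagged when the RO ratio between
#' the two promoters is `fold`-or-more (either direction) in every
#' replicate. The mRNA differential effect is the ratio of the two
#' promoters' mRNA changes (replicate-mean based, oriented p1/p2).
#'
#' @param fracs output of [fraction_matrix()], typically after
#'   [filter_expressed()]
#' @param fold fold threshold for the RO ratio (inclusive)
#' @inheritParams compute_ro
#' @return `data.table` with one row per pair: `gene_id`, `p1`, `p2`,
#'   `ro_ratio_control`, `ro_ratio_stress` (mean-based p1/p2),
#'   `diff_control`, `diff_stress` (logical), `mrna_differential_effect`
#' @export
call_differential_pairs <- function(fracs, fold = 2, pseudocount = 0.5) {
  stats <- translation_stats(fracs, pseudocount)
  reps <- attr(stats, "replicates", exact = TRUE)
  genes <- stats[, .N, by = gene_id][N >= 2L, gene_id]
  empty <- data.table(gene_id = character(), p1 = character(),
                      p2 = character(), ro_ratio_control = numeric(),
                      ro_ratio_stress = numeric(), diff_control = logical(),
                      diff_stress = logical(),
                      mrna_differential_effect = numeric())
  if (length(genes) == 0L) return(empty)
  pair_rows <- lapply(genes, function(g) {
    ids <- sort(stats[gene_id == g, promoter_id])
    cmb <- utils::combn(ids, 2L)
    data.table(gene_id = g, p1 = cmb[1L, ], p2 = cmb[2L, ])
  })
  pairs <- rbindlist(pair_rows)
  flag_pair <- function(a, b, col) {
    ra <- reps[promoter_id == a][order(replicate)][[col]]
    rb <- reps[promoter_id == b][order(replicate)][[col]]
    all(pmax(ra / rb, rb / ra) >= fold)
  }
  pairs[, `:=`(
    ro_ratio_control = stats[match(p1, promoter_id), ro_control] /
                       stats[match(p2, promoter_id), ro_control],
    ro_ratio_stress = stats[match(p1, promoter_id), ro_stress] /
                      stats[match(p2, promoter_id), ro_stress],
    diff_control = mapply(flag_pair, p1, p2,
                          MoreArgs = list(col = "ro_control")),
    diff_stress = mapply(flag_pair, p1, p2,
                         MoreArgs = list(col = "ro_stress")),
    mrna_differential_effect = stats[match(p1, promoter_id), mrna_change] /
                               stats[match(p2, promoter_id), mrna_change])]
  pairs[]
}

#' Summaries of differential alternative-promoter pairs
#'
#' Counts flagged pairs and genes with at least one flagged pair per
#' condition, and the pair-level and gene-level overlap between conditions
#' (the Venn partition: control-only, both, stress-only).
#'
#' @param pairs output of [call_differential_pairs()]
#' @return list with `pairs_control`, `pairs_stress`, `genes_control`,
#'   `genes_stress`, `pair_venn` and `gene_venn` (each a named vector
#'   `control_only` / `both` / `stress_only`), and
#'   `percent_increase_genes` / `percent_increase_pairs`
#' @export
ap_summary <- function(pairs) {
  pc <- pairs[diff_control == TRUE]
  ps <- pairs[diff_stress == TRUE]
  key <- function(dt) paste(dt$gene_id, dt$p1, dt$p2)
  both_pairs <- intersect(key(pc), key(ps))
  gc <- unique(pc$gene_id); gs <- unique(ps$gene_id)
  list(
    pairs_control = nrow(pc), pairs_stress = nrow(ps),
    genes_control = length(gc), genes_stress = length(gs),
    pair_venn = c(control_only = nrow(pc) - length(both_pairs),
                  both = length(both_pairs),
                  stress_only = nrow(ps) - length(both_pairs)),
    gene_venn = c(control_only = length(setdiff(gc, gs)),
                  both = length(intersect(gc, gs)),
                  stress_only = length(setdiff(gs, gc))),
    percent_increase_genes = percent_increase(length(gc), length(gs)),
    percent_increase_pairs = percent_increase(nrow(pc), nrow(ps)))
}

#' Percent increase between two counts
#' @param count_basal,count_stress non-negative counts
#' @return `(count_stress - count_basal) / count_basal * 100`
#' @export
percent_increase <- function(count_basal, count_stress) {
  stopifnot(count_basal > 0)
  (count_stress - count_basal) / count_basal * 100
}

## spliced exonic distance from the summit (inclusive) to the CDS start
## (exclusive), in transcription direction; NA when the summit lies
## downstream of the CDS start or the transcript is non-coding
spliced_utr5 <- function(exon_starts, exon_ends, strand, cds_start, summit) {
  if (is.na(cds_start)) return(NA_integer_)
  if (strand == "+") {
    if (summit > cds_start) return(NA_integer_)
    lo <- summit; hi <- cds_start
  } else {
    if (summit < cds_start) return(NA_integer_)
    lo <- cds_start + 1L; hi <- summit + 1L
  }
  as.integer(sum(pmax(0L, pmin(exon_ends, hi) - pmax(exon_starts, lo))))
}

#' Spliced 5'UTR length from a promoter summit
#' @param tx one-row transcript table (see [read_transcripts()])
#' @param summit 0-based genomic summit position
#' @return nt length, or `NA` if the summit is downstream of the CDS start
#'   or the transcript has no CDS
#' @export
utr5_length <- function(tx, summit) {
  spliced_utr5(tx$exon_starts[[1L]], tx$exon_ends[[1L]], tx$strand,
               tx$cds_start, summit)
}

#' Assign promoters to transcript models
#'
#' A promoter is the `annotated` promoter of a transcript when its summit
#' lies within `window` nt of the transcript 5' end (same chromosome and
#' strand); failing that it is `exonic` when the summit overlaps a 5'UTR
#' exon (exonic sequence upstream of the CDS start); otherwise
#' `unassigned`. Among eligible transcripts the one whose 5' end is nearest
#' the summit wins. The 5'UTR length is the spliced distance from the
#' summit to the CDS start on the matched transcript.
#'
#' @param summits `data.table` with `promoter_id`, `chrom`, `summit`,
#'   `strand` (e.g. the `summits` attribute of [quantify_promoters()])
#' @param transcripts from [read_transcripts()]
#' @param window maximum summit-to-5'-end distance for `annotated` (nt)
#' @return `data.table` with `promoter_id`, `transcript_id`, `relation`
#'   (`annotated`/`exonic`/`unassigned`), `utr5_length`
#' @export
assign_promoters <- function(summits, transcripts, window = 100) {
  summits <- as.data.table(summits)
  out <- lapply(seq_len(nrow(summits)), function(i) {
    ch <- summits$chrom[i]; st <- summits$strand[i]; sm <- summits$summit[i]
    res <- data.table(promoter_id = summits$promoter_id[i],
                      transcript_id = NA_character_,
                      relation = "unassigned", utr5_length = NA_integer_)
    if (is.na(sm)) return(res)
    cand <- transcripts[chrom == ch & strand == st]
    if (nrow(cand) == 0L) return(res)
    cand <- copy(cand)[, distance := abs(tss - sm)]
    ann <- cand[distance <= window][order(distance)]
    if (nrow(ann)) {
      hit <- ann[1L]
      res[, `:=`(transcript_id = hit$transcript_id, relation = "annotated",
                 utr5_length = utr5_length(hit, sm))]
      return(res)
    }
    exonic <- cand[vapply(seq_len(.N), function(j) {
      es <- exon_starts[[j]]; ee <- exon_ends[[j]]; cs <- cds_start[j]
      if (is.na(cs)) return(FALSE)
      in_exon <- any(sm >= es & sm < ee)
      upstream <- if (st == "+") sm < cs else sm > cs
      in_exon && upstream
    }, logical(1L))][order(distance)]
    if (nrow(exonic)) {
      hit <- exonic[1L]
      res[, `:=`(transcript_id = hit$transcript_id, relation = "exonic",
                 utr5_length = utr5_length(hit, sm))]
    }
    res
  })
  rbindlist(out)
}

#' Do two promoters feed the same annotated ORF?
#'
#' TRUE when both promoters are assigned (annotated or exonic) to
#' transcripts sharing the same genomic CDS start, i.e. both transcript
#' isoforms encode the same protein.
#'
#' @param assignments output of [assign_promoters()]
#' @param transcripts from [read_transcripts()]
#' @param pairs output of [call_differential_pairs()]
#' @return `pairs` with a logical `same_orf` column (`NA` when either
#'   promoter is unassigned)
#' @export
flag_same_orf <- function(pairs, assignments, transcripts) {
  cds_of <- function(p) {
    a <- assignments[match(p, promoter_id)]
    ifelse(a$relation == "unassigned", NA_integer_,
           transcripts[match(a$transcript_id, transcript_id), cds_start])
  }
  out <- copy(pairs)
  out[, same_orf := cds_of(p1) == cds_of(p2)]
  out[]
}

#' Global per-fraction read sums
#'
#' Sums replicate-mean fraction counts over a promoter set per condition;
#' proportions are within-condition shares of the three fractions.
#'
#' @param fracs output of [fraction_matrix()]
#' @return `data.table` with `condition`, `free`, `light`, `heavy`,
#'   `free_prop`, `light_prop`, `heavy_prop`
#' @export
global_fraction_sums <- function(fracs) {
  if (nrow(fracs) == 0L)
    return(data.table(condition = character(), free = numeric(),
                      light = numeric(), heavy = numeric(),
                      free_prop = numeric(), light_prop = numeric(),
                      heavy_prop = numeric()))
  m <- mean_replicates(fracs)
  g <- m[, .(free = sum(free), light = sum(light), heavy = sum(heavy)),
         by = condition]
  g[, `:=`(free_prop = free / (free + light + heavy),
           light_prop = light / (free + light + heavy),
           heavy_prop = heavy / (free + light + heavy))]
  g[]
}

#' Per-fraction sums restricted to TOP promoters
#' @inheritParams global_fraction_sums
#' @param top_ids promoter ids classified as TOP (see [classify_top()])
#' @export
top_subset_sums <- function(fracs, top_ids) {
  global_fraction_sums(fracs[promoter_id %in% top_ids])
}
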