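#' Coverage tracks of capped 5' ends
#'
#' A coverage track is the in-memory form of a stranded pair of bedGraph
#' files: one read mass per (chromosome, strand, position). Positions are
#' 0-based; mass is an integer count before normalization and a non-negative
#' real after. Duplicate positions are summed, zero-mass positions dropped,
#' and rows kept sorted so tracks have a unique canonical form.
#'
#' @param chrom character chromosome names
#' @param pos integer 0-based positions
#' @param strand character, each `"+"` or `"-"`
#' @param mass non-negative numeric read mass per position
#' @return a `coverage_track`: a `data.table` with columns
#'   `chrom`, `pos`, `strand`, `mass`
#' @export
coverage_track <- function(chrom = character(), pos = integer(),
                           strand = character(), mass = numeric()) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n) || n == 0L,
            length(strand) %in% c(1L, n) || n == 0L,
            length(mass) == n)
  if (n > 0 && any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (n > 0 && any(mass < 0))
    stop("coverage mass must be non-negative")
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), mass = as.numeric(mass))
  dt <- dt[mass > 0, .(mass = sum(mass)), by = .(chrom, strand, pos)]
  setorder(dt, chrom, strand, pos)
  setcolorder(dt, c("chrom", "pos", "strand", "mass"))
  setattr(dt, "class", c("coverage_track", class(dt)))
  dt[]
}

as_coverage_track <- function(dt) {
  coverage_track(dt$chrom, dt$pos, dt$strand, dt$mass)
}

#' Scale a coverage track by a positive factor
#' @param track a [coverage_track()]
#' @param factor positive scalar
#' @return scaled track
#' @export
scale_track <- function(track, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  out <- copy(track)
  out[, mass := mass * factor]
  out[]
}

parse_bedgraph_file <- function(path, strand) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), mass = numeric()))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop(sprintf("malformed bedGraph line %d in '%s': expected 4 fields, got %d",
                 keep[which(nf != 4L)[1L]], path, nf[nf != 4L][1L]))
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  s <- suppressWarnings(as.integer(m[, 2L]))
  e <- suppressWarnings(as.integer(m[, 3L]))
  v <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | s < 0L | e <= s)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in '%s': '%s'",
                 keep[bad[1L]], path, lines[keep[bad[1L]]]))
  if (any(v < 0))
    stop(sprintf("negative coverage value at line %d in '%s'",
                 keep[which(v < 0)[1L]], path))
  w <- e - s
  data.table(chrom = rep(m[, 1L], w),
             pos = rep(s, w) + sequence(w) - 1L,
             strand = strand,
             mass = rep(v, w))
}

#' Read a stranded pair of bedGraph files into a coverage track
#'
#' Intervals are 0-based half-open; a run `chrom 100 103 2` contributes mass
#' 2 at each of positions 100, 101 and 102.
#'
#' @param plus_path bedGraph of plus-strand 5'-end mass
#' @param minus_path bedGraph of minus-strand 5'-end mass
#' @return a [coverage_track()]
#' @export
read_coverage <- function(plus_path, minus_path) {
  as_coverage_track(rbind(parse_bedgraph_file(plus_path, "+"),
                          parse_bedgraph_file(minus_path, "-")))
}

bedgraph_runs <- function(dt) {
  ## merge consecutive equal-mass positions into half-open runs
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  setorder(dt, chrom, pos)
  newrun <- c(TRUE, dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
                    dt$pos[-1L] != dt$pos[-nrow(dt)] + 1L |
                    dt$mass[-1L] != dt$mass[-nrow(dt)])
  dt[, run_id := cumsum(newrun)]
  dt[, .(chrom = chrom[1L], start = pos[1L], end = pos[.N] + 1L,
         value = mass[1L]), by = run_id][, run_id := NULL][]
}

#' Write a coverage track as a stranded bedGraph pair
#'
#' The output is canonical: sorted, with consecutive equal-mass positions
#' merged into runs, so `read_coverage(write_coverage(x))` round-trips
#' byte-identically on canonical input.
#'
#' @param track a [coverage_track()]
#' @param plus_path,minus_path output paths
#' @return invisibly, the two paths
#' @export
write_coverage <- function(track, plus_path, minus_path) {
  for (s in c("+", "-")) {
    runs <- bedgraph_runs(copy(track[strand == s, .(chrom, pos, mass)]))
    fwrite(runs, if (s == "+") plus_path else minus_path,
           sep = "\t", col.names = FALSE)
  }
  invisible(c(plus_path, minus_path))
}

split_name_field <- function(name, path, what) {
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s name '%s' in '%s' is not of the form id|gene",
                 what, name[bad[1L]], path))
  list(id = vapply(parts, `[`, "", 1L), gene = vapply(parts, `[`, "", 2L))
}

#' Read promoter intervals from BED6
#'
#' BED is 0-based half-open. The name field must be `promoterID|geneID`.
#'
#' @param path BED6 file
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `promoter_id`, `gene_id`, `score`
#' @export
read_promoters <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "name", "score", "strand"),
              colClasses = list(character = c(1, 4, 6), integer = c(2, 3)))
  if (any(dt$start < 0L | dt$end <= dt$start))
    stop(sprintf("invalid interval in '%s'", path))
  if (any(!dt$strand %in% c("+", "-")))
    stop(sprintf("promoter strand must be '+' or '-' in '%s'", path))
  ids <- split_name_field(dt$name, path, "promoter")
  dt[, `:=`(promoter_id = ids$id, gene_id = ids$gene, name = NULL)]
  setcolorder(dt, c("chrom", "start", "end", "strand",
                    "promoter_id", "gene_id", "score"))
  dt[]
}

#' Write promoter intervals to BED6
#' @param promoters as returned by [read_promoters()]
#' @param path output path
#' @export
write_promoters <- function(promoters, path) {
  out <- data.table(promoters$chrom, promoters$start, promoters$end,
                    paste0(promoters$promoter_id, "|", promoters$gene_id),
                    if (is.null(promoters$score)) 0L else promoters$score,
                    promoters$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

int_list <- function(x) lapply(strsplit(sub(",$", "", x), ","), as.integer)

#' Read transcript models from BED12
#'
#' The name field must be `transcriptID|geneID`; thickStart/thickEnd delimit
#' the CDS. The genomic CDS start (first transcribed coding base) is
#' thickStart on plus-strand and thickEnd−1 on minus-strand transcripts;
#' the transcript 5' end is `start` (plus) or `end`−1 (minus).
#'
#' @param path BED12 file
#' @return `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss` (genomic 5' end),
#'   `cds_start` (genomic, `NA` for non-coding), and list-columns
#'   `exon_starts`, `exon_ends` (0-based half-open, sorted)
#' @export
read_transcripts <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "name", "score", "strand",
                            "thickStart", "thickEnd", "itemRgb",
                            "blockCount", "blockSizes", "blockStarts"),
              colClasses = list(character = c(1, 4, 6, 9, 11, 12)))
  ids <- split_name_field(dt$name, path, "transcript")
  sizes <- int_list(dt$blockSizes)
  offs <- int_list(dt$blockStarts)
  exon_starts <- Map(function(s, o) s + o, dt$start, offs)
  exon_ends <- Map(`+`, exon_starts, sizes)
  cds_start <- ifelse(dt$thickStart == dt$thickEnd, NA_integer_,
                      ifelse(dt$strand == "+", dt$thickStart,
                             dt$thickEnd - 1L))
  for (i in seq_len(nrow(dt))) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (is.unsorted(es) || any(ee[-length(ee)] > es[-1L]))
      stop(sprintf("transcript '%s': exon blocks unsorted or overlapping",
                   ids$id[i]))
    if (!is.na(cds_start[i]) &&
        !any(cds_start[i] >= es & cds_start[i] < ee))
      stop(sprintf("transcript '%s': CDS start %d outside exons",
                   ids$id[i], cds_start[i]))
  }
  out <- data.table(transcript_id = ids$id, gene_id = ids$gene,
                    chrom = dt$chrom, start = dt$start, end = dt$end,
                    strand = dt$strand,
                    tss = ifelse(dt$strand == "+", dt$start, dt$end - 1L),
                    cds_start = as.integer(cds_start),
                    thick_start = dt$thickStart, thick_end = dt$thickEnd)
  out[, `:=`(exon_starts = exon_starts, exon_ends = exon_ends)]
  out[]
}

#' Write transcript models to BED12
#' @param tx as returned by [read_transcripts()]
#' @param path output path
#' @export
write_transcripts <- function(tx, path) {
  out <- data.table(
    tx$chrom, tx$start, tx$end,
    paste0(tx$transcript_id, "|", tx$gene_id), 0L, tx$strand,
    tx$thick_start, tx$thick_end, "0",
    lengths(tx$exon_starts),
    vapply(Map(`-`, tx$exon_ends, tx$exon_starts),
           function(x) paste0(paste(x, collapse = ","), ","), ""),
    vapply(Map(`-`, tx$exon_starts, tx$start),
           function(x) paste0(paste(x, collapse = ","), ","), ""))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read spike-in read counts
#' @param path TSV with columns `spike_id`, `reads`
#' @return `data.table`
#' @export
read_spike_counts <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("spike_id", "reads") %in% names(dt)))
  dt[, .(spike_id = as.character(spike_id), reads = as.numeric(reads))]
}

#' Assemble a CapSeq experiment
#'
#' Binds a sample sheet (the factorial design: condition x fraction x
#' replicate), one coverage track per sample, per-sample spike read counts
#' and the known spike input masses into one object that the quantification
#' functions consume.
#'
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"control"`/`"stress"`), `fraction` (`"free"`/`"light"`/`"heavy"`),
#'   `replicate` (integer)
#' @param tracks named list of [coverage_track()], names matching `sample_id`
#' @param spikes data.frame with columns `sample_id`, `spike_id`, `reads`
#' @param spike_truth named numeric vector of spike input masses
#'   (arbitrary but consistent units, e.g. ng)
#' @return a `capseq_experiment` object
#' @export
capseq_experiment <- function(samples, tracks, spikes, spike_truth) {
  samples <- as.data.table(samples)
  need <- c("sample_id", "condition", "fraction", "replicate")
  stopifnot(all(need %in% names(samples)))
  if (any(!samples$condition %in% c("control", "stress")))
    stop("condition must be 'control' or 'stress'")
  if (any(!samples$fraction %in% c("free", "light", "heavy")))
    stop("fraction must be 'free', 'light' or 'heavy'")
  full <- CJ(condition = unique(samples$condition),
             fraction = c("free", "light", "heavy"),
             replicate = unique(samples$replicate))
  if (nrow(samples) != nrow(full) ||
      nrow(merge(samples, full, by = c("condition", "fraction", "replicate"))) !=
        nrow(full))
    stop("sample sheet is not a complete condition x fraction x replicate design")
  if (!all(samples$sample_id %in% names(tracks)))
    stop("every sample needs a coverage track")
  structure(list(samples = samples[],
                 tracks = tracks[samples$sample_id],
                 spikes = as.data.table(spikes),
                 spike_truth = spike_truth,
                 norm_factors = NULL),
            class = "capseq_experiment")
}

#' @export
print.capseq_experiment <- function(x, ...) {
  cat(sprintf("capseq_experiment: %d samples (%d condition(s) x 3 fractions x %d replicate(s))\n",
              nrow(x$samples), length(unique(x$samples$condition)),
              length(unique(x$samples$replicate))))
  cat(sprintf("  spikes: %s\n", paste(names(x$spike_truth), collapse = ", ")))
  cat(sprintf("  normalized: %s\n", !is.null(x$norm_factors)))
  invisible(x)
}

#' Read a sample sheet and load the experiment it describes
#'
#' The sheet is a TSV with columns `sample_id`, `condition`, `fraction`,
#' `replicate`, `coverage_plus`, `coverage_minus`, `spike_counts` (paths
#' relative to the sheet's directory), plus a separate two-column TSV of
#' spike input masses.
#'
#' @param sheet_path sample sheet TSV
#' @param spike_truth_path TSV with columns `spike_id`, `input_mass`
#' @return a [capseq_experiment()]
#' @export
read_sample_sheet <- function(sheet_path, spike_truth_path) {
  dir <- dirname(sheet_path)
  sheet <- fread(sheet_path, header = TRUE, sep = "\t")
  tracks <- lapply(seq_len(nrow(sheet)), function(i)
    read_coverage(file.path(dir, sheet$coverage_plus[i]),
                  file.path(dir, sheet$coverage_minus[i])))
  names(tracks) <- sheet$sample_id
  spikes <- rbindlist(lapply(seq_len(nrow(sheet)), function(i)
    cbind(sample_id = sheet$sample_id[i],
          read_spike_counts(file.path(dir, sheet$spike_counts[i])))))
  truth_dt <- fread(spike_truth_path, header = TRUE, sep = "\t")
  spike_truth <- setNames(truth_dt$input_mass, truth_dt$spike_id)
  capseq_experiment(sheet[, .(sample_id, condition, fraction, replicate)],
                    tracks, spikes, spike_truth)
}

#' Write an experiment to disk (sample sheet, bedGraph pairs, spike TSVs)
#' @param experiment a [capseq_experiment()]
#' @param outdir output directory, created if missing
#' @return invisibly, the sample sheet path
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- copy(experiment$samples)
  s[, `:=`(coverage_plus = paste0(sample_id, ".plus.bedgraph"),
           coverage_minus = paste0(sample_id, ".minus.bedgraph"),
           spike_counts = paste0(sample_id, ".spikes.tsv"))]
  for (i in seq_len(nrow(s))) {
    id <- s$sample_id[i]
    write_coverage(experiment$tracks[[id]],
                   file.path(outdir, s$coverage_plus[i]),
                   file.path(outdir, s$coverage_minus[i]))
    fwrite(experiment$spikes[sample_id == id, .(spike_id, reads)],
           file.path(outdir, s$spike_counts[i]), sep = "\t")
  }
  fwrite(s, file.path(outdir, "sample_sheet.tsv"), sep = "\t")
  fwrite(data.table(spike_id = names(experiment$spike_truth),
                    input_mass = unname(experiment$spike_truth)),
         file.path(outdir, "spike_truth.tsv"), sep = "\t")
  invisible(file.path(outdir, "sample_sheet.tsv"))
}
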