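## run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}

NT <- c("A", "C", "G", "T")
comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Configuration for a synthetic CapSeq experiment
#'
#' The defaults emulate the structure of the real experiment: mostly
#' single-promoter genes (about three quarters), a small TOP-promoter
#' class, an initiating-nucleotide mix of roughly 34/23/30/13 percent
#' A/C/G/T, pyrimidine-initiated transcripts translationally repressed
#' under stress, an overall mRNA drop of ~15%, and two capped spikes (GFP
#' at 0.25, luciferase at 0.001 input-mass units) in every fraction pool.
#'
#' @param n_genes number of simulated genes
#' @param promoters_per_gene_dist named probabilities over promoter counts
#'   (names are integers, e.g. `c("1"=.75, "2"=.17, "3"=.08)`)
#' @param tss_per_promoter TSS positions per promoter peak
#' @param frac_top_promoters proportion of promoters carrying a TOP (CYYYY)
#'   summit
#' @param baseline_expression_dist `c(meanlog=, sdlog=)` of per-promoter
#'   expected reads per sample trio
#' @param ro_basal_dist `c(meanlog=, sdlog=)` of per-gene basal ribosome
#'   occupancy
#' @param top_repression_fold fold by which TOP-promoter RO drops under
#'   stress (>= 1)
#' @param nucleotide_effect named multiplicative RO-effect modifier per
#'   initiating nucleotide
#' @param nt_freq initiating-nucleotide frequencies for non-TOP TSSs
#' @param global_mrna_drop proportional drop of total mRNA under stress
#' @param frac_diff_pairs fraction of multi-promoter genes given a planted
#'   differentially translated promoter pair
#' @param diff_pair_fold basal-RO fold separating a planted pair's promoters
#' @param spike_truth named spike input masses
#' @param spike_yield expected reads per spike input-mass unit at depth 1
#' @param depth_sdlog sdlog of the per-sample log-normal depth factors
#' @param noise_model negative-binomial overdispersion (variance =
#'   mu + noise_model * mu^2); 0 gives Poisson
#' @param n_replicates biological replicates per condition
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_genes = 200,
                       promoters_per_gene_dist = c("1" = 0.75, "2" = 0.17,
                                                   "3" = 0.08),
                       tss_per_promoter = 3,
                       frac_top_promoters = 0.045,
                       baseline_expression_dist = c(meanlog = log(2000),
                                                    sdlog = 1),
                       ro_basal_dist = c(meanlog = log(3), sdlog = 0.3),
                       top_repression_fold = 4,
                       nucleotide_effect = c(A = 1, C = 0.6, G = 1, T = 0.7),
                       nt_freq = c(A = 0.34, C = 0.23, G = 0.30, T = 0.13),
                       global_mrna_drop = 0.15,
                       frac_diff_pairs = 0.3,
                       diff_pair_fold = 4,
                       spike_truth = c(GFP = 0.25, LUC = 0.001),
                       spike_yield = 1e5,
                       depth_sdlog = 0.2,
                       noise_model = 0.05,
                       n_replicates = 2,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              promoters_per_gene_dist = promoters_per_gene_dist,
              tss_per_promoter = as.integer(tss_per_promoter),
              frac_top_promoters = frac_top_promoters,
              baseline_expression_dist = baseline_expression_dist,
              ro_basal_dist = ro_basal_dist,
              top_repression_fold = top_repression_fold,
              nucleotide_effect = nucleotide_effect,
              nt_freq = nt_freq,
              global_mrna_drop = global_mrna_drop,
              frac_diff_pairs = frac_diff_pairs,
              diff_pair_fold = diff_pair_fold,
              spike_truth = spike_truth,
              spike_yield = spike_yield,
              depth_sdlog = depth_sdlog,
              noise_model = noise_model,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  props <- c(cfg$frac_top_promoters, cfg$global_mrna_drop, cfg$frac_diff_pairs)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  pd <- cfg$promoters_per_gene_dist
  if (any(pd < 0) || abs(sum(pd) - 1) > 1e-9 ||
      any(is.na(suppressWarnings(as.integer(names(pd))))))
    stop("promoters_per_gene_dist must be integer-named probabilities summing to 1")
  if (any(cfg$nt_freq < 0) || abs(sum(cfg$nt_freq) - 1) > 1e-9 ||
      !identical(sort(names(cfg$nt_freq)), NT))
    stop("nt_freq must be A/C/G/T probabilities summing to 1")
  if (cfg$frac_top_promoters > 0 && cfg$nt_freq[["C"]] == 0)
    stop("contradictory config: TOP promoter summits must initiate with C, but nt_freq['C'] is 0")
  if (cfg$top_repression_fold < 1 || cfg$diff_pair_fold <= 0 ||
      any(cfg$nucleotide_effect <= 0))
    stop("folds and nucleotide effects must be positive (repression fold >= 1)")
  if (cfg$noise_model < 0) stop("noise_model (overdispersion) must be >= 0")
  if (cfg$n_genes < 1 || cfg$tss_per_promoter < 1 || cfg$n_replicates < 1)
    stop("counts must be positive")
  if (cfg$tss_per_promoter > 12)
    stop("at most 12 TSSs per promoter are supported")
  structure(cfg, class = "sim_config")
}

plant_base <- function(chars, pos, strand, base) {
  chars[pos + 1L] <- if (strand == "+") base else comp_base[[base]]
  chars
}

## read the sense-strand k-mer from a character genome vector
read_kmer <- function(chars, pos, strand, k) {
  if (strand == "+") {
    paste(chars[(pos + 1L):(pos + k)], collapse = "")
  } else {
    paste(unname(comp_base[chars[(pos + 1L):(pos - k + 2L)]]), collapse = "")
  }
}

#' Simulate a genome with promoter and transcript annotation
#'
#' Lays genes along one chromosome on alternating strands, each with 1-3
#' promoters of several TSS positions (one designated summit), one
#' transcript model per promoter whose 5' end sits at the summit, and a
#' CDS start downstream by a drawn spliced 5'UTR length (a fraction of
#' transcripts are two-exon with the intron inside the 5'UTR). The genome
#' sequence is random with initiating-nucleotide contexts planted at each
#' TSS; TOP-flagged promoters get a CYYYY summit 5-mer, and non-TOP
#' summits are guaranteed not to match it. Two extra contigs, GFP and LUC,
#' carry the spikes.
#'
#' @param config a [sim_config()]
#' @return list of class `capseq_annotation`: `genome` (named
#'   `DNAStringSet`), `promoters` (BED6-style table), `transcripts`
#'   ([read_transcripts()] layout), `tss` (per-TSS table with `weight`,
#'   `is_summit`, `first_nt`, `trinucleotide`, `pentamer`), `promoter_info`
#'   (per-promoter `summit`, `is_top`, `utr5_length` truth)
#' @export
simulate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    pd <- config$promoters_per_gene_dist
    n_prom_per_gene <- as.integer(names(pd))[
      sample.int(length(pd), config$n_genes, replace = TRUE, prob = pd)]
    prom_rows <- list(); tx_rows <- list(); tss_rows <- list()
    cur <- 0L
    block_per_prom <- 3000L
    for (g in seq_len(config$n_genes)) {
      np <- n_prom_per_gene[g]
      gene_id <- sprintf("g%04d", g)
      gstrand <- if (g %% 2L == 1L) "+" else "-"
      width_block <- np * block_per_prom + 1500L
      flip_pt <- function(p) if (gstrand == "+") cur + p else
        cur + width_block - 1L - p
      flip_iv <- function(s, e) if (gstrand == "+") c(cur + s, cur + e) else
        c(cur + width_block - e, cur + width_block - s)
      for (k in seq_len(np)) {
        a <- (k - 1L) * block_per_prom + 300L
        n_tss <- config$tss_per_promoter
        tss_local <- sort(a + (sample.int(12L, n_tss) - 1L) * 6L)
        summit_idx <- sample.int(n_tss, 1L)
        w <- if (n_tss == 1L) 1 else {
          x <- rep(0.4 / (n_tss - 1L), n_tss); x[summit_idx] <- 0.6; x
        }
        pid <- sprintf("%s_p%d", gene_id, k)
        iv <- flip_iv(min(tss_local) - 5L, max(tss_local) + 6L)
        prom_rows[[pid]] <- data.table(
          chrom = "chr1", start = iv[1L], end = iv[2L], strand = gstrand,
          promoter_id = pid, gene_id = gene_id, score = 0L)
        tss_rows[[pid]] <- data.table(
          chrom = "chr1", pos = vapply(tss_local, flip_pt, 0L),
          strand = gstrand, promoter_id = pid, gene_id = gene_id,
          weight = w, is_summit = seq_len(n_tss) == summit_idx)
        ## transcript in local plus-strand coordinates, then flipped
        summit_local <- tss_local[summit_idx]
        u <- sample(40:500, 1L)
        two_exon <- u > 40L && runif(1L) < 0.3
        if (two_exon) {
          e1 <- sample(10:(u - 10L), 1L)
          intron <- 200L
          cds_local <- summit_local + e1 + intron + (u - e1)
          tx_end_local <- cds_local + 600L
          ex_s <- c(summit_local, summit_local + e1 + intron)
          ex_e <- c(summit_local + e1, tx_end_local)
        } else {
          cds_local <- summit_local + u
          tx_end_local <- cds_local + 600L
          ex_s <- summit_local; ex_e <- tx_end_local
        }
        ivx <- flip_iv(summit_local, tx_end_local)
        exg <- Map(function(s, e) flip_iv(s, e), ex_s, ex_e)
        ex_starts <- sort(vapply(exg, `[`, 0L, 1L))
        ex_ends <- sort(vapply(exg, `[`, 0L, 2L))
        cds_g <- flip_pt(cds_local)
        thick <- if (gstrand == "+") c(cds_g, ivx[2L]) else c(ivx[1L], cds_g + 1L)
        tx_rows[[pid]] <- data.table(
          transcript_id = sprintf("%s_t%d", gene_id, k), gene_id = gene_id,
          chrom = "chr1", start = ivx[1L], end = ivx[2L], strand = gstrand,
          tss = flip_pt(summit_local), cds_start = cds_g,
          thick_start = thick[1L], thick_end = thick[2L],
          exon_starts = list(ex_starts), exon_ends = list(ex_ends),
          utr5_truth = u)
      }
      cur <- cur + width_block + 200L
    }
    promoters <- rbindlist(prom_rows)
    transcripts <- rbindlist(tx_rows)
    tss <- rbindlist(tss_rows)

    ## TOP designation
    n_prom <- nrow(promoters)
    if (config$frac_top_promoters > 0 && config$nt_freq[["C"]] == 0)
      stop("contradictory config: TOP promoter summits must initiate with C, but nt_freq['C'] is 0")
    n_top <- round(config$frac_top_promoters * n_prom)
    top_ids <- sample(promoters$promoter_id, n_top)
    tss[, is_top := promoter_id %in% top_ids]

    ## draw initiating contexts: full 5-mer at summits, first base elsewhere
    tss[, first_nt := sample(NT, .N, replace = TRUE, prob = config$nt_freq)]
    summit_kmers <- character(nrow(tss))
    for (i in which(tss$is_summit)) {
      if (tss$is_top[i]) {
        km <- c("C", sample(c("C", "T"), 4L, replace = TRUE))
      } else {
        km <- c(tss$first_nt[i], sample(NT, 4L, replace = TRUE))
        if (km[1L] == "C" && all(km[2:5] %in% c("C", "T")))
          km[1L + sample.int(4L, 1L)] <- sample(c("A", "G"), 1L)
      }
      summit_kmers[i] <- paste(km, collapse = "")
      tss$first_nt[i] <- km[1L]
    }

    ## build chr1 and plant contexts
    chars <- sample(NT, cur + 10L, replace = TRUE)
    for (i in seq_len(nrow(tss))) {
      if (tss$is_summit[i]) {
        km <- strsplit(summit_kmers[i], "")[[1L]]
        for (j in 0:4) {
          gp <- if (tss$strand[i] == "+") tss$pos[i] + j else tss$pos[i] - j
          chars <- plant_base(chars, gp, tss$strand[i], km[j + 1L])
        }
      } else {
        chars <- plant_base(chars, tss$pos[i], tss$strand[i], tss$first_nt[i])
      }
    }
    tss[, pentamer := vapply(seq_len(.N), function(i)
      read_kmer(chars, pos[i], strand[i], 5L), "")]
    tss[, trinucleotide := substr(pentamer, 1L, 3L)]
    stopifnot(identical(substr(tss$pentamer, 1L, 1L), tss$first_nt))

    genome <- Biostrings::DNAStringSet(c(
      chr1 = paste(chars, collapse = ""),
      GFP = paste(sample(NT, 600L, replace = TRUE), collapse = ""),
      LUC = paste(sample(NT, 600L, replace = TRUE), collapse = "")))

    promoter_info <- tss[is_summit == TRUE,
                         .(promoter_id, gene_id, summit = pos, strand,
                           is_top, summit_pentamer = pentamer)]
    promoter_info <- merge(promoter_info,
                           transcripts[, .(gene_id, transcript_id,
                                           tss, utr5_truth)],
                           by.x = c("gene_id", "summit"),
                           by.y = c("gene_id", "tss"), all.x = TRUE)
    structure(list(genome = genome, promoters = promoters,
                   transcripts = transcripts[, utr5_truth := NULL][],
                   tss = tss, promoter_info = promoter_info,
                   config = config),
              class = "capseq_annotation")
  })
}

draw_counts <- function(mu, phi, mode) {
  if (mode == "expectation") return(mu)
  if (phi > 0) rnbinom(length(mu), mu = mu, size = 1 / phi)
  else rpois(length(mu), mu)
}

#' Simulate CapSeq 5'-end counts over an annotation
#'
#' Draws per-gene basal ribosome occupancies and per-promoter expression,
#' plants differential alternative-promoter pairs and the stress response
#' (nucleotide effects, TOP repression, the global mRNA drop), splits each
#' TSS's mass across polysome fractions according to its RO, applies
#' per-sample depth factors, and emits coverage tracks, spike reads and the
#' ground truth. In `"expectation"` mode counts are exact real-valued
#' expectations (no sampling noise), for oracle tests.
#'
#' @param config a [sim_config()]
#' @param annotation from [simulate_genome_and_annotation()]
#' @param mode `"sample"` (negative-binomial / Poisson counts) or
#'   `"expectation"`
#' @return list with `experiment` (a [capseq_experiment()]) and `truth`:
#'   per-promoter table (`ro_control`, `ro_stress`, `ro_effect`,
#'   `mrna_change`, `is_top`, `expression`), per-TSS table (per-TSS RO
#'   effects and contexts), `pairs` (planted and true differential
#'   promoter pairs), and `depth_factors`
#' @export
simulate_capseq_counts <- function(config, annotation,
                                   mode = c("sample", "expectation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "capseq_annotation"))
  with_seed(config$seed + 1L, {
    tss <- copy(annotation$tss)
    proms <- annotation$promoters[, .(promoter_id, gene_id)]
    genes <- unique(proms$gene_id)

    ## basal RO per gene; planted differential pairs bump promoter 2+
    ro_gene <- setNames(rlnorm(length(genes),
                               config$ro_basal_dist[["meanlog"]],
                               config$ro_basal_dist[["sdlog"]]), genes)
    proms[, n_prom := .N, by = gene_id]
    multi <- unique(proms[n_prom >= 2L, gene_id])
    planted_genes <- multi[runif(length(multi)) < config$frac_diff_pairs]
    proms[, ro_basal := ro_gene[gene_id]]
    proms[gene_id %in% planted_genes,
          ro_basal := ro_basal *
            ifelse(seq_len(.N) == 2L, config$diff_pair_fold, 1),
          by = gene_id]
    proms[, expression := rlnorm(.N,
                                 config$baseline_expression_dist[["meanlog"]],
                                 config$baseline_expression_dist[["sdlog"]])]

    tss <- merge(tss, proms[, .(promoter_id, ro_basal, expression)],
                 by = "promoter_id", sort = FALSE)
    tss[, eff := config$nucleotide_effect[first_nt] /
          ifelse(is_top, config$top_repression_fold, 1)]
    tss[, `:=`(ro_control = ro_basal, ro_stress = ro_basal * eff)]

    ## promoter-level truth: expected fraction sums over the promoter's TSSs
    ptruth <- tss[, .(
      gene_id = gene_id[1L], is_top = is_top[1L],
      ro_control = sum(weight * ro_control / (1 + ro_control)) /
                   sum(weight / (1 + ro_control)),
      ro_stress = sum(weight * ro_stress / (1 + ro_stress)) /
                  sum(weight / (1 + ro_stress)),
      expression = expression[1L]), by = promoter_id]
    ptruth[, `:=`(ro_effect = ro_stress / ro_control,
                  mrna_change = 1 - config$global_mrna_drop)]

    samples <- CJ(condition = c("control", "stress"),
                  fraction = c("free", "light", "heavy"),
                  replicate = seq_len(config$n_replicates), sorted = FALSE)
    samples[, sample_id := sprintf("%s_%s_r%d", condition, fraction, replicate)]
    depth <- setNames(rlnorm(nrow(samples), 0, config$depth_sdlog),
                      samples$sample_id)

    tracks <- vector("list", nrow(samples))
    names(tracks) <- samples$sample_id
    spike_rows <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      cond <- samples$condition[i]; frac <- samples$fraction[i]
      ro_use <- if (cond == "control") tss$ro_control else tss$ro_stress
      mchange <- if (cond == "control") 1 else 1 - config$global_mrna_drop
      share <- switch(frac,
                      free = 1 / (1 + ro_use),
                      light = ro_use / (1 + ro_use) / 2,
                      heavy = ro_use / (1 + ro_use) / 2)
      mu <- tss$expression * tss$weight * mchange * share *
        depth[[samples$sample_id[i]]]
      cnt <- draw_counts(mu, config$noise_model, mode)
      tracks[[i]] <- coverage_track(tss$chrom, tss$pos, tss$strand, cnt)
      mu_sp <- config$spike_truth * config$spike_yield *
        depth[[samples$sample_id[i]]]
      ## spikes are technical controls: counting (Poisson) noise only,
      ## no biological overdispersion
      spike_rows[[i]] <- data.table(
        sample_id = samples$sample_id[i],
        spike_id = names(config$spike_truth),
        reads = draw_counts(unname(mu_sp), 0, mode))
    }

    ## truth for every unordered within-gene promoter pair
    pair_truth <- {
      pp <- ptruth[, .N, by = gene_id][N >= 2L, gene_id]
      if (length(pp)) rbindlist(lapply(pp, function(g) {
        ids <- sort(ptruth[gene_id == g, promoter_id])
        cmb <- utils::combn(ids, 2L)
        dt <- data.table(gene_id = g, p1 = cmb[1L, ], p2 = cmb[2L, ])
        r1c <- ptruth[match(dt$p1, promoter_id), ro_control]
        r2c <- ptruth[match(dt$p2, promoter_id), ro_control]
        r1s <- ptruth[match(dt$p1, promoter_id), ro_stress]
        r2s <- ptruth[match(dt$p2, promoter_id), ro_stress]
        dt[, `:=`(ratio_control = r1c / r2c, ratio_stress = r1s / r2s,
                  diff_control = pmax(r1c / r2c, r2c / r1c) >= 2,
                  diff_stress = pmax(r1s / r2s, r2s / r1s) >= 2,
                  planted = gene_id %in% planted_genes &
                    (p1 == paste0(g, "_p2") | p2 == paste0(g, "_p2")))]
        dt
      })) else data.table(gene_id = character(), p1 = character(),
                          p2 = character(), ratio_control = numeric(),
                          ratio_stress = numeric(), diff_control = logical(),
                          diff_stress = logical(), planted = logical())
    }

    experiment <- capseq_experiment(
      samples[, .(sample_id, condition, fraction, replicate)],
      tracks, rbindlist(spike_rows), config$spike_truth)
    list(experiment = experiment,
         truth = list(promoters = ptruth[],
                      tss = tss[, .(chrom, pos, strand, promoter_id, gene_id,
                                    weight, is_summit, is_top, first_nt,
                                    trinucleotide, pentamer,
                                    ro_control, ro_stress, eff)],
                      pairs = pair_truth,
                      depth_factors = depth,
                      samples = samples[]))
  })
}

#' Simulate a fluorescence titration
#'
#' Evaluates the depletion-corrected isotherm at the given ligand series
#' and adds i.i.d. Gaussian noise.
#'
#' @inheritParams isotherm
#' @param ligand_concs strictly increasing positive concentrations (nM)
#' @param noise_sd Gaussian noise SD in signal units (0 = noiseless)
#' @param seed optional RNG seed
#' @return a [titration_curve()]
#' @export
simulate_titration <- function(kd, f0, finf, protein_conc, ligand_concs,
                               noise_sd = 0, seed = NULL) {
  if (kd <= 0 || protein_conc < 0 || any(ligand_concs <= 0))
    stop("concentrations must be positive")
  backbone <- isotherm(kd, f0, finf, protein_conc, ligand_concs)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) with_seed(seed, rnorm(length(backbone), 0, noise_sd))
    else rnorm(length(backbone), 0, noise_sd)
  } else 0
  titration_curve(ligand_concs, backbone + noise, protein_conc)
}

#' Write a simulated annotation and experiment to disk
#'
#' Emits genome FASTA, promoter BED6, transcript BED12, per-sample stranded
#' bedGraph pairs, spike TSVs, sample sheet and ground-truth tables.
#'
#' @param annotation from [simulate_genome_and_annotation()]
#' @param sim from [simulate_capseq_counts()]
#' @param outdir output directory
#' @return invisibly, `outdir`
#' @export
write_simulation <- function(annotation, sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(annotation$genome,
                              file.path(outdir, "genome.fa"))
  write_promoters(annotation$promoters, file.path(outdir, "promoters.bed"))
  write_transcripts(annotation$transcripts,
                    file.path(outdir, "transcripts.bed12"))
  write_experiment(sim$experiment, outdir)
  fwrite(sim$truth$promoters, file.path(outdir, "truth_promoters.tsv"),
         sep = "\t")
  fwrite(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"), sep = "\t")
  invisible(outdir)
}
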