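library(data.table)

## random fraction-count table: genes of <= max_per_gene promoters, two
## conditions, two replicates, non-negative counts
random_fracs <- function(n_prom, max_per_gene = 3, max_count = 400) {
  gene_sizes <- integer(0)
  while (sum(gene_sizes) < n_prom)
    gene_sizes <- c(gene_sizes, sample.int(max_per_gene, 1L))
  gene_sizes[length(gene_sizes)] <- gene_sizes[length(gene_sizes)] -
    (sum(gene_sizes) - n_prom)
  gene_sizes <- gene_sizes[gene_sizes > 0L]
  gene_id <- rep(sprintf("g%03d", seq_along(gene_sizes)), gene_sizes)
  promoter_id <- paste0(gene_id, "_p", unlist(lapply(gene_sizes, seq_len)))
  grid <- CJ(condition = c("control", "stress"), replicate = 1:2)
  out <- rbindlist(lapply(seq_len(nrow(grid)), function(i)
    data.table(promoter_id, gene_id,
               condition = grid$condition[i], replicate = grid$replicate[i],
               free = runif(n_prom, 0, max_count),
               light = runif(n_prom, 0, max_count),
               heavy = runif(n_prom, 0, max_count))))
  out
}

## independent brute-force RO via plain arithmetic on one promoter/replicate
oracle_ro <- function(f, l, h, pc = 0.5) (l + pc + h + pc) / (f + pc)

## brute-force affected-promoter calls: nested loops over a tidy table
oracle_affected <- function(fracs, fold = 2, pc = 0.5) {
  res <- list()
  for (p in unique(fracs$promoter_id)) {
    effects <- c()
    for (r in unique(fracs$replicate)) {
      rc <- fracs[fracs$promoter_id == p & fracs$replicate == r &
                    fracs$condition == "control", ]
      rs <- fracs[fracs$promoter_id == p & fracs$replicate == r &
                    fracs$condition == "stress", ]
      effects <- c(effects, oracle_ro(rs$free, rs$light, rs$heavy, pc) /
                              oracle_ro(rc$free, rc$light, rc$heavy, pc))
    }
    dir <- "unaffected"
    if (all(effects <= 1 / fold)) dir <- "repressed"
    if (all(effects >= fold)) dir <- "induced"
    res[[p]] <- dir
  }
  unlist(res)
}

## brute-force differential AP-pair flags
oracle_pairs <- function(fracs, fold = 2, pc = 0.5) {
  out <- list()
  for (g in unique(fracs$gene_id)) {
    proms <- sort(unique(fracs$promoter_id[fracs$gene_id == g]))
    if (length(proms) < 2) next
    for (i in seq_len(length(proms) - 1)) for (j in (i + 1):length(proms)) {
      flags <- c(control = TRUE, stress = TRUE)
      for (cond in c("control", "stress")) {
        for (r in unique(fracs$replicate)) {
          a <- fracs[fracs$promoter_id == proms[i] & fracs$replicate == r &
                       fracs$condition == cond, ]
          b <- fracs[fracs$promoter_id == proms[j] & fracs$replicate == r &
                       fracs$condition == cond, ]
          ra <- oracle_ro(a$free, a$light, a$heavy, pc)
          rb <- oracle_ro(b$free, b$light, b$heavy, pc)
          if (max(ra / rb, rb / ra) < fold) flags[[cond]] <- FALSE
        }
      }
      out[[paste(g, proms[i], proms[j])]] <- flags
    }
  }
  out
}

## tiny in-memory experiment: one promoter-like locus per entry of `masses`,
## masses[[sample_id]] = named numeric of pos -> mass on chr1 plus strand
toy_experiment <- function(masses, spikes, spike_truth) {
  samples <- CJ(condition = c("control", "stress"),
                fraction = c("free", "light", "heavy"), replicate = 1:2)
  samples[, sample_id := sprintf("%s_%s_r%d", condition, fraction, replicate)]
  tracks <- lapply(samples$sample_id, function(id) {
    m <- masses[[id]]
    if (is.null(m)) coverage_track()
    else coverage_track("chr1", as.integer(names(m)), "+", m)
  })
  names(tracks) <- samples$sample_id
  capseq_experiment(samples, tracks, spikes, spike_truth)
}
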