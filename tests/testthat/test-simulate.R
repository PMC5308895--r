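test_that("the same seed reproduces FASTA and BED outputs byte for byte", {
  cfg <- sim_config(n_genes = 10, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    ann <- simulate_genome_and_annotation(cfg)
    sim <- simulate_capseq_counts(cfg, ann)
    write_simulation(ann, sim, d)
  }
  for (f in c("genome.fa", "promoters.bed", "transcripts.bed12",
              "control_free_r1.plus.bedgraph", "stress_heavy_r2.minus.bedgraph"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("forcing every promoter to be TOP plants CYYYY at every summit", {
  cfg <- sim_config(n_genes = 30, frac_top_promoters = 1, seed = 2)
  ann <- simulate_genome_and_annotation(cfg)
  expect_true(all(grepl("^C[CT]{4}", ann$promoter_info$summit_pentamer)))
  expect_true(all(ann$promoter_info$is_top))
})

test_that("contradictory TOP configuration is rejected with a message", {
  expect_error(sim_config(frac_top_promoters = 0.5,
                          nt_freq = c(A = 0.5, C = 0, G = 0.4, T = 0.1)),
               "initiate with C")
})

test_that("promoters-per-gene distribution is honored (binomial check)", {
  cfg <- sim_config(n_genes = 400,
                    promoters_per_gene_dist = c("1" = 0.75, "2" = 0.25),
                    seed = 9)
  ann <- simulate_genome_and_annotation(cfg)
  singletons <- ann$promoters[, .N, by = gene_id][N == 1L, .N]
  ## binomial oracle: 99% CI for the observed singleton count at p = 0.75
  ci <- qbinom(c(0.005, 0.995), 400, 0.75)
  expect_gte(singletons, ci[1])
  expect_lte(singletons, ci[2])
})

test_that("initiating-nucleotide frequencies match the configured mix", {
  cfg <- sim_config(n_genes = 300, seed = 13)
  ann <- simulate_genome_and_annotation(cfg)
  obs <- table(factor(ann$tss$first_nt, levels = c("A", "C", "G", "T")))
  ## TOP summits force extra C; restrict to non-TOP TSSs for the planted mix
  obs <- table(factor(ann$tss[is_top == FALSE, first_nt],
                      levels = c("A", "C", "G", "T")))
  p <- chisq.test(obs, p = c(0.34, 0.23, 0.30, 0.13))$p.value
  expect_gt(p, 0.01)
})

test_that("expectation-mode fraction split matches the RO identity exactly", {
  cfg <- sim_config(n_genes = 15, noise_model = 0, depth_sdlog = 0, seed = 4)
  ann <- simulate_genome_and_annotation(cfg)
  sim <- simulate_capseq_counts(cfg, ann, mode = "expectation")
  pq <- quantify_promoters(sim$experiment, ann$promoters)
  fm <- fraction_matrix(pq)
  ## F : (L+H) = 1 : RO for every promoter in both conditions
  ctrl <- fm[condition == "control" & replicate == 1L]
  ro <- sim$truth$promoters[match(ctrl$promoter_id, promoter_id), ro_control]
  expect_equal((ctrl$light + ctrl$heavy) / ctrl$free, ro, tolerance = 1e-12)
})

test_that("deep noisy simulation recovers a planted 4-fold RO effect within 10%", {
  cfg <- sim_config(n_genes = 12, promoters_per_gene_dist = c("1" = 1),
                    frac_top_promoters = 1, top_repression_fold = 4,
                    nucleotide_effect = c(A = 1, C = 1, G = 1, T = 1),
                    baseline_expression_dist = c(meanlog = log(2e5),
                                                 sdlog = 0.1),
                    ro_basal_dist = c(meanlog = log(4), sdlog = 0),
                    noise_model = 0, depth_sdlog = 0, seed = 21)
  ann <- simulate_genome_and_annotation(cfg)
  sim <- simulate_capseq_counts(cfg, ann)   # Poisson noise at high depth
  st <- translation_stats(fraction_matrix(quantify_promoters(sim$experiment,
                                                             ann$promoters)))
  expect_true(all(abs(st$ro_effect - 0.25) / 0.25 < 0.1))
})

test_that("the global mRNA drop propagates to summed expected masses", {
  cfg <- sim_config(n_genes = 25, global_mrna_drop = 0.15, noise_model = 0,
                    depth_sdlog = 0, seed = 6)
  ann <- simulate_genome_and_annotation(cfg)
  sim <- simulate_capseq_counts(cfg, ann, mode = "expectation")
  fm <- fraction_matrix(quantify_promoters(sim$experiment, ann$promoters))
  g <- global_fraction_sums(fm)
  ratio <- g[condition == "stress", free + light + heavy] /
    g[condition == "control", free + light + heavy]
  expect_equal(ratio, 0.85, tolerance = 1e-9)
})

test_that("read mass is conserved: track totals = promoter counts + spikes", {
  cfg <- sim_config(n_genes = 10, seed = 8)
  ann <- simulate_genome_and_annotation(cfg)
  sim <- simulate_capseq_counts(cfg, ann)
  fm <- fraction_matrix(quantify_promoters(sim$experiment, ann$promoters))
  for (i in seq_len(nrow(sim$experiment$samples))) {
    id <- sim$experiment$samples$sample_id[i]
    cond <- sim$experiment$samples$condition[i]
    fr <- sim$experiment$samples$fraction[i]
    rep <- sim$experiment$samples$replicate[i]
    in_promoters <- sum(fm[condition == cond & replicate == rep][[fr]])
    expect_equal(sum(sim$experiment$tracks[[id]]$mass), in_promoters)
  }
})

test_that("titration simulation is a deterministic backbone plus seeded noise", {
  concs <- 10^seq(0, 4, length.out = 12)
  clean <- simulate_titration(561, 1, 0.4, 300, concs)
  expect_equal(clean$fluorescence,
               isotherm(561, 1, 0.4, 300, concs))
  n1 <- simulate_titration(561, 1, 0.4, 300, concs, noise_sd = 0.01, seed = 1)
  n1b <- simulate_titration(561, 1, 0.4, 300, concs, noise_sd = 0.01, seed = 1)
  n2 <- simulate_titration(561, 1, 0.4, 300, concs, noise_sd = 0.01, seed = 2)
  expect_identical(n1$fluorescence, n1b$fluorescence)
  expect_false(identical(n1$fluorescence, n2$fluorescence))
  expect_error(simulate_titration(561, 1, 0.4, 300, c(-1, 2, 3, 4, 5)),
               "positive")
})

test_that("half-saturation: at L = Kd with vanishing protein, signal is midway", {
  f <- isotherm(kd = 100, f0 = 1, finf = 0.4, protein_conc = 1e-9,
                ligand_conc = 100)
  expect_equal(f, (1 + 0.4) / 2, tolerance = 1e-6)
})
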