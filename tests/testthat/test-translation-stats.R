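test_that("ribosome occupancy follows the pseudo-counted (L+H)/F formula", {
  expect_equal(compute_ro(100, 150, 250), (150.5 + 250.5) / 100.5)
  expect_equal(round(compute_ro(100, 150, 250), 3), 3.990)
  expect_equal(compute_ro(0, 0, 0), 2.0)          # finite on empty promoter
  ## at large counts the pseudo-count vanishes: ratio tends to (L+H)/F
  expect_equal(compute_ro(100e3, 150e3, 250e3), 4.0, tolerance = 1e-4)
  expect_equal(compute_ro(1, 2, 3, pseudocount = 0), 5)
  expect_error(compute_ro(-1, 0, 0), ">= 0")
})

test_that("RO effect and mRNA change are the stated quotients", {
  expect_equal(compute_ro_effect(1.0, 4.0), 0.25)
  expect_equal(compute_mrna_change(10, 20, 30, 10, 20, 30), 1.0)
  ## control totals 1000, stress totals 850: pseudo-count is negligible
  expect_equal(compute_mrna_change(300, 300, 250, 400, 350, 250), 0.85,
               tolerance = 0.01)
})

test_that("RO is scale-invariant without pseudo-count and monotone in fractions", {
  withr::local_seed(3)
  for (i in 1:20) {
    x <- runif(3, 1, 500); c <- runif(1, 0.1, 10)
    expect_equal(compute_ro(x[1] * c, x[2] * c, x[3] * c, pseudocount = 0),
                 compute_ro(x[1], x[2], x[3], pseudocount = 0))
    ## with pseudo-count, large counts make scaling nearly invariant
    big <- x * 1e6
    expect_equal(compute_ro(big[1] * c, big[2] * c, big[3] * c),
                 compute_ro(big[1], big[2], big[3]), tolerance = 1e-4)
    expect_gt(compute_ro(x[1], x[2], x[3] + 1), compute_ro(x[1], x[2], x[3]))
    expect_lt(compute_ro(x[1] + 1, x[2], x[3]), compute_ro(x[1], x[2], x[3]))
  }
})

test_that("affected calls need the fold in every replicate, bounds inclusive", {
  mk <- function(e1, e2) data.table(promoter_id = "p", replicate = 1:2,
                                    ro_effect = c(e1, e2))
  expect_equal(call_affected(mk(0.40, 0.45))$direction, "repressed")
  expect_equal(call_affected(mk(0.40, 0.60))$direction, "unaffected")
  expect_equal(call_affected(mk(2.0, 2.0))$direction, "induced")
  expect_equal(call_affected(mk(0.5, 0.5))$direction, "repressed")
})

test_that("pair flags apply the two-fold rule per replicate and are symmetric", {
  mk_fracs <- function(ro1, ro2) {
    ## free=100 fixed, polysomal mass chosen so that RO (pseudo-count 0) = ro
    rbindlist(lapply(1:2, function(r)
      data.table(promoter_id = c("g_p1", "g_p2"), gene_id = "g",
                 condition = rep(c("control", "stress"), each = 2),
                 replicate = r, free = 100,
                 light = 50 * c(ro1[r], ro2[r], ro1[r], ro2[r]),
                 heavy = 50 * c(ro1[r], ro2[r], ro1[r], ro2[r]))))
  }
  pairs <- call_differential_pairs(mk_fracs(c(4.0, 4.2), c(1.5, 1.9)),
                                   pseudocount = 0)
  expect_true(pairs$diff_control)
  pairs2 <- call_differential_pairs(mk_fracs(c(4.0, 4.0), c(2.1, 1.9)),
                                    pseudocount = 0)
  expect_false(pairs2$diff_control)   # replicate 1 ratio 1.90 < 2
  ## swapping the promoters flips the ratio but not the flag
  pairs_sw <- call_differential_pairs(mk_fracs(c(1.5, 1.9), c(4.0, 4.2)),
                                      pseudocount = 0)
  expect_equal(pairs_sw$diff_control, pairs$diff_control)
  expect_equal(pairs_sw$ro_ratio_control, 1 / pairs$ro_ratio_control)
})

test_that("affected and pair calls match the brute-force oracle", {
  withr::local_seed(17)
  for (i in 1:10) {
    fracs <- random_fracs(n_prom = sample(10:60, 1))
    st <- translation_stats(fracs)
    imp <- call_affected(st)
    ora <- oracle_affected(as.data.frame(fracs))
    expect_equal(setNames(imp$direction, imp$promoter_id), ora[imp$promoter_id])
    pairs <- call_differential_pairs(fracs)
    ora_p <- oracle_pairs(as.data.frame(fracs))
    if (nrow(pairs)) {
      keys <- paste(pairs$gene_id, pairs$p1, pairs$p2)
      expect_equal(pairs$diff_control,
                   vapply(ora_p[keys], `[[`, TRUE, "control"),
                   ignore_attr = TRUE)
      expect_equal(pairs$diff_stress,
                   vapply(ora_p[keys], `[[`, TRUE, "stress"),
                   ignore_attr = TRUE)
    }
  }
})

test_that("percent increase reproduces simple count arithmetic", {
  expect_equal(percent_increase(100, 100), 0)
  expect_equal(percent_increase(200, 300), 50)
  expect_equal(percent_increase(40, 30), -25)
})

test_that("promoter assignment honors the 100 nt window and spliced 5'UTRs", {
  tx <- data.table(transcript_id = c("t_long", "t_short"), gene_id = "g",
                   chrom = "chr1", start = c(1000L, 1404L),
                   end = c(2200L, 2200L), strand = "+",
                   tss = c(1000L, 1404L), cds_start = 1467L,
                   thick_start = 1467L, thick_end = 2100L,
                   exon_starts = list(1000L, 1404L),
                   exon_ends = list(2200L, 2200L))
  summits <- data.table(promoter_id = c("p1", "p2", "p3"), chrom = "chr1",
                        summit = c(1000L, 1404L, 700L), strand = "+")
  asn <- assign_promoters(summits, tx)
  expect_equal(asn[promoter_id == "p1", .(relation, utr5_length)],
               data.table(relation = "annotated", utr5_length = 467L))
  expect_equal(asn[promoter_id == "p2", .(relation, utr5_length)],
               data.table(relation = "annotated", utr5_length = 63L))
  ## 300 nt from the 5' end, upstream of the transcript: unassigned
  expect_equal(asn[promoter_id == "p3", relation], "unassigned")
  ## 150 nt downstream of the long 5' end, inside its 5'UTR exon: exonic
  asn2 <- assign_promoters(data.table(promoter_id = "pe", chrom = "chr1",
                                      summit = 1150L, strand = "+"),
                           tx[1])
  expect_equal(asn2$relation, "exonic")
  expect_equal(asn2$utr5_length, 1467L - 1150L)
  ## a summit downstream of the CDS start has no defined 5'UTR
  asn3 <- assign_promoters(data.table(promoter_id = "pd", chrom = "chr1",
                                      summit = 1500L, strand = "+"),
                           tx[2])
  expect_true(is.na(asn3$utr5_length))
  ## other-strand transcripts never match
  asn4 <- assign_promoters(data.table(promoter_id = "pm", chrom = "chr1",
                                      summit = 1000L, strand = "-"), tx)
  expect_equal(asn4$relation, "unassigned")
})

test_that("same-ORF flags compare the assigned transcripts' CDS starts", {
  tx <- data.table(transcript_id = c("tA", "tB"), gene_id = "g",
                   chrom = "chr1", start = c(100L, 300L), end = 1000L,
                   strand = "+", tss = c(100L, 300L),
                   cds_start = c(500L, 500L), thick_start = 500L,
                   thick_end = 900L,
                   exon_starts = list(100L, 300L), exon_ends = list(1000L, 1000L))
  asn <- assign_promoters(data.table(promoter_id = c("g_p1", "g_p2"),
                                     chrom = "chr1", summit = c(100L, 300L),
                                     strand = "+"), tx)
  pairs <- data.table(gene_id = "g", p1 = "g_p1", p2 = "g_p2")
  expect_true(flag_same_orf(pairs, asn, tx)$same_orf)
  tx2 <- copy(tx)[2, `:=`(cds_start = 700L, thick_start = 700L)]
  expect_false(flag_same_orf(pairs, asn, tx2)$same_orf)
})

test_that("global fraction sums are element-wise with unit proportions", {
  fracs <- data.table(promoter_id = c("p1", "p2"), gene_id = c("a", "b"),
                      condition = "control", replicate = 1L,
                      free = c(1, 9), light = c(2, 8), heavy = c(3, 7))
  fracs <- rbind(fracs, copy(fracs)[, condition := "stress"])
  g <- global_fraction_sums(fracs)
  expect_equal(g[condition == "control", c(free, light, heavy)], c(10, 10, 10))
  expect_equal(g[, free_prop + light_prop + heavy_prop], c(1, 1))
  expect_equal(nrow(global_fraction_sums(fracs[0])), 0L)
  sub <- top_subset_sums(fracs, "p1")
  expect_equal(sub[condition == "control", c(free, light, heavy)], c(1, 2, 3))
})
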