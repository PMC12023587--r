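cfg <- caller_config()

test_that("TMB counts VAF-passing nonsynonymous calls per panel megabase", {
  expect_equal(compute_tmb(make_variant("S1")[0, ],
                           caller_config(panel_size_mb = 1)), 0)
  v50 <- do.call(rbind, replicate(50, make_variant("S1", vaf = 0.2),
                                  simplify = FALSE))
  expect_equal(compute_tmb(v50, caller_config(panel_size_mb = 0.5)), 100)
  ## 10 variants, 4 below the 5% sensitivity
  v10 <- rbind(do.call(rbind, replicate(6, make_variant("S1", vaf = 0.10),
                                        simplify = FALSE)),
               do.call(rbind, replicate(4, make_variant("S1", vaf = 0.03),
                                        simplify = FALSE)))
  expect_equal(compute_tmb(v10, caller_config(panel_size_mb = 1)), 6)
  ## synonymous calls never count
  syn <- make_variant("S1", consequence = "synonymous", vaf = 0.4)
  expect_equal(compute_tmb(syn, caller_config(panel_size_mb = 1)), 0)
  expect_error(caller_config(panel_size_mb = 0), class = "ec_config_error")
})

test_that("POLE positivity needs a listed hotspot or EDM variant + ultramutation", {
  hot <- make_variant("S1", gene = "POLE", hgvs_p = "p.P286R", vaf = 0.25)
  expect_true(assess_pole(hot, tmb = 1, cfg))
  syn <- make_variant("S1", gene = "POLE", hgvs_p = "p.L100L",
                      consequence = "synonymous", vaf = 0.3)
  expect_false(assess_pole(syn, tmb = 5, cfg))
  ## unlisted exonuclease-domain missense qualifies only when ultramutated
  edm <- make_variant("S1", gene = "POLE", hgvs_p = "p.T278M", vaf = 0.3)
  expect_true(assess_pole(edm, tmb = 150, cfg))
  expect_false(assess_pole(edm, tmb = 50, cfg))
  ## outside the domain: never via the ultramutated clause
  out <- make_variant("S1", gene = "POLE", hgvs_p = "p.K777N", vaf = 0.3)
  expect_false(assess_pole(out, tmb = 150, cfg))
  ## below the VAF filter the hotspot does not count
  low <- make_variant("S1", gene = "POLE", hgvs_p = "p.P286R", vaf = 0.03)
  expect_false(assess_pole(low, tmb = 150, cfg))
  expect_false(assess_pole(hot[0, ], tmb = 150, cfg))
})

test_that("TP53 status requires a protein-altering, VAF-passing call", {
  expect_true(assess_tp53(make_variant("S1", gene = "TP53",
                                       hgvs_p = "p.R273H", vaf = 0.4), cfg))
  expect_false(assess_tp53(make_variant("S1", gene = "TP53",
                                        consequence = "synonymous", vaf = 0.4), cfg))
  expect_false(assess_tp53(make_variant("S1", gene = "KRAS", vaf = 0.4), cfg))
  expect_false(assess_tp53(make_variant("S1", gene = "TP53", vaf = 0.02), cfg))
})

test_that("locus instability uses the novel-read fraction with a strict boundary", {
  expect_false(score_locus_instability(make_locus(), cfg))
  ## 30 of 100 reads at unsupported lengths
  unstable <- make_locus(observed = c(`10` = 3, `11` = 14, `12` = 35,
                                      `13` = 14, `14` = 4, `6` = 18, `5` = 12))
  expect_true(score_locus_instability(unstable, cfg))
  ## exactly at the threshold: stable
  at_tau <- make_locus(observed = c(`12` = 90, `5` = 10))
  expect_false(score_locus_instability(at_tau, cfg))
  just_over <- make_locus(observed = c(`12` = 89, `5` = 11))
  expect_true(score_locus_instability(just_over, cfg))
  expect_error(score_locus_instability(make_locus(observed = c(`12` = 0)), cfg),
               class = "ec_evaluability_error")
})

test_that("locus instability is invariant to rescaling read counts", {
  set.seed(11)
  for (i in 1:25) {
    obs <- stats::setNames(rpois(7, 12), c(10:14, 5, 6))
    obs["12"] <- obs["12"] + 20
    locus <- make_locus(observed = obs)
    base <- score_locus_instability(locus, cfg)
    for (s in c(0.5, 3, 17)) {
      scaled <- locus
      scaled$observed_hist <- obs * s
      expect_identical(score_locus_instability(scaled, cfg), base)
    }
  }
})

test_that("sample-level MSI combines locus fraction with hypermutation", {
  stable <- make_locus()
  unstable <- make_locus(observed = c(`12` = 60, `5` = 40))
  loci <- function(n_unstable, n_total) {
    c(replicate(n_unstable, unstable, simplify = FALSE),
      replicate(n_total - n_unstable, stable, simplify = FALSE))
  }
  expect_equal(call_msi(loci(10, 25), tmb = 20, cfg), "MSI-H")
  ## instability without hypermutation is not MSI-H
  expect_equal(call_msi(loci(10, 25), tmb = 5, cfg), "MSI-L")
  expect_equal(call_msi(loci(3, 25), tmb = 20, cfg), "MSI-L")
  expect_equal(call_msi(loci(0, 25), tmb = 20, cfg), "MSS")
  expect_error(call_msi(list(), tmb = 0, cfg), class = "ec_evaluability_error")
  ## zero-read loci are skipped with a warning, not counted in the denominator
  dead <- make_locus(observed = c(`12` = 0))
  expect_warning(res <- call_msi(c(loci(1, 2), list(dead)), tmb = 20, cfg),
                 "no observed reads")
  expect_equal(res, "MSI-H")  # 1/2 scoreable loci unstable
})

test_that("adding an unstable locus never moves MSI toward MSS", {
  rank <- c(MSS = 1, `MSI-L` = 2, `MSI-H` = 3)
  stable <- make_locus()
  unstable <- make_locus(observed = c(`12` = 60, `5` = 40))
  for (k in 0:9) {
    loci <- c(replicate(k, unstable, simplify = FALSE),
              replicate(10 - k, stable, simplify = FALSE))
    before <- call_msi(loci, tmb = 20, cfg)
    after <- call_msi(c(loci, list(unstable)), tmb = 20, cfg)
    expect_gte(rank[after], rank[before])
  }
})

test_that("raising a VAF above the filter never lowers TMB", {
  set.seed(3)
  v <- do.call(rbind, lapply(1:12, function(i) {
    make_variant("S1", vaf = runif(1, 0.01, 0.6))
  }))
  base <- compute_tmb(v, cfg)
  for (i in seq_len(nrow(v))) {
    raised <- v
    raised$vaf[i] <- 0.5
    expect_gte(compute_tmb(raised, cfg), base)
  }
})

test_that("FGA is length-weighted and matches base-by-base enumeration", {
  flat <- data.frame(sample_id = "S", chrom = "chr1", start = 0, end = 1e6,
                     log2_ratio = 0.1)
  expect_equal(compute_fga(flat, cfg), 0)
  half <- data.frame(sample_id = "S", chrom = c("chr1", "chr2"),
                     start = 0, end = c(1e6, 1e6), log2_ratio = c(0.9, 0))
  expect_equal(compute_fga(half, cfg), 0.5)
  expect_equal(compute_fga(half[0, ], cfg), 0)

  ## five mixed segments at 1 bp resolution: brute-force oracle
  seg <- data.frame(sample_id = "S", chrom = "chr1",
                    start = c(0, 100, 400, 450, 800),
                    end = c(100, 400, 450, 800, 1000),
                    log2_ratio = c(0.5, -0.1, -0.8, 0.31, 0.3))
  bases <- rep(seg$log2_ratio, seg$end - seg$start)
  oracle <- mean(abs(bases) > cfg$fga_log2_threshold)
  expect_equal(compute_fga(seg, cfg), oracle)
})

test_that("FGA is invariant to splitting a segment into equal-ratio pieces", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    ends <- sort(sample(seq(1000, 99000, by = 1000), k - 1))
    seg <- data.frame(sample_id = "S", chrom = "chr1",
                      start = c(0, 50000), end = c(50000, 100000),
                      log2_ratio = round(runif(2, -1, 1), 3))
    cuts <- c(0, ends[ends < 50000], 50000)
    split1 <- data.frame(sample_id = "S", chrom = "chr1",
                         start = cuts[-length(cuts)], end = cuts[-1],
                         log2_ratio = seg$log2_ratio[1])
    combined <- rbind(split1, seg[2, ])
    expect_equal(compute_fga(combined, cfg), compute_fga(seg, cfg))
  }
})

test_that("the copy-number rule routes TP53 and FGA as configured", {
  expect_equal(classify_cn(TRUE, 0, cfg), "CNH")
  expect_equal(classify_cn(FALSE, 0.05, cfg), "CNL")
  expect_equal(classify_cn(FALSE, 0.35, cfg), "CNH")
  tp53_only <- caller_config(cn_rule = "tp53_only")
  expect_equal(classify_cn(FALSE, 0.35, tp53_only), "CNL")
  expect_equal(classify_cn(TRUE, 0.35, tp53_only), "CNH")
  ## boundary: >= at the sample-level FGA threshold
  expect_equal(classify_cn(FALSE, 0.2, cfg), "CNH")
})

test_that("a quiet sample yields the neutral marker profile", {
  prof <- marker_profile(make_variant("S1")[0, ],
                         replicate(5, make_locus(), simplify = FALSE),
                         data.frame(sample_id = "S1", chrom = "chr1",
                                    start = 0, end = 1e6, log2_ratio = 0)[0, ],
                         cfg)
  expect_false(prof$pole_positive)
  expect_false(prof$tp53_mutated)
  expect_equal(prof$tmb, 0)
  expect_equal(prof$msi_status, "MSS")
  expect_equal(prof$fga, 0)
})

test_that("vectorized cohort profiling agrees with per-sample calls", {
  cohort <- generate_cohort(light_sim_config(n_samples = 40), seed = 9)
  prof <- profile_cohort(cohort, cfg)
  for (id in sample_ids(cohort)[c(1, 7, 20, 40)]) {
    v <- cohort$variants[cohort$variants$sample_id == id, ]
    seg <- cohort$segments[cohort$segments$sample_id == id, ]
    single <- marker_profile(v, msi_loci_for_sample(cohort, id), seg, cfg)
    row <- prof[prof$sample_id == id, ]
    expect_equal(row$pole_positive, single$pole_positive)
    expect_equal(row$tp53_mutated, single$tp53_mutated)
    expect_equal(row$tmb, single$tmb)
    expect_equal(row$msi_status, single$msi_status)
    expect_equal(row$fga, single$fga)
  }
})

test_that("caller configuration round-trips through JSON", {
  custom <- caller_config(vaf_min = 0.1, cn_rule = "tp53_only",
                          gene_vaf_min = list(KRAS = 0.01))
  path <- withr::local_tempfile(fileext = ".json")
  write_caller_config(custom, path)
  back <- read_caller_config(path)
  expect_equal(unclass(back), unclass(custom))
  expect_error(caller_config(msi_l_locus_fraction = 0.4,
                             msi_h_locus_fraction = 0.3),
               class = "ec_config_error")
})
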