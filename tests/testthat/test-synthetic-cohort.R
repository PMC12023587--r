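test_that("generation is reproducible and restores the session RNG", {
  set.seed(777)
  state <- .Random.seed
  a <- generate_cohort(light_sim_config(n_samples = 50), seed = 3)
  expect_identical(.Random.seed, state)
  b <- generate_cohort(light_sim_config(n_samples = 50), seed = 3)
  expect_identical(a, b)
  c <- generate_cohort(light_sim_config(n_samples = 50), seed = 4)
  expect_false(identical(a$variants, c$variants))
})

test_that("degenerate proportions plant a single subtype", {
  co <- generate_cohort(light_sim_config(n_samples = 30,
                                         subtype_proportions = c(1, 0, 0, 0)),
                        seed = 2)
  expect_true(all(co$truth$subtype == "POLE"))
  cls <- classify_cohort(co)
  expect_true(all(cls$subtype == "POLE"))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(subtype_proportions = c(0.5, 0.2, 0.2, 0.2)),
               class = "ec_config_error")
  expect_error(simulation_config(subtype_proportions = c(1, 0, 0)),
               class = "ec_config_error")
  expect_error(simulation_config(cnh_median_os = -3), class = "ec_config_error")
  expect_error(simulation_config(censor_window = c(10, 5)),
               class = "ec_config_error")
  expect_error(generate_cohort(list(n_samples = 10), seed = 1),
               class = "ec_config_error")
})

test_that("subtype counts follow the configured multinomial in expectation", {
  cfg <- light_sim_config(n_samples = 233)
  counts <- matrix(0, 200, 4,
                   dimnames = list(NULL, c("POLE", "MSI-H", "CNH", "CNL")))
  for (s in 1:200) {
    co <- generate_cohort(cfg, seed = 5000 + s)
    tab <- table(factor(co$truth$subtype,
                        levels = c("POLE", "MSI-H", "CNH", "CNL")))
    counts[s, ] <- as.integer(tab)
  }
  means <- colMeans(counts)
  expect_true(all(abs(means - c(19, 44, 27, 143)) <= 1))
})

test_that("generated cohorts round-trip losslessly through the writers", {
  co <- generate_cohort(light_sim_config(n_samples = 40), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort_dir(dir)
  expect_identical(back$clinical, co$clinical)
  expect_identical(back$variants, co$variants)
  expect_identical(back$msi, co$msi)
  expect_identical(back$segments, co$segments)
  expect_identical(back$gene_mutations, co$gene_mutations)
  expect_identical(back$truth, co$truth)
})

test_that("the generated follow-up matches the emulated study's availability", {
  co <- generate_cohort(simulation_config(n_samples = 2000), seed = 21)
  avail <- mean(!is.na(co$clinical$os_months))
  expect_equal(avail, 131 / 233, tolerance = 0.08)
  obs <- co$clinical$os_months[!is.na(co$clinical$os_months)]
  expect_true(all(obs >= 0 & obs <= 122))
  ## disease-specific deaths are a subset of deaths
  dss1 <- !is.na(co$clinical$dss_event) & co$clinical$dss_event == 1
  expect_true(all(co$clinical$os_event[dss1] == 1))
})

test_that("a planted biomarker log-hazard is recovered by Cox regression", {
  ## event-rich configuration so the partial likelihood is well conditioned:
  ## equal CNL/MSI-H baselines, ZFHX4 prevalence 0.5, planted log-HR = 1
  cfg <- simulation_config(
    n_samples = 2000, os_available_fraction = 1,
    surv_10yr = c(POLE = 0.99, `MSI-H` = 0.35, CNL = 0.35),
    arid1a_hr = 1, zfhx4_hr = exp(1),
    gene_prevalence = list(`MSI-H` = c(ARID1A = 0.2, ZFHX4 = 0.5),
                           CNL = c(ARID1A = 0.2, ZFHX4 = 0.5)),
    n_msi_loci = 4, msi_reads_per_locus = 40)
  co <- generate_cohort(cfg, seed = 33)
  sel <- co$truth$subtype %in% c("CNL", "MSI-H")
  ids <- co$truth$sample_id[sel]
  mat <- mutation_matrix(co)
  clin <- co$clinical[match(ids, co$clinical$sample_id), ]
  fit <- cox_ph(cbind(zfhx4 = mat[ids, "ZFHX4"]),
                clin$os_months, clin$os_event)
  expect_true(fit$converged)
  expect_lt(abs(fit$table$log_hr - 1), 0.15)
})

test_that("unknown fixtures are rejected and known ones are deterministic", {
  expect_error(load_fixture("nope"), class = "ec_validation_error")
  expect_identical(load_fixture("fig4"), load_fixture("fig4"))
  expect_identical(load_fixture("table1"), load_fixture("table1"))
})

test_that("the table1 fixture reproduces every printed cross-tab cell", {
  t1 <- load_fixture("table1")
  s <- summarize_cohort(t1, t1$truth$subtype)
  expect_equal(s$n_total, 233)
  expect_equal(s$subtypes$count[match(c("POLE", "MSI-H", "CNH", "CNL"),
                                      s$subtypes$subtype)],
               c(19, 44, 27, 143))
  st <- s$cross_tabs$stage
  expect_equal(unname(st[c("POLE", "MSI-H", "CNH", "CNL"), "I"]),
               c(16, 26, 12, 103))
  expect_equal(unname(st[c("POLE", "MSI-H", "CNH", "CNL"), "II"]),
               c(0, 6, 3, 8))
  expect_equal(unname(st[c("POLE", "MSI-H", "CNH", "CNL"), "III"]),
               c(2, 6, 8, 18))
  expect_equal(unname(st[c("POLE", "MSI-H", "CNH", "CNL"), "IV"]),
               c(0, 0, 1, 2))
  expect_equal(unname(st[c("POLE", "MSI-H", "CNH", "CNL"), "unknown"]),
               c(1, 6, 3, 12))
  lv <- s$cross_tabs$lvsi
  expect_equal(unname(lv[c("POLE", "MSI-H", "CNH", "CNL"), "yes"]),
               c(2, 1, 5, 5))
  expect_equal(sum(lv[, "yes"]), 13)
  hist <- s$cross_tabs$histology
  expect_equal(unname(hist[c("POLE", "MSI-H", "CNH", "CNL"), "endometrioid"]),
               c(15, 34, 15, 119))
  expect_equal(sum(hist[, "serous"]), 11)
  gr <- s$cross_tabs$grade
  expect_equal(unname(gr[c("POLE", "MSI-H", "CNH", "CNL"), "G1"]),
               c(9, 12, 4, 72))
  expect_equal(unname(gr[c("POLE", "MSI-H", "CNH", "CNL"), "G3"]),
               c(6, 11, 14, 14))
  ## printed marginal percentages at the full-cohort denominator
  expect_equal(s$subtypes$percent[match(c("POLE", "MSI-H", "CNH", "CNL"),
                                        s$subtypes$subtype)],
               c(8.15, 18.88, 11.59, 61.37))
})

test_that("the 39-sample composition is the unique solution of the search", {
  comp <- derive_fig4_composition()
  expect_equal(comp$n_deceased, 13L)
  expect_equal(comp$n_surviving, 26L)
  expect_equal(comp$arid1a_deceased, 7L)
  expect_equal(comp$arid1a_surviving, 8L)
  expect_equal(comp$zfhx4_deceased, 4L)

  ## independent brute force over all splits and counts
  r1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10
  sols <- list()
  for (d in 1:38) {
    s <- 39 - d
    if (r1(100 * 4 / d) != 30.8) next
    for (ad in 0:d) {
      if (r1(100 * ad / d) != 53.8) next
      for (as_ in 0:s) {
        if (r1(100 * as_ / s) != 30.8) next
        sols[[length(sols) + 1]] <- c(d, ad, as_)
      }
    }
  }
  expect_equal(length(sols), 1)
  expect_equal(sols[[1]], c(13, 7, 8))

  f4 <- load_fixture("fig4")
  expect_equal(sum(f4$clinical$vital_status == "deceased"), 13)
  expect_equal(table(f4$truth$subtype)[["CNL"]], 27)
  expect_equal(table(f4$truth$subtype)[["MSI-H"]], 12)
})
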