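## Shared builders for small in-code fixtures.

make_variant <- function(sample_id = "S1", gene = "PTEN", hgvs_p = "",
                         consequence = "missense", vaf = 0.30,
                         chrom = "chr1", pos = 1000L, ref = "A", alt = "G") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, hgvs_p = hgvs_p,
             consequence = consequence, vaf = vaf, stringsAsFactors = FALSE)
}

make_variants <- function(...) do.call(rbind, list(...))

## A locus object for score_locus_instability(): named histograms keyed by
## repeat length.
make_locus <- function(baseline = c(`10` = 0.05, `11` = 0.2, `12` = 0.5,
                                    `13` = 0.2, `14` = 0.05),
                       observed = c(`10` = 5, `11` = 20, `12` = 50,
                                    `13` = 20, `14` = 5),
                       locus_id = "MS01") {
  list(locus_id = locus_id, repeat_unit = "A",
       baseline_hist = baseline, observed_hist = observed)
}

## Long-format MSI rows for one sample/locus.
msi_rows <- function(sample_id, locus_id, lengths, baseline, observed) {
  data.frame(sample_id = sample_id, locus_id = locus_id, repeat_unit = "A",
             length = lengths, baseline_prob = baseline,
             observed_count = observed, stringsAsFactors = FALSE)
}

make_clinical <- function(sample_id, age = 55, stage = "I", grade = "G1",
                          histology = "endometrioid", lvsi = "no",
                          os_months = NA_real_, os_event = NA_integer_,
                          dss_months = NA_real_, dss_event = NA_integer_,
                          vital_status = "unknown") {
  data.frame(sample_id = sample_id, age = age, stage = stage, grade = grade,
             histology = histology, lvsi = lvsi, os_months = os_months,
             os_event = os_event, dss_months = dss_months,
             dss_event = dss_event, vital_status = vital_status,
             stringsAsFactors = FALSE)
}

## Three-sample cohort exercising all layers.
make_tiny_cohort <- function() {
  clin <- rbind(
    make_clinical("A", os_months = 24.5, os_event = 1L, dss_months = 24.5,
                  dss_event = 1L, vital_status = "deceased"),
    make_clinical("B", os_months = 60, os_event = 0L, vital_status = "alive"),
    make_clinical("C"))
  variants <- make_variants(
    make_variant("A", gene = "POLE", hgvs_p = "p.P286R", vaf = 0.25),
    make_variant("A", gene = "PTEN", vaf = 0.4),
    make_variant("B", gene = "TP53", hgvs_p = "p.R273H", vaf = 0.35),
    make_variant("C", gene = "KRAS", vaf = 0.1234))
  msi <- rbind(
    msi_rows("A", "MS01", 10:14, c(.05, .2, .5, .2, .05), c(5, 20, 50, 20, 5)),
    msi_rows("B", "MS01", 10:14, c(.05, .2, .5, .2, .05), c(4, 21, 49, 21, 5)),
    msi_rows("C", "MS01", 10:14, c(.05, .2, .5, .2, .05), c(5, 20, 50, 20, 5)))
  segments <- data.frame(
    sample_id = c("A", "B", "B", "C"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(0, 0, 0, 0), end = c(1e6, 1e6, 1e6, 1e6),
    log2_ratio = c(0.01, 0.9, -0.02, 0),
    stringsAsFactors = FALSE)
  new_cohort(clin, variants, msi, segments)
}

## Small simulation config for fast property tests: light molecular layers,
## everything else at the study defaults.
light_sim_config <- function(...) {
  simulation_config(n_msi_loci = 4, msi_reads_per_locus = 40,
                    tmb_median = c(POLE = 150, `MSI-H` = 30, CNH = 4, CNL = 4),
                    ...)
}
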