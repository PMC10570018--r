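imp_spec <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_transcripts = 5, seed = 7,
                    implant_spec = imp_spec(
                      mirna_id = "sim-miR-1", region = "CDS",
                      template = "perfect", n_copies = 3),
                    n_decoy_reads = 30)
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1, simulate_hybrid_reads(s1))
  write_simulation(s2, d2, simulate_hybrid_reads(s2))
  for (f in c("genome.fa", "mirnas.fa", "transcripts.bed",
              "implant_truth.tsv", "hybrid_reads.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("written FASTA/BED12 reload into the generator's models", {
  cfg <- sim_config(n_transcripts = 6, seed = 13,
                    minus_strand_fraction = 0.5)
  sim <- simulate_transcriptome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  tx2 <- load_transcript_models(paths[["bed"]], paths[["genome"]])
  for (id in names(sim$transcripts)) {
    expect_identical(tx2[[id]]$seq, sim$transcripts[[id]]$seq)
    expect_identical(tx2[[id]]$cds, as.integer(sim$transcripts[[id]]$cds))
    expect_identical(tx2[[id]]$utr3,
                     as.integer(sim$transcripts[[id]]$utr3))
  }
})

test_that("implanted sites have exactly their template's pairing zones", {
  spec <- imp_spec(
    mirna_id = rep(c("sim-miR-1", "sim-miR-2"), 4),
    region = "CDS",
    template = c("perfect", "central_bulge_1", "central_bulge_2",
                 "central_bulge_4", "seed_only", "seedless_3prime",
                 "terminal_mm_2", "terminal_mm_3"),
    n_copies = 3)
  cfg <- sim_config(n_transcripts = 12, seed = 19, implant_spec = spec,
                    n_decoy_reads = 0)
  sim <- simulate_transcriptome(cfg)
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    m <- sim$mirnas[[tr$mirna_id]]
    site <- substr(sim$transcripts[[tr$transcript_id]]$seq,
                   tr$start + 1, tr$end)
    d <- mircds:::gapless_site_duplex(m, site)
    got <- classify(zone_profile(d))$label
    expect_identical(got, tr$expected_class, info = tr$template)
    # unpaired positions are exactly the template's
    want_unp <- mircds:::template_unpaired(tr$template, nchar(m))
    expect_identical(setdiff(seq_len(nchar(m)), d$pairs[, 1]),
                     as.integer(want_unp), info = tr$template)
  }
  # 20 central_bulge_4 implants all classify NONFUNCTIONAL
  expect_identical(
    unique(sim$truth$expected_class[sim$truth$template ==
                                      "central_bulge_4"]),
    "NONFUNCTIONAL")
})

test_that("read simulation conserves totals and nibbling stays in bounds", {
  spec <- imp_spec(mirna_id = "sim-miR-1", region = "CDS",
                   template = "perfect", n_copies = 10)
  cfg <- sim_config(n_transcripts = 10, seed = 13, implant_spec = spec,
                    n_decoy_reads = 150, reads_per_implant = 4)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_hybrid_reads(sim)
  # conservation: emitted rows == sum of duplication counts;
  # collapsing returns the emitted total
  expect_identical(nrow(rd$reads), sum(rd$read_truth$dup))
  cc <- collapse_duplicates(rd$reads)
  expect_identical(sum(cc$count), nrow(rd$reads))
  # every implant read, expanded by 3, re-covers its implant interval
  tr <- sim$truth
  imp <- rd$read_truth[rd$read_truth$origin != "decoy", ]
  expanded <- expand_intervals(
    imp[, c("ref", "start", "end", "strand", "mirna_id")], pad = 3,
    bounds = vapply(sim$genome, nchar, integer(1)))
  for (i in seq_len(nrow(imp))) {
    t <- tr[tr$implant_id == imp$origin[i], ]
    expect_lte(expanded$start[i], t$gstart)
    expect_gte(expanded$end[i], t$gend)
  }
  # with max_nibble 0 reads cover implants exactly
  cfg0 <- sim_config(n_transcripts = 6, seed = 29, implant_spec = spec,
                     max_nibble = 0, n_decoy_reads = 0)
  sim0 <- simulate_transcriptome(cfg0)
  rd0 <- simulate_hybrid_reads(sim0)
  key_r <- unique(paste(rd0$reads$ref, rd0$reads$start, rd0$reads$end))
  key_t <- paste(sim0$truth$chrom, sim0$truth$gstart, sim0$truth$gend)
  expect_setequal(key_r, key_t)
})

test_that("decoy-only datasets yield no candidate sites at budget 2", {
  cfg <- sim_config(n_transcripts = 10, seed = 37, n_decoy_reads = 50)
  sim <- simulate_transcriptome(cfg)
  res <- scan_transcriptome(sim$mirnas, sim$transcripts,
                            scan_params(max_mismatches_rest = 2,
                                        regions = c("CDS", "UTR3")))
  expect_identical(nrow(res$sites), 0L)
})

test_that("recovery metrics are perfect on a perfect-implant dataset", {
  spec <- imp_spec(mirna_id = c("sim-miR-1", "sim-miR-2"), region = "CDS",
                   template = "perfect", n_copies = 5)
  cfg <- sim_config(n_transcripts = 10, seed = 43, implant_spec = spec,
                    n_decoy_reads = 0)
  sim <- simulate_transcriptome(cfg)
  scan <- scan_transcriptome(sim$mirnas, sim$transcripts,
                             scan_params(max_mismatches_rest = 0))
  rep <- recovery_report(sim, scan = scan,
                         params = scan_params(max_mismatches_rest = 0))
  expect_equal(rep$site_sensitivity, 1)
  expect_identical(rep$n_false_sites, 0L)
})
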