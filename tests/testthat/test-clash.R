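mk_reads <- function(ref, start, end, mirna = "m1", strand = "+",
                     count = 1L) {
  data.frame(ref = ref, start = as.integer(start), end = as.integer(end),
             strand = strand, mirna_id = mirna, count = as.integer(count),
             stringsAsFactors = FALSE)
}

test_that("interval expansion pads, clamps and drops unknown references", {
  bounds <- c(chr1 = 1000L)
  r <- expand_intervals(mk_reads("chr1", 100, 130), pad = 3, bounds = bounds)
  expect_identical(c(r$start, r$end), c(97L, 133L))
  r0 <- expand_intervals(mk_reads("chr1", 1, 10), pad = 3, bounds = bounds)
  expect_identical(c(r0$start, r0$end), c(0L, 13L))
  rhi <- expand_intervals(mk_reads("chr1", 990, 999), pad = 3,
                          bounds = bounds)
  expect_identical(rhi$end, 1000L)
  rid <- expand_intervals(mk_reads("chr1", 100, 130), pad = 0,
                          bounds = bounds)
  expect_identical(c(rid$start, rid$end), c(100L, 130L))
  expect_warning(
    rdrop <- expand_intervals(mk_reads(c("chr1", "chrX"), c(1, 1),
                                       c(10, 10)), pad = 3,
                              bounds = bounds),
    "unknown")
  expect_identical(nrow(rdrop), 1L)
})

test_that("region annotation applies the 3'UTR-priority rule", {
  # transcript-local model: 100 nt 5'UTR, 200 nt CDS, 100 nt 3'UTR
  set.seed(105)
  tx <- toy_tx(rand_rna(400), utr5 = 100L, cds = 200L)
  reads <- mk_reads("tx1", c(150, 290, 50, 95, 310),
                    c(180, 310, 80, 120, 340))
  ann <- annotate_region(reads, list(tx))
  expect_identical(ann$region,
                   c("CDS", "UTR3", "UTR5", "UTR5", "UTR3"))
  # a read overlapping both CDS and 3'UTR is 3'UTR by priority
  expect_true(ann$exonic[2] && ann$utr3[2])
  # intergenic reads are discarded
  out <- annotate_region(mk_reads("chrZ", 10, 40), list(tx))
  expect_identical(out$region, "discarded_intergenic")
})

test_that("genomic annotation distinguishes introns and both strands", {
  cfg <- sim_config(n_transcripts = 4, seed = 17,
                    minus_strand_fraction = 0.5, n_decoy_reads = 0)
  sim <- simulate_transcriptome(cfg)
  for (id in names(sim$transcripts)) {
    lay <- sim$layout[[id]]
    tx <- sim$transcripts[[id]]
    # a read fully inside the intron
    ia <- lay$flank_len + lay$split
    giv <- if (lay$strand == "+") c(ia + 10L, ia + 40L) else
      c(lay$chrom_len - (ia + 40L), lay$chrom_len - (ia + 10L))
    r <- annotate_region(mk_reads(lay$chrom, giv[1], giv[2]),
                         sim$transcripts)
    expect_identical(r$region, "intron")
    # a read inside the CDS (first exon side)
    giv2 <- mircds:::spliced_to_genomic(lay, tx$cds[1] + 5L,
                                        tx$cds[1] + 30L)
    r2 <- annotate_region(mk_reads(lay$chrom, giv2[1], giv2[2]),
                          sim$transcripts)
    expect_identical(r2$region, "CDS")
  }
})

test_that("duplicate collapsing conserves counts and respects the key", {
  r <- rbind(mk_reads("chr1", 100, 130), mk_reads("chr1", 100, 130),
             mk_reads("chr1", 100, 130), mk_reads("chr1", 200, 230))
  cc <- collapse_duplicates(r)
  expect_identical(nrow(cc), 2L)
  expect_identical(sort(cc$count), c(1L, 3L))
  expect_identical(sum(cc$count), nrow(r))
  # same interval, different miRNA: not collapsed
  r2 <- rbind(mk_reads("chr1", 100, 130, "m1"),
              mk_reads("chr1", 100, 130, "m2"))
  expect_identical(nrow(collapse_duplicates(r2)), 2L)
  # conservation on random input
  set.seed(111)
  r3 <- mk_reads("chr1", s <- sample(50, 300, TRUE) * 10,
                 s + 25, sample(c("m1", "m2"), 300, TRUE))
  expect_identical(sum(collapse_duplicates(r3)$count), 300L)
})

test_that("hybrid duplexes recover implanted pairing in mRNA orientation", {
  set.seed(115)
  m <- c(mir = rand_rna(22))
  frag <- reverse_complement(m[["mir"]])
  seqs <- c(chrP = paste0(rand_rna(30), frag, rand_rna(30)),
            chrM = paste0(rand_rna(30), reverse_complement(frag),
                          rand_rna(30)))
  reads <- rbind(mk_reads("chrP", 30, 52, "mir", "+"),
                 mk_reads("chrM", 30, 52, "mir", "-"),
                 mk_reads("chrP", 0, 25, "unknown-mir", "+"))
  reads$region <- "CDS"
  ann <- hybrid_duplexes(reads, seqs, m)
  expect_identical(nrow(ann$duplex[[1]]$pairs), 22L)
  expect_identical(nrow(ann$duplex[[2]]$pairs), 22L)
  expect_false(ann$mirna_known[3])
  expect_null(ann$duplex[[3]])
})

test_that("pairing matrices aggregate count-weighted anchored vectors", {
  set.seed(121)
  m <- c(mir = rand_rna(22))
  frag <- reverse_complement(m[["mir"]])
  reads <- rbind(mk_reads("c1", 0, 22, "mir", count = 3L),
                 mk_reads("c2", 0, 22, "mir", count = 1L))
  reads$region <- "CDS"
  seqs <- c(c1 = frag, c2 = rand_rna(22))
  ann <- hybrid_duplexes(reads, seqs, m)
  pm <- pairing_matrices(ann, "five_prime", region = "CDS", width = 23)
  expect_identical(nrow(pm$rows), 2L)
  expect_true(all(pm$col_fraction >= 0 & pm$col_fraction <= 1))
  # the perfect hybrid carries weight 3 of 4
  expect_gte(pm$col_fraction[5], 0.75)
  expect_identical(pm$col_fraction[23], 0)
  # empty region class gives an empty matrix, not an error
  expect_identical(nrow(pairing_matrices(ann, region = "UTR3")$rows), 0L)
})

test_that("3'-anchored matrices are the 5'-anchored matrices shifted", {
  set.seed(125)
  mirnas <- stats::setNames(
    vapply(seq(16, 25), rand_rna, character(1)), paste0("m", 16:25))
  reads <- do.call(rbind, lapply(names(mirnas), function(id)
    mk_reads(id, 0, 30, id)))
  reads$region <- "CDS"
  seqs <- stats::setNames(vapply(rep(30, length(mirnas)), rand_rna,
                                 character(1)), names(mirnas))
  ann <- hybrid_duplexes(reads, seqs, mirnas)
  w <- 28L
  p5 <- pairing_matrices(ann, "five_prime", width = w)
  p3 <- pairing_matrices(ann, "three_prime", width = w)
  for (i in seq_len(nrow(p5$rows))) {
    L <- ann$duplex[[i]]$mirna_len
    expect_identical(p3$rows[i, ],
                     c(rep(FALSE, w - L), p5$rows[i, seq_len(L)]))
  }
})

test_that("region summaries are count-weighted fractions that sum to 1", {
  r <- mk_reads("x", c(1, 1, 1), c(10, 10, 10))
  r$region <- c("CDS", "CDS", "UTR3")
  r$count <- c(5L, 1L, 2L)
  rs <- region_summary(r)
  expect_equal(sum(rs$fraction), 1)
  expect_equal(rs$fraction[rs$region == "CDS"], 0.75)
  r$region <- "CDS"
  expect_equal(region_summary(r)$fraction, 1)
})

test_that("implant reads recover seed pairing through the full pipeline", {
  # chimeric reads from seed-paired implant templates should re-derive
  # a seed-paired duplex after nibbling, expansion and duplex calling
  spec <- data.frame(
    mirna_id = rep(c("sim-miR-1", "sim-miR-2", "sim-miR-3"), each = 2),
    region = "CDS",
    template = rep(c("perfect", "central_bulge_1", "terminal_mm_2"),
                   each = 2),
    n_copies = 9, stringsAsFactors = FALSE)
  cfg <- sim_config(n_transcripts = 25, implant_spec = spec,
                    reads_per_implant = 19, n_decoy_reads = 0,
                    dup_geom_p = 1, seed = 42)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_hybrid_reads(sim)
  expect_gte(nrow(rd$reads), 1000L)
  ann <- clash_pipeline(rd$reads, sim$transcripts, sim$genome,
                        sim$mirnas)
  seed_ok <- vapply(ann$duplex, function(d)
    !is.null(d) && zone_profile(d)$seed_paired, logical(1))
  expect_gte(mean(seed_ok), 0.95)
})

test_that("profile matrices resolve a seed-only / non-pairing hybrid mix", {
  # A designed low-complementarity background isolates the matrix
  # arithmetic from spurious helices: the miRNA and decoy fragments
  # are drawn from {A,C} (no WC or wobble pair exists within {A,C}),
  # while seed-only fragments carry the seed complement and {A,C}
  # elsewhere. Expected column fractions are then binomial with
  # p = mix fraction at seed slots and exactly 0 beyond the seed.
  set.seed(7)
  L <- 22L
  m <- c(mir = paste(sample(c("A", "C"), L, TRUE), collapse = ""))
  seed_rc <- reverse_complement(substr(m[["mir"]], 2, 8))
  n <- 2000L
  is_seed <- sample(rep(c(TRUE, FALSE), n / 2))
  frags <- vapply(is_seed, function(s) {
    f <- paste(sample(c("A", "C"), L, TRUE), collapse = "")
    if (s) substr(f, L - 7L, L - 1L) <- seed_rc
    f
  }, character(1))
  seqs <- stats::setNames(frags, sprintf("r%04d", seq_len(n)))
  reads <- data.frame(ref = names(seqs), start = 0L, end = L,
                      strand = "+", mirna_id = "mir", count = 1L,
                      region = "CDS", stringsAsFactors = FALSE)
  ann <- hybrid_duplexes(reads, seqs, m)
  pm <- pairing_matrices(ann, "five_prime", region = "CDS", width = L)
  expect_true(all(abs(pm$col_fraction[2:8] - 0.5) < 0.05))
  expect_true(all(pm$col_fraction[13:L] < 0.05))
})

test_that("region fractions recover the decoy multinomial mix", {
  mix <- c(UTR3 = 0.5, CDS = 0.3, UTR5 = 0.1, intron = 0.1)
  cfg <- sim_config(n_transcripts = 25, n_decoy_reads = 5000L,
                    region_mix = mix, seed = 11)
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_hybrid_reads(sim)
  reads <- expand_intervals(rd$reads, pad = 3,
                            bounds = vapply(sim$genome, nchar,
                                            integer(1)))
  ann <- annotate_region(collapse_duplicates(reads), sim$transcripts)
  rs <- region_summary(ann)
  got <- stats::setNames(rs$fraction, rs$region)
  want <- tapply(rd$read_truth$dup, rd$read_truth$region_true, sum)
  want <- want / sum(want)
  for (r in names(mix)) {
    expect_lt(abs(got[[r]] - want[[r]]), 0.03)
  }
  expect_equal(sum(rs$fraction), 1)
})
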