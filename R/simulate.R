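# Seeded generator of miRNAs, transcript models with genomic layout,
# implanted MREs of specified class templates, and CLASH-like hybrid
# reads with nuclease nibbling and read duplication — with full ground
# truth, so every pipeline stage is testable without external data.
#
# Background sequence is i.i.d. at a given GC content (no codon usage,
# no secondary structure); each transcript occupies its own chromosome
# as two exons separated by an intron, with intergenic flanks.

IMPLANT_TEMPLATES <- c("perfect", "central_bulge_1", "central_bulge_2",
                       "central_bulge_4", "seed_only", "seedless_3prime",
                       "terminal_mm_2", "terminal_mm_3")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# miRNA positions mutated by each template (the written target site is
# made non-complementary opposite these positions)
template_unpaired <- function(template, L) {
  switch(template,
    perfect = integer(0),
    central_bulge_1 = 12L,
    central_bulge_2 = c(11L, 12L),
    central_bulge_4 = c(10L, 11L, 12L, 13L),
    seed_only = c(1L, 9:L),
    seedless_3prime = c(3L, 4L, 5L),
    terminal_mm_2 = c(L - 1L, L),
    terminal_mm_3 = c(L - 2L, L - 1L, L),
    stop("unknown implant template: ", template, call. = FALSE)
  )
}

#' Expected MRE class of an implant template
#'
#' Derived by classifying the template's idealised pairing pattern, so
#' generator truth and classifier semantics cannot drift apart.
#'
#' @param template Template name (see `IMPLANT_TEMPLATES`).
#' @param L miRNA length.
#' @param rules [mre_rules()].
#' @return Class label.
#' @export
template_expected_class <- function(template, L = 22L,
                                    rules = mre_rules()) {
  d <- duplex_from_pattern(L, template_unpaired(template, L))
  classify(zone_profile(d), rules)$label
}

#' Simulation configuration
#'
#' @param n_transcripts Number of transcripts (one per chromosome).
#' @param utr5_len,cds_len,utr3_len Length ranges (min, max) per
#'   region; CDS lengths are forced divisible by 3.
#' @param gc_content Background GC fraction.
#' @param n_mirnas,mirna_len Generated miRNA set (ignored when
#'   `mirnas` supplies sequences).
#' @param mirnas Optional named character vector of miRNA sequences.
#' @param implant_spec Data.frame with columns `mirna_id`, `region`
#'   (`"CDS"`/`"UTR3"`), `template`, `n_copies`.
#' @param max_nibble Maximum truncation per read end (nt).
#' @param dup_geom_p Success probability of the geometric (counting
#'   from 1) read-duplication distribution.
#' @param reads_per_implant Distinct chimeric reads drawn per implant.
#' @param n_decoy_reads Decoy reads with no implanted site.
#' @param region_mix Named multinomial over decoy regions
#'   (`UTR3`, `CDS`, `UTR5`, `intron`).
#' @param decoy_len Decoy fragment length range.
#' @param intron_len,flank_len Intron and intergenic flank lengths.
#' @param minus_strand_fraction Fraction of minus-strand transcripts.
#' @param seed Integer seed; the generator is fully deterministic
#'   given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 20L,
                       utr5_len = c(100L, 250L),
                       cds_len = c(300L, 900L),
                       utr3_len = c(200L, 500L),
                       gc_content = 0.5,
                       n_mirnas = 10L, mirna_len = 22L,
                       mirnas = NULL,
                       implant_spec = NULL,
                       max_nibble = 3L,
                       dup_geom_p = 0.5,
                       reads_per_implant = 3L,
                       n_decoy_reads = 200L,
                       region_mix = c(UTR3 = 0.5, CDS = 0.3,
                                      UTR5 = 0.1, intron = 0.1),
                       decoy_len = c(20L, 40L),
                       intron_len = 150L, flank_len = 50L,
                       minus_strand_fraction = 0.3,
                       seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1, max_nibble >= 0,
            abs(sum(region_mix) - 1) < 1e-8,
            all(region_mix >= 0), dup_geom_p > 0, dup_geom_p <= 1)
  structure(list(n_transcripts = n_transcripts, utr5_len = utr5_len,
                 cds_len = cds_len, utr3_len = utr3_len,
                 gc_content = gc_content, n_mirnas = n_mirnas,
                 mirna_len = mirna_len, mirnas = mirnas,
                 implant_spec = implant_spec, max_nibble = max_nibble,
                 dup_geom_p = dup_geom_p,
                 reads_per_implant = reads_per_implant,
                 n_decoy_reads = n_decoy_reads, region_mix = region_mix,
                 decoy_len = decoy_len, intron_len = intron_len,
                 flank_len = flank_len,
                 minus_strand_fraction = minus_strand_fraction,
                 seed = seed),
            class = "sim_config")
}

random_rna <- function(n, gc) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a base that pairs (WC or GU) with neither given miRNA base
non_pairing_base <- function(mb) {
  choices <- switch(mb, A = c("A", "C", "G"), C = c("A", "C", "U"),
                    G = c("A", "G"), U = c("C", "U"))
  sample(choices, 1)
}

# target site (5'->3') for a miRNA under a template: complement
# everywhere except opposite the template's mutated positions
implant_site_seq <- function(mirna, template) {
  L <- nchar(mirna)
  mut <- template_unpaired(template, L)
  m <- substring(mirna, 1:L, 1:L)
  site <- chartr("ACGU", "UGCA", paste(rev(m), collapse = ""))
  site <- strsplit(site, "", fixed = TRUE)[[1]]
  for (k in mut) site[L + 1L - k] <- non_pairing_base(m[k])
  paste(site, collapse = "")
}

spliced_to_construct <- function(s, split, intron_len, flank_len) {
  flank_len + s + ifelse(s >= split, intron_len, 0L)
}

# covering genomic interval of a spliced interval [a, b)
spliced_to_genomic <- function(layout, a, b) {
  c1 <- spliced_to_construct(a, layout$split, layout$intron_len,
                             layout$flank_len)
  c2 <- spliced_to_construct(b - 1L, layout$split, layout$intron_len,
                             layout$flank_len) + 1L
  if (layout$strand == "+") c(c1, c2)
  else c(layout$chrom_len - c2, layout$chrom_len - c1)
}

#' Simulate a transcriptome with implanted MREs
#'
#' Generates the miRNA set, per-transcript spliced sequences with the
#' configured region structure, writes the reverse complement of each
#' (template-mutated) miRNA into the chosen region at non-overlapping
#' positions, then lays each transcript onto its own chromosome as two
#' exons flanking an intron (some on the minus strand). Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `mirna_sim` list: `mirnas`, `transcripts`
#'   (`transcript_model`s), `genome` (named chromosome sequences),
#'   `truth` (one row per implant with spliced and genomic
#'   coordinates and the expected MRE class), `layout`, `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  with_seed(config$seed, {
    mirnas <- config$mirnas
    if (is.null(mirnas)) {
      mirnas <- stats::setNames(
        vapply(seq_len(config$n_mirnas), function(i)
          random_rna(config$mirna_len, config$gc_content), character(1)),
        sprintf("sim-miR-%d", seq_len(config$n_mirnas)))
    }
    validate_mirnas(mirnas)
    n <- config$n_transcripts
    rlen <- function(rg) sample(seq(rg[1], rg[2]), n, replace = TRUE)
    u5 <- rlen(config$utr5_len)
    cds <- rlen(config$cds_len); cds <- cds - cds %% 3L
    u3 <- rlen(config$utr3_len)
    strands <- ifelse(stats::runif(n) < config$minus_strand_fraction,
                      "-", "+")
    spliced <- vapply(u5 + cds + u3, random_rna, character(1),
                      gc = config$gc_content)
    tx_ids <- sprintf("tx%02d", seq_len(n))
    chroms <- sprintf("chr%02d", seq_len(n))

    # ---- implants -----------------------------------------------------
    truth <- NULL
    occupied <- vector("list", n)  # implant intervals per transcript
    spec <- config$implant_spec
    if (!is.null(spec) && nrow(spec)) {
      implant_id <- 0L
      for (r in seq_len(nrow(spec))) {
        mid <- spec$mirna_id[r]
        stopifnot(mid %in% names(mirnas))
        L <- nchar(mirnas[[mid]])
        for (cp in seq_len(spec$n_copies[r])) {
          implant_id <- implant_id + 1L
          site <- implant_site_seq(mirnas[[mid]], spec$template[r])
          placed <- FALSE
          for (try in 1:200) {
            ti <- sample.int(n, 1)
            iv <- switch(spec$region[r],
                         CDS = c(u5[ti], u5[ti] + cds[ti]),
                         UTR3 = c(u5[ti] + cds[ti], u5[ti] + cds[ti] + u3[ti]),
                         stop("implant region must be CDS or UTR3"))
            lo <- iv[1] + 10L; hi <- iv[2] - 10L - L
            if (hi < lo) next
            s0 <- sample(seq(lo, hi), 1)
            clash <- any(vapply(occupied[[ti]], function(o)
              s0 < o[2] + 5L && s0 + L > o[1] - 5L, logical(1)))
            if (clash) next
            substr(spliced[ti], s0 + 1L, s0 + L) <- site
            occupied[[ti]] <- c(occupied[[ti]], list(c(s0, s0 + L)))
            truth <- rbind(truth, data.frame(
              implant_id = sprintf("imp%03d", implant_id),
              mirna_id = mid, transcript_id = tx_ids[ti],
              region = spec$region[r], start = s0, end = s0 + L,
              template = spec$template[r],
              expected_class = template_expected_class(
                spec$template[r], L),
              stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
          if (!placed) stop("could not place implant (region too small ",
                            "or too many copies)", call. = FALSE)
        }
      }
    }

    # ---- genomic layout ----------------------------------------------
    genome <- character(n); names(genome) <- chroms
    transcripts <- vector("list", n); names(transcripts) <- tx_ids
    layouts <- vector("list", n); names(layouts) <- tx_ids
    for (i in seq_len(n)) {
      slen <- u5[i] + cds[i] + u3[i]
      split <- u5[i] + cds[i] %/% 2L
      if (length(occupied[[i]])) {
        # move the split out of any implant (implants never straddle exons)
        shift <- 0L
        repeat {
          cand <- split + shift
          inside <- any(vapply(occupied[[i]], function(o)
            cand > o[1] && cand < o[2], logical(1)))
          if (!inside && cand > u5[i] && cand < u5[i] + cds[i]) break
          shift <- if (shift <= 0L) -shift + 1L else -shift
        }
        split <- cand
      }
      flank <- config$flank_len; intr <- config$intron_len
      exon1 <- substr(spliced[i], 1, split)
      exon2 <- substr(spliced[i], split + 1L, slen)
      construct <- paste0(random_rna(flank, config$gc_content), exon1,
                          random_rna(intr, config$gc_content), exon2,
                          random_rna(flank, config$gc_content))
      chrom_len <- nchar(construct)
      if (strands[i] == "+") {
        genome[i] <- construct
        ex <- rbind(c(flank, flank + split),
                    c(flank + split + intr, flank + slen + intr))
      } else {
        genome[i] <- reverse_complement(construct)
        ex <- rbind(c(chrom_len - (flank + slen + intr),
                      chrom_len - (flank + split + intr)),
                    c(chrom_len - (flank + split), chrom_len - flank))
      }
      colnames(ex) <- c("start", "end")
      transcripts[[i]] <- new_transcript_model(
        id = tx_ids[i], seq = spliced[i],
        utr5 = c(0L, u5[i]), cds = c(u5[i], u5[i] + cds[i]),
        utr3 = c(u5[i] + cds[i], slen),
        chrom = chroms[i], strand = strands[i], exons = ex,
        coding = TRUE)
      layouts[[i]] <- list(split = split, intron_len = intr,
                           flank_len = flank, chrom_len = chrom_len,
                           strand = strands[i], chrom = chroms[i])
    }
    if (!is.null(truth)) {
      g <- t(vapply(seq_len(nrow(truth)), function(r) {
        spliced_to_genomic(layouts[[truth$transcript_id[r]]],
                           truth$start[r], truth$end[r])
      }, integer(2)))
      truth$chrom <- vapply(layouts[truth$transcript_id], `[[`,
                            character(1), "chrom")
      truth$gstart <- g[, 1]; truth$gend <- g[, 2]
      truth$strand <- strands[match(truth$transcript_id, tx_ids)]
    }
    structure(list(mirnas = mirnas, transcripts = transcripts,
                   genome = genome, truth = truth, layout = layouts,
                   config = config),
              class = "mirna_sim")
  })
}

#' Simulate CLASH-like hybrid reads from a simulated transcriptome
#'
#' Implant reads cover their implanted site, each end independently
#' truncated by Uniform{0..max_nibble} nucleotides of nuclease
#' nibbling; decoy reads are placed uniformly within a region drawn
#' from the configured region mix, avoiding implants. Every read is
#' emitted `d` times with `d` drawn from the duplication distribution,
#' so the raw table contains duplicate rows for the pipeline to
#' collapse.
#'
#' @param sim A `mirna_sim` from [simulate_transcriptome()].
#' @param seed Seed for the read-level randomness (defaults to the
#'   config seed offset by 1).
#' @return List with `reads` (raw hybrid table, one row per emitted
#'   read, count 1) and `read_truth` (one row per distinct read:
#'   origin implant id or `"decoy"`, true region, duplication count).
#' @export
simulate_hybrid_reads <- function(sim, seed = sim$config$seed + 1L) {
  config <- sim$config
  with_seed(seed, {
    rt_list <- list()
    mk_read <- function(chrom, gstart, gend, strand, mirna_id, origin,
                        region) {
      d <- 1L + stats::rgeom(1, config$dup_geom_p)
      data.frame(ref = chrom, start = gstart, end = gend,
                 strand = strand, mirna_id = mirna_id, origin = origin,
                 region_true = region, dup = d,
                 stringsAsFactors = FALSE)
    }
    if (!is.null(sim$truth)) {
      for (r in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[r, ]
        for (k in seq_len(config$reads_per_implant)) {
          nib <- sample.int(config$max_nibble + 1L, 2, replace = TRUE) - 1L
          rt_list[[length(rt_list) + 1L]] <-
            mk_read(tr$chrom, tr$gstart + nib[1], tr$gend - nib[2],
                    tr$strand, tr$mirna_id, tr$implant_id, tr$region)
        }
      }
    }
    if (config$n_decoy_reads > 0) {
      regions <- sample(names(config$region_mix), config$n_decoy_reads,
                        replace = TRUE, prob = config$region_mix)
      tx_ids <- names(sim$transcripts)
      for (j in seq_len(config$n_decoy_reads)) {
        len <- sample(seq(config$decoy_len[1], config$decoy_len[2]), 1)
        placed <- FALSE
        for (try in 1:100) {
          ti <- sample(tx_ids, 1)
          tx <- sim$transcripts[[ti]]
          lay <- sim$layout[[ti]]
          if (regions[j] == "intron") {
            # construct coords of the intron, mapped to genomic
            ia <- lay$flank_len + lay$split
            ib <- ia + lay$intron_len
            if (ib - ia <= len) next
            a <- ia + sample.int(ib - ia - len, 1) - 1L
            giv <- if (lay$strand == "+") c(a, a + len)
              else c(lay$chrom_len - (a + len), lay$chrom_len - a)
          } else {
            iv <- tx_region(tx, regions[j])
            if (iv[2] - iv[1] <= len) next
            a <- iv[1] + sample.int(iv[2] - iv[1] - len, 1) - 1L
            occ <- sim$truth
            if (!is.null(occ)) {
              occ <- occ[occ$transcript_id == ti, , drop = FALSE]
              if (nrow(occ) &&
                  any(a < occ$end & a + len > occ$start)) next
            }
            giv <- spliced_to_genomic(lay, a, a + len)
          }
          rt_list[[length(rt_list) + 1L]] <-
            mk_read(lay$chrom, giv[1], giv[2], lay$strand,
                    sample(names(sim$mirnas), 1), "decoy", regions[j])
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place decoy read", call. = FALSE)
      }
    }
    rt <- do.call(rbind, rt_list)
    rownames(rt) <- NULL
    reads <- rt[rep(seq_len(nrow(rt)), rt$dup),
                c("ref", "start", "end", "strand", "mirna_id")]
    reads$count <- 1L
    rownames(reads) <- NULL
    list(reads = reads, read_truth = rt)
  })
}

#' Write a simulation to disk (FASTA + BED12 + TSV)
#'
#' Emits the chromosome FASTA, the miRNA FASTA, a BED12 of the
#' transcript models, the implant truth table, and (when reads are
#' supplied) the hybrid table in the internal 0-based dialect.
#'
#' @param sim A `mirna_sim`.
#' @param dir Output directory.
#' @param reads Optional result of [simulate_hybrid_reads()].
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             mirnas = file.path(dir, "mirnas.fa"),
             bed = file.path(dir, "transcripts.bed"),
             truth = file.path(dir, "implant_truth.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_fasta(sim$mirnas, paths["mirnas"])
  bed <- do.call(rbind, lapply(sim$transcripts, function(tx) {
    ex <- tx$exons
    lay <- sim$layout[[tx$id]]
    cg <- spliced_to_genomic(lay, tx$cds[1], tx$cds[2])
    data.frame(chrom = tx$chrom, start = ex[1, "start"],
               end = ex[nrow(ex), "end"], name = tx$id, score = 0L,
               strand = tx$strand, thickStart = cg[1], thickEnd = cg[2],
               rgb = "0", blockCount = nrow(ex),
               blockSizes = paste0(paste(ex[, "end"] - ex[, "start"],
                                         collapse = ","), ","),
               blockStarts = paste0(paste(ex[, "start"] - ex[1, "start"],
                                          collapse = ","), ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$truth)) {
    utils::write.table(sim$truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(reads)) {
    paths <- c(paths, hybrids = file.path(dir, "hybrid_reads.tsv"))
    write_hybrid_table(reads$reads, paths[["hybrids"]])
  }
  invisible(paths)
}

#' Recovery metrics of pipeline outputs against simulator truth
#'
#' @param sim A `mirna_sim`.
#' @param scan Optional [scan_transcriptome()] result: site-recovery
#'   sensitivity and false-discovery proportion are computed by exact
#'   interval matching against the implant truth (only implants whose
#'   template is recoverable at the scan's anchor/budget count toward
#'   sensitivity).
#' @param annotated Optional annotated hybrid table (with duplexes):
#'   region-fraction error versus per-read truth and a class confusion
#'   matrix for implant-derived reads.
#' @param read_truth Per-read truth from [simulate_hybrid_reads()]
#'   (required with `annotated`).
#' @param params Scan parameters used (for recoverability).
#' @param rules [mre_rules()].
#' @return List of metric components.
#' @export
recovery_report <- function(sim, scan = NULL, annotated = NULL,
                            read_truth = NULL, params = scan_params(),
                            rules = mre_rules()) {
  out <- list()
  if (!is.null(scan)) {
    truth <- sim$truth
    recoverable <- rep(FALSE, NROW(truth))
    if (NROW(truth)) {
      a <- params$anchor_range
      recoverable <- vapply(seq_len(nrow(truth)), function(r) {
        mut <- template_unpaired(truth$template[r],
                                 nchar(sim$mirnas[[truth$mirna_id[r]]]))
        length(intersect(mut, a)) == 0 &&
          length(setdiff(mut, a)) <= params$max_mismatches_rest &&
          truth$region[r] %in% params$regions
      }, logical(1))
    }
    sites <- scan$sites
    key_truth <- if (NROW(truth))
      paste(truth$transcript_id, truth$start, truth$end, truth$mirna_id)
      else character(0)
    key_sites <- paste(sites$transcript_id, sites$start, sites$end,
                       sites$mirna_id)
    hit <- key_truth %in% key_sites
    out$site_sensitivity <- if (any(recoverable))
      mean(hit[recoverable]) else NA_real_
    out$n_recoverable <- sum(recoverable)
    out$n_false_sites <- sum(!key_sites %in% key_truth)
    out$site_fdp <- if (nrow(sites)) out$n_false_sites / nrow(sites) else 0
  }
  if (!is.null(annotated)) {
    stopifnot(!is.null(read_truth))
    truth_frac <- tapply(read_truth$dup, read_truth$region_true, sum)
    truth_frac <- truth_frac / sum(truth_frac)
    obs <- region_summary(annotated)
    obs_frac <- stats::setNames(obs$fraction, obs$region)
    regions <- union(names(truth_frac), names(obs_frac))
    err <- vapply(regions, function(r) {
      abs((if (r %in% names(obs_frac)) obs_frac[[r]] else 0) -
          (if (r %in% names(truth_frac)) truth_frac[[r]] else 0))
    }, numeric(1))
    out$region_fraction_error <- max(err)
    # class confusion for implant reads: match collapsed reads back to
    # implants by miRNA + containment of the implant genomic interval
    if (NROW(sim$truth)) {
      conf <- table(factor(character(0), MRE_LEVELS),
                    factor(character(0), MRE_LEVELS))
      pred <- expected <- character(0)
      for (i in seq_len(nrow(annotated))) {
        d <- annotated$duplex[[i]]
        if (is.null(d)) next
        tr <- sim$truth
        m <- tr$chrom == annotated$ref[i] &
          tr$mirna_id == annotated$mirna_id[i] &
          tr$gstart >= annotated$start[i] & tr$gend <= annotated$end[i]
        if (!any(m)) next
        pred <- c(pred, classify(zone_profile(d), rules)$label)
        expected <- c(expected, tr$expected_class[which(m)[1]])
      }
      out$class_confusion <- table(
        expected = factor(expected, MRE_LEVELS),
        predicted = factor(pred, MRE_LEVELS))
    }
  }
  out
}
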