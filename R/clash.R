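# CLEAR-CLIP / CLASH hybrid-read pipeline: nibbling-compensation
# interval expansion, transcript-region annotation with the
# 3'UTR-priority rule, duplicate collapsing, per-hybrid duplex calls,
# region summaries and 5'/3'-anchored base-pairing profile matrices.

#' Expand hybrid-read intervals to compensate for nuclease nibbling
#'
#' Each target interval is widened by `pad` bases on both ends and
#' clamped to the reference bounds. Reads on unknown references are
#' dropped with a warning.
#'
#' @param reads Hybrid-read data.frame (`ref`, `start`, `end`, ...).
#' @param pad Bases added to each end (default 3, matching the
#'   truncation depth typical of CLIP library preparation).
#' @param bounds Named integer vector of reference lengths.
#' @return The reads with expanded intervals.
#' @export
expand_intervals <- function(reads, pad = 3L, bounds) {
  stopifnot(pad >= 0)
  pad <- as.integer(pad)
  known <- reads$ref %in% names(bounds)
  if (!all(known)) {
    warning(sprintf("expand_intervals: dropped %d read(s) on unknown references",
                    sum(!known)), call. = FALSE)
    reads <- reads[known, , drop = FALSE]
  }
  reads$start <- as.integer(pmax(0L, reads$start - pad))
  reads$end <- as.integer(pmin(unname(bounds[reads$ref]),
                               reads$end + pad))
  reads
}

# Genomic (or transcript-local) feature ranges of a transcript set:
# GRanges with mcols$feature in {exonic, intronic, utr5, utr3}.
transcript_features <- function(transcripts) {
  grs <- lapply(transcripts, function(tx) {
    if (!is.null(tx$exons) && !is.na(tx$chrom)) {
      ref <- tx$chrom
      ex <- tx$exons
      feats <- list()
      feats$exonic <- ex
      if (nrow(ex) > 1) {
        feats$intronic <- cbind(start = ex[-nrow(ex), "end"],
                                end = ex[-1, "start"])
      }
      # project a spliced interval [a,b) to genomic interval(s)
      proj <- function(iv) {
        if (iv[2] <= iv[1]) return(NULL)
        widths <- ex[, "end"] - ex[, "start"]
        offs <- cumsum(c(0L, widths))
        if (tx$strand == "-") {
          tot <- sum(widths)
          iv <- c(tot - iv[2], tot - iv[1])  # flip to plus-spliced coords
        }
        segs <- NULL
        for (j in seq_len(nrow(ex))) {
          a <- max(iv[1], offs[j]); b <- min(iv[2], offs[j + 1])
          if (a < b) {
            segs <- rbind(segs, cbind(
              start = ex[j, "start"] + (a - offs[j]),
              end = ex[j, "start"] + (b - offs[j])))
          }
        }
        segs
      }
      feats$utr5 <- proj(tx$utr5)
      feats$utr3 <- proj(tx$utr3)
      feats <- feats[!vapply(feats, is.null, logical(1))]
    } else {
      # transcript-local coordinates: the whole spliced seq is exonic
      ref <- tx$id
      feats <- list(exonic = cbind(start = 0L, end = nchar(tx$seq)))
      if (tx$utr5[2] > tx$utr5[1]) feats$utr5 <- rbind(tx$utr5)
      if (tx$utr3[2] > tx$utr3[1]) feats$utr3 <- rbind(tx$utr3)
      feats <- lapply(feats, function(m) {
        colnames(m) <- c("start", "end"); m
      })
    }
    do.call(rbind, lapply(names(feats), function(f) {
      data.frame(ref = ref, start = feats[[f]][, "start"],
                 end = feats[[f]][, "end"], feature = f,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, grs)
  GenomicRanges::GRanges(df$ref,
                         IRanges::IRanges(df$start + 1L, df$end),
                         feature = df$feature)
}

#' Annotate hybrid reads with transcript regions
#'
#' Each read takes the union of overlap flags (`exonic`, `intronic`,
#' `utr5`, `utr3`) over all overlapping transcripts; the single region
#' label is then resolved by priority: 3'UTR if the read overlaps any
#' 3'UTR, else CDS if exonic and not 5'UTR, else 5'UTR, else intron;
#' reads overlapping no transcript are marked `discarded_intergenic`.
#'
#' @param reads Hybrid-read data.frame.
#' @param transcripts List of `transcript_model`s.
#' @return The reads with logical flag columns and a `region` column.
#' @export
annotate_region <- function(reads, transcripts) {
  feats <- transcript_features(transcripts)
  q <- GenomicRanges::GRanges(reads$ref,
                              IRanges::IRanges(reads$start + 1L, reads$end))
  for (f in c("exonic", "intronic", "utr5", "utr3")) {
    sub <- feats[S4Vectors::mcols(feats)$feature == f]
    # references absent from the transcript set (intergenic contigs)
    # are legitimate queries, so the seqlevel mismatch is expected
    reads[[f]] <- suppressWarnings(IRanges::overlapsAny(q, sub))
  }
  reads$region <- ifelse(reads$utr3, "UTR3",
                  ifelse(reads$exonic & !reads$utr5, "CDS",
                  ifelse(reads$utr5, "UTR5",
                  ifelse(reads$intronic, "intron", "discarded_intergenic"))))
  reads
}

#' Collapse duplicate hybrid reads
#'
#' Reads with identical target interval (reference, start, end, strand)
#' and miRNA are merged into one entry whose `count` is the sum of the
#' collapsed counts; the total count is conserved.
#'
#' @param reads Hybrid-read data.frame (post-expansion).
#' @return Collapsed data.frame.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  key <- paste(reads$ref, reads$start, reads$end, reads$strand,
               reads$mirna_id, sep = "\r")
  counts <- tapply(reads$count, key, sum)
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(counts[key[first]])
  rownames(out) <- NULL
  out
}

#' Attach duplex predictions to annotated hybrids
#'
#' Retrieves each read's target fragment in mRNA (5'->3') orientation —
#' reverse-complementing minus-strand genomic fragments — and runs
#' [predict_duplex()] against the read's miRNA. Reads naming an unknown
#' miRNA are flagged (`mirna_known = FALSE`) and later excluded from
#' pairing matrices.
#'
#' @param reads Annotated hybrid-read data.frame.
#' @param sequences Named character vector of reference sequences
#'   (chromosomes or spliced transcripts), RNA alphabet.
#' @param mirnas Named character vector of miRNA sequences.
#' @param params [duplex_params()].
#' @return The reads with `mirna_known`, `dot_bracket`, `score` columns
#'   and a `duplex` list-column.
#' @export
hybrid_duplexes <- function(reads, sequences, mirnas,
                            params = duplex_params()) {
  stopifnot(all(reads$ref %in% names(sequences)))
  reads$mirna_known <- reads$mirna_id %in% names(mirnas)
  n <- nrow(reads)
  dlist <- vector("list", n)
  db <- rep(NA_character_, n); sc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!reads$mirna_known[i]) next
    frag <- substr(sequences[[reads$ref[i]]], reads$start[i] + 1L,
                   reads$end[i])
    if (!is.null(reads$strand) && identical(reads$strand[i], "-")) {
      frag <- reverse_complement(frag)
    }
    d <- predict_duplex(mirnas[[reads$mirna_id[i]]], frag, params,
                        mirna_id = reads$mirna_id[i])
    dlist[[i]] <- d
    db[i] <- d$dot_bracket
    sc[i] <- d$score
  }
  reads$dot_bracket <- db
  reads$score <- sc
  reads$duplex <- dlist
  reads
}

#' Anchored base-pairing profile matrix
#'
#' Stacks the per-hybrid miRNA pairing vectors of one region class into
#' a matrix, aligning miRNAs of different lengths at their 5' or 3'
#' ends, and computes the (count-weighted) fraction of reads paired at
#' each slot — the aggregate pairing-pattern profile.
#'
#' @param reads Hybrid data.frame with attached duplexes.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param region Region class to profile (`"UTR3"`, `"CDS"`, ...), or
#'   `NULL` for all non-discarded reads.
#' @param width Slot count; defaults to the maximum miRNA length among
#'   contributing hybrids.
#' @param weighted Weight rows by duplicate `count` (default `TRUE`).
#' @return A `pairing_matrix` list: `rows` (logical matrix), `weights`,
#'   `col_fraction`, `anchor`, `region`, `width`.
#' @export
pairing_matrices <- function(reads, anchor = c("five_prime", "three_prime"),
                             region = NULL, width = NULL,
                             weighted = TRUE) {
  anchor <- match.arg(anchor)
  keep <- reads$mirna_known & !vapply(reads$duplex, is.null, logical(1))
  if (!is.null(region)) keep <- keep & reads$region == region
  sel <- reads[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(structure(list(rows = matrix(logical(0), 0, 0),
                          weights = numeric(0), col_fraction = numeric(0),
                          anchor = anchor, region = region, width = 0L),
                     class = "pairing_matrix"))
  }
  if (is.null(width)) {
    width <- max(vapply(sel$duplex, `[[`, integer(1), "mirna_len"))
  }
  rows <- t(vapply(sel$duplex, pairing_vector, logical(width),
                   anchor = anchor, width = width))
  w <- if (weighted) sel$count else rep(1, nrow(sel))
  col_fraction <- colSums(rows * w) / sum(w)
  structure(list(rows = rows, weights = w, col_fraction = col_fraction,
                 anchor = anchor, region = region, width = width),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat(sprintf("<pairing_matrix> %s%s  %d hybrids x %d slots\n",
              x$anchor, if (is.null(x$region)) "" else
                paste0(" / ", x$region), nrow(x$rows), x$width))
  invisible(x)
}

#' Region summary of annotated hybrid reads
#'
#' Count-weighted fraction of reads per region among non-discarded
#' reads; fractions sum to 1. Discarded (intergenic) reads are
#' reported separately via the `n_discarded` attribute.
#'
#' @param reads Annotated hybrid-read data.frame.
#' @return Data.frame with `region`, `count`, `fraction`.
#' @export
region_summary <- function(reads) {
  kept <- reads[reads$region != "discarded_intergenic", , drop = FALSE]
  counts <- tapply(kept$count, kept$region, sum)
  out <- data.frame(region = names(counts),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_discarded") <-
    sum(reads$count[reads$region == "discarded_intergenic"])
  out
}

#' Run the full hybrid-read pipeline
#'
#' Expansion (before annotation and collapsing, so that "identical
#' target intervals" is evaluated on the nibbling-compensated
#' intervals), region annotation, duplicate collapsing and duplex
#' calls, in the order the stages are designed to compose.
#'
#' @param reads Raw hybrid-read data.frame.
#' @param transcripts List of `transcript_model`s.
#' @param sequences Named reference sequences.
#' @param mirnas Named miRNA sequences.
#' @param pad Interval expansion (default 3).
#' @param params [duplex_params()].
#' @return Annotated, collapsed hybrid data.frame with duplexes.
#' @export
clash_pipeline <- function(reads, transcripts, sequences, mirnas,
                           pad = 3L, params = duplex_params()) {
  bounds <- vapply(sequences, nchar, integer(1))
  reads <- expand_intervals(reads, pad = pad, bounds = bounds)
  reads <- collapse_duplicates(reads)
  reads <- annotate_region(reads, transcripts)
  hybrid_duplexes(reads, sequences, mirnas, params)
}

#' Write an annotated hybrid table to TSV
#'
#' Mirrors the processed supplementary layout: interval, miRNA, overlap
#' flags, region, dot-bracket, score, counts (the duplex list-column is
#' dropped).
#'
#' @param reads Annotated hybrid data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotated_hybrids <- function(reads, path) {
  reads$duplex <- NULL
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
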