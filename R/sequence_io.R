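#' @useDynLib mircds, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")

#' miRNA position zones
#'
#' Named 1-based position ranges on a miRNA of length `L`: the seed
#' (nt 2-8), the central/cleavage extension (nt 9-12), the supplementary
#' region (nt 12-17) and the three 3'-terminal nucleotides.
#'
#' @param L miRNA length (nucleotides).
#' @return Named list of integer vectors.
#' @export
mirna_zones <- function(L) {
  stopifnot(L >= 16L)
  list(
    seed = 2:8,
    central = 9:12,
    supplementary = 12:17,
    three_prime_terminal = (L - 2L):L
  )
}

check_rna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-RNA characters (allowed: A,C,G,U): %s",
                 what, substr(seq[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A<->U, C<->G), reversed. Input must be
#' upper-case RNA.
#'
#' @param seq Character vector of RNA sequences (5'->3').
#' @return Character vector of reverse complements (5'->3').
#' @export
reverse_complement <- function(seq) {
  check_rna(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file of sequences
#'
#' Sequences are upper-cased; when `alphabet = "RNA"`, T is
#' transliterated to U (miRBase-style RNA and genome-style DNA FASTA
#' differ only in that letter). Mixed or unexpected characters and
#' duplicate or empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"RNA"` (default; T->U applied) or `"DNA"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record: ", ids[nchar(seqs) == 0][1], call. = FALSE)
  }
  if (alphabet == "RNA") {
    seqs <- chartr("T", "U", seqs)
    check_rna(seqs, "FASTA record")
  } else if (any(grepl("[^ACGTN]", seqs))) {
    stop("non-DNA characters in FASTA", call. = FALSE)
  }
  names(seqs) <- ids
  message(sprintf("read_fasta: %d records from %s", length(seqs), path))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Load a set of miRNAs from FASTA
#'
#' Validates the miRNA invariants: RNA alphabet, length 16-28 nt,
#' unique identifiers.
#'
#' @param path FASTA path (T is accepted and transliterated to U).
#' @return Named character vector of miRNA sequences.
#' @export
read_mirnas <- function(path) {
  seqs <- read_fasta(path, alphabet = "RNA")
  validate_mirnas(seqs)
}

#' Validate a miRNA collection
#'
#' @param seqs Named character vector of RNA sequences.
#' @return `seqs`, invisibly validated (returned visibly).
#' @export
validate_mirnas <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  check_rna(seqs, "miRNA")
  len <- nchar(seqs)
  if (any(len < 16 | len > 28)) {
    stop("miRNA length out of range 16-28: ",
         names(seqs)[len < 16 | len > 28][1], call. = FALSE)
  }
  seqs
}

# ---- transcript models ------------------------------------------------

new_transcript_model <- function(id, seq, utr5, cds, utr3,
                                 chrom = NA_character_, strand = "+",
                                 exons = NULL, coding = TRUE) {
  structure(
    list(id = id, seq = seq, utr5 = utr5, cds = cds, utr3 = utr3,
         chrom = chrom, strand = strand, exons = exons, coding = coding),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s  %dnt  5'UTR[%d,%d) CDS[%d,%d) 3'UTR[%d,%d)%s\n",
    x$id, nchar(x$seq), x$utr5[1], x$utr5[2], x$cds[1], x$cds[2],
    x$utr3[1], x$utr3[2],
    if (!is.na(x$chrom)) sprintf("  %s(%s)", x$chrom, x$strand) else ""
  ))
  invisible(x)
}

#' Region interval of a transcript model
#'
#' @param tx A `transcript_model`.
#' @param region One of `"UTR5"`, `"CDS"`, `"UTR3"`.
#' @return Integer `c(start, end)`, 0-based half-open on the spliced
#'   sequence.
#' @export
tx_region <- function(tx, region = c("CDS", "UTR3", "UTR5")) {
  region <- match.arg(region)
  switch(region, UTR5 = tx$utr5, CDS = tx$cds, UTR3 = tx$utr3)
}

#' Load transcript models from BED12 + genome FASTA
#'
#' Assembles the spliced 5'->3' mRNA sequence of each BED12 record from
#' its exon blocks, reverse-complementing minus-strand models, and
#' projects thickStart/thickEnd into spliced coordinates to delimit the
#' 5'UTR, CDS and 3'UTR (all 0-based half-open). Records with
#' `thickStart == thickEnd` are flagged non-coding with an empty CDS.
#'
#' @param bed12_path Path to a BED12 file.
#' @param fasta_path Path to a genome FASTA keyed by chromosome.
#' @return List of `transcript_model` objects, named by transcript id.
#' @export
load_transcript_models <- function(bed12_path, fasta_path) {
  genome <- read_fasta(fasta_path, alphabet = "RNA")
  gr <- rtracklayer::import(bed12_path, format = "BED")
  models <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) strand <- "+"
    if (!chrom %in% names(genome)) {
      stop("missing sequence for chromosome ", chrom, call. = FALSE)
    }
    chrom_start <- GenomicRanges::start(gr[i]) - 1L   # back to 0-based
    blocks <- gr$blocks[[i]]                          # 1-based, relative
    bstart <- chrom_start + IRanges::start(blocks) - 1L  # 0-based genomic
    bend <- chrom_start + IRanges::end(blocks)           # half-open
    tstart <- IRanges::start(gr$thick)[i] - 1L
    tend <- IRanges::end(gr$thick)[i]
    pieces <- substring(genome[[chrom]], bstart + 1L, bend)
    plus_seq <- paste(pieces, collapse = "")
    slen <- sum(bend - bstart)
    # project a 0-based genomic position (must fall in a block, or at a
    # block end for half-open ends) onto 0-based plus-strand spliced coords
    offsets <- cumsum(c(0L, bend - bstart))
    project <- function(g, is_end = FALSE) {
      k <- which(g >= bstart & g < bend)
      if (length(k) == 0 && is_end) k <- which(g == bend)
      if (length(k) == 0) {
        stop("thick interval outside exon blocks in ", gr$name[i],
             call. = FALSE)
      }
      offsets[k[1]] + (g - bstart[k[1]])
    }
    coding <- tend > tstart
    if (coding) {
      s5 <- project(tstart)
      s3 <- project(tend, is_end = TRUE)
    } else {
      s5 <- s3 <- slen
    }
    if (strand == "+") {
      seq <- plus_seq
      utr5 <- c(0L, s5); cds <- c(s5, s3); utr3 <- c(s3, slen)
    } else {
      seq <- reverse_complement(plus_seq)
      utr5 <- c(0L, slen - s3); cds <- c(slen - s3, slen - s5)
      utr3 <- c(slen - s5, slen)
    }
    if (!coding) { utr5 <- c(0L, 0L); cds <- c(0L, 0L); utr3 <- c(0L, slen) }
    models[[i]] <- new_transcript_model(
      id = gr$name[i], seq = seq, utr5 = utr5, cds = cds, utr3 = utr3,
      chrom = chrom, strand = strand,
      exons = cbind(start = bstart, end = bend), coding = coding
    )
  }
  names(models) <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(names(models))) {
    stop("duplicate transcript id in BED12", call. = FALSE)
  }
  message(sprintf("load_transcript_models: %d models from %s",
                  length(models), bed12_path))
  models
}

# ---- hybrid read tables -----------------------------------------------

#' Column dialect for hybrid-read tables
#'
#' Processed CLASH/CLEAR-CLIP tables differ in column naming and
#' coordinate convention; a dialect maps them onto the internal
#' 0-based half-open representation.
#'
#' @param ref,start,end,mirna Column names for the target reference,
#'   interval and miRNA identifier.
#' @param count,strand Optional column names; when absent, count
#'   defaults to 1 and strand to `"+"`.
#' @param one_based If `TRUE`, input intervals are 1-based inclusive
#'   and converted on read.
#' @param header Whether the TSV has a header row.
#' @return A `hybrid_dialect` list.
#' @export
hybrid_dialect <- function(ref = "ref", start = "start", end = "end",
                           mirna = "mirna_id", count = NULL,
                           strand = NULL, one_based = FALSE,
                           header = TRUE) {
  structure(list(ref = ref, start = start, end = end, mirna = mirna,
                 count = count, strand = strand, one_based = one_based,
                 header = header),
            class = "hybrid_dialect")
}

#' Read a hybrid (chimeric) read table
#'
#' Each row is one CLASH chimera: the mapped target interval and the
#' name of the ligated miRNA. Coordinates are normalised to 0-based
#' half-open; rows whose interval is empty or inverted are dropped with
#' a warning rather than aborting the run.
#'
#' @param path TSV path.
#' @param dialect A [hybrid_dialect()].
#' @return `data.frame` with columns `ref`, `start`, `end`, `strand`,
#'   `mirna_id`, `count`.
#' @export
read_hybrid_table <- function(path, dialect = hybrid_dialect()) {
  raw <- utils::read.delim(path, header = dialect$header,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!dialect$header) {
    base_cols <- c(dialect$ref, dialect$start, dialect$end, dialect$mirna,
                   dialect$count, dialect$strand)
    names(raw)[seq_along(base_cols)] <- base_cols
  }
  need <- c(dialect$ref, dialect$start, dialect$end, dialect$mirna)
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("hybrid table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(raw[[dialect$start]]))
  end <- suppressWarnings(as.integer(raw[[dialect$end]]))
  if (dialect$one_based) start <- start - 1L
  count <- if (!is.null(dialect$count) && dialect$count %in% names(raw)) {
    suppressWarnings(as.integer(raw[[dialect$count]]))
  } else rep(1L, nrow(raw))
  strand <- if (!is.null(dialect$strand) && dialect$strand %in% names(raw)) {
    as.character(raw[[dialect$strand]])
  } else rep("+", nrow(raw))
  out <- data.frame(
    ref = as.character(raw[[dialect$ref]]),
    start = start, end = end, strand = strand,
    mirna_id = as.character(raw[[dialect$mirna]]),
    count = count, stringsAsFactors = FALSE
  )
  bad <- is.na(out$start) | is.na(out$end) | out$start >= out$end |
    is.na(out$count) | out$count < 1L
  if (any(bad)) {
    warning(sprintf("read_hybrid_table: dropped %d malformed row(s)",
                    sum(bad)), call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  message(sprintf("read_hybrid_table: %d reads from %s", nrow(out), path))
  out
}

#' Write a hybrid-read table (internal 0-based dialect)
#'
#' @param reads Hybrid-read `data.frame` as returned by
#'   [read_hybrid_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hybrid_table <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
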