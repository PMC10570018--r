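# Transcriptome-wide search for extensively complementary miRNA sites:
# exact matching of the reverse complement of the seed+cleavage anchor
# (miRNA nt 2-12 by default) followed by gapless antiparallel extension
# across the full miRNA and a mismatch budget on the remaining
# interface. Bulged candidates are deliberately out of scope here (the
# duplex module handles them); the anchor is matched without wobble,
# while G:U outside the anchor counts as a match by default.

#' Scan parameters
#'
#' @param anchor_range Integer range of miRNA positions requiring full
#'   complementarity (default 2:12, the seed + cleavage region).
#' @param max_mismatches_rest Mismatch budget outside the anchor
#'   (settings of interest: 2 and 3).
#' @param require_3prime_terminal_3 Require perfect pairing of the
#'   three 3'-terminal miRNA nucleotides.
#' @param regions Regions to scan, subset of `c("CDS", "UTR3")`.
#' @param gu_outside Count G:U wobble outside the anchor as a match.
#' @param mirna_allowlist Optional character vector of miRNA ids to
#'   restrict the scan to (e.g. an expression-filtered subset).
#' @return A `scan_params` list.
#' @export
scan_params <- function(anchor_range = 2:12, max_mismatches_rest = 2L,
                        require_3prime_terminal_3 = FALSE,
                        regions = "CDS", gu_outside = TRUE,
                        mirna_allowlist = NULL) {
  stopifnot(all(diff(anchor_range) == 1), min(anchor_range) >= 1,
            max_mismatches_rest >= 0,
            all(regions %in% c("CDS", "UTR3")))
  structure(list(anchor_range = as.integer(anchor_range),
                 max_mismatches_rest = as.integer(max_mismatches_rest),
                 require_3prime_terminal_3 = require_3prime_terminal_3,
                 regions = regions, gu_outside = gu_outside,
                 mirna_allowlist = mirna_allowlist),
            class = "scan_params")
}

# gapless duplex over a full-length site: pair k <-> site position L+1-k
gapless_site_duplex <- function(mirna, site_seq, gu = TRUE,
                                mirna_id = NULL) {
  L <- nchar(mirna)
  a <- substring(mirna, 1:L, 1:L)
  b <- substring(site_seq, L:1, L:1)
  ok <- can_pair(a, b, gu = gu)
  pairs <- cbind(which(ok), L + 1L - which(ok))
  new_duplex(mirna_id, L, L, pairs, score = NA_real_,
             gu_pairs = (a[ok] == "G" & b[ok] == "U") |
               (a[ok] == "U" & b[ok] == "G"),
             mode = "gapless")
}

#' Scan one transcript for candidate extensively-complementary sites
#'
#' Finds exact occurrences of the reverse complement of the miRNA
#' anchor within the selected region(s) of the spliced transcript,
#' extends each gaplessly to cover the full miRNA (antiparallel),
#' counts mismatches at positions outside the anchor, and keeps sites
#' within the budget. Sites truncated by the transcript ends are
#' discarded; sites straddling a region boundary are labelled by the
#' 3'UTR-priority rule.
#'
#' @param mirna miRNA sequence (5'->3' RNA).
#' @param tx A `transcript_model`.
#' @param params [scan_params()].
#' @param mirna_id Identifier reported in the result.
#' @param rules [mre_rules()] used to attach a functional class.
#' @return Data.frame of candidate sites (possibly 0 rows): interval on
#'   the spliced sequence (0-based half-open), region label, mismatch
#'   positions/count, 3'-terminal status and MRE class.
#' @export
scan_transcript <- function(mirna, tx, params = scan_params(),
                            mirna_id = NA_character_,
                            rules = mre_rules()) {
  L <- nchar(mirna)
  a1 <- min(params$anchor_range); a2 <- max(params$anchor_range)
  stopifnot(a2 <= L)
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      region = character(0), start = integer(0),
                      end = integer(0), n_mismatches_outside = integer(0),
                      mismatch_positions = character(0),
                      terminal3_perfect = logical(0), class = character(0),
                      stringsAsFactors = FALSE)
  region_iv <- lapply(params$regions, tx_region, tx = tx)
  if (all(vapply(region_iv, function(r) r[2] <= r[1], logical(1)))) {
    return(empty)
  }
  anchor_rc <- reverse_complement(substr(mirna, a1, a2))
  hits <- Biostrings::matchPattern(anchor_rc,
                                   Biostrings::RNAString(tx$seq))
  if (length(hits) == 0) return(empty)
  starts0 <- IRanges::start(hits) - 1L              # 0-based anchor starts
  anchor_w <- a2 - a1 + 1L
  # anchor occupies site-local positions (L+1-a2)..(L+1-a1);
  # site start (0-based) = anchor start - (L - a2)
  in_region <- vapply(starts0, function(s) {
    any(vapply(region_iv, function(r) s >= r[1] && s + anchor_w <= r[2],
               logical(1)))
  }, logical(1))
  starts0 <- starts0[in_region]
  if (length(starts0) == 0) return(empty)
  out <- lapply(starts0, function(as0) {
    site_start <- as0 - (L - a2)
    site_end <- site_start + L
    if (site_start < 0 || site_end > nchar(tx$seq)) return(NULL)
    site_seq <- substr(tx$seq, site_start + 1L, site_end)
    mk <- substring(mirna, 1:L, 1:L)
    sk <- substring(site_seq, L:1, L:1)
    match_ok <- can_pair(mk, sk, gu = params$gu_outside)
    outside <- setdiff(seq_len(L), a1:a2)
    mm <- outside[!match_ok[outside]]
    if (length(mm) > params$max_mismatches_rest) return(NULL)
    term_ok <- all(can_pair(mk[(L - 2):L], sk[(L - 2):L],
                            gu = params$gu_outside))
    if (params$require_3prime_terminal_3 && !term_ok) return(NULL)
    region <- if (site_end > tx$utr3[1] && tx$utr3[2] > tx$utr3[1] &&
                  site_start < tx$utr3[2]) "UTR3" else "CDS"
    dup <- gapless_site_duplex(mirna, site_seq, gu = params$gu_outside,
                               mirna_id = mirna_id)
    cl <- classify(zone_profile(dup), rules)
    data.frame(mirna_id = mirna_id, transcript_id = tx$id,
               region = region, start = site_start, end = site_end,
               n_mismatches_outside = length(mm),
               mismatch_positions = paste(mm, collapse = ";"),
               terminal3_perfect = term_ok, class = cl$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Scan a transcriptome with a set of miRNAs
#'
#' Applies [scan_transcript()] over every (miRNA, transcript) pair and
#' additionally tabulates candidate counts across mismatch budgets and
#' the 3'-terminal toggle (derived by filtering the most permissive
#' scan, so one pass suffices).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts List of `transcript_model`s.
#' @param params [scan_params()]; its budget is the one reported in
#'   `sites`.
#' @param budgets Budgets tabulated in the summary (default `c(2, 3)`).
#' @return List with `sites` (rows at the params budget/toggle) and
#'   `summary` (counts by budget x 3'-terminal requirement).
#' @export
scan_transcriptome <- function(mirnas, transcripts,
                               params = scan_params(),
                               budgets = c(2L, 3L)) {
  if (!is.null(params$mirna_allowlist)) {
    mirnas <- mirnas[names(mirnas) %in% params$mirna_allowlist]
  }
  stopifnot(length(mirnas) > 0, length(transcripts) > 0)
  loose <- params
  loose$max_mismatches_rest <- max(c(budgets, params$max_mismatches_rest))
  loose$require_3prime_terminal_3 <- FALSE
  all_sites <- list()
  for (mid in names(mirnas)) {
    for (tx in transcripts) {
      s <- scan_transcript(mirnas[[mid]], tx, loose, mirna_id = mid)
      if (nrow(s)) all_sites[[length(all_sites) + 1L]] <- s
    }
  }
  all_sites <- if (length(all_sites)) do.call(rbind, all_sites) else
    scan_transcript(mirnas[[1]], transcripts[[1]], params,
                    mirna_id = names(mirnas)[1])[0, ]
  keep <- all_sites$n_mismatches_outside <= params$max_mismatches_rest
  if (params$require_3prime_terminal_3) {
    keep <- keep & all_sites$terminal3_perfect
  }
  grid <- expand.grid(budget = budgets, require_3p_terminal = c(TRUE, FALSE))
  grid$n_sites <- vapply(seq_len(nrow(grid)), function(i) {
    k <- all_sites$n_mismatches_outside <= grid$budget[i]
    if (grid$require_3p_terminal[i]) k <- k & all_sites$terminal3_perfect
    sum(k)
  }, integer(1))
  list(sites = all_sites[keep, , drop = FALSE], summary = grid)
}

#' Write scan results to TSV
#'
#' @param scan Result of [scan_transcriptome()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_scan_results <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "candidate_sites.tsv")
  mp <- file.path(dir, "scan_summary.tsv")
  utils::write.table(scan$sites, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$summary, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sites = sp, summary = mp))
}
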