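# Independent oracles used to cross-check the package implementations.
# They deliberately share no code with the implementation paths.

RNA4 <- c("A", "C", "G", "U")

rand_rna <- function(n) paste(sample(RNA4, n, replace = TRUE),
                              collapse = "")

# Exhaustive enumeration of all antiparallel non-crossing intermolecular
# pairings (helix runs >= 2), scored by the same model definition:
# pair weights, interior-loop penalty gap_open + gap_extend * total
# unpaired between helices, free dangling ends. Returns the optimum.
oracle_duplex_score <- function(mirna, target, params = duplex_params()) {
  mi <- strsplit(mirna, "")[[1]]
  tg <- rev(strsplit(target, "")[[1]])  # reversed: pairs are co-linear
  m <- length(mi); n <- length(tg)
  wt <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(params$gc)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(params$au)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(params$gu)
    0
  }
  W <- matrix(0, m, n)
  for (i in seq_len(m)) for (k in seq_len(n)) W[i, k] <- wt(mi[i], tg[k])
  best <- 0
  rec <- function(i0, k0, li, lk, run, score) {
    if (run != 1L && score > best) best <<- score
    if (i0 > m || k0 > n) return()
    for (i in i0:m) {
      for (k in k0:n) {
        w <- W[i, k]
        if (w == 0) next
        if (run == 0L) {                      # very first pair
          rec(i + 1L, k + 1L, i, k, 1L, w)
        } else if (i == li + 1L && k == lk + 1L) {  # helix continuation
          rec(i + 1L, k + 1L, i, k, run + 1L, score + w)
        } else if (run >= 2L) {               # close helix, open another
          g <- (i - li - 1L) + (k - lk - 1L)
          rec(i + 1L, k + 1L, i, k, 1L,
              score + w - (params$gap_open + params$gap_extend * g))
        }
      }
    }
  }
  rec(1L, 1L, 0L, 0L, 0L, 0)
  best
}

# All-windows scanner oracle: tests every full-length window of the
# spliced sequence against the anchor/extension/budget definition by
# direct per-position comparison (vectorised over window starts).
oracle_scan <- function(mirna, tx, params) {
  L <- nchar(mirna)
  a1 <- min(params$anchor_range); a2 <- max(params$anchor_range)
  seqv <- strsplit(tx$seq, "")[[1]]
  n <- length(seqv)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_mismatches_outside = integer(0))
  if (n < L) return(empty)
  mk <- strsplit(mirna, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  nw <- n - L + 1L
  wc <- pairok <- matrix(FALSE, nw, L)
  for (k in seq_len(L)) {
    b <- seqv[(L - k + 1L):(n - k + 1L)]   # base opposite miRNA pos k
    wc[, k] <- b == comp[[mk[k]]]
    gu <- (mk[k] == "G" & b == "U") | (mk[k] == "U" & b == "G")
    pairok[, k] <- wc[, k] | (params$gu_outside & gu)
  }
  anchor_ok <- rowSums(wc[, a1:a2, drop = FALSE]) == (a2 - a1 + 1L)
  outside <- setdiff(seq_len(L), a1:a2)
  mm <- length(outside) - rowSums(pairok[, outside, drop = FALSE])
  term_ok <- rowSums(pairok[, (L - 2L):L, drop = FALSE]) == 3L
  s0 <- seq_len(nw) - 1L
  astart <- s0 + L - a2; aend <- s0 + L - a1 + 1L
  in_region <- rep(FALSE, nw)
  for (rg in params$regions) {
    iv <- tx_region(tx, rg)
    in_region <- in_region | (astart >= iv[1] & aend <= iv[2])
  }
  keep <- anchor_ok & mm <= params$max_mismatches_rest & in_region
  if (params$require_3prime_terminal_3) keep <- keep & term_ok
  data.frame(start = s0[keep], end = s0[keep] + L,
             n_mismatches_outside = as.integer(mm[keep]))
}

# bare transcript model for unit tests (transcript-local coordinates)
toy_tx <- function(seq, utr5 = 0L, cds = nchar(seq), id = "tx1") {
  slen <- nchar(seq)
  mircds:::new_transcript_model(
    id = id, seq = seq, utr5 = c(0L, utr5),
    cds = c(utr5, utr5 + cds), utr3 = c(utr5 + cds, slen))
}
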