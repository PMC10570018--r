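# Intermolecular miRNA:target duplex prediction.
#
# The default scoring mode is a self-contained base-pair-weight model
# with interior-loop penalties, solved exactly by dynamic programming
# over non-crossing antiparallel pairings; an adapter mode ingests
# dot-bracket strings (and free energies) produced by an external
# nearest-neighbour duplex folder in the two-part "query&target"
# notation. Downstream classification consumes only the pairing map,
# which both modes provide.

PAIR_WEIGHT_DEFAULT <- c(GC = 3, AU = 2, GU = 1)

#' Scoring parameters for duplex prediction
#'
#' @param gc,au,gu Weights for G:C, A:U and G:U (wobble) pairs.
#'   Set `gu = 0` to forbid wobble pairs.
#' @param gap_open,gap_extend Penalty for an interior loop/bulge
#'   between two helices: `gap_open + gap_extend * g` where `g` is the
#'   total number of unpaired bases (both strands) enclosed by the
#'   flanking pairs. Dangling ends are free.
#' @param min_helix Minimum run of consecutive pairs (fixed at 2:
#'   isolated pairs are not stable and are never reported).
#' @return A `duplex_params` list.
#' @export
duplex_params <- function(gc = 3, au = 2, gu = 1, gap_open = 4,
                          gap_extend = 1, min_helix = 2L) {
  stopifnot(min_helix == 2L, gc > 0, au > 0, gu >= 0)
  structure(list(gc = gc, au = au, gu = gu, gap_open = gap_open,
                 gap_extend = gap_extend, min_helix = min_helix),
            class = "duplex_params")
}

base_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_ALPHABET) - 1L
}

pair_weight_matrix <- function(params) {
  w <- matrix(0, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  w["A", "U"] <- w["U", "A"] <- params$au
  w["G", "C"] <- w["C", "G"] <- params$gc
  w["G", "U"] <- w["U", "G"] <- params$gu
  w
}

#' Can two RNA bases pair?
#'
#' @param a,b Single upper-case RNA bases (vectorised).
#' @param gu Count G:U wobble as a pair.
#' @return Logical vector.
#' @export
can_pair <- function(a, b, gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (gu) wc | (a == "G" & b == "U") | (a == "U" & b == "G") else wc
}

new_duplex <- function(mirna_id, mirna_len, target_len, pairs, score,
                       dot_bracket = NULL, gu_pairs = NULL,
                       target = NULL, mode = "internal") {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("mirna_pos", "target_pos")))
  if (nrow(pairs) > 1) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (is.null(dot_bracket)) {
    dot_bracket <- emit_dot_bracket(pairs, mirna_len, target_len)
  }
  structure(list(mirna_id = mirna_id, mirna_len = as.integer(mirna_len),
                 target_len = as.integer(target_len), pairs = pairs,
                 score = score, dot_bracket = dot_bracket,
                 gu_pairs = gu_pairs, target = target, mode = mode),
            class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  cat(sprintf("<duplex> %s  %d pairs  score %.2f (%s)\n  %s\n",
              if (is.null(x$mirna_id)) "<miRNA>" else x$mirna_id,
              nrow(x$pairs), x$score, x$mode, x$dot_bracket))
  invisible(x)
}

#' Predict the optimal miRNA:target duplex
#'
#' Finds the maximum-score non-crossing intermolecular pairing between
#' a miRNA and a target window by dynamic programming (hybridization
#' only; no intramolecular structure). Ties are broken deterministically
#' in favour of more paired miRNA bases, then the 5'-most paired target
#' base.
#'
#' @param mirna miRNA sequence, 5'->3' RNA.
#' @param target_window Target sequence window, 5'->3' RNA (>= 4 nt).
#' @param params [duplex_params()].
#' @param mirna_id Optional identifier carried on the result.
#' @return A `duplex` object: `pairs` (1-based positions from each 5'
#'   end), `dot_bracket` in "miRNA&target" notation, and `score`
#'   (dimensionless; higher is better).
#' @export
predict_duplex <- function(mirna, target_window, params = duplex_params(),
                           mirna_id = NULL) {
  check_rna(mirna, "miRNA"); check_rna(target_window, "target window")
  if (nchar(target_window) < 4) {
    stop("target window shorter than 4 nt", call. = FALSE)
  }
  mi <- base_codes(mirna)
  tg <- base_codes(target_window)
  res <- duplex_dp_cpp(mi, tg, pair_weight_matrix(params),
                       params$gap_open, params$gap_extend)
  pairs <- res$pairs
  gu <- if (nrow(pairs)) {
    a <- substring(mirna, pairs[, 1], pairs[, 1])
    b <- substring(target_window, pairs[, 2], pairs[, 2])
    (a == "G" & b == "U") | (a == "U" & b == "G")
  } else logical(0)
  new_duplex(mirna_id, nchar(mirna), nchar(target_window), pairs,
             res$score, gu_pairs = gu, mode = "internal")
}

#' Emit two-part dot-bracket notation for a pairing map
#'
#' @param pairs Two-column matrix of (miRNA position, target position),
#'   both 1-based from their 5' ends.
#' @param len_mirna,len_target Sequence lengths.
#' @return A string `"mirna-part&target-part"` using `(`, `)` and `.`.
#' @export
emit_dot_bracket <- function(pairs, len_mirna, len_target) {
  p1 <- rep(".", len_mirna); p2 <- rep(".", len_target)
  if (NROW(pairs)) {
    p1[pairs[, 1]] <- "("
    p2[pairs[, 2]] <- ")"
  }
  paste0(paste(p1, collapse = ""), "&", paste(p2, collapse = ""))
}

#' Parse two-part dot-bracket notation into a pairing map
#'
#' The k-th `(` of the miRNA part is matched with the k-th-from-last
#' `)` of the target part (the standard last-open/first-close
#' intermolecular rule). This is the inverse of [emit_dot_bracket()]
#' and enables ingesting output of external duplex folders.
#'
#' @param db Dot-bracket string containing exactly one `&`.
#' @param len_mirna,len_target Expected part lengths.
#' @return Two-column integer matrix of (miRNA position, target
#'   position) pairs.
#' @export
parse_dot_bracket <- function(db, len_mirna, len_target) {
  parts <- strsplit(db, "&", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("dot-bracket must contain exactly one '&'",
                               call. = FALSE)
  c1 <- strsplit(parts[1], "", fixed = TRUE)[[1]]
  c2 <- strsplit(parts[2], "", fixed = TRUE)[[1]]
  if (length(c1) != len_mirna || length(c2) != len_target) {
    stop("dot-bracket part lengths do not match declared lengths",
         call. = FALSE)
  }
  if (any(!c1 %in% c("(", ".")) || any(!c2 %in% c(")", "."))) {
    stop("intramolecular or unknown brackets: only '(' allowed in the ",
         "miRNA part and ')' in the target part", call. = FALSE)
  }
  open <- which(c1 == "(")
  close <- which(c2 == ")")
  if (length(open) != length(close)) {
    stop("unbalanced brackets across the two parts", call. = FALSE)
  }
  cbind(mirna_pos = open, target_pos = rev(close))
}

#' Construct a duplex from an externally predicted dot-bracket
#'
#' Adapter for nearest-neighbour duplex folders that report a two-part
#' dot-bracket and a free energy: the pairing map is parsed and carried
#' with the energy as the score (kcal/mol; lower = more stable).
#'
#' @param db Dot-bracket string.
#' @param mirna,target_window The two sequences (for length and wobble
#'   bookkeeping).
#' @param energy Free energy reported by the external folder.
#' @param mirna_id Optional identifier.
#' @return A `duplex` object with `mode = "external"`.
#' @export
duplex_from_dot_bracket <- function(db, mirna, target_window, energy = NA_real_,
                                    mirna_id = NULL) {
  pairs <- parse_dot_bracket(db, nchar(mirna), nchar(target_window))
  gu <- if (nrow(pairs)) {
    a <- substring(mirna, pairs[, 1], pairs[, 1])
    b <- substring(target_window, pairs[, 2], pairs[, 2])
    (a == "G" & b == "U") | (a == "U" & b == "G")
  } else logical(0)
  new_duplex(mirna_id, nchar(mirna), nchar(target_window), pairs, energy,
             dot_bracket = db, gu_pairs = gu, mode = "external")
}

#' Anchored per-position pairing vector of a duplex
#'
#' Projects the miRNA-side pairing state onto a fixed-width slot vector
#' so that miRNAs of different lengths can be stacked: with
#' `anchor = "five_prime"` slot k reports miRNA position k; with
#' `anchor = "three_prime"` the vector is right-aligned (slot
#' `width - L + k` reports position k).
#'
#' @param duplex A `duplex`.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param width Slot count, `>= ` miRNA length.
#' @return Logical vector of length `width`.
#' @export
pairing_vector <- function(duplex, anchor = c("five_prime", "three_prime"),
                           width) {
  anchor <- match.arg(anchor)
  L <- duplex$mirna_len
  if (width < L) stop("width smaller than miRNA length", call. = FALSE)
  v <- logical(width)
  paired <- duplex$pairs[, 1]
  if (anchor == "five_prime") v[paired] <- TRUE
  else v[width - L + paired] <- TRUE
  v
}
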