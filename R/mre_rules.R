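# Rule-based classification of miRNA-response-element functionality,
# encoding the reporter-mutagenesis taxonomy: repression through CDS
# sites requires extensive complementarity including a perfect seed;
# contiguous pairing across nt 2-12 licenses AGO2-mediated slicing; a
# central bulge of 1 nt preserves repression, 2 nt weakens it, >= 3 nt
# abolishes it; 3'-terminal pairing is dispensable within a small
# interface mismatch budget.

MRE_LEVELS <- c("NONFUNCTIONAL", "WEAK", "REPRESSIVE", "SLICING")

#' Rank of an MRE functional class
#'
#' @param label Class label(s).
#' @return Integer rank: NONFUNCTIONAL = 0 ... SLICING = 3.
#' @export
mre_rank <- function(label) {
  match(label, MRE_LEVELS) - 1L
}

#' Classification rule set
#'
#' Thresholds of the functional taxonomy, configurable because the
#' underlying reporter data show a dose-response rather than sharp
#' cut-offs.
#'
#' @param max_outside_mismatches Budget of unpaired miRNA nucleotides
#'   outside positions 2-12 (default 3; tighten to 2 to match the
#'   genome-wide scan's strict setting).
#' @param central_bulge_weak Central bulge size classed WEAK (default 2).
#' @param central_bulge_dead Central bulge size abolishing function
#'   (default 3; must exceed `central_bulge_weak`).
#' @param require_three_prime_terminal If `TRUE`, SLICING additionally
#'   requires the three 3'-terminal nucleotides paired.
#' @return A `mre_rules` list.
#' @export
mre_rules <- function(max_outside_mismatches = 3L,
                      central_bulge_weak = 2L,
                      central_bulge_dead = 3L,
                      require_three_prime_terminal = FALSE) {
  stopifnot(central_bulge_weak < central_bulge_dead,
            max_outside_mismatches >= 0L)
  structure(list(max_outside_mismatches = max_outside_mismatches,
                 central_bulge_weak = central_bulge_weak,
                 central_bulge_dead = central_bulge_dead,
                 require_three_prime_terminal = require_three_prime_terminal),
            class = "mre_rules")
}

#' Per-zone pairing profile of a duplex
#'
#' Summarises the pairing map by miRNA zone: the seed (nt 2-8), the
#' seed+cleavage region (nt 2-12), the central bulge (unpaired miRNA
#' nt within 9-12 plus target-side insertions bounded by pairs in
#' 9-12), the supplementary region (nt 12-17) and the three 3'-terminal
#' nucleotides. Seed pairing requires contiguity on the target side:
#' a target-side bulge inside the seed counts as a seed imperfection.
#'
#' @param duplex A `duplex` object.
#' @param mirna Optional miRNA sequence (consistency check only).
#' @param seed_gu Count G:U wobbles in the seed as paired (default
#'   `TRUE`; setting `FALSE` needs a duplex that carries base
#'   identities, i.e. one built from sequences).
#' @return A `zone_profile` list; see fields in the description.
#' @export
zone_profile <- function(duplex, mirna = NULL, seed_gu = TRUE) {
  L <- duplex$mirna_len
  if (!is.null(mirna) && nchar(mirna) != L) {
    stop("duplex does not belong to this miRNA (length mismatch)",
         call. = FALSE)
  }
  pairs <- duplex$pairs
  if (!seed_gu) {
    if (is.null(duplex$gu_pairs)) {
      stop("seed_gu = FALSE requires a duplex with base identities",
           call. = FALSE)
    }
    drop <- duplex$gu_pairs & pairs[, 1] >= 2 & pairs[, 1] <= 8
    pairs <- pairs[!drop, , drop = FALSE]
  }
  paired <- logical(L)
  paired[pairs[, 1]] <- TRUE
  tpos <- rep(NA_integer_, L)
  tpos[pairs[, 1]] <- pairs[, 2]

  truncated <- L < 17L
  zones <- list(seed = 2:8, central = 9:12,
                supplementary = 12:min(17L, L),
                terminal = (L - 2L):L)

  # target-side insertion between consecutive paired miRNA positions:
  # antiparallel, so target positions decrease as miRNA positions
  # increase; gap beyond the miRNA-side gap is an insertion.
  contiguous <- function(range) {
    idx <- which(paired & seq_len(L) %in% range)
    if (length(idx) < 2) return(TRUE)
    all(diff(tpos[idx]) == -diff(idx))
  }
  seed_paired <- all(paired[zones$seed]) && contiguous(zones$seed)
  seed_cleave_paired <- all(paired[2:12]) && contiguous(2:12)

  central_unpaired <- sum(!paired[zones$central])
  insert_central <- 0L
  anchors <- which(paired & seq_len(L) %in% zones$central)
  if (length(anchors) >= 2) {
    for (a in seq_len(length(anchors) - 1)) {
      i1 <- anchors[a]; i2 <- anchors[a + 1]
      gi <- i2 - i1 - 1L
      gj <- tpos[i1] - tpos[i2] - 1L
      insert_central <- insert_central + max(0L, gj - gi)
    }
  }
  central_bulge <- central_unpaired + insert_central

  structure(list(
    seed_paired = seed_paired,
    seed_cleave_paired = seed_cleave_paired,
    central_bulge = as.integer(central_bulge),
    supp_paired_count = as.integer(sum(paired[zones$supplementary])),
    three_prime_terminal_paired = all(paired[zones$terminal]),
    total_mismatches = as.integer(sum(!paired)),
    interface_mismatches_outside_2_12 =
      as.integer(sum(!paired[setdiff(seq_len(L), 2:12)])),
    mirna_len = L,
    truncated_supplementary = truncated
  ), class = "zone_profile")
}

#' Classify an MRE from its zone profile
#'
#' Assigns one of `SLICING`, `REPRESSIVE`, `WEAK`, `NONFUNCTIONAL`
#' (ranks 3..0). SLICING needs contiguous pairing across nt 2-12 within
#' the interface mismatch budget (plus the 3'-terminal rule when
#' enabled); REPRESSIVE tolerates a central bulge of <= 1 nt;
#' WEAK is a central bulge at the weak threshold; any seed
#' imperfection, a larger bulge, or a blown mismatch budget is
#' NONFUNCTIONAL.
#'
#' @param profile A [zone_profile()].
#' @param rules A [mre_rules()].
#' @return List with `label` and integer `rank`.
#' @export
classify <- function(profile, rules = mre_rules()) {
  out <- profile$interface_mismatches_outside_2_12
  budget_ok <- out <= rules$max_outside_mismatches
  label <- "NONFUNCTIONAL"
  if (profile$seed_cleave_paired && budget_ok &&
      (!rules$require_three_prime_terminal ||
       profile$three_prime_terminal_paired)) {
    label <- "SLICING"
  } else if (profile$seed_paired && budget_ok &&
             profile$central_bulge <= 1L) {
    label <- "REPRESSIVE"
  } else if (profile$seed_paired && budget_ok &&
             profile$central_bulge == rules$central_bulge_weak) {
    label <- "WEAK"
  }
  list(label = label, rank = mre_rank(label))
}

# ---- packaged reporter-construct fixture ------------------------------

#' Build a duplex from an abstract binding-model pattern
#'
#' Reporter binding models are described by the miRNA length, the set
#' of unpaired miRNA positions (symmetric mismatches) and optional
#' target-side insertions (`"p:n"` = n extra target nucleotides between
#' the bases opposite miRNA positions p+1 and p). Used to encode figure
#' constructs without their exact sequences.
#'
#' @param mirna_len miRNA length.
#' @param unpaired Integer vector of unpaired miRNA positions (may be
#'   empty).
#' @param insertions Character vector of `"p:n"` specs (may be empty).
#' @param mirna_id Optional identifier.
#' @return A `duplex` object.
#' @export
duplex_from_pattern <- function(mirna_len, unpaired = integer(0),
                                insertions = character(0),
                                mirna_id = NULL) {
  ins <- stats::setNames(integer(0), character(0))
  if (length(insertions)) {
    sp <- strsplit(insertions, ":", fixed = TRUE)
    ins <- stats::setNames(as.integer(vapply(sp, `[`, "", 2)),
                           vapply(sp, `[`, "", 1))
  }
  t <- 0L
  pairs <- NULL
  for (k in seq(mirna_len, 1L)) {
    if (as.character(k) %in% names(ins)) t <- t + ins[[as.character(k)]]
    t <- t + 1L
    if (!k %in% unpaired) pairs <- rbind(pairs, c(k, t))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  new_duplex(mirna_id, mirna_len, t, pairs, score = NA_real_,
             gu_pairs = rep(FALSE, nrow(pairs)), mode = "pattern")
}

#' Path to the packaged reporter binding-model fixture
#' @return File path of the TSV shipped with the package.
#' @export
reporter_models_path <- function() {
  system.file("extdata", "reporter_models.tsv", package = "mircds",
              mustWork = TRUE)
}

#' Validate the classifier against the reporter-construct fixture
#'
#' Runs every named binding model of the packaged (or user-supplied)
#' fixture table through [duplex_from_pattern()], [zone_profile()] and
#' [classify()], and compares the predicted class and repressed/not
#' dichotomy with the outcome observed in the reporter assays.
#'
#' @param fixture A data.frame with columns `model`, `mirna_length`,
#'   `unpaired_positions` (semicolon-separated), `target_insertions`,
#'   `expected_class`, `expected_repressed`; or a TSV path. Defaults to
#'   the packaged table.
#' @param rules A [mre_rules()].
#' @return Data.frame per model with predicted/expected class, the
#'   dichotomy agreement, and attribute `n_failed`.
#' @export
fixture_validation <- function(fixture = reporter_models_path(),
                               rules = mre_rules()) {
  if (is.character(fixture)) {
    fixture <- utils::read.delim(fixture, stringsAsFactors = FALSE)
  }
  parse_pos <- function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  res <- lapply(seq_len(nrow(fixture)), function(i) {
    row <- fixture[i, ]
    ins <- if (is.na(row$target_insertions) || !nzchar(row$target_insertions))
      character(0) else strsplit(row$target_insertions, ";")[[1]]
    d <- duplex_from_pattern(row$mirna_length,
                             parse_pos(row$unpaired_positions), ins)
    cl <- classify(zone_profile(d), rules)
    data.frame(model = row$model,
               predicted_class = cl$label,
               expected_class = row$expected_class,
               predicted_repressed = cl$rank >= mre_rank("WEAK"),
               expected_repressed = row$expected_repressed,
               class_ok = cl$label == row$expected_class,
               dichotomy_ok = (cl$rank >= mre_rank("WEAK")) ==
                 row$expected_repressed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  failed <- out$model[!(out$class_ok & out$dichotomy_ok)]
  if (length(failed)) {
    message("fixture_validation: disagreement for ",
            paste(failed, collapse = ", "))
  }
  attr(out, "n_failed") <- length(failed)
  out
}
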