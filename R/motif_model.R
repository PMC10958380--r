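#' Infer critical peptide positions from a substitution-scan profile
#'
#' An alanine (or anchor-exchange) scan reports, per nonamer position, the
#' residual TCR activation after substituting that position, as a fraction of
#' the CD3-normalised wild-type response. Positions whose substitution drops
#' activation below \code{abolition_threshold} are called critical: they are
#' the positions the recognition motif constrains.
#'
#' Positions absent from the profile are reported as untested (in the
#' \code{"untested"} attribute), never silently treated as critical.
#'
#' @param scan Named numeric vector; names are positions \code{"P1"} ..
#'   \code{"P9"} (a subset is allowed), values are activation fractions in
#'   \[0, 1\] (small overshoot above 1 is tolerated).
#' @param abolition_threshold Activation below this fraction counts as
#'   abolished. Default 0.2, which separates near-zero "completely abolished"
#'   responses from tolerated substitutions.
#'
#' @return Character vector of critical positions (in P1..P9 order) with an
#'   \code{"untested"} attribute listing positions not in the profile.
#' @examples
#' scan <- c(P1 = 1, P2 = 0.02, P3 = 0.9, P4 = 1, P5 = 0.01,
#'           P6 = 0.95, P7 = 0.03, P8 = 0, P9 = 0.05)
#' inferCriticalPositions(scan)
#' @export
inferCriticalPositions <- function(scan, abolition_threshold = 0.2) {
  if (length(scan) == 0L) {
    stop("empty substitution-scan profile", call. = FALSE)
  }
  if (is.null(names(scan)) || !all(.is_position(names(scan)))) {
    stop("profile names must be positions P1..P9", call. = FALSE)
  }
  if (!is.numeric(abolition_threshold) || abolition_threshold <= 0 ||
      abolition_threshold >= 1) {
    stop("'abolition_threshold' must lie in (0, 1)", call. = FALSE)
  }
  if (any(is.na(scan)) || any(scan < 0)) {
    stop("activation values must be non-negative and non-missing",
         call. = FALSE)
  }
  tested <- names(scan)
  crit <- tested[scan < abolition_threshold]
  crit <- NONAMER_POSITIONS[NONAMER_POSITIONS %in% crit]
  structure(crit, untested = setdiff(NONAMER_POSITIONS, tested))
}

#' Build a position-frequency model from stimulatory ligands
#'
#' Counts residues per nonamer position across a ligand set. Octamers are
#' lifted to the nonamer register (octamer index i contributes to P(i+1));
#' their unknown P1 is excluded from the counts. Frequencies are formed with
#' an additive pseudocount; with pseudocount 0 a column with no observations
#' (e.g. P1 under an all-octamer input) has \code{NA} frequencies.
#'
#' @param ligands Character vector of peptide sequences (length 8 or 9), or a
#'   data frame with columns \code{sequence} and optionally
#'   \code{stimulatory} (only stimulatory rows are counted).
#' @param pseudocount Non-negative smoothing constant, default 0 (logos built
#'   from small ligand panels are reported unsmoothed; raise for scoring).
#'
#' @return A [PositionFrequencyModel-class] with 9 columns P1..P9.
#' @export
buildFrequencyModel <- function(ligands, pseudocount = 0) {
  if (is.data.frame(ligands)) {
    if (!"sequence" %in% names(ligands)) {
      stop("ligand table must have a 'sequence' column", call. = FALSE)
    }
    if ("stimulatory" %in% names(ligands)) {
      ligands <- ligands$sequence[as.logical(ligands$stimulatory)]
    } else {
      ligands <- ligands$sequence
    }
  }
  ligands <- as.character(ligands)
  if (length(ligands) == 0L) {
    stop("no stimulatory ligands to count", call. = FALSE)
  }
  lens <- nchar(ligands)
  if (!all(lens %in% c(8L, 9L))) {
    stop("ligand lengths must be 8 or 9 (octamer/nonamer registers); got ",
         paste(unique(lens[!lens %in% c(8L, 9L)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- matrix(0L, nrow = 20L, ncol = 9L,
                   dimnames = list(AA_ALPHABET, NONAMER_POSITIONS))
  for (seq in ligands) {
    pos <- nonamerPositions(seq)
    for (p in NONAMER_POSITIONS) {
      if (!is.na(pos[[p]])) {
        counts[pos[[p]], p] <- counts[pos[[p]], p] + 1L
      }
    }
  }
  freqs <- .frequencies_from_counts(counts, pseudocount)
  new("PositionFrequencyModel", counts = counts, pseudocount = pseudocount,
      frequencies = freqs)
}

.frequencies_from_counts <- function(counts, pseudocount) {
  sm <- counts + pseudocount
  tot <- colSums(sm)
  freqs <- sweep(sm, 2L, tot, "/")
  freqs[, tot == 0] <- NA_real_
  freqs
}

#' Per-column information content in bits
#'
#' The sequence-logo column height: \eqn{IC_j = \log_2 20 - H_j}, where
#' \eqn{H_j} is the Shannon entropy of column j's residue frequencies. No
#' small-sample correction is applied. Columns without observations give
#' \code{NA}.
#'
#' @param model A [PositionFrequencyModel-class].
#' @return Named numeric vector of bits per column, each in
#'   \[0, log2(20) ~ 4.32\].
#' @export
informationContent <- function(model) {
  stopifnot(is(model, "PositionFrequencyModel"))
  f <- model@frequencies
  apply(f, 2L, function(col) {
    if (any(is.na(col))) return(NA_real_)
    nz <- col[col > 0]
    ent <- -sum(nz * log2(nz))
    max(0, min(log2(20), log2(20) - ent))
  })
}

#' Derive a recognition motif from a frequency model and critical positions
#'
#' Critical positions become constrained: their allowed set is every residue
#' whose observed frequency among the stimulatory ligands reaches
#' \code{allowed_fraction_threshold}. With the default threshold 0 the
#' allowed set is the union of residues observed at least once -- the ligand
#' panels behind such motifs are small, so observation unions, not frequency
#' cut-offs, define the published sets. A critical position where a single
#' residue was observed becomes fixed. Non-critical positions are free.
#'
#' @param model [PositionFrequencyModel-class] built from the same ligand
#'   family as \code{critical_positions}.
#' @param critical_positions Character vector of positions (e.g. from
#'   [inferCriticalPositions()]).
#' @param allowed_fraction_threshold Minimum observed (unsmoothed) frequency
#'   for a residue to enter the allowed set; default 0 means "observed at
#'   least once".
#' @param forbidden,annotations Passed through to [RecognitionMotif()];
#'   annotations typically mark HLA anchors (P2, P9), the auxiliary anchor
#'   (P7) and TCR contacts (P5, P8).
#'
#' @return A [RecognitionMotif-class].
#' @export
deriveRecognitionMotif <- function(model, critical_positions,
                                   allowed_fraction_threshold = 0,
                                   forbidden = list(),
                                   annotations = character(0)) {
  stopifnot(is(model, "PositionFrequencyModel"))
  if (!all(.is_position(critical_positions))) {
    stop("critical positions must be P1..P9 labels", call. = FALSE)
  }
  counts <- model@counts
  allowed <- list()
  for (p in critical_positions) {
    col <- counts[, p]
    tot <- sum(col)
    if (tot == 0) {
      stop("critical position ", p, " has no ligand observations",
           call. = FALSE)
    }
    keep <- if (allowed_fraction_threshold > 0) {
      col / tot >= allowed_fraction_threshold
    } else {
      col >= 1
    }
    if (!any(keep)) {
      stop("allowed_fraction_threshold leaves no residues at ", p,
           call. = FALSE)
    }
    allowed[[p]] <- AA_ALPHABET[keep]
  }
  RecognitionMotif(allowed = allowed, forbidden = forbidden,
                   annotations = annotations)
}

#' Compile degenerate octamer search patterns from a motif
#'
#' Patterns are octamer-register strings (character i corresponds to nonamer
#' position P(i+1)) over residue letters plus the wildcard \code{X}. Free
#' positions are always \code{X}; fixed positions are their residue. Under
#' \code{policy = "cartesian"} every combination of allowed residues at the
#' multi-residue constrained positions is emitted. Under
#' \code{policy = "explicit"}, \code{combinations} supplies the pattern list
#' (as octamer pattern strings); each is validated against the motif and a
#' residue outside the allowed set raises an error naming the position. An
#' explicit pattern may put \code{X} at a constrained position (a wildcard
#' relaxation); such patterns are flagged rather than rejected, since
#' published search matrices sometimes leave the auxiliary-anchor position
#' open.
#'
#' @param motif A [RecognitionMotif-class] with octamer-expressible
#'   constraints (P2..P9; a constrained P1 cannot be encoded and errors).
#' @param policy \code{"cartesian"} or \code{"explicit"}.
#' @param combinations Character vector of octamer patterns (explicit policy
#'   only).
#'
#' @return A data frame with columns \code{pattern}, one provenance column
#'   per variable constrained position (residue used, \code{X} if wildcard),
#'   and \code{wildcard_relaxed} (logical).
#' @examples
#' m <- RecognitionMotif(allowed = list(
#'   P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"), P8 = "R",
#'   P9 = c("L", "M", "V", "F", "I")))
#' nrow(compileSearchPatterns(m))  # 3 * 2 * 5 = 30
#' @export
compileSearchPatterns <- function(motif, policy = c("cartesian", "explicit"),
                                  combinations = NULL) {
  stopifnot(is(motif, "RecognitionMotif"))
  policy <- match.arg(policy)
  if (!is.null(allowedResidues(motif, "P1"))) {
    stop("motif constrains P1, which the octamer register cannot encode",
         call. = FALSE)
  }
  octamer_pos <- NONAMER_POSITIONS[2:9]
  sets <- lapply(octamer_pos, function(p) allowedResidues(motif, p))
  names(sets) <- octamer_pos
  variable <- octamer_pos[vapply(sets, function(s)
    !is.null(s) && length(s) > 1L, logical(1))]

  if (policy == "cartesian") {
    grids <- sets
    grids[vapply(grids, is.null, logical(1))] <- list("X")
    grid <- expand.grid(rev(grids), stringsAsFactors = FALSE)[, 8:1,
                                                              drop = FALSE]
    names(grid) <- octamer_pos
    patterns <- apply(grid, 1L, .collapse)
    out <- data.frame(pattern = patterns, stringsAsFactors = FALSE)
    for (p in variable) out[[p]] <- grid[[p]]
    out$wildcard_relaxed <- FALSE
    rownames(out) <- NULL
    return(out)
  }

  ## explicit policy
  if (is.null(combinations) || length(combinations) == 0L) {
    stop("explicit policy requires 'combinations' (octamer patterns)",
         call. = FALSE)
  }
  combinations <- toupper(as.character(combinations))
  out <- data.frame(pattern = combinations, stringsAsFactors = FALSE)
  for (p in variable) out[[p]] <- NA_character_
  out$wildcard_relaxed <- FALSE
  for (k in seq_along(combinations)) {
    pat <- combinations[[k]]
    if (nchar(pat) != 8L) {
      stop("pattern '", pat, "' is not an octamer", call. = FALSE)
    }
    chars <- .chars(pat)
    .check_residues(setdiff(chars, "X"), "pattern")
    for (i in 1:8) {
      p <- octamer_pos[[i]]
      set <- sets[[p]]
      ch <- chars[[i]]
      if (ch == "X") {
        if (!is.null(set)) out$wildcard_relaxed[[k]] <- TRUE
      } else if (!is.null(set) && !ch %in% set) {
        stop("pattern '", pat, "' uses residue ", ch, " at ", p,
             ", which the motif does not allow", call. = FALSE)
      }
      if (p %in% variable) out[[p]][[k]] <- ch
    }
  }
  rownames(out) <- NULL
  out
}

#' Test a peptide against a recognition motif
#'
#' A peptide matches when every constrained position carries an allowed
#' residue and no forbidden residue occurs at its position. Octamers are
#' evaluated in the octamer register: P1 is absent and a P1 constraint is
#' skipped (reported among \code{untested}).
#'
#' @param peptide Octamer or nonamer residue string.
#' @param motif A [RecognitionMotif-class].
#' @param apply_forbidden Also veto on the motif's forbidden map (default
#'   TRUE; the scanner applies forbidden rules at the curation stage
#'   instead).
#'
#' @return A list: \code{match} (logical), \code{failures} (data frame with
#'   columns position, residue, reason -- every failing position is listed),
#'   \code{untested} (positions constrained by the motif but absent from the
#'   register).
#' @examples
#' m <- RecognitionMotif(allowed = list(
#'   P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"), P8 = "R",
#'   P9 = c("L", "M", "V", "F", "I")))
#' matchesMotif("LRMRRCRRM", m)$match   # wheat-derived nonamer: TRUE
#' matchesMotif("VRHDGGNVL", m)$match   # control peptide: FALSE (P5 = G)
#' @export
matchesMotif <- function(peptide, motif, apply_forbidden = TRUE) {
  stopifnot(is(motif, "RecognitionMotif"))
  pos <- nonamerPositions(peptide)
  failures <- data.frame(position = character(0), residue = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  untested <- character(0)
  for (p in NONAMER_POSITIONS) {
    res <- pos[[p]]
    set <- motif@allowed[[p]]
    if (is.na(res)) {
      if (!is.null(set)) untested <- c(untested, p)
      next
    }
    if (!is.null(set) && !res %in% set) {
      failures <- rbind(failures, data.frame(
        position = p, residue = res,
        reason = paste0(res, " not in {", paste(set, collapse = ","), "}"),
        stringsAsFactors = FALSE))
    }
    if (apply_forbidden && p %in% names(motif@forbidden) &&
        res %in% motif@forbidden[[p]]) {
      failures <- rbind(failures, data.frame(
        position = p, residue = res,
        reason = paste0(res, " forbidden"), stringsAsFactors = FALSE))
    }
  }
  list(match = nrow(failures) == 0L, failures = failures,
       untested = untested)
}
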