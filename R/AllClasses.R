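#' Per-position recognition-motif constraint model
#'
#' A \code{RecognitionMotif} records, for each nonamer position P1--P9, the
#' residues a peptide may carry there. A position is either constrained to an
#' allowed set (a singleton set is a "fixed" position) or free (no
#' constraint). Separately, \code{forbidden} lists residues that veto a match
#' at otherwise neutral positions -- the curation layer uses these (e.g. Arg
#' at P6 prevents TCR activation even when the motif proper is satisfied).
#' \code{annotations} carries the structural role of each position
#' (HLA anchor, auxiliary anchor, TCR contact, neutral); roles are
#' informative only and not enforced differently during matching.
#'
#' @slot allowed Named list of length 9 (names \code{P1}..\code{P9}); each
#'   element is either \code{NULL} (free position) or a character vector of
#'   allowed one-letter residues.
#' @slot forbidden Named list mapping positions to character vectors of
#'   residues that must not occur there.
#' @slot annotations Named character vector mapping positions to roles.
#'
#' @seealso [deriveRecognitionMotif()], [compileSearchPatterns()],
#'   [matchesMotif()]
#' @export
setClass("RecognitionMotif",
  representation(
    allowed = "list",
    forbidden = "list",
    annotations = "character"
  ),
  prototype(
    allowed = stats::setNames(vector("list", 9L), paste0("P", 1:9)),
    forbidden = list(),
    annotations = character(0)
  )
)

setValidity("RecognitionMotif", function(object) {
  msgs <- character(0)
  if (length(object@allowed) != 9L ||
      !identical(names(object@allowed), NONAMER_POSITIONS)) {
    msgs <- c(msgs, "'allowed' must be a list named P1..P9")
  } else {
    for (p in NONAMER_POSITIONS) {
      set <- object@allowed[[p]]
      if (is.null(set)) next
      if (!is.character(set) || length(set) == 0L) {
        msgs <- c(msgs, paste0("allowed set at ", p,
                               " must be a non-empty character vector"))
      } else if (length(setdiff(set, AA_ALPHABET)) > 0L) {
        msgs <- c(msgs, paste0("allowed set at ", p,
                               " contains invalid residue letters"))
      }
    }
  }
  if (length(object@forbidden) > 0L) {
    if (is.null(names(object@forbidden)) ||
        !all(.is_position(names(object@forbidden)))) {
      msgs <- c(msgs, "'forbidden' names must be positions P1..P9")
    } else {
      for (p in names(object@forbidden)) {
        set <- object@allowed[[p]]
        if (!is.null(set) && length(intersect(set, object@forbidden[[p]]))) {
          msgs <- c(msgs, paste0("forbidden residues at ", p,
                                 " overlap the allowed set"))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RecognitionMotif
#'
#' @param allowed Named list mapping constrained positions (\code{"P1"} ..
#'   \code{"P9"}) to character vectors of allowed residues. Positions not
#'   named are free.
#' @param forbidden Named list mapping positions to vetoed residues
#'   (curation layer; default none).
#' @param annotations Named character vector of position roles, e.g.
#'   \code{c(P2 = "HLA anchor", P5 = "TCR contact")}.
#'
#' @return A [RecognitionMotif-class] object.
#' @examples
#' m <- RecognitionMotif(
#'   allowed = list(P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"),
#'                  P8 = "R", P9 = c("L", "M", "V", "F", "I")),
#'   forbidden = list(P6 = "R")
#' )
#' constrainedPositions(m)
#' @export
RecognitionMotif <- function(allowed = list(), forbidden = list(),
                             annotations = character(0)) {
  full <- stats::setNames(vector("list", 9L), NONAMER_POSITIONS)
  if (length(allowed)) {
    if (is.null(names(allowed)) || !all(.is_position(names(allowed)))) {
      stop("'allowed' must be named with positions P1..P9", call. = FALSE)
    }
    for (p in names(allowed)) {
      full[[p]] <- toupper(as.character(allowed[[p]]))
    }
  }
  forb <- lapply(forbidden, function(x) toupper(as.character(x)))
  new("RecognitionMotif", allowed = full, forbidden = forb,
      annotations = annotations)
}

#' @describeIn RecognitionMotif Positions carrying an allowed-set constraint.
#' @param x A \code{RecognitionMotif}.
#' @export
constrainedPositions <- function(x) {
  stopifnot(is(x, "RecognitionMotif"))
  NONAMER_POSITIONS[!vapply(x@allowed, is.null, logical(1))]
}

#' @describeIn RecognitionMotif Allowed residue set at one position
#'   (\code{NULL} for a free position).
#' @param position Position label, e.g. \code{"P5"}.
#' @export
allowedResidues <- function(x, position) {
  stopifnot(is(x, "RecognitionMotif"), .is_position(position))
  x@allowed[[position]]
}

#' @describeIn RecognitionMotif Forbidden residue map (curation layer).
#' @export
forbiddenResidues <- function(x) {
  stopifnot(is(x, "RecognitionMotif"))
  x@forbidden
}

#' @describeIn RecognitionMotif Position role annotations.
#' @export
positionRoles <- function(x) {
  stopifnot(is(x, "RecognitionMotif"))
  x@annotations
}

setMethod("show", "RecognitionMotif", function(object) {
  cat("RecognitionMotif (nonamer register P1-P9)\n")
  for (p in NONAMER_POSITIONS) {
    set <- object@allowed[[p]]
    lab <- if (is.null(set)) {
      "free"
    } else if (length(set) == 1L) {
      paste0("fixed ", set)
    } else {
      paste0("{", paste(set, collapse = ","), "}")
    }
    role <- if (p %in% names(object@annotations)) {
      paste0("  [", object@annotations[[p]], "]")
    } else ""
    forb <- if (p %in% names(object@forbidden)) {
      paste0("  forbidden: ", paste(object@forbidden[[p]], collapse = ","))
    } else ""
    cat(sprintf("  %s: %s%s%s\n", p, lab, role, forb))
  }
  invisible(object)
})

#' Position-frequency model of a ligand family
#'
#' Residue counts per nonamer position across a set of stimulatory ligands,
#' with derived (pseudocount-smoothed) frequencies and per-column Shannon
#' information content in bits -- the numeric content of a sequence logo.
#' Columns with no observations and zero pseudocount (e.g. P1 when all
#' ligands are octamers) have \code{NA} frequencies.
#'
#' @slot counts 20 x L integer matrix (rows = residues, columns = positions).
#' @slot pseudocount Non-negative smoothing constant added to every cell
#'   before frequencies are formed.
#' @slot frequencies Derived 20 x L numeric matrix; each informative column
#'   sums to 1.
#'
#' @seealso [buildFrequencyModel()], [informationContent()]
#' @export
setClass("PositionFrequencyModel",
  representation(
    counts = "matrix",
    pseudocount = "numeric",
    frequencies = "matrix"
  )
)

setValidity("PositionFrequencyModel", function(object) {
  msgs <- character(0)
  if (nrow(object@counts) != 20L ||
      !identical(rownames(object@counts), AA_ALPHABET)) {
    msgs <- c(msgs, "'counts' must be a 20-row matrix with residue rownames")
  }
  if (any(object@counts < 0)) msgs <- c(msgs, "'counts' must be non-negative")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0) {
    msgs <- c(msgs, "'pseudocount' must be a single non-negative number")
  }
  cs <- colSums(object@frequencies)
  informative <- !is.na(cs)
  if (any(informative) && any(abs(cs[informative] - 1) > 1e-9)) {
    msgs <- c(msgs, "informative frequency columns must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PositionFrequencyModel Raw residue counts.
#' @param x A \code{PositionFrequencyModel}.
#' @export
residueCounts <- function(x) {
  stopifnot(is(x, "PositionFrequencyModel"))
  x@counts
}

#' @describeIn PositionFrequencyModel Pseudocount-smoothed frequencies.
#' @export
residueFrequencies <- function(x) {
  stopifnot(is(x, "PositionFrequencyModel"))
  x@frequencies
}

setMethod("show", "PositionFrequencyModel", function(object) {
  L <- ncol(object@counts)
  cat("PositionFrequencyModel:", L, "columns,",
      sum(object@counts), "residue observations, pseudocount",
      object@pseudocount, "\n")
  ic <- informationContent(object)
  cat("  information content (bits):",
      paste(sprintf("%s=%.2f", colnames(object@counts), ic), collapse = " "),
      "\n")
  invisible(object)
})
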