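#' @import methods
NULL

## Canonical one-letter amino-acid alphabet (alphabetical, 20 residues)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity / non-standard codes that make a scan window unevaluable
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

## Nonamer position labels
NONAMER_POSITIONS <- paste0("P", 1:9)

#' Amino-acid alphabet used throughout the package
#'
#' @return Character vector of the 20 canonical one-letter residue codes.
#' @export
aminoAcidAlphabet <- function() AA_ALPHABET

.is_position <- function(x) x %in% NONAMER_POSITIONS

.position_index <- function(p) match(p, NONAMER_POSITIONS)

## Octamer index i maps to nonamer position P(i + 1)
.octamer_index_to_position <- function(i) NONAMER_POSITIONS[i + 1L]

.check_residues <- function(res, what = "residue") {
  bad <- setdiff(res, AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid ", what, " letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(res)
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

## Split a residue string into a character vector of single letters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.collapse <- function(x) paste0(x, collapse = "")
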