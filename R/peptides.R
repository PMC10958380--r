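#' Validate a peptide sequence and resolve its register
#'
#' Peptides are octamers or nonamers over the 20 canonical residues. In the
#' octamer register the NH2-terminal residue corresponds to nonamer position
#' P2, i.e. octamer index i maps to P(i+1); P1 is simply absent.
#'
#' @param sequence Residue string, length 8 or 9; lower case accepted.
#' @param register Optional; \code{"octamer"} or \code{"nonamer"}. Inferred
#'   from the length when missing; an explicit register that contradicts the
#'   length is an error.
#'
#' @return A list with elements \code{sequence} (uppercase canonical form)
#'   and \code{register}.
#' @examples
#' asPeptide("LRMRRCRRM")$register
#' @export
asPeptide <- function(sequence, register = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!n %in% c(8L, 9L)) {
    stop("peptide length must be 8 or 9, got ", n, call. = FALSE)
  }
  .check_residues(.chars(sequence))
  inferred <- if (n == 8L) "octamer" else "nonamer"
  if (!is.null(register)) {
    register <- match.arg(register, c("octamer", "nonamer"))
    if (register != inferred) {
      stop("register '", register, "' contradicts peptide length ", n,
           call. = FALSE)
    }
  }
  list(sequence = sequence, register = inferred)
}

#' Map a peptide to nonamer positions P1..P9
#'
#' @param sequence Octamer or nonamer residue string.
#' @return Named character vector over P1..P9; P1 is \code{NA} for octamers.
#' @export
nonamerPositions <- function(sequence) {
  pep <- asPeptide(sequence)
  chars <- .chars(pep$sequence)
  out <- stats::setNames(rep(NA_character_, 9L), NONAMER_POSITIONS)
  if (pep$register == "nonamer") {
    out[] <- chars
  } else {
    out[2:9] <- chars
  }
  out
}
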