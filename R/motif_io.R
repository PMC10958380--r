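#' Read a ligand table
#'
#' Tab-separated with a header row and columns \code{sequence},
#' \code{register}, \code{stimulatory}, \code{activation}. \code{register}
#' may be empty (inferred from length); \code{activation} is the fraction of
#' the CD3-normalised response and may be missing.
#'
#' @param path File path.
#' @param activation_cutoff When both \code{stimulatory} and
#'   \code{activation} are present, rows where the flag contradicts
#'   \code{activation >= activation_cutoff} raise an error (consistency
#'   check). Default \code{NULL} skips the check, since no quantitative
#'   cutoff defining "stimulatory" is standard -- the flag is taken as input.
#' @return Data frame with canonicalised columns.
#' @export
readLigandTable <- function(path, activation_cutoff = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "stimulatory")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ligand table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$sequence <- toupper(df$sequence)
  for (s in df$sequence) asPeptide(s)
  df$stimulatory <- as.logical(df$stimulatory)
  if (!"activation" %in% names(df)) df$activation <- NA_real_
  df$activation <- as.numeric(df$activation)
  act <- df$activation
  if (any(!is.na(act) & (act < 0 | act > 1.2))) {
    stop("activation values must lie in [0, 1.2]", call. = FALSE)
  }
  if (!is.null(activation_cutoff)) {
    both <- !is.na(act)
    bad <- both & (df$stimulatory != (act >= activation_cutoff))
    if (any(bad)) {
      stop("stimulatory flag contradicts activation cutoff for: ",
           paste(df$sequence[bad], collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Read a substitution-scan profile table
#'
#' Tab-separated with header and columns \code{position} (P1..P9),
#' \code{residue} (the substituting residue), \code{activation}. When a
#' position was probed with several substitutions (anchor-exchange panels),
#' the alanine row defines the profile value when present; otherwise the
#' rows are averaged.
#'
#' @param path File path.
#' @return Named numeric vector keyed by position, suitable for
#'   [inferCriticalPositions()].
#' @export
readScanProfile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "residue", "activation")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("scan table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(.is_position(df$position))) {
    stop("scan positions must be P1..P9", call. = FALSE)
  }
  vals <- vapply(split(df, df$position), function(rows) {
    ala <- rows$activation[toupper(rows$residue) == "A"]
    if (length(ala)) mean(ala) else mean(rows$activation)
  }, numeric(1))
  vals[order(.position_index(names(vals)))]
}

#' Serialise / deserialise a motif as JSON
#'
#' @param motif A [RecognitionMotif-class].
#' @param path File path; for \code{motifToJson} omit to get the JSON string.
#' @return \code{motifToJson}: the path (or JSON string) invisibly;
#'   \code{motifFromJson}: a [RecognitionMotif-class].
#' @export
motifToJson <- function(motif, path = NULL) {
  stopifnot(is(motif, "RecognitionMotif"))
  obj <- list(
    register = "nonamer",
    allowed = Filter(Negate(is.null), motif@allowed),
    forbidden = motif@forbidden,
    annotations = as.list(positionRoles(motif))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname motifToJson
#' @export
motifFromJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  RecognitionMotif(
    allowed = lapply(obj$allowed, as.character),
    forbidden = lapply(obj$forbidden, as.character),
    annotations = unlist(obj$annotations) %||% character(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read search patterns
#'
#' Plain dialect: one octamer pattern per line, residue letters plus
#' \code{X}. PROSITE dialect: positions joined by \code{-}, wildcards as
#' \code{x}, residue alternatives in square brackets (e.g.
#' \code{R-x-x-[RNQ]-x-[RL]-R-L}).
#'
#' @param patterns Character vector of patterns, or the data frame from
#'   [compileSearchPatterns()].
#' @param path File path.
#' @param dialect \code{"plain"} or \code{"prosite"}.
#' @return \code{readPatterns}: character vector of plain octamer patterns.
#' @export
writePatterns <- function(patterns, path, dialect = c("plain", "prosite")) {
  dialect <- match.arg(dialect)
  if (is.data.frame(patterns)) patterns <- patterns$pattern
  lines <- if (dialect == "plain") patterns else
    vapply(patterns, patternToProsite, character(1), USE.NAMES = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePatterns
#' @export
readPatterns <- function(path, dialect = c("plain", "prosite")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "plain") toupper(lines) else
    vapply(lines, prositeToPattern, character(1), USE.NAMES = FALSE)
}

#' @rdname writePatterns
#' @param pattern A single plain pattern string.
#' @export
patternToProsite <- function(pattern) {
  chars <- .chars(toupper(pattern))
  paste(ifelse(chars == "X", "x", chars), collapse = "-")
}

#' @rdname writePatterns
#' @param prosite A single PROSITE-style pattern (alternatives in brackets
#'   are expanded only when singleton; multi-residue brackets are rejected in
#'   the plain octamer dialect and should be compiled per combination).
#' @export
prositeToPattern <- function(prosite) {
  parts <- strsplit(trimws(prosite), "-", fixed = TRUE)[[1L]]
  out <- vapply(parts, function(el) {
    el <- trimws(el)
    if (el %in% c("x", "X")) return("X")
    if (grepl("^\\[[A-Za-z]+\\]$", el)) {
      inner <- toupper(gsub("\\[|\\]", "", el))
      if (nchar(inner) != 1L) {
        stop("multi-residue alternative '", el,
             "' cannot be expressed in the plain octamer dialect; ",
             "compile one pattern per combination", call. = FALSE)
      }
      return(inner)
    }
    toupper(el)
  }, character(1))
  .check_residues(setdiff(out, "X"), "pattern")
  .collapse(out)
}
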