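#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: sequences are
#' uppercased, \code{*} stop codons are stripped (with a warning), and an
#' empty file yields an empty set. FASTA names keep the full header; the
#' first whitespace-delimited token is the protein id.
#'
#' @param path FASTA file (line wrapping allowed).
#' @return An [Biostrings::AAStringSet] in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(Biostrings::AAStringSet())
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop symbols from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param proteins An [Biostrings::AAStringSet] or named character vector.
#' @param path Output file.
#' @export
writeFasta <- function(proteins, path) {
  if (!is(proteins, "XStringSet")) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

.protein_ids <- function(proteins) {
  nms <- names(proteins)
  if (is.null(nms)) nms <- sprintf("protein_%d", seq_along(proteins))
  vapply(strsplit(nms, "\\s+"), `[`, character(1), 1L)
}

## Allowed residue sets per octamer index 1..8, as indices into AA_ALPHABET
## (NULL = free). From a motif or from a single plain pattern.
.octamer_constraints <- function(motif = NULL, pattern = NULL) {
  sets <- vector("list", 8L)
  if (!is.null(motif)) {
    for (i in 1:8) {
      set <- motif@allowed[[.octamer_index_to_position(i)]]
      if (!is.null(set)) sets[[i]] <- match(set, AA_ALPHABET)
    }
  } else {
    chars <- .chars(toupper(pattern))
    if (length(chars) != 8L) {
      stop("search pattern must be an octamer: ", pattern, call. = FALSE)
    }
    for (i in 1:8) {
      if (chars[[i]] != "X") sets[[i]] <- match(chars[[i]], AA_ALPHABET)
    }
  }
  sets
}

## Vectorised octamer-window scan of one sequence. Returns 0-based offsets
## of matching windows; attributes carry scanned/skipped window counts.
.scan_sequence <- function(seq, constraints) {
  L <- nchar(seq)
  n <- L - 7L
  if (n < 1L) {
    return(structure(integer(0), scanned = 0L, skipped = 0L))
  }
  xi <- match(.chars(seq), AA_ALPHABET)  # NA for X, B, Z, U, O, gaps, ...
  ok <- rep(TRUE, n)
  valid <- rep(TRUE, n)
  for (j in 1:8) {
    sub <- xi[j:(j + n - 1L)]
    valid <- valid & !is.na(sub)
    set <- constraints[[j]]
    if (!is.null(set)) ok <- ok & sub %in% set
  }
  structure(which(ok & valid) - 1L, scanned = n, skipped = sum(!valid))
}

#' Scan a proteome for motif-matching octamer windows
#'
#' Every octamer window of every protein is tested against either a
#' [RecognitionMotif-class] (allowed-set constraints only; forbidden
#' residues belong to the curation stage, see [curateHits()]) or a set of
#' plain octamer patterns, in which case a window is a hit when any pattern
#' matches. Windows containing non-standard residue codes (X, B, Z, U, O)
#' are skipped and counted. Overlapping hits are all reported, in
#' deterministic (protein order, then offset) order.
#'
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @param motif A [RecognitionMotif-class]; mutually exclusive with
#'   \code{patterns}.
#' @param patterns Character vector of plain octamer patterns (or the data
#'   frame from [compileSearchPatterns()]).
#'
#' @return Data frame of hits with columns \code{protein_id}, \code{start}
#'   (0-based octamer offset), \code{octamer}, \code{nonamer} (\code{NA}
#'   until [completeNonamer()]), \code{p1}, \code{flags}, \code{score}, and
#'   in pattern mode \code{pattern} (semicolon-joined matching patterns).
#'   Attributes \code{windows_scanned} and \code{windows_skipped} summarise
#'   the scan.
#' @export
scanProteome <- function(proteins, motif = NULL, patterns = NULL) {
  if (is.null(motif) == is.null(patterns)) {
    stop("supply exactly one of 'motif' or 'patterns'", call. = FALSE)
  }
  if (is.data.frame(patterns)) patterns <- patterns$pattern
  seqs <- if (is(proteins, "XStringSet")) as.character(proteins)
          else as.character(proteins)
  ids <- .protein_ids(proteins)
  scanned <- 0L
  skipped <- 0L
  rows <- vector("list", length(seqs))
  con_list <- if (!is.null(motif)) {
    stopifnot(is(motif, "RecognitionMotif"))
    list(.octamer_constraints(motif = motif))
  } else {
    lapply(toupper(patterns), function(p) .octamer_constraints(pattern = p))
  }
  for (k in seq_along(seqs)) {
    seq <- toupper(seqs[[k]])
    per_pattern <- lapply(con_list, function(con) .scan_sequence(seq, con))
    scanned <- scanned + attr(per_pattern[[1L]], "scanned")
    skipped <- skipped + attr(per_pattern[[1L]], "skipped")
    offs <- sort(unique(unlist(per_pattern)))
    if (length(offs) == 0L) next
    df <- data.frame(
      protein_id = ids[[k]],
      start = as.integer(offs),
      octamer = substring(seq, offs + 1L, offs + 8L),
      nonamer = NA_character_,
      p1 = NA_character_,
      flags = "",
      score = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(patterns)) {
      df$pattern <- vapply(offs, function(o) {
        hit_pats <- patterns[vapply(per_pattern, function(v) o %in% v,
                                    logical(1))]
        paste(hit_pats, collapse = ";")
      }, character(1))
    }
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), start = integer(0),
                      octamer = character(0), nonamer = character(0),
                      p1 = character(0), flags = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(patterns)) out$pattern <- character(0)
  }
  rownames(out) <- NULL
  structure(out, windows_scanned = scanned, windows_skipped = skipped)
}

#' Complete octamer hits to nonamers from the natural protein sequence
#'
#' The residue preceding the matched octamer supplies P1, giving the nonamer
#' register. A hit at offset 0 has no upstream residue: its nonamer stays
#' absent and the hit is flagged \code{no_P1} (octamers lacking P1 can still
#' stimulate, so such hits are kept).
#'
#' @param hits Data frame from [scanProteome()].
#' @param proteins The same proteome the hits refer to.
#' @return \code{hits} with \code{nonamer}, \code{p1} and flags filled in.
#' @export
completeNonamer <- function(hits, proteins) {
  seqs <- if (is(proteins, "XStringSet")) as.character(proteins)
          else as.character(proteins)
  seqs <- toupper(seqs)
  names(seqs) <- .protein_ids(proteins)
  unknown <- setdiff(unique(hits$protein_id), names(seqs))
  if (length(unknown)) {
    stop("hits refer to unknown protein(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[[i]]
    if (s == 0L) {
      hits$flags[[i]] <- .add_flag(hits$flags[[i]], "no_P1")
      next
    }
    seq <- seqs[[hits$protein_id[[i]]]]
    hits$nonamer[[i]] <- substring(seq, s, s + 8L)
    hits$p1[[i]] <- substring(seq, s, s)
  }
  hits
}

.add_flag <- function(flags, flag) {
  if (!nzchar(flags)) return(flag)
  if (flag %in% strsplit(flags, ";", fixed = TRUE)[[1L]]) return(flags)
  paste(flags, flag, sep = ";")
}

#' Curation rule set
#'
#' @param forbidden Named list mapping nonamer positions to vetoed residues;
#'   the default vetoes Arg at P6, which blocks TCR activation even in
#'   otherwise motif-positive peptides.
#' @param preference_weights Optional named list position -> named numeric
#'   residue weights, used by [rankHits()] callers to encode P3/P4
#'   preferences; no default is shipped.
#' @return A list of class \code{curation_rules}.
#' @export
curationRules <- function(forbidden = list(P6 = "R"),
                          preference_weights = NULL) {
  if (length(forbidden)) {
    if (is.null(names(forbidden)) || !all(.is_position(names(forbidden)))) {
      stop("forbidden rule positions must be P1..P9", call. = FALSE)
    }
    forbidden <- lapply(forbidden, function(x) toupper(as.character(x)))
  }
  structure(list(forbidden = forbidden,
                 preference_weights = preference_weights),
            class = "curation_rules")
}

#' Apply curation rules to motif hits
#'
#' A hit is removed iff some forbidden rule fires on it; the reason names the
#' rule (\code{"P6:R forbidden"}). Rules touching P1 cannot be evaluated on
#' octamer-only hits (offset 0, no nonamer): such hits are flagged
#' \code{unevaluable}, kept, and a message is logged. Coordinates are never
#' altered; \code{kept} and \code{removed} partition the input.
#'
#' @param hits Data frame from [scanProteome()] / [completeNonamer()].
#' @param rules A [curationRules()] object (or compatible list).
#' @return List with data frames \code{kept} and \code{removed}; the latter
#'   carries a \code{reason} column.
#' @export
curateHits <- function(hits, rules = curationRules()) {
  forb <- rules$forbidden
  keep <- rep(TRUE, nrow(hits))
  reasons <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pos <- if (!is.na(hits$nonamer[[i]])) {
      nonamerPositions(hits$nonamer[[i]])
    } else {
      nonamerPositions(hits$octamer[[i]])
    }
    for (p in names(forb)) {
      res <- pos[[p]]
      if (is.na(res)) {
        hits$flags[[i]] <- .add_flag(hits$flags[[i]], "unevaluable")
        message("hit ", hits$protein_id[[i]], ":", hits$start[[i]],
                " lacks ", p, "; rule left unevaluated, hit kept")
        next
      }
      if (res %in% forb[[p]]) {
        keep[[i]] <- FALSE
        reasons[[i]] <- paste0(p, ":", res, " forbidden")
        break
      }
    }
  }
  removed <- hits[!keep, , drop = FALSE]
  removed$reason <- reasons[!keep]
  rownames(removed) <- NULL
  kept <- hits[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Score and rank hits by log-odds against a background composition
#'
#' Each hit is scored \eqn{\sum_j \log_2 f_{model}(r_j, j) / f_{bg}(r_j)}
#' over its available nonamer positions (P2..P9 for octamer-only hits;
#' model columns without observations are skipped). Hits are returned sorted
#' by decreasing score with deterministic tie-breaking by (protein_id,
#' offset), independent of input order.
#'
#' @param hits Hit data frame.
#' @param model A [PositionFrequencyModel-class] (use a positive pseudocount
#'   to avoid -Inf scores for unobserved residues).
#' @param background Named numeric vector of residue frequencies over the
#'   20-letter alphabet (default uniform 1/20). A zero background frequency
#'   is an error: smooth the background with a pseudocount instead.
#' @return \code{hits} with \code{score} filled, sorted.
#' @export
rankHits <- function(hits, model, background = NULL) {
  stopifnot(is(model, "PositionFrequencyModel"))
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  if (is.null(names(background)) ||
      !all(AA_ALPHABET %in% names(background))) {
    stop("background must be named by the 20 residue letters", call. = FALSE)
  }
  if (any(background[AA_ALPHABET] <= 0)) {
    stop("zero background frequency; apply a background pseudocount",
         call. = FALSE)
  }
  f <- model@frequencies
  scores <- vapply(seq_len(nrow(hits)), function(i) {
    pos <- if (!is.na(hits$nonamer[[i]])) {
      nonamerPositions(hits$nonamer[[i]])
    } else {
      nonamerPositions(hits$octamer[[i]])
    }
    total <- 0
    for (p in NONAMER_POSITIONS) {
      res <- pos[[p]]
      if (is.na(res)) next
      fm <- f[res, p]
      if (is.na(fm)) next  # uninformative model column
      total <- total + log2(fm / background[[res]])
    }
    total
  }, numeric(1))
  hits$score <- scores
  ord <- order(-scores, hits$protein_id, hits$start, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Analytic per-window background match probability
#'
#' For i.i.d. background residues, the probability that a random octamer
#' window satisfies the motif is the product, over constrained positions, of
#' the summed frequencies of the allowed residues (free positions contribute
#' 1). Also accepts a single plain pattern, whose non-wildcard symbols act
#' as singleton constraints.
#'
#' @param motif A [RecognitionMotif-class] or a plain octamer pattern
#'   string.
#' @param frequencies Named residue frequencies summing to 1 (default
#'   uniform 1/20).
#' @return Probability per window.
#' @examples
#' m <- RecognitionMotif(allowed = list(
#'   P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"), P8 = "R",
#'   P9 = c("L", "M", "V", "F", "I")))
#' expectedBackgroundMatchRate(m)  # 30 / 20^5 = 9.375e-6
#' @export
expectedBackgroundMatchRate <- function(motif, frequencies = NULL) {
  if (is.null(frequencies)) {
    frequencies <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  if (abs(sum(frequencies[AA_ALPHABET]) - 1) > 1e-6) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  sets <- if (is(motif, "RecognitionMotif")) {
    Filter(Negate(is.null), motif@allowed)
  } else {
    chars <- .chars(toupper(as.character(motif)))
    as.list(chars[chars != "X"])
  }
  prod(vapply(sets, function(s) sum(frequencies[s]), numeric(1)))
}

#' Annotate hits with HLA-binding information
#'
#' External peptide--HLA affinity prediction is deliberately a pluggable
#' hook: the pipeline runs without it, using the built-in anchor-residue
#' surrogate (P2 must be Arg, the C-terminal anchor P9 one of
#' Leu/Met/Val/Phe/Ile) recorded in an \code{anchor_ok} column. When
#' \code{hook} (a function nonamer -> numeric score) is supplied, its value
#' is stored in \code{binding_score}; a hook failure flags the hit
#' \code{binding_unscored} instead of dropping it.
#'
#' @param hits Hit data frame (nonamers completed where possible).
#' @param hook Optional function taking a nonamer string.
#' @param anchor_p2,anchor_p9 Allowed anchor residues for the surrogate
#'   filter.
#' @return \code{hits} with \code{anchor_ok} (and \code{binding_score}).
#' @export
annotateHlaBinding <- function(hits, hook = NULL, anchor_p2 = "R",
                               anchor_p9 = c("L", "M", "V", "F", "I")) {
  anchor_ok <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pos <- if (!is.na(hits$nonamer[[i]])) {
      nonamerPositions(hits$nonamer[[i]])
    } else {
      nonamerPositions(hits$octamer[[i]])
    }
    anchor_ok[[i]] <- pos[["P2"]] %in% anchor_p2 && pos[["P9"]] %in% anchor_p9
  }
  hits$anchor_ok <- anchor_ok
  if (!is.null(hook)) {
    stopifnot(is.function(hook))
    hits$binding_score <- NA_real_
    for (i in seq_len(nrow(hits))) {
      pep <- if (!is.na(hits$nonamer[[i]])) hits$nonamer[[i]]
             else hits$octamer[[i]]
      val <- tryCatch(as.numeric(hook(pep)), error = function(e) NA_real_)
      if (is.na(val)) {
        hits$flags[[i]] <- .add_flag(hits$flags[[i]], "binding_unscored")
      } else {
        hits$binding_score[[i]] <- val
      }
    }
  }
  hits
}

#' Write / read a hits table as TSV
#'
#' Coordinates are 0-based half-open internally; the TSV uses a 1-based
#' inclusive \code{start_1based} column (bioinformatics convention).
#'
#' @param hits Hit data frame.
#' @param path File path.
#' @return \code{readHitsTsv}: hit data frame with the internal 0-based
#'   \code{start}.
#' @export
writeHitsTsv <- function(hits, path) {
  out <- hits
  out$start_1based <- out$start + 1L
  out$start <- NULL
  front <- c("protein_id", "start_1based", "octamer", "nonamer", "p1",
             "flags", "score")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeHitsTsv
#' @export
readHitsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df$start <- as.integer(df$start_1based) - 1L
  df$start_1based <- NULL
  df$flags[is.na(df$flags)] <- ""
  if (!"nonamer" %in% names(df)) df$nonamer <- NA_character_
  df$nonamer <- as.character(df$nonamer)
  df$p1 <- as.character(df$p1)
  front <- c("protein_id", "start", "octamer", "nonamer", "p1", "flags",
             "score")
  df[, c(front, setdiff(names(df), front)), drop = FALSE]
}

#' Collapse duplicate peptides across a hit table
#'
#' Overlapping and duplicated peptides across proteins are all reported by
#' the scanner; this summary collapses identical nonamers (octamers for
#' hits without P1) and counts their occurrences, mirroring how unique
#' peptides are listed for stimulation panels.
#'
#' @param hits Hit data frame.
#' @return Data frame with columns \code{peptide}, \code{n_occurrences},
#'   \code{proteins}.
#' @export
dedupHits <- function(hits) {
  pep <- ifelse(is.na(hits$nonamer), hits$octamer, hits$nonamer)
  if (length(pep) == 0L) {
    return(data.frame(peptide = character(0), n_occurrences = integer(0),
                      proteins = character(0), stringsAsFactors = FALSE))
  }
  agg <- lapply(split(seq_along(pep), pep), function(idx) {
    data.frame(n_occurrences = length(idx),
               proteins = paste(sort(unique(hits$protein_id[idx])),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- data.frame(peptide = rownames(out), out, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$peptide), , drop = FALSE]
}
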