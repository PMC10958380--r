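#' Read a gluten-free-diet cohort table
#'
#' Tab-separated, one row per patient, mirroring the published
#' patient-characteristics layout: \code{patient_id}, \code{sex},
#' \code{clinical_type} (comma-separated subset of PsO/PsA/PPPP),
#' \code{age_of_onset_y}, \code{gliadin_screen} (\code{pos}/\code{neg}/
#' \code{ND}), quantitative titers \code{igg_plus_iga_u_ml} and
#' \code{iga_u_ml} (empty when not determined or reported negative),
#' \code{age_at_gfd_y}, \code{treatment}, \code{pasi_baseline},
#' \code{pasi_improvement} (\code{NI}/\code{PASI75}/\code{PASI90}),
#' \code{psa_improvement} (\code{Yes}/\code{NI}/\code{not_applicable}),
#' \code{relapse_on_dietary_error} (\code{Yes}/\code{NR}).
#'
#' The transcription of the published 13-patient table ships with the
#' package: \code{system.file("extdata", "table1_cohort.tsv", package =
#' "mimoScan")}.
#'
#' @param path File path.
#' @return Data frame of patient records.
#' @export
readCohortTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "ND", "neg"))
  need <- c("patient_id", "gliadin_screen", "pasi_baseline",
            "pasi_improvement", "psa_improvement",
            "relapse_on_dietary_error")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ## screen column must keep its categorical values
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  df$gliadin_screen <- raw$gliadin_screen
  df$gliadin_screen[!nzchar(df$gliadin_screen)] <- "ND"
  for (col in c("igg_plus_iga_u_ml", "iga_u_ml")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if (any(!is.na(df$pasi_baseline) & df$pasi_baseline <= 0)) {
    stop("pasi_baseline must be positive", call. = FALSE)
  }
  df
}

#' Classify diet response from the PASI improvement class
#'
#' A patient is a responder when the improvement reaches PASI 75 or better
#' (classes \code{PASI75} and \code{PASI90}); \code{NI} is a non-responder.
#'
#' @param pasi_improvement Character vector of improvement classes.
#' @return Logical vector.
#' @export
classifyResponse <- function(pasi_improvement) {
  if (any(is.na(pasi_improvement))) {
    stop("missing PASI improvement class", call. = FALSE)
  }
  bad <- setdiff(unique(pasi_improvement), c("NI", "PASI75", "PASI90"))
  if (length(bad)) {
    stop("unknown PASI improvement class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pasi_improvement %in% c("PASI75", "PASI90")
}

#' Percent PASI improvement and its class
#'
#' @param baseline Positive baseline PASI.
#' @param follow_up Follow-up PASI (>= 0; may exceed baseline, giving a
#'   negative improvement and class \code{NI}).
#' @return List with \code{percent} = \code{100 * (baseline - follow_up) /
#'   baseline} and \code{class} (\code{PASI90} iff >= 90, else \code{PASI75}
#'   iff >= 75, else \code{NI}).
#' @examples
#' pasiPercentImprovement(28.5, 2.85)$class  # "PASI90"
#' @export
pasiPercentImprovement <- function(baseline, follow_up) {
  if (any(baseline <= 0)) stop("baseline PASI must be > 0", call. = FALSE)
  if (any(follow_up < 0)) stop("follow-up PASI must be >= 0", call. = FALSE)
  pct <- 100 * (baseline - follow_up) / baseline
  cls <- ifelse(pct >= 90, "PASI90", ifelse(pct >= 75, "PASI75", "NI"))
  list(percent = pct, class = cls)
}

#' Classify gliadin serology
#'
#' Elevated iff any available quantitative titer (combined IgG+IgA, or IgA)
#' reaches the threshold (>= 10 U/ml, inclusive). When no titer is present
#' the categorical screen column is used as fallback; with neither, the
#' result is \code{NA} (not determined).
#'
#' @param records Cohort data frame (columns \code{igg_plus_iga_u_ml},
#'   \code{iga_u_ml}, \code{gliadin_screen}).
#' @param threshold U/ml cut-off, default 10.
#' @param use_screen_fallback Use the categorical screen when titers are
#'   absent (default TRUE; set FALSE to exclude titer-less patients).
#' @return Logical vector (\code{NA} = not determined).
#' @export
classifySerology <- function(records, threshold = 10,
                             use_screen_fallback = TRUE) {
  igg <- if ("igg_plus_iga_u_ml" %in% names(records)) {
    records$igg_plus_iga_u_ml
  } else rep(NA_real_, nrow(records))
  iga <- if ("iga_u_ml" %in% names(records)) records$iga_u_ml
         else rep(NA_real_, nrow(records))
  screen <- if ("gliadin_screen" %in% names(records)) {
    records$gliadin_screen
  } else rep("ND", nrow(records))
  out <- rep(NA, nrow(records))
  for (i in seq_len(nrow(records))) {
    titers <- c(igg[[i]], iga[[i]])
    titers <- titers[!is.na(titers)]
    if (length(titers)) {
      out[[i]] <- any(titers >= threshold)
    } else if (use_screen_fallback && screen[[i]] %in% c("pos", "neg")) {
      out[[i]] <- screen[[i]] == "pos"
    }
  }
  out
}

#' Serology--response association (2x2 Fisher exact test)
#'
#' Cross-tabulates diet response against elevated gliadin serology and
#' computes the two-sided Fisher exact (hypergeometric) p-value. Patients
#' whose serology is not determined on the chosen basis are excluded from
#' the table. A degenerate table (an empty row or column) yields p = 1 with
#' a warning.
#'
#' @param records Cohort data frame.
#' @param basis \code{"screen"} uses the categorical screen column only;
#'   \code{"titer"} uses quantitative titers with screen fallback (see
#'   [classifySerology()]).
#' @param threshold Titer threshold in U/ml.
#' @param use_screen_fallback Only for \code{basis = "titer"}.
#' @return List with \code{table} (2x2; rows responder TRUE/FALSE, columns
#'   elevated TRUE/FALSE), \code{p} and \code{basis}.
#' @export
serologyResponseAssociation <- function(records,
                                        basis = c("screen", "titer"),
                                        threshold = 10,
                                        use_screen_fallback = TRUE) {
  basis <- match.arg(basis)
  responder <- classifyResponse(records$pasi_improvement)
  elevated <- if (basis == "screen") {
    ifelse(records$gliadin_screen == "pos", TRUE,
           ifelse(records$gliadin_screen == "neg", FALSE, NA))
  } else {
    classifySerology(records, threshold = threshold,
                     use_screen_fallback = use_screen_fallback)
  }
  keep <- !is.na(elevated)
  if (!any(keep)) stop("no classifiable records", call. = FALSE)
  tab <- table(factor(responder[keep], levels = c(TRUE, FALSE)),
               factor(elevated[keep], levels = c(TRUE, FALSE)),
               dnn = c("responder", "elevated"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table; association untestable, p = 1")
    return(list(table = tab, p = 1, basis = basis))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p = min(1, ft$p.value), basis = basis)
}

#' Summarise a gluten-free-diet cohort
#'
#' Counts responders (PASI 75 or better), relapses after dietary errors,
#' patients whose psoriatic arthritis became symptom-free, and the
#' serology--response association on both serology bases.
#'
#' @param records Cohort data frame (e.g. from [readCohortTable()]).
#' @return List: \code{n_total}, \code{n_responders},
#'   \code{n_relapse_after_error}, \code{n_psa_symptom_free},
#'   \code{serology_screen} and \code{serology_titer} (each a
#'   [serologyResponseAssociation()] result).
#' @export
summarizeCohort <- function(records) {
  if (nrow(records) == 0L) {
    return(list(n_total = 0L, n_responders = 0L,
                n_relapse_after_error = 0L, n_psa_symptom_free = 0L,
                serology_screen = NULL, serology_titer = NULL))
  }
  if (anyDuplicated(records$patient_id)) {
    stop("duplicate patient_id in cohort", call. = FALSE)
  }
  responder <- classifyResponse(records$pasi_improvement)
  list(
    n_total = nrow(records),
    n_responders = sum(responder),
    n_relapse_after_error = sum(records$relapse_on_dietary_error == "Yes",
                                na.rm = TRUE),
    n_psa_symptom_free = sum(records$psa_improvement == "Yes",
                             na.rm = TRUE),
    serology_screen = serologyResponseAssociation(records, basis = "screen"),
    serology_titer = serologyResponseAssociation(records, basis = "titer")
  )
}
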