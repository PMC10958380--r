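#' Sample peptides uniformly from a motif's language
#'
#' Constrained positions draw uniformly from their allowed set; free
#' positions draw uniformly from the 20-letter alphabet, excluding (by
#' default) residues the motif forbids there, so sampled peptides survive
#' curation. Set \code{exclude_forbidden = FALSE} to deliberately plant
#' curation-negative peptides.
#'
#' @param motif A [RecognitionMotif-class].
#' @param n Number of nonamers.
#' @param exclude_forbidden Avoid forbidden residues at free positions.
#' @return Character vector of nonamers.
#' @export
sampleMotifPeptides <- function(motif, n, exclude_forbidden = TRUE) {
  stopifnot(is(motif, "RecognitionMotif"), n >= 0)
  vapply(seq_len(n), function(i) {
    chars <- vapply(NONAMER_POSITIONS, function(p) {
      set <- motif@allowed[[p]]
      if (is.null(set)) {
        set <- AA_ALPHABET
        if (exclude_forbidden && p %in% names(motif@forbidden)) {
          set <- setdiff(set, motif@forbidden[[p]])
        }
      }
      sample(set, 1L)
    }, character(1))
    .collapse(chars)
  }, character(1))
}

#' Generate a seeded synthetic proteome with planted motif instances
#'
#' Background residues are drawn i.i.d. from the stated composition
#' (uniform 1/20 by default). Planted nonamers -- sampled from the motif
#' language or given verbatim -- overwrite the background at recorded
#' coordinates, and the truth table suffices to score scanner sensitivity.
#' The same seed yields byte-identical output.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer c(min, max); lengths drawn uniformly.
#' @param background Named residue frequencies (default uniform).
#' @param planted Either \code{NULL}, a count of motif-sampled nonamers to
#'   place at random (requires \code{motif}), or a data frame with columns
#'   \code{nonamer}, \code{protein} (index) and \code{start} (1-based
#'   nonamer start, >= 1 so the P1-supplementing octamer offset has an
#'   upstream residue).
#' @param motif A [RecognitionMotif-class]; needed when \code{planted} is a
#'   count.
#' @param exclude_forbidden Passed to [sampleMotifPeptides()].
#' @param seed Mandatory integer seed.
#' @return List with \code{proteins} ([Biostrings::AAStringSet]) and
#'   \code{truth} (data frame \code{protein_id}, \code{nonamer_start}
#'   1-based, \code{octamer_start} 0-based, \code{nonamer}).
#' @export
generateProteome <- function(n_proteins, length_range = c(300L, 800L),
                             background = NULL, planted = NULL,
                             motif = NULL, exclude_forbidden = TRUE, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  if (abs(sum(background[AA_ALPHABET]) - 1) > 1e-6) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  .with_seed(seed, {
    if (n_proteins == 0L) {
      return(list(proteins = Biostrings::AAStringSet(),
                  truth = data.frame(protein_id = character(0),
                                     nonamer_start = integer(0),
                                     octamer_start = integer(0),
                                     nonamer = character(0),
                                     stringsAsFactors = FALSE)))
    }
    lmin <- as.integer(length_range[[1L]])
    lmax <- as.integer(length_range[[2L]])
    lens <- lmin + sample.int(lmax - lmin + 1L, n_proteins,
                              replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      .collapse(sample(AA_ALPHABET, L, replace = TRUE,
                       prob = background[AA_ALPHABET]))
    }, character(1))
    ids <- sprintf("synth_%03d", seq_len(n_proteins))

    if (is.numeric(planted) && length(planted) == 1L) {
      n_plant <- as.integer(planted)
      if (n_plant > 0L && is.null(motif)) {
        stop("planting a count of instances requires 'motif'", call. = FALSE)
      }
      planted <- if (n_plant == 0L) NULL else {
        data.frame(
          nonamer = sampleMotifPeptides(motif, n_plant, exclude_forbidden),
          protein = sample(n_proteins, n_plant, replace = TRUE),
          start = NA_integer_, stringsAsFactors = FALSE)
      }
      if (!is.null(planted)) {
        occupied <- vector("list", n_proteins)
        for (i in seq_len(nrow(planted))) {
          k <- planted$protein[[i]]
          L <- lens[[k]]
          for (attempt in 1:100) {
            st <- sample(1:(L - 9L), 1L)
            clash <- any(vapply(occupied[[k]], function(iv)
              st <= iv[[2L]] && st + 8L >= iv[[1L]], logical(1)))
            if (!clash) break
            if (attempt == 100L) {
              stop("could not place planted instance without collision",
                   call. = FALSE)
            }
          }
          occupied[[k]] <- c(occupied[[k]], list(c(st, st + 8L)))
          planted$start[[i]] <- st
        }
      }
    }

    truth <- data.frame(protein_id = character(0), nonamer_start = integer(0),
                        octamer_start = integer(0), nonamer = character(0),
                        stringsAsFactors = FALSE)
    if (!is.null(planted) && nrow(planted) > 0L) {
      for (s in split(planted, planted$protein)) {
        iv <- cbind(s$start, s$start + 8L)
        o <- order(iv[, 1L])
        iv <- iv[o, , drop = FALSE]
        if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
          stop("planted windows overlap in protein ",
               s$protein[[1L]], call. = FALSE)
        }
      }
      for (i in seq_len(nrow(planted))) {
        k <- planted$protein[[i]]
        st <- planted$start[[i]]
        nonamer <- toupper(planted$nonamer[[i]])
        if (st < 1L || st + 8L > lens[[k]]) {
          stop("planted window outside protein ", k, call. = FALSE)
        }
        substr(seqs[[k]], st, st + 8L) <- nonamer
        truth <- rbind(truth, data.frame(
          protein_id = ids[[k]], nonamer_start = st,
          octamer_start = st,  # 0-based octamer offset equals 1-based nonamer start
          nonamer = nonamer, stringsAsFactors = FALSE))
      }
    }
    proteins <- Biostrings::AAStringSet(seqs)
    names(proteins) <- ids
    list(proteins = proteins, truth = truth)
  })
}

#' Generate a seeded synthetic assay dataset
#'
#' Emulates two-group stimulation assays: each subject has a log-normal
#' baseline; unstimulated controls are baseline times replicate-level
#' log-normal noise, and stimulated replicates additionally carry the
#' configured multiplicative group effect. CD137-style percentage readouts
#' are clipped to \[0, 100\].
#'
#' @param n_pso,n_hc Group sizes. Defaults mirror a typical proliferation
#'   cohort (41 patients, 12 controls).
#' @param effects Named list: one entry per peptide, each a numeric vector
#'   \code{c(Pso = ..., HC = ...)} of multiplicative effects (> 0; 1 =
#'   null).
#' @param control_mean Mean unstimulated readout (cpm, or percent for
#'   CD137).
#' @param sigma Replicate-level log-normal sdlog.
#' @param sigma_subject Subject-level baseline sdlog.
#' @param replicates,ctrl_replicates Stimulated / control replicate counts.
#' @param readout \code{"cpm_triplicate"} or \code{"cd137_duplicate"}.
#' @param seed Mandatory integer seed.
#' @return List with \code{assay} (wide data frame in the assay-table
#'   schema) and \code{truth} (subject, group, peptide, true effect).
#' @export
generateAssayDataset <- function(n_pso = 41, n_hc = 12,
                                 effects = list(antigen = c(Pso = 3, HC = 1),
                                                control = c(Pso = 1, HC = 1)),
                                 control_mean = 500, sigma = 0.5,
                                 sigma_subject = 0.6, replicates = 3,
                                 ctrl_replicates = 3,
                                 readout = c("cpm_triplicate",
                                             "cd137_duplicate"),
                                 seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  readout <- match.arg(readout)
  stopifnot(all(unlist(effects) > 0), sigma > 0, sigma_subject >= 0)
  .with_seed(seed, {
    subjects <- data.frame(
      subject_id = c(sprintf("Pso_%02d", seq_len(n_pso)),
                     sprintf("HC_%02d", seq_len(n_hc))),
      group = c(rep("Pso", n_pso), rep("HC", n_hc)),
      stringsAsFactors = FALSE)
    subjects$baseline <- control_mean *
      stats::rlnorm(nrow(subjects), 0, sigma_subject)
    clip <- function(x) if (readout == "cd137_duplicate") {
      pmin(100, x)
    } else x
    rows <- list()
    truth <- list()
    for (pep in names(effects)) {
      for (i in seq_len(nrow(subjects))) {
        eff <- effects[[pep]][[subjects$group[[i]]]]
        ctrl <- clip(subjects$baseline[[i]] *
                       stats::rlnorm(ctrl_replicates, 0, sigma))
        stim <- clip(subjects$baseline[[i]] * eff *
                       stats::rlnorm(replicates, 0, sigma))
        row <- data.frame(subject_id = subjects$subject_id[[i]],
                          group = subjects$group[[i]], peptide = pep,
                          readout = readout, stringsAsFactors = FALSE)
        for (r in seq_len(replicates)) row[[paste0("rep", r)]] <- stim[[r]]
        for (r in seq_len(ctrl_replicates)) {
          row[[paste0("ctrl", r)]] <- ctrl[[r]]
        }
        rows[[length(rows) + 1L]] <- row
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = subjects$subject_id[[i]],
          group = subjects$group[[i]], peptide = pep, true_effect = eff,
          stringsAsFactors = FALSE)
      }
    }
    list(assay = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate a seeded synthetic gluten-free-diet cohort
#'
#' Draws responder status and elevated serology independently (or with the
#' configured dependence), filling in plausible titers, baseline PASI and
#' improvement classes. Supplying \code{classes} and/or \code{screens}
#' verbatim freezes those columns (e.g. to mirror a published table).
#'
#' @param n Number of patients.
#' @param response_prob P(responder).
#' @param elevated_prob_responder,elevated_prob_nonresponder P(elevated
#'   serology) by response status; equal values encode independence.
#' @param classes Optional character vector of PASI improvement classes to
#'   use verbatim (overrides \code{response_prob}).
#' @param screens Optional character vector of screen values to use
#'   verbatim.
#' @param seed Mandatory integer seed.
#' @return List with \code{cohort} (data frame in the cohort-table schema)
#'   and \code{truth} (responder / elevated per patient).
#' @export
generateCohortTable <- function(n = 13, response_prob = 0.5,
                                elevated_prob_responder = 0.5,
                                elevated_prob_nonresponder = 0.5,
                                classes = NULL, screens = NULL, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  .with_seed(seed, {
    if (is.null(classes)) {
      responder <- stats::runif(n) < response_prob
      classes <- ifelse(responder,
                        ifelse(stats::runif(n) < 0.5, "PASI90", "PASI75"),
                        "NI")
    } else {
      stopifnot(length(classes) == n)
      responder <- classifyResponse(classes)
    }
    if (is.null(screens)) {
      p_elev <- ifelse(responder, elevated_prob_responder,
                       elevated_prob_nonresponder)
      elevated <- stats::runif(n) < p_elev
      screens <- ifelse(elevated, "pos", "neg")
    } else {
      stopifnot(length(screens) == n)
      elevated <- screens == "pos"
    }
    titer <- ifelse(elevated, stats::runif(n, 10, 25),
                    stats::runif(n, 0.5, 9.9))
    cohort <- data.frame(
      patient_id = seq_len(n),
      sex = sample(c("M", "F"), n, replace = TRUE),
      clinical_type = "PsO",
      age_of_onset_y = sample(5:55, n, replace = TRUE),
      gliadin_screen = screens,
      igg_plus_iga_u_ml = round(titer, 1),
      iga_u_ml = NA_real_,
      age_at_gfd_y = sample(25:75, n, replace = TRUE),
      treatment = "synthetic",
      pasi_baseline = round(stats::runif(n, 8, 30), 1),
      pasi_improvement = classes,
      psa_improvement = "not_applicable",
      relapse_on_dietary_error = "NR",
      stringsAsFactors = FALSE)
    truth <- data.frame(patient_id = seq_len(n), responder = responder,
                        elevated = elevated, stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}
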