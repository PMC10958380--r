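#' Stimulation index of one assay record
#'
#' The stimulation index (SI) is the central stimulated readout divided by
#' the mean of the unstimulated controls. The central statistic follows the
#' readout: the median for cpm triplicates from proliferation assays, the
#' mean for CD137 percentage duplicates (and for sGFP fractions).
#'
#' @param stimulated Non-empty numeric vector of stimulated readouts.
#' @param controls Non-empty numeric vector of unstimulated control
#'   readouts; their mean must be positive.
#' @param readout One of \code{"cpm_triplicate"}, \code{"cd137_duplicate"},
#'   \code{"sgfp_fraction"}.
#' @return The SI (positive scalar).
#' @examples
#' stimulationIndex(c(100, 200, 300), c(100, 100, 100))  # 2
#' @export
stimulationIndex <- function(stimulated, controls,
                             readout = c("cpm_triplicate", "cd137_duplicate",
                                         "sgfp_fraction")) {
  readout <- match.arg(readout)
  if (length(stimulated) == 0L || length(controls) == 0L) {
    stop("stimulated and control values must be non-empty", call. = FALSE)
  }
  if (any(stimulated < 0) || any(controls < 0)) {
    stop("assay readouts must be non-negative", call. = FALSE)
  }
  ctrl <- mean(controls)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control mean must be positive (SI undefined)", call. = FALSE)
  }
  central <- if (readout == "cpm_triplicate") stats::median(stimulated)
             else mean(stimulated)
  central / ctrl
}

#' Normalise readouts to the same-experiment CD3 response
#'
#' @param values Numeric readouts (e.g. percent sGFP+ cells).
#' @param cd3_values Same-experiment CD3 (positive-control) readouts; their
#'   mean must be positive.
#' @return \code{values / mean(cd3_values)}.
#' @export
normalizeToCd3 <- function(values, cd3_values) {
  if (length(cd3_values) == 0L || any(is.na(cd3_values))) {
    stop("missing CD3 control values", call. = FALSE)
  }
  m <- mean(cd3_values)
  if (m <= 0) stop("CD3 control mean must be positive", call. = FALSE)
  values / m
}

#' Two-group Mann-Whitney U comparison
#'
#' Two-sided unpaired Mann-Whitney U test via [stats::wilcox.test()]. The
#' exact enumeration p-value is used when the combined sample size is at
#' most 12 and no ties are present; otherwise the tie-corrected normal
#' approximation (with continuity correction) applies.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List with \code{U} (the Mann-Whitney statistic for group a),
#'   \code{p} (two-sided), \code{exact} (logical), \code{n_a}, \code{n_b}.
#' @examples
#' compareTwoGroups(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by exact enumeration
#' @export
compareTwoGroups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- (n <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided", exact = use_exact,
    correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = use_exact,
       n_a = length(values_a), n_b = length(values_b))
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (default \code{length(p)}).
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < 1) stop("family size must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' Multi-group Kruskal-Wallis comparison with Bonferroni-corrected pairwise
#' tests
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param comparisons Optional character vector of pairwise comparisons to
#'   run, each \code{"groupA|groupB"}; referencing an absent group is an
#'   error. Default: all pairs.
#' @param family_size Bonferroni family size; default the number of pairwise
#'   comparisons performed. The family is configurable because it is
#'   study-design dependent (e.g. the number of peptides tested within a
#'   readout).
#' @return List with \code{H}, \code{p} (tie-corrected Kruskal-Wallis) and a
#'   data frame \code{pairwise} (group_a, group_b, U, p_raw, p_adj).
#' @export
compareMultipleGroups <- function(groups, comparisons = NULL,
                                  family_size = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a named list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named", call. = FALSE)
  }
  kw <- stats::kruskal.test(groups)
  pairs <- utils::combn(names(groups), 2L)
  all_labels <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  if (!is.null(comparisons)) {
    rev_labels <- paste(pairs[2L, ], pairs[1L, ], sep = "|")
    idx <- match(comparisons, all_labels)
    idx[is.na(idx)] <- match(comparisons[is.na(idx)], rev_labels)
    if (any(is.na(idx))) {
      stop("comparison(s) reference absent groups: ",
           paste(comparisons[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    pairs <- pairs[, idx, drop = FALSE]
  }
  m <- if (is.null(family_size)) ncol(pairs) else family_size
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    res <- compareTwoGroups(groups[[a]], groups[[b]])
    data.frame(group_a = a, group_b = b, U = res$U, p_raw = res$p,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- bonferroniAdjust(pw$p_raw, m)
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw,
       family_size = m)
}

#' Read an assay table
#'
#' Tab-separated with header; columns \code{subject_id}, \code{group}
#' (\code{Pso}/\code{HC}), \code{peptide}, \code{readout}, then stimulated
#' replicates \code{rep1..repk} and unstimulated controls \code{ctrl1..ctrlk}
#' (k may differ between the two blocks).
#'
#' @param path File path.
#' @return Data frame with the replicate columns left wide.
#' @export
readAssayTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "peptide", "readout")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("assay table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!length(grep("^rep[0-9]+$", names(df))) ||
      !length(grep("^ctrl[0-9]+$", names(df)))) {
    stop("assay table needs rep1..repk and ctrl1..ctrlk columns",
         call. = FALSE)
  }
  df
}

.assay_value_cols <- function(df, prefix) {
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(df), value = TRUE)
  cols[order(as.integer(sub(prefix, "", cols)))]
}

#' Compute per-record stimulation indices for an assay table
#'
#' @param assay Data frame from [readAssayTable()].
#' @return Data frame \code{subject_id}, \code{group}, \code{peptide},
#'   \code{readout}, \code{si}.
#' @export
computeStimulationIndices <- function(assay) {
  rep_cols <- .assay_value_cols(assay, "rep")
  ctrl_cols <- .assay_value_cols(assay, "ctrl")
  si <- vapply(seq_len(nrow(assay)), function(i) {
    stim <- as.numeric(assay[i, rep_cols])
    ctrl <- as.numeric(assay[i, ctrl_cols])
    stimulationIndex(stim[!is.na(stim)], ctrl[!is.na(ctrl)],
                     readout = assay$readout[[i]])
  }, numeric(1))
  data.frame(subject_id = assay$subject_id, group = assay$group,
             peptide = assay$peptide, readout = assay$readout, si = si,
             stringsAsFactors = FALSE)
}

#' Exclude subjects whose positive control failed
#'
#' Stimulation experiments are dropped when the positive-control record for
#' the subject does not reach a minimum SI; the exclusion is rule-driven and
#' logged, never silent.
#'
#' @param si_table Data frame from [computeStimulationIndices()].
#' @param positive_control_peptide Label of the positive-control peptide
#'   (e.g. \code{"CD3"}); subjects lacking the record are kept.
#' @param min_si Minimum SI the positive control must reach (default 2).
#' @return List \code{kept} / \code{excluded} of SI tables; excluded rows
#'   keep all their columns.
#' @export
excludeFailedControls <- function(si_table, positive_control_peptide,
                                  min_si = 2) {
  ctrl <- si_table[si_table$peptide == positive_control_peptide, ,
                   drop = FALSE]
  failed <- unique(ctrl$subject_id[ctrl$si < min_si])
  if (length(failed)) {
    message("excluding subject(s) with failed positive control: ",
            paste(failed, collapse = ", "))
  }
  drop <- si_table$subject_id %in% failed
  list(kept = si_table[!drop, , drop = FALSE],
       excluded = si_table[drop, , drop = FALSE])
}

#' Per-peptide group comparison of stimulation indices
#'
#' For each peptide, compares SI between the two groups with the
#' Mann-Whitney U test and applies a Bonferroni correction across the
#' family of peptides tested within each readout.
#'
#' @param si_table Data frame from [computeStimulationIndices()].
#' @param group_a,group_b Group labels (defaults \code{"Pso"}, \code{"HC"}).
#' @param family_size Bonferroni family; default the number of peptides per
#'   readout.
#' @return Data frame \code{readout}, \code{peptide}, \code{n_a},
#'   \code{n_b}, \code{U}, \code{p_raw}, \code{p_adj}.
#' @export
testPeptideGroupDifferences <- function(si_table, group_a = "Pso",
                                        group_b = "HC",
                                        family_size = NULL) {
  out <- lapply(split(si_table, si_table$readout), function(block) {
    peptides <- unique(block$peptide)
    m <- if (is.null(family_size)) length(peptides) else family_size
    rows <- lapply(peptides, function(pep) {
      sub <- block[block$peptide == pep, , drop = FALSE]
      a <- sub$si[sub$group == group_a]
      b <- sub$si[sub$group == group_b]
      res <- compareTwoGroups(a, b)
      data.frame(readout = block$readout[[1L]], peptide = pep,
                 n_a = res$n_a, n_b = res$n_b, U = res$U, p_raw = res$p,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$p_adj <- bonferroniAdjust(rows$p_raw, m)
    rows
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Type-I error and power summary by simulation
#'
#' Simulates two-group stimulation-index datasets under configured
#' multiplicative effect sizes and reports the fraction of replicates in
#' which the two-sided Mann-Whitney test rejects at \code{alpha}. With
#' effect 1 (the null) the rejection rate estimates the type-I error; with
#' larger effects it estimates power. Reproducible given the seed.
#'
#' @param effects Numeric vector of multiplicative group effects (ratio of
#'   the first group's SI scale over the second's); 1 = null.
#' @param n_a,n_b Group sizes.
#' @param replicates Simulation replicates per effect.
#' @param sigma Log-normal noise sdlog for the per-subject SI.
#' @param alpha Significance level (default 0.05, two-tailed).
#' @param seed Mandatory integer seed.
#' @return Data frame \code{effect}, \code{n_a}, \code{n_b},
#'   \code{replicates}, \code{rejection_rate}.
#' @export
type1AndPowerSummary <- function(effects, n_a = 10, n_b = 10,
                                 replicates = 2000, sigma = 0.5,
                                 alpha = 0.05, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  .with_seed(seed, {
    rates <- vapply(effects, function(eff) {
      rej <- 0L
      for (r in seq_len(replicates)) {
        a <- eff * stats::rlnorm(n_a, 0, sigma)
        b <- stats::rlnorm(n_b, 0, sigma)
        if (compareTwoGroups(a, b)$p < alpha) rej <- rej + 1L
      }
      rej / replicates
    }, numeric(1))
    data.frame(effect = effects, n_a = n_a, n_b = n_b,
               replicates = replicates, rejection_rate = rates)
  })
}
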