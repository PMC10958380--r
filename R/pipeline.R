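## Pipeline stage wrappers: each reads the standard input formats, runs the
## corresponding module, writes machine-readable outputs plus a provenance
## block (config, seed, package version) so any run is reproducible from its
## outputs alone. These functions are the package's command surface; they
## are thin over the module functions and return their results invisibly.

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with optional blocks: \code{paths} (ligand_table, fasta,
#' assay_table, cohort_table, out_dir), \code{motif} (abolition_threshold,
#' pseudocount, allowed_fraction_threshold, policy, patterns),
#' \code{curation} (forbidden: position -> residues), \code{statistics}
#' (alpha, family_size, positive_control, min_control_si) and \code{seed}.
#'
#' @param path Config file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  cfg
}

.write_provenance <- function(out_dir, stage, config) {
  prov <- list(
    stage = stage,
    package = "mimoScan",
    version = as.character(utils::packageVersion("mimoScan")),
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = "")))
  )
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage,
                                                       "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Derive a recognition motif from ligand and scan tables
#'
#' Stage 1: reads a substitution-scan table and a stimulatory ligand table,
#' infers the critical positions, builds the position-frequency model, and
#' derives the motif. Writes \code{motif.json} and \code{logo.tsv}
#' (per-position frequencies and information content) to \code{out_dir}.
#'
#' @param ligand_path,scan_path Input TSVs (see [readLigandTable()],
#'   [readScanProfile()]).
#' @param out_dir Output directory (created if absent).
#' @param abolition_threshold,pseudocount,allowed_fraction_threshold See
#'   the motif-model functions.
#' @param forbidden,annotations Passed to [deriveRecognitionMotif()].
#' @return The [RecognitionMotif-class], invisibly.
#' @export
runDeriveMotif <- function(ligand_path, scan_path, out_dir,
                           abolition_threshold = 0.2, pseudocount = 0,
                           allowed_fraction_threshold = 0,
                           forbidden = list(P6 = "R"),
                           annotations = c(P2 = "HLA anchor",
                                           P5 = "TCR contact",
                                           P7 = "auxiliary anchor",
                                           P8 = "TCR contact",
                                           P9 = "HLA anchor")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ligands <- readLigandTable(ligand_path)
  if (!any(ligands$stimulatory)) {
    stop("ligand table contains no stimulatory ligands", call. = FALSE)
  }
  scan <- readScanProfile(scan_path)
  crit <- inferCriticalPositions(scan, abolition_threshold)
  model <- buildFrequencyModel(ligands, pseudocount = pseudocount)
  motif <- deriveRecognitionMotif(model, crit,
                                  allowed_fraction_threshold,
                                  forbidden = forbidden,
                                  annotations = annotations)
  motifToJson(motif, file.path(out_dir, "motif.json"))
  ic <- informationContent(model)
  logo <- data.frame(position = NONAMER_POSITIONS,
                     information_bits = ic,
                     t(residueFrequencies(model)),
                     stringsAsFactors = FALSE)
  utils::write.table(logo, file.path(out_dir, "logo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_provenance(out_dir, "derive_motif",
                    list(ligand_path = ligand_path, scan_path = scan_path,
                         abolition_threshold = abolition_threshold,
                         pseudocount = pseudocount,
                         allowed_fraction_threshold =
                           allowed_fraction_threshold))
  invisible(motif)
}

#' Scan a FASTA proteome and write curated, ranked hits
#'
#' Stage 2: scans every octamer window, completes P1 from the natural
#' protein sequence, curates on the forbidden-residue rules, optionally
#' ranks against a frequency model, and writes \code{hits.tsv} (kept hits,
#' 1-based coordinates), \code{removed.tsv} and a scan summary log line.
#'
#' @param fasta_path Input FASTA.
#' @param motif [RecognitionMotif-class]; or supply \code{patterns}.
#' @param patterns Plain octamer pattern vector (explicit-pattern mode).
#' @param rules A [curationRules()] object.
#' @param model Optional [PositionFrequencyModel-class] for ranking.
#' @param out_dir Output directory.
#' @return List \code{kept} / \code{removed}, invisibly.
#' @export
runScan <- function(fasta_path, motif = NULL, patterns = NULL,
                    rules = curationRules(), model = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- readFasta(fasta_path)
  hits <- scanProteome(proteins, motif = motif, patterns = patterns)
  hits <- completeNonamer(hits, proteins)
  cur <- curateHits(hits, rules)
  if (!is.null(model)) cur$kept <- rankHits(cur$kept, model)
  writeHitsTsv(cur$kept, file.path(out_dir, "hits.tsv"))
  removed <- cur$removed
  writeHitsTsv(removed, file.path(out_dir, "removed.tsv"))
  message(sprintf(
    "scan: %d windows scanned, %d skipped (ambiguous), %d hits, %d curated out",
    attr(hits, "windows_scanned"), attr(hits, "windows_skipped"),
    nrow(hits), nrow(cur$removed)))
  .write_provenance(out_dir, "scan",
                    list(fasta_path = fasta_path,
                         mode = if (is.null(patterns)) "motif" else "patterns",
                         patterns = patterns,
                         forbidden = rules$forbidden))
  invisible(cur)
}

#' Compute stimulation indices and group tests for an assay table
#'
#' Stage 3: reads the assay TSV, computes per-record stimulation indices,
#' applies the positive-control exclusion rule when configured, tests
#' group differences per peptide (Mann-Whitney, Bonferroni across the
#' peptide family) and writes \code{si.tsv} and \code{tests.tsv}.
#'
#' @param assay_path Input TSV (see [readAssayTable()]).
#' @param out_dir Output directory.
#' @param positive_control_peptide,min_control_si Optional exclusion rule
#'   (see [excludeFailedControls()]).
#' @param family_size Bonferroni family (default: peptides per readout).
#' @return List with \code{si} and \code{tests} data frames, invisibly.
#' @export
runStats <- function(assay_path, out_dir, positive_control_peptide = NULL,
                     min_control_si = 2, family_size = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- readAssayTable(assay_path)
  si <- computeStimulationIndices(assay)
  if (!is.null(positive_control_peptide)) {
    si <- excludeFailedControls(si, positive_control_peptide,
                                min_control_si)$kept
  }
  tests <- testPeptideGroupDifferences(si, family_size = family_size)
  utils::write.table(si, file.path(out_dir, "si.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tests, file.path(out_dir, "tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_provenance(out_dir, "stats",
                    list(assay_path = assay_path,
                         positive_control_peptide = positive_control_peptide,
                         min_control_si = min_control_si,
                         family_size = family_size))
  invisible(list(si = si, tests = tests))
}

#' Summarise a cohort table and write the report
#'
#' Stage 4: reads a cohort TSV, classifies response and serology, counts
#' the summary quantities and computes the serology--response Fisher exact
#' association on both serology bases; writes \code{cohort_summary.json}.
#'
#' @param cohort_path Input TSV (see [readCohortTable()]).
#' @param out_dir Output directory.
#' @return The [summarizeCohort()] list, invisibly.
#' @export
runCohort <- function(cohort_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- readCohortTable(cohort_path)
  summary <- summarizeCohort(records)
  report <- list(
    n_total = summary$n_total,
    n_responders = summary$n_responders,
    n_relapse_after_error = summary$n_relapse_after_error,
    n_psa_symptom_free = summary$n_psa_symptom_free,
    serology_screen = list(
      table = as.vector(summary$serology_screen$table),
      p = summary$serology_screen$p),
    serology_titer = list(
      table = as.vector(summary$serology_titer$table),
      p = summary$serology_titer$p)
  )
  jsonlite::write_json(report, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_provenance(out_dir, "cohort", list(cohort_path = cohort_path))
  invisible(summary)
}

#' Generate the synthetic bundles for a full pipeline rehearsal
#'
#' Stage 5: writes a planted-proteome FASTA, an assay TSV and a cohort TSV
#' with their truth tables, all derived from one seed.
#'
#' @param out_dir Output directory.
#' @param motif [RecognitionMotif-class] used for planting.
#' @param n_proteins,n_planted Proteome size and planted instance count.
#' @param seed Mandatory integer seed.
#' @return List of generated objects, invisibly.
#' @export
runSimulate <- function(out_dir, motif, n_proteins = 50, n_planted = 10,
                        seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- generateProteome(n_proteins, planted = n_planted, motif = motif,
                           seed = seed)
  writeFasta(prot$proteins, file.path(out_dir, "proteome.fasta"))
  utils::write.table(prot$truth, file.path(out_dir, "proteome_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assay <- generateAssayDataset(seed = seed + 1L)
  utils::write.table(assay$assay, file.path(out_dir, "assay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assay$truth, file.path(out_dir, "assay_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- generateCohortTable(seed = seed + 2L)
  utils::write.table(cohort$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(out_dir, "cohort_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_provenance(out_dir, "simulate",
                    list(n_proteins = n_proteins, n_planted = n_planted,
                         seed = seed))
  invisible(list(proteome = prot, assay = assay, cohort = cohort))
}
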