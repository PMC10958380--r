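## Shared fixtures and independent oracles.

AA20 <- aminoAcidAlphabet()

## The five-position recognition motif of the autoreactive TCR: Arg anchors
## at P2 and P8, degenerate sets at P5/P7/P9, Arg vetoed at P6 by curation.
canonical_motif <- function() {
  RecognitionMotif(
    allowed = list(P2 = "R", P5 = c("R", "N", "Q"), P7 = c("R", "L"),
                   P8 = "R", P9 = c("L", "M", "V", "F", "I")),
    forbidden = list(P6 = "R"),
    annotations = c(P2 = "HLA anchor", P5 = "TCR contact",
                    P7 = "auxiliary anchor", P8 = "TCR contact",
                    P9 = "HLA anchor")
  )
}

## The eight published octamer search matrices.
eight_patterns <- function() {
  c("RXXRXXRL", "RXXNXRRL", "RXXRXRRL", "RXXNXLRL",
    "RXXRXLRL", "RXXQXLRL", "RXXRXLRM", "RXXRXRRM")
}

## A small stimulatory ligand family whose per-position observation unions
## equal the canonical allowed sets.
ligand_family <- function() {
  p5 <- c("R", "N", "Q", "R", "N")
  p7 <- c("R", "L", "R", "L", "R")
  p9 <- c("L", "M", "V", "F", "I")
  vapply(1:5, function(i) {
    paste0("A", "R", "S", "T", p5[i], "C", p7[i], "R", p9[i])
  }, character(1))
}

## Alanine-scan style profile: near-zero at the five motif positions.
scan_profile_fixture <- function() {
  c(P1 = 1.0, P2 = 0.02, P3 = 0.95, P4 = 1.0, P5 = 0.01,
    P6 = 0.9, P7 = 0.05, P8 = 0.0, P9 = 0.03)
}

random_protein <- function(len) {
  paste0(sample(AA20, len, replace = TRUE), collapse = "")
}

## Independent scan oracle: PCRE lookahead regex built from the motif, with
## overlapping matches; windows containing non-standard codes cannot match
## because every position class is restricted to the 20-letter alphabet.
regex_scan_oracle <- function(seq, motif) {
  classes <- vapply(1:8, function(i) {
    set <- allowedResidues(motif, paste0("P", i + 1))
    if (is.null(set)) paste0("[", paste(AA20, collapse = ""), "]")
    else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

## Exact two-sided Mann-Whitney p by full enumeration of group assignments
## (tie-free inputs). U counts pairs with a-value > b-value.
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n_a)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

## Two-sided Fisher exact p by direct hypergeometric enumeration with
## choose(), independent of stats::fisher.test / dhyper.
fisher_enumeration_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

write_ligand_tsv <- function(path, sequences, stimulatory = TRUE,
                             activation = NA) {
  n <- length(sequences)
  df <- data.frame(sequence = sequences,
                   register = ifelse(nchar(sequences) == 9,
                                     "nonamer", "octamer"),
                   stimulatory = rep_len(stimulatory, n),
                   activation = rep_len(activation, n))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_scan_tsv <- function(path, profile = scan_profile_fixture()) {
  df <- data.frame(position = names(profile), residue = "A",
                   activation = unname(profile))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

table1_path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "mimoScan")
}
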