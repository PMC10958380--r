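test_that("critical-position inference equals direct thresholding and tracks untested positions", {
  crit <- inferCriticalPositions(scan_profile_fixture(), 0.2)
  expect_equal(as.character(crit), c("P2", "P5", "P7", "P8", "P9"))
  expect_length(attr(crit, "untested"), 0)

  all_wt <- setNames(rep(1, 9), paste0("P", 1:9))
  expect_length(inferCriticalPositions(all_wt), 0)

  partial <- c(P2 = 0.05, P5 = 0.5)
  res <- inferCriticalPositions(partial, 0.2)
  expect_equal(as.character(res), "P2")
  expect_true(all(c("P1", "P9") %in% attr(res, "untested")))

  set.seed(11)
  for (i in 1:100) {
    k <- sample(1:9, 1)
    pos <- sample(paste0("P", 1:9), k)
    vals <- setNames(runif(k, 0, 1.1), pos)
    thr <- runif(1, 0.05, 0.95)
    got <- inferCriticalPositions(vals, thr)
    oracle <- names(vals)[vals < thr]
    expect_setequal(as.character(got), oracle)
  }

  expect_error(inferCriticalPositions(numeric(0)), "empty")
  expect_error(inferCriticalPositions(c(P2 = 0.1), abolition_threshold = 0))
  expect_error(inferCriticalPositions(c(Q1 = 0.1)), "P1")
})

test_that("frequency model counts observed residues and smooths with the pseudocount", {
  single <- buildFrequencyModel("ARSTRCRRL", pseudocount = 0)
  f <- residueFrequencies(single)
  expect_equal(unname(f["A", "P1"]), 1)
  expect_equal(unname(f["R", "P2"]), 1)
  expect_equal(colSums(f), setNames(rep(1, 9), paste0("P", 1:9)))

  trio <- c("ARSTRCRRL", "GRSTNCLRM", "ARSTQCRRV")
  m <- buildFrequencyModel(trio, pseudocount = 0)
  f <- residueFrequencies(m)
  expect_equal(unname(f["A", "P1"]), 2 / 3)
  expect_equal(unname(f["G", "P1"]), 1 / 3)
  expect_equal(unname(f["R", "P5"]), 1 / 3)
  expect_equal(unname(f["N", "P5"]), 1 / 3)
  expect_equal(unname(f["Q", "P5"]), 1 / 3)
  expect_equal(unname(residueCounts(m)["R", "P8"]), 3)

  ## octamers lift to P2..P9; P1 stays uninformative with pseudocount 0
  oct <- buildFrequencyModel("RSTRCRRL", pseudocount = 0)
  expect_true(all(is.na(residueFrequencies(oct)[, "P1"])))
  expect_equal(unname(residueFrequencies(oct)["R", "P2"]), 1)

  sm <- buildFrequencyModel("ARSTRCRRL", pseudocount = 1)
  expect_equal(unname(residueFrequencies(sm)["A", "P1"]), 2 / 21)
  expect_equal(unname(colSums(residueFrequencies(sm))[1]), 1)

  expect_error(buildFrequencyModel(c("ARSTRCRRL", "SHORT")), "length")
  expect_error(buildFrequencyModel(character(0)), "no stimulatory")
})

test_that("information content follows the closed-form entropy and stays in bounds", {
  single_col <- buildFrequencyModel(c("ARSTRCRRL"), pseudocount = 0)
  ic <- informationContent(single_col)
  expect_equal(unname(ic["P2"]), log2(20), tolerance = 1e-12)

  two <- buildFrequencyModel(c("ARSTRCRRL", "ARSTNCRRL"), pseudocount = 0)
  ic <- informationContent(two)
  expect_equal(unname(ic["P5"]), log2(20) - 1, tolerance = 1e-12)

  ## near-uniform column via pseudocount flooding -> IC near 0
  flood <- buildFrequencyModel("ARSTRCRRL", pseudocount = 1e6)
  expect_lt(max(informationContent(flood)), 1e-4)

  set.seed(7)
  for (i in 1:20) {
    seqs <- vapply(1:sample(1:6, 1), function(j) random_protein(9),
                   character(1))
    ic <- informationContent(buildFrequencyModel(seqs,
                                                 pseudocount = runif(1)))
    expect_true(all(ic >= 0 - 1e-12 & ic <= log2(20) + 1e-12))
  }
})

test_that("motif derivation recovers the published allowed sets from a ligand family", {
  model <- buildFrequencyModel(ligand_family(), pseudocount = 0)
  crit <- inferCriticalPositions(scan_profile_fixture(), 0.2)
  motif <- deriveRecognitionMotif(model, crit, forbidden = list(P6 = "R"))
  expect_equal(allowedResidues(motif, "P2"), "R")
  expect_setequal(allowedResidues(motif, "P5"), c("R", "N", "Q"))
  expect_setequal(allowedResidues(motif, "P7"), c("R", "L"))
  expect_equal(allowedResidues(motif, "P8"), "R")
  expect_setequal(allowedResidues(motif, "P9"), c("L", "M", "V", "F", "I"))
  for (p in c("P1", "P3", "P4", "P6")) {
    expect_null(allowedResidues(motif, p))
  }
  expect_equal(constrainedPositions(motif), c("P2", "P5", "P7", "P8", "P9"))

  ## single ligand, all positions critical -> fully fixed motif
  one <- buildFrequencyModel("ARSTRCRRL", pseudocount = 0)
  fixed <- deriveRecognitionMotif(one, paste0("P", 1:9))
  expect_true(matchesMotif("ARSTRCRRL", fixed)$match)
  expect_false(matchesMotif("GRSTRCRRL", fixed)$match)

  ## allowed sets equal the direct frequency-threshold oracle
  set.seed(23)
  for (i in 1:20) {
    seqs <- vapply(1:sample(2:8, 1), function(j) random_protein(9),
                   character(1))
    m <- buildFrequencyModel(seqs, pseudocount = 0)
    thr <- runif(1, 0, 0.6)
    counts <- residueCounts(m)
    oracle <- lapply(c(P3 = "P3", P8 = "P8"), function(p) {
      if (thr > 0) {
        rownames(counts)[counts[, p] / sum(counts[, p]) >= thr]
      } else rownames(counts)[counts[, p] >= 1]
    })
    if (any(lengths(oracle) == 0)) {
      expect_error(
        deriveRecognitionMotif(m, c("P3", "P8"),
                               allowed_fraction_threshold = thr),
        "no residues")
    } else {
      motif_i <- deriveRecognitionMotif(m, c("P3", "P8"),
                                        allowed_fraction_threshold = thr)
      for (p in c("P3", "P8")) {
        expect_setequal(allowedResidues(motif_i, p), oracle[[p]])
      }
    }
  }

  expect_error(
    deriveRecognitionMotif(buildFrequencyModel("RSTRCRRL", 0), "P1"),
    "no ligand observations")
})

test_that("re-deriving from motif-language samples recovers the allowed sets", {
  motif <- canonical_motif()
  set.seed(41)
  seqs <- sampleMotifPeptides(motif, 200)
  model <- buildFrequencyModel(seqs, pseudocount = 0)
  re <- deriveRecognitionMotif(model, constrainedPositions(motif))
  for (p in constrainedPositions(motif)) {
    expect_setequal(allowedResidues(re, p), allowedResidues(motif, p))
  }
})

test_that("explicit pattern compilation reproduces the eight published search matrices", {
  motif <- canonical_motif()
  pats <- compileSearchPatterns(motif, "explicit",
                                combinations = eight_patterns())
  expect_identical(pats$pattern, eight_patterns())
  ## only the P7-wildcard matrix is a relaxation of the motif
  expect_identical(pats$wildcard_relaxed, c(TRUE, rep(FALSE, 7)))
  expect_equal(pats$P5[2], "N")
  expect_equal(pats$P9[8], "M")

  expect_error(
    compileSearchPatterns(motif, "explicit", combinations = "RXXGXRRL"),
    "P5")
  expect_error(compileSearchPatterns(motif, "explicit",
                                     combinations = "RXXRL"), "octamer")
  expect_error(compileSearchPatterns(motif, "explicit"), "combinations")
})

test_that("cartesian compilation enumerates the full allowed-set product", {
  motif <- canonical_motif()
  pats <- compileSearchPatterns(motif, "cartesian")
  combos <- expand.grid(P5 = c("R", "N", "Q"), P7 = c("R", "L"),
                        P9 = c("L", "M", "V", "F", "I"),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(pats), nrow(combos))  # 30
  brute <- apply(combos, 1, function(cc) {
    paste0("R", "X", "X", cc[["P5"]], "X", cc[["P7"]], "R", cc[["P9"]])
  })
  expect_setequal(pats$pattern, brute)
  expect_false(any(pats$wildcard_relaxed))

  fixed <- RecognitionMotif(allowed = setNames(
    as.list(strsplit("RSTRCRRL", "")[[1]]), paste0("P", 2:9)))
  single <- compileSearchPatterns(fixed, "cartesian")
  expect_equal(single$pattern, "RSTRCRRL")
})

test_that("every non-wildcard compiled pattern matches only motif-language peptides", {
  motif <- canonical_motif()
  pats <- compileSearchPatterns(motif, "cartesian")
  set.seed(5)
  for (pat in pats$pattern) {
    for (rep in 1:5) {
      chars <- strsplit(pat, "")[[1]]
      chars[chars == "X"] <- sample(AA20, sum(chars == "X"),
                                    replace = TRUE)
      octamer <- paste(chars, collapse = "")
      expect_true(matchesMotif(octamer, motif,
                               apply_forbidden = FALSE)$match)
    }
  }
})

test_that("peptide verdicts localise failures to the offending positions", {
  motif <- canonical_motif()
  expect_true(matchesMotif("LRMRRCRRM", motif)$match)
  expect_true(matchesMotif("VRAGRVLRV", motif)$match)

  falk <- matchesMotif("VRHDGGNVL", motif)
  expect_false(falk$match)
  expect_true("P5" %in% falk$failures$position)
  p5 <- falk$failures[falk$failures$position == "P5", ]
  expect_equal(p5$residue, "G")

  ## octamer register: P1 constraint would be untested, others evaluated
  oct <- matchesMotif("RMRRCRRM", motif)
  expect_true(oct$match)

  ## forbidden P6 Arg vetoes an otherwise motif-positive nonamer
  veto <- matchesMotif("ARSTRRRRL", motif)
  expect_false(veto$match)
  expect_equal(veto$failures$reason, "R forbidden")
  expect_true(matchesMotif("ARSTRRRRL", motif,
                           apply_forbidden = FALSE)$match)

  expect_error(matchesMotif("ARSTRCRR1", motif))
  expect_error(matchesMotif("ARSTRCRRLL", motif), "length")
})

test_that("motif JSON and pattern files round-trip through their dialects", {
  motif <- canonical_motif()
  js <- tempfile(fileext = ".json")
  motifToJson(motif, js)
  back <- motifFromJson(js)
  for (p in paste0("P", 1:9)) {
    expect_identical(allowedResidues(back, p), allowedResidues(motif, p))
  }
  expect_identical(forbiddenResidues(back), forbiddenResidues(motif))

  pf <- tempfile(fileext = ".txt")
  writePatterns(eight_patterns(), pf)
  expect_identical(readPatterns(pf), eight_patterns())

  writePatterns(eight_patterns(), pf, dialect = "prosite")
  expect_identical(readPatterns(pf, dialect = "prosite"), eight_patterns())
  expect_identical(patternToProsite("RXXRXXRL"), "R-x-x-R-x-x-R-L")
  expect_identical(prositeToPattern("R-x-x-[R]-x-x-R-L"), "RXXRXXRL")
  expect_error(prositeToPattern("R-x-x-[RNQ]-x-x-R-L"), "combination")
})

test_that("ligand and scan tables are read with validation", {
  lt <- write_ligand_tsv(tempfile(fileext = ".tsv"),
                         c(ligand_family(), "VRHDGGNVL"),
                         stimulatory = c(rep(TRUE, 5), FALSE),
                         activation = c(0.8, 0.9, 0.7, 0.85, 0.6, 0.01))
  df <- readLigandTable(lt)
  expect_equal(nrow(df), 6)
  expect_equal(sum(df$stimulatory), 5)
  model <- buildFrequencyModel(df)
  expect_equal(sum(residueCounts(model)), 5 * 9)

  expect_error(readLigandTable(lt, activation_cutoff = 0.75), "contradicts")

  st <- write_scan_tsv(tempfile(fileext = ".tsv"))
  prof <- readScanProfile(st)
  expect_equal(prof, scan_profile_fixture()[names(prof)])

  ## anchor-exchange rows: the alanine value defines the profile
  df2 <- data.frame(position = c("P9", "P9", "P9"),
                    residue = c("A", "F", "V"),
                    activation = c(0.02, 0.9, 0.8))
  p2 <- tempfile(fileext = ".tsv")
  write.table(df2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(readScanProfile(p2)["P9"]), 0.02)
})
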