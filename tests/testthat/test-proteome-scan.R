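test_that("FASTA reading preserves order, wraps, and round-trips", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 first protein", "AAALRMRR", "CRRMAAA",
               ">prot2", "MKVLRTY"), fa)
  set <- readFasta(fa)
  expect_equal(length(set), 2)
  expect_equal(.subset2(strsplit(names(set)[1], " "), 1)[1], "prot1")
  expect_equal(as.character(set[[1]]), "AAALRMRRCRRMAAA")
  expect_equal(as.character(set[[2]]), "MKVLRTY")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(length(readFasta(empty)), 0)

  ## round trip
  out <- tempfile(fileext = ".fasta")
  writeFasta(set, out)
  again <- readFasta(out)
  expect_identical(as.character(again), as.character(set))

  ## stop symbols stripped with a warning
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">p", "MKVL*"), fa2)
  expect_warning(s2 <- readFasta(fa2), "stop")
  expect_equal(as.character(s2[[1]]), "MKVL")
})

test_that("scanner finds hand-planted octamers at the right offsets", {
  motif <- canonical_motif()
  hits <- scanProteome(c(toy = "AAALRMRRCRRMAAA"), motif = motif)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4L)
  expect_equal(hits$octamer, "RMRRCRRM")
  expect_equal(attr(hits, "windows_scanned"), 8L)

  empty <- scanProteome(Biostrings::AAStringSet(), motif = motif)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("protein_id", "start", "octamer", "nonamer", "p1",
                        "flags", "score"), ignore.order = TRUE)
})

test_that("scanner equals the independent regex oracle on random sequences", {
  motif <- canonical_motif()
  set.seed(101)
  for (i in 1:25) {
    seq <- random_protein(sample(200:1500, 1))
    hits <- scanProteome(setNames(seq, "p"), motif = motif)
    expect_identical(hits$start, regex_scan_oracle(seq, motif))
  }
})

test_that("windows with non-standard residue codes are skipped and counted", {
  motif <- canonical_motif()
  ## an X inside an otherwise matching window kills it
  seq <- "AAALRMRRCRRMAAA"
  broken <- sub("C", "X", seq)
  hits <- scanProteome(c(p = broken), motif = motif)
  expect_equal(nrow(hits), 0)
  expect_gt(attr(hits, "windows_skipped"), 0)

  ## oracle agreement with embedded ambiguity codes
  set.seed(55)
  for (i in 1:10) {
    chars <- sample(c(AA20, "X", "B", "Z", "U", "O"), 800, replace = TRUE,
                    prob = c(rep(0.0485, 20), rep(0.006, 5)))
    seq <- paste(chars, collapse = "")
    hits <- scanProteome(c(p = seq), motif = motif)
    expect_identical(hits$start, regex_scan_oracle(seq, motif))
  }
})

test_that("pattern-mode scanning equals the union of per-pattern scans", {
  set.seed(77)
  pats <- eight_patterns()
  seq <- random_protein(5000)
  ## salt the sequence with instances of two patterns
  substr(seq, 100, 107) <- "RAARAARL"   # matches RXXRXXRL
  substr(seq, 300, 307) <- "RAANARRL"   # matches RXXNXRRL (and RXXRXXRL? no: P5=N)
  joint <- scanProteome(c(p = seq), patterns = pats)
  per <- lapply(pats, function(pp) scanProteome(c(p = seq),
                                                patterns = pp)$start)
  expect_identical(joint$start, sort(unique(unlist(per))))
  expect_true(100 - 1 %in% joint$start && 300 - 1 %in% joint$start)
  ## matched patterns recorded per hit
  expect_true(grepl("RXXRXXRL", joint$pattern[joint$start == 99]))
})

test_that("nonamer completion supplements P1 from the natural sequence", {
  motif <- canonical_motif()
  prot <- c(toy = "AAALRMRRCRRMAAA")
  hits <- completeNonamer(scanProteome(prot, motif = motif), prot)
  expect_equal(hits$nonamer, "LRMRRCRRM")
  expect_equal(hits$p1, "L")

  edge <- c(p = "RMRRCRRMAAA")
  h0 <- completeNonamer(scanProteome(edge, motif = motif), edge)
  expect_equal(h0$start, 0L)
  expect_true(is.na(h0$nonamer))
  expect_match(h0$flags, "no_P1")

  ## substring invariants on random planted fixtures
  set.seed(31)
  gen <- generateProteome(5, c(100, 200), planted = 8,
                          motif = motif, seed = 909)
  hits <- completeNonamer(scanProteome(gen$proteins, motif = motif),
                          gen$proteins)
  seqs <- setNames(as.character(gen$proteins), names(gen$proteins))
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    seq <- seqs[[hits$protein_id[i]]]
    expect_equal(hits$octamer[i], substring(seq, s + 1, s + 8))
    if (!is.na(hits$nonamer[i])) {
      expect_equal(hits$nonamer[i], substring(seq, s, s + 8))
    }
  }
})

test_that("curation removes forbidden-residue hits with named reasons and partitions the input", {
  motif <- canonical_motif()
  prot <- c(p = "AARSTRRRRLAA")  # nonamer ARSTRRRRL has Arg at P6
  hits <- completeNonamer(scanProteome(prot, motif = motif), prot)
  cur <- curateHits(hits, curationRules(forbidden = list(P6 = "R")))
  expect_equal(nrow(cur$removed), 1)
  expect_equal(cur$removed$reason, "P6:R forbidden")
  expect_equal(nrow(cur$kept), 0)

  ## empty rule set is the identity
  idrules <- curationRules(forbidden = list())
  cur2 <- curateHits(hits, idrules)
  expect_equal(cur2$kept[, names(hits)], hits, ignore_attr = TRUE)
  expect_equal(nrow(cur2$removed), 0)

  ## kept + removed partition arbitrary hits; coordinates untouched
  set.seed(13)
  gen <- generateProteome(4, c(150, 300), planted = 10,
                          motif = motif, exclude_forbidden = FALSE,
                          seed = 321)
  hits <- completeNonamer(scanProteome(gen$proteins, motif = motif),
                          gen$proteins)
  cur3 <- curateHits(hits, curationRules())
  expect_equal(nrow(cur3$kept) + nrow(cur3$removed), nrow(hits))
  recombined <- rbind(cur3$kept[, names(hits)],
                      cur3$removed[, names(hits)])
  key <- function(df) sort(paste(df$protein_id, df$start))
  expect_identical(key(recombined), key(hits))
  ## direct re-evaluation oracle
  for (i in seq_len(nrow(cur3$removed))) {
    expect_equal(substring(cur3$removed$nonamer[i], 6, 6), "R")
  }
  for (i in seq_len(nrow(cur3$kept))) {
    pep <- cur3$kept$nonamer[i]
    if (!is.na(pep)) expect_false(substring(pep, 6, 6) == "R")
  }
})

test_that("a P1 curation rule on an octamer-only hit flags it unevaluable and keeps it", {
  motif <- canonical_motif()
  edge <- c(p = "RMRRCRRMAAA")
  hits <- completeNonamer(scanProteome(edge, motif = motif), edge)
  expect_message(
    cur <- curateHits(hits, curationRules(forbidden = list(P1 = "L"))),
    "unevaluable|kept")
  expect_equal(nrow(cur$kept), 1)
  expect_match(cur$kept$flags, "unevaluable")
})

test_that("log-odds ranking is deterministic and matches hand-computed scores", {
  motif <- canonical_motif()
  set.seed(3)
  ligs <- sampleMotifPeptides(motif, 40)
  model <- buildFrequencyModel(ligs, pseudocount = 0.5)
  f <- residueFrequencies(model)

  mk_hit <- function(id, start, nonamer) {
    data.frame(protein_id = id, start = start,
               octamer = substring(nonamer, 2, 9), nonamer = nonamer,
               p1 = substring(nonamer, 1, 1), flags = "", score = NA_real_,
               stringsAsFactors = FALSE)
  }
  h1 <- mk_hit("a", 5, "ARSTRCRRL")
  h2 <- mk_hit("b", 9, "WRSTNCLRM")
  ranked <- rankHits(rbind(h1, h2), model)
  hand <- function(pep) {
    chars <- strsplit(pep, "")[[1]]
    sum(vapply(1:9, function(j) log2(f[chars[j], j] / 0.05), numeric(1)))
  }
  expect_equal(sort(ranked$score, decreasing = TRUE),
               sort(c(hand("ARSTRCRRL"), hand("WRSTNCLRM")),
                    decreasing = TRUE))
  expect_equal(ranked$score[1] - ranked$score[2],
               abs(hand("ARSTRCRRL") - hand("WRSTNCLRM")))

  ## the per-column modal peptide outscores any sampled competitor
  modal <- paste(vapply(1:9, function(j) {
    rownames(f)[which.max(f[, j])]
  }, character(1)), collapse = "")
  competitors <- sampleMotifPeptides(motif, 20)
  hits <- do.call(rbind, c(list(mk_hit("m", 1, modal)),
                           lapply(seq_along(competitors), function(i) {
                             mk_hit(paste0("c", i), i, competitors[i])
                           })))
  ranked <- rankHits(hits, model)
  expect_equal(ranked$protein_id[1], "m")

  ## input order never changes the output order
  sh <- rankHits(hits[sample(nrow(hits)), ], model)
  expect_identical(sh, ranked)

  bg <- setNames(rep(0.05, 20), AA20)
  bg[["W"]] <- 0
  bg[["A"]] <- 0.1
  expect_error(rankHits(hits, model, background = bg), "pseudocount")
})

test_that("analytic background match rate multiplies constrained-position masses", {
  motif <- canonical_motif()
  expect_equal(expectedBackgroundMatchRate(motif), 30 / 20^5)
  expect_equal(expectedBackgroundMatchRate(RecognitionMotif()), 1)
  expect_equal(expectedBackgroundMatchRate("RXXRXRRL"), (1 / 20)^5)

  skew <- setNames(rep(0.8 / 19, 20), AA20)
  skew[["R"]] <- 0.2
  expect_equal(expectedBackgroundMatchRate("RXXXXXXX", skew), 0.2)
  expect_error(expectedBackgroundMatchRate(motif, skew * 2), "sum to 1")
})

test_that("HLA-binding annotation uses the anchor surrogate and survives hook failure", {
  motif <- canonical_motif()
  prot <- c(p = "AAALRMRRCRRMAAAGVHDGGNVLAA")
  hits <- completeNonamer(scanProteome(prot, motif = motif), prot)
  ann <- annotateHlaBinding(hits)
  expect_true(all(ann$anchor_ok))  # motif constraints imply the anchors

  ## non-anchored peptide fails the surrogate
  fake <- data.frame(protein_id = "q", start = 3, octamer = "KHDGGNVK",
                     nonamer = "VKHDGGNVK", p1 = "V", flags = "",
                     score = NA_real_, stringsAsFactors = FALSE)
  expect_false(annotateHlaBinding(fake)$anchor_ok)

  scored <- annotateHlaBinding(hits, hook = function(p) nchar(p))
  expect_equal(scored$binding_score, rep(9, nrow(hits)))
  failing <- annotateHlaBinding(hits, hook = function(p) stop("server down"))
  expect_true(all(grepl("binding_unscored", failing$flags)))
  expect_true(all(is.na(failing$binding_score)))
})

test_that("hit tables round-trip through 1-based TSV output", {
  motif <- canonical_motif()
  gen <- generateProteome(3, c(120, 250), planted = 6, motif = motif,
                          seed = 99)
  hits <- completeNonamer(scanProteome(gen$proteins, motif = motif),
                          gen$proteins)
  tsv <- tempfile(fileext = ".tsv")
  writeHitsTsv(hits, tsv)
  header <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_true("start_1based" %in% header)
  first <- read.delim(tsv, nrows = 1)
  expect_equal(first$start_1based, hits$start[1] + 1)
  back <- readHitsTsv(tsv)
  expect_equal(back$start, hits$start)
  expect_equal(back$octamer, hits$octamer)
  expect_equal(back$nonamer, hits$nonamer)
})

test_that("duplicate peptides collapse into a dedup summary", {
  hits <- data.frame(
    protein_id = c("a", "b", "a"), start = c(1L, 7L, 30L),
    octamer = c("RMRRCRRM", "RMRRCRRM", "RAARAARL"),
    nonamer = c("LRMRRCRRM", "LRMRRCRRM", NA),
    p1 = c("L", "L", NA), flags = c("", "", "no_P1"),
    score = NA_real_, stringsAsFactors = FALSE)
  dd <- dedupHits(hits)
  expect_equal(nrow(dd), 2)
  row <- dd[dd$peptide == "LRMRRCRRM", ]
  expect_equal(row$n_occurrences, 2)
  expect_equal(row$proteins, "a;b")
  expect_equal(nrow(dedupHits(hits[0, ])), 0)
})
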