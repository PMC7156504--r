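test_that("substitution calling reports codon-level nonsynonymous events", {
  ev <- callSubstitutions("ATGTTT", "ATGTCT")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$position, 2L)
  expect_identical(ev$parent_aa, "F"); expect_identical(ev$mutant_aa, "S")
  expect_identical(ev$parent_codon, "TTT")
  expect_identical(ev$mutant_codon, "TCT")
  expect_identical(ev$n_nt, 1L)

  expect_identical(nrow(callSubstitutions("ATGTTT", "ATGTTT")), 0L)

  ev2 <- callSubstitutions("ATGTTT", "ATGCCT")  # TTT -> CCT, 2 nt
  expect_identical(ev2$n_nt, 2L)
  expect_identical(ev2$mutant_aa, "P")

  # synonymous changes are counted, not reported as events
  ev3 <- callSubstitutions("ATGTTT", "ATGTTC")
  expect_identical(nrow(ev3), 0L)
  expect_identical(attr(ev3, "syn"), 1L)

  # internal stop flagged
  ev4 <- callSubstitutions("TGGAAA", "TGAAAA")
  expect_true(attr(ev4, "internal_stop"))

  expect_error(callSubstitutions("ATGTTT", "ATGTT"), "indel")
  expect_error(mutantLibrary("ATGTT", c(v = "ATGTT")), "divisible by 3")
})

test_that("library construction excludes indels and applies the stop policy", {
  parent <- "ATGTTTAAACCC"
  vars <- c(ok = "ATGTCTAAACCC",      # F2S
            stopv = "ATGTAAAAACCC",   # internal stop at codon 2
            indel = "ATGTTTAAACC")    # length mismatch
  lib <- mutantLibrary(parent, vars)
  expect_identical(excludedVariants(lib)$variant, "indel")
  expect_identical(excludedVariants(lib)$reason, "indel")
  expect_identical(stopVariants(lib), "stopv")
  expect_setequal(retainedVariants(lib), "ok")
  expect_false("stopv" %in% substitutionEvents(lib)$variant)
  # naive mode keeps stop variants in the tallies
  naive <- mutantLibrary(parent, vars, excludeStops = FALSE)
  expect_setequal(retainedVariants(naive), c("ok", "stopv"))
})

test_that("per-kb mutation rate is total changes over total bases x 1000", {
  parent <- randomParent(100, seed = 42)  # 300 bp
  # 10 variants with 2, 3, ..., 11 substitutions: 65 changes over 3000 bp
  set.seed(9)
  vars <- vapply(1:10, function(i) {
    pos <- sample.int(300, i + 1)
    v <- strsplit(parent, "")[[1]]
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), character(1))
    paste(v, collapse = "")
  }, character(1))
  names(vars) <- paste0("m", 1:10)
  lib <- mutantLibrary(parent, vars, excludeStops = FALSE)
  expect_equal(mutationRatePerKb(lib), 65 / 3000 * 1000)
  # zero changes
  lib0 <- mutantLibrary(parent, c(a = parent), excludeStops = FALSE)
  expect_equal(mutationRatePerKb(lib0), 0)
})

test_that("positional profiles normalise to 1 and conserve event counts", {
  parent <- "ATGTTTAAACCCGGG"
  vars <- c(a = mutateSeq(parent, 13, "T"),  # codon 5 G->? GGG->TGG W
            b = mutateSeq(parent, 13, "C"),
            c = mutateSeq(parent, 4, "G"))   # codon 2 TTT->GTT V
  lib <- mutantLibrary(parent, vars)
  prof <- positionalProfile(lib)
  f <- mutationFrequencies(prof)
  expect_equal(sum(f), 1)
  expect_equal(f[5], 2 / 3)
  expect_equal(f[2], 1 / 3)
  expect_identical(sum(mutationCounts(prof)),
                   nrow(substitutionEvents(lib)))
  # two variants mutating only one position -> frequency 1 there
  lib2 <- mutantLibrary(parent, c(x = mutateSeq(parent, 13, "T"),
                                  y = mutateSeq(parent, 13, "C")))
  expect_equal(mutationFrequencies(positionalProfile(lib2))[5], 1)
  expect_error(positionalProfile(mutantLibrary(parent, c(z = parent))),
               "degenerate")
})

test_that("random libraries match an independent per-position tally", {
  parent <- randomParent(40, seed = 5)
  lib <- simulateEpcr(parent, 300, epcrModel(rate = 20), seed = 6,
                      excludeStops = TRUE)
  prof <- positionalProfile(lib)
  # independent tally: translate retained variants and diff the proteins
  pAA <- strsplit(translateDNA(parent), "")[[1]]
  counts <- integer(40)
  for (v in as.character(variantSeqs(lib))) {
    vAA <- strsplit(translateDNA(v), "")[[1]]
    d <- which(vAA != pAA & vAA != "*")
    counts[d] <- counts[d] + 1L
  }
  expect_identical(mutationCounts(prof), counts)
  expect_equal(sum(mutationFrequencies(prof)), 1)
})

test_that("hotspot calling applies the > mean + 2 sigma rule", {
  # uniform profile: sigma 0 -> no hotspots
  prof <- new("MutationalProfile", counts = rep(2L, 10),
              frequency = rep(0.1, 10), mean = 0.1, sigma = 0,
              hotspots = integer(0), mode = "all",
              labels = as.character(1:10))
  expect_length(callHotspots(prof), 0L)
  # dominant spike among ~uniform background
  counts <- c(rep(1L, 99), 99L)
  freq <- counts / sum(counts)
  mu <- mean(freq); sig <- sd(freq)
  prof2 <- new("MutationalProfile", counts = counts, frequency = freq,
               mean = mu, sigma = sig,
               hotspots = which(freq > mu + 2 * sig), mode = "all",
               labels = as.character(1:100))
  expect_identical(callHotspots(prof2), 100L)
})

test_that("the 2-sigma rule has a low false-positive rate on an exchangeable null", {
  # phenotype-blind library over a repeated-codon parent, so every
  # position is i.i.d. under the mutational process and no selection acts
  parent <- strrep("AAC", 200)
  lib <- simulateEpcr(parent, 2000, epcrModel(rate = 8.1), seed = 32,
                      excludeStops = TRUE)
  hs <- callHotspots(lib)
  expect_lt(length(hs) / 200, 0.05)
})

test_that("substitution spectra count mutants with deterministic tie-breaks", {
  parent <- "ATGTTT"
  vars <- c(
    setNames(rep(mutateSeq(parent, 5, "C"), 8), paste0("s", 1:8)),  # F->S
    setNames(rep(mutateSeq(parent, 4, "C"), 2), paste0("l", 1:2)))  # F->L
  lib <- mutantLibrary(parent, vars)
  sp <- substitutionSpectrum(lib, 2)
  expect_identical(sp$most_frequent, "S")
  expect_equal(sp$table$freq[1], 0.8)
  expect_identical(sp$observed_order, "SL")
  # tie: equal counts -> earlier in hydropathy order wins (T before N)
  vars2 <- c(setNames(rep("ATGACT", 5), paste0("t", 1:5)),  # T2T? ACT = T
             setNames(rep("ATGAAT", 5), paste0("n", 1:5)))  # AAT = N
  lib2 <- mutantLibrary("ATGTTT", vars2)
  sp2 <- substitutionSpectrum(lib2, 2)
  expect_identical(sp2$most_frequent, "T")
  expect_identical(sp2$observed_order, "TN")
  # two-base substitutions get the multi-base (bold) flag
  vars3 <- c(p = "ATGCCT")  # TTT -> CCT = P, 2 bases
  sp3 <- substitutionSpectrum(mutantLibrary("ATGTTT", vars3), 2)
  expect_true(sp3$table$multi_base[sp3$table$aa == "P"])
  expect_identical(sp3$table$min_nt[sp3$table$aa == "P"], 2L)
  expect_error(substitutionSpectrum(lib, 1), "not mutated")
})

test_that("nucleotide bias estimation tallies, smooths and row-normalises", {
  parent <- "ATGTTTTTTTTT"
  vars <- c(a = mutateSeq(parent, 5, "C"), b = mutateSeq(parent, 8, "C"),
            c = mutateSeq(parent, 11, "C"))
  lib <- mutantLibrary(parent, vars, excludeStops = FALSE)
  bs <- estimateNtBias(lib, pseudocount = 0.5)
  expect_gt(biasMatrix(bs)["T", "C"], 0.7)
  expect_equal(rowSums(biasMatrix(bs)), c(A = 1, C = 1, G = 1, T = 1))
  expect_equal(diag(biasMatrix(bs)), c(A = 0, C = 0, G = 0, T = 0))
  # no changes + pseudocount -> uniform rows
  libU <- mutantLibrary(parent, c(u = parent), excludeStops = FALSE)
  expect_equal(unname(biasMatrix(estimateNtBias(libU, 1))[1, -1]),
               rep(1 / 3, 3))
  expect_error(estimateNtBias(libU, pseudocount = 0), "pseudocount")
})

test_that("a known bias matrix is recovered from a simulated library", {
  # transition-heavy spectrum, as mutagenesis kits show
  M <- matrix(c(0, 1, 6, 1,
                1, 0, 1, 6,
                6, 1, 0, 1,
                1, 6, 1, 0), 4, 4, byrow = TRUE,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  bias <- nucleotideBias(M)
  parent <- randomParent(300, seed = 77)  # 900 bp
  # ~10^4 changes: 1200 variants x ~8.3 changes
  lib <- simulateEpcr(parent, 1200, epcrModel(rate = 9.3, bias = bias),
                      seed = 78)
  est <- estimateNtBias(lib)
  # total-variation distance per row small at this sampling depth
  tv <- rowSums(abs(biasMatrix(est) - biasMatrix(bias))) / 2
  expect_true(all(tv < 0.05))
})

test_that("expected substitution frequencies follow the bias-weighted neighbour model", {
  expect_equal(expectedSubstitutionFrequency("TGG", "R"), 2 / 7)
  expect_equal(expectedSubstitutionFrequency("TGG", "W"), 0)  # synonymous
  expect_equal(expectedSubstitutionFrequency("TTT", "S"), 1 / 8)
  expect_equal(expectedSubstitutionFrequency("TTT", "P"), 0)  # two-base
  expect_error(expectedSubstitutionFrequency("TTT", "*"), "stop")
  # non-uniform bias shifts the expectation toward favoured changes
  M <- diag(4) * 0; M[] <- 1; M[4, 2] <- 50  # T->C dominant
  dimnames(M) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  b <- nucleotideBias(M)
  # TTT -> S requires T->C at position 2; expectation approaches its weight
  expect_gt(expectedSubstitutionFrequency("TTT", "S", b), 0.3)
})

test_that("expected frequencies sum to 1 over reachable nonsynonymous amino acids", {
  set.seed(13)
  biases <- c(list(uniformBias()), replicate(3, randomBias(),
                                             simplify = FALSE))
  for (cd in senseCodons()) {
    own <- translateDNA(cd)
    targets <- setdiff(strsplit(reachableAminoAcids(cd), "")[[1]], own)
    for (b in biases) {
      tot <- sum(vapply(targets, function(a)
        expectedSubstitutionFrequency(cd, a, b), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("observed/expected enrichment reports ratios and multi-base events", {
  parent <- "ATGTTT"
  vars <- c(setNames(rep(mutateSeq(parent, 5, "C"), 8), paste0("s", 1:8)),
            setNames(rep(mutateSeq(parent, 4, "C"), 2), paste0("l", 1:2)))
  sp <- substitutionSpectrum(mutantLibrary(parent, vars), 2)
  oe <- observedVsExpected(sp)
  expect_equal(oe$expected[oe$aa == "S"], 1 / 8)
  expect_equal(oe$ratio[oe$aa == "S"], 0.8 / (1 / 8))
  expect_true(oe$enriched[oe$aa == "S"])
  # observed multi-base event: expected 0, no ratio
  sp3 <- substitutionSpectrum(mutantLibrary(parent, c(p = "ATGCCT")), 2)
  oe3 <- observedVsExpected(sp3)
  expect_true(is.na(oe3$ratio[oe3$aa == "P"]))
  expect_true(oe3$multi_base[oe3$aa == "P"])
})

test_that("neutral (phenotype-blind) selection leaves enrichment ratios near 1", {
  parent <- randomParent(60, seed = 91)
  lib <- simulateEpcr(parent, 4000, epcrModel(rate = 30), seed = 92,
                      excludeStops = TRUE)
  ev <- substitutionEvents(lib)
  # pick the three most-mutated positions and check the dominant
  # substitution's observed frequency against its expectation
  topPos <- as.integer(names(sort(table(ev$position),
                                  decreasing = TRUE)[1:3]))
  for (p in topPos) {
    sp <- substitutionSpectrum(lib, p)
    oe <- observedVsExpected(sp)
    oe <- oe[!oe$multi_base, , drop = FALSE]
    expect_true(all(abs(oe$ratio - 1) < 0.45))
  }
})

test_that("FASTA round trip preserves the library", {
  parent <- randomParent(20, seed = 55)
  lib <- simulateEpcr(parent, 10, epcrModel(rate = 40), seed = 56)
  fa <- tempfile(fileext = ".fasta")
  writeFastaLibrary(lib, fa)
  lib2 <- readFastaLibrary(fa, excludeStops = FALSE)
  expect_identical(as.character(parentSeq(lib2)), parent)
  expect_identical(as.character(variantSeqs(lib2, retained = FALSE)),
                   as.character(variantSeqs(lib, retained = FALSE)))
  expect_identical(substitutionEvents(lib2, retained = FALSE),
                   substitutionEvents(lib, retained = FALSE))
})
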