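# Library profiling: substitution calling against the parent, per-kb
# mutation rate, positional mutational-frequency profiles with >2-sigma
# hotspot calls, substitution spectra, nucleotide-bias estimation and
# bias-weighted expected substitution frequencies.

#' Build a MutantLibrary from parent and variant sequences
#'
#' Derives codon-level substitution events for every variant against the
#' parent. Variants whose length differs from the parent are excluded as
#' indels and logged; variants with an internal stop codon are flagged and,
#' under the default survivor-library policy, excluded from all tallies.
#'
#' @param parent Parent coding sequence (character or \code{DNAString});
#'   length divisible by 3, strict A/C/G/T.
#' @param variants Named character vector or \code{DNAStringSet} of variant
#'   sequences. Unnamed input gets ids \code{v1..vN}.
#' @param excludeStops Logical; \code{TRUE} (default) for screened/survivor
#'   libraries, \code{FALSE} for naive libraries used to estimate the
#'   mutagenesis rate and bias.
#' @return A \code{\linkS4class{MutantLibrary}}.
#' @examples
#' lib <- mutantLibrary("ATGTTTAAA", c(v1 = "ATGTCTAAA", v2 = "ATGTTTAAA"))
#' substitutionEvents(lib)
#' @export
mutantLibrary <- function(parent, variants, excludeStops = TRUE) {
  parent <- .checkDna(as.character(parent), "parent")
  plen <- nchar(parent)
  if (plen %% 3L != 0L)
    stop("parent length must be divisible by 3 (frame error)", call. = FALSE)
  nm <- names(variants)          # as.character() drops names
  vars <- toupper(as.character(variants))
  names(vars) <- nm
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    names(vars) <- paste0("v", seq_along(vars))
  if (anyDuplicated(names(vars)))
    stop("duplicate variant ids", call. = FALSE)
  for (v in vars) .checkDna(v, "variant")

  lens <- nchar(vars)
  indel <- lens != plen
  excluded <- data.frame(variant = names(vars)[indel],
                         reason = rep("indel", sum(indel)),
                         stringsAsFactors = FALSE)
  vars <- vars[!indel]

  pvec <- strsplit(parent, "")[[1]]
  pcodons <- substring(parent, seq(1L, plen, 3L), seq(3L, plen, 3L))
  paa <- .codonToAA(pcodons)

  ntDiffs <- integer(0)
  synCounts <- integer(0)
  stopIds <- character(0)
  evs <- list()

  if (length(vars)) {
    M <- do.call(rbind, strsplit(vars, ""))
    diffs <- M != matrix(pvec, nrow(M), plen, byrow = TRUE)
    ntDiffs <- setNames(as.integer(rowSums(diffs)), names(vars))
    synCounts <- setNames(integer(length(vars)), names(vars))
    hits <- which(diffs, arr.ind = TRUE)
    if (nrow(hits)) {
      codIdx <- (hits[, "col"] - 1L) %/% 3L + 1L
      key <- paste(hits[, "row"], codIdx)
      first <- !duplicated(key)
      vrow <- hits[first, "row"]
      vcod <- codIdx[first]
      starts <- (vcod - 1L) * 3L
      mcodon <- paste0(M[cbind(vrow, starts + 1L)],
                       M[cbind(vrow, starts + 2L)],
                       M[cbind(vrow, starts + 3L)])
      maa <- .codonToAA(mcodon)
      nnt <- as.integer(table(key)[key[first]])
      ev <- data.frame(
        variant = names(vars)[vrow],
        position = vcod,
        parent_aa = paa[vcod],
        mutant_aa = maa,
        parent_codon = pcodons[vcod],
        mutant_codon = mcodon,
        n_nt = nnt,
        stringsAsFactors = FALSE)
      syn <- ev$parent_aa == ev$mutant_aa
      st <- tapply(syn, ev$variant, sum)
      synCounts[names(st)] <- as.integer(st)
      # any stop gained truncates the fusion: variant is nonfunctional
      stopIds <- unique(ev$variant[ev$mutant_aa == STOP_CHAR])
      evs <- ev[!syn & ev$mutant_aa != STOP_CHAR, , drop = FALSE]
    }
  }
  if (!length(evs) || is.null(nrow(evs)))
    evs <- data.frame(variant = character(0), position = integer(0),
                      parent_aa = character(0), mutant_aa = character(0),
                      parent_codon = character(0), mutant_codon = character(0),
                      n_nt = integer(0), stringsAsFactors = FALSE)
  rownames(evs) <- NULL

  new("MutantLibrary",
      parent = Biostrings::DNAString(parent),
      variants = Biostrings::DNAStringSet(vars),
      events = evs,
      ntDiffs = ntDiffs,
      synCounts = synCounts,
      stopVariants = stopIds,
      excluded = excluded,
      excludeStops = isTRUE(excludeStops))
}

#' Call substitution events for one variant against a parent
#'
#' Codon-wise comparison reporting nonsynonymous events; synonymous and
#' stop-gain changes are summarised in attributes \code{syn} and
#' \code{internal_stop}.
#'
#' @param parent,variant Coding sequences of equal length (divisible by 3).
#' @return \code{data.frame} of events (columns as in
#'   \code{\link{substitutionEvents}}), with attributes \code{syn}
#'   (synonymous codon-change count) and \code{internal_stop} (logical).
#' @export
callSubstitutions <- function(parent, variant) {
  parent <- .checkDna(as.character(parent), "parent")
  variant <- .checkDna(as.character(variant), "variant")
  if (nchar(parent) != nchar(variant))
    stop("length mismatch between parent and variant (indel)", call. = FALSE)
  lib <- mutantLibrary(parent, c(v = variant), excludeStops = FALSE)
  ev <- substitutionEvents(lib, retained = FALSE)
  ev$variant <- NULL
  attr(ev, "syn") <- unname(lib@synCounts["v"])
  attr(ev, "internal_stop") <- "v" %in% stopVariants(lib)
  ev
}

#' Per-kilobase nucleotide substitution rate of a library
#'
#' Total nucleotide differences across contributing variants divided by
#' total bases compared, times 1000. For a naive library built with
#' \code{excludeStops = FALSE} every length-matched variant contributes,
#' matching how a mutagenesis kit's error rate is characterised.
#'
#' @param library A \code{\linkS4class{MutantLibrary}}.
#' @return Mutations per 1000 bp (numeric).
#' @export
mutationRatePerKb <- function(library) {
  ids <- retainedVariants(library)
  if (length(ids) == 0L)
    stop("library has no contributing variants", call. = FALSE)
  total <- sum(library@ntDiffs[ids])
  bases <- length(ids) * length(parentSeq(library))
  total / bases * 1000
}

#' Positional mutational-frequency profile
#'
#' Counts nonsynonymous substitution events per residue position across
#' the library's retained variants and normalises so the cumulative
#' frequency over the scored region is 1. Hotspots are positions whose
#' frequency exceeds the profile mean by more than two standard
#' deviations; by default mean and sigma are computed over all residue
#' positions of the region, zeros included.
#'
#' @param library A \code{\linkS4class{MutantLibrary}} with at least one
#'   nonsynonymous event among retained variants.
#' @param mode \code{"all"} (default) computes the mean and sigma over
#'   every position; \code{"mutated"} restricts them to positions with at
#'   least one event.
#' @param labels Optional character vector of position labels (e.g. IMGT
#'   strings), one per residue.
#' @return A \code{\linkS4class{MutationalProfile}}.
#' @export
positionalProfile <- function(library, mode = c("all", "mutated"),
                              labels = NULL) {
  mode <- match.arg(mode)
  ev <- substitutionEvents(library)
  npos <- length(parentSeq(library)) %/% 3L
  if (nrow(ev) == 0L)
    stop("no nonsynonymous events among retained variants ",
         "(degenerate profile)", call. = FALSE)
  counts <- tabulate(ev$position, nbins = npos)
  freq <- counts / sum(counts)
  idx <- if (mode == "all") seq_len(npos) else which(counts > 0L)
  mu <- mean(freq[idx])
  sig <- if (length(idx) > 1L) stats::sd(freq[idx]) else 0
  hot <- if (sig > 0) which(freq > mu + 2 * sig) else integer(0)
  if (is.null(labels)) labels <- as.character(seq_len(npos))
  if (length(labels) != npos)
    stop("labels must have one entry per residue position", call. = FALSE)
  new("MutationalProfile", counts = as.integer(counts), frequency = freq,
      mean = mu, sigma = sig, hotspots = as.integer(sort(hot)),
      mode = mode, labels = labels)
}

#' Hotspot positions of a profile or library
#'
#' Positions with normalised mutational frequency greater than
#' \code{mean + 2 sigma}. A uniform profile (sigma = 0) yields no
#' hotspots.
#'
#' @param x A \code{\linkS4class{MutationalProfile}} or
#'   \code{\linkS4class{MutantLibrary}} (profiled with defaults).
#' @param ... Passed to \code{\link{positionalProfile}} when \code{x} is a
#'   library.
#' @return Integer vector of positions, ascending.
#' @export
callHotspots <- function(x, ...) {
  if (is(x, "MutantLibrary")) x <- positionalProfile(x, ...)
  if (!is(x, "MutationalProfile"))
    stop("x must be a MutationalProfile or MutantLibrary", call. = FALSE)
  hotspotPositions(x)
}

#' Substitution spectrum at one residue position
#'
#' Counts of each mutant amino acid observed at a position across the
#' retained library, the most frequent substitution (ties: higher count,
#' then earlier in hydropathy order), the observed-order string in
#' decreasing count, and the minimum number of codon base changes needed
#' for each substitution from the parent codon (>= 2 flags the
#' multi-base events that a table would set in bold).
#'
#' @param library A \code{\linkS4class{MutantLibrary}}.
#' @param position 1-based residue position, mutated in >= 1 retained
#'   variant.
#' @return List with elements \code{position}, \code{parent_aa},
#'   \code{parent_codon}, \code{table} (\code{data.frame}: \code{aa},
#'   \code{count}, \code{freq}, \code{min_nt}, \code{multi_base}),
#'   \code{most_frequent}, \code{observed_order} (hydropathy-tie-broken,
#'   decreasing count).
#' @export
substitutionSpectrum <- function(library, position) {
  ev <- substitutionEvents(library)
  ev <- ev[ev$position == position, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("position ", position, " is not mutated in any retained variant",
         call. = FALSE)
  cnt <- table(ev$mutant_aa)
  aa <- names(cnt)
  ord <- order(-as.integer(cnt), match(aa, KD_ORDER))
  aa <- aa[ord]
  counts <- as.integer(cnt)[ord]
  pcod <- ev$parent_codon[1]
  minnt <- vapply(aa, function(a) minBaseChanges(pcod, a), integer(1))
  tab <- data.frame(aa = aa, count = counts, freq = counts / sum(counts),
                    min_nt = minnt, multi_base = minnt >= 2L,
                    stringsAsFactors = FALSE)
  list(position = position, parent_aa = ev$parent_aa[1],
       parent_codon = pcod, table = tab,
       most_frequent = aa[1L],
       observed_order = paste(aa, collapse = ""))
}

#' Uniform nucleotide bias
#'
#' The unbiased 4x4 substitution matrix: every off-diagonal entry 1/3.
#'
#' @return A \code{\linkS4class{NucleotideBiasMatrix}}.
#' @export
uniformBias <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  new("NucleotideBiasMatrix", matrix = m, pseudocount = 0)
}

#' Construct a bias matrix from off-diagonal weights
#'
#' @param m Numeric 4x4 with A,C,G,T dimnames; diagonal ignored; rows are
#'   normalised to sum to 1 over off-diagonal entries.
#' @param pseudocount Recorded pseudocount (metadata only here).
#' @return A \code{\linkS4class{NucleotideBiasMatrix}}.
#' @export
nucleotideBias <- function(m, pseudocount = 0) {
  if (is.null(dimnames(m))) dimnames(m) <- list(DNA_BASES, DNA_BASES)
  m <- m[DNA_BASES, DNA_BASES]
  diag(m) <- 0
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("each row needs positive off-diagonal mass",
                         call. = FALSE)
  new("NucleotideBiasMatrix", matrix = m / rs, pseudocount = pseudocount)
}

#' Estimate the nucleotide substitution bias of a naive library
#'
#' Tallies from->to single-nucleotide changes over all contributing
#' variants, adds a pseudocount to every off-diagonal cell and
#' row-normalises.
#'
#' @param library A \code{\linkS4class{MutantLibrary}} (typically built
#'   with \code{excludeStops = FALSE}).
#' @param pseudocount Per-cell pseudocount (default 0.5).
#' @return A \code{\linkS4class{NucleotideBiasMatrix}}.
#' @export
estimateNtBias <- function(library, pseudocount = 0.5) {
  ids <- retainedVariants(library)
  if (length(ids) == 0L) stop("empty library", call. = FALSE)
  parent <- as.character(parentSeq(library))
  pvec <- strsplit(parent, "")[[1]]
  vars <- as.character(variantSeqs(library))
  counts <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (length(vars)) {
    M <- do.call(rbind, strsplit(vars, ""))
    diffs <- M != matrix(pvec, nrow(M), length(pvec), byrow = TRUE)
    hits <- which(diffs, arr.ind = TRUE)
    if (nrow(hits)) {
      from <- pvec[hits[, "col"]]
      to <- M[hits]
      tb <- table(factor(from, DNA_BASES), factor(to, DNA_BASES))
      counts <- counts + unclass(tb)
    }
  }
  if (sum(counts) == 0 && pseudocount <= 0)
    stop("no nucleotide changes observed and pseudocount is 0", call. = FALSE)
  counts <- counts + pseudocount
  diag(counts) <- 0
  nucleotideBias(counts, pseudocount = pseudocount)
}

#' Expected frequency of a substitution under a nucleotide bias
#'
#' Probability that a single-base change of \code{codon}, conditioned on
#' being nonsynonymous and non-stop, yields \code{target}:
#' \deqn{P = \frac{\sum_{c \to c': aa(c') = target} w(c \to c')}
#'            {\sum_{c \to c': nonsyn, non-stop} w(c \to c')}}
#' where \code{w} is the bias probability of the underlying nucleotide
#' change (position-independent). Amino acids needing >= 2 base changes
#' get 0.
#'
#' @param codon Parent codon.
#' @param target One-letter amino-acid code (stop rejected; the parent's
#'   own amino acid returns 0 since a nonsynonymous expectation is asked).
#' @param bias A \code{\linkS4class{NucleotideBiasMatrix}} (default
#'   uniform).
#' @return Probability in [0, 1].
#' @examples
#' expectedSubstitutionFrequency("TGG", "R")  # 2/7 under uniform bias
#' @export
expectedSubstitutionFrequency <- function(codon, target,
                                          bias = uniformBias()) {
  codon <- .checkCodon(codon)
  target <- toupper(as.character(target))
  if (identical(target, STOP_CHAR))
    stop("stop is not a valid target", call. = FALSE)
  if (!target %in% AA_CODES)
    stop("unknown amino acid '", target, "'", call. = FALSE)
  nb <- singleBaseNeighbors(codon)
  own <- .codonToAA(codon)
  w <- biasMatrix(bias)[cbind(nb$from, nb$to)]
  ok <- nb$aa != STOP_CHAR & nb$aa != own
  denom <- sum(w[ok])
  if (denom <= 0)
    stop("codon '", codon, "' has no nonsynonymous non-stop neighbour ",
         "with positive bias weight (degenerate denominator)", call. = FALSE)
  sum(w[ok & nb$aa == target]) / denom
}

#' Observed vs expected substitution frequencies at a position
#'
#' Joins the observed spectrum at a position with the bias-weighted
#' expected frequencies of each substitution, reporting the ratio and an
#' enrichment flag. Substitutions requiring >= 2 base changes have
#' expected frequency 0 and are reported as multi-base events rather than
#' ratios.
#'
#' @param spectrum Output of \code{\link{substitutionSpectrum}}.
#' @param bias A \code{\linkS4class{NucleotideBiasMatrix}}.
#' @return \code{data.frame}: \code{aa}, \code{observed}, \code{expected},
#'   \code{ratio} (\code{NA} for multi-base events), \code{enriched},
#'   \code{multi_base}.
#' @export
observedVsExpected <- function(spectrum, bias = uniformBias()) {
  tab <- spectrum$table
  expd <- vapply(tab$aa, function(a)
    expectedSubstitutionFrequency(spectrum$parent_codon, a, bias),
    numeric(1))
  ratio <- ifelse(expd > 0, tab$freq / expd, NA_real_)
  data.frame(aa = tab$aa, observed = tab$freq, expected = expd,
             ratio = ratio,
             enriched = !is.na(ratio) & tab$freq > expd,
             multi_base = tab$multi_base,
             stringsAsFactors = FALSE)
}
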