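# Synthetic screen generator: error-prone PCR libraries, a latent
# aggregation-propensity phenotype, noisy MCD growth curves over an
# ampicillin gradient, plate selection, and the end-to-end hotspot
# recovery benchmark.

#' Error-prone PCR model parameters
#'
#' @param rate Substitution rate, mutations per 1000 bp (default 8.1 per
#'   kb, an aggressive directed-evolution library setting).
#' @param bias A \code{\linkS4class{NucleotideBiasMatrix}} for the
#'   substituted base (default uniform).
#' @return Validated parameter list of class \code{"EpcrModel"}.
#' @export
epcrModel <- function(rate = 8.1, bias = uniformBias()) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0,
            is(bias, "NucleotideBiasMatrix"))
  structure(list(rate = rate, bias = bias), class = "EpcrModel")
}

#' Latent phenotype model parameters
#'
#' Additive map from a variant's substitutions to a latent in vivo growth
#' score: baseline plus a positive effect for each nonsynonymous hit at a
#' liability position, a Bernoulli deleterious penalty for other
#' nonsynonymous changes, and Gaussian noise. A variant with an internal
#' stop scores 0 (no functional fusion).
#'
#' @param baseline Parent score (A.U.); default 172, an aggregation-prone
#'   parent.
#' @param liabilities Integer vector of liability residue positions.
#' @param liabilityEffect Score gain per liability hit (default +300).
#' @param deleteriousProb Probability that a non-liability nonsynonymous
#'   change is deleterious (default 0.2).
#' @param deleteriousEffect Score change when deleterious (default -40).
#' @param noiseSd Gaussian score noise s.d. (default 25).
#' @return Parameter list of class \code{"PhenotypeModel"}.
#' @export
phenotypeModel <- function(baseline = 172, liabilities = integer(0),
                           liabilityEffect = 300, deleteriousProb = 0.2,
                           deleteriousEffect = -40, noiseSd = 25) {
  stopifnot(is.finite(baseline), is.finite(liabilityEffect),
            deleteriousProb >= 0, deleteriousProb <= 1,
            is.finite(deleteriousEffect), noiseSd >= 0)
  structure(list(baseline = baseline,
                 liabilities = as.integer(liabilities),
                 liabilityEffect = liabilityEffect,
                 deleteriousProb = deleteriousProb,
                 deleteriousEffect = deleteriousEffect,
                 noiseSd = noiseSd),
            class = "PhenotypeModel")
}

#' Plate-selection model parameters
#'
#' Links the latent score to an MIC by an affine map clamped to
#' [\code{micFloor}, \code{micCeiling}], and the MIC to the observed MCD at
#' concentration x by a step-like logistic:
#' \code{MCD(x) = round(Mmax * plogis(k * (MIC - x)))}.
#'
#' @param conc Selection ampicillin concentration, ug/mL (default 80).
#' @param minMcd Minimum MCD at \code{conc} for survival (default 1).
#' @param k Logistic steepness per ug/mL (default 0.08; curves drop over
#'   roughly +/- 25 ug/mL around the MIC, step-like as observed plates).
#' @param micSlope MIC gain per score unit (default 0.16 ug/mL per A.U.).
#' @param micIntercept MIC at score 0 (default 0 ug/mL).
#' @param micFloor,micCeiling Clamp range for the MIC (default 0-320).
#' @param Mmax Maximum MCD, the number of 10-fold dilutions spotted
#'   (default 8).
#' @param mcdNoiseProb Probability of a +/-1-step read error per curve
#'   point (default 0).
#' @return Parameter list of class \code{"SelectionModel"}.
#' @export
selectionModel <- function(conc = 80, minMcd = 1, k = 0.08,
                           micSlope = 0.16, micIntercept = 0,
                           micFloor = 0, micCeiling = 320, Mmax = 8,
                           mcdNoiseProb = 0) {
  stopifnot(conc >= 0, minMcd >= 0, k > 0, Mmax >= 1,
            micCeiling >= micFloor,
            mcdNoiseProb >= 0, mcdNoiseProb <= 1)
  structure(list(conc = conc, minMcd = minMcd, k = k, micSlope = micSlope,
                 micIntercept = micIntercept, micFloor = micFloor,
                 micCeiling = micCeiling, Mmax = Mmax,
                 mcdNoiseProb = mcdNoiseProb),
            class = "SelectionModel")
}

#' Simulate an error-prone PCR library
#'
#' Per variant the mutation count is Poisson(rate x length / 1000),
#' mutated positions are drawn uniformly without replacement, and each
#' substituted base is drawn from the bias row of the parent base.
#' Seeded runs are reproducible.
#'
#' @param parent Parent coding sequence (length divisible by 3).
#' @param n Number of variants.
#' @param model An \code{\link{epcrModel}}.
#' @param seed Optional integer seed (\code{set.seed} is called when
#'   given).
#' @param excludeStops Exclusion policy for the returned library
#'   (default \code{FALSE}: a naive, unselected library).
#' @return A \code{\linkS4class{MutantLibrary}} with variants
#'   \code{v1..vn}.
#' @export
simulateEpcr <- function(parent, n, model = epcrModel(), seed = NULL,
                         excludeStops = FALSE) {
  parent <- .checkDna(as.character(parent), "parent")
  len <- nchar(parent)
  stopifnot(n >= 1)
  mean_mut <- model$rate * len / 1000
  if (mean_mut > len)
    stop("configured rate implies more mutations than bases", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pvec <- strsplit(parent, "")[[1]]
  B <- biasMatrix(model$bias)
  counts <- pmin(stats::rpois(n, mean_mut), len)
  vars <- character(n)
  for (i in seq_len(n)) {
    k <- counts[i]
    if (k == 0L) { vars[i] <- parent; next }
    v <- pvec
    pos <- sample.int(len, k)
    for (p in pos) {
      from <- v[p]
      v[p] <- sample(DNA_BASES, 1L, prob = B[from, ])
    }
    vars[i] <- paste(v, collapse = "")
  }
  names(vars) <- paste0("v", seq_len(n))
  mutantLibrary(parent, vars, excludeStops = excludeStops)
}

#' Assign latent growth scores to library variants
#'
#' Applies a \code{\link{phenotypeModel}} to every length-matched variant:
#' internal-stop variants score exactly 0; otherwise baseline + liability
#' effects + deleterious draws + Gaussian noise.
#'
#' @param library A \code{\linkS4class{MutantLibrary}}.
#' @param model A \code{\link{phenotypeModel}}.
#' @param seed Optional integer seed.
#' @return Named numeric vector of latent scores, one per length-matched
#'   variant.
#' @export
assignPhenotype <- function(library, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(variantSeqs(library, retained = FALSE))
  ev <- substitutionEvents(library, retained = FALSE)
  scores <- setNames(rep(model$baseline, length(ids)), ids)
  if (nrow(ev)) {
    isLiab <- ev$position %in% model$liabilities
    liabHits <- tapply(isLiab, ev$variant, sum)
    scores[names(liabHits)] <- scores[names(liabHits)] +
      as.numeric(liabHits) * model$liabilityEffect
    otherHits <- tapply(!isLiab, ev$variant, sum)
    otherHits <- otherHits[otherHits > 0]
    if (length(otherHits)) {
      del <- vapply(as.integer(otherHits), function(m)
        sum(stats::runif(m) < model$deleteriousProb), numeric(1))
      scores[names(otherHits)] <- scores[names(otherHits)] +
        del * model$deleteriousEffect
    }
  }
  if (model$noiseSd > 0)
    scores <- scores + stats::rnorm(length(scores), 0, model$noiseSd)
  st <- stopVariants(library)
  scores[ids %in% st] <- 0
  scores
}

#' Convert latent scores to survival curves
#'
#' \code{MCD(x) = round(Mmax * plogis(k * (MIC(score) - x)))} with the MIC
#' affine in the score and clamped to the model's range, clipped to
#' [0, Mmax]. A latent score of zero or below means no functional
#' beta-lactamase fusion at all and maps to the all-zero curve. Optional
#' +/-1-step read noise. The resulting growth score (curve area)
#' increases with the latent score.
#'
#' @param scores Numeric latent scores (named by variant).
#' @param grid Ascending ampicillin concentrations (default 0-140 by 20).
#' @param model A \code{\link{selectionModel}}.
#' @param seed Optional integer seed (used for read noise).
#' @return Long \code{data.frame}: \code{variant}, \code{conc},
#'   \code{mcd}.
#' @export
scoreToCurve <- function(scores, grid = seq(0, 140, by = 20),
                         model = selectionModel(), seed = NULL) {
  if (any(diff(grid) <= 0))
    stop("concentration grid must be strictly ascending", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("v", seq_along(scores))
  mic <- pmin(pmax(model$micIntercept + model$micSlope * scores,
                   model$micFloor), model$micCeiling)
  out <- data.frame(
    variant = rep(ids, each = length(grid)),
    conc = rep(grid, length(scores)),
    mcd = as.integer(round(model$Mmax *
      stats::plogis(model$k * (rep(mic, each = length(grid)) -
                                 rep(grid, length(scores)))))),
    stringsAsFactors = FALSE)
  if (model$mcdNoiseProb > 0) {
    flip <- stats::runif(nrow(out)) < model$mcdNoiseProb
    step <- ifelse(stats::runif(nrow(out)) < 0.5, -1L, 1L)
    out$mcd[flip] <- out$mcd[flip] + step[flip]
  }
  out$mcd <- pmin(pmax(out$mcd, 0L), as.integer(model$Mmax))
  out$mcd[rep(scores <= 0, each = length(grid))] <- 0L
  out
}

#' Apply plate selection to a library with curves
#'
#' Retains the variants whose MCD at the selection concentration is at
#' least the survival minimum.
#'
#' @param curves Long curve \code{data.frame} (\code{variant},
#'   \code{conc}, \code{mcd}); the grid must include the selection
#'   concentration.
#' @param model A \code{\link{selectionModel}}.
#' @return Character vector of surviving variant ids.
#' @export
applySelection <- function(curves, model = selectionModel()) {
  at <- curves[curves$conc == model$conc, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("selection concentration ", model$conc,
         " ug/mL is absent from the curve grid", call. = FALSE)
  unique(at$variant[at$mcd >= model$minMcd])
}

#' Generate a random stop-free coding parent
#'
#' Random codons drawn uniformly from the 61 sense codons, so the parent
#' contains no stop and translation is well defined at every position.
#'
#' @param nCodons Number of codons (parent length is 3x this).
#' @param seed Optional integer seed.
#' @return Single DNA string.
#' @export
randomParent <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

#' Nonsynonymous accessibility of each codon of a parent
#'
#' Number of the 9 single-base neighbours of each codon that are
#' nonsynonymous and non-stop: how visible a residue is to single-base
#' mutagenesis. A liability at a codon where most changes are synonymous
#' cannot surface in a substitution profile however strong its effect.
#'
#' @param parent Coding sequence (length divisible by 3).
#' @return Integer vector, one entry per codon (range 5-9 over the
#'   standard code).
#' @export
codonAccessibility <- function(parent) {
  parent <- .checkDna(as.character(parent), "parent")
  n <- nchar(parent)
  if (n %% 3L != 0L) stop("parent length must be divisible by 3",
                          call. = FALSE)
  codons <- substring(parent, seq(1L, n, 3L), seq(3L, n, 3L))
  vapply(codons, function(cd) {
    nb <- singleBaseNeighbors(cd)
    own <- .codonToAA(cd)
    sum(nb$aa != STOP_CHAR & nb$aa != own)
  }, integer(1), USE.NAMES = FALSE)
}

#' Default configuration of the synthetic screen benchmark
#'
#' Mirrors the screen's stated conditions: a 750-bp parent, 5000
#' error-prone PCR variants at 8.1 mutations per kb, 12 planted strong
#' liability positions, selection on 80 ug/mL ampicillin plates, and the
#' 0-140 by 20 ug/mL assay gradient. Liability positions are planted at
#' codons with at least \code{minAccessibility} nonsynonymous non-stop
#' single-base neighbours, the observability property shared by every
#' hotspot the screen reported (a position whose codon mutates mostly
#' synonymously is invisible to single-base mutagenesis and is not a
#' plantable liability).
#'
#' @param seed Integer master seed (default 1).
#' @param nVariants Library size (default 5000).
#' @param nCodons Parent length in codons (default 250, i.e. 750 bp).
#' @param nLiabilities Number of planted liability positions (default 12).
#' @param rate Mutations per 1000 bp (default 8.1).
#' @param minAccessibility Minimum nonsynonymous non-stop single-base
#'   neighbours of a plantable liability codon (default 6).
#' @param ... Overrides passed to \code{\link{phenotypeModel}} (e.g.
#'   \code{liabilityEffect}, \code{noiseSd}).
#' @return Named list consumed by \code{\link{endToEndBenchmark}}.
#' @export
benchmarkConfig <- function(seed = 1, nVariants = 5000, nCodons = 250,
                            nLiabilities = 12, rate = 8.1,
                            minAccessibility = 6, ...) {
  list(seed = seed, nVariants = nVariants, nCodons = nCodons,
       nLiabilities = nLiabilities, rate = rate,
       minAccessibility = minAccessibility,
       phenotype = list(...),
       grid = seq(0, 140, by = 20))
}

#' Run the end-to-end synthetic screen benchmark
#'
#' Full emulation of the screen: simulate an error-prone PCR library,
#' assign latent aggregation phenotypes with planted liability positions,
#' synthesise survival curves, select on the ampicillin plate, profile the
#' survivor sequences and call >2-sigma hotspots. Reports the recovery of
#' the planted positions. An empty survivor set (the vanishing-effect
#' limit) yields a zero-recovery report.
#'
#' @param config A \code{\link{benchmarkConfig}} list.
#' @return List: \code{planted}, \code{called}, \code{sensitivity},
#'   \code{falseDiscoveries}, \code{fdr}, \code{nSurvivors},
#'   \code{nVariants}, \code{profile} (the survivor
#'   \code{\linkS4class{MutationalProfile}}), \code{library} (the survivor
#'   \code{\linkS4class{MutantLibrary}}), \code{scores} (latent scores),
#'   \code{survivors} (ids).
#' @export
endToEndBenchmark <- function(config = benchmarkConfig()) {
  set.seed(config$seed)
  parent <- randomParent(config$nCodons)
  minAcc <- if (is.null(config$minAccessibility)) 6L
            else config$minAccessibility
  eligible <- which(codonAccessibility(parent) >= minAcc)
  if (length(eligible) < config$nLiabilities)
    stop("parent offers too few plantable liability positions", call. = FALSE)
  liab <- sort(sample(eligible, config$nLiabilities))
  pheno <- do.call(phenotypeModel,
                   c(list(liabilities = liab), config$phenotype))
  sel <- selectionModel()
  lib <- simulateEpcr(parent, config$nVariants,
                      epcrModel(rate = config$rate))
  scores <- assignPhenotype(lib, pheno)
  curves <- scoreToCurve(scores, grid = config$grid, model = sel)
  survivors <- applySelection(curves, sel)
  # an empty survivor set is the vanishing-signal limit: the report then
  # states zero recovery rather than erroring
  called <- integer(0)
  prof <- NULL
  survLib <- NULL
  if (length(survivors)) {
    survLib <- mutantLibrary(as.character(parentSeq(lib)),
                             as.character(variantSeqs(lib))[survivors],
                             excludeStops = TRUE)
    if (nrow(substitutionEvents(survLib))) {
      prof <- positionalProfile(survLib)
      called <- hotspotPositions(prof)
    }
  }
  tp <- intersect(called, liab)
  fp <- setdiff(called, liab)
  list(planted = liab, called = called,
       sensitivity = if (config$nLiabilities > 0)
         length(tp) / config$nLiabilities else NA_real_,
       falseDiscoveries = fp,
       fdr = if (length(called)) length(fp) / length(called) else 0,
       nSurvivors = length(survivors),
       nVariants = config$nVariants,
       profile = prof, library = survLib,
       scores = scores, survivors = survivors)
}
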