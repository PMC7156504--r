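#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

setOldClass("data.frame")

#' MutantLibrary: a parent gene and its point-mutant variants
#'
#' Container for a directed-evolution library: the parent coding sequence,
#' all length-matched variant sequences, the codon-level substitution
#' events derived against the parent, and a log of excluded variants.
#' Variants whose length differs from the parent are treated as indels and
#' excluded. Variants carrying an internal stop codon are flagged; by
#' default (\code{excludeStops = TRUE}, the survivor-library convention)
#' they are excluded from all profile tallies, since survivors must express
#' the full-length fusion. A naive (unselected) library is built with
#' \code{excludeStops = FALSE} so that premature stops still inform the
#' mutation-rate and nucleotide-bias estimates.
#'
#' @slot parent \code{DNAString}, the parent coding sequence.
#' @slot variants \code{DNAStringSet} of all length-matched variants.
#' @slot events \code{data.frame} of nonsynonymous substitution events
#'   (columns \code{variant}, \code{position}, \code{parent_aa},
#'   \code{mutant_aa}, \code{parent_codon}, \code{mutant_codon},
#'   \code{n_nt}).
#' @slot ntDiffs Named integer, total nucleotide differences per
#'   length-matched variant (synonymous included).
#' @slot synCounts Named integer, synonymous codon changes per variant.
#' @slot stopVariants Character, ids of variants with internal stops.
#' @slot excluded \code{data.frame} (\code{variant}, \code{reason}) of
#'   variants excluded from tallies.
#' @slot excludeStops Logical scalar, the exclusion policy in force.
#' @exportClass MutantLibrary
setClass("MutantLibrary",
  representation(
    parent = "DNAString",
    variants = "DNAStringSet",
    events = "data.frame",
    ntDiffs = "integer",
    synCounts = "integer",
    stopVariants = "character",
    excluded = "data.frame",
    excludeStops = "logical"
  )
)

setValidity("MutantLibrary", function(object) {
  msgs <- character(0)
  w <- Biostrings::width(object@variants)
  if (length(w) && any(w != length(object@parent)))
    msgs <- c(msgs, "all retained variants must equal the parent length")
  if (length(object@parent) %% 3L != 0L)
    msgs <- c(msgs, "parent length must be divisible by 3")
  if (!identical(sort(names(object@ntDiffs)),
                 sort(names(object@variants))))
    msgs <- c(msgs, "ntDiffs must be named by variant")
  if (length(msgs)) msgs else TRUE
})

#' MutationalProfile: per-residue mutation frequencies with hotspot calls
#'
#' Per-position nonsynonymous mutation counts across a library, normalised
#' so the cumulative frequency over the scored region is 1, with mean,
#' standard deviation (sigma) and the >2-sigma hotspot flags.
#'
#' @slot counts Integer vector, nonsynonymous events per residue position
#'   (full scored region, zeros included).
#' @slot frequency Numeric vector summing to 1.
#' @slot mean,sigma Profile mean and standard deviation used for calling.
#' @slot hotspots Integer vector of positions with frequency > mean +
#'   2 sigma (ascending).
#' @slot mode \code{"all"} (statistics over every residue position) or
#'   \code{"mutated"} (over mutated positions only).
#' @slot labels Character position labels (defaults to the position
#'   numbers; users may supply e.g. IMGT strings).
#' @exportClass MutationalProfile
setClass("MutationalProfile",
  representation(
    counts = "integer",
    frequency = "numeric",
    mean = "numeric",
    sigma = "numeric",
    hotspots = "integer",
    mode = "character",
    labels = "character"
  )
)

setValidity("MutationalProfile", function(object) {
  msgs <- character(0)
  if (length(object@counts) != length(object@frequency))
    msgs <- c(msgs, "counts and frequency lengths differ")
  if (length(object@frequency) &&
      abs(sum(object@frequency) - 1) > 1e-9)
    msgs <- c(msgs, "frequencies must sum to 1 (+/- 1e-9)")
  if (any(object@frequency < 0)) msgs <- c(msgs, "negative frequency")
  if (!object@mode %in% c("all", "mutated"))
    msgs <- c(msgs, "mode must be 'all' or 'mutated'")
  if (length(msgs)) msgs else TRUE
})

#' NucleotideBiasMatrix: single-nucleotide substitution spectrum
#'
#' 4x4 matrix of substitution probabilities \code{P[from, to]} estimated
#' from an unselected library: zero diagonal, each row summing to 1 over
#' the three off-diagonal entries. Models the mutagenesis kit's nucleotide
#' bias, position-independent, on the sequenced strand.
#'
#' @slot matrix Numeric 4x4, rows/cols A, C, G, T.
#' @slot pseudocount Pseudocount per cell used in estimation.
#' @exportClass NucleotideBiasMatrix
setClass("NucleotideBiasMatrix",
  representation(matrix = "matrix", pseudocount = "numeric")
)

setValidity("NucleotideBiasMatrix", function(object) {
  m <- object@matrix
  msgs <- character(0)
  if (!all(dim(m) == c(4L, 4L)) ||
      !identical(rownames(m), DNA_BASES) ||
      !identical(colnames(m), DNA_BASES))
    msgs <- c(msgs, "matrix must be 4x4 with A,C,G,T dimnames")
  else {
    if (any(diag(m) != 0)) msgs <- c(msgs, "diagonal must be zero")
    if (any(m < 0)) msgs <- c(msgs, "negative entries")
    if (any(abs(rowSums(m) - 1) > 1e-9))
      msgs <- c(msgs, "each row must sum to 1 over off-diagonal entries")
  }
  if (length(msgs)) msgs else TRUE
})

# ---- accessors --------------------------------------------------------------

#' @describeIn MutantLibrary-accessors Parent coding sequence
#'   (\code{DNAString}).
#' @export
parentSeq <- function(x) x@parent

#' Accessors for MutantLibrary
#'
#' @param x A \code{MutantLibrary}.
#' @param retained Logical; restrict to variants contributing to tallies
#'   under the library's exclusion policy.
#' @name MutantLibrary-accessors
NULL

#' @describeIn MutantLibrary-accessors Variant sequences
#'   (\code{DNAStringSet}); with \code{retained = TRUE} stop-carrying
#'   variants are dropped when the policy excludes them.
#' @export
variantSeqs <- function(x, retained = TRUE) {
  v <- x@variants
  if (retained && x@excludeStops)
    v <- v[!names(v) %in% x@stopVariants]
  v
}

#' @describeIn MutantLibrary-accessors Ids of variants contributing to
#'   profile tallies.
#' @export
retainedVariants <- function(x) names(variantSeqs(x, retained = TRUE))

#' @describeIn MutantLibrary-accessors Nonsynonymous substitution events
#'   (\code{data.frame}); restricted to retained variants by default.
#' @export
substitutionEvents <- function(x, retained = TRUE) {
  ev <- x@events
  if (retained) ev[ev$variant %in% retainedVariants(x), , drop = FALSE]
  else ev
}

#' @describeIn MutantLibrary-accessors Total nucleotide differences per
#'   variant (synonymous changes included); restricted to retained
#'   variants by default.
#' @export
variantNtChanges <- function(x, retained = TRUE) {
  if (retained) x@ntDiffs[retainedVariants(x)] else x@ntDiffs
}

#' @describeIn MutantLibrary-accessors Excluded-variant log with reasons.
#' @export
excludedVariants <- function(x) x@excluded

#' @describeIn MutantLibrary-accessors Ids of variants carrying an
#'   internal stop codon.
#' @export
stopVariants <- function(x) x@stopVariants

#' Accessors for MutationalProfile
#'
#' @param x A \code{MutationalProfile}.
#' @name MutationalProfile-accessors
NULL

#' @describeIn MutationalProfile-accessors Per-position nonsynonymous
#'   event counts.
#' @export
mutationCounts <- function(x) x@counts

#' @describeIn MutationalProfile-accessors Normalised per-position
#'   frequencies (sum to 1).
#' @export
mutationFrequencies <- function(x) x@frequency

#' @describeIn MutationalProfile-accessors Hotspot positions (frequency >
#'   mean + 2 sigma), ascending.
#' @export
hotspotPositions <- function(x) x@hotspots

#' @describeIn MutationalProfile-accessors Profile as a \code{data.frame}
#'   (position, label, count, frequency, hotspot flag).
#' @export
profileTable <- function(x) {
  data.frame(position = seq_along(x@counts), label = x@labels,
             count = x@counts, frequency = x@frequency,
             hotspot = seq_along(x@counts) %in% x@hotspots,
             stringsAsFactors = FALSE)
}

#' Bias matrix accessor
#'
#' @param x A \code{NucleotideBiasMatrix}.
#' @return Numeric 4x4 matrix (rows = from, cols = to).
#' @export
biasMatrix <- function(x) x@matrix

# ---- show methods -----------------------------------------------------------

setMethod("show", "MutantLibrary", function(object) {
  nv <- length(object@variants)
  cat("MutantLibrary of", nv, "length-matched variant(s);",
      "parent", length(object@parent), "bp (",
      length(object@parent) %/% 3L, "codons)\n")
  cat("  nonsynonymous events:", nrow(substitutionEvents(object)),
      "| internal-stop variants:", length(object@stopVariants),
      if (object@excludeStops) "(excluded)" else "(retained: naive mode)",
      "\n")
  if (nrow(object@excluded))
    cat("  excluded:", nrow(object@excluded), "variant(s) (",
        paste(unique(object@excluded$reason), collapse = ", "), ")\n")
})

setMethod("show", "MutationalProfile", function(object) {
  cat("MutationalProfile over", length(object@counts), "positions (mode:",
      object@mode, ")\n")
  cat(sprintf("  mean %.3g, sigma %.3g; %d hotspot(s) > mean + 2 sigma\n",
              object@mean, object@sigma, length(object@hotspots)))
  if (length(object@hotspots))
    cat("  hotspots:", paste(object@labels[object@hotspots], collapse = ", "),
        "\n")
})

setMethod("show", "NucleotideBiasMatrix", function(object) {
  cat("NucleotideBiasMatrix (rows = from, cols = to; pseudocount",
      object@pseudocount, ")\n")
  print(round(object@matrix, 3))
})
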