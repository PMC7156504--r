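#' @importFrom methods new validObject is
#' @importFrom stats rpois runif rnorm sd setNames aggregate
#' @importFrom utils write.table read.csv
NULL

# ---- internal codon helpers -------------------------------------------------

#' @noRd
.checkDna <- function(dna, what = "sequence") {
  dna <- toupper(as.character(dna))
  if (length(dna) != 1L || is.na(dna))
    stop(what, " must be a single character string", call. = FALSE)
  bad <- setdiff(strsplit(dna, "")[[1]], DNA_BASES)
  if (nchar(dna) > 0L && length(bad) > 0L)
    stop(what, " contains non-ACGT characters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  dna
}

#' @noRd
.checkCodon <- function(codon) {
  codon <- .checkDna(codon, "codon")
  if (nchar(codon) != 3L)
    stop("codon must be exactly 3 bases, got '", codon, "'", call. = FALSE)
  codon
}

# standard genetic code as a named lookup, sourced from Biostrings
.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.GENETIC_CODE_TAB <- NULL

#' @noRd
.codonToAA <- function(codons) {
  tab <- Biostrings::GENETIC_CODE
  unname(tab[codons])
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# ---- exported operations ----------------------------------------------------

#' Translate a DNA sequence with the standard genetic code
#'
#' Translates an in-frame coding sequence. Stops are rendered as the
#' sentinel character \code{"*"}; translation does not terminate at the
#' first stop (internal stops stay visible, which is what library QC needs).
#'
#' @param dna Single character string over A/C/G/T, length divisible by 3.
#'   The empty string translates to the empty string.
#' @return Single amino-acid string (one-letter codes, \code{"*"} for stop).
#' @examples
#' translateDNA("ATGAAA")   # "MK"
#' translateDNA("TGGTAA")   # "W*"
#' @export
translateDNA <- function(dna) {
  dna <- .checkDna(dna, "dna")
  n <- nchar(dna)
  if (n == 0L) return("")
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3 (frame error)",
         call. = FALSE)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(.codonToAA(codons), collapse = "")
}

#' Enumerate the nine single-base neighbours of a codon
#'
#' Every codon has exactly 9 Hamming-distance-1 neighbours (3 positions x 3
#' alternative bases). Rows are ordered by position then by substituted base
#' (A < C < G < T).
#'
#' @param codon Single codon string (3 bases, A/C/G/T).
#' @return \code{data.frame} with columns \code{neighbor}, \code{position}
#'   (1-3), \code{from}, \code{to}, \code{aa} (amino acid encoded by the
#'   neighbour, \code{"*"} for stop).
#' @examples
#' singleBaseNeighbors("TGG")
#' @export
singleBaseNeighbors <- function(codon) {
  codon <- .checkCodon(codon)
  bases <- strsplit(codon, "")[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (b in DNA_BASES) {
      if (b == bases[pos]) next
      nb <- bases
      nb[pos] <- b
      k <- k + 1L
      out[[k]] <- data.frame(
        neighbor = paste(nb, collapse = ""),
        position = pos, from = bases[pos], to = b,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$aa <- .codonToAA(res$neighbor)
  res
}

#' Amino acids reachable from a codon by one base change
#'
#' The set of amino acids encoded by the 9 single-base neighbours of a
#' codon, stops excluded. The parent amino acid is included when a
#' synonymous neighbour exists (so F is in its own reachable set from TTT,
#' while W is not reachable from TGG). Rendered in decreasing
#' Kyte-Doolittle hydropathy with the fixed tie order \code{KD_ORDER}.
#'
#' @param codon Single sense codon (stop codons are rejected).
#' @return Single string of one-letter codes, most hydrophobic first.
#' @examples
#' reachableAminoAcids("TTT")  # "IVLFCSY"
#' reachableAminoAcids("TGG")  # "LCGSR"
#' @export
reachableAminoAcids <- function(codon) {
  codon <- .checkCodon(codon)
  if (codon %in% .STOP_CODONS)
    stop("codon '", codon, "' is a stop codon", call. = FALSE)
  aa <- singleBaseNeighbors(codon)$aa
  aa <- unique(aa[aa != STOP_CHAR])
  hydropathySort(aa)
}

#' Minimum base changes from a codon to an amino acid
#'
#' Minimum Hamming distance from \code{codon} to any codon encoding
#' \code{target}. Zero for the codon's own amino acid; Table-style reports
#' flag substitutions with a value >= 2 as multi-base events.
#'
#' @param codon Single codon string.
#' @param target One-letter amino-acid code (stop is rejected).
#' @return Integer in 0..3.
#' @examples
#' minBaseChanges("TTT", "P")  # 2
#' @export
minBaseChanges <- function(codon, target) {
  codon <- .checkCodon(codon)
  target <- toupper(as.character(target))
  if (identical(target, STOP_CHAR))
    stop("stop is not a valid substitution target", call. = FALSE)
  if (!target %in% AA_CODES)
    stop("unknown amino acid '", target, "'", call. = FALSE)
  tab <- Biostrings::GENETIC_CODE
  targets <- names(tab)[tab == target]
  cb <- strsplit(codon, "")[[1]]
  dists <- vapply(strsplit(targets, ""),
                  function(t) sum(t != cb), integer(1))
  as.integer(min(dists))
}

#' Order amino acids by decreasing hydropathy
#'
#' Sorts a set of amino acids by decreasing Kyte-Doolittle value, ties
#' broken by the fixed priority in \code{KD_ORDER} (E, Q, D, N at -3.5).
#' Idempotent; output is a permutation of the (unique) input.
#'
#' @param aas Character vector of one-letter codes, or a single string.
#' @return Single ordered string.
#' @examples
#' hydropathySort(c("S", "L", "Y"))  # "LSY"
#' @export
hydropathySort <- function(aas) {
  if (length(aas) == 1L && nchar(aas[1]) > 1L)
    aas <- strsplit(aas, "")[[1]]
  aas <- toupper(aas)
  bad <- setdiff(aas, AA_CODES)
  if (length(bad) > 0L)
    stop("unknown amino acid symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  aas <- unique(aas)
  paste(aas[order(match(aas, KD_ORDER))], collapse = "")
}

#' Single-base reachability report for a set of codons
#'
#' Tabulates, for each codon, its hydropathy-ordered reachable amino-acid
#' set and the neighbour codons encoding each reachable amino acid.
#'
#' @param codons Character vector of sense codons.
#' @return \code{data.frame} with columns \code{codon}, \code{aa} (the
#'   codon's own amino acid), \code{reachable}, \code{neighbors} (semicolon
#'   separated \code{AA:codon1,codon2} entries, in reachable-set order).
#' @export
reachabilityTable <- function(codons) {
  rows <- lapply(codons, function(cd) {
    cd <- .checkCodon(cd)
    nb <- singleBaseNeighbors(cd)
    reach <- reachableAminoAcids(cd)
    per <- vapply(strsplit(reach, "")[[1]], function(a) {
      paste0(a, ":", paste(sort(unique(nb$neighbor[nb$aa == a])),
                           collapse = ","))
    }, character(1))
    data.frame(codon = cd, aa = .codonToAA(cd), reachable = reach,
               neighbors = paste(per, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
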