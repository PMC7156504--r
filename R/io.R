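# Readers and writers for the screen's file formats: FASTA libraries,
# long-format curve CSVs and fixed-format TSV reports.

#' Read a mutant library from FASTA
#'
#' One record per variant, ids preserved from the FASTA headers. The
#' parent may be supplied as a separate FASTA/string, or as the record
#' named by \code{parentId} inside the same file.
#'
#' @param file Path to the library FASTA.
#' @param parent Parent sequence (string), path to a single-record FASTA,
#'   or \code{NULL} to use \code{parentId}.
#' @param parentId Record id treated as parent when \code{parent} is
#'   \code{NULL}.
#' @param excludeStops Exclusion policy (see \code{\link{mutantLibrary}}).
#' @return A \code{\linkS4class{MutantLibrary}}.
#' @export
readFastaLibrary <- function(file, parent = NULL, parentId = "parent",
                             excludeStops = TRUE) {
  seqs <- Biostrings::readDNAStringSet(file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(parent)) {
    if (!parentId %in% names(seqs))
      stop("no record named '", parentId, "' in ", file, call. = FALSE)
    parent <- as.character(seqs[[parentId]])
    seqs <- seqs[names(seqs) != parentId]
  } else if (length(parent) == 1L && file.exists(parent)) {
    parent <- as.character(Biostrings::readDNAStringSet(parent)[[1L]])
  }
  mutantLibrary(as.character(parent), as.character(seqs),
                excludeStops = excludeStops)
}

#' Write a library to FASTA
#'
#' Writes the parent (first record, id \code{"parent"}) followed by all
#' length-matched variants.
#'
#' @param library A \code{\linkS4class{MutantLibrary}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeFastaLibrary <- function(library, file) {
  all <- c(Biostrings::DNAStringSet(
             stats::setNames(list(parentSeq(library)), "parent")),
           variantSeqs(library, retained = FALSE))
  Biostrings::writeXStringSet(all, file)
  invisible(file)
}

#' Read survival curves from CSV
#'
#' Long format, one row per variant x replicate x concentration. Column
#' aliases \code{conc_ug_per_ml} and \code{mcd_growth} are accepted.
#'
#' @param file CSV path with columns \code{variant}, \code{replicate},
#'   \code{conc} (or \code{conc_ug_per_ml}), \code{mcd} (or
#'   \code{mcd_growth}).
#' @return \code{data.frame} with canonical column names.
#' @export
readSurvivalCurves <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  nm <- names(df)
  nm[nm == "conc_ug_per_ml"] <- "conc"
  nm[nm == "mcd_growth"] <- "mcd"
  names(df) <- nm
  need <- c("variant", "replicate", "conc", "mcd")
  if (!all(need %in% names(df)))
    stop("curve CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$variant <- as.character(df$variant)
  df
}

#' Write survival curves to CSV
#'
#' @param curves Long curve \code{data.frame} (\code{variant},
#'   \code{conc}, \code{mcd}, optional \code{replicate}).
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeSurvivalCurves <- function(curves, file) {
  if (is.null(curves$replicate)) curves$replicate <- 1L
  utils::write.csv(
    curves[, c("variant", "replicate", "conc", "mcd")],
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a TSV report with fixed float formatting
#'
#' Numeric columns are rendered with 6 significant digits so repeated
#' runs diff cleanly.
#'
#' @param df \code{data.frame} to write.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeReportTsv <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Hotspot summary report for a library
#'
#' One row per hotspot: position, most frequent substitution with its
#' observed and expected frequencies, the observed-order string, the
#' single-base reachable set, and (optionally) the residue RSA.
#'
#' @param library A \code{\linkS4class{MutantLibrary}}.
#' @param bias A \code{\linkS4class{NucleotideBiasMatrix}} for expected
#'   frequencies (default uniform).
#' @param rsaTable Optional \code{data.frame} with columns \code{resno}
#'   and \code{rsa} (e.g. from \code{\link{rsaFromPdb}}).
#' @param profile Optional precomputed
#'   \code{\linkS4class{MutationalProfile}}.
#' @return \code{data.frame}, one row per hotspot.
#' @export
hotspotReport <- function(library, bias = uniformBias(), rsaTable = NULL,
                          profile = NULL) {
  if (is.null(profile)) profile <- positionalProfile(library)
  hs <- hotspotPositions(profile)
  rows <- lapply(hs, function(p) {
    sp <- substitutionSpectrum(library, p)
    oe <- observedVsExpected(sp, bias)
    top <- oe[oe$aa == sp$most_frequent, , drop = FALSE]
    data.frame(
      position = p,
      parent_aa = sp$parent_aa,
      rsa = if (!is.null(rsaTable) && p %in% rsaTable$resno)
        rsaTable$rsa[match(p, rsaTable$resno)] else NA_real_,
      most_frequent = sp$most_frequent,
      observed_freq = top$observed,
      expected_freq = top$expected,
      observed_order = sp$observed_order,
      reachable = reachableAminoAcids(sp$parent_codon),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), parent_aa = character(0),
                      rsa = numeric(0), most_frequent = character(0),
                      observed_freq = numeric(0), expected_freq = numeric(0),
                      observed_order = character(0), reachable = character(0),
                      stringsAsFactors = FALSE)
  out
}
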