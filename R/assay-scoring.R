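# In vivo growth scoring: area under the MCD_GROWTH vs ampicillin curve,
# replicate statistics, ranking and representative selection.

#' In vivo growth score of an antibiotic survival curve
#'
#' Area under the maximal-cell-dilution-allowing-growth (MCD) curve over an
#' ampicillin gradient, computed as the sum of n-1 trapezia
#' \deqn{A = \sum_i (y_i + y_{i+1})/2 \times (x_{i+1} - x_i).}
#' On the standard 8-concentration gradient (0-140 ug/mL by 20) this is a
#' sum of exactly 7 trapezia. Units are dilution-steps x ug/mL (arbitrary
#' units, A.U.).
#'
#' @param conc Numeric vector of ampicillin concentrations (ug/mL),
#'   strictly ascending, length >= 2. Alternatively a \code{data.frame}
#'   with columns \code{conc} and \code{mcd} (then \code{mcd} is ignored).
#' @param mcd Numeric vector of MCD values (number of 10-fold serial
#'   dilutions still showing growth; 0 = no growth undiluted), same length,
#'   all >= 0.
#' @return Single numeric area (A.U.).
#' @examples
#' growthScore(seq(0, 140, by = 20), rep(5, 8))  # 700
#' @export
growthScore <- function(conc, mcd = NULL) {
  if (is.data.frame(conc)) {
    if (!all(c("conc", "mcd") %in% names(conc)))
      stop("curve data.frame needs columns 'conc' and 'mcd'", call. = FALSE)
    mcd <- conc$mcd
    conc <- conc$conc
  }
  if (length(conc) < 2L)
    stop("a survival curve needs at least 2 points", call. = FALSE)
  if (length(conc) != length(mcd))
    stop("conc and mcd lengths differ", call. = FALSE)
  if (anyNA(conc) || anyNA(mcd))
    stop("curve contains missing values", call. = FALSE)
  if (any(diff(conc) <= 0))
    stop("concentrations must be strictly ascending (no duplicates)",
         call. = FALSE)
  if (any(mcd < 0))
    stop("MCD values must be >= 0", call. = FALSE)
  n <- length(conc)
  sum((mcd[-n] + mcd[-1]) / 2 * diff(conc))
}

#' Replicate statistics for one variant's growth scores
#'
#' Scores each replicate curve then summarises: mean, standard deviation
#' (n-1 denominator) and s.e.m. = s.d./sqrt(n). With a single replicate the
#' s.d. and s.e.m. are \code{NA} (flagged unavailable, not zero).
#'
#' @param curves List of curves, each a \code{data.frame} with columns
#'   \code{conc}, \code{mcd}; all replicates must share the same
#'   concentration grid.
#' @param id Variant identifier carried into the result.
#' @return One-row \code{data.frame}: \code{variant}, \code{n},
#'   \code{mean}, \code{sd}, \code{sem}.
#' @export
aggregateReplicates <- function(curves, id = "variant") {
  if (!is.list(curves) || length(curves) == 0L || is.data.frame(curves))
    stop("curves must be a non-empty list of data.frames", call. = FALSE)
  grid <- curves[[1]]$conc
  for (cv in curves)
    if (length(cv$conc) != length(grid) || any(cv$conc != grid))
      stop("replicates have mismatched concentration grids", call. = FALSE)
  scores <- vapply(curves, growthScore, numeric(1))
  n <- length(scores)
  s <- if (n > 1L) stats::sd(scores) else NA_real_
  data.frame(variant = id, n = n, mean = mean(scores), sd = s,
             sem = if (n > 1L) s / sqrt(n) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Score a long-format table of survival curves
#'
#' Convenience wrapper around \code{\link{growthScore}} and
#' \code{\link{aggregateReplicates}} for the standard long table (one row
#' per variant x replicate x concentration).
#'
#' @param curves \code{data.frame} with columns \code{variant},
#'   \code{replicate}, \code{conc}, \code{mcd}.
#' @return \code{data.frame} with one row per variant: \code{variant},
#'   \code{n}, \code{mean}, \code{sd}, \code{sem}.
#' @export
scoreCurveTable <- function(curves) {
  need <- c("variant", "replicate", "conc", "mcd")
  if (!all(need %in% names(curves)))
    stop("curve table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(curves, curves$variant), function(df) {
    reps <- lapply(split(df, df$replicate), function(r)
      r[order(r$conc), c("conc", "mcd")])
    aggregateReplicates(unname(reps), id = df$variant[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$variant), , drop = FALSE]
}

#' Percentage of a reference enhancement achieved by a variant
#'
#' \code{100 * (variant - baseline) / (reference - baseline)}, rounded
#' half-away-from-zero to the nearest integer percent. With the screen's
#' printed mean scores (aggregation-prone parent 172, engineered
#' reference 690 A.U.), a variant at 643 achieves 91 percent of the
#' enhancement.
#'
#' @param variant,baseline,reference Mean growth scores (A.U.).
#' @return Integer percentage.
#' @examples
#' percentEnhancement(643, 172, 690)  # 91
#' @export
percentEnhancement <- function(variant, baseline, reference) {
  if (reference == baseline)
    stop("reference equals baseline: enhancement undefined", call. = FALSE)
  p <- 100 * (variant - baseline) / (reference - baseline)
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Rank variants by mean growth score
#'
#' Descending by mean score; ties broken by fewest substitutions relative
#' to the parent, then lexicographic variant id. Ranks are 1..N with 1 the
#' highest score.
#'
#' @param scores \code{data.frame} with columns \code{variant},
#'   \code{mean} and optionally \code{n_subs} (substitution count,
#'   defaults to 0 when absent).
#' @return Input rows reordered, with columns \code{rank}, \code{variant},
#'   \code{mean}, \code{n_subs}.
#' @export
rankVariants <- function(scores) {
  if (nrow(scores) == 0L) stop("no variants to rank", call. = FALSE)
  if (anyDuplicated(scores$variant))
    stop("duplicate variant ids", call. = FALSE)
  if (is.null(scores$n_subs)) scores$n_subs <- 0L
  ord <- order(-scores$mean, scores$n_subs, scores$variant)
  out <- scores[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Select rank representatives spaced by one replicate s.d.
#'
#' Mirrors the screen's sequential pick across the rank: starting from the
#' top score, successive score bins of width \code{sd} are laid down
#' (\code{(top - k*sd, top - (k-1)*sd]}); within each occupied bin the
#' variant with the fewest substitutions is picked (ties: higher score,
#' then lexicographic id). Bins whose upper edge falls at or below
#' \code{baseline} are not walked.
#'
#' @param ranked Output of \code{\link{rankVariants}} (columns
#'   \code{variant}, \code{mean}, \code{n_subs}).
#' @param sd Replicate standard deviation of the score (> 0); the screen
#'   used s.d. = 130 A.U. (n = 16 replicates of the resistant control).
#' @param baseline Optional score floor (e.g. the parent's mean score);
#'   default \code{-Inf} walks all bins down to the lowest variant.
#' @return Subset of \code{ranked} rows, one per occupied bin, with a
#'   \code{bin} column (1 = top).
#' @export
selectRepresentatives <- function(ranked, sd, baseline = -Inf) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd <= 0)
    stop("sd must be a single positive number", call. = FALSE)
  if (nrow(ranked) == 0L) stop("no ranked variants", call. = FALSE)
  if (is.null(ranked$n_subs)) ranked$n_subs <- 0L
  top <- max(ranked$mean)
  # bin index 1..k, bin k covers (top - k*sd, top - (k-1)*sd]
  bin <- ceiling(pmax(top - ranked$mean, 0) / sd)
  bin[bin == 0L] <- 1L          # the top scorer itself
  upper <- top - (bin - 1L) * sd
  keep <- upper > baseline
  picks <- lapply(split(which(keep), bin[keep]), function(idx) {
    sub <- ranked[idx, , drop = FALSE]
    ord <- order(sub$n_subs, -sub$mean, sub$variant)
    sub[ord[1L], , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  out <- cbind(bin = as.integer(names(picks)), out)
  rownames(out) <- NULL
  out[order(out$bin), , drop = FALSE]
}

#' HTRF ratio
#'
#' Ratiometric FRET readout: \code{665 nm emission / 590 nm emission x
#' 10,000}.
#'
#' @param em665,em590 Fluorescence emissions; \code{em590} must be > 0.
#' @return Numeric ratio (vectorised).
#' @export
htrfRatio <- function(em665, em590) {
  if (any(em590 <= 0))
    stop("590 nm emission must be > 0", call. = FALSE)
  em665 / em590 * 10000
}

#' Percent delta F of an HTRF competition measurement
#'
#' \code{(sample ratio - negative control ratio) / negative control ratio
#' x 100}.
#'
#' @param sampleRatio,controlRatio HTRF ratios; \code{controlRatio} > 0.
#' @return Numeric percentage (vectorised).
#' @export
deltaFPercent <- function(sampleRatio, controlRatio) {
  if (any(controlRatio <= 0))
    stop("negative control ratio must be > 0", call. = FALSE)
  (sampleRatio - controlRatio) / controlRatio * 100
}
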