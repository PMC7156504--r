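# Solvent accessibility: Shrake-Rupley SASA and relative surface
# accessibility (RSA) normalised by residue-type maxima.

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-spiral (Fibonacci) lattice; adequate quadrature
#' for Shrake-Rupley at a few hundred points per atom.
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi),
        y = sin(theta) * sin(phi),
        z = cos(phi))
}

#' @noRd
.atomRadii <- function(atoms) {
  if (!is.null(atoms$radius)) return(atoms$radius)
  el <- toupper(atoms$element)
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    unknown <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using carbon radius 1.70 A", call. = FALSE)
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe of radius 1.4 A over the heavy atoms: each atom carries a
#' quasi-uniform lattice of \code{points} test points on its expanded
#' sphere (vdW radius + probe); a point is accessible when it lies outside
#' every neighbouring expanded sphere, and the atom's area is the
#' accessible fraction of \code{4 pi (r + probe)^2}. Hydrogens are ignored
#' (heavy-atom convention). Coincident atom centres are deduplicated with
#' a warning (the duplicate contributes zero area), keeping the result
#' deterministic.
#'
#' @param atoms \code{data.frame} with columns \code{x}, \code{y},
#'   \code{z} (Angstrom) and either \code{radius} or \code{element}
#'   (looked up in \code{VDW_RADII}); optional \code{resno} and
#'   \code{resid} for per-residue sums.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param points Sphere points per atom (default 960; >= 100 required).
#' @return Numeric vector of per-atom areas (Angstrom^2), with attribute
#'   \code{"residue"}: a \code{data.frame} of per-residue sums when
#'   \code{resno} is present.
#' @examples
#' # isolated atom: full sphere 4*pi*(1.7+1.4)^2
#' sasa(data.frame(x = 0, y = 0, z = 0, radius = 1.7))
#' @export
sasa <- function(atoms, probe = 1.4, points = 960) {
  stopifnot(points >= 100, probe >= 0)
  if (!is.null(atoms$element)) {
    h <- toupper(atoms$element) == "H"
    atoms <- atoms[!h, , drop = FALSE]
  }
  n <- nrow(atoms)
  if (n == 0L) stop("no heavy atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  r <- .atomRadii(atoms) + probe
  dup <- duplicated(round(xyz, 6))
  if (any(dup))
    warning(sum(dup), " atom(s) with coincident centres; duplicates ",
            "contribute zero area", call. = FALSE)
  pts <- spherePoints(points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    if (dup[i]) next
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < r[i] + r & seq_len(n) != i & !dup)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    P <- pts * r[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, points)
    for (j in nb) {
      if (!any(accessible)) break
      dd <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      accessible <- accessible & dd >= r[j]^2
    }
    areas[i] <- sum(accessible) / points * 4 * pi * r[i]^2
  }
  if (!is.null(atoms$resno)) {
    res <- stats::aggregate(areas,
                            by = list(resno = atoms$resno),
                            FUN = sum)
    names(res)[2] <- "area"
    if (!is.null(atoms$resid))
      res$resid <- atoms$resid[match(res$resno, atoms$resno)]
    attr(areas, "residue") <- res
  }
  areas
}

#' Relative surface accessibility of a residue
#'
#' Absolute solvent-accessible area divided by the maximum possible area
#' for the residue type (Miller et al. Gly-X-Gly maxima,
#' \code{MILLER_MAX_ASA}). 0 = completely buried, 1 = maximally exposed.
#' Values slightly above 1 can occur for extended conformations and are
#' flagged, not clipped.
#'
#' @param area Absolute area(s), Angstrom^2.
#' @param residueType Three-letter residue name(s), case-insensitive.
#' @return Numeric RSA value(s); attribute \code{"exceeds_max"} flags
#'   entries > 1.
#' @export
rsa <- function(area, residueType) {
  rt <- toupper(residueType)
  mx <- MILLER_MAX_ASA[rt]
  if (anyNA(mx))
    stop("unknown residue type(s): ",
         paste(unique(rt[is.na(mx)]), collapse = ", "), call. = FALSE)
  if (any(area < 0)) stop("negative area", call. = FALSE)
  out <- unname(area / mx)
  attr(out, "exceeds_max") <- out > 1
  out
}

#' Per-residue RSA profile from a PDB file
#'
#' Reads ATOM records (first model; alternate location 'A' preferred),
#' drops hydrogens, computes Shrake-Rupley areas and normalises per
#' residue by the Miller maxima. Residue types outside the 20 canonical
#' amino acids get \code{NA} RSA.
#'
#' @param pdbFile Path to a PDB file.
#' @param probe Probe radius (default 1.4 A).
#' @param points Sphere points per atom (default 960).
#' @return \code{data.frame}: \code{resno}, \code{resid}, \code{area},
#'   \code{rsa}, \code{exceeds_max}.
#' @export
rsaFromPdb <- function(pdbFile, probe = 1.4, points = 960) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("rsaFromPdb needs the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(pdbFile, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$alt %in% c(NA, "", "A"), , drop = FALSE]
  atoms <- data.frame(x = at$x, y = at$y, z = at$z,
                      element = at$elesy, resno = at$resno,
                      resid = at$resid, stringsAsFactors = FALSE)
  a <- sasa(atoms, probe = probe, points = points)
  res <- attr(a, "residue")
  known <- res$resid %in% names(MILLER_MAX_ASA)
  res$rsa <- NA_real_
  if (any(known)) {
    v <- rsa(res$area[known], res$resid[known])
    res$rsa[known] <- v
  }
  res$exceeds_max <- !is.na(res$rsa) & res$rsa > 1
  res[, c("resno", "resid", "area", "rsa", "exceeds_max")]
}
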