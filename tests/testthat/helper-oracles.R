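# Independent oracles and fixture builders used across the suite.

# all 64 codons, enumerated independently of the package's helpers
allCodons <- function() {
  g <- expand.grid(b3 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                   b1 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# translate one codon through Biostrings' own translate() (independent of
# the package's genetic-code lookup path)
oracleTranslate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force reachable set: scan all 64 codons at Hamming distance 1,
# translate each, drop stops, order by Kyte-Doolittle value with the
# E < Q < D < N tie priority spelled out locally
oracleReachable <- function(codon) {
  cods <- allCodons()
  nb <- cods[vapply(cods, hamming, integer(1), a = codon) == 1L]
  aa <- unique(vapply(nb, oracleTranslate, character(1)))
  aa <- aa[aa != "*"]
  kd <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
          G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
          H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
          R = -4.5)
  tie <- c(E = 1, Q = 2, D = 3, N = 4)
  t2 <- ifelse(aa %in% names(tie), tie[aa], 0)
  paste(aa[order(-kd[aa], t2)], collapse = "")
}

senseCodons <- function() setdiff(allCodons(), c("TAA", "TAG", "TGA"))

# random row-normalised off-diagonal bias matrix
randomBias <- function() {
  m <- matrix(stats::runif(16, 0.05, 1), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  nucleotideBias(m)
}

# mutate given positions of a sequence to given bases
mutateSeq <- function(seq, pos, to) {
  v <- strsplit(seq, "")[[1]]
  v[pos] <- to
  paste(v, collapse = "")
}

# ---- idealised extended Gly-Ala-Gly tripeptide ------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF atom placement: D from A-B-C with bond r, angle theta(B-C-D),
# torsion phi(A-B-C-D)
.placeAtom <- function(A, B, C, r, theta, phi) {
  bc <- (C - B); bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# fully extended (phi = psi = omega = 180) Gly-Ala-Gly with ideal bond
# geometry; heavy atoms only
buildExtendedGAG <- function() {
  deg <- function(x) x * pi / 180
  rows <- list()
  add <- function(name, resno, resid, xyz)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resno = resno, resid = resid,
      x = xyz[1], y = xyz[2], z = xyz[3],
      element = substr(name, 1, 1), stringsAsFactors = FALSE)
  N1 <- c(0, 0, 0); CA1 <- c(1.46, 0, 0)
  C1 <- .placeAtom(c(-1, 1, 0), N1, CA1, 1.52, deg(110.5), deg(180))
  O1 <- .placeAtom(N1, CA1, C1, 1.23, deg(120.5), deg(0))
  add("N", 1, "GLY", N1); add("CA", 1, "GLY", CA1)
  add("C", 1, "GLY", C1); add("O", 1, "GLY", O1)
  N2 <- .placeAtom(N1, CA1, C1, 1.33, deg(116.5), deg(180))
  CA2 <- .placeAtom(CA1, C1, N2, 1.46, deg(121.5), deg(180))
  C2 <- .placeAtom(C1, N2, CA2, 1.52, deg(110.5), deg(180))
  O2 <- .placeAtom(N2, CA2, C2, 1.23, deg(120.5), deg(0))
  CB2 <- .placeAtom(C2, N2, CA2, 1.53, deg(110.5), deg(-122))
  add("N", 2, "ALA", N2); add("CA", 2, "ALA", CA2); add("C", 2, "ALA", C2)
  add("O", 2, "ALA", O2); add("CB", 2, "ALA", CB2)
  N3 <- .placeAtom(N2, CA2, C2, 1.33, deg(116.5), deg(180))
  CA3 <- .placeAtom(CA2, C2, N3, 1.46, deg(121.5), deg(180))
  C3 <- .placeAtom(C2, N3, CA3, 1.52, deg(110.5), deg(180))
  O3 <- .placeAtom(N3, CA3, C3, 1.23, deg(120.5), deg(0))
  add("N", 3, "GLY", N3); add("CA", 3, "GLY", CA3)
  add("C", 3, "GLY", C3); add("O", 3, "GLY", O3)
  do.call(rbind, rows)
}

# write a minimal fixed-column PDB file for an atom table (synthetic
# fixture): name cols 14-16, resName 18-20, chain 22, resSeq 23-26
writeSyntheticPdb <- function(atoms, file) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-4s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, atoms$name[i], atoms$resid[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), file)
  file
}
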