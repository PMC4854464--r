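# Shrake-Rupley accessible surface area.
#
# Quasi-uniform test points are placed on each atom's solvent-expanded
# sphere (van der Waals radius + probe radius); a point is accessible iff
# it lies outside every other expanded sphere. The accessible area of the
# atom is the accessible point fraction times the expanded-sphere area.

#' Van der Waals radii by element
#'
#' Standard heavy-atom radii (Angstrom) used for surface-area calculations.
#' Elements not listed fall back to `default`.
#'
#' @param default radius for unknown elements.
#' @return named numeric vector.
#' @export
vdw_radii <- function(default = 1.80) {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    H = 1.20, D = 1.20, X = default)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley accessible surface area of a set of spheres
#'
#' @param centers numeric matrix (n x 3) of sphere centers (Angstrom).
#' @param radii numeric vector of sphere radii (Angstrom), recycled to n.
#' @param probe_radius solvent probe radius, default 1.4 Angstrom (water).
#' @param n_points number of test points per sphere (>= 92); more points
#'   give a finer quadrature.
#' @return numeric vector of per-sphere accessible areas (Angstrom^2).
#' @examples
#' # an isolated sphere: full expanded-sphere area 4*pi*(r+probe)^2
#' shrake_rupley_asa(matrix(0, 1, 3), 1.9)
#' @export
shrake_rupley_asa <- function(centers, radii, probe_radius = 1.4,
                              n_points = 960L) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("`centers` must be an n x 3 matrix")
  n <- nrow(centers)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("non-positive sphere radius")
  if (n_points < 92) stop("n_points must be >= 92")
  pts <- fibonacci_sphere(n_points)
  rexp <- radii + probe_radius
  area <- numeric(n)
  # neighbor prefilter: only spheres whose expanded shells can intersect
  for (i in seq_len(n)) {
    d2 <- (centers[, 1] - centers[i, 1])^2 +
          (centers[, 2] - centers[i, 2])^2 +
          (centers[, 3] - centers[i, 3])^2
    nb <- which(d2 < (rexp + rexp[i])^2 & seq_len(n) != i)
    full <- 4 * pi * rexp[i]^2
    if (length(nb) == 0) { area[i] <- full; next }
    p <- pts * rexp[i]
    p <- sweep(p, 2, centers[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
             (p[, 3] - centers[j, 3])^2
      acc <- acc & dj2 > rexp[j]^2
      if (!any(acc)) break
    }
    area[i] <- full * mean(acc)
  }
  area
}

#' Per-residue accessible surface area of a structure
#'
#' Runs the Shrake-Rupley calculation over all heavy atoms of the structure
#' and sums atom areas within each residue.
#'
#' @param structure an `enzgrad_structure`.
#' @param probe_radius probe radius (Angstrom).
#' @param n_points test points per atom.
#' @param radii named vector of van der Waals radii by element symbol.
#' @param uniform_radius if non-`NULL`, every atom gets this radius instead
#'   (used for coarse pseudo-atom models such as the synthetic generator's
#'   one-sphere-per-residue structures).
#' @param chain restrict the calculation to one chain's atoms (the chain in
#'   isolation), e.g. for interface detection.
#' @return numeric vector of per-residue ASA (Angstrom^2), aligned with
#'   `structure$residues`; residues of other chains are `NA` when `chain`
#'   is given.
#' @export
structure_asa <- function(structure, probe_radius = 1.4, n_points = 960L,
                          radii = vdw_radii(), uniform_radius = NULL,
                          chain = NULL) {
  at <- structure$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  el <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy))
  heavy <- !(el %in% c("H", "D"))
  at <- at[heavy, , drop = FALSE]
  el <- el[heavy]
  r <- if (is.null(uniform_radius)) {
    out <- radii[el]
    out[is.na(out)] <- radii[["X"]]
    unname(out)
  } else rep(uniform_radius, nrow(at))
  asa_atom <- shrake_rupley_asa(as.matrix(at[, c("x", "y", "z")]), r,
                                probe_radius, n_points)
  res <- structure$residues
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  out <- rep(NA_real_, nrow(res))
  sums <- tapply(asa_atom, factor(akey, levels = rkey), sum)
  out[match(names(sums), rkey)] <- as.numeric(sums)
  if (is.null(chain)) out[is.na(out)] <- 0
  out
}

#' Maximum per-residue accessible surface area (Gly-X-Gly)
#'
#' Theoretical maximum ASA of residue X in an extended Gly-X-Gly
#' tripeptide (Tien et al. 2013, theoretical values), used to normalize
#' ASA into relative solvent accessibility.
#'
#' @return named numeric vector (Angstrom^2), one entry per standard
#'   amino acid (3-letter codes).
#' @export
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Read per-residue accessible areas from a DSSP output file
#'
#' For reproduction against DSSP-derived accessibilities, the ACC column
#' of a classic-format `mkdssp` output can be used in place of the
#' built-in Shrake-Rupley calculation.
#'
#' @param text DSSP output text (character scalar or lines).
#' @return data frame with columns `chain`, `resno`, `aa` (one-letter) and
#'   `acc` (Angstrom^2).
#' @export
read_dssp_acc <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n")[[1]] else text
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: header row not found")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  keep <- !is.na(resno)  # chain breaks have blank residue numbers
  body <- body[keep]
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    resno = resno[keep],
    aa = trimws(substr(body, 14, 14)),
    acc = as.numeric(substr(body, 35, 38)),
    stringsAsFactors = FALSE
  )
}
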