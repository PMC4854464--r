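# Per-residue metrics: weighted contact number, distance to the nearest
# catalytic residue, relative solvent accessibility, interface flags, and
# their assembly into the per-residue site table.

#' Weighted contact number
#'
#' The packing density of residue i is the sum over all other residues j
#' of the inverse squared distance between their side-chain geometric
#' centers:
#' \deqn{WCN_i = \sum_{j \ne i} 1 / r_{ij}^2}{WCN_i = sum_j 1/r_ij^2}
#' High values mark the densely packed protein core.
#'
#' @param centers numeric matrix (n x 3) of residue centers (Angstrom).
#' @return numeric vector of WCN values (Angstrom^-2). A single-residue
#'   input returns 0 with a warning.
#' @export
weighted_contact_number <- function(centers) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0) stop("no centers")
  if (any(!is.finite(centers))) stop("non-finite center coordinates")
  if (n == 1) {
    warning("single residue: WCN is 0 by convention")
    return(0)
  }
  d <- as.matrix(dist(centers))
  zero <- which(d == 0 & row(d) < col(d), arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop(sprintf("coincident centers: residues %d and %d are 0 Angstrom apart",
                 zero[1, 1], zero[1, 2]))
  w <- 1 / d^2
  diag(w) <- 0
  unname(rowSums(w))
}

#' Distance to the nearest catalytic residue
#'
#' @param centers numeric matrix (n x 3) of residue centers (Angstrom).
#' @param catalytic_indices integer indices (rows of `centers`) of the
#'   catalytic residues; must be non-empty.
#' @return numeric vector d (Angstrom); catalytic residues get exactly 0.
#' @export
distance_to_catalytic <- function(centers, catalytic_indices) {
  centers <- as.matrix(centers)
  catalytic_indices <- as.integer(catalytic_indices)
  if (length(catalytic_indices) == 0)
    stop("empty catalytic set")
  if (any(catalytic_indices < 1 | catalytic_indices > nrow(centers)))
    stop("catalytic index out of range")
  cat_xyz <- centers[catalytic_indices, , drop = FALSE]
  d <- vapply(seq_len(nrow(centers)), function(i) {
    sqrt(min(colSums((t(cat_xyz) - centers[i, ])^2)))
  }, numeric(1))
  d[catalytic_indices] <- 0
  d
}

#' Relative solvent accessibility
#'
#' ASA divided by the residue type's maximum ASA in an extended Gly-X-Gly
#' tripeptide. Residues participating in cross-chain peptide linkages
#' (typically disulfide bridges) are assigned an RSA of zero. Values above
#' 1 are retained, not clipped; their count is reported in a message.
#'
#' @param asa numeric per-residue ASA (Angstrom^2).
#' @param residue_types 3-letter codes, same length as `asa`.
#' @param max_asa named maximum-ASA table, see [max_asa_table()].
#' @param cross_chain_linked integer indices forced to RSA 0.
#' @return numeric vector of RSA fractions.
#' @export
relative_solvent_accessibility <- function(asa, residue_types,
                                           max_asa = max_asa_table(),
                                           cross_chain_linked = integer()) {
  if (length(asa) != length(residue_types))
    stop("`asa` and `residue_types` lengths differ")
  unknown <- setdiff(unique(residue_types), names(max_asa))
  if (length(unknown) > 0)
    stop("lookup error: no max ASA for residue type(s): ",
         paste(unknown, collapse = ", "))
  rsa <- asa / unname(max_asa[residue_types])
  if (length(cross_chain_linked) > 0) rsa[cross_chain_linked] <- 0
  n_over <- sum(rsa > 1, na.rm = TRUE)
  if (n_over > 0)
    message(sprintf("%d residues with RSA > 1 (kept unclipped)", n_over))
  rsa
}

#' Detect residues in cross-chain covalent linkages
#'
#' Flags residues with any heavy-atom pair closer than `cutoff` to an atom
#' of a different chain -- covalent-bond range, i.e. inter-chain disulfide
#' bridges or other cross-links, which by convention get RSA 0.
#'
#' @param structure an `enzgrad_structure`.
#' @param cutoff Angstrom; default 2.2, above S-S bond length (2.05).
#' @return integer indices into `structure$residues`.
#' @export
detect_cross_chain_links <- function(structure, cutoff = 2.2) {
  at <- structure$atoms
  if (length(unique(at$chain)) < 2) return(integer())
  el <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy))
  at <- at[!(el %in% c("H", "D")), , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  cross <- outer(at$chain, at$chain, "!=")
  linked <- which(apply(d < cutoff & cross, 1, any))
  if (length(linked) == 0) return(integer())
  res <- structure$residues
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  akey <- paste(at$chain[linked], at$resno[linked], at$insert[linked],
                sep = "\r")
  sort(unique(match(akey, rkey)))
}

#' Flag subunit-interface residues
#'
#' A residue is at a protein-protein interface when its RSA computed for
#' the isolated chain exceeds its RSA in the full biological assembly by
#' at least `threshold` -- burial caused by the neighboring subunits. The
#' threshold is read as an absolute RSA difference by default ("10%" of
#' the RSA scale); `relative = TRUE` instead requires a 10% relative drop.
#'
#' @param rsa_single_chain per-residue RSA from the chain in isolation.
#' @param rsa_assembly per-residue RSA from the full assembly, aligned.
#' @param threshold minimum difference, default 0.10.
#' @param relative interpret `threshold` as a relative drop.
#' @return logical vector.
#' @export
detect_interface <- function(rsa_single_chain, rsa_assembly,
                             threshold = 0.10, relative = FALSE) {
  if (length(rsa_single_chain) != length(rsa_assembly))
    stop("RSA vectors have different lengths")
  delta <- rsa_single_chain - rsa_assembly
  flag <- if (relative) {
    base <- pmax(rsa_single_chain, .Machine$double.eps)
    delta / base >= threshold
  } else {
    delta >= threshold
  }
  flag & !is.na(flag)
}

#' Assemble the per-residue site table
#'
#' Computes all per-residue metrics of a structure -- WCN, ASA, RSA,
#' distance d to the nearest catalytic residue, 5 Angstrom distance shell,
#' catalytic and interface flags -- and attaches normalized evolutionary
#' rates, producing the table every downstream analysis consumes. Metrics
#' are always computed on the full selected coordinate set; when
#' `interfaces = "exclude"`, interface records are dropped only afterwards
#' (rates are re-normalized to mean 1 over the retained records).
#'
#' @param structure an `enzgrad_structure`.
#' @param annotation optional `enzgrad_annotation` of catalytic residues;
#'   without it, `d`, `shell` and `is_catalytic` are `NA`/`FALSE`.
#' @param rates optional `enzgrad_rates` object (see [normalize_rates()])
#'   or numeric vector of raw rates aligned to residue order.
#' @param interfaces `"keep"` (default) or `"exclude"`.
#' @param probe_radius,n_points Shrake-Rupley parameters.
#' @param uniform_radius see [structure_asa()]; used by the synthetic
#'   generator's pseudo-atom structures.
#' @param compute_interface detect interfaces on multi-chain structures
#'   (requires a second, per-chain ASA pass); default `TRUE`.
#' @return data frame of class `enzgrad_site_table` with fixed columns
#'   `protein_id, chain, residue_number, residue_type, K, wcn, asa, rsa,
#'   d, shell, is_catalytic, is_interface` and attributes `provenance`,
#'   `interfaces`.
#' @export
build_site_table <- function(structure, annotation = NULL, rates = NULL,
                             interfaces = c("keep", "exclude"),
                             probe_radius = 1.4, n_points = 960L,
                             uniform_radius = NULL,
                             compute_interface = TRUE) {
  interfaces <- match.arg(interfaces)
  res <- structure$residues
  n <- nrow(res)
  ctr <- residue_centers(structure)

  wcn <- weighted_contact_number(ctr)
  asa <- structure_asa(structure, probe_radius, n_points,
                      uniform_radius = uniform_radius)
  linked <- detect_cross_chain_links(structure)
  rsa <- relative_solvent_accessibility(asa, res$resid,
                                        cross_chain_linked = linked)

  is_interface <- rep(FALSE, n)
  if (compute_interface && length(structure$chains) > 1) {
    rsa_single <- rep(NA_real_, n)
    for (ch in structure$chains) {
      sel <- res$chain == ch
      asa_ch <- structure_asa(structure, probe_radius, n_points,
                              uniform_radius = uniform_radius, chain = ch)
      rsa_single[sel] <- asa_ch[sel] / unname(max_asa_table()[res$resid[sel]])
    }
    if (length(linked) > 0) rsa_single[linked] <- 0
    is_interface <- detect_interface(rsa_single, rsa)
  }

  d <- rep(NA_real_, n)
  shell <- rep(NA_integer_, n)
  is_cat <- rep(FALSE, n)
  if (!is.null(annotation)) {
    d <- distance_to_catalytic(ctr, annotation$index)
    shell <- assign_shell(d)
    is_cat <- d == 0
  }

  K <- rep(NA_real_, n)
  if (!is.null(rates)) {
    raw <- if (inherits(rates, "enzgrad_rates")) rates$raw else rates
    if (length(raw) != n)
      stop(sprintf("mapping error: %d rates for %d residues",
                   length(raw), n))
    K <- normalize_rates(raw)$K
  }

  tab <- data.frame(
    protein_id = structure$pdb_id,
    chain = res$chain,
    residue_number = res$resno,
    residue_type = res$resid,
    K = K, wcn = wcn, asa = asa, rsa = rsa, d = d, shell = shell,
    is_catalytic = is_cat, is_interface = is_interface,
    stringsAsFactors = FALSE
  )
  if (interfaces == "exclude") {
    keep <- !tab$is_interface
    tab <- tab[keep, , drop = FALSE]
    ctr <- ctr[keep, , drop = FALSE]
    rownames(tab) <- NULL
    if (!all(is.na(tab$K))) tab$K <- tab$K / mean(tab$K)
  }
  attr(tab, "centers") <- ctr
  attr(tab, "provenance") <- structure$provenance
  attr(tab, "interfaces") <-
    if (interfaces == "keep") "interfaces_kept" else "interfaces_excluded"
  class(tab) <- c("enzgrad_site_table", "data.frame")
  tab
}

#' Write / read a site table as TSV
#'
#' Fixed column set and order: `protein_id, chain, residue_number,
#' residue_type, K, wcn, asa, rsa, d, shell, is_catalytic, is_interface`.
#'
#' @param table an `enzgrad_site_table`.
#' @param path output path.
#' @export
write_site_table <- function(table, path) {
  cols <- c("protein_id", "chain", "residue_number", "residue_type", "K",
            "wcn", "asa", "rsa", "d", "shell", "is_catalytic",
            "is_interface")
  write.table(as.data.frame(table)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("enzgrad_site_table", "data.frame")
  tab
}
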