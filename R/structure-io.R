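# Reading PDB structures and catalytic-site annotations.
#
# Structures are represented as a list with an atom-level data frame and a
# residue-level data frame carrying the side-chain geometric center of each
# residue. Multi-MODEL biological-assembly files are concatenated into one
# coordinate set with symmetry copies renamed chain "A" -> "A-2", "A-3", ...

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse a PDB structure
#'
#' Reads a structure from PDB text (or a file), keeping standard amino-acid
#' residues only. HETATM records, waters and ligands are excluded, except
#' selenomethionine (MSE), which is mapped to MET. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by file order).
#' Multi-MODEL files -- the usual layout of symmetric biological
#' assemblies -- are concatenated into a single coordinate set, with chains
#' of the second and later MODELs renamed `"A"` to `"A-2"`, `"A-3"`, and so
#' on, so that contact and distance metrics see every subunit copy.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB-format text;
#'   exactly one of `pdb_text` and `file` must be given.
#' @param file path to a PDB file.
#' @param mode `"assembly"` (default) keeps all chains and MODELs;
#'   `"single_chain"` keeps one chain of the first MODEL.
#' @param chain chain identifier, required when `mode = "single_chain"`.
#' @param pdb_id optional identifier stored in the result.
#' @return An object of class `enzgrad_structure`: a list with elements
#'   `atoms` (atom-level data frame), `residues` (one row per residue, file
#'   order, with side-chain geometric center columns `x`, `y`, `z`),
#'   `chains`, `provenance` and `pdb_id`.
#' @examples
#' pdb <- example_pdb_text()
#' s <- parse_structure(pdb)
#' nrow(s$residues)
#' @export
parse_structure <- function(pdb_text = NULL, file = NULL,
                            mode = c("assembly", "single_chain"),
                            chain = NULL, pdb_id = "structure") {
  mode <- match.arg(mode)
  if (is.null(pdb_text) == is.null(file))
    stop("supply exactly one of `pdb_text` or `file`")
  if (!is.null(pdb_text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(paste(pdb_text, collapse = "\n"), file)
  }
  txt <- readLines(file, warn = FALSE)
  if (!any(grepl("^ATOM|^HETATM", txt)))
    stop("parse error: no ATOM records in PDB input")

  pdb <- suppressWarnings(
    bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE)
  )
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L

  # MSE (selenomethionine) is deposited as HETATM; map to MET
  is_mse <- at$type == "HETATM" & at$resid == "MSE"
  at$resid[is_mse] <- "MET"
  at$type[is_mse] <- "ATOM"

  nonstd <- at$type == "ATOM" & !(at$resid %in% STANDARD_AA)
  if (any(nonstd)) {
    warning(sprintf("excluding %d atoms of nonstandard residues: %s",
                    sum(nonstd),
                    paste(unique(at$resid[nonstd]), collapse = ", ")))
  }
  keep <- at$type == "ATOM" & at$resid %in% STANDARD_AA
  if (!any(keep)) stop("parse error: no standard amino-acid ATOM records")
  at <- at[keep, , drop = FALSE]
  xyz_idx <- matrix(rep((which(keep) - 1L) * 3L, each = 3L) + 1:3,
                    ncol = 3L, byrow = TRUE)

  build_model <- function(m) {
    a <- at
    if (n_models > 1L) {
      xyz <- pdb$xyz[m, ]
      a$x <- xyz[xyz_idx[, 1]]
      a$y <- xyz[xyz_idx[, 2]]
      a$z <- xyz[xyz_idx[, 3]]
      if (m > 1L) a$chain <- paste0(a$chain, "-", m)
    }
    a
  }
  at <- do.call(rbind, lapply(seq_len(n_models), build_model))

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- resolve_altloc(at)

  if (mode == "single_chain") {
    if (is.null(chain)) stop("mode = 'single_chain' requires `chain`")
    if (!chain %in% at$chain)
      stop(sprintf("lookup error: chain '%s' not present (have: %s)",
                   chain, paste(sort(unique(at$chain)), collapse = ", ")))
    at <- at[at$chain == chain, , drop = FALSE]
  }

  res <- residue_table(at)
  structure(
    list(atoms = at, residues = res, chains = unique(res$chain),
         provenance = mode, pdb_id = pdb_id),
    class = "enzgrad_structure"
  )
}

# keep, per residue and atom name, the highest-occupancy altloc
# (ties: first in file order)
resolve_altloc <- function(at) {
  if (all(at$alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

residue_table <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resid = at$resid[first],
    stringsAsFactors = FALSE
  )
  ctr <- t(vapply(split(seq_len(nrow(at)), factor(key, levels = key[first])),
                  function(i) residue_center(at[i, , drop = FALSE]),
                  numeric(3)))
  res$x <- ctr[, 1]; res$y <- ctr[, 2]; res$z <- ctr[, 3]
  rownames(res) <- NULL
  res
}

#' Side-chain geometric center of one residue
#'
#' The unweighted mean of the side-chain (non-backbone, non-hydrogen) atom
#' coordinates. For glycine, which has no side chain, the C-alpha position
#' is used. Any other residue whose side-chain atoms are all absent from
#' the record (disordered side chains) also falls back to C-alpha, with a
#' message, so sites are not silently dropped.
#'
#' @param atoms data frame with columns `elety` (atom name), `x`, `y`, `z`,
#'   `resid` and optionally `elesy` (element), for the atoms of one residue.
#' @return numeric length-3 vector (Angstrom).
#' @export
residue_center <- function(atoms) {
  if (nrow(atoms) == 0) stop("center error: residue has no atoms")
  is_h <- if ("elesy" %in% names(atoms))
    !is.na(atoms$elesy) & atoms$elesy %in% c("H", "D")
  else grepl("^[0-9]*[HD]", atoms$elety)
  side <- atoms[!(atoms$elety %in% BACKBONE_ATOMS) & !is_h, , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  resid <- atoms$resid[1]
  if (nrow(side) == 0 && nrow(ca) == 0)
    stop(sprintf("center error: residue %s has neither side-chain atoms nor CA",
                 resid))
  use_ca <- (identical(resid, "GLY") || nrow(side) == 0) && nrow(ca) > 0
  if (use_ca && !identical(resid, "GLY"))
    message(sprintf("residue %s: no side-chain atoms, using CA", resid))
  sel <- if (use_ca) ca else side
  ctr <- c(mean(sel$x), mean(sel$y), mean(sel$z))
  if (any(!is.finite(ctr))) stop("center error: non-finite coordinates")
  ctr
}

#' Residue centers of a structure as a matrix
#'
#' @param structure an `enzgrad_structure`.
#' @return numeric matrix, one row per residue (file order), columns x/y/z.
#' @export
residue_centers <- function(structure) {
  as.matrix(structure$residues[, c("x", "y", "z")])
}

#' Load a catalytic-residue annotation
#'
#' Catalytic residues are supplied as a table with columns `chain` and
#' `residue_number` (an optional `pdb_id` column is filtered on). Every row
#' must resolve to a residue of the target structure. When the structure is
#' a multi-copy biological assembly, an annotation on a chain is propagated
#' to all symmetry copies of that chain (chain `"A"` also marks `"A-2"`,
#' ...), since the copies are chemically identical.
#'
#' @param table a data frame, or character text of a CSV with a header
#'   containing `chain` and `residue_number` columns.
#' @param structure the `enzgrad_structure` the annotation refers to.
#' @return data frame of class `enzgrad_annotation` with columns `chain`,
#'   `residue_number`, and `index` (row index into `structure$residues`).
#' @export
load_catalytic_annotation <- function(table, structure) {
  if (is.character(table))
    table <- read.csv(text = table, stringsAsFactors = FALSE)
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("annotation error: empty catalytic-site table")
  names(table) <- tolower(names(table))
  if (!all(c("chain", "residue_number") %in% names(table)))
    stop("annotation error: need columns `chain`, `residue_number`")
  if ("pdb_id" %in% names(table) &&
      any(table$pdb_id == structure$pdb_id))
    table <- table[table$pdb_id == structure$pdb_id, , drop = FALSE]

  res <- structure$residues
  base_chain <- sub("-[0-9]+$", "", res$chain)
  hits <- lapply(seq_len(nrow(table)), function(i) {
    which(base_chain == table$chain[i] & res$resno == table$residue_number[i])
  })
  bad <- lengths(hits) == 0
  if (any(bad))
    stop("annotation error: unresolvable rows: ",
         paste(sprintf("(%s,%s)", table$chain[bad],
                       table$residue_number[bad]), collapse = " "))
  idx <- sort(unique(unlist(hits)))
  out <- data.frame(chain = res$chain[idx], residue_number = res$resno[idx],
                    index = idx, stringsAsFactors = FALSE)
  class(out) <- c("enzgrad_annotation", "data.frame")
  out
}

#' @export
print.enzgrad_structure <- function(x, ...) {
  cat(sprintf("<enzgrad_structure> %s: %d residues, %d chains (%s), %s\n",
              x$pdb_id, nrow(x$residues), length(x$chains),
              paste(x$chains, collapse = ","), x$provenance))
  invisible(x)
}

#' Minimal two-residue PDB fixture used in examples
#' @return character scalar of PDB text.
#' @export
example_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       5.000   0.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       6.000   0.000   0.000  1.00  0.00           C",
    "TER",
    "END",
    sep = "\n")
}
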