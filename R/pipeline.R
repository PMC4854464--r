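# Orchestration: one-call pipeline over synthetic cohorts or user-supplied
# files, reproduction of dataset-level statistics from a deposited
# per-residue table, TSV writers, and a thin command-line front end.

#' Pipeline run configuration
#'
#' Exactly one input source must be given: `simulate` (a cohort of
#' synthetic enzymes), `table` (a deposited per-residue table for
#' [reproduce_from_table()]), or `pdb` (+ `annotation`, `rates`) for a
#' single real structure.
#'
#' @param out output directory.
#' @param simulate number of synthetic proteins to generate (0 = off).
#' @param table path to a per-residue table (TSV/CSV).
#' @param pdb,annotation,rates paths for the single-structure route.
#' @param mode `"assembly"` or `"single_chain"`; `chain` selects the
#'   chain in single-chain mode.
#' @param chain chain id for single-chain mode.
#' @param interfaces `"keep"` or `"exclude"`.
#' @param seed integer seed for the synthetic route.
#' @param n_sites_range synthetic protein size range.
#' @return list of class `enzgrad_runconfig`.
#' @export
run_config <- function(out, simulate = 0L, table = NULL, pdb = NULL,
                       annotation = NULL, rates = NULL,
                       mode = c("assembly", "single_chain"), chain = NULL,
                       interfaces = c("keep", "exclude"), seed = 1L,
                       n_sites_range = c(100L, 400L)) {
  mode <- match.arg(mode)
  interfaces <- match.arg(interfaces)
  sources <- c(simulate > 0, !is.null(table), !is.null(pdb))
  if (sum(sources) != 1)
    stop("usage error: exactly one input source (simulate / table / pdb)")
  structure(list(out = out, simulate = as.integer(simulate), table = table,
                 pdb = pdb, annotation = annotation, rates = rates,
                 mode = mode, chain = chain, interfaces = interfaces,
                 seed = as.integer(seed), n_sites_range = n_sites_range),
            class = "enzgrad_runconfig")
}

#' Run the full pipeline
#'
#' Produces deterministic TSV outputs in `config$out`: per-residue site
#' tables, per-protein model fits, shell summaries, recovery outcomes and
#' an aggregate report, plus a JSON run manifest. On the `table` route it
#' instead writes the [reproduce_from_table()] statistics.
#'
#' @param config an `enzgrad_runconfig`.
#' @return invisibly, the result bundle (list).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("enzgrad")),
                   seed = config$seed, mode = config$mode,
                   interfaces = config$interfaces)

  if (!is.null(config$table)) {
    rep <- reproduce_from_table(config$table)
    jsonlite::write_json(rep, file.path(config$out, "reproduce.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(reproduce = rep)))
  }

  if (config$simulate > 0) {
    sims <- simulate_cohort(config$simulate, seed = config$seed,
                            n_sites_range = config$n_sites_range)
    tables <- lapply(sims, `[[`, "table")
    bundle <- analyze_tables(tables,
                             centers = lapply(sims, function(s)
                               residue_centers(s$structure)),
                             truth = lapply(sims, function(s)
                               s$annotation$index))
  } else {
    s <- parse_structure(file = config$pdb, mode = config$mode,
                         chain = config$chain,
                         pdb_id = tools::file_path_sans_ext(basename(config$pdb)))
    ann <- if (!is.null(config$annotation))
      load_catalytic_annotation(read.csv(config$annotation,
                                         stringsAsFactors = FALSE), s)
    rts <- if (!is.null(config$rates))
      parse_rates(readLines(config$rates), format = "two_column")
    tab <- build_site_table(s, ann, rts, interfaces = config$interfaces)
    bundle <- analyze_tables(list(tab),
                             centers = list(attr(tab, "centers")),
                             truth = list(if (is.null(ann)) NULL else
                               which(tab$is_catalytic)))
  }

  for (tab in bundle$tables)
    write_site_table(tab, file.path(config$out,
                                    paste0(tab$protein_id[1], ".sites.tsv")))
  write_fits_tsv(bundle$fits, file.path(config$out, "fits.tsv"))
  write.table(bundle$shells[, c("shell", "count", "mean_K")],
              file.path(config$out, "shells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$recovery))
    write.table(bundle$recovery, file.path(config$out, "recovery.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$aggregate,
                       file.path(config$out, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

# shared analysis core: fits, shell summary, recovery, aggregates
analyze_tables <- function(tables, centers = NULL, truth = NULL) {
  fits <- lapply(tables, fit_all_models)
  shells <- shell_summary(tables)
  agg <- aggregate_fits(fits)

  recovery <- NULL
  scores_d <- scores_w <- NULL
  if (!is.null(centers) && !is.null(truth) &&
      !any(vapply(truth, is.null, logical(1)))) {
    rec <- lapply(seq_along(tables), function(i) {
      recover_active_site(centers[[i]], tables[[i]]$K, tables[[i]]$wcn,
                          truth[[i]], tables[[i]]$protein_id[1])
    })
    recovery <- do.call(rbind, lapply(rec, function(r)
      as.data.frame(r)[, c("protein_id", "method", "putative_index",
                           "score", "distance_to_truth", "category")]))
    scores_d <- do.call(rbind, lapply(rec, function(r)
      data.frame(score = attr(r, "scores_optimized_d"),
                 is_catalytic = attr(r, "is_catalytic"))))
    scores_w <- do.call(rbind, lapply(rec, function(r)
      data.frame(score = attr(r, "scores_max_wcn"),
                 is_catalytic = attr(r, "is_catalytic"))))
  }

  aggregate <- list(
    n_proteins = length(tables),
    n_sites = sum(vapply(tables, nrow, 0L)),
    mean_r2 = setNames(as.list(agg$mean_r2$mean_r2), agg$mean_r2$formula),
    frac_within_27.5 = {
      d <- unlist(lapply(tables, `[[`, "d"))
      mean(d[!is.na(d)] <= 27.5)
    },
    mean_catalytic_K = {
      k <- unlist(lapply(tables, function(t) t$K[t$is_catalytic]))
      if (length(k)) mean(k) else NA_real_
    }
  )
  comparison <- NULL
  if (!is.null(recovery)) {
    oa <- recovery[recovery$method == "optimized_d", ]
    ob <- recovery[recovery$method == "max_wcn", ]
    comparison <- compare_methods(oa, ob, scores_d, scores_w)
    aggregate$recovery_optimized_d <- evaluate_recovery(oa)
    aggregate$recovery_max_wcn <- evaluate_recovery(ob)
    aggregate$odds_ratio <- comparison$odds_ratio
    aggregate$fisher_p <- comparison$p_value
    aggregate$auc_optimized_d <- unname(comparison$auc_by_method["a"])
    aggregate$auc_max_wcn <- unname(comparison$auc_by_method["b"])
  }
  list(tables = tables, fits = fits, shells = shells, recovery = recovery,
       comparison = comparison, aggregate = aggregate)
}

#' Write per-protein model fits as TSV
#'
#' Columns `protein_id, formula, r_squared, coef_intercept, coef_d,
#' coef_wcn, coef_rsa` (coefficients absent from a formula are empty).
#'
#' @param fits list of per-protein fit lists ([fit_all_models()] output).
#' @param path output path.
#' @export
write_fits_tsv <- function(fits, path) {
  rows <- do.call(rbind, lapply(unlist(fits, recursive = FALSE),
                                function(f) {
    cf <- f$coefficients
    data.frame(protein_id = f$protein_id, formula = f$formula,
               r_squared = f$r_squared,
               coef_intercept = unname(cf["(Intercept)"]),
               coef_d = unname(cf["d"]), coef_wcn = unname(cf["wcn"]),
               coef_rsa = unname(cf["rsa"]), stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Recompute dataset-level statistics from a deposited per-residue table
#'
#' Takes a per-residue table (one row per residue across a whole dataset,
#' with per-protein identifiers, normalized rates and precomputed WCN,
#' RSA and distance d) and recomputes the headline aggregate statistics:
#' the pooled fraction of residues within 27.5 Angstrom of a catalytic
#' residue, mean per-protein R^2 of the canonical linear models, mean
#' relative rates of catalytic and interface residues, and the number of
#' proteins per active-site-location category.
#'
#' Recognized columns (case-insensitive; aliases in parentheses):
#' `protein_id` (`pdb`, `pdb_id`, `protein`, `id`), `K` (`rate`, `r4s`,
#' `rate4site`), `wcn` (`wcn_sc`, `wcnsc`), `rsa`, `d` (`distance`,
#' `dist`), optional `is_catalytic` (`catalytic`, `cat`; otherwise
#' derived as `d == 0`), optional `is_interface` (`interface`, `int`).
#'
#' @param x data frame or path to a TSV/CSV file.
#' @param refit_formulas formulas to refit per protein.
#' @return list of aggregate statistics (fractions on the 0-1 scale).
#' @export
reproduce_from_table <- function(x, refit_formulas = rate_model_formulas()) {
  if (is.character(x)) {
    if (length(x) != 1 || !nzchar(x) || !file.exists(x))
      stop("per-residue table not found: '", paste(x, collapse = ""), "'")
    first <- readLines(x, n = 1)
    x <- if (grepl("\t", first)) read.delim(x, stringsAsFactors = FALSE)
         else read.csv(x, stringsAsFactors = FALSE)
  }
  nm <- tolower(names(x))
  pick <- function(aliases) {
    hit <- match(aliases, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  cols <- list(
    protein_id = pick(c("protein_id", "pdb", "pdb_id", "protein", "id")),
    K = pick(c("k", "rate", "r4s", "rate4site")),
    wcn = pick(c("wcn", "wcn_sc", "wcnsc")),
    rsa = pick(c("rsa")),
    d = pick(c("d", "distance", "dist"))
  )
  missing <- names(cols)[vapply(cols, is.na, logical(1))]
  if (length(missing) > 0)
    stop("schema mismatch: missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- data.frame(protein_id = as.character(x[[cols$protein_id]]),
                    K = as.numeric(x[[cols$K]]),
                    wcn = as.numeric(x[[cols$wcn]]),
                    rsa = as.numeric(x[[cols$rsa]]),
                    d = as.numeric(x[[cols$d]]),
                    stringsAsFactors = FALSE)
  icat <- pick(c("is_catalytic", "catalytic", "cat"))
  tab$is_catalytic <- if (!is.na(icat)) as.logical(x[[icat]]) else tab$d == 0
  iint <- pick(c("is_interface", "interface", "int"))
  tab$is_interface <- if (!is.na(iint)) as.logical(x[[iint]]) else NA

  per_protein <- split(tab, tab$protein_id)
  # proteins too small for a formula (n < predictors + 2) are left out of
  # that formula's mean rather than aborting the whole reproduction
  r2 <- vapply(refit_formulas, function(f) {
    vapply(per_protein, function(pt) {
      class(pt) <- c("enzgrad_site_table", "data.frame")
      tryCatch(fit_rate_model(pt, f)$r_squared,
               error = function(e) NA_real_)
    }, numeric(1))
  }, numeric(length(per_protein)))
  r2 <- matrix(r2, nrow = length(per_protein),
               dimnames = list(names(per_protein), refit_formulas))
  mean_r2 <- colMeans(r2, na.rm = TRUE)
  mean_r2 <- mean_r2[is.finite(mean_r2)]
  pairs <- list(c("K ~ rsa", "K ~ rsa + d"),
                c("K ~ wcn", "K ~ wcn + d"),
                c("K ~ wcn + rsa", "K ~ wcn + rsa + d"))
  delta <- list()
  for (p in pairs) {
    if (!all(p %in% colnames(r2))) next
    dd <- r2[, p[2]] - r2[, p[1]]
    if (any(is.finite(dd))) delta[[p[1]]] <- mean(dd, na.rm = TRUE)
  }

  lengths <- vapply(per_protein, nrow, 0L)
  cat_rsa <- vapply(per_protein, function(pt) {
    if (any(pt$is_catalytic)) mean(pt$rsa[pt$is_catalytic]) else NA_real_
  }, 0)
  location <- ifelse(is.na(cat_rsa), NA,
                     ifelse(cat_rsa < 0.05, "core",
                            ifelse(cat_rsa < 0.25, "intermediate",
                                   "surface")))

  list(
    n_proteins = length(per_protein),
    n_sites = nrow(tab),
    frac_within_27.5 = mean(tab$d <= 27.5, na.rm = TRUE),
    mean_r2 = as.list(mean_r2),
    mean_catalytic_K = mean(tab$K[tab$is_catalytic]),
    mean_interface_K = if (!any(tab$is_interface %in% TRUE)) NA_real_
                       else mean(tab$K[tab$is_interface %in% TRUE]),
    n_location = as.list(table(location)),
    mean_delta_r2 = if (length(delta)) delta else NULL
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `metrics`, `fit`, `shells`, `recover`,
#' `reproduce`. Flags: `--out DIR`, `--seed N`, `--n N` (cohort size),
#' `--mode assembly|single-chain`, `--chain C`,
#' `--interfaces keep|exclude`, `--table PATH`, `--pdb PATH`,
#' `--annotation PATH`, `--rates PATH`. A thin wrapper script is
#' installed at `system.file("cli", "enzgrad.R", package = "enzgrad")`.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the pipeline result bundle.
#' @export
enzgrad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: enzgrad <simulate|metrics|fit|shells|recover|reproduce> ",
         "[--flags]", call. = FALSE)
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  getf <- function(name, default = NULL)
    if (name %in% names(flags)) flags[[name]] else default
  out <- getf("out", "enzgrad_out")
  seed <- as.integer(getf("seed", "1"))
  mode <- sub("-", "_", getf("mode", "assembly"))
  interfaces <- getf("interfaces", "keep")

  cfg <- switch(cmd,
    simulate = ,
    fit = ,
    shells = ,
    recover = run_config(out, simulate = as.integer(getf("n", "5")),
                         seed = seed, interfaces = interfaces),
    metrics = run_config(out, pdb = getf("pdb"),
                         annotation = getf("annotation"),
                         rates = getf("rates"), mode = mode,
                         chain = getf("chain"), interfaces = interfaces,
                         seed = seed),
    reproduce = run_config(out, table = getf("table"), seed = seed),
    stop("usage error: unknown subcommand '", cmd, "'", call. = FALSE)
  )
  message("enzgrad ", cmd, ": writing to ", out)
  run_pipeline(cfg)
}

parse_cli_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("usage error: unexpected argument '", a, "'", call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("usage error: flag --", key, " needs a value", call. = FALSE)
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}
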