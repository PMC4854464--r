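# Per-protein linear models of rate.
#
# For each protein, relative rate K is regressed on combinations of the
# distance d to the nearest catalytic residue, weighted contact number
# (WCN) and relative solvent accessibility (RSA). Comparing R^2 across
# nested formulas decomposes rate variation into structural (WCN, RSA)
# and functional (d) components.

#' The canonical model formulas
#'
#' All combinations of d, RSA and WCN used in the analysis, in display
#' notation (`K ~ d`, ..., `K ~ wcn + rsa + d`).
#'
#' @return character vector of formula strings.
#' @export
rate_model_formulas <- function() {
  c("K ~ d", "K ~ rsa", "K ~ wcn",
    "K ~ rsa + d", "K ~ wcn + d", "K ~ wcn + rsa",
    "K ~ wcn + rsa + d")
}

#' Fit one linear rate model for one protein
#'
#' Ordinary least squares with intercept, fit to the site table's rows
#' with complete predictor and rate values. A constant response returns
#' `r_squared = 0` with zero slopes by convention; a constant predictor is
#' an error.
#'
#' @param table an `enzgrad_site_table` with a `K` column and the
#'   predictors the formula names.
#' @param formula model formula as a string (see [rate_model_formulas()])
#'   or a `formula`.
#' @return object of class `enzgrad_fit`: list with `protein_id`,
#'   `formula`, `coefficients`, `r_squared`, `residuals`, `fitted`, `n`.
#' @export
fit_rate_model <- function(table, formula) {
  fstr <- if (inherits(formula, "formula"))
    paste(deparse(formula), collapse = " ") else as.character(formula)
  f <- stats::as.formula(fstr)
  preds <- all.vars(f)[-1]
  need <- c("K", preds)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  dat <- as.data.frame(table)[, need, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(preds) + 2)
    stop("too few sites to fit ", fstr)
  const <- preds[vapply(preds, function(p) var(dat[[p]]) == 0, logical(1))]
  if (length(const) > 0)
    stop("rank error: constant predictor(s): ", paste(const, collapse = ", "))

  pid <- if ("protein_id" %in% names(table)) table$protein_id[1] else "protein"
  if (var(dat$K) == 0) {
    cf <- c(`(Intercept)` = mean(dat$K), setNames(rep(0, length(preds)), preds))
    out <- list(protein_id = pid, formula = fstr, coefficients = cf,
                r_squared = 0, residuals = rep(0, nrow(dat)),
                fitted = rep(mean(dat$K), nrow(dat)), n = nrow(dat))
    class(out) <- "enzgrad_fit"
    return(out)
  }
  m <- lm(f, data = dat)
  ss_res <- sum(m$residuals^2)
  ss_tot <- sum((dat$K - mean(dat$K))^2)
  out <- list(protein_id = pid, formula = fstr, coefficients = coef(m),
              r_squared = 1 - ss_res / ss_tot,
              residuals = unname(m$residuals),
              fitted = unname(m$fitted.values), n = nrow(dat),
              std_errors = suppressWarnings(
                summary(m)$coefficients[, "Std. Error"]))
  class(out) <- "enzgrad_fit"
  out
}

#' Fit all canonical formulas for one protein
#'
#' @param table an `enzgrad_site_table`.
#' @param formulas formulas to fit, default [rate_model_formulas()].
#' @return named list of `enzgrad_fit` objects, keyed by formula.
#' @export
fit_all_models <- function(table, formulas = rate_model_formulas()) {
  setNames(lapply(formulas, function(f) fit_rate_model(table, f)), formulas)
}

#' Mean model residual per distance shell
#'
#' Mean of (observed - predicted) rate within each shell. A structural
#' model that misses the conservation gradient overestimates rates near
#' the active site, giving negative mean residuals in the inner shells.
#'
#' @param fit an `enzgrad_fit` produced from `table`.
#' @param table the `enzgrad_site_table` the fit used (must have `shell`).
#' @return data frame with `shell`, `n`, `mean_residual`.
#' @export
residuals_by_shell <- function(fit, table) {
  if (!"shell" %in% names(table) || all(is.na(table$shell)))
    stop("site table lacks shell assignments")
  preds <- all.vars(stats::as.formula(fit$formula))[-1]
  dat <- as.data.frame(table)
  cc <- complete.cases(dat[, c("K", preds), drop = FALSE])
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) != length(fit$residuals))
    stop("fit was not produced from this table")
  sh <- sort(unique(dat$shell))
  f <- factor(dat$shell, levels = sh)
  data.frame(
    shell = sh,
    n = as.integer(table(f)),
    mean_residual = as.numeric(tapply(fit$residuals, f, mean))
  )
}

#' Classify a protein by active-site location and size
#'
#' Location comes from the mean RSA of the catalytic residues: core
#' (`< 0.05`), intermediate (`[0.05, 0.25)`) or surface (`>= 0.25`).
#' Size class comes from tertiles of the dataset's length distribution,
#' ties assigned to the lower class.
#'
#' @param table an `enzgrad_site_table` with at least one catalytic
#'   residue.
#' @param dataset_lengths integer vector of site counts of all proteins in
#'   the dataset (used for the tertile boundaries).
#' @return list with `location`, `size_class`, `mean_catalytic_rsa`,
#'   `n_sites`.
#' @export
classify_protein <- function(table, dataset_lengths) {
  cat_rsa <- table$rsa[table$is_catalytic]
  if (length(cat_rsa) == 0) stop("no catalytic residues in table")
  m <- mean(cat_rsa)
  location <- if (m < 0.05) "core" else if (m < 0.25) "intermediate"
              else "surface"
  n <- nrow(table)
  q <- quantile(dataset_lengths, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  size_class <- if (n <= q[1]) "small" else if (n <= q[2]) "medium"
                else "large"
  list(location = location, size_class = size_class,
       mean_catalytic_rsa = m, n_sites = n)
}

#' Aggregate per-protein fits
#'
#' Per-formula mean R^2 across proteins (unweighted: one protein, one
#' vote), the full R^2 distributions, and the gain from adding distance
#' to each structural formula,
#' `delta R^2 = R^2(structural + d) - R^2(structural)`.
#'
#' @param fits list of per-protein fit lists as returned by
#'   [fit_all_models()] (one element per protein), or a flat list of
#'   `enzgrad_fit` objects.
#' @param labels optional list of [classify_protein()] labels, one per
#'   protein, to additionally aggregate within location / size groups.
#' @return list with `mean_r2` (data frame formula x mean R^2 x n),
#'   `r2` (long data frame protein x formula x R^2), `delta_r2` (per
#'   protein, per structural formula), and `by_group` when labels given.
#' @export
aggregate_fits <- function(fits, labels = NULL) {
  if (length(fits) > 0 && inherits(fits[[1]], "enzgrad_fit"))
    fits <- split(fits, vapply(fits, `[[`, "", "protein_id"))
  long <- do.call(rbind, lapply(fits, function(pf) {
    data.frame(protein_id = vapply(pf, `[[`, "", "protein_id"),
               formula = vapply(pf, `[[`, "", "formula"),
               r_squared = vapply(pf, `[[`, 0, "r_squared"),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  fl <- unique(long$formula)
  per_protein <- table(long$protein_id)
  if (length(unique(per_protein)) > 1 || any(per_protein != length(fl)))
    stop("missing formula for some protein")
  mean_r2 <- data.frame(
    formula = fl,
    mean_r2 = vapply(fl, function(f)
      mean(long$r_squared[long$formula == f]), 0),
    n = vapply(fl, function(f) sum(long$formula == f), 0L),
    row.names = NULL
  )
  pairs <- list(c("K ~ rsa", "K ~ rsa + d"),
                c("K ~ wcn", "K ~ wcn + d"),
                c("K ~ wcn + rsa", "K ~ wcn + rsa + d"))
  delta <- do.call(rbind, lapply(pairs, function(p) {
    if (!all(p %in% fl)) return(NULL)
    base <- long[long$formula == p[1], ]
    plus <- long[long$formula == p[2], ]
    m <- match(base$protein_id, plus$protein_id)
    if (any(is.na(m))) stop("missing formula for some protein")
    data.frame(protein_id = base$protein_id, structural = p[1],
               delta_r2 = plus$r_squared[m] - base$r_squared,
               stringsAsFactors = FALSE)
  }))
  out <- list(mean_r2 = mean_r2, r2 = long, delta_r2 = delta)
  if (!is.null(labels)) {
    pid <- unique(long$protein_id)
    if (length(labels) != length(pid))
      stop("one label per protein required")
    lab <- data.frame(
      protein_id = pid,
      location = vapply(labels, `[[`, "", "location"),
      size_class = vapply(labels, `[[`, "", "size_class"),
      stringsAsFactors = FALSE
    )
    merged <- merge(long, lab, by = "protein_id")
    agg <- stats::aggregate(r_squared ~ formula + location + size_class,
                            data = merged, FUN = mean)
    names(agg)[names(agg) == "r_squared"] <- "mean_r2"
    out$by_group <- agg
  }
  out
}
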