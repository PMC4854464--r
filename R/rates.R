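# Site-specific evolutionary rates: parsing and mean-1 normalization.
#
# Rates come from Rate4Site output or plain two-column tables, aligned to
# structure residues by order. Relative rates K are scaled so the protein
# mean is exactly 1; K < 1 means conserved, K > 1 variable.

#' Parse site-specific rates
#'
#' Two formats are supported. `rate4site`: "#" header/footer lines, then
#' whitespace-separated columns POS, SEQ, SCORE (further columns ignored).
#' `two_column`: whitespace-separated `position rate` lines. Positions
#' must be consecutive from 1, so a silent misalignment with the
#' structure is impossible.
#'
#' @param text character scalar or vector of lines.
#' @param format `"rate4site"` or `"two_column"`.
#' @return numeric vector of raw scores in position order.
#' @export
parse_rates <- function(text, format = c("rate4site", "two_column")) {
  format <- match.arg(format)
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (format == "rate4site") lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) stop("format error: no data lines")

  pos <- numeric(length(lines))
  score <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    ok <- if (format == "two_column") length(f) >= 2 else length(f) >= 3
    p <- suppressWarnings(as.numeric(f[1]))
    s <- suppressWarnings(as.numeric(f[if (format == "two_column") 2 else 3]))
    if (!ok || is.na(p) || is.na(s))
      stop(sprintf("format error at line %d: '%s'", i, lines[i]))
    pos[i] <- p
    score[i] <- s
  }
  if (!identical(as.integer(pos), seq_along(pos)))
    stop("gap error: positions are not consecutive from 1")
  score
}

#' Normalize rates to a per-protein mean of 1
#'
#' @param raw numeric vector of raw site-specific rates (negative values,
#'   possible under some estimators, are accepted with a warning).
#' @param protein_id identifier stored in the result.
#' @return object of class `enzgrad_rates`: list with `protein_id`, `raw`
#'   and `K` (normalized; `mean(K) == 1`).
#' @export
normalize_rates <- function(raw, protein_id = "protein") {
  if (length(raw) == 0) stop("no rates")
  if (any(!is.finite(raw))) stop("non-finite rates")
  m <- mean(raw)
  if (m == 0) stop("normalization error: rates have zero mean")
  if (any(raw < 0))
    warning(sprintf("%d negative raw rates", sum(raw < 0)))
  structure(list(protein_id = protein_id, raw = raw, K = raw / m),
            class = "enzgrad_rates")
}
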