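# Distance shells: 5-Angstrom-wide bands around the catalytic site.
# Shell 0 is [0, 2.5] (the catalytic residues and immediate overlaps);
# shell k >= 1 spans (5k - 2.5, 5k + 2.5], so 7.5 A is the outer edge of
# shell 1 and 27.5 A the outer edge of shell 5. 5 A is roughly the minimum
# separation of two side chains, so shell 1 holds direct contacts.

#' Assign distances to 5 Angstrom shells
#'
#' @param d numeric vector of distances (Angstrom), all `>= 0` (`NA`
#'   passes through).
#' @return integer shell indices; `d = 0` gives shell 0, `d = 27.5` gives
#'   shell 5.
#' @export
assign_shell <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("negative distance")
  as.integer(pmax(0, ceiling((d - 2.5) / 5)))
}

#' Per-shell rate summary
#'
#' Counts and mean relative rates per distance shell, pooled across one or
#' several site tables (pooling is residue-weighted: all residues are
#' thrown together before averaging). With `by = "interface_distance"`,
#' shells are recomputed from each residue's distance to the nearest
#' interface residue instead of the nearest catalytic residue.
#'
#' @param tables an `enzgrad_site_table` or a list of them.
#' @param by `"catalytic_distance"` (default) or `"interface_distance"`.
#' @return data frame with columns `shell`, `count`, `mean_K`, and a
#'   `rates` list-column of per-shell rate values. Empty shells are
#'   absent, not zero.
#' @export
shell_summary <- function(tables,
                          by = c("catalytic_distance", "interface_distance")) {
  by <- match.arg(by)
  if (inherits(tables, "enzgrad_site_table")) tables <- list(tables)
  if (length(tables) == 0) stop("no tables")
  pieces <- lapply(tables, function(tab) {
    if (nrow(tab) == 0) stop("empty site table")
    if (by == "interface_distance") {
      if (!any(tab$is_interface))
        stop("interface_distance requested but table has no interface residues")
      d <- interface_distance(tab)
      data.frame(shell = assign_shell(d), K = tab$K)
    } else {
      data.frame(shell = tab$shell, K = tab$K)
    }
  })
  all <- do.call(rbind, pieces)
  all <- all[!is.na(all$shell), , drop = FALSE]
  sh <- sort(unique(all$shell))
  out <- data.frame(
    shell = sh,
    count = as.integer(table(factor(all$shell, levels = sh))),
    mean_K = as.numeric(tapply(all$K, factor(all$shell, levels = sh), mean))
  )
  out$rates <- lapply(sh, function(s) all$K[all$shell == s])
  out
}

# distance to nearest interface residue, from the distance geometry
# implicit in the site table is not available; recompute from centers if
# attached, else approximate via d is impossible -- so interface-shell
# summaries require center coordinates stored by build_site_table.
interface_distance <- function(tab) {
  ctr <- attr(tab, "centers")
  if (is.null(ctr)) {
    stop("interface distances need center coordinates; build the table ",
         "with build_site_table() (centers attribute missing)")
  }
  idx <- which(tab$is_interface)
  distance_to_catalytic(ctr, idx)
}

#' Binned-mean rate smoother
#'
#' A deterministic stand-in for scatterplot smoothing of rate against
#' distance: mean rate in half-open distance bins `[m*w, (m+1)*w)`, with
#' the standard error of the mean where a bin has at least two points.
#'
#' @param d numeric distances (Angstrom).
#' @param K numeric rates, same length.
#' @param bin_width bin width w (Angstrom), default 2.5.
#' @return data frame with `bin_center`, `n`, `mean_K`, `se` (NA for
#'   single-point bins). Empty bins are absent.
#' @export
binned_smooth <- function(d, K, bin_width = 2.5) {
  if (length(d) != length(K)) stop("`d` and `K` lengths differ")
  if (bin_width <= 0) stop("bin_width must be positive")
  bin <- floor(d / bin_width)
  bs <- sort(unique(bin))
  f <- factor(bin, levels = bs)
  n <- as.integer(table(f))
  out <- data.frame(
    bin_center = (bs + 0.5) * bin_width,
    n = n,
    mean_K = as.numeric(tapply(K, f, mean)),
    se = as.numeric(tapply(K, f, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_))
  )
  out
}
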