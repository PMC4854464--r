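# Fixture builders and independent oracles used across the suite.

# one PDB ATOM line at the standard column positions
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, bfac = 0, element = NULL, alt = "",
                          record = "ATOM") {
  if (is.null(element))
    element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d  %-3s%1s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, x, y, z,
          occ, bfac, element)
}

# a small PDB text: residues given as list(list(resid, chain, resno,
# atoms = list(c(name, x, y, z))))
make_pdb <- function(residues, models = NULL) {
  serial <- 0
  render <- function(res, shift = c(0, 0, 0)) {
    unlist(lapply(res, function(r) {
      vapply(r$atoms, function(a) {
        serial <<- serial + 1
        pdb_atom_line(serial, a[[1]], r$resid, r$chain, r$resno,
                      as.numeric(a[[2]]) + shift[1],
                      as.numeric(a[[3]]) + shift[2],
                      as.numeric(a[[4]]) + shift[3])
      }, character(1))
    }))
  }
  if (is.null(models)) {
    paste(c(render(residues), "TER", "END"), collapse = "\n")
  } else {
    body <- unlist(lapply(seq_len(models), function(m) {
      c(sprintf("MODEL     %4d", m),
        render(residues, shift = c(50 * (m - 1), 0, 0)), "TER", "ENDMDL")
    }))
    paste(c(body, "END"), collapse = "\n")
  }
}

# a simple 3-residue protein fixture (ALA with CB side chains)
three_res_pdb <- function() {
  make_pdb(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = list(list("N", 0, 0, 0), list("CA", 1, 0, 0),
                      list("CB", 2, 0, 0))),
    list(resid = "ALA", chain = "A", resno = 2,
         atoms = list(list("CA", 7, 0, 0), list("CB", 8, 0, 0))),
    list(resid = "GLY", chain = "A", resno = 3,
         atoms = list(list("N", 11, 0, 0), list("CA", 12, 0, 0)))
  ))
}

# brute-force WCN: explicit double loop over pairs
wcn_oracle <- function(centers) {
  n <- nrow(centers)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out[i] <- out[i] + 1 / sum((centers[i, ] - centers[j, ])^2)
    }
  }
  out
}

# OLS via explicit normal equations
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- as.vector(X1 %*% beta)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(beta = as.vector(beta), r2 = r2)
}

# two-sided Fisher exact p by full hypergeometric enumeration of tables
# with the observed margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k)
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1)),
    numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by all-pairs concordance count (ties worth 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# minimal handmade site table for unit tests
toy_site_table <- function(K, shell = NULL, d = NULL, rsa = NULL,
                           wcn = NULL, is_catalytic = NULL,
                           is_interface = NULL, centers = NULL,
                           protein_id = "toy") {
  n <- length(K)
  tab <- data.frame(
    protein_id = protein_id, chain = "A", residue_number = seq_len(n),
    residue_type = "ALA", K = K,
    wcn = if (is.null(wcn)) rep(1, n) else wcn,
    asa = 0,
    rsa = if (is.null(rsa)) rep(0.5, n) else rsa,
    d = if (is.null(d)) rep(NA_real_, n) else d,
    shell = if (is.null(shell)) rep(NA_integer_, n) else shell,
    is_catalytic = if (is.null(is_catalytic)) rep(FALSE, n) else is_catalytic,
    is_interface = if (is.null(is_interface)) rep(FALSE, n) else is_interface,
    stringsAsFactors = FALSE
  )
  if (!is.null(centers)) attr(tab, "centers") <- centers
  class(tab) <- c("enzgrad_site_table", "data.frame")
  tab
}

quiet_sim <- function(...) suppressMessages(simulate_enzyme(...))
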