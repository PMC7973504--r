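# Shared builders for small in-code fixtures.

# A toy protein-groups data.frame with controllable flags and LFQ columns.
toyProteinGroups <- function(n = 10, nReverse = 0, nContaminant = 0,
                             nSiteOnly = 0, samples = c("UNT_1", "UNT_2",
                                                        "FAC_1", "FAC_2"),
                             seed = 1) {
  set.seed(seed)
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = sprintf("P%03d", seq_len(n)),
    `Gene names` = sprintf("G%03d", seq_len(n)),
    Reverse = "", `Potential contaminant` = "",
    `Only identified by site` = "")
  flagged <- seq_len(nReverse + nContaminant + nSiteOnly)
  if (nReverse) df$Reverse[flagged[seq_len(nReverse)]] <- "+"
  if (nContaminant)
    df[["Potential contaminant"]][
      flagged[nReverse + seq_len(nContaminant)]] <- "+"
  if (nSiteOnly)
    df[["Only identified by site"]][
      flagged[nReverse + nContaminant + seq_len(nSiteOnly)]] <- "+"
  for (s in samples)
    df[[paste("LFQ intensity", s)]] <- round(2^rnorm(n, 25, 1), 3)
  df
}

# Textbook Welch formulas, coded independently of the package route.
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Independent Benjamini-Hochberg step-up.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
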