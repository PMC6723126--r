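# construct an fc_profiles object directly from matrices (for call-level tests)
make_profiles <- function(log2fc, raw_p, design, layer = "transcript",
                          adj_p = NULL) {
  structure(list(log2fc = log2fc, raw_p = raw_p, adj_p = adj_p,
                 n_obs = NULL, layer = layer, design = design),
            class = "fc_profiles")
}

# matrix of one value per condition replicated over columns of a sample table
cond_matrix <- function(values, design, layer, ids = names(values)) {
  st <- sample_table(design, layer)
  conds <- design_conditions(design, layer)$condition
  out <- do.call(rbind, lapply(seq_along(ids), function(i)
    values[[i]][match(st$condition, conds)]))
  dimnames(out) <- list(ids, st$sample)
  out
}

# independent brute-force Pearson correlation (oracle for grid tests)
pearson_brute <- function(x, y) {
  n <- length(x)
  num <- sum((x - sum(x) / n) * (y - sum(y) / n))
  den <- sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
  num / den
}

# independent step-up BH oracle
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
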