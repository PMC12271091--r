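# Shared fixtures, all built in code at test time.

# wrap an S matrix (and optional V) as an sv_matrices object
make_sv <- function(s, v = NULL, traits = rownames(s)) {
  if (is.null(traits)) traits <- paste0("y", seq_len(nrow(s)))
  dimnames(s) <- list(traits, traits)
  nv <- nrow(s) * (nrow(s) + 1) / 2
  if (is.null(v)) v <- diag(nv) * 1e-4
  structure(list(traits = traits, S = s, V = v, n_blocks = NA_integer_,
                 smoothed = TRUE),
            class = "sv_matrices")
}

# write a sumstats_table-shaped data.frame to a temp file in a given dialect
write_sumstats_fixture <- function(df, headers = c("SNP", "A1", "A2", "Z", "N"),
                                   path = tempfile(fileext = ".tsv")) {
  write.table(setNames(df, headers), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# brute-force all-pairs LD scores (the independent oracle for ld_scores)
brute_ld_scores <- function(genotypes, window) {
  m <- nrow(genotypes); n <- ncol(genotypes)
  l <- numeric(m)
  for (j in seq_len(m)) {
    acc <- 1  # self term
    for (k in seq_len(m)) {
      if (k == j || abs(k - j) > window) next
      r <- suppressWarnings(cor(genotypes[j, ], genotypes[k, ]))
      if (is.na(r)) r <- 0
      acc <- acc + (r^2 - (1 - r^2) / (n - 2))
    }
    l[j] <- max(acc, 0)
  }
  l
}

# tiny multivariate normal sampler for Monte Carlo oracles
MASS_free_mvrnorm <- function(n, mu, sigma) {
  l <- t(chol(sigma))
  t(mu + l %*% matrix(rnorm(n * length(mu)), length(mu)))
}

# a small non-trivial harmonized panel built directly (bypasses file IO)
direct_panel <- function(arch, ld) harmonize(simulate_sumstats_direct(arch, ld))
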