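# shared fixtures built in code

# a consistent 3x3 judgment matrix with known weights (4/7, 2/7, 1/7)
consistent3 <- function() {
  judgment_matrix(matrix(c(1, 2, 4,
                           1/2, 1, 2,
                           1/4, 1/2, 1), 3, byrow = TRUE),
                  labels = c("a", "b", "c"))
}

# a deliberately inconsistent 3x3 reciprocal matrix
inconsistent3 <- function() {
  suppressWarnings(judgment_matrix(matrix(c(1, 2, 1/2,
                                            1/2, 1, 4,
                                            2, 1/4, 1), 3, byrow = TRUE)))
}

# random positive weights of length n under a fixed seed
rand_weights <- function(n, seed) {
  w <- landsec:::with_seed(seed, stats::runif(n, 0.05, 1))
  weight_vector(w / sum(w), labels = paste0("c", seq_len(n)))
}

# dense-eigendecomposition oracle for lambda_max and the principal vector
eigen_oracle <- function(m) {
  ev <- eigen(unclass(m))
  i <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, i])
  v <- abs(v) / sum(abs(v))
  list(lambda_max = Re(ev$values[i]), weights = v)
}

# small raw panel CSV on disk for reader tests
write_tiny_panel_csv <- function(path, registry = default_registry(),
                                 years = 2004:2006, tweak = identity) {
  set.seed(42)
  vals <- matrix(stats::runif(length(years) * nrow(registry), 1, 100),
                 nrow = length(years))
  colnames(vals) <- registry$id
  df <- tweak(data.frame(year = years, vals, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
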