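# Independent oracles, deliberately on different code paths from the package.

# Classic constant-n Fleiss' kappa, textbook form (uses the sum-of-squares
# identity rather than the per-subject pair counts the package uses).
classic_fleiss_kappa <- function(counts) {
  N <- nrow(counts)
  n <- unique(rowSums(counts))
  stopifnot(length(n) == 1)
  p_j <- colSums(counts) / (N * n)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  P_bar <- sum(P_i) / N
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

# Random rating matrix with mixed raters-per-subject (n_i in 2..n_max).
random_rating_matrix <- function(seed, n_subjects_max = 50, k_max = 4,
                                 n_max = 8) {
  withr::with_seed(seed, {
    N <- sample(2:n_subjects_max, 1)
    k <- sample(2:k_max, 1)
    counts <- t(vapply(seq_len(N), function(i) {
      n_i <- sample(2:n_max, 1)
      tabulate(sample.int(k, n_i, replace = TRUE), nbins = k)
    }, integer(k)))
    rating_matrix(counts, indicator_id = "synthetic")
  })
}

# Brute-force composite-index evaluator: recomputes the herd ASR-WI from raw
# records without the domain_score intermediate (consensus -> herd mean ->
# one flat weighted sum over all 16 index members).
brute_force_asrwi <- function(records, registry = load_registry()) {
  ind <- registry$indicators
  members <- ind[!is.na(ind$index_weight), ]
  dw <- c(behaviour_mental = 0.20, environment = 0.30,
          nutrition = 0.20, health = 0.30)
  total <- 0
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]
    rec <- records[records$indicator_id == id, ]
    cons <- vapply(split(rec$score, rec$animal_id), function(s) {
      floor(stats::median(s))
    }, numeric(1))
    herd_mean <- mean(cons)
    total <- total + dw[[members$domain[i]]] * members$index_weight[i] *
      herd_mean / members$scale_max[i] * 100
  }
  total
}

# Tiny valid sheet written to a temp CSV for I/O tests.
write_fixture_sheet <- function(rows, path = withr::local_tempfile(
                                  fileext = ".csv",
                                  .local_envir = parent.frame())) {
  header <- "animal_id,species,assessor_id,indicator_id,score"
  writeLines(c(header, rows), path)
  path
}
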