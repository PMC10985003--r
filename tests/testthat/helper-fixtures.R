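# hand-built manifest: 5 probes, 2 transcripts, distances chosen to probe the
# 1500-bp window boundary from both sides
tiny_manifest <- function() {
  tibble::tibble(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    chrom = "chr1",
    pos = c(10000L, 11500L, 11501L, 20100L, 21600L),
    strand = c("+", "+", "+", "-", "-"),
    transcript_id = c("T1", "T1", "T1", "T2", "T2"),
    tss_pos = c(10000L, 10000L, 10000L, 20000L, 20000L),
    region_tag = c("TSS200", "Body", "Body", "1stExon", "Body"),
    gene = c("GA", "GA", "GA", "GB", "GB")
  )
}

# beta matrix with named dims filled from a generating function
beta_fixture <- function(probe_ids, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(length(probe_ids) * n_samples), length(probe_ids), n_samples,
              dimnames = list(probe_ids, sprintf("S%02d", seq_len(n_samples))))
  m
}

# random binary knowledge matrix with guaranteed nonzero rows/cols
random_knowledge <- function(n_features, n_sets, density = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    C <- matrix(rbinom(n_features * n_sets, 1, density), n_features, n_sets,
                dimnames = list(paste0("f", seq_len(n_features)),
                                paste0("set", seq_len(n_sets))))
    if (all(rowSums(C) > 0) && all(colSums(C) > 0)) return(C)
  }
}

# exactly realizable factorization instance D = (C Utrue) Btrue
realizable_instance <- function(n_features = 40, n_sets = 8, k = 3,
                                n_samples = 30, seed = 3) {
  set.seed(seed)
  C <- random_knowledge(n_features, n_sets, seed = seed)
  U <- matrix(0, n_sets, k)
  for (j in seq_len(k)) U[sample(n_sets, 2), j] <- runif(2, 0.5, 1.5)
  Z <- C %*% U
  B <- matrix(rnorm(k * n_samples), k, n_samples)
  D <- Z %*% B
  rownames(D) <- rownames(C)
  list(D = D, C = C, U = U, Z = Z, B = B)
}

# the default planted fixture used across solver tests
default_fixture <- function() {
  mf <- simulate_manifest(120, 1, 5, seed = 7)
  simulate_plier_dataset(mf, n_sets = 12, k = 6, n_samples = 80,
                         noise_sd = 0.3, seed = 17)
}

# Hungarian-matched absolute correlations between recovered and planted columns
matched_abs_cor <- function(A, B) {
  cc <- abs(stats::cor(A, B))
  perm <- clue::solve_LSAP(cc, maximum = TRUE)
  cc[cbind(seq_len(nrow(cc)), perm)]
}
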