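#' Simulate a probe manifest
#'
#' Lays out synthetic genes along chromosomes (cycling chr1..chr5), with
#' `transcripts_per_gene` transcripts per gene on alternating strands and
#' `probes_per_transcript` probes placed uniformly within +/- 1500 bp of each
#' transcript's TSS. Region tags follow the array convention relative to the
#' strand-aware TSS: upstream within 200 bp is `TSS200`, upstream within
#' 1500 bp `TSS1500`, downstream within 300 bp `1stExon`, else `Body`.
#' Deterministic per seed.
#'
#' @param n_genes,transcripts_per_gene,probes_per_transcript counts (>= 1).
#' @param seed integer RNG seed.
#' @param window_bp probe placement half-width; default 1500.
#' @return manifest tibble (see [read_manifest()]) including a `gene` column.
#' @export
simulate_manifest <- function(n_genes, transcripts_per_gene = 1L,
                              probes_per_transcript = 5L, seed = 1L,
                              window_bp = 1500L) {
  stopifnot(n_genes >= 1, transcripts_per_gene >= 1, probes_per_transcript >= 1)
  set.seed(seed)
  rows <- list()
  probe_counter <- 0L
  tx_counter <- 0L
  for (g in seq_len(n_genes)) {
    gene <- sprintf("G%04d", g)
    chrom <- paste0("chr", ((g - 1L) %% 5L) + 1L)
    gene_base <- 100000L + ((g - 1L) %/% 5L) * 50000L
    for (t in seq_len(transcripts_per_gene)) {
      tx_counter <- tx_counter + 1L
      tss <- gene_base + (t - 1L) * 8000L
      strand <- if (tx_counter %% 2L == 1L) "+" else "-"
      offs <- sample(seq(-window_bp, window_bp), probes_per_transcript, replace = TRUE)
      pos <- tss + offs
      # strand-aware signed distance: negative = upstream
      d <- if (strand == "+") pos - tss else tss - pos
      tag <- dplyr::case_when(d <= 0 & d >= -200 ~ "TSS200",
                              d < -200 ~ "TSS1500",
                              d <= 300 ~ "1stExon",
                              TRUE ~ "Body")
      rows[[tx_counter]] <- tibble(
        probe_id = sprintf("cg%08d", probe_counter + seq_len(probes_per_transcript)),
        chrom = chrom, pos = as.integer(pos), strand = strand,
        transcript_id = paste0(gene, ".T", t), tss_pos = as.integer(tss),
        region_tag = tag, gene = gene
      )
      probe_counter <- probe_counter + probes_per_transcript
    }
  }
  validate_manifest(dplyr::bind_rows(rows))
}

#' Simulate a planted factorization dataset
#'
#' Inverts the analysis pipeline: a sparse non-negative gene-set weight
#' matrix `Utrue` is drawn; the planted gene-level latent matrix is
#' `Ztrue = C_gene Utrue + half-normal noise`; sample loadings `Btrue` carry
#' group-structured column means; the gene signal is
#' `G = Ztrue Btrue + N(0, noise_sd)`; and probe betas arise through an
#' inverse-logit link of the per-gene standardized signal with per-probe
#' offsets, so probes of one gene are correlated and PCA compression
#' recovers the gene signal up to an affine transform.
#'
#' @param manifest from [simulate_manifest()] (its `gene` column defines the
#'   gene universe).
#' @param n_sets number of gene sets; each samples 12-20 genes.
#' @param k number of planted latent variables (`k <= n_sets`).
#' @param n_samples samples to draw.
#' @param noise_sd Gaussian noise SD on the gene signal; default 0.3.
#' @param u_density fraction of sets active per latent variable; default 0.25.
#' @param seed integer RNG seed.
#' @param n_groups planted sample groups (balanced); default 2.
#' @param link_slope,probe_offset_sd inverse-logit link slope (1.5) and
#'   per-probe offset SD (0.5); chosen so beta mass sits mostly in
#'   `[0.05, 0.95]`.
#' @return list: `beta` (probes x samples), `gene_signal` (genes x samples),
#'   `collection` (gene-set tibble as from [read_gmt()]), `manifest`,
#'   `groups` (factor), and `truth`
#'   (`Ztrue`, `Utrue`, `Btrue`, `C_gene`, `noise_sd`, `seed`).
#' @export
simulate_plier_dataset <- function(manifest, n_sets = 12L, k = 6L,
                                   n_samples = 80L, noise_sd = 0.3,
                                   u_density = 0.25, seed = 17L,
                                   n_groups = 2L, link_slope = 1.5,
                                   probe_offset_sd = 0.5) {
  stopifnot(k <= n_sets, u_density > 0, u_density <= 1, n_samples >= 2)
  manifest <- validate_manifest(manifest)
  set.seed(seed)
  genes <- unique(manifest$gene)
  n_genes <- length(genes)

  set_sizes <- sample(seq(min(12L, n_genes), min(20L, n_genes)), n_sets, replace = TRUE)
  sets <- lapply(set_sizes, function(s) sort(sample(genes, s)))
  collection <- tibble(set_name = sprintf("SET%02d", seq_len(n_sets)),
                       source = "synthetic", genes = sets)
  C_gene <- vapply(sets, function(g) as.numeric(genes %in% g), numeric(n_genes))
  dimnames(C_gene) <- list(genes, collection$set_name)

  n_active <- max(1L, round(u_density * n_sets))
  Utrue <- matrix(0, n_sets, k, dimnames = list(collection$set_name,
                                                paste0("LV", seq_len(k))))
  # supports with bounded pairwise overlap: planted LVs must stay mutually
  # distinguishable for the fixture to define a well-posed recovery problem
  max_overlap <- max(0L, n_active - 2L)
  supports <- list()
  for (j in seq_len(k)) {
    best <- NULL; best_ov <- Inf
    for (try in 1:50) {
      s <- sample(n_sets, n_active)
      ov <- if (length(supports)) max(vapply(supports, function(p)
        length(intersect(p, s)), integer(1))) else 0L
      if (ov < best_ov) { best <- s; best_ov <- ov }
      if (ov <= max_overlap) break
    }
    supports[[j]] <- best
    Utrue[best, j] <- runif(n_active, 0.5, 1.5)
  }
  Ztrue <- C_gene %*% Utrue + abs(matrix(rnorm(n_genes * k, sd = 0.1), n_genes, k))

  groups <- factor(rep(seq_len(n_groups), length.out = n_samples))
  mu <- matrix(rnorm(k * n_groups), k, n_groups)
  Btrue <- mu[, as.integer(groups), drop = FALSE] +
    matrix(rnorm(k * n_samples, sd = 0.5), k, n_samples)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  dimnames(Btrue) <- list(paste0("LV", seq_len(k)), sample_ids)

  G <- Ztrue %*% Btrue + matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                                n_genes, n_samples)
  dimnames(G) <- list(genes, sample_ids)

  # probe betas: logistic link of the per-gene standardized signal
  Gs <- t(scale(t(G)))
  Gs[is.nan(Gs)] <- 0
  offsets <- rnorm(nrow(manifest), sd = probe_offset_sd)
  beta <- plogis(link_slope * Gs[manifest$gene, , drop = FALSE] + offsets)
  rownames(beta) <- manifest$probe_id

  list(beta = beta, gene_signal = G, collection = collection,
       manifest = manifest, groups = groups,
       truth = list(Ztrue = Ztrue, Utrue = Utrue, Btrue = Btrue,
                    C_gene = C_gene, noise_sd = noise_sd, seed = seed))
}

#' Simulate two-group survival data
#'
#' Exponential event times with the second group's hazard multiplied by
#' `hazard_ratio`, and independent exponential censoring calibrated so that
#' `censor_rate` is the expected censored fraction in the baseline group
#' (`censor_rate = 0` observes every event).
#'
#' @param groups either a vector of group labels (one per subject) or a
#'   length-2 integer vector of group sizes.
#' @param hazard_ratio hazard multiplier for group 2 vs group 1 (> 0).
#' @param censor_rate expected censored fraction under the baseline hazard,
#'   in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param baseline_hazard group-1 event hazard; default 1.
#' @return tibble: `sample_id`, `time`, `event` (1 = event), `group`.
#' @export
simulate_survival <- function(groups, hazard_ratio = 1, censor_rate = 0,
                              seed = 1L, baseline_hazard = 1) {
  stopifnot(hazard_ratio > 0, censor_rate >= 0, censor_rate < 1)
  if (is.numeric(groups) && length(groups) == 2L && all(groups == round(groups))) {
    groups <- rep(c("g1", "g2"), times = groups)
  }
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L)
  set.seed(seed)
  n <- length(groups)
  hz <- baseline_hazard * ifelse(groups == levels(groups)[2], hazard_ratio, 1)
  t_event <- rexp(n, rate = hz)
  if (censor_rate > 0) {
    cz <- baseline_hazard * censor_rate / (1 - censor_rate)
    t_cens <- rexp(n, rate = cz)
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble(sample_id = sprintf("P%03d", seq_len(n)),
         time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens),
         group = groups)
}

#' Apply a monotone beta-value distortion
#'
#' `beta^gamma / (beta^gamma + (1 - beta)^gamma)`: a strictly monotone map of
#' `[0,1]` onto itself that mimics the systematic distribution shifts
#' different platforms or preprocessing pipelines impose on beta values
#' (`gamma = 1` is the identity; `gamma < 1` pushes values toward 0.5,
#' `gamma > 1` toward the extremes).
#'
#' @param beta matrix/vector of beta values in `[0,1]`.
#' @param gamma distortion exponent (> 0).
#' @return distorted values, same shape.
#' @export
distort_beta <- function(beta, gamma) {
  stopifnot(gamma > 0)
  b <- beta^gamma
  b / (b + (1 - beta)^gamma)
}
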