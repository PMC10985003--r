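#' Compress probe-level betas into per-transcript principal-component scores
#'
#' For each transcript, the beta values of its selected probes are centered
#' per probe (training means are stored) and a PCA is taken with samples as
#' observations. The smallest number of leading components whose cumulative
#' explained-variance fraction reaches `cum_threshold` is retained; their
#' scores become the transcript's rows of the feature-by-sample matrix. The
#' stored eigenvectors and probe means later project new cohorts into the
#' identical feature space via [project_compression()].
#'
#' Probes with more than `max_missing` missing fraction are dropped from a
#' transcript before PCA; remaining missing entries are imputed at the
#' probe's observed mean. Transcripts whose probes are all constant keep a
#' single zero-variance feature (q = 1, explained variance defined as 1).
#' Each eigenvector's sign is fixed so its largest-magnitude element is
#' positive, making models stable across runs.
#'
#' @param beta probes x samples matrix of beta values in `[0,1]` (rownames =
#'   probe ids, colnames = sample ids); `NA` for missing.
#' @param probe_map tibble from [select_region_probes()] mapping transcripts
#'   to ordered probes.
#' @param cum_threshold cumulative explained-variance fraction to retain;
#'   default 0.8.
#' @param max_missing per-probe missing-fraction tolerance; default 0.2.
#' @param mode,window_bp metadata recorded in the model (how `probe_map` was
#'   built).
#' @return a list with `model` (a `meth_compression` object) and `scores`
#'   (features x samples matrix; feature labels `<transcript>.PC<i>`).
#' @export
fit_compression <- function(beta, probe_map, cum_threshold = 0.8,
                            max_missing = 0.2, mode = "tss_window",
                            window_bp = 1500L) {
  beta <- validate_beta_matrix(beta)
  if (ncol(beta) < 2L) abort("fit_compression needs at least 2 samples.")
  if (!all(c("transcript_id", "probe_id") %in% names(probe_map))) {
    abort("`probe_map` must have transcript_id and probe_id columns.")
  }
  if (!(cum_threshold > 0 && cum_threshold <= 1)) {
    abort("`cum_threshold` must be in (0, 1].")
  }

  probe_map <- probe_map[probe_map$probe_id %in% rownames(beta), , drop = FALSE]
  tx_split <- split(probe_map$probe_id, probe_map$transcript_id)
  gene_of_tx <- if ("gene" %in% names(probe_map)) {
    vapply(split(probe_map$gene, probe_map$transcript_id), `[[`, "", 1L)
  } else {
    setNames(names(tx_split), names(tx_split))
  }

  transcripts <- list()
  score_rows <- list()
  for (tx in names(tx_split)) {
    blk <- prepare_block(beta[tx_split[[tx]], , drop = FALSE], max_missing)
    if (is.null(blk)) next
    pc <- transcript_pca(blk, cum_threshold)
    transcripts[[tx]] <- list(
      probe_ids = rownames(blk), center = pc$center, rotation = pc$rotation,
      q = pc$q, var_fraction = pc$var_fraction, cum_var = pc$cum_var
    )
    rn <- paste0(tx, ".PC", seq_len(pc$q))
    rownames(pc$scores) <- rn
    score_rows[[tx]] <- pc$scores
  }
  if (!length(transcripts)) abort("no transcript had usable probes after filtering.")

  scores <- do.call(rbind, score_rows)
  colnames(scores) <- colnames(beta)
  features <- rownames(scores)
  feature_gene <- setNames(
    as.character(gene_of_tx[sub("\\.PC[0-9]+$", "", features)]), features
  )

  model <- structure(
    list(transcripts = transcripts, features = features,
         feature_gene = feature_gene, mode = mode, window_bp = window_bp,
         cum_threshold = cum_threshold, max_missing = max_missing,
         n_train_samples = ncol(beta), version = "methlv-compression-1"),
    class = "meth_compression"
  )
  list(model = model, scores = scores)
}

# drop over-missing probes, impute the rest at the probe mean
prepare_block <- function(x, max_missing) {
  miss <- rowMeans(is.na(x))
  x <- x[miss <= max_missing, , drop = FALSE]
  if (nrow(x) == 0L) return(NULL)
  for (i in which(rowSums(is.na(x)) > 0L)) {
    mu <- mean(x[i, ], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    x[i, is.na(x[i, ])] <- mu
  }
  x
}

# PCA of a probes x samples block with samples as observations
transcript_pca <- function(x, cum_threshold) {
  center <- rowMeans(x)
  xc <- x - center
  n <- ncol(x)
  sv <- svd(t(xc))                       # samples x probes
  ev <- sv$d^2
  if (sum(ev) <= .Machine$double.eps * n) {
    # all probes constant: single zero-variance feature, variance defined 1
    rotation <- matrix(0, nrow(x), 1, dimnames = list(rownames(x), NULL))
    rotation[1, 1] <- 1
    return(list(center = center, rotation = rotation, q = 1L,
                var_fraction = 1, cum_var = 1,
                scores = matrix(0, 1, n)))
  }
  frac <- ev / sum(ev)
  q <- which(cumsum(frac) >= cum_threshold - 1e-12)[1]
  if (is.na(q)) q <- length(frac)
  rotation <- sv$v[, seq_len(q), drop = FALSE]
  scores <- t(xc) %*% rotation           # samples x q
  # sign convention: largest-magnitude eigenvector element positive
  for (j in seq_len(q)) {
    piv <- which.max(abs(rotation[, j]))
    if (rotation[piv, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(rotation) <- rownames(x)
  list(center = center, rotation = rotation, q = q,
       var_fraction = frac[seq_len(q)], cum_var = sum(frac[seq_len(q)]),
       scores = t(scores))               # q x samples
}

#' Project a new cohort with a fitted compression model
#'
#' New-data probe rows are centered with the training means and multiplied by
#' the stored eigenvectors, yielding features identical in order and meaning
#' to the training scores. Probes absent (or `NA`) in the new data are imputed
#' at the training mean, i.e. contribute zero after centering; the per-
#' transcript imputation counts are attached as the `"imputation_report"`
#' attribute. A transcript whose probes are all missing yields `NA` feature
#' rows.
#'
#' @param beta_new probes x samples matrix (any subset of training probes).
#' @param model a `meth_compression` object from [fit_compression()].
#' @return features x samples score matrix with attribute
#'   `imputation_report` (tibble: transcript_id, n_probes, n_imputed).
#' @export
project_compression <- function(beta_new, model) {
  stopifnot(inherits(model, "meth_compression"))
  beta_new <- validate_beta_matrix(beta_new, "beta_new")
  if (ncol(beta_new) < 1L) abort("beta_new must have at least one sample.")

  out <- matrix(NA_real_, length(model$features), ncol(beta_new),
                dimnames = list(model$features, colnames(beta_new)))
  rep_rows <- vector("list", length(model$transcripts))
  for (i in seq_along(model$transcripts)) {
    tx <- names(model$transcripts)[i]
    info <- model$transcripts[[i]]
    have <- info$probe_ids %in% rownames(beta_new)
    x <- matrix(info$center, length(info$probe_ids), ncol(beta_new))
    n_imp <- sum(!have) * ncol(beta_new)
    if (any(have)) {
      xi <- beta_new[info$probe_ids[have], , drop = FALSE]
      na_here <- is.na(xi)
      n_imp <- n_imp + sum(na_here)
      xi[na_here] <- matrix(info$center[have], sum(have), ncol(beta_new))[na_here]
      x[have, ] <- xi
    }
    rep_rows[[i]] <- tibble(transcript_id = tx,
                            n_probes = length(info$probe_ids),
                            n_imputed = n_imp)
    feats <- paste0(tx, ".PC", seq_len(info$q))
    if (!any(have)) {
      inform(paste0("transcript ", tx, ": all probes missing in new data; ",
                    "features set to NA."))
      next
    }
    out[feats, ] <- t(t(x - info$center) %*% info$rotation)
  }
  attr(out, "imputation_report") <- dplyr::bind_rows(rep_rows)
  out
}

#' @export
print.meth_compression <- function(x, ...) {
  cat("<meth_compression> ", length(x$transcripts), " transcripts, ",
      length(x$features), " features\n", sep = "")
  cat("  mode=", x$mode, " window=", x$window_bp,
      " cum_threshold=", x$cum_threshold, "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_compression per-transcript summary: probes, retained
#'   components and cumulative explained variance.
#' @param x a `meth_compression` object.
#' @param ... unused.
#' @export
tidy.meth_compression <- function(x, ...) {
  purrr::imap_dfr(x$transcripts, function(info, tx) {
    tibble(transcript_id = tx, n_probes = length(info$probe_ids),
           q = info$q, cum_var = info$cum_var)
  })
}

#' @export
glance.meth_compression <- function(x, ...) {
  td <- tidy(x)
  tibble(n_transcripts = nrow(td), n_features = length(x$features),
         cum_threshold = x$cum_threshold, min_cum_var = min(td$cum_var),
         mean_q = mean(td$q))
}
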