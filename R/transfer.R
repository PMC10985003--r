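#' Transfer a frozen latent matrix onto a new cohort
#'
#' Given a fitted model (or a raw latent matrix `Z`), solves the same ridge
#' problem as the model's B step with `Z` held fixed:
#' `B_new = (Z'Z + lambda2 I)^{-1} Z' D_new`. When a full model is supplied,
#' the new data's feature rows are first standardized with the *training*
#' centers and scales, so loadings of different cohorts live in one latent
#' coordinate system.
#'
#' @param D_new features x samples matrix for the new cohort; feature
#'   rownames must match the latent matrix rows.
#' @param model a `meth_plier` model, or a features x k latent matrix `Z`.
#' @param lambda2 ridge penalty; defaults to the model's effective value
#'   (required when a bare matrix is given).
#' @return a `meth_loadings` object: `B` (k x samples), `lambda2`, and
#'   provenance.
#' @export
transfer_loadings <- function(D_new, model, lambda2 = NULL) {
  D_new <- assert_matrix_like(D_new, "D_new")
  if (inherits(model, "meth_plier")) {
    Z <- model$Z
    lambda2 <- lambda2 %||% model$lambda2
    if (model$config$standardize_rows) {
      D_new <- align_features(D_new, Z)
      D_new <- (D_new - model$row_center) / model$row_scale
    }
    provenance <- model$version
  } else {
    Z <- assert_matrix_like(model, "Z")
    if (is.null(lambda2)) abort("`lambda2` is required when `model` is a bare latent matrix.")
    provenance <- "frozen-Z"
  }
  if (lambda2 <= 0) abort("`lambda2` must be > 0 for a transfer decomposition.")
  D_new <- align_features(D_new, Z)
  B <- update_b(D_new, Z, lambda2)
  dimnames(B) <- list(colnames(Z) %||% paste0("LV", seq_len(ncol(Z))), colnames(D_new))
  structure(list(B = B, lambda2 = lambda2, provenance = provenance,
                 sample_ids = colnames(D_new)),
            class = "meth_loadings")
}

align_features <- function(D_new, Z) {
  if (is.null(rownames(Z)) || is.null(rownames(D_new))) {
    if (nrow(D_new) != nrow(Z)) abort("feature dimension mismatch and no rownames to align by.")
    return(D_new)
  }
  missing <- setdiff(rownames(Z), rownames(D_new))
  if (length(missing)) {
    abort(paste0("new data lacks ", length(missing), " latent-matrix feature(s); first: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  D_new[rownames(Z), , drop = FALSE]
}

#' @export
print.meth_loadings <- function(x, ...) {
  cat("<meth_loadings> ", nrow(x$B), " LVs x ", ncol(x$B), " samples (lambda2=",
      signif(x$lambda2, 4), ")\n", sep = "")
  invisible(x)
}

#' @describeIn transfer_loadings long tibble (lv, sample_id, loading).
#' @param x a `meth_loadings` object.
#' @param ... unused.
#' @export
tidy.meth_loadings <- function(x, ...) {
  as_tibble(as.data.frame.table(x$B, stringsAsFactors = FALSE),
            .name_repair = "minimal") |>
    stats::setNames(c("lv", "sample_id", "loading"))
}

as_sample_matrix <- function(X) {
  if (inherits(X, "meth_loadings")) X <- t(X$B)
  X <- assert_matrix_like(X, "X")
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  X
}

#' Hierarchical clustering of samples (Ward linkage, Euclidean distance)
#'
#' Agglomerates samples by Ward's minimum-variance criterion on Euclidean
#' distances and cuts the tree into `n_clusters` groups. Accepts a samples x
#' dims matrix or a `meth_loadings` object (samples taken from the columns
#' of `B`).
#'
#' @param X samples x dims matrix, or `meth_loadings`.
#' @param n_clusters number of clusters (>= 2, <= samples).
#' @return tibble (`sample_id`, `cluster`); the `hclust` tree is attached as
#'   attribute `"tree"`.
#' @export
hca_clusters <- function(X, n_clusters) {
  X <- as_sample_matrix(X)
  if (anyDuplicated(rownames(X))) abort("duplicate sample labels.")
  if (n_clusters < 2 || n_clusters > nrow(X)) {
    abort("`n_clusters` must be in [2, number of samples].")
  }
  tree <- hclust(dist(X, method = "euclidean"), method = "ward.D2")
  labels <- cutree(tree, k = n_clusters)
  out <- tibble(sample_id = rownames(X), cluster = unname(labels))
  attr(out, "tree") <- tree
  out
}

#' k-means clustering of samples (Hartigan-Wong)
#'
#' Hartigan-Wong k-means with at most 100 iterations and `n_init` random
#' restarts, keeping the lowest within-cluster sum of squares. Deterministic
#' for a fixed seed.
#'
#' @inheritParams hca_clusters
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @param n_init random restarts; default 10.
#' @param max_iter Hartigan-Wong iteration cap; default 100.
#' @return tibble (`sample_id`, `cluster`) with attributes
#'   `"tot_withinss"` and `"centers"`.
#' @export
kmeans_clusters <- function(X, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  X <- as_sample_matrix(X)
  if (k > nrow(X)) abort("k must not exceed the number of samples.")
  set.seed(seed)
  fit <- withCallingHandlers(
    kmeans(X, centers = k, iter.max = max_iter, nstart = n_init,
           algorithm = "Hartigan-Wong"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) {
        inform("k-means produced an empty cluster in a restart; centroid re-seeded.")
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- tibble(sample_id = rownames(X), cluster = unname(fit$cluster))
  attr(out, "tot_withinss") <- fit$tot.withinss
  attr(out, "centers") <- fit$centers
  out
}

#' UMAP embedding of samples
#'
#' Two-dimensional uniform manifold approximation and projection on the
#' Euclidean metric (fuzzy simplicial set on the k-nearest-neighbor graph,
#' stochastic-gradient layout), via the uwot implementation. Defaults follow
#' the package's standard analysis settings: 15 neighbors, 2 components,
#' 200 epochs. Deterministic for a fixed seed.
#'
#' @inheritParams hca_clusters
#' @param n_neighbors local neighborhood size; default 15.
#' @param n_components embedding dimension; default 2.
#' @param n_epochs optimization epochs; default 200.
#' @param seed integer RNG seed.
#' @return tibble (`sample_id`, `UMAP1`, `UMAP2`, ...).
#' @export
umap_embed <- function(X, n_neighbors = 15L, n_components = 2L,
                       n_epochs = 200L, seed = 1L) {
  X <- as_sample_matrix(X)
  if (nrow(X) <= n_neighbors) {
    abort(sprintf("need more samples (%d) than n_neighbors (%d); lower n_neighbors.",
                  nrow(X), n_neighbors))
  }
  set.seed(seed)
  emb <- uwot::umap(X, n_neighbors = n_neighbors, n_components = n_components,
                    n_epochs = n_epochs, metric = "euclidean",
                    n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  if (!all(is.finite(emb))) abort("UMAP produced non-finite coordinates.")
  colnames(emb) <- paste0("UMAP", seq_len(ncol(emb)))
  dplyr::bind_cols(tibble(sample_id = rownames(X)), as_tibble(emb))
}
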