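#' Serialize and restore model archives
#'
#' Archives are plain directories of TSV matrices plus a `meta.json` block,
#' so they diff cleanly, survive version control, and can be read outside R.
#' [write_plier_model()]/[read_plier_model()] handle fitted factorization
#' models; [write_compression_model()]/[read_compression_model()] handle
#' compression models (per-transcript eigenvectors and centering means).
#'
#' @param model fitted object.
#' @param dir archive directory (created, contents overwritten).
#' @return `dir`, invisibly; readers return the restored object.
#' @name model_archive
NULL

write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
}

read_tsv_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' @rdname model_archive
#' @export
write_plier_model <- function(model, dir) {
  stopifnot(inherits(model, "meth_plier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(model$Z, file.path(dir, "Z.tsv"))
  write_tsv_matrix(model$U, file.path(dir, "U.tsv"))
  write_tsv_matrix(model$B, file.path(dir, "B.tsv"))
  readr::write_tsv(model$trace, file.path(dir, "trace.tsv"), progress = FALSE)
  cfg <- model$config
  class(cfg) <- NULL
  meta <- list(version = model$version, set_names = model$set_names,
               lambda1 = model$lambda1, lambda2 = model$lambda2,
               lambda3 = model$lambda3, converged = model$converged,
               iterations = model$iterations,
               frac_achieved = model$frac_achieved,
               row_center = as.list(setNames(model$row_center, rownames(model$Z))),
               row_scale = as.list(setNames(model$row_scale, rownames(model$Z))),
               config = cfg)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname model_archive
#' @export
read_plier_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- plier_config(k = cfg$k, lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                         lambda3 = cfg$lambda3, l1_fraction = cfg$l1_fraction,
                         frac = cfg$frac, max_iter = cfg$max_iter, tol = cfg$tol,
                         max_path = cfg$max_path, seed = cfg$seed,
                         standardize_rows = cfg$standardize_rows)
  Z <- read_tsv_matrix(file.path(dir, "Z.tsv"))
  structure(
    list(Z = Z,
         U = read_tsv_matrix(file.path(dir, "U.tsv")),
         B = read_tsv_matrix(file.path(dir, "B.tsv")),
         set_names = meta$set_names,
         lambda1 = meta$lambda1, lambda2 = meta$lambda2, lambda3 = meta$lambda3,
         config = config,
         trace = readr::read_tsv(file.path(dir, "trace.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
         converged = meta$converged, iterations = meta$iterations,
         row_center = unlist(meta$row_center)[rownames(Z)],
         row_scale = unlist(meta$row_scale)[rownames(Z)],
         frac_achieved = meta$frac_achieved,
         version = meta$version),
    class = "meth_plier"
  )
}

#' @rdname model_archive
#' @export
write_compression_model <- function(model, dir) {
  stopifnot(inherits(model, "meth_compression"))
  dir.create(file.path(dir, "transcripts"), showWarnings = FALSE, recursive = TRUE)
  for (tx in names(model$transcripts)) {
    info <- model$transcripts[[tx]]
    rot <- info$rotation
    rownames(rot) <- info$probe_ids
    write_tsv_matrix(cbind(center = info$center, rot),
                     file.path(dir, "transcripts", paste0(tx, ".tsv")))
  }
  meta <- list(version = model$version, mode = model$mode,
               window_bp = model$window_bp, cum_threshold = model$cum_threshold,
               max_missing = model$max_missing,
               n_train_samples = model$n_train_samples,
               features = model$features,
               feature_gene = as.list(model$feature_gene),
               transcript_stats = lapply(model$transcripts, function(i)
                 list(q = i$q, cum_var = i$cum_var,
                      var_fraction = i$var_fraction)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname model_archive
#' @export
read_compression_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  transcripts <- lapply(names(meta$transcript_stats), function(tx) {
    m <- read_tsv_matrix(file.path(dir, "transcripts", paste0(tx, ".tsv")))
    st <- meta$transcript_stats[[tx]]
    list(probe_ids = rownames(m), center = m[, 1],
         rotation = m[, -1, drop = FALSE],
         q = st$q, cum_var = st$cum_var, var_fraction = st$var_fraction)
  })
  names(transcripts) <- names(meta$transcript_stats)
  structure(
    list(transcripts = transcripts, features = meta$features,
         feature_gene = unlist(meta$feature_gene),
         mode = meta$mode, window_bp = meta$window_bp,
         cum_threshold = meta$cum_threshold, max_missing = meta$max_missing,
         n_train_samples = meta$n_train_samples, version = meta$version),
    class = "meth_compression"
  )
}
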