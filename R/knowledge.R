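#' Read gene-set collections in GMT format
#'
#' Each GMT line is `set_name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Several files may be given; when the same set name occurs in more than one
#' file, both are kept and disambiguated by prefixing the file's base name
#' (`file:SET`). Gene symbols are uppercased and deduplicated within a set.
#'
#' @param paths character vector of GMT file paths.
#' @return tibble with columns `set_name`, `source`, `genes` (list column of
#'   character vectors).
#' @export
read_gmt <- function(paths) {
  one <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) {
      abort(sprintf("malformed GMT line %d in %s (needs name, description, >=1 gene)",
                    bad[1], path))
    }
    tibble(
      set_name = vapply(parts, `[[`, "", 1L),
      source = rep(basename(path), length(parts)),
      genes = lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
    )
  }
  out <- dplyr::bind_rows(lapply(paths, one))
  dup <- out$set_name[duplicated(out$set_name)]
  if (length(dup)) {
    hit <- out$set_name %in% dup
    out$set_name[hit] <- paste0(sub("\\.gmt$", "", out$source[hit]), ":",
                                out$set_name[hit])
  }
  if (anyDuplicated(out$set_name)) abort("duplicate set names within a single GMT file.")
  if (any(lengths(out$genes) == 0L)) abort("GMT contains a set with no genes.")
  out
}

#' Build the binary feature-by-gene-set knowledge matrix
#'
#' Gene-set membership is known at the gene level; every compressed feature
#' (principal-component score of a transcript) inherits the memberships of
#' its gene, so all PC features of all transcripts of a gene share a row
#' pattern. Sets supported by fewer than `min_genes` *distinct* genes present
#' in the feature space are dropped. Features whose gene belongs to no
#' retained set are dropped too (the companion data matrix should be filtered
#' identically, see [align_to_knowledge()]), unless `keep_orphan_features`.
#'
#' @param collection tibble from [read_gmt()].
#' @param feature_gene_map named character vector (names = feature labels,
#'   values = gene symbols) or a tibble with columns `feature`, `gene`. The
#'   `feature_gene` field of a fitted compression model fits directly.
#' @param min_genes minimum distinct-gene overlap per retained set; default 10.
#' @param keep_orphan_features keep all-zero feature rows; default `FALSE`.
#' @return binary matrix `C` (features x sets) with dimnames; attribute
#'   `"set_overlap"` holds the distinct-gene overlap per retained column.
#' @export
build_knowledge <- function(collection, feature_gene_map, min_genes = 10L,
                            keep_orphan_features = FALSE) {
  if (is.data.frame(feature_gene_map)) {
    feature_gene_map <- setNames(toupper(feature_gene_map$gene),
                                 feature_gene_map$feature)
  } else {
    feature_gene_map <- setNames(toupper(feature_gene_map), names(feature_gene_map))
  }
  features <- names(feature_gene_map)
  if (is.null(features)) abort("`feature_gene_map` must be named by feature label.")
  genes_present <- unique(feature_gene_map)

  overlap <- vapply(collection$genes,
                    function(g) length(intersect(toupper(g), genes_present)),
                    integer(1))
  keep <- overlap >= min_genes
  if (!any(keep)) abort("knowledge matrix empty after filtering (no set overlaps >= min_genes).")
  sets <- collection[keep, , drop = FALSE]

  C <- vapply(sets$genes, function(g) {
    as.numeric(feature_gene_map %in% toupper(g))
  }, numeric(length(features)))
  dim(C) <- c(length(features), nrow(sets))
  dimnames(C) <- list(features, sets$set_name)

  if (!keep_orphan_features) {
    C <- C[rowSums(C) > 0, , drop = FALSE]
    if (nrow(C) == 0L) abort("knowledge matrix empty after filtering (no feature in any retained set).")
  }
  attr(C, "set_overlap") <- setNames(overlap[keep], sets$set_name)
  C
}

#' Filter a feature matrix to the rows of a knowledge matrix
#'
#' Subsets `D` to the (ordered) feature rows of `C`, erroring on features the
#' data does not carry. Keeps the data matrix and knowledge matrix row-aligned
#' after orphan-feature dropping.
#'
#' @param D features x samples matrix with feature rownames.
#' @param C knowledge matrix from [build_knowledge()].
#' @return `D` restricted and reordered to `rownames(C)`.
#' @export
align_to_knowledge <- function(D, C) {
  D <- assert_matrix_like(D, "D")
  missing <- setdiff(rownames(C), rownames(D))
  if (length(missing)) {
    abort(paste0("data matrix lacks ", length(missing), " knowledge feature(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  D[rownames(C), , drop = FALSE]
}
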