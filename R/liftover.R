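#' Read per-CpG bisulfite methylation calls
#'
#' Accepts two tab-delimited dialects and normalizes both to 1-based
#' coordinates:
#' * `bed`: BED-like, columns `chrom`, `start` (0-based), `end`, then either
#'   `beta` or `methylated`,`total`, optionally `strand`;
#' * `tsv1`: 1-based, columns `chrom`, `pos`, then the same value columns.
#' `auto` picks `bed` when the header names a `start` column.
#'
#' @param path input file.
#' @param format `"auto"`, `"bed"` or `"tsv1"`.
#' @param assembly genome-assembly label (e.g. `"hg19"`) recorded on the
#'   table and checked at liftover time.
#' @return tibble with columns `chrom`, `pos` (1-based cytosine coordinate),
#'   `strand`, and `beta` or `methylated`/`total`; attribute `"assembly"`.
#' @export
read_cpg_calls <- function(path, format = c("auto", "bed", "tsv1"),
                           assembly = NULL) {
  format <- match.arg(format)
  tab <- read_delim_auto(path)
  if (format == "auto") format <- if ("start" %in% names(tab)) "bed" else "tsv1"
  if (format == "bed") {
    if (!all(c("chrom", "start") %in% names(tab))) {
      abort("bed dialect requires `chrom` and `start` columns.")
    }
    tab$pos <- as.integer(tab$start) + 1L
    tab$start <- NULL; tab$end <- NULL
  } else if (!all(c("chrom", "pos") %in% names(tab))) {
    abort("tsv1 dialect requires `chrom` and `pos` columns.")
  }
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  validate_cpg_calls(tab, assembly)
}

#' @rdname read_cpg_calls
#' @param calls a data frame of calls to validate.
#' @export
validate_cpg_calls <- function(calls, assembly = NULL) {
  calls <- as_tibble(calls)
  if (!all(c("chrom", "pos") %in% names(calls))) {
    abort("calls need `chrom` and `pos` columns.")
  }
  has_counts <- all(c("methylated", "total") %in% names(calls))
  if (has_counts) {
    if (any(calls$methylated < 0 | calls$total < calls$methylated)) {
      abort("need 0 <= methylated <= total.")
    }
  } else if ("beta" %in% names(calls)) {
    if (any(calls$beta < 0 | calls$beta > 1, na.rm = TRUE)) {
      abort("`beta` must lie in [0,1].")
    }
  } else {
    abort("calls need either `beta` or `methylated` + `total` columns.")
  }
  if (!"strand" %in% names(calls)) calls$strand <- "+"
  attr(calls, "assembly") <- assembly %||% attr(calls, "assembly")
  calls
}

#' Convert per-CpG calls to array probe-wise beta values
#'
#' Matches CpG calls to manifest probes by exact coordinate: a probe at
#' `(chrom, pos)` takes the call at `pos` and, for the reverse-strand
#' cytosine of the CpG dinucleotide, the call at `pos + 1` on the `-`
#' strand. When both strands report, betas are combined by coverage-weighted
#' mean (unweighted when only betas are available). With count input, probes
#' whose combined coverage falls below `min_total` are set missing.
#' Duplicate call rows at one (chrom, pos, strand) are merged with summed
#' counts (a warning is raised).
#'
#' @param calls tibble from [read_cpg_calls()] / [validate_cpg_calls()].
#' @param manifest probe manifest (see [read_manifest()]).
#' @param min_total minimum combined read coverage for count input;
#'   default 5. Ignored for beta-only input.
#' @param sample_id column name of the single output sample.
#' @param assembly assembly label of the manifest; compared with the calls'
#'   label when both are known.
#' @param force proceed despite an assembly mismatch.
#' @return list: `beta` (single-column probe matrix, `NA` = unmatched or
#'   under-covered), `matched_fraction`, `per_chrom` counts tibble,
#'   `n_below_min_total`.
#' @export
liftover_to_probes <- function(calls, manifest, min_total = 5L,
                               sample_id = "sample1", assembly = NULL,
                               force = FALSE) {
  calls <- validate_cpg_calls(calls)
  manifest <- validate_manifest(manifest)
  calls_asm <- attr(calls, "assembly")
  if (!is.null(calls_asm) && !is.null(assembly) &&
      !identical(calls_asm, assembly) && !force) {
    abort(sprintf("assembly mismatch: calls are %s, manifest is %s (use force = TRUE to override).",
                  calls_asm, assembly))
  }
  has_counts <- all(c("methylated", "total") %in% names(calls))

  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key)) {
    warn("duplicate (chrom, pos, strand) call rows merged by summing counts.")
    if (has_counts) {
      calls <- calls |>
        dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
        dplyr::summarise(methylated = sum(.data$methylated),
                         total = sum(.data$total), .groups = "drop")
    } else {
      calls <- calls |>
        dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
        dplyr::summarise(beta = mean(.data$beta), .groups = "drop")
    }
  }
  if (has_counts) {
    calls$beta <- ifelse(calls$total > 0, calls$methylated / calls$total, NA_real_)
    calls$weight <- calls$total
  } else {
    calls$weight <- 1
  }

  probes <- dplyr::distinct(manifest[, c("probe_id", "chrom", "pos")])
  # forward-strand cytosine at pos, reverse-strand cytosine at pos + 1
  fwd <- dplyr::inner_join(
    probes, calls[calls$strand != "-", c("chrom", "pos", "beta", "weight")],
    by = c("chrom", "pos"))
  rev <- dplyr::inner_join(
    dplyr::mutate(probes, pos = .data$pos + 1L),
    calls[calls$strand == "-", c("chrom", "pos", "beta", "weight")],
    by = c("chrom", "pos"))
  hits <- dplyr::bind_rows(fwd, rev) |>
    dplyr::filter(!is.na(.data$beta)) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(beta = sum(.data$beta * .data$weight) / sum(.data$weight),
                     coverage = sum(.data$weight), .groups = "drop")

  n_below <- 0L
  if (has_counts) {
    low <- hits$coverage < min_total
    n_below <- sum(low)
    hits <- hits[!low, , drop = FALSE]
  }

  beta <- matrix(NA_real_, nrow(probes), 1,
                 dimnames = list(probes$probe_id, sample_id))
  beta[hits$probe_id, 1] <- hits$beta

  matched <- probes$probe_id %in% hits$probe_id
  per_chrom <- probes |>
    dplyr::mutate(matched = matched) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n_probes = dplyr::n(), n_matched = sum(.data$matched),
                     .groups = "drop")
  list(beta = beta,
       matched_fraction = mean(matched),
       per_chrom = per_chrom,
       n_below_min_total = n_below)
}
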