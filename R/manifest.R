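#' Read and validate a probe manifest
#'
#' A manifest annotates array probes with genomic coordinates and the
#' transcript(s) they serve: one row per (probe, transcript) pair, so a probe
#' annotating several transcripts appears once per transcript. Required
#' columns: `probe_id`, `chrom`, `pos` (1-based), `strand` (`+`/`-`),
#' `transcript_id`, `tss_pos` (1-based TSS coordinate). Optional: `region_tag`
#' (`TSS1500`, `TSS200`, `1stExon`, `Body`, `3'UTR`, `other`) and `gene`
#' (symbol used to join against gene-set collections; defaults to the
#' transcript id when absent).
#'
#' @param path TSV/CSV file with a header.
#' @return a tibble, one row per (probe, transcript) annotation.
#' @export
read_manifest <- function(path) {
  validate_manifest(read_delim_auto(path))
}

#' @rdname read_manifest
#' @param manifest a data frame to validate in place.
#' @export
validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  required <- c("probe_id", "chrom", "pos", "strand", "transcript_id", "tss_pos")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  manifest$pos <- as.integer(manifest$pos)
  manifest$tss_pos <- as.integer(manifest$tss_pos)
  if (any(manifest$pos < 1L, na.rm = TRUE)) abort("manifest `pos` must be >= 1 (1-based).")
  if (anyDuplicated(manifest[, c("probe_id", "transcript_id")])) {
    abort("manifest rows must be unique per (probe_id, transcript_id) pair.")
  }
  bad_strand <- setdiff(unique(manifest$strand), c("+", "-"))
  if (length(bad_strand)) {
    abort(paste0("manifest `strand` must be '+' or '-'; found: ",
                 paste(bad_strand, collapse = ", ")))
  }
  if (!"gene" %in% names(manifest)) manifest$gene <- manifest$transcript_id
  manifest
}

#' Select probes near each transcript
#'
#' In `tss_window` mode a probe qualifies for a transcript when its genomic
#' distance to that transcript's TSS is at most `window_bp`; by default the
#' window is symmetric around the TSS, while `upstream_only = TRUE` restricts
#' it to the strand-aware upstream side (the array's own "TSS1500" convention).
#' In `first_exon` mode probes tagged `1stExon` are used instead. Transcripts
#' with no qualifying probe are omitted; probes are ordered by genomic
#' position within each transcript.
#'
#' @param manifest a validated manifest (see [read_manifest()]).
#' @param mode `"tss_window"` (default) or `"first_exon"`.
#' @param window_bp window half-width in base pairs; default 1500.
#' @param upstream_only restrict the window to the upstream side of the TSS
#'   on the annotated strand (TSS itself always included).
#' @return tibble with columns `transcript_id`, `probe_id`, `pos`, `gene`,
#'   ordered by transcript then position.
#' @export
select_region_probes <- function(manifest, mode = c("tss_window", "first_exon"),
                                 window_bp = 1500L, upstream_only = FALSE) {
  mode <- match.arg(mode)
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) == 0L) abort("manifest is empty.")

  if (mode == "tss_window") {
    if (!is.numeric(window_bp) || window_bp <= 0) abort("`window_bp` must be > 0.")
    no_tss <- is.na(manifest$tss_pos)
    if (any(no_tss)) {
      skipped <- unique(manifest$transcript_id[no_tss])
      warn(paste0("skipping ", length(skipped),
                  " transcript(s) with missing tss_pos: ",
                  paste(head(skipped, 5), collapse = ", ")))
      manifest <- manifest[!manifest$transcript_id %in% skipped, , drop = FALSE]
    }
    d <- manifest$pos - manifest$tss_pos
    keep <- if (upstream_only) {
      # upstream means lower coordinates on '+', higher on '-'
      ifelse(manifest$strand == "+", d <= 0 & -d <= window_bp, d >= 0 & d <= window_bp)
    } else {
      abs(d) <= window_bp
    }
    sel <- manifest[keep, , drop = FALSE]
  } else {
    if (!"region_tag" %in% names(manifest)) {
      abort("first_exon mode requires a `region_tag` column in the manifest.")
    }
    sel <- manifest[!is.na(manifest$region_tag) & manifest$region_tag == "1stExon", ,
                    drop = FALSE]
  }

  sel <- sel[order(sel$transcript_id, sel$pos), , drop = FALSE]
  tibble(transcript_id = sel$transcript_id, probe_id = sel$probe_id,
         pos = sel$pos, gene = sel$gene)
}
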