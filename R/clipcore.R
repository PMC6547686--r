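#' Call conversion-supported binding-site clusters
#'
#' Merges transitively overlapping reads on each transcript into candidate
#' clusters (the union of read extents) and keeps a cluster only if it has at
#' least `min_reads` reads, at least `min_crosslinked` reads carrying a
#' T-to-C conversion, and a conversion fraction (crosslinked / total reads)
#' of at least `min_conversion_fraction`. This is a transparent re-statement
#' of the conversion-supported-cluster concept used for PAR-CLIP binding
#' sites; kernel-density refinement of cluster boundaries is out of scope.
#' Each kept cluster is annotated to the transcript region with maximal
#' overlap (ties broken 5'UTR > 3'UTR > CDS) with a `spanning` flag when the
#' overlap is split across a region boundary.
#'
#' @param reads Tibble with transcript_id, start, end (0-based half-open) and
#'   conversion_offsets (list-column of integer offsets, or comma-separated
#'   strings as written by [write_reads_tsv()]).
#' @param transcripts Tibble with transcript_id, gene_id, utr5_len, cds_len,
#'   utr3_len (and length).
#' @param min_reads,min_crosslinked,min_conversion_fraction Cluster filters.
#'
#' @return Tibble (class `clip_clusters`): transcript_id, gene_id, start,
#'   end, n_reads, n_crosslinked, conversion_fraction, category (one of
#'   "utr5", "cds", "utr3"), spanning. Disjoint per transcript, sorted by
#'   transcript and start.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
#'                      utr5_len = 100L, cds_len = 300L, utr3_len = 200L,
#'                      length = 600L)
#' reads <- tibble::tibble(
#'   transcript_id = "t1", start = c(10L, 15L), end = c(30L, 35L),
#'   conversion_offsets = list(3L, 5L)
#' )
#' call_clusters(reads, tx, min_reads = 2)
#' @export
call_clusters <- function(reads, transcripts,
                          min_reads = 5L, min_crosslinked = 2L,
                          min_conversion_fraction = 0.2) {
  assert_columns(transcripts,
                 c("transcript_id", "gene_id", "utr5_len", "cds_len",
                   "utr3_len"), "transcripts")
  assert_scalar_number(min_reads, "min_reads", min = 0)
  assert_scalar_number(min_crosslinked, "min_crosslinked", min = 0)
  assert_scalar_number(min_conversion_fraction, "min_conversion_fraction",
                       min = 0, max = 1)
  empty <- tibble(
    transcript_id = character(), gene_id = character(),
    start = integer(), end = integer(), n_reads = integer(),
    n_crosslinked = integer(), conversion_fraction = double(),
    category = character(), spanning = logical()
  )
  class(empty) <- c("clip_clusters", class(empty))
  if (nrow(reads) == 0L) {
    return(empty)
  }
  reads <- reads_with_offsets(reads)
  unknown <- setdiff(unique(reads$transcript_id), transcripts$transcript_id)
  if (length(unknown) > 0L) {
    abort(sprintf("reads reference unknown transcript(s): %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }

  clusters <- reads |>
    dplyr::mutate(crosslinked = lengths(.data$conversion_offsets) > 0L) |>
    dplyr::arrange(.data$transcript_id, .data$start, .data$end) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      cluster = cumsum(.data$start >= dplyr::lag(cummax(.data$end),
                                                 default = -1L))
    ) |>
    dplyr::group_by(.data$transcript_id, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_reads = dplyr::n(),
      n_crosslinked = sum(.data$crosslinked),
      .groups = "drop"
    ) |>
    dplyr::mutate(conversion_fraction = .data$n_crosslinked / .data$n_reads) |>
    dplyr::filter(
      .data$n_reads >= min_reads,
      .data$n_crosslinked >= min_crosslinked,
      .data$conversion_fraction >= min_conversion_fraction
    ) |>
    dplyr::select(-"cluster")

  out <- clusters |>
    dplyr::left_join(
      dplyr::select(transcripts, "transcript_id", "gene_id",
                    "utr5_len", "cds_len", "utr3_len"),
      by = "transcript_id"
    ) |>
    assign_annotation() |>
    dplyr::select(
      "transcript_id", "gene_id", "start", "end", "n_reads",
      "n_crosslinked", "conversion_fraction", "category", "spanning"
    ) |>
    dplyr::arrange(.data$transcript_id, .data$start)
  class(out) <- c("clip_clusters", class(out))
  out
}

#' Assign clusters to transcript regions by maximal overlap
#'
#' Adds `category` ("utr5", "cds", "utr3") and `spanning` columns to a tibble
#' of intervals. The category is the region with maximal overlap; ties are
#' broken UTR over CDS, 5'UTR first (precedence 5'UTR > 3'UTR > CDS).
#' `spanning` is TRUE when the interval crosses a region boundary, so the
#' single label was a tie-break rather than containment.
#'
#' @param clusters Tibble with start, end, utr5_len, cds_len, utr3_len
#'   (region lengths in transcript space; joined from the transcript model).
#' @return The input with `category` and `spanning` columns.
#' @export
assign_annotation <- function(clusters) {
  assert_columns(clusters, c("start", "end", "utr5_len", "cds_len",
                             "utr3_len"), "clusters")
  a <- clusters$utr5_len
  b <- clusters$utr5_len + clusters$cds_len
  L <- b + clusters$utr3_len
  if (any(clusters$start < 0L | clusters$end > L)) {
    abort("cluster interval outside transcript bounds.")
  }
  ov <- cbind(
    utr5 = interval_overlap(clusters$start, clusters$end, 0L, a),
    utr3 = interval_overlap(clusters$start, clusters$end, b, L),
    cds  = interval_overlap(clusters$start, clusters$end, a, b)
  )
  # max.col with ties.method = "first" applies the precedence ordering of
  # the columns: utr5, then utr3, then cds
  pick <- max.col(ov, ties.method = "first")
  clusters$category <- colnames(ov)[pick]
  clusters$spanning <- rowSums(ov > 0L) > 1L
  clusters
}

#' Transcripts per million from a count matrix
#'
#' Standard length-normalized abundance: per-gene count divided by transcript
#' length in kb, rescaled per sample to sum to 1e6, then averaged over the
#' selected samples.
#'
#' @param counts Counts tibble (gene_id + sample columns).
#' @param transcripts Tibble with gene_id and length (nt).
#' @param samples Character vector of sample columns to use; default all
#'   columns matching `RNA_WT` (wild-type RNA-seq).
#' @return Tibble: gene_id, tpm.
#' @export
compute_tpm <- function(counts, transcripts, samples = NULL) {
  assert_columns(counts, "gene_id", "counts")
  assert_columns(transcripts, c("gene_id", "length"), "transcripts")
  if (is.null(samples)) {
    samples <- grep("^RNA_WT", names(counts), value = TRUE)
  }
  if (length(samples) == 0L) {
    abort("no sample columns selected for TPM computation.")
  }
  lens <- transcripts$length[match(counts$gene_id, transcripts$gene_id)]
  if (anyNA(lens)) {
    abort("some genes in `counts` have no length in `transcripts`.")
  }
  rate <- as.matrix(counts[, samples, drop = FALSE]) / (lens / 1000)
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  tibble(gene_id = counts$gene_id, tpm = rowMeans(tpm))
}

#' Per-gene NXPM occupancy profiles
#'
#' XPM(g) = 1e6 x crosslinked reads assigned to gene g / total crosslinked
#' reads in the library (summed over all clusters); NXPM(g) = XPM(g) /
#' abundance(g) in TPM. Per-region NXPM uses the crosslinked reads of
#' clusters assigned to that region, with the same library total. Genes
#' below `min_tpm` are kept but flagged `low_abundance` with NXPM set NA.
#'
#' @param clusters A `clip_clusters` tibble from [call_clusters()].
#' @param abundance Tibble: gene_id, tpm (see [compute_tpm()]).
#' @param min_tpm Minimum abundance for a gene to be scored.
#' @return Tibble (class `gene_profiles`): gene_id, n_clusters,
#'   crosslinked_total, xpm, tpm, nxpm, nxpm_utr5, nxpm_cds, nxpm_utr3,
#'   low_abundance.
#' @examples
#' # a gene with 10 crosslinked reads in a library of 1000, at 50 TPM,
#' # scores XPM = 10000 and NXPM = 200
#' @export
compute_nxpm <- function(clusters, abundance, min_tpm = 1) {
  assert_columns(clusters, c("gene_id", "n_crosslinked", "category"),
                 "clusters")
  assert_columns(abundance, c("gene_id", "tpm"), "abundance")
  total <- sum(clusters$n_crosslinked)
  if (total == 0) {
    abort("no crosslinked reads in any cluster: cannot compute NXPM.")
  }
  missing <- setdiff(unique(clusters$gene_id), abundance$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("no abundance for gene(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  per_gene <- clusters |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      crosslinked_total = sum(.data$n_crosslinked),
      xl_utr5 = sum(.data$n_crosslinked[.data$category == "utr5"]),
      xl_cds = sum(.data$n_crosslinked[.data$category == "cds"]),
      xl_utr3 = sum(.data$n_crosslinked[.data$category == "utr3"]),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::select(abundance, "gene_id", "tpm"),
                     by = "gene_id") |>
    dplyr::mutate(
      low_abundance = .data$tpm < min_tpm,
      xpm = 1e6 * .data$crosslinked_total / total,
      nxpm = ifelse(.data$low_abundance, NA_real_, .data$xpm / .data$tpm),
      nxpm_utr5 = ifelse(.data$low_abundance, NA_real_,
                         1e6 * .data$xl_utr5 / total / .data$tpm),
      nxpm_cds = ifelse(.data$low_abundance, NA_real_,
                        1e6 * .data$xl_cds / total / .data$tpm),
      nxpm_utr3 = ifelse(.data$low_abundance, NA_real_,
                         1e6 * .data$xl_utr3 / total / .data$tpm)
    ) |>
    dplyr::select(
      "gene_id", "n_clusters", "crosslinked_total", "xpm", "tpm", "nxpm",
      "nxpm_utr5", "nxpm_cds", "nxpm_utr3", "low_abundance"
    )
  class(per_gene) <- c("gene_profiles", class(per_gene))
  per_gene
}

#' Replicate reproducibility of NXPM profiles
#'
#' Coefficient of determination (squared Pearson correlation) of
#' `log10(NXPM + eps)` over genes scored in both replicates. PAR-CLIP
#' libraries of the same protein typically reach R^2 around 0.8-0.95.
#'
#' @param profile_rep1,profile_rep2 `gene_profiles` tibbles from
#'   [compute_nxpm()].
#' @param eps Pseudo-NXPM added before the log transform.
#' @return A single number, R^2 in \[0, 1\].
#' @export
replicate_r2 <- function(profile_rep1, profile_rep2, eps = 1e-3) {
  assert_columns(profile_rep1, c("gene_id", "nxpm"), "profile_rep1")
  assert_columns(profile_rep2, c("gene_id", "nxpm"), "profile_rep2")
  j <- dplyr::inner_join(
    dplyr::filter(profile_rep1, !is.na(.data$nxpm)) |>
      dplyr::select("gene_id", nxpm1 = "nxpm"),
    dplyr::filter(profile_rep2, !is.na(.data$nxpm)) |>
      dplyr::select("gene_id", nxpm2 = "nxpm"),
    by = "gene_id"
  )
  if (nrow(j) < 3L) {
    abort("fewer than 3 genes shared between replicates.")
  }
  cor(log10(j$nxpm1 + eps), log10(j$nxpm2 + eps))^2
}
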