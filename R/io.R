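# File formats: FASTA via Biostrings; everything else is plain TSV with the
# column layouts documented on each function.

#' Read and write transcript sequences as FASTA
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with transcript_id and sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(transcript_id = names(set), sequence = as.character(set))
}

#' @rdname read_fasta
#' @param transcripts Tibble with transcript_id and sequence columns.
#' @export
write_fasta <- function(transcripts, path) {
  assert_columns(transcripts, c("transcript_id", "sequence"), "transcripts")
  set <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                           transcripts$transcript_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write transcript-space PAR-CLIP reads as TSV
#'
#' Columns: transcript_id, start, end (0-based half-open),
#' conversion_offsets (comma-separated read-relative offsets, empty for
#' unconverted reads).
#'
#' @param path TSV path.
#' @return `read_reads_tsv()`: reads tibble with a list-column of offsets.
#' @export
read_reads_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    conversion_offsets = readr::col_character()
  ))
  df$conversion_offsets <- parse_offsets(df$conversion_offsets)
  df
}

#' @rdname read_reads_tsv
#' @param reads Reads tibble (list-column or string offsets).
#' @export
write_reads_tsv <- function(reads, path) {
  reads <- reads_with_offsets(reads)
  out <- dplyr::mutate(
    reads,
    conversion_offsets = format_offsets(.data$conversion_offsets)
  )
  readr::write_tsv(out[, c("transcript_id", "start", "end",
                           "conversion_offsets")], path)
  invisible(path)
}

#' Write clusters as BED6
#'
#' chrom = transcript_id, name = `gene_id:category`, score =
#' n_crosslinked reads, strand = "+" (transcript space).
#'
#' @param clusters `clip_clusters` tibble.
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  assert_columns(clusters, c("transcript_id", "start", "end", "gene_id",
                             "category", "n_crosslinked"), "clusters")
  bed <- tibble(
    chrom = clusters$transcript_id,
    start = clusters$start,
    end = clusters$end,
    name = paste0(clusters$gene_id, ":", clusters$category),
    score = clusters$n_crosslinked,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a full synthetic dataset to a directory
#'
#' Runs the three generators and writes: `transcripts.fasta`,
#' `annotation.tsv` (transcript_id, gene_id, len_5utr, len_cds, len_3utr;
#' transcript-space, 0-based half-open regions), `reads.tsv`, `counts.tsv`,
#' and `truth.tsv`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  sim <- simulate_transcriptome(config)
  reads <- simulate_parclip_reads(sim$transcripts, sim$truth, config)
  counts <- simulate_counts(sim$transcripts, sim$truth, config)
  paths <- list(
    fasta = file.path(dir, "transcripts.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    reads = file.path(dir, "reads.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(sim$transcripts, paths$fasta)
  readr::write_tsv(
    tibble(
      transcript_id = sim$transcripts$transcript_id,
      gene_id = sim$transcripts$gene_id,
      len_5utr = sim$transcripts$utr5_len,
      len_cds = sim$transcripts$cds_len,
      len_3utr = sim$transcripts$utr3_len
    ),
    paths$annotation
  )
  write_reads_tsv(reads, paths$reads)
  readr::write_tsv(counts, paths$counts)
  readr::write_tsv(sim$truth, paths$truth)
  invisible(paths)
}

#' Read an annotation TSV into a transcript model tibble
#'
#' Expects transcript_id, gene_id, len_5utr, len_cds, len_3utr and restores
#' the package-internal utr5_len/cds_len/utr3_len/length columns. Sequence
#' can be merged in from [read_fasta()].
#'
#' @param path Annotation TSV path.
#' @param fasta Optional FASTA path with the matching sequences.
#' @return Transcript model tibble.
#' @export
read_annotation_tsv <- function(path, fasta = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  assert_columns(df, c("transcript_id", "gene_id", "len_5utr", "len_cds",
                       "len_3utr"), "annotation")
  out <- tibble(
    transcript_id = df$transcript_id, gene_id = df$gene_id,
    utr5_len = as.integer(df$len_5utr), cds_len = as.integer(df$len_cds),
    utr3_len = as.integer(df$len_3utr)
  )
  out$length <- out$utr5_len + out$cds_len + out$utr3_len
  if (!is.null(fasta)) {
    out <- dplyr::left_join(out, read_fasta(fasta), by = "transcript_id")
  }
  out
}
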