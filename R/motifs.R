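#' Count overlapping k-mers across a set of sequences
#'
#' Overlapping occurrences are summed across all sequences and reported in
#' the complete 4^k table (absent k-mers get count 0). U is treated as T.
#'
#' @param sequences Character vector of sequences, or a tibble with
#'   transcript_id and sequence columns.
#' @param k k-mer length (default 5, the classic RRE unit).
#' @return Tibble: kmer, count, ordered alphabetically over the DNA alphabet.
#' @examples
#' count_kmers("GGGGGG", k = 5) |> dplyr::filter(count > 0)
#' @export
count_kmers <- function(sequences, k = 5L) {
  assert_scalar_number(k, "k", min = 1, integer = TRUE)
  seqs <- normalize_sequences(sequences)
  if (length(seqs) == 0L) {
    abort("`sequences` is empty.")
  }
  long_enough <- nchar(seqs) >= k
  if (any(long_enough)) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs[long_enough]), width = k
    ))
  } else {
    counts <- setNames(
      rep(0, 4^k),
      Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    )
  }
  tibble(kmer = names(counts), count = as.numeric(counts))
}

#' Scramble a sequence preserving its full nucleotide composition
#'
#' Uniformly random permutation of the characters, so the output has exactly
#' the input's base composition (and therefore its GC content). This is the
#' background generator for [kmer_zscores()].
#'
#' @param sequence A single non-empty sequence.
#' @param seed Optional seed for reproducibility.
#' @return The scrambled sequence.
#' @examples
#' scramble_preserving_composition("ACGTACGT", seed = 1)
#' @export
scramble_preserving_composition <- function(sequence, seed = NULL) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(sample(chars), collapse = "")
}

scramble_set <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) paste(sample(ch), collapse = ""), character(1))
}

#' Classify 5-mers as G-rich, AU-rich, or other
#'
#' G-rich means at least three guanines; otherwise AU-rich means at least
#' four of the five bases are A or U/T; everything else is "other". G-rich
#' takes precedence.
#'
#' @param kmer Character vector of 5-mers (U or T alphabet).
#' @return Character vector of labels.
#' @examples
#' classify_kmer(c("GGGAC", "AUUAU", "ACGUC"))
#' @export
classify_kmer <- function(kmer) {
  seqs <- normalize_sequences(kmer, what = "kmer")
  if (any(nchar(seqs) != 5L)) {
    abort("`kmer` entries must have length 5.")
  }
  n_g <- stringr::str_count(seqs, "G")
  n_au <- stringr::str_count(seqs, "[AT]")
  dplyr::case_when(
    n_g >= 3L ~ "G-rich",
    n_au >= 4L ~ "AU-rich",
    .default = "other"
  )
}

#' k-mer Z-score enrichment against a composition-preserving shuffled null
#'
#' For each k-mer, the target proportion is X = count / total counts over the
#' target sequences. The background is `n_background` independent draws in
#' which every target sequence is scrambled (full composition-preserving
#' permutation) and the proportion vector recomputed; mu and sigma are the
#' per-k-mer mean and standard deviation over draws, and Z = (X - mu) / sigma.
#' Degenerate k-mers (sigma = 0) get Z = 0 when X = mu, and are flagged and
#' excluded from ranking when X != mu.
#'
#' @param target_sequences Character vector (or tibble with sequence column)
#'   of binding-site sequences.
#' @param k k-mer length.
#' @param n_background Number of background draws (>= 2).
#' @param seed Optional seed.
#' @return Tibble (class `kmer_enrichment`): kmer, count, x, mu, sigma, z,
#'   label, degenerate; sorted by decreasing z (degenerate entries last).
#' @examples
#' enr <- kmer_zscores(rep("GGGGGACATC", 20), n_background = 20, seed = 1)
#' head(enr, 3)
#' @export
kmer_zscores <- function(target_sequences, k = 5L, n_background = 50L,
                         seed = NULL) {
  assert_scalar_number(n_background, "n_background", min = 2, integer = TRUE)
  seqs <- normalize_sequences(target_sequences, what = "target_sequences")
  target <- count_kmers(seqs, k = k)
  total <- sum(target$count)
  if (total == 0) {
    abort("no k-mers of the requested length in the target sequences.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  x <- target$count / total
  bg <- vapply(seq_len(n_background), function(b) {
    cnt <- count_kmers(scramble_set(seqs), k = k)$count
    cnt / sum(cnt)
  }, numeric(nrow(target)))
  mu <- rowMeans(bg)
  sigma <- apply(bg, 1L, sd)
  # sigma = 0 with X = mu (e.g. homopolymer targets) is a well-defined null:
  # Z = 0; sigma = 0 with X != mu is infinite-degenerate and excluded from
  # ranking, but still reported
  z <- ifelse(sigma > 0, (x - mu) / sigma,
              ifelse(x == mu, 0, sign(x - mu) * Inf))
  degenerate <- sigma == 0
  out <- tibble(
    kmer = target$kmer, count = target$count,
    x = x, mu = mu, sigma = sigma, z = z,
    label = if (k == 5L) classify_kmer(target$kmer) else NA_character_,
    degenerate = degenerate
  ) |>
    dplyr::arrange(.data$degenerate, dplyr::desc(.data$z))
  class(out) <- c("kmer_enrichment", class(out))
  out
}

#' Scan sequences for canonical rG4 motifs
#'
#' Leftmost-greedy scan for runs of at least `min_tracts` maximal G-tracts of
#' length >= `min_tract`, separated by loops of 1 to `max_loop` nt. Motifs
#' are maximally extended (further qualifying tracts within loop distance are
#' absorbed) and non-overlapping, reported leftmost first. Coordinates are
#' 0-based half-open; tract and loop structure is returned as list-columns.
#' The defaults encode the canonical rG4 criteria (four G-tracts of three or
#' more Gs with short loops); relaxed parameters accommodate the looser
#' grammars recent work suggests can still fold.
#'
#' @param sequences Character vector (names used as transcript_id) or a
#'   tibble with transcript_id and sequence columns.
#' @param min_tract Minimum G-tract length.
#' @param max_loop Maximum loop length between consecutive tracts.
#' @param min_tracts Minimum number of tracts per motif.
#' @return Tibble (class `g4_motifs`): transcript_id, start, end, n_tracts,
#'   tract_lengths, loop_lengths.
#' @examples
#' scan_g4(c(t1 = "GGGAGGGAGGGAGGG"))
#' @export
scan_g4 <- function(sequences, min_tract = 3L, max_loop = 7L,
                    min_tracts = 4L) {
  assert_scalar_number(min_tract, "min_tract", min = 1, integer = TRUE)
  assert_scalar_number(max_loop, "max_loop", min = 1, integer = TRUE)
  assert_scalar_number(min_tracts, "min_tracts", min = 2, integer = TRUE)
  seqs <- normalize_sequences(sequences)
  hits <- purrr::imap(seqs, function(s, id) {
    scan_g4_one(s, id, min_tract, max_loop, min_tracts)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    out <- tibble(
      transcript_id = character(), start = integer(), end = integer(),
      n_tracts = integer(), tract_lengths = list(), loop_lengths = list()
    )
  }
  class(out) <- c("g4_motifs", class(out))
  out
}

scan_g4_one <- function(s, id, min_tract, max_loop, min_tracts) {
  m <- gregexpr("G+", s)[[1]]
  if (m[1] == -1L) {
    return(NULL)
  }
  starts <- as.integer(m) - 1L # to 0-based
  lens <- attr(m, "match.length")
  keep <- lens >= min_tract
  starts <- starts[keep]
  lens <- lens[keep]
  ends <- starts + lens
  nq <- length(starts)
  if (nq < min_tracts) {
    return(NULL)
  }
  res <- list()
  i <- 1L
  while (i <= nq) {
    j <- i
    while (j < nq && (starts[j + 1L] - ends[j]) >= 1L &&
           (starts[j + 1L] - ends[j]) <= max_loop) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_tracts) {
      res[[length(res) + 1L]] <- tibble(
        transcript_id = id,
        start = starts[i], end = ends[j],
        n_tracts = j - i + 1L,
        tract_lengths = list(lens[i:j]),
        loop_lengths = list(
          if (j > i) starts[(i + 1L):j] - ends[i:(j - 1L)] else integer(0)
        )
      )
    }
    i <- j + 1L
  }
  if (length(res) == 0L) NULL else dplyr::bind_rows(res)
}

#' Fraction of motif sites recovered by binding clusters
#'
#' A site counts as recovered if it overlaps any cluster on the same
#' transcript by at least 1 nt. Fractions are reported overall and, when
#' `by_region = TRUE`, per annotation region of the site.
#'
#' @param g4_sites Tibble: transcript_id, start, end (and region if
#'   `by_region`). Typically [scan_g4()] output or an external rG4 catalog.
#' @param clusters Tibble with transcript_id, start, end ([call_clusters()]).
#' @param by_region Also report fractions per site region?
#' @return Tibble: region ("all" plus regions when requested), n_sites,
#'   n_recovered, fraction.
#' @examples
#' sites <- tibble::tibble(transcript_id = "t1", start = 10L, end = 20L)
#' clus <- tibble::tibble(transcript_id = "t1", start = 15L, end = 40L)
#' overlap_with_sites(sites, clus)
#' @export
overlap_with_sites <- function(g4_sites, clusters, by_region = FALSE) {
  assert_columns(g4_sites, c("transcript_id", "start", "end"), "g4_sites")
  assert_columns(clusters, c("transcript_id", "start", "end"), "clusters")
  if (by_region && !"region" %in% names(g4_sites)) {
    abort("`g4_sites` needs a `region` column when `by_region = TRUE`.")
  }
  recovered <- vapply(seq_len(nrow(g4_sites)), function(i) {
    cc <- clusters[clusters$transcript_id == g4_sites$transcript_id[i], ,
                   drop = FALSE]
    any(interval_overlap(g4_sites$start[i], g4_sites$end[i],
                         cc$start, cc$end) > 0L)
  }, logical(1))
  overall <- tibble(
    region = "all",
    n_sites = nrow(g4_sites),
    n_recovered = sum(recovered),
    fraction = if (nrow(g4_sites) > 0L) mean(recovered) else NA_real_
  )
  if (!by_region) {
    return(overall)
  }
  per_region <- tibble(region = g4_sites$region, recovered = recovered) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_recovered = sum(.data$recovered),
      fraction = mean(.data$recovered),
      .groups = "drop"
    )
  dplyr::bind_rows(overall, per_region)
}
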