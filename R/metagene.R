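# Shared geometry for metagene computations: everything is expressed
# relative to the anchor (start codon = CDS start, stop codon = CDS end),
# over the window [0, window_length) downstream of it.
metagene_geometry <- function(transcripts, anchor, window_length, bin_width) {
  if (window_length %% bin_width != 0L) {
    abort("`bin_width` must divide `window_length` exactly.")
  }
  assert_columns(transcripts, c("transcript_id", "utr5_len", "cds_len",
                                "length"), "transcripts")
  anchor_pos <- switch(anchor,
    start_codon = transcripts$utr5_len,
    stop_codon = transcripts$utr5_len + transcripts$cds_len
  )
  n_bins <- window_length %/% bin_width
  bin_start <- seq(0L, window_length - bin_width, by = bin_width)
  bin_end <- bin_start + bin_width
  # nt of each bin actually covered by each transcript (windows truncated at
  # transcript ends contribute partially)
  valid <- pmin(window_length, transcripts$length - anchor_pos)
  avail <- vapply(seq_len(n_bins), function(bi) {
    sum(pmax(0L, pmin(valid, bin_end[bi]) - bin_start[bi]))
  }, numeric(1))
  list(
    anchor_pos = setNames(anchor_pos, transcripts$transcript_id),
    valid = setNames(valid, transcripts$transcript_id),
    n_bins = n_bins, bin_start = bin_start, bin_end = bin_end,
    avail = avail
  )
}

# Per-bin density from cluster intervals given precomputed geometry.
# rel_s/rel_e are anchor-relative cluster bounds; valid is the per-cluster
# usable window extent on its transcript.
metagene_bin_density <- function(rel_s, rel_e, valid, geom, normalize = TRUE) {
  s <- pmax(rel_s, 0)
  e <- pmin(rel_e, valid)
  keep <- e > s
  cov <- numeric(geom$n_bins)
  if (any(keep)) {
    s <- s[keep]
    e <- e[keep]
    for (bi in seq_len(geom$n_bins)) {
      cov[bi] <- sum(pmax(0, pmin(e, geom$bin_end[bi]) -
                            pmax(s, geom$bin_start[bi])))
    }
  }
  # per-bin transcript-availability normalization keeps 3'-truncated
  # windows from deflating distal bins
  dens <- ifelse(geom$avail > 0, cov / geom$avail, 0)
  tot <- sum(dens)
  if (normalize && tot > 0) dens / tot else dens
}

#' Metagene profile of cluster density downstream of an anchor
#'
#' Per-nt coverage by clusters within a window downstream of the start or
#' stop codon, summed over transcripts, weighted by per-bin transcript
#' availability (transcripts whose region is shorter than the window
#' contribute their truncated part rather than being dropped), binned, and
#' normalized to sum to 1. With no signal in any window the all-zero profile
#' is returned un-normalized and flagged via `attr(, "normalized")`.
#'
#' @param clusters Tibble with transcript_id, start, end ([call_clusters()]).
#' @param transcripts Transcript models (utr5_len, cds_len, length).
#' @param anchor "start_codon" or "stop_codon".
#' @param window_length Window in nt downstream of the anchor (defaults: 200
#'   after the start codon, 500 after the stop codon).
#' @param bin_width Bin width in nt; must divide `window_length`.
#' @return Tibble (class `metagene_profile`): bin_start, bin_end, observed.
#' @export
metagene_profile <- function(clusters, transcripts,
                             anchor = c("start_codon", "stop_codon"),
                             window_length = if (anchor == "start_codon")
                               200L else 500L,
                             bin_width = 10L) {
  anchor <- match.arg(anchor)
  geom <- metagene_geometry(transcripts, anchor, window_length, bin_width)
  assert_columns(clusters, c("transcript_id", "start", "end"), "clusters")
  apos <- geom$anchor_pos[clusters$transcript_id]
  dens <- metagene_bin_density(
    clusters$start - apos, clusters$end - apos,
    geom$valid[clusters$transcript_id], geom
  )
  out <- tibble(
    bin_start = geom$bin_start, bin_end = geom$bin_end, observed = dens
  )
  attr(out, "anchor") <- anchor
  attr(out, "normalized") <- sum(dens) > 0
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Randomized-placement null for a metagene profile
#'
#' Each iteration repositions every cluster uniformly at random within its
#' own transcript (length preserved, any in-bounds start) and recomputes the
#' binned profile, giving an empirical null for positional enrichment that
#' preserves per-transcript cluster load and cluster lengths.
#'
#' @inheritParams metagene_profile
#' @param n Number of randomizations (>= 2; 1000 is the conventional choice).
#' @param seed Optional seed.
#' @return List of class `metagene_null`: `bins` (tibble with bin_start,
#'   bin_end, null_mean, null_sd), `draws` (n x n_bins matrix of
#'   per-iteration profiles), `n`, `anchor`.
#' @export
metagene_null <- function(clusters, transcripts,
                          anchor = c("start_codon", "stop_codon"),
                          window_length = if (anchor == "start_codon")
                            200L else 500L,
                          bin_width = 10L, n = 1000L, seed = NULL) {
  anchor <- match.arg(anchor)
  assert_scalar_number(n, "n", min = 2, integer = TRUE)
  geom <- metagene_geometry(transcripts, anchor, window_length, bin_width)
  assert_columns(clusters, c("transcript_id", "start", "end"), "clusters")
  tx_len <- setNames(transcripts$length, transcripts$transcript_id)
  L <- tx_len[clusters$transcript_id]
  len <- clusters$end - clusters$start
  if (any(len > L)) {
    abort("some clusters are longer than their transcript.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  apos <- geom$anchor_pos[clusters$transcript_id]
  valid <- geom$valid[clusters$transcript_id]
  draws <- matrix(0, nrow = n, ncol = geom$n_bins)
  for (it in seq_len(n)) {
    s <- floor(runif(nrow(clusters)) * (L - len + 1))
    draws[it, ] <- metagene_bin_density(s - apos, s + len - apos, valid, geom)
  }
  bins <- tibble(
    bin_start = geom$bin_start, bin_end = geom$bin_end,
    null_mean = colMeans(draws),
    null_sd = apply(draws, 2L, sd)
  )
  structure(
    list(bins = bins, draws = draws, n = n, anchor = anchor),
    class = "metagene_null"
  )
}

#' @export
print.metagene_null <- function(x, ...) {
  cat("<metagene_null>", x$n, "randomizations,", ncol(x$draws),
      "bins, anchor =", x$anchor, "\n")
  invisible(x)
}

#' Observed metagene profile joined with its randomized null
#'
#' Convenience wrapper running [metagene_profile()] and [metagene_null()]
#' with shared parameters and joining the results for plotting and
#' enrichment assessment.
#'
#' @inheritParams metagene_null
#' @return Tibble (class `metagene_profile`): bin_start, bin_end, observed,
#'   null_mean, null_sd, enrichment ((observed - null_mean) / null_sd).
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", utr5_len = 100L,
#'                      cds_len = 600L, utr3_len = 300L, length = 1000L)
#' cl <- tibble::tibble(transcript_id = "t1", start = 105L, end = 125L)
#' metagene(cl, tx, "start_codon", n = 50, seed = 1)
#' @export
metagene <- function(clusters, transcripts,
                     anchor = c("start_codon", "stop_codon"),
                     window_length = if (anchor == "start_codon") 200L
                       else 500L,
                     bin_width = 10L, n = 1000L, seed = NULL) {
  anchor <- match.arg(anchor)
  obs <- metagene_profile(clusters, transcripts, anchor, window_length,
                          bin_width)
  nul <- metagene_null(clusters, transcripts, anchor, window_length,
                       bin_width, n = n, seed = seed)
  out <- obs |>
    dplyr::left_join(nul$bins, by = c("bin_start", "bin_end")) |>
    dplyr::mutate(
      enrichment = ifelse(.data$null_sd > 0,
                          (.data$observed - .data$null_mean) / .data$null_sd,
                          NA_real_)
    )
  attr(out, "anchor") <- anchor
  attr(out, "normalized") <- attr(obs, "normalized")
  attr(out, "n_randomizations") <- n
  class(out) <- c("metagene_profile", class(out))
  out
}
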