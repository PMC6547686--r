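#' Configuration for the synthetic PAR-CLIP / expression simulator
#'
#' Bundles and validates every tunable of the generator: transcript geometry,
#' which fraction of genes receives a planted G4 binding site and where,
#' the occupancy distribution of those sites, the planted knockout effects on
#' mRNA and ribosome-protected fragments (RPFs), negative-binomial dispersion,
#' library depths, and T-to-C conversion probabilities.
#'
#' Planted effects are defined on scaled occupancy: raw occupancies are drawn
#' log-normal (median 1, `sdlog = occupancy_scale`), clipped at their 95th
#' percentile and divided by it, so every planted log2 fold change is bounded
#' by `beta_mrna` (respectively `beta_rpf`). `occupancy_scale = 0` is the
#' degenerate case where every target has occupancy exactly 1, so every
#' target's planted mRNA LFC equals `beta_mrna`.
#'
#' @param n_genes Number of genes (one principal transcript each).
#' @param utr5_range,cds_range,utr3_range Length ranges in nt for the three
#'   transcript regions; CDS lengths are rounded to multiples of 3.
#' @param target_fraction Fraction of genes given one planted binding site.
#' @param region_weights Placement probabilities over 5'UTR/CDS/3'UTR
#'   (must sum to 1).
#' @param occupancy_scale Log-normal sdlog for site strength (>= 0).
#' @param beta_mrna,beta_rpf Planted log2 fold change in KO per unit scaled
#'   occupancy, for mRNA and RPF counts.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param depth_parclip,depth_rna,depth_rpf Library depths: PAR-CLIP reads
#'   per library, expected RNA-seq and Ribo-seq counts per sample.
#' @param n_reps Replicates per (assay, condition).
#' @param conv_prob_site,conv_prob_background T-to-C conversion probability
#'   per eligible T for site reads and background reads.
#' @param site_read_fraction Expected fraction of PAR-CLIP reads originating
#'   from planted sites.
#' @param read_length PAR-CLIP read length in nt.
#' @param expr_sdlog Log-normal sdlog of baseline gene expression.
#' @param seed Integer master seed; each generator derives its own stream.
#'
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' @export
sim_config <- function(n_genes = 500,
                       utr5_range = c(100L, 300L),
                       cds_range = c(300L, 1500L),
                       utr3_range = c(200L, 800L),
                       target_fraction = 0.3,
                       region_weights = c(utr5 = 0.2, cds = 0.4, utr3 = 0.4),
                       occupancy_scale = 1,
                       beta_mrna = 0.3,
                       beta_rpf = 0,
                       nb_dispersion = 0.05,
                       depth_parclip = 30000L,
                       depth_rna = 2e6,
                       depth_rpf = 1e6,
                       n_reps = 3L,
                       conv_prob_site = 0.25,
                       conv_prob_background = 0.01,
                       site_read_fraction = 0.8,
                       read_length = 30L,
                       expr_sdlog = 1,
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", min = 0, integer = TRUE)
  assert_scalar_number(target_fraction, "target_fraction", min = 0, max = 1)
  assert_scalar_number(occupancy_scale, "occupancy_scale", min = 0)
  assert_scalar_number(beta_mrna, "beta_mrna")
  assert_scalar_number(beta_rpf, "beta_rpf")
  if (!is.finite(beta_mrna) || !is.finite(beta_rpf)) {
    abort("`beta_mrna` and `beta_rpf` must be finite.")
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", min = 1e-12)
  assert_scalar_number(depth_parclip, "depth_parclip", min = 0, integer = TRUE)
  assert_scalar_number(depth_rna, "depth_rna", min = 0)
  assert_scalar_number(depth_rpf, "depth_rpf", min = 0)
  assert_scalar_number(n_reps, "n_reps", min = 1, integer = TRUE)
  assert_scalar_number(conv_prob_site, "conv_prob_site", min = 0, max = 1)
  assert_scalar_number(conv_prob_background, "conv_prob_background",
                       min = 0, max = 1)
  assert_scalar_number(site_read_fraction, "site_read_fraction",
                       min = 0, max = 1)
  assert_scalar_number(read_length, "read_length", min = 10, integer = TRUE)
  assert_scalar_number(expr_sdlog, "expr_sdlog", min = 0)
  assert_scalar_number(seed, "seed", integer = TRUE)
  for (rng in list(utr5_range, cds_range, utr3_range)) {
    if (length(rng) != 2L || any(rng < 1) || rng[1] > rng[2]) {
      abort("region length ranges must be increasing pairs of positive nt.")
    }
  }
  if (length(region_weights) != 3L || any(region_weights < 0) ||
      abs(sum(region_weights) - 1) > 1e-8) {
    abort("`region_weights` must be 3 non-negative values summing to 1.")
  }
  names(region_weights) <- c("utr5", "cds", "utr3")
  structure(
    list(
      n_genes = as.integer(n_genes),
      utr5_range = as.integer(utr5_range),
      cds_range = as.integer(cds_range),
      utr3_range = as.integer(utr3_range),
      target_fraction = target_fraction,
      region_weights = region_weights,
      occupancy_scale = occupancy_scale,
      beta_mrna = beta_mrna,
      beta_rpf = beta_rpf,
      nb_dispersion = nb_dispersion,
      depth_parclip = as.integer(depth_parclip),
      depth_rna = depth_rna,
      depth_rpf = depth_rpf,
      n_reps = as.integer(n_reps),
      conv_prob_site = conv_prob_site,
      conv_prob_background = conv_prob_background,
      site_read_fraction = site_read_fraction,
      read_length = as.integer(read_length),
      expr_sdlog = expr_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "genes,",
      sprintf("%.0f%% targets,", 100 * x$target_fraction),
      "beta_mrna =", x$beta_mrna, "beta_rpf =", x$beta_rpf,
      "seed =", x$seed, "\n")
  invisible(x)
}

# Random background with every G-run capped below 3 nt: sample uniform ACGT,
# then rewrite the 3rd and later G of each maximal run to a random non-G base.
# Guarantees the planted motifs are the only canonical G4s in the transcript.
random_background <- function(len) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  r <- rle(chars)
  long_g <- which(r$values == "G" & r$lengths >= 3L)
  if (length(long_g) > 0L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fix <- unlist(lapply(long_g, function(i) (starts[i] + 2L):ends[i]))
    chars[fix] <- sample(c("A", "C", "T"), length(fix), replace = TRUE)
  }
  paste(chars, collapse = "")
}

# One planted rG4: >= 4 G-tracts of 3-4 nt, loops of 1-7 nt drawn from
# {A,C,T} so the motif grammar matches scan_g4() defaults exactly.
random_g4_motif <- function(n_tracts = 4L, tract_range = c(3L, 4L),
                            loop_range = c(1L, 7L)) {
  tracts <- sample(seq(tract_range[1], tract_range[2]), n_tracts,
                   replace = TRUE)
  loops <- sample(seq(loop_range[1], loop_range[2]), n_tracts - 1L,
                  replace = TRUE)
  pieces <- character(2L * n_tracts - 1L)
  pieces[seq(1L, by = 2L, length.out = n_tracts)] <-
    vapply(tracts, function(l) strrep("G", l), character(1))
  pieces[seq(2L, by = 2L, length.out = n_tracts - 1L)] <-
    vapply(loops, function(l) {
      paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  paste(pieces, collapse = "")
}

#' Simulate a transcriptome with planted G4 binding sites
#'
#' Generates `n_genes` transcripts, each partitioned into contiguous
#' 5'UTR/CDS/3'UTR segments, with background sequence whose G-runs are capped
#' below 3 nt. A `target_fraction` of genes receives exactly one planted
#' canonical rG4 motif (four G-tracts of >= 3 G, loops of 1-7 nt) in a region
#' chosen by `region_weights`, so the planted motifs are the only canonical
#' G4s present. Ground truth records site coordinates, occupancy, and the
#' planted log2 fold changes consistent with `lfc_te = lfc_rpf - lfc_mrna`.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this generator; defaults to `config$seed`.
#'
#' @return A list with `transcripts` (tibble: transcript_id, gene_id,
#'   utr5_len, cds_len, utr3_len, length, sequence) and `truth` (tibble:
#'   gene_id, transcript_id, is_target, region, site_start, site_end,
#'   occupancy, scaled_occupancy, expr_rel, lfc_mrna, lfc_rpf, lfc_te).
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_genes = 20, seed = 1))
#' sim$truth
#' @export
simulate_transcriptome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  empty_tx <- tibble(
    transcript_id = character(), gene_id = character(),
    utr5_len = integer(), cds_len = integer(), utr3_len = integer(),
    length = integer(), sequence = character()
  )
  empty_truth <- tibble(
    gene_id = character(), transcript_id = character(),
    is_target = logical(), region = character(),
    site_start = integer(), site_end = integer(),
    occupancy = double(), scaled_occupancy = double(), expr_rel = double(),
    lfc_mrna = double(), lfc_rpf = double(), lfc_te = double()
  )
  if (n == 0L) {
    return(list(transcripts = empty_tx, truth = empty_truth))
  }
  withr::local_seed(seed)

  gene_id <- sprintf("gene%04d", seq_len(n))
  transcript_id <- sprintf("tx%04d", seq_len(n))
  utr5 <- sample(config$utr5_range[1]:config$utr5_range[2], n, replace = TRUE)
  cds <- sample(config$cds_range[1]:config$cds_range[2], n, replace = TRUE)
  cds <- pmax(3L, (cds %/% 3L) * 3L)
  utr3 <- sample(config$utr3_range[1]:config$utr3_range[2], n, replace = TRUE)
  total <- utr5 + cds + utr3
  sequence <- vapply(total, random_background, character(1))

  is_target <- runif(n) < config$target_fraction
  n_t <- sum(is_target)
  region <- rep(NA_character_, n)
  site_start <- rep(NA_integer_, n)
  site_end <- rep(NA_integer_, n)
  occupancy <- rep(0, n)
  if (n_t > 0L) {
    region[is_target] <- sample(names(config$region_weights), n_t,
                                replace = TRUE,
                                prob = config$region_weights)
    occ <- if (config$occupancy_scale == 0) {
      rep(1, n_t)
    } else {
      rlnorm(n_t, meanlog = 0, sdlog = config$occupancy_scale)
    }
    occupancy[is_target] <- occ
    for (i in which(is_target)) {
      motif <- random_g4_motif()
      ml <- nchar(motif)
      bounds <- switch(region[i],
        utr5 = c(0L, utr5[i]),
        cds  = c(utr5[i], utr5[i] + cds[i]),
        utr3 = c(utr5[i] + cds[i], total[i])
      )
      # region lengths are always > max motif length (37 nt) by construction
      s <- bounds[1] + sample.int(bounds[2] - bounds[1] - ml + 1L, 1L) - 1L
      substr(sequence[i], s + 1L, s + ml) <- motif
      # non-G buffer on both flanks so the planted G-tracts never fuse with
      # background Gs and the recorded site interval stays exact
      for (flank in c(s, s + ml + 1L)) {
        if (flank >= 1L && flank <= total[i] &&
            substr(sequence[i], flank, flank) == "G") {
          substr(sequence[i], flank, flank) <- sample(c("A", "C", "T"), 1L)
        }
      }
      site_start[i] <- s
      site_end[i] <- s + ml
    }
  }
  q95 <- if (n_t > 0L) quantile(occupancy[is_target], 0.95, names = FALSE) else 1
  scaled <- if (q95 > 0) pmin(occupancy, q95) / q95 else occupancy
  lfc_mrna <- config$beta_mrna * scaled
  lfc_rpf <- config$beta_rpf * scaled
  expr_rel <- rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)

  transcripts <- tibble(
    transcript_id = transcript_id, gene_id = gene_id,
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    length = total, sequence = sequence
  )
  truth <- tibble(
    gene_id = gene_id, transcript_id = transcript_id,
    is_target = is_target, region = region,
    site_start = site_start, site_end = site_end,
    occupancy = occupancy, scaled_occupancy = scaled, expr_rel = expr_rel,
    lfc_mrna = lfc_mrna, lfc_rpf = lfc_rpf,
    lfc_te = lfc_rpf - lfc_mrna
  )
  attr(truth, "seed") <- seed
  list(transcripts = transcripts, truth = truth)
}

# Draw T-to-C conversions for reads over one transcript, vectorized across
# reads: tpos is the sorted 0-based positions of reference Ts.
draw_conversions <- function(starts, ends, tpos, prob) {
  n <- length(starts)
  out <- rep(list(integer(0)), n)
  if (n == 0L || length(tpos) == 0L || prob <= 0) {
    return(out)
  }
  lo <- findInterval(starts - 0.5, tpos) + 1L
  hi <- findInterval(ends - 0.5, tpos)
  cnt <- pmax(0L, hi - lo + 1L)
  keep <- cnt > 0L
  if (!any(keep)) {
    return(out)
  }
  idx <- sequence(cnt[keep]) + rep(lo[keep] - 1L, cnt[keep])
  read_of <- rep(which(keep), cnt[keep])
  hit <- runif(length(idx)) < prob
  if (any(hit)) {
    offs <- tpos[idx[hit]] - starts[read_of[hit]]
    got <- split(offs, read_of[hit])
    out[as.integer(names(got))] <- got
  }
  out
}

#' Simulate transcript-space PAR-CLIP reads
#'
#' Site reads are drawn with probability `site_read_fraction`, assigned to
#' target genes with rate proportional to occupancy times relative expression,
#' and placed so that each read overlaps the planted site by at least 1 nt.
#' Background reads pick a gene proportional to expression and a uniform
#' position. Every T within a read converts to C independently with
#' `conv_prob_site` (site reads) or `conv_prob_background`; conversion
#' offsets are read-relative and fall only on reference-T positions.
#'
#' @param transcripts,truth Output of [simulate_transcriptome()].
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 1`.
#'
#' @return Tibble: transcript_id, start, end, conversion_offsets
#'   (list-column of 0-based integer offsets), origin ("site"/"background").
#' @examples
#' cfg <- sim_config(n_genes = 20, depth_parclip = 200, seed = 1)
#' sim <- simulate_transcriptome(cfg)
#' reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
#' @export
simulate_parclip_reads <- function(transcripts, truth, config,
                                   seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(transcripts, c("transcript_id", "length", "sequence"),
                 "transcripts")
  if (!identical(truth$transcript_id, transcripts$transcript_id)) {
    abort("`truth` and `transcripts` must describe the same transcripts.")
  }
  empty <- tibble(
    transcript_id = character(), start = integer(), end = integer(),
    conversion_offsets = list(), origin = character()
  )
  depth <- config$depth_parclip
  if (depth == 0L || nrow(transcripts) == 0L) {
    return(empty)
  }
  withr::local_seed(seed)

  rl <- config$read_length
  L <- transcripts$length
  is_site_read <- runif(depth) < config$site_read_fraction
  targets <- which(truth$is_target)
  if (length(targets) == 0L) {
    is_site_read[] <- FALSE
  }
  n_site <- sum(is_site_read)
  n_bg <- depth - n_site

  tx_idx <- integer(depth)
  starts <- integer(depth)
  if (n_site > 0L) {
    w <- truth$occupancy[targets] * truth$expr_rel[targets]
    gi <- targets[sample.int(length(targets), n_site, replace = TRUE,
                             prob = w)]
    lo <- pmax(0L, truth$site_start[gi] - rl + 1L)
    hi <- pmin(L[gi] - rl, truth$site_end[gi] - 1L)
    hi <- pmax(hi, lo)
    s <- lo + floor(runif(n_site) * (hi - lo + 1L))
    tx_idx[is_site_read] <- gi
    starts[is_site_read] <- as.integer(s)
  }
  if (n_bg > 0L) {
    gi <- sample.int(nrow(transcripts), n_bg, replace = TRUE,
                     prob = truth$expr_rel)
    s <- floor(runif(n_bg) * (L[gi] - rl + 1L))
    tx_idx[!is_site_read] <- gi
    starts[!is_site_read] <- as.integer(s)
  }
  ends <- starts + rl

  tpos_all <- lapply(strsplit(transcripts$sequence, "", fixed = TRUE),
                     function(ch) which(ch == "T") - 1L)
  offsets <- rep(list(integer(0)), depth)
  for (sflag in c(TRUE, FALSE)) {
    prob <- if (sflag) config$conv_prob_site else config$conv_prob_background
    sel <- which(is_site_read == sflag)
    if (length(sel) == 0L) next
    for (tx in unique(tx_idx[sel])) {
      rows <- sel[tx_idx[sel] == tx]
      offsets[rows] <- draw_conversions(starts[rows], ends[rows],
                                        tpos_all[[tx]], prob)
    }
  }
  out <- tibble(
    transcript_id = transcripts$transcript_id[tx_idx],
    start = starts, end = ends,
    conversion_offsets = offsets,
    origin = ifelse(is_site_read, "site", "background")
  )
  attr(out, "seed") <- seed
  out
}

#' Simulate WT/KO RNA-seq and Ribo-seq count matrices
#'
#' Baseline per-gene means follow the relative expression fixed by
#' [simulate_transcriptome()], scaled to the library depth. KO means are the
#' WT means times `2^(beta * scaled occupancy)` (beta_mrna for RNA, beta_rpf
#' for RPF). Counts are negative binomial with the configured dispersion.
#'
#' @param transcripts,truth Output of [simulate_transcriptome()].
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 2`.
#'
#' @return A tibble (class `expression_table`) with `gene_id` and one integer
#'   column per sample, named `{assay}_{condition}_{replicate}` (for example
#'   `RNA_WT_1`); sample metadata is in `attr(, "samples")` and via
#'   [sample_info()].
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' sim <- simulate_transcriptome(cfg)
#' counts <- simulate_counts(sim$transcripts, sim$truth, cfg)
#' sample_info(counts)
#' @export
simulate_counts <- function(transcripts, truth, config,
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(truth$transcript_id, transcripts$transcript_id)) {
    abort("`truth` and `transcripts` must describe the same transcripts.")
  }
  withr::local_seed(seed)
  n <- nrow(truth)
  p <- truth$expr_rel / sum(truth$expr_rel)
  size <- 1 / config$nb_dispersion

  grid <- expand.grid(
    replicate = seq_len(config$n_reps),
    condition = c("WT", "KO"),
    assay = c("RNA", "RPF"),
    stringsAsFactors = FALSE
  )
  samples <- tibble(
    sample = sprintf("%s_%s_%d", grid$assay, grid$condition, grid$replicate),
    assay = grid$assay, condition = grid$condition,
    replicate = grid$replicate
  )
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    depth <- if (samples$assay[j] == "RNA") config$depth_rna else
      config$depth_rpf
    lfc <- if (samples$assay[j] == "RNA") truth$lfc_mrna else truth$lfc_rpf
    mu <- depth * p
    if (samples$condition[j] == "KO") {
      mu <- mu * 2^lfc
    }
    counts[, j] <- rnbinom(n, mu = mu, size = size)
  }
  out <- tibble(gene_id = truth$gene_id)
  out <- dplyr::bind_cols(out, as_tibble(counts))
  attr(out, "samples") <- samples
  attr(out, "seed") <- seed
  class(out) <- c("expression_table", class(out))
  out
}

#' Sample metadata of a simulated expression table
#'
#' @param x An `expression_table` from [simulate_counts()] or a counts tibble
#'   whose column names follow the `{assay}_{condition}_{replicate}` pattern.
#' @return Tibble: sample, assay, condition, replicate.
#' @export
sample_info <- function(x) {
  s <- attr(x, "samples")
  if (!is.null(s)) {
    return(s)
  }
  cols <- setdiff(names(x), "gene_id")
  m <- regmatches(cols, regexec("^(RNA|RPF)_(WT|KO)_(\\d+)$", cols))
  ok <- lengths(m) == 4L
  if (!any(ok)) {
    abort("no sample columns match the {assay}_{condition}_{replicate} pattern.")
  }
  tibble(
    sample = cols[ok],
    assay = vapply(m[ok], `[`, character(1), 2L),
    condition = vapply(m[ok], `[`, character(1), 3L),
    replicate = as.integer(vapply(m[ok], `[`, character(1), 4L))
  )
}
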