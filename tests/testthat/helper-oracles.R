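# Independent reference implementations used as oracles. Each is written to
# be obviously correct (brute force / closed form), not fast, and shares no
# code with the package internals it checks.

# O(n^2) interval merge: repeatedly fuse any two overlapping read extents
# until a fixed point, then apply the three cluster filters.
oracle_call_clusters <- function(reads, min_reads, min_crosslinked,
                                 min_conv_frac) {
  out <- list()
  for (tx in unique(reads$transcript_id)) {
    r <- reads[reads$transcript_id == tx, ]
    groups <- as.list(seq_len(nrow(r)))
    repeat {
      fused <- FALSE
      for (i in seq_along(groups)) {
        if (is.null(groups[[i]])) next
        for (j in seq_along(groups)) {
          if (j <= i || is.null(groups[[j]])) next
          si <- min(r$start[groups[[i]]]); ei <- max(r$end[groups[[i]]])
          sj <- min(r$start[groups[[j]]]); ej <- max(r$end[groups[[j]]])
          if (max(si, sj) < min(ei, ej)) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[j] <- list(NULL)
            fused <- TRUE
          }
        }
      }
      if (!fused) break
    }
    for (g in groups) {
      if (is.null(g)) next
      n_conv <- sum(lengths(r$conversion_offsets[g]) > 0)
      n <- length(g)
      if (n >= min_reads && n_conv >= min_crosslinked &&
          n_conv / n >= min_conv_frac) {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = tx,
          start = min(r$start[g]), end = max(r$end[g]),
          n_reads = n, n_crosslinked = n_conv
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), n_reads = integer(),
                      n_crosslinked = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$transcript_id, res$start), , drop = FALSE]
}

# Exhaustive G4 scanner: enumerate every maximal chain of qualifying
# G-tracts with all loops in 1..max_loop, then keep non-overlapping motifs
# leftmost-first. G-runs found by a character walk, not regex.
oracle_scan_g4 <- function(seq, min_tract, max_loop, min_tracts) {
  ch <- strsplit(seq, "")[[1]]
  runs <- list()
  i <- 1
  while (i <= length(ch)) {
    if (ch[i] == "G") {
      j <- i
      while (j < length(ch) && ch[j + 1] == "G") j <- j + 1
      if (j - i + 1 >= min_tract) {
        runs[[length(runs) + 1]] <- c(start = i - 1, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) < min_tracts) {
    return(data.frame(start = integer(), end = integer(),
                      n_tracts = integer()))
  }
  rs <- vapply(runs, `[`, numeric(1), "start")
  re <- vapply(runs, `[`, numeric(1), "end")
  nq <- length(rs)
  # all chains [a, b] of consecutive runs with every gap in 1..max_loop
  ok_gap <- function(a, b) {
    all(rs[(a + 1):b] - re[a:(b - 1)] >= 1 &
          rs[(a + 1):b] - re[a:(b - 1)] <= max_loop)
  }
  chains <- list()
  for (a in seq_len(nq)) {
    for (b in a:nq) {
      if (b - a + 1 < min_tracts) next
      if (b > a && !ok_gap(a, b)) next
      chains[[length(chains) + 1]] <- c(a = a, b = b)
    }
  }
  if (length(chains) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      n_tracts = integer()))
  }
  # maximal chains only (not extensible left or right)
  maximal <- Filter(function(cc) {
    a <- cc["a"]; b <- cc["b"]
    left <- a > 1 && (rs[a] - re[a - 1]) >= 1 && (rs[a] - re[a - 1]) <= max_loop
    right <- b < nq && (rs[b + 1] - re[b]) >= 1 &&
      (rs[b + 1] - re[b]) <= max_loop
    !left && !right
  }, chains)
  df <- do.call(rbind, lapply(maximal, function(cc) {
    data.frame(start = rs[cc["a"]], end = re[cc["b"]],
               n_tracts = cc["b"] - cc["a"] + 1)
  }))
  df <- df[order(df$start), , drop = FALSE]
  # non-overlapping, leftmost-first
  keep <- rep(TRUE, nrow(df))
  last_end <- -1
  for (i in seq_len(nrow(df))) {
    if (df$start[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- df$end[i]
    }
  }
  rownames(df) <- NULL
  df[keep, , drop = FALSE]
}

# Two-sample KS by full enumeration over all assignments of the pooled
# sample: D and the exact two-sided p-value P(D* >= D_obs) under exchange.
oracle_ks <- function(x, y) {
  ks_d <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
  }
  d_obs <- ks_d(x, y)
  pool <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pool), n)
  ds <- apply(combos, 2, function(idx) ks_d(pool[idx], pool[-idx]))
  list(d = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# Closed-form least squares for ln(level) = a + b t via normal equations.
oracle_loglinear_slope <- function(t, y) {
  ly <- log(y)
  b <- sum((t - mean(t)) * (ly - mean(ly))) / sum((t - mean(t))^2)
  a <- mean(ly) - b * mean(t)
  c(intercept = a, slope = b)
}

# Plain substring k-mer counter.
oracle_count_kmer <- function(seqs, kmer) {
  k <- nchar(kmer)
  sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    sum(vapply(seq_len(n - k + 1), function(i) {
      substr(s, i, i + k - 1) == kmer
    }, logical(1)))
  }, integer(1)))
}

# Random read sets for cluster-calling property tests.
random_reads <- function(n, tx_ids = c("t1", "t2"), L = 300, seed) {
  withr::with_seed(seed, {
    start <- sample.int(L - 30, n, replace = TRUE) - 1L
    len <- sample(10:30, n, replace = TRUE)
    nconv <- stats::rbinom(n, 3, 0.4)
    tibble::tibble(
      transcript_id = sample(tx_ids, n, replace = TRUE),
      start = start,
      end = pmin(start + len, L),
      conversion_offsets = lapply(seq_len(n), function(i) {
        if (nconv[i] == 0) integer(0) else sort(sample.int(len[i], nconv[i]) - 1L)
      })
    )
  })
}

toy_transcripts <- function(ids = c("t1", "t2"), utr5 = 100L, cds = 300L,
                            utr3 = 200L) {
  tibble::tibble(
    transcript_id = ids,
    gene_id = paste0("g_", ids),
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    length = utr5 + cds + utr3
  )
}
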