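#' Normalize a count matrix
#'
#' Two transparent schemes: `cpm` (counts per million: 1e6 x count /
#' column sum) and `median_of_ratios` (per-sample size factor = median over
#' genes of count / geometric row mean, genes with any zero excluded from
#' factor estimation; normalized abundance = count / size factor). The
#' latter is the standard library-composition-robust normalization for
#' differential comparisons.
#'
#' @param counts Tibble: gene_id + integer sample columns.
#' @param method "median_of_ratios" or "cpm".
#' @return Tibble of normalized abundances, same shape as `counts`; size
#'   factors (median_of_ratios) in `attr(, "size_factors")`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                          s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
#' normalize_counts(counts, "median_of_ratios")
#' @export
normalize_counts <- function(counts,
                             method = c("median_of_ratios", "cpm")) {
  method <- match.arg(method)
  assert_columns(counts, "gene_id", "counts")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  if (any(m < 0)) {
    abort("counts must be non-negative.")
  }
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(sprintf("all-zero sample column(s): %s",
                  paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  if (method == "cpm") {
    norm <- sweep(m, 2L, cs, "/") * 1e6
    sf <- cs / 1e6
  } else {
    all_nonzero <- rowSums(m == 0) == 0L
    if (!any(all_nonzero)) {
      abort("median-of-ratios needs >= 1 gene with nonzero counts in all samples.")
    }
    geo <- exp(rowMeans(log(m[all_nonzero, , drop = FALSE])))
    sf <- apply(m[all_nonzero, , drop = FALSE] / geo, 2L, median)
    norm <- sweep(m, 2L, sf, "/")
  }
  out <- dplyr::bind_cols(tibble(gene_id = counts$gene_id), as_tibble(norm))
  attr(out, "size_factors") <- sf
  attr(out, "method") <- method
  out
}

#' Per-gene log2 fold change between conditions
#'
#' `log2((mean_KO + pseudocount) / (mean_WT + pseudocount))`, means taken
#' over the replicate columns of normalized abundance.
#'
#' @param abundance Normalized abundance tibble (gene_id + sample columns),
#'   e.g. from [normalize_counts()].
#' @param wt_samples,ko_samples Column names of the two replicate groups;
#'   defaults use the `{assay}_{condition}_{replicate}` pattern restricted to
#'   the columns present.
#' @param pseudocount Positive stabilizer added to both means.
#' @return Tibble: gene_id, mean_wt, mean_ko, lfc.
#' @export
log2fc <- function(abundance,
                   wt_samples = grep("_WT_", names(abundance), value = TRUE),
                   ko_samples = grep("_KO_", names(abundance), value = TRUE),
                   pseudocount = 1) {
  assert_columns(abundance, c("gene_id", wt_samples, ko_samples),
                 "abundance")
  assert_scalar_number(pseudocount, "pseudocount", min = 1e-300)
  mean_wt <- rowMeans(as.matrix(abundance[, wt_samples, drop = FALSE]))
  mean_ko <- rowMeans(as.matrix(abundance[, ko_samples, drop = FALSE]))
  tibble(
    gene_id = abundance$gene_id,
    mean_wt = mean_wt, mean_ko = mean_ko,
    lfc = log2((mean_ko + pseudocount) / (mean_wt + pseudocount))
  )
}

#' Translational efficiency and its knockout response
#'
#' TE = RPF abundance / RNA abundance per condition (replicate means of
#' normalized abundance); delta_te = log2(TE_KO / TE_WT). Genes whose mean
#' abundance falls below `min_abund` in any of the four (assay, condition)
#' groups are flagged `excluded` rather than silently dropped, and their TE
#' values set NA.
#'
#' @param rna_abund,rpf_abund Normalized abundance tibbles for RNA-seq and
#'   Ribo-seq, with matched gene universes and `_WT_` / `_KO_` replicate
#'   columns.
#' @param min_abund Minimum mean normalized abundance in every group.
#' @return Tibble: gene_id, te_wt, te_ko, delta_te, excluded.
#' @examples
#' rna <- tibble::tibble(gene_id = "g", RNA_WT_1 = 5, RNA_KO_1 = 10)
#' rpf <- tibble::tibble(gene_id = "g", RPF_WT_1 = 10, RPF_KO_1 = 10)
#' translational_efficiency(rna, rpf) # TE 2 -> 1, delta_te = -1
#' @export
translational_efficiency <- function(rna_abund, rpf_abund, min_abund = 1) {
  assert_columns(rna_abund, "gene_id", "rna_abund")
  assert_columns(rpf_abund, "gene_id", "rpf_abund")
  if (!identical(sort(rna_abund$gene_id), sort(rpf_abund$gene_id))) {
    abort("`rna_abund` and `rpf_abund` must cover the same genes.")
  }
  rpf_abund <- rpf_abund[match(rna_abund$gene_id, rpf_abund$gene_id), ]
  grp_mean <- function(df, pat) {
    cols <- grep(pat, names(df), value = TRUE)
    if (length(cols) == 0L) {
      abort(sprintf("no columns matching `%s`.", pat))
    }
    rowMeans(as.matrix(df[, cols, drop = FALSE]))
  }
  rna_wt <- grp_mean(rna_abund, "_WT_")
  rna_ko <- grp_mean(rna_abund, "_KO_")
  rpf_wt <- grp_mean(rpf_abund, "_WT_")
  rpf_ko <- grp_mean(rpf_abund, "_KO_")
  excluded <- rna_wt < min_abund | rna_ko < min_abund |
    rpf_wt < min_abund | rpf_ko < min_abund
  te_wt <- ifelse(excluded | rna_wt == 0, NA_real_, rpf_wt / rna_wt)
  te_ko <- ifelse(excluded | rna_ko == 0, NA_real_, rpf_ko / rna_ko)
  tibble(
    gene_id = rna_abund$gene_id,
    te_wt = te_wt, te_ko = te_ko,
    delta_te = log2(te_ko / te_wt),
    excluded = excluded
  )
}

#' Bin genes by binding occupancy
#'
#' Partitions a gene universe into a non-target reference bin (genes with no
#' clusters), right-open metric bins over `bounds`, and — when binning on an
#' NXPM metric — an "unscored" bin for genes that have clusters but were
#' excluded from NXPM by the abundance filter.
#'
#' @param genes Character vector of gene ids (the full universe), or a tibble
#'   with a gene_id column.
#' @param profiles `gene_profiles` tibble from [compute_nxpm()].
#' @param metric One of "nxpm", "nxpm_utr5", "nxpm_cds", "nxpm_utr3",
#'   "n_clusters".
#' @param bounds Strictly increasing numeric bounds; bin i is
#'   \[bounds\[i\], bounds\[i+1\]).
#' @return Tibble: gene_id, metric_value, bin (factor: "non-target", the
#'   interval labels, possibly "unscored").
#' @examples
#' prof <- tibble::tibble(gene_id = "g1", n_clusters = 2L, nxpm = 150,
#'                        low_abundance = FALSE)
#' bin_targets(c("g1", "g2"), prof, bounds = c(0, 10, 100, Inf))
#' @export
bin_targets <- function(genes, profiles,
                        metric = c("nxpm", "nxpm_utr5", "nxpm_cds",
                                   "nxpm_utr3", "n_clusters"),
                        bounds = c(0, 10, 100, Inf)) {
  metric <- match.arg(metric)
  if (is.data.frame(genes)) {
    assert_columns(genes, "gene_id", "genes")
    genes <- genes$gene_id
  }
  if (anyDuplicated(genes)) {
    abort("`genes` must be unique.")
  }
  if (length(bounds) < 2L || any(diff(bounds) <= 0)) {
    abort("`bounds` must be strictly increasing with >= 2 values.")
  }
  assert_columns(profiles, c("gene_id", metric), "profiles")
  val <- profiles[[metric]][match(genes, profiles$gene_id)]
  has_clusters <- genes %in% profiles$gene_id
  labels <- sprintf("[%s,%s)", format(bounds[-length(bounds)], trim = TRUE),
                    format(bounds[-1L], trim = TRUE))
  bin <- rep(NA_character_, length(genes))
  bin[!has_clusters] <- "non-target"
  scored <- has_clusters & !is.na(val)
  bin[scored] <- labels[findInterval(val[scored], bounds,
                                     rightmost.closed = FALSE)]
  # findInterval returns 0 below bounds[1]: clamp into the first bin is
  # wrong; those genes are unscored relative to the requested bounds
  below <- scored & val < bounds[1L]
  bin[below] <- "unscored"
  bin[has_clusters & is.na(val)] <- "unscored"
  lev <- c("non-target", labels,
           if (any(bin == "unscored", na.rm = TRUE)) "unscored")
  tibble(
    gene_id = genes,
    metric_value = val,
    bin = factor(bin, levels = lev)
  )
}

#' Occupancy-binned CDF comparison with two-sided KS tests
#'
#' For each bin, compares the per-gene values (log2 fold changes or delta-TE)
#' against the reference bin with a two-sided two-sample Kolmogorov-Smirnov
#' test: D = sup |ECDF_bin - ECDF_ref|, exact p-values in the small-sample
#' regime handled by [stats::ks.test()] (exact when the product of sample
#' sizes is < 10000 and there are no ties), asymptotic otherwise. Bin
#' medians are reported for effect direction.
#'
#' @param values Tibble: gene_id, value. NA values are dropped.
#' @param bins Tibble from [bin_targets()] (gene_id, bin).
#' @param reference Reference bin label (default "non-target").
#' @param min_n Minimum bin size; smaller bins are skipped with a warning.
#' @return Tibble (class `binned_comparison`): bin, n, n_ref, statistic,
#'   p_value, median, median_ref, shift ("right"/"left").
#' @export
cdf_ks_compare <- function(values, bins, reference = "non-target",
                           min_n = 10L) {
  assert_columns(values, c("gene_id", "value"), "values")
  assert_columns(bins, c("gene_id", "bin"), "bins")
  df <- dplyr::inner_join(values, bins, by = "gene_id") |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$bin))
  ref_vals <- df$value[df$bin == reference]
  if (length(ref_vals) == 0L) {
    abort(sprintf("reference bin `%s` is empty.", reference))
  }
  other <- setdiff(levels(droplevels(factor(df$bin))), reference)
  rows <- purrr::map(other, function(b) {
    v <- df$value[df$bin == b]
    if (length(v) < min_n) {
      warn(sprintf("bin `%s` has %d < %d values; skipped.", b, length(v),
                   min_n))
      return(NULL)
    }
    kt <- suppressWarnings(ks.test(v, ref_vals, alternative = "two.sided"))
    tibble(
      bin = b, n = length(v), n_ref = length(ref_vals),
      statistic = unname(kt$statistic), p_value = kt$p.value,
      median = median(v), median_ref = median(ref_vals),
      shift = ifelse(median(v) >= median(ref_vals), "right", "left")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      bin = character(), n = integer(), n_ref = integer(),
      statistic = double(), p_value = double(), median = double(),
      median_ref = double(), shift = character()
    )
  }
  attr(out, "reference") <- reference
  class(out) <- c("binned_comparison", class(out))
  out
}

#' Fit an exponential mRNA decay curve
#'
#' Least-squares fit of `ln(level) ~ time` (the log-linear form of
#' first-order decay, the model behind actinomycin-D chase experiments
#' sampled at e.g. 0/2/4/8 h); decay constant k = -slope and half-life =
#' ln(2)/k when k > 0, otherwise the series is flagged non-decaying.
#'
#' @param timepoints Numeric vector of times in hours (>= 3 points).
#' @param levels Positive relative abundances (conventionally normalized to
#'   the t = 0 value).
#' @return Object of class `decay_fit`: k (per hour), half_life (hours),
#'   r_squared, non_decaying, n. Has [tidy()], [glance()], and `autoplot()`
#'   methods.
#' @examples
#' fit_halflife(c(0, 4, 8), c(1, 0.5, 0.25)) # half-life 4 h
#' @export
fit_halflife <- function(timepoints, levels) {
  if (length(timepoints) != length(levels) || length(timepoints) < 3L) {
    abort("need >= 3 matched timepoints and levels.")
  }
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    abort("levels must be positive (log of non-positive level undefined).")
  }
  fit <- lm(log(levels) ~ timepoints)
  k <- -unname(coef(fit)[2L])
  ss_tot <- sum((log(levels) - mean(log(levels)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  non_decaying <- k <= 1e-12
  structure(
    list(
      k = k,
      half_life = if (non_decaying) NA_real_ else log(2) / k,
      r_squared = r2,
      non_decaying = non_decaying,
      n = length(timepoints),
      timepoints = timepoints,
      levels = levels
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$non_decaying) {
    cat("<decay_fit> non-decaying (k =", format(x$k, digits = 3), "per h)\n")
  } else {
    cat("<decay_fit> k =", format(x$k, digits = 4),
        "per h, half-life =", format(x$half_life, digits = 4),
        "h, R^2 =", format(x$r_squared, digits = 4), "\n")
  }
  invisible(x)
}

#' Fit decay curves gene-wise on a long table
#'
#' @param data Long tibble with one row per (gene, timepoint).
#' @param gene,time,level Column names (strings) holding gene id, time in
#'   hours, and positive relative level.
#' @return Tibble: one row per gene with k, half_life, r_squared,
#'   non_decaying, n.
#' @export
fit_halflives <- function(data, gene = "gene_id", time = "time",
                          level = "level") {
  assert_columns(data, c(gene, time, level), "data")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gene))) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_halflife(d[[time]], d[[level]])
      tibble(k = f$k, half_life = f$half_life, r_squared = f$r_squared,
             non_decaying = f$non_decaying, n = f$n)
    }) |>
    dplyr::ungroup()
}

#' Corrected total cell fluorescence
#'
#' CTCF = integrated density - (cell area x mean background fluorescence),
#' the standard background correction for per-cell fluorescence
#' quantification. Negative values are possible (background over-estimation)
#' and flagged.
#'
#' @param integrated_density,cell_area,background_mean Numeric vectors
#'   (recycled); `cell_area` must be non-negative.
#' @return Tibble: integrated_density, cell_area, background_mean, ctcf,
#'   negative.
#' @examples
#' ctcf(1000, 50, 2) # 900
#' @export
ctcf <- function(integrated_density, cell_area, background_mean) {
  if (any(cell_area < 0)) {
    abort("`cell_area` must be non-negative.")
  }
  val <- integrated_density - cell_area * background_mean
  tibble(
    integrated_density = integrated_density,
    cell_area = cell_area,
    background_mean = background_mean,
    ctcf = val,
    negative = val < 0
  )
}
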