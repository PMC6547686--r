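test_that("cpm normalization sums to 1e6 per sample and keeps zeros", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           s1 = c(0L, 10L, 90L))
  n <- normalize_counts(counts, "cpm")
  expect_equal(sum(n$s1), 1e6)
  expect_equal(n$s1[1], 0)
  expect_error(normalize_counts(tibble::tibble(gene_id = "a", s1 = 0L)),
               "all-zero")
})

test_that("median-of-ratios equalizes a pure depth difference", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           s1 = c(10L, 20L, 30L),
                           s2 = c(20L, 40L, 60L))
  n <- normalize_counts(counts, "median_of_ratios")
  sf <- attr(n, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(n$s1, n$s2)
})

test_that("median-of-ratios matches the DESeq size-factor estimator", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(44, {
    m <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 6)
    m[, 4:6] <- m[, 4:6] * 2L
  })
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:50)),
    tibble::as_tibble(as.data.frame(m), .name_repair = ~ paste0("s", 1:6))
  )
  sf <- attr(normalize_counts(counts, "median_of_ratios"), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same estimator up to the overall scale convention; at even gene counts
  # the median interpolates on the ratio scale here vs the log scale there,
  # so agreement is near- but not bit-exact
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(ref / exp(mean(log(ref)))),
               tolerance = 1e-3)
})

test_that("log2fc reproduces hand-computed cases", {
  ab <- tibble::tibble(gene_id = c("up", "flat", "zero"),
                       X_WT_1 = c(1, 5, 0), X_WT_2 = c(1, 5, 0),
                       X_KO_1 = c(4, 5, 0), X_KO_2 = c(4, 5, 0))
  out <- log2fc(ab, pseudocount = 1e-9)
  expect_equal(out$lfc[1], 2, tolerance = 1e-6)
  expect_equal(out$lfc[2], 0)
  out1 <- log2fc(ab, pseudocount = 1)
  expect_equal(out1$lfc[3], 0) # pseudocount floor for 0/0
  expect_error(log2fc(ab, pseudocount = 0), "pseudocount")
})

test_that("TE is RPF over RNA and drops by doubling RNA alone", {
  rna <- tibble::tibble(gene_id = "g", RNA_WT_1 = 5, RNA_KO_1 = 10)
  rpf <- tibble::tibble(gene_id = "g", RPF_WT_1 = 10, RPF_KO_1 = 10)
  te <- translational_efficiency(rna, rpf, min_abund = 1)
  expect_equal(te$te_wt, 2)
  expect_equal(te$te_ko, 1)
  expect_equal(te$delta_te, -1)
  expect_false(te$excluded)
  low <- translational_efficiency(
    dplyr::mutate(rna, RNA_WT_1 = 0.5), rpf, min_abund = 1
  )
  expect_true(low$excluded)
  expect_true(is.na(low$te_wt))
})

test_that("binning partitions the gene universe with right-open intervals", {
  prof <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    n_clusters = c(2L, 1L, 3L),
    nxpm = c(150, 5, NA),
    nxpm_utr3 = c(150, 0, NA),
    low_abundance = c(FALSE, FALSE, TRUE)
  )
  universe <- c("g1", "g2", "g3", "g4")
  bins <- bin_targets(universe, prof, metric = "nxpm",
                      bounds = c(0, 10, 100, Inf))
  expect_equal(nrow(bins), 4L)
  expect_equal(sum(table(bins$bin)), 4L) # partition: sizes sum to universe
  expect_equal(as.character(bins$bin[bins$gene_id == "g1"]), "[100,Inf)")
  expect_equal(as.character(bins$bin[bins$gene_id == "g2"]), "[0,10)")
  expect_equal(as.character(bins$bin[bins$gene_id == "g3"]), "unscored")
  expect_equal(as.character(bins$bin[bins$gene_id == "g4"]), "non-target")
  # boundary value goes right (right-open intervals)
  b10 <- bin_targets("g2", dplyr::mutate(prof[2, ], nxpm = 10),
                     metric = "nxpm", bounds = c(0, 10, 100, Inf))
  expect_equal(as.character(b10$bin), "[10,100)")
  # metric selection: 3'UTR occupancy bins differently
  b3 <- bin_targets(universe, prof, metric = "nxpm_utr3",
                    bounds = c(0, 10, 100, Inf))
  expect_equal(as.character(b3$bin[b3$gene_id == "g2"]), "[0,10)")
  expect_error(bin_targets(universe, prof, bounds = c(0, 0, 10)),
               "increasing")
})

test_that("genes with no clusters are non-targets for every metric", {
  prof <- tibble::tibble(gene_id = "g1", n_clusters = 5L, nxpm = 50,
                         low_abundance = FALSE)
  for (m in c("nxpm", "n_clusters")) {
    b <- bin_targets(c("g1", "lonely"), prof, metric = m,
                     bounds = c(0, 100, Inf))
    expect_equal(as.character(b$bin[b$gene_id == "lonely"]), "non-target")
  }
})

test_that("KS comparison handles identical and disjoint supports", {
  vals <- tibble::tibble(gene_id = paste0("g", 1:40),
                         value = rep(c(1, 2, 3, 4), 10))
  bins <- tibble::tibble(gene_id = paste0("g", 1:40),
                         bin = rep(c("non-target", "top"), each = 20))
  same <- cdf_ks_compare(vals, bins, min_n = 5)
  # the two bins see identical value multisets
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- cdf_ks_compare(
    tibble::tibble(gene_id = paste0("g", 1:20),
                   value = c(rep(1:3, length.out = 10), rep(7:9, length.out = 10))),
    tibble::tibble(gene_id = paste0("g", 1:20),
                   bin = rep(c("non-target", "top"), each = 10)),
    min_n = 5
  )
  expect_equal(disjoint$statistic, 1)
  expect_equal(disjoint$shift, "right")
})

test_that("KS statistic and exact p match full enumeration for n,m <= 6", {
  withr::with_seed(55, {
    for (rep in 1:12) {
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      x <- round(rnorm(n), 3)
      y <- round(rnorm(m, mean = sample(c(0, 1), 1)), 3)
      if (anyDuplicated(c(x, y))) next
      got <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
      want <- oracle_ks(x, y)
      expect_equal(unname(got$statistic), want$d, tolerance = 1e-12)
      expect_equal(got$p.value, want$p, tolerance = 1e-9)
      # and through the package interface
      vals <- tibble::tibble(gene_id = paste0("g", seq_len(n + m)),
                             value = c(x, y))
      bins <- tibble::tibble(gene_id = vals$gene_id,
                             bin = rep(c("a", "non-target"), c(n, m)))
      cmp <- cdf_ks_compare(vals, bins, min_n = 2)
      expect_equal(cmp$statistic, want$d, tolerance = 1e-12)
      expect_equal(cmp$p_value, want$p, tolerance = 1e-9)
    }
  })
})

test_that("small bins are skipped with a warning, empty reference errors", {
  vals <- tibble::tibble(gene_id = paste0("g", 1:15), value = rnorm(15))
  bins <- tibble::tibble(gene_id = vals$gene_id,
                         bin = c(rep("non-target", 12), rep("tiny", 3)))
  expect_warning(out <- cdf_ks_compare(vals, bins, min_n = 10), "skipped")
  expect_equal(nrow(out), 0L)
  expect_error(cdf_ks_compare(vals, dplyr::mutate(bins, bin = "x"),
                              reference = "non-target"),
               "empty")
})

test_that("half-life fitting is exact on noiseless decay", {
  fit <- fit_halflife(c(0, 4, 8), c(1, 0.5, 0.25))
  expect_equal(fit$half_life, 4)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$non_decaying)
  flat <- fit_halflife(c(0, 2, 4, 8), c(1, 1, 1, 1))
  expect_true(flat$non_decaying)
  expect_equal(flat$k, 0)
  expect_true(is.na(flat$half_life))
  expect_error(fit_halflife(c(0, 2, 4), c(1, 0, 0.5)), "positive")
  expect_error(fit_halflife(c(0, 2), c(1, 0.5)), ">= 3")
})

test_that("half-life fit matches the normal-equations oracle under noise", {
  withr::with_seed(66, {
    t <- c(0, 2, 4, 8)
    for (rep in 1:20) {
      k <- runif(1, 0.05, 0.6)
      y <- exp(-k * t) * exp(rnorm(4, sd = 0.1))
      fit <- fit_halflife(t, y)
      slope <- oracle_loglinear_slope(t, y)["slope"]
      expect_equal(fit$k, unname(-slope), tolerance = 1e-10)
    }
  })
})

test_that("half-life estimation is nearly unbiased at 10% noise", {
  withr::with_seed(13, {
    t <- c(0, 2, 4, 8)
    k_true <- 0.3
    ks <- replicate(1000, {
      y <- exp(-k_true * t) * exp(rnorm(4, sd = 0.1))
      fit_halflife(t, y)$k
    })
  })
  expect_lt(abs(mean(ks) / k_true - 1), 0.02)
})

test_that("gene-wise decay fitting works on long tables", {
  d <- tibble::tibble(
    gene_id = rep(c("fast", "slow"), each = 4),
    time = rep(c(0, 2, 4, 8), 2),
    level = c(2^(-c(0, 2, 4, 8) / 2), 2^(-c(0, 2, 4, 8) / 8))
  )
  fits <- fit_halflives(d)
  expect_equal(fits$half_life[fits$gene_id == "fast"], 2)
  expect_equal(fits$half_life[fits$gene_id == "slow"], 8)
})

test_that("CTCF follows the stated background correction", {
  expect_equal(ctcf(1000, 50, 2)$ctcf, 900)
  expect_equal(ctcf(123, 50, 0)$ctcf, 123) # zero background is identity
  neg <- ctcf(100, 100, 2)
  expect_equal(neg$ctcf, -100)
  expect_true(neg$negative)
  expect_error(ctcf(100, -1, 2), "non-negative")
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  fit <- fit_halflife(c(0, 4, 8), c(1, 0.5, 0.25))
  td <- tidy(fit)
  expect_equal(td$term, c("k", "half_life"))
  expect_equal(td$estimate[2], 4)
  gl <- glance(fit)
  expect_equal(gl$r_squared, 1)
  vals <- tibble::tibble(gene_id = paste0("g", 1:30), value = rnorm(30))
  bins <- tibble::tibble(gene_id = vals$gene_id,
                         bin = rep(c("non-target", "top"), 15))
  cmp <- cdf_ks_compare(vals, bins, min_n = 5)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$n_bins, 1L)
  expect_equal(glance(cmp)$reference, "non-target")
})
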