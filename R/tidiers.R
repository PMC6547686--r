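#' Tidy a decay fit
#'
#' @param x A `decay_fit` from [fit_halflife()].
#' @param ... Unused.
#' @return One row per estimated quantity (k, half_life) with its value.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("k", "half_life"),
    estimate = c(x$k, x$half_life)
  )
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    non_decaying = x$non_decaying,
    n = x$n
  )
}

#' Tidy a binned KS comparison
#'
#' @param x A `binned_comparison` from [cdf_ks_compare()].
#' @param ... Unused.
#' @return The comparison as a plain tibble (one row per bin).
#' @export
tidy.binned_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "binned_comparison")
  as_tibble(out)
}

#' @rdname tidy.binned_comparison
#' @export
glance.binned_comparison <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    reference = attr(x, "reference") %||% NA_character_,
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_
  )
}
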