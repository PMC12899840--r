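# Group comparison protocol: per-plant temporal means are the biological
# replicates; treatments are compared with Welch two-sample t-tests.

#' Aggregate a per-time phenotype series to one plant-level value
#'
#' Arithmetic mean across time of the non-missing values. Missing entries
#' (e.g. Dispersion+ at time points with fewer than two components) are
#' excluded from numerator and denominator alike. An all-missing series
#' yields `NA` with a warning; such plants drop out of downstream tests.
#'
#' @param values numeric vector, possibly with `NA`s.
#' @return scalar mean, or `NA_real_` when every value is missing.
#' @export
plant_level_aggregate <- function(values) {
  keep <- !is.na(values)
  if (!any(keep)) {
    warning("all values missing; plant excluded from aggregation", call. = FALSE)
    return(NA_real_)
  }
  mean(values[keep])
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test: t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' When both groups have zero variance, equal means give t = 0, p = 1;
#' different means leave the statistic undefined and raise an error.
#'
#' @param group_a,group_b numeric vectors of plant-level values, each of
#'   length >= 2 (`NA`s dropped first).
#' @return list with `t_stat`, `df`, `p_two_sided`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t needs at least 2 non-missing values per group")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = length(a) + length(b) - 2,
                  p_two_sided = 1, n_a = length(a), n_b = length(b),
                  mean_a = mean(a), mean_b = mean(b)))
    stop("degenerate groups: both have zero variance but different means")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value, n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' Per-time mean and 95% confidence interval across replicates
#'
#' For each time point, the mean over replicates and a Student-t confidence
#' half-width `qt(1-(1-level)/2, n-1) * s / sqrt(n)`. Time points with one
#' replicate report the mean with an absent (NA) half-width.
#'
#' @param df data frame with columns `t` and `value` (one row per replicate
#'   and time point; `NA` values dropped).
#' @param level confidence level, default 0.95.
#' @return data frame with `t`, `n`, `mean`, `ci_half_width`.
#' @export
summarize_mean_ci <- function(df, level = 0.95) {
  stopifnot(all(c("t", "value") %in% names(df)))
  df <- df[!is.na(df$value), , drop = FALSE]
  out <- lapply(sort(unique(df$t)), function(tt) {
    v <- df$value[df$t == tt]
    n <- length(v)
    hw <- if (n >= 2L) qt(1 - (1 - level) / 2, n - 1) * sd(v) / sqrt(n)
          else NA_real_
    data.frame(t = tt, n = n, mean = mean(v), ci_half_width = hw)
  })
  do.call(rbind, out)
}

#' Treatment comparison table over phenotype columns
#'
#' Reproduces the aggregate-then-test protocol over a tidy phenotype table:
#' within each species, each phenotype column is averaged across time per
#' plant ([plant_level_aggregate()]) and the two treatments are compared
#' with [welch_t()]. Prints how many tests were run (no multiplicity
#' correction is applied; apply your own if needed).
#'
#' @param df tidy data frame with columns `species`, `treatment`,
#'   `plant_id`, plus the phenotype columns.
#' @param phenotypes character vector of phenotype column names.
#' @param treatments length-2 character vector; the contrast is
#'   `treatments[1]` vs `treatments[2]` (default control vs drought).
#' @return data frame with one row per species x phenotype: `species`,
#'   `phenotype`, `t_stat`, `df`, `p`, `n_a`, `n_b`; skipped combinations
#'   (too few plants, degenerate groups) are reported with `NA` statistics
#'   and a warning.
#' @export
compare_treatments <- function(df, phenotypes,
                               treatments = c("control", "drought")) {
  stopifnot(all(c("species", "treatment", "plant_id") %in% names(df)),
            all(phenotypes %in% names(df)), length(treatments) == 2L)
  rows <- list()
  for (sp in sort(unique(df$species))) {
    d <- df[df$species == sp, , drop = FALSE]
    for (ph in phenotypes) {
      agg <- vapply(split(d[[ph]], d$plant_id), plant_level_aggregate,
                    numeric(1L))
      trt <- vapply(split(d$treatment, d$plant_id), `[`, character(1L), 1L)
      res <- tryCatch(
        welch_t(agg[trt == treatments[1L]], agg[trt == treatments[2L]]),
        error = function(e) {
          warning("species ", sp, ", phenotype ", ph, ": ",
                  conditionMessage(e), call. = FALSE)
          list(t_stat = NA_real_, df = NA_real_, p_two_sided = NA_real_,
               n_a = sum(trt == treatments[1L] & !is.na(agg)),
               n_b = sum(trt == treatments[2L] & !is.na(agg)))
        })
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, phenotype = ph, t_stat = res$t_stat, df = res$df,
        p = res$p_two_sided, n_a = res$n_a, n_b = res$n_b)
    }
  }
  out <- do.call(rbind, rows)
  message(nrow(out), " Welch test(s) run; no multiple-testing correction applied")
  out
}
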