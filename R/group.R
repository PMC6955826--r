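welch_from_moments <- function(m1, v1, n1, m2, v2, n2) {
  if (v1 == 0 && v2 == 0) {
    abort("both samples have zero variance; Welch t is undefined",
          class = "fnconn_degenerate")
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p = p)
}

#' Welch's unpaired two-sample t test
#'
#' The unequal-variance t test with Welch--Satterthwaite degrees of freedom
#' and a two-sided p value, delegated to [stats::t.test()]. This is the
#' test used for every between-group comparison of network measures.
#'
#' @param sample_a,sample_b Numeric vectors with at least two observations
#'   each; at least one must have nonzero variance.
#' @return A one-row tibble with columns `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(rnorm(27), rnorm(24, mean = 1))
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs at least two observations",
          class = "fnconn_invalid_argument")
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    abort("both samples have zero variance; Welch t is undefined",
          class = "fnconn_degenerate")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Welch's t test from summary statistics
#'
#' Same test as [welch_t()] computed directly from group means, standard
#' deviations and sizes, for re-deriving test statistics from published
#' summary tables:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch--Satterthwaite
#' degrees of freedom.
#'
#' @param m1,sd1,n1 Mean, standard deviation and size of the first group.
#' @param m2,sd2,n2 Same for the second group.
#' @return A one-row tibble with columns `t`, `df`, `p`.
#' @export
#' @examples
#' # average degree, healthy controls vs unresponsive patients
#' welch_t_from_summary(3.81, 2.10, 27, 1.71, 2.59, 24)
welch_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("group sizes must be at least 2", class = "fnconn_invalid_argument")
  }
  if (sd1 < 0 || sd2 < 0) {
    abort("standard deviations must be non-negative",
          class = "fnconn_invalid_argument")
  }
  welch_from_moments(m1, sd1^2, n1, m2, sd2^2, n2)
}

default_group_pairs <- function() {
  c("HC-MCS", "HC-UWS", "HC-DOC", "MCS-UWS")
}

resolve_pair_members <- function(pair, groups) {
  parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    abort(sprintf("malformed pair label '%s'", pair),
          class = "fnconn_invalid_argument")
  }
  resolve <- function(side) {
    if (side == "DOC") {
      doc <- intersect(c("MCS", "UWS"), groups)
      if (length(doc) == 0) {
        abort("pair requires DOC but no MCS/UWS groups are present",
              class = "fnconn_invalid_argument")
      }
      doc
    } else {
      if (!side %in% groups) {
        abort(sprintf("unknown group '%s' in pair '%s'", side, pair),
              class = "fnconn_invalid_argument")
      }
      side
    }
  }
  list(a = resolve(parts[1]), b = resolve(parts[2]))
}

#' Between-group comparison of network measures
#'
#' Runs one Welch t test per (measure, node-or-average, group pair) on a
#' long metrics table (see [cohort_metrics()]). The DOC group is formed as
#' the union of the MCS and UWS subjects. Nodal tests are flagged
#' significant at `alpha / family` (Bonferroni over the `family = 10` RSNs,
#' i.e. the p < .005 convention at `alpha = 0.05`); the network-average
#' pseudo-node `"average"` is tested at `alpha` uncorrected since it is a
#' single global test per measure.
#'
#' @param metrics Long tibble with columns `subject`, `group`, `rsn`,
#'   `measure`, `value`.
#' @param pairs Character vector of group pairs, `"A-B"`; `"DOC"` denotes
#'   the MCS+UWS union.
#' @param alpha Family-wise significance level.
#' @param family Bonferroni family size for nodal tests.
#' @return A tibble of class `group_comparison`: one row per test with
#'   columns `measure`, `rsn`, `pair`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `significant`.
#' @export
compare_groups <- function(metrics, pairs = default_group_pairs(),
                           alpha = 0.05, family = 10) {
  needed <- c("subject", "group", "rsn", "measure", "value")
  if (!all(needed %in% names(metrics))) {
    abort("`metrics` must have subject, group, rsn, measure, value columns",
          class = "fnconn_invalid_argument")
  }
  groups <- unique(metrics$group)
  grid <- tidyr::expand_grid(
    pair = pairs,
    measure = unique(metrics$measure),
    rsn = unique(metrics$rsn)
  )
  rows <- purrr::pmap(grid, function(pair, measure, rsn) {
    members <- resolve_pair_members(pair, groups)
    sub <- metrics[metrics$measure == measure & metrics$rsn == rsn, ]
    a <- sub$value[sub$group %in% members$a]
    b <- sub$value[sub$group %in% members$b]
    # a measure can be constant in both groups (e.g. clustering all zero in
    # a sparse cohort); report NA rather than fail the whole table
    res <- tryCatch(
      welch_from_moments(mean(a), var(a), length(a),
                         mean(b), var(b), length(b)),
      fnconn_degenerate = function(e) {
        tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_)
      })
    thr <- if (rsn == "average") alpha else alpha / family
    tibble::tibble(measure = measure, rsn = rsn, pair = pair,
                   mean_a = mean(a), mean_b = mean(b),
                   t = res$t, df = res$df, p = res$p,
                   significant = !is.na(res$p) && res$p < thr)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_comparison", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  out
}

#' @describeIn compare_groups One-row summary: number of tests, number
#'   significant, the correction settings.
#' @param x A `group_comparison` table.
#' @param ... Unused.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    family = attr(x, "family")
  )
}
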