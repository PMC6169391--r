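#' Remobilization frequency of a promoter-trap screen
#'
#' Reporter-positive individuals divided by individuals screened, as a
#' percentage rounded half-up to two decimals (the convention of screen
#' summary tables), with an exact binomial 95% confidence interval as an
#' auxiliary column.
#'
#' @param n_events number of reporter-positive individuals (vectorised).
#' @param n_screened number of individuals screened (vectorised).
#' @return data.frame with `n_events`, `n_screened`, `frequency`
#'   (percent, 2 dp), `frequency_raw` (unrounded percent), `ci_lower`,
#'   `ci_upper` (percent).
#' @examples
#' remobilization_frequency(274, 34918)$frequency  # 0.78
#' @export
remobilization_frequency <- function(n_events, n_screened) {
  if (any(n_screened <= 0)) stop("n_screened must be positive")
  if (any(n_events < 0) || any(n_events > n_screened)) {
    stop("n_events must lie in [0, n_screened]")
  }
  ci <- t(mapply(function(x, n) stats::binom.test(x, n)$conf.int,
                 n_events, n_screened))
  raw <- 100 * n_events / n_screened
  data.frame(n_events = n_events, n_screened = n_screened,
             frequency = round_half_up(raw, 2), frequency_raw = raw,
             ci_lower = 100 * ci[, 1], ci_upper = 100 * ci[, 2])
}

#' Per-line remobilization table with a totals row
#'
#' @param counts data.frame with columns `line_id`, `n_screened`,
#'   `n_events` (extra columns such as `locus_label` are carried through).
#' @return data.frame with per-line frequencies and a final `TOTAL` row.
#' @export
remobilization_table <- function(counts) {
  stopifnot(all(c("line_id", "n_screened", "n_events") %in% names(counts)))
  freq <- remobilization_frequency(counts$n_events, counts$n_screened)
  out <- cbind(counts[, setdiff(names(counts), c("n_events", "n_screened")),
                      drop = FALSE],
               freq)
  total <- remobilization_frequency(sum(counts$n_events), sum(counts$n_screened))
  total_row <- out[1, , drop = FALSE]
  total_row[] <- NA
  total_row$line_id <- "TOTAL"
  for (cl in names(freq)) total_row[[cl]] <- total[[cl]]
  rbind(out, total_row)
}

#' Pearson chi-square goodness of fit
#'
#' Tests observed category counts against expected proportions (uniform by
#' default); expected counts are `proportions * sum(observed)`, the degrees
#' of freedom `k - 1`. Warns when any expected count falls below 5.
#'
#' @param observed vector of non-negative counts (length >= 2).
#' @param expected_proportions proportions summing to 1; default uniform.
#' @return object of class `trap_gof`: `chi2`, `df`, `p`, `observed`,
#'   `expected`.
#' @examples
#' chisq_gof(c(10, 0))  # chi2 = 10, df = 1
#' @export
chisq_gof <- function(observed, expected_proportions = NULL) {
  if (length(observed) < 2L) stop("at least two categories are required")
  if (sum(observed) <= 0) stop("total observed count must be positive")
  k <- length(observed)
  p <- expected_proportions %||% rep(1 / k, k)
  if (length(p) != k) stop("expected_proportions length must match observed")
  if (abs(sum(p) - 1) > 1e-9) stop("expected_proportions must sum to 1")
  expected <- p * sum(observed)
  if (any(expected < 5)) {
    warning("expected count below 5 in some category; chi-square ",
            "approximation may be poor")
  }
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  structure(list(chi2 = unname(ht$statistic), df = as.integer(ht$parameter),
                 p = ht$p.value, observed = observed, expected = expected),
            class = "trap_gof")
}

#' @export
print.trap_gof <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Chi-square test of intron-position preference
#'
#' Tests whether insertion events concentrate in particular intron ordinals
#' (e.g. the first intron) against a null in which each intron of each hit
#' gene is equally likely: an event in a gene with `n` introns lands in
#' ordinal `j <= n` with probability `1/n`, so the expected count for
#' ordinal `j` is `sum_events [j <= n_e] / n_e`. The category layout is
#' configurable: one category per ordinal with ordinals beyond
#' `pool_beyond` pooled (default: the maximum ordinal present), or first
#' intron versus all the rest.
#'
#' @param ordinals intron ordinal of each event.
#' @param n_introns total introns of each event's host gene (same length).
#' @param layout category layout.
#' @param pool_beyond ordinals greater than this are pooled into the last
#'   category (per-ordinal layout only).
#' @return a `trap_gof`.
#' @export
intron_position_test <- function(ordinals, n_introns,
                                 layout = c("per_ordinal", "first_vs_rest"),
                                 pool_beyond = NULL) {
  layout <- match.arg(layout)
  stopifnot(length(ordinals) == length(n_introns),
            all(ordinals >= 1), all(ordinals <= n_introns))
  if (layout == "first_vs_rest") {
    obs <- c(first = sum(ordinals == 1L), rest = sum(ordinals > 1L))
    e_first <- sum(1 / n_introns)
    expected <- c(e_first, length(ordinals) - e_first)
  } else {
    kmax <- pool_beyond %||% max(ordinals)
    cat_of <- pmin(ordinals, kmax)
    obs <- vapply(seq_len(kmax), function(j) sum(cat_of == j), integer(1))
    expected <- vapply(seq_len(kmax), function(j) {
      if (j < kmax) {
        sum((j <= n_introns) / n_introns)
      } else {
        # pooled tail: ordinals kmax..n for every gene
        sum(pmax(0, n_introns - kmax + 1) / n_introns)
      }
    }, numeric(1))
  }
  chi2 <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = obs, expected = expected),
            class = "trap_gof")
}

#' Five-number summary of insertion distances
#'
#' @param distances numeric vector of distances (bp), length >= 1.
#' @return data.frame with `n`, `min`, `q1`, `median`, `q3`, `max`;
#'   the median of an even-length vector is the mean of the central pair.
#' @examples
#' distance_summary(c(183, 2600, 44882))
#' @export
distance_summary <- function(distances) {
  if (!length(distances) || all(is.na(distances))) stop("no distances supplied")
  d <- distances[!is.na(distances)]
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  data.frame(n = length(d), min = min(d), q1 = q[1],
             median = stats::median(d), q3 = q[2], max = max(d))
}
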