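#' Odds of a proportion
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return `p / (1 - p)`; `Inf` at `p = 1`.
#' @examples
#' odds(0.5)     # 1
#' odds(1/9)     # 0.125
#' @export
odds <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportion must lie in [0, 1]")
  ifelse(p == 1, Inf, p / (1 - p))
}

#' Kimmerer-Slaughter electivity index
#'
#' Odds-ratio-based diet-selection score comparing the proportion `g` of a
#' prey taxon in predator guts with its proportion `a` in the habitat:
#' \deqn{X = \frac{O}{1 + O}, \qquad O = \frac{g/(1-g)}{a/(1-a)}.}
#' `X` ranges over `[0, 1]`; 0.5 means no selection (`g = a`), values above
#' 0.5 active selection, values below 0.5 avoidance. For a taxon eaten but
#' absent from the habitat sample (`a = 0`, `g > 0`) the odds ratio is
#' undefined and `NA` is returned.
#'
#' @param g Gut proportion(s) in `[0, 1)`.
#' @param a Habitat proportion(s) in `[0, 1)`.
#' @return Index value(s) in `[0, 1]`, `NA` where undefined.
#' @examples
#' electivity_index(1/9, 2/40)    # 0.704: apparent preference
#' electivity_index(0.2, 0.2)     # 0.5: no selection
#' @export
electivity_index <- function(g, a) {
  stopifnot(is.numeric(g), is.numeric(a))
  n <- max(length(g), length(a))
  g <- rep_len(g, n)
  a <- rep_len(a, n)
  og <- odds(g)
  oa <- odds(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (oa[i] == 0 && og[i] > 0) { out[i] <- NA_real_; next }   # a = 0, g > 0
    if (oa[i] == 0 && og[i] == 0) { out[i] <- NA_real_; next }  # both absent
    if (is.infinite(og[i]) && is.infinite(oa[i])) { out[i] <- 0.5; next }
    if (is.infinite(og[i])) { out[i] <- 1; next }
    O <- og[i] / oa[i]
    out[i] <- O / (1 + O)
  }
  out
}

#' Beta Monte-Carlo confidence interval for the electivity index
#'
#' Propagates the sampling uncertainty of both composition counts into the
#' index by drawing `n_sims` posterior samples
#' \eqn{g^* \sim \mathrm{Beta}(G_i + 1,\; N_G - G_i + 1)} and
#' \eqn{a^* \sim \mathrm{Beta}(A_i + 1,\; N_A - A_i + 1)}
#' (Bayes-Laplace uniform prior, well-defined at zero counts), recomputing
#' \eqn{X^*} for each draw, and reporting the percentile interval.
#'
#' @param G_i Count of the taxon in guts, `0 <= G_i <= N_G`.
#' @param N_G Total identified prey items in guts, >= 1.
#' @param A_i Count of the taxon in the habitat sample, `0 <= A_i <= N_A`.
#' @param N_A Total prey counted in the habitat sample, >= 1.
#' @param n_sims Number of Monte-Carlo draws (default 10000).
#' @param seed Optional integer seed; identical seeds give identical
#'   intervals.
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @return Named vector `c(ci_low, ci_high)`.
#' @examples
#' beta_mc_ci(1, 9, 2, 40, seed = 1)
#' @export
beta_mc_ci <- function(G_i, N_G, A_i, N_A, n_sims = 10000, seed = NULL,
                       alpha = 0.05) {
  check_count <- function(k, n, what) {
    if (!is.finite(k) || !is.finite(n) || k != round(k) || n != round(n) ||
        n < 1 || k < 0 || k > n)
      stop("invalid ", what, " counts: need 0 <= count <= total, total >= 1")
  }
  check_count(G_i, N_G, "gut")
  check_count(A_i, N_A, "habitat")
  if (!is.null(seed)) set.seed(seed)
  gs <- stats::rbeta(n_sims, G_i + 1, N_G - G_i + 1)
  as <- stats::rbeta(n_sims, A_i + 1, N_A - A_i + 1)
  O <- (gs / (1 - gs)) / (as / (1 - as))
  X <- O / (1 + O)
  q <- stats::quantile(X, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(ci_low = q[1L], ci_high = q[2L])
}

#' Classify diet selection from an index and its confidence interval
#'
#' @param X Point estimate of the electivity index (may be `NA`).
#' @param ci_low,ci_high Interval bounds.
#' @return `"none"` if the interval includes 0.5, `"positive"` if entirely
#'   above, `"negative"` if entirely below, `"undefined"` if `X` is `NA`.
#' @export
classify_selection <- function(X, ci_low, ci_high) {
  if (is.na(X)) return("undefined")
  stopifnot(ci_low <= ci_high)
  if (ci_low > 0.5) "positive"
  else if (ci_high < 0.5) "negative"
  else "none"
}

#' Prey composition table from counts
#'
#' @param taxon Character vector of taxon names (unique).
#' @param count Non-negative integer counts per taxon.
#' @return An object of class `composition_table` with `taxon`, `count`,
#'   `total`, `prop`.
#' @export
composition_table <- function(taxon, count) {
  stopifnot(is.character(taxon), is.numeric(count),
            length(taxon) == length(count))
  if (anyDuplicated(taxon)) stop("duplicated taxon names")
  if (any(!is.finite(count)) || any(count < 0) || any(count != round(count)))
    stop("counts must be non-negative integers")
  total <- sum(count)
  if (total < 1) stop("composition table must contain at least one individual")
  structure(list(taxon = taxon, count = as.integer(count),
                 total = as.integer(total), prop = count / total),
            class = "composition_table")
}

#' Reconstruct integer counts from printed percentages
#'
#' Published composition tables often print percentages of a known total.
#' This helper recovers the underlying integer counts, verifying that the
#' rounded reconstruction reproduces each printed percentage to within
#' `tol` percentage points.
#'
#' @param pct Printed percentages.
#' @param total Known total count.
#' @param tol Permitted discrepancy, percentage points (default 0.05).
#' @return Integer counts summing to at most `total`.
#' @examples
#' counts_from_percent(c(11.1, 33.3, 11.1, 11.1, 33.3), total = 9)
#' @export
counts_from_percent <- function(pct, total, tol = 0.05) {
  stopifnot(is.numeric(pct), is.numeric(total), length(total) == 1L)
  if (any(pct < 0) || any(pct > 100)) stop("percentages must lie in [0, 100]")
  counts <- round(pct / 100 * total)
  back <- 100 * counts / total
  bad <- abs(back - pct) > tol
  if (any(bad))
    stop(sprintf(
      "percentage %.3f is not consistent with an integer count out of %d (nearest gives %.3f)",
      pct[which(bad)[1L]], total, back[which(bad)[1L]]))
  as.integer(counts)
}

#' Electivity table for a gut/habitat composition pair
#'
#' Computes the Kimmerer-Slaughter index, its Beta Monte-Carlo confidence
#' interval, and the selection classification for every prey taxon, in the
#' layout of a published diet-electivity table. Taxa present only in the
#' habitat sample (never eaten) get no index; taxa found only in guts get
#' an undefined classification.
#'
#' @param gut A [composition_table()] of identified gut contents.
#' @param habitat A [composition_table()] of the environmental sample.
#' @param n_sims Monte-Carlo draws per taxon (default 10000).
#' @param seed Integer seed; per-taxon draws are derived from it so the
#'   whole table is reproducible.
#' @param alpha Two-sided error rate for the intervals.
#' @return A data frame with one row per taxon: `taxon`, `gut_pct`,
#'   `habitat_pct`, `index`, `ci_low`, `ci_high`, `classification`.
#' @export
electivity_table <- function(gut, habitat, n_sims = 10000, seed = 1,
                             alpha = 0.05) {
  stopifnot(inherits(gut, "composition_table"),
            inherits(habitat, "composition_table"))
  taxa <- union(habitat$taxon, gut$taxon)
  G <- ifelse(taxa %in% gut$taxon,
              gut$count[match(taxa, gut$taxon)], 0L)
  A <- ifelse(taxa %in% habitat$taxon,
              habitat$count[match(taxa, habitat$taxon)], 0L)
  out <- data.frame(taxon = taxa,
                    gut_pct = 100 * G / gut$total,
                    habitat_pct = 100 * A / habitat$total,
                    index = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    classification = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    if (A[i] == 0 && G[i] > 0) {          # eaten but unseen in the habitat
      out$classification[i] <- "undefined"
      next
    }
    if (G[i] == 0) next                   # habitat-only: printed as "-"
    g <- G[i] / gut$total
    a <- A[i] / habitat$total
    out$index[i] <- electivity_index(g, a)
    ci <- beta_mc_ci(G[i], gut$total, A[i], habitat$total,
                     n_sims = n_sims, seed = seed + i, alpha = alpha)
    out$ci_low[i] <- ci[["ci_low"]]
    out$ci_high[i] <- ci[["ci_high"]]
    out$classification[i] <- classify_selection(out$index[i], ci[["ci_low"]],
                                                ci[["ci_high"]])
  }
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- seed
  out
}
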