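#' Normalise and zero-clip a scaling matrix
#'
#' Connections are conventionally "strong" when their scaling factor
#' exceeds `strong_fraction` of the upper bound: entries are first divided
#' by `w_max`, then entries at or below `strong_fraction` are set to zero.
#'
#' @param w scaling-factor matrix
#' @param w_max upper bound of the scaling factor
#' @param strong_fraction clipping threshold, in `(0, 1)`
#' @return normalised, zero-clipped matrix
#' @export
normalize_clip <- function(w, w_max = 1, strong_fraction = 0.5) {
  if (strong_fraction <= 0 || strong_fraction >= 1)
    stop("strong_fraction must be in (0, 1)")
  wt <- w / w_max
  wt[wt <= strong_fraction] <- 0
  wt
}

#' Symmetry index of a clipped weight matrix
#'
#' Measures the preponderance of reciprocal over unidirectional strong
#' motifs by the average similarity of symmetric entries,
#' \deqn{s = \frac{1}{N(N-1)/2 - N_0} \sum_{i<j}
#'       \left(1 - \frac{|w_{ij} - w_{ji}|}{w_{ij} + w_{ji}}\right)}
#' over the non-null pairs; the `N0` null pairs (both entries zero, by
#' clipping, initialisation or pruning) are excluded. `s = 1` when every
#' connected pair is reciprocal with equal weights, `s = 0` when every
#' connected pair is strictly unidirectional.
#'
#' @param w normalised, zero-clipped square matrix (see [normalize_clip()])
#' @param subset optional neuron indices: the index is computed on the
#'   induced submatrix
#' @return object of class `symmetry_result`: list with `s`, `N`, `N0` and
#'   the number of pairs used; `s` is `NA` (with a reason) when every pair
#'   is null
#' @export
symmetry_index <- function(w, subset = NULL) {
  if (!is.null(subset)) w <- w[subset, subset, drop = FALSE]
  stopifnot(nrow(w) == ncol(w))
  N <- nrow(w)
  ut <- upper.tri(w)
  a <- w[ut]
  b <- t(w)[ut]
  null_pair <- a == 0 & b == 0
  N0 <- sum(null_pair)
  n_pairs <- N * (N - 1) / 2
  if (N0 == n_pairs) {
    return(structure(list(s = NA_real_, N = N, N0 = N0, n_used = 0,
                          reason = "all pairs null"),
                     class = "symmetry_result"))
  }
  sim <- 1 - abs(a - b) / (a + b)
  structure(list(s = mean(sim[!null_pair]), N = N, N0 = N0,
                 n_used = n_pairs - N0, reason = NULL),
            class = "symmetry_result")
}

#' Monte-Carlo significance of an observed symmetry index
#'
#' Draws uniform-random scaling matrices with the same size, pruning and
#' clipping pipeline as the observed one, computes the full null
#' distribution of `s`, and returns the `(k + 1) / (n + 1)` tail
#' probability of observing a value at least as extreme.
#'
#' @param s_observed observed symmetry index
#' @param N network size
#' @param prune_fraction pruning used when wiring the network
#' @param strong_fraction clipping threshold
#' @param w_max scaling-factor upper bound
#' @param n_draws number of Monte-Carlo draws (>= 1000)
#' @param seed RNG seed
#' @param tail `"upper"` (s larger than chance, facilitating networks),
#'   `"lower"` (depressing networks) or `"both"`
#' @return p-value (for `"both"`, twice the smaller tail, capped at 1)
#' @export
symmetry_null_pvalue <- function(s_observed, N, prune_fraction = 0.2,
                                 strong_fraction = 0.5, w_max = 1,
                                 n_draws = 10000, seed = 1,
                                 tail = c("upper", "lower", "both")) {
  tail <- match.arg(tail)
  if (n_draws < 1000) stop("n_draws must be >= 1000")
  set.seed(seed)
  s_null <- vapply(seq_len(n_draws), function(k) {
    C <- matrix(rbinom(N * N, 1, 1 - prune_fraction), N, N)
    diag(C) <- 0L
    w <- matrix(runif(N * N, 0, w_max), N, N) * C
    symmetry_index(normalize_clip(w, w_max, strong_fraction))$s
  }, numeric(1))
  s_null <- s_null[!is.na(s_null)]
  n <- length(s_null)
  p_up <- (sum(s_null >= s_observed) + 1) / (n + 1)
  p_lo <- (sum(s_null <= s_observed) + 1) / (n + 1)
  switch(tail, upper = p_up, lower = p_lo,
         both = min(1, 2 * min(p_up, p_lo)))
}

#' Tally pairwise connectivity motifs by short-term dynamics kind
#'
#' Each unordered neuron pair falls in exactly one category given the
#' presence and kind of its strong directed links: no strong link
#' `(-,-)`; one strong link of kind X `(X,-)`; two strong links of kinds
#' X, Y `(X,Y)` (with the mixed reciprocal category written `(F,D)`).
#'
#' @param w normalised, zero-clipped matrix of strong connections
#' @param kind character matrix of per-synapse kinds (`"D"`/`"F"`, `NA`
#'   where unwired), same orientation as `w`
#' @return object of class `motif_tally`: category counts, estimated
#'   connection frequency `p_c` and conditional kind frequencies `p_F`,
#'   `p_D` (estimated on strong connections)
#' @export
count_pair_motifs <- function(w, kind) {
  stopifnot(all(dim(w) == dim(kind)))
  if (any(w > 0 & (is.na(kind) | !kind %in% c("D", "F"))))
    stop("every strong connection needs a 'D' or 'F' kind label")
  N <- nrow(w)
  cats <- c("(-,-)", "(D,-)", "(F,-)", "(D,D)", "(F,F)", "(F,D)")
  counts <- setNames(integer(6), cats)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    sij <- w[i, j] > 0
    sji <- w[j, i] > 0
    cat <- if (!sij && !sji) "(-,-)"
    else if (xor(sij, sji)) {
      k <- if (sij) kind[i, j] else kind[j, i]
      if (k == "D") "(D,-)" else "(F,-)"
    } else {
      ks <- sort(c(kind[i, j], kind[j, i]))
      if (all(ks == "D")) "(D,D)" else if (all(ks == "F")) "(F,F)"
      else "(F,D)"
    }
    counts[cat] <- counts[cat] + 1L
  }
  strong <- w > 0
  n_strong <- sum(strong)
  p_c <- n_strong / (N * (N - 1))
  p_F <- if (n_strong > 0) sum(kind[strong] == "F") / n_strong else NA_real_
  structure(list(counts = counts, n_pairs = N * (N - 1) / 2, p_c = p_c,
                 p_F = p_F, p_D = if (is.na(p_F)) NA_real_ else 1 - p_F),
            class = "motif_tally")
}

#' Null expectations for the motif categories
#'
#' Under independence of Bernoulli connection events, a pair has two
#' independent chances `p_c` of a strong link, each of kind F with
#' probability `p_F`: the chance fractions are `(1-p_c)^2` for `(-,-)`,
#' `2 p_c (1-p_c) p_X` for `(X,-)`, `p_c^2 p_X^2` for `(X,X)` and
#' `2 p_c^2 p_F p_D` for `(F,D)`. Prediction intervals for the observed
#' counts come from the binomial under the null (exact quantiles).
#'
#' @param p_c strong-connection frequency
#' @param p_F,p_D conditional kind frequencies (`p_F + p_D = 1`)
#' @param n_pairs number of unordered pairs
#' @param confidence confidence level for the intervals
#' @return data frame with one row per category: expected fraction, lower
#'   and upper interval bounds (as fractions)
#' @export
motif_null_expectations <- function(p_c, p_F, p_D = 1 - p_F, n_pairs,
                                    confidence = 0.95) {
  if (p_c < 0 || p_c > 1 || p_F < 0 || p_F > 1)
    stop("probabilities must lie in [0, 1]")
  if (abs(p_F + p_D - 1) > 1e-8) stop("p_F + p_D must equal 1")
  expected <- c("(-,-)" = (1 - p_c)^2,
                "(D,-)" = 2 * p_c * (1 - p_c) * p_D,
                "(F,-)" = 2 * p_c * (1 - p_c) * p_F,
                "(D,D)" = p_c^2 * p_D^2,
                "(F,F)" = p_c^2 * p_F^2,
                "(F,D)" = 2 * p_c^2 * p_F * p_D)
  alpha <- 1 - confidence
  lo <- qbinom(alpha / 2, n_pairs, expected) / n_pairs
  hi <- qbinom(1 - alpha / 2, n_pairs, expected) / n_pairs
  data.frame(category = names(expected), expected = unname(expected),
             ci_low = unname(lo), ci_high = unname(hi),
             stringsAsFactors = FALSE)
}

#' Compare an observed motif tally with its Bernoulli null
#'
#' @param tally a [count_pair_motifs()] result
#' @param confidence confidence level for the null prediction intervals
#' @return data frame with observed fractions, null expectations, interval
#'   bounds and a significance flag per category
#' @export
motif_tally_table <- function(tally, confidence = 0.95) {
  stopifnot(inherits(tally, "motif_tally"))
  null <- motif_null_expectations(tally$p_c, tally$p_F, tally$p_D,
                                  tally$n_pairs, confidence)
  obs <- tally$counts / tally$n_pairs
  null$observed <- unname(obs[null$category])
  null$significant <- null$observed < null$ci_low |
    null$observed > null$ci_high
  null[, c("category", "observed", "expected", "ci_low", "ci_high",
           "significant")]
}
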