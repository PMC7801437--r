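# Conservation permutation test: are observed mutation positions more
# or less conserved than randomly drawn covered positions?

#' Mean conservation score at observed mutation positions
#'
#' Positions are deduplicated before averaging (the observed set is a
#' position set, not a call multiset; multi-allelic positions count
#' once).
#'
#' @param mutation_positions integer positions.
#' @param track a [conservation_track()].
#' @return Arithmetic mean score; errors on any uncovered position.
#' @export
observed_mean_score <- function(mutation_positions, track) {
  pos <- unique(as.integer(mutation_positions))
  if (!length(pos)) stop_ctx("no mutation positions supplied")
  mean(track_score_at(track, pos))
}

#' Permutation null for the mean conservation score
#'
#' Per iteration, `n_positions` positions are drawn without replacement
#' from the pool and their mean score recorded; the expected mean is
#' the average over iterations.
#'
#' @param n_positions observed number of mutation positions.
#' @param pool integer positions forming the sampling universe
#'   (typically all coding positions covered at the variant-calling
#'   depth).
#' @param track a [conservation_track()].
#' @param n_iter iterations (default 10000).
#' @param seed integer seed.
#' @return List with `iteration_means` and `expected_mean`.
#' @export
permutation_null <- function(n_positions, pool, track, n_iter = 10000,
                             seed = 1L) {
  pool <- unique(as.integer(pool))
  if (length(pool) < n_positions)
    stop_ctx("pool (", length(pool), ") smaller than n_positions (",
             n_positions, ")")
  scores <- track_score_at(track, pool)
  means <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    mean(scores[sample.int(length(pool), n_positions)]), numeric(1)))
  list(iteration_means = means, expected_mean = mean(means))
}

#' Conservation-score permutation test
#'
#' Computes the observed mean score at the (deduplicated) mutation
#' positions, the resampling expectation over the pool, their ratio,
#' and a one-sided empirical p: when the ratio is below 1, the fraction
#' of iterations with a mean below the observed; when above 1, the
#' fraction above. With `add_one = TRUE` the (k+1)/(N+1) correction is
#' used instead of the plain fraction.
#'
#' @param mutation_positions observed positions.
#' @param pool sampling universe of positions.
#' @param track a [conservation_track()].
#' @param n_iter iterations (default 10000).
#' @param seed integer seed.
#' @param add_one use the add-one-corrected empirical p.
#' @return A `conservation_result`: observed_mean, expected_mean,
#'   ratio, p_value, direction, n_iterations, iteration_means.
#' @export
conservation_test <- function(mutation_positions, pool, track,
                              n_iter = 10000, seed = 1L,
                              add_one = FALSE) {
  obs <- observed_mean_score(mutation_positions, track)
  nul <- permutation_null(length(unique(mutation_positions)), pool,
                          track, n_iter = n_iter, seed = seed)
  if (nul$expected_mean == 0)
    stop_ctx("expected mean score is 0: ratio undefined")
  ratio <- obs / nul$expected_mean
  if (ratio < 1) {
    k <- sum(nul$iteration_means < obs); direction <- "lower"
  } else {
    k <- sum(nul$iteration_means > obs); direction <- "higher"
  }
  p <- if (add_one) (k + 1) / (n_iter + 1) else k / n_iter
  structure(list(observed_mean = obs, expected_mean = nul$expected_mean,
                 ratio = ratio, p_value = p, direction = direction,
                 n_iterations = n_iter, seed = seed,
                 iteration_means = nul$iteration_means),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(paste0("conservation test: observed %.4f, expected %.4f, ",
                     "ratio %.3f (%s), p = %.4g (%d iterations)\n"),
              x$observed_mean, x$expected_mean, x$ratio, x$direction,
              x$p_value, x$n_iterations))
  invisible(x)
}
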