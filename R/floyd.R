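#' Sample distinct indices without replacement by Floyd's algorithm
#'
#' Draws `sample_size` distinct indices from `1:population_size` using Floyd's
#' ordered-hash-table algorithm, under which every subset of the requested size
#' is equiprobable. This is the classical O(k) subset sampler: for
#' `j = n - k + 1, ..., n` draw `t` uniform on `1..j` and insert `j` if `t` is
#' already in the sample, else insert `t`.
#'
#' Indices are 1-based, following R convention.
#'
#' @param population_size total number of units (positive integer).
#' @param sample_size number of distinct indices to draw, `0 <= sample_size <=
#'   population_size`.
#' @param seed optional integer seed; when given the draw is deterministic and
#'   the caller's RNG state is untouched.
#' @return sorted integer vector of `sample_size` distinct indices in
#'   `1:population_size`.
#' @examples
#' floyd_sample(10, 3, seed = 1)
#' @export
floyd_sample <- function(population_size, sample_size, seed = NULL) {
  population_size <- as.integer(population_size)
  sample_size <- as.integer(sample_size)
  if (is.na(population_size) || population_size < 0) {
    stop_invalid("floyd_sample: population_size must be a non-negative integer")
  }
  if (is.na(sample_size) || sample_size < 0) {
    stop_invalid("floyd_sample: sample_size must be a non-negative integer")
  }
  if (sample_size > population_size) {
    stop_invalid(
      "floyd_sample: sample_size (%d) exceeds population_size (%d)",
      sample_size, population_size
    )
  }
  if (sample_size == 0L) return(integer(0))
  with_seed(seed, {
    in_sample <- logical(population_size)
    for (j in (population_size - sample_size + 1L):population_size) {
      t <- sample.int(j, 1L)
      if (in_sample[t]) in_sample[j] <- TRUE else in_sample[t] <- TRUE
    }
    which(in_sample)
  })
}
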