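# Synthetic case generator: random binary observations whose outputs
# follow a planted system of sum-of-products models, optionally
# perturbed by output noise.  Used throughout the test suite for
# planted-system recovery and property checks.

#' Simulate case-level data from a planted system
#'
#' Draws input configurations uniformly at random (with replacement)
#' and sets each output by evaluating its planted model, then flips
#' each output value independently with probability `noise`.  With
#' `noise = 0` and enough cases that all relevant configurations are
#' observed, solving the simulated table recovers a solution containing
#' the planted system.
#'
#' Randomness comes from R's RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param n_cases Number of cases to draw (default 30, a typical
#'   configurational study size).
#' @param k Number of inputs (default 4).
#' @param m Number of outputs (default 2).
#' @param planted Named list: per output, a list of cubes of width `k`.
#'   `NULL` plants a random system with one or two product terms of one
#'   to three literals per output.
#' @param noise Per-output flip probability in `[0, 1]` (default 0).
#' @param input_names,output_names Variable names.
#' @return A [case_table()]; the planted models are attached as
#'   attribute `"planted"`.
#' @export
simulate_cases <- function(n_cases = 30, k = 4, m = 2, planted = NULL,
                           noise = 0,
                           input_names = paste0("x", seq_len(k)),
                           output_names = paste0("f", seq_len(m))) {
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (is.null(planted)) {
    planted <- lapply(seq_len(m), function(j) {
      lapply(seq_len(sample(1:2, 1)), function(t) {
        nl <- sample(1:min(3, k), 1)
        pos <- sample(seq_len(k) - 1L, nl)
        mask <- 0L
        value <- 0L
        for (b in pos) {
          mask <- bitwOr(mask, bitwShiftL(1L, b))
          if (stats::runif(1) < 0.5) value <- bitwOr(value, bitwShiftL(1L, b))
        }
        new_cube(mask, value, k)
      })
    })
    names(planted) <- output_names
  }
  if (!setequal(names(planted), output_names))
    stop("planted model names must match output_names")
  mt <- sample.int(2L^k, n_cases, replace = TRUE) - 1L
  inputs <- t(vapply(mt, function(x)
    bitwAnd(bitwShiftR(x, (k - 1):0), 1L), integer(k)))
  colnames(inputs) <- input_names
  outputs <- vapply(output_names, function(j)
    evaluate_model(planted[[j]], mt), integer(n_cases))
  if (n_cases == 1L) outputs <- matrix(outputs, 1L,
                                       dimnames = list(NULL, output_names))
  if (noise > 0) {
    flip <- matrix(stats::runif(length(outputs)) < noise, nrow(outputs))
    outputs <- abs(outputs - flip)
  }
  ct <- case_table(inputs, outputs)
  attr(ct, "planted") <- planted
  ct
}
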