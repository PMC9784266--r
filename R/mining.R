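# Ascending-size search over input subsets ("tuples") for the smallest
# input sets whose solutions meet the researcher's fit criteria.

#' Restrict a case table to a subset of inputs
#'
#' @param cases A [case_table()].
#' @param inputs Character vector of input names to keep (in the order
#'   given, which fixes the reduced bit order).
#' @return A [case_table()] over the reduced inputs; rows are kept
#'   as-is (duplicated configurations aggregate later).
#' @export
subset_inputs <- function(cases, inputs) {
  missing <- setdiff(inputs, cases$input_names)
  if (length(missing))
    stop(sprintf("unknown input(s): %s", paste(missing, collapse = ", ")))
  case_table(cases$inputs[, inputs, drop = FALSE], cases$outputs,
             case_ids = cases$case_ids)
}

#' Mine minimal input tuples
#'
#' Tests input subsets in ascending size (lexicographic within a size):
#' for each candidate tuple the truth table is rebuilt over those
#' inputs, outputs are assigned at `inc_threshold`, and the solution is
#' computed.  A tuple passes when at least one of its irredundant
#' systems reaches coverage `>= cov_threshold` for every output
#' (consistency at least `inc_threshold` holds by the assignment rule
#' and is recorded).  Both criteria are mandatory: mining has no silent
#' defaults.
#'
#' @param cases A [case_table()].
#' @param inc_threshold Inclusion cut for row assignment, in (0, 1].
#' @param cov_threshold Minimum per-output model coverage, in `[0, 1]`.
#' @param pool Input names to draw tuples from (default all).
#' @param max_k Largest tuple size to try.
#' @param mode `"first_size"` stops after the first size with a passing
#'   tuple; `"exhaustive"` tests all sizes up to `max_k`.
#' @param n_threshold Truth-table frequency cut (default 1).
#' @param tuple_cap Capacity guard on the number of candidate tuples.
#' @return An object of class `"mining_result"`: a `tested` data frame
#'   (tuple, size, number of systems, minimum per-output consistency
#'   and coverage of the best system, pass flag) and a `passing` list
#'   carrying the winning solutions.
#' @export
mine_tuples <- function(cases, inc_threshold, cov_threshold,
                        pool = cases$input_names, max_k = length(pool),
                        mode = c("first_size", "exhaustive"),
                        n_threshold = 1, tuple_cap = 1e5) {
  mode <- match.arg(mode)
  if (missing(inc_threshold) || missing(cov_threshold))
    stop("mining requires explicit inc_threshold and cov_threshold")
  if (!is.numeric(cov_threshold) || cov_threshold < 0 || cov_threshold > 1)
    stop("cov_threshold must lie in [0, 1]")
  if (!all(pool %in% cases$input_names))
    stop("pool must be a subset of the input names")
  if (max_k < 1 || max_k > length(pool))
    stop("max_k must lie between 1 and the pool size")
  tested <- list()
  passing <- list()
  n_tested <- 0L
  for (s in seq_len(max_k)) {
    if (n_tested + choose(length(pool), s) > tuple_cap)
      stop("capacity: tuple count exceeds the cap; reduce the pool or max_k")
    tuples <- utils::combn(pool, s, simplify = FALSE)
    found <- FALSE
    for (tp in tuples) {
      n_tested <- n_tested + 1L
      sol <- mopir_solve(subset_inputs(cases, tp),
                         inc_threshold = inc_threshold,
                         n_threshold = n_threshold)
      best <- NULL
      best_min_cov <- -Inf
      for (sys in sol$systems) {
        covg <- sys$fit[, "coverage"]
        mc <- min(covg, na.rm = FALSE)
        if (is.na(mc)) mc <- 1  # vacuous outputs pass
        if (mc > best_min_cov) {
          best_min_cov <- mc
          best <- sys
        }
      }
      covg <- best$fit[, "coverage"]
      cons <- best$fit[, "consistency"]
      pass <- all(is.na(covg) | covg >= cov_threshold)
      tested[[length(tested) + 1L]] <- data.frame(
        tuple = paste(tp, collapse = ","), size = s,
        n_systems = length(sol$systems),
        min_consistency = suppressWarnings(min(cons, na.rm = TRUE)),
        min_coverage = suppressWarnings(min(covg, na.rm = TRUE)),
        pass = pass)
      if (pass) {
        found <- TRUE
        passing[[length(passing) + 1L]] <-
          list(tuple = tp, size = s, solution = sol)
      }
    }
    if (found && mode == "first_size") break
  }
  structure(list(tested = do.call(rbind, tested), passing = passing,
                 params = list(inc_threshold = inc_threshold,
                               cov_threshold = cov_threshold,
                               pool = pool, max_k = max_k, mode = mode,
                               n_threshold = n_threshold)),
            class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("Tuple mining: %d tuple(s) tested, %d passing\n",
              nrow(x$tested), length(x$passing)))
  print(x$tested, row.names = FALSE)
  invisible(x)
}
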