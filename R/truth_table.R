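# Truth tables: observed input configurations with case counts and
# per-output inclusion (consistency) scores, and their conversion to
# on/off/dc minterm sets.

#' Aggregate cases into a truth table
#'
#' One row per distinct observed input configuration, in ascending
#' minterm order.  The inclusion score of output j in a row is the
#' fraction of the row's cases exhibiting the output, so `n * Inc` is
#' always an integer.  Output values are not assigned here; see
#' [assign_outputs()].
#'
#' @param cases A [case_table()].
#' @return An object of class `"truth_table"`.
#' @export
aggregate_cases <- function(cases) {
  if (!inherits(cases, "case_table")) stop("expected a case_table")
  if (n_cases(cases) == 0L) stop("empty case table")
  mt <- case_minterms(cases)
  uniq <- sort(unique(mt))
  idx <- match(mt, uniq)
  n <- as.integer(tabulate(idx, length(uniq)))
  inc <- rowsum(cases$outputs + 0, idx) / n
  dimnames(inc) <- list(NULL, cases$output_names)
  structure(list(input_names = cases$input_names,
                 output_names = cases$output_names,
                 width = length(cases$input_names),
                 minterm = uniq, n = n, inc = inc,
                 value = NULL, included = NULL,
                 inc_threshold = NULL, n_threshold = NULL),
            class = "truth_table")
}

#' Assign output values under thresholds
#'
#' Each observed row with at least `n_threshold` cases is assigned, per
#' output, the value 1 when its inclusion score reaches `inc_threshold`
#' and 0 otherwise; rows below the frequency threshold are excluded
#' (their configurations become don't-cares), as are all unobserved
#' configurations.  Contradictory rows (0 < Inc < 1) fall under the
#' same single cut.
#'
#' @param tt A truth table from [aggregate_cases()].
#' @param inc_threshold Inclusion cut in (0, 1].
#' @param n_threshold Minimum case count per row (positive integer).
#' @return The truth table with `value` and `included` filled in.
#' @export
assign_outputs <- function(tt, inc_threshold = 0.6, n_threshold = 1) {
  if (!inherits(tt, "truth_table")) stop("expected a truth_table")
  if (!is.numeric(inc_threshold) || length(inc_threshold) != 1L ||
      inc_threshold <= 0 || inc_threshold > 1)
    stop("inc_threshold must lie in (0, 1]")
  if (!is.numeric(n_threshold) || length(n_threshold) != 1L ||
      n_threshold < 1 || n_threshold != round(n_threshold))
    stop("n_threshold must be a positive integer")
  tt$value <- (tt$inc >= inc_threshold) + 0L
  tt$included <- tt$n >= n_threshold
  tt$inc_threshold <- inc_threshold
  tt$n_threshold <- as.integer(n_threshold)
  tt
}

#' @export
print.truth_table <- function(x, digits = 2, ...) {
  cfg <- vapply(x$minterm, function(m)
    cube_string(cube_from_minterm(m, x$width)), "")
  df <- data.frame(cfg, minterm = x$minterm, n = x$n,
                   round(x$inc, digits), check.names = FALSE)
  names(df)[1] <- paste(x$input_names, collapse = "")
  names(df)[3 + seq_along(x$output_names)] <-
    paste0("Inc(", x$output_names, ")")
  if (!is.null(x$value)) {
    v <- x$value
    colnames(v) <- paste0("f(", x$output_names, ")")
    df <- cbind(df, v, excluded = ifelse(x$included, "", "*"))
  }
  cat(sprintf("Truth table: %d configuration(s) over %d input(s), %d case(s)\n",
              length(x$minterm), x$width, sum(x$n)))
  print(df, row.names = FALSE)
  invisible(x)
}

new_function_spec <- function(width, on, off, input_names, output_names) {
  width <- as.integer(width)
  stopifnot(length(on) == length(output_names),
            length(off) == length(output_names))
  on <- lapply(on, function(v) sort(unique(as.integer(v))))
  off <- lapply(off, function(v) sort(unique(as.integer(v))))
  names(on) <- names(off) <- output_names
  for (j in output_names) {
    if (length(intersect(on[[j]], off[[j]])))
      stop(sprintf("on- and off-set of '%s' overlap", j))
    rng <- c(on[[j]], off[[j]])
    if (length(rng) && (min(rng) < 0L || max(rng) >= 2^width))
      stop("minterm index out of range for the declared width")
    if (length(on[[j]]) == 0L)
      warning(sprintf("empty on-set for output '%s': its model is the empty disjunction", j))
  }
  structure(list(width = width, input_names = input_names,
                 output_names = output_names, on = on, off = off),
            class = "function_spec")
}

#' Derive on/off/dc minterm sets from an assigned truth table
#'
#' Included rows valued 1 form the on-set, included rows valued 0 the
#' off-set; everything else (unobserved or below the frequency
#' threshold) is don't-care.
#'
#' @param x An assigned truth table (see [assign_outputs()]), or another
#'   object with a method.
#' @param ... Passed on to methods.
#' @return An object of class `"function_spec"`.
#' @export
function_spec <- function(x, ...) UseMethod("function_spec")

#' @export
function_spec.truth_table <- function(x, ...) {
  if (is.null(x$value))
    stop("assign output values first (assign_outputs)")
  on <- off <- vector("list", length(x$output_names))
  for (j in seq_along(x$output_names)) {
    on[[j]] <- x$minterm[x$included & x$value[, j] == 1L]
    off[[j]] <- x$minterm[x$included & x$value[, j] == 0L]
  }
  new_function_spec(x$width, on, off, x$input_names, x$output_names)
}

#' Specify a system of functions by on-set (and dc-set) minterm lists
#'
#' The off-set of each output is the complement of its on- and dc-sets,
#' so omitting `dc` gives a completely specified function.
#'
#' @param width Number of inputs k.
#' @param on Named list: per output, integer vector of on-set minterms.
#' @param dc Optional named list of don't-care minterms (disjoint from
#'   `on`); missing outputs get an empty dc-set.
#' @param input_names Input names; default `x1..xk` (or the declared
#'   names you pass).
#' @param output_names Output names; default taken from `names(on)`.
#' @return A `"function_spec"`.
#' @examples
#' spec_from_minterms(3, list(f1 = c(1, 3, 7), f2 = c(2, 6, 7)),
#'                    input_names = c("x", "y", "z"))
#' @export
spec_from_minterms <- function(width, on, dc = NULL,
                               input_names = NULL, output_names = NULL) {
  if (is.null(output_names)) output_names <- names(on)
  if (is.null(output_names))
    output_names <- paste0("f", seq_along(on))
  if (is.null(input_names)) input_names <- paste0("x", seq_len(width))
  if (length(input_names) != width)
    stop("need one input name per position")
  all_m <- seq_len(2^width) - 1L
  on <- lapply(on, as.integer)
  off <- vector("list", length(on))
  for (j in seq_along(on)) {
    d <- if (!is.null(dc) && output_names[j] %in% names(dc))
      as.integer(dc[[output_names[j]]]) else integer(0)
    if (length(intersect(on[[j]], d)))
      stop(sprintf("on- and dc-lists of '%s' overlap", output_names[j]))
    if (any(c(on[[j]], d) < 0L) || any(c(on[[j]], d) >= 2^width))
      stop("minterm index out of range for the declared width")
    off[[j]] <- setdiff(all_m, union(on[[j]], d))
  }
  new_function_spec(width, on, off, input_names, output_names)
}

# dc-set computed on demand (it can be large)
dc_set <- function(spec, output) {
  setdiff(seq_len(2^spec$width) - 1L,
          union(spec$on[[output]], spec$off[[output]]))
}

#' @export
print.function_spec <- function(x, ...) {
  cat(sprintf("Function spec: %d input(s) (%s), %d output(s)\n",
              x$width, paste(x$input_names, collapse = ", "),
              length(x$output_names)))
  for (j in x$output_names)
    cat(sprintf("  %s: |on| = %d, |off| = %d, |dc| = %d\n", j,
                length(x$on[[j]]), length(x$off[[j]]),
                2^x$width - length(x$on[[j]]) - length(x$off[[j]])))
  invisible(x)
}
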