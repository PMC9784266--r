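# MOPI charts and the enumeration of all irredundant systems.
#
# The chart has one row per MOPI and one column per (output, on-minterm)
# pair; a row marks a column when its tag contains the output and its
# cube covers the minterm.  Petrick's method -- product-of-sums over the
# columns expanded to sum-of-products with absorption after every
# distribution step -- yields exactly the inclusion-minimal covers.  No
# row or column dominance pruning is applied: dominance can delete rows
# that participate in non-minimum irredundant covers, and the solution
# is defined as ALL of them.  Only duplicate columns (identical mark
# sets) are collapsed during the expansion.

#' Build the MOPI chart
#'
#' @param mopis A `"mopi_list"` from [generate_mopis()].
#' @param spec The [function_spec] the MOPIs were generated for.
#' @return An object of class `"mopi_chart"` with the marks matrix and
#'   column labels; row and column order is deterministic.
#' @export
build_chart <- function(mopis, spec) {
  col_output <- character(0)
  col_minterm <- integer(0)
  for (j in spec$output_names) {
    ms <- sort(spec$on[[j]])
    col_output <- c(col_output, rep.int(j, length(ms)))
    col_minterm <- c(col_minterm, ms)
  }
  marks <- matrix(FALSE, length(mopis), length(col_output))
  for (i in seq_along(mopis)) {
    ti <- mopis[[i]]
    for (cc in seq_along(col_output)) {
      marks[i, cc] <- (col_output[cc] %in% ti$tag) &&
        covers(ti$cube, col_minterm[cc])
    }
  }
  if (length(col_output) && any(colSums(marks) == 0L)) {
    bad <- which(colSums(marks) == 0L)[1]
    stop(sprintf("internal consistency error: on-minterm %d of output '%s' is covered by no tagged implicant",
                 col_minterm[bad], col_output[bad]))
  }
  structure(list(mopis = mopis, spec = spec,
                 col_output = col_output, col_minterm = col_minterm,
                 marks = marks),
            class = "mopi_chart")
}

#' Essential rows of a chart
#'
#' Rows that are the unique mark of at least one column; they appear in
#' every irredundant system.
#'
#' @param chart A [build_chart()] result.
#' @return Sorted integer vector of row indices.
#' @export
essential_rows <- function(chart) {
  single <- which(colSums(chart$marks) == 1L)
  sort(unique(unlist(lapply(single, function(cc) which(chart$marks[, cc])))))
}

#' @export
print.mopi_chart <- function(x, ...) {
  cat(format_chart(x), sep = "\n")
  invisible(x)
}

#' Text rendering of a MOPI chart
#'
#' A grid with one row per implicant (labelled p1, p2, ... in canonical
#' order) and per-output minterm columns, marks shown as "x".
#'
#' @param chart A `"mopi_chart"`.
#' @return Character vector of lines.
#' @export
format_chart <- function(chart) {
  inp <- chart$spec$input_names
  labels <- vapply(chart$mopis, function(ti) format_cube(ti$cube, inp), "")
  wl <- max(nchar(labels), 0L) + 2L
  heads <- sprintf("%s:%d", chart$col_output, chart$col_minterm)
  wc <- pmax(nchar(heads), 1L)
  hdr <- paste0(formatC("", width = wl + 6L),
                paste(mapply(formatC, heads, width = wc), collapse = " "))
  rows <- vapply(seq_along(chart$mopis), function(i) {
    cells <- ifelse(chart$marks[i, ], "x", ".")
    paste0(formatC(paste0("p", i), width = 5L, flag = "-"),
           formatC(labels[i], width = wl, flag = "-"),
           paste(mapply(formatC, cells, width = wc), collapse = " "))
  }, "")
  c(hdr, rows)
}

# All inclusion-minimal covers of the chart columns, as sorted integer
# row sets in canonical order (size, then lexicographic).
petrick_covers <- function(marks, term_cap = 1e6) {
  R <- nrow(marks)
  if (ncol(marks) == 0L) return(list(integer(0)))
  col_sets <- lapply(seq_len(ncol(marks)), function(cc) which(marks[, cc]))
  col_sets <- col_sets[!duplicated(vapply(col_sets, paste, "", collapse = ","))]
  col_sets <- col_sets[order(lengths(col_sets))]
  terms <- matrix(FALSE, 1L, R)
  for (S in col_sets) {
    covered <- rowSums(terms[, S, drop = FALSE]) > 0L
    parts <- list(terms[covered, , drop = FALSE])
    base <- terms[!covered, , drop = FALSE]
    if (nrow(base)) {
      for (r in S) {
        t2 <- base
        t2[, r] <- TRUE
        parts <- c(parts, list(t2))
      }
    }
    terms <- do.call(rbind, parts)
    terms <- terms[!duplicated(apply(terms, 1L, paste, collapse = "")), ,
                   drop = FALSE]
    if (nrow(terms) > 1L) {
      M <- terms + 0
      contain <- (M %*% t(1 - M)) == 0   # [i,j]: rows of i all in j
      terms <- terms[colSums(contain) <= 1L, , drop = FALSE]
    }
    if (nrow(terms) > term_cap)
      stop("capacity: Petrick expansion exceeded the term cap; consider mining or raising thresholds")
  }
  covers <- lapply(seq_len(nrow(terms)), function(i) which(terms[i, ]))
  key <- vapply(covers, function(s) paste(sprintf("%05d", s), collapse = ""), "")
  covers[order(lengths(covers), key)]
}

#' Write the per-output models of a MOPI selection
#'
#' A selected MOPI is written into the model of every output in its tag
#' whose on-set it touches.  A shared MOPI may be absorbable inside a
#' single output's sum (e.g. `mys·roca + roca`); it is retained there
#' because cancellation operates on the system as a whole, not
#' per-output.
#'
#' @param selected List of tagged implicants (e.g.
#'   `solution$systems[[1]]$implicants`).
#' @param spec The [function_spec].
#' @return Named list: per output, list of cubes in canonical order.
#' @export
write_models <- function(selected, spec) {
  models <- vector("list", length(spec$output_names))
  names(models) <- spec$output_names
  for (j in spec$output_names) {
    keep <- vapply(selected, function(ti)
      (j %in% ti$tag) && any(covers(ti$cube, spec$on[[j]])), TRUE)
    models[[j]] <- sort_cubes(lapply(selected[keep], function(ti) ti$cube))
  }
  models
}

#' Is a set of models F-equivalent to a specification?
#'
#' True iff, for every output, the model evaluates to 1 on every
#' on-minterm and 0 on every off-minterm (don't-cares are free).
#'
#' @param models Named list: per output, list of cubes.
#' @param spec A [function_spec].
#' @return Logical scalar.
#' @export
is_f_equivalent <- function(models, spec) {
  for (j in spec$output_names) {
    if (length(spec$on[[j]]) &&
        !all(evaluate_model(models[[j]], spec$on[[j]]) == 1L)) return(FALSE)
    if (length(spec$off[[j]]) &&
        any(evaluate_model(models[[j]], spec$off[[j]]) == 1L)) return(FALSE)
  }
  TRUE
}

# Definition-level literal irredundancy: cancelling one literal in the
# writing of a selected MOPI -- the expanded product replaces the
# original in exactly the models where it was written -- must break
# F-equivalence.  Inclusion-minimal covers do not guarantee this when
# don't-cares are present: a shared-tag MOPI used only where a weaker
# expansion suffices could have a literal cancelled.  Such covers are
# discarded.
literal_irredundant <- function(selected, spec) {
  outs <- spec$output_names
  written <- lapply(selected, function(ti)
    outs[vapply(outs, function(j)
      (j %in% ti$tag) && any(covers(ti$cube, spec$on[[j]])), TRUE)])
  base <- write_models(selected, spec)
  for (i in seq_along(selected)) {
    key <- cube_string(selected[[i]]$cube)
    for (e in expansions(selected[[i]]$cube)) {
      mod <- base
      for (j in written[[i]]) {
        mod[[j]] <- c(Filter(function(c) cube_string(c) != key, mod[[j]]),
                      list(e))
      }
      if (is_f_equivalent(mod, spec)) return(FALSE)
    }
  }
  TRUE
}

new_mo_system <- function(sel, chart) {
  impl <- chart$mopis[sel]
  models <- write_models(impl, chart$spec)
  attr(models, "input_names") <- chart$spec$input_names
  structure(list(selected = sel, implicants = impl, models = models,
                 input_names = chart$spec$input_names,
                 output_names = chart$spec$output_names),
            class = "mo_system")
}

#' @export
format.mo_system <- function(x, ...) {
  vapply(x$output_names, function(j)
    format_model(x$models[[j]], j, x$input_names), "")
}

#' @export
print.mo_system <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Enumerate all irredundant systems of a chart
#'
#' Applies Petrick's method to the chart, discards the (rare) covers in
#' which a literal of a selected implicant could still be cancelled
#' without losing F-equivalence, and materializes each remaining cover
#' as a system with its per-output model writings.  Systems are
#' ordered canonically: fewer selected
#' implicants first, then lexicographically by row index.
#'
#' @param chart A [build_chart()] result.
#' @param term_cap Cap on the Petrick sum-of-products size (capacity
#'   error beyond it).
#' @return An object of class `"mo_solution"`: the complete set of
#'   irredundant systems.
#' @export
enumerate_irredundant_systems <- function(chart, term_cap = 1e6) {
  covers <- petrick_covers(chart$marks, term_cap)
  covers <- covers[vapply(covers, function(sel)
    literal_irredundant(chart$mopis[sel], chart$spec), TRUE)]
  systems <- lapply(covers, new_mo_system, chart = chart)
  structure(list(systems = systems, chart = chart, mopis = chart$mopis,
                 spec = chart$spec,
                 params = list(term_cap = term_cap)),
            class = "mo_solution")
}

#' @export
print.mo_solution <- function(x, ...) {
  cat(sprintf("Solution: %d irredundant system(s), %d MOPI(s)\n",
              length(x$systems), length(x$mopis)))
  for (i in seq_along(x$systems)) {
    cat(sprintf("S*%d:\n", i))
    cat(paste0("  ", format(x$systems[[i]])), sep = "\n")
  }
  invisible(x)
}

#' Consistency and coverage of a model over cases
#'
#' Consistency is the share of model-satisfying cases that exhibit the
#' output; coverage is the share of output-positive cases the model
#' captures.  A 0/0 ratio is reported as `NA` (undefined).
#'
#' @param model List of cubes over the case inputs.
#' @param output Output name.
#' @param cases A [case_table()].
#' @return Named numeric vector `c(consistency =, coverage =)`.
#' @export
model_fit <- function(model, output, cases) {
  mv <- evaluate_model(model, case_minterms(cases)) == 1L
  ov <- cases$outputs[, output] == 1L
  both <- sum(mv & ov)
  consistency <- if (sum(mv) == 0L) NA_real_ else both / sum(mv)
  coverage <- if (sum(ov) == 0L) NA_real_ else both / sum(ov)
  c(consistency = consistency, coverage = coverage)
}

system_fit <- function(system, cases) {
  t(vapply(system$output_names, function(j)
    model_fit(system$models[[j]], j, cases), c(consistency = 0, coverage = 0)))
}

#' Solve a multi-output minimization problem end to end
#'
#' For a [case_table()]: aggregate cases into a truth table, assign
#' output values under the thresholds, derive the on/off/dc sets,
#' generate all MOPIs, build the chart, and enumerate every irredundant
#' system; per-system fit statistics against the cases are attached.
#' For a [function_spec] (or an assigned truth table) the pipeline
#' starts at the corresponding stage.  Everything is deterministic.
#'
#' @param x A `case_table`, `truth_table` (with assigned outputs), or
#'   `function_spec`.
#' @param ... Passed on to methods.
#' @return An object of class `"mo_solution"`.
#' @examples
#' spec <- spec_from_minterms(3, list(f1 = c(1, 3, 7), f2 = c(2, 6, 7)),
#'                            input_names = c("x", "y", "z"))
#' mopir_solve(spec)
#' @export
mopir_solve <- function(x, ...) UseMethod("mopir_solve")

#' @rdname mopir_solve
#' @param inc_threshold,n_threshold Truth-table assignment thresholds,
#'   see [assign_outputs()].
#' @param algorithm MOPI generation route, see [generate_mopis()].
#' @param term_cap Petrick capacity, see
#'   [enumerate_irredundant_systems()].
#' @export
mopir_solve.case_table <- function(x, inc_threshold = 0.6, n_threshold = 1,
                                   algorithm = c("on-dc", "on-off"),
                                   term_cap = 1e6, ...) {
  tt <- assign_outputs(aggregate_cases(x), inc_threshold, n_threshold)
  sol <- mopir_solve(function_spec(tt), algorithm = algorithm,
                     term_cap = term_cap)
  sol$truth_table <- tt
  sol$cases <- x
  sol$params$inc_threshold <- inc_threshold
  sol$params$n_threshold <- n_threshold
  for (i in seq_along(sol$systems))
    sol$systems[[i]]$fit <- system_fit(sol$systems[[i]], x)
  sol
}

#' @rdname mopir_solve
#' @export
mopir_solve.truth_table <- function(x, algorithm = c("on-dc", "on-off"),
                                    term_cap = 1e6, ...) {
  mopir_solve(function_spec(x), algorithm = algorithm, term_cap = term_cap)
}

#' @rdname mopir_solve
#' @export
mopir_solve.function_spec <- function(x, algorithm = c("on-dc", "on-off"),
                                      term_cap = 1e6, ...) {
  algorithm <- match.arg(algorithm)
  mopis <- generate_mopis(x, algorithm)
  chart <- build_chart(mopis, x)
  sol <- enumerate_irredundant_systems(chart, term_cap)
  sol$params$algorithm <- algorithm
  sol
}

#' Export a solution as structured JSON
#'
#' One record per system: selected implicants (positional strings and
#' tags) and per-output model strings.
#'
#' @param solution A `"mo_solution"`.
#' @param file Optional path; omit to return the JSON text.
#' @return JSON text, invisibly when writing.
#' @export
export_solution <- function(solution, file = NULL) {
  inp <- solution$spec$input_names
  recs <- lapply(solution$systems, function(s) {
    list(selected = vapply(s$implicants, function(ti) cube_string(ti$cube), ""),
         tags = lapply(s$implicants, function(ti) ti$tag),
         models = lapply(s$output_names, function(j)
           format_model(s$models[[j]], j, inp)))
  })
  txt <- jsonlite::toJSON(list(n_systems = length(solution$systems),
                               input_names = inp,
                               output_names = solution$spec$output_names,
                               systems = recs),
                          auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
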