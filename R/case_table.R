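# Case-level data: one row per case (patient group, country, ...), a
# binary vector of inputs and a binary vector of outputs.

#' Build a case table
#'
#' @param inputs Matrix or data frame of 0/1 input values with named
#'   columns; the column order fixes the minterm bit order (first input
#'   is the most significant bit).
#' @param outputs Matrix or data frame of 0/1 outcome values with named
#'   columns, disjoint from the input names.
#' @param case_ids Optional character vector of unique case labels;
#'   defaults to row numbers.
#' @return An object of class `"case_table"`.
#' @examples
#' ct <- case_table(
#'   inputs  = data.frame(x = c(0, 1), y = c(1, 1)),
#'   outputs = data.frame(f = c(0, 1)))
#' ct
#' @export
case_table <- function(inputs, outputs, case_ids = NULL) {
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  storage.mode(inputs) <- "integer"
  storage.mode(outputs) <- "integer"
  if (is.null(colnames(inputs)) || is.null(colnames(outputs)))
    stop("input and output columns must be named")
  if (ncol(inputs) == 0L || ncol(outputs) == 0L)
    stop("at least one input and one output column are required")
  if (length(intersect(colnames(inputs), colnames(outputs))))
    stop("input and output names must be disjoint")
  if (nrow(inputs) != nrow(outputs))
    stop("inputs and outputs must have the same number of cases")
  if (anyNA(inputs) || anyNA(outputs) ||
      !all(inputs %in% c(0L, 1L)) || !all(outputs %in% c(0L, 1L)))
    stop("all case values must be 0 or 1 (missing values are rejected)")
  if (is.null(case_ids)) case_ids <- as.character(seq_len(nrow(inputs)))
  case_ids <- as.character(case_ids)
  if (length(case_ids) != nrow(inputs))
    stop("one case id per row is required")
  if (anyDuplicated(case_ids))
    stop(sprintf("duplicate case id '%s'", case_ids[duplicated(case_ids)][1]))
  rownames(inputs) <- rownames(outputs) <- NULL
  structure(list(case_ids = case_ids,
                 input_names = colnames(inputs),
                 output_names = colnames(outputs),
                 inputs = inputs, outputs = outputs),
            class = "case_table")
}

#' Read cases from CSV
#'
#' The header must contain all declared input and output columns (file
#' column order does not matter; the declared `input_names` order
#' defines the minterm bit order).  An unnamed first column, or a first
#' column whose name is not among the declared variables, is taken as
#' the case identifiers.
#'
#' @param file Path, connection, or literal CSV text.
#' @param input_names,output_names Declared variable names.
#' @return A [case_table()].
#' @export
read_cases_csv <- function(file, input_names, output_names) {
  if (is.character(file) && length(file) == 1L && grepl("\n", file))
    file <- textConnection(file)
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  declared <- c(input_names, output_names)
  ids <- NULL
  if (ncol(df) > 0L && !(names(df)[1] %in% declared)) {
    ids <- df[[1]]
    df <- df[-1]
  }
  missing <- setdiff(declared, names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in CSV header: %s",
                 paste(missing, collapse = ", ")))
  vals <- as.matrix(df[declared])
  bad <- which(!(vals %in% c("0", "1")), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(vals))
    stop(sprintf("non-binary value '%s' in row %d, column '%s'",
                 vals[bad[1]], rc[1], declared[rc[2]]))
  }
  num <- matrix(as.integer(vals), nrow = nrow(vals),
                dimnames = list(NULL, declared))
  case_table(num[, input_names, drop = FALSE],
             num[, output_names, drop = FALSE], case_ids = ids)
}

#' Write a case table back to CSV
#'
#' @param cases A [case_table()].
#' @param file Path or connection.
#' @export
write_cases_csv <- function(cases, file) {
  df <- data.frame(cases$case_ids, cases$inputs, cases$outputs,
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

n_cases <- function(cases) length(cases$case_ids)

# decimal configuration per case, first input = MSB
case_minterms <- function(cases) {
  k <- length(cases$input_names)
  as.integer(cases$inputs %*% 2^((k - 1):0))
}

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf("Case table: %d case(s), inputs (%s), outputs (%s)\n",
              n_cases(x), paste(x$input_names, collapse = ", "),
              paste(x$output_names, collapse = ", ")))
  df <- data.frame(id = x$case_ids, x$inputs, x$outputs,
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Render a model in report notation
#'
#' Disjuncts are joined by `" + "` in canonical order (fewer literals
#' first, then positional string) and terminated by `" <=> "` and the
#' output name, e.g. `"mys·roca + roca <=> mvta"`.
#'
#' @param model List of cubes.
#' @param output_name Name of the explained output.
#' @param input_names Input names fixing the literal rendering.
#' @return A single string; the empty model renders as `"0 <=> ..."`.
#' @export
format_model <- function(model, output_name, input_names) {
  if (length(model) == 0L) return(paste0("0 <=> ", output_name))
  terms <- vapply(sort_cubes(model), format_cube, "", names = input_names)
  paste0(paste(terms, collapse = " + "), " <=> ", output_name)
}

#' Parse a model rendered by [format_model()]
#'
#' @param text A string like `"x'z + yz <=> f1"` (the `<=>` part is
#'   optional).
#' @param input_names Input names fixing width and positions.
#' @return A list of cubes in canonical order.
#' @export
parse_model <- function(text, input_names) {
  lhs <- trimws(sub("<=>.*$", "", text))
  if (lhs == "0") return(list())
  terms <- trimws(strsplit(lhs, "+", fixed = TRUE)[[1]])
  sort_cubes(lapply(terms, cube_from_literals, input_names = input_names))
}
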