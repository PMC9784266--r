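# Product terms (cubes) over k binary inputs, encoded as a care mask plus
# a value word: bit b of `mask` is 1 iff input bit b is a literal of the
# cube, and then bit b of `value` gives its polarity.  The first declared
# input is the most significant bit, so decimal minterm indices read off
# the input vector directly (input 1 of k sits at bit k-1).

bit_count <- function(x) {
  x <- as.integer(x)
  r <- integer(length(x))
  while (any(x != 0L)) {
    r <- r + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  r
}

mask_bits <- function(x, width) {
  which(bitwAnd(bitwShiftR(as.integer(x), seq_len(width) - 1L), 1L) == 1L) - 1L
}

new_cube <- function(mask, value, width) {
  mask <- as.integer(mask)
  structure(list(mask = mask, value = bitwAnd(as.integer(value), mask),
                 width = as.integer(width)),
            class = "cube")
}

#' Construct a cube from its positional string
#'
#' A cube (product of literals) is written positionally with one
#' character per input: `"0"` for a negated literal, `"1"` for an
#' asserted literal, `"-"` for an absent input.  `"0-1"` over inputs
#' x, y, z is the product x'z.
#'
#' @param x A positional string such as `"0-1"`, or an existing cube
#'   (returned unchanged).
#' @return An object of class `"cube"` with fields `mask`, `value` and
#'   `width`.
#' @examples
#' cube("0-1")
#' cube("---")   # the universal cube, covering every minterm
#' @seealso [cube_from_minterm()], [cube_from_literals()]
#' @export
cube <- function(x) {
  if (inherits(x, "cube")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("a cube is built from a single positional string such as \"0-1\"")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("0", "1", "-")))
    stop("positional cube strings may only contain 0, 1 and -")
  w <- length(ch)
  mask <- 0L
  value <- 0L
  for (i in seq_len(w)) {
    b <- w - i
    if (ch[i] != "-") {
      mask <- bitwOr(mask, bitwShiftL(1L, b))
      if (ch[i] == "1") value <- bitwOr(value, bitwShiftL(1L, b))
    }
  }
  new_cube(mask, value, w)
}

#' Cube covering exactly one minterm
#'
#' @param index Minterm index in `[0, 2^width)`; the first input is the
#'   most significant bit, so index 1 over three inputs is `001`.
#' @param width Number of inputs.
#' @return A full cube (no absent positions) covering exactly `index`.
#' @examples
#' cube_from_minterm(3, 3)  # 011, i.e. x'yz
#' @export
cube_from_minterm <- function(index, width) {
  index <- as.integer(index)
  width <- as.integer(width)
  if (length(index) != 1L || is.na(index) || index < 0L || index >= 2^width)
    stop(sprintf("minterm index %s out of range for %d input(s)", index, width))
  new_cube(2L^width - 1L, index, width)
}

#' Does a cube cover given minterms?
#'
#' @param c A cube.
#' @param m Integer vector of minterm indices in `[0, 2^width)`.
#' @return Logical vector: `TRUE` where every literal of `c` agrees with
#'   the corresponding bit of the minterm.
#' @export
covers <- function(c, m) {
  m <- as.integer(m)
  if (any(m < 0L | m >= 2^c$width))
    stop("minterm index outside the cube's input space (width mismatch?)")
  bitwAnd(m, c$mask) == c$value
}

#' Merge two adjacent cubes (Quine-McCluskey step)
#'
#' Two cubes merge when they have identical absent positions and differ
#' in exactly one literal; the merged cube drops that literal and covers
#' exactly the union of the two inputs' minterms.
#'
#' @param a,b Cubes of the same width.
#' @return The merged cube, or `NULL` when the cubes are not adjacent.
#' @export
merge_adjacent <- function(a, b) {
  if (a$width != b$width) stop("cubes have different widths")
  if (a$mask != b$mask) return(NULL)
  d <- bitwXor(a$value, b$value)
  if (bit_count(d) != 1L) return(NULL)
  keep <- bitwAnd(a$mask, bitwNot(d))
  new_cube(keep, bitwAnd(a$value, keep), a$width)
}

#' One-literal expansions of a cube
#'
#' Each expansion cancels one literal (sets one specified position to
#' absent) and therefore covers a strict superset of the cube's
#' minterms.  Primality of an implicant means no expansion is still an
#' implicant of the same (or a larger) set of outputs.
#'
#' @param c A cube.
#' @return A list of cubes, one per literal of `c`; empty for the
#'   universal cube.
#' @export
expansions <- function(c) {
  lapply(mask_bits(c$mask, c$width), function(b) {
    keep <- bitwAnd(c$mask, bitwNot(bitwShiftL(1L, b)))
    new_cube(keep, bitwAnd(c$value, keep), c$width)
  })
}

#' Minterms covered by a cube
#'
#' @param c A cube.
#' @return Sorted integer vector of the `2^(number of absent positions)`
#'   covered minterm indices.
#' @export
covered_minterms <- function(c) {
  free <- setdiff(seq_len(c$width) - 1L, mask_bits(c$mask, c$width))
  ms <- c$value
  for (b in free) ms <- c(ms, bitwOr(ms, bitwShiftL(1L, b)))
  sort(ms)
}

#' Evaluate a disjunction of cubes at minterms
#'
#' @param model List of cubes of equal width (a sum-of-products model).
#'   The empty model evaluates to 0 everywhere.
#' @param m Integer vector of minterm indices.
#' @return Integer vector of 0/1 values, one per minterm.
#' @export
evaluate_model <- function(model, m) {
  m <- as.integer(m)
  if (length(model) == 0L) return(integer(length(m)))
  w <- model[[1]]$width
  if (!all(vapply(model, function(c) c$width, 0L) == w))
    stop("model cubes have different widths")
  as.integer(Reduce(`|`, lapply(model, covers, m = m)))
}

cube_string <- function(c) {
  w <- c$width
  ch <- character(w)
  for (i in seq_len(w)) {
    b <- w - i
    ch[i] <- if (bitwAnd(bitwShiftR(c$mask, b), 1L) == 0L) "-"
             else as.character(bitwAnd(bitwShiftR(c$value, b), 1L))
  }
  paste(ch, collapse = "")
}

#' @export
format.cube <- function(x, names = NULL, ...) {
  if (is.null(names)) return(cube_string(x))
  if (length(names) != x$width)
    stop("need one input name per cube position")
  if (x$mask == 0L) return("1")
  sep <- if (any(nchar(names) > 1L)) "·" else ""
  parts <- character(0)
  for (i in seq_len(x$width)) {
    b <- x$width - i
    if (bitwAnd(bitwShiftR(x$mask, b), 1L) == 1L) {
      neg <- bitwAnd(bitwShiftR(x$value, b), 1L) == 0L
      parts <- c(parts, paste0(names[i], if (neg) "'" else ""))
    }
  }
  paste(parts, collapse = sep)
}

#' Render a cube with input names
#'
#' Uses the field's conventional notation: lower-case names, postfix
#' apostrophe for negation, juxtaposition for single-letter inputs and a
#' middle dot for multi-letter ones (`"x'z"`, `"mys·roca"`).
#'
#' @param c A cube.
#' @param names Character vector of input names, one per position;
#'   `NULL` gives the positional string form.
#' @return A single string; the universal cube renders as `"1"`.
#' @export
format_cube <- function(c, names = NULL) format(c, names = names)

#' @export
print.cube <- function(x, ...) {
  cat("<cube ", cube_string(x), ">\n", sep = "")
  invisible(x)
}

cube_eq <- function(a, b) {
  a$width == b$width && a$mask == b$mask && a$value == b$value
}

n_literals <- function(c) bit_count(c$mask)

# canonical order: fewer literals first, then positional string
sort_cubes <- function(cubes) {
  if (length(cubes) == 0L) return(cubes)
  key <- vapply(cubes, cube_string, "")
  cubes[order(vapply(cubes, n_literals, 0L), key)]
}

#' Parse a product of literals
#'
#' Inverse of [format_cube()]: reads e.g. `"x'z"` or `"mys·roca"`
#' (also `*` as separator) against a declared input order.
#'
#' @param text The product; `"1"` denotes the universal cube.
#' @param input_names Character vector fixing position and width.
#' @return A cube.
#' @export
cube_from_literals <- function(text, input_names) {
  k <- length(input_names)
  s <- gsub("\\s+", "", text)
  if (s == "1") return(new_cube(0L, 0L, k))
  toks <- character(0)
  if (grepl("[·*]", s)) {
    toks <- strsplit(s, "[·*]")[[1]]
  } else {
    # greedy longest-name match for juxtaposed literals
    byl <- input_names[order(nchar(input_names), decreasing = TRUE)]
    pos <- 1L
    while (pos <= nchar(s)) {
      hit <- NULL
      for (nm in byl) {
        if (substr(s, pos, pos + nchar(nm) - 1L) == nm) { hit <- nm; break }
      }
      if (is.null(hit))
        stop(sprintf("cannot parse literal at '%s'", substr(s, pos, nchar(s))))
      pos <- pos + nchar(hit)
      if (substr(s, pos, pos) == "'") {
        hit <- paste0(hit, "'")
        pos <- pos + 1L
      }
      toks <- c(toks, hit)
    }
  }
  mask <- 0L
  value <- 0L
  for (t in toks) {
    neg <- grepl("'$", t)
    nm <- sub("'$", "", t)
    i <- match(nm, input_names)
    if (is.na(i)) stop(sprintf("unknown input name '%s'", nm))
    b <- bitwShiftL(1L, k - i)
    if (bitwAnd(mask, b) == b) {
      set <- bitwAnd(value, b) == b
      if (set == neg) stop(sprintf("conflicting polarities for '%s'", nm))
    }
    mask <- bitwOr(mask, b)
    if (!neg) value <- bitwOr(value, b)
  }
  new_cube(mask, value, k)
}
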