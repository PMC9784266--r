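# Multi-output prime implicants (MOPIs).  A MOPI is a cube that is a
# prime implicant of some output function or of a product of output
# functions.  We store each cube with its maximal output tag: the set
# of outputs whose off-sets it avoids.  Tag maximality makes the
# per-subset PI lists redundant:
#
#   Claim. c is a PI of the product of the outputs in T, for some
#   non-empty T, iff tag(c) is non-empty, T = tag(c) works, and no
#   one-literal expansion e of c has tag(e) >= tag(c).
#   Sketch: e covers a superset of c's minterms, so tag(e) <= tag(c)
#   always; "c prime for product over T" means every e hits the off-set
#   of some member of T, i.e. tag(e) is a strict subset of T whenever
#   T <= tag(c).  Taking T = tag(c), primality for the largest product
#   is exactly "no expansion keeps the full tag", and primality for any
#   smaller T follows for the T that need it.
#
# Only "useful" MOPIs -- those covering at least one on-minterm of a
# tagged output -- are kept: a cube covering only don't-cares can never
# mark a chart column.

tag_bits <- function(mask, value, offs) {
  t <- 0L
  for (j in seq_along(offs)) {
    if (!any(bitwAnd(offs[[j]], mask) == value))
      t <- bitwOr(t, bitwShiftL(1L, j - 1L))
  }
  t
}

tag_names <- function(t, output_names) {
  output_names[bitwAnd(bitwShiftR(t, seq_along(output_names) - 1L), 1L) == 1L]
}

#' Maximal output tag of a cube
#'
#' The largest set of outputs whose off-sets the cube avoids, i.e. the
#' largest product function the cube implies.  An empty tag means the
#' cube is an implicant of nothing.
#'
#' @param c A cube over the spec's inputs.
#' @param spec A [function_spec].
#' @return Character vector of output names (in declared order).
#' @export
output_tag <- function(c, spec) {
  if (c$width != spec$width) stop("cube width disagrees with the spec")
  tag_names(tag_bits(c$mask, c$value, spec$off), spec$output_names)
}

#' Is a cube a (useful) multi-output prime implicant?
#'
#' True iff the cube's maximal tag is non-empty, no one-literal
#' expansion keeps a superset of that tag, and the cube covers at least
#' one on-minterm of some tagged output.
#'
#' @inheritParams output_tag
#' @return Logical scalar.
#' @export
is_mopi <- function(c, spec) {
  tag <- output_tag(c, spec)
  if (length(tag) == 0L) return(FALSE)
  for (e in expansions(c)) {
    if (all(tag %in% output_tag(e, spec))) return(FALSE)
  }
  any(vapply(tag, function(j) any(covers(c, spec$on[[j]])), TRUE))
}

new_tagged_implicant <- function(cube, tag) {
  structure(list(cube = cube, tag = tag), class = "tagged_implicant")
}

#' @export
print.tagged_implicant <- function(x, ...) {
  cat("<", cube_string(x$cube), " {", paste(x$tag, collapse = ","), "}>\n",
      sep = "")
  invisible(x)
}

# shared finish: explicit primality + usefulness filter, canonical order
finish_mopis <- function(mask, value, spec) {
  keep <- logical(length(mask))
  cubes <- vector("list", length(mask))
  for (i in seq_along(mask)) {
    c <- new_cube(mask[i], value[i], spec$width)
    cubes[[i]] <- c
    keep[i] <- is_mopi(c, spec)
  }
  cubes <- cubes[keep]
  key <- vapply(cubes, cube_string, "")
  cubes <- cubes[!duplicated(key)]
  key <- key[!duplicated(key)]
  cubes <- cubes[order(vapply(cubes, n_literals, 0L), key)]
  out <- lapply(cubes, function(c)
    new_tagged_implicant(c, output_tag(c, spec)))
  structure(out, class = "mopi_list",
            input_names = spec$input_names,
            output_names = spec$output_names)
}

#' Generate the complete set of multi-output prime implicants
#'
#' Two equivalent routes are provided.  `"on-dc"` is a tagged
#' Quine-McCluskey pass: every minterm lying outside the off-set of at
#' least one output is seeded with the tag of those outputs; adjacent
#' cubes merge with the intersection of their tags, and a cube is
#' checked off only by a merge that preserves its full tag.  `"on-off"`
#' grows cubes from on-minterms by literal cancellation, testing each
#' candidate directly against the off-sets; it is preferable when the
#' off-sets are small.  Both finish with an explicit primality and
#' usefulness filter and return bit-identical results.
#'
#' @param spec A [function_spec].
#' @param algorithm `"on-dc"` (default) or `"on-off"`.
#' @param max_width Hard capacity limit on the number of inputs
#'   (default 20); beyond it, consider input-tuple mining
#'   ([mine_tuples()]).
#' @return An object of class `"mopi_list"`: tagged implicants in
#'   canonical order (fewer literals first, then positional string).
#' @export
generate_mopis <- function(spec, algorithm = c("on-dc", "on-off"),
                           max_width = 20L) {
  algorithm <- match.arg(algorithm)
  k <- spec$width
  if (k > max_width)
    stop(sprintf("capacity: %d inputs exceeds the limit of %d; consider mining a smaller input tuple",
                 k, max_width))
  if (algorithm == "on-dc") mopis_on_dc(spec) else mopis_on_off(spec)
}

mopis_on_dc <- function(spec) {
  k <- spec$width
  m <- length(spec$output_names)
  nmt <- 2L^k
  tag0 <- rep.int(as.integer(2^m - 1), nmt)
  for (j in seq_len(m)) {
    hit <- spec$off[[j]] + 1L
    tag0[hit] <- bitwAnd(tag0[hit], bitwNot(bitwShiftL(1L, j - 1L)))
  }
  seeds <- which(tag0 != 0L) - 1L
  full <- as.integer(nmt - 1L)
  gen <- list(mask = rep.int(full, length(seeds)), value = seeds,
              tag = tag0[seeds + 1L])
  cand_mask <- cand_value <- integer(0)
  while (length(gen$mask)) {
    n <- length(gen$mask)
    keys <- paste(gen$mask, gen$value)
    checked <- logical(n)
    nxt <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      for (b in mask_bits(gen$mask[i], k)) {
        bit <- bitwShiftL(1L, b)
        pv <- bitwXor(gen$value[i], bit)
        j <- match(paste(gen$mask[i], pv), keys)
        if (!is.na(j) && j > i) {
          t <- bitwAnd(gen$tag[i], gen$tag[j])
          if (t != 0L) {
            keep <- bitwAnd(gen$mask[i], bitwNot(bit))
            assign(paste(keep, bitwAnd(gen$value[i], keep)),
                   c(keep, bitwAnd(gen$value[i], keep), t), envir = nxt)
            if (t == gen$tag[i]) checked[i] <- TRUE
            if (t == gen$tag[j]) checked[j] <- TRUE
          }
        }
      }
    }
    surv <- which(!checked)
    cand_mask <- c(cand_mask, gen$mask[surv])
    cand_value <- c(cand_value, gen$value[surv])
    rows <- as.list(nxt)
    if (length(rows)) {
      mat <- do.call(rbind, rows)
      gen <- list(mask = mat[, 1], value = mat[, 2], tag = mat[, 3])
    } else gen <- list(mask = integer(0), value = integer(0), tag = integer(0))
  }
  finish_mopis(cand_mask, cand_value, spec)
}

mopis_on_off <- function(spec) {
  k <- spec$width
  full <- as.integer(2L^k - 1L)
  seen <- new.env(parent = emptyenv())
  queue <- unique(unlist(spec$on, use.names = FALSE))
  qm <- rep.int(full, length(queue))
  qv <- as.integer(queue)
  for (i in seq_along(qv)) assign(paste(qm[i], qv[i]), TRUE, envir = seen)
  all_mask <- all_value <- integer(0)
  while (length(qm)) {
    all_mask <- c(all_mask, qm)
    all_value <- c(all_value, qv)
    nm <- nv <- integer(0)
    for (i in seq_along(qm)) {
      for (b in mask_bits(qm[i], k)) {
        keep <- bitwAnd(qm[i], bitwNot(bitwShiftL(1L, b)))
        val <- bitwAnd(qv[i], keep)
        key <- paste(keep, val)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          if (tag_bits(keep, val, spec$off) != 0L) {
            nm <- c(nm, keep)
            nv <- c(nv, val)
          }
        }
      }
    }
    qm <- nm
    qv <- nv
  }
  finish_mopis(all_mask, all_value, spec)
}

#' Brute-force MOPI oracle
#'
#' Enumerates all `3^k` cubes and applies the MOPI definition literally
#' via [is_mopi()].  Reference implementation for verifying
#' [generate_mopis()]; limited to 10 inputs.
#'
#' @inheritParams generate_mopis
#' @return A `"mopi_list"`, identical to the fast routes.
#' @export
brute_force_mopis <- function(spec) {
  k <- spec$width
  if (k > 10L) stop("capacity: brute force is limited to 10 inputs")
  masks <- values <- integer(0)
  for (mask in seq_len(2L^k) - 1L) {
    v <- mask
    repeat {
      masks <- c(masks, mask)
      values <- c(values, v)
      if (v == 0L) break
      v <- bitwAnd(v - 1L, mask)
    }
  }
  finish_mopis(masks, values, spec)
}

#' @export
print.mopi_list <- function(x, ...) {
  inp <- attr(x, "input_names")
  cat(sprintf("%d multi-output prime implicant(s):\n", length(x)))
  for (ti in x)
    cat(sprintf("  %-18s {%s}\n", format_cube(ti$cube, inp),
                paste(ti$tag, collapse = ", ")))
  invisible(x)
}

#' Serialize a MOPI list
#'
#' Tab-separated lines `cube-string<TAB>tag members`.
#'
#' @param mopis A `"mopi_list"`.
#' @param file Optional path or connection.
#' @return Character vector of lines, invisibly when writing.
#' @export
write_mopis <- function(mopis, file = NULL) {
  lines <- vapply(mopis, function(ti)
    paste0(cube_string(ti$cube), "\t", paste(ti$tag, collapse = ",")), "")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

mopi_signature <- function(mopis) {
  vapply(mopis, function(ti)
    paste0(cube_string(ti$cube), "|", paste(ti$tag, collapse = ",")), "")
}
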