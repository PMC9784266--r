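# Two-level gate netlists for logic diagrams: input rails, AND gates
# (one per multi-literal product), OR gates (one per output with two or
# more terms), with shared-gate fan-out when a product appears in
# several models.  Negation is a marker on the source end of a wire;
# inverters are deduplicated per rail.

#' Build a gate netlist from per-output models
#'
#' @param models Named list: per output, a list of cubes -- e.g. the
#'   `models` field of a system -- or an `"mo_system"`.
#' @param input_names Input names (one per cube position); taken from
#'   the system when `models` is an `"mo_system"`.
#' @param shared When `TRUE`, identical multi-literal products across
#'   outputs map to one AND gate fanning out to every user (joint
#'   optimization); when `FALSE`, each model instantiates its own gates
#'   (separate circuits).
#' @return An object of class `"netlist"`.
#' @export
build_netlist <- function(models, input_names = NULL, shared = TRUE) {
  if (inherits(models, "mo_system")) {
    if (is.null(input_names)) input_names <- models$input_names
    models <- models$models
  }
  if (is.null(input_names)) input_names <- attr(models, "input_names")
  if (is.null(input_names))
    stop("input_names are required to label the rails")
  outputs <- names(models)
  if (is.null(outputs) || length(outputs) == 0L)
    stop("models must be a non-empty named list")
  k <- length(input_names)

  lits <- function(c) {
    bs <- mask_bits(c$mask, k)
    data.frame(rail = input_names[k - bs],
               negated = bitwAnd(bitwShiftR(c$value, bs), 1L) == 0L)
  }

  and_gates <- list()   # id -> list(cube, key)
  wires <- list()
  or_gates <- character(0)
  gate_of <- new.env(parent = emptyenv())

  add_and <- function(c, key) {
    id <- sprintf("and%d", length(and_gates) + 1L)
    and_gates[[id]] <<- c
    for (r in seq_len(nrow(lits(c))))
      wires[[length(wires) + 1L]] <<-
        data.frame(from = paste0("in:", lits(c)$rail[r]), to = id,
                   negated = lits(c)$negated[r])
    assign(key, id, envir = gate_of)
    id
  }

  term_node <- function(c, j) {
    l <- lits(c)
    if (nrow(l) == 0L)   # universal cube: a constant-1 term
      return(list(node = "const:1", negated = FALSE))
    if (nrow(l) == 1L)
      return(list(node = paste0("in:", l$rail), negated = l$negated))
    key <- if (shared) cube_string(c) else paste0(j, "/", cube_string(c))
    id <- if (exists(key, envir = gate_of, inherits = FALSE))
      get(key, envir = gate_of) else add_and(c, key)
    list(node = id, negated = FALSE)
  }

  # instantiate gates in deterministic order: outputs in declared order,
  # terms in canonical cube order
  for (j in outputs) {
    terms <- sort_cubes(models[[j]])
    if (length(terms) == 0L) next
    sink <- paste0("out:", j)
    if (length(terms) >= 2L) {
      orid <- paste0("or:", j)
      or_gates <- c(or_gates, j)
      for (c in terms) {
        tn <- term_node(c, j)
        wires[[length(wires) + 1L]] <-
          data.frame(from = tn$node, to = orid, negated = tn$negated)
      }
      wires[[length(wires) + 1L]] <-
        data.frame(from = orid, to = sink, negated = FALSE)
    } else {
      tn <- term_node(terms[[1]], j)
      wires[[length(wires) + 1L]] <-
        data.frame(from = tn$node, to = sink, negated = tn$negated)
    }
  }
  wires <- if (length(wires)) do.call(rbind, wires)
           else data.frame(from = character(0), to = character(0),
                           negated = logical(0))
  used <- sub("^in:", "", wires$from[startsWith(wires$from, "in:")])
  rails <- input_names[input_names %in% used]
  neg_rails <- unique(sub("^in:", "",
    wires$from[startsWith(wires$from, "in:") & wires$negated]))
  structure(list(width = k, input_names = input_names, rails = rails,
                 outputs = outputs, and_gates = and_gates,
                 or_gates = or_gates, wires = wires,
                 inv_rails = rails[rails %in% neg_rails],
                 models = models, shared = shared),
            class = "netlist")
}

#' Gate counts of a netlist
#'
#' @param n A [build_netlist()] result.
#' @return Named integer vector `c(and =, or =, inv =)`; inverters are
#'   counted once per rail with at least one negated use.
#' @export
count_gates <- function(n) {
  c(and = length(n$and_gates), or = length(n$or_gates),
    inv = length(n$inv_rails))
}

#' Evaluate a netlist at a minterm
#'
#' Propagates 0/1 values from the rails through the wires; used to
#' check that the circuit realizes exactly the models it was built
#' from.
#'
#' @param n A netlist.
#' @param m Minterm index over the full declared input order.
#' @return Named integer vector of output values.
#' @export
eval_netlist <- function(n, m) {
  k <- n$width
  railv <- bitwAnd(bitwShiftR(as.integer(m), (k - 1):0), 1L)
  names(railv) <- n$input_names
  node_val <- function(node) {
    if (node == "const:1") return(1L)
    if (startsWith(node, "in:")) return(railv[[sub("^in:", "", node)]])
    inw <- n$wires[n$wires$to == node, , drop = FALSE]
    vals <- mapply(function(f, neg) {
      v <- node_val(f)
      if (neg) 1L - v else v
    }, inw$from, inw$negated)
    if (startsWith(node, "and")) as.integer(all(vals == 1L))
    else as.integer(any(vals == 1L))   # or gates and output sinks
  }
  out <- vapply(n$outputs, function(j) {
    sink <- paste0("out:", j)
    inw <- n$wires[n$wires$to == sink, , drop = FALSE]
    if (nrow(inw) == 0L) return(0L)
    v <- mapply(function(f, neg) {
      x <- node_val(f)
      if (neg) 1L - x else x
    }, inw$from, inw$negated)
    as.integer(any(v == 1L))
  }, 0L)
  names(out) <- n$outputs
  out
}

#' Emit a netlist as a Graphviz DOT digraph
#'
#' Rails are sources, AND/OR gates labelled nodes, outputs sinks;
#' negation is drawn as a dot on the source end of the wire
#' (`arrowtail=odot`).  Output is deterministic: two builds of the same
#' system give byte-identical text.
#'
#' @param n A netlist.
#' @return A single string of DOT source.
#' @export
netlist_to_dot <- function(n) {
  esc <- function(x) gsub("\"", "\\\"", x)
  lines <- c("digraph logigram {", "  rankdir=LR;",
             "  node [fontname=\"Helvetica\"];")
  for (r in n$rails)
    lines <- c(lines, sprintf("  \"in:%s\" [shape=plaintext, label=\"%s\"];",
                              esc(r), esc(r)))
  for (id in names(n$and_gates))
    lines <- c(lines, sprintf("  \"%s\" [shape=box, label=\"AND\"];", id))
  for (j in n$or_gates)
    lines <- c(lines, sprintf("  \"or:%s\" [shape=ellipse, label=\"OR\"];",
                              esc(j)))
  for (j in n$outputs)
    lines <- c(lines, sprintf("  \"out:%s\" [shape=plaintext, label=\"%s\"];",
                              esc(j), esc(j)))
  if (nrow(n$wires) && any(n$wires$from == "const:1"))
    lines <- c(lines, "  \"const:1\" [shape=plaintext, label=\"1\"];")
  if (nrow(n$wires)) {
    for (i in seq_len(nrow(n$wires))) {
      w <- n$wires[i, ]
      attr <- if (w$negated) " [dir=both, arrowtail=odot]" else ""
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", esc(w$from),
                                esc(w$to), attr))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Emit a netlist as a simple SVG drawing
#'
#' A schematic layered layout (rails, AND column, OR column, outputs)
#' with simplified distinctive gate shapes; negation is a filled dot at
#' the source end of the wire.
#'
#' @param n A netlist.
#' @param file Optional path to write to.
#' @return SVG text, invisibly when writing.
#' @export
netlist_to_svg <- function(n, file = NULL) {
  ys <- function(ids) stats::setNames(40 * seq_along(ids), ids)
  ry <- ys(paste0("in:", n$rails))
  ay <- ys(names(n$and_gates))
  oy <- ys(paste0("or:", n$or_gates))
  sy <- ys(paste0("out:", n$outputs))
  xy <- function(node) {
    if (node == "const:1") c(60, 20)
    else if (node %in% names(ry)) c(60, ry[[node]])
    else if (node %in% names(ay)) c(200, ay[[node]])
    else if (node %in% names(oy)) c(340, oy[[node]])
    else c(460, sy[[node]])
  }
  h <- 40 * (1 + max(length(ry), length(ay), length(oy), length(sy), 1))
  out <- c(sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"540\" height=\"%d\">", h))
  for (r in n$rails) {
    p <- xy(paste0("in:", r))
    out <- c(out, sprintf("<text x=\"%d\" y=\"%d\" text-anchor=\"end\">%s</text>",
                          p[1] - 8, p[2] + 4, r))
  }
  for (id in names(ay))
    out <- c(out, sprintf("<rect x=\"%d\" y=\"%d\" width=\"48\" height=\"24\" fill=\"none\" stroke=\"black\"/><text x=\"%d\" y=\"%d\" font-size=\"10\">AND</text>",
                          200, ay[[id]] - 12, 206, ay[[id]] + 4))
  for (j in n$or_gates) {
    p <- xy(paste0("or:", j))
    out <- c(out, sprintf("<ellipse cx=\"%d\" cy=\"%d\" rx=\"26\" ry=\"13\" fill=\"none\" stroke=\"black\"/><text x=\"%d\" y=\"%d\" font-size=\"10\">OR</text>",
                          p[1] + 24, p[2], p[1] + 14, p[2] + 4))
  }
  for (j in n$outputs) {
    p <- xy(paste0("out:", j))
    out <- c(out, sprintf("<text x=\"%d\" y=\"%d\">%s</text>", p[1], p[2] + 4, j))
  }
  if (nrow(n$wires)) {
    for (i in seq_len(nrow(n$wires))) {
      w <- n$wires[i, ]
      a <- xy(w$from)
      b <- xy(if (startsWith(w$to, "and") || startsWith(w$to, "or:") ||
                  startsWith(w$to, "out:")) w$to else w$to)
      out <- c(out, sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\"/>",
                            a[1], a[2], b[1], b[2]))
      if (w$negated)
        out <- c(out, sprintf("<circle cx=\"%d\" cy=\"%d\" r=\"3\" fill=\"black\"/>",
                              a[1] + 6, a[2]))
    }
  }
  txt <- paste(c(out, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.netlist <- function(x, ...) {
  g <- count_gates(x)
  cat(sprintf("Netlist: %d rail(s), %d AND, %d OR, %d inverter(s), %d output(s)%s\n",
              length(x$rails), g["and"], g["or"], g["inv"],
              length(x$outputs), if (x$shared) " (shared gates)" else ""))
  invisible(x)
}
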