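# Berkeley PLA interchange for multi-output covers (.type fr dialect:
# output 1 = on, 0 = off, - = don't care).

#' Read a function specification from a Berkeley PLA file
#'
#' Supports `.i`, `.o`, `.ilb`, `.ob`, `.p`, `.type fr` (the default)
#' and `.e`.  Cube lines have an input part over `{0,1,-}` and an
#' output part over `{0,1,-}`; input dashes are expanded to minterms.
#' A minterm asserted both on and off for the same output is a
#' contradiction error.
#'
#' @param file Path, connection, or literal PLA text.
#' @return A [function_spec].
#' @export
read_pla <- function(file) {
  if (is.character(file) && length(file) == 1L && grepl("\n", file))
    file <- textConnection(file)
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  if (any(grepl("~", lines, fixed = TRUE)))
    stop("'~' lines are not supported in PLA input")
  lines <- lines[!grepl("^#", lines)]
  ni <- no <- NA_integer_
  ilb <- ob <- NULL
  cubes <- character(0)
  for (ln in lines) {
    if (startsWith(ln, ".")) {
      f <- strsplit(ln, "\\s+")[[1]]
      switch(f[1],
        ".i" = ni <- as.integer(f[2]),
        ".o" = no <- as.integer(f[2]),
        ".ilb" = ilb <- f[-1],
        ".ob" = ob <- f[-1],
        ".p" = NULL,
        ".e" = NULL,
        ".end" = NULL,
        ".type" = if (f[2] != "fr")
          stop(sprintf("unsupported PLA type '%s' (only fr)", f[2])),
        stop(sprintf("unknown PLA directive '%s'", f[1])))
    } else cubes <- c(cubes, ln)
  }
  if (is.na(ni) || is.na(no)) stop("PLA file must declare .i and .o")
  if (is.null(ilb)) ilb <- paste0("x", seq_len(ni))
  if (is.null(ob)) ob <- paste0("f", seq_len(no))
  if (length(ilb) != ni || length(ob) != no)
    stop(".ilb/.ob name counts disagree with .i/.o")
  on <- off <- rep(list(integer(0)), no)
  for (ln in cubes) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) == 1L && nchar(f) == ni + no)
      f <- c(substr(f, 1L, ni), substr(f, ni + 1L, ni + no))
    if (length(f) != 2L || nchar(f[1]) != ni || nchar(f[2]) != no)
      stop(sprintf("PLA cube line '%s' disagrees with .i %d / .o %d",
                   ln, ni, no))
    inc <- cube(f[1])
    och <- strsplit(f[2], "")[[1]]
    if (!all(och %in% c("0", "1", "-")))
      stop(sprintf("invalid output part in PLA line '%s'", ln))
    ms <- covered_minterms(inc)
    for (j in seq_len(no)) {
      if (och[j] == "1") on[[j]] <- c(on[[j]], ms)
      else if (och[j] == "0") off[[j]] <- c(off[[j]], ms)
    }
  }
  for (j in seq_len(no)) {
    both <- intersect(on[[j]], off[[j]])
    if (length(both))
      stop(sprintf("contradiction: minterm %d asserted both on and off for output '%s'",
                   both[1], ob[j]))
  }
  new_function_spec(ni, on, off, ilb, ob)
}

#' Write a function specification as a canonical minterm-level PLA file
#'
#' Emits one line per minterm in the union of the on- and off-sets, in
#' ascending order, with `.type fr` semantics; [read_pla()] restores
#' the identical on/off/dc sets.
#'
#' @param spec A [function_spec].
#' @param file Path or connection; omit to return the text invisibly
#'   without writing.
#' @return The PLA text, invisibly.
#' @export
write_pla <- function(spec, file = NULL) {
  ms <- sort(unique(unlist(c(spec$on, spec$off))))
  body <- vapply(ms, function(m) {
    ochr <- vapply(spec$output_names, function(j) {
      if (m %in% spec$on[[j]]) "1" else if (m %in% spec$off[[j]]) "0" else "-"
    }, "")
    paste0(cube_string(cube_from_minterm(m, spec$width)), " ",
           paste(ochr, collapse = ""))
  }, "")
  txt <- c(paste(".i", spec$width),
           paste(".o", length(spec$output_names)),
           paste(".ilb", paste(spec$input_names, collapse = " ")),
           paste(".ob", paste(spec$output_names, collapse = " ")),
           paste(".type fr"),
           paste(".p", length(body)),
           body, ".e")
  if (!is.null(file)) writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}
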