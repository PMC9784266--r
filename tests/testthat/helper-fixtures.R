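# Shared fixtures and independent oracles for the test suite.

injury_cases <- function() {
  read_cases_csv(system.file("extdata", "injury_rates.csv", package = "mopir"),
                 c("gnp", "mys", "apac", "unem", "roca"), c("mvta", "ssii"))
}

patient_cases <- function() {
  read_cases_csv(system.file("extdata", "patient_groups.csv", package = "mopir"),
                 c("g", "i", "f", "m"), c("a", "e"))
}

# two-output three-input toy system: f1 = sum m(1,3,7), f2 = sum m(2,6,7)
toy_spec <- function() {
  spec_from_minterms(3, list(f1 = c(1, 3, 7), f2 = c(2, 6, 7)),
                     input_names = c("x", "y", "z"))
}

# three-output four-input system with heavy output overlap
overlap_spec <- function() {
  spec_from_minterms(4, list(f1 = c(2, 3, 5, 7, 8, 9, 10, 11, 13, 15),
                             f2 = c(2, 3, 5, 6, 7, 10, 11, 14, 15),
                             f3 = c(6, 7, 8, 9, 13, 14, 15)),
                     input_names = c("a", "b", "c", "d"))
}

mopi_sig <- function(mopis) {
  vapply(mopis, function(ti)
    paste0(mopir:::cube_string(ti$cube), "|", paste(ti$tag, collapse = ",")), "")
}

model_strings <- function(model) sort(vapply(model, mopir:::cube_string, ""))

system_sig <- function(system) {
  paste(vapply(system$output_names, function(j)
    paste(model_strings(system$models[[j]]), collapse = "+"), ""),
    collapse = ";")
}

# random incompletely specified multi-output function; every output is
# guaranteed a non-empty on-set
random_spec <- function(k, m, p_on = 0.3, p_off = 0.4) {
  nm <- 2^k
  on <- off <- vector("list", m)
  for (j in seq_len(m)) {
    repeat {
      r <- stats::runif(nm)
      on[[j]] <- which(r < p_on) - 1L
      if (length(on[[j]])) break
    }
    off[[j]] <- which(r >= p_on & r < p_on + p_off) - 1L
  }
  names(on) <- names(off) <- paste0("f", seq_len(m))
  dc <- lapply(seq_len(m), function(j)
    setdiff(0:(nm - 1L), c(on[[j]], off[[j]])))
  names(dc) <- names(on)
  spec_from_minterms(k, on, dc = dc)
}

# independent oracle: all inclusion-minimal covers of a chart's columns
# by exhaustive subset enumeration (rows <= 15)
exhaustive_min_covers <- function(marks) {
  R <- nrow(marks)
  stopifnot(R <= 15L)
  if (ncol(marks) == 0L) return(list(integer(0)))
  colmask <- vapply(seq_len(ncol(marks)), function(cc)
    sum(2L^(which(marks[, cc]) - 1L)), 0)
  colmask <- unique(as.integer(colmask))
  nsub <- 2L^R
  covering <- vapply(0:(nsub - 1L), function(s)
    all(bitwAnd(s, colmask) != 0L), TRUE)
  mins <- list()
  for (s in which(covering) - 1L) {
    bits <- which(bitwAnd(s, 2L^(0:(R - 1L))) != 0L)
    if (!any(vapply(bits, function(b)
      covering[bitwXor(s, 2L^(b - 1L)) + 1L], TRUE)))
      mins[[length(mins) + 1L]] <- bits
  }
  mins
}

cover_key <- function(covers) {
  sort(vapply(covers, function(s) paste(sort(s), collapse = ","), ""))
}
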