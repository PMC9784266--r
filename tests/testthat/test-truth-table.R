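test_that("aggregating the country data reproduces all seven (n, Inc) rows", {
  tt <- aggregate_cases(injury_cases())
  expect_equal(tt$minterm, c(3L, 5L, 7L, 23L, 24L, 30L, 31L))
  expect_equal(tt$n, c(1L, 1L, 1L, 1L, 5L, 1L, 2L))
  expect_equal(unname(tt$inc[, "mvta"]), c(1, 1, 1, 1, 0, 0, 1))
  expect_equal(unname(tt$inc[, "ssii"]), c(0, 0, 0, 0, 0.6, 1, 1))
  # n * Inc is integral
  expect_true(all(abs(tt$n * tt$inc - round(tt$n * tt$inc)) < 1e-12))
})

test_that("aggregation is invariant under case-row permutation", {
  inj <- injury_cases()
  set.seed(5)
  perm <- sample(mopir:::n_cases(inj))
  shuf <- case_table(inj$inputs[perm, ], inj$outputs[perm, ],
                     inj$case_ids[perm])
  expect_equal(aggregate_cases(shuf)$inc, aggregate_cases(inj)$inc)
  expect_equal(aggregate_cases(shuf)$minterm, aggregate_cases(inj)$minterm)
})

test_that("patient groups give eleven singleton rows with crisp scores", {
  tt <- aggregate_cases(patient_cases())
  expect_length(tt$minterm, 11)
  expect_true(all(tt$n == 1L))
  expect_true(all(tt$inc %in% c(0, 1)))
})

test_that("threshold assignment follows the single-cut rule", {
  tt <- aggregate_cases(injury_cases())
  a1 <- assign_outputs(tt, inc_threshold = 0.6)
  r24 <- which(a1$minterm == 24L)
  expect_equal(unname(a1$value[r24, "ssii"]), 1L)
  expect_equal(unname(a1$value[r24, "mvta"]), 0L)
  a2 <- assign_outputs(tt, inc_threshold = 1.0)
  expect_equal(unname(a2$value[r24, "ssii"]), 0L)
  expect_error(assign_outputs(tt, inc_threshold = 0), "inc_threshold")
  expect_error(assign_outputs(tt, inc_threshold = 1.2), "inc_threshold")
  expect_error(assign_outputs(tt, n_threshold = 0), "n_threshold")
})

test_that("raising the inclusion threshold never flips a row from 0 to 1", {
  set.seed(19)
  for (rep in 1:10) {
    tt <- aggregate_cases(simulate_cases(n_cases = 25, k = 3, m = 2,
                                         noise = 0.3))
    lo <- assign_outputs(tt, inc_threshold = 0.4)$value
    hi <- assign_outputs(tt, inc_threshold = 0.8)$value
    expect_true(all(hi <= lo))
  }
})

test_that("frequency threshold drops rows into the dc-set", {
  tt <- assign_outputs(aggregate_cases(injury_cases()), 0.6, n_threshold = 2)
  spec <- function_spec(tt)
  # only minterms 24 (n=5) and 31 (n=2) survive
  expect_setequal(c(spec$on$mvta, spec$off$mvta), c(24, 31))
  expect_setequal(c(spec$on$ssii, spec$off$ssii), c(24, 31))
})

test_that("on/off/dc sets from the country truth table match the chart columns", {
  spec <- function_spec(assign_outputs(aggregate_cases(injury_cases()), 0.6))
  expect_equal(spec$on$mvta, c(3L, 5L, 7L, 23L, 31L))
  expect_equal(spec$off$mvta, c(24L, 30L))
  expect_length(mopir:::dc_set(spec, "mvta"), 25)
  expect_equal(spec$on$ssii, c(24L, 30L, 31L))
  expect_equal(spec$off$ssii, c(3L, 5L, 7L, 23L))
  # unobserved configurations are dc
  expect_true(0L %in% mopir:::dc_set(spec, "mvta"))
})

test_that("patient data at full inclusion give the expected partition", {
  spec <- function_spec(assign_outputs(aggregate_cases(patient_cases()), 1.0))
  expect_setequal(spec$on$a, c(0, 3, 6, 10, 11, 14, 15))
  expect_setequal(spec$off$a, c(1, 4, 5, 9))
  expect_setequal(mopir:::dc_set(spec, "a"), c(2, 7, 8, 12, 13))
  expect_equal(spec$off$e, 4L)
})

test_that("on/off/dc partition the minterm space after every construction", {
  set.seed(23)
  for (rep in 1:10) {
    spec <- random_spec(sample(2:5, 1), sample(1:3, 1))
    for (j in spec$output_names) {
      expect_length(intersect(spec$on[[j]], spec$off[[j]]), 0)
      expect_setequal(c(spec$on[[j]], spec$off[[j]], mopir:::dc_set(spec, j)),
                      0:(2^spec$width - 1))
    }
  }
})

test_that("minterm specification computes complements and checks input", {
  sp <- toy_spec()
  expect_equal(sp$off$f1, c(0L, 2L, 4L, 5L, 6L))
  expect_error(spec_from_minterms(3, list(f = c(1, 9))), "range")
  expect_error(spec_from_minterms(3, list(f = 1), dc = list(f = 1)), "overlap")
  expect_warning(spec_from_minterms(1, list(f = integer(0))), "empty on-set")
  # constant-1 function has an empty off-set
  sp1 <- spec_from_minterms(1, list(f = c(0, 1)))
  expect_length(sp1$off$f, 0)
})

test_that("PLA files round-trip the on/off/dc sets exactly", {
  for (spec in list(toy_spec(), overlap_spec())) {
    tmp <- tempfile(fileext = ".pla")
    write_pla(spec, tmp)
    back <- read_pla(tmp)
    expect_equal(back$on, spec$on)
    expect_equal(back$off, spec$off)
    expect_equal(back$input_names, spec$input_names)
    unlink(tmp)
  }
})

test_that("PLA reader enforces the fr dialect and flags contradictions", {
  txt <- ".i 3\n.o 2\n001 10\n111 11\n.e\n"
  sp <- read_pla(txt)
  expect_true(1 %in% sp$on$f1)
  expect_true(7 %in% sp$on$f1 && 7 %in% sp$on$f2)
  expect_true(1 %in% sp$off$f2)
  expect_error(read_pla(".i 3\n.o 1\n001 1\n001 0\n.e\n"),
               "contradiction.*minterm 1")
  expect_error(read_pla(".i 3\n.o 1\n0011 1\n.e\n"), "disagrees")
  expect_error(read_pla(".i 3\n.o 1\n.type ff\n001 1\n.e\n"), "unsupported")
  expect_error(read_pla(".i 3\n.o 1\n~comment\n001 1\n.e\n"), "~")
  # input dashes expand to minterms
  sp2 <- read_pla(".i 3\n.o 1\n0-1 1\n.e\n")
  expect_setequal(sp2$on$f1, c(1, 3))
})
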