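test_that("the toy chart has the expected shape and marks", {
  sp <- toy_spec()
  chart <- build_chart(generate_mopis(sp), sp)
  expect_equal(dim(chart$marks), c(5L, 6L))
  expect_equal(chart$col_output, c("f1", "f1", "f1", "f2", "f2", "f2"))
  expect_equal(chart$col_minterm, c(1L, 3L, 7L, 2L, 6L, 7L))
  xyz <- which(vapply(chart$mopis, function(ti)
    mopir:::cube_string(ti$cube) == "111", TRUE))
  expect_equal(which(chart$marks[xyz, ]), c(3L, 6L))  # both minterm-7 columns
  expect_true(all(colSums(chart$marks) >= 1))
  expect_true(all(rowSums(chart$marks) >= 1))
})

test_that("the country chart is 11 x 8 with mys·roca marking both 31-columns", {
  spec <- function_spec(assign_outputs(aggregate_cases(injury_cases()), 0.6))
  chart <- build_chart(generate_mopis(spec), spec)
  expect_equal(dim(chart$marks), c(11L, 8L))
  mr <- which(vapply(chart$mopis, function(ti)
    format_cube(ti$cube, spec$input_names) == "mys·roca", TRUE))
  expect_equal(chart$col_minterm[which(chart$marks[mr, ])], c(31L, 31L))
})

test_that("essential rows are the unique marks of some column", {
  spec <- function_spec(assign_outputs(aggregate_cases(injury_cases()), 0.6))
  one_out <- function(j) {
    spec_from_minterms(spec$width, stats::setNames(list(spec$on[[j]]), j),
                       dc = stats::setNames(list(mopir:::dc_set(spec, j)), j),
                       input_names = spec$input_names)
  }
  sm <- one_out("mvta")
  chm <- build_chart(generate_mopis(sm), sm)
  ess <- essential_rows(chm)
  expect_equal(format_cube(chm$mopis[[ess]]$cube, sm$input_names), "roca")
  ss <- one_out("ssii")
  chs <- build_chart(generate_mopis(ss), ss)
  expect_equal(format_cube(chs$mopis[[essential_rows(chs)]]$cube,
                           ss$input_names), "mys")
  # chart where every column has two marks has no essential rows
  joint <- build_chart(generate_mopis(spec), spec)
  expect_length(essential_rows(joint), 0)
})

test_that("the toy system enumerates exactly its two irredundant systems", {
  sol <- mopir_solve(toy_spec())
  expect_length(sol$systems, 2)
  sigs <- vapply(sol$systems, system_sig, "")
  expect_setequal(sigs, c("0-1+111;-10+111", "-11+0-1;-10+11-"))
  s1 <- sol$systems[[which(sigs == "0-1+111;-10+111")]]
  expect_equal(format_model(s1$models$f1, "f1", c("x", "y", "z")),
               "x'z + xyz <=> f1")
  expect_equal(format_model(s1$models$f2, "f2", c("x", "y", "z")),
               "yz' + xyz <=> f2")
})

test_that("the country data give the four known systems", {
  sol <- mopir_solve(injury_cases(), inc_threshold = 0.6)
  expect_length(sol$systems, 4)
  sel <- lapply(sol$systems, function(s)
    vapply(s$implicants, function(ti)
      format_cube(ti$cube, sol$spec$input_names), ""))
  has_sel <- function(...) any(vapply(sel, setequal, TRUE, y = c(...)))
  expect_true(has_sel("mys", "roca"))
  expect_true(has_sel("roca", "mys·roca", "roca'"))
  expect_true(has_sel("mys'", "mys·roca", "mys"))
  expect_true(has_sel("mys'", "mys·roca", "roca'"))
})

test_that("shared MOPIs are written into every tagged output they serve", {
  sol <- mopir_solve(injury_cases(), inc_threshold = 0.6)
  inp <- sol$spec$input_names
  # the system {roca, mys·roca, roca'} writes mys·roca into both models,
  # even though roca absorbs it inside mvta's sum
  sel <- vapply(sol$systems, function(s)
    setequal(vapply(s$implicants, function(ti) format_cube(ti$cube, inp), ""),
             c("roca", "mys·roca", "roca'")), TRUE)
  s2 <- sol$systems[[which(sel)]]
  expect_equal(format_model(s2$models$mvta, "mvta", inp),
               "roca + mys·roca <=> mvta")
  expect_equal(format_model(s2$models$ssii, "ssii", inp),
               "roca' + mys·roca <=> ssii")
})

test_that("patient data yield one system with the data-implied polarity", {
  sol <- mopir_solve(patient_cases(), inc_threshold = 1.0)
  expect_length(sol$systems, 1)
  s <- sol$systems[[1]]
  inp <- sol$spec$input_names
  expect_length(s$models$a, 2)   # diabetes: two disjuncts
  expect_length(s$models$e, 3)   # depression: three disjuncts
  astr <- vapply(s$models$a, format_cube, "", names = inp)
  estr <- vapply(s$models$e, format_cube, "", names = inp)
  # the shared two-literal conjunction is i'm' as the data imply
  expect_true("i'm'" %in% astr)
  expect_true("i'm'" %in% estr)
  expect_true("f" %in% astr)
  expect_true(all(c("f", "m") %in% estr))
})

test_that("the overlapping three-output system yields five systems sharing up to 3 MOPIs", {
  sol <- mopir_solve(overlap_spec())
  expect_length(sol$systems, 5)
  shared <- vapply(sol$systems, function(s)
    length(intersect(model_strings(s$models$f1), model_strings(s$models$f2))), 0L)
  expect_equal(max(shared), 3L)
  mx <- sol$systems[[which.max(shared)]]
  # the shared complex causes are drawn from a'bd, b'c, bcd, cd
  expect_true(all(intersect(model_strings(mx$models$f1),
                            model_strings(mx$models$f2)) %in%
                    c("01-1", "-01-", "-111", "--11")))
})

test_that("Petrick expansion equals exhaustive minimal-cover search", {
  set.seed(61)
  reps <- 0
  while (reps < 12) {
    sp <- random_spec(sample(2:4, 1), sample(1:2, 1))
    chart <- build_chart(generate_mopis(sp), sp)
    if (nrow(chart$marks) > 15) next
    reps <- reps + 1
    got <- mopir:::petrick_covers(chart$marks)
    expect_identical(cover_key(got), cover_key(exhaustive_min_covers(chart$marks)))
  }
  # one-column chart: one singleton cover per marked row
  marks <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  expect_identical(cover_key(mopir:::petrick_covers(marks)),
                   cover_key(list(1L, 2L)))
})

test_that("every returned system is F-equivalent and irredundant", {
  set.seed(67)
  for (rep in 1:10) {
    sp <- random_spec(sample(2:5, 1), sample(1:3, 1))
    sol <- mopir_solve(sp)
    chart <- sol$chart
    expect_gt(length(sol$systems), 0)
    for (s in sol$systems) {
      # F-equivalence of the written models
      expect_true(is_f_equivalent(s$models, sp))
      # cover-level irredundancy: dropping any row uncovers a column
      for (r in s$selected) {
        rest <- setdiff(s$selected, r)
        expect_true(any(colSums(chart$marks[rest, , drop = FALSE]) == 0))
      }
      # literal-level irredundancy: no expansion of a selected MOPI can
      # replace it in its written models and preserve F-equivalence
      expect_true(mopir:::literal_irredundant(s$implicants, sp))
      # no system's selection is a subset of another's
      for (s2 in sol$systems) {
        if (!identical(s$selected, s2$selected))
          expect_false(all(s$selected %in% s2$selected))
      }
    }
  }
})

test_that("renaming inputs and permuting outputs preserves the solution", {
  sp <- overlap_spec()
  base <- sort(vapply(mopir_solve(sp)$systems, system_sig, ""))
  perm <- spec_from_minterms(4, list(f3 = sp$on$f3, f1 = sp$on$f1,
                                     f2 = sp$on$f2),
                             input_names = c("p", "q", "r", "s"))
  got <- mopir_solve(perm)$systems
  resig <- sort(vapply(got, function(s)
    paste(vapply(c("f1", "f2", "f3"), function(j)
      paste(model_strings(s$models[[j]]), collapse = "+"), ""),
      collapse = ";"), ""))
  expect_identical(resig, base)
})

test_that("fit statistics count cases as defined", {
  inj <- injury_cases()
  inp <- inj$input_names
  mys <- list(cube_from_literals("mys", inp))
  expect_equal(model_fit(mys, "ssii", inj),
               c(consistency = 6 / 8, coverage = 1.0))
  roca <- list(cube_from_literals("roca", inp))
  expect_equal(model_fit(roca, "mvta", inj),
               c(consistency = 1.0, coverage = 1.0))
  empty <- model_fit(list(), "mvta", inj)
  expect_true(is.na(empty["consistency"]))
  expect_equal(unname(empty["coverage"]), 0)
})

test_that("solutions export to structured JSON and text reports", {
  sol <- mopir_solve(toy_spec())
  js <- jsonlite::fromJSON(export_solution(sol), simplifyVector = FALSE)
  expect_equal(js$n_systems, 2)
  expect_length(js$systems, 2)
  grid <- format_chart(sol$chart)
  expect_length(grid, 6)  # header + 5 rows
  expect_match(grid[1], "f1:1")
})
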