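test_that("packaged reference table matches the frozen transcription", {
  ref <- load_reference()
  frozen <- frozen_reference_stats()
  expect_equal(nrow(ref), 20)
  key <- order(ref$type, ref$label)
  fkey <- order(frozen$type, frozen$label)
  for (cl in names(frozen)) {
    expect_equal(ref[[cl]][key], frozen[[cl]][fkey], info = cl)
  }
  expect_equal(hmwgs:::hmw_window(ref), c(25, 42))
})

test_that("packaged reference satisfies the RSD and window invariants", {
  ref <- load_reference()
  rsd <- 100 * ref$sd_rt / ref$mean_rt
  expect_true(all(abs(rsd - ref$rsd_pct) <= 0.005))
  expect_lte(max(rsd), 0.38)
  expect_true(all(ref$mean_rt >= 25 & ref$mean_rt <= 42))
  expect_true(all(ref$n_analyses >= ref$n_cultivars))
})

test_that("mean RTs follow the elution order with the By8/By16 exceptions", {
  ref <- load_reference()
  m <- function(ty) ref$mean_rt[ref$type == ty]
  expect_lt(max(m("Dy")), min(m("By")))
  expect_lt(max(m("By")), min(m("Bx")))
  expect_lt(max(m("Bx")), min(m("Ax")))
  expect_lt(max(m("Dy")), min(m("Dx")))
  late_by <- ref$subunit %in% c("By8", "By16")
  expect_lt(max(ref$mean_rt[ref$type == "By" & !late_by]), min(m("Dx")))
  expect_gt(min(ref$mean_rt[late_by]), max(m("Dx")))
})

test_that("load_reference rejects malformed input", {
  write_ref <- function(df) {
    f <- tempfile(fileext = ".tsv")
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    f
  }
  good <- utils::read.delim(system.file("extdata", "reference_rt.tsv",
                                        package = "hmwgs"),
                            colClasses = c(type = "character",
                                           label = "character"))
  expect_error(load_reference(write_ref(good[, -3])),
               class = "hmwgs_format_error")
  expect_error(load_reference(write_ref(good[c(1, 1, 2:20), ])),
               class = "hmwgs_format_error")
  bad <- good; bad$mean_rt[3] <- "abc"
  expect_error(load_reference(write_ref(bad)), class = "hmwgs_format_error")
  bad <- good; bad$rsd_pct[good$label == "13" & good$type == "Bx"] <- 9.9
  expect_error(load_reference(write_ref(bad)),
               class = "hmwgs_invariant_error")
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(load_reference(empty), class = "hmwgs_format_error")
})

test_that("summarize_rts reproduces hand-computed statistics", {
  s <- summarize_rts(c(10, 10, 10))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 0)
  expect_equal(s$rsd_pct, 0)

  s <- summarize_rts(c(26.4, 26.5, 26.6))
  expect_equal(s$mean, 26.5)
  expect_equal(s$sd, 0.1)
  expect_equal(s$rsd_pct, 100 * 0.1 / 26.5)
  expect_equal(c(s$q1, s$median, s$q3), c(26.45, 26.5, 26.55))
  expect_equal(c(s$whisker_lo, s$whisker_hi), c(26.4, 26.6))
  expect_equal(c(s$ci_lo, s$ci_hi), 26.5 + c(-1, 1) * 1.96 * 0.1 / sqrt(3))
  expect_true(s$whisker_lo <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$whisker_hi)

  expect_error(summarize_rts(26.5), class = "hmwgs_insufficient_data")
})

test_that("summarize_rts RSD of simulated replicates lands in the bracket", {
  set.seed(42)
  x <- rnorm(18, 26.528, 0.098)
  s <- summarize_rts(x)
  expect_gt(s$rsd_pct, 0.2)
  expect_lt(s$rsd_pct, 0.6)
})

test_that("rt_window gives mean +/- k*sd", {
  ref <- load_reference()
  expect_equal(rt_window(ref, "Bx13", 3), c(37.195, 37.375))
  expect_equal(rt_window(ref, "Dy12", 3), c(26.234, 26.822))
  w <- rt_window(ref, "Bx7", 1e-9)
  expect_lt(diff(w), 1e-6)
  expect_error(rt_window(ref, "Bx99"), class = "hmwgs_lookup_error")
  expect_error(rt_window(ref, "Bx7", k = 0))
})

test_that("derived ambiguity groups match the canonical set and the oracle", {
  ref <- load_reference()
  derived <- lapply(derive_ambiguity_groups(ref, k = 3), `[[`, "members")
  canon <- lapply(canonical_ambiguity_groups(), `[[`, "members")
  expect_setequal(vapply(derived, paste, "", collapse = "|"),
                  vapply(canon, paste, "", collapse = "|"))
  expect_setequal(vapply(derived, paste, "", collapse = "|"),
                  vapply(oracle_ambiguity_groups(ref, 3), paste, "",
                         collapse = "|"))
})

test_that("derived groups agree with the oracle across window multipliers", {
  ref <- load_reference()
  for (k in c(0.5, 1, 2, 3, 5, 8)) {
    derived <- lapply(derive_ambiguity_groups(ref, k = k), `[[`, "members")
    expect_setequal(vapply(derived, paste, "", collapse = "|"),
                    vapply(oracle_ambiguity_groups(ref, k), paste, "",
                           collapse = "|"))
  }
  single <- ref[ref$subunit == "Bx13", , drop = FALSE]
  expect_length(derive_ambiguity_groups(single, 3), 0)
})

test_that("canonical ambiguity groups partition their members", {
  groups <- canonical_ambiguity_groups()
  expect_length(groups, 5)
  members <- unlist(lapply(groups, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(unique(vapply(groups, `[[`, "", "resolution")),
                  c("gel", "intensity", "linkage"))
  # subunits documented as readily distinguished by RT stay out of groups
  for (s in c("Bx6", "Bx13", "Bx17", "Bx20x", "By8", "By16",
              "Dx2.2", "Dx5")) {
    expect_false(s %in% members, info = s)
  }
})
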