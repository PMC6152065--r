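make_peaks <- function(apexes, areas = 37.6) {
  data.frame(apex_rt = apexes, height = rep_len(100, length(apexes)),
             area = rep_len(areas, length(apexes)),
             left_rt = apexes - 0.5, right_rt = apexes + 0.5)
}

test_that("match_peak returns all subunits whose window holds the apex", {
  ref <- load_reference()
  expect_equal(match_peak(37.285, ref), "Bx13")
  expect_setequal(match_peak(33.942, ref),
                  c("By8*", "By9", "By18", "By20y"))
  expect_length(match_peak(24.0, ref), 0)
  expect_setequal(match_peak(38.842, ref), c("Bx7", "Bx7OE"))
  expect_setequal(match_peak(35.195, ref), c("Dx2", "Dx4"))
})

test_that("assignment reproduces the fraction-collection elution orders", {
  ref <- load_reference()
  pairing <- load_pairing()
  m <- function(s) ref$mean_rt[ref$subunit == s]

  # Chinese Spring: Dy12, Dx2, By8, Bx7 in elution order
  a <- assign_peaks(make_peaks(c(m("Dy12"), m("Dx2"), m("By8"), m("Bx7"))),
                    ref, pairing)$assignment
  expect_equal(a$type, c("Dy", "Dx", "By", "Bx"))
  expect_gt(a$apex_rt[a$type == "By"], a$apex_rt[a$type == "Dx"])

  # Opata/Sukang: Dy12, Dx2, By16, Bx13, Ax2*
  a <- assign_peaks(make_peaks(c(m("Dy12"), m("Dx2"), m("By16"),
                                 m("Bx13"), m("Ax2*"))),
                    ref, pairing)$assignment
  expect_equal(a$type, c("Dy", "Dx", "By", "Bx", "Ax"))

  # Cappelle-Desprez: Bx7 alone, Ax null
  a <- assign_peaks(make_peaks(c(m("Dy12"), m("Dx2"), m("Bx7"))),
                    ref, pairing)$assignment
  expect_equal(a$type, c("Dy", "Dx", "Bx"))
})

test_that("assignment agrees with the exhaustive enumeration oracle", {
  ref <- load_reference()
  pairing <- load_pairing()
  fx <- load_fixtures()
  for (p in c(fx$standards, fx$korean)) {
    subs <- hmwgs:::profile_subunits(p)
    apexes <- sort(ref$mean_rt[match(subs, ref$subunit)])
    got <- assign_peaks(make_peaks(apexes), ref, pairing)$assignment
    want <- oracle_assign(apexes, ref, pairing)
    expect_equal(got$type, want$types, info = p$name)
    expect_equal(sum(got$z_best^2), want$score, tolerance = 1e-9,
                 info = p$name)
  }
})

test_that("assignment agrees with the oracle on jittered panels", {
  ref <- load_reference()
  pairing <- load_pairing()
  fx <- load_fixtures()
  set.seed(19)
  for (r in 1:25) {
    p <- fx$standards[[sample(16, 1)]]
    subs <- hmwgs:::profile_subunits(p)
    i <- match(subs, ref$subunit)
    apexes <- sort(ref$mean_rt[i] + rnorm(length(i), 0, ref$sd_rt[i]))
    got <- tryCatch(assign_peaks(make_peaks(apexes), ref, pairing),
                    hmwgs_unassignable = function(e) NULL)
    want <- oracle_assign(apexes, ref, pairing)
    if (is.null(got)) {
      expect_null(want)
    } else {
      expect_equal(got$assignment$type, want$types)
      expect_equal(sum(got$assignment$z_best^2), want$score,
                   tolerance = 1e-9)
    }
  }
})

test_that("inconsistent peak sets are unassignable; no-window peaks are set aside", {
  ref <- load_reference()
  pairing <- load_pairing()
  # two peaks that can only both be Dy
  expect_error(assign_peaks(make_peaks(c(26.528, 26.736, 35.195)),
                            ref, pairing),
               class = "hmwgs_unassignable")
  # no peak matches anything
  expect_error(assign_peaks(make_peaks(c(24, 30)), ref, pairing),
               class = "hmwgs_unassignable")
  # a stray peak between windows is reported as unmatched, not fatal
  a <- assign_peaks(make_peaks(c(26.528, 30.0, 35.195, 36.060, 38.842)),
                    ref, pairing)
  expect_equal(a$unmatched$apex_rt, 30.0)
  expect_equal(nrow(a$assignment), 4)
})

test_that("overexpression is called from the area ratio", {
  others <- make_peaks(c(26.7, 34.8, 33.9), areas = 37.6)
  expect_equal(call_overexpression(make_peaks(38.8, areas = 75.2), others),
               "7OE")
  expect_equal(call_overexpression(make_peaks(38.8, areas = 37.6), others),
               "7")
  # inclusive boundary
  expect_equal(call_overexpression(make_peaks(38.8, areas = 1.5 * 37.6),
                                   others), "7OE")
  expect_error(call_overexpression(make_peaks(38.8), make_peaks(numeric(0))),
               class = "hmwgs_config_error")
})

test_that("the Glu-D1 linkage maps Dx to Dy", {
  expect_equal(infer_dy("5"), "10")
  expect_equal(infer_dy("2.2"), "12")
  expect_equal(infer_dy("4"), "12")
  expect_equal(infer_dy("Dx2"), "12")
  expect_error(infer_dy("7"), class = "hmwgs_lookup_error")
})

test_that("call_composition reproduces the documented example calls", {
  ref <- load_reference()
  pairing <- load_pairing()
  mob <- load_mobility()
  fx <- load_fixtures()

  cs <- fixture_by_name(fx, "Chinese Spring")
  res <- call_composition(simulate_chromatogram(cs, ref, sim_config()),
                          ref, pairing, mob,
                          lane = simulate_gel(cs, mob))
  expect_true(is.na(res$profile$ax))
  expect_equal(c(res$profile$bx, res$profile$by), c("7", "8"))
  expect_equal(c(res$profile$dx, res$profile$dy), c("2", "12"))
  expect_length(res$flags, 0)
  expect_equal(unname(res$evidence[c("Ax", "By", "Dy")]),
               c("absent", "rt", "linkage"))
  expect_equal(unname(res$evidence[["Dx"]]), "gel")

  # Sinmichal1's Dx peak sits at the Dx2 mean, not Dx2.2
  sm1 <- fixture_by_name(fx, "Sinmichal1")
  res <- call_composition(simulate_chromatogram(sm1, ref, sim_config()),
                          ref, pairing, mob,
                          lane = simulate_gel(sm1, mob))
  expect_equal(res$profile$dx, "2")
  dx_apex <- res$per_peak$apex_rt[res$per_peak$type == "Dx"]
  expect_equal(round(dx_apex, 3), 35.195)

  # Joongmo2008's By needs the gel; without it the locus is flagged
  jm <- fixture_by_name(fx, "Joongmo2008")
  tr <- simulate_chromatogram(jm, ref, sim_config())
  no_lane <- call_composition(tr, ref, pairing, mob, lane = NULL)
  expect_true(any(grepl("Glu-B1/By ambiguous", no_lane$flags)))
  with_lane <- call_composition(tr, ref, pairing, mob,
                                lane = simulate_gel(jm, mob))
  expect_equal(with_lane$profile$by, "18")
  expect_equal(unname(with_lane$evidence[["By"]]), "gel")
  expect_length(with_lane$flags, 0)
})

test_that("overexpressed and ordinary Bx7 are separated by intensity", {
  ref <- load_reference()
  pairing <- load_pairing()
  mob <- load_mobility()
  fx <- load_fixtures()
  for (name in c("Glenlea", "Cheyenne")) {
    p <- fixture_by_name(fx, name)
    res <- call_composition(simulate_chromatogram(p, ref, sim_config()),
                            ref, pairing, mob,
                            lane = simulate_gel(p, mob))
    expect_equal(res$profile$bx, p$bx, info = name)
  }
  gl <- fixture_by_name(fx, "Glenlea")
  res <- call_composition(simulate_chromatogram(gl, ref, sim_config()),
                          ref, pairing, mob, lane = simulate_gel(gl, mob))
  expect_equal(unname(res$evidence[["Bx"]]), "intensity")
})

test_that("no detected HMW peak is silently dropped", {
  ref <- load_reference()
  fx <- load_fixtures()
  p <- fixture_by_name(fx, "Chinese Spring")
  res <- call_composition(simulate_chromatogram(p, ref, sim_config()),
                          lane = NULL)
  expect_equal(nrow(res$per_peak), 4)
  expect_false(anyNA(res$per_peak$type))
  expect_false(anyDuplicated(stats::na.omit(res$per_peak$type)) > 0)
})

test_that("compare_to_prior reports slot-level differences", {
  fx <- load_fixtures()
  jonong <- fixture_by_name(fx, "Jonong")
  d <- compare_to_prior(jonong, fx$priors[["Jonong"]])
  expect_equal(nrow(d), 1)
  expect_equal(d$locus, "Glu-B1/By")
  expect_equal(c(d$prior, d$called), c("8", "9"))

  expect_equal(nrow(compare_to_prior(jonong, jonong)), 0)
  expect_error(compare_to_prior(jonong, fx$priors[["Sinmichal"]]),
               class = "hmwgs_config_error")
})
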