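# The combined identification procedure: retention-time matching against
# the reference windows, exhaustive constraint-based assignment of peaks to
# locus types, then candidate reduction by pairing, gel mobility, peak
# intensity and Dx-Dy linkage, in that order.

#' Match a peak apex against the reference windows
#'
#' @param apex_rt apex retention time in minutes (may also be a one-row
#'   peak data.frame).
#' @param table reference table.
#' @param k window multiplier (default 3).
#' @return character vector of all subunits whose `k`-window contains the
#'   apex (possibly empty).
#' @examples
#' match_peak(37.285, load_reference())
#' @export
match_peak <- function(apex_rt, table, k = 3) {
  if (is.data.frame(apex_rt)) apex_rt <- apex_rt$apex_rt
  stopifnot(length(apex_rt) == 1, k > 0)
  table$subunit[abs(apex_rt - table$mean_rt) <= k * table$sd_rt]
}

peak_z <- function(apex_rt, table, subunits) {
  i <- match(subunits, table$subunit)
  (apex_rt - table$mean_rt[i]) / table$sd_rt[i]
}

#' Assign detected peaks to locus types
#'
#' Exhaustively enumerates injective assignments of peaks to the five locus
#' types, subject to: every matched peak is assigned a type drawn from its
#' candidate windows; at most one peak per type; Dx and Dy are both
#' assigned; a By peak requires a Bx peak; some (Bx, By) candidate pair is
#' allowed by the pairing table (with By absent, some Bx candidate must be
#' allowed alone). Among consistent assignments the one minimizing the sum
#' of squared z-scores `((apex - mean_rt) / sd_rt)`, taking each peak's
#' best candidate of its assigned type, is returned; exact ties keep the
#' first assignment in enumeration order (peaks by ascending apex, types
#' in Ax, Bx, By, Dx, Dy order).
#'
#' Peaks matching no reference window are set aside as `unmatched` rather
#' than failing the search.
#'
#' @param peaks peak data.frame from [detect_peaks()] (at most 8 rows).
#' @param table reference table.
#' @param pairing pairing table.
#' @param k window multiplier.
#' @return list with `assignment` (data.frame: `peak`, `apex_rt`, `type`,
#'   `candidates` comma-joined same-type candidate labels, `z_best`) and
#'   `unmatched` (data.frame of unassigned peaks).
#' @export
assign_peaks <- function(peaks, table, pairing, k = 3) {
  if (nrow(peaks) > 8) {
    hmwgs_stop("more than 8 peaks in the HMW window", "hmwgs_unassignable")
  }
  cand <- lapply(peaks$apex_rt, match_peak, table = table, k = k)
  matched <- which(lengths(cand) > 0)
  unmatched <- peaks[setdiff(seq_len(nrow(peaks)), matched), , drop = FALSE]
  if (length(matched) > length(HMW_TYPES)) {
    hmwgs_stop(sprintf(
      "%d peaks match reference windows but only %d locus types exist",
      length(matched), length(HMW_TYPES)), "hmwgs_unassignable")
  }
  type_opts <- lapply(cand[matched], function(s) {
    intersect(HMW_TYPES, unique(subunit_type(s)))
  })

  best <- NULL
  best_score <- Inf
  n <- length(matched)
  assign_rec <- function(i, used, types) {
    if (i > n) {
      if (!all(c("Dx", "Dy") %in% types)) return()
      if ("By" %in% types && !("Bx" %in% types)) return()
      # pairing feasibility over candidate labels
      if ("Bx" %in% types) {
        bxc <- subunit_label(grep("^Bx", cand[[matched[match("Bx", types)]]],
                                  value = TRUE))
        byc <- if ("By" %in% types) {
          subunit_label(grep("^By", cand[[matched[match("By", types)]]],
                             value = TRUE))
        } else NA_character_
        ok <- any(vapply(bxc, function(b) {
          any(vapply(byc, function(y) pair_allowed(pairing, b, y),
                     logical(1)))
        }, logical(1)))
        if (!ok) return()
      }
      score <- 0
      for (j in seq_len(n)) {
        same <- cand[[matched[j]]][subunit_type(cand[[matched[j]]]) ==
                                     types[j]]
        score <- score +
          min(peak_z(peaks$apex_rt[matched[j]], table, same)^2)
      }
      if (score < best_score - 1e-12) {
        best_score <<- score
        best <<- types
      }
      return()
    }
    for (ty in type_opts[[i]]) {
      if (ty %in% used) next
      assign_rec(i + 1L, c(used, ty), c(types, ty))
    }
  }
  assign_rec(1L, character(0), character(0))
  if (is.null(best) && n > 0) {
    hmwgs_stop(paste0(
      "no consistent peak-to-locus assignment for apexes ",
      paste(sprintf("%.3f", peaks$apex_rt[matched]), collapse = ", ")),
      "hmwgs_unassignable")
  }
  if (n == 0) {
    hmwgs_stop("no peak matches any reference window (Glu-D1 unaccounted)",
               "hmwgs_unassignable")
  }
  rows <- lapply(seq_len(n), function(j) {
    same <- cand[[matched[j]]][subunit_type(cand[[matched[j]]]) == best[j]]
    z <- peak_z(peaks$apex_rt[matched[j]], table, same)
    data.frame(peak = matched[j], apex_rt = peaks$apex_rt[matched[j]],
               type = best[j],
               candidates = paste(subunit_label(same), collapse = ","),
               z_best = z[which.min(abs(z))])
  })
  list(assignment = do.call(rbind, rows), unmatched = unmatched)
}

#' Call 1Bx7 overexpression from relative peak intensity
#'
#' The overexpressed Bx7 variant co-elutes and co-migrates with ordinary
#' Bx7 but yields roughly twice the peak. The call compares the Bx peak
#' area to the median area of the other HMW peaks: at or above `threshold`
#' the subunit is called 7OE.
#'
#' @param bx_peak one-row peak data.frame (the Bx-assigned peak).
#' @param other_peaks data.frame of the remaining HMW peaks (>= 1 row).
#' @param threshold area ratio cutoff, inclusive (default 1.5; the
#'   simulator's overexpression factor is 2, so 1.5 separates cleanly).
#' @return `"7OE"` or `"7"`.
#' @export
call_overexpression <- function(bx_peak, other_peaks, threshold = 1.5) {
  if (nrow(other_peaks) < 1) {
    hmwgs_stop("overexpression call needs at least one non-Bx peak",
               "hmwgs_config_error")
  }
  ratio <- bx_peak$area / stats::median(other_peaks$area)
  if (ratio >= threshold) "7OE" else "7"
}

#' Infer the Dy allele from the Dx allele
#'
#' The y-type allele at Glu-D1 is strictly linked to the x-type: Dy10
#' occurs only with Dx5, and Dy12 with Dx2, Dx2.2 or Dx4.
#'
#' @param dx Dx allele label (`"2"`, `"2.2"`, `"4"` or `"5"`), optionally
#'   prefixed (`"Dx5"`).
#' @return the linked Dy label, `"10"` or `"12"`.
#' @examples
#' infer_dy("5")
#' infer_dy("2.2")
#' @export
infer_dy <- function(dx) {
  dx <- sub("^Dx", "", dx)
  if (identical(dx, "5")) return("10")
  if (dx %in% c("2", "2.2", "4")) return("12")
  hmwgs_stop(paste0("not a Dx allele: ", dx), "hmwgs_lookup_error")
}

#' Call the HMW-GS composition of a chromatogram
#'
#' Runs the full pipeline: peak detection in the HMW window, constraint
#' based peak-to-locus assignment, then per-locus candidate reduction in a
#' fixed evidence order — pairing constraints, gel mobility (when a lane is
#' supplied), relative intensity (Bx7 vs Bx7OE), and Dx-Dy linkage. Glu-A1
#' is called null when no peak matches any Ax window at the detection
#' threshold. A candidate set that stays ambiguous is flagged and the
#' lowest-|z| candidate reported provisionally; detected HMW peaks are
#' never silently dropped (unmatched ones are flagged).
#'
#' @param trace a [chromatogram()].
#' @param table reference table ([load_reference()]).
#' @param pairing pairing table ([load_pairing()]).
#' @param mobility mobility table ([load_mobility()]).
#' @param lane optional [gel_lane()] with SDS-PAGE evidence.
#' @param k retention-time window multiplier (default 3).
#' @param oe_threshold overexpression area-ratio cutoff (default 1.5).
#' @param min_height,smooth_width passed to [detect_peaks()].
#' @param evidence_steps evidence mechanisms to apply, in order; subset of
#'   `c("pairing", "gel", "intensity", "linkage")`. Mainly for ablation.
#' @return list of class `hmwgs_call`: `profile` (the called
#'   [cultivar_profile()], unvalidated), `per_peak` (peak table with
#'   assigned type, final call, candidate set and z-score), `evidence`
#'   (named map locus type -> `"rt"`, `"pairing"`, `"gel"`, `"intensity"`,
#'   `"linkage"` or `"absent"`), `flags` (character vector of warnings).
#' @examples
#' fx <- load_fixtures()
#' ref <- load_reference()
#' mob <- load_mobility()
#' cs <- fx$standards[[4]]  # Chinese Spring
#' res <- call_composition(simulate_chromatogram(cs, ref),
#'                         lane = simulate_gel(cs, mob))
#' res$profile
#' @export
call_composition <- function(trace, table = load_reference(),
                             pairing = load_pairing(),
                             mobility = load_mobility(), lane = NULL,
                             k = 3, oe_threshold = 1.5, min_height = NULL,
                             smooth_width = 0.05,
                             evidence_steps = c("pairing", "gel",
                                                "intensity", "linkage")) {
  peaks <- detect_peaks(trace, window = hmw_window(table),
                        min_height = min_height,
                        smooth_width = smooth_width)
  asg <- assign_peaks(peaks, table, pairing, k = k)
  a <- asg$assignment
  flags <- character(0)
  for (rt in asg$unmatched$apex_rt) {
    flags <- c(flags, sprintf("no-match peak at %.3f min", rt))
  }

  # candidate labels per assigned type
  cand <- stats::setNames(
    lapply(a$candidates, function(s) strsplit(s, ",", fixed = TRUE)[[1]]),
    a$type)
  evid <- stats::setNames(rep("absent", length(HMW_TYPES)), HMW_TYPES)
  evid[names(cand)] <- "rt"

  reduce <- function(type, keep, mechanism) {
    if (!type %in% names(cand)) return()
    old <- cand[[type]]
    new <- intersect(old, keep)
    if (length(new) >= 1 && length(new) < length(old)) {
      cand[[type]] <<- new
      if (length(new) == 1) evid[[type]] <<- mechanism
    }
  }

  for (step in evidence_steps) {
    if (step == "pairing" && "Bx" %in% names(cand)) {
      # the x-type is narrowed to candidates with an allowed partner; the
      # y-type is deliberately never narrowed from the x-type, so that
      # gel-resolvable By ambiguity stays visible without a lane
      byc <- if ("By" %in% names(cand)) cand[["By"]] else NA_character_
      ok <- vapply(cand[["Bx"]], function(b) {
        any(vapply(byc, function(y) pair_allowed(pairing, b, y),
                   logical(1)))
      }, logical(1))
      if (any(ok)) reduce("Bx", cand[["Bx"]][ok], "pairing")
    } else if (step == "gel" && !is.null(lane)) {
      for (ty in names(cand)) {
        if (length(cand[[ty]]) < 2) next
        res <- resolve_with_gel(subunit_id(ty, cand[[ty]]), lane, mobility)
        if (isTRUE(attr(res, "no_evidence"))) {
          flags <- c(flags, sprintf("no gel evidence for %s candidates %s",
                                    ty, paste(cand[[ty]], collapse = ",")))
        } else {
          reduce(ty, subunit_label(res), "gel")
        }
      }
    } else if (step == "intensity" && "Bx" %in% names(cand)) {
      if (all(c("7", "7OE") %in% cand[["Bx"]])) {
        i <- a$peak[a$type == "Bx"]
        label <- call_overexpression(peaks[i, , drop = FALSE],
                                     peaks[setdiff(seq_len(nrow(peaks)), i),
                                           , drop = FALSE],
                                     threshold = oe_threshold)
        reduce("Bx", label, "intensity")
      }
    } else if (step == "linkage" && "Dy" %in% names(cand)) {
      if (length(cand[["Dy"]]) > 1 && "Dx" %in% names(cand)) {
        dys <- unique(vapply(cand[["Dx"]], infer_dy, character(1)))
        if (length(dys) == 1) reduce("Dy", dys, "linkage")
      }
    }
  }

  # provisional pick (lowest |z|) for anything still ambiguous
  final <- stats::setNames(rep(NA_character_, length(HMW_TYPES)), HMW_TYPES)
  for (ty in names(cand)) {
    labs <- cand[[ty]]
    if (length(labs) > 1) {
      flags <- c(flags, sprintf("Glu-%s1/%s ambiguous: %s",
                                substr(ty, 1, 1), ty,
                                paste(labs, collapse = ",")))
      apex <- a$apex_rt[a$type == ty]
      z <- peak_z(apex, table, subunit_id(ty, labs))
      labs <- labs[which.min(abs(z))]
    }
    final[[ty]] <- labs
  }
  if (!is.na(final[["Bx"]]) &&
      !pair_allowed(pairing, final[["Bx"]], final[["By"]])) {
    flags <- c(flags, sprintf("called Glu-B1 pair (%s, %s) not in pairing table",
                              final[["Bx"]],
                              ifelse(is.na(final[["By"]]), "absent",
                                     final[["By"]])))
  }
  if (is.na(final[["Bx"]]) && "By" %in% names(cand)) {
    flags <- c(flags, "By peak without a Bx peak")
  }

  per_peak <- data.frame(
    apex_rt = peaks$apex_rt, height = peaks$height, area = peaks$area,
    type = NA_character_, call = NA_character_,
    candidates = NA_character_, z = NA_real_)
  per_peak$type[a$peak] <- a$type
  per_peak$candidates[a$peak] <- a$candidates
  per_peak$call[a$peak] <- final[a$type]
  per_peak$z[a$peak] <- vapply(seq_len(nrow(a)), function(j) {
    peak_z(a$apex_rt[j], table, subunit_id(a$type[j], final[[a$type[j]]]))
  }, numeric(1))

  profile <- cultivar_profile(trace$sample_id, final[["Ax"]],
                              final[["Bx"]], final[["By"]], final[["Dx"]],
                              final[["Dy"]], check = FALSE)
  structure(list(profile = profile, per_peak = per_peak,
                 evidence = evid, flags = flags),
            class = "hmwgs_call")
}

#' @export
print.hmwgs_call <- function(x, ...) {
  print(x$profile)
  ev <- paste(names(x$evidence), x$evidence, sep = ":", collapse = " ")
  cat("evidence ", ev, "\n", sep = "")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Compare a called composition to a prior assignment
#'
#' @param result an `hmwgs_call` or [cultivar_profile()].
#' @param prior the previously published [cultivar_profile()]; must carry
#'   the same cultivar name.
#' @return data.frame with one row per differing allele slot: `locus`
#'   (e.g. `"Glu-B1/By"`), `prior`, `called`. Zero rows when identical.
#' @examples
#' fx <- load_fixtures()
#' jonong <- fx$korean[[which(vapply(fx$korean, `[[`, "", "name") == "Jonong")]]
#' compare_to_prior(jonong, fx$priors[["Jonong"]])
#' @export
compare_to_prior <- function(result, prior) {
  called <- if (inherits(result, "hmwgs_call")) result$profile else result
  if (!identical(called$name, prior$name)) {
    hmwgs_stop(sprintf("cultivar name mismatch: '%s' vs '%s'",
                       called$name, prior$name), "hmwgs_config_error")
  }
  slots <- c(ax = "Glu-A1/Ax", bx = "Glu-B1/Bx", by = "Glu-B1/By",
             dx = "Glu-D1/Dx", dy = "Glu-D1/Dy")
  rows <- lapply(names(slots), function(sl) {
    p <- prior[[sl]]
    q <- called[[sl]]
    if (identical(is.na(p), is.na(q)) && (is.na(p) || p == q)) return(NULL)
    data.frame(locus = slots[[sl]],
               prior = ifelse(is.na(p), "absent", p),
               called = ifelse(is.na(q), "absent", q))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(locus = character(0), prior = character(0),
                      called = character(0))
  }
  rownames(out) <- NULL
  out
}
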