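# Independent oracles and frozen expected values. Everything here is
# deliberately re-implemented from scratch (no calls into the package's
# own algorithms) so the tests check the implementation against an
# independent route.

# Hand-frozen transcription of the packaged per-subunit RT statistics,
# retyped independently of inst/extdata so the loader is checked against a
# second transcription.
frozen_reference_stats <- function() {
  txt <- "
type label mean_rt sd_rt n_cultivars n_analyses rsd_pct
Ax 1 40.307 0.078 2 9 0.195
Ax 2* 40.354 0.077 7 18 0.190
Bx 6 38.516 0.059 3 8 0.154
Bx 7 38.842 0.077 9 25 0.199
Bx 7OE 38.770 0.078 1 6 0.201
Bx 13 37.285 0.030 1 3 0.081
Bx 17 39.075 0.053 1 5 0.138
Bx 20x 39.603 0.061 1 4 0.155
By 8 36.060 0.083 4 12 0.231
By 8* 33.948 0.098 4 10 0.290
By 9 34.091 0.085 2 5 0.252
By 16 35.604 0.039 1 3 0.109
By 18 34.022 0.108 1 5 0.319
By 20y 33.894 0.043 1 3 0.127
Dx 2 35.195 0.114 8 24 0.325
Dx 2.2 34.428 0.082 1 3 0.238
Dx 4 35.269 0.094 1 3 0.267
Dx 5 34.792 0.119 6 17 0.343
Dy 10 26.736 0.101 6 10 0.377
Dy 12 26.528 0.098 10 18 0.370
"
  read.table(text = txt, header = TRUE, colClasses = c(
    type = "character", label = "character"))
}

# Brute-force ambiguity grouping: pairwise mean-in-window edges, then
# components by breadth-first search over the edge list.
oracle_ambiguity_groups <- function(table, k = 3) {
  out <- list()
  for (ty in unique(table$type)) {
    s <- table[table$type == ty, , drop = FALSE]
    n <- nrow(s)
    edges <- list()
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          d <- abs(s$mean_rt[i] - s$mean_rt[j])
          if (d <= k * s$sd_rt[i] || d <= k * s$sd_rt[j]) {
            edges[[length(edges) + 1L]] <- c(i, j)
          }
        }
      }
    }
    seen <- logical(n)
    for (start in seq_len(n)) {
      if (seen[start]) next
      queue <- start
      comp <- integer(0)
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        comp <- c(comp, v)
        for (e in edges) {
          if (v %in% e) queue <- c(queue, setdiff(e, v))
        }
      }
      if (length(comp) >= 2) {
        out[[length(out) + 1L]] <- sort(paste0(ty, s$label[comp]))
      }
    }
  }
  out
}

# Exhaustive assignment oracle: enumerates every injective map of peaks to
# locus types via expand.grid, with no pruning, and returns the best
# (minimum sum of squared z-scores) feasible type vector and its score.
oracle_assign <- function(apexes, table, pairing, k = 3) {
  types <- c("Ax", "Bx", "By", "Dx", "Dy")
  cand <- lapply(apexes, function(a) {
    table$subunit[abs(a - table$mean_rt) <= k * table$sd_rt]
  })
  keep <- which(lengths(cand) > 0)
  n <- length(keep)
  if (n == 0 || n > 5) return(NULL)
  grids <- expand.grid(rep(list(types), n), stringsAsFactors = FALSE)
  best <- NULL
  best_score <- Inf
  for (r in seq_len(nrow(grids))) {
    tv <- as.character(grids[r, ])
    if (anyDuplicated(tv)) next
    ok <- TRUE
    for (j in seq_len(n)) {
      if (!tv[j] %in% substr(cand[[keep[j]]], 1, 2)) ok <- FALSE
    }
    if (!ok) next
    if (!all(c("Dx", "Dy") %in% tv)) next
    if ("By" %in% tv && !"Bx" %in% tv) next
    if ("Bx" %in% tv) {
      bxs <- substring(grep("^Bx", cand[[keep[which(tv == "Bx")]]],
                            value = TRUE), 3)
      bys <- if ("By" %in% tv) {
        substring(grep("^By", cand[[keep[which(tv == "By")]]],
                       value = TRUE), 3)
      } else NA_character_
      feas <- FALSE
      for (b in bxs) {
        for (y in bys) {
          if (is.na(y)) {
            if (any(pairing$bx == b & is.na(pairing$by))) feas <- TRUE
          } else if (any(pairing$bx == b & !is.na(pairing$by) &
                         pairing$by == y)) feas <- TRUE
        }
      }
      if (!feas) next
    }
    score <- 0
    for (j in seq_len(n)) {
      same <- cand[[keep[j]]][substr(cand[[keep[j]]], 1, 2) == tv[j]]
      i <- match(same, table$subunit)
      score <- score + min(((apexes[keep[j]] - table$mean_rt[i]) /
                              table$sd_rt[i])^2)
    }
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- tv
    }
  }
  if (is.null(best)) NULL else list(types = best, score = best_score,
                                    peaks = keep)
}

fixture_by_name <- function(fx, name) {
  all <- c(fx$standards, fx$korean)
  all[[which(vapply(all, `[[`, "", "name") == name)[1]]]
}

# ids of subunits whose ambiguity group is resolved by gel
gel_group_subunits <- function() {
  gs <- Filter(function(g) identical(g$resolution, "gel"),
               canonical_ambiguity_groups())
  unlist(lapply(gs, `[[`, "members"))
}

ambiguity_flag_types <- function(result) {
  fl <- grep(" ambiguous: ", result$flags, value = TRUE)
  sub("^Glu-.1/([A-D][xy]) ambiguous.*$", "\\1", fl)
}
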