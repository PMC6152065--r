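# Statistical retention-time reference: per-subunit mean/SD over replicate
# RP-HPLC runs of standard cultivars, plus the resolvability structure the
# window rule induces.

#' Load a retention-time reference table
#'
#' Reads the per-subunit retention-time statistics used for peak matching.
#' Each row holds the mean and standard deviation (minutes) of a subunit's
#' retention time over replicate runs, the number of cultivars and analyses
#' behind it, and the printed relative standard deviation (percent). The
#' packaged default covers the 20 HMW-GS alleles observed in the standard
#' cultivar panel; Ax-null carries no peak and has no row.
#'
#' @param path tab-separated file with columns `type`, `label`, `mean_rt`,
#'   `sd_rt`, `n_cultivars`, `n_analyses`, `rsd_pct`.
#' @param hmw_window numeric length-2, the retention-time interval (minutes)
#'   in which HMW-GS elute. All reference means must fall inside it.
#' @return data.frame of class `hmwgs_reference` with an added `subunit`
#'   column and attribute `hmw_window`.
#' @details Validation enforces: unique subunits; positive means and
#'   non-negative SDs; `n_analyses >= n_cultivars >= 1`; the printed RSD
#'   agrees with `100 * sd_rt / mean_rt` to within 0.005 (printed-rounding
#'   slack); all means inside `hmw_window`.
#' @examples
#' ref <- load_reference()
#' ref[ref$subunit == "Bx13", ]
#' @export
load_reference <- function(path = system.file("extdata", "reference_rt.tsv",
                                              package = "hmwgs"),
                           hmw_window = c(25, 42)) {
  tab <- tryCatch(
    utils::read.delim(path, colClasses = c(type = "character",
                                           label = "character")),
    error = function(e) hmwgs_stop(
      paste0("cannot parse reference table: ", conditionMessage(e)),
      "hmwgs_format_error"))
  need <- c("type", "label", "mean_rt", "sd_rt", "n_cultivars",
            "n_analyses", "rsd_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    hmwgs_stop(paste0("reference table missing column(s): ",
                      paste(miss, collapse = ", ")), "hmwgs_format_error")
  }
  if (nrow(tab) == 0) {
    hmwgs_stop("reference table is empty", "hmwgs_format_error")
  }
  num <- c("mean_rt", "sd_rt", "n_cultivars", "n_analyses", "rsd_pct")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    if (anyNA(v)) {
      hmwgs_stop(sprintf("non-numeric %s in reference row(s) %s", cl,
                         paste(which(is.na(v)), collapse = ", ")),
                 "hmwgs_format_error")
    }
    tab[[cl]] <- v
  }
  if (!all(tab$type %in% HMW_TYPES)) {
    hmwgs_stop("reference type must be one of Ax, Bx, By, Dx, Dy",
               "hmwgs_format_error")
  }
  tab$subunit <- subunit_id(tab$type, tab$label)
  dup <- tab$subunit[duplicated(tab$subunit)]
  if (length(dup)) {
    hmwgs_stop(paste0("duplicate subunit in reference: ",
                      paste(unique(dup), collapse = ", ")),
               "hmwgs_format_error")
  }
  bad <- which(!(tab$mean_rt > 0 & tab$sd_rt >= 0 &
                 tab$n_analyses >= tab$n_cultivars & tab$n_cultivars >= 1))
  if (length(bad)) {
    hmwgs_stop(paste0("invalid statistics in reference row(s) ",
                      paste(bad, collapse = ", ")), "hmwgs_invariant_error")
  }
  bad <- which(abs(tab$rsd_pct - 100 * tab$sd_rt / tab$mean_rt) > 0.005)
  if (length(bad)) {
    hmwgs_stop(paste0("rsd_pct inconsistent with mean/sd in row(s) ",
                      paste(bad, collapse = ", ")), "hmwgs_invariant_error")
  }
  bad <- which(tab$mean_rt < hmw_window[1] | tab$mean_rt > hmw_window[2])
  if (length(bad)) {
    hmwgs_stop(paste0("mean_rt outside HMW window in row(s) ",
                      paste(bad, collapse = ", ")), "hmwgs_invariant_error")
  }
  structure(tab, hmw_window = as.numeric(hmw_window),
            class = c("hmwgs_reference", "data.frame"))
}

hmw_window <- function(table) attr(table, "hmw_window", exact = TRUE)

#' Classification window of a reference subunit
#'
#' The window used to decide whether a peak apex is compatible with a
#' subunit: `mean_rt +/- k * sd_rt`.
#'
#' @param table a `hmwgs_reference` table.
#' @param subunit subunit id present in `table`.
#' @param k positive window half-width multiplier (default 3).
#' @return numeric length-2 interval in minutes.
#' @examples
#' rt_window(load_reference(), "Bx13")
#' @export
rt_window <- function(table, subunit, k = 3) {
  stopifnot(k > 0)
  i <- match(subunit, table$subunit)
  if (is.na(i)) {
    hmwgs_stop(paste0("subunit not in reference: ", subunit),
               "hmwgs_lookup_error")
  }
  table$mean_rt[i] + c(-1, 1) * k * table$sd_rt[i]
}

#' Summary statistics of replicate retention times
#'
#' Computes the reproducibility statistics reported per subunit: mean,
#' sample standard deviation (n-1 denominator), relative standard deviation
#' (percent), quartiles by linear interpolation, Tukey whiskers (most
#' extreme observations within 1.5 IQR of the quartiles) and a 95% normal
#' approximation confidence interval of the mean.
#'
#' @param replicates numeric vector of retention times (minutes), length >= 2.
#' @return one-row data.frame with columns `n`, `mean`, `sd`, `rsd_pct`,
#'   `q1`, `median`, `q3`, `whisker_lo`, `whisker_hi`, `ci_lo`, `ci_hi`.
#' @examples
#' summarize_rts(c(26.4, 26.5, 26.6))
#' @export
summarize_rts <- function(replicates) {
  x <- as.numeric(replicates)
  if (length(x) < 2 || anyNA(x)) {
    hmwgs_stop("need at least 2 non-missing replicate retention times",
               "hmwgs_insufficient_data")
  }
  m <- mean(x)
  s <- stats::sd(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  ci <- m + c(-1, 1) * 1.96 * s / sqrt(length(x))
  data.frame(n = length(x), mean = m, sd = s, rsd_pct = 100 * s / m,
             q1 = q[1], median = q[2], q3 = q[3],
             whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
             whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
             ci_lo = ci[1], ci_hi = ci[2])
}

#' Ambiguity groups induced by retention-time windows
#'
#' Two same-type subunits are confusable when the mean retention time of one
#' lies inside the other's `k`-window. `derive_ambiguity_groups()` returns
#' the connected components (size >= 2) of that relation within each locus
#' type. Containment of means, not interval overlap, is used: at the default
#' `k = 3` containment reproduces the documented resolvability structure,
#' whereas interval overlap would spuriously merge Bx6 with Bx7.
#'
#' @param table a `hmwgs_reference` table.
#' @param k window multiplier (default 3).
#' @return list of groups; each group is a list with `members` (character
#'   subunit ids) and `resolution` (`NA` for derived groups).
#' @seealso [canonical_ambiguity_groups()] for the curated groups with their
#'   resolution mechanisms.
#' @examples
#' derive_ambiguity_groups(load_reference())
#' @export
derive_ambiguity_groups <- function(table, k = 3) {
  out <- list()
  for (ty in unique(table$type)) {
    s <- table[table$type == ty, , drop = FALSE]
    n <- nrow(s)
    if (n < 2) next
    adj <- diag(n) > 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- abs(s$mean_rt[i] - s$mean_rt[j])
        if (d <= k * s$sd_rt[i] || d <= k * s$sd_rt[j]) adj[i, j] <- TRUE
      }
    }
    comp <- connected_components(adj)
    for (cc in unique(comp)) {
      mem <- s$subunit[comp == cc]
      if (length(mem) >= 2) {
        out[[length(out) + 1L]] <- list(members = sort(mem),
                                        resolution = NA_character_)
      }
    }
  }
  out
}

# components of an undirected adjacency matrix by label propagation
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ] | adj[, i])
      new <- min(comp[c(i, nb)])
      if (new < comp[i]) {
        comp[i] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Curated ambiguity groups and their resolution mechanisms
#'
#' The five groups of subunits that a retention time alone cannot separate,
#' together with the evidence that resolves each: gel mobility for
#' Ax1/Ax2*, Dx2/Dx4 and the By8*/By9/By18/By20y cluster; relative peak
#' intensity for Bx7/Bx7OE (the overexpressed variant gives roughly double
#' the peak); Dx-Dy linkage for Dy10/Dy12 (Dy10 co-occurs strictly with
#' Dx5, Dy12 with Dx2/Dx2.2/Dx4).
#'
#' @return list of groups, each a list with `members` and `resolution`
#'   (`"gel"`, `"intensity"` or `"linkage"`).
#' @examples
#' canonical_ambiguity_groups()
#' @export
canonical_ambiguity_groups <- function() {
  list(
    list(members = c("Ax1", "Ax2*"), resolution = "gel"),
    list(members = c("Bx7", "Bx7OE"), resolution = "intensity"),
    list(members = c("By18", "By20y", "By8*", "By9"), resolution = "gel"),
    list(members = c("Dx2", "Dx4"), resolution = "gel"),
    list(members = c("Dy10", "Dy12"), resolution = "linkage")
  )
}

# group (if any) containing a subunit
ambiguity_resolution <- function(subunits) {
  for (g in canonical_ambiguity_groups()) {
    if (all(subunits %in% g$members)) return(g$resolution)
  }
  NA_character_
}
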