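# Batch study driver: simulate every fixture cultivar, call compositions,
# compare against the fixture truth and against prior assignments.

#' Reproduce the panel study on synthetic data
#'
#' For every cultivar in `profiles`, simulates a chromatogram (and, when
#' `use_gel`, an SDS-PAGE lane), calls the composition, and tabulates exact
#' matches to the fixture profile, flags, and discrepancies against
#' `priors` where a prior exists. Deterministic under a fixed `cfg$seed`:
#' cultivar `i` is simulated with seed `cfg$seed + i`.
#'
#' @param profiles list of [cultivar_profile()]s (e.g. a panel from
#'   [load_fixtures()]).
#' @param cfg a [sim_config()]; its `seed` anchors the per-cultivar seeds.
#' @param table,pairing,mobility reference, pairing and mobility tables.
#' @param priors optional named list of prior [cultivar_profile()]s.
#' @param use_gel simulate and use gel-lane evidence (default `TRUE`).
#' @param k,oe_threshold passed to [call_composition()].
#' @return list of class `hmwgs_study`: `calls` (per-cultivar results:
#'   `name`, `call` or `error`, `exact`, `n_flags`, `discrepancies`),
#'   `summary` (counts: `n_called`, `n_exact`, `n_flagged`,
#'   `n_discrepant`), `discrepancies` (row-bound table with cultivar
#'   names), `config` (the simulation and calling parameters).
#' @examples
#' fx <- load_fixtures()
#' st <- run_study(fx$standards[1:3], sim_config(seed = 1))
#' st$summary
#' @export
run_study <- function(profiles, cfg = sim_config(),
                      table = load_reference(), pairing = load_pairing(),
                      mobility = load_mobility(), priors = NULL,
                      use_gel = TRUE, k = 3, oe_threshold = 1.5) {
  calls <- vector("list", length(profiles))
  disc_rows <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ci <- cfg
    if (!is.null(cfg$seed)) ci$seed <- cfg$seed + i
    rec <- list(name = p$name, exact = FALSE, n_flags = NA_integer_,
                discrepancies = NULL, error = NA_character_)
    res <- tryCatch({
      trace <- simulate_chromatogram(p, table, ci)
      lane <- if (use_gel) simulate_gel(p, mobility) else NULL
      call_composition(trace, table, pairing, mobility, lane = lane,
                       k = k, oe_threshold = oe_threshold)
    }, hmwgs_error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
    } else {
      rec$call <- res
      rec$exact <- profiles_equal(res$profile, p)
      rec$n_flags <- length(res$flags)
      if (!is.null(priors) && p$name %in% names(priors)) {
        d <- compare_to_prior(res, priors[[p$name]])
        if (nrow(d)) {
          rec$discrepancies <- d
          disc_rows[[length(disc_rows) + 1L]] <-
            cbind(cultivar = p$name, d)
        }
      }
    }
    calls[[i]] <- rec
  }
  ok <- !is.na(vapply(calls, function(r) r$n_flags, NA_integer_))
  discrepancies <- if (length(disc_rows)) {
    do.call(rbind, disc_rows)
  } else {
    data.frame(cultivar = character(0), locus = character(0),
               prior = character(0), called = character(0))
  }
  structure(list(
    calls = stats::setNames(calls, vapply(profiles, `[[`, "", "name")),
    summary = list(
      n_called = sum(ok),
      n_exact = sum(vapply(calls, `[[`, FALSE, "exact")),
      n_flagged = sum(vapply(calls, function(r) {
        isTRUE(r$n_flags > 0)
      }, logical(1))),
      n_discrepant = length(unique(discrepancies$cultivar))),
    discrepancies = discrepancies,
    config = c(unclass(cfg)[setdiff(names(cfg), "seed")],
               list(seed = cfg$seed, k = k, oe_threshold = oe_threshold,
                    use_gel = use_gel))),
    class = "hmwgs_study")
}

profiles_equal <- function(a, b) {
  all(vapply(c("ax", "bx", "by", "dx", "dy"), function(sl) {
    identical(is.na(a[[sl]]), is.na(b[[sl]])) &&
      (is.na(a[[sl]]) || a[[sl]] == b[[sl]])
  }, logical(1)))
}

#' @export
print.hmwgs_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<hmwgs study: %d called, %d exact, %d flagged, %d discrepant vs priors>\n",
    s$n_called, s$n_exact, s$n_flagged, s$n_discrepant))
  invisible(x)
}

#' Serialize / restore a study report
#'
#' JSON round trip for [run_study()] reports: per-cultivar profiles,
#' evidence, flags, discrepancies, summary counts and the run
#' configuration.
#'
#' @param study an `hmwgs_study`.
#' @param path output JSON path.
#' @return `write_study_report()` returns `path` invisibly;
#'   `read_study_report()` returns the parsed report (plain lists, with the
#'   same summary, discrepancy and per-cultivar content).
#' @export
write_study_report <- function(study, path) {
  rep <- list(
    version = as.character(utils::packageVersion("hmwgs")),
    config = study$config,
    summary = study$summary,
    discrepancies = study$discrepancies,
    cultivars = lapply(unname(study$calls), function(r) {
      out <- list(name = r$name, exact = r$exact, error = r$error)
      if (!is.null(r$call)) {
        out$profile <- unclass(r$call$profile)
        out$evidence <- as.list(r$call$evidence)
        out$flags <- r$call$flags
      }
      out
    }))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_study_report
#' @export
read_study_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Reproducibility summary of replicate retention times
#'
#' Builds the per-subunit reproducibility report (the box-and-whisker
#' analogue): one row of [summarize_rts()] statistics per subunit.
#' Subunits with fewer than two replicates are skipped with a warning.
#'
#' @param replicate_rts named list of numeric retention-time vectors, e.g.
#'   from [simulate_replicate_rts()].
#' @return data.frame with a `subunit` column followed by the
#'   [summarize_rts()] columns.
#' @export
summarize_reference <- function(replicate_rts) {
  rows <- lapply(names(replicate_rts), function(s) {
    x <- replicate_rts[[s]]
    if (length(x) < 2) {
      warning("skipping ", s, ": fewer than 2 replicates")
      return(NULL)
    }
    cbind(subunit = s, summarize_rts(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
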