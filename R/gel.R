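# SDS-PAGE evidence as ordinal band mobilities. Band positions are modelled
# as ranks (1 = slowest / largest apparent MW), not Rf values: gel photos
# support relative order only. The packaged order is an internally
# consistent convention shared by the simulator and the caller, and can be
# replaced via TSV.

#' Load a band-mobility table
#'
#' @param path tab-separated file with columns `type`, `label`, `rank`
#'   (1 = slowest-migrating band). Subunits sharing a rank co-migrate;
#'   with the packaged table the co-migrating sets are exactly
#'   Bx7/Bx7OE and Dy10/Dy12.
#' @return data.frame of class `hmwgs_mobility` with an added `subunit`
#'   column.
#' @export
load_mobility <- function(path = system.file("extdata", "mobility.tsv",
                                             package = "hmwgs")) {
  tab <- utils::read.delim(path, colClasses = c(type = "character",
                                                label = "character"))
  need <- c("type", "label", "rank")
  if (!all(need %in% names(tab))) {
    hmwgs_stop("mobility table needs columns type, label, rank",
               "hmwgs_format_error")
  }
  tab$rank <- suppressWarnings(as.integer(tab$rank))
  if (anyNA(tab$rank)) {
    hmwgs_stop("non-integer rank in mobility table", "hmwgs_format_error")
  }
  tab$subunit <- subunit_id(tab$type, tab$label)
  if (anyDuplicated(tab$subunit)) {
    hmwgs_stop("duplicate subunit in mobility table", "hmwgs_format_error")
  }
  structure(tab, class = c("hmwgs_mobility", "data.frame"))
}

# sets of subunits sharing a rank
comigrating_sets <- function(mobility) {
  sp <- split(mobility$subunit, mobility$rank)
  unname(lapply(Filter(function(s) length(s) >= 2, sp), sort))
}

band_rank <- function(mobility, subunit) {
  r <- mobility$rank[match(subunit, mobility$subunit)]
  if (anyNA(r)) {
    hmwgs_stop(paste0("subunit(s) missing from mobility table: ",
                      paste(subunit[is.na(r)], collapse = ", ")),
               "hmwgs_config_error")
  }
  r
}

#' Construct a gel lane
#'
#' @param sample_id sample label.
#' @param bands integer vector of observed band mobility ranks.
#' @return list of class `gel_lane` with `sample_id` and ascending `bands`.
#' @export
gel_lane <- function(sample_id, bands) {
  structure(list(sample_id = as.character(sample_id),
                 bands = sort(unique(as.integer(bands)))),
            class = "gel_lane")
}

#' Read gel lanes from TSV
#'
#' @param path tab-separated file with columns `sample_id`, `band_rank`
#'   (one row per band).
#' @return named list of [gel_lane()] objects.
#' @export
load_gel_lanes <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(sample_id = "character"))
  if (!all(c("sample_id", "band_rank") %in% names(tab))) {
    hmwgs_stop("gel lane table needs columns sample_id, band_rank",
               "hmwgs_format_error")
  }
  sp <- split(tab$band_rank, tab$sample_id)
  lanes <- lapply(names(sp), function(s) gel_lane(s, sp[[s]]))
  stats::setNames(lanes, names(sp))
}

#' Write gel lanes to TSV
#'
#' @param lanes a [gel_lane()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gel_lanes <- function(lanes, path) {
  if (inherits(lanes, "gel_lane")) lanes <- list(lanes)
  rows <- do.call(rbind, lapply(lanes, function(l) {
    data.frame(sample_id = l$sample_id, band_rank = l$bands)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Resolve retention-time-ambiguous candidates with gel evidence
#'
#' Keeps the candidates whose band rank appears in the lane. When no
#' candidate's rank is present (no usable evidence), the input is returned
#' unchanged with attribute `no_evidence = TRUE` rather than an empty set.
#' Co-migrating candidates (e.g. Dy10/Dy12) share a rank and therefore
#' remain unresolved.
#'
#' @param candidates character vector of subunit ids, all of one locus type.
#' @param lane a [gel_lane()].
#' @param mobility a mobility table from [load_mobility()].
#' @return subset of `candidates` (never empty; never enlarged).
#' @export
resolve_with_gel <- function(candidates, lane, mobility) {
  stopifnot(length(candidates) >= 1)
  if (length(unique(subunit_type(candidates))) != 1) {
    hmwgs_stop("candidates must share a locus type", "hmwgs_config_error")
  }
  ranks <- band_rank(mobility, candidates)
  keep <- ranks %in% lane$bands
  if (!any(keep)) {
    return(structure(candidates, no_evidence = TRUE))
  }
  candidates[keep]
}
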