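#' @keywords internal
"_PACKAGE"

# Subunit identifiers are plain strings "<type><label>": "Ax1", "Ax2*",
# "Bx7OE", "Dx2.2", "By20y", ... The type prefix is always two characters.

HMW_TYPES <- c("Ax", "Bx", "By", "Dx", "Dy")

#' Subunit identifier helpers
#'
#' HMW glutenin subunits are identified throughout the package by strings of
#' the form `"<type><label>"`, where type is one of `Ax`, `Bx`, `By`, `Dx`,
#' `Dy` and label is the allele name as printed in the field's nomenclature
#' (`"1"`, `"2*"`, `"7OE"`, `"2.2"`, ...). The `x`/`y` suffixes on the
#' Glu-B1 20 alleles (`"20x"`, `"20y"`) disambiguate the Bx20/By20 pair that
#' shares the printed label 20.
#'
#' @param type character vector of locus types.
#' @param label character vector of allele labels.
#' @param subunit character vector of subunit ids.
#' @return `subunit_id()` pastes type and label; `subunit_type()` and
#'   `subunit_label()` split an id back into its parts.
#' @examples
#' subunit_id("Bx", "7OE")
#' subunit_type("Dx2.2")
#' subunit_label("Ax2*")
#' @export
subunit_id <- function(type, label) {
  stopifnot(all(type %in% HMW_TYPES))
  paste0(type, label)
}

#' @rdname subunit_id
#' @export
subunit_type <- function(subunit) substr(subunit, 1L, 2L)

#' @rdname subunit_id
#' @export
subunit_label <- function(subunit) substring(subunit, 3L)

# classed conditions so callers (and the CLI) can distinguish validation
# failures from unassignable traces
hmwgs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hmwgs_error")))
}

#' Allowed Bx-By subunit pairs at Glu-B1
#'
#' The x- and y-type genes at Glu-B1 are tightly linked, so only certain
#' combinations of Bx and By alleles occur in cultivars. The packaged table
#' lists the observed pairs; `by = NA` encodes a Bx subunit occurring alone
#' (only 1Bx7 does).
#'
#' @param path path to a tab-separated file with columns `bx`, `by`; `"-"`
#'   or an empty `by` field encodes an absent By subunit. Defaults to the
#'   packaged table.
#' @return data.frame with character columns `bx` and `by` (`NA` = absent).
#' @examples
#' load_pairing()
#' @export
load_pairing <- function(path = system.file("extdata", "pairing.tsv",
                                            package = "hmwgs")) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("bx", "by") %in% names(tab))) {
    hmwgs_stop("pairing table needs columns bx, by", "hmwgs_format_error")
  }
  tab$by[tab$by %in% c("-", "")] <- NA_character_
  if (anyDuplicated(paste(tab$bx, tab$by))) {
    hmwgs_stop("duplicate pair in pairing table", "hmwgs_format_error")
  }
  tab
}

pair_allowed <- function(pairing, bx, by) {
  if (is.na(by)) {
    any(pairing$bx == bx & is.na(pairing$by))
  } else {
    any(pairing$bx == bx & !is.na(pairing$by) & pairing$by == by)
  }
}
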