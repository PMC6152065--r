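# Cultivar allele profiles and the packaged fixture panels.

#' Construct a cultivar HMW-GS profile
#'
#' A profile gives the allele at each Glu-1 locus: `ax` (`NA` = null
#' allele), the `bx`/`by` pair at Glu-B1 (`by` may be absent) and the
#' complete `dx`/`dy` pair at Glu-D1. Labels are the bare allele names
#' ("2*", "7OE", "2.2", ...).
#'
#' @param name cultivar name.
#' @param ax,bx,by,dx,dy allele labels (`NA` where absent).
#' @param check validate the genetic invariants (default `TRUE`): Glu-D1
#'   complete; Dy10 only with Dx5 and Dy12 only with Dx2/Dx2.2/Dx4; the
#'   (bx, by) pair present in `pairing`. Called compositions built from
#'   evidence use `check = FALSE` so that violations surface as flags, not
#'   errors.
#' @param pairing pairing table for the Glu-B1 check.
#' @return list of class `cultivar_profile`.
#' @examples
#' cultivar_profile("Chinese Spring", NA, "7", "8", "2", "12")
#' @export
cultivar_profile <- function(name, ax, bx, by, dx, dy, check = TRUE,
                             pairing = load_pairing()) {
  p <- structure(list(name = as.character(name),
                      ax = as.character(ax), bx = as.character(bx),
                      by = as.character(by), dx = as.character(dx),
                      dy = as.character(dy)),
                 class = "cultivar_profile")
  if (check) {
    if (is.na(p$dx) || is.na(p$dy)) {
      hmwgs_stop(paste0(name, ": Glu-D1 must be complete"),
                 "hmwgs_invariant_error")
    }
    ok_link <- (p$dy == "10" && p$dx == "5") ||
      (p$dy == "12" && p$dx %in% c("2", "2.2", "4"))
    if (!ok_link) {
      hmwgs_stop(paste0(name, ": Dx", p$dx, " + Dy", p$dy,
                        " violates the Glu-D1 linkage"),
                 "hmwgs_invariant_error")
    }
    if (is.na(p$bx) || !pair_allowed(pairing, p$bx, p$by)) {
      hmwgs_stop(paste0(name, ": Glu-B1 pair (", p$bx, ", ",
                        ifelse(is.na(p$by), "absent", p$by),
                        ") not in pairing table"),
                 "hmwgs_invariant_error")
    }
  }
  p
}

#' @export
print.cultivar_profile <- function(x, ...) {
  cat(sprintf("<%s: Glu-A1 %s | Glu-B1 %s | Glu-D1 %s + %s>\n",
              x$name, ifelse(is.na(x$ax), "N", x$ax),
              paste0(x$bx, ifelse(is.na(x$by), "", paste0(" + ", x$by))),
              x$dx, x$dy))
  invisible(x)
}

# subunit ids expressed by a profile (null/absent slots dropped)
profile_subunits <- function(profile) {
  out <- character(0)
  if (!is.na(profile$ax)) out <- c(out, subunit_id("Ax", profile$ax))
  if (!is.na(profile$bx)) out <- c(out, subunit_id("Bx", profile$bx))
  if (!is.na(profile$by)) out <- c(out, subunit_id("By", profile$by))
  c(out, subunit_id("Dx", profile$dx), subunit_id("Dy", profile$dy))
}

profiles_from_frame <- function(df, pairing) {
  lapply(seq_len(nrow(df)), function(i) {
    cultivar_profile(df$name[i], df$ax[i], df$bx[i], df$by[i],
                     df$dx[i], df$dy[i], pairing = pairing)
  })
}

standards_frame <- function() {
  read.fixture("
name|ax|bx|by|dx|dy
Brimstone|N|6|8*|2|12
Cappelle-Desprez|N|7|-|2|12
Cheyenne|2*|7|9|5|10
Chinese Spring|N|7|8|2|12
Clement|N|6|8*|2|12
Gabo|2*|17|18|2|12
Glenlea|2*|7OE|8*|5|10
Insignia|1|20x|20y|5|10
Nanbu-komugi|1|7|8|4|12
Neepwa|2*|7|9|5|10
Norin61|2*|7|8|2.2|12
Orca|N|7|-|2|12
Sukang|2*|13|16|2|12
Petrel|N|7|-|5|10
Soissons|2*|7|8|5|10
Thesee|N|6|8*|2|12
")
}

korean_frame <- function() {
  read.fixture("
name|ax|bx|by|dx|dy
Alchan|2*|7|8|5|10
Anbaek|N|7|9|2|12
Baekchal|2*|7|8*|5|10
Baekjoong|2*|13|16|2.2|12
Chungkye|N|7|8|2.2|12
Dabun|2*|7|8|2.2|12
Dahong|N|7|8|2.2|12
Dajoong|2*|13|16|2.2|12
Eunpa|N|7|9|2.2|12
Geuru|N|7|8|2.2|12
Gobun|N|7|9|2|12
Goso|2*|7|8|2.2|12
Hanbaek|2*|7|8|5|10
Hojoong|2*|7|8|2.2|12
Jeokjoong|2*|13|16|2.2|12
Jinpoom|N|7|8|2.2|12
Joa|2*|7|8|2.2|12
Joeun|N|13|16|2.2|12
Jojoong|N|13|16|2.2|12
Jokyung|1|7|8|5|10
Jonong|N|7|9|2|12
Joongmo2008|N|17|18|5|10
Joongmo2012|2*|7|8|5|10
Jopoom|N|13|16|2.2|12
Keumkang|2*|7|8|5|10
Milsung|N|7|8|2.2|12
Namhae|N|7|8|2.2|12
Ol|N|7|8|2.2|12
Olgeuru|2*|7|8|2.2|12
Saeol|N|7|8|2.2|12
Seodun|N|7|8|2.2|12
Sinmichal|2*|7|8*|2.2|12
Sinmichal1|N|7|9|2|12
Suan|2*|7|8|2.2|12
Sukang|2*|13|16|2|12
Tapdong|2*|7|8|5|10
Uri|N|7|8|2.2|12
Younbaek|2*|13|16|2.2|12
")
}

# cultivars first characterized in the re-analysis itself (no prior)
NEW_KOREAN <- c("Baekchal", "Hojoong", "Joa", "Jojoong",
                "Joongmo2008", "Joongmo2012")

read.fixture <- function(txt) {
  df <- utils::read.delim(text = txt, sep = "|",
                          colClasses = "character")
  for (cl in c("ax", "by")) df[[cl]][df[[cl]] %in% c("N", "-")] <- NA
  df
}

#' Packaged cultivar fixture panels
#'
#' Returns the three cultivar panels the package ships for end-to-end
#' testing: the 16 standard cultivars of known composition (Sukang serving
#' as the Opata-equivalent standard), the 38 Korean cultivars, and the
#' prior assignments for the 32 Korean cultivars that had been typed
#' before. The priors equal the current profiles except for the three
#' documented misassignments: Jonong (By8 instead of By9), Sinmichal (By8
#' instead of By8*) and Sinmichal1 (Dx2.2 instead of Dx2).
#'
#' @param pairing pairing table used for profile validation.
#' @return list with elements `standards` (16 [cultivar_profile()]s),
#'   `korean` (38) and `priors` (32, named by cultivar).
#' @examples
#' fx <- load_fixtures()
#' length(fx$standards)
#' fx$korean[[3]]
#' @export
load_fixtures <- function(pairing = load_pairing()) {
  std <- standards_frame()
  kor <- korean_frame()
  pri <- kor[!kor$name %in% NEW_KOREAN, , drop = FALSE]
  pri$by[pri$name == "Jonong"] <- "8"
  pri$by[pri$name == "Sinmichal"] <- "8"
  pri$dx[pri$name == "Sinmichal1"] <- "2.2"
  priors <- profiles_from_frame(pri, pairing)
  names(priors) <- pri$name
  list(standards = profiles_from_frame(std, pairing),
       korean = profiles_from_frame(kor, pairing),
       priors = priors)
}
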