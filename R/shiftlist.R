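## Parser for printed 1H shift lists in the ACD-style dialect
## "1H NMR (500 MHz, DMSO-d6) Shift 10.54 (s, 1H), 7.44 (d, J = 7.7 Hz,
## 1H), ..." with en-dash ranges, br-prefixed multiplicities, fractional
## (half-proton) rotamer integrals and isomer tags.

.knownMult <- c("s", "d", "t", "q", "quin", "dd", "dt", "td", "qd", "dq",
                "dqd", "dquin", "m")

## internal: parse one parenthesized group body, e.g.
## "dt, J = 47.5, 6.1 Hz, 2H" or "s, 0.5H, isomer1"
.parseGroup <- function(body) {
  rest <- trimws(body)
  jValues <- numeric(0)
  jm <- regmatches(rest,
                   regexec("J\\s*=\\s*([0-9][0-9., ]*?)\\s*Hz", rest))[[1]]
  if (length(jm)) {
    jValues <- as.numeric(trimws(strsplit(jm[2], ",")[[1]]))
    rest <- sub("J\\s*=\\s*[0-9][0-9., ]*?\\s*Hz,?\\s*", "", rest)
  }
  im <- regmatches(rest, regexec("([0-9]*\\.?[0-9]+)\\s*H", rest))[[1]]
  if (!length(im)) return(NULL)
  integral <- as.numeric(im[2])
  tag <- NA_character_
  if (grepl("isomer1\\s*\\+\\s*isomer2", rest)) tag <- "both"
  else if (grepl("isomer1", rest)) tag <- "isomer1"
  else if (grepl("isomer2", rest)) tag <- "isomer2"
  mult <- trimws(strsplit(rest, ",")[[1]][1])
  bare <- sub("^br\\s*", "", mult)
  if (!(bare %in% .knownMult))
    warning("unknown multiplicity token '", mult, "' stored verbatim")
  if (anyNA(jValues)) return(NULL)
  list(multiplicity = mult, jValues = jValues, integral = integral,
       isomerTag = tag)
}

#' Parse a printed proton shift list
#'
#' Parses text of the form \code{"1H NMR (500 MHz, DMSO-d6) Shift 10.54 (s,
#' 1H), 7.44 (d, J = 7.7 Hz, 1H), ..."} into structured entries: every
#' parenthesized group after \code{Shift} becomes one entry, chemical-shift
#' ranges (\code{"3.37-3.33 (m, 1H)"}) keep their bounds and report the
#' midpoint, \code{isomer1+isomer2} tags become \code{"both"}, and the
#' spectrometer frequency and solvent are read from the header. Malformed
#' groups are reported (with their text span) in the \code{problems} slot
#' and via warnings; no group is silently dropped: parsed entries plus
#' problems account for every group. Unknown multiplicity tokens warn and
#' are stored verbatim.
#'
#' @param text the shift-list text (single string or lines)
#' @param compound optional compound label stored in the result
#' @return a \linkS4class{ShiftList}
#' @export
parseShiftList <- function(text, compound = "") {
  text <- paste(text, collapse = " ")
  text <- gsub("\\s+", " ", text)
  head <- regmatches(text,
                     regexec("\\(([0-9]+)\\s*MHz,\\s*([^)]+)\\)", text))[[1]]
  freq <- if (length(head)) as.numeric(head[2]) else NA_real_
  solvent <- if (length(head)) trimws(head[3]) else NA_character_
  bodyStart <- regexpr("Shift", text)
  body <- if (bodyStart > 0)
    substring(text, bodyStart + attr(bodyStart, "match.length")) else text
  pat <- "([0-9]+\\.[0-9]+)(\\s*[–—-]\\s*([0-9]+\\.[0-9]+))?\\s*\\(([^()]*)\\)"
  m <- gregexpr(pat, body, perl = TRUE)
  groups <- regmatches(body, m)[[1]]
  nParen <- lengths(regmatches(body, gregexpr("\\(", body)))
  entries <- list()
  problems <- character(0)
  for (g in groups) {
    parts <- regmatches(g, regexec(pat, g, perl = TRUE))[[1]]
    hi <- as.numeric(parts[2])
    lo <- if (nzchar(parts[4])) as.numeric(parts[4]) else hi
    parsed <- tryCatch(.parseGroup(parts[5]), error = function(e) NULL)
    if (is.null(parsed)) {
      problems <- c(problems, g)
      next
    }
    entries[[length(entries) + 1L]] <- data.frame(
      delta = (lo + hi) / 2, deltaLow = min(lo, hi), deltaHigh = max(lo, hi),
      multiplicity = parsed$multiplicity,
      jValues = I(list(parsed$jValues)),
      integral = parsed$integral, isomerTag = parsed$isomerTag,
      raw = g, stringsAsFactors = FALSE)
  }
  ## groups that did not even match the delta-group pattern
  orphan <- nParen - length(groups)
  if (orphan > 0)
    problems <- c(problems, rep("<unmatched parenthesized group>", orphan))
  if (length(problems))
    warning("failed to parse ", length(problems), " group(s): ",
            paste(utils::head(problems, 3), collapse = "; "))
  ent <- if (length(entries)) do.call(rbind, entries) else
    data.frame(delta = numeric(0), deltaLow = numeric(0),
               deltaHigh = numeric(0), multiplicity = character(0),
               jValues = I(list()), integral = numeric(0),
               isomerTag = character(0), raw = character(0))
  rownames(ent) <- NULL
  new("ShiftList", compound = compound, frequencyMHz = freq,
      solvent = solvent, entries = ent, problems = problems)
}

#' Serialize a shift list back to its printed dialect
#'
#' Inverse of \code{\link{parseShiftList}} up to numeric formatting
#' (deltas with two decimals, J with one): re-parsing the output yields an
#' identical structure.
#'
#' @param list a \linkS4class{ShiftList}
#' @return single character string
#' @export
formatShiftList <- function(list) {
  stopifnot(is(list, "ShiftList"))
  e <- list@entries
  fmtEntry <- function(i) {
    d <- if (e$deltaLow[i] != e$deltaHigh[i])
      sprintf("%.2f–%.2f", e$deltaHigh[i], e$deltaLow[i])
    else sprintf("%.2f", e$delta[i])
    j <- e$jValues[[i]]
    jtxt <- if (length(j))
      sprintf(", J = %s Hz", paste(sprintf("%.1f", j), collapse = ", "))
    else ""
    tag <- e$isomerTag[i]
    tagtxt <- if (is.na(tag)) ""
      else if (tag == "both") ", isomer1+isomer2" else paste0(", ", tag)
    sprintf("%s (%s%s, %sH%s)", d, e$multiplicity[i], jtxt,
            format(e$integral[i]), tagtxt)
  }
  paste0("1H NMR (", format(list@frequencyMHz), " MHz, ", list@solvent,
         ") Shift ",
         paste(vapply(seq_len(nrow(e)), fmtEntry, character(1)),
               collapse = ", "))
}

#' Rotamer fractions from singly-tagged integrals
#'
#' For a slow-exchange rotamer pair each resolved signal is printed once
#' per isomer; the molar fraction of isomer i is the sum of integrals of
#' entries tagged only \code{isomer_i}, over the sum across all
#' singly-tagged entries. Entries tagged \code{isomer1+isomer2} carry no
#' resolution and are excluded. When the printed tags are internally
#' inconsistent, the resulting imbalance is reported (attribute
#' \code{imbalance} and a warning), never silently corrected.
#'
#' @param list a \linkS4class{ShiftList}
#' @param tol imbalance beyond which the flag is raised (default 0.01)
#' @return named fractions summing to 1, with attributes \code{integrals}
#'   (per-isomer sums) and \code{imbalance} (logical)
#' @export
rotamerFractions <- function(list, tol = 0.01) {
  stopifnot(is(list, "ShiftList"))
  e <- list@entries
  single <- e[!is.na(e$isomerTag) & e$isomerTag != "both", ]
  if (nrow(single) == 0) stop("no resolved rotamer signals")
  sums <- tapply(single$integral, single$isomerTag, sum)
  frac <- sums / sum(sums)
  imbalance <- max(abs(frac - 1 / length(frac))) > tol
  if (imbalance)
    warning(sprintf(paste0("rotamer integrals are imbalanced (%s): the ",
                           "printed isomer tags may be inconsistent"),
                    paste(sprintf("%s = %.3g", names(sums), sums),
                          collapse = ", ")))
  out <- as.numeric(frac)
  names(out) <- names(frac)
  attr(out, "integrals") <- sums
  attr(out, "imbalance") <- imbalance
  out
}

#' Total proton count of a shift list
#'
#' Sum of the printed integrals; half-proton rotamer integrals are handled
#' in exact half-unit arithmetic so 1:1 rotamer accounting stays exact.
#'
#' @param list a \linkS4class{ShiftList}
#' @return proton count (possibly fractional)
#' @export
totalProtons <- function(list) {
  stopifnot(is(list, "ShiftList"))
  ints <- list@entries$integral
  if (length(ints) == 0) return(0)
  halves <- 2 * ints
  if (all(abs(halves - round(halves)) < 1e-9))
    sum(round(halves)) / 2
  else sum(ints)
}

#' Path to a bundled shift-list fixture
#'
#' The package ships the printed proton shift lists of the three study
#' compounds (dimethyl, des-methyl analogs and the parent) as plain-text
#' fixtures.
#'
#' @param compound 1, 2 or 3
#' @return file path
#' @export
shiftListFixture <- function(compound) {
  path <- system.file("extdata",
                      sprintf("compound%d_shifts.txt", as.integer(compound)),
                      package = "ligandconf")
  if (!nzchar(path)) stop("no fixture for compound ", compound)
  path
}
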