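#' Standard monoisotopic residue masses
#'
#' Monoisotopic masses in Da of the 20 standard amino-acid residues (L and
#' I are isobaric at 113.08406 Da). A peptide's monoisotopic mass is the
#' sum of its residue masses plus one water (18.010565 Da).
#'
#' @return named numeric(20).
#' @export
residueMasses <- function() c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.WATER <- 18.010565

#' Default modification set
#'
#' The fixed and variable modifications of the search protocol: fixed
#' carbamidomethylation of Cys (+57.02146 Da), variable oxidation of Met
#' (+15.99491 Da) and variable Lys -> pyrrolysine (+109.05276 Da). Deltas
#' are standard Unimod monoisotopic values.
#'
#' @return list with data.frames `fixed` and `variable`, columns `residue`
#'   and `delta`.
#' @export
defaultModificationSet <- function() list(
  fixed = data.frame(residue = "C", delta = 57.02146,
    name = "Carbamidomethyl", stringsAsFactors = FALSE),
  variable = data.frame(residue = c("M", "K"),
    delta = c(15.99491, 109.05276),
    name = c("Oxidation", "Lys->PyrLys"), stringsAsFactors = FALSE))

#' Monoisotopic mass of a peptide
#'
#' Sum of standard monoisotopic residue masses plus one water, plus any
#' positional modification deltas and any fixed modifications applied to
#' every matching residue. Lowercase (stop-translated) letters are
#' normalized to their uppercase residue.
#'
#' @param peptide amino-acid string (standard 20-letter alphabet).
#' @param mods optional data.frame of positional modifications with columns
#'   `position` (1-based) and `delta` (Da).
#' @param fixed optional data.frame of fixed modifications with columns
#'   `residue` and `delta`, applied at every occurrence of the residue.
#' @return numeric(1) mass in Da.
#' @examples
#' monoisotopicMass("G")  # 75.03203
#' monoisotopicMass("C", fixed = defaultModificationSet()$fixed)  # 178.04122
#' @export
monoisotopicMass <- function(peptide, mods = NULL, fixed = NULL) {
  peptide <- toupper(as.character(peptide))
  if (!nzchar(peptide)) stop("empty peptide", call. = FALSE)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  m <- residueMasses()[aa]
  if (anyNA(m))
    stop("unknown amino-acid letter '", aa[which(is.na(m))[1L]], "'",
      call. = FALSE)
  total <- sum(m) + .WATER
  if (!is.null(fixed) && nrow(fixed))
    total <- total + sum(fixed$delta[match(aa, fixed$residue)], na.rm = TRUE)
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$position < 1L | mods$position > length(aa)))
      stop("modification position out of range", call. = FALSE)
    total <- total + sum(mods$delta)
  }
  total
}

#' Parts-per-million mass difference
#'
#' `1e6 * (observed - expected) / expected`: the signed relative deviation
#' between an observed and an expected mass.
#'
#' @param observed,expected masses in Da; `expected` must be positive.
#' @return numeric ppm.
#' @export
ppmDifference <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected mass must be > 0", call. = FALSE)
  1e6 * (observed - expected) / expected
}

#' Cleavage rule
#'
#' A protease-style cleavage specification: the targeted residue (L and I
#' merged), the cut side (`"carboxyl"` cuts after the residue, `"amino"`
#' before it) and the missed-cleavage budget.
#'
#' @param residue one letter of the 19-letter merged alphabet.
#' @param side `"carboxyl"` or `"amino"`.
#' @param maxMissed maximum number of missed cleavages (default 1).
#' @return list of class `CleavageRule`.
#' @export
cleavageRule <- function(residue, side = c("carboxyl", "amino"),
                         maxMissed = 1L) {
  side <- match.arg(side)
  residue <- toupper(residue)
  if (residue == "I") residue <- "L"
  stopifnot(residue %in% stopAlphabet(), maxMissed >= 0L)
  structure(list(residue = residue, side = side,
    maxMissed = as.integer(maxMissed)), class = "CleavageRule")
}

#' In-silico digestion of a peptide
#'
#' Cuts the peptide at every site selected by the rule (after each targeted
#' residue for carboxyl-side rules, before it for amino-side rules; sites
#' at the peptide termini are no-ops) and returns every fragment obtainable
#' by merging up to `maxMissed` adjacent cuts. Isoleucine matches a leucine
#' rule and vice versa.
#'
#' @param peptide amino-acid string (case ignored for site matching).
#' @param rule a [cleavageRule()].
#' @return data.frame with columns `fragment`, `offset0` (0-based offset in
#'   the parent), `length` and `missed` (number of internal uncut sites).
#' @examples
#' digestPeptide("GAKRPK", cleavageRule("K", "carboxyl", 1))$fragment
#' # "GAK" "GAKRPK" "RPK"
#' @export
digestPeptide <- function(peptide, rule) {
  stopifnot(inherits(rule, "CleavageRule"))
  pep <- as.character(peptide)
  if (!nzchar(pep)) stop("empty peptide", call. = FALSE)
  n <- nchar(pep)
  aa <- toupper(strsplit(collapseIL(pep), "", fixed = TRUE)[[1L]])
  hit <- which(aa == rule$residue)
  ## cut boundaries in 0..n (positions between residues); termini excluded
  cuts <- if (rule$side == "carboxyl") hit else hit - 1L
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  np <- length(bounds) - 1L         # number of zero-missed pieces
  out <- list()
  for (i in seq_len(np)) {
    for (m in 0:min(rule$maxMissed, np - i)) {
      from <- bounds[i]; to <- bounds[i + 1L + m]
      out[[length(out) + 1L]] <- c(from, to, m)
    }
  }
  m <- do.call(rbind, out)
  data.frame(fragment = substring(pep, m[, 1L] + 1L, m[, 2L]),
    offset0 = m[, 1L], length = m[, 2L] - m[, 1L], missed = m[, 3L],
    stringsAsFactors = FALSE)
}

#' Enumerate the per-sample search configurations
#'
#' One search per (residue, extremity) pair over the 19 mass-
#' distinguishable amino acids (L and I merged) and the two cut sides:
#' exactly 2 x 19 = 38 configurations, residues alphabetical with carboxyl
#' before amino.
#'
#' @param maxMissed missed-cleavage budget for every configuration.
#' @return data.frame with columns `label`, `residue`, `side`.
#' @examples
#' nrow(enumerateSearchConfigs())  # 38
#' @export
enumerateSearchConfigs <- function(maxMissed = 1L) {
  res <- stopAlphabet()
  data.frame(
    label = paste0(rep(res, each = 2L), ":",
      rep(c("carboxyl", "amino"), length(res))),
    residue = rep(res, each = 2L),
    side = rep(c("carboxyl", "amino"), length(res)),
    maxMissed = as.integer(maxMissed),
    stringsAsFactors = FALSE)
}
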