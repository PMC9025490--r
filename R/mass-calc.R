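# Monoisotopic atomic masses (Da) of the most abundant natural isotope,
# IUPAC/AME2020 values to >= 6 decimal places. Table precision matters:
# a 2 ppm annotation window at m/z 600 is only 0.0012 Da wide.
.ELEMENT_MASSES <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Na = 22.98976928,
  K  = 38.96370668,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.97692653,
  Se = 79.9165213,
  B  = 11.0093054,
  Li = 7.01600455,
  Mg = 23.98504170,
  Ca = 39.96259098,
  Fe = 55.93493750,
  Zn = 63.92914220
)

# Electron-corrected cation masses for singly charged positive adducts:
# proton, Na+ and K+ (neutral atom minus one electron, 0.000549 Da --
# about 1 ppm at m/z 550, so the correction is not optional).
.BUILTIN_ADDUCTS <- data.frame(
  name       = c("[M+H]+", "[M+Na]+", "[M+K]+"),
  mass_shift = c(1.007276, 22.989218, 38.963158),
  charge     = c(1L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Monoisotopic element mass table
#'
#' @return Named numeric vector of monoisotopic atomic masses (Da) for the
#'   elements the formula parser understands.
#' @examples
#' elementMasses()[c("C", "H", "O")]
#' @export
elementMasses <- function() .ELEMENT_MASSES

#' Built-in positive-mode adducts
#'
#' The three singly charged cation adducts formed under positive
#' electrospray: protonated, sodiated and potassiated molecules. Mass
#' shifts are electron-corrected cation masses in Da.
#'
#' @return A data.frame with columns `name`, `mass_shift`, `charge`.
#' @examples
#' defaultAdducts()
#' @export
defaultAdducts <- function() .BUILTIN_ADDUCTS

#' Define an adduct
#'
#' Registers a user-defined adduct specification compatible with
#' [adductMz()] and [annotateIons()].
#'
#' @param name adduct label, e.g. `"[M+NH4]+"`.
#' @param massShift mass added to the neutral molecule (Da); use the
#'   electron-corrected cation mass for charged species.
#' @param charge positive integer charge state.
#' @return A one-row data.frame with columns `name`, `mass_shift`, `charge`.
#' @examples
#' adductSpec("[M+NH4]+", 18.033823)
#' @export
adductSpec <- function(name, massShift, charge = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  massShift <- as.numeric(massShift)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("adduct charge must be a positive integer")
  data.frame(name = name, mass_shift = massShift, charge = charge,
             stringsAsFactors = FALSE)
}

#' Parse a Hill-notation molecular formula
#'
#' Element symbols are one uppercase letter optionally followed by one
#' lowercase letter; an absent count means 1 (`"C22H23ClN6O"`,
#' `"H2O"`). The empty string is the valid empty formula.
#'
#' @param text formula string.
#' @return Named integer vector of element counts (class
#'   `MolecularFormula`), one entry per element.
#' @examples
#' parseFormula("C22H23ClN6O")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  out <- integer(0)
  if (nzchar(text)) {
    m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
    tokens <- if (m[1] == -1L) character(0) else regmatches(text, list(m))[[1]]
    # every character must be covered by some token, in order
    covered <- logical(nchar(text))
    if (length(tokens))
      for (i in seq_along(m))
        covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    if (!all(covered))
      stop(sprintf("malformed formula '%s': unexpected character at position %d",
                   text, which(!covered)[1]))
    sym <- sub("[0-9]*$", "", tokens)
    unknown <- setdiff(sym, names(.ELEMENT_MASSES))
    if (length(unknown))
      stop("unknown element symbol(s) in formula '", text, "': ",
           paste(unknown, collapse = ", "))
    cnt <- sub("^[A-Za-z]+", "", tokens)
    cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
    if (anyNA(cnt))
      stop("malformed element count in formula '", text, "'")
    agg <- tapply(cnt, sym, sum)
    out <- as.integer(agg)
    names(out) <- names(agg)
    # keep first-appearance order for readable round-trips
    out <- out[order(match(names(out), sym))]
  }
  class(out) <- "MolecularFormula"
  out
}

#' Serialize a parsed formula back to Hill-style text
#'
#' @param f a parsed formula from [parseFormula()] (named counts).
#' @return A formula string; count 1 is left implicit.
#' @examples
#' formulaToString(parseFormula("H2O"))
#' @export
formulaToString <- function(f) {
  f <- unclass(f)
  f <- f[f > 0]
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", as.character(f)), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the monoisotopic atomic mass of the
#' most abundant isotope.
#'
#' @param f a formula string or a parsed formula from [parseFormula()].
#' @return Neutral monoisotopic mass in Da (0 for the empty formula).
#' @examples
#' monoisotopicMass("C22H23ClN6O") # losartan, 422.1622 Da
#' @export
monoisotopicMass <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  f <- unclass(f)
  if (!length(f)) return(0)
  unknown <- setdiff(names(f), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(f < 0)) stop("element counts must be >= 0")
  sum(.ELEMENT_MASSES[names(f)] * f)
}

.resolveAdducts <- function(adduct, adducts = defaultAdducts()) {
  if (is.data.frame(adduct)) {
    stopifnot(all(c("name", "mass_shift", "charge") %in% colnames(adduct)))
    return(adduct)
  }
  idx <- match(adduct, adducts$name)
  if (anyNA(idx))
    stop("unknown adduct(s): ", paste(adduct[is.na(idx)], collapse = ", "),
         " (registry: ", paste(adducts$name, collapse = ", "), ")")
  adducts[idx, , drop = FALSE]
}

#' m/z of an adduct ion
#'
#' For a neutral monoisotopic mass M and an adduct with mass shift s and
#' charge z, the observed m/z is (M + s) / z.
#'
#' @param neutralMass neutral monoisotopic mass(es), Da; must be >= 0.
#' @param adduct adduct name(s) from the registry, or a data.frame as
#'   returned by [adductSpec()]. Recycled against `neutralMass`.
#' @param adducts the adduct registry to resolve names in.
#' @return Numeric vector of theoretical m/z values (Da).
#' @examples
#' adductMz(422.16219, "[M+H]+")  # 423.169
#' adductMz(595.59, "[M+Na]+")    # 618.58
#' @export
adductMz <- function(neutralMass, adduct = "[M+H]+", adducts = defaultAdducts()) {
  if (any(neutralMass < 0)) stop("neutralMass must be >= 0")
  a <- .resolveAdducts(adduct, adducts)
  (neutralMass + a$mass_shift) / a$charge
}

#' Signed mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da); must be > 0.
#' @return Signed ppm error(s).
#' @examples
#' ppmError(423.16985, 423.169) # about +2 ppm
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

# half-width of a symmetric ppm window in Da
.ppmToDa <- function(mzVal, tolPpm) mzVal * tolPpm * 1e-6
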