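# MS1 lipid annotation: molecular-formula monoisotopic masses, positive
# adduct m/z calculation, and ppm-tolerance matching against a library of
# (name, formula, class) records. Annotation is putative MS1-only; no
# MS/MS or mobility evidence is modelled.

# Most-abundant-isotope masses (CODATA/AME), Da.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069,
  Na = 22.98976928,
  K = 38.96370668)

# Positive-ion adduct cation masses with electron-mass correction.
.ADDUCT_MASS <- c(
  "[M+H]+" = 1.0078250319 - .ELECTRON_MASS,
  "[M+Na]+" = 22.98976928 - .ELECTRON_MASS,
  "[M+K]+" = 38.96370668 - .ELECTRON_MASS,
  "[M+NH4]+" = 14.0030740052 + 4 * 1.0078250319 - .ELECTRON_MASS)

#' Positive DESI adducts considered during annotation
#' @return Character vector of adduct names.
#' @export
positive_adducts <- function() names(.ADDUCT_MASS)

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope masses over the elements C, H, N, O, P, S,
#' Na, K.
#'
#' @param formula Formula string such as `"C40H80NO8P"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C40H80NO8P") # PC(32:0), 733.5622
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("empty or invalid formula", call. = FALSE)
  toks <- regmatches(formula,
                     gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(toks, collapse = "")) ||
      nchar(paste(toks, collapse = "")) != nchar(formula))
    stop("cannot parse formula: ", formula, call. = FALSE)
  total <- 0
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[^0-9]", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ATOMIC_MASS))
      stop("unknown element '", el, "' in formula ", formula, call. = FALSE)
    total <- total + .ATOMIC_MASS[[el]] * n
  }
  total
}

#' Adduct ion m/z from a neutral monoisotopic mass
#'
#' Adds the adduct cation mass; by default this includes electron-mass
#' correction (physically correct for a cation). The
#' `electron_correction = FALSE` convention matches calibrant constants
#' quoted as plain elemental sums (see [rhodamine_6g_mz()]).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"`, `"[M+NH4]+"`.
#' @param electron_correction Subtract the electron mass (default `TRUE`).
#' @return Ion m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct, electron_correction = TRUE) {
  if (!adduct %in% names(.ADDUCT_MASS))
    stop("unknown adduct: ", adduct, call. = FALSE)
  m <- neutral_mass + .ADDUCT_MASS[[adduct]]
  if (!electron_correction) m <- m + .ELECTRON_MASS
  m
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da, > 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Build a lipid shorthand formula
#'
#' Standard shorthand gives total acyl carbons and double bonds:
#' phosphatidylcholines PC(c:d) have formula C(c+8)H(2c-2d+16)NO8P and
#' triacylglycerides TG(c:d) have C(c+3)H(2c-2d+2)O6.
#'
#' @param class `"PC"` or `"TG"`.
#' @param carbons Total acyl carbon count.
#' @param double_bonds Total double bond count.
#' @return Formula string.
#' @export
lipid_formula <- function(class = c("PC", "TG"), carbons, double_bonds) {
  class <- match.arg(class)
  if (class == "PC")
    sprintf("C%dH%dNO8P", carbons + 8, 2 * carbons - 2 * double_bonds + 16)
  else
    sprintf("C%dH%dO6", carbons + 3, 2 * carbons - 2 * double_bonds + 2)
}

#' Read a lipid library table
#'
#' @param path Tab-delimited file with columns `name`, `formula`, `class`.
#' @return Data frame library.
#' @export
read_lipid_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "class")
  if (!all(need %in% names(lib)))
    stop("lipid library needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lib
}

#' The packaged Daphnia lipid library
#'
#' Phosphatidylcholine and triacylglyceride species reported for
#' *Daphnia magna*, including the four species examined individually in
#' the study (PC(32:0), PC(34:3), TG(48:5), TG(50:6)); user libraries in
#' the same three-column format are drop-in replacements.
#'
#' @return Data frame with columns `name`, `formula`, `class`.
#' @export
default_lipid_library <- function() {
  path <- system.file("extdata", "lipid_library.tsv", package = "daphmsi")
  if (nzchar(path)) return(read_lipid_library(path))
  # fallback when called from a source tree
  build_lipid_library()
}

build_lipid_library <- function() {
  pc <- list(c(32, 0), c(34, 3), c(30, 0), c(32, 1), c(34, 1), c(34, 2),
             c(36, 2), c(36, 4), c(38, 4), c(38, 6))
  tg <- list(c(48, 5), c(50, 6), c(46, 2), c(48, 2), c(50, 1), c(50, 3),
             c(52, 2), c(52, 4), c(54, 4), c(54, 6))
  rows <- c(
    lapply(pc, function(v) data.frame(
      name = sprintf("PC(%d:%d)", v[1], v[2]),
      formula = lipid_formula("PC", v[1], v[2]), class = "PC")),
    lapply(tg, function(v) data.frame(
      name = sprintf("TG(%d:%d)", v[1], v[2]),
      formula = lipid_formula("TG", v[1], v[2]), class = "TG")))
  do.call(rbind, rows)
}

#' Annotate feature m/z values against a lipid library
#'
#' Every (lipid, adduct) combination whose theoretical ion m/z lies within
#' `tol_ppm` of a feature is reported, sorted per feature by absolute ppm
#' error, with the minimum-|ppm| hit flagged as best. The adduct each
#' study lipid actually ionized as is unknown, so all four common
#' positive DESI adducts are searched.
#'
#' @param feature_mz Numeric vector of feature m/z values.
#' @param library Data frame with columns `name`, `formula`, `class`
#'   (default [default_lipid_library()]). An optional `adduct` column
#'   restricts each lipid to that single adduct (targeted annotation,
#'   e.g. against a panel whose emission adducts are known); without it
#'   every adduct in `adducts` is searched for every lipid.
#' @param tol_ppm Matching tolerance in ppm (default 25).
#' @param adducts Adducts to search (default all of [positive_adducts()]).
#' @return Data frame: `feature_mz`, `name`, `formula`, `class`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `best`. Features without any hit are
#'   absent.
#' @export
annotate_features <- function(feature_mz, library = default_lipid_library(),
                              tol_ppm = 25, adducts = positive_adducts()) {
  if (nrow(library) == 0L) stop("empty lipid library", call. = FALSE)
  masses <- vapply(library$formula, monoisotopic_mass, numeric(1))
  theo <- outer(masses, .ADDUCT_MASS[adducts], `+`)  # lipids x adducts
  if (!is.null(library$adduct)) {
    known <- outer(library$adduct, adducts, `!=`)
    theo[known] <- NA_real_
  }
  hits <- list()
  for (i in seq_along(feature_mz)) {
    ppm <- (feature_mz[i] - theo) / theo * 1e6
    sel <- which(abs(ppm) <= tol_ppm, arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    h <- data.frame(
      feature_mz = feature_mz[i],
      name = library$name[sel[, 1]],
      formula = library$formula[sel[, 1]],
      class = library$class[sel[, 1]],
      adduct = adducts[sel[, 2]],
      theoretical_mz = theo[sel],
      ppm_error = ppm[sel])
    h <- h[order(abs(h$ppm_error)), , drop = FALSE]
    h$best <- seq_len(nrow(h)) == 1L
    hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L)
    return(data.frame(feature_mz = numeric(0), name = character(0),
                      formula = character(0), class = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), best = logical(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
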