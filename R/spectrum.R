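# Peak lists, precursor ion types and fragment-to-peak assignment.

# Supported singly charged precursor ion types. Adduct masses are the exact
# mass difference between the observed ion and the neutral molecule, with
# the electron mass folded in.
.precursor_type_table <- function() {
  H <- .ISOTOPE_MASS[["H"]]; C <- .ISOTOPE_MASS[["C"]]
  N <- .ISOTOPE_MASS[["N"]]; O <- .ISOTOPE_MASS[["O"]]
  Na <- .ISOTOPE_MASS[["Na"]]; K <- .ISOTOPE_MASS[["K"]]
  Cl <- .ISOTOPE_MASS[["Cl"]]; e <- .ELECTRON_MASS
  data.frame(
    name = c("[M+H]+", "[M]+", "[M]-", "[M-H]-", "[M+Na]+", "[M+K]+",
             "[M+NH4]+", "[M+Cl]-", "[M+HCOO]-", "[M+CH3COO]-"),
    adduct_mass = c(H - e, -e, e, -(H - e), Na - e, K - e,
                    N + 4 * H - e, Cl + e, C + 2 * O + H + e,
                    2 * C + 3 * H + 2 * O + e),
    polarity = c(1, 1, -1, -1, 1, 1, 1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Precursor ion types
#'
#' @param name Ion type name, e.g. `"[M+H]+"`. With no argument, the full
#'   table of supported types is returned.
#' @return A one-row list with `name`, `adduct_mass` (Da, electron mass
#'   folded in) and `polarity` (+1/-1), or the full data frame.
#' @export
#' @examples
#' precursor_type("[M+H]+")$adduct_mass  # 1.00728
precursor_type <- function(name) {
  tab <- .precursor_type_table()
  if (missing(name)) return(tab)
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unsupported precursor ion type '", name, "'; supported: ",
         paste(tab$name, collapse = ", "))
  }
  as.list(tab[i, ])
}

#' Construct an MS/MS spectrum
#'
#' @param mz,intensity Numeric vectors of peak positions (Th) and
#'   intensities (> 0).
#' @param neutral_mass Neutral monoisotopic precursor mass in Da (give this
#'   or `formula`).
#' @param formula Precursor molecular formula (string or `chem_formula`).
#' @param type Precursor ion type name (default `"[M+H]+"`).
#' @param retention_time Optional retention time in minutes.
#' @return An object of class `ms2_spectrum` with peaks sorted by m/z.
#' @export
ms2_spectrum <- function(mz, intensity, neutral_mass = NULL, formula = NULL,
                         type = "[M+H]+", retention_time = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (any(mz <= 0)) stop("non-positive m/z in peak list")
  if (any(intensity <= 0)) stop("non-positive intensity in peak list")
  if (is.null(neutral_mass)) {
    if (is.null(formula)) stop("give neutral_mass or formula")
    if (is.character(formula)) formula <- parse_formula(formula)
    neutral_mass <- monoisotopic_mass(formula)
  }
  ord <- order(mz)
  structure(list(
    peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
    neutral_mass = neutral_mass,
    precursor_type = precursor_type(type),
    retention_time = retention_time
  ), class = "ms2_spectrum")
}

#' Read a peak list file
#'
#' Plain text, one `mz intensity` pair per line (whitespace- or
#' tab-separated); `#` comments and blank lines are ignored.
#'
#' @param path Path to the peak list file.
#' @inheritParams ms2_spectrum
#' @return An `ms2_spectrum`.
#' @export
read_peaklist <- function(path, neutral_mass = NULL, formula = NULL,
                          type = "[M+H]+", retention_time = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no peaks in file: ", path)
  toks <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) stop("malformed peak list line ", bad[1], " in ", path)
  mz <- as.numeric(vapply(toks, `[[`, character(1), 1L))
  int <- as.numeric(vapply(toks, `[[`, character(1), 2L))
  if (anyNA(mz) || anyNA(int)) stop("non-numeric peak entry in ", path)
  ms2_spectrum(mz, int, neutral_mass = neutral_mass, formula = formula,
               type = type, retention_time = retention_time)
}

#' Matching settings
#'
#' Additive relative (ppm) and absolute (Da) mass deviations plus the
#' allowed hydrogen shifts between a neutral fragment and its observed ion.
#'
#' @param relative_ppm Relative deviation in ppm (default 5).
#' @param absolute_da Absolute deviation in Da (default 0.001).
#' @param hydrogen_shifts Integer set of allowed +/- hydrogen transfers
#'   (default `c(-1, 0, 1)`).
#' @return An object of class `match_settings`.
#' @export
match_settings <- function(relative_ppm = 5, absolute_da = 0.001,
                           hydrogen_shifts = c(-1L, 0L, 1L)) {
  stopifnot(relative_ppm >= 0, absolute_da >= 0)
  structure(list(relative_ppm = relative_ppm, absolute_da = absolute_da,
                 hydrogen_shifts = as.integer(hydrogen_shifts)),
            class = "match_settings")
}

#' Mass tolerance at a given m/z
#'
#' The relative and absolute deviations are additive:
#' `mz * ppm * 1e-6 + absolute_da`.
#'
#' @param mz Observed m/z in Th.
#' @param settings A `match_settings`.
#' @return Tolerance in Da.
#' @export
#' @examples
#' mass_tolerance(200, match_settings(5, 0.001))  # 0.002
mass_tolerance <- function(mz, settings = match_settings()) {
  stopifnot(all(mz > 0))
  mz * settings$relative_ppm * 1e-6 + settings$absolute_da
}

#' Theoretical ion m/z of a neutral fragment
#'
#' Adds the precursor type's adduct mass (electron mass included) and any
#' hydrogen shift (as neutral hydrogen atoms) to the neutral fragment mass.
#'
#' @param neutral_mass Neutral fragment mass in Da.
#' @param ptype A precursor type (name or result of [precursor_type()]).
#' @param h_shift Integer hydrogen shift.
#' @return m/z in Th (singly charged).
#' @export
theoretical_ion_mz <- function(neutral_mass, ptype = "[M+H]+",
                               h_shift = 0L) {
  if (is.character(ptype)) ptype <- precursor_type(ptype)
  neutral_mass + ptype$adduct_mass + h_shift * .ISOTOPE_MASS[["H"]]
}

#' Assign generated fragments to measured peaks
#'
#' For each peak, every matchable fragment is considered at every allowed
#' hydrogen shift; a fragment matches when the absolute difference between
#' its theoretical ion m/z and the peak m/z is within the additive tolerance
#' at that peak. When several fragments match one peak, the one with the
#' lowest cumulative bond dissociation energy is assigned (the lowest
#' fragmenter-score denominator); ties are broken by the smaller absolute
#' hydrogen shift, then by the smaller fragment mass. Each peak receives at
#' most one assignment.
#'
#' @param spec An `ms2_spectrum`.
#' @param fragments A `fragment_set` generated for the candidate.
#' @param settings A `match_settings`.
#' @return A data frame with one row per assigned peak: `peak` (index into
#'   the sorted peak list), `mz`, `intensity`, `fragment` (index into
#'   `fragments$fragments`), `h_shift`, `theoretical_mz`, `bde`,
#'   `fragment_mass`.
#' @export
match_peaks <- function(spec, fragments, settings = match_settings()) {
  stopifnot(inherits(spec, "ms2_spectrum"),
            inherits(fragments, "fragment_set"))
  frs <- fragments$fragments
  keep <- which(vapply(frs, `[[`, logical(1), "matchable"))
  out <- list()
  if (length(keep) && nrow(spec$peaks)) {
    fmass <- vapply(frs[keep], `[[`, numeric(1), "mass")
    fbde <- vapply(frs[keep], `[[`, numeric(1), "bde")
    grid <- expand.grid(fi = seq_along(keep),
                        h = settings$hydrogen_shifts)
    theo <- theoretical_ion_mz(fmass[grid$fi], spec$precursor_type, grid$h)
    for (p in seq_len(nrow(spec$peaks))) {
      mz <- spec$peaks$mz[p]
      tol <- mass_tolerance(mz, settings)
      hit <- which(abs(theo - mz) <= tol)
      if (!length(hit)) next
      cand <- data.frame(
        fi = grid$fi[hit], h = grid$h[hit],
        bde = fbde[grid$fi[hit]], mass = fmass[grid$fi[hit]],
        theo = theo[hit]
      )
      cand <- cand[order(cand$bde, abs(cand$h), cand$mass, cand$fi), ]
      best <- cand[1L, ]
      out[[length(out) + 1L]] <- data.frame(
        peak = p, mz = mz, intensity = spec$peaks$intensity[p],
        fragment = keep[best$fi], h_shift = best$h,
        theoretical_mz = best$theo, bde = best$bde,
        fragment_mass = best$mass
      )
    }
  }
  if (!length(out)) {
    return(data.frame(peak = integer(0), mz = numeric(0),
                      intensity = numeric(0), fragment = integer(0),
                      h_shift = integer(0), theoretical_mz = numeric(0),
                      bde = numeric(0), fragment_mass = numeric(0)))
  }
  do.call(rbind, out)
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", nrow(x$peaks), " peaks, neutral mass ",
      sprintf("%.4f", x$neutral_mass), " Da, ", x$precursor_type$name,
      if (!is.null(x$retention_time))
        paste0(", RT ", x$retention_time, " min"),
      "\n", sep = "")
  invisible(x)
}
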