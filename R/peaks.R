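#' Default electrospray adduct rules
#'
#' A minimal common adduct set: `[M+H]+`, `[M+Na]+`, `[M+NH4]+` in positive
#' mode and `[M-H]-`, `[M+Cl]-` in negative mode.  Mass shifts are in
#' Daltons (proton mass 1.007276 Da).  Fully replaceable by a user table.
#'
#' @return `data.frame` with columns `name`, `mode`, `mass_shift`, `charge`.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+Cl]-"),
    mode = c("positive", "positive", "positive", "negative", "negative"),
    mass_shift = c(1.007276, 22.989218, 18.033823, -1.007276, 34.969402),
    charge = c(1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of a neutral mass under an adduct rule
#'
#' `(mass + mass_shift) / charge`; vectorized over `mass`.
#'
#' @param mass neutral monoisotopic mass(es), Daltons, > 0.
#' @param mass_shift adduct mass shift in Daltons.
#' @param charge absolute charge, a positive integer.
#' @return theoretical m/z value(s).
#' @examples
#' theoretical_mz(180, mass_shift = 1.00728, charge = 1)
#' @export
theoretical_mz <- function(mass, mass_shift, charge = 1L) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop_value("`mass` must be positive and finite")
  }
  if (length(charge) != 1L || charge < 1) {
    stop_value("`charge` must be a positive integer")
  }
  mz <- (mass + mass_shift) / charge
  if (any(mz <= 0)) {
    stop_value("adduct with shift %g yields nonpositive m/z for mass %g",
               mass_shift, mass[which(mz <= 0)[1L]])
  }
  mz
}

#' Match untargeted m/z peaks to candidate metabolites
#'
#' Adduct-aware ppm matching: a peak matches a metabolite when, for some
#' adduct of the peak's ionization mode,
#' `|observed - theoretical| / theoretical * 1e6 <= ppm_tol`.  Every
#' candidate within tolerance is kept as a separate peak-metabolite edge;
#' the downstream network optimization, not a hard assignment, resolves the
#' ambiguity.  Matches of one pair through several adducts collapse to one
#' edge annotated with all adduct names and the smallest ppm error.
#'
#' @param peaks `data.frame` with columns `peak_id`, `mz` (> 0), `mode`
#'   (`"positive"` or `"negative"`).
#' @param db metabolite database `data.frame` with columns `met_id`,
#'   `monoisotopic_mass` (> 0) and optionally `name`.
#' @param adducts adduct rules as in [default_adducts()].
#' @param ppm_tol matching tolerance in parts per million (default 10).
#' @param cost cost put on the emitted peak-metabolite edges (near zero:
#'   connecting a peak to its candidates must be essentially free so the
#'   prize/topology trade-off decides).
#' @return edge `data.frame` in the [compose_interactome()] layout with
#'   extra columns `adducts` and `ppm_error`; `u` is the peak, `v` the
#'   metabolite.
#' @export
match_peaks <- function(peaks, db, adducts = default_adducts(),
                        ppm_tol = 10, cost = 1e-6) {
  if (is.null(adducts) || nrow(adducts) == 0L) {
    stop_value("adduct list is empty: at least one adduct rule is required")
  }
  if (!is.numeric(ppm_tol) || length(ppm_tol) != 1L || ppm_tol <= 0) {
    stop_value("`ppm_tol` must be a single positive number")
  }
  stopifnot(all(c("peak_id", "mz", "mode") %in% names(peaks)),
            all(c("met_id", "monoisotopic_mass") %in% names(db)))
  if (any(peaks$mz <= 0)) stop_value("peak m/z values must be positive")
  if (any(db$monoisotopic_mass <= 0)) {
    stop_value("metabolite masses must be positive")
  }
  if (anyDuplicated(db$met_id)) stop_value("duplicate met_id in database")
  modes_present <- unique(peaks$mode)
  if (!all(modes_present %in% adducts$mode)) {
    stop_value("no adduct rule covers ionization mode '%s'",
               setdiff(modes_present, adducts$mode)[1L])
  }

  hits <- vector("list", nrow(adducts))
  for (i in seq_len(nrow(adducts))) {
    ad <- adducts[i, ]
    psel <- peaks[peaks$mode == ad$mode, , drop = FALSE]
    if (nrow(psel) == 0L) next
    theo <- theoretical_mz(db$monoisotopic_mass, ad$mass_shift, ad$charge)
    # ppm error of every peak against every theoretical m/z
    err <- abs(outer(psel$mz, theo, "-")) /
      matrix(theo, nrow(psel), length(theo), byrow = TRUE) * 1e6
    idx <- which(err <= ppm_tol, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    hits[[i]] <- data.frame(
      peak_id = psel$peak_id[idx[, 1L]],
      met_id = db$met_id[idx[, 2L]],
      adduct = ad$name,
      ppm_error = err[idx],
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(u = character(), v = character(),
                      kind_u = character(), kind_v = character(),
                      confidence = numeric(), cost = numeric(),
                      layer = character(), adducts = character(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(hits$peak_id, hits$met_id, sep = "\r")
  adduct_joined <- tapply(hits$adduct, key,
                          function(a) paste(sort(unique(a)), collapse = ";"))
  ppm_min <- tapply(hits$ppm_error, key, min)
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    u = vapply(parts, `[`, "", 1L),
    v = vapply(parts, `[`, "", 2L),
    kind_u = "peak",
    kind_v = "metabolite",
    confidence = 1,
    cost = cost,
    layer = "peak_metabolite",
    adducts = unname(adduct_joined[keys]),
    ppm_error = unname(ppm_min[keys]),
    stringsAsFactors = FALSE
  )
  out[order(out$u, out$v), , drop = FALSE]
}
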