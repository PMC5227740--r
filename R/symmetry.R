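#' Helical symmetry (twist, rise)
#'
#' The lattice of a helical polymer: consecutive subunits are related by
#' an azimuthal rotation `twist_deg` about the filament axis and an
#' axial translation `rise_A`.  For myosin-decorated F-actin the
#' refined values are -166.67 degrees and 27.6 Angstrom.  Twist is
#' normalised to the half-open interval (-180, 180].
#'
#' @param twist_deg rotation per subunit, degrees.
#' @param rise_A axial translation per subunit, Angstrom (> 0).
#' @return object of class `helical_symmetry`.
#' @export
helical_symmetry <- function(twist_deg, rise_A) {
  if (!is.finite(twist_deg) || !is.finite(rise_A))
    stop("twist and rise must be finite")
  if (rise_A <= 0) stop("'rise_A' must be > 0")
  t <- twist_deg %% 360
  if (t > 180) t <- t - 360
  structure(list(twist_deg = t, rise_A = rise_A),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("<helical_symmetry> twist %.4f deg, rise %.4f A\n",
              x$twist_deg, x$rise_A))
  invisible(x)
}

#' @export
format.helical_symmetry <- function(x, ...) {
  sprintf("(%.4f deg, %.4f A)", x$twist_deg, x$rise_A)
}
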