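## Small internal helpers shared across modules.

#' Wrap angles to the interval (-180, 180] degrees
#'
#' @param x numeric vector or matrix of angles in degrees.
#' @return object of the same shape with every finite value in (-180, 180].
#' @keywords internal
#' @noRd
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)   # [-180, 180)
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even; table reproduction needs the
#' conventional half-away-from-zero rule (0.125 -> 0.13).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @keywords internal
#' @noRd
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are reproducible
#' without perturbing the global random stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Column indices into a flat xyz row (x1,y1,z1,x2,...) for atom indices `sel`.
xyz_cols <- function(sel) {
  as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
}

## Flat xyz vector -> n x 3 matrix.
vec2mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

## n x 3 matrix -> flat xyz vector.
mat2vec <- function(m) as.vector(t(m))

#' Torsion angle for stacked coordinate rows
#'
#' Dihedral p1-p2-p3-p4 for each row of four n x 3 coordinate matrices,
#' using the atan2 formulation (right-handed, IUPAC sign convention).
#'
#' @return numeric vector of angles in degrees on (-180, 180].
#' @keywords internal
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

## Standard atomic masses (Da) for elements seen in protein heavy-atom work.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38
)

#' Infer element symbols from PDB atom names
#'
#' Uses the element column when present; otherwise strips digits/primes and
#' takes the leading letter, with the usual PDB special cases (no two-letter
#' metals are expected in single-chain protein work).
#'
#' @keywords internal
#' @noRd
infer_element <- function(atom_names, elety = NULL) {
  el <- toupper(trimws(if (is.null(elety)) rep("", length(atom_names)) else elety))
  missing <- is.na(el) | el == ""
  if (any(missing)) {
    nm <- toupper(gsub("[^A-Z]", "", atom_names[missing]))
    first <- substr(nm, 1, 1)
    ## names like "1HB" reduce to "HB" -> H; "SE" of selenomethionine stays SE
    first[nm == "SE"] <- "SE"
    first[substr(nm, 1, 2) == "FE"] <- "FE"
    first[substr(nm, 1, 2) == "ZN"] <- "ZN"
    el[missing] <- first
  }
  el
}

mass_from_element <- function(element) {
  m <- .element_masses[element]
  m[is.na(m)] <- 12.011  # unknown heavy atoms treated as carbon-like
  unname(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
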