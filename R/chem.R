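## Elemental formulas, adduct m/z, and isotopic pattern simulation.
##
## Conventions (positive mode, singly charged, as in AP-SMALDI Orbitrap
## acquisitions of paint sections): the m/z of a +1 species is the neutral
## monoisotopic mass of M (+ any adduct atom) minus one electron mass.
## Under this convention all printed reference values are reproduced within
## 0.5 mDa.

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula string such as `"C22H16N2O2"` or
#' `"FeOOH"` into a named count vector. Repeated element tokens accumulate
#' (`"FeOOH"` gives Fe1 O2 H1). Parentheses are not supported.
#'
#' @param x formula string, or an already-parsed named count vector.
#' @return named integer vector of element counts, class `"chem_formula"`.
#' @examples
#' parse_formula("FeO4H6")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    fail_if(!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x),
            "formula must be a single non-empty string")
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    parts <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
    fail_if(sum(nchar(parts)) != nchar(x),
            "cannot parse formula '%s'", x)
    el <- sub("[0-9]+$", "", parts)
    n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
    n[is.na(n)] <- 1L
    counts <- tapply(n, el, sum)
    counts <- setNames(as.integer(counts), names(counts))
  }
  fail_if(any(counts < 0), "negative element count in formula")
  counts <- counts[counts > 0]
  fail_if(length(counts) == 0L, "formula has no atoms")
  unknown <- setdiff(names(counts), names(.isotope_table))
  fail_if(length(unknown) > 0, "unknown element(s): %s",
          paste(unknown, collapse = ", "))
  structure(counts, class = "chem_formula")
}

## Sum two formulas (either may be NULL).
formula_add <- function(a, b) {
  if (is.null(b)) return(parse_formula(a))
  if (is.null(a)) return(parse_formula(b))
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  parse_formula(out)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times principal-isotope mass.
#'
#' @param formula formula string or parsed formula.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(vapply(names(f), principal_mass, numeric(1)) * unclass(f))
}

## Built-in positive-mode adducts. delta = atoms added to the neutral;
## every species is +1 and loses one electron.
.adducts <- list(
  "[M+H]+"  = list(name = "[M+H]+",  delta = "H",  charge = 1L),
  "[M+Na]+" = list(name = "[M+Na]+", delta = "Na", charge = 1L),
  "[M+K]+"  = list(name = "[M+K]+",  delta = "K",  charge = 1L),
  "M+."     = list(name = "M+.",     delta = NULL, charge = 1L)
)

#' Adduct specification
#'
#' Returns the specification of one of the supported positive-mode adducts:
#' `[M+H]+`, `[M+Na]+`, `[M+K]+` or the radical cation `M+.`.
#'
#' @param name adduct name.
#' @return list with fields `name`, `delta` (formula of added atoms or NULL)
#'   and `charge` (always +1), class `"adduct_spec"`.
#' @export
adduct_spec <- function(name) {
  if (inherits(name, "adduct_spec")) return(name)
  a <- .adducts[[name]]
  fail_if(is.null(a), "unknown adduct '%s' (supported: %s)", name,
          paste(names(.adducts), collapse = ", "))
  structure(a, class = "adduct_spec")
}

#' Theoretical m/z of an adduct ion
#'
#' m/z of the singly charged species: monoisotopic mass of the neutral plus
#' adduct atoms, minus one electron mass.
#'
#' @param formula neutral elemental formula.
#' @param adduct adduct name or [adduct_spec()].
#' @return m/z in Th.
#' @examples
#' adduct_mz("C22H16N2O2", "[M+H]+")   # pigment red 122
#' adduct_mz("C32H16CuN8", "M+.")      # copper phthalocyanine
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  a <- adduct_spec(adduct)
  monoisotopic_mass(formula_add(formula, a$delta)) - .electron_mass
}

## -- isotopic pattern simulation --------------------------------------------

## Aggregate a (mass, abundance) distribution on a fixed 0.5 mDa lattice,
## keeping abundance-weighted mean masses, and prune tiny terms.
.aggregate_dist <- function(mass, ab, resolution = 5e-4, prune = 1e-10) {
  key <- round(mass / resolution)
  ab_sum <- vapply(split(ab, key), sum, numeric(1))
  m_mean <- vapply(split(seq_along(mass), key),
                   function(i) weighted.mean(mass[i], ab[i]), numeric(1))
  keep <- ab_sum > prune
  o <- order(m_mean[keep])
  list(mass = m_mean[keep][o], ab = ab_sum[keep][o])
}

.convolve_dist <- function(a, b, resolution = 5e-4, prune = 1e-10) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$ab, b$ab)
  .aggregate_dist(as.vector(mass), as.vector(ab), resolution, prune)
}

## Isotope distribution of n atoms of one element (binary exponentiation).
.element_dist <- function(element, n, resolution = 5e-4, prune = 1e-10) {
  tab <- isotope_table(element)
  d <- list(mass = tab[, "mass"], ab = tab[, "abundance"])
  out <- NULL
  while (n > 0) {
    if (n %% 2L == 1L)
      out <- if (is.null(out)) d else .convolve_dist(out, d, resolution, prune)
    n <- n %/% 2L
    if (n > 0) d <- .convolve_dist(d, d, resolution, prune)
  }
  out
}

#' Theoretical isotopic pattern of an adduct ion
#'
#' Convolves the elemental isotope distributions of the ion's composition
#' (neutral plus adduct atoms), aggregates isotopologues at 0.5 mDa
#' resolution, subtracts the electron mass, and returns the `top_n` most
#' abundant isotopologues renormalized so the base peak is 1.
#'
#' @param formula neutral elemental formula.
#' @param adduct adduct name or [adduct_spec()] (default `[M+H]+`).
#' @param top_n maximum number of isotopologues returned.
#' @param prune abundance below which intermediate terms are dropped.
#' @return data.frame with columns `mz` (Th) and `abundance` (base peak = 1),
#'   sorted by decreasing abundance.
#' @examples
#' isotope_pattern("C32H16CuN8", "M+.", top_n = 5)
#' @export
isotope_pattern <- function(formula, adduct = "[M+H]+", top_n = 10,
                            prune = 1e-10) {
  fail_if(top_n < 1, "top_n must be >= 1")
  a <- adduct_spec(adduct)
  f <- formula_add(formula, a$delta)
  dist <- NULL
  for (el in names(f)) {
    d <- .element_dist(el, unclass(f)[[el]], prune = prune)
    dist <- if (is.null(dist)) d else .convolve_dist(dist, d, prune = prune)
  }
  o <- order(dist$ab, decreasing = TRUE)
  o <- o[seq_len(min(top_n, length(o)))]
  out <- data.frame(mz = dist$mass[o] - .electron_mass,
                    abundance = dist$ab[o] / max(dist$ab[o]))
  rownames(out) <- NULL
  out
}

#' Cosine score between an observed and a theoretical isotope pattern
#'
#' Theoretical isotopologues are matched greedily (most abundant first) to
#' the nearest unused observed peak within `tol_ppm`; unmatched theoretical
#' peaks contribute zero observed intensity. The score is the cosine
#' similarity between the matched observed intensities and the theoretical
#' abundances.
#'
#' @param observed data.frame with columns `mz`, `intensity`.
#' @param theoretical data.frame with columns `mz`, `abundance`
#'   (e.g. from [isotope_pattern()]).
#' @param tol_ppm matching tolerance in ppm.
#' @return score in `[0, 1]`.
#' @export
isotope_score <- function(observed, theoretical, tol_ppm = 5) {
  fail_if(nrow(observed) == 0 || nrow(theoretical) == 0,
          "observed and theoretical patterns must be non-empty")
  th <- theoretical[order(theoretical$abundance, decreasing = TRUE), ]
  used <- rep(FALSE, nrow(observed))
  matched <- numeric(nrow(th))
  for (i in seq_len(nrow(th))) {
    d <- abs(observed$mz - th$mz[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= ppm_tol(th$mz[i], tol_ppm)) {
      matched[i] <- observed$intensity[j]
      used[j] <- TRUE
    }
  }
  if (all(matched == 0)) return(0)
  sum(matched * th$abundance) /
    (sqrt(sum(matched^2)) * sqrt(sum(th$abundance^2)))
}
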