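## Embedded element isotope table (monoisotopic masses in Da, natural
## abundances as fractions). Values follow the IUPAC/CODATA compilations as
## distributed with mainstream cheminformatics toolkits; abundances per
## element sum to 1 within 1e-6. Covering the elements that occur in
## historical and modern artist materials (organic colourants, earth
## pigments, lead white, ultramarine, gilding, bronze/copper pigments).

.isotope_table <- local({
  iso <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("mass", "abundance")))
    m[, "abundance"] <- m[, "abundance"] / sum(m[, "abundance"])
    m
  }
  list(
    H  = iso(1.00782503207, 0.999885, 2.01410177785, 0.000115),
    C  = iso(12.0, 0.9893, 13.00335483507, 0.0107),
    N  = iso(14.00307400443, 0.99632, 15.00010889888, 0.00368),
    O  = iso(15.99491461957, 0.99757, 16.99913175650, 0.00038,
             17.99915961286, 0.00205),
    Na = iso(22.98976928, 1.0),
    Mg = iso(23.985041697, 0.7899, 24.985836964, 0.1000, 25.982592971, 0.1101),
    Al = iso(26.98153853, 1.0),
    Si = iso(27.97692653465, 0.922297, 28.97649466490, 0.046832,
             29.973770136, 0.030872),
    P  = iso(30.97376199842, 1.0),
    S  = iso(31.9720711744, 0.9493, 32.9714589098, 0.0076,
             33.967867004, 0.0429, 35.96708071, 0.0002),
    Cl = iso(34.968852682, 0.7578, 36.965902602, 0.2422),
    K  = iso(38.9637064864, 0.932581, 39.963998166, 0.000117,
             40.9618252579, 0.067302),
    Ca = iso(39.962590863, 0.96941, 41.95861783, 0.00647, 42.95876644, 0.00135,
             43.95548156, 0.02086, 45.9536890, 0.00004, 47.95252276, 0.00187),
    Ti = iso(45.95262772, 0.0825, 46.95175879, 0.0744, 47.94794198, 0.7372,
             48.94786568, 0.0541, 49.94478689, 0.0518),
    Cr = iso(49.94604183, 0.04345, 51.94050623, 0.83789, 52.94064815, 0.09501,
             53.93887916, 0.02365),
    Mn = iso(54.93804391, 1.0),
    Fe = iso(53.93960899, 0.05845, 55.93493633, 0.91754, 56.93539284, 0.02119,
             57.93327443, 0.00282),
    Co = iso(58.93319429, 1.0),
    Ni = iso(57.93534241, 0.680769, 59.93078588, 0.262231, 60.93105557, 0.011399,
             61.92834537, 0.036345, 63.92796682, 0.009256),
    Cu = iso(62.92959772, 0.6915, 64.92778970, 0.3085),
    Zn = iso(63.92914201, 0.4917, 65.92603381, 0.2773, 66.92712775, 0.0404,
             67.92484455, 0.1845, 69.9253192, 0.0061),
    As = iso(74.92159457, 1.0),
    Cd = iso(105.90645941, 0.0125, 107.90418384, 0.0089, 109.90300661, 0.1249,
             110.90418287, 0.1280, 111.90276287, 0.2413, 112.90440813, 0.1222,
             113.90336509, 0.2873, 115.90476315, 0.0749),
    Ba = iso(129.9063207, 0.00106, 131.9050611, 0.00101, 133.90450818, 0.02417,
             134.90568838, 0.06592, 135.90457573, 0.07854, 136.90582714, 0.11232,
             137.90524700, 0.71698),
    Au = iso(196.96656879, 1.0),
    Hg = iso(195.9658326, 0.0015, 197.96676860, 0.0997, 198.96828064, 0.1687,
             199.96832659, 0.2310, 200.97030284, 0.1318, 201.97064340, 0.2986,
             203.97349398, 0.0687),
    Pb = iso(203.9730440, 0.014, 205.9744657, 0.241, 206.9758973, 0.221,
             207.9766525, 0.524)
  )
})

## Rest mass of the electron (Da); subtracted once for every +1 ion.
.electron_mass <- 0.000548579909

#' Element isotope table
#'
#' The packaged table of isotope masses and natural abundances used by all
#' mass computations, optionally restricted to one element.
#'
#' @param element optional element symbol; if given, only that element's
#'   matrix (columns `mass`, `abundance`) is returned.
#' @return a named list of isotope matrices, or a single matrix.
#' @examples
#' isotope_table("Fe")
#' @export
isotope_table <- function(element = NULL) {
  if (is.null(element)) return(.isotope_table)
  m <- .isotope_table[[element]]
  fail_if(is.null(m), "unknown element '%s' in isotope table", element)
  m
}

## Principal (most abundant) isotope mass of an element.
principal_mass <- function(element) {
  m <- isotope_table(element)
  m[which.max(m[, "abundance"]), "mass"]
}
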