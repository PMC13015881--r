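## Kendrick mass defect (KMD) and referenced-KMD (RKMD) transforms, plus
## detection of metal-isotopologue "fork" clusters and homologous series
## (e.g. successive FeOOH additions / water losses in ochre).

## Named repeat units commonly used with paint data.
.kendrick_units <- list(CH2 = "CH2", FeOOH = "FeOOH", H2O = "H2O")

kendrick_unit_mass <- function(unit) monoisotopic_mass(parse_formula(unit))

#' Kendrick transform of a set of m/z values
#'
#' Rescales each m/z by `round(base mass) / base mass`; the Kendrick mass
#' defect is the (signed) distance of the Kendrick mass to its nearest
#' integer: `kmd = round(km) - km`. Peaks of a homologous series differing by
#' whole base units share the same KMD. Round-to-nearest (rather than
#' ceiling) keeps defects symmetric around zero for metal species below
#' integer mass.
#'
#' @param mzs numeric vector of m/z values (Th).
#' @param base repeat-unit formula (string or parsed), default CH2.
#' @param intensity optional intensities carried along (used by plots and as
#'   the default RKMD reference).
#' @return data.frame of class `"kendrick_points"` with columns `mz`,
#'   `kendrick_mass`, `kmd` (and `intensity` if given); the base is kept as
#'   an attribute.
#' @export
kendrick_transform <- function(mzs, base = "CH2", intensity = NULL) {
  bm <- kendrick_unit_mass(base)
  fail_if(bm <= 0, "base must have positive mass")
  km <- mzs * round(bm) / bm
  out <- data.frame(mz = mzs, kendrick_mass = km, kmd = round(km) - km)
  if (!is.null(intensity)) out$intensity <- intensity
  structure(out, base = format(parse_formula(base)),
            class = c("kendrick_points", "data.frame"))
}

#' Referenced Kendrick mass defect
#'
#' Re-expresses KMD in units of the KMD spacing of one heavy-to-light
#' isotope substitution of a reference element, relative to a reference
#' point, so that isotopologue branches fall on near-integer levels
#' (the "fork" pattern of iron pigments).
#'
#' @param points a `kendrick_points` data.frame from [kendrick_transform()].
#' @param element reference element symbol (needs at least two isotopes).
#' @param isotope_pair masses of the (light, heavy) isotopes to use; default
#'   the two most abundant isotopes of `element`.
#' @param reference index of the reference point; default the most intense
#'   point (first point if no intensities).
#' @return the input with an `rkmd` column added.
#' @export
rkmd <- function(points, element = "Fe", isotope_pair = NULL,
                 reference = NULL) {
  tab <- isotope_table(element)
  fail_if(nrow(tab) < 2, "element '%s' has a single isotope; RKMD undefined",
          element)
  if (is.null(isotope_pair)) {
    o <- order(tab[, "abundance"], decreasing = TRUE)[1:2]
    isotope_pair <- sort(tab[o, "mass"])
  }
  delta <- isotope_pair[2] - isotope_pair[1]
  base <- attr(points, "base")
  bm <- kendrick_unit_mass(base)
  dk <- delta * round(bm) / bm
  spacing <- round(dk) - dk
  fail_if(abs(spacing) < 1e-9,
          "isotope spacing has no Kendrick defect for base %s", base)
  if (is.null(reference)) {
    reference <- if (!is.null(points$intensity)) which.max(points$intensity)
                 else 1L
  }
  points$rkmd <- (points$kmd - points$kmd[reference]) / spacing
  points
}

#' Detect metal-isotopologue clusters ("forks")
#'
#' Searches the peak list for clusters whose member spacings equal the
#' isotope mass differences of `element` within `mz_tol_ppm` and whose
#' intensity ratios match natural abundances within `abundance_tol`
#' (absolute difference on the principal-normalized scale). A candidate
#' anchor peak is treated as the principal-isotope species; all isotopes
#' with relative abundance at least `required_rel` must be found for the
#' cluster to be accepted.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param element element symbol, default `"Fe"`.
#' @param mz_tol_ppm mass tolerance, ppm.
#' @param abundance_tol tolerance on principal-normalized intensity ratios.
#' @param required_rel relative abundance above which an isotopologue is
#'   mandatory.
#' @return list of clusters; each has `anchor_mz`, a `members` data.frame
#'   (`isotope_mass`, `mz`, `intensity`, `expected_rel`, `observed_rel`) and
#'   a cosine `score` in `[0, 1]`.
#' @export
detect_fork <- function(peaks, element = "Fe", mz_tol_ppm = 5,
                        abundance_tol = 0.2, required_rel = 0.05) {
  if (is.null(peaks) || nrow(peaks) == 0) return(list())
  tab <- isotope_table(element)
  p_idx <- which.max(tab[, "abundance"])
  rel <- tab[, "abundance"] / tab[p_idx, "abundance"]
  dm <- tab[, "mass"] - tab[p_idx, "mass"]
  clusters <- list()
  for (a in order(peaks$mz)) {
    m0 <- peaks$mz[a]; i0 <- peaks$intensity[a]
    members <- data.frame(isotope_mass = tab[p_idx, "mass"], mz = m0,
                          intensity = i0, expected_rel = 1, observed_rel = 1)
    ok <- TRUE
    for (k in seq_len(nrow(tab))) {
      if (k == p_idx) next
      target <- m0 + dm[k]
      d <- abs(peaks$mz - target)
      j <- which.min(d)
      found <- length(j) > 0 && d[j] <= ppm_tol(target, mz_tol_ppm)
      if (found) {
        obs_rel <- peaks$intensity[j] / i0
        if (abs(obs_rel - rel[k]) > abundance_tol) {
          if (rel[k] >= required_rel) { ok <- FALSE; break } else next
        }
        members <- rbind(members, data.frame(
          isotope_mass = tab[k, "mass"], mz = peaks$mz[j],
          intensity = peaks$intensity[j], expected_rel = rel[k],
          observed_rel = obs_rel))
      } else if (rel[k] >= required_rel) {
        ok <- FALSE; break
      }
    }
    if (!ok || nrow(members) < 2) next
    score <- sum(members$observed_rel * members$expected_rel) /
      (sqrt(sum(members$observed_rel^2)) * sqrt(sum(members$expected_rel^2)))
    clusters[[length(clusters) + 1]] <-
      list(anchor_mz = m0, members = members[order(members$mz), ],
           score = score)
  }
  clusters
}

#' Detect homologous series along a repeat unit
#'
#' Finds maximal chains of peaks whose consecutive mass differences equal
#' the unit mass within `tol_ppm` (of the heavier member). Ascending chains
#' along e.g. FeOOH describe cluster extensions; the same machinery run with
#' unit H2O describes water-loss ladders read in the other direction.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param unit repeat-unit formula, e.g. `"FeOOH"` or `"H2O"`.
#' @param max_steps maximum number of steps per chain.
#' @param tol_ppm tolerance, ppm.
#' @return list of series; each has `anchor_mz`, `member_mzs`, `unit`,
#'   `step_signs` (+1 per ascending step) and `ppm_errors` per step.
#' @export
detect_series <- function(peaks, unit = "FeOOH", max_steps = 10, tol_ppm = 5) {
  fail_if(max_steps < 1, "max_steps must be >= 1")
  if (is.null(peaks) || nrow(peaks) < 2) return(list())
  u <- kendrick_unit_mass(unit)
  mz <- sort(peaks$mz)
  successor <- function(m) {
    target <- m + u
    d <- abs(mz - target)
    j <- which.min(d)
    if (d[j] <= ppm_tol(target, tol_ppm)) j else NA_integer_
  }
  has_pred <- vapply(mz, function(m) {
    target <- m - u
    any(abs(mz - target) <= ppm_tol(m, tol_ppm))
  }, logical(1))
  series <- list()
  for (r in which(!has_pred)) {
    chain <- r
    while (length(chain) <= max_steps) {
      nxt <- successor(mz[chain[length(chain)]])
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
    }
    if (length(chain) >= 2) {
      steps <- diff(mz[chain])
      series[[length(series) + 1]] <- list(
        anchor_mz = mz[chain[1]], member_mzs = mz[chain],
        unit = format(parse_formula(unit)),
        step_signs = rep(1L, length(chain) - 1L),
        ppm_errors = (steps - u) / mz[chain][-1] * 1e6)
    }
  }
  series
}

#' Write a KMD/RKMD table to a delimited file
#'
#' @param points a `kendrick_points` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kendrick <- function(points, path) {
  write.table(as.data.frame(points), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Scatter plot of a Kendrick mass defect table
#'
#' Plots KMD (or RKMD when present) against m/z, coloured by log intensity
#' when intensities are available, to PNG or SVG depending on the file
#' extension.
#'
#' @param points a `kendrick_points` data.frame.
#' @param path output path ending in `.png` or `.svg`; NULL plots to the
#'   active device.
#' @param use_rkmd plot the `rkmd` column if present.
#' @return `path`, invisibly.
#' @export
plot_kmd <- function(points, path = NULL, use_rkmd = !is.null(points$rkmd)) {
  yvals <- if (use_rkmd && !is.null(points$rkmd)) points$rkmd else points$kmd
  ylab <- if (use_rkmd && !is.null(points$rkmd)) "RKMD" else "KMD"
  col <- "grey25"
  if (!is.null(points$intensity)) {
    z <- log10(points$intensity + 1)
    z <- (z - min(z)) / max(1e-12, diff(range(z)))
    col <- rgb(z, 0.2, 1 - z)
  }
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) svg(path, width = 7, height = 5)
    else png(path, width = 900, height = 650)
    on.exit(dev.off(), add = TRUE)
  }
  plot(points$mz, yvals, pch = 16, cex = 0.7, col = col,
       xlab = "m/z (Th)", ylab = ylab,
       main = sprintf("Kendrick plot (base %s)", attr(points, "base")))
  invisible(path)
}
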