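## Pigment/binder signature database and ppm matching of aligned peaks.

#' Read a pigment/colourant database
#'
#' Reads a tab-delimited database of pigments, dyes and varnish markers.
#' Columns: `name`, `ci_name` (colour-index label, may be empty), `formula`
#' (elemental formula, may be empty for species whose printed m/z has no
#' unambiguous formula assignment), `adducts` (semicolon-separated adduct
#' names), `observed_mz` (reference m/z used when `formula` is empty) and
#' `note`. The packaged database (`system.file("extdata", "pigment_db.tsv",
#' package = "paintmsi")`) covers the modern organic pigments, earth-pigment
#' cluster ions, gilding and triterpenoid varnish markers relevant to paint
#' cross sections.
#'
#' @param path path to the TSV; defaults to the packaged database.
#' @return data.frame of class `"pigment_db"`.
#' @export
read_pigment_db <- function(path = system.file("extdata", "pigment_db.tsv",
                                               package = "paintmsi")) {
  fail_if(!file.exists(path), "pigment database not found: %s", path)
  db <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("name", "ci_name", "formula", "adducts", "observed_mz")
  missing <- setdiff(need, names(db))
  fail_if(length(missing) > 0, "pigment database lacks column(s): %s",
          paste(missing, collapse = ", "))
  for (i in seq_len(nrow(db))) {
    if (!is.na(db$formula[i])) parse_formula(db$formula[i]) # validate
    fail_if(is.na(db$adducts[i]) || !nzchar(db$adducts[i]),
            "entry '%s' has no adducts", db$name[i])
    fail_if(is.na(db$formula[i]) && is.na(db$observed_mz[i]),
            "entry '%s' has neither formula nor observed m/z", db$name[i])
  }
  class(db) <- c("pigment_db", "data.frame")
  db
}

## Expand a database into one row per (record, adduct) with theoretical m/z.
## Formula-free entries keep their recorded observed m/z, one row only.
.db_theoretical <- function(db) {
  out <- lapply(seq_len(nrow(db)), function(i) {
    if (is.na(db$formula[i])) {
      return(data.frame(name = db$name[i], ci_name = db$ci_name[i],
                        formula = NA_character_, adduct = "observed",
                        theoretical_mz = db$observed_mz[i]))
    }
    ads <- strsplit(db$adducts[i], ";", fixed = TRUE)[[1]]
    data.frame(name = db$name[i], ci_name = db$ci_name[i],
               formula = db$formula[i], adduct = ads,
               theoretical_mz = vapply(ads, function(a)
                 adduct_mz(db$formula[i], a), numeric(1)))
  })
  do.call(rbind, out)
}

#' Match aligned m/z bins against a pigment database
#'
#' Every (record, adduct) whose theoretical m/z lies within `tol_ppm` of an
#' observed bin yields one annotation. Bins matched by more than one distinct
#' record are isobaric hits and are flagged `ambiguous`.
#'
#' @param bins numeric vector of observed bin m/z, or a [feature_matrix]
#'   (its `bin_mz` axis is used).
#' @param db a `pigment_db` (default: the packaged database).
#' @param tol_ppm matching tolerance in ppm (default 5, appropriate for an
#'   Orbitrap at 70k resolving power).
#' @return data.frame of annotations: `observed_mz`, `name`, `ci_name`,
#'   `formula`, `adduct`, `theoretical_mz`, `ppm_error`, `ambiguous`.
#' @export
match_database <- function(bins, db = read_pigment_db(), tol_ppm = 5) {
  fail_if(tol_ppm <= 0, "tol_ppm must be positive")
  if (inherits(bins, "feature_matrix")) bins <- bins$bin_mz
  empty <- data.frame(observed_mz = numeric(0), name = character(0),
                      ci_name = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), ambiguous = logical(0))
  if (nrow(db) == 0 || length(bins) == 0) return(empty)
  theo <- .db_theoretical(db)
  hits <- lapply(seq_len(nrow(theo)), function(i) {
    err <- ppm_error(bins, theo$theoretical_mz[i])
    j <- which(abs(err) <= tol_ppm)
    if (length(j) == 0) return(NULL)
    cbind(data.frame(observed_mz = bins[j]), theo[rep(i, length(j)), ],
          data.frame(ppm_error = err[j]))
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  rownames(hits) <- NULL
  n_records <- vapply(split(hits$name, hits$observed_mz),
                      function(x) length(unique(x)), integer(1))
  hits$ambiguous <- n_records[as.character(hits$observed_mz)] > 1L
  hits[order(hits$observed_mz, hits$name), ]
}

#' Write annotations to a delimited file
#'
#' @param annotations data.frame from [match_database()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
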