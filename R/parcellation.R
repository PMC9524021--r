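#' Load the 18-ROI default mode network parcellation
#'
#' Returns the sphere-ROI parcellation of the default mode network used
#' throughout the package: 18 regions of 10 mm radius grouped into the
#' PCC--aMPFC core, the dMPFC subsystem and the MTL subsystem, each with its
#' MNI centroid coordinate. The definition ships with the package as a plain
#' CSV fixture.
#'
#' @return An object of class `parcellation`: a data frame with columns
#'   `index`, `name`, `abbrev`, `subsystem`, `mni_x`, `mni_y`, `mni_z`,
#'   `radius_mm`, and attribute `n` (number of ROIs).
#' @examples
#' p <- load_dmn_parcellation()
#' subset(p, abbrev == "PCC")
#' @export
load_dmn_parcellation <- function() {
  path <- system.file("extdata", "dmn_parcellation.csv", package = "dccmst")
  if (!nzchar(path) || !file.exists(path)) {
    stopf("packaged parcellation fixture is missing; the installation is corrupt")
  }
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_parcellation(p)
}

#' Construct a parcellation from a data frame
#'
#' Validates ROI definitions (consecutive 1..N indices, unique abbreviations,
#' positive radii) and attaches the `parcellation` class. Useful for ad-hoc
#' node sets, e.g. synthetic cohorts with fewer nodes.
#'
#' @param df data frame with at least columns `index`, `abbrev`; optional
#'   `name`, `subsystem`, `mni_x`, `mni_y`, `mni_z`, `radius_mm`.
#' @return A `parcellation` object.
#' @export
as_parcellation <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("index", "abbrev")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("parcellation lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  if (n < 1L) stopf("parcellation has no ROIs")
  if (!identical(as.integer(df$index), seq_len(n))) {
    stopf("ROI indices must be consecutive 1..%d", n)
  }
  if (anyDuplicated(df$abbrev)) {
    stopf("duplicate ROI abbreviation(s): %s",
          paste(unique(df$abbrev[duplicated(df$abbrev)]), collapse = ", "))
  }
  if ("radius_mm" %in% names(df) && any(df$radius_mm <= 0)) {
    stopf("ROI radii must be positive")
  }
  structure(df, class = c("parcellation", "data.frame"), n = n)
}

#' Minimal generic parcellation of n unnamed nodes
#'
#' @param n node count.
#' @param labels optional character labels (defaults to `n01`, `n02`, ...).
#' @return A `parcellation` with `n` rows.
#' @export
generic_parcellation <- function(n, labels = NULL) {
  labels <- labels %||% sprintf("n%02d", seq_len(n))
  as_parcellation(data.frame(index = seq_len(n), abbrev = labels,
                             stringsAsFactors = FALSE))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation with %d ROIs\n", nrow(x)))
  NextMethod()
  invisible(x)
}
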