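# phenotype table handling and cohort-level filtering

ADOS_COLS <- c("ados_total", "ados_comm", "ados_social", "ados_stereo_behav")
PHENO_REQUIRED <- c("subject_id", "group", "age", "sex", "iq", "site",
                    "func_mean_fd", "func_perc_fd")

#' Construct a cohort from a phenotype data frame
#'
#' @param records data frame with columns `subject_id`, `group` (ASD/TD),
#'   `age`, `sex`, `iq`, `site`, `func_mean_fd`, `func_perc_fd`, and the
#'   optional ADOS columns `ados_total`, `ados_comm`, `ados_social`,
#'   `ados_stereo_behav` (NA where not assessed).
#' @param series_paths optional named character vector mapping subject_id to
#'   a time-series file path.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, series_paths = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(PHENO_REQUIRED, names(records))
  if (length(missing_cols)) {
    stopf("phenotype table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records$subject_id <- as.character(records$subject_id)
  if (anyDuplicated(records$subject_id)) {
    stopf("duplicated subject_id(s): %s",
          paste(unique(records$subject_id[duplicated(records$subject_id)]),
                collapse = ", "))
  }
  grp <- toupper(trimws(as.character(records$group)))
  bad_grp <- setdiff(unique(grp), c("ASD", "TD"))
  if (length(bad_grp)) {
    stopf("unrecognized group label(s): %s (expected ASD or TD)",
          paste(bad_grp, collapse = ", "))
  }
  records$group <- factor(grp, levels = c("ASD", "TD"))
  fpf <- records$func_perc_fd
  if (any(!is.na(fpf) & (fpf < 0 | fpf > 100))) {
    stopf("func_perc_fd outside [0, 100] for subject(s): %s",
          paste(records$subject_id[!is.na(fpf) & (fpf < 0 | fpf > 100)],
                collapse = ", "))
  }
  for (col in ADOS_COLS) if (!col %in% names(records)) records[[col]] <- NA_real_
  if (!is.null(series_paths)) {
    if (is.null(names(series_paths)) || !all(records$subject_id %in% names(series_paths))) {
      stopf("series_paths must be named by subject_id and cover every record")
    }
    series_paths <- series_paths[records$subject_id]
  }
  structure(list(records = records, series_paths = series_paths),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$records$group)
  cat(sprintf("Cohort: %d subjects (%s), %d site(s)\n",
              nrow(x$records),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
              length(unique(x$records$site))))
  invisible(x)
}

#' Read a phenotype CSV into a cohort
#'
#' Expects the exact column names `subject_id`, `group`, `age`, `sex`, `iq`,
#' `site`, `func_mean_fd`, `func_perc_fd` and optionally `ados_total`,
#' `ados_comm`, `ados_social`, `ados_stereo_behav`. Empty ADOS cells are kept
#' as explicit missing values. Group labels are normalized to ASD/TD.
#'
#' @param path CSV file path.
#' @param series_dir optional directory; when given, each subject is mapped to
#'   `<series_dir>/<subject_id>.tsv`.
#' @return A [cohort].
#' @export
read_phenotype <- function(path, series_dir = NULL) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp <- NULL
  if (!is.null(series_dir)) {
    sp <- file.path(series_dir, paste0(as.character(rec$subject_id), ".tsv"))
    names(sp) <- as.character(rec$subject_id)
  }
  cohort(rec, series_paths = sp)
}

#' Write a cohort's phenotype table to CSV
#'
#' @param x a [cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the motion / IQ / site inclusion criteria to a cohort
#'
#' Sequentially excludes subjects with mean framewise displacement at or above
#' `max_mean_fd`, percent of high-motion frames at or above `max_perc_fd`, or
#' IQ at or below `min_iq`; records missing any of these required fields are
#' excluded and logged. Finally, whole sites are dropped unless both groups
#' retain strictly more than `min_site_n` subjects at that site. Per-criterion
#' exclusion counts are attached as the `"filter_log"` attribute. The
#' operation is idempotent.
#'
#' @param x a [cohort].
#' @param max_mean_fd exclusion threshold on `func_mean_fd` in mm (default 0.2;
#'   subjects must be strictly below it).
#' @param max_perc_fd exclusion threshold on `func_perc_fd` in percent
#'   (default 25; strictly below).
#' @param min_iq subjects must have IQ strictly above this (default 75).
#' @param min_site_n sites are kept only with strictly more than this many
#'   subjects in each group (default 3).
#' @return The filtered [cohort], with attribute `filter_log`.
#' @export
filter_cohort <- function(x, max_mean_fd = 0.2, max_perc_fd = 25,
                          min_iq = 75, min_site_n = 3) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  log <- list(n_input = nrow(rec))

  required_num <- c("func_mean_fd", "func_perc_fd", "iq")
  incomplete <- !stats::complete.cases(rec[, required_num])
  log$missing_required <- rec$subject_id[incomplete]
  rec <- rec[!incomplete, , drop = FALSE]

  keep <- rec$func_mean_fd < max_mean_fd
  log$excluded_mean_fd <- rec$subject_id[!keep]
  rec <- rec[keep, , drop = FALSE]

  keep <- rec$func_perc_fd < max_perc_fd
  log$excluded_perc_fd <- rec$subject_id[!keep]
  rec <- rec[keep, , drop = FALSE]

  keep <- rec$iq > min_iq
  log$excluded_iq <- rec$subject_id[!keep]
  rec <- rec[keep, , drop = FALSE]

  # site rule applied last, on the survivors of the per-subject criteria
  if (nrow(rec)) {
    counts <- table(rec$site, rec$group)
    ok_sites <- rownames(counts)[apply(counts, 1L, function(z) all(z > min_site_n))]
    log$excluded_sites <- setdiff(unique(as.character(rec$site)), ok_sites)
    rec <- rec[rec$site %in% ok_sites, , drop = FALSE]
  } else {
    log$excluded_sites <- character(0)
  }

  log$n_output <- nrow(rec)
  if (!nrow(rec)) warnf("filter_cohort: no subjects survive the criteria")
  sp <- x$series_paths
  if (!is.null(sp)) sp <- sp[rec$subject_id]
  out <- cohort(rec, series_paths = sp)
  attr(out, "filter_log") <- log
  out
}
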