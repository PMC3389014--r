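#' Parse a FreeSurfer regional-volume stats file
#'
#' Reads the two volumetric stats dialects produced by the FreeSurfer
#' `recon-all` pipeline: `aseg.stats` (subcortical segmentation; the volume
#' lives in the `Volume_mm3` column) and per-hemisphere `aparc.stats`
#' (cortical parcellation; the gray-matter volume lives in the `GrayVol`
#' column). Lines starting with `#` are header/comment lines and are ignored
#' except for `# subjectname`, `# hemi` and the `# ColHeaders` line that
#' names the data columns. Whole-brain summary measures (ICV, total gray and
#' the like) appear as `# Measure` comment lines and are therefore never
#' part of the regional record.
#'
#' Anatomical labels are kept verbatim. In particular FreeSurfer labels the
#' basal putamen as `vessel` (it is an area with prominent vascular space);
#' the label is preserved as-is.
#'
#' @param path path to the stats file.
#' @param dialect `"aseg"` or `"aparc"`.
#' @param hemi for the aparc dialect, `"lh"` or `"rh"`; region names are
#'   prefixed `"lh_"`/`"rh_"` to keep bilateral structures distinct. When
#'   `NULL` the hemisphere is taken from the file's `# hemi` line.
#'
#' @return An object of class `region_volume_record`: a list with
#'   `subject_id` (possibly `NA`), `source_file`, and `volumes`, a named
#'   numeric vector of region volumes in mm^3 in file order.
#' @export
parse_stats_file <- function(path, dialect = c("aseg", "aparc"), hemi = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("stats file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  is_comment <- startsWith(trimws(lines), "#")
  comments <- trimws(lines[is_comment])

  subject_id <- NA_character_
  sn <- grep("^#\\s*subjectname\\s+", comments, value = TRUE)
  if (length(sn)) {
    subject_id <- trimws(sub("^#\\s*subjectname\\s+", "", sn[1L]))
  }
  if (dialect == "aparc" && is.null(hemi)) {
    hl <- grep("^#\\s*hemi\\s+", comments, value = TRUE)
    if (length(hl)) hemi <- trimws(sub("^#\\s*hemi\\s+", "", hl[1L]))
  }
  if (dialect == "aparc") {
    if (is.null(hemi) || !hemi %in% c("lh", "rh")) {
      stop("aparc dialect needs a hemisphere ('lh' or 'rh'); none found in ",
           path, " and none supplied")
    }
  }

  ch <- grep("^#\\s*ColHeaders\\s+", comments, value = TRUE)
  if (!length(ch)) {
    stop("format error: no '# ColHeaders' line in ", path)
  }
  headers <- strsplit(trimws(sub("^#\\s*ColHeaders\\s+", "", ch[length(ch)])),
                      "\\s+")[[1L]]
  vol_name <- if (dialect == "aseg") "Volume_mm3" else "GrayVol"
  vol_col <- match(vol_name, headers)
  name_col <- match("StructName", headers)
  if (is.na(vol_col)) {
    stop("format error: no '", vol_name, "' column in ", path)
  }
  if (is.na(name_col)) {
    stop("format error: no 'StructName' column in ", path)
  }

  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  names_out <- character(0)
  vols_out <- numeric(0)
  for (k in data_idx) {
    fields <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    if (length(fields) < max(vol_col, name_col)) {
      stop("parse error at line ", k, " of ", path,
           ": expected at least ", max(vol_col, name_col), " fields")
    }
    vol <- suppressWarnings(as.numeric(fields[vol_col]))
    if (is.na(vol)) {
      stop("parse error at line ", k, " of ", path,
           ": non-numeric volume '", fields[vol_col], "'")
    }
    if (!is.finite(vol) || vol < 0) {
      stop("parse error at line ", k, " of ", path,
           ": volume must be finite and non-negative")
    }
    names_out <- c(names_out, fields[name_col])
    vols_out <- c(vols_out, vol)
  }
  if (dialect == "aparc") names_out <- paste0(hemi, "_", names_out)
  if (anyDuplicated(names_out)) {
    stop("validation error: duplicate region label(s) in ", path, ": ",
         paste(unique(names_out[duplicated(names_out)]), collapse = ", "))
  }
  volumes <- stats::setNames(vols_out, names_out)
  structure(list(subject_id = subject_id, source_file = path,
                 volumes = volumes),
            class = "region_volume_record")
}

#' @export
print.region_volume_record <- function(x, ...) {
  cat(sprintf("region_volume_record: subject %s, %d regions (%s)\n",
              x$subject_id, length(x$volumes), basename(x$source_file)))
  invisible(x)
}

#' Assemble a feature table from per-subject volume records
#'
#' Groups the records by subject, merges each subject's regions (a subject
#' typically contributes one aseg record plus one aparc record per
#' hemisphere), joins the demographics, and returns the subjects-by-regions
#' matrix in a fixed region order.
#'
#' @param records a list of [parse_stats_file()] records (or a single one).
#' @param demographics a data frame with columns `subject_id`, `group`,
#'   `age`, `sex` (0/1). Subjects appear in the output in this order.
#' @param region_list optional ordered character vector of region names to
#'   extract; every demographics subject must cover all of them. When `NULL`
#'   the intersection of regions present for all subjects is used, sorted
#'   lexicographically (C collation, so the order is locale-independent).
#' @param positive_class passed to [feature_table()].
#'
#' @return A [feature_table()]. Subjects present in `records` but not in
#'   `demographics` are dropped with a warning.
#' @export
assemble_feature_table <- function(records, demographics, region_list = NULL,
                                   positive_class = NULL) {
  if (inherits(records, "region_volume_record")) records <- list(records)
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(demographics))) {
    stop("demographics must contain columns: ", paste(need, collapse = ", "))
  }
  rec_subj <- vapply(records, function(r) as.character(r$subject_id), character(1))
  if (anyNA(rec_subj)) stop("every record needs a subject_id")

  extra <- setdiff(unique(rec_subj), demographics$subject_id)
  if (length(extra)) {
    warning("excluding subject(s) with records but no demographics: ",
            paste(extra, collapse = ", "))
  }

  per_subject <- lapply(demographics$subject_id, function(s) {
    rs <- records[rec_subj == s]
    if (!length(rs)) {
      stop("validation error: no volume records for subject ", s)
    }
    vols <- do.call(c, lapply(rs, `[[`, "volumes"))
    dup <- names(vols)[duplicated(names(vols))]
    if (length(dup)) {
      stop("validation error: region(s) appear in more than one record for subject ",
           s, ": ", paste(unique(dup), collapse = ", "))
    }
    vols
  })
  names(per_subject) <- demographics$subject_id

  if (is.null(region_list)) {
    region_list <- Reduce(intersect, lapply(per_subject, names))
    region_list <- sort(region_list, method = "radix")
    if (length(region_list) < 2L) {
      stop("fewer than 2 regions shared by all subjects")
    }
  }

  X <- matrix(NA_real_, nrow = nrow(demographics), ncol = length(region_list),
              dimnames = list(demographics$subject_id, region_list))
  for (i in seq_along(per_subject)) {
    vols <- per_subject[[i]]
    missing <- setdiff(region_list, names(vols))
    if (length(missing)) {
      stop("validation error: subject ", demographics$subject_id[i],
           " is missing region(s): ", paste(missing, collapse = ", "))
    }
    X[i, ] <- vols[region_list]
  }
  feature_table(X, demographics$subject_id, demographics$group,
                demographics$age, demographics$sex,
                region_names = region_list, positive_class = positive_class)
}
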