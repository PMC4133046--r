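#' Initial label assignment from profile naming conventions
#'
#' Builds the per-data-type map profile id -> subject id that seeds the
#' matching procedure.  A profile is linked to a subject when (in order of
#' precedence) the annotation table has a `<data_type>_profile` column naming
#' it, the profile id equals a subject id, or the profile id equals a subject
#' id after stripping a leading alphabetic prefix such as `GT_` or `EXPR.`.
#' Profiles with no annotation row are left unassigned with a warning.
#'
#' @param profiles list of `ProfileMatrix` objects (any subset of the four
#'   data types, at least two).
#' @param annotation data frame with a `subject_id` column and optionally
#'   `gender`, `stratum` and `<data_type>_profile` columns.
#' @return A `LabelAssignment`: named list (by data type) of data frames
#'   `profile_id`, `subject_id`, `provenance`, plus the annotation and the
#'   per-pair-type co-label counts as attributes.
#' @export
harmonize <- function(profiles, annotation) {
  if (!"subject_id" %in% names(annotation)) stop("annotation needs `subject_id`")
  if (anyDuplicated(annotation$subject_id))
    stop("duplicate subject_id in annotation")
  types <- vapply(profiles, function(p) p$data_type, character(1))
  if (anyDuplicated(types)) stop("more than one ProfileMatrix per data type")
  names(profiles) <- types
  la <- lapply(profiles, function(pm) {
    ids <- profile_ids(pm)
    mapcol <- paste0(pm$data_type, "_profile")
    if (mapcol %in% names(annotation)) {
      subj <- annotation$subject_id[match(ids, annotation[[mapcol]])]
    } else if (all(ids %in% annotation$subject_id)) {
      subj <- ids
    } else {
      stripped <- sub("^[A-Za-z]+[_.]", "", ids)
      subj <- ifelse(stripped %in% annotation$subject_id, stripped,
                     ifelse(ids %in% annotation$subject_id, ids, NA_character_))
    }
    dup <- duplicated(subj, incomparables = NA)
    if (any(dup))
      stop(sprintf("subject '%s' labeled more than once in %s profiles",
                   subj[dup][1], pm$data_type))
    if (anyNA(subj))
      warning(sprintf("%d %s profile(s) have no annotation row; left unassigned",
                      sum(is.na(subj)), pm$data_type), call. = FALSE)
    data.frame(profile_id = ids, subject_id = subj,
               provenance = ifelse(is.na(subj), NA_character_, "initial"),
               stringsAsFactors = FALSE)
  })
  counts <- colabel_counts(la)
  if (length(counts) > 0 && all(counts == 0))
    stop("no co-labeled subjects shared between any pair of data types; ",
         "check profile naming against the annotation table")
  structure(la, class = "LabelAssignment", annotation = annotation,
            colabel_counts = counts)
}

colabel_counts <- function(la) {
  types <- names(la)
  if (length(types) < 2) return(integer())
  cmb <- utils::combn(types, 2)
  counts <- apply(cmb, 2, function(tt) {
    length(intersect(stats::na.omit(la[[tt[1]]]$subject_id),
                     stats::na.omit(la[[tt[2]]]$subject_id)))
  })
  setNames(as.integer(counts), apply(cmb, 2, paste, collapse = "-"))
}

#' @export
print.LabelAssignment <- function(x, ...) {
  cat("LabelAssignment:\n")
  for (t in names(x))
    cat(sprintf("  %-12s %d profiles (%d assigned)\n", t, nrow(x[[t]]),
                sum(!is.na(x[[t]]$subject_id))))
  cc <- attr(x, "colabel_counts")
  if (length(cc) > 0)
    cat("  co-labeled subjects:",
        paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  invisible(x)
}

subjects_of <- function(la, type) setNames(la[[type]]$subject_id, la[[type]]$profile_id)

#' Write a label assignment to TSV
#'
#' @param la a `LabelAssignment`.
#' @param path output file.
#' @export
write_labels <- function(la, path) {
  rows <- do.call(rbind, lapply(names(la), function(t)
    cbind(data_type = t, la[[t]])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
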