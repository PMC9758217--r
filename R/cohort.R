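#' Cohort schema for long-format CSV import
#'
#' Describes how the on-disk cohort table maps onto a [longitudinal_cohort()].
#' Each CSV row is one subject-visit record; clinical features are columns.
#' Visit labels must map onto a strictly increasing month offset (baseline at
#' month 0, typically annual thereafter).
#'
#' @param subject_id Name of the subject-identifier column.
#' @param visit Name of the visit-label column.
#' @param group Name of the case/control column (values `"case"`/`"control"`).
#' @param feature_columns Character vector of clinical feature column names.
#' @param metadata_columns Character vector of subject-level metadata columns
#'   (constant within subject), e.g. sex, baseline age, GRS.
#' @param visit_levels Named numeric vector mapping visit labels to month
#'   offsets, in chronological order (default `BL`, `V04` ... `V12` at 0-60
#'   months).
#' @return An object of class `cohort_schema`.
#' @export
cohort_schema <- function(subject_id = "subject_id",
                          visit = "visit",
                          group = "group",
                          feature_columns,
                          metadata_columns = character(),
                          visit_levels = c(BL = 0, V04 = 12, V06 = 24,
                                           V08 = 36, V10 = 48, V12 = 60)) {
  stopifnot(is.character(feature_columns), length(feature_columns) > 0)
  if (anyDuplicated(feature_columns))
    stop("schema error: duplicated feature columns: ",
         paste(unique(feature_columns[duplicated(feature_columns)]), collapse = ", "))
  if (is.null(names(visit_levels)) || any(names(visit_levels) == ""))
    stop("schema error: visit_levels must be a named numeric vector")
  if (any(diff(as.numeric(visit_levels)) <= 0))
    stop("schema error: visit month offsets must be strictly increasing")
  structure(list(subject_id = subject_id, visit = visit, group = group,
                 feature_columns = feature_columns,
                 metadata_columns = metadata_columns,
                 visit_levels = visit_levels),
            class = "cohort_schema")
}

#' Feature metadata table
#'
#' @param name Feature names.
#' @param domain One of `"motor"`, `"cognitive"`, `"sleep"`, `"biomarker"`,
#'   `"vital"`, `"demographic"`, `"genetic"` per feature (recycled).
#' @param higher_is_worse Logical (or `NA` for unknown) per feature.
#' @param visit_varying Logical; does the feature vary across visits?
#' @return A `data.frame` with one row per feature.
#' @export
feature_meta <- function(name, domain,
                         higher_is_worse = NA,
                         visit_varying = TRUE) {
  domains <- c("motor", "cognitive", "sleep", "biomarker", "vital",
               "demographic", "genetic")
  domain <- rep_len(domain, length(name))
  if (!all(domain %in% domains))
    stop("unknown feature domain: ",
         paste(setdiff(unique(domain), domains), collapse = ", "))
  data.frame(name = as.character(name), domain = domain,
             higher_is_worse = rep_len(higher_is_worse, length(name)),
             visit_varying = rep_len(visit_varying, length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a longitudinal cohort
#'
#' The central data container: a long panel of clinical measurements (one row
#' per subject x visit x feature, missing cells kept explicitly as `NA`),
#' together with subject-level metadata, feature metadata and the visit
#' schedule.
#'
#' @param data `data.frame` with columns `subject_id`, `visit`, `feature`,
#'   `value` (missing cells as `NA` value).
#' @param subjects `data.frame` with `subject_id`, `group`
#'   (`"case"`/`"control"`) and optional metadata columns.
#' @param features Feature metadata as returned by [feature_meta()].
#' @param visits `data.frame` with `label` and `month` (strictly increasing).
#' @return An object of class `longitudinal_cohort`.
#' @export
longitudinal_cohort <- function(data, subjects, features, visits) {
  stopifnot(all(c("subject_id", "visit", "feature", "value") %in% names(data)),
            all(c("subject_id", "group") %in% names(subjects)),
            all(c("name", "domain") %in% names(features)),
            all(c("label", "month") %in% names(visits)))
  if (any(diff(visits$month) <= 0))
    stop("visit months must be strictly increasing")
  bad_group <- setdiff(unique(subjects$group), c("case", "control"))
  if (length(bad_group))
    stop("group labels must be 'case'/'control'; found: ",
         paste(bad_group, collapse = ", "))
  key <- paste(data$subject_id, data$visit, data$feature, sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (subject, visit, feature) records")
  if (anyDuplicated(subjects$subject_id))
    stop("integrity error: duplicate subject ids in subject table")
  data$subject_id <- as.character(data$subject_id)
  data$visit <- as.character(data$visit)
  data$feature <- as.character(data$feature)
  structure(list(data = data, subjects = subjects,
                 features = features, visits = visits),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("longitudinal_cohort:",
      nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "case"), "cases /",
      sum(x$subjects$group == "control"), "controls ),",
      nrow(x$features), "features,",
      nrow(x$visits), "visits\n")
  cat("  missing cells:", sum(is.na(x$data$value)), "/", nrow(x$data), "\n")
  invisible(x)
}

#' Number of missing cells in a cohort panel
#' @param cohort A [longitudinal_cohort()].
#' @return Integer count of `NA` cells.
#' @export
n_missing <- function(cohort) sum(is.na(cohort$data$value))

#' Read a cohort from a long-format CSV
#'
#' Each CSV row is one subject-visit record with feature columns; the panel is
#' pivoted to the internal long representation with explicit `NA` for missing
#' cells.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()].
#' @param meta Feature metadata from [feature_meta()]; must cover every
#'   feature column.
#' @return A [longitudinal_cohort()].
#' @export
read_cohort <- function(path, schema, meta) {
  stopifnot(inherits(schema, "cohort_schema"))
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c(schema$subject_id, schema$visit, schema$group,
                schema$feature_columns, schema$metadata_columns)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  unknown_vis <- setdiff(unique(raw[[schema$visit]]), names(schema$visit_levels))
  if (length(unknown_vis))
    stop("schema error: visit label(s) not in schema: ",
         paste(unknown_vis, collapse = ", "))
  if (anyDuplicated(paste(raw[[schema$subject_id]], raw[[schema$visit]], sep = "\r")))
    stop("integrity error: duplicate (subject, visit) rows")
  no_meta <- setdiff(schema$feature_columns, meta$name)
  if (length(no_meta))
    stop("feature(s) without metadata: ", paste(no_meta, collapse = ", "))

  long <- do.call(rbind, lapply(schema$feature_columns, function(f) {
    data.frame(subject_id = as.character(raw[[schema$subject_id]]),
               visit = raw[[schema$visit]],
               feature = f,
               value = as.numeric(raw[[f]]),
               stringsAsFactors = FALSE)
  }))
  subj_cols <- c(schema$subject_id, schema$group, schema$metadata_columns)
  subjects <- unique(raw[subj_cols])
  names(subjects)[1:2] <- c("subject_id", "group")
  subjects$subject_id <- as.character(subjects$subject_id)
  visits <- data.frame(label = names(schema$visit_levels),
                       month = as.numeric(schema$visit_levels),
                       stringsAsFactors = FALSE)
  visits <- visits[visits$label %in% unique(raw[[schema$visit]]), , drop = FALSE]
  longitudinal_cohort(long, subjects,
                      meta[meta$name %in% schema$feature_columns, , drop = FALSE],
                      visits)
}

#' Write a cohort back to long-format CSV
#'
#' Inverse of [read_cohort()]: one row per subject-visit, feature columns wide,
#' subject metadata repeated per row. Non-missing values round-trip exactly.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  wide <- cohort_wide(cohort)
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subject-visit wide view (feature columns + subject metadata)
cohort_wide <- function(cohort) {
  d <- cohort$data
  feats <- cohort$features$name
  d$visit <- factor(d$visit, levels = cohort$visits$label)
  base <- expand.grid(subject_id = cohort$subjects$subject_id,
                      visit = cohort$visits$label,
                      stringsAsFactors = FALSE)
  for (f in feats) {
    sub <- d[d$feature == f, c("subject_id", "visit", "value")]
    names(sub)[3] <- f
    base <- merge(base, sub, by = c("subject_id", "visit"),
                  all.x = TRUE, sort = FALSE)
  }
  out <- merge(base, cohort$subjects, by = "subject_id", sort = FALSE)
  out <- out[order(out$subject_id,
                   match(out$visit, cohort$visits$label)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# months for each visit label in panel order
visit_months <- function(cohort, labels) {
  cohort$visits$month[match(labels, cohort$visits$label)]
}

# clinical (factorization) feature names, given domains
clinical_features <- function(cohort, domains = c("motor", "cognitive", "sleep")) {
  cohort$features$name[cohort$features$domain %in% domains &
                         cohort$features$visit_varying]
}
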