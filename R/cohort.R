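#' Long-format cohort table
#'
#' Container for an individual-by-visit cohort: one row per individual and
#' time point with anthropometry, blood measurements and smoking status, plus
#' per-individual administrative flags used by the eligibility cascade.
#'
#' @param records Data frame with at least `individual_id` and `time_point`
#'   (integer in `1:3`). Recognised measurement columns: `age`, `sex`, `sbp`,
#'   `dbp`, `weight` (kg), `height` (m), `wc` (cm), `bmi` (kg/m^2), `hdl`,
#'   `total_chol`, `glucose` (mg/dL), `smoking`
#'   (smoker / non-smoker / ex-smoker). Missing columns are created as `NA`;
#'   extra columns (for example imputation flags) are kept.
#' @param individuals Optional data frame of per-individual metadata with
#'   columns `individual_id`, `prior_cvd`, `health_card`, `registry_located`.
#'   Defaults to no prior CVD, health card held, located in the registry.
#' @param validate Run [validate_cohort()] on the result.
#'
#' @return An object of class `cohort_table`: a list with elements `records`
#'   and `individuals`.
#' @export
cohort_table <- function(records, individuals = NULL, validate = TRUE) {
  stopifnot(is.data.frame(records))
  if (!all(c("individual_id", "time_point") %in% names(records))) {
    stop("records must contain 'individual_id' and 'time_point'")
  }
  records$individual_id <- as.character(records$individual_id)
  records$time_point <- as.integer(records$time_point)
  for (col in setdiff(record_columns(), names(records))) {
    records[[col]] <- if (col %in% c("sex", "smoking")) NA_character_ else NA_real_
  }
  if (!is.null(records$smoking)) {
    records$smoking <- normalize_smoking_labels(records$smoking)
  }
  records <- records[order(records$individual_id, records$time_point), ,
                     drop = FALSE]
  rownames(records) <- NULL

  ids <- unique(records$individual_id)
  if (is.null(individuals)) {
    individuals <- data.frame(
      individual_id = ids,
      prior_cvd = FALSE,
      health_card = TRUE,
      registry_located = TRUE,
      stringsAsFactors = FALSE
    )
  } else {
    individuals$individual_id <- as.character(individuals$individual_id)
    for (col in c("prior_cvd", "health_card", "registry_located")) {
      if (is.null(individuals[[col]])) {
        individuals[[col]] <- col != "prior_cvd"
      }
      individuals[[col]] <- as.logical(individuals[[col]])
    }
    if (!all(ids %in% individuals$individual_id)) {
      stop("individuals table is missing ids present in records")
    }
    individuals <- individuals[individuals$individual_id %in% ids, , drop = FALSE]
    individuals <- individuals[order(individuals$individual_id), , drop = FALSE]
    rownames(individuals) <- NULL
  }

  out <- structure(list(records = records, individuals = individuals),
                   class = "cohort_table")
  if (validate) validate_cohort(out)
  out
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a [cohort_table()]: unique
#' (individual, time point) pairs, time points in `1:3`, strictly positive
#' physiological values where present, and consistency of BMI with
#' weight/height.
#'
#' @param cohort A `cohort_table`.
#' @param bmi_tol Tolerance (kg/m^2) for `bmi == weight/height^2` where all
#'   three are present. Generated data are exact; source CSVs often carry
#'   rounded BMI, hence a non-zero default.
#' @return `cohort`, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort, bmi_tol = 0.1) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  key <- paste(rec$individual_id, rec$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rec[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for individual '%s' at time point %d",
                 d$individual_id, d$time_point))
  }
  if (any(!rec$time_point %in% 1:3)) {
    stop("time_point must be in {1, 2, 3}")
  }
  for (col in setdiff(measure_columns(), "score")) {
    v <- rec[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("non-positive value in '%s'", col))
    }
  }
  ok <- !is.na(rec$bmi) & !is.na(rec$weight) & !is.na(rec$height)
  if (any(ok)) {
    dev <- abs(rec$bmi[ok] - rec$weight[ok] / rec$height[ok]^2)
    if (any(dev > bmi_tol)) {
      stop(sprintf("bmi inconsistent with weight/height^2 (max deviation %.3g)",
                   max(dev)))
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- nrow(x$individuals)
  cat(sprintf("<cohort_table> %d individuals, %d visit records\n",
              n, nrow(x$records)))
  tab <- table(factor(x$records$time_point, levels = 1:3))
  cat(sprintf("  visits: t1=%d t2=%d t3=%d\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

#' CSV dialect for cohort files
#'
#' Describes how a long-format cohort CSV maps onto the canonical
#' [cohort_table()] fields.
#'
#' @param col_map Named character vector mapping canonical field names to
#'   column names in the file. Defaults to identity for every recognised
#'   field; entries may be dropped for columns absent from the file.
#' @param na Strings treated as missing values.
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @return A list of class `cohort_dialect`.
#' @export
cohort_dialect <- function(col_map = NULL, na = c("", "NA"), sep = ",",
                           dec = ".") {
  all_cols <- c(record_columns(),
                "prior_cvd", "health_card", "registry_located")
  default <- stats::setNames(all_cols, all_cols)
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), all_cols)
    if (length(unknown)) {
      stop("unknown canonical field(s) in col_map: ",
           paste(unknown, collapse = ", "))
    }
    default[names(col_map)] <- col_map
  }
  structure(list(col_map = default, na = na, sep = sep, dec = dec),
            class = "cohort_dialect")
}

#' Read a long-format cohort CSV
#'
#' Parses one row per individual and visit. Missing cells become explicit
#' `NA`; BMI is recomputed from weight and height when the file lacks a BMI
#' column or leaves the cell empty. Per-individual flags (`prior_cvd`,
#' `health_card`, `registry_located`), when present as columns, must be
#' constant within individual and are lifted into the metadata table.
#'
#' @param path CSV file path.
#' @param dialect A [cohort_dialect()].
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", sep = dialect$sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  cm <- dialect$col_map
  present <- cm[cm %in% names(raw)]
  if (!all(c("individual_id", "time_point") %in% names(present))) {
    stop("file must provide columns for 'individual_id' and 'time_point'")
  }

  is_missing <- function(x) is.na(x) | trimws(x) %in% dialect$na
  parse_num <- function(x, field) {
    x <- trimws(x)
    if (dialect$dec != ".") x <- gsub(dialect$dec, ".", x, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    out[is_missing(x)] <- NA_real_
    bad <- which(!is_missing(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' for '%s' at row %d",
                   x[bad[1]], field, bad[1]))
    }
    out
  }
  parse_lgl <- function(x, field) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is_missing(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' for '%s' at row %d",
                   x[bad[1]], field, bad[1]))
    }
    out
  }

  rec <- data.frame(individual_id = trimws(raw[[present["individual_id"]]]),
                    stringsAsFactors = FALSE)
  tp <- parse_num(raw[[present["time_point"]]], "time_point")
  if (any(is.na(tp)) || any(tp != round(tp))) {
    stop(sprintf("malformed value for 'time_point' at row %d",
                 which(is.na(tp) | tp != round(tp))[1]))
  }
  rec$time_point <- as.integer(tp)
  for (field in setdiff(measure_columns(), "score")) {
    if (field %in% names(present)) {
      rec[[field]] <- parse_num(raw[[present[field]]], field)
    }
  }
  if ("score" %in% names(present)) {
    rec$score <- parse_num(raw[[present["score"]]], "score")
  }
  for (field in c("sex", "smoking")) {
    if (field %in% names(present)) {
      v <- trimws(raw[[present[field]]])
      v[is_missing(v)] <- NA_character_
      rec[[field]] <- v
    }
  }
  key <- paste(rec$individual_id, rec$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (individual_id, time_point) = ('%s', %d) at row %d",
                 rec$individual_id[d], rec$time_point[d], d))
  }

  # fill BMI from weight/height where absent
  if (is.null(rec$bmi)) rec$bmi <- NA_real_
  need <- is.na(rec$bmi) & !is.na(rec$weight) & !is.na(rec$height)
  rec$bmi[need] <- rec$weight[need] / rec$height[need]^2

  individuals <- NULL
  flag_cols <- intersect(c("prior_cvd", "health_card", "registry_located"),
                         names(present))
  if (length(flag_cols)) {
    flags <- data.frame(individual_id = rec$individual_id,
                        stringsAsFactors = FALSE)
    for (field in flag_cols) {
      flags[[field]] <- parse_lgl(raw[[present[field]]], field)
    }
    individuals <- unique(flags)
    if (anyDuplicated(individuals$individual_id)) {
      stop("per-individual flags vary within an individual")
    }
  }
  cohort_table(rec, individuals = individuals)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: one row per individual and visit, with the
#' per-individual flags repeated on each row. `write_cohort` then
#' `read_cohort` round-trips values and missingness.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  out <- merge(rec, cohort$individuals, by = "individual_id", sort = FALSE)
  out <- out[order(out$individual_id, out$time_point), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Eligibility cascade
#'
#' Applies the study's exclusion filters in their fixed order: (1) women,
#' (2) individuals with cardiovascular disease before inclusion, (3) without a
#' public health-system card, (4) not located in the health registry,
#' (5) attendance at fewer than 2 of the 3 medical tests. The counts are
#' order-dependent, so the order is part of the contract.
#'
#' @param cohort A `cohort_table` with metadata flags.
#' @return A list with elements `cohort` (the filtered table) and `report`
#'   (class `eligibility_report`: per-stage removal counts, with attributes
#'   `initial_n` and `final_n`).
#' @export
apply_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  meta <- cohort$individuals
  initial_n <- nrow(meta)

  sex_of <- tapply(rec$sex, rec$individual_id, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) s[1] else NA_character_
  })
  visits_of <- table(rec$individual_id)

  keep <- meta$individual_id
  removed <- integer(5)
  stages <- c("women", "prior_cvd", "no_health_card",
              "not_in_registry", "fewer_than_2_visits")

  drop_stage <- function(keep, is_out) {
    out <- keep[is_out]
    list(keep = setdiff(keep, out), n = length(out))
  }

  s <- drop_stage(keep, tolower(sex_of[keep]) %in% "female")
  keep <- s$keep; removed[1] <- s$n
  flag <- function(col) {
    v <- meta[[col]][match(keep, meta$individual_id)]
    v & !is.na(v)
  }
  s <- drop_stage(keep, flag("prior_cvd"))
  keep <- s$keep; removed[2] <- s$n
  no_card <- !meta$health_card[match(keep, meta$individual_id)]
  s <- drop_stage(keep, no_card & !is.na(no_card))
  keep <- s$keep; removed[3] <- s$n
  not_loc <- !meta$registry_located[match(keep, meta$individual_id)]
  s <- drop_stage(keep, not_loc & !is.na(not_loc))
  keep <- s$keep; removed[4] <- s$n
  s <- drop_stage(keep, as.vector(visits_of[keep]) < 2)
  keep <- s$keep; removed[5] <- s$n

  report <- structure(
    data.frame(stage = stages, removed = removed, stringsAsFactors = FALSE),
    class = c("eligibility_report", "data.frame"),
    initial_n = initial_n, final_n = length(keep)
  )
  filtered <- cohort
  filtered$records <- rec[rec$individual_id %in% keep, , drop = FALSE]
  rownames(filtered$records) <- NULL
  filtered$individuals <- meta[meta$individual_id %in% keep, , drop = FALSE]
  rownames(filtered$individuals) <- NULL
  list(cohort = filtered, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("Eligibility cascade: %d -> %d individuals\n",
              attr(x, "initial_n"), attr(x, "final_n")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' BMI groups
#'
#' Classifies body mass index with the WHO cutoffs: normal weight below 25,
#' overweight in \[25, 30), obesity at 30 and above. Underweight (BMI < 18.5)
#' is reported inside the normal-weight group by default, with an optional
#' split.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2); `NA` passes through.
#' @param split_underweight Report underweight as its own level.
#' @return Factor with levels `normal weight`, `overweight`, `obesity`
#'   (preceded by `underweight` when split).
#' @export
bmi_group <- function(bmi, split_underweight = FALSE) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be strictly positive")
  levels <- c(if (split_underweight) "underweight", "normal weight",
              "overweight", "obesity")
  out <- rep(NA_character_, length(bmi))
  ok <- !is.na(bmi)
  out[ok & bmi < 25] <- "normal weight"
  if (split_underweight) out[ok & bmi < 18.5] <- "underweight"
  out[ok & bmi >= 25 & bmi < 30] <- "overweight"
  out[ok & bmi >= 30] <- "obesity"
  factor(out, levels = levels)
}
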