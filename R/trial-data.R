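#' Read a NONMEM-dialect PK dataset
#'
#' Reads a long-format CSV in the pharmacometrics lingua franca: one row per
#' dose event or concentration observation. Mandatory columns are `ID`,
#' `TIME`, `AMT`, `DV`, `EVID`, `MDV`, `WT`, `AGE`, `STAT`, `GRP`; `TAD`
#' (time after most recent dose) is read when present and derived from the
#' dose events otherwise. Extra columns are ignored. Missing values may be
#' empty strings or `"."`.
#'
#' Units: `TIME`/`TAD` hours since first dose / since last dose, `AMT` nmol,
#' `DV` nM, `WT` kg, `AGE` years. `STAT` is `healthy` or `hiv`; `GRP` is
#' `ISG`, `DSG` or `naive`.
#'
#' @param path Path to the CSV file.
#' @param config An [analysis_config()]; currently only carried along for
#'   provenance (units are fixed by the dialect).
#' @return A list of class `pk_dataset` with elements `records` (tibble: one
#'   row per event, columns `subject_id`, `time`, `time_after_dose`, `amt`,
#'   `dv`, `evid`, `mdv`) and `subjects` (tibble: `subject_id`, `weight`,
#'   `age`, `status`, `group`, deduplicated in order of first appearance).
#' @export
read_pk_dataset <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  mandatory <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT", "AGE", "STAT", "GRP")
  missing_cols <- setdiff(mandatory, hdr)
  if (length(missing_cols)) {
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, na = c("", ".", "NA"), col_types = readr::cols(
    .default = readr::col_guess(), ID = readr::col_character(),
    STAT = readr::col_character(), GRP = readr::col_character()
  ), progress = FALSE)
  for (col in c("TIME", "DV", "AMT", "WT", "AGE")) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(!is.na(raw[[col]]) & is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop(sprintf("non-numeric %s at data line(s) %s", col,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")), call. = FALSE)
    }
  }

  records <- tibble::tibble(
    subject_id = raw$ID,
    time = raw$TIME,
    time_after_dose = if ("TAD" %in% names(raw)) as.numeric(raw$TAD) else NA_real_,
    amt = as.numeric(raw$AMT),
    dv = as.numeric(raw$DV),
    evid = as.integer(raw$EVID),
    mdv = as.integer(raw$MDV)
  )
  records <- derive_tad(records)

  subjects <- tibble::tibble(
    subject_id = raw$ID, weight = as.numeric(raw$WT), age = as.numeric(raw$AGE),
    status = tolower(raw$STAT), group = raw$GRP
  ) |>
    dplyr::distinct(.data$subject_id, .keep_all = TRUE)

  structure(list(records = records, subjects = subjects, config = config),
            class = "pk_dataset")
}

# Fill time_after_dose from the most recent EVID=1 row where it is missing.
derive_tad <- function(records) {
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      .last_dose = cumulative_last_dose_time(.data$time, .data$evid),
      time_after_dose = dplyr::if_else(
        is.na(.data$time_after_dose) & !is.na(.data$.last_dose),
        .data$time - .data$.last_dose,
        .data$time_after_dose
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".last_dose")
}

cumulative_last_dose_time <- function(time, evid) {
  t <- ifelse(evid == 1L, time, NA_real_)
  filled <- rep(NA_real_, length(t))
  last <- NA_real_
  for (i in seq_along(t)) {
    if (!is.na(t[i])) last <- t[i]
    filled[i] <- last
  }
  filled
}

#' Write a PK dataset in the same CSV dialect read by [read_pk_dataset()]
#'
#' @param dataset A `pk_dataset` (or a list with `records` and `subjects`
#'   tibbles).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  rec <- dataset$records
  sub <- dataset$subjects
  out <- rec |>
    dplyr::left_join(sub, by = "subject_id") |>
    dplyr::transmute(
      ID = .data$subject_id, TIME = .data$time, TAD = .data$time_after_dose,
      AMT = .data$amt, DV = .data$dv, EVID = .data$evid, MDV = .data$mdv,
      WT = .data$weight, AGE = .data$age, STAT = .data$status, GRP = .data$group
    )
  readr::write_csv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Validate a PK dataset against the dialect invariants
#'
#' Report-only: the dataset is never modified. Checked invariants:
#' dose rows (`EVID=1`) have `AMT>0` and `MDV=1`; observation rows have no
#' dose amount; times are non-decreasing within subject; observed
#' concentrations are non-negative; subject covariates are finite and
#' positive; subject ids are unique in the subject table.
#'
#' @param records,subjects Tibbles as returned by [read_pk_dataset()], or a
#'   single `pk_dataset` passed as `records`.
#' @return A tibble of violations with columns `subject_id`, `row`
#'   (row number in `records`, NA for subject-level issues) and `problem`;
#'   zero rows when the dataset is valid.
#' @export
validate_pk_dataset <- function(records, subjects = NULL) {
  if (inherits(records, "pk_dataset")) {
    subjects <- records$subjects
    records <- records$records
  }
  v <- list()
  add <- function(ids, rows, problem) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- tibble::tibble(subject_id = ids, row = rows,
                                             problem = problem)
    }
  }

  bad <- which(records$evid == 1L & (is.na(records$amt) | records$amt <= 0))
  add(records$subject_id[bad], bad, "dose event with amt <= 0 or missing")
  bad <- which(records$evid == 1L & records$mdv != 1L)
  add(records$subject_id[bad], bad, "dose event with mdv != 1")
  bad <- which(records$evid == 0L & !is.na(records$amt) & records$amt != 0)
  add(records$subject_id[bad], bad, "observation row with non-zero amt")
  bad <- which(!is.na(records$dv) & records$dv < 0)
  add(records$subject_id[bad], bad, "dv < 0")
  bad <- which(records$evid == 0L & records$mdv == 0L & is.na(records$dv))
  add(records$subject_id[bad], bad, "usable observation (mdv=0) with missing dv")

  dec <- records |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(.data$time < dplyr::lag(.data$time, default = -Inf)) |>
    dplyr::ungroup()
  add(dec$subject_id, dec$.row, "time decreases within subject")

  if (!is.null(subjects)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)]
    add(dup, rep(NA_integer_, length(dup)), "duplicated subject_id")
    bad <- which(!is.finite(subjects$weight) | subjects$weight <= 0)
    add(subjects$subject_id[bad], rep(NA_integer_, length(bad)),
        "weight not finite positive")
    bad <- which(!is.finite(subjects$age) | subjects$age <= 0)
    add(subjects$subject_id[bad], rep(NA_integer_, length(bad)),
        "age not finite positive")
    bad <- which(!subjects$status %in% c("healthy", "hiv"))
    add(subjects$subject_id[bad], rep(NA_integer_, length(bad)),
        "status not in {healthy, hiv}")
  }

  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(subject_id = character(), row = integer(), problem = character())
  }
}
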