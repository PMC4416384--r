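#' Dosing events and regimens
#'
#' A regimen is an ordered table of oral dose events (time in hours since
#' the first dose, amount in mg).  The study regimen is a 900 mg loading
#' dose at time 0 followed by 600 mg every 24 h through Day 9.
#'
#' @param time hours since first dose (>= 0)
#' @param amount dose amount in mg (> 0)
#' @return `dose_event()` a one-row data frame; `regimen()` a data frame of
#'   class `"regimen"` with columns `time` and `amount`.
#' @examples
#' regimen(c(0, 24), c(900, 600))
#' @export
dose_event <- function(time, amount) {
  stopifnot(length(time) == 1, length(amount) == 1)
  if (!is.finite(time) || time < 0) stop("dose time must be >= 0")
  if (!is.finite(amount) || amount <= 0) stop("dose amount must be > 0")
  data.frame(time = as.numeric(time), amount = as.numeric(amount))
}

#' @rdname dose_event
#' @param times,amounts vectors of dose times (strictly increasing) and
#'   amounts
#' @export
regimen <- function(times, amounts) {
  if (length(times) == 0) stop("a regimen needs at least one dose")
  if (length(times) != length(amounts))
    stop("times and amounts must have equal length")
  if (any(!is.finite(times)) || any(times < 0)) stop("dose times must be >= 0")
  if (any(!is.finite(amounts)) || any(amounts <= 0))
    stop("dose amounts must be > 0")
  if (any(diff(times) <= 0)) stop("dose times must be strictly increasing")
  structure(data.frame(time = as.numeric(times), amount = as.numeric(amounts)),
            class = c("regimen", "data.frame"))
}

#' @rdname dose_event
#' @param x a `regimen`
#' @export
total_dose <- function(x) sum(x$amount)

#' The study design: regimen and nominal sampling times
#'
#' Returns the multiple-dose design used throughout: a 900 mg oral loading
#' dose at 0 h, then 600 mg every 24 h on Days 2-9 (total 5700 mg), with 14
#' nominal PK sampling times and 10 nominal PD sampling times over 0-216 h.
#' Rich sampling surrounds the final dose at 192 h.
#'
#' @return list with elements `regimen`, `pk_times` (length 14), `pd_times`
#'   (length 10).
#' @examples
#' d <- study_design()
#' length(d$pk_times)  # 14
#' total_dose(d$regimen)  # 5700
#' @export
study_design <- function() {
  list(
    regimen = regimen(c(0, 24 * (1:8)), c(900, rep(600, 8))),
    pk_times = c(0, 24, 48, 96, 144, 168, 192, 192.5, 193, 194, 196, 199,
                 202, 216),
    pd_times = c(0, 24, 48, 96, 144, 168, 192, 196, 202, 216)
  )
}

# Lower limit of quantification of the HTB assay (ug/mL).
LLOQ <- 1

#' Construct a longitudinal PK-PD dataset
#'
#' The container mirrors a NONMEM-style analysis dataset split into four
#' tables: subjects (id, weight and optional covariates), dose events,
#' PK concentration observations and binary PD observations.
#'
#' @param subjects data frame with at least `id` and `weight` (kg > 0);
#'   optional covariate columns (e.g. `age`, `height`, `albumin`,
#'   `creatinine`, `ast`, `alt`, `clcr`)
#' @param doses data frame with `id`, `time`, `amount`
#' @param pk data frame with `id`, `time`, `conc` (ug/mL); a logical
#'   `blq` column is derived if absent (conc < 1 ug/mL LLOQ)
#' @param pd data frame with `id`, `time`, `dv` in \{0, 1\}; optional `agg`
#'   (\% aggregation, 0-100) must be consistent with the 74\% rule
#' @return object of class `"pkpd_dataset"`
#' @seealso [read_dataset()], [write_dataset()], [simulate_trial()]
#' @export
pkpd_dataset <- function(subjects, doses, pk, pd) {
  stopifnot(all(c("id", "weight") %in% names(subjects)),
            all(c("id", "time", "amount") %in% names(doses)),
            all(c("id", "time", "conc") %in% names(pk)),
            all(c("id", "time", "dv") %in% names(pd)))
  if (isTRUE(any(subjects$weight <= 0))) stop("subject weights must be > 0")
  if (anyDuplicated(subjects$id)) stop("duplicate subject ids")
  ids <- subjects$id
  for (tab in list(doses, pk, pd)) {
    if (nrow(tab) && !all(tab$id %in% ids))
      stop("observation/dose rows refer to unknown subject ids")
    if (nrow(tab) && any(tab$time < 0)) stop("times must be >= 0")
  }
  if (nrow(pk)) {
    if (any(pk$conc < 0)) stop("concentrations must be >= 0")
    if (is.null(pk$blq)) pk$blq <- pk$conc < LLOQ
    if (any(pk$blq != (pk$conc < LLOQ)))
      stop("blq flag inconsistent with the 1 ug/mL LLOQ")
  } else pk$blq <- logical(0)
  if (nrow(pd)) {
    if (!all(pd$dv %in% c(0, 1))) stop("pd dv must be 0 or 1")
    if (is.null(pd$agg)) pd$agg <- NA_real_
    has <- !is.na(pd$agg)
    if (any(has) && any(binarize(pd$agg[has]) != pd$dv[has]))
      stop("pd dv inconsistent with the 74% aggregation rule")
  } else pd$agg <- numeric(0)
  structure(list(subjects = subjects, doses = doses, pk = pk, pd = pd),
            class = "pkpd_dataset")
}

#' @export
print.pkpd_dataset <- function(x, ...) {
  cat("<pkpd_dataset>", nrow(x$subjects), "subjects,",
      nrow(x$doses), "dose events,",
      nrow(x$pk), "PK observations (", sum(x$pk$blq), "BLQ ),",
      nrow(x$pd), "PD observations\n")
  invisible(x)
}

#' Extract the regimen of one subject
#' @param data a [pkpd_dataset()]
#' @param id subject id
#' @return a [regimen()]
#' @export
subject_regimen <- function(data, id) {
  d <- data$doses[data$doses$id == id, , drop = FALSE]
  regimen(d$time, d$amount)
}

# NONMEM-style column order used on disk; AGG carries the continuous
# aggregation when present, extra covariate columns are appended.
NM_COLUMNS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "CMT", "WT")
COVARIATE_MAP <- c(age = "AGE", height = "HT", albumin = "ALB",
                   creatinine = "CRE", ast = "AST", alt = "ALT",
                   clcr = "CLCR")

#' Read and write NONMEM-style dataset tables
#'
#' The on-disk dialect is a delimited text table (comma or whitespace)
#' with header columns ID, TIME, AMT, DV, EVID, MDV, CMT, WT and `"."` for
#' missing cells.  Dose rows have EVID = 1 (depot, CMT = 1); observation
#' rows have EVID = 0, MDV = 0 with CMT = 2 for HTB concentration and
#' CMT = 3 for the binary platelet-aggregation outcome.  An optional AGG
#' column carries the continuous \% aggregation alongside the binary DV,
#' and optional covariate columns (AGE, HT, ALB, CRE, AST, ALT, CLCR) are
#' attached to the subject table.  `write_dataset()` followed by
#' `read_dataset()` is lossless.
#'
#' @param path file path
#' @return a [pkpd_dataset()]
#' @examples
#' d <- simulate_trial(simulation_config(n_subjects = 2, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_dataset(d, f)
#' d2 <- read_dataset(f)
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- read.table(path, header = TRUE, sep = sep, na.strings = ".",
                    colClasses = "character", strip.white = TRUE)
  need <- c("ID", "TIME", "DV", "AMT", "EVID", "MDV")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$CMT)) raw$CMT <- "2"
  num <- raw
  for (cn in names(num)) {
    v <- suppressWarnings(as.numeric(num[[cn]]))
    bad <- which(!is.na(num[[cn]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column ", cn, ", data row ", bad[1])
    num[[cn]] <- v
  }
  if (any(num$EVID == 1 & !is.na(num$DV)))
    warning("DV present on dose (EVID=1) rows; ignored")
  sub_rows <- !duplicated(num$ID)
  subjects <- data.frame(id = num$ID[sub_rows])
  subjects$weight <- if (!is.null(num$WT)) num$WT[sub_rows] else NA_real_
  for (cov in names(COVARIATE_MAP)) {
    cn <- COVARIATE_MAP[[cov]]
    if (!is.null(num[[cn]])) subjects[[cov]] <- num[[cn]][sub_rows]
  }
  dose <- num[num$EVID == 1, , drop = FALSE]
  obs <- num[num$EVID == 0 & num$MDV == 0, , drop = FALSE]
  pk_rows <- obs[obs$CMT == 2, , drop = FALSE]
  pd_rows <- obs[obs$CMT == 3, , drop = FALSE]
  pd <- data.frame(id = pd_rows$ID, time = pd_rows$TIME, dv = pd_rows$DV)
  pd$agg <- if (!is.null(pd_rows$AGG)) pd_rows$AGG
            else rep(NA_real_, nrow(pd_rows))
  pkpd_dataset(
    subjects = subjects,
    doses = data.frame(id = dose$ID, time = dose$TIME, amount = dose$AMT),
    pk = data.frame(id = pk_rows$ID, time = pk_rows$TIME, conc = pk_rows$DV),
    pd = pd
  )
}

#' @rdname read_dataset
#' @param data a [pkpd_dataset()]
#' @param sep field separator, `","` (default) or `" "`
#' @export
write_dataset <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "pkpd_dataset"))
  has_agg <- nrow(data$pd) > 0 && any(!is.na(data$pd$agg))
  covs <- intersect(names(COVARIATE_MAP), names(data$subjects))
  cols <- c(NM_COLUMNS, if (has_agg) "AGG", unname(COVARIATE_MAP[covs]))
  row_of <- function(id, time, amt, dv, evid, mdv, cmt, agg) {
    s <- data$subjects[data$subjects$id == id, , drop = FALSE]
    r <- data.frame(ID = id, TIME = time, AMT = amt, DV = dv, EVID = evid,
                    MDV = mdv, CMT = cmt, WT = s$weight)
    if (has_agg) r$AGG <- agg
    for (cov in covs) r[[COVARIATE_MAP[[cov]]]] <- s[[cov]]
    r
  }
  rows <- list()
  for (id in data$subjects$id) {
    d <- data$doses[data$doses$id == id, , drop = FALSE]
    pk <- data$pk[data$pk$id == id, , drop = FALSE]
    pd <- data$pd[data$pd$id == id, , drop = FALSE]
    ev <- rbind(
      if (nrow(d)) do.call(rbind, Map(row_of, id, d$time, d$amount,
                                      NA_real_, 1, 1, 1, NA_real_)),
      if (nrow(pk)) do.call(rbind, Map(row_of, id, pk$time, NA_real_,
                                       pk$conc, 0, 0, 2, NA_real_)),
      if (nrow(pd)) do.call(rbind, Map(row_of, id, pd$time, NA_real_,
                                       pd$dv, 0, 0, 3, pd$agg))
    )
    # stable sort: time, then dose rows before observations at equal time
    rows[[length(rows) + 1L]] <- ev[order(ev$TIME, ev$EVID != 1, ev$CMT), ]
  }
  out <- do.call(rbind, rows)[, cols]
  fmt <- out
  for (cn in names(fmt))
    fmt[[cn]] <- ifelse(is.na(out[[cn]]), ".",
                        formatC(out[[cn]], format = "g", digits = 15))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  write.table(fmt, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
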