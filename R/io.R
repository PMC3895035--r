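# NONMEM-style dataset file and parameter JSON serialization.
#
# Dataset CSV columns (fixed order):
#   ID, TIME (day), EVID (0 obs / 1 dose), AMT (mg, dose rows),
#   DRUG (ACZ/FUR, dose rows), DVID (BICAR/MV/PACO2, obs rows),
#   DV (obs rows), SAPS2, CHLORIDE, CORT (0/1), SEX (0 male / 1 female),
#   VENT (0 pressure-support / 1 volume-assist)
# Missing fields carry the NONMEM placeholder ".". Rows are ordered by
# ID, TIME, EVID; an observation at a dose time is post-dose.

.acz_columns <- c("ID", "TIME", "EVID", "AMT", "DRUG", "DVID", "DV",
                  "SAPS2", "CHLORIDE", "CORT", "SEX", "VENT")

#' Convert a dataset to its NONMEM-style table
#'
#' @param x an `acz_dataset`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return `data.frame` with the canonical columns, ordered by ID, TIME,
#'   EVID; missing fields are `"."`.
#' @export
as.data.frame.acz_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$subjects, function(s) {
    cv <- s$covariates
    base <- data.frame(SAPS2 = cv$saps2, CHLORIDE = cv$chloride,
                       CORT = as.integer(cv$corticosteroid),
                       SEX = as.integer(cv$female),
                       VENT = as.integer(cv$volume_assist))
    dose <- rbind(
      if (nrow(s$ace_doses)) data.frame(TIME = s$ace_doses$time, EVID = 1L,
                                        AMT = s$ace_doses$amount, DRUG = "ACZ",
                                        DVID = ".", DV = ".") else NULL,
      if (nrow(s$fur_doses)) data.frame(TIME = s$fur_doses$time, EVID = 1L,
                                        AMT = s$fur_doses$amount, DRUG = "FUR",
                                        DVID = ".", DV = ".") else NULL)
    obs <- if (nrow(s$observations))
      data.frame(TIME = s$observations$time, EVID = 0L, AMT = ".", DRUG = ".",
                 DVID = s$observations$dvid,
                 DV = sprintf("%.17g", s$observations$value)) else NULL
    if (!is.null(dose)) dose$AMT <- sprintf("%.17g", as.numeric(dose$AMT))
    tab <- rbind(dose, obs)
    if (is.null(tab)) return(NULL)
    tab <- cbind(ID = s$id, tab, base)
    tab[order(tab$TIME, tab$EVID), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(.acz_columns), character(0), simplify = FALSE),
      .acz_columns))
    return(out)
  }
  out <- out[, .acz_columns]
  rownames(out) <- NULL
  out
}

#' Write a dataset to a NONMEM-style CSV file
#'
#' Deterministic: identical datasets produce byte-identical files
#' (fixed column order, rows ordered by ID, TIME, EVID, full-precision
#' numbers).
#'
#' @param dataset an `acz_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "acz_dataset"))
  tab <- as.data.frame(dataset)
  if (is.null(tab) || nrow(tab) == 0L) {
    writeLines(paste(.acz_columns, collapse = ","), path)
    return(invisible(path))
  }
  tab$TIME <- sprintf("%.17g", tab$TIME)
  tab$SAPS2 <- sprintf("%.17g", tab$SAPS2)
  tab$CHLORIDE <- sprintf("%.17g", tab$CHLORIDE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NONMEM-style dataset CSV
#'
#' Validates the header and every row (dose/observation field
#' exclusivity, covariates constant within subject, non-negative times,
#' positive observed values); all violations are reported together with
#' their row numbers.
#'
#' @param path CSV file path.
#' @param time_unit `"day"` (canonical) or `"hour"`; hours are converted
#'   to days on input.
#' @return An `acz_dataset`.
#' @export
read_dataset <- function(path, time_unit = c("day", "hour")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path))
    stop("read_dataset: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.acz_columns, names(raw))
  if (length(missing_cols))
    stop("read_dataset: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, .acz_columns]
  if (nrow(raw) == 0L)
    return(structure(list(subjects = list(), design = NULL, seed = NA),
                     class = "acz_dataset"))
  errs <- character(0)
  num <- function(x) suppressWarnings(as.numeric(x))
  tfac <- if (time_unit == "hour") 1 / 24 else 1
  tm <- num(raw$TIME) * tfac
  ev <- num(raw$EVID)
  for (r in seq_len(nrow(raw))) {
    if (is.na(tm[r]) || tm[r] < 0)
      errs <- c(errs, sprintf("row %d: TIME must be a number >= 0", r))
    if (is.na(ev[r]) || !ev[r] %in% c(0, 1)) {
      errs <- c(errs, sprintf("row %d: EVID must be 0 or 1", r)); next
    }
    if (ev[r] == 1) {
      if (raw$DV[r] != "." || raw$DVID[r] != ".")
        errs <- c(errs, sprintf("row %d: dose row (EVID=1) must not carry DV/DVID", r))
      if (is.na(num(raw$AMT[r])) || num(raw$AMT[r]) < 0)
        errs <- c(errs, sprintf("row %d: dose row needs AMT >= 0", r))
      if (!raw$DRUG[r] %in% c("ACZ", "FUR"))
        errs <- c(errs, sprintf("row %d: DRUG must be ACZ or FUR on dose rows", r))
    } else {
      if (raw$AMT[r] != "." || raw$DRUG[r] != ".")
        errs <- c(errs, sprintf("row %d: observation row (EVID=0) must not carry AMT/DRUG", r))
      if (!raw$DVID[r] %in% c("BICAR", "MV", "PACO2"))
        errs <- c(errs, sprintf("row %d: DVID must be BICAR, MV or PACO2", r))
      if (is.na(num(raw$DV[r])) || num(raw$DV[r]) <= 0)
        errs <- c(errs, sprintf("row %d: DV must be a number > 0", r))
    }
  }
  ids <- raw$ID
  for (id in unique(ids)) {
    sel <- which(ids == id)
    for (cc in c("SAPS2", "CHLORIDE", "CORT", "SEX", "VENT"))
      if (length(unique(raw[[cc]][sel])) != 1L)
        errs <- c(errs, sprintf("subject %s: covariate %s is not constant", id, cc))
  }
  if (length(errs))
    stop("read_dataset: invalid dataset:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  subjects <- lapply(unique(ids), function(id) {
    sel <- raw[ids == id, , drop = FALSE]
    tms <- num(sel$TIME) * tfac
    cov <- covariate_set(saps2 = num(sel$SAPS2[1]),
                         chloride = num(sel$CHLORIDE[1]),
                         corticosteroid = num(sel$CORT[1]) == 1,
                         female = num(sel$SEX[1]) == 1,
                         volume_assist = num(sel$VENT[1]) == 1)
    dsel <- sel$EVID == "1" | num(sel$EVID) == 1
    ace <- sel[dsel & sel$DRUG == "ACZ", , drop = FALSE]
    fur <- sel[dsel & sel$DRUG == "FUR", , drop = FALSE]
    oo <- sel[!dsel, , drop = FALSE]
    subject_record(
      id = utils::type.convert(id, as.is = TRUE),
      covariates = cov,
      ace_doses = dose_events(tms[dsel & sel$DRUG == "ACZ"], num(ace$AMT), "acz"),
      fur_doses = dose_events(tms[dsel & sel$DRUG == "FUR"], num(fur$AMT), "fur"),
      observations = data.frame(time = tms[!dsel], dvid = oo$DVID,
                                value = num(oo$DV), stringsAsFactors = FALSE))
  })
  structure(list(subjects = subjects, design = NULL, seed = NA),
            class = "acz_dataset")
}

.acz_fixed_keys <- c("bicar0_pop", "kout", "a50", "emax", "fur50",
                     "mv0_pop", "paco2_0_pop", "half_life", "fur_half_life",
                     "beta_saps", "beta_chloride", "cortico_mult", "va_mult",
                     "female_mult", "pow_bicar_mv", "bicar_ref",
                     "pow_mv_paco2")
.acz_ranef_keys <- c("omega_bicar0", "omega_kout", "omega_mv0",
                     "omega_paco2_0", "omega_pow_mv_paco2")
.acz_resid_keys <- c("sigma_bicar", "sigma_mv", "sigma_paco2")

#' Write model parameters to JSON
#'
#' Serializes a [model_parameters()] bundle to a JSON file with blocks
#' `fixed_effects`, `random_effects`, `residual` and `fixed_mask`; the
#' round trip through [read_parameters()] is lossless.
#'
#' @param params [model_parameters()].
#' @param path output path.
#' @param fixed_mask character vector of parameters held fixed during
#'   estimation (default: the non-identifiable / literature-fixed set).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path,
                             fixed_mask = c("emax", "half_life",
                                            "bicar_ref", "fur50",
                                            "fur_half_life")) {
  stopifnot(inherits(params, "acz_params"))
  obj <- list(
    fixed_effects = unclass(params$fixed),
    random_effects = stats::setNames(unclass(params$random),
                                     .acz_ranef_keys),
    residual = stats::setNames(unclass(params$residual), .acz_resid_keys),
    fixed_mask = as.list(fixed_mask))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path JSON file written by [write_parameters()].
#' @return A [model_parameters()] object; the fixed mask is attached as
#'   attribute `"fixed_mask"`. Unknown keys in any block are rejected.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path))
    stop("read_parameters: file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (blk in c("fixed_effects", "random_effects", "residual")) {
    if (is.null(obj[[blk]]))
      stop("read_parameters: missing block '", blk, "'", call. = FALSE)
    known <- switch(blk, fixed_effects = .acz_fixed_keys,
                    random_effects = .acz_ranef_keys,
                    residual = .acz_resid_keys)
    unknown <- setdiff(names(obj[[blk]]), known)
    if (length(unknown))
      stop("read_parameters: unknown key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  fx <- do.call(fixed_effects, as.list(obj$fixed_effects))
  re <- do.call(random_effects, as.list(obj$random_effects))
  rs <- do.call(residual_error, as.list(obj$residual))
  out <- model_parameters(fx, re, rs)
  attr(out, "fixed_mask") <- unlist(obj$fixed_mask)
  out
}
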