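#' Write a synthetic cohort to the CSV/JSON dialect
#'
#' Emits four files under `dir`: `intensity.csv` (long format: subject_id,
#' state, time_s, channel, wavelength_nm, intensity), `glucose.csv`
#' (subject_id, state, time_s, glucose_mmol_per_l), `metadata.json`
#' (sampling rate, geometry, seed, config echo) and `ground_truth.csv`
#' (true glucose curve and coupling coefficients per channel).
#'
#' @param cohort an `fnirs_cohort`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  wl <- as.numeric(rownames(cohort$optics$eps))
  intens <- data.table::rbindlist(lapply(cohort$subjects, function(sub) {
    data.table::rbindlist(lapply(c("fasting", "glucose"), function(st) {
      rec <- sub$recordings[[st]]
      n <- dim(rec$intensity)[1]
      t0 <- if (st == "fasting") 0 else cfg$fasting_duration
      data.table::rbindlist(lapply(seq_len(dim(rec$intensity)[2]), function(ch) {
        data.table::data.table(
          subject_id = sub$subject_id, state = st,
          time_s = rep(t0 + (seq_len(n) - 1) / cfg$sampling_rate, 2),
          channel = ch,
          wavelength_nm = rep(wl, each = n),
          intensity = c(rec$intensity[, ch, 1], rec$intensity[, ch, 2]))
      }))
    }))
  }))
  glucose <- data.table::rbindlist(lapply(cohort$subjects, function(sub) {
    data.table::data.table(subject_id = sub$subject_id,
                           state = sub$glucose_refs$state,
                           time_s = sub$glucose_refs$time_s,
                           glucose_mmol_per_l = sub$glucose_refs$glucose_mmol_per_l)
  }))
  truth <- data.table::rbindlist(lapply(cohort$subjects, function(sub) {
    data.table::data.table(subject_id = sub$subject_id,
                           channel = seq_along(sub$truth$betas),
                           coupling_beta = sub$truth$betas)
  }))
  paths <- file.path(dir, c("intensity.csv", "glucose.csv",
                            "metadata.json", "ground_truth.csv"))
  fmt <- function(dt) {
    num <- vapply(dt, is.double, TRUE)
    for (j in names(dt)[num]) data.table::set(dt, j = j,
                                              value = signif(dt[[j]], 15))
    dt
  }
  data.table::fwrite(fmt(intens), paths[1])
  data.table::fwrite(fmt(glucose), paths[2])
  jsonlite::write_json(
    list(sampling_rate_hz = cfg$sampling_rate,
         geometry = default_geometry(cfg$n_channels),
         seed = cfg$rng_seed,
         config = unclass(cfg)),
    paths[3], digits = NA, auto_unbox = TRUE)
  data.table::fwrite(fmt(truth), paths[4])
  invisible(paths)
}

#' Read a cohort from the CSV/JSON dialect
#'
#' Inverse of [write_cohort()] (ground truth is restored only to the extent
#' serialized: coupling coefficients). Malformed input produces an error
#' naming the missing column.
#'
#' @param dir directory holding `intensity.csv`, `glucose.csv`,
#'   `metadata.json`.
#' @return an `fnirs_cohort`.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("intensity.csv", "glucose.csv", "metadata.json"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing cohort file(s): ",
                         paste(basename(miss), collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  cfgl <- meta$config
  cfgl$coupled_channels <- as.integer(cfgl$coupled_channels)
  cfg <- do.call(fnirs_config, cfgl)
  intens <- data.table::fread(need[1], data.table = FALSE)
  req <- c("subject_id", "state", "time_s", "channel", "wavelength_nm",
           "intensity")
  miss <- setdiff(req, names(intens))
  if (length(miss)) stop("intensity.csv: missing column '", miss[1], "'",
                         call. = FALSE)
  if (nrow(intens) == 0) stop("empty cohort", call. = FALSE)
  glucose <- data.table::fread(need[2], data.table = FALSE)
  geom <- default_geometry(cfg$n_channels)
  wls <- sort(unique(intens$wavelength_nm))
  subjects <- lapply(sort(unique(intens$subject_id)), function(sid) {
    recs <- lapply(c("fasting", "glucose"), function(st) {
      sub <- intens[intens$subject_id == sid & intens$state == st, ]
      times <- sort(unique(sub$time_s))
      arr <- array(0, dim = c(length(times), cfg$n_channels, 2),
                   dimnames = list(NULL, NULL, as.character(wls)))
      for (w in seq_along(wls)) {
        sw <- sub[sub$wavelength_nm == wls[w], ]
        arr[, , w] <- matrix(sw$intensity[order(sw$channel, sw$time_s)],
                             nrow = length(times))
      }
      new_recording(sid, st, arr, cfg$sampling_rate, geom)
    })
    names(recs) <- c("fasting", "glucose")
    refs <- glucose[glucose$subject_id == sid,
                    c("state", "time_s", "glucose_mmol_per_l")]
    rownames(refs) <- NULL
    list(subject_id = sid, recordings = recs, glucose_refs = refs,
         truth = NULL)
  })
  structure(list(config = cfg, optics = default_optics(i0 = cfg$i0),
                 subjects = subjects),
            class = "fnirs_cohort")
}

#' Write processed hemoglobin series
#'
#' @param hemo_by_subject list of per-subject state pairs from
#'   [preprocess_subject()].
#' @param path CSV output path (subject_id, state, time_s, channel, dhbo_um,
#'   dhbr_um).
#' @return invisible path.
#' @export
write_hemo <- function(hemo_by_subject, path) {
  dt <- data.table::rbindlist(lapply(seq_along(hemo_by_subject), function(i) {
    sub <- hemo_by_subject[[i]]
    data.table::rbindlist(lapply(c("fasting", "glucose"), function(st) {
      h <- sub[[st]]
      n <- nrow(h$dhbo)
      t0 <- if (is.null(h$time_offset_s)) 0 else h$time_offset_s
      data.table::rbindlist(lapply(seq_len(ncol(h$dhbo)), function(ch) {
        data.table::data.table(subject_id = i, state = st,
                               time_s = t0 + (seq_len(n) - 1) / h$sampling_rate,
                               channel = ch,
                               dhbo_um = signif(h$dhbo[, ch], 15),
                               dhbr_um = signif(h$dhbr[, ch], 15))
      }))
    }))
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}
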