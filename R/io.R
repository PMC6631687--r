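# CSV readers and writers for the pipeline's external interfaces. All files
# are plain comma-separated text with a header row.

#' Read microsomal depletion time courses from CSV
#'
#' Expects columns `compound_id`, `replicate`, `time_min`, `remaining_pct`.
#'
#' @param path Path to the CSV file.
#' @return List of [depletion_timecourse()] objects (one per
#'   compound-replicate).
#' @export
read_depletion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "replicate", "time_min", "remaining_pct")
  if (!all(need %in% names(df)))
    stop_invalid_input(paste("depletion CSV must have columns:",
                             paste(need, collapse = ", ")))
  keys <- unique(df[c("compound_id", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compound_id == keys$compound_id[i] &
                df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$time_min), ]
    depletion_timecourse(keys$compound_id[i], sub$time_min, sub$remaining_pct)
  })
}

#' Write depletion time courses to CSV
#'
#' @param timecourses List of [depletion_timecourse()] objects; replicates of
#'   the same compound are numbered in order of appearance.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depletion_csv <- function(timecourses, path) {
  ids <- vapply(timecourses, function(tc) tc$compound_id, character(1))
  rep_no <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  rows <- lapply(seq_along(timecourses), function(i) {
    tc <- timecourses[[i]]
    data.frame(compound_id = tc$compound_id, replicate = rep_no[i],
               time_min = tc$times, remaining_pct = tc$remaining)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read ultrafiltration count pairs from CSV
#'
#' Expects columns `animal_id`, `compound_id`, `counts_plasma`,
#' `counts_filtrate`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with those columns.
#' @export
read_ultrafiltration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "compound_id", "counts_plasma", "counts_filtrate")
  if (!all(need %in% names(df)))
    stop_invalid_input(paste("ultrafiltration CSV must have columns:",
                             paste(need, collapse = ", ")))
  df
}

#' Read a multi-animal PK study from CSV files
#'
#' @param samples_path CSV with columns `animal_id`, `time_min`,
#'   `activity_bq`, `plasma_mass_g` (raw, decay-uncorrected total
#'   radioactivity).
#' @param metadata_path CSV with columns `animal_id`,
#'   `injected_activity_bq`, `injected_amount_nmol`, `body_weight_kg`.
#' @param parent_fraction_path CSV with columns `time_min`, `fraction` and
#'   optionally `animal_id` (without it, one shared series is applied to all
#'   animals).
#' @param isotope_half_life Radionuclide half-life, minutes.
#' @return List of [animal_study()] objects.
#' @export
read_pk_study_csv <- function(samples_path, metadata_path, parent_fraction_path,
                              isotope_half_life = 109.77) {
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  pf <- utils::read.csv(parent_fraction_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$animal_id[i]
    s <- samples[samples$animal_id == id, ]
    if (nrow(s) == 0)
      stop_invalid_input(sprintf("no samples found for animal '%s'", id))
    s <- s[order(s$time_min), ]
    pfa <- if ("animal_id" %in% names(pf)) pf[pf$animal_id == id, ] else pf
    pfa <- pfa[order(pfa$time_min), ]
    animal_study(id,
                 injected_activity = meta$injected_activity_bq[i],
                 injected_amount = meta$injected_amount_nmol[i],
                 body_weight = meta$body_weight_kg[i],
                 samples = data.frame(time_pi = s$time_min,
                                      activity_measured = s$activity_bq,
                                      plasma_mass = s$plasma_mass_g),
                 parent_fractions = data.frame(times = pfa$time_min,
                                               fractions = pfa$fraction),
                 isotope_half_life = isotope_half_life)
  })
}

#' Write a multi-animal PK study to the CSV dialect read by
#' [read_pk_study_csv()]
#'
#' @param studies List of [animal_study()] objects.
#' @param samples_path,metadata_path,parent_fraction_path Output paths.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_pk_study_csv <- function(studies, samples_path, metadata_path,
                               parent_fraction_path) {
  samples <- do.call(rbind, lapply(studies, function(st)
    data.frame(animal_id = st$animal_id, time_min = st$samples$time_pi,
               activity_bq = st$samples$activity_measured,
               plasma_mass_g = st$samples$plasma_mass)))
  meta <- do.call(rbind, lapply(studies, function(st)
    data.frame(animal_id = st$animal_id,
               injected_activity_bq = st$injected_activity,
               injected_amount_nmol = st$injected_amount,
               body_weight_kg = st$body_weight)))
  pf <- do.call(rbind, lapply(studies, function(st)
    data.frame(animal_id = st$animal_id,
               time_min = st$parent_fractions$times,
               fraction = st$parent_fractions$fractions)))
  utils::write.csv(samples, samples_path, row.names = FALSE)
  utils::write.csv(meta, metadata_path, row.names = FALSE)
  utils::write.csv(pf, parent_fraction_path, row.names = FALSE)
  invisible(c(samples = samples_path, metadata = metadata_path,
              parent_fractions = parent_fraction_path))
}

#' Read a key-value configuration file
#'
#' Parses lines of the form `key = value` or `key: value` (# starts a
#' comment). Values that parse as numbers are returned numeric. Intended for
#' overriding [assay_context()] and [scaling_factors()] defaults.
#'
#' @param path Path to the file.
#' @return Named list.
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3)
      stop_invalid_input(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
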