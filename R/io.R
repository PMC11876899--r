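#' Read a trial table from delimited text
#'
#' Expects the flat interchange format (CSV or TSV by extension or sniffed
#' separator): one row per trial with columns `subject_id, trial_index,
#' status, ms1, mo1, ms2, mo2, choice, rt` (plus optional `group`,
#' `censored`).  Status labels are case-folded; RTs must be positive
#' seconds — a median RT above 100 triggers a millisecond-unit rejection.
#' `delta_ms` / `delta_mo` are recomputed from the payoffs.
#'
#' @param path file path.
#' @return validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "status", "ms1", "mo1", "ms2",
            "mo2", "choice", "rt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  df$status <- as_status(df$status)
  for (col in c("ms1", "mo1", "ms2", "mo2", "choice", "rt"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad_rt <- which(!is.na(df$rt) & df$rt <= 0)
  if (length(bad_rt) > 0)
    stopf("non-positive RT at row(s): %s",
          paste(utils::head(bad_rt, 10), collapse = ", "))
  if (median(df$rt, na.rm = TRUE) > 100)
    stopf(paste("RT column looks like milliseconds (median > 100);",
                "convert to seconds before import"))
  bad_choice <- which(!is.na(df$choice) & !df$choice %in% c(0, 1))
  if (length(bad_choice) > 0)
    stopf("choice must be 0/1; offending row(s): %s",
          paste(utils::head(bad_choice, 10), collapse = ", "))
  dms <- df$ms1 - df$ms2
  if (any(dms <= 0))
    stopf("ms1 must exceed ms2 on every row (larger-Ms labelling)")
  df$delta_ms <- dms
  df$delta_mo <- df$mo1 - df$mo2
  if (!"censored" %in% names(df)) df$censored <- is.na(df$choice)
  df
}

#' Write a trial table as CSV
#'
#' @param data trial records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  cols <- intersect(c("subject_id", "group", "trial_index", "status",
                      "ms1", "mo1", "ms2", "mo2", "choice", "rt",
                      "censored"), names(data))
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate (or load) -> exclude -> fit the requested variants -> BMS ->
#' behavioural analyses, writing tidy outputs and a manifest to `out_dir`.
#' Rerunning with the same config reproduces the outputs.
#'
#' @param out_dir output directory (created).
#' @param spec a [cohort_spec()]; ignored when `data` is given.
#' @param data optional pre-loaded trial table.
#' @param variants variants to fit.
#' @param scale `"desk"` or `"full"` fitting profile.
#' @param seed master seed.
#' @param like_cfg,de_cfg optional overrides of the profile's fitting
#'   configuration (e.g. for quick smoke runs).
#' @param verbose progress messages.
#' @return list with `fits`, `bms`, `betas`, `proportions`, `manifest`.
#' @export
run_pipeline <- function(out_dir, spec = NULL, data = NULL, variants = 1:4,
                         scale = "desk", seed = 1, like_cfg = NULL,
                         de_cfg = NULL, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- fit_profile(scale, seed = derive_seed(seed, "fit"))
  if (!is.null(like_cfg)) prof$like <- like_cfg
  if (!is.null(de_cfg)) {
    de_cfg$seed <- derive_seed(seed, "fit")
    prof$de <- de_cfg
  }
  if (is.null(data)) {
    spec <- spec %||% cohort_spec(seed = derive_seed(seed, "cohort"))
    data <- generate_cohort(spec)
    write_trials(data, file.path(out_dir, "cohort.csv"))
  }
  excl <- exclude_trials(data)
  utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  fits <- fit_cohort(excl$kept, variants, prof$like, prof$de,
                     exclude = FALSE, verbose = verbose)
  ev <- evidence_matrix(fits)
  bms <- random_effects_bms(ev, seed = derive_seed(seed, "bms"))
  betas <- decision_betas(excl$kept)
  props <- choice_proportions(excl$kept)
  utils::write.csv(betas, file.path(out_dir, "decision_betas.csv"),
                   row.names = FALSE)
  utils::write.csv(props, file.path(out_dir, "choice_proportions.csv"),
                   row.names = FALSE)
  fit_tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, variant_id = f$variant_id,
               nll = f$nll, bic = f$evidence_bic,
               params = paste(sprintf("%s=%.6g", names(f$best_vector),
                                      f$best_vector), collapse = ";"))))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rstddm")),
    seed = seed, scale = scale,
    n_sims_per_trial = prof$like$n_sims_per_trial,
    de_iterations = prof$de$n_iterations,
    de_restarts = prof$de$n_restarts,
    variants = variants,
    n_subjects = length(unique(data$subject_id)),
    n_trials = nrow(data),
    exceedance_prob = as.list(bms$exceedance_prob))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(alpha = bms$alpha, expected_freq = bms$expected_freq,
         exceedance_prob = bms$exceedance_prob),
    file.path(out_dir, "bms.json"), auto_unbox = FALSE, pretty = TRUE,
    digits = NA)
  utils::write.csv(fit_tab, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  invisible(list(fits = fits, bms = bms, betas = betas,
                 proportions = props, manifest = manifest))
}
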