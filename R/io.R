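# Plain-text readers/writers: TSV tables, per-subject matrix CSVs with a
# region-label header, and JSON model/ground-truth serialization.

#' Write / read a connectivity matrix as labeled CSV
#'
#' The first row and first column carry the region labels.
#'
#' @param mat Square matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_csv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' Supports `combat_model` and `normative_model` objects; matrices are
#' stored with their dimnames and restored by [read_model_json()].
#'
#' @param model The model object.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  # restore numeric matrices lost to row-major lists
  fix_mat <- function(m, rn, cn) {
    m <- as.matrix(m)
    dimnames(m) <- list(rn, cn)
    m
  }
  if (identical(cls, "combat_model")) {
    obj$gamma_star <- fix_mat(obj$gamma_star, obj$batch_levels, obj$feature_names)
    obj$delta_star <- fix_mat(obj$delta_star, obj$batch_levels, obj$feature_names)
    obj$beta_hat <- fix_mat(obj$beta_hat, obj$covariate_names, obj$feature_names)
    obj$alpha_hat <- stats::setNames(as.numeric(obj$alpha_hat), obj$feature_names)
    obj$sigma_hat <- stats::setNames(as.numeric(obj$sigma_hat), obj$feature_names)
    obj$n_per_batch <- stats::setNames(as.integer(obj$n_per_batch), obj$batch_levels)
    obj$zero_variance <- stats::setNames(as.logical(obj$zero_variance), obj$feature_names)
  } else if (identical(cls, "normative_model")) {
    obj$coefficients <- fix_mat(obj$coefficients,
                                c("intercept", "age", "sexM"), obj$features)
    obj$residual_sd <- stats::setNames(as.numeric(obj$residual_sd), obj$features)
  }
  structure(obj, class = cls)
}

#' Write a simulated cohort to a directory
#'
#' Emits `subjects.tsv`, `volumes.tsv`, one labeled matrix CSV per
#' subject under `matrices/`, and `ground_truth.json`.
#'
#' @param cohort A `thal_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_tsv(cohort$volumes, file.path(dir, "volumes.tsv"))
  for (id in names(cohort$matrices))
    write_matrix_csv(cohort$matrices[[id]],
                     file.path(dir, "matrices", paste0(id, ".csv")))
  gt <- cohort$ground_truth
  gt$mean_matrix <- NULL  # regenerable via population_mean_matrix()
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `subjects`, `volumes`, `matrices`.
#' @export
read_cohort <- function(dir) {
  subjects <- read_tsv(file.path(dir, "subjects.tsv"))
  volumes <- read_tsv(file.path(dir, "volumes.tsv"))
  files <- list.files(file.path(dir, "matrices"), pattern = "\\.csv$",
                      full.names = TRUE)
  mats <- lapply(files, read_matrix_csv)
  names(mats) <- sub("\\.csv$", "", basename(files))
  mats <- mats[subjects$subject_id[subjects$subject_id %in% names(mats)]]
  structure(list(subjects = subjects, volumes = volumes, matrices = mats),
            class = "thal_cohort")
}
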