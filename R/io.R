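# CSV/JSON interchange: thin readers and writers for the toolkit's
# experimental input dialects and result objects.

#' Read a quenching dataset from CSV
#'
#' Expected columns: `fluorophore_tag`, `replicate_id`, `deltaF_over_G`.
#'
#' @param path CSV path (header row required).
#' @param labeled_site_tag,quencher_site_tag Site labels for the dataset.
#' @return A [quenching_dataset()].
#' @export
read_quenching_csv <- function(path, labeled_site_tag = "",
                               quencher_site_tag = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fluorophore_tag", "replicate_id", "deltaF_over_G")
  if (!all(need %in% names(df)))
    stop("read_quenching_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  reps <- split(df$deltaF_over_G, df$fluorophore_tag)
  reps <- reps[unique(df$fluorophore_tag)]
  quenching_dataset(reps, labeled_site_tag, quencher_site_tag)
}

#' Write a quenching dataset to CSV
#'
#' @param dataset A [quenching_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quenching_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "quenching_dataset"))
  df <- do.call(rbind, lapply(names(dataset$replicates), function(tag)
    data.frame(fluorophore_tag = tag,
               replicate_id = seq_along(dataset$replicates[[tag]]),
               deltaF_over_G = dataset$replicates[[tag]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sweep record from CSV
#'
#' Expected columns: `time_ms`, `voltage_mV`, `current_nA`,
#' `fluorescence_au`.
#'
#' @param path CSV path.
#' @param e_k Potassium equilibrium potential (mV), default -90.
#' @param temperature Temperature (K), default 294.
#' @return A [sweep_record()].
#' @export
read_sweep_csv <- function(path, e_k = -90, temperature = .T_DEFAULT) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "voltage_mV", "current_nA", "fluorescence_au")
  if (!all(need %in% names(df)))
    stop("read_sweep_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sweep_record(df$time_ms, df$fluorescence_au, df$current_nA, df$voltage_mV,
               e_k = e_k, temperature = temperature)
}

#' Read a Stern-Volmer titration table from CSV
#'
#' Expected columns: `conc_M`, `fluorescence`, `absorbance`.
#'
#' @param path CSV path.
#' @return The data.frame, validated.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("conc_M", "fluorescence", "absorbance")
  if (!all(need %in% names(df)))
    stop("read_titration_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a DEPET distance solution to JSON
#'
#' Serializes the estimates, configuration and (optionally) the full
#' bootstrap draws of a [run_depet()] result.
#'
#' @param solution A `depet_fit`.
#' @param path Output path.
#' @param include_draws Write the full bootstrap distributions, default
#'   TRUE.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path, include_draws = TRUE) {
  stopifnot(inherits(solution, "depet_fit"))
  obj <- list(mode = solution$mode, seed = solution$seed,
              n_bootstrap = solution$n_bootstrap,
              n_fits_total = solution$n_fits_total,
              retained_fraction = solution$retained_fraction,
              estimates = solution$estimates,
              fitted = as.list(solution$fitted),
              observed = as.list(solution$observed))
  if (include_draws) obj$draws <- solution$draws
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Write a conformer ensemble as an XYZ trajectory
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  lab <- ensemble$atom_labels
  con <- file(path, "w")
  on.exit(close(con))
  for (f in ensemble$frames) {
    writeLines(c(as.character(nrow(f)), ensemble$source_tag), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Write structure coordinates as a minimal PDB
#'
#' @param struct A [structure_coords()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "structure_coords"))
  a <- struct$atoms
  lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   seq_len(nrow(a)),
                   ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
                   a$residue_name, a$residue_id, a$x, a$y, a$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
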