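#' Write a 3D map or 4D run as NIfTI
#'
#' @param x A [bold_run()], a 3D/4D array, or a logical mask (written as
#'   0/1).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm Voxel size, mm (taken from the run when `x` is a
#'   `bold_run`).
#' @param tr_s Repetition time recorded in the header for 4D images.
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(3, 3, 3), tr_s = NULL) {
  if (inherits(x, "bold_run")) {
    voxel_size_mm <- x$voxel_size_mm
    tr_s <- x$tr_s
    x <- x$data
  }
  if (is.logical(x)) x <- array(as.numeric(x), dim = dim(x))
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  pix <- if (length(dim(x)) == 4L)
    c(voxel_size_mm, if (is.null(tr_s)) 1 else tr_s) else voxel_size_mm
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI image as an array or BOLD run
#'
#' @param path NIfTI file path.
#' @param as_run Return 4D images as a [bold_run()]?
#' @return Array, or `bold_run` for 4D images when `as_run = TRUE`.
#' @export
read_nifti <- function(path, as_run = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && as_run) {
    pd <- RNifti::pixdim(img)
    return(bold_run(arr, tr_s = if (length(pd) >= 4) pd[4] else 1,
                    voxel_size_mm = pd[1:3]))
  }
  arr
}

#' Write a synthetic cohort to disk
#'
#' Materializes each subject's runs as NIfTI, the event schedules as a
#' TSV, the per-subject ground truth as NIfTI maps with a JSON sidecar,
#' and a cohort manifest TSV (`subject_id`, `group`, paths).
#'
#' @param cohort A [make_group_cohort()] object.
#' @param dir Output directory (created if needed).
#' @param subjects Subject indices to write (default: all).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, subjects = seq_len(nrow(cohort$subjects))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  des <- cohort$design
  write_event_tsv(rep(list(des$schedules), des$n_runs),
                  file.path(dir, "events.tsv"))
  rows <- lapply(subjects, function(i) {
    s <- cohort$subjects[i, ]
    runs <- simulate_subject_runs(cohort, i)
    run_paths <- vapply(seq_along(runs), function(r) {
      p <- file.path(dir, sprintf("%s_run-%d_bold.nii.gz", s$subject, r))
      write_nifti(runs[[r]], p)
      p
    }, character(1))
    truth <- ground_truth_maps(cohort, i)
    gt_path <- file.path(dir, sprintf("%s_truth_tau.nii.gz", s$subject))
    write_nifti(truth$tau_map, gt_path, des$voxel_size_mm)
    jsonlite::write_json(
      list(subject = s$subject, group = as.character(s$group),
           a = s$a, b = s$b, tau = s$tau, seed = s$seed),
      file.path(dir, sprintf("%s_truth.json", s$subject)),
      auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = s$subject, group = as.character(s$group),
               runs = paste(run_paths, collapse = ";"),
               truth_tau = gt_path)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
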