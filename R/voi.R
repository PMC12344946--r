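# VOI-level parameter extraction and cohort table assembly.

#' Mean parameter value inside a VOI
#'
#' Arithmetic mean of a parametric map over the voxels where both the VOI
#' mask and the map's validity mask are true, pooling the whole 3-D VOI as a
#' single set of voxels.
#'
#' @param map A `parameter_map` (one element of [fit_parameter_maps()]).
#' @param mask Logical or 0/1 3-D array aligned to the map grid.
#' @param voxel_volume Volume of one voxel in mm^3 (default `2.2^3`, the
#'   2.2 mm isotropic grid of the default acquisition).
#' @return List with `mean`, `n_voxels` (valid voxels averaged) and
#'   `volume_mm3` (`n_voxels * voxel_volume`).
#' @export
extract_voi_mean <- function(map, mask, voxel_volume = 2.2^3) {
  stopifnot(inherits(map, "parameter_map"))
  mask <- array(as.logical(mask), dim(map$values))
  if (!any(mask)) stop("empty VOI mask")
  use <- mask & map$valid
  n <- sum(use)
  if (n == 0) stop("no valid voxels inside the VOI")
  list(mean = mean(map$values[use]), n_voxels = n,
       volume_mm3 = n * voxel_volume)
}

#' Assemble the per-subject cohort table
#'
#' One row per subject: molecular labels, morphology flags, VOI volume and
#' the VOI-mean of each of the nine diffusion parameters. Subjects missing a
#' parameter (e.g. a failed fit for one model) keep their row with `NA` in
#' that column and are flagged incomplete; downstream statistics drop them
#' per comparison, not globally.
#'
#' @param subjects A list; each element is a list with elements `id`,
#'   `idh_status` (`"wild-type"` or `"mutant"`), `codeletion_status`
#'   (`"codeleted"`, `"non-codeleted"` or `"not-applicable"`), optionally
#'   `flags` (named logical vector of morphology flags), `maps` (named list
#'   of `parameter_map`s) and `mask`.
#' @param voxel_volume Voxel volume in mm^3 passed to [extract_voi_mean()].
#' @return A tibble of class `cohort_table`.
#' @export
build_cohort_table <- function(subjects, voxel_volume = 2.2^3) {
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate subject id")
  pars <- parameter_registry()
  rows <- lapply(subjects, function(s) {
    idh <- match.arg(s$idh_status, c("wild-type", "mutant"))
    codel <- match.arg(s$codeletion_status,
                       c("codeleted", "non-codeleted", "not-applicable"))
    if (codel != "not-applicable" && idh != "mutant") {
      stop("codeletion status applies only to IDH-mutant subjects (", s$id, ")")
    }
    vals <- stats::setNames(rep(NA_real_, length(pars)), pars)
    vol <- NA_real_
    for (p in pars) {
      if (!is.null(s$maps[[p]])) {
        m <- tryCatch(extract_voi_mean(s$maps[[p]], s$mask, voxel_volume),
                      error = function(e) NULL)
        if (!is.null(m)) { vals[p] <- m$mean; vol <- m$volume_mm3 }
      }
    }
    flags <- s$flags %||% logical(0)
    c(list(subject_id = as.character(s$id), idh_status = idh,
           codeletion_status = codel, voi_volume_mm3 = vol,
           incomplete = anyNA(vals)),
      as.list(vals), as.list(flags))
  })
  tbl <- do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
  class(tbl) <- c("cohort_table", class(tbl))
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort table as CSV
#'
#' Round-trips through `write.csv`/`read.csv` preserving values to full
#' double precision (15 significant digits in the file).
#'
#' @param cohort A `cohort_table`.
#' @param path CSV file path.
#' @return `read_cohort_table` returns the tibble with class restored.
#' @export
write_cohort_table <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tbl <- tibble::as_tibble(df)
  for (nm in intersect(names(tbl), c("incomplete", "cystic_necrosis",
                                     "hemorrhage", "edema", "enhancement",
                                     "frontal_insula"))) {
    tbl[[nm]] <- as.logical(tbl[[nm]])
  }
  class(tbl) <- c("cohort_table", class(tbl))
  tbl
}
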