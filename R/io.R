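# Matrix-TSV dialect: first column `subject`, remaining columns named by voxel
# linear index, one row per subject. Labels TSV: columns `subject`, `class`.

#' Read / write activation matrices and labels as TSV
#'
#' @param X Voxels x subjects activation matrix.
#' @param path File path.
#' @param subjects Subject identifiers (default `s1..sn`).
#' @return `write_*` return the path invisibly; `read_activation_tsv` returns
#'   a list with `X` (voxels x subjects) and `subjects`;
#'   `read_labels_tsv` returns a named factor.
#' @export
write_activation_tsv <- function(X, path, subjects = NULL) {
  X <- as.matrix(X)
  subjects <- subjects %||% paste0("s", seq_len(ncol(X)))
  tbl <- as.data.frame(t(X))
  names(tbl) <- as.character(seq_len(nrow(X)))
  readr::write_tsv(dplyr::bind_cols(tibble(subject = subjects), tbl), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_activation_tsv
#' @export
read_activation_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  X <- t(as.matrix(tbl[, -1]))
  dimnames(X) <- NULL
  list(X = X, subjects = as.character(tbl[[1]]))
}

#' @rdname write_activation_tsv
#' @param labels Per-subject labels.
#' @export
write_labels_tsv <- function(labels, path, subjects = NULL) {
  subjects <- subjects %||% paste0("s", seq_along(labels))
  readr::write_tsv(tibble(subject = subjects, class = as.character(labels)),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_activation_tsv
#' @export
read_labels_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stats::setNames(factor(tbl$class), tbl$subject)
}

#' Build an activation matrix from 4D NIfTI images
#'
#' Averages each in-space voxel's time series over the 4th dimension for every
#' subject image and assembles the voxels x subjects matrix in the grid's
#' linear-index order. All images must share the mask's spatial shape and
#' affine.
#'
#' @param paths Character vector of per-subject 4D NIfTI files.
#' @param mask Path to (or array of) the 3D search-space mask.
#' @param connectivity Passed to [voxel_grid()].
#' @return List with `X` and the `grid`.
#' @export
load_subjects <- function(paths, mask, connectivity = 26L) {
  grid <- voxel_grid(mask, connectivity = connectivity)
  ref_aff <- if (!is.null(grid$ref)) RNifti::xform(grid$ref) else NULL
  X <- matrix(NA_real_, grid$p, length(paths))
  keep <- which(grid$in_space)
  for (s in seq_along(paths)) {
    img <- RNifti::readNifti(paths[s])
    d <- dim(img)
    if (length(d) != 4L || !all(d[1:3] == grid$shape))
      abort(sprintf("image %s does not match the mask's spatial shape", paths[s]))
    if (!is.null(ref_aff) &&
        max(abs(RNifti::xform(img) - ref_aff)) > 1e-4)
      abort(sprintf("image %s has a different affine than the mask", paths[s]))
    vol <- matrix(as.array(img), prod(d[1:3]), d[4])
    X[, s] <- rowMeans(vol[keep, , drop = FALSE])
  }
  list(X = X, grid = grid)
}

#' Write a per-voxel map as NIfTI
#'
#' Out-of-mask voxels are written as 0; the mask's affine is preserved when
#' the grid was built from a NIfTI file.
#'
#' @param map An `information_map` (or a numeric vector of per-voxel values).
#' @param grid The [voxel_grid()] the map lives on.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_information_map <- function(map, grid, path) {
  vals <- if (is.numeric(map)) map else map$score
  if (length(vals) != grid$p) abort("map length does not match the grid")
  vol <- array(0, grid$shape)
  vol[which(grid$in_space)] <- ifelse(is.finite(vals), vals, 0)
  img <- if (!is.null(grid$ref)) RNifti::asNifti(vol, reference = grid$ref)
         else RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export the synthetic dataset to files
#'
#' `format = "tsv"` writes the activation matrix, labels and ground-truth
#' voxel list; `format = "nifti"` additionally regenerates the per-subject
#' time courses (same seed, hence identical data) and writes one 4D image per
#' subject plus the mask and a 3D ground-truth volume.
#'
#' @param data An `ics_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"nifti"`.
#' @return Character vector of the files written.
#' @export
write_dataset <- function(data, dir, format = c("tsv", "nifti")) {
  stopifnot(inherits(data, "ics_dataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_path <- file.path(dir, "truth_voxels.tsv")
  readr::write_tsv(tibble(voxel = data$truth), truth_path, progress = FALSE)
  files <- c(
    write_activation_tsv(data$X, file.path(dir, "activation.tsv")),
    write_labels_tsv(data$labels, file.path(dir, "labels.tsv")),
    truth_path)
  if (format == "nifti") {
    grid <- data$grid
    spec <- data$spec
    grid6 <- voxel_grid(grid$in_space, connectivity = 6L)
    lam <- mixing_weight(spec$spatial_rho, grid6)
    M <- if (lam > 0) neighbor_mean_op(grid6) else NULL
    keep <- which(grid$in_space)
    n <- sum(spec$n_per_class)
    with_private_seed(spec$seed, {
      for (s in seq_len(n)) {
        Z <- subject_timecourse(spec, grid, M, lam, data$labels[s] == "case")
        vol <- array(0, c(grid$shape, spec$t_points))
        idx <- rep(keep, spec$t_points) +
          prod(grid$shape) * rep(seq_len(spec$t_points) - 1L, each = grid$p)
        vol[idx] <- as.vector(Z)
        f <- file.path(dir, sprintf("subject_%03d.nii.gz", s))
        RNifti::writeNifti(RNifti::asNifti(vol), f)
        files <- c(files, f)
      }
    })
    mask_f <- file.path(dir, "mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(grid$in_space),
                                             grid$shape)), mask_f)
    truth_vol <- array(0, grid$shape)
    truth_vol[which(grid$in_space)[data$truth]] <- 1
    truth_f <- file.path(dir, "truth.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(truth_vol), truth_f)
    files <- c(files, mask_f, truth_f)
  }
  invisible(files)
}

#' Write the full output set of a search run
#'
#' Writes the cluster table (TSV + JSON), the per-origin information map and
#' the overlap-resolved overlay map as NIfTI, a JSON echo of the run
#' configuration, and a short log file.
#'
#' @param result An `ics_result` (information scores optional).
#' @param outdir Output directory.
#' @return Character vector of files written.
#' @export
write_ics_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "ics_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- result$grid
  cl <- result$clusters
  tab <- dplyr::mutate(dplyr::select(cl, -"members"),
                       members = vapply(cl$members, paste, character(1),
                                        collapse = ","))
  tsv <- file.path(outdir, "clusters.tsv")
  readr::write_tsv(tab, tsv, progress = FALSE)
  json <- file.path(outdir, "clusters.json")
  jsonlite::write_json(
    lapply(seq_len(nrow(cl)), function(i) list(
      origin = cl$origin[i],
      coord = as.integer(grid$coords[cl$origin[i], ]),
      size = cl$size[i],
      relevance = cl$relevance[i],
      information = if ("information" %in% names(cl)) cl$information[i] else NULL,
      members = cl$members[[i]])),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(tsv, json)

  rel_map <- file.path(outdir, "relevance_map.nii.gz")
  per_origin <- cl$relevance
  write_information_map(per_origin, grid, rel_map)
  files <- c(files, rel_map)
  if ("information" %in% names(cl)) {
    inf_map <- file.path(outdir, "information_map.nii.gz")
    write_information_map(cl$information, grid, inf_map)
    ov_map <- file.path(outdir, "overlay_map.nii.gz")
    write_information_map(ics_overlay_map(result), grid, ov_map)
    files <- c(files, inf_map, ov_map)
  }
  cfg <- file.path(outdir, "config.json")
  jsonlite::write_json(result$config, cfg, auto_unbox = TRUE, digits = NA)
  log <- file.path(outdir, "run.log")
  writeLines(c(sprintf("[%s] icsearch run", format(Sys.time())),
               sprintf("voxels: %d, clusters: %d", grid$p, nrow(cl)),
               sprintf("median size: %d, max size: %d",
                       as.integer(median(cl$size)), max(cl$size)),
               sprintf("mi pairs computed: %d", nrow(result$mi_pairs))), log)
  invisible(c(files, cfg, log))
}
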