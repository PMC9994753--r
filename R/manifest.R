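# Dataset manifests: one row per sample with input/target/mask TIFF paths
# and a split tag.  The clean split (hand-curated, low-noise samples used
# for the high-penalty training phase) must be a subset of the complete
# split, mirroring the 179-of-944 curation structure of the training data.

MANIFEST_TAGS <- c("clean_train", "clean_val", "complete_train", "complete_val")

#' Construct and validate a dataset manifest
#'
#' @param entries data.frame with columns `input_path`, `target_path`,
#'   `mask_path`, `split_tag`.
#' @param check_files verify that all referenced files exist and that the
#'   three volumes of each entry share `(z, y, x)` dimensions (read from
#'   TIFF headers only).
#' @return a `dataset_manifest` (a data.frame subclass).
#' @export
dataset_manifest <- function(entries, check_files = TRUE) {
  req <- c("input_path", "target_path", "mask_path", "split_tag")
  if (!all(req %in% names(entries)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)[, req]
  bad <- setdiff(unique(entries$split_tag), MANIFEST_TAGS)
  if (length(bad) > 0)
    stop("unknown split tags: ", paste(bad, collapse = ", "))
  key <- function(df) paste(df$input_path, df$target_path, df$mask_path)
  is_clean <- startsWith(entries$split_tag, "clean")
  if (!all(key(entries[is_clean, , drop = FALSE]) %in%
           key(entries[!is_clean, , drop = FALSE])) && any(is_clean))
    stop("clean entries must be a subset of complete entries")
  if (check_files && nrow(entries) > 0) {
    for (i in seq_len(nrow(entries))) {
      paths <- unlist(entries[i, c("input_path", "target_path", "mask_path")])
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0)
        stop("manifest entry ", i, ": missing file(s) ",
             paste(missing, collapse = ", "))
      infos <- lapply(paths, tiff_info)
      dims <- vapply(infos, function(x)
        c(x$pages, x$height, x$width), numeric(3))
      if (any(dims[, 2] != dims[, 1]) || any(dims[, 3] != dims[, 1]))
        stop("manifest entry ", i, ": volumes differ in (z, y, x) dims")
    }
  }
  structure(entries, class = c("dataset_manifest", "data.frame"))
}

#' Read a dataset manifest from CSV
#'
#' Relative paths in the CSV are resolved against the CSV's directory.
#'
#' @param path CSV with columns `input_path`, `target_path`, `mask_path`,
#'   `split_tag`.
#' @param check_files see [dataset_manifest()].
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  for (col in c("input_path", "target_path", "mask_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  dataset_manifest(df, check_files = check_files)
}

#' Write a dataset manifest to CSV
#'
#' Paths under `dirname(path)` are stored relative to it so the dataset
#' directory stays relocatable.
#'
#' @param manifest a `dataset_manifest`.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  base <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
  for (col in c("input_path", "target_path", "mask_path")) {
    ap <- normalizePath(df[[col]], mustWork = FALSE)
    hit <- startsWith(ap, base)
    df[[col]][hit] <- substring(ap[hit], nchar(base) + 1L)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Subset a manifest by split
#'
#' @param manifest a `dataset_manifest`.
#' @param split one of `"clean"`, `"complete"` (both train+val rows of the
#'   dataset), or a full tag such as `"clean_val"`.
#' @export
manifest_split <- function(manifest, split) {
  tags <- if (split %in% c("clean", "complete"))
    paste0(split, c("_train", "_val")) else split
  if (!all(tags %in% MANIFEST_TAGS)) stop("unknown split: ", split)
  out <- manifest[manifest$split_tag %in% tags, , drop = FALSE]
  structure(out, class = c("dataset_manifest", "data.frame"))
}
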