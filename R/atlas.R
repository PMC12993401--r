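#' Build an atlas specification table
#'
#' An atlas specification lists the parcellation's regions of interest (ROIs)
#' and classifies each as cerebral or cerebellar. The default emulates a
#' whole-brain parcellation with 246 cerebral and 27 cerebellar regions
#' (273 ROIs in total).
#'
#' @param n_cerebral Number of cerebral ROIs.
#' @param n_cerebellar Number of cerebellar ROIs.
#' @param labels Optional character vector of unique ROI labels, cerebral
#'   regions first. Defaults to zero-padded `CER_*` / `CBL_*` labels.
#' @return A tibble with columns `roi_label` and `roi_class`
#'   (`"cerebral"` or `"cerebellar"`), one row per ROI.
#' @examples
#' atlas <- atlas_spec(246, 27)
#' nrow(atlas) # 273
#' @export
atlas_spec <- function(n_cerebral = 246, n_cerebellar = 27, labels = NULL) {
  n <- n_cerebral + n_cerebellar
  if (n < 1) abort("Atlas must contain at least one ROI.")
  if (is.null(labels)) {
    w <- max(3L, nchar(as.character(n)))
    labels <- c(
      sprintf(paste0("CER_%0", w, "d"), seq_len(n_cerebral)),
      sprintf(paste0("CBL_%0", w, "d"), seq_len(n_cerebellar))
    )
  }
  if (length(labels) != n) {
    abort("`labels` must have length n_cerebral + n_cerebellar.")
  }
  if (anyDuplicated(labels)) abort("ROI labels must be unique.")
  tibble::tibble(
    roi_label = as.character(labels),
    roi_class = rep(c("cerebral", "cerebellar"), c(n_cerebral, n_cerebellar))
  )
}

#' Write / read an atlas table as TSV
#'
#' @param atlas An atlas tibble from [atlas_spec()].
#' @param path File path for the TSV.
#' @return `write_atlas()` returns `path` invisibly; `read_atlas()` returns
#'   the validated atlas tibble with attributes `n_cerebral`, `n_cerebellar`
#'   and `n_rois`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(all(c("roi_label", "roi_class") %in% names(atlas)))
  readr::write_tsv(atlas, path)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, col_types = readr::cols(
    roi_label = readr::col_character(),
    roi_class = readr::col_character()
  ))
  if (anyDuplicated(atlas$roi_label)) abort("Atlas labels must be unique.")
  bad <- setdiff(unique(atlas$roi_class), c("cerebral", "cerebellar"))
  if (length(bad)) {
    abort(sprintf("Unknown roi_class value(s): %s", paste(bad, collapse = ", ")))
  }
  attr(atlas, "n_cerebral") <- sum(atlas$roi_class == "cerebral")
  attr(atlas, "n_cerebellar") <- sum(atlas$roi_class == "cerebellar")
  attr(atlas, "n_rois") <- nrow(atlas)
  atlas
}
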