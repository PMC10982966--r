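#' Tissue class scheme
#'
#' Defines the ordered set of tile classes, the subset regarded as tumor, and
#' the per-diagnosis set of permitted tile classes. The default scheme carries
#' the five classes used throughout the package: the three adult-type diffuse
#' glioma subtypes -- astrocytoma (`ac`), oligodendroglioma (`odg`),
#' glioblastoma (`gbm`) -- plus `normal` brain tissue and `necrosis`.
#'
#' A slide with tumor diagnosis `d` may only contain tiles of class `d`,
#' `normal`, or `necrosis`. A normal-control slide may only contain `normal`
#' tiles. The tumor rule reflects how pathologists annotate a single-entity
#' resection; the control rule is this package's convention: necrotic tissue
#' on a non-cancer control is not represented in the cohorts the pipeline
#' models, so it is excluded rather than silently allowed.
#'
#' @param labels Character vector of unique class identifiers, in a fixed
#'   order that is also used for deterministic tie-breaking.
#' @param tumor_labels Subset of `labels` regarded as tumor classes.
#' @param normal_label The label naming normal (non-neoplastic) tissue.
#' @param necrosis_label The label naming necrotic tissue.
#' @return An object of class `class_scheme`: a list with elements `labels`,
#'   `tumor_labels`, `normal_label`, `necrosis_label` and `diagnosis_allowed`
#'   (a named list mapping each diagnosis to its permitted tile classes).
#' @examples
#' sch <- class_scheme()
#' sch$diagnosis_allowed$gbm
#' @export
class_scheme <- function(labels = c("ac", "odg", "gbm", "normal", "necrosis"),
                         tumor_labels = c("ac", "odg", "gbm"),
                         normal_label = "normal",
                         necrosis_label = "necrosis") {
  stopifnot(is.character(labels), length(labels) >= 2)
  if (anyDuplicated(labels)) stop("class labels must be unique")
  if (!all(tumor_labels %in% labels)) stop("tumor_labels must be a subset of labels")
  if (!normal_label %in% labels) stop("normal_label must be one of labels")
  if (!necrosis_label %in% labels) stop("necrosis_label must be one of labels")
  if (normal_label %in% tumor_labels || necrosis_label %in% tumor_labels) {
    stop("normal and necrosis labels cannot be tumor labels")
  }
  allowed <- lapply(tumor_labels, function(d) c(d, normal_label, necrosis_label))
  names(allowed) <- tumor_labels
  allowed[[normal_label]] <- normal_label
  structure(
    list(
      labels = labels,
      tumor_labels = tumor_labels,
      normal_label = normal_label,
      necrosis_label = necrosis_label,
      diagnosis_allowed = allowed
    ),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme> ", length(x$labels), " classes: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("  tumor: ", paste(x$tumor_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Permitted tile classes for a slide diagnosis
#'
#' For a tumor diagnosis `d` the permitted classes are `d`, normal tissue and
#' necrosis; for the normal-control diagnosis only normal tissue is permitted.
#' This is the slide-level consistency rule used by the diagnosis-constrained
#' pseudo-label filter.
#'
#' @param diagnosis A diagnosis label present in the scheme.
#' @param scheme A [class_scheme()].
#' @return Character vector of permitted class labels.
#' @examples
#' allowed_classes("gbm", class_scheme())
#' @export
allowed_classes <- function(diagnosis, scheme = class_scheme()) {
  stopifnot(inherits(scheme, "class_scheme"), length(diagnosis) == 1)
  out <- scheme$diagnosis_allowed[[diagnosis]]
  if (is.null(out)) stop("unknown diagnosis: ", diagnosis)
  out
}

assert_labels <- function(labels, scheme, what = "label") {
  bad <- setdiff(unique(labels), scheme$labels)
  if (length(bad)) {
    stop("unknown ", what, "(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
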