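#' Base nutritional conditions and condition groupings
#'
#' The experimental design crosses two nutrients (molybdenum and iron) at two
#' levels (sufficiency/starvation), giving four base conditions. Samples are
#' pooled into four overlapping groupings, one per factor level: e.g. the
#' Fe-starvation grouping pools every sample grown without iron, whatever its
#' Mo status.
#'
#' @return `base_conditions()` returns the four base condition labels.
#'   `condition_groupings()` returns a named list mapping each grouping name
#'   (`Fe_sufficiency`, `Fe_starvation`, `Mo_sufficiency`, `Mo_starvation`)
#'   to the two base conditions it pools.
#' @examples
#' base_conditions()
#' condition_groupings()$Mo_starvation
#' @export
base_conditions <- function() {
  c("+Mo+Fe", "+Mo-Fe", "-Mo+Fe", "-Mo-Fe")
}

#' @rdname base_conditions
#' @export
condition_groupings <- function() {
  list(
    Fe_sufficiency = c("+Mo+Fe", "-Mo+Fe"),
    Fe_starvation  = c("+Mo-Fe", "-Mo-Fe"),
    Mo_sufficiency = c("+Mo+Fe", "+Mo-Fe"),
    Mo_starvation  = c("-Mo+Fe", "-Mo-Fe")
  )
}

#' Samples belonging to a condition grouping
#'
#' @param meta sample metadata: a data.frame with columns `sample` and
#'   `condition` (base condition labels).
#' @param grouping a grouping name (see [condition_groupings()]) or a
#'   character vector of base conditions.
#' @return character vector of sample ids.
#' @export
grouping_samples <- function(meta, grouping) {
  validate_metadata(meta)
  if (length(grouping) == 1L && grouping %in% names(condition_groupings())) {
    members <- condition_groupings()[[grouping]]
  } else {
    members <- grouping
  }
  unknown <- setdiff(members, base_conditions())
  if (length(unknown) > 0L) {
    stop("unknown base condition(s): ", paste(unknown, collapse = ", "))
  }
  meta$sample[meta$condition %in% members]
}

validate_metadata <- function(meta) {
  if (!is.data.frame(meta) || !all(c("sample", "condition") %in% names(meta))) {
    stop("sample metadata must be a data.frame with columns 'sample' and 'condition'")
  }
  bad <- setdiff(unique(meta$condition), base_conditions())
  if (length(bad) > 0L) {
    stop("metadata contains unknown condition(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
  invisible(meta)
}

validate_spc_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("counts must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix needs protein rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate protein ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(m < 0)) stop("spectral counts must be non-negative")
  invisible(m)
}
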