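#' @keywords internal
"_PACKAGE"

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Extract the bare counts matrix from a count_matrix or plain matrix input.
.counts_of <- function(x) {
  if (inherits(x, "count_matrix")) return(x$counts)
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("counts matrix must carry gene ids as rownames and sample ids as colnames")
  m
}

.lengths_of <- function(x) {
  if (inherits(x, "count_matrix")) return(x$lengths)
  NULL
}

## Validate a sample sheet against a counts matrix and return the sheet with
## rows ordered to match the matrix columns.
.align_sheet <- function(counts, sheet) {
  m <- .counts_of(counts)
  sheet <- as.data.frame(sheet)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    .stopf("sample sheet must have columns 'sample_id' and 'group'")
  if (anyDuplicated(sheet$sample_id))
    .stopf("duplicate sample_id in sample sheet: %s",
           paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    .stopf("samples missing from sample sheet: %s", paste(missing, collapse = ", "))
  sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
}

## Group index list in first-appearance order (or given level order).
.group_index <- function(sheet, levels = NULL) {
  g <- as.character(sheet$group)
  levels <- levels %||% unique(g)
  unknown <- setdiff(g, levels)
  if (length(unknown))
    .stopf("unknown group label(s): %s", paste(unique(unknown), collapse = ", "))
  idx <- lapply(levels, function(l) which(g == l))
  names(idx) <- levels
  empty <- levels[lengths(idx) == 0L]
  if (length(empty))
    .stopf("group '%s' has no samples", empty[[1L]])
  idx
}
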