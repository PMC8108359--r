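## Delimited-text readers/writers for the cluster-by-sample count matrix and
## the sample metadata table. TSV is the canonical interchange format.

#' Read a cluster-by-sample count matrix
#'
#' Expects delimited text with cluster ids in the first column and one column
#' per sample; cells must be nonnegative integers.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Integer matrix with cluster rownames and sample colnames.
#' @export
read_counts <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated cluster ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicated sample ids: ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at cluster '%s', sample '%s': %s",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]],
                 format(m[bad[1, , drop = FALSE]])))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a cluster-by-sample count matrix
#'
#' Inverse of [read_counts()]; round-trips exactly.
#'
#' @param counts Integer matrix with cluster rownames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_counts <- function(counts, path, sep = "\t") {
  df <- data.frame(cluster_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads delimited text with one row per sample and maps the configured
#' columns onto the canonical names `sample_id`, `time`, `event`; all other
#' columns are kept as covariates/grouping factors. The event indicator is
#' parsed from 0/1 or TRUE/FALSE. An optional log transform with positive
#' offset, time -> log(time + offset), can be applied to shift-and-compress a
#' survival scale that includes values near (or below) zero.
#'
#' @param path File path.
#' @param column_map Named list mapping canonical names (`sample_id`, `time`,
#'   `event`) to the file's column names.
#' @param time_transform `"log"` to apply log(time + offset), or `NULL`.
#' @param time_offset Offset added before the log (must make all times
#'   positive).
#' @param counts Optional count matrix; if given, metadata must cover all its
#'   sample columns and is reordered to match.
#' @param sep Field separator (default tab).
#' @return data.frame with columns `sample_id`, `time`, `event`, plus any
#'   extra columns from the file.
#' @export
read_metadata <- function(path,
                          column_map = list(sample_id = "sample_id",
                                            time = "time", event = "event"),
                          time_transform = NULL, time_offset = 0,
                          counts = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- unlist(column_map[c("sample_id", "time", "event")])
  if (!all(need %in% names(df)))
    stop("missing metadata columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  names(df)[match(need, names(df))] <- c("sample_id", "time", "event")
  ev <- df$event
  if (is.character(ev)) ev <- toupper(ev) %in% c("1", "TRUE", "T")
  df$event <- as.logical(ev)
  if (anyNA(df$event)) stop("event column must be 0/1 or TRUE/FALSE")
  df$time <- as.numeric(df$time)
  if (!is.null(time_transform)) {
    time_transform <- match.arg(time_transform, "log")
    if (any(df$time + time_offset <= 0))
      stop("time + offset must be positive for the log transform")
    df$time <- log(df$time + time_offset)
  }
  # positivity is enforced by the survival machinery where it matters; a
  # transformed covariate scale may legitimately include zero
  if (anyNA(df$time) || any(!is.finite(df$time)))
    stop("time column contains missing or non-finite values")
  if (!is.null(counts)) {
    missing_s <- setdiff(colnames(counts), df$sample_id)
    if (length(missing_s))
      stop("samples in counts but not metadata: ",
           paste(missing_s, collapse = ", "))
    df <- df[match(colnames(counts), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a sample metadata table
#'
#' @param metadata data.frame with one row per sample.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_metadata <- function(metadata, path, sep = "\t") {
  md <- metadata
  md$event <- as.integer(md$event)
  utils::write.table(md, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
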