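#' Validate a cross-sectional binary event dataset
#'
#' Checks a sample-by-event table: entries strictly 0/1, unique non-empty
#' column labels, and the per-sample active-event limits of the restricted
#' likelihood engine (hard error above 32 active events, warning above 25,
#' beyond which computation becomes impractically heavy).
#'
#' @param data matrix or data frame of 0/1 entries, rows = samples,
#'   columns = events; column names are the event labels.
#' @param events optional character vector the column labels must match.
#' @return an integer 0/1 matrix with column (and any row) names preserved.
#' @export
validate_dataset <- function(data, events = NULL) {
  if (is.data.frame(data))
    data <- as.matrix(data)
  if (!is.matrix(data))
    stop("`data` must be a matrix or data frame")
  rn <- rownames(data)
  cn <- colnames(data)
  ok <- !is.na(data) & (data == 0 | data == 1)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary entry at row %d, column %d%s",
                 bad[1L], bad[2L],
                 if (!is.null(cn)) sprintf(" ('%s')", cn[bad[2L]]) else ""))
  }
  storage.mode(data) <- "integer"
  if (is.null(cn))
    cn <- paste0("E", seq_len(ncol(data)))
  if (anyDuplicated(cn) || !all(nzchar(cn)))
    stop("event labels must be unique and non-empty")
  if (!is.null(events)) {
    if (!identical(as.character(cn), as.character(events)))
      stop("dataset events (", paste(cn, collapse = ", "),
           ") do not match the model's events (",
           paste(events, collapse = ", "), ")")
  }
  k <- rowSums(data)
  if (any(k > 32L))
    stop("sample ", which(k > 32L)[1L], " has ", max(k),
         " active events; the technical limit is 32 active events per observation")
  if (any(k > 25L))
    warning(sum(k > 25L), " sample(s) with more than 25 active events; ",
            "computations on these samples will be slow")
  dimnames(data) <- list(rn, cn)
  data
}

#' Read a cross-sectional dataset from CSV
#'
#' Reads a comma-separated binary event matrix: a required header row of
#' event labels, one row per tumor sample, entries 1 if the event is
#' present.  A leading sample-id column is auto-detected by non-0/1
#' content (override with \code{id_column}).
#'
#' @param path CSV file path.
#' @param id_column \code{"auto"} (default), \code{"yes"} to force the
#'   first column to be sample ids, or \code{"no"}.
#' @return an integer 0/1 matrix, row names set to the sample ids when an
#'   id column is present.
#' @export
read_dataset <- function(path, id_column = c("auto", "yes", "no")) {
  id_column <- match.arg(id_column)
  if (!file.exists(path))
    stop("dataset file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("ragged CSV: rows with differing field counts (",
         paste(sort(unique(nf)), collapse = ", "), ") in ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 1L || nrow(raw) < 1L)
    stop("dataset ", path, " has no data rows")
  has_ids <- switch(id_column,
                    yes = TRUE,
                    no = FALSE,
                    auto = !all(raw[[1L]] %in% c("0", "1")))
  ids <- NULL
  if (has_ids) {
    if (ncol(raw) < 2L)
      stop("dataset ", path, " has an id column but no event columns")
    ids <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  m <- as.matrix(raw)
  bad <- which(!(m %in% c("0", "1")))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-binary value '%s' at row %d, column '%s' of %s",
                 m[bad[1L]], rc[1L], colnames(m)[rc[2L]], path))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_dataset(m)
}

#' Write a dataset to CSV
#'
#' Writes the same dialect [read_dataset()] accepts (comma-separated,
#' UTF-8, header row); a \code{sample_id} column is emitted when the
#' matrix has row names, so a read/write round trip is cell-identical.
#'
#' @param data binary sample-by-event matrix.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  df <- as.data.frame(data, check.names = FALSE)
  if (!is.null(rownames(data))) {
    df <- cbind(sample_id = rownames(data), df)
    rownames(df) <- NULL
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# aggregate identical genotypes; deterministic order (sorted by bit string)
aggregate_dataset <- function(data) {
  key <- apply(data, 1L, paste, collapse = "")
  tab <- table(key)
  keys <- sort(names(tab))
  geno <- t(vapply(keys,
                   function(k) as.integer(strsplit(k, "")[[1L]]),
                   integer(ncol(data))))
  if (ncol(data) == 1L) geno <- matrix(geno, ncol = 1L)
  dimnames(geno) <- list(NULL, colnames(data))
  list(genotypes = geno,
       counts = as.integer(tab[keys]),
       keys = keys)
}
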