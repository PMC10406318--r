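#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored with the grid affine in the sform (code 2). Probability
#' maps are written as float64, masks as uint8, label volumes as int32.
#'
#' @param x the object to write.
#' @param file path to a `.nii` or `.nii.gz` file.
#' @name nifti_io
NULL

grid_from_nifti <- function(img) {
  d <- dim(img)
  stopifnot(length(d) >= 3L)
  aff <- unclass(RNifti::xform(img))[, , drop = FALSE]
  aff <- matrix(as.numeric(aff), 4, 4)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  volume_grid(d[1:3], voxel_size = vox, affine = aff)
}

nifti_of <- function(values, grid, datatype) {
  img <- RNifti::asNifti(values, datatype = datatype)
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

#' @rdname nifti_io
#' @export
write_probability_map <- function(x, file) {
  RNifti::writeNifti(nifti_of(x$values, x$grid, "double"), file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_probability_map <- function(file) {
  img <- RNifti::readNifti(file)
  probability_map(grid_from_nifti(img), array(as.numeric(img), dim = dim(img)[1:3]))
}

#' @rdname nifti_io
#' @export
write_region_mask <- function(x, file) {
  RNifti::writeNifti(nifti_of(array(as.integer(x$members), dim = x$grid$shape),
                              x$grid, "uint8"), file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_region_mask <- function(file, name = "mask") {
  img <- RNifti::readNifti(file)
  region_mask(grid_from_nifti(img),
              array(as.integer(img) != 0L, dim = dim(img)[1:3]), name = name)
}

#' @rdname nifti_io
#' @param table_file path to the TSV label table (columns label, name,
#'   hemisphere, group).
#' @export
write_parcellation <- function(x, file, table_file = NULL) {
  RNifti::writeNifti(nifti_of(x$labels, x$grid, "int32"), file)
  if (!is.null(table_file)) write_tsv(x$table, table_file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_parcellation <- function(file, table_file) {
  img <- RNifti::readNifti(file)
  tab <- read_tsv_checked(table_file, c("label", "name", "hemisphere", "group"))
  parcellation(grid_from_nifti(img),
               array(as.integer(img), dim = dim(img)[1:3]), table = tab)
}

#' @rdname nifti_io
#' @param networks_file path to a TSV with columns label, name for the
#'   network names.
#' @export
write_network_partition <- function(x, file, networks_file = NULL) {
  RNifti::writeNifti(nifti_of(x$labels, x$grid, "int32"), file)
  if (!is.null(networks_file))
    write_tsv(data.frame(label = seq_along(x$networks), name = x$networks),
              networks_file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_network_partition <- function(file, networks_file) {
  img <- RNifti::readNifti(file)
  nets <- read_tsv_checked(networks_file, c("label", "name"))
  nets <- nets[order(nets$label), ]
  network_partition(grid_from_nifti(img),
                    array(as.integer(img), dim = dim(img)[1:3]),
                    networks = nets$name)
}

#' @rdname nifti_io
#' @param tr repetition time in seconds.
#' @param subject_id subject identifier.
#' @export
write_bold4d <- function(x, file) {
  arr <- array(x$series, dim = c(x$grid$shape, ncol(x$series)))
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(x$grid$affine, code = 2L))
  img$pixdim[5] <- x$tr
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_bold4d <- function(file, subject_id = NULL, tr = NULL) {
  img <- RNifti::readNifti(file)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  grid <- grid_from_nifti(img)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  series <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])
  bold4d(grid, series, tr = tr, subject_id = subject_id)
}

# ---- plain-table I/O ------------------------------------------------------

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv_checked <- function(file, required_cols) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")))
  df
}

#' Read and write coordinate-database tables
#'
#' The foci table is a TSV with columns `study_id`, `x`, `y`, `z` (MNI mm);
#' the frequency table is a wide TSV with a `study_id` column followed by one
#' column per term, values in \[0, 1\]. Malformed rows are reported with
#' their line number.
#'
#' @param file path to the TSV file.
#' @name db_io
NULL

#' @rdname db_io
#' @export
read_foci_tsv <- function(file) {
  df <- read_tsv_checked(file, c("study_id", "x", "y", "z"))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at data line %d", file, col, bad[1]))
    if (anyNA(v))
      stop(sprintf("%s: missing %s at data line %d", file, col, which(is.na(v))[1]))
    df[[col]] <- v
  }
  df$study_id <- as.character(df$study_id)
  df
}

#' @rdname db_io
#' @export
write_foci_tsv <- function(foci, file) write_tsv(foci, file)

#' @rdname db_io
#' @export
read_term_freq_tsv <- function(file) {
  df <- read_tsv_checked(file, "study_id")
  ids <- as.character(df$study_id)
  m <- as.matrix(df[, setdiff(names(df), "study_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m > 1))
    stop(sprintf("%s: term frequencies must be numeric in [0, 1]", file))
  rownames(m) <- ids
  m
}

#' @rdname db_io
#' @param freq study x term matrix with study ids as rownames.
#' @export
write_term_freq_tsv <- function(freq, file) {
  df <- data.frame(study_id = rownames(freq), freq, check.names = FALSE)
  write_tsv(df, file)
}

#' Read/write a term-to-topic mapping
#'
#' TSV with columns `term`, `topic_id`, `topic_name` and optionally
#' `loading`. When several rows carry loadings for one term, the argmax
#' loading decides the hard assignment, subject to a minimum-loading floor.
#'
#' @param file path to the TSV file.
#' @param min_loading minimum loading for an assignment to count.
#' @return a `topic_mapping` (see [topic_mapping()]).
#' @export
read_topic_mapping <- function(file, min_loading = 0.001) {
  df <- read_tsv_checked(file, c("term", "topic_id", "topic_name"))
  if ("loading" %in% names(df)) {
    df <- df[df$loading >= min_loading, , drop = FALSE]
    df <- df[order(df$term, -df$loading), , drop = FALSE]
    df <- df[!duplicated(df$term), , drop = FALSE]
  }
  if (anyDuplicated(df$term))
    stop(sprintf("%s: term mapped to more than one topic", file))
  topic_mapping(stats::setNames(as.integer(df$topic_id), df$term),
                topic_names = stats::setNames(
                  as.character(df$topic_name)[!duplicated(df$topic_id)],
                  df$topic_id[!duplicated(df$topic_id)]))
}

#' @rdname read_topic_mapping
#' @param mapping a `topic_mapping`.
#' @export
write_topic_mapping <- function(mapping, file) {
  df <- data.frame(term = names(mapping$topic_of),
                   topic_id = unname(mapping$topic_of),
                   topic_name = unname(mapping$topic_names[
                     as.character(mapping$topic_of)]))
  write_tsv(df, file)
}

#' Read a construct-term allowlist (one term per line)
#'
#' @param file path to a plain-text file.
#' @return character vector of terms.
#' @export
read_allowlist <- function(file) {
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_allowlist
#' @param terms character vector of allowlisted terms.
#' @export
write_allowlist <- function(terms, file) {
  writeLines(terms, file)
  invisible(file)
}
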