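strip_mate_tag <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

validate_fastq_lines <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ %s: truncated record %d", path,
                 n %/% 4L + 1L), call. = FALSE)
  }
  invisible(n %/% 4L)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_fastq_lines(path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) {
                  stop(sprintf("malformed FASTQ %s: %s", path,
                               conditionMessage(e)), call. = FALSE)
                })
  tibble::tibble(read_id = strip_mate_tag(names(x)),
                 seq = unname(as.character(x)))
}

#' Read paired FASTQ files
#'
#' Reads two mate files (gzip transparent), strips `/1`, `/2` and
#' space-delimited mate tags from the ids, and pairs records by id.
#'
#' @param path1,path2 FASTQ paths for read 1 and read 2.
#' @return List with `read1` and `read2` tibbles (`read_id`, `seq`), in
#'   read-1 file order.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("mate files differ in record count (%d vs %d)",
                 nrow(r1), nrow(r2)), call. = FALSE)
  }
  idx <- match(r1$read_id, r2$read_id)
  if (any(is.na(idx))) {
    stop("read ids do not pair between mate files", call. = FALSE)
  }
  list(read1 = r1, read2 = r2[idx, , drop = FALSE])
}

#' Write paired FASTQ files
#'
#' Writes `/1` and `/2` suffixed records with constant quality. A `.gz`
#' extension triggers gzip compression.
#'
#' @param read1,read2 Tibbles with `read_id`, `seq`.
#' @param path1,path2 Output paths.
#' @param qual_char Quality character used for every base (default `"I"`).
#' @return Invisibly, the paths.
#' @export
write_fastq_pair <- function(read1, read2, path1, path2, qual_char = "I") {
  write_one <- function(tbl, path, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else
      file(path, "wb")
    on.exit(close(con))
    recs <- paste0("@", tbl$read_id, "/", mate, "\n", tbl$seq, "\n+\n",
                   strrep(qual_char, nchar(tbl$seq)))
    writeLines(recs, con)
  }
  write_one(read1, path1, 1L)
  write_one(read2, path2, 2L)
  invisible(c(path1, path2))
}

#' Read a reference FASTA
#'
#' Multi-line records are concatenated, sequences are upper-cased and `U`
#' converted to `T`; duplicate ids are an error.
#'
#' @param path FASTA path (gzip transparent).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, call. = FALSE)
  }
  seqs <- chartr("u", "t", as.character(x))
  seqs <- chartr("U", "T", toupper(seqs))
  check_alphabet(seqs, path)
  setNames(seqs, ids)
}

#' Write result tables deterministically
#'
#' Writes each tibble in a named list as a TSV (tab-separated, no quoting,
#' `.` for missing values) sorted by its leading columns, so identical
#' results produce byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    tbl <- tibble::as_tibble(tables[[nm]])
    tbl <- tbl[, !vapply(tbl, is.list, logical(1L)), drop = FALSE]
    key <- intersect(names(tbl), names(tbl)[1:min(3L, ncol(tbl))])
    if (nrow(tbl) > 1L && length(key) > 0L) {
      tbl <- tbl[do.call(order, unname(tbl[key])), , drop = FALSE]
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, path, na = ".")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a table written by [write_tables()]
#'
#' @param path TSV path.
#' @return A tibble (`.` read as missing).
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE, progress = FALSE)
}

#' Write a JSON run summary
#'
#' @param x Named list of scalars / small vectors.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_json_summary <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a counts TSV (genes x samples)
#'
#' First column is the gene id; remaining columns are integer counts.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  tbl <- read_table_tsv(path)
  m <- as.matrix(tbl[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl[[1L]]
  m
}

#' Read a gene list (one id per line)
#'
#' @param path Text file path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}
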