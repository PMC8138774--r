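# Shared I/O: tab-delimited tables/matrices and GMT gene-set libraries.
# Canonical dialect: UTF-8, tab separator, Unix newlines, "." decimal,
# header row always present. Files written here round-trip losslessly
# through the matching readers.

#' Read a delimited table
#'
#' Reads a tab-delimited text file with a header row. Every row must have
#' the same number of fields as the header; the first offending line is
#' reported by number.
#'
#' @param path File path.
#' @return A `data.frame` with `check.names = FALSE` column names.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop("empty file: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed table %s: line %d has %d fields, header has %d",
      path, bad[1L], nf[bad[1L]], nf[1L]
    ))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Write a delimited table
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read an expression matrix
#'
#' Reads a genes-by-samples matrix written by [write_matrix()]: a header
#' row of sample identifiers preceded by a gene-identifier column.
#'
#' @param path File path.
#' @return Numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @export
read_matrix <- function(path) {
  df <- read_table(path)
  if (ncol(df) < 2L) {
    stop("malformed matrix ", path,
         ": line 1 must name a gene-id column plus at least one sample")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("malformed matrix ", path, ": duplicated gene identifiers")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#'
#' @param mat Numeric matrix, genes in rows (row names required), samples
#'   in columns (column names required).
#' @param path Output file path.
#' @param id_col Name of the gene-identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "gene_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  write_table(df, path)
}

#' Read a GMT gene-set library
#'
#' GMT: one set per line, tab-separated fields `name<TAB>description<TAB>
#' gene1<TAB>gene2...`. Duplicate genes within a set are removed with a
#' warning; lines with fewer than three fields are rejected by number.
#'
#' @param path File path.
#' @return Named list of character vectors (gene sets); set descriptions
#'   are attached as the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT %s: line %d has %d fields (need >= 3)",
                   path, i, length(f)))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s' (line %d): %d duplicate genes removed",
                      f[1L], i, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    nms[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) stop("duplicated set names in GMT file: ", path)
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set library
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` when absent).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample-to-group assignment
#'
#' @param path File path to a headered two-column table (sample, group).
#' @return Named character vector mapping sample identifier to group label.
#' @export
read_groups <- function(path) {
  df <- read_table(path)
  if (ncol(df) != 2L) stop("group file ", path, " must have two columns")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a two-column sample-to-group assignment
#'
#' @param groups Named character vector (names are sample identifiers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(!is.null(names(groups)))
  write_table(data.frame(sample = names(groups),
                         group = as.character(groups),
                         stringsAsFactors = FALSE), path)
}

#' Read a mouse-to-human orthology map
#'
#' Reads a headered two-column file (`mouse_gene`, `human_gene`) and
#' restricts it to strict 1:1 pairs: any gene occurring in more than one
#' pair disqualifies all pairs it touches. The number of dropped pairs is
#' reported via a message.
#'
#' @param path File path.
#' @return An `orthology_map` (see [orthology_map()]).
#' @export
read_orthology <- function(path) {
  df <- read_table(path)
  if (ncol(df) != 2L) {
    stop("orthology map ", path, " must have two columns (mouse, human)")
  }
  orthology_map(as.character(df[[1L]]), as.character(df[[2L]]))
}
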