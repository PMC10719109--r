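#' Per-colony variant and total read-count matrices
#'
#' The central container of the package: for every candidate mutation (rows)
#' and every colony (columns) it stores the number of variant-supporting reads
#' `NV` and the total sequencing depth `NR`. All filtering, genotyping and
#' branch-assignment steps operate on this object.
#'
#' @param NV integer matrix of variant read counts (mutation x colony).
#' @param NR integer matrix of total read counts, same dimensions as `NV`.
#' @param mutations data frame with one row per mutation carrying at least
#'   `chrom`, `pos` (1-based), `ref`, `alt` and `class` (`"SNV"` or
#'   `"indel"`); SNVs may carry a pyrimidine-strand trinucleotide `context`
#'   and a logical `hemizygous` flag for male X/Y sites.
#' @param colonies character vector of colony identifiers (defaults to the
#'   column names of `NV`).
#'
#' @return An object of class `read_counts`.
#' @export
read_count_matrix <- function(NV, NR, mutations = NULL, colonies = NULL) {
  NV <- as.matrix(NV); NR <- as.matrix(NR)
  assert_that(all(dim(NV) == dim(NR)), "NV and NR must have identical dimensions")
  assert_that(all(NV >= 0) && all(NR >= 0), "read counts must be non-negative")
  assert_that(all(NV <= NR), "NV must not exceed NR anywhere")
  storage.mode(NV) <- "integer"; storage.mode(NR) <- "integer"
  colonies <- colonies %||% colnames(NV) %||% paste0("colony", seq_len(ncol(NV)))
  if (is.null(mutations)) {
    mutations <- data.frame(
      chrom = rep("1", nrow(NV)), pos = seq_len(nrow(NV)),
      ref = "C", alt = "T", class = "SNV", stringsAsFactors = FALSE
    )
  }
  assert_that(nrow(mutations) == nrow(NV), "one mutation record per NV row required")
  if (is.null(mutations$hemizygous)) mutations$hemizygous <- FALSE
  ids <- rownames(NV) %||% with(mutations, paste(chrom, pos, ref, alt, sep = "_"))
  dimnames(NV) <- dimnames(NR) <- list(ids, colonies)
  rownames(mutations) <- ids
  structure(
    list(NV = NV, NR = NR, mutations = mutations, colonies = colonies),
    class = "read_counts"
  )
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf(
    "<read_counts> %d candidate mutations x %d colonies (%d SNV, %d indel)\n",
    nrow(x$NV), ncol(x$NV), sum(x$mutations$class == "SNV"),
    sum(x$mutations$class == "indel")
  ))
  invisible(x)
}

#' @export
dim.read_counts <- function(x) dim(x$NV)

#' Subset a read-count matrix
#'
#' @param x a [read_count_matrix()] object.
#' @param i mutation (row) index. @param j colony (column) index.
#' @param ... ignored.
#' @return a `read_counts` object.
#' @export
`[.read_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$NV))
  if (missing(j)) j <- seq_len(ncol(x$NV))
  if (is.character(i)) i <- match(i, rownames(x$NV))
  if (is.character(j)) j <- match(j, x$colonies)
  assert_that(!anyNA(i) && !anyNA(j), "unknown mutation or colony id in subset")
  read_count_matrix(
    x$NV[i, j, drop = FALSE], x$NR[i, j, drop = FALSE],
    x$mutations[i, , drop = FALSE], x$colonies[j]
  )
}

#' Read or write read-count matrices as TSV
#'
#' `write_read_counts()` writes `<prefix>_NV.tsv`, `<prefix>_NR.tsv` and
#' `<prefix>_mutations.tsv`; `read_read_counts()` reads them back.
#'
#' @param x a `read_counts` object.
#' @param prefix file-path prefix.
#' @return `read_read_counts()` returns a `read_counts` object;
#'   `write_read_counts()` returns the file paths invisibly.
#' @export
write_read_counts <- function(x, prefix) {
  paths <- paste0(prefix, c("_NV.tsv", "_NR.tsv", "_mutations.tsv"))
  write.table(x$NV, paths[1], sep = "\t", quote = FALSE, col.names = NA)
  write.table(x$NR, paths[2], sep = "\t", quote = FALSE, col.names = NA)
  write.table(x$mutations, paths[3], sep = "\t", quote = FALSE, col.names = NA)
  invisible(paths)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(prefix) {
  nv <- as.matrix(read.delim(paste0(prefix, "_NV.tsv"), row.names = 1, check.names = FALSE))
  nr <- as.matrix(read.delim(paste0(prefix, "_NR.tsv"), row.names = 1, check.names = FALSE))
  mut <- read.delim(paste0(prefix, "_mutations.tsv"), row.names = 1, check.names = FALSE)
  read_count_matrix(nv, nr, mut, colnames(nv))
}
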