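#' Construct an OTU count table
#'
#' An `otu_table` is an n x m matrix of non-negative integer read counts with
#' samples as rows and OTUs as columns.  It is the common input to all
#' distance computations and to the simulation harnesses.
#'
#' @param counts numeric matrix, samples x OTUs, non-negative integer-valued.
#'   Row names are sample identifiers, column names are OTU identifiers; both
#'   must be present and unique.
#' @return An object of class `otu_table` (a matrix with validated axes).
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("otu_table must have at least one sample and one OTU")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("otu_table requires sample (row) and OTU (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integer-valued")
  storage.mode(counts) <- "double"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

n_samples <- function(x) nrow(x)
n_otus <- function(x) ncol(x)

#' Read an OTU count table
#'
#' Reads a tab-separated count table (samples as rows, first header row = OTU
#' ids, first column = sample ids) or a dense JSON BIOM table (observations
#' as rows, samples as columns, transposed on read).
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE, comment.char = "")
    if (nrow(df) == 0L) stop("empty table (0 samples) in ", path)
    mat <- as.matrix(df)
    if (!is.numeric(mat))
      stop("non-numeric count field in ", path)
    return(otu_table(mat))
  }
  biom <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(biom$data)) stop("BIOM file has no 'data' field: ", path)
  mtype <- if (is.null(biom$matrix_type)) "dense" else biom$matrix_type
  if (!identical(mtype, "dense"))
    stop("only dense JSON BIOM tables are supported (matrix_type = '",
         mtype, "')")
  data <- as.matrix(biom$data)
  otu_ids <- if (is.data.frame(biom$rows)) biom$rows$id else
    vapply(biom$rows, function(r) r$id, "")
  sample_ids <- if (is.data.frame(biom$columns)) biom$columns$id else
    vapply(biom$columns, function(r) r$id, "")
  if (nrow(data) != length(otu_ids) || ncol(data) != length(sample_ids))
    stop("BIOM data dimensions do not match row/column metadata in ", path)
  mat <- t(data)                      # BIOM rows are observations (OTUs)
  dimnames(mat) <- list(sample_ids, otu_ids)
  otu_table(mat)
}

#' Write an OTU count table as TSV
#'
#' Inverse of [read_otu_table()] with `format = "tsv"`.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table),
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample (row) is divided by its row total.  Samples with zero total
#' reads stay all-zero and are recorded in the `zero_samples` attribute; they
#' are excluded later from distance computation rather than producing NaN.
#'
#' @param table an [otu_table()] (any non-negative numeric matrix accepted).
#' @return A `proportion_table`: matrix of row-stochastic proportions with
#'   attribute `zero_samples` (character vector of flagged sample ids).
#' @export
to_proportions <- function(table) {
  mat <- unclass(as.matrix(table))
  totals <- rowSums(mat)
  zero <- rownames(mat)[totals == 0]
  totals[totals == 0] <- 1           # leave zero rows as all-zero
  props <- mat / totals
  structure(props, zero_samples = zero,
            class = c("proportion_table", "matrix", "array"))
}

#' Convert counts to presence-absence indicators
#'
#' Codes any positive value to 1 and zero to 0.
#'
#' @param table an [otu_table()], `proportion_table`, or numeric matrix.
#' @return A `presence_table`: 0/1 matrix with the same axes.
#' @export
to_presence <- function(table) {
  mat <- unclass(as.matrix(table))
  pres <- (mat > 0) + 0
  structure(pres, class = c("presence_table", "matrix", "array"))
}

#' Rarefy samples to equal sequencing depth
#'
#' Draws a uniform without-replacement subsample of reads (multivariate
#' hypergeometric) from each sample so every retained sample sums exactly to
#' `depth`.  Samples with fewer than `depth` reads are dropped with a
#' message, mirroring the usual read-depth filter applied before
#' presence-absence analyses.
#'
#' @param table an [otu_table()].
#' @param depth target read depth (positive integer).
#' @param seed integer seed; the subsample is reproducible given the seed.
#' @return An [otu_table()] whose rows all sum to `depth`; dropped sample ids
#'   are recorded in the `dropped_samples` attribute.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (length(depth) != 1L || is.na(depth) || depth <= 0 || depth != round(depth))
    stop("depth must be a positive integer")
  mat <- unclass(as.matrix(table))
  totals <- rowSums(mat)
  drop <- totals < depth
  if (any(drop))
    message(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(mat)[drop], collapse = ", "))
  keep <- mat[!drop, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no samples with total reads >= ", depth)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  m <- ncol(keep)
  out <- t(apply(keep, 1, function(row) {
    total <- sum(row)
    if (total == depth) return(row)
    reads <- sample.int(total, depth)            # which reads survive
    cum <- cumsum(row)
    tabulate(findInterval(reads, c(0, cum), left.open = TRUE), m)
  }))
  dimnames(out) <- dimnames(keep)
  res <- otu_table(out)
  attr(res, "dropped_samples") <- rownames(mat)[drop]
  res
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Drop OTUs supported by a single read
#'
#' Optional preprocessing filter: removes OTUs whose total count across all
#' samples is exactly one (likely sequencing artifacts).  Off by default in
#' all pipelines; exposed for users who want it.
#'
#' @param table an [otu_table()].
#' @return An [otu_table()] without singleton OTUs.
#' @export
drop_singleton_otus <- function(table) {
  mat <- unclass(as.matrix(table))
  keep <- colSums(mat) != 1
  otu_table(mat[, keep, drop = FALSE])
}
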